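# Species delineation: pairwise fragment-ANI distances, hierarchical
# clustering cut at 0.05 (95% ANI), and N50-based representatives.

#' Pairwise ANI distance matrix
#'
#' For every genome pair, fragment ANI is computed in both directions and
#' averaged; the distance is `1 - ANI/100`. Pairs with no qualifying
#' fragments in either direction (undefined ANI) are set to `cap`, which
#' exceeds any sensible species cut so such pairs can never merge; the
#' capped matrix is finite but not metric.
#'
#' @param genomes Named list of [genome_assembly()] (or
#'   `simulated_genome`) objects, >= 2.
#' @param cap Distance assigned to undefined-ANI pairs.
#' @param ... Passed to [fragment_ani()].
#' @return Symmetric numeric matrix with zero diagonal and attributes
#'   `cap` and `ani` (the averaged ANI matrix, `NA` where undefined).
#' @export
ani_distance_matrix <- function(genomes, cap = 0.3, ...) {
  if (length(genomes) < 2L) stop("need at least two genomes")
  genomes <- lapply(genomes, as_assembly)
  ids <- names(genomes)
  if (is.null(ids)) ids <- vapply(genomes, function(g) g$id, "")
  n <- length(genomes)
  ani <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(ani) <- 100
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- ani_between(genomes[[i]], genomes[[j]], ...)
      ani[i, j] <- ani[j, i] <- a
    }
  }
  d <- 1 - ani / 100
  d[is.na(d)] <- cap
  diag(d) <- 0
  attr(d, "cap") <- cap
  attr(d, "ani") <- ani
  d
}

#' Cut species clusters from an ANI distance matrix
#'
#' Agglomerative hierarchical clustering (default complete linkage) of
#' the ANI distance matrix, cut at height `cut` (0.05 corresponds to the
#' conventional 95%-ANI species boundary). Clusters are relabelled
#' deterministically by their lexicographically smallest member id.
#'
#' @param D Distance matrix from [ani_distance_matrix()].
#' @param cut Tree cut height, in (0, cap].
#' @param linkage `hclust` agglomeration method.
#' @return A `species_clusters`: list with `membership` (data frame
#'   `genome_id`, `cluster_id`), `clusters` (named list of member id
#'   vectors) and `cut`.
#' @export
cluster_species <- function(D, cut = 0.05, linkage = "complete") {
  cap <- attr(D, "cap")
  if (is.null(cap)) cap <- max(D)
  if (cut <= 0 || cut > cap) stop("cut must be in (0, cap]")
  ids <- rownames(D)
  if (nrow(D) == 1L) {
    membership <- data.frame(genome_id = ids, cluster_id = 1L,
                             stringsAsFactors = FALSE)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = linkage)
    raw <- stats::cutree(hc, h = cut)
    # renumber by smallest member id for order-invariance
    smallest <- tapply(ids, raw, min)
    new_id <- setNames(rank(smallest[as.character(sort(unique(raw)))]),
                       sort(unique(raw)))
    membership <- data.frame(genome_id = ids,
                             cluster_id = as.integer(new_id[as.character(raw)]),
                             stringsAsFactors = FALSE)
  }
  membership <- membership[order(membership$cluster_id, membership$genome_id), ]
  rownames(membership) <- NULL
  clusters <- split(membership$genome_id, membership$cluster_id)
  structure(list(membership = membership, clusters = clusters, cut = cut),
            class = "species_clusters")
}

#' @export
print.species_clusters <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("species_clusters: %d genomes in %d clusters at cut %.3f (sizes %s)\n",
              nrow(x$membership), length(x$clusters), x$cut,
              paste(sort(sizes, decreasing = TRUE), collapse = "/")))
  invisible(x)
}

#' Pick cluster representative genomes
#'
#' The member with the largest scaffold N50; ties broken by total length,
#' then by genome id.
#'
#' @param clusters A `species_clusters`.
#' @param stats Data frame with `genome_id`, `scaffold_n50`, `total_len`
#'   (e.g. assembled from [assembly_stats()] per genome).
#' @return Named character vector: cluster id -> representative genome id.
#' @export
representatives <- function(clusters, stats) {
  stopifnot(inherits(clusters, "species_clusters"))
  missing <- setdiff(clusters$membership$genome_id, stats$genome_id)
  if (length(missing)) stop("stats missing for genomes: ",
                            paste(head(missing, 3), collapse = ", "))
  vapply(clusters$clusters, function(members) {
    s <- stats[match(members, stats$genome_id), , drop = FALSE]
    s <- s[order(-s$scaffold_n50, -s$total_len, s$genome_id), , drop = FALSE]
    s$genome_id[1L]
  }, "")
}
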