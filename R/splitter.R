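# Splitting multi-genome isolate assemblies: density clustering of
# scaffolds in (GC%, depth) space, marker-based validation of the
# resulting components, and alignment rescue of noise or mis-split
# scaffolds against each component's closest reference genome.

#' Scaffold features for splitting
#'
#' GC percent over unambiguous bases and per-scaffold depth, with depth
#' log10-transformed (coverage is multiplicative) and both axes
#' z-standardized across scaffolds.
#'
#' @param assembly A [genome_assembly()].
#' @param depth Named per-scaffold depth; defaults to the assembly's own.
#' @return Data frame with `scaffold_id`, `gc`, `depth`, `gc_z`,
#'   `depth_z`.
#' @export
scaffold_features <- function(assembly, depth = assembly$depth) {
  if (is.null(depth)) stop("per-scaffold depth is required")
  sc <- names(assembly$sequences)
  missing <- setdiff(sc, names(depth))
  if (length(missing)) stop("depth missing for scaffolds: ",
                            paste(head(missing, 3), collapse = ", "))
  freq <- Biostrings::letterFrequency(assembly$sequences, c("G", "C", "A", "T"))
  valid <- rowSums(freq)
  if (any(valid == 0)) stop("scaffold with no unambiguous bases")
  gc <- 100 * rowSums(freq[, c("G", "C"), drop = FALSE]) / valid
  d <- as.numeric(depth[sc])
  zscore <- function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  data.frame(scaffold_id = sc, gc = gc, depth = d,
             gc_z = zscore(gc), depth_z = zscore(log10(d)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Density-based clustering of scaffold features
#'
#' DBSCAN in the standardized (GC, log-depth) plane: a core point has at
#' least `min_pts` neighbours (itself included) within `eps`; clusters
#' are the connected components of core points plus their border points;
#' unreachable points are labelled `-1` (noise). Deterministic: points
#' are processed in input order and clusters are numbered by first core
#' point encountered.
#'
#' @param features A [scaffold_features()] data frame, or any data frame
#'   with `gc_z` and `depth_z` columns.
#' @param eps Neighbourhood radius in standardized units.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer vector of labels (named by scaffold id when present):
#'   1..k for clusters, -1 for noise.
#' @export
density_cluster <- function(features, eps = 0.5, min_pts = 3L) {
  if (eps <= 0) stop("eps must be positive")
  x <- cbind(features$gc_z, features$depth_z)
  n <- nrow(x)
  if (n < min_pts) stop("fewer points than min_pts")
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 0L) >= min_pts
  labels <- rep(NA_integer_, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    next_label <- next_label + 1L
    queue <- i
    labels[i] <- next_label
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      for (m in nb[[j]]) {
        if (is.na(labels[m])) {
          labels[m] <- next_label
          if (core[m]) queue <- c(queue, m)
        }
      }
    }
  }
  labels[is.na(labels)] <- -1L
  if (!is.null(features$scaffold_id)) names(labels) <- features$scaffold_id
  labels
}

#' Detect a multi-genome assembly
#'
#' The splitting trigger: marker-based contamination strictly above
#' `threshold` percent (two full single-copy marker sets give 100%).
#'
#' @param marker_hits Marker hit table (see [marker_completeness()]).
#' @param expected_markers Expected single-copy marker ids.
#' @param threshold Contamination trigger in percent (strict `>`).
#' @return Logical.
#' @export
detect_multigenome <- function(marker_hits, expected_markers, threshold = 5) {
  marker_completeness(marker_hits, expected_markers)$contamination > threshold
}

#' Rescue a scaffold by alignment to candidate references
#'
#' Aligns the scaffold to each candidate reference with seed-and-extend,
#' greedily collecting non-overlapping local hits (the unaligned flanks
#' of each hit are searched recursively). A candidate qualifies when its
#' best hit is longer than `min_hit_len` nt and its qualifying hits cover
#' at least `min_coverage` of the scaffold; among qualifying candidates
#' the one with the greatest covered length wins, ties going to the
#' lexicographically smaller reference id.
#'
#' @param scaffold Character DNA sequence.
#' @param candidate_refs Named list of [genome_assembly()] references.
#' @param min_hit_len Minimum qualifying hit length (nt, strict `>`).
#' @param min_coverage Minimum scaffold coverage (fraction, `>=`).
#' @param k Seed word size.
#' @param scheme DNA [scoring_scheme()].
#' @return List with `reference_id` (`NA` if unassigned), `covered`,
#'   `coverage`, `best_hit_len`, and `hits` (per-candidate summary).
#' @export
rescue_assign <- function(scaffold, candidate_refs, min_hit_len = 90L,
                          min_coverage = 0.5, k = 15L,
                          scheme = scoring_scheme("dna")) {
  if (length(candidate_refs) == 0L) stop("no candidate references")
  candidate_refs <- lapply(candidate_refs, as_assembly)
  ids <- names(candidate_refs)
  if (is.null(ids)) ids <- vapply(candidate_refs, function(a) a$id, "")
  len <- nchar(scaffold)
  summaries <- lapply(seq_along(candidate_refs), function(i) {
    spans <- collect_hits(scaffold, candidate_refs[[i]], k, scheme,
                          min_hit_len)
    hit_lens <- if (nrow(spans)) spans$end - spans$start + 1L else integer(0)
    covered <- sum(hit_lens)
    data.frame(reference_id = ids[i],
               best_hit_len = if (length(hit_lens)) max(hit_lens) else 0L,
               covered = covered, coverage = covered / len,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, summaries)
  ok <- hits$best_hit_len > min_hit_len & hits$coverage >= min_coverage
  chosen <- NA_character_
  if (any(ok)) {
    q <- hits[ok, , drop = FALSE]
    q <- q[order(-q$covered, q$reference_id), , drop = FALSE]
    chosen <- q$reference_id[1L]
  }
  sel <- match(chosen, hits$reference_id)
  list(reference_id = chosen,
       covered = if (!is.na(sel)) hits$covered[sel] else 0L,
       coverage = if (!is.na(sel)) hits$coverage[sel] else 0,
       best_hit_len = if (!is.na(sel)) hits$best_hit_len[sel] else 0L,
       hits = hits)
}

# Greedy non-overlapping hit collection on the query: best local hit,
# then recurse into the flanks left and right of the hit.
collect_hits <- function(scaffold, ref, k, scheme, min_len, depth = 0L) {
  if (nchar(scaffold) < max(k, min_len) || depth > 6L)
    return(data.frame(start = integer(0), end = integer(0)))
  aln <- seed_and_extend(scaffold, paste(assembly_chars(ref),
                                         collapse = strrep("N", 100L)),
                         k = k, scheme = scheme)
  if (is.null(aln)) return(data.frame(start = integer(0), end = integer(0)))
  qs <- aln$query_span[["start"]]; qe <- aln$query_span[["end"]]
  out <- data.frame(start = qs, end = qe)
  if (qs > min_len) {
    left <- collect_hits(substring(scaffold, 1L, qs - 1L), ref, k, scheme,
                         min_len, depth + 1L)
    out <- rbind(out, left)
  }
  if (nchar(scaffold) - qe > min_len) {
    right <- collect_hits(substring(scaffold, qe + 1L, nchar(scaffold)), ref,
                          k, scheme, min_len, depth + 1L)
    if (nrow(right)) {
      right$start <- right$start + qe
      right$end <- right$end + qe
      out <- rbind(out, right)
    }
  }
  out
}

#' Split a multi-genome assembly
#'
#' The full splitting pipeline: density clustering of scaffolds in
#' standardized (GC, log-depth) space, per-component marker validation,
#' closest-reference search (ANI > `ani_floor`) for flagged components
#' (marker contamination > `contamination_flag`), and alignment rescue of
#' noise scaffolds and flagged components' scaffolds against the closest
#' references. If the assembly does not trigger [detect_multigenome()], a
#' single-component identity result is returned.
#'
#' @param assembly A [genome_assembly()] with depth.
#' @param marker_hits,expected_markers Marker validation inputs.
#' @param refdb Optional [reference_db()] for closest-reference search
#'   and rescue; without it flagged components are emitted unresolved.
#' @param eps,min_pts Density clustering parameters.
#' @param contamination_flag Component contamination flag threshold
#'   (percent, strict `>`).
#' @param ani_floor Minimum ANI for a closest reference (percent).
#' @param max_refs Closest-reference search budget.
#' @return A `split_result`: list with `labels` (final component per
#'   scaffold; `"unassigned"` possible), `components` (named list of
#'   [genome_assembly()]), `validation` (per-component completeness /
#'   contamination / flag / closest reference), `rescue_log`,
#'   `multi_genome` (the trigger verdict) and `unassigned`.
#' @export
split_assembly <- function(assembly, marker_hits, expected_markers,
                           refdb = NULL, eps = 0.5, min_pts = 3L,
                           contamination_flag = 15, ani_floor = 90,
                           max_refs = 500L) {
  sc_ids <- names(assembly$sequences)
  multi <- detect_multigenome(marker_hits, expected_markers)
  if (!multi) {
    return(structure(list(
      labels = setNames(rep("component_1", length(sc_ids)), sc_ids),
      components = setNames(list(assembly), "component_1"),
      validation = data.frame(
        component = "component_1",
        completeness = marker_completeness(marker_hits, expected_markers)$completeness,
        contamination = marker_completeness(marker_hits, expected_markers)$contamination,
        flagged = FALSE, closest_reference = NA_character_,
        unresolved = FALSE, stringsAsFactors = FALSE),
      rescue_log = empty_rescue_log(), multi_genome = FALSE,
      unassigned = character(0)), class = "split_result"))
  }

  feats <- scaffold_features(assembly)
  labels <- density_cluster(feats, eps = eps, min_pts = min_pts)
  comp_ids <- sort(unique(labels[labels > 0]))
  comp_name <- function(k) sprintf("component_%d", k)
  members <- lapply(comp_ids, function(k) sc_ids[labels == k])
  names(members) <- comp_name(comp_ids)

  validate <- function(scafs) {
    hits <- marker_hits[marker_hits$scaffold_id %in% scafs, , drop = FALSE]
    marker_completeness(hits, expected_markers)
  }
  val <- lapply(members, validate)
  flagged <- vapply(val, function(v) v$contamination > contamination_flag,
                    FALSE)
  noise <- sc_ids[labels == -1L]

  # closest references: always for flagged components; for all components
  # when noise scaffolds need a rescue target
  need_ref <- flagged | (length(noise) > 0 & !is.null(refdb))
  closest <- setNames(rep(NA_character_, length(members)), names(members))
  unresolved <- flagged & is.null(refdb)
  if (!is.null(refdb)) {
    for (nm in names(members)[need_ref]) {
      sub <- genome_assembly(assembly$sequences[members[[nm]]], id = nm)
      closest[nm] <- closest_reference(sub, refdb, ani_floor, max_refs)
      if (flagged[nm] && is.na(closest[nm])) unresolved[nm] <- TRUE
    }
  }

  # rescue: scaffolds of flagged components plus noise scaffolds
  rescue_pool <- c(unlist(members[flagged & !unresolved], use.names = FALSE),
                   noise)
  candidates <- closest[!is.na(closest)]
  rescue_log <- empty_rescue_log()
  final <- setNames(rep(NA_character_, length(sc_ids)), sc_ids)
  for (nm in names(members)[!flagged | unresolved])
    final[members[[nm]]] <- nm

  if (length(rescue_pool) && length(candidates)) {
    cand_refs <- lapply(candidates, function(rid) refdb$assemblies[[rid]])
    names(cand_refs) <- candidates
    chars <- assembly_chars(assembly)
    for (sc in rescue_pool) {
      res <- rescue_assign(chars[[sc]], cand_refs)
      target <- if (!is.na(res$reference_id))
        names(candidates)[match(res$reference_id, candidates)] else NA_character_
      final[sc] <- if (!is.na(target)) target else "unassigned"
      rescue_log <- rbind(rescue_log, data.frame(
        scaffold_id = sc, chosen_reference = res$reference_id,
        component = final[sc], hit_length = res$best_hit_len,
        coverage = res$coverage, stringsAsFactors = FALSE))
    }
  } else if (length(rescue_pool)) {
    final[rescue_pool] <- "unassigned"
  }
  final[is.na(final)] <- "unassigned"

  out_components <- lapply(setdiff(unique(final), "unassigned"), function(nm) {
    genome_assembly(assembly$sequences[final == nm],
                    depth = if (!is.null(assembly$depth))
                      assembly$depth[final == nm],
                    id = nm)
  })
  names(out_components) <- setdiff(unique(final), "unassigned")
  ord <- order(names(out_components))
  out_components <- out_components[ord]

  final_val <- lapply(names(out_components), function(nm)
    validate(names(out_components[[nm]]$sequences)))
  validation <- data.frame(
    component = names(out_components),
    completeness = vapply(final_val, `[[`, 0, "completeness"),
    contamination = vapply(final_val, `[[`, 0, "contamination"),
    flagged = flagged[names(out_components)] %in% TRUE,
    closest_reference = unname(closest[names(out_components)]),
    unresolved = unresolved[names(out_components)] %in% TRUE,
    stringsAsFactors = FALSE)

  structure(list(labels = final, components = out_components,
                 validation = validation, rescue_log = rescue_log,
                 multi_genome = TRUE,
                 unassigned = sc_ids[final == "unassigned"]),
            class = "split_result")
}

empty_rescue_log <- function() {
  data.frame(scaffold_id = character(0), chosen_reference = character(0),
             component = character(0), hit_length = integer(0),
             coverage = numeric(0), stringsAsFactors = FALSE)
}

# Assign-style closest-reference search restricted to ANI > ani_floor.
closest_reference <- function(assembly, refdb, ani_floor, max_refs) {
  if (total_length(assembly) < 2000) return(NA_character_)
  ranked <- rank_references(tetra_profile(assembly), refdb$profiles)
  for (rid in head(ranked$reference_id, max_refs)) {
    r <- fragment_ani(assembly, refdb$assemblies[[rid]])
    if (r$defined && r$ani > ani_floor) return(rid)
  }
  NA_character_
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %s, %d component(s), %d rescued, %d unassigned\n",
              if (x$multi_genome) "multi-genome" else "single genome",
              length(x$components), nrow(x$rescue_log), length(x$unassigned)))
  invisible(x)
}

#' Write a split result to disk
#'
#' One FASTA per component (plus `unassigned.fna` when needed), a
#' `split_report.tsv` with per-scaffold GC, depth, final label and rescue
#' reference, and a JSON validation summary.
#'
#' @param split A `split_result`.
#' @param assembly The original [genome_assembly()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_split_result <- function(split, assembly, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(split$components))
    write_assembly_fasta(split$components[[nm]],
                         file.path(dir, paste0(nm, ".fna")))
  if (length(split$unassigned))
    write_assembly_fasta(
      genome_assembly(assembly$sequences[split$unassigned], id = "unassigned"),
      file.path(dir, "unassigned.fna"))
  feats <- if (!is.null(assembly$depth)) scaffold_features(assembly) else NULL
  report <- data.frame(scaffold_id = names(split$labels),
                       label = unname(split$labels),
                       stringsAsFactors = FALSE)
  if (!is.null(feats))
    report <- merge(report, feats[, c("scaffold_id", "gc", "depth")],
                    by = "scaffold_id", sort = TRUE)
  rl <- split$rescue_log[, c("scaffold_id", "chosen_reference")]
  names(rl)[2L] <- "rescue_ref"
  report <- merge(report, rl, by = "scaffold_id", all.x = TRUE, sort = TRUE)
  write.table(report, file.path(dir, "split_report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(split$validation, file.path(dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
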