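# Pan-genome analytics: greedy gene-family clustering, the core /
# accessory / unique partition, accumulation curves, Heaps-law openness
# fitting, and boolean pathway-completeness calls.

#' Greedy incremental gene-family clustering
#'
#' Genes are sorted by decreasing length (ties by id) and each gene joins
#' the first existing family whose seed it matches at `>= identity` over
#' `>= coverage` of the shorter (default) or longer sequence, by local
#' alignment; otherwise it founds a new family. Seeds are therefore
#' always the longest member of their family, and the result is
#' deterministic given the input. The defaults (0.95 identity over 0.90
#' of the shorter sequence) are the gene-catalog preset; pan-genome runs
#' at broader identity and the protein-space preset (`coverage_on =
#' "longer"`) reuse the same engine.
#'
#' @param genes Data frame with `gene_id`, `genome_id`, `sequence`
#'   columns (amino-acid or nucleotide, not mixed).
#' @param identity Minimum alignment identity (fraction).
#' @param coverage Minimum aligned-region coverage (fraction).
#' @param coverage_on Which sequence the coverage rule measures.
#' @param mode Sequence alphabet: `"dna"` or `"protein"`.
#' @param k Seed word size for the candidate prescreen (exact shared
#'   k-mer); candidates failing the prescreen cannot reach the identity
#'   threshold at these lengths.
#' @param scheme Optional [scoring_scheme()] override.
#' @return List of `gene_family` objects: `family_id`, `seed_gene`,
#'   `members` (gene ids), `genomes` (presence set).
#' @export
cluster_gene_families <- function(genes, identity = 0.95, coverage = 0.90,
                                  coverage_on = c("shorter", "longer"),
                                  mode = c("dna", "protein"), k = NULL,
                                  scheme = NULL) {
  coverage_on <- match.arg(coverage_on)
  mode <- match.arg(mode)
  stopifnot(nrow(genes) > 0, all(c("gene_id", "genome_id", "sequence")
                                 %in% names(genes)))
  if (is.null(scheme)) scheme <- scoring_scheme(mode)
  if (is.null(k)) k <- if (mode == "dna") 12L else 5L
  ord <- order(-nchar(genes$sequence), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  seqs <- toupper(genes$sequence)

  kmer_set <- function(s) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  }
  fam_seed_seq <- character(0)
  fam_seed_id <- character(0)
  fam_kmers <- list()
  fam_members <- list()
  fam_genomes <- list()

  for (i in seq_len(nrow(genes))) {
    s <- seqs[i]
    km <- kmer_set(s)
    placed <- FALSE
    for (f in seq_along(fam_seed_seq)) {
      if (!any(km %in% fam_kmers[[f]])) next
      aln <- local_align(s, fam_seed_seq[f], scheme,
                         both_strands = mode == "dna")
      if (is.null(aln)) next
      shorter <- min(nchar(s), nchar(fam_seed_seq[f]))
      longer <- max(nchar(s), nchar(fam_seed_seq[f]))
      span_q <- aln$query_span[["end"]] - aln$query_span[["start"]] + 1L
      span_t <- aln$target_span[["end"]] - aln$target_span[["start"]] + 1L
      cov <- if (coverage_on == "shorter")
        max(span_q, span_t) / shorter else min(span_q, span_t) / longer
      if (aln$identity >= identity && cov >= coverage) {
        fam_members[[f]] <- c(fam_members[[f]], genes$gene_id[i])
        fam_genomes[[f]] <- union(fam_genomes[[f]], genes$genome_id[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      f <- length(fam_seed_seq) + 1L
      fam_seed_seq[f] <- s
      fam_seed_id[f] <- genes$gene_id[i]
      fam_kmers[[f]] <- km
      fam_members[[f]] <- genes$gene_id[i]
      fam_genomes[[f]] <- genes$genome_id[i]
    }
  }
  lapply(seq_along(fam_seed_seq), function(f) {
    structure(list(family_id = sprintf("GF%05d", f),
                   seed_gene = fam_seed_id[f],
                   members = fam_members[[f]],
                   genomes = sort(fam_genomes[[f]])),
              class = "gene_family")
  })
}

# Accept either gene_family lists or a truth table (family_id, genome_id
# pairs, e.g. a pan_collection's genes) as the family input.
family_presence <- function(families) {
  if (is.data.frame(families)) {
    stopifnot(all(c("family_id", "genome_id") %in% names(families)))
    return(lapply(split(families$genome_id, families$family_id), unique))
  }
  pres <- lapply(families, function(f) f$genomes)
  names(pres) <- vapply(families, function(f) f$family_id, "")
  pres
}

family_members <- function(families) {
  if (is.data.frame(families))
    return(lapply(split(families$gene_id, families$family_id), unique))
  mem <- lapply(families, function(f) f$members)
  names(mem) <- vapply(families, function(f) f$family_id, "")
  mem
}

#' Core / accessory / unique partition
#'
#' Families present in all genomes are core; in exactly one, unique; the
#' rest accessory. Accessory plus unique form the dispensable genome.
#'
#' @param families Output of [cluster_gene_families()], or a data frame
#'   with `family_id` and `genome_id` columns (e.g. a
#'   [simulate_pangenome_collection()] truth table).
#' @param genome_ids The full genome id set of the cluster.
#' @return A `pan_partition`: list with `core`, `accessory`, `unique`
#'   (family id vectors), `dispensable`, `presence` (named list),
#'   `n_genomes`.
#' @export
partition_pangenome <- function(families, genome_ids) {
  pres <- family_presence(families)
  if (any(lengths(pres) == 0L)) stop("empty family")
  extra <- setdiff(unique(unlist(pres)), genome_ids)
  if (length(extra)) stop("family presence outside the genome set: ",
                          paste(head(extra, 3), collapse = ", "))
  n <- length(genome_ids)
  sizes <- lengths(pres)
  ids <- names(pres)
  core <- ids[sizes == n]
  unique_f <- ids[sizes == 1L & n > 1L]
  accessory <- setdiff(ids, c(core, unique_f))
  structure(list(core = core, accessory = accessory, unique = unique_f,
                 dispensable = c(accessory, unique_f), presence = pres,
                 n_genomes = n),
            class = "pan_partition")
}

#' @export
print.pan_partition <- function(x, ...) {
  cat(sprintf("pan_partition over %d genomes: %d core, %d accessory, %d unique\n",
              x$n_genomes, length(x$core), length(x$accessory),
              length(x$unique)))
  invisible(x)
}

#' Pan- and core-genome accumulation curves
#'
#' For each random genome ordering, `pan(N)` counts families present in
#' the first N genomes and `core(N)` counts families present in all of
#' the first N; the reported curves are medians over permutations. The
#' endpoints are order-invariant: `pan(n)` is the total family count and
#' `core(n)` the core count.
#'
#' @param families As in [partition_pangenome()].
#' @param genome_ids Genome id set (>= 2).
#' @param n_permutations Number of random orderings (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `N`, `pan_median`, `core_median`.
#' @export
accumulation_curves <- function(families, genome_ids, n_permutations = 100L,
                                seed = 1L) {
  if (length(genome_ids) < 2L) stop("need >= 2 genomes")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  pres <- family_presence(families)
  n <- length(genome_ids)
  M <- vapply(genome_ids, function(g)
    vapply(pres, function(p) g %in% p, FALSE), logical(length(pres)))
  if (length(pres) == 1L) M <- matrix(M, nrow = 1L,
                                      dimnames = list(names(pres), genome_ids))
  with_seed(seed, {
    pan <- matrix(0L, n_permutations, n)
    core <- matrix(0L, n_permutations, n)
    for (p in seq_len(n_permutations)) {
      o <- sample.int(n)
      seen <- matrixStats_cumany(M[, o, drop = FALSE])
      allseen <- matrixStats_cumall(M[, o, drop = FALSE])
      pan[p, ] <- colSums(seen)
      core[p, ] <- colSums(allseen)
    }
    data.frame(N = seq_len(n),
               pan_median = apply(pan, 2L, median),
               core_median = apply(core, 2L, median))
  })
}

# row-wise cumulative any/all across columns (logical matrices)
matrixStats_cumany <- function(M) {
  t(apply(M, 1L, function(r) cummax(r) > 0))
}
matrixStats_cumall <- function(M) {
  t(apply(M, 1L, function(r) cummin(r) > 0))
}

#' Fit a Heaps-law power curve to a pan-genome accumulation curve
#'
#' Ordinary least squares on the log-log scale for
#' `pan(N) = kappa * N^gamma`. The pan-genome is called open when
#' `gamma >= gamma_open`; a flat curve (gamma ~ 0) is closed. A nonlinear
#' fit of the same model is available via `method = "nls"`.
#'
#' @param curve Data frame with `N` and `pan_median` (or `pan`) columns,
#'   >= 3 points, positive sizes.
#' @param gamma_open Openness threshold on the exponent.
#' @param method `"loglog"` (default) or `"nls"`.
#' @return A `power_law_fit`: list with `kappa`, `gamma`, `r_squared`,
#'   `classification`.
#' @export
fit_pan_curve <- function(curve, gamma_open = 0.05,
                          method = c("loglog", "nls")) {
  method <- match.arg(method)
  pan <- if ("pan_median" %in% names(curve)) curve$pan_median else curve$pan
  N <- curve$N
  if (length(N) < 3L) stop("need >= 3 curve points")
  if (any(pan <= 0)) stop("pan sizes must be positive")
  if (method == "loglog") {
    fit <- lm(log(pan) ~ log(N))
    kappa <- exp(coef(fit)[[1L]])
    gamma <- coef(fit)[[2L]]
    lp <- log(pan)
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((lp - mean(lp))^2)
  } else {
    start <- list(kappa = pan[1L], gamma = 0.2)
    fit <- minpack.lm::nlsLM(pan ~ kappa * N^gamma, start = start)
    kappa <- coef(fit)[["kappa"]]
    gamma <- coef(fit)[["gamma"]]
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((pan - mean(pan))^2)
  }
  structure(list(kappa = kappa, gamma = gamma, r_squared = r2,
                 classification = if (gamma >= gamma_open) "open" else "closed"),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("pan curve fit: pan(N) = %.1f * N^%.3f (r2 = %.3f) -> %s\n",
              x$kappa, x$gamma, x$r_squared, x$classification))
  invisible(x)
}

#' Exponential decay fit for the core-genome curve
#'
#' Secondary descriptive fit `core(N) = c + a * exp(-N / tau)`;
#' parameters are reported without an open/closed call.
#'
#' @param curve Data frame with `N` and `core_median` (or `core`).
#' @return List with `c`, `a`, `tau`, or `NULL` when the fit fails.
#' @export
fit_core_curve <- function(curve) {
  core <- if ("core_median" %in% names(curve)) curve$core_median else curve$core
  N <- curve$N
  out <- try(minpack.lm::nlsLM(core ~ cc + a * exp(-N / tau),
                        start = list(cc = min(core),
                                     a = max(core) - min(core) + 1,
                                     tau = max(N) / 3)),
             silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  p <- coef(out)
  list(c = p[["cc"]], a = p[["a"]], tau = p[["tau"]])
}

#' Boolean pathway-completeness call
#'
#' Evaluates a boolean expression over enzyme symbols (e.g.
#' `"Thl & Hbd & Cro & Bcd & (But | (Ptb & Buk))"` for the two
#' acetyl-CoA-to-butyrate routes) against the symbols present in the core
#' families; if unsatisfied there, against symbols present anywhere in
#' the pan-genome. Symbols with no annotated family evaluate to absent.
#'
#' @param partition A [partition_pangenome()] result.
#' @param annotations Data frame mapping `family_id` to enzyme `symbol`.
#' @param pathway Boolean expression string over symbols using `&`, `|`,
#'   `!` and parentheses.
#' @param known_symbols Optional symbol universe; referencing a symbol
#'   outside it is an error.
#' @return `"complete_in_core"`, `"complete_in_pan_only"` or
#'   `"incomplete"`.
#' @export
pathway_completeness <- function(partition, annotations, pathway,
                                 known_symbols = NULL) {
  stopifnot(inherits(partition, "pan_partition"),
            all(c("family_id", "symbol") %in% names(annotations)))
  tokens <- parse_pathway_symbols(pathway)
  if (!is.null(known_symbols)) {
    unknown <- setdiff(tokens, known_symbols)
    if (length(unknown)) stop("unknown symbol referenced: ",
                              paste(unknown, collapse = ", "))
  }
  core_syms <- unique(annotations$symbol[annotations$family_id %in%
                                           partition$core])
  pan_syms <- unique(annotations$symbol[annotations$family_id %in%
                                          names(partition$presence)])
  if (eval_pathway(pathway, tokens, core_syms)) return("complete_in_core")
  if (eval_pathway(pathway, tokens, pan_syms)) return("complete_in_pan_only")
  "incomplete"
}

parse_pathway_symbols <- function(pathway) {
  if (!grepl("^[A-Za-z0-9_&|!()[:space:]]+$", pathway))
    stop("malformed pathway expression")
  tokens <- regmatches(pathway, gregexpr("[A-Za-z_][A-Za-z0-9_]*", pathway))[[1L]]
  if (length(tokens) == 0L) stop("malformed pathway expression: no symbols")
  unique(tokens)
}

eval_pathway <- function(pathway, tokens, present) {
  env <- new.env(parent = baseenv())
  for (tok in tokens) assign(tok, tok %in% present, envir = env)
  isTRUE(eval(parse(text = pathway)[[1L]], envir = env))
}
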