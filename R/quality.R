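# Draft-genome quality gating: the six HMP high-quality draft criteria
# plus single-copy-marker completeness and contamination.

#' Assembly summary statistics
#'
#' Contigs are obtained by splitting scaffolds at runs of >= `gap_min`
#' ambiguous bases (scaffolds without gaps are their own contigs). N50 is
#' the length at which the cumulative descending-sorted lengths first
#' reach half the total. The depth criterion input
#' (`pct_bases_ge_5x`) weights scaffold lengths by their per-scaffold
#' mean depth, since depth arrives as a TSV summary rather than per-base
#' coverage.
#'
#' @param assembly A [genome_assembly()].
#' @param depth Named per-scaffold depth; defaults to the assembly's own.
#' @param gap_min Minimum N-run length treated as a scaffolding gap.
#' @param min_depth Depth threshold for the covered-bases percentage.
#' @return An `assembly_stats`: list with `contig_n50`, `scaffold_n50`,
#'   `pct_assembly_in_contigs_gt500`, `pct_bases_ge_5x`,
#'   `avg_contig_len`, `total_len`, `n_contigs`.
#' @export
assembly_stats <- function(assembly, depth = assembly$depth, gap_min = 10L,
                           min_depth = 5) {
  sc_len <- scaffold_lengths(assembly)
  contig_len <- unlist(lapply(assembly_chars(assembly), function(s) {
    parts <- strsplit(gsub(sprintf("N{%d,}", gap_min), "\n", s), "\n",
                      fixed = TRUE)[[1L]]
    nchar(parts[nzchar(parts)])
  }), use.names = FALSE)
  if (length(contig_len) == 0L) stop("assembly has no contigs")
  total <- sum(contig_len)
  pct5x <- if (is.null(depth)) NA_real_ else {
    missing <- setdiff(names(sc_len), names(depth))
    if (length(missing)) stop("depth missing for scaffolds: ",
                              paste(head(missing, 3), collapse = ", "))
    100 * sum(sc_len[depth[names(sc_len)] >= min_depth]) / sum(sc_len)
  }
  structure(list(contig_n50 = n50(contig_len),
                 scaffold_n50 = n50(sc_len),
                 pct_assembly_in_contigs_gt500 =
                   100 * sum(contig_len[contig_len > 500]) / total,
                 pct_bases_ge_5x = pct5x,
                 avg_contig_len = mean(contig_len),
                 total_len = total,
                 n_contigs = length(contig_len)),
            class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "assembly_stats: %d contigs, %.1f kb total, contig N50 %.1f kb, scaffold N50 %.1f kb\n",
    x$n_contigs, x$total_len / 1e3, x$contig_n50 / 1e3, x$scaffold_n50 / 1e3))
  invisible(x)
}

#' Marker-based completeness and contamination
#'
#' From a single-copy marker hit table, completeness is the percentage of
#' expected markers present at least once, and contamination is the sum
#' of extra copies beyond one per expected marker, as a percentage of the
#' expected set size. Markers outside the expected set are ignored;
#' duplicate copies never raise completeness, so completeness cannot
#' exceed 100.
#'
#' @param marker_hits Data frame with `marker_id`, `scaffold_id`,
#'   `copy_count` (one row per marker-scaffold occurrence).
#' @param expected_markers Character vector of expected marker ids.
#' @return List with `completeness` and `contamination` (percent).
#' @examples
#' hits <- data.frame(marker_id = c("m1", "m1", "m2"),
#'                    scaffold_id = c("s1", "s2", "s1"), copy_count = 1L)
#' marker_completeness(hits, c("m1", "m2", "m3", "m4"))
#' @export
marker_completeness <- function(marker_hits, expected_markers) {
  if (length(expected_markers) == 0L) stop("expected marker set is empty")
  expected_markers <- unique(expected_markers)
  hits <- marker_hits[marker_hits$marker_id %in% expected_markers, ,
                      drop = FALSE]
  copies <- tapply(hits$copy_count, hits$marker_id, sum)
  present <- sum(copies >= 1)
  extra <- sum(pmax(copies - 1, 0))
  list(completeness = 100 * present / length(expected_markers),
       contamination = 100 * extra / length(expected_markers))
}

#' HMP draft-quality gating
#'
#' Applies the six high-quality draft criteria with strict inequalities:
#' (i) > 90% of the assembly in contigs > 500 bp, (ii) > 90% of bases at
#' > 5x coverage, (iii) contig N50 > 5 kb, (iv) scaffold N50 > 20 kb,
#' (v) average contig length > 5 kb, (vi) > 90% of core genes present.
#' `pass_hmp` is the conjunction of the six; `pass_resource` additionally
#' requires completeness > 95% and contamination < 5%. rRNA completeness
#' (5S/16S/23S flags) is reported alongside but gates neither verdict.
#'
#' @param stats An [assembly_stats()].
#' @param core_gene_pct Percentage of expected core genes present.
#' @param completeness,contamination Marker-based percentages (see
#'   [marker_completeness()]).
#' @param rrna_flags Logical length-3 vector: 5S, 16S, 23S present.
#' @return A `quality_report`: list with the six criterion booleans,
#'   `core_gene_pct`, `completeness`, `contamination`, `rrna_complete`,
#'   `pass_hmp`, `pass_resource`.
#' @export
hmp_quality <- function(stats, core_gene_pct, completeness = NA_real_,
                        contamination = NA_real_,
                        rrna_flags = c(FALSE, FALSE, FALSE)) {
  stopifnot(inherits(stats, "assembly_stats"))
  crit <- c(contigs_gt500 = stats$pct_assembly_in_contigs_gt500 > 90,
            coverage_5x = !is.na(stats$pct_bases_ge_5x) &&
              stats$pct_bases_ge_5x > 90,
            contig_n50 = stats$contig_n50 > 5000,
            scaffold_n50 = stats$scaffold_n50 > 20000,
            avg_contig = stats$avg_contig_len > 5000,
            core_genes = core_gene_pct > 90)
  pass_hmp <- all(crit)
  pass_resource <- pass_hmp && !is.na(completeness) && !is.na(contamination) &&
    completeness > 95 && contamination < 5
  structure(list(criteria = crit, core_gene_pct = core_gene_pct,
                 completeness = completeness, contamination = contamination,
                 rrna_complete = all(rrna_flags),
                 pass_hmp = pass_hmp, pass_resource = pass_resource),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("quality_report:\n")
  for (nm in names(x$criteria))
    cat(sprintf("  %-14s %s\n", nm, if (x$criteria[[nm]]) "pass" else "FAIL"))
  cat(sprintf("  completeness %.1f%%, contamination %.1f%%, rRNA %s\n",
              x$completeness, x$contamination,
              if (x$rrna_complete) "complete" else "incomplete"))
  cat(sprintf("  pass_hmp: %s, pass_resource: %s\n", x$pass_hmp, x$pass_resource))
  invisible(x)
}
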