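#' Scoring schemes for local alignment
#'
#' Bundles the substitution scores, affine gap penalties and ungapped
#' Karlin-Altschul parameters used by [local_align()], [seed_and_extend()]
#' and everything built on them (fragment ANI, POCP, gene-family
#' clustering, scaffold rescue).
#'
#' Defaults follow classic aligner settings: DNA match +1 / mismatch -2
#' with gap open 5 / extend 2; protein BLOSUM62 with gap open 11 /
#' extend 1. A gap of length L costs `gap_open + L * gap_extend`.
#' Karlin-Altschul lambda and K default to published ungapped values for
#' each scheme and are only used for E-value estimation, where thresholds
#' (not exact external-tool E-values) are what matter.
#'
#' @param mode `"dna"` or `"protein"`.
#' @param match,mismatch DNA match reward and mismatch penalty (mismatch
#'   must be negative).
#' @param matrix Protein substitution matrix name; only `"BLOSUM62"`
#'   (from Biostrings) is shipped.
#' @param gap_open,gap_extend Non-negative gap penalties with
#'   `gap_open >= gap_extend`.
#' @param karlin_lambda,karlin_k Positive Karlin-Altschul parameters;
#'   defaults chosen per mode.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("dna")
#' scoring_scheme("protein", gap_open = 11, gap_extend = 1)
#' @export
scoring_scheme <- function(mode = c("dna", "protein"), match = 1,
                           mismatch = -2, matrix = "BLOSUM62",
                           gap_open = NULL, gap_extend = NULL,
                           karlin_lambda = NULL, karlin_k = NULL) {
  mode <- match.arg(mode)
  if (mode == "dna") {
    if (is.null(gap_open)) gap_open <- 5
    if (is.null(gap_extend)) gap_extend <- 2
    if (is.null(karlin_lambda)) karlin_lambda <- 1.28
    if (is.null(karlin_k)) karlin_k <- 0.46
    stopifnot(match > 0, mismatch < 0)
    alphabet <- c("A", "C", "G", "T")
    submat <- base::matrix(mismatch, 4, 4, dimnames = list(alphabet, alphabet))
    diag(submat) <- match
  } else {
    if (is.null(gap_open)) gap_open <- 11
    if (is.null(gap_extend)) gap_extend <- 1
    if (is.null(karlin_lambda)) karlin_lambda <- 0.3176
    if (is.null(karlin_k)) karlin_k <- 0.134
    if (matrix != "BLOSUM62")
      stop("only the BLOSUM62 protein matrix is available")
    submat <- blosum62_matrix()
    alphabet <- rownames(submat)
  }
  if (gap_open < gap_extend) stop("gap_open must be >= gap_extend")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (karlin_lambda <= 0 || karlin_k <= 0)
    stop("Karlin parameters must be positive")
  structure(list(mode = mode, submat = submat, alphabet = alphabet,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k),
            class = "scoring_scheme")
}

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  storage.mode(m) <- "double"
  m
}

# Encode a sequence as 0-based codes for the C++ engine. DNA: A/C/G/T ->
# 0..3, anything else (N, IUPAC ambiguity) -> 4, which can never align.
# Protein: row index in the substitution matrix; unknown letters -> X.
encode_seq <- function(x, scheme) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  if (scheme$mode == "dna") {
    code <- match(chars, c("A", "C", "G", "T")) - 1L
    bad <- is.na(code)
    if (any(bad)) {
      if (!all(chars[bad] %in% c("N", "R", "Y", "S", "W", "K", "M",
                                 "B", "D", "H", "V", "U", "-")))
        stop("invalid DNA characters: ",
             paste(unique(chars[bad & !chars %in% "N"])[1:5], collapse = ", "))
      code[bad] <- 4L
    }
  } else {
    code <- match(chars, scheme$alphabet) - 1L
    if (anyNA(code)) {
      xi <- match("X", scheme$alphabet) - 1L
      if (is.na(xi)) stop("invalid protein characters")
      code[is.na(code)] <- xi
    }
  }
  code
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

new_local_alignment <- function(raw, strand = "+") {
  structure(list(score = raw$score,
                 identity = if (raw$aligned > 0) raw$matches / raw$aligned else NA_real_,
                 aligned_length = raw$aligned,
                 matches = raw$matches,
                 query_span = c(start = raw$a_start, end = raw$a_end),
                 target_span = c(start = raw$b_start, end = raw$b_end),
                 strand = strand),
            class = "local_alignment")
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local alignment: score %.1f, identity %.3f over %d columns, q %d-%d, t %d-%d (%s)\n",
    x$score, x$identity, x$aligned_length, x$query_span[1], x$query_span[2],
    x$target_span[1], x$target_span[2], x$strand))
  invisible(x)
}

#' Optimal Smith-Waterman local alignment
#'
#' Full affine-gap local alignment between two sequences. For DNA both
#' strands are searched and the better-scoring orientation is reported
#' (ties favour the forward strand); a `-` strand means the reverse
#' complement of `a` matches `b`, with `a`'s span reported in forward
#' coordinates. Coordinates are 1-based inclusive. The traceback is
#' deterministic (diagonal preferred over gaps, earliest maximal cell).
#'
#' @param a,b Character sequences over the scheme's alphabet.
#' @param scheme A [scoring_scheme()].
#' @param both_strands Search the reverse complement of `a` too (DNA only).
#' @return A `local_alignment` with score, identity (matches / aligned
#'   columns including gaps), spans and strand, or `NULL` if no positive-
#'   scoring alignment exists.
#' @examples
#' aln <- local_align("ACGTACGTAC", "ACGTACGTAC", scoring_scheme("dna"))
#' aln$identity
#' @export
local_align <- function(a, b, scheme = scoring_scheme("dna"),
                        both_strands = scheme$mode == "dna") {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  ea <- encode_seq(a, scheme)
  eb <- encode_seq(b, scheme)
  fwd <- .sw_align_cpp(ea, eb, scheme$submat, scheme$gap_open, scheme$gap_extend)
  best <- fwd
  strand <- "+"
  if (both_strands && scheme$mode == "dna") {
    ear <- rev(ifelse(ea <= 3L, 3L - ea, ea))
    rc <- .sw_align_cpp(ear, eb, scheme$submat, scheme$gap_open, scheme$gap_extend)
    if (rc$score > best$score) {
      n <- length(ea)
      rc_map <- rc
      rc_map$a_start <- n - rc$a_end + 1L
      rc_map$a_end <- n - rc$a_start + 1L
      best <- rc_map
      strand <- "-"
    }
  }
  if (best$empty) return(NULL)
  new_local_alignment(best, strand)
}

#' Seed-and-extend local alignment
#'
#' Finds exact `k`-mer seeds of the query in the target, votes on the
#' best-supported diagonal band, and runs full Smith-Waterman on the
#' windowed target only. Both DNA strands are searched. Returns `NULL`
#' when query and target share no `k`-mer. When a seed overlaps the
#' optimal local alignment the result matches [local_align()].
#'
#' @param query,target DNA character sequences.
#' @param k Exact word size for seeding (>= 8).
#' @param scheme A DNA [scoring_scheme()].
#' @param margin Extra target bases kept on each side of the seed window.
#' @return A `local_alignment` or `NULL`.
#' @export
seed_and_extend <- function(query, target, k = 15L,
                            scheme = scoring_scheme("dna"), margin = 120L) {
  if (scheme$mode != "dna") stop("seed_and_extend is DNA-only")
  if (k < 8L) stop("k must be >= 8 for DNA seeding")
  if (k > nchar(query)) stop("k exceeds the query length")
  eq <- encode_seq(query, scheme)
  et <- encode_seq(target, scheme)
  hit <- .map_fragments_cpp(list(eq), et, as.integer(k), scheme$submat,
                            scheme$gap_open, scheme$gap_extend,
                            as.integer(margin), 64L)
  if (!hit$has_hit[1L]) return(NULL)
  raw <- list(score = hit$score[1L], a_start = hit$q_start[1L],
              a_end = hit$q_end[1L], b_start = hit$t_start[1L],
              b_end = hit$t_end[1L], matches = hit$matches[1L],
              aligned = hit$aligned[1L], empty = FALSE)
  new_local_alignment(raw, hit$strand[1L])
}

#' Karlin-Altschul expect value
#'
#' `E = K * m * n * exp(-lambda * score)` using the scheme's ungapped
#' Karlin parameters. E may exceed 1 for weak scores.
#'
#' @param score Alignment score.
#' @param m,n Effective query and database lengths (positive).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return The expect value (numeric scalar).
#' @examples
#' sc <- scoring_scheme("protein", karlin_lambda = 0.32, karlin_k = 0.13)
#' karlin_altschul_evalue(40, 100, 100, sc) # ~3.6e-3
#' @export
karlin_altschul_evalue <- function(score, m, n, scheme) {
  if (m <= 0 || n <= 0) stop("sequence lengths must be positive")
  if (score <= 0) warning("non-positive score: E-value exceeds K*m*n scale")
  scheme$karlin_k * m * n * exp(-scheme$karlin_lambda * score)
}
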