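# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds so one user seed can drive several draws.
child_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) * 7919L + as.integer(i) * 104729L) %% 2147483647L
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

#' Assembly N50
#'
#' Length at which the cumulative sum of descending-sorted sequence lengths
#' first reaches half the total assembly length.
#'
#' @param lengths Integer or numeric vector of sequence lengths.
#' @return The N50 length (numeric scalar); 0 for an empty input.
#' @examples
#' n50(c(10000, 6000, 5000, 4000)) # 6000
#' @export
n50 <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) == 0L || sum(lengths) == 0) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}
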