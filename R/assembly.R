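#' Genome assembly container
#'
#' The unit flowing through quality control, splitting, taxonomy and
#' clustering: named scaffold sequences plus optional per-scaffold mean
#' sequencing depth.
#'
#' @param sequences A named character vector or a
#'   [Biostrings::DNAStringSet] of scaffold sequences.
#' @param depth Optional named numeric vector of per-scaffold mean depth;
#'   names must cover every scaffold.
#' @param id Assembly identifier.
#' @return An object of class `genome_assembly` with elements `id`,
#'   `sequences` (`DNAStringSet`) and `depth`.
#' @export
genome_assembly <- function(sequences, depth = NULL, id = "assembly") {
  if (is.character(sequences)) {
    if (is.null(names(sequences)))
      names(sequences) <- sprintf("scaffold_%03d", seq_along(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  stopifnot(methods::is(sequences, "DNAStringSet"), length(sequences) >= 1L)
  if (anyDuplicated(names(sequences))) stop("duplicated scaffold ids")
  if (!is.null(depth)) {
    missing <- setdiff(names(sequences), names(depth))
    if (length(missing))
      stop("depth missing for scaffolds: ", paste(head(missing, 3), collapse = ", "))
    if (any(depth <= 0)) stop("depths must be positive")
    depth <- depth[names(sequences)]
  }
  structure(list(id = id, sequences = sequences, depth = depth),
            class = "genome_assembly")
}

#' @export
print.genome_assembly <- function(x, ...) {
  w <- Biostrings::width(x$sequences)
  cat(sprintf("genome_assembly '%s': %d scaffolds, %.1f kb total, N50 %.1f kb%s\n",
              x$id, length(w), sum(w) / 1e3, n50(w) / 1e3,
              if (is.null(x$depth)) "" else ", depth attached"))
  invisible(x)
}

scaffold_lengths <- function(assembly) {
  setNames(Biostrings::width(assembly$sequences), names(assembly$sequences))
}

total_length <- function(assembly) sum(Biostrings::width(assembly$sequences))

# One character string per scaffold (uppercase).
assembly_chars <- function(assembly) {
  setNames(toupper(as.character(assembly$sequences)), names(assembly$sequences))
}

#' Read and write assemblies and sidecar tables
#'
#' FASTA via Biostrings (wrapped at 80 columns on write); depth tables as
#' `scaffold_id<TAB>mean_depth`; marker tables as
#' `marker_id<TAB>scaffold_id<TAB>copy_count`, all with header lines.
#'
#' @param path File path.
#' @param depth_path Optional depth TSV read alongside the FASTA.
#' @param id Assembly id (defaults to the file name).
#' @return `read_assembly()` returns a [genome_assembly()]; writers return
#'   the path invisibly.
#' @name assembly_io
NULL

#' @rdname assembly_io
#' @export
read_assembly <- function(path, depth_path = NULL, id = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  depth <- if (!is.null(depth_path)) read_depth_tsv(depth_path)
  genome_assembly(seqs, depth = depth,
                  id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id)
}

#' @rdname assembly_io
#' @param assembly A [genome_assembly()].
#' @export
write_assembly_fasta <- function(assembly, path) {
  Biostrings::writeXStringSet(assembly$sequences, path, width = 80L)
  invisible(path)
}

#' @rdname assembly_io
#' @export
read_depth_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.numeric(d$mean_depth), d$scaffold_id)
}

#' @rdname assembly_io
#' @param depth Named numeric vector of per-scaffold depth.
#' @export
write_depth_tsv <- function(depth, path) {
  write.table(data.frame(scaffold_id = names(depth), mean_depth = depth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname assembly_io
#' @export
read_marker_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c("character", "character", "integer"))
}

#' @rdname assembly_io
#' @param markers Data frame with `marker_id`, `scaffold_id`, `copy_count`.
#' @export
write_marker_tsv <- function(markers, path) {
  write.table(markers[, c("marker_id", "scaffold_id", "copy_count")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
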