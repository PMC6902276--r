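#' Read and write FASTA genome sequences
#'
#' Sequences are returned as a named character vector of upper-case DNA,
#' IUPAC ambiguity codes preserved. Sequence ids are the first whitespace
#' token of each header line.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  check_file(path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop_format(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0L) stop_format(paste0("no FASTA records in ", path))
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop_format("duplicated sequence ids in FASTA")
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @param genome Named character vector of sequences.
#' @param width Line-wrap width.
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path, width = width)
  invisible(path)
}
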