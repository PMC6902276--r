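#' Splice-site motif sets
#'
#' A splice motif set is a tibble of donor/acceptor dinucleotide pairs (the
#' two intronic bases at each intron end). `default_splice_motifs()` returns
#' the canonical eukaryotic set GT-AG, GC-AG, AT-AC, which is also shipped as
#' `inst/extdata/splice_sites.txt` and used whenever no file is given.
#'
#' @return Tibble with character columns `donor` and `acceptor`.
#' @export
#' @examples
#' default_splice_motifs()
default_splice_motifs <- function() {
  tibble(donor = c("GT", "GC", "AT"), acceptor = c("AG", "AG", "AC"))
}

#' @rdname default_splice_motifs
#' @param path Plain-text file, one whitespace-separated donor/acceptor pair
#'   per line; `#` starts a comment. Motifs must be length-2 IUPAC strings.
#' @export
read_splice_motifs <- function(path) {
  check_file(path)
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_format(paste0("no splice motifs in ", path))
  parts <- strsplit(lines, "\\s+")
  bad <- vapply(parts, function(p) length(p) != 2L, logical(1))
  if (any(bad)) stop_format(paste0("malformed splice motif line: '", lines[which(bad)[1]], "'"))
  donor <- toupper(vapply(parts, `[[`, character(1), 1L))
  acceptor <- toupper(vapply(parts, `[[`, character(1), 2L))
  ok <- function(x) nchar(x) == 2L & vapply(strsplit(x, ""), function(cc) all(is_iupac(cc)), logical(1))
  if (!all(ok(donor) & ok(acceptor))) {
    stop_format("splice motifs must be length-2 IUPAC nucleotide strings")
  }
  distinct(tibble(donor = donor, acceptor = acceptor))
}

#' Read and write coarse alignment range pairs
#'
#' The range-pair file is the package's neutral interchange format for coarse
#' whole-genome alignments (e.g. derived from MUMmer or minimap2 output):
#' seven whitespace-delimited columns `ref_chrom ref_start ref_end
#' query_chrom query_start query_end strand`, 1-based inclusive on disk,
#' 0-based half-open in the returned tibble.
#'
#' @param path File path.
#' @param ref_genome,query_genome Optional genomes for bounds validation.
#' @return Tibble with columns `ref_chrom`, `ref_start`, `ref_end`,
#'   `query_chrom`, `query_start`, `query_end`, `same_strand` (logical).
#' @export
read_range_pairs <- function(path, ref_genome = NULL, query_genome = NULL) {
  check_file(path)
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop_format(paste0("no range pairs in ", path))
  parts <- strsplit(lines, "\\s+")
  if (any(vapply(parts, length, integer(1)) != 7L)) {
    stop_format("range-pair lines must have 7 whitespace-delimited fields")
  }
  m <- do.call(rbind, parts)
  rp <- tibble(
    ref_chrom = m[, 1], ref_start = as.integer(m[, 2]) - 1L, ref_end = as.integer(m[, 3]),
    query_chrom = m[, 4], query_start = as.integer(m[, 5]) - 1L, query_end = as.integer(m[, 6]),
    same_strand = m[, 7] == "+"
  )
  if (anyNA(rp$ref_start) || anyNA(rp$query_start) ||
      !all(m[, 7] %in% c("+", "-"))) {
    stop_format("malformed range-pair coordinates or strand")
  }
  validate_range_pairs(rp, ref_genome, query_genome)
}

#' @rdname read_range_pairs
#' @param range_pairs Range-pair tibble.
#' @export
write_range_pairs <- function(range_pairs, path) {
  rp <- range_pairs
  writeLines(paste(rp$ref_chrom, rp$ref_start + 1L, rp$ref_end,
                   rp$query_chrom, rp$query_start + 1L, rp$query_end,
                   ifelse(rp$same_strand, "+", "-"), sep = "\t"), path)
  invisible(path)
}

#' @noRd
validate_range_pairs <- function(rp, ref_genome = NULL, query_genome = NULL) {
  if (any(rp$ref_end < rp$ref_start) || any(rp$query_end < rp$query_start)) {
    stop_validation("range pair with end < start")
  }
  check_side <- function(genome, chrom, start, end, side) {
    if (is.null(genome)) return(invisible())
    bad <- setdiff(unique(chrom), names(genome))
    if (length(bad)) stop_validation(paste0(side, " chromosome not in genome: ", bad[[1]]))
    if (any(start < 0L) || any(end > nchar(genome[chrom]))) {
      stop_validation(paste0(side, " range out of chromosome bounds"))
    }
  }
  check_side(ref_genome, rp$ref_chrom, rp$ref_start, rp$ref_end, "reference")
  check_side(query_genome, rp$query_chrom, rp$query_start, rp$query_end, "query")
  rp
}
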