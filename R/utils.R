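# Internal helpers: IUPAC nucleotide algebra, sequence utilities, error classes.

# 4-bit base masks; ambiguity codes are unions of A/C/G/T bits.
.iupac_masks <- c(
  A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

iupac_mask <- function(chars) {
  m <- unname(.iupac_masks[toupper(chars)])
  m[is.na(m)] <- 0L
  m
}

#' @noRd
is_iupac <- function(chars) {
  toupper(chars) %in% names(.iupac_masks)
}

# TRUE where the base sets of a and b intersect (IUPAC-permissive equality).
bases_intersect <- function(a, b) {
  bitwAnd(iupac_mask(a), iupac_mask(b)) > 0L
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

substr0 <- function(x, start, end) {
  # 0-based half-open substring
  if (end <= start) return("")
  substr(x, start + 1L, end)
}

stop_format <- function(msg, ...) {
  abort(msg, class = c("zebralift_format_error", "zebralift_error"), ...)
}

stop_validation <- function(msg, ...) {
  abort(msg, class = c("zebralift_validation_error", "zebralift_error"), ...)
}

stop_contract <- function(msg, ...) {
  abort(msg, class = c("zebralift_contract_error", "zebralift_error"), ...)
}

check_file <- function(path) {
  if (!file.exists(path)) {
    stop_format(paste0("file does not exist: ", path))
  }
  if (file.size(path) == 0L) {
    stop_format(paste0("file is empty: ", path))
  }
  invisible(path)
}

# Deterministic local RNG: runs code with a seed, restoring global RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}
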