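#' Feature classes used by the zebraic aligner
#'
#' Reference bases are labelled with one of five feature classes. When a base
#' is claimed by several features the highest-precedence class wins:
#' `START_STOP_CODON > SPLICE_SITE > CDS > INTRON > OTHER`. The integer codes
#' are ordered by precedence and are the row order of a [score_profile()].
#'
#' @return Named integer vector of class codes.
#' @export
#' @examples
#' feature_classes()
feature_classes <- function() {
  c(OTHER = 0L, INTRON = 1L, CDS = 2L, SPLICE_SITE = 3L, START_STOP_CODON = 4L)
}

.class_levels <- c("OTHER", "INTRON", "CDS", "SPLICE_SITE", "START_STOP_CODON")

# config-key aliases for the five classes
.class_keys <- c(
  other = "OTHER", intron = "INTRON", cds = "CDS",
  splice = "SPLICE_SITE", startstop = "START_STOP_CODON"
)

#' Per-feature-class scoring profile
#'
#' A zebraic scoring profile holds, for every feature class, a match score
#' (> 0), a mismatch score (<= 0), and affine gap penalties `gap_open` and
#' `gap_ext` (both >= 0, subtracted from the score). Deletions (gap in the
#' query) are charged with the class of the reference column they consume;
#' insertions (gap in the reference) with the class of the most recently
#' consumed reference column.
#'
#' The intended weighting puts coding features above intronic ones:
#' start/stop-codon and splice-site penalties >= CDS penalties >= intron
#' penalties. Profiles violating that ordering are accepted with a warning.
#'
#' @param ... Per-class vectors named `other`, `intron`, `cds`, `splice`,
#'   `startstop`, each `c(match, mismatch, gap_open, gap_ext)`. Unspecified
#'   classes fall back to the default profile; `other` falls back to `intron`.
#' @return Object of class `zl_profile`: an integer matrix with one row per
#'   feature class and columns `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @export
#' @examples
#' default_profile()
#' uniform_profile(match = 2, mismatch = -3, gap_open = 5, gap_ext = 2)
score_profile <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), names(.class_keys))
  if (length(bad)) {
    stop_validation(paste0("unknown profile class: ", paste(bad, collapse = ", ")))
  }
  mat <- .default_profile_matrix()
  if (!is.null(args$intron) && is.null(args$other)) {
    args$other <- args$intron
  }
  for (nm in names(args)) {
    v <- as.integer(args[[nm]])
    if (length(v) != 4L || anyNA(v)) {
      stop_validation(paste0("profile class '", nm, "' must be 4 integers: match, mismatch, gap_open, gap_ext"))
    }
    mat[.class_keys[[nm]], ] <- v
  }
  new_profile(mat)
}

.default_profile_matrix <- function() {
  mat <- rbind(
    OTHER            = c(2L, -2L, 4L, 1L),
    INTRON           = c(2L, -2L, 4L, 1L),
    CDS              = c(6L, -6L, 26L, 2L),
    SPLICE_SITE      = c(30L, -30L, 110L, 110L),
    START_STOP_CODON = c(30L, -30L, 110L, 110L)
  )
  colnames(mat) <- c("match", "mismatch", "gap_open", "gap_ext")
  mat
}

new_profile <- function(mat) {
  stopifnot(identical(rownames(mat), .class_levels),
            identical(colnames(mat), c("match", "mismatch", "gap_open", "gap_ext")))
  if (any(mat[, "match"] <= 0L)) stop_validation("match scores must be > 0")
  if (any(mat[, "mismatch"] > 0L)) stop_validation("mismatch scores must be <= 0")
  if (any(mat[, c("gap_open", "gap_ext")] < 0L)) stop_validation("gap penalties must be >= 0")
  if (any(mat[, "gap_open"] < mat[, "gap_ext"])) {
    stop_validation("gap_open must be >= gap_ext for every class")
  }
  ord <- function(col) {
    v <- abs(mat[, col])
    v["SPLICE_SITE"] >= v["CDS"] && v["START_STOP_CODON"] >= v["CDS"] &&
      v["CDS"] >= v["INTRON"]
  }
  if (!all(vapply(c("mismatch", "gap_open", "gap_ext"), ord, logical(1)))) {
    warn(paste(
      "profile does not weight coding features above intronic ones",
      "(expected splice/start-stop penalties >= CDS >= intron)"
    ), class = "zebralift_profile_order_warning")
  }
  structure(mat, class = c("zl_profile", class(mat)))
}

#' @rdname score_profile
#' @export
default_profile <- function() {
  new_profile(.default_profile_matrix())
}

#' @rdname score_profile
#' @param match,mismatch,gap_open,gap_ext Scores applied uniformly to every
#'   feature class, reducing the aligner to standard semi-global affine-gap
#'   alignment.
#' @export
uniform_profile <- function(match = 2L, mismatch = -3L, gap_open = 5L, gap_ext = 2L) {
  mat <- .default_profile_matrix()
  mat[, ] <- rep(as.integer(c(match, mismatch, gap_open, gap_ext)), each = 5L)
  new_profile(mat)
}

#' Read or write a scoring-profile configuration file
#'
#' Flat `key=value` text with keys `<class>.match`, `<class>.mismatch`,
#' `<class>.gap_open`, `<class>.gap_ext` for `class` in `cds`, `intron`,
#' `splice`, `startstop`, `other`. Keys absent from the file keep their
#' default value.
#'
#' @param path File path.
#' @return `read_score_profile()` returns a `zl_profile`;
#'   `write_score_profile()` returns `path` invisibly.
#' @export
read_score_profile <- function(path) {
  check_file(path)
  lines <- str_trim(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mat <- .default_profile_matrix()
  for (ln in lines) {
    kv <- str_trim(strsplit(ln, "=", fixed = TRUE)[[1]])
    if (length(kv) != 2L) stop_format(paste0("malformed profile line: '", ln, "'"))
    key <- strsplit(kv[[1]], ".", fixed = TRUE)[[1]]
    if (length(key) != 2L || !key[[1]] %in% names(.class_keys) ||
        !key[[2]] %in% c("match", "mismatch", "gap_open", "gap_ext")) {
      stop_format(paste0("unknown profile key: '", kv[[1]], "'"))
    }
    val <- suppressWarnings(as.integer(kv[[2]]))
    if (is.na(val)) stop_format(paste0("non-integer profile value: '", ln, "'"))
    mat[.class_keys[[key[[1]]]], key[[2]]] <- val
  }
  new_profile(mat)
}

#' @rdname read_score_profile
#' @param profile A `zl_profile`.
#' @export
write_score_profile <- function(profile, path) {
  stopifnot(inherits(profile, "zl_profile"))
  keys <- names(.class_keys)
  lines <- unlist(lapply(keys, function(k) {
    row <- profile[.class_keys[[k]], ]
    paste0(k, ".", names(row), "=", row)
  }))
  writeLines(lines, path)
  invisible(path)
}
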