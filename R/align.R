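#' Zebraic feature-weighted semi-global alignment
#'
#' Aligns a query sequence against a reference window whose bases carry
#' feature-class labels ([build_feature_track()]), using per-class match,
#' mismatch and affine gap parameters from a [score_profile()]. The
#' reference is aligned end-to-end (its unconsumed prefix is emitted as free
#' deletions), the query locally (free overhangs at both ends). Traceback
#' starts from the maximum-score cell of the last reference column (smallest
#' query index on ties).
#'
#' `zdp_align()` is the scalar reference implementation. `zsdp_align()` is
#' the striped equivalent — per-class query profiles, batched column
#' evaluation with a lazy-F correction pass, and 8/16/32-bit score storage
#' escalated on saturation — and returns identical results.
#' `sliding_window_align()` tiles the DP space with `window_size` square
#' blocks for linear-time alignment of long sequences; the maximum cell of
#' each block's last row or column anchors the next block, and with
#' `window_size >= max(length)` the result equals `zdp_align()` exactly.
#'
#' @param ref_seq Reference sequence (single string).
#' @param feature_track Integer feature-class vector, one label per
#'   reference base (see [feature_classes()]). `NULL` labels everything
#'   `OTHER`.
#' @param query_seq Query sequence (single string).
#' @param profile [score_profile()].
#' @param window_size Block size for the sliding-window driver (>= 2).
#' @return Object of class `zl_alignment`: list with `score`, `ref_aligned`
#'   and `query_aligned` (equal-length gapped strings covering the whole
#'   reference), `ref_span` and `query_span` (0-based half-open), `width`
#'   (integer width used by the striped solver), and an edit-operation
#'   tibble available via [tidy()].
#' @export
#' @examples
#' track <- rep(feature_classes()[["CDS"]], 4)
#' zdp_align("ACGT", track, "ACGT", default_profile())
zdp_align <- function(ref_seq, feature_track, query_seq, profile = default_profile()) {
  x <- .check_align_args(ref_seq, feature_track, query_seq, profile)
  res <- zdp_align_cpp(x$ref, x$query, x$track, unclass(profile))
  new_alignment(res, method = "zdp")
}

#' @rdname zdp_align
#' @export
zsdp_align <- function(ref_seq, feature_track, query_seq, profile = default_profile()) {
  x <- .check_align_args(ref_seq, feature_track, query_seq, profile)
  res <- zsdp_align_cpp(x$ref, x$query, x$track, unclass(profile))
  new_alignment(res, method = "zsdp")
}

#' @rdname zdp_align
#' @export
sliding_window_align <- function(ref_seq, feature_track, query_seq,
                                 profile = default_profile(), window_size = 1000L) {
  x <- .check_align_args(ref_seq, feature_track, query_seq, profile)
  if (window_size < 2L) stop_contract("window_size must be >= 2")
  res <- sliding_align_cpp(x$ref, x$query, x$track, unclass(profile),
                           as.integer(window_size))
  new_alignment(res, method = "sliding")
}

.check_align_args <- function(ref_seq, feature_track, query_seq, profile) {
  if (!is.character(ref_seq) || length(ref_seq) != 1L || nchar(ref_seq) == 0L) {
    stop_contract("reference must be a non-empty string")
  }
  if (!is.character(query_seq) || length(query_seq) != 1L || nchar(query_seq) == 0L) {
    stop_contract("query must be a non-empty string")
  }
  if (is.null(feature_track)) {
    feature_track <- integer(nchar(ref_seq))
  }
  track <- as.integer(feature_track)
  if (length(track) != nchar(ref_seq)) {
    stop_contract("feature track length must equal reference length")
  }
  if (any(track < 0L) || any(track > 4L)) stop_contract("invalid feature-class code")
  if (!inherits(profile, "zl_profile")) stop_contract("profile must be a zl_profile")
  list(ref = toupper(ref_seq), query = toupper(query_seq), track = track)
}

new_alignment <- function(res, method) {
  structure(
    list(score = res$score,
         ref_aligned = res$ref_aligned,
         query_aligned = res$query_aligned,
         ref_span = c(0L, nchar(gsub("-", "", res$ref_aligned, fixed = TRUE))),
         query_span = c(res$qstart, res$qend),
         width = res$width,
         method = method),
    class = "zl_alignment"
  )
}

#' @exportS3Method base::print
print.zl_alignment <- function(x, ...) {
  g <- glance(x)
  cat("<zl_alignment> ", x$method, ", score ", x$score,
      ", ref ", x$ref_span[1], "-", x$ref_span[2],
      ", query ", x$query_span[1], "-", x$query_span[2],
      " (", g$n_match, "=, ", g$n_mismatch, "X, ",
      g$n_ins, "I, ", g$n_del, "D)\n", sep = "")
  invisible(x)
}

# column-wise op codes for an alignment: "=", "X", "I" (gap in ref), "D"
alignment_columns <- function(aln) {
  rc <- seq_chars(aln$ref_aligned)
  qc <- seq_chars(aln$query_aligned)
  op <- ifelse(rc == "-", "I", ifelse(qc == "-", "D", ifelse(rc == qc, "=", "X")))
  list(rc = rc, qc = qc, op = op)
}

#' @describeIn zdp_align Tidy the edit operations of an alignment: one row
#'   per run of `=`, `X`, `I` (insertion, gap in reference) or `D`
#'   (deletion, gap in query) with reference/query offsets and lengths.
#' @param x A `zl_alignment`.
#' @param ... Unused.
#' @export
tidy.zl_alignment <- function(x, ...) {
  cols <- alignment_columns(x)
  r <- rle(cols$op)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ref_adv <- ifelse(r$values == "I", 0L, r$lengths)
  q_adv <- ifelse(r$values == "D", 0L, r$lengths)
  tibble(
    op = r$values,
    length = r$lengths,
    ref_start = c(0L, cumsum(ref_adv))[seq_along(r$values)],
    query_start = x$query_span[1] + c(0L, cumsum(q_adv))[seq_along(r$values)],
    column_start = starts
  )
}

#' @describeIn zdp_align One-row summary: score, column counts by type,
#'   percent identity over aligned (non-gap) columns, solver width.
#' @export
glance.zl_alignment <- function(x, ...) {
  cols <- alignment_columns(x)
  n_match <- sum(cols$op == "=")
  n_mismatch <- sum(cols$op == "X")
  tibble(
    score = x$score,
    columns = length(cols$op),
    n_match = n_match,
    n_mismatch = n_mismatch,
    n_ins = sum(cols$op == "I"),
    n_del = sum(cols$op == "D"),
    identity = if (n_match + n_mismatch > 0) n_match / (n_match + n_mismatch) else NA_real_,
    width = x$width %||% NA_integer_
  )
}

#' Plot alignment edit operations along the reference
#'
#' @param object A `zl_alignment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zl_alignment <- function(object, ...) {
  ops <- tidy(object)
  ops$ref_end <- ops$ref_start + ifelse(ops$op == "I", 0L, ops$length)
  ggplot2::ggplot(ops) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$ref_start, xend = pmax(.data$ref_end, .data$ref_start + 0.2),
      y = .data$op, yend = .data$op, colour = .data$op
    ), linewidth = 4) +
    ggplot2::labs(x = "reference position (bp)", y = NULL,
                  title = "alignment edit operations") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Score a given alignment under a profile
#'
#' Recomputes the zebraic path score of an explicit alignment (equal-length
#' gapped strings) from first principles: per-column class-specific
#' match/mismatch scores, run-based affine gap costs (deletions charged with
#' the class of each consumed reference column, insertions with the class of
#' the last consumed reference column), and free leading runs under the
#' semi-global boundary rules. Useful for comparing alternative placements
#' of the same edit.
#'
#' @param ref_aligned,query_aligned Equal-length gapped strings.
#' @param feature_track Feature classes of the ungapped reference.
#' @param profile [score_profile()].
#' @param free_ends If `TRUE` (default) a leading deletion run and leading
#'   insertion run are free, matching the aligner's boundary rules.
#' @return Numeric score.
#' @export
alignment_score <- function(ref_aligned, query_aligned, feature_track,
                            profile = default_profile(), free_ends = TRUE) {
  rc <- seq_chars(ref_aligned)
  qc <- seq_chars(query_aligned)
  if (length(rc) != length(qc)) stop_contract("aligned strings must have equal length")
  track <- as.integer(feature_track)
  if (sum(rc != "-") != length(track)) {
    stop_contract("feature track length must equal ungapped reference length")
  }
  mat <- unclass(profile)
  op <- ifelse(rc == "-", "I", ifelse(qc == "-", "D", "M"))
  # under the semi-global boundary rules the path may start after a free
  # run of skipped reference (leading deletions) or clipped query (leading
  # insertions); trailing gap runs are paid.
  free_prefix <- 0L
  if (free_ends && op[1] %in% c("D", "I")) {
    free_prefix <- rle(op)$lengths[1]
  }
  score <- 0
  j <- 0L  # reference bases consumed
  last_op <- ""
  for (k in seq_along(op)) {
    if (op[k] == "M") {
      j <- j + 1L
      cl <- track[j] + 1L
      score <- score + if (rc[k] == qc[k]) mat[cl, "match"] else mat[cl, "mismatch"]
    } else if (op[k] == "D") {
      j <- j + 1L
      if (k > free_prefix) {
        cl <- track[j] + 1L
        score <- score - if (last_op == "D") mat[cl, "gap_ext"] else mat[cl, "gap_open"]
      }
    } else {
      if (k > free_prefix) {
        cl <- track[max(j, 1L)] + 1L
        score <- score - if (last_op == "I") mat[cl, "gap_ext"] else mat[cl, "gap_open"]
      }
    }
    last_op <- if (k <= free_prefix) "" else op[k]
  }
  score
}

# Per-reference-base query coordinates implied by an alignment.
# Returns integer vector over reference bases of the aligned region
# (0-based query positions, NA where the reference base is deleted).
alignment_map <- function(aln) {
  cols <- alignment_columns(aln)
  refpos <- cumsum(cols$rc != "-") - 1L
  qpos <- aln$query_span[1] + cumsum(cols$qc != "-") - 1L
  keep <- cols$rc != "-"
  out <- rep(NA_integer_, sum(keep))
  hit <- keep & cols$qc != "-"
  out[refpos[hit] + 1L] <- qpos[hit]
  out
}

# Map a 0-based half-open reference interval [s, e) (window coordinates)
# through an alignment to query coordinates, snapping boundaries landing in
# gaps toward the interval interior. Returns c(qs, qe); qe <= qs means the
# interval is fully deleted.
map_interval <- function(map, qstart, qend, s, e) {
  n <- length(map)
  qs <- NA_integer_
  if (s < n) {
    k <- s + 1L
    while (k <= n && is.na(map[k])) k <- k + 1L
    if (k <= n && (k - 1L) < e) qs <- map[k]
  }
  qe <- NA_integer_
  if (e >= 1L) {
    k <- e
    while (k >= 1L && is.na(map[k])) k <- k - 1L
    if (k >= 1L && (k - 1L) >= s) qe <- map[k] + 1L
  }
  if (is.na(qs) || is.na(qe)) return(c(qstart, qstart))  # fully deleted
  c(qs, qe)
}
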