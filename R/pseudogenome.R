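#' Build a pseudo-genome by applying variants to a reference
#'
#' Substitutes each REF allele span by its ALT allele, left to right, and
#' returns both the pseudo-genome and per-chromosome shift indexes for
#' coordinate lift-over. Variants must be non-overlapping and agree with the
#' reference; both conditions are validation errors.
#'
#' @param genome Named character vector of reference sequences.
#' @param variants Variant tibble (see [variant_tibble()]).
#' @return List with elements `genome` (named character vector) and `shift`
#'   (named list of `zl_shift_index`, one per chromosome of the input
#'   genome).
#' @export
#' @examples
#' apply_variants(c(c1 = "ACGT"),
#'                tibble::tibble(chrom = "c1", pos = 1, ref = "C", alt = "CTT"))
apply_variants <- function(genome, variants) {
  v <- validate_variants(genome, variants)
  pseudo <- genome
  shift <- lapply(names(genome), function(ch) {
    vv <- filter(v, .data$chrom == ch)
    build_shift_index(vv, nchar(genome[[ch]]))
  })
  names(shift) <- names(genome)
  for (ch in names(genome)) {
    vv <- filter(v, .data$chrom == ch)
    if (!nrow(vv)) next
    src <- genome[[ch]]
    bounds <- c(0L, rbind(vv$pos, vv$pos + nchar(vv$ref)), nchar(src))
    keep_start <- bounds[seq(1L, length(bounds), by = 2L)]
    keep_end <- bounds[seq(2L, length(bounds), by = 2L)]
    kept <- substring(src, keep_start + 1L, keep_end)
    pieces <- character(2L * nrow(vv) + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- kept
    pieces[seq(2L, length(pieces), by = 2L)] <- vv$alt
    pseudo[[ch]] <- paste(pieces, collapse = "")
  }
  list(genome = pseudo, shift = shift)
}

#' Shift index for coordinate lift-over
#'
#' Records, per variant, the reference span replaced and where its ALT
#' allele lands in the pseudo-genome, so positions can be lifted by counting
#' the base pairs shifted by upstream variants.
#'
#' @param variants Variant tibble for a single chromosome (may be empty).
#' @param ref_len Reference chromosome length.
#' @return Object of class `zl_shift_index`.
#' @export
build_shift_index <- function(variants, ref_len) {
  v <- arrange(as_tibble(variants), .data$pos)
  rl <- nchar(v$ref); al <- nchar(v$alt)
  delta <- al - rl
  pseudo_start <- v$pos + c(0L, cumsum(delta))[seq_len(nrow(v))]
  structure(
    list(ref_start = v$pos, ref_end = v$pos + rl,
         alt_len = al,
         pseudo_start = as.integer(pseudo_start),
         pseudo_end = as.integer(pseudo_start + al),
         ref_len = as.integer(ref_len),
         pseudo_len = as.integer(ref_len + sum(delta))),
    class = "zl_shift_index"
  )
}

# Swap reference and pseudo roles so the same lookup code runs both ways.
invert_shift_index <- function(shift) {
  structure(
    list(ref_start = shift$pseudo_start, ref_end = shift$pseudo_end,
         alt_len = shift$ref_end - shift$ref_start,
         pseudo_start = shift$ref_start, pseudo_end = shift$ref_end,
         ref_len = shift$pseudo_len, pseudo_len = shift$ref_len),
    class = "zl_shift_index"
  )
}

#' Lift base positions through a shift index
#'
#' Positions strictly upstream or downstream of all variants move by the
#' cumulative offset of upstream variants. A position inside a deleted
#' reference span is reported with `mapped = NA` and the gap locus in
#' destination coordinates as both flanks (`flank_left` is one past the last
#' surviving base on the left, `flank_right` the first surviving base on the
#' right; for a deletion both coincide).
#'
#' @param shift `zl_shift_index`.
#' @param pos Integer vector of 0-based positions within the source
#'   sequence.
#' @param direction `"ref2pseudo"` or `"pseudo2ref"`.
#' @return Tibble with columns `pos`, `mapped`, `flank_left`, `flank_right`.
#' @export
lift_positions <- function(shift, pos, direction = c("ref2pseudo", "pseudo2ref")) {
  direction <- match.arg(direction)
  s <- if (direction == "pseudo2ref") invert_shift_index(shift) else shift
  pos <- as.integer(pos)
  if (any(pos < 0L) || any(pos >= s$ref_len)) {
    stop_contract("position out of sequence range")
  }
  n <- length(pos)
  mapped <- integer(n); deleted <- logical(n)
  if (length(s$ref_start)) {
    idx <- findInterval(pos, s$ref_start)
    for (i in seq_len(n)) {
      j <- idx[i]
      if (j == 0L || pos[i] >= s$ref_end[j]) {
        off <- if (j == 0L) 0L else s$pseudo_end[j] - s$ref_end[j]
        mapped[i] <- pos[i] + off
      } else {
        k <- pos[i] - s$ref_start[j]
        if (k < s$alt_len[j]) {
          mapped[i] <- s$pseudo_start[j] + k
        } else {
          deleted[i] <- TRUE
          mapped[i] <- s$pseudo_start[j] + s$alt_len[j]  # gap locus
        }
      }
    }
  } else {
    mapped <- pos
  }
  locus <- as.integer(mapped)
  tibble(pos = pos,
         mapped = ifelse(deleted, NA_integer_, locus),
         flank_left = locus,
         flank_right = locus)
}

#' @rdname lift_positions
#' @return `lift_position()` returns the mapped position, or the gap locus
#'   with attributes `deleted = TRUE`, `flank_left`, `flank_right` when the
#'   position falls in deleted sequence.
#' @export
lift_position <- function(shift, pos, direction = c("ref2pseudo", "pseudo2ref")) {
  r <- lift_positions(shift, pos, direction)
  if (is.na(r$mapped)) {
    structure(r$flank_right, deleted = TRUE,
              flank_left = r$flank_left, flank_right = r$flank_right)
  } else {
    r$mapped
  }
}

# Monotone prefix-length boundary map: b in [0, ref_len] -> [0, pseudo_len].
# Start boundaries landing in deleted sequence snap right, exclusive ends
# snap left; both coincide with the gap locus, so features never grow across
# deleted sequence and adjacent features keep tiling.
lift_boundary <- function(shift, b, direction = c("ref2pseudo", "pseudo2ref")) {
  direction <- match.arg(direction)
  s <- if (direction == "pseudo2ref") invert_shift_index(shift) else shift
  b <- as.integer(b)
  if (any(b < 0L) || any(b > s$ref_len)) stop_contract("boundary out of range")
  if (!length(s$ref_start)) return(b)
  out <- integer(length(b))
  idx <- findInterval(b, s$ref_start)
  for (i in seq_along(b)) {
    j <- idx[i]
    if (j == 0L || b[i] >= s$ref_end[j]) {
      off <- if (j == 0L) 0L else s$pseudo_end[j] - s$ref_end[j]
      out[i] <- b[i] + off
    } else {
      out[i] <- s$pseudo_start[j] + min(b[i] - s$ref_start[j], s$alt_len[j])
    }
  }
  out
}

#' Lift an annotation through per-chromosome shift indexes
#'
#' Every feature boundary is lifted with the monotone boundary map; a
#' boundary inside a deleted span snaps toward the feature interior. Features
#' whose lifted interval is empty are dropped with a warning and the owning
#' transcript flagged. Transcripts whose span intersects any variant are
#' flagged for ORF re-checking.
#'
#' @param annotation Annotation tibble.
#' @param shift Named list of `zl_shift_index` keyed by chromosome (as
#'   returned by [apply_variants()]); chromosomes without an entry are lifted
#'   by identity.
#' @return List with `annotation` (lifted tibble) and `flagged` (character
#'   vector of transcript ids needing ORF re-check).
#' @export
lift_annotation <- function(annotation, shift) {
  ann <- validate_annotation(annotation)
  flagged <- character(0)
  dropped <- character(0)
  out <- ann
  for (ch in unique(ann$chrom)) {
    s <- shift[[ch]]
    if (is.null(s) || !length(s$ref_start)) next
    i <- which(ann$chrom == ch)
    out$start[i] <- lift_boundary(s, ann$start[i])
    out$end[i] <- lift_boundary(s, ann$end[i])
    touched <- vapply(i, function(k) {
      any(s$ref_end > ann$start[k] & s$ref_start < ann$end[k])
    }, logical(1))
    flagged <- c(flagged, stats::na.omit(unique(ann$transcript_id[i][touched])))
  }
  empty <- out$end <= out$start
  if (any(empty)) {
    dropped <- unique(stats::na.omit(out$transcript_id[empty]))
    warn(paste0("dropping ", sum(empty), " feature(s) fully deleted in the pseudo-genome"),
         class = "zebralift_dropped_feature_warning")
    flagged <- c(flagged, dropped)
    out <- out[!empty, , drop = FALSE]
  }
  list(annotation = out, flagged = unique(flagged))
}
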