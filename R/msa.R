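# Population-scale variant uniformization: the reference is partitioned at
# feature boundaries, each element is multiple-aligned across accessions
# (reference-centred star alignment built from pairwise zebraic
# alignments), and every accession's variant records are re-derived from
# its row so identical haplotypes share identical records.

#' Partition the reference at feature boundaries
#'
#' Splits every chromosome at exon/CDS/gene edges into elements (CDS
#' segment, intron, intergenic block) and derives, per accession, the
#' corresponding pseudo-genome interval through its shift indexes.
#'
#' @param ref_annotation Annotation tibble.
#' @param accession_shifts Named list (per accession) of per-chromosome
#'   `zl_shift_index` lists, as produced by [apply_variants()].
#' @param ref_genome Named character vector (for chromosome lengths).
#' @return List of class `zl_partition` with `elements` (tibble:
#'   `element_id`, `chrom`, `start`, `end`, `class`) and `spans` (tibble:
#'   `element_id`, `accession`, `start`, `end`, `absent`).
#' @export
partition_by_feature <- function(ref_annotation, accession_shifts, ref_genome) {
  ann <- validate_annotation(ref_annotation)
  el_rows <- list()
  for (ch in names(ref_genome)) {
    L <- nchar(ref_genome[[ch]])
    feats <- filter(ann, .data$chrom == ch, .data$type %in% c("gene", "exon", "CDS"))
    cuts <- sort(unique(c(0L, L, feats$start, feats$end)))
    cuts <- cuts[cuts >= 0L & cuts <= L]
    cds <- filter(feats, .data$type == "CDS")
    genes <- filter(feats, .data$type == "gene")
    k <- length(cuts) - 1L
    if (k < 1L) next
    s <- cuts[seq_len(k)]; e <- cuts[-1L]
    cls <- vapply(seq_len(k), function(i) {
      if (nrow(cds) && any(cds$start < e[i] & cds$end > s[i])) return("CDS")
      if (nrow(genes) && any(genes$start < e[i] & genes$end > s[i])) return("INTRON")
      "OTHER"
    }, character(1))
    el_rows[[ch]] <- tibble(chrom = ch, start = s, end = e, class = cls)
  }
  elements <- bind_rows(el_rows)
  elements$element_id <- paste0(elements$chrom, ":", elements$start, "-", elements$end)
  span_rows <- list()
  for (acc in names(accession_shifts)) {
    sh <- accession_shifts[[acc]]
    ps <- integer(nrow(elements)); pe <- integer(nrow(elements))
    for (i in seq_len(nrow(elements))) {
      s <- sh[[elements$chrom[i]]]
      if (is.null(s)) { ps[i] <- NA_integer_; pe[i] <- NA_integer_; next }
      ps[i] <- lift_boundary(s, elements$start[i])
      pe[i] <- lift_boundary(s, elements$end[i])
    }
    span_rows[[acc]] <- tibble(element_id = elements$element_id, accession = acc,
                               start = ps, end = pe,
                               absent = is.na(ps) | pe <= ps)
  }
  structure(list(elements = select(elements, "element_id", "chrom", "start", "end", "class"),
                 spans = bind_rows(span_rows)),
            class = "zl_partition")
}

#' Multiple-align one element across accessions
#'
#' Reference-centred star alignment: every sequence is aligned pairwise
#' against the first (the reference element) with class-specific zebraic
#' scoring — directly when it fits in one window, through the anchored
#' sliding-window aligner otherwise — and the pairwise alignments are merged
#' into consistent columns (per reference slot, the longest insertion run
#' wins; shorter runs are gap-padded).
#'
#' @param sequences Character vector; first element is the reference
#'   element. Empty strings (absent accessions) become all-gap rows.
#' @param element_class Feature-class name or code used for scoring.
#' @param profile [score_profile()].
#' @param window_size Window above which the sliding-window aligner is used.
#' @return Character vector of equal-length gapped rows (same order and
#'   names as the input); all-empty input yields empty strings.
#' @export
msa_element <- function(sequences, element_class = "OTHER",
                        profile = default_profile(), window_size = 1000L) {
  if (length(sequences) < 2L) stop_contract("msa_element needs >= 2 sequences")
  if (all(!nzchar(sequences))) return(stats::setNames(character(length(sequences)) , names(sequences)))
  center <- sequences[[1]]
  others <- sequences[-1L]
  cls_code <- if (is.character(element_class)) {
    feature_classes()[[match.arg(element_class, names(feature_classes()))]]
  } else as.integer(element_class)
  n <- nchar(center)
  if (n == 0L) {
    # degenerate: no reference sequence, rows are left-aligned and padded
    w <- max(nchar(sequences))
    out <- vapply(sequences, function(s) paste0(s, strrep("-", w - nchar(s))), character(1))
    return(stats::setNames(out, names(sequences)))
  }
  track <- rep(cls_code, n)
  pair <- lapply(others, function(s) {
    if (!nzchar(s)) {
      return(list(ins = integer(n + 1L), row = rep("-", n), ins_chars = NULL))
    }
    aln <- if (max(n, nchar(s)) <= window_size) {
      zsdp_align(center, track, s, profile)
    } else {
      sliding_window_align(center, track, s, profile, window_size)
    }
    aln$query_string <- s
    padded <- .pad_query(aln, nchar(s))
    rc <- seq_chars(padded$ref_aligned)
    qc <- seq_chars(padded$query_aligned)
    # insertion lengths per reference slot (slot j = before ref base j+1)
    slot <- cumsum(rc != "-")
    ins <- integer(n + 1L)
    gap_cols <- which(rc == "-")
    if (length(gap_cols)) {
      tb <- table(slot[gap_cols])
      ins[as.integer(names(tb)) + 1L] <- as.integer(tb)
    }
    # per-slot query insertions and per-ref-base query characters
    row_chars <- character(n)
    ins_chars <- vector("list", n + 1L)
    qi <- 0L
    for (k in seq_along(rc)) {
      if (rc[k] == "-") {
        ins_chars[[slot[k] + 1L]] <- c(ins_chars[[slot[k] + 1L]], qc[k])
      } else {
        row_chars[slot[k]] <- qc[k]
      }
    }
    list(ins = ins, row = row_chars, ins_chars = ins_chars)
  })
  max_ins <- Reduce(pmax, lapply(pair, `[[`, "ins"), integer(n + 1L))
  build_row <- function(base_chars, ins_chars) {
    out <- character(0)
    for (j in 0:n) {
      ic <- if (is.null(ins_chars)) character(0) else ins_chars[[j + 1L]] %||% character(0)
      out <- c(out, ic, rep("-", max_ins[j + 1L] - length(ic)),
               if (j < n) base_chars[j + 1L])
    }
    paste(out, collapse = "")
  }
  center_row <- build_row(seq_chars(center), NULL)
  rows <- vapply(pair, function(p) build_row(p$row, p$ins_chars), character(1))
  stats::setNames(c(center_row, rows), names(sequences))
}

# Chromosome-level feature-class track: per-transcript tracks merged by
# class precedence.
.chrom_track <- function(annotation, chrom, L) {
  track <- integer(L)
  txs <- as_transcripts(filter(validate_annotation(annotation), .data$chrom == !!chrom))
  for (i in seq_len(nrow(txs))) {
    cd <- txs$cds[[i]]
    if (!nrow(cd)) next
    ws <- min(cd[, 1]); we <- max(cd[, 2])
    t <- build_feature_track(txs[i, ], ws, we)
    idx <- (ws + 1L):we
    track[idx] <- pmax(track[idx], as.integer(t))
  }
  track
}

# Project reference boundaries 0..L onto the query through a deterministic
# chromosome-scale alignment. Bvec[b + 1] = query bases consumed strictly
# before reference base b; insertions immediately left of a boundary belong
# to the left element.
.boundary_map <- function(ref_seq, track, query_seq, profile, window_size) {
  L <- nchar(ref_seq); qlen <- nchar(query_seq)
  aln <- sliding_window_align(ref_seq, track, query_seq, profile, window_size)
  aln$query_string <- query_seq
  padded <- .pad_query(aln, qlen)
  rc <- seq_chars(padded$ref_aligned)
  qc <- seq_chars(padded$query_aligned)
  cols <- which(rc != "-")
  qcum <- cumsum(qc != "-")
  B <- integer(L + 1L)
  B[1L] <- 0L
  B[L + 1L] <- qlen
  if (L > 1L) {
    col <- cols[2:L]
    B[2:L] <- ifelse(col == 1L, 0L, qcum[pmax(col - 1L, 1L)])
  }
  B
}

#' Uniformize variant records across accessions
#'
#' Builds every accession's pseudo-genome, partitions the reference at
#' feature boundaries, multiple-aligns each element whose sequences differ,
#' and re-derives each accession's records from its alignment row against
#' the reference row. Accessions carrying byte-identical element sequences
#' receive byte-identical records, and each accession's new records
#' regenerate its pseudo-genome exactly.
#'
#' @param ref_genome Named character vector.
#' @param ref_annotation Annotation tibble.
#' @param per_accession_variants Named list of variant tibbles.
#' @param profile [score_profile()].
#' @param window_size Window size for element alignment.
#' @return Named list of uniformized variant tibbles (same names).
#' @export
uniformize_variants <- function(ref_genome, ref_annotation, per_accession_variants,
                                profile = default_profile(), window_size = 1000L) {
  accs <- names(per_accession_variants)
  pseudos <- lapply(per_accession_variants, function(v) apply_variants(ref_genome, v))
  part <- partition_by_feature(ref_annotation,
                               lapply(pseudos, `[[`, "shift"), ref_genome)
  # Canonical element spans: the input records' own coordinates are exactly
  # what uniformization must not trust, so element boundaries are projected
  # through a deterministic chromosome-scale zebraic alignment of each
  # pseudo-genome. Identical pseudo sequences then yield identical spans.
  bmaps <- lapply(accs, function(a) {
    maps <- list()
    for (ch in names(ref_genome)) {
      ps <- pseudos[[a]]$genome[[ch]]
      if (is.null(ps)) next
      maps[[ch]] <- .boundary_map(ref_genome[[ch]],
                                  .chrom_track(ref_annotation, ch, nchar(ref_genome[[ch]])),
                                  ps, profile, window_size)
    }
    maps
  })
  names(bmaps) <- accs
  out <- stats::setNames(vector("list", length(accs)), accs)
  for (a in accs) out[[a]] <- list()
  for (i in seq_len(nrow(part$elements))) {
    el <- part$elements[i, ]
    ref_el <- substr0(ref_genome[[el$chrom]], el$start, el$end)
    acc_span <- lapply(accs, function(a) {
      bm <- bmaps[[a]][[el$chrom]]
      if (is.null(bm)) return(NULL)
      c(bm[el$start + 1L], bm[el$end + 1L])
    })
    names(acc_span) <- accs
    acc_seq <- vapply(accs, function(a) {
      sp <- acc_span[[a]]
      if (is.null(sp) || sp[2] <= sp[1]) "" else
        substr0(pseudos[[a]]$genome[[el$chrom]], sp[1], sp[2])
    }, character(1))
    if (all(acc_seq == ref_el)) next
    # identical accession sequences share one pairwise alignment: dedupe
    uniq <- unique(acc_seq)
    msa <- msa_element(c(ref_el, uniq), el$class, profile, window_size)
    ref_row <- msa[[1]]
    for (a in accs) {
      if (acc_seq[[a]] == ref_el) next
      row <- msa[[1L + match(acc_seq[[a]], uniq)]]
      keep <- !(seq_chars(ref_row) == "-" & seq_chars(row) == "-")
      rstr <- paste(seq_chars(ref_row)[keep], collapse = "")
      qstr <- paste(seq_chars(row)[keep], collapse = "")
      vars <- recall_variants(list(ref_aligned = rstr, query_aligned = qstr),
                              chrom = el$chrom, ref_origin = el$start,
                              query_origin = acc_span[[a]][1])
      out[[a]][[el$element_id]] <- vars
    }
  }
  lapply(out, function(lst) {
    if (!length(lst)) {
      variant_tibble(tibble(chrom = character(0), pos = integer(0),
                            ref = character(0), alt = character(0)))
    } else {
      variant_tibble(bind_rows(lst))
    }
  })
}
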