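# End-to-end annotation lift-over: standard shift-based lift, ORF check,
# zebraic realignment of broken transcripts, variant recall/replacement, and
# assembly-mode projection through coarse range pairs.

#' Realign a transcript against a query region with zebraic scoring
#'
#' Builds the reference window from start codon to stop codon with its
#' feature-class track, aligns the supplied query region with the striped
#' zebraic aligner, and maps every exon/CDS boundary through the alignment
#' columns to query coordinates. The caller chooses the query region; per
#' the pipeline it is the expected locus extended by one gene length on each
#' side.
#'
#' @param tx One-row transcript tibble (reference model, reference
#'   coordinates).
#' @param ref_genome Named character vector (reference sequences).
#' @param query_seq_region Query region string.
#' @param profile [score_profile()].
#' @param params [orf_params()].
#' @param query_origin 0-based coordinate of the region start on its
#'   chromosome; returned model coordinates are absolute.
#' @param query_chrom Chromosome name for the returned model.
#' @return List with `transcript` (re-derived one-row transcript tibble, or
#'   `NULL` when unplaced), `orf` (`zl_orf_state` or `NULL`), `alignment`
#'   (`zl_alignment`), `placed` (flag). A query region that the alignment
#'   cannot cover yields `placed = FALSE`, not an error.
#' @export
realign_transcript <- function(tx, ref_genome, query_seq_region,
                               profile = default_profile(), params = orf_params(),
                               query_origin = 0L, query_chrom = tx$chrom) {
  cd <- tx$cds[[1]]
  if (!nrow(cd)) stop_contract("transcript has no CDS")
  ws <- min(cd[, 1]); we <- max(cd[, 2])
  track <- build_feature_track(tx, ws, we)
  ref_window <- substr0(ref_genome[[tx$chrom]], ws, we)
  if (nchar(query_seq_region) == 0L) {
    return(list(transcript = NULL, orf = NULL, alignment = NULL, placed = FALSE))
  }
  aln <- zsdp_align(ref_window, track, query_seq_region, profile)
  qspan <- aln$query_span
  map <- alignment_map(aln)
  if (qspan[2] - qspan[1] <= 0L || all(is.na(map))) {
    return(list(transcript = NULL, orf = NULL, alignment = aln, placed = FALSE))
  }
  left_off <- qspan[1] - 0L   # window-local offset of the aligned query start
  right_off <- qspan[2] - (we - ws)
  map_boundary <- function(b, is_end) {
    bl <- b - ws
    if (bl <= 0L) return(max(0L, bl + left_off))
    if (bl >= we - ws) return(min(nchar(query_seq_region), bl + right_off))
    iv <- map_interval(map, qspan[1], qspan[2],
                       if (is_end) 0L else bl, if (is_end) bl else we - ws)
    if (is_end) iv[2] else iv[1]
  }
  remap <- function(ivs) {
    if (!nrow(ivs)) return(ivs)
    out <- t(apply(ivs, 1L, function(iv) {
      c(map_boundary(iv[1], FALSE), map_boundary(iv[2], TRUE))
    }))
    colnames(out) <- c("start", "end")
    out <- out[out[, 2] > out[, 1], , drop = FALSE]
    out
  }
  new_cds <- remap(cd)
  if (!nrow(new_cds)) {
    return(list(transcript = NULL, orf = NULL, alignment = aln, placed = FALSE))
  }
  new_exons <- remap(tx$exons[[1]])
  if (!nrow(new_exons)) new_exons <- new_cds
  local_tx <- tibble(
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    chrom = query_chrom, strand = tx$strand,
    exons = list(new_exons), cds = list(new_cds)
  )
  region_genome <- stats::setNames(query_seq_region, query_chrom)
  orf <- check_orf_state(local_tx, region_genome, params)
  abs_tx <- local_tx
  abs_tx$exons[[1]] <- new_exons + as.integer(query_origin)
  abs_tx$cds[[1]] <- new_cds + as.integer(query_origin)
  list(transcript = abs_tx, orf = orf, alignment = aln, placed = TRUE,
       query_origin = as.integer(query_origin), ref_window = c(ws, we))
}

.report_row <- function(tx, method, orf_before, orf_after) {
  fmt <- function(o) if (is.null(o)) NA_character_ else format(o)
  ib <- if (is.null(orf_before)) NA else orf_before$intact
  ia <- if (is.null(orf_after)) NA else orf_after$intact
  fb <- fmt(orf_before); fa <- fmt(orf_after)
  tibble(transcript_id = tx$transcript_id, gene_id = tx$gene_id,
         method = method, orf_before = fb, orf_after = fa,
         intact_before = ib, intact_after = ia)
}

new_lift_result <- function(annotation, report, genome = NULL) {
  structure(list(annotation = annotation, report = report, genome = genome),
            class = "zl_lift_result")
}

#' @exportS3Method base::print
print.zl_lift_result <- function(x, ...) {
  cat("<zl_lift_result> ", nrow(x$report), " transcripts: ",
      paste(names(table(x$report$method)), table(x$report$method),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
glance.zl_lift_result <- function(x, ...) {
  tibble(
    n_transcripts = nrow(x$report),
    n_standard = sum(x$report$method == "STANDARD"),
    n_realigned = sum(x$report$method == "ZDP_REALIGNED"),
    n_hook = sum(x$report$method == "ORTHOLOGUE_HOOK"),
    n_unplaced = sum(x$report$method == "UNPLACED"),
    n_intact = sum(x$report$intact_after, na.rm = TRUE)
  )
}

#' @export
tidy.zl_lift_result <- function(x, ...) x$report

#' Plot lift-over outcome counts
#'
#' @param object A `zl_lift_result`.
#' @param ... Unused.
#' @export
autoplot.zl_lift_result <- function(object, ...) {
  d <- dplyr::count(object$report, .data$method,
                    outcome = ifelse(.data$intact_after %in% TRUE, "intact", "lost"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$method, y = .data$n, fill = .data$outcome)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "transcripts", title = "annotation lift-over outcomes") +
    ggplot2::theme_minimal()
}

#' Resequencing-mode annotation lift-over
#'
#' Builds the accession's pseudo-genome, lifts all transcripts by shift
#' counting, checks each lifted ORF against the pseudo-genome, and realigns
#' broken transcripts with the zebraic aligner (query region = lifted locus
#' extended by one gene length per side). Realignment is recorded as
#' `ZDP_REALIGNED` when it rescues the ORF; otherwise the standard-lift
#' model is retained and reported lost.
#'
#' @param annotation Annotation tibble (reference).
#' @param ref_genome Named character vector.
#' @param variants Variant tibble (one accession).
#' @param profile [score_profile()].
#' @param params [orf_params()].
#' @return `zl_lift_result` with the lifted `annotation` (pseudo-genome
#'   coordinates, `orf_state` attribute per mRNA), per-transcript `report`,
#'   and the pseudo `genome`.
#' @export
lift_annotation_resequencing <- function(annotation, ref_genome, variants,
                                         profile = default_profile(),
                                         params = orf_params()) {
  pseudo <- apply_variants(ref_genome, variants)
  lifted <- lift_annotation(annotation, pseudo$shift)
  txs_ref <- as_transcripts(annotation)
  txs_lift <- as_transcripts(lifted$annotation)
  out_rows <- list(); rep_rows <- list()
  for (i in seq_len(nrow(txs_ref))) {
    tx_ref <- txs_ref[i, ]
    tid <- tx_ref$transcript_id
    j <- which(txs_lift$transcript_id == tid)
    if (!length(j) || !nrow(txs_lift$cds[[j[1]]])) {
      rep_rows[[tid]] <- .report_row(tx_ref, "UNPLACED", NULL, NULL)
      next
    }
    tx_lift <- txs_lift[j[1], ]
    orf_std <- check_orf_state(tx_lift, pseudo$genome, params)
    if (orf_std$intact) {
      out_rows[[tid]] <- tx_lift
      rep_rows[[tid]] <- .report_row(tx_ref, "STANDARD", orf_std, orf_std)
      next
    }
    ra <- .realign_in_pseudo(tx_ref, tx_lift, ref_genome, pseudo$genome,
                             profile, params)
    if (ra$placed && ra$orf$intact) {
      out_rows[[tid]] <- ra$transcript
      rep_rows[[tid]] <- .report_row(tx_ref, "ZDP_REALIGNED", orf_std, ra$orf)
    } else {
      out_rows[[tid]] <- tx_lift
      rep_rows[[tid]] <- .report_row(tx_ref, "STANDARD", orf_std, orf_std)
    }
  }
  report <- bind_rows(rep_rows)
  ann_out <- if (length(out_rows)) {
    transcripts_to_annotation(
      bind_rows(out_rows),
      extra = tibble(transcript_id = report$transcript_id,
                     orf_state = ifelse(report$intact_after %in% TRUE, "intact", "lost"))
    )
  } else {
    lifted$annotation[0, ]
  }
  new_lift_result(ann_out, report, pseudo$genome)
}

.realign_in_pseudo <- function(tx_ref, tx_lift, ref_genome, pseudo_genome,
                               profile, params) {
  cd_ref <- tx_ref$cds[[1]]
  gene_len <- max(cd_ref[, 2]) - min(cd_ref[, 1])
  cd_lift <- tx_lift$cds[[1]]
  L <- nchar(pseudo_genome[[tx_lift$chrom]])
  qs <- max(0L, min(cd_lift[, 1]) - gene_len)
  qe <- min(L, max(cd_lift[, 2]) + gene_len)
  region <- substr0(pseudo_genome[[tx_lift$chrom]], qs, qe)
  realign_transcript(tx_ref, ref_genome, region, profile, params,
                     query_origin = qs, query_chrom = tx_lift$chrom)
}

#' Recall variants from an alignment
#'
#' Walks alignment columns and emits SNP/INS/DEL records in reference
#' coordinates. Adjacent gap columns (of either orientation) merge into one
#' INDEL record; INDELs carry a VCF-style anchor base (left anchor, or right
#' anchor for a run at reference position 0).
#'
#' @param alignment `zl_alignment`, or any list with `ref_aligned`,
#'   `query_aligned`.
#' @param chrom Chromosome name for the emitted records.
#' @param ref_origin,query_origin 0-based offsets of the aligned reference /
#'   query region on their chromosomes.
#' @return Variant tibble.
#' @export
recall_variants <- function(alignment, chrom, ref_origin = 0L, query_origin = 0L) {
  rc <- seq_chars(alignment$ref_aligned)
  qc <- seq_chars(alignment$query_aligned)
  op <- ifelse(rc == "-", "I", ifelse(qc == "-", "D", ifelse(rc == qc, "=", "X")))
  refidx <- cumsum(rc != "-")  # 1-based index of ref base at/before column
  rows <- list()
  r <- rle(op != "=")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (g in which(r$values)) {
    ks <- starts[g]:ends[g]
    if (all(op[ks] == "X")) {
      # pure substitution run: one SNP per column
      for (k in ks) {
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, pos = ref_origin + refidx[k] - 1L, ref = rc[k], alt = qc[k]
        )
      }
      next
    }
    ref_sub <- paste(rc[ks][rc[ks] != "-"], collapse = "")
    q_sub <- paste(qc[ks][qc[ks] != "-"], collapse = "")
    first_ref <- if (starts[g] > 1L) refidx[starts[g] - 1L] else 0L  # ref bases before run
    if (nchar(ref_sub) == nchar(q_sub) && nchar(ref_sub) > 0L) {
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, pos = ref_origin + first_ref, ref = ref_sub, alt = q_sub
      )
    } else if (first_ref > 0L) {
      anchor_col <- max(which(rc[seq_len(starts[g] - 1L)] != "-"))
      anchor <- rc[anchor_col]
      rows[[length(rows) + 1L]] <- tibble(
        chrom = chrom, pos = ref_origin + first_ref - 1L,
        ref = paste0(anchor, ref_sub), alt = paste0(anchor, q_sub)
      )
    } else {
      after <- which(rc != "-")
      after <- after[after > ends[g]]
      if (!length(after)) {
        if (nchar(ref_sub) == 0L || nchar(q_sub) == 0L) next  # nothing anchorable
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, pos = ref_origin, ref = ref_sub, alt = q_sub
        )
      } else {
        anchor <- rc[after[1L]]
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, pos = ref_origin + first_ref,
          ref = paste0(ref_sub, anchor), alt = paste0(q_sub, anchor)
        )
      }
    }
  }
  if (!length(rows)) {
    return(variant_tibble(tibble(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0))))
  }
  out <- arrange(bind_rows(rows), .data$pos)
  # a right-anchored run at the alignment start spans its anchor base; if the
  # following run left-anchors on that same base, fuse the two records
  merged <- list(out[1, ])
  for (k in seq_len(nrow(out))[-1]) {
    cur <- merged[[length(merged)]]
    nxt <- out[k, ]
    cur_end <- cur$pos + nchar(cur$ref)
    if (nxt$pos >= cur_end) {
      merged[[length(merged) + 1L]] <- nxt
    } else if (nxt$pos == cur_end - 1L &&
               substr(nxt$ref, 1, 1) == substr(cur$ref, nchar(cur$ref), nchar(cur$ref))) {
      cur$ref <- paste0(cur$ref, substring(nxt$ref, 2))
      cur$alt <- paste0(cur$alt, substring(nxt$alt, 2))
      merged[[length(merged)]] <- cur
    } else {
      stop_contract("recalled variant records overlap inconsistently")
    }
  }
  variant_tibble(bind_rows(merged))
}

#' Replace the variant records of a region
#'
#' Removes every record whose reference span intersects `[start, end)` on
#' `chrom` and inserts `new_variants` (which must lie inside the region).
#' The replacement is representation-only: applying the updated list yields
#' the same pseudo-genome as the old list.
#'
#' @param variants Variant tibble.
#' @param region List or tibble row with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param new_variants Variant tibble confined to the region.
#' @return Updated, sorted variant tibble.
#' @export
replace_region_variants <- function(variants, region, new_variants) {
  v <- variant_tibble(variants)
  nv <- variant_tibble(new_variants)
  if (nrow(nv)) {
    inside <- nv$chrom == region$chrom & nv$pos >= region$start &
      nv$pos + nchar(nv$ref) <= region$end
    if (!all(inside)) stop_contract("new variants outside the region")
  }
  spans <- v$pos + nchar(v$ref)
  drop <- v$chrom == region$chrom & v$pos < region$end & spans > region$start
  variant_tibble(bind_rows(v[!drop, ], nv))
}

#' Realign broken transcripts and rewrite an accession's variant records
#'
#' For every transcript rescued by zebraic realignment, recalls the variant
#' records implied by the realignment and replaces the old records of the
#' transcript's CDS window, keeping the pseudo-genome sequence byte-
#' identical (a replacement that would change it is skipped and the old
#' records kept).
#'
#' @inheritParams lift_annotation_resequencing
#' @return List with `variants` (updated tibble), `report` (lift report
#'   with a `rewritten` column), `lift` (the underlying `zl_lift_result`).
#' @export
rewrite_variants <- function(annotation, ref_genome, variants,
                             profile = default_profile(), params = orf_params()) {
  variants <- variant_tibble(variants)
  res <- lift_annotation_resequencing(annotation, ref_genome, variants,
                                      profile, params)
  txs_ref <- as_transcripts(annotation)
  out <- variants
  rewritten <- character(0)
  for (tid in res$report$transcript_id[res$report$method == "ZDP_REALIGNED"]) {
    tx_ref <- txs_ref[txs_ref$transcript_id == tid, ]
    tx_lift <- as_transcripts(res$annotation)
    tx_lift <- tx_lift[tx_lift$transcript_id == tid, ]
    ra <- .realign_in_pseudo(tx_ref, tx_lift, ref_genome, res$genome,
                             profile, params)
    if (!ra$placed) next
    ws <- ra$ref_window[1]; we <- ra$ref_window[2]
    ch <- tx_ref$chrom
    new_vars <- recall_variants(ra$alignment, ch, ref_origin = ws,
                                query_origin = ra$query_origin)
    cand <- replace_region_variants(out, list(chrom = ch, start = ws, end = we),
                                    new_vars)
    ok <- tryCatch({
      identical(apply_variants(ref_genome, cand)$genome, res$genome)
    }, error = function(e) FALSE)
    if (ok) {
      out <- cand
      rewritten <- c(rewritten, tid)
    }
  }
  report <- mutate(res$report, rewritten = .data$transcript_id %in% rewritten)
  list(variants = out, report = report, lift = res)
}

#' Assembly-mode annotation lift-over
#'
#' Projects the reference annotation onto a de novo assembly through coarse
#' range pairs: each pair is aligned base-pair-resolution with the
#' sliding-window zebraic aligner, contained transcripts are lifted through
#' the alignment columns, ORF-checked against the query genome, and broken
#' transcripts realigned with [realign_transcript()]. Transcripts contained
#' in no range pair are reported `UNPLACED`.
#'
#' @param annotation Annotation tibble (reference).
#' @param ref_genome,query_genome Named character vectors.
#' @param range_pairs Range-pair tibble (see [read_range_pairs()]).
#' @param profile [score_profile()].
#' @param params [orf_params()].
#' @param window_size Sliding-window size for the coarse alignment.
#' @return `zl_lift_result` (annotation in query coordinates).
#' @export
lift_annotation_assembly <- function(annotation, ref_genome, query_genome,
                                     range_pairs, profile = default_profile(),
                                     params = orf_params(), window_size = 1000L) {
  rp <- validate_range_pairs(as_tibble(range_pairs), ref_genome, query_genome)
  rp <- arrange(rp, .data$ref_chrom, .data$ref_start)
  for (ch in unique(rp$ref_chrom)) {
    rr <- filter(rp, .data$ref_chrom == ch)
    if (nrow(rr) > 1L && any(rr$ref_start[-1L] < rr$ref_end[-nrow(rr)])) {
      stop_validation(paste0("overlapping range pairs on reference ", ch))
    }
  }
  txs <- as_transcripts(annotation)
  out_rows <- list(); rep_rows <- list()
  assigned <- rep(NA_integer_, nrow(txs))
  spans <- t(vapply(txs$cds, function(cd) range(cd), integer(2)))
  for (r in seq_len(nrow(rp))) {
    hit <- which(txs$chrom == rp$ref_chrom[r] &
                   spans[, 1] >= rp$ref_start[r] & spans[, 2] <= rp$ref_end[r])
    assigned[hit[is.na(assigned[hit])]] <- r
  }
  aligned_pairs <- lapply(seq_len(nrow(rp)), function(r) {
    rseq <- substr0(ref_genome[[rp$ref_chrom[r]]], rp$ref_start[r], rp$ref_end[r])
    qseq <- substr0(query_genome[[rp$query_chrom[r]]], rp$query_start[r], rp$query_end[r])
    if (!rp$same_strand[r]) qseq <- revcomp(qseq)
    aln <- sliding_window_align(rseq, NULL, qseq, profile, window_size)
    list(aln = aln, map = alignment_map(aln), qlen = nchar(qseq))
  })
  for (i in seq_len(nrow(txs))) {
    tx <- txs[i, ]
    r <- assigned[i]
    if (is.na(r)) {
      rep_rows[[tx$transcript_id]] <- .report_row(tx, "UNPLACED", NULL, NULL)
      next
    }
    ap <- aligned_pairs[[r]]
    to_query <- function(iv) {
      loc <- map_interval(ap$map, ap$aln$query_span[1], ap$aln$query_span[2],
                          iv[1] - rp$ref_start[r], iv[2] - rp$ref_start[r])
      if (rp$same_strand[r]) {
        rp$query_start[r] + loc
      } else {
        sort(rp$query_start[r] + ap$qlen - rev(loc))
      }
    }
    remap <- function(ivs) {
      out <- t(apply(ivs, 1L, to_query))
      colnames(out) <- c("start", "end")
      out <- out[out[, 2] > out[, 1], , drop = FALSE]
      out[order(out[, 1]), , drop = FALSE]
    }
    new_cds <- remap(tx$cds[[1]])
    if (!nrow(new_cds)) {
      rep_rows[[tx$transcript_id]] <- .report_row(tx, "UNPLACED", NULL, NULL)
      next
    }
    new_exons <- remap(tx$exons[[1]])
    if (!nrow(new_exons)) new_exons <- new_cds
    tx_lift <- tx
    tx_lift$chrom <- rp$query_chrom[r]
    tx_lift$strand <- if (rp$same_strand[r]) tx$strand else if (tx$strand == "+") "-" else "+"
    tx_lift$exons[[1]] <- new_exons
    tx_lift$cds[[1]] <- new_cds
    orf_std <- check_orf_state(tx_lift, query_genome, params)
    if (orf_std$intact) {
      out_rows[[tx$transcript_id]] <- tx_lift
      rep_rows[[tx$transcript_id]] <- .report_row(tx, "STANDARD", orf_std, orf_std)
      next
    }
    ra <- .realign_in_assembly(tx, tx_lift, ref_genome, query_genome,
                               rp[r, ], profile, params)
    if (!is.null(ra) && ra$placed && ra$orf$intact) {
      out_rows[[tx$transcript_id]] <- ra$transcript
      rep_rows[[tx$transcript_id]] <- .report_row(tx, "ZDP_REALIGNED", orf_std, ra$orf)
    } else {
      out_rows[[tx$transcript_id]] <- tx_lift
      rep_rows[[tx$transcript_id]] <- .report_row(tx, "STANDARD", orf_std, orf_std)
    }
  }
  report <- bind_rows(rep_rows)
  ann_out <- if (length(out_rows)) {
    transcripts_to_annotation(
      bind_rows(out_rows),
      extra = tibble(
        transcript_id = report$transcript_id,
        orf_state = ifelse(report$intact_after %in% TRUE, "intact", "lost")
      )
    )
  } else {
    validate_annotation(annotation)[0, ]
  }
  new_lift_result(ann_out, report, query_genome)
}

# Realignment on the assembly: same-strand ranges align the forward query
# region; opposite-strand ranges align the reverse complement and map back.
.realign_in_assembly <- function(tx_ref, tx_lift, ref_genome, query_genome,
                                 rpr, profile, params) {
  cd_ref <- tx_ref$cds[[1]]
  gene_len <- max(cd_ref[, 2]) - min(cd_ref[, 1])
  cd_lift <- tx_lift$cds[[1]]
  ch <- tx_lift$chrom
  L <- nchar(query_genome[[ch]])
  qs <- max(0L, min(cd_lift[, 1]) - gene_len)
  qe <- min(L, max(cd_lift[, 2]) + gene_len)
  region <- substr0(query_genome[[ch]], qs, qe)
  if (rpr$same_strand) {
    return(realign_transcript(tx_ref, ref_genome, region, profile, params,
                              query_origin = qs, query_chrom = ch))
  }
  # align against the reverse complement, with a mirrored reference model
  rc_region <- revcomp(region)
  flip_tx <- tx_ref
  flip_tx$strand <- if (tx_ref$strand == "+") "-" else "+"
  ra <- realign_transcript(flip_tx, ref_genome, rc_region, profile, params,
                           query_origin = 0L, query_chrom = ch)
  if (!ra$placed) return(ra)
  W <- nchar(region)
  flip_iv <- function(ivs) {
    out <- cbind(start = qs + W - ivs[, 2], end = qs + W - ivs[, 1])
    out[order(out[, 1]), , drop = FALSE]
  }
  tx_out <- ra$transcript
  tx_out$strand <- tx_lift$strand
  tx_out$exons[[1]] <- flip_iv(ra$transcript$exons[[1]])
  tx_out$cds[[1]] <- flip_iv(ra$transcript$cds[[1]])
  orf <- check_orf_state(tx_out, query_genome, params)
  list(transcript = tx_out, orf = orf, alignment = ra$alignment, placed = TRUE)
}

#' Merge externally produced gene models (annotation cascade hook)
#'
#' Interface for the annotation cascade below zebraic realignment
#' (orthologue search, ab initio prediction, transcript assembly): candidate
#' models produced by external tools are merged by priority order — a
#' candidate replaces a lifted model only when that model's ORF is not
#' intact and the candidate's is.
#'
#' @param result `zl_lift_result`.
#' @param candidates Transcript tibble (as [as_transcripts()]) of external
#'   models on the query genome, keyed by `transcript_id`.
#' @param query_genome Named character vector.
#' @param params [orf_params()].
#' @return Updated `zl_lift_result` with `ORTHOLOGUE_HOOK` rows.
#' @export
integrate_external_models <- function(result, candidates, query_genome,
                                      params = orf_params()) {
  stopifnot(inherits(result, "zl_lift_result"))
  txs <- as_transcripts(result$annotation)
  report <- result$report
  changed <- FALSE
  for (i in seq_len(nrow(report))) {
    if (report$intact_after[i] %in% TRUE) next
    tid <- report$transcript_id[i]
    j <- which(candidates$transcript_id == tid)
    if (!length(j)) next
    cand <- candidates[j[1], ]
    orf <- check_orf_state(cand, query_genome, params)
    if (!orf$intact) next
    k <- which(txs$transcript_id == tid)
    if (length(k)) txs[k[1], ] <- cand else txs <- bind_rows(txs, cand)
    report$method[i] <- "ORTHOLOGUE_HOOK"
    report$orf_after[i] <- format(orf)
    report$intact_after[i] <- TRUE
    changed <- TRUE
  }
  if (changed) {
    result$annotation <- transcripts_to_annotation(
      txs, extra = tibble(transcript_id = report$transcript_id,
                          orf_state = ifelse(report$intact_after %in% TRUE, "intact", "lost")))
    result$report <- report
  }
  result
}
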