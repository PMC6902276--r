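# Gene-ID-anchored whole-genome alignment and base-pair-resolution variant
# calling between a reference and a de novo assembly, with lossless genome
# reconstruction from the calls.

#' Match gene orders between two annotations
#'
#' Globally aligns the per-chromosome gene-ID sequences of the two
#' annotations with a Needleman-Wunsch algorithm (identical IDs match +1,
#' differing IDs -1, gap -1); matched identical IDs become anchor pairs
#' whose gene spans (outermost start/stop-codon bases) pin the genome-wide
#' alignment. Matches breaking coordinate monotonicity are discarded, so
#' relocated genes surface later as plain INDELs.
#'
#' @param ref_annotation,query_annotation Annotation tibbles; the query
#'   annotation must carry reference gene IDs (i.e. come from lift-over).
#' @return Tibble of anchors: `gene_id`, `ref_chrom`, `ref_start`,
#'   `ref_end`, `query_chrom`, `query_start`, `query_end`. Empty annotations
#'   yield an empty tibble.
#' @export
match_gene_orders <- function(ref_annotation, query_annotation) {
  empty <- tibble(gene_id = character(0), ref_chrom = character(0),
                  ref_start = integer(0), ref_end = integer(0),
                  query_chrom = character(0), query_start = integer(0),
                  query_end = integer(0))
  rg <- .gene_table(ref_annotation)
  qg <- .gene_table(query_annotation)
  if (!nrow(rg) || !nrow(qg)) return(empty)
  out <- list()
  for (ch in unique(rg$chrom)) {
    rr <- filter(rg, .data$chrom == ch)
    qch <- .pair_chromosome(ch, rr$gene_id, qg)
    if (is.na(qch)) next
    qq <- filter(qg, .data$chrom == qch)
    hits <- nw_id_matches(rr$gene_id, qq$gene_id)
    if (!nrow(hits)) next
    anch <- tibble(
      gene_id = rr$gene_id[hits$i],
      ref_chrom = ch, ref_start = rr$start[hits$i], ref_end = rr$end[hits$i],
      query_chrom = qch, query_start = qq$start[hits$j], query_end = qq$end[hits$j]
    )
    out[[ch]] <- .enforce_colinear(anch)
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

.gene_table <- function(annotation) {
  txs <- as_transcripts(annotation)
  if (!nrow(txs)) {
    return(tibble(chrom = character(0), gene_id = character(0),
                  start = integer(0), end = integer(0)))
  }
  spans <- t(vapply(txs$cds, function(cd) {
    if (nrow(cd)) range(cd) else c(NA_integer_, NA_integer_)
  }, integer(2)))
  tibble(chrom = txs$chrom, gene_id = txs$gene_id,
         start = spans[, 1], end = spans[, 2]) |>
    filter(!is.na(.data$start)) |>
    group_by(.data$chrom, .data$gene_id) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    arrange(.data$chrom, .data$start)
}

# query chromosome sharing the most gene IDs with the reference chromosome;
# same-named chromosomes win outright when they share any gene.
.pair_chromosome <- function(ref_chrom, ref_ids, query_genes) {
  shared <- query_genes |>
    filter(.data$gene_id %in% ref_ids) |>
    dplyr::count(.data$chrom, sort = TRUE)
  if (!nrow(shared)) return(NA_character_)
  if (ref_chrom %in% shared$chrom) return(ref_chrom)
  shared$chrom[[1]]
}

# Needleman-Wunsch on ID vectors; returns matched index pairs (i, j) where
# IDs are identical. Match +1, mismatch -1, gap -1.
nw_id_matches <- function(a, b) {
  n <- length(a); m <- length(b)
  H <- matrix(0L, n + 1L, m + 1L)
  H[, 1] <- -(0:n); H[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    s <- ifelse(a[i] == b, 1L, -1L)
    for (j in seq_len(m)) {
      H[i + 1L, j + 1L] <- max(H[i, j] + s[j], H[i, j + 1L] - 1L, H[i + 1L, j] - 1L)
    }
  }
  i <- n; j <- m
  hits <- list()
  while (i > 0L && j > 0L) {
    s <- if (a[i] == b[j]) 1L else -1L
    if (H[i + 1L, j + 1L] == H[i, j] + s) {
      if (a[i] == b[j]) hits[[length(hits) + 1L]] <- c(i = i, j = j)
      i <- i - 1L; j <- j - 1L
    } else if (H[i + 1L, j + 1L] == H[i, j + 1L] - 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  if (!length(hits)) return(tibble(i = integer(0), j = integer(0)))
  m <- do.call(rbind, rev(hits))
  tibble(i = m[, "i"], j = m[, "j"])
}

# keep a strictly increasing subset (both genomes); anchors are already
# monotone in ref order, so drop any that step backwards on the query.
.enforce_colinear <- function(anchors) {
  keep <- logical(nrow(anchors))
  last_ref <- -1L; last_q <- -1L
  for (k in seq_len(nrow(anchors))) {
    if (anchors$ref_start[k] >= last_ref && anchors$query_start[k] >= last_q) {
      keep[k] <- TRUE
      last_ref <- anchors$ref_end[k]; last_q <- anchors$query_end[k]
    }
  }
  anchors[keep, ]
}

#' Split a chromosome pair into fragments between anchors
#'
#' Uses each anchor gene's span boundaries as split points on both genomes;
#' consecutive split points bound paired fragments tiling both sequences
#' (leading and trailing intervals included; empty intervals yield
#' zero-length fragments encoding pure insertions or deletions).
#'
#' @param anchors Anchor tibble for one chromosome pair (colinear).
#' @param ref_len,query_len Chromosome lengths.
#' @return Tibble of fragments: `ref_start`, `ref_end`, `query_start`,
#'   `query_end`.
#' @export
split_fragments <- function(anchors, ref_len, query_len) {
  rpts <- c(0L, as.vector(rbind(anchors$ref_start, anchors$ref_end)), ref_len)
  qpts <- c(0L, as.vector(rbind(anchors$query_start, anchors$query_end)), query_len)
  if (is.unsorted(rpts) || is.unsorted(qpts)) {
    stop_contract("anchors are not colinear")
  }
  k <- length(rpts) - 1L
  tibble(ref_start = rpts[seq_len(k)], ref_end = rpts[-1L],
         query_start = qpts[seq_len(k)], query_end = qpts[-1L])
}

# pad a fragment alignment so the query interval is fully covered:
# clipped query overhangs become insertion columns.
.pad_query <- function(aln, qlen) {
  pre <- aln$query_span[1]
  post <- qlen - aln$query_span[2]
  list(
    ref_aligned = paste0(strrep("-", pre), aln$ref_aligned, strrep("-", post)),
    query_aligned = paste0(
      substr(aln$query_string, 1L, pre),
      aln$query_aligned,
      substr(aln$query_string, qlen - post + 1L, qlen)
    )
  )
}

#' Base-pair-resolution variant calling between two assemblies
#'
#' Matches gene orders, splits both genomes into anchored fragments, aligns
#' every fragment pair with the sliding-window aligner (intergenic-class
#' scoring), and recalls one sorted, non-overlapping variant set per
#' chromosome covering every base of both genomes — structural changes such
#' as relocations decompose into plain SNP/INDEL records, so the query
#' genome can be reconstructed exactly from the calls.
#'
#' @param ref_genome,query_genome Named character vectors.
#' @param ref_annotation,query_annotation Annotation tibbles sharing gene
#'   IDs (the query annotation typically from [lift_annotation_assembly()]).
#' @param profile [score_profile()]; fragments are aligned with its
#'   `OTHER`-class scores.
#' @param window_size Sliding-window size.
#' @return Variant tibble.
#' @export
call_variants <- function(ref_genome, query_genome, ref_annotation,
                          query_annotation, profile = default_profile(),
                          window_size = 1000L) {
  anchors <- match_gene_orders(ref_annotation, query_annotation)
  rows <- list()
  for (ch in names(ref_genome)) {
    anch <- filter(anchors, .data$ref_chrom == ch)
    qch <- if (nrow(anch)) anch$query_chrom[[1]] else if (ch %in% names(query_genome)) ch else NA_character_
    if (is.na(qch)) {
      warn(paste0("no query chromosome paired with ", ch, "; skipped"))
      next
    }
    frags <- split_fragments(anch, nchar(ref_genome[[ch]]), nchar(query_genome[[qch]]))
    Ra <- character(nrow(frags)); Qa <- character(nrow(frags))
    for (f in seq_len(nrow(frags))) {
      rfrag <- substr0(ref_genome[[ch]], frags$ref_start[f], frags$ref_end[f])
      qfrag <- substr0(query_genome[[qch]], frags$query_start[f], frags$query_end[f])
      if (nchar(rfrag) == 0L && nchar(qfrag) == 0L) next
      if (nchar(rfrag) == 0L) {
        Ra[f] <- strrep("-", nchar(qfrag)); Qa[f] <- qfrag
      } else if (nchar(qfrag) == 0L) {
        Ra[f] <- rfrag; Qa[f] <- strrep("-", nchar(rfrag))
      } else {
        aln <- sliding_window_align(rfrag, NULL, qfrag, profile, window_size)
        aln$query_string <- qfrag
        padded <- .pad_query(aln, nchar(qfrag))
        Ra[f] <- padded$ref_aligned; Qa[f] <- padded$query_aligned
      }
    }
    rows[[ch]] <- recall_variants(
      list(ref_aligned = paste(Ra, collapse = ""),
           query_aligned = paste(Qa, collapse = "")),
      chrom = ch
    )
  }
  if (!length(rows)) {
    return(variant_tibble(tibble(chrom = character(0), pos = integer(0),
                                 ref = character(0), alt = character(0))))
  }
  variant_tibble(bind_rows(rows))
}

#' Reconstruct the query genome from variant calls
#'
#' Applies a [call_variants()] result to the reference; the product is
#' byte-identical to the query genome the calls were derived from.
#'
#' @param ref_genome Named character vector.
#' @param variants Variant tibble.
#' @return Named character vector of reconstructed sequences.
#' @export
reconstruct_query <- function(ref_genome, variants) {
  apply_variants(ref_genome, variants)$genome
}
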