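#' Nest an annotation tibble into per-transcript models
#'
#' Collapses the per-feature annotation rows into one row per transcript with
#' list-columns `exons` and `cds`, each a two-column integer matrix of
#' 0-based half-open `(start, end)` intervals sorted by coordinate.
#' Transcripts without exon rows inherit their CDS intervals as exons.
#'
#' @param annotation Annotation tibble (see [read_gff3()]).
#' @return Tibble with columns `transcript_id`, `gene_id`, `chrom`, `strand`,
#'   `exons`, `cds`.
#' @export
as_transcripts <- function(annotation) {
  ann <- validate_annotation(annotation)
  feats <- filter(ann, .data$type %in% c("exon", "CDS"), !is.na(.data$transcript_id))
  mrna <- filter(ann, .data$type == "mRNA")
  ids <- unique(c(mrna$transcript_id, feats$transcript_id))
  if (!length(ids)) {
    return(tibble(transcript_id = character(0), gene_id = character(0),
                  chrom = character(0), strand = character(0),
                  exons = list(), cds = list()))
  }
  rows <- lapply(ids, function(tid) {
    fx <- filter(feats, .data$transcript_id == tid)
    mr <- filter(mrna, .data$transcript_id == tid)
    chrom <- c(fx$chrom, mr$chrom)[1]
    strand <- c(fx$strand, mr$strand)[1]
    gid <- c(stats::na.omit(c(fx$gene_id, mr$gene_id)), NA_character_)[1]
    ivmat <- function(d) {
      if (!nrow(d)) return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
      d <- arrange(d, .data$start)
      cbind(start = d$start, end = d$end)
    }
    cds <- ivmat(filter(fx, .data$type == "CDS"))
    exons <- ivmat(filter(fx, .data$type == "exon"))
    if (!nrow(exons)) exons <- cds
    tibble(transcript_id = tid, gene_id = gid, chrom = chrom, strand = strand,
           exons = list(exons), cds = list(cds))
  })
  bind_rows(rows)
}

#' Rebuild an annotation tibble from transcript models
#'
#' Inverse of [as_transcripts()]: expands nested transcripts back into
#' gene/mRNA/exon/CDS rows (gene span = union of its transcripts).
#'
#' @param transcripts Transcript tibble from [as_transcripts()].
#' @param extra Optional tibble keyed by `transcript_id` whose remaining
#'   columns (e.g. `orf_state`) are attached to mRNA rows.
#' @return Annotation tibble.
#' @export
transcripts_to_annotation <- function(transcripts, extra = NULL) {
  if (is.null(transcripts) || !nrow(transcripts)) {
    return(tibble(chrom = character(0), type = character(0), start = integer(0),
                  end = integer(0), strand = character(0), gene_id = character(0),
                  transcript_id = character(0), phase = integer(0)))
  }
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    ex <- tx$exons[[1]]; cd <- tx$cds[[1]]
    span <- range(c(ex, cd))
    bind_rows(
      tibble(chrom = tx$chrom, type = "mRNA", start = span[1], end = span[2],
             strand = tx$strand, gene_id = tx$gene_id, transcript_id = tx$transcript_id,
             phase = NA_integer_),
      if (nrow(ex)) tibble(chrom = tx$chrom, type = "exon", start = ex[, 1], end = ex[, 2],
                           strand = tx$strand, gene_id = tx$gene_id,
                           transcript_id = tx$transcript_id, phase = NA_integer_),
      if (nrow(cd)) tibble(chrom = tx$chrom, type = "CDS", start = cd[, 1], end = cd[, 2],
                           strand = tx$strand, gene_id = tx$gene_id,
                           transcript_id = tx$transcript_id, phase = cds_phases(cd, tx$strand))
    )
  })
  feats <- bind_rows(rows)
  genes <- feats |>
    filter(.data$type == "mRNA") |>
    group_by(.data$chrom, .data$gene_id, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end), .groups = "drop") |>
    mutate(type = "gene", transcript_id = NA_character_, phase = NA_integer_)
  ann <- bind_rows(genes, feats)
  if (!is.null(extra)) {
    ann <- left_join(ann, extra, by = "transcript_id")
    extra_cols <- setdiff(names(extra), "transcript_id")
    for (cc in extra_cols) ann[[cc]][ann$type != "mRNA"] <- NA
  }
  validate_annotation(ann)
}

# GFF3 phase per CDS interval, in transcription order.
cds_phases <- function(cds, strand) {
  if (!nrow(cds)) return(integer(0))
  lens <- cds[, 2] - cds[, 1]
  ord <- if (strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
  ph <- integer(nrow(cds))
  acc <- 0L
  for (k in ord) {
    ph[k] <- (3L - acc %% 3L) %% 3L
    acc <- acc + lens[k]
  }
  ph
}

# CDS-internal introns of a transcript, genomic order: matrix (start, end).
cds_introns <- function(tx) {
  cd <- tx$cds[[1]]
  if (nrow(cd) < 2L) {
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = cd[-nrow(cd), 2], end = cd[-1L, 1])
}

#' Label a reference window with feature classes
#'
#' Builds the per-base feature-class track that drives zebraic scoring:
#' CDS bases are `CDS`, the first and last three coding bases (genomic
#' orientation) are `START_STOP_CODON`, the two intronic bases flanking every
#' CDS-internal intron boundary are `SPLICE_SITE`, remaining intronic bases
#' are `INTRON`, and everything else (including UTR exons) is `OTHER`.
#'
#' @param tx One-row transcript tibble (from [as_transcripts()]).
#' @param window_start,window_end 0-based half-open genomic window; must
#'   cover the transcript's CDS span.
#' @return Integer vector of feature-class codes (see [feature_classes()])
#'   with attribute `origin = window_start`.
#' @export
build_feature_track <- function(tx, window_start, window_end) {
  cd <- tx$cds[[1]]
  if (!nrow(cd)) stop_contract("transcript has no CDS")
  span <- range(cd)
  if (window_start > span[1] || window_end < span[2]) {
    stop_contract("window does not cover the transcript CDS span")
  }
  n <- window_end - window_start
  track <- integer(n)  # OTHER
  fc <- feature_classes()
  put <- function(s, e, code) {
    s <- max(s, window_start); e <- min(e, window_end)
    if (e > s) track[(s - window_start + 1L):(e - window_start)] <<- code
  }
  introns <- cds_introns(tx)
  if (nrow(introns)) {
    for (k in seq_len(nrow(introns))) put(introns[k, 1], introns[k, 2], fc[["INTRON"]])
  }
  for (k in seq_len(nrow(cd))) put(cd[k, 1], cd[k, 2], fc[["CDS"]])
  if (nrow(introns)) {
    for (k in seq_len(nrow(introns))) {
      s <- introns[k, 1]; e <- introns[k, 2]
      put(s, min(s + 2L, e), fc[["SPLICE_SITE"]])
      put(max(e - 2L, s), e, fc[["SPLICE_SITE"]])
    }
  }
  # first/last 3 coding bases in genomic order (may straddle short exons)
  coding <- unlist(lapply(seq_len(nrow(cd)), function(k) seq.int(cd[k, 1], cd[k, 2] - 1L)))
  ends <- c(utils::head(coding, 3L), utils::tail(coding, 3L))
  track[ends - window_start + 1L] <- fc[["START_STOP_CODON"]]
  attr(track, "origin") <- as.integer(window_start)
  track
}

#' Extract the coding sequence of a transcript
#'
#' Concatenates the CDS intervals in transcription order; minus-strand
#' transcripts are reverse-complemented.
#'
#' @param tx One-row transcript tibble.
#' @param genome Named character vector of sequences.
#' @return DNA string.
#' @export
extract_cds_sequence <- function(tx, genome) {
  cd <- tx$cds[[1]]
  if (!nrow(cd)) stop_contract("transcript has no CDS")
  if (!tx$chrom %in% names(genome)) {
    stop_contract(paste0("chromosome not in genome: ", tx$chrom))
  }
  chrom_seq <- genome[[tx$chrom]]
  if (min(cd) < 0L || max(cd) > nchar(chrom_seq)) {
    stop_contract("CDS interval out of chromosome bounds")
  }
  s <- paste(substring(chrom_seq, cd[, 1] + 1L, cd[, 2]), collapse = "")
  if (tx$strand == "-") revcomp(s) else s
}
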