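#' Read a GFF3 genome annotation
#'
#' Parses gene/mRNA/exon/CDS features linked by `ID`/`Parent` into a tidy
#' annotation tibble. External GFF3 coordinates are 1-based inclusive; the
#' returned tibble (and everything else inside the package) uses 0-based
#' half-open intervals. Features are sorted by chromosome and start.
#'
#' The annotation tibble has columns `chrom`, `type` (gene/mRNA/exon/CDS),
#' `start`, `end`, `strand`, `gene_id`, `transcript_id`, `phase`, and
#' optionally extra attribute columns such as `orf_state`.
#'
#' @param path GFF3 file path.
#' @return Annotation tibble.
#' @export
read_gff3 <- function(path) {
  check_file(path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop_format(paste0("malformed GFF3 in ", path, ": ", conditionMessage(e)))
  )
  if (length(gr) == 0L) stop_format(paste0("no features in GFF3 ", path))
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  keep <- type %in% c("gene", "mRNA", "transcript", "exon", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  type[type == "transcript"] <- "mRNA"
  id <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))

  known <- stats::na.omit(id)
  orphan <- parent[!is.na(parent) & !(parent %in% known)]
  if (length(orphan)) {
    stop_format(paste0("Parent references unknown feature ID: ", orphan[[1]]))
  }

  mrna_ids <- id[type == "mRNA"]
  bad_child <- which(type %in% c("exon", "CDS") & !(parent %in% mrna_ids))
  if (length(bad_child)) {
    stop_format(paste0(
      type[bad_child[[1]]], " feature at ",
      as.character(GenomicRanges::seqnames(gr))[bad_child[[1]]], ":",
      GenomicRanges::start(gr)[bad_child[[1]]],
      " has no mRNA parent (Parent=", parent[bad_child[[1]]] %||% "<missing>", ")"
    ))
  }

  gene_of_tx <- stats::setNames(parent[type == "mRNA"], mrna_ids)
  gene_id <- ifelse(type == "gene", id,
             ifelse(type == "mRNA", parent, unname(gene_of_tx[parent])))
  transcript_id <- ifelse(type == "mRNA", id,
                   ifelse(type %in% c("exon", "CDS"), parent, NA_character_))
  phase <- if ("phase" %in% names(mc)) as.integer(mc$phase) else rep(NA_integer_, length(gr))

  ann <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    type = type,
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gene_id,
    transcript_id = transcript_id,
    phase = phase
  )
  if ("orf_state" %in% names(mc)) ann$orf_state <- as.character(mc$orf_state)
  arrange(ann, .data$chrom, .data$start, .data$end)
}

#' Write an annotation tibble as GFF3
#'
#' @param annotation Annotation tibble (see [read_gff3()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  ann <- validate_annotation(annotation)
  n <- nrow(ann)
  id <- ifelse(ann$type == "gene", ann$gene_id,
        ifelse(ann$type == "mRNA", ann$transcript_id, NA_character_))
  parent <- ifelse(ann$type == "mRNA", ann$gene_id,
            ifelse(ann$type %in% c("exon", "CDS"), ann$transcript_id, NA_character_))
  gr <- GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand
  )
  mc <- S4Vectors::DataFrame(
    source = rep("zebralift", n),
    type = ann$type,
    ID = id,
    Parent = ifelse(is.na(parent), "", parent)
  )
  mc$Parent <- S4Vectors::splitAsList(parent[!is.na(parent)],
                                      factor(seq_len(n)[!is.na(parent)], levels = seq_len(n)))
  if (!is.null(ann$phase)) mc$phase <- ann$phase
  if ("orf_state" %in% names(ann)) mc$orf_state <- ann$orf_state
  S4Vectors::mcols(gr) <- mc
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @noRd
validate_annotation <- function(annotation) {
  need <- c("chrom", "type", "start", "end", "strand", "gene_id", "transcript_id")
  missing_cols <- setdiff(need, names(annotation))
  if (length(missing_cols)) {
    stop_contract(paste0("annotation is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  ann <- as_tibble(annotation)
  if (!"phase" %in% names(ann)) ann$phase <- NA_integer_
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (any(ann$end < ann$start)) stop_contract("annotation has end < start")
  arrange(ann, .data$chrom, .data$start, .data$end)
}
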