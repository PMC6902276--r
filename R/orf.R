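#' ORF-check parameters
#'
#' @param min_intron_length Minimum intron length in bp; every CDS-internal
#'   intron must be strictly longer. Default 5 bp admits the smallest
#'   biologically sensible introns.
#' @param min_cds_length Minimum CDS length in bp (strictly longer required).
#'   Default 9 bp (a start codon, one residue, a stop codon).
#' @param splice_motifs Donor/acceptor motif tibble
#'   (see [default_splice_motifs()]).
#' @return Object of class `zl_orf_params`.
#' @export
orf_params <- function(min_intron_length = 5L, min_cds_length = 9L,
                       splice_motifs = default_splice_motifs()) {
  if (min_intron_length <= 0L || min_cds_length <= 0L) {
    stop_validation("ORF length thresholds must be > 0")
  }
  structure(
    list(min_intron_length = as.integer(min_intron_length),
         min_cds_length = as.integer(min_cds_length),
         splice_motifs = splice_motifs),
    class = "zl_orf_params"
  )
}

.stop_codons <- c("TAA", "TAG", "TGA")

# Permissive IUPAC codon comparison: TRUE if some resolution of `codon`
# equals some resolution of `target` (per-position base-set intersection).
codon_can_be <- function(codon, target) {
  a <- seq_chars(codon); b <- seq_chars(target)
  length(a) == length(b) && all(bases_intersect(a, b))
}

codon_can_be_stop <- function(codon) {
  any(vapply(.stop_codons, function(s) codon_can_be(codon, s), logical(1)))
}

# Strict semantics for premature stops: TRUE only if EVERY resolution of the
# codon is a stop codon ("TRA" is; "NNN" is not).
codon_certainly_stop <- function(codon) {
  sets <- lapply(seq_chars(codon), function(ch) {
    m <- iupac_mask(ch)
    if (m == 0L) return(character(0))
    c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) > 0L]
  })
  if (any(lengths(sets) == 0L)) return(FALSE)
  for (b1 in sets[[1]]) for (b2 in sets[[2]]) for (b3 in sets[[3]]) {
    if (!paste0(b1, b2, b3) %in% .stop_codons) return(FALSE)
  }
  TRUE
}

# Permissive motif match, IUPAC on both sides.
motif_matches <- function(obs, motif) {
  a <- seq_chars(obs); b <- seq_chars(motif)
  length(a) == 2L && length(b) == 2L && all(bases_intersect(a, b))
}

#' Check the ORF state of a transcript
#'
#' Evaluates seven integrity rules against the genome sequence and reports
#' every failure (rules are not short-circuited):
#' \enumerate{
#'   \item `SPLICE_MOTIF`: each CDS-internal intron's terminal dinucleotides
#'     (donor/acceptor, read on the coding strand) match some motif pair;
#'   \item `MIN_INTRON`: every CDS-internal intron is longer than
#'     `min_intron_length`;
#'   \item `MIN_CDS_LEN`: the CDS is longer than `min_cds_length`;
#'   \item `FRAME`: CDS length is divisible by 3;
#'   \item `PREMATURE_STOP`: no in-frame stop codon before the final codon;
#'   \item `NO_END_STOP`: the final codon is a stop codon;
#'   \item `NO_START`: the first codon is ATG.
#' }
#'
#' IUPAC ambiguity codes are handled by base-set intersection: motif, start
#' and terminal-stop comparisons succeed if any resolution matches, while a
#' codon only counts as a premature stop if every resolution is a stop.
#'
#' @param tx One-row transcript tibble (from [as_transcripts()]).
#' @param genome Named character vector of sequences.
#' @param params [orf_params()].
#' @return Object of class `zl_orf_state`: list with `intact` (flag) and
#'   `failed_rules` (character vector).
#' @export
#' @examples
#' genome <- c(c1 = "ATGGCCTAA")
#' tx <- tibble::tibble(
#'   transcript_id = "t1", gene_id = "g1", chrom = "c1", strand = "+",
#'   exons = list(cbind(start = 0L, end = 9L)), cds = list(cbind(start = 0L, end = 9L))
#' )
#' check_orf_state(tx, genome, orf_params(min_cds_length = 3))
check_orf_state <- function(tx, genome, params = orf_params()) {
  cds_seq <- extract_cds_sequence(tx, genome)  # contract-errors on empty CDS
  failed <- character(0)

  introns <- cds_introns(tx)
  chrom_seq <- genome[[tx$chrom]]
  if (nrow(introns)) {
    lens <- introns[, 2] - introns[, 1]
    if (any(lens <= params$min_intron_length)) failed <- c(failed, "MIN_INTRON")
    ok <- vapply(seq_len(nrow(introns)), function(k) {
      s <- introns[k, 1]; e <- introns[k, 2]
      if (e - s < 2L) return(FALSE)
      left <- substr0(chrom_seq, s, s + 2L)
      right <- substr0(chrom_seq, e - 2L, e)
      if (tx$strand == "-") {
        donor <- revcomp(right); acceptor <- revcomp(left)
      } else {
        donor <- left; acceptor <- right
      }
      any(vapply(seq_len(nrow(params$splice_motifs)), function(j) {
        motif_matches(donor, params$splice_motifs$donor[[j]]) &&
          motif_matches(acceptor, params$splice_motifs$acceptor[[j]])
      }, logical(1)))
    }, logical(1))
    if (!all(ok)) failed <- c(failed, "SPLICE_MOTIF")
  }

  L <- nchar(cds_seq)
  if (L <= params$min_cds_length) failed <- c(failed, "MIN_CDS_LEN")
  if (L %% 3L != 0L) failed <- c(failed, "FRAME")

  n_codons <- L %/% 3L
  if (n_codons >= 1L) {
    codons <- substring(cds_seq, seq.int(1L, by = 3L, length.out = n_codons),
                        seq.int(3L, by = 3L, length.out = n_codons))
    if (n_codons > 1L &&
        any(vapply(codons[-n_codons], codon_certainly_stop, logical(1)))) {
      failed <- c(failed, "PREMATURE_STOP")
    }
    if (!codon_can_be_stop(codons[n_codons])) failed <- c(failed, "NO_END_STOP")
    if (!codon_can_be(codons[1L], "ATG")) failed <- c(failed, "NO_START")
  } else {
    failed <- c(failed, "NO_END_STOP", "NO_START")
  }

  new_orf_state(failed)
}

new_orf_state <- function(failed_rules) {
  failed_rules <- unique(failed_rules)
  structure(list(intact = length(failed_rules) == 0L, failed_rules = failed_rules),
            class = "zl_orf_state")
}

#' @exportS3Method base::format
format.zl_orf_state <- function(x, ...) {
  if (x$intact) "intact" else paste0("lost[", paste(x$failed_rules, collapse = ","), "]")
}

#' @exportS3Method base::print
print.zl_orf_state <- function(x, ...) {
  cat("<orf_state> ", format(x), "\n", sep = "")
  invisible(x)
}

#' ORF-check every transcript of an annotation
#'
#' @param annotation Annotation tibble.
#' @param genome Named character vector of sequences.
#' @param params [orf_params()].
#' @return Tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `intact`, `failed_rules` (comma-joined, `""` when intact).
#' @export
orf_check_annotation <- function(annotation, genome, params = orf_params()) {
  txs <- as_transcripts(annotation)
  rows <- lapply(seq_len(nrow(txs)), function(i) {
    st <- check_orf_state(txs[i, ], genome, params)
    tibble(transcript_id = txs$transcript_id[[i]], gene_id = txs$gene_id[[i]],
           intact = st$intact, failed_rules = paste(st$failed_rules, collapse = ","))
  })
  bind_rows(rows)
}
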