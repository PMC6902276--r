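# Independent oracles and small builders shared across tests.

suppressPackageStartupMessages(library(dplyr))
suppressPackageStartupMessages(library(tibble))

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# One-row transcript tibble from interval matrices.
make_tx <- function(chrom = "c1", strand = "+", exons, cds = exons,
                    id = "t1", gene = "g1") {
  iv <- function(m) {
    m <- matrix(as.integer(m), ncol = 2L)
    colnames(m) <- c("start", "end")
    m
  }
  tibble(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
         exons = list(iv(exons)), cds = list(iv(cds)))
}

# Exhaustive enumeration over all monotone alignment paths under zebraic
# scoring: free start on row 0 or column 0, candidate score whenever the
# whole reference is consumed, run-based affine gap costs (deletions charged
# per consumed reference column's class, insertions with the class of the
# last consumed reference column). Feasible for lengths <= 8.
enum_best_score <- function(ref, query, track, profile) {
  mat <- unclass(profile)
  r <- strsplit(ref, "")[[1]]; q <- strsplit(query, "")[[1]]
  n <- length(r); m <- length(q)
  best <- -Inf
  rec <- function(i, j, sc, last) {
    if (j == n && sc > best) best <<- sc
    if (j < n) {
      cl <- track[j + 1] + 1
      if (i < m) {
        s <- if (q[i + 1] == r[j + 1]) mat[cl, "match"] else mat[cl, "mismatch"]
        rec(i + 1, j + 1, sc + s, "M")
      }
      pen <- if (last == "D") mat[cl, "gap_ext"] else mat[cl, "gap_open"]
      rec(i, j + 1, sc - pen, "D")
    }
    if (i < m && j >= 1) {
      cl <- track[j] + 1
      pen <- if (last == "I") mat[cl, "gap_ext"] else mat[cl, "gap_open"]
      rec(i + 1, j, sc - pen, "I")
    }
  }
  for (i0 in 0:m) rec(i0, 0, 0, "")
  if (n >= 1) for (j0 in 1:n) rec(0, j0, 0, "")
  best
}

# Textbook semi-global affine-gap aligner (Gotoh, full matrices, uniform
# scores, free leading overhangs, best cell of the last reference column).
gotoh_semiglobal <- function(ref, query, match, mismatch, gap_open, gap_ext) {
  r <- strsplit(ref, "")[[1]]; q <- strsplit(query, "")[[1]]
  n <- length(r); m <- length(q)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap consuming reference columns
  F <- matrix(NEG, m + 1, n + 1)  # gap consuming query rows
  for (j in 1:n) {
    for (i in 1:m) {
      E[i + 1, j + 1] <- max(E[i + 1, j] - gap_ext, H[i + 1, j] - gap_open)
      F[i + 1, j + 1] <- max(F[i, j + 1] - gap_ext, H[i, j + 1] - gap_open)
      M <- H[i, j] + if (q[i] == r[j]) match else mismatch
      H[i + 1, j + 1] <- max(M, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  max(H[, n + 1])
}

# random admissible zebraic profile (ordering warnings suppressed: random
# draws need not respect the coding-over-intron weighting)
random_profile <- function() {
  suppressWarnings(score_profile(
    intron = c(sample(1:4, 1), -sample(1:4, 1), sample(4:8, 1), sample(1:3, 1)),
    cds = c(sample(2:8, 1), -sample(2:8, 1), sample(8:16, 1), sample(2:5, 1)),
    splice = c(sample(8:14, 1), -sample(8:14, 1), sample(16:30, 1), sample(10:16, 1)),
    startstop = c(sample(8:14, 1), -sample(8:14, 1), sample(16:30, 1), sample(10:16, 1))
  ))
}

empty_variants <- function() {
  tibble(chrom = character(0), pos = integer(0), ref = character(0), alt = character(0))
}

# fixture with engineered ambiguous-INDEL loci on plus-strand multi-exon
# genes; returns genome, annotation and one locus descriptor per row.
ambiguous_fixture <- function(seed, n_loci = 4L, n_genes = max(6L, n_loci + 2L),
                              chromosome_length = 2500L * n_genes) {
  spec <- fixture_spec(seed = seed, chromosome_length = chromosome_length,
                       n_genes = n_genes, exons_per_gene = c(2L, 3L),
                       intron_length = c(60L, 140L), minus_strand_frac = 0)
  fx <- generate_genome_with_annotation(spec)
  txs <- as_transcripts(fx$annotation)
  txs <- txs[vapply(txs$cds, nrow, integer(1)) >= 2L, ]
  stopifnot(nrow(txs) >= n_loci)
  genome <- fx$genome
  loci <- list()
  for (k in seq_len(n_loci)) {
    am <- plant_ambiguous_indel_locus(genome, txs[k, ])
    genome <- am$genome
    loci[[k]] <- am$locus
  }
  list(genome = genome, annotation = fx$annotation, loci = bind_rows(loci))
}

locus_record <- function(loci, which = c("crossing", "intronic")) {
  which <- match.arg(which)
  if (which == "crossing") {
    tibble(chrom = loci$chrom, pos = loci$pos_crossing,
           ref = loci$ref_crossing, alt = loci$alt_crossing)
  } else {
    tibble(chrom = loci$chrom, pos = loci$pos_intronic,
           ref = loci$ref_intronic, alt = loci$alt_intronic)
  }
}

all_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}
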