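test_that("realignment against an identical region reproduces the model", {
  spec <- fixture_spec(seed = 61, chromosome_length = 8000, n_genes = 3,
                       exons_per_gene = c(2, 2))
  fx <- generate_genome_with_annotation(spec)
  txs <- as_transcripts(fx$annotation)
  tx <- txs[1, ]
  cd <- tx$cds[[1]]
  ws <- min(cd); we <- max(cd)
  gene_len <- we - ws
  qs <- max(0L, ws - gene_len); qe <- min(nchar(fx$genome[[tx$chrom]]), we + gene_len)
  region <- substr(fx$genome[[tx$chrom]], qs + 1, qe)
  ra <- realign_transcript(tx, fx$genome, region, query_origin = qs)
  expect_true(ra$placed)
  expect_true(ra$orf$intact)
  expect_equal(ra$transcript$cds[[1]], cd)
  expect_equal(ra$transcript$exons[[1]], tx$exons[[1]])
})

test_that("realignment follows an intronic insertion downstream", {
  spec <- fixture_spec(seed = 62, chromosome_length = 8000, n_genes = 3,
                       exons_per_gene = c(2, 2), minus_strand_frac = 0)
  fx <- generate_genome_with_annotation(spec)
  txs <- as_transcripts(fx$annotation)
  tx <- txs[1, ]
  cd <- tx$cds[[1]]
  mid <- as.integer((cd[1, 2] + cd[2, 1]) %/% 2)
  a <- substr(fx$genome[[tx$chrom]], mid + 1, mid + 1)
  ins <- tibble(chrom = tx$chrom, pos = mid, ref = a, alt = paste0(a, "TTT"))
  pseudo <- apply_variants(fx$genome, ins)$genome
  ws <- min(cd); we <- max(cd)
  gene_len <- we - ws
  qs <- max(0L, ws - gene_len)
  region <- substr(pseudo[[tx$chrom]], qs + 1, min(nchar(pseudo[[tx$chrom]]), we + gene_len + 3))
  ra <- realign_transcript(tx, fx$genome, region, query_origin = qs)
  expect_true(ra$placed && ra$orf$intact)
  expect_equal(ra$transcript$cds[[1]][1, ], cd[1, ])
  expect_equal(ra$transcript$cds[[1]][2, ], cd[2, ] + 3L)
})

test_that("empty-variant lift-over is the identity with all transcripts intact", {
  spec <- fixture_spec(seed = 63, chromosome_length = 9000, n_genes = 4)
  fx <- generate_genome_with_annotation(spec)
  res <- lift_annotation_resequencing(fx$annotation, fx$genome, empty_variants())
  expect_true(all(res$report$method == "STANDARD"))
  expect_true(all(res$report$intact_after))
  cols <- c("chrom", "type", "start", "end", "strand", "gene_id", "transcript_id")
  expect_equal(as.data.frame(res$annotation[cols]),
               as.data.frame(fx$annotation[cols]))
})

test_that("a synonymous coding SNP lifts as STANDARD and intact", {
  spec <- fixture_spec(seed = 64, chromosome_length = 8000, n_genes = 3,
                       minus_strand_frac = 0)
  fx <- generate_genome_with_annotation(spec)
  txs <- as_transcripts(fx$annotation)
  tx <- txs[1, ]
  cd <- tx$cds[[1]]
  # third base of a GCx (alanine) codon can switch freely; find one
  cds_seq <- extract_cds_sequence(tx, fx$genome)
  k <- regexpr("GCA", cds_seq)[1]
  expect_gte(k, 1)  # an alanine codon is present in this fixture
  # map CDS offset to genomic position (plus strand, maybe multi-exon)
  coding <- unlist(lapply(seq_len(nrow(cd)), function(i) seq.int(cd[i, 1], cd[i, 2] - 1L)))
  gpos <- coding[k + 2L]
  v <- tibble(chrom = tx$chrom, pos = gpos, ref = "A", alt = "G")
  res <- lift_annotation_resequencing(fx$annotation, fx$genome, v)
  row <- res$report[res$report$transcript_id == tx$transcript_id, ]
  expect_equal(row$method, "STANDARD")
  expect_true(row$intact_after)
})

test_that("ambiguously placed INDELs are rescued by zebraic realignment", {
  fxa <- ambiguous_fixture(seed = 65, n_loci = 4, n_genes = 8)
  crossing <- locus_record(fxa$loci, "crossing")
  res <- lift_annotation_resequencing(fxa$annotation, fxa$genome, crossing)
  hit <- res$report$transcript_id %in% fxa$loci$transcript_id
  expect_true(all(res$report$method[hit] == "ZDP_REALIGNED"))
  expect_true(all(!res$report$intact_before[hit]))
  expect_true(all(res$report$intact_after[hit]))
  expect_true(all(res$report$method[!hit] == "STANDARD"))
  expect_true(all(res$report$intact_after[!hit]))
})

test_that("recalled variants mirror the alignment's edits", {
  ident <- list(ref_aligned = "ACGT", query_aligned = "ACGT")
  expect_equal(nrow(recall_variants(ident, "c1")), 0L)

  one_snp <- list(ref_aligned = "ACGTACGTAC", query_aligned = "ACGTACGAAC")
  v <- recall_variants(one_snp, "c1")
  expect_equal(nrow(v), 1L)
  expect_equal(v$pos, 7L)
  expect_equal(v$kind, "SNP")

  ins <- recall_variants(list(ref_aligned = "AC--GT", query_aligned = "ACTTGT"), "c1")
  expect_equal(nrow(ins), 1L)
  expect_equal(ins$pos, 1L)
  expect_equal(ins$ref, "C")
  expect_equal(ins$alt, "CTT")

  # adjacent gap columns merge into one record
  mix <- recall_variants(list(ref_aligned = "ACG--T", query_aligned = "A--CGT"), "c1")
  expect_equal(nrow(mix), 1L)
})

test_that("region variant replacement preserves the implied pseudo-genome", {
  g <- c(c1 = "ACGTACGTACGTACGTACGT")
  old <- variant_tibble(tibble(chrom = "c1", pos = c(2L, 10L),
                               ref = c("G", "G"), alt = c("T", "GAA")))
  same <- replace_region_variants(old, list(chrom = "c1", start = 0L, end = 20L), old)
  expect_equal(as.data.frame(same), as.data.frame(old))

  trimmed <- replace_region_variants(old, list(chrom = "c1", start = 8L, end = 16L),
                                     empty_variants())
  expect_equal(nrow(trimmed), 1L)
  expect_equal(trimmed$pos, 2L)

  expect_error(
    replace_region_variants(old, list(chrom = "c1", start = 0L, end = 5L),
                            tibble(chrom = "c1", pos = 10L, ref = "G", alt = "C")),
    class = "zebralift_contract_error"
  )
})

test_that("variant rewriting re-places INDELs without changing the haplotype", {
  fxa <- ambiguous_fixture(seed = 66, n_loci = 2, n_genes = 5)
  crossing <- locus_record(fxa$loci, "crossing")
  rw <- rewrite_variants(fxa$annotation, fxa$genome, crossing)
  expect_true(any(rw$report$rewritten))
  # same pseudo-genome, different record coordinates
  expect_identical(apply_variants(fxa$genome, rw$variants)$genome,
                   apply_variants(fxa$genome, crossing)$genome)
  moved <- rw$variants[rw$variants$chrom == fxa$loci$chrom[1], ]
  expect_false(any(moved$pos %in% crossing$pos[rw$report$rewritten[
    match(fxa$loci$transcript_id, rw$report$transcript_id)]]))
})

test_that("assembly-mode lift with an identical query keeps everything standard", {
  spec <- fixture_spec(seed = 67, chromosome_length = 9000, n_genes = 4)
  fx <- generate_genome_with_annotation(spec)
  rp <- tibble(ref_chrom = "chr1", ref_start = 0L, ref_end = 9000L,
               query_chrom = "chr1", query_start = 0L, query_end = 9000L,
               same_strand = TRUE)
  res <- lift_annotation_assembly(fx$annotation, fx$genome, fx$genome, rp)
  expect_true(all(res$report$method == "STANDARD"))
  expect_true(all(res$report$intact_after))
  txs <- as_transcripts(fx$annotation)
  txs2 <- as_transcripts(res$annotation)
  for (i in seq_len(nrow(txs))) {
    j <- which(txs2$transcript_id == txs$transcript_id[i])
    expect_equal(txs2$cds[[j]], txs$cds[[i]])
  }
})

test_that("assembly-mode lift places genes across planted INDELs and realigns ambiguity", {
  fxa <- ambiguous_fixture(seed = 68, n_loci = 2, n_genes = 6)
  # the query assembly is the pseudo-genome carrying the ambiguous deletions
  query <- apply_variants(fxa$genome, locus_record(fxa$loci, "intronic"))$genome
  L <- nchar(fxa$genome[["chr1"]])
  rp <- tibble(ref_chrom = "chr1", ref_start = 0L, ref_end = L,
               query_chrom = "chr1", query_start = 0L, query_end = nchar(query[["chr1"]]),
               same_strand = TRUE)
  res <- lift_annotation_assembly(fxa$annotation, fxa$genome, query, rp,
                                  window_size = 2000L)
  expect_true(all(res$report$method %in% c("STANDARD", "ZDP_REALIGNED")))
  expect_true(all(res$report$intact_after))

  # a transcript on a chromosome absent from the range pairs is UNPLACED
  ann2 <- fxa$annotation
  ann2$chrom[ann2$gene_id == ann2$gene_id[1]] <- "chrX"
  g2 <- c(fxa$genome, chrX = fxa$genome[["chr1"]])
  q2 <- c(query, chrX = query[["chr1"]])
  res2 <- lift_annotation_assembly(ann2, g2, q2, rp, window_size = 2000L)
  expect_true("UNPLACED" %in% res2$report$method)
})

test_that("opposite-strand range pairs map models onto the reverse complement", {
  spec <- fixture_spec(seed = 69, chromosome_length = 6000, n_genes = 2)
  fx <- generate_genome_with_annotation(spec)
  L <- nchar(fx$genome[["chr1"]])
  query <- c(chr1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fx$genome[["chr1"]]))))
  rp <- tibble(ref_chrom = "chr1", ref_start = 0L, ref_end = L,
               query_chrom = "chr1", query_start = 0L, query_end = L,
               same_strand = FALSE)
  res <- lift_annotation_assembly(fx$annotation, fx$genome, query, rp)
  expect_true(all(res$report$intact_after))
  txs <- as_transcripts(fx$annotation)
  txs2 <- as_transcripts(res$annotation)
  for (i in seq_len(nrow(txs))) {
    j <- which(txs2$transcript_id == txs$transcript_id[i])
    expect_equal(extract_cds_sequence(txs2[j, ], query),
                 extract_cds_sequence(txs[i, ], fx$genome))
  }
})

test_that("external candidate models fill in through the cascade hook", {
  fxa <- ambiguous_fixture(seed = 70, n_loci = 1, n_genes = 4)
  crossing <- locus_record(fxa$loci, "crossing")
  res <- lift_annotation_resequencing(fxa$annotation, fxa$genome, crossing)
  # force the rescued transcript back to its broken standard model
  tid <- fxa$loci$transcript_id[1]
  rescued <- as_transcripts(res$annotation)
  cand <- rescued[rescued$transcript_id == tid, ]
  res$report$method[res$report$transcript_id == tid] <- "STANDARD"
  res$report$intact_after[res$report$transcript_id == tid] <- FALSE
  merged <- integrate_external_models(res, cand, res$genome)
  row <- merged$report[merged$report$transcript_id == tid, ]
  expect_equal(row$method, "ORTHOLOGUE_HOOK")
  expect_true(row$intact_after)
})
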