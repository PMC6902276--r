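test_that("FASTA reading uppercases, handles multiline records and rejects bad input", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  expect_equal(read_fasta(f), c(c1 = "ACGT"))

  writeLines(c(">c1", "ac", "gt", ">c2", "NNN"), f)
  expect_equal(read_fasta(f), c(c1 = "ACGT", c2 = "NNN"))

  writeLines(character(0), f)
  expect_error(read_fasta(f), class = "zebralift_format_error")

  writeLines(c("not a fasta", "at all"), f)
  expect_error(read_fasta(f), class = "zebralift_format_error")
})

test_that("FASTA round trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  g <- c(chr1 = "ACGTNRYACGT", chr2 = strrep("ACGT", 40))
  write_fasta(g, f)
  expect_equal(read_fasta(f), g)
})

test_that("GFF3 parsing builds transcript models and validates parent links", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t11\t40\t.\t+\t.\tID=g1",
    "c1\ttest\tmRNA\t11\t40\t.\t+\t.\tID=g1.1;Parent=g1",
    "c1\ttest\texon\t11\t40\t.\t+\t.\tParent=g1.1",
    "c1\ttest\tCDS\t11\t40\t.\t+\t0\tParent=g1.1"
  ), f)
  ann <- read_gff3(f)
  txs <- as_transcripts(ann)
  expect_equal(nrow(txs), 1L)
  expect_equal(txs$cds[[1]], cbind(start = 10L, end = 40L))
  expect_equal(txs$exons[[1]], cbind(start = 10L, end = 40L))

  # two-exon minus-strand mRNA: exons stored in genomic order, strand kept
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tgene\t11\t100\t.\t-\t.\tID=g1",
    "c1\ttest\tmRNA\t11\t100\t.\t-\t.\tID=g1.1;Parent=g1",
    "c1\ttest\texon\t61\t100\t.\t-\t.\tParent=g1.1",
    "c1\ttest\texon\t11\t40\t.\t-\t.\tParent=g1.1",
    "c1\ttest\tCDS\t61\t100\t.\t-\t0\tParent=g1.1",
    "c1\ttest\tCDS\t11\t40\t.\t-\t2\tParent=g1.1"
  ), f)
  txs <- as_transcripts(read_gff3(f))
  expect_equal(txs$strand, "-")
  expect_equal(txs$exons[[1]][, "start"], c(10L, 60L))

  # orphan Parent reference names the offending ID
  writeLines(c(
    "##gff-version 3",
    "c1\ttest\tCDS\t11\t40\t.\t+\t0\tID=x;Parent=ghost"
  ), f)
  expect_error(read_gff3(f), "ghost", class = "zebralift_format_error")
})

test_that("GFF3 writing round trips annotation tibbles", {
  spec <- fixture_spec(seed = 21, chromosome_length = 8000, n_genes = 2,
                       exons_per_gene = c(2, 3))
  fx <- generate_genome_with_annotation(spec)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(fx$annotation, f)
  back <- read_gff3(f)
  cols <- c("chrom", "type", "start", "end", "strand", "gene_id", "transcript_id")
  expect_equal(as.data.frame(back[cols]), as.data.frame(fx$annotation[cols]))
})

test_that("VCF reading splits multi-allelic records and validates REF alleles", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "c1\t5\t.\tA\tT\t.\t.\t.",
    "c1\t9\t.\tG\tGA,GTT\t.\t.\t."
  ), f)
  v <- read_vcf(f)
  expect_equal(nrow(v), 3L)
  expect_equal(v$pos, c(4L, 8L, 8L))
  expect_equal(v$kind, c("SNP", "INS", "INS"))

  genome <- c(c1 = "CCCCACCCGCC")
  expect_silent(read_vcf(f, genome))
  genome_bad <- c(c1 = "CCCCTCCCGCC")
  expect_error(read_vcf(f, genome_bad), class = "zebralift_validation_error")

  writeLines(character(0), f)
  expect_error(read_vcf(f), class = "zebralift_format_error")
})

test_that("VCF write/read round trips variant records", {
  genome <- c(c1 = "ACGTACGTACGTACGT")
  v <- variant_tibble(tibble(
    chrom = "c1", pos = c(1L, 5L, 9L),
    ref = c("C", "C", "CGTA"), alt = c("T", "CAA", "C")
  ))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, f, genome)
  expect_equal(as.data.frame(read_vcf(f, genome)), as.data.frame(v))
})

test_that("splice-motif files parse, fold case and reject malformed motifs", {
  f <- withr::local_tempfile()
  writeLines(c("GT AG", "GC AG", "AT AC"), f)
  expect_equal(read_splice_motifs(f), default_splice_motifs())

  shipped <- system.file("extdata", "splice_sites.txt", package = "zebralift")
  expect_equal(read_splice_motifs(shipped), default_splice_motifs())

  writeLines("gt ag", f)
  expect_equal(read_splice_motifs(f), tibble(donor = "GT", acceptor = "AG"))

  writeLines("GTX AG", f)
  expect_error(read_splice_motifs(f), class = "zebralift_format_error")
  writeLines(character(0), f)
  expect_error(read_splice_motifs(f), class = "zebralift_format_error")
})

test_that("range-pair files round trip and validate coordinates", {
  rp <- tibble(ref_chrom = "c1", ref_start = 0L, ref_end = 100L,
               query_chrom = "s1", query_start = 10L, query_end = 120L,
               same_strand = TRUE)
  f <- withr::local_tempfile()
  write_range_pairs(rp, f)
  expect_equal(as.data.frame(read_range_pairs(f)), as.data.frame(rp))

  writeLines("c1 1 100 s1 11", f)
  expect_error(read_range_pairs(f), class = "zebralift_format_error")
  writeLines("c1 100 1 s1 11 120 +", f)
  expect_error(read_range_pairs(f), class = "zebralift_validation_error")
})

test_that("scoring-profile config round trips and flags inverted weighting", {
  f <- withr::local_tempfile()
  write_score_profile(default_profile(), f)
  expect_equal(read_score_profile(f), default_profile())

  writeLines(c("cds.match=6", "cds.gap_open=40"), f)
  p <- read_score_profile(f)
  expect_equal(p["CDS", "gap_open"], 40L)
  expect_equal(p["INTRON", ], default_profile()["INTRON", ])

  writeLines("cds.bogus=1", f)
  expect_error(read_score_profile(f), class = "zebralift_format_error")

  expect_warning(score_profile(cds = c(2, -2, 4, 1), splice = c(1, -1, 2, 1)),
                 class = "zebralift_profile_order_warning")
})
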