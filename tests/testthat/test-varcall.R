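# tiny annotation with the given gene-ID order, one single-exon gene each
order_annotation <- function(ids, chrom = "chr1", gap = 200L, len = 90L) {
  rows <- lapply(seq_along(ids), function(k) {
    s <- gap * k + (k - 1L) * len
    make_tx(chrom = chrom, exons = c(s, s + len),
            id = paste0(ids[k], ".1"), gene = ids[k])
  })
  transcripts_to_annotation(bind_rows(rows))
}

test_that("gene-order matching aligns identical IDs and keeps colinear anchors", {
  a3 <- order_annotation(c("A", "B", "C"))
  m <- match_gene_orders(a3, a3)
  expect_equal(m$gene_id, c("A", "B", "C"))
  expect_equal(m$ref_start, m$query_start)

  ab <- match_gene_orders(a3, order_annotation(c("A", "C")))
  expect_equal(ab$gene_id, c("A", "C"))

  shuffled <- match_gene_orders(order_annotation(c("A", "B", "C", "D")),
                                order_annotation(c("A", "C", "B", "D")))
  expect_true(all(c("A", "D") %in% shuffled$gene_id))
  expect_equal(nrow(shuffled), 3L)  # A, D, plus exactly one of B/C
  expect_equal(length(intersect(shuffled$gene_id, c("B", "C"))), 1L)
  # anchors stay colinear
  expect_false(is.unsorted(shuffled$ref_start))
  expect_false(is.unsorted(shuffled$query_start))

  empty <- order_annotation(character(0))
  expect_equal(nrow(match_gene_orders(a3, a3[0, ])), 0L)
})

test_that("fragments tile both genomes between anchors", {
  none <- split_fragments(match_gene_orders(order_annotation("Z"), order_annotation("Y")),
                          1000L, 1200L)
  expect_equal(nrow(none), 1L)
  expect_equal(none$ref_end, 1000L)
  expect_equal(none$query_end, 1200L)

  a2 <- order_annotation(c("A", "B"))
  anch <- match_gene_orders(a2, a2)
  fr <- split_fragments(anch, 1000L, 1000L)
  # leading, gene A, inter, gene B, trailing
  expect_equal(nrow(fr), 5L)
  expect_equal(fr$ref_start[1], 0L)
  expect_equal(fr$ref_end[nrow(fr)], 1000L)
  expect_true(all(fr$ref_start[-1] == fr$ref_end[-nrow(fr)]))
  expect_true(all(fr$query_start[-1] == fr$query_end[-nrow(fr)]))

  # zero-length reference gap with query content encodes a pure insertion
  anch2 <- anch
  anch2$query_start <- anch2$query_start + c(0L, 500L)
  anch2$query_end <- anch2$query_end + c(0L, 500L)
  fr2 <- split_fragments(anch2, 1000L, 1500L)
  ins <- fr2[fr2$ref_end - fr2$ref_start < fr2$query_end - fr2$query_start, ]
  expect_true(any(ins$query_end - ins$query_start >= 500L))

  bad <- anch
  bad$query_start <- rev(bad$query_start); bad$query_end <- rev(bad$query_end)
  expect_error(split_fragments(bad, 1000L, 1000L), class = "zebralift_contract_error")
})

test_that("variant calling on an identical assembly yields no records", {
  spec <- fixture_spec(seed = 71, chromosome_length = 8000, n_genes = 4)
  fx <- generate_genome_with_annotation(spec)
  v <- call_variants(fx$genome, fx$genome, fx$annotation, fx$annotation,
                     window_size = 600)
  expect_equal(nrow(v), 0L)
})

test_that("planted variants round trip through calling and reconstruction", {
  spec <- fixture_spec(seed = 72, chromosome_length = 15000, n_genes = 6,
                       n_snp = 15, n_ins = 5, n_del = 5)
  fx <- generate_genome_with_annotation(spec)
  pv <- plant_variants(fx$genome, fx$annotation, spec)
  lift <- lift_annotation_resequencing(fx$annotation, fx$genome, pv$truth)
  v <- call_variants(fx$genome, pv$genome, fx$annotation, lift$annotation,
                     window_size = 600)
  expect_identical(reconstruct_query(fx$genome, v), pv$genome)
  # non-interacting SNP counts agree with the planted truth
  expect_equal(sum(v$kind == "SNP"), sum(pv$truth$kind == "SNP"))
  # recovered and planted sets imply the same sequence even if representations differ
  expect_identical(apply_variants(fx$genome, v)$genome,
                   apply_variants(fx$genome, pv$truth)$genome)
})

test_that("a relocated segment decomposes into INDELs with exact reconstruction", {
  spec <- fixture_spec(seed = 73, chromosome_length = 15000, n_genes = 6,
                       n_snp = 8)
  fx <- generate_genome_with_annotation(spec)
  pv <- plant_variants(fx$genome, fx$annotation, spec)
  lift <- lift_annotation_resequencing(fx$annotation, fx$genome, pv$truth)
  genes <- dplyr::filter(fx$annotation, type == "gene")
  g <- genes[3, ]
  rl <- relocate_segment(pv$genome, lift$annotation, "chr1",
                         g$start - 40L, g$end + 40L, 10L)
  v <- call_variants(fx$genome, rl$genome, fx$annotation, rl$annotation,
                     window_size = 600)
  expect_identical(reconstruct_query(fx$genome, v), rl$genome)
  expect_true(any(v$kind %in% c("INS", "DEL")))

  # empty call set reconstructs the reference unchanged
  expect_identical(reconstruct_query(fx$genome, empty_variants()), fx$genome)
  snp1 <- tibble(chrom = "chr1", pos = 10L,
                 ref = substr(fx$genome[["chr1"]], 11, 11),
                 alt = setdiff(c("A", "C", "G", "T"),
                               substr(fx$genome[["chr1"]], 11, 11))[1])
  rec <- reconstruct_query(fx$genome, snp1)
  diffs <- which(strsplit(rec[["chr1"]], "")[[1]] !=
                   strsplit(fx$genome[["chr1"]], "")[[1]])
  expect_equal(diffs, 11L)
})
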