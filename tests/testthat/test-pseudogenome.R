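test_that("applying variants substitutes alleles and tracks offsets", {
  g <- c(c1 = "ACGT")
  r0 <- apply_variants(g, empty_variants())
  expect_equal(r0$genome, g)
  expect_equal(lift_positions(r0$shift$c1, 0:3)$mapped, 0:3)

  r1 <- apply_variants(g, tibble(chrom = "c1", pos = 1L, ref = "C", alt = "CTT"))
  expect_equal(unname(r1$genome["c1"]), "ACTTGT")
  expect_equal(lift_positions(r1$shift$c1, c(1L, 2L))$mapped, c(1L, 4L))

  g2 <- c(c1 = "ACGTACGT")
  r2 <- apply_variants(g2, tibble(chrom = "c1", pos = 2L, ref = "GTA", alt = "G"))
  expect_equal(unname(r2$genome["c1"]), "ACGCGT")
  expect_equal(lift_positions(r2$shift$c1, 7L)$mapped, 5L)
})

test_that("invalid variant sets are rejected with validation errors", {
  g <- c(c1 = "ACGTACGTAC")
  overlapping <- tibble(chrom = "c1", pos = c(1L, 2L),
                        ref = c("CGT", "GT"), alt = c("C", "G"))
  expect_error(apply_variants(g, overlapping), "overlapping",
               class = "zebralift_validation_error")
  wrong_ref <- tibble(chrom = "c1", pos = 0L, ref = "G", alt = "T")
  expect_error(apply_variants(g, wrong_ref), "mismatch",
               class = "zebralift_validation_error")
})

test_that("position lift-over adds upstream offsets and reports deleted spans", {
  L <- 30L
  g <- c(c1 = paste(rep("ACGTA", 6), collapse = ""))
  # +3 insertion at position 10
  ins <- tibble(chrom = "c1", pos = 10L, ref = substr(g, 11, 11),
                alt = paste0(substr(g, 11, 11), "TTT"))
  sh <- apply_variants(g, ins)$shift$c1
  expect_equal(lift_positions(sh, 20L)$mapped, 23L)
  expect_equal(lift_positions(sh, 9L)$mapped, 9L)

  # deletion of [5, 7): interior positions report the gap locus as flanks
  del <- tibble(chrom = "c1", pos = 4L, ref = substr(g, 5, 7), alt = substr(g, 5, 5))
  sh2 <- apply_variants(g, del)$shift$c1
  r <- lift_positions(sh2, 6L)
  expect_true(is.na(r$mapped))
  expect_equal(r$flank_left, 5L)
  expect_equal(r$flank_right, 5L)
  expect_equal(lift_positions(sh2, 20L)$mapped, 18L)
  expect_error(lift_positions(sh2, L + 5L), class = "zebralift_contract_error")
})

test_that("pseudo->reference lift inverts reference->pseudo on surviving positions", {
  withr::local_seed(7)
  for (case in 1:60) {
    L <- 400L
    g <- c(c1 = rand_seq(L))
    n_var <- sample(1:8, 1)
    pos <- sort(sample(seq(5L, L - 20L, by = 15L), n_var))
    rows <- lapply(pos, function(p) {
      kind <- sample(c("SNP", "INS", "DEL"), 1)
      a <- substr(g, p + 1, p + 1)
      if (kind == "SNP") tibble(chrom = "c1", pos = p, ref = a,
                                alt = sample(setdiff(c("A", "C", "G", "T"), a), 1))
      else if (kind == "INS") tibble(chrom = "c1", pos = p, ref = a,
                                     alt = paste0(a, rand_seq(sample(1:6, 1))))
      else tibble(chrom = "c1", pos = p,
                  ref = substr(g, p + 1, p + 1 + sample(1:6, 1)), alt = a)
    })
    v <- variant_tibble(bind_rows(rows))
    res <- apply_variants(g, v)
    sh <- res$shift$c1
    fwd <- lift_positions(sh, 0:(L - 1L))
    surv <- fwd$pos[!is.na(fwd$mapped)]
    back <- lift_positions(sh, fwd$mapped[!is.na(fwd$mapped)], "pseudo2ref")
    expect_equal(back$mapped, surv)
    expect_equal(nchar(res$genome[["c1"]]),
                 L + sum(nchar(v$alt)) - sum(nchar(v$ref)))
  }
})

test_that("annotation lift shifts boundaries and flags deleted features", {
  spec <- fixture_spec(seed = 51, chromosome_length = 8000, n_genes = 3,
                       exons_per_gene = c(2, 2))
  fx <- generate_genome_with_annotation(spec)

  # identity
  id <- lift_annotation(fx$annotation, apply_variants(fx$genome, empty_variants())$shift)
  expect_equal(as.data.frame(id$annotation), as.data.frame(fx$annotation))
  expect_length(id$flagged, 0L)

  # 3-bp insertion inside an intron shifts only downstream features
  txs <- as_transcripts(fx$annotation)
  tx <- txs[vapply(txs$cds, nrow, integer(1)) == 2, ][1, ]
  cd <- tx$cds[[1]]
  mid <- as.integer((cd[1, 2] + cd[2, 1]) %/% 2)
  a <- substr(fx$genome[[tx$chrom]], mid + 1, mid + 1)
  ins <- tibble(chrom = tx$chrom, pos = mid, ref = a, alt = paste0(a, "TTT"))
  lifted <- lift_annotation(fx$annotation, apply_variants(fx$genome, ins)$shift)
  txs2 <- as_transcripts(lifted$annotation)
  tx2 <- txs2[txs2$transcript_id == tx$transcript_id, ]
  expect_equal(tx2$cds[[1]][1, ], cd[1, ])
  expect_equal(tx2$cds[[1]][2, ], cd[2, ] + 3L)
  expect_true(tx$transcript_id %in% lifted$flagged)

  # deletion covering a whole exon drops it and flags the transcript
  del_span <- c(cd[1, 1] - 2L, cd[1, 2] + 2L)
  del <- tibble(chrom = tx$chrom, pos = del_span[1] - 1L,
                ref = substr(fx$genome[[tx$chrom]], del_span[1], del_span[2]),
                alt = substr(fx$genome[[tx$chrom]], del_span[1], del_span[1]))
  expect_warning(
    lifted2 <- lift_annotation(fx$annotation, apply_variants(fx$genome, del)$shift),
    class = "zebralift_dropped_feature_warning"
  )
  txs3 <- as_transcripts(lifted2$annotation)
  tx3 <- txs3[txs3$transcript_id == tx$transcript_id, ]
  expect_equal(nrow(tx3$cds[[1]]), 1L)
  expect_true(tx$transcript_id %in% lifted2$flagged)
})

test_that("unaffected transcripts conserve their CDS through the lift", {
  spec <- fixture_spec(seed = 52, chromosome_length = 10000, n_genes = 4)
  fx <- generate_genome_with_annotation(spec)
  txs <- as_transcripts(fx$annotation)
  # one SNP far from gene 2's span
  tx <- txs[2, ]
  span <- range(tx$cds[[1]])
  pos <- if (span[1] > 200) 50L else span[2] + 150L
  a <- substr(fx$genome[[tx$chrom]], pos + 1, pos + 1)
  v <- tibble(chrom = tx$chrom, pos = pos, ref = a,
              alt = setdiff(c("A", "C", "G", "T"), a)[1])
  res <- apply_variants(fx$genome, v)
  lifted <- lift_annotation(fx$annotation, res$shift)
  txs2 <- as_transcripts(lifted$annotation)
  tx2 <- txs2[txs2$transcript_id == tx$transcript_id, ]
  expect_equal(extract_cds_sequence(tx2, res$genome),
               extract_cds_sequence(tx, fx$genome))
})
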