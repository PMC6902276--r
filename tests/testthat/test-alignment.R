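fc <- feature_classes()

test_that("identity and semi-global overhang alignments behave as specified", {
  track <- rep(fc[["CDS"]], 4)
  prof <- suppressWarnings(score_profile(cds = c(2, -2, 5, 2)))
  a <- zdp_align("ACGT", track, "ACGT", prof)
  expect_equal(a$score, 8)
  g <- glance(a)
  expect_equal(g$n_match, 4L)
  expect_equal(g$n_mismatch + g$n_ins + g$n_del, 0L)

  # query overhangs are free: reference fully covered, no edits inside it
  b <- zdp_align("ACGT", track, "TTACGTTT", prof)
  gb <- glance(b)
  expect_equal(gb$n_match, 4L)
  expect_equal(gb$n_mismatch + gb$n_ins + gb$n_del, 0L)
  expect_equal(b$query_span, c(2L, 6L))

  expect_error(zdp_align("", track, "ACGT"), class = "zebralift_contract_error")
  expect_error(zdp_align("ACGT", track, ""), class = "zebralift_contract_error")
  expect_error(sliding_window_align("ACGT", track, "ACGT", window_size = 1),
               class = "zebralift_contract_error")
})

test_that("the DP score equals exhaustive path enumeration on small cases", {
  withr::local_seed(11)
  for (case in 1:40) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    ref <- rand_seq(n); query <- rand_seq(m)
    track <- sample(0:4, n, replace = TRUE)
    prof <- random_profile()
    a <- zdp_align(ref, track, query, prof)
    expect_equal(a$score, enum_best_score(ref, query, track, prof))
    # the emitted alignment achieves the reported score
    expect_equal(alignment_score(a$ref_aligned, a$query_aligned, track, prof),
                 a$score)
  }
})

test_that("a uniform profile reduces to textbook semi-global affine alignment", {
  withr::local_seed(12)
  for (case in 1:25) {
    n <- sample(20:60, 1); m <- sample(20:60, 1)
    ref <- rand_seq(n); query <- rand_seq(m)
    prof <- uniform_profile(3, -2, 6, 2)
    a <- zdp_align(ref, NULL, query, prof)
    expect_equal(a$score, gotoh_semiglobal(ref, query, 3, -2, 6, 2))
  }
})

test_that("the striped solver matches the scalar solver bitwise and escalates width", {
  withr::local_seed(13)
  for (case in 1:60) {
    n <- sample(50:200, 1); m <- sample(50:200, 1)
    ref <- rand_seq(n); query <- rand_seq(m)
    track <- sample(0:4, n, replace = TRUE)
    a <- zdp_align(ref, track, query)
    b <- zsdp_align(ref, track, query)
    expect_identical(a$ref_aligned, b$ref_aligned)
    expect_identical(a$query_aligned, b$query_aligned)
    expect_identical(a$score, b$score)
  }
  # a long perfect match overflows 8-bit scores and escalates to 16
  s <- rand_seq(300)
  b <- zsdp_align(s, rep(fc[["CDS"]], 300), s)
  expect_equal(b$width, 16L)
  expect_equal(b$score, zdp_align(s, rep(fc[["CDS"]], 300), s)$score)
  # tiny intron-scored pair stays in 8 bits
  t8 <- zsdp_align("ACGTACGT", NULL, "ACGTACGT")
  expect_equal(t8$width, 8L)
})

test_that("sliding windows reproduce the exact solver when they cover the input", {
  withr::local_seed(14)
  for (case in 1:25) {
    n <- sample(30:120, 1); m <- sample(30:120, 1)
    ref <- rand_seq(n); query <- rand_seq(m)
    track <- sample(0:4, n, replace = TRUE)
    a <- zdp_align(ref, track, query)
    s <- sliding_window_align(ref, track, query, window_size = max(n, m))
    expect_identical(a$ref_aligned, s$ref_aligned)
    expect_identical(a$query_aligned, s$query_aligned)
    expect_identical(a$score, s$score)
  }
})

test_that("small windows still recover scattered SNPs over long sequences", {
  withr::local_seed(15)
  ref <- rand_seq(3000)
  qc <- strsplit(ref, "")[[1]]
  pos <- sort(sample(seq(50, 2950, by = 120), 6))
  for (p in pos) qc[p] <- setdiff(c("A", "C", "G", "T"), qc[p])[1]
  query <- paste(qc, collapse = "")
  a <- sliding_window_align(ref, NULL, query, uniform_profile(), window_size = 400)
  g <- glance(a)
  expect_equal(g$n_mismatch, 6L)
  expect_equal(g$n_ins + g$n_del, 0L)
  v <- recall_variants(a, "c1")
  expect_equal(v$pos, pos - 1L)
})

test_that("aligned strings conserve bases and gap counts", {
  withr::local_seed(16)
  for (case in 1:30) {
    n <- sample(10:80, 1); m <- sample(10:80, 1)
    ref <- rand_seq(n); query <- rand_seq(m)
    track <- sample(0:4, n, replace = TRUE)
    a <- zsdp_align(ref, track, query)
    expect_equal(nchar(a$ref_aligned), nchar(a$query_aligned))
    expect_equal(gsub("-", "", a$ref_aligned, fixed = TRUE), ref)
    expect_equal(gsub("-", "", a$query_aligned, fixed = TRUE),
                 substr(query, a$query_span[1] + 1, a$query_span[2]))
    g <- glance(a)
    expect_equal(g$n_ins, a$query_span[2] - a$query_span[1] - g$n_match - g$n_mismatch)
    expect_equal(g$n_del, n - g$n_match - g$n_mismatch)
  }
})

test_that("raising the splice-site gap penalty never pulls gaps into splice columns", {
  fxa <- ambiguous_fixture(seed = 17, n_loci = 3)
  txs <- as_transcripts(fxa$annotation)
  for (k in seq_len(nrow(fxa$loci))) {
    loc <- fxa$loci[k, ]
    tx <- txs[txs$transcript_id == loc$transcript_id, ]
    cd <- tx$cds[[1]]
    ws <- min(cd); we <- max(cd)
    track <- build_feature_track(tx, ws, we)
    refw <- substr(fxa$genome[[loc$chrom]], ws + 1, we)
    pseudo <- apply_variants(fxa$genome, locus_record(loc, "intronic"))$genome
    qw <- substr(pseudo[[loc$chrom]], ws + 1, we - 13)
    for (open in c(40L, 110L, 400L)) {
      prof <- score_profile(splice = c(30L, -30L, open, min(open, 110L)),
                            startstop = c(30L, -30L, open, min(open, 110L)))
      a <- zsdp_align(refw, track, qw, prof)
      cols <- strsplit(a$ref_aligned, "")[[1]]
      qcols <- strsplit(a$query_aligned, "")[[1]]
      refidx <- cumsum(cols != "-")
      gap_classes <- track[refidx[qcols == "-" & cols != "-"]]
      expect_false(any(gap_classes %in% c(fc[["SPLICE_SITE"]], fc[["START_STOP_CODON"]])))
    }
  }
})

test_that("alignment tidiers and plots expose the edit structure", {
  a <- zdp_align("ACGTACGT", NULL, "ACGACGT", uniform_profile())
  ops <- tidy(a)
  expect_true(all(ops$op %in% c("=", "X", "I", "D")))
  expect_equal(sum(ops$length[ops$op != "I"]), 8L)
  p <- autoplot(a)
  expect_s3_class(p, "ggplot")
})
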