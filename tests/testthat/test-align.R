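test_that("perfect self-alignment scores match x length", {
  s <- "ACGTACGTAC"
  h <- smith_waterman(s, s)
  expect_equal(h$score, 10)
  expect_equal(h$ops, strrep("=", 10))
  expect_equal(h$query_interval, c(0, 10))
  expect_equal(h$ref_interval, c(0, 10))
})

test_that("a single substitution reads through rather than splitting", {
  q <- "ACGTAAGTAC"; r <- "ACGTACGTAC"   # sub at position 5 (0-based)
  h <- smith_waterman(q, r)               # match 1 / mismatch -3
  expect_equal(h$score, 6)                # 9*1 - 3 beats split 5+4
  expect_equal(h$ops, "=====X====")
  # masking the mismatched reference position rescues the score to 9
  hm <- smith_waterman(q, "ACGTANGTAC")
  expect_equal(hm$score, 9)
  expect_equal(hm$ops, "=====N====")
})

test_that("affine gap costs follow open + extend*(L-1)", {
  # force a 2-base deletion: read lacks 2 middle bases of a 20-mer
  r <- "ACGTACGTACGTACGTACGT"
  q <- paste0(substr(r, 1, 9), substr(r, 12, 20))
  h <- smith_waterman(q, r)
  # 18 matches - (6 + 3*1) = 9
  expect_equal(h$score, 9)
  expect_equal(trnacharge:::score_from_ops(h$ops, align_scheme()), h$score)
})

test_that("compiled aligner agrees with the exhaustive DP oracle", {
  set.seed(99)
  schemes <- list(align_scheme(), realign_scheme())
  for (sch in schemes) {
    for (case in 1:120) {
      q <- random_seq(sample(8:30, 1))
      r <- random_seq(sample(8:30, 1))
      if (case %% 2 == 0) r <- mask_random(r, sample(1:4, 1))
      got <- smith_waterman(q, r, sch)$score
      want <- oracle_sw_score(q, r, sch$match, sch$mismatch, sch$n_score,
                              sch$gap_open, sch$gap_extend)
      expect_equal(got, want,
                   info = sprintf("q=%s r=%s scheme=%d/%d", q, r,
                                  sch$mismatch, sch$gap_open))
      # score recomputed from the traceback ops equals the DP score
      h <- smith_waterman(q, r, sch)
      expect_equal(trnacharge:::score_from_ops(h$ops, sch), h$score)
    }
  }
})

test_that("masking changes the score by at most covered-masked x max score", {
  set.seed(5)
  sch <- align_scheme()
  for (case in 1:40) {
    r <- random_seq(30)
    q <- substr(r, 5, 28)
    rm <- mask_random(r, 3)
    s_un <- smith_waterman(q, r, sch)$score
    s_ma <- smith_waterman(q, rm, sch)$score
    n_masked <- nchar(gsub("[^N]", "", rm))
    bound <- n_masked * max(abs(sch$match), abs(sch$mismatch))
    expect_lte(abs(s_ma - s_un), bound)
  }
})

test_that("reads map to their source transcript; reverse strand never maps", {
  sim <- fixture_reference(divergence = 0.2)
  ref <- sim$ref
  read <- substr(ref$sequence[3], 10, nchar(ref$sequence[3]))
  ann <- align_reads(read, ref)
  expect_true(ann$mapped[1])
  expect_equal(ann$transcript[1], ref$id[3])
  expect_true(ann$unique_transcript[1])
  rc <- trnacharge:::revcomp(read)
  ann_rc <- align_reads(rc, ref, min_score = 20)
  expect_false(ann_rc$mapped[1])
})

test_that("low-scoring random reads are unmapped at min_score 20", {
  sim <- fixture_reference()
  set.seed(17)
  reads <- vapply(1:20, function(i) random_seq(30), character(1))
  ann <- align_reads(reads, sim$ref, min_score = 20)
  # cross-check each claimed mapping with the oracle
  for (i in which(ann$mapped)) {
    best <- max(vapply(sim$ref$sequence, function(r)
      oracle_sw_score(reads[i], r), numeric(1)))
    expect_gte(best, 20)
  }
  for (i in which(!ann$mapped)) {
    best <- max(vapply(sim$ref$sequence, function(r)
      oracle_sw_score(reads[i], r), numeric(1)))
    expect_lt(best, 20)
  }
})

test_that("ties between identical family members merge annotations", {
  sim <- simulate_reference(2, 2, divergence = 0, seed = 3)
  ref <- sim$ref   # members identical within family (distinct ids)
  read <- substr(ref$sequence[1], 5, nchar(ref$sequence[1]))
  ann <- align_reads(read, ref)
  expect_equal(ann$n_tied[1], 2)
  expect_false(ann$unique_transcript[1])
  expect_true(ann$unique_anticodon[1])    # same family, same anticodon
  expect_true(ann$unique_amino_acid[1])
  expect_equal(length(strsplit(ann$hits_kept[1], ",")[[1]]), 2)
})

test_that("uniqueness flags nest: transcript => anticodon => amino acid", {
  sim <- fixture_reference(divergence = 0.05)
  truth <- sim_truth(sim$ref, charge = 0.5, seq_error = 0.002)
  rd <- simulate_reads(sim$ref, truth, 800, example_adapters(2), seed = 8)
  dm <- demultiplex_reads(rd$reads, example_adapters(2))
  ann <- align_reads(dm$reads, sim$ref)
  m <- ann$mapped %in% TRUE
  expect_true(all(!m | !ann$unique_transcript | ann$unique_anticodon))
  expect_true(all(!m | !ann$unique_anticodon | ann$unique_amino_acid))
})

test_that("3' ends classify as CCA, CC or other by terminal matches", {
  ref_seq <- "GGGGATTAGCTCAGCTGGGAGAGCCCA"
  ref <- trnacharge:::new_reference("tRNA-Ala-AGC-1-1", ref_seq)
  len <- nchar(ref_seq)
  # flush CCA end
  ann <- align_reads(substr(ref_seq, 5, len), ref)
  expect_equal(ann$end_class[1], "CCA")
  # one base short: CC
  ann_cc <- align_reads(substr(ref_seq, 5, len - 1), ref)
  expect_equal(ann_cc$end_class[1], "CC")
  # two bases short: other
  ann_o <- align_reads(substr(ref_seq, 5, len - 2), ref)
  expect_equal(ann_o$end_class[1], "other")
  # terminal mismatch: other (local alignment clips the terminal base)
  mut <- paste0(substr(ref_seq, 5, len - 1), "G")
  ann_m <- align_reads(mut, ref)
  expect_equal(ann_m$end_class[1], "other")
})

test_that("alignment results are deterministic across repeated runs", {
  sim <- fixture_reference()
  truth <- sim_truth(sim$ref, charge = 0.5, seq_error = 0.003)
  rd <- simulate_reads(sim$ref, truth, 300, example_adapters(2), seed = 21)
  dm <- demultiplex_reads(rd$reads, example_adapters(2))
  a1 <- align_reads(dm$reads, sim$ref)
  a2 <- align_reads(dm$reads, sim$ref)
  expect_identical(a1, a2)
  # order-invariance: permuting reads permutes results identically
  perm <- rev(seq_len(nrow(dm$reads)))
  a3 <- align_reads(dm$reads[perm, ], sim$ref)
  rownames(a3) <- NULL
  a1p <- a1[perm, ]; rownames(a1p) <- NULL
  expect_identical(a3, a1p)
})
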