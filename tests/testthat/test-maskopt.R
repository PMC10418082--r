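test_that("frequency table applies the 200/100 observation filters", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref, n = 3000)
  ann <- align_reads(reads, ref)
  freqs <- mismatch_frequencies(ann, ref, unique_anno = TRUE)
  # both transcripts well over 200 observations; hotspot frequency is high
  expect_true(all(freqs$n_obs >= 100))
  hs <- freqs[freqs$transcript == "tRNA-Val-TAC-1-1" & freqs$position == 20, ]
  expect_equal(nrow(hs), 1)
  expect_gt(hs$freq, 0.2)
  # a transcript with too few observations is absent entirely
  few <- ann[1:50, ]
  freqs_few <- mismatch_frequencies(few, ref, unique_anno = TRUE)
  expect_equal(nrow(freqs_few), 0)
  # per-position filter: positions below 100 observations are absent
  sub <- ann[ann$transcript == "tRNA-Val-TAC-1-1" & ann$mapped, ][1:250, ]
  f2 <- mismatch_frequencies(sub, ref, unique_anno = TRUE,
                             min_position_obs = 10000L)
  expect_equal(nrow(f2), 0)
})

test_that("mask selection is inclusive at the threshold, CCA never masked", {
  freqs <- data.frame(transcript = "t1", position = c(5L, 6L, 70L),
                      n_obs = 200L, freq = c(0.0999, 0.10, 0.9))
  ref <- trnacharge:::new_reference("t1", paste0(strrep("A", 70), "CCA"))
  mask <- select_mask_positions(freqs, 0.10, ref)
  expect_equal(mask$t1, 6L)               # 0.0999 below, 0.10 included
  expect_false(70L %in% mask$t1)          # position 70 is the first C of CCA
  expect_length(select_mask_positions(
    data.frame(transcript = "t1", position = 5L, n_obs = 200L, freq = 0.5),
    1.1, ref), 0)                         # unattainable threshold
})

test_that("mask donation respects similarity, nucleotide and observation rules", {
  ref <- trnacharge:::new_reference(
    c("t1", "t2", "t3"),
    c(paste0(strrep("ACGT", 17), "CCA"),
      paste0(strrep("ACGT", 17), "CCA"),       # identical to t1
      paste0(random_seq(68), "CCA")))          # unrelated
  mask <- list(t1 = c(8L))
  # acceptor position unobserved -> copied to the identical t2 only
  obs0 <- data.frame(transcript = character(0), position = integer(0),
                     n_obs = integer(0))
  out <- donate_masks(mask, ref, obs0, frac_max_score = 1.0)
  expect_equal(out$t2, 8L)
  expect_null(out$t3)
  # acceptor position with >= 100 observations blocks donation
  obs100 <- data.frame(transcript = "t2", position = 8L, n_obs = 150L)
  out2 <- donate_masks(mask, ref, obs100, frac_max_score = 1.0)
  expect_null(out2$t2)
  # differing nucleotide at the mapped position blocks donation
  s2 <- ref$sequence[2]
  substr(s2, 9, 9) <- "T"   # position 8 (0-based) was 'A'
  ref2 <- trnacharge:::new_reference(c("t1", "t2"),
                                     c(ref$sequence[1], s2))
  out3 <- donate_masks(mask, ref2, obs0, frac_max_score = 0.9)
  expect_null(out3$t2)
})

test_that("error-free reads yield an empty mask", {
  sim <- fixture_reference(n_families = 2, members = 1)
  truth <- sim_truth(sim$ref, charge = 1, seq_error = 0, falloff_prob = 0)
  rd <- simulate_reads(sim$ref, truth, 1000, example_adapters(2), seed = 31)
  reads <- demultiplex_reads(rd$reads, example_adapters(2))$reads
  im <- iterate_masking(reads, sim$ref,
                        masking_params(TRUE, 0.05, 1.0, 1))
  expect_equal(trnacharge:::mask_size(im$mask), 0)
})

test_that("a planted hypermutated position ends up in the mask", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref)
  im <- iterate_masking(reads, ref, masking_params(TRUE, 0.1, 1.0, 2))
  expect_true(20L %in% im$mask[["tRNA-Val-TAC-1-1"]])
  # iteration stability: final two iterations agree within 5%
  expect_lte(abs(im$sizes[2] - im$sizes[1]),
             max(1, 0.05 * max(im$sizes)))
})

test_that("iteration=1 equals a single masking pass", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref, n = 1500)
  im1 <- iterate_masking(reads, ref, masking_params(TRUE, 0.1, 1.0, 1))
  ann <- align_reads(reads, ref)
  freqs <- mismatch_frequencies(ann, ref, unique_anno = TRUE)
  manual <- select_mask_positions(freqs, 0.1, ref)
  manual <- donate_masks(manual, ref, attr(freqs, "position_obs"), 1.0)
  expect_equal(im1$mask, manual)
})

test_that("grid search reduces multi-anticodon reads without losing mapping", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref)
  ann0 <- align_reads(reads, ref)            # unmasked baseline
  m0 <- ann0$mapped %in% TRUE
  pct_multi0 <- 100 * mean(!(ann0$unique_anticodon[m0] %in% TRUE))
  pct_mapped0 <- 100 * mean(m0)
  expect_gt(pct_multi0, 5)                    # the confusion is real
  grid <- expand.grid(unique_anno = TRUE, min_mut_freq = c(0.1, 0.2),
                      frac_max_score = 1.0, iteration = 1:2,
                      KEEP.OUT.ATTRS = FALSE)
  gs <- grid_search(reads, ref, grid)
  best <- gs$results[gs$best, ]
  expect_lt(best$pct_multi_anticodon, pct_multi0)   # strict reduction
  expect_gte(best$pct_mapped, pct_mapped0 - 1)      # no mapping trade-off
  expect_gt(best$mask_size, 0)
})

test_that("grid search tie-breaking prefers smaller masks then grid order", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref, n = 1200)
  # single-combination grid returns that combination
  g1 <- expand.grid(unique_anno = TRUE, min_mut_freq = 0.1,
                    frac_max_score = 1.0, iteration = 1,
                    KEEP.OUT.ATTRS = FALSE)
  gs1 <- grid_search(reads, ref, g1)
  expect_equal(gs1$best, 1)
  # duplicated combination ties on the objective and mask; first row wins
  g2 <- rbind(g1, g1)
  gs2 <- grid_search(reads, ref, g2)
  expect_equal(gs2$best, 1)
})

test_that("masking never changes reference length", {
  ref <- make_confusable_pair()
  reads <- confusable_reads(ref, n = 1500)
  im <- iterate_masking(reads, ref, masking_params(TRUE, 0.1, 1.0, 1))
  masked <- apply_mask(ref, im$mask)
  expect_equal(nchar(masked$sequence), nchar(ref$sequence))
  for (i in seq_len(nrow(ref))) {
    a <- strsplit(ref$sequence[i], "")[[1]]
    b <- strsplit(masked$sequence[i], "")[[1]]
    diffs <- which(a != b)
    expect_true(all(b[diffs] == "N"))
    expect_equal(length(diffs), length(im$mask[[ref$id[i]]]))
  }
})
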