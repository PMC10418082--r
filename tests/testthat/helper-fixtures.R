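# Shared small fixtures, built in code at test time.

fixture_reference <- function(seed = 11, n_families = 4, members = 2,
                              divergence = 0.05) {
  simulate_reference(n_families, members, divergence = divergence, seed = seed)
}

# A tiny FASTA on disk; returns the path.
write_fixture_fasta <- function(ids, seqs, dir = tempdir()) {
  path <- tempfile("ref_", tmpdir = dir, fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", ids), seqs)), path)
  path
}

# Two transcripts with different anticodons, identical everywhere except
# the anticodon's middle base (diagnostic) and a hotspot position where a
# modification in t1 causes frequent misincorporation. When the hotspot
# error happens to convert t1's base into t2's base, the read ties between
# the two anticodons -- unless the hotspot is masked.
make_confusable_pair <- function() {
  set.seed(301)
  body <- random_seq(70)
  ch1 <- strsplit(body, "")[[1]]
  ch1[34:36] <- c("T", "A", "C")          # anticodon of t1 (aa Val)
  ch2 <- ch1
  ch2[35] <- "G"                          # t2 anticodon TGC (aa Ala)
  ch1[21] <- "A"; ch2[21] <- "G"          # hotspot position 20 (0-based)
  t1 <- paste(c(ch1, "C", "C", "A"), collapse = "")
  t2 <- paste(c(ch2, "C", "C", "A"), collapse = "")
  trnacharge:::new_reference(c("tRNA-Val-TAC-1-1", "tRNA-Ala-TGC-1-1"),
                             c(t1, t2))
}

confusable_reads <- function(ref, n = 3000, mism = 0.5) {
  truth <- sim_truth(ref, charge = 1, seq_error = 0, falloff_prob = 0,
                     hotspots = list("tRNA-Val-TAC-1-1" = data.frame(
                       position = 20, mismatch_prob = mism, gap_prob = 0,
                       falloff_prob = 0)))
  rd <- simulate_reads(ref, truth, n, example_adapters(2), seed = 77)
  demultiplex_reads(rd$reads, example_adapters(2))$reads
}

# Noise-free titration data straight from the mixture model.
fixture_titration <- function(F_true = 2, T_A = 90, T_B = 10,
                              ratios = c(100, 85, 70, 55, 40, 25, 10, 0),
                              n_reps = 4) {
  simulate_titration("tx1", F_true = F_true, T_A_true = T_A, T_B_true = T_B,
                     ratios = ratios, n_reps = n_reps, noise_sd = 0, seed = 1)
}
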