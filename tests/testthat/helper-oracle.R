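# Independent plain-R exhaustive local-alignment oracle (Gotoh, affine
# gaps). Same scoring convention as the package (gap of length L costs
# open + ext * (L - 1); reference N scores n_score for any query base) but
# a completely separate implementation: full three-matrix DP in R, score
# only. Used to verify the compiled aligner.
oracle_sw_score <- function(q, r, match = 1, mismatch = -3, n_score = 0,
                            gap_open = 6, gap_extend = 3) {
  qc <- strsplit(q, "")[[1]]
  rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes reference)
  F <- matrix(NEG, n + 1, m + 1)  # gap in reference (consumes query)
  for (i in 1:n) for (j in 1:m) {
    s <- if (rc[j] == "N") n_score
         else if (qc[i] == rc[j] && qc[i] != "N") match else mismatch
    E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open, E[i + 1, j] - gap_extend)
    F[i + 1, j + 1] <- max(H[i, j + 1] - gap_open, F[i, j + 1] - gap_extend)
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
  }
  max(H)
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# Inject Ns at random positions (masking emulation for oracle tests).
mask_random <- function(s, n_mask) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(ch), min(n_mask, length(ch)))
  ch[pos] <- "N"
  paste(ch, collapse = "")
}
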