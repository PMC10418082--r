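#' Re-align reads to their unmasked annotated transcript
#'
#' Misincorporation profiling needs the true per-column events at masked
#' positions, so each read with a unique transcript annotation is re-aligned
#' to the *unmasked* transcript sequence under the softer
#' [realign_scheme()] (match +1, mismatch -2, gap 3/2), which keeps
#' modification-induced mismatches inside the alignment instead of clipping
#' them.
#'
#' @param ann annotation data.frame from [align_reads()] (needs `seq`,
#'   `transcript`, `unique_transcript`).
#' @param ref the unmasked `trna_reference`.
#' @param scheme a [scoring_scheme()]; default [realign_scheme()].
#' @return data.frame of realignments: `transcript`, `seq`, `umi`,
#'   coordinates (`qstart`,`qend`,`rstart`,`rend`, 0-based half-open) and
#'   `ops`.
#' @export
realign_unmasked <- function(ann, ref, scheme = realign_scheme()) {
  keep <- ann$mapped %in% TRUE & ann$unique_transcript %in% TRUE
  idx <- which(keep)
  ref_i <- match(ann$transcript[idx], ref$id)
  if (anyNA(ref_i)) stop("annotation refers to transcript absent from reference")
  tb <- .sw_align_pairs(ann$seq[idx], ref$sequence[ref_i],
                        scheme$match, scheme$mismatch, scheme$n_score,
                        scheme$gap_open, scheme$gap_extend)
  data.frame(transcript = ann$transcript[idx],
             seq = ann$seq[idx],
             umi = if (is.null(ann$umi)) NA_character_ else ann$umi[idx],
             qstart = tb$qstart, qend = tb$qend,
             rstart = tb$rstart, rend = tb$rend,
             ops = as.character(tb$ops), stringsAsFactors = FALSE)
}

# Map an ops string to per-reference-position events.
# Returns list(mismatch = 0-based ref positions with a mismatch,
#              gap = ref positions carrying a gap event).
# Deletions are attributed to the 5'-most deleted reference base; an
# insertion is attributed to the reference index immediately 3' of it.
.ops_events <- function(ops, rstart) {
  o <- strsplit(ops, "")[[1]]
  rpos <- rstart
  mism <- integer(0); gap <- integer(0)
  i <- 1L
  while (i <= length(o)) {
    op <- o[i]
    if (op == "=" || op == "N") {
      rpos <- rpos + 1L; i <- i + 1L
    } else if (op == "X") {
      mism <- c(mism, rpos); rpos <- rpos + 1L; i <- i + 1L
    } else if (op == "D") {
      gap <- c(gap, rpos)              # 5'-most base of the deletion run
      while (i <= length(o) && o[i] == "D") { rpos <- rpos + 1L; i <- i + 1L }
    } else { # insertion run: attribute to ref index 3' of it (= current rpos)
      gap <- c(gap, rpos)
      while (i <= length(o) && o[i] == "I") i <- i + 1L
    }
  }
  list(mismatch = mism, gap = gap)
}

#' Per-position misincorporation and RT-stop profiles
#'
#' From UMI-corrected realignments, computes for every covered transcript
#' position the coverage, the fraction of molecules with a mismatch, the
#' fraction with a gap event, and the RT-stop percentage. Reverse
#' transcription starts at the tRNA 3' end, so coverage is non-increasing
#' moving 3'->5'; the RT-stop percentage at position p is the drop in
#' coverage from its 3' neighbour, as a percentage of the transcript's
#' maximal (3'-side) coverage:
#' `rt_stop_pct(p) = 100 * (coverage(p+1) - coverage(p)) / max coverage`.
#' Realignments spanning fewer than `min_span` reference positions are
#' excluded as uninformative micro-alignments.
#'
#' @param realn realignments from [realign_unmasked()].
#' @param ref the `trna_reference` (for transcript lengths).
#' @param umi_corrected collapse identical (sequence, UMI) pairs first.
#' @param min_span minimum aligned reference span per read.
#' @return data.frame: `transcript`, `position` (0-based), `coverage`,
#'   `mismatch_frac`, `gap_frac`, `rt_stop_pct` (NA where coverage is 0).
#' @export
build_profiles <- function(realn, ref, umi_corrected = TRUE, min_span = 10L) {
  realn <- realn[(realn$rend - realn$rstart) >= min_span, , drop = FALSE]
  if (umi_corrected && !all(is.na(realn$umi)))
    realn <- realn[!duplicated(realn[c("transcript", "seq", "umi")]), , drop = FALSE]
  out <- list()
  for (tid in unique(realn$transcript)) {
    sub <- realn[realn$transcript == tid, , drop = FALSE]
    len <- nchar(ref$sequence[match(tid, ref$id)])
    cov <- integer(len); mism <- integer(len); gap <- integer(len)
    stop5 <- integer(len + 1L)  # count of molecules whose 5'-most index is p
    for (r in seq_len(nrow(sub))) {
      a <- sub$rstart[r]; b <- sub$rend[r]
      cov[(a + 1L):b] <- cov[(a + 1L):b] + 1L
      stop5[a + 1L] <- stop5[a + 1L] + 1L
      ev <- .ops_events(sub$ops[r], sub$rstart[r])
      for (p in ev$mismatch) mism[p + 1L] <- mism[p + 1L] + 1L
      for (p in ev$gap) if (p < len) gap[p + 1L] <- gap[p + 1L] + 1L
    }
    maxcov <- max(cov)
    pos <- 0:(len - 1L)
    cov_next <- c(cov[-1L], NA)  # coverage at the 3'-ward neighbour
    rt <- ifelse(is.na(cov_next), 0, 100 * (cov_next - cov) / maxcov)
    out[[tid]] <- data.frame(
      transcript = tid, position = pos, coverage = cov,
      mismatch_frac = ifelse(cov > 0, mism / cov, NA_real_),
      gap_frac = ifelse(cov > 0, gap / cov, NA_real_),
      rt_stop_pct = rt, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(transcript = character(0), position = integer(0),
                      coverage = integer(0), mismatch_frac = numeric(0),
                      gap_frac = numeric(0), rt_stop_pct = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
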