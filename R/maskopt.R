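#' Masking tuning parameters
#'
#' The four parameters controlling reference-mask construction:
#' `unique_anno` — count only reads with a unique transcript annotation when
#' computing mismatch frequencies; `min_mut_freq` — minimum position-wise
#' mismatch frequency to trigger masking (inclusive); `frac_max_score` —
#' minimum fraction of the pairwise maximum alignment score between two
#' reference sequences for one to donate its mask to the other (inclusive;
#' normalized by the smaller self-alignment score); `iteration` — number of
#' masking iterations (annotations shift once the reference is masked, so
#' iterating stabilizes the mask).
#'
#' @param unique_anno logical.
#' @param min_mut_freq in (0, 1].
#' @param frac_max_score in (0, 1].
#' @param iteration positive integer.
#' @return a `masking_params` list.
#' @export
masking_params <- function(unique_anno = TRUE, min_mut_freq = 0.1,
                           frac_max_score = 0.9, iteration = 2L) {
  stopifnot(is.logical(unique_anno),
            min_mut_freq > 0, min_mut_freq <= 1,
            frac_max_score > 0, frac_max_score <= 1,
            iteration >= 1)
  structure(list(unique_anno = unique_anno, min_mut_freq = min_mut_freq,
                 frac_max_score = frac_max_score,
                 iteration = as.integer(iteration)),
            class = "masking_params")
}

#' Default grid of masking parameters
#'
#' All combinations of unique_anno in \{TRUE, FALSE\}, min_mut_freq in
#' \{0.05, 0.10, 0.15, 0.20\}, frac_max_score in \{0.85, 0.90, 0.95, 1.00\}
#' and iteration in \{1, 2, 3\}.
#'
#' @return data.frame of parameter combinations for [grid_search()].
#' @export
default_masking_grid <- function() {
  expand.grid(unique_anno = c(TRUE, FALSE),
              min_mut_freq = c(0.05, 0.10, 0.15, 0.20),
              frac_max_score = c(0.85, 0.90, 0.95, 1.00),
              iteration = c(1L, 2L, 3L),
              KEEP.OUT.ATTRS = FALSE)
}

#' Position-wise mismatch frequencies for mask selection
#'
#' Computes, from realignments to the unmasked annotated transcripts, the
#' UMI-corrected mismatch frequency at every transcript position, filtered
#' to transcripts with at least `min_transcript_obs` observations and
#' positions with at least `min_position_obs` observations. The unfiltered
#' per-position observation counts are attached as attribute
#' `position_obs` (needed by the mask-donation rule, which requires an
#' acceptor position to have *fewer* than 100 observations).
#'
#' @param ann annotation data.frame from [align_reads()].
#' @param ref unmasked `trna_reference`.
#' @param unique_anno restrict to reads with a unique transcript annotation.
#'   When FALSE, reads tied among up to three transcripts contribute to each
#'   tied transcript's counts.
#' @param min_transcript_obs,min_position_obs frequency-table filters.
#' @param scheme realignment [scoring_scheme()].
#' @return data.frame `transcript`, `position`, `n_obs`, `freq`, with
#'   attribute `position_obs` (same columns minus `freq`, unfiltered).
#' @export
mismatch_frequencies <- function(ann, ref, unique_anno = TRUE,
                                 min_transcript_obs = 200L,
                                 min_position_obs = 100L,
                                 scheme = realign_scheme()) {
  if (!unique_anno) {
    # expand multi-annotation reads to each kept transcript
    keep <- ann$mapped %in% TRUE
    sub <- ann[keep, , drop = FALSE]
    hits <- strsplit(sub$hits_kept, ",", fixed = TRUE)
    times <- lengths(hits)
    sub <- sub[rep(seq_len(nrow(sub)), times), , drop = FALSE]
    sub$transcript <- unlist(hits)
    sub$unique_transcript <- TRUE   # treat every expanded row as countable
    ann <- sub
  }
  realn <- realign_unmasked(ann, ref, scheme)
  prof <- build_profiles(realn, ref)
  if (nrow(prof) == 0) {
    out <- data.frame(transcript = character(0), position = integer(0),
                      n_obs = integer(0), freq = numeric(0))
    attr(out, "position_obs") <- data.frame(transcript = character(0),
                                            position = integer(0),
                                            n_obs = integer(0))
    return(out)
  }
  pos_obs <- data.frame(transcript = prof$transcript, position = prof$position,
                        n_obs = prof$coverage, stringsAsFactors = FALSE)
  # UMI-corrected transcript observation counts
  realn_u <- realn[!duplicated(realn[c("transcript", "seq", "umi")]), ]
  tr_obs <- table(realn_u$transcript)
  keep_tr <- names(tr_obs)[tr_obs >= min_transcript_obs]
  out <- prof[prof$transcript %in% keep_tr & prof$coverage >= min_position_obs,
              c("transcript", "position", "coverage", "mismatch_frac")]
  names(out) <- c("transcript", "position", "n_obs", "freq")
  rownames(out) <- NULL
  attr(out, "position_obs") <- pos_obs
  out
}

#' Select positions to mask from a frequency table
#'
#' Positions whose mismatch frequency is at least `min_mut_freq` are masked.
#' The three 3'-terminal (CCA) positions of each transcript are never
#' maskable: charge classification requires terminal matches, so masking
#' them would confound CCA/CC calling.
#'
#' @param freqs frequency table from [mismatch_frequencies()].
#' @param min_mut_freq inclusive masking threshold.
#' @param ref `trna_reference` (for transcript lengths).
#' @return mask set: named list of 0-based integer position vectors.
#' @export
select_mask_positions <- function(freqs, min_mut_freq, ref) {
  sel <- freqs[freqs$freq >= min_mut_freq, , drop = FALSE]
  mask <- list()
  for (tid in unique(sel$transcript)) {
    len <- nchar(ref$sequence[match(tid, ref$id)])
    pos <- sel$position[sel$transcript == tid]
    pos <- pos[pos < len - 3L]          # CCA positions never maskable
    if (length(pos)) mask[[tid]] <- sort(unique(as.integer(pos)))
  }
  mask
}

# Pairwise alignment-based mapping of donor positions onto an acceptor.
# Returns an integer vector: mapped[donor_pos + 1] = acceptor 0-based
# position, NA where the donor position falls in a gap / outside.
.map_positions <- function(donor_seq, acceptor_seq, scheme) {
  tb <- .sw_align_pairs(donor_seq, acceptor_seq,
                        scheme$match, scheme$mismatch, scheme$n_score,
                        scheme$gap_open, scheme$gap_extend)
  o <- strsplit(as.character(tb$ops[1]), "")[[1]]
  dpos <- tb$qstart[1]; apos <- tb$rstart[1]
  mapped <- rep(NA_integer_, nchar(donor_seq))
  for (op in o) {
    if (op %in% c("=", "X", "N")) {
      mapped[dpos + 1L] <- apos
      dpos <- dpos + 1L; apos <- apos + 1L
    } else if (op == "I") dpos <- dpos + 1L
    else apos <- apos + 1L
  }
  mapped
}

#' Donate masks between highly similar transcripts
#'
#' An abundant transcript donates its masked positions to a highly similar
#' but less abundant transcript likely carrying the same modifications. For
#' every ordered (donor, acceptor) pair whose pairwise alignment score is at
#' least `frac_max_score` times the smaller of the two self-alignment
#' scores, each donor masked position is mapped through the pairwise
#' alignment and copied iff (i) donor and acceptor carry the same nucleotide
#' at the mapped pair and (ii) the acceptor position has fewer than
#' `max_acceptor_obs` observations.
#'
#' @param mask mask set from [select_mask_positions()].
#' @param ref unmasked `trna_reference`.
#' @param position_obs unfiltered per-position observation table (attribute
#'   `position_obs` of [mismatch_frequencies()]).
#' @param frac_max_score inclusive similarity threshold in (0, 1].
#' @param max_acceptor_obs donation requires acceptor observations strictly
#'   below this (default 100).
#' @param scheme pairwise [scoring_scheme()] (same as first-pass alignment).
#' @return expanded mask set.
#' @export
donate_masks <- function(mask, ref, position_obs, frac_max_score,
                         max_acceptor_obs = 100L, scheme = align_scheme()) {
  if (length(mask) == 0 || frac_max_score > 1) return(mask)
  n <- nrow(ref)
  self_score <- scheme$match * nchar(ref$sequence)
  pair_sc <- .sw_score_matrix(ref$sequence, ref$sequence,
                              scheme$match, scheme$mismatch, scheme$n_score,
                              scheme$gap_open, scheme$gap_extend)
  obs_lookup <- function(tid, pos) {
    hit <- position_obs$n_obs[position_obs$transcript == tid &
                                position_obs$position == pos]
    if (length(hit) == 0) 0L else hit[1]
  }
  out <- mask
  for (d in seq_len(n)) {
    did <- ref$id[d]
    dpos <- mask[[did]]
    if (is.null(dpos) || length(dpos) == 0) next
    dch <- strsplit(ref$sequence[d], "")[[1]]
    for (a in seq_len(n)) {
      if (a == d) next
      if (pair_sc[d, a] < frac_max_score * min(self_score[d], self_score[a])) next
      aid <- ref$id[a]
      mapped <- .map_positions(ref$sequence[d], ref$sequence[a], scheme)
      ach <- strsplit(ref$sequence[a], "")[[1]]
      alen <- length(ach)
      for (p in dpos) {
        ap <- mapped[p + 1L]
        if (is.na(ap) || ap >= alen - 3L) next  # unmapped or in the CCA zone
        if (dch[p + 1L] != ach[ap + 1L]) next
        if (obs_lookup(aid, ap) >= max_acceptor_obs) next
        out[[aid]] <- sort(unique(c(out[[aid]], ap)))
      }
    }
  }
  out
}

#' Iterative reference masking
#'
#' Runs `params$iteration` rounds of: align reads to the current masked
#' reference, re-align annotated reads to their unmasked transcripts,
#' compute filtered mismatch frequencies, select positions at or above
#' `min_mut_freq`, and donate masks between similar transcripts. Masking
#' changes the annotations, which changes the frequencies, so iterating
#' stabilizes the mask.
#'
#' @param reads read data.frame (as from [demultiplex_reads()] or
#'   [simulate_reads()]).
#' @param ref unmasked `trna_reference`.
#' @param params a [masking_params()].
#' @param scheme first-pass [scoring_scheme()].
#' @param min_score mapping threshold for [align_reads()].
#' @param min_transcript_obs,min_position_obs frequency filters.
#' @return list with `mask` (final mask set) and `sizes` (mask size per
#'   iteration).
#' @export
iterate_masking <- function(reads, ref, params = masking_params(),
                            scheme = align_scheme(), min_score = 20L,
                            min_transcript_obs = 200L, min_position_obs = 100L) {
  mask <- list()
  sizes <- integer(params$iteration)
  for (it in seq_len(params$iteration)) {
    masked_ref <- apply_mask(ref, mask)
    ann <- align_reads(reads, masked_ref, scheme, min_score)
    freqs <- mismatch_frequencies(ann, ref, unique_anno = params$unique_anno,
                                  min_transcript_obs = min_transcript_obs,
                                  min_position_obs = min_position_obs)
    mask <- select_mask_positions(freqs, params$min_mut_freq, ref)
    mask <- donate_masks(mask, ref, attr(freqs, "position_obs"),
                         params$frac_max_score, scheme = scheme)
    sizes[it] <- mask_size(mask)
  }
  list(mask = mask, sizes = sizes)
}

#' Grid search over masking parameters
#'
#' Runs [iterate_masking()] for every parameter combination, re-annotates
#' the reads under the resulting mask, and scores each combination by the
#' percentage of mapped reads assigned to transcripts with multiple
#' anticodons (the objective to minimize; minimizing multi-*transcript*
#' reads instead can reward masks that make truncated reads spuriously
#' unique). Ties go to the smaller mask, then to stable grid order. The
#' mapped-read percentage is reported alongside to expose any
#' sensitivity-vs-specificity trade-off.
#'
#' @param reads read data.frame.
#' @param ref unmasked `trna_reference`.
#' @param grid data.frame of parameter combinations (see
#'   [default_masking_grid()]).
#' @inheritParams iterate_masking
#' @return list with `best` (row index into `results`), `mask` (best mask
#'   set), and `results` (data.frame: parameters, pct_multi_anticodon,
#'   pct_mapped, mask_size).
#' @export
grid_search <- function(reads, ref, grid = default_masking_grid(),
                        scheme = align_scheme(), min_score = 20L,
                        min_transcript_obs = 200L, min_position_obs = 100L) {
  stopifnot(nrow(grid) >= 1)
  results <- grid
  results$pct_multi_anticodon <- NA_real_
  results$pct_mapped <- NA_real_
  results$mask_size <- NA_integer_
  masks <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- masking_params(grid$unique_anno[g], grid$min_mut_freq[g],
                             grid$frac_max_score[g], grid$iteration[g])
    im <- iterate_masking(reads, ref, params, scheme, min_score,
                          min_transcript_obs, min_position_obs)
    ann <- align_reads(reads, apply_mask(ref, im$mask), scheme, min_score)
    mp <- ann$mapped %in% TRUE
    results$pct_multi_anticodon[g] <-
      if (any(mp)) 100 * mean(!(ann$unique_anticodon[mp] %in% TRUE)) else NA_real_
    results$pct_mapped[g] <- 100 * mean(mp)
    results$mask_size[g] <- mask_size(im$mask)
    masks[[g]] <- im$mask
  }
  ord <- order(results$pct_multi_anticodon, results$mask_size,
               seq_len(nrow(results)))
  best <- ord[1]
  list(best = best, mask = masks[[best]], results = results)
}
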