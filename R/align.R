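#' Alignment scoring schemes
#'
#' `scoring_scheme()` builds the parameter set for local alignment: match
#' and mismatch scores, the score of any column whose *reference* base is N
#' (masked positions score neutrally), and affine gap penalties where a gap
#' of length L costs `gap_open + gap_extend * (L - 1)` (the opening penalty
#' includes the first gapped base).
#'
#' `align_scheme()` is the default first-pass scheme used against the masked
#' reference (match +1, mismatch -3, N 0, gaps 6/3). `realign_scheme()` is
#' the softer scheme used when re-aligning a read to its unmasked annotated
#' transcript for misincorporation profiling (match +1, mismatch -2, gaps
#' 3/2), which tolerates modification-induced errors instead of clipping
#' them away.
#'
#' @param match positive match score.
#' @param mismatch negative mismatch score.
#' @param n_score score for a masked (N) reference column, any query base.
#' @param gap_open nonnegative penalty opening a gap (includes first base).
#' @param gap_extend nonnegative penalty per additional gapped base.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, n_score = 0L,
                           gap_open = 6L, gap_extend = 3L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 n_score = as.integer(n_score), gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' @rdname scoring_scheme
#' @export
align_scheme <- function() scoring_scheme(1L, -3L, 0L, 6L, 3L)

#' @rdname scoring_scheme
#' @export
realign_scheme <- function() scoring_scheme(1L, -2L, 0L, 3L, 2L)

#' Guaranteed-best local alignment of one query to one reference
#'
#' Exhaustive Smith-Waterman dynamic programming (no heuristic seeding) with
#' affine gaps under a [scoring_scheme()]. Path ties are broken
#' deterministically: diagonal over deletion over insertion during
#' traceback, and the first-scanned end cell on score ties, so results are
#' reproducible across runs and worker counts.
#'
#' @param query,ref_seq sequences (character scalars, ACGTN).
#' @param scheme a [scoring_scheme()].
#' @return an alignment hit: list with `score`, 0-based half-open
#'   `query_interval` and `ref_interval`, and `ops`, a string over
#'   `=` (match), `X` (mismatch), `N` (masked reference column),
#'   `I` (insertion), `D` (deletion).
#' @export
smith_waterman <- function(query, ref_seq, scheme = align_scheme()) {
  r <- .sw_align_pairs(query, ref_seq, scheme$match, scheme$mismatch,
                       scheme$n_score, scheme$gap_open, scheme$gap_extend)
  list(score = r$score[1],
       query_interval = c(r$qstart[1], r$qend[1]),
       ref_interval = c(r$rstart[1], r$rend[1]),
       ops = as.character(r$ops[1]))
}

# Recompute an alignment score from its ops string (consistency checks).
score_from_ops <- function(ops, scheme) {
  if (!nzchar(ops)) return(0L)
  o <- strsplit(ops, "")[[1]]
  s <- sum((o == "=") * scheme$match + (o == "X") * scheme$mismatch +
             (o == "N") * scheme$n_score)
  r <- rle(o)
  gaps <- r$lengths[r$values %in% c("I", "D")]
  s - sum(scheme$gap_open + scheme$gap_extend * (gaps - 1))
}

#' Align reads to a (masked) reference and annotate them
#'
#' Scores every read against every transcript (plus strand only) by
#' exhaustive Smith-Waterman, keeps reads whose best score reaches
#' `min_score`, and merges tied best-scoring transcripts into the read's
#' annotation (up to three reported; more than three flags the read
#' over-tied). Uniqueness at the transcript, anticodon and amino-acid level
#' is computed over *all* tied transcripts, not just the reported three.
#' The best alignment is traced back for each mapped read and its 3' end is
#' classified CCA / CC / other (see [classify_3prime_end()]).
#'
#' @param reads data.frame with at least a `seq` column (plus `sample_id`,
#'   `adapter_id`, `umi` if present, carried through), or a character vector.
#' @param ref a `trna_reference` (typically masked via [apply_mask()]).
#' @param scheme a [scoring_scheme()]; default [align_scheme()].
#' @param min_score minimum best score for a read to count as mapped.
#' @return annotation data.frame, one row per read: `mapped`, `score`,
#'   `n_tied`, `hits_kept` (comma-joined ids, max 3), `transcript` (first
#'   best hit), `anticodon`, `amino_acid` (NA unless unique at that level),
#'   `unique_transcript`, `unique_anticodon`, `unique_amino_acid`,
#'   `over_tied`, `end_class`, alignment coordinates and `ops`.
#' @export
align_reads <- function(reads, ref, scheme = align_scheme(), min_score = 20L) {
  if (is.character(reads)) reads <- data.frame(seq = reads, stringsAsFactors = FALSE)
  n <- nrow(reads)
  sc <- .sw_score_matrix(reads$seq, ref$sequence, scheme$match, scheme$mismatch,
                         scheme$n_score, scheme$gap_open, scheme$gap_extend)
  best <- if (n > 0) apply(sc, 1L, max) else integer(0)
  mapped <- best >= min_score

  n_tied <- rep(NA_integer_, n); hits_kept <- rep(NA_character_, n)
  transcript <- anticodon <- amino_acid <- rep(NA_character_, n)
  uniq_tr <- uniq_ac <- uniq_aa <- over_tied <- rep(NA, n)

  idx <- which(mapped)
  if (length(idx) > 0) {
    first_hit <- max.col(sc[idx, , drop = FALSE] == best[idx],
                         ties.method = "first")
    nt <- rowSums(sc[idx, , drop = FALSE] == best[idx])
    n_tied[idx] <- nt
    over_tied[idx] <- nt > 3L
    transcript[idx] <- ref$id[first_hit]
    uniq_tr[idx] <- nt == 1L
    # fast path: single best transcript
    single <- nt == 1L
    is1 <- idx[single]
    hits_kept[is1] <- ref$id[first_hit[single]]
    anticodon[is1] <- ref$anticodon[first_hit[single]]
    amino_acid[is1] <- ref$amino_acid[first_hit[single]]
    uniq_ac[is1] <- TRUE; uniq_aa[is1] <- TRUE
    for (k in which(!single)) {           # tied reads: stable reference order
      i <- idx[k]
      tied <- which(sc[i, ] == best[i])
      kept <- tied[seq_len(min(3L, length(tied)))]
      hits_kept[i] <- paste(ref$id[kept], collapse = ",")
      acs <- unique(ref$anticodon[tied])
      aas <- unique(ref$amino_acid[tied])
      uniq_ac[i] <- length(acs) == 1L
      uniq_aa[i] <- length(aas) == 1L
      if (length(acs) == 1L) anticodon[i] <- acs
      if (length(aas) == 1L) amino_acid[i] <- aas
    }
  }

  ann <- data.frame(
    mapped = mapped, score = ifelse(mapped, best, NA_integer_),
    n_tied = n_tied, hits_kept = hits_kept,
    transcript = transcript, anticodon = anticodon, amino_acid = amino_acid,
    unique_transcript = uniq_tr, unique_anticodon = uniq_ac,
    unique_amino_acid = uniq_aa,
    over_tied = over_tied, end_class = NA_character_,
    qstart = NA_integer_, qend = NA_integer_,
    rstart = NA_integer_, rend = NA_integer_, ops = NA_character_,
    stringsAsFactors = FALSE)
  for (col in c("sample_id", "adapter_id", "umi", "seq"))
    if (!is.null(reads[[col]])) ann[[col]] <- reads[[col]]
  if (length(idx) == 0) return(ann)

  tb <- .sw_align_pairs(reads$seq[idx], ref$sequence[first_hit],
                        scheme$match, scheme$mismatch, scheme$n_score,
                        scheme$gap_open, scheme$gap_extend)
  ann$qstart[idx] <- tb$qstart; ann$qend[idx] <- tb$qend
  ann$rstart[idx] <- tb$rstart; ann$rend[idx] <- tb$rend
  ann$ops[idx] <- as.character(tb$ops)
  ann$end_class[idx] <- classify_3prime_end(
    qend = tb$qend, rend = tb$rend, ops = as.character(tb$ops),
    read_len = nchar(reads$seq[idx]),
    ref_len = nchar(ref$sequence[first_hit]))
  ann
}

#' Classify the 3' end of an aligned read as CCA, CC or other
#'
#' The assay leaves charged (aminoacylation-protected) molecules with their
#' full 3'-terminal CCA while uncharged molecules lose the terminal A and
#' end in CC. A read is classified `CCA` when its 3'-terminal base aligns as
#' a match to the transcript's final base and the last three aligned columns
#' are matches (to C, C, A); `CC` when its 3'-terminal base aligns as a
#' match to the penultimate C; anything else (truncated 3' end, terminal
#' mismatch, soft-clipped terminal base) is `other`. Masked (N) columns do
#' not count as matches, which is why the terminal three reference positions
#' are never allowed into a mask.
#'
#' @param qend,rend 0-based half-open end coordinates of the alignment on
#'   query and reference.
#' @param ops alignment operation string(s).
#' @param read_len,ref_len sequence lengths.
#' @return character vector over `"CCA"`, `"CC"`, `"other"`.
#' @export
classify_3prime_end <- function(qend, rend, ops, read_len, ref_len) {
  out <- rep("other", length(qend))
  terminal_match <- endsWith(ops, "=")
  last3 <- vapply(ops, function(o)
    nchar(o) >= 3 && substr(o, nchar(o) - 2, nchar(o)) == "===", logical(1),
    USE.NAMES = FALSE)
  out[qend == read_len & rend == ref_len & last3] <- "CCA"
  out[qend == read_len & rend == ref_len - 1L & terminal_match] <- "CC"
  out
}
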