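#' Load an adapter-barcode table
#'
#' The table (TSV with columns `adapter_id`, `barcode`, `splint_context`)
#' describes the 3' adapters ligated to the tRNA: a 5-8 nt barcode followed
#' by the region complementary to the ligation splint. Matching uses the
#' concatenation of both (the `search_seq`), so the table is validated to
#' guarantee that a Hamming distance-1 match is unambiguous: equal-length
#' search sequences must be pairwise Hamming distance > 2 apart.
#'
#' @param path TSV path, or a data.frame with the same columns.
#' @return data.frame with an added `search_seq` column.
#' @export
read_adapters <- function(path) {
  ad <- if (is.data.frame(path)) path
        else read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("adapter_id", "barcode", "splint_context") %in% names(ad)))
  ad$barcode <- toupper(ad$barcode)
  ad$splint_context <- toupper(ad$splint_context)
  if (any(!nzchar(ad$barcode))) stop("empty barcode in adapter table")
  if (any(!grepl("^[ACGT]+$", ad$barcode)))
    stop("barcodes must be ACGT strings")
  ad$search_seq <- paste0(ad$barcode, ad$splint_context)
  n <- nrow(ad)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (nchar(ad$search_seq[i]) == nchar(ad$search_seq[j]) &&
          hamming(ad$search_seq[i], ad$search_seq[j]) <= 2)
        stop(sprintf("adapters %s and %s are within Hamming distance 2; distance-1 assignment would be ambiguous",
                     ad$adapter_id[i], ad$adapter_id[j]))
    }
  }
  ad
}

#' Assign a merged read to an adapter barcode
#'
#' A read is assigned to an adapter if its 3' end contains a substring within
#' Hamming distance one of that adapter's barcode + splint-context sequence.
#' The search is restricted to a 3' window (search length + `window_slack`)
#' to avoid spurious internal hits. If two or more adapters match within
#' distance one the read is ambiguous; the matched region and everything 3'
#' of it is trimmed from assigned reads.
#'
#' @param read merged read sequence (character scalar).
#' @param adapters adapter table from [read_adapters()].
#' @param window_slack extra bases beyond the search-sequence length included
#'   in the 3' search window.
#' @return list with `status` ("assigned", "ambiguous", "no_match"),
#'   `adapter_id`, and `trimmed` (the tRNA-portion + UMI read).
#' @export
assign_adapter_barcode <- function(read, adapters, window_slack = 4L) {
  m <- .barcode_match(read, adapters$search_seq, as.integer(window_slack))
  if (m$n_hits == 0)
    return(list(status = "no_match", adapter_id = NA_character_, trimmed = NA_character_))
  if (m$n_hits > 1)
    return(list(status = "ambiguous", adapter_id = NA_character_, trimmed = NA_character_))
  list(status = "assigned", adapter_id = adapters$adapter_id[m$adapter],
       trimmed = substr(read, 1L, m$match_start - 1L))
}

#' Extract the 5' UMI from an adapter-trimmed read
#'
#' The first 10 bases are the unique molecular identifier (a purine followed
#' by 9 random nucleotides on the RT oligo); the remainder is the tRNA
#' portion, possibly still carrying 5' non-template bases which the local
#' alignment later soft-clips.
#'
#' @param read adapter-trimmed read (character scalar).
#' @param umi_len UMI length (default 10).
#' @return list with `status` ("ok" or "too_short"), `umi`, `seq`.
#' @export
extract_umi <- function(read, umi_len = 10L) {
  if (nchar(read) <= umi_len)
    return(list(status = "too_short", umi = NA_character_, seq = NA_character_))
  list(status = "ok", umi = substr(read, 1L, umi_len),
       seq = substr(read, umi_len + 1L, nchar(read)))
}

#' Merge a trimmed read pair by 3' overlap
#'
#' Built-in overlap merger for proper pairs: sequencing adapters (if given)
#' are trimmed from the 3' ends by exact prefix match, read 2 is
#' reverse-complemented, and the longest 3' overlap of at least
#' `min_overlap` bases with at most 10% mismatches is collapsed into a
#' single read preserving the 5' end of read 1 (read-1 base wins at
#' disagreeing columns). Merged reads shorter than `min_len` are rejected.
#'
#' @param read1,read2 the two mates, 5'->3' as sequenced.
#' @param adapter1_seq,adapter2_seq sequencing adapter expected at the 3' end
#'   of each mate (trimmed if found; `NULL` to skip).
#' @param min_overlap minimum overlap length (default 10).
#' @param min_len minimum merged length; 25 for blunt-end ligation libraries,
#'   39 for splint-assisted ligation libraries.
#' @return list with `status` ("merged" or "rejected"), `seq`, `reason`.
#' @export
merge_trim_pairs <- function(read1, read2, adapter1_seq = NULL,
                             adapter2_seq = NULL, min_overlap = 10L,
                             min_len = 25L) {
  trim_adapter <- function(r, ad) {
    if (is.null(ad) || !nzchar(ad)) return(r)
    for (k in seq(nchar(ad), 6L)) {   # full adapter first, then long prefixes
      hit <- regexpr(substr(ad, 1, k), r, fixed = TRUE)
      if (hit > 0) return(substr(r, 1L, hit - 1L))
    }
    r
  }
  r1 <- trim_adapter(toupper(read1), adapter1_seq)
  r2 <- trim_adapter(toupper(read2), adapter2_seq)
  r2rc <- revcomp(r2)
  n1 <- nchar(r1); n2 <- nchar(r2rc)
  if (n1 == 0 || n2 == 0)
    return(list(status = "rejected", seq = NA_character_, reason = "empty_after_trim"))
  merged <- NULL
  for (o in seq(min(n1, n2), min_overlap)) {
    a <- substr(r1, n1 - o + 1L, n1)
    b <- substr(r2rc, 1L, o)
    if (hamming(a, b) <= floor(o / 10)) {
      merged <- paste0(r1, substr(r2rc, o + 1L, n2))
      break
    }
  }
  if (is.null(merged))
    return(list(status = "rejected", seq = NA_character_, reason = "no_overlap"))
  if (nchar(merged) < min_len)
    return(list(status = "rejected", seq = NA_character_, reason = "too_short"))
  list(status = "merged", seq = merged, reason = NA_character_)
}

#' Demultiplex merged reads by adapter barcode and extract UMIs
#'
#' Applies [assign_adapter_barcode()] and [extract_umi()] to every merged
#' read of a sample and tallies the outcome categories. The category counts
#' always conserve the input: assigned + ambiguous + no_match + too_short =
#' input reads.
#'
#' @param seqs character vector of merged reads.
#' @param adapters adapter table ([read_adapters()]).
#' @param sample_id sample label carried into the output.
#' @param min_seq_len minimum tRNA-portion length after UMI removal.
#' @return list with `reads` (data.frame: sample_id, adapter_id, umi, seq)
#'   and `counts` (named integer vector).
#' @export
demultiplex_reads <- function(seqs, adapters, sample_id = "sample",
                              min_seq_len = 15L, window_slack = 4L) {
  n <- length(seqs)
  m <- .barcode_match(seqs, adapters$search_seq, as.integer(window_slack))
  status <- ifelse(m$n_hits == 0, "no_match",
                   ifelse(m$n_hits > 1, "ambiguous", "assigned"))
  trimmed <- ifelse(status == "assigned",
                    substr(seqs, 1L, m$match_start - 1L), NA_character_)
  umi_len <- 10L
  too_short <- status == "assigned" &
    nchar(trimmed) < umi_len + min_seq_len
  status[too_short] <- "too_short"
  keep <- status == "assigned"
  adapter_id <- ifelse(keep, adapters$adapter_id[pmax(m$adapter, 1L)], NA_character_)
  umi <- ifelse(keep, substr(trimmed, 1L, umi_len), NA_character_)
  seq_out <- ifelse(keep, substr(trimmed, umi_len + 1L, nchar(trimmed)),
                    NA_character_)
  counts <- c(input = n,
              assigned = sum(keep),
              ambiguous = sum(status == "ambiguous"),
              no_match = sum(status == "no_match"),
              too_short = sum(status == "too_short"))
  list(reads = data.frame(sample_id = sample_id,
                          adapter_id = adapter_id[keep],
                          umi = umi[keep], seq = seq_out[keep],
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Downsample reads to a fixed cap
#'
#' Samples with more than `cap` reads are reduced to a uniform random subset
#' of exactly `cap` reads (reproducible for a fixed seed); smaller samples
#' pass through unchanged. The default cap mirrors typical practice of
#' capping deeply sequenced samples at 2e6 reads.
#'
#' @param reads character vector or data.frame of reads.
#' @param cap maximum number of reads to keep.
#' @param seed RNG seed.
#' @return the (possibly subset) reads, in original relative order.
#' @export
downsample <- function(reads, cap = 2e6, seed = 1L) {
  stopifnot(cap > 0)
  n <- if (is.data.frame(reads)) nrow(reads) else length(reads)
  if (n <= cap) return(reads)
  idx <- sort(with_seed(seed, sample.int(n, cap)))
  if (is.data.frame(reads)) reads[idx, , drop = FALSE] else reads[idx]
}

#' Expected number of unique UMIs among n uniform draws
#'
#' Occupancy expectation for `n_reads` molecules labelled uniformly at random
#' from `umi_space` possible UMIs:
#' \deqn{E[X] = k\,\left(1 - \left(\frac{k-1}{k}\right)^n\right)}
#' with k the UMI space size. Comparing this expectation against the
#' observed number of distinct UMIs is a library-complexity QC. Setting
#' `literal_roles = TRUE` swaps the roles of n and k, reproducing the
#' formula with reads in the base and UMI space in the exponent; the two
#' agree in the unsaturated regime but only the occupancy form matches
#' simulation when n approaches or exceeds k.
#'
#' @param n_reads number of reads (draws).
#' @param umi_space number of possible UMIs (see [umi_space_size()]).
#' @param literal_roles use the swapped-role variant.
#' @return expected number of distinct UMIs (real).
#' @export
expected_unique_umis <- function(n_reads, umi_space, literal_roles = FALSE) {
  if (any(umi_space < 1)) stop("umi_space must be >= 1")
  if (any(n_reads < 0)) stop("n_reads must be >= 0")
  if (literal_roles) { tmp <- n_reads; n_reads <- umi_space; umi_space <- tmp }
  k <- umi_space; n <- n_reads
  # k * (1 - ((k-1)/k)^n), in log space for numerical stability
  ifelse(n == 0, 0, -k * expm1(n * log1p(-1 / k)))
}

#' Size of the UMI space
#'
#' `4^n_random_nt`, doubled when the design prepends a random purine (R = A
#' or G), as in an RT oligo with one purine plus 9 random nucleotides:
#' 2 x 4^9 = 524288 possible UMIs.
#'
#' @param n_random_nt number of fully random positions.
#' @param leading_purine whether a random purine precedes them.
#' @return integer count of possible UMIs.
#' @export
umi_space_size <- function(n_random_nt, leading_purine = TRUE) {
  stopifnot(n_random_nt >= 0)
  4^n_random_nt * (if (leading_purine) 2 else 1)
}

#' UMI-based sample QC
#'
#' @param umis character vector of observed UMIs for one sample.
#' @param umi_space UMI space size.
#' @param max_umi_n UMIs with more than this many Ns are excluded.
#' @return data.frame with n_reads, umi_space, observed_unique,
#'   expected_unique.
#' @export
umi_qc <- function(umis, umi_space = umi_space_size(9), max_umi_n = 2L) {
  nN <- nchar(gsub("[^N]", "", umis))
  usable <- umis[nN <= max_umi_n]
  data.frame(n_reads = length(usable), umi_space = umi_space,
             observed_unique = length(unique(usable)),
             expected_unique = expected_unique_umis(length(usable), umi_space))
}
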