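.level_group <- function(ann, level) {
  switch(level,
    transcript = ifelse(ann$unique_transcript %in% TRUE, ann$transcript, NA_character_),
    anticodon  = ifelse(ann$unique_anticodon %in% TRUE, ann$anticodon, NA_character_),
    amino_acid = ifelse(ann$unique_amino_acid %in% TRUE, ann$amino_acid, NA_character_),
    stop("level must be transcript, anticodon or amino_acid"))
}

.group_is_spikein <- function(groups, level, ref) {
  if (is.null(ref)) return(rep(FALSE, length(groups)))
  key <- switch(level, transcript = ref$id, anticodon = ref$anticodon,
                amino_acid = ref$amino_acid)
  spike <- tapply(ref$is_spikein, key, all)
  unname(spike[groups]) %in% TRUE
}

#' UMI-corrected counts per group
#'
#' Collapses reads with identical sequence *and* UMI to a single molecule,
#' then counts molecules per transcript / anticodon / amino-acid group.
#' Only reads unique at the requested level contribute (a read tied between
#' transcripts of one anticodon still counts at the anticodon level).
#' Reads whose UMI carries more than `max_umi_n` Ns are excluded from
#' UMI-corrected counting.
#'
#' @param ann annotation data.frame from [align_reads()] (must carry `seq`
#'   and `umi`).
#' @param level `"transcript"`, `"anticodon"` or `"amino_acid"`.
#' @param max_umi_n maximum number of Ns tolerated in a UMI.
#' @return named integer vector of UMI-corrected counts per group.
#' @export
umi_collapse_counts <- function(ann, level = "transcript", max_umi_n = 2L) {
  grp <- .level_group(ann, level)
  keep <- ann$mapped %in% TRUE & !is.na(grp)
  if (!is.null(ann$umi)) {
    nN <- nchar(gsub("[^N]", "", ann$umi))
    keep <- keep & (nN <= max_umi_n)
  }
  if (!any(keep)) return(setNames(integer(0), character(0)))
  d <- data.frame(grp = grp[keep], seq = ann$seq[keep],
                  umi = if (is.null(ann$umi)) seq_len(sum(keep)) else ann$umi[keep])
  d <- d[!duplicated(d[c("grp", "seq", "umi")]), ]
  tab <- table(d$grp)
  setNames(as.integer(tab), names(tab))
}

#' Aminoacylation charge per group
#'
#' Charge is the fraction of molecules protected by their amino acid:
#' reads ending in the full CCA over reads ending in CCA or CC,
#' `100 * n_cca / (n_cca + n_cc)`. Raw (non-UMI-collapsed) read counts are
#' used, since charge is a ratio and PCR duplication affects numerator and
#' denominator alike. Reads with `other` 3' ends are excluded from both.
#' Groups with fewer than `min_reads` contributing reads are flagged
#' low-coverage but kept.
#'
#' @inheritParams umi_collapse_counts
#' @param min_reads minimum reads for a confident charge estimate (flag only).
#' @param ref optional `trna_reference` used to flag spike-in groups.
#' @return data.frame: `group`, `n_cca`, `n_cc`, `charge_pct`,
#'   `low_coverage`, `is_spikein`.
#' @export
charge_table <- function(ann, level = "transcript", min_reads = 100L, ref = NULL) {
  grp <- .level_group(ann, level)
  keep <- ann$mapped %in% TRUE & !is.na(grp) & ann$end_class %in% c("CCA", "CC")
  groups <- sort(unique(grp[keep]))
  n_cca <- vapply(groups, function(g)
    sum(keep & grp == g & ann$end_class == "CCA", na.rm = TRUE), integer(1))
  n_cc <- vapply(groups, function(g)
    sum(keep & grp == g & ann$end_class == "CC", na.rm = TRUE), integer(1))
  denom <- n_cca + n_cc
  data.frame(group = groups, n_cca = n_cca, n_cc = n_cc,
             charge_pct = ifelse(denom > 0, 100 * n_cca / denom, NA_real_),
             low_coverage = denom < min_reads,
             is_spikein = .group_is_spikein(groups, level, ref),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Relative expression per group (reads per million, UMI-corrected)
#'
#' RPM over UMI-corrected molecule counts: `1e6 * count / total`. Reads with
#' degraded (`other`) 3' ends still represent real molecules and are
#' included. By default spike-in control groups are reported but excluded
#' from the denominator used for cellular tRNAs (their own RPM is relative
#' to the same cellular total).
#'
#' @inheritParams charge_table
#' @param include_spikeins_in_total include spike-in counts in the RPM
#'   denominator.
#' @return data.frame: `group`, `n_umi_corrected`, `rpm`, `is_spikein`.
#'   RPM sums to 1e6 over the denominator groups.
#' @export
rpm_table <- function(ann, level = "transcript", ref = NULL,
                      include_spikeins_in_total = FALSE) {
  counts <- umi_collapse_counts(ann, level)
  if (length(counts) == 0) {
    warning("no mapped reads; empty RPM table")
    return(data.frame(group = character(0), n_umi_corrected = integer(0),
                      rpm = numeric(0), is_spikein = logical(0)))
  }
  spike <- .group_is_spikein(names(counts), level, ref)
  total <- if (include_spikeins_in_total) sum(counts) else sum(counts[!spike])
  data.frame(group = names(counts), n_umi_corrected = as.integer(counts),
             rpm = 1e6 * as.numeric(counts) / total,
             is_spikein = spike, row.names = NULL, stringsAsFactors = FALSE)
}
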