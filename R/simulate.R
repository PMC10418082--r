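# Anticodon -> amino acid via the standard genetic code (codon is the
# reverse complement of the anticodon).
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Sup")

anticodon_to_aa <- function(anticodon) {
  codon <- revcomp(anticodon)
  aa1 <- as.character(Biostrings::GENETIC_CODE[codon])
  out <- AA3[aa1]
  out[is.na(out)] <- "Und"
  unname(out)
}

#' Simulate a tRNA transcript reference with isodecoder families
#'
#' Builds families of near-identical transcripts (members differ by point
#' mutations at rate `divergence`, never inside the 3'-terminal CCA), each
#' family carrying one anticodon, named GtRNAdb-style
#' `tRNA-<AA>-<anticodon>-<family>-<copy>`. With `divergence = 0`, family
#' members are sequence-identical apart from their ids (useful for
#' tie-handling tests; deduplication would collapse them).
#'
#' @param n_families number of anticodon families.
#' @param members_per_family transcripts per family.
#' @param length_range min/max transcript length (nt, including CCA).
#' @param divergence per-position point-mutation probability between family
#'   members, in `[0, 1]`.
#' @param seed RNG seed.
#' @return list with `ref` (a `trna_reference`) and `families`
#'   (data.frame: id, family, anticodon).
#' @export
simulate_reference <- function(n_families = 4L, members_per_family = 2L,
                               length_range = c(70L, 76L), divergence = 0.05,
                               seed = 1L) {
  stopifnot(n_families >= 1, members_per_family >= 1,
            divergence >= 0, divergence <= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    anticodons <- character(0)
    while (length(anticodons) < n_families) {
      cand <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cand %in% anticodons && anticodon_to_aa(cand) != "Und")
        anticodons <- c(anticodons, cand)
    }
    ids <- character(0); seqs <- character(0); fam_rows <- list()
    for (f in seq_len(n_families)) {
      len <- sample(length_range[1]:length_range[2], 1)
      body_len <- len - 3L
      base_body <- paste(sample(bases, body_len, replace = TRUE), collapse = "")
      # embed the anticodon so families differ by a recognizable core
      substr(base_body, 34, 36) <- anticodons[f]
      aa <- anticodon_to_aa(anticodons[f])
      for (m in seq_len(members_per_family)) {
        body <- base_body
        if (m > 1 && divergence > 0) {
          ch <- strsplit(body, "")[[1]]
          mut <- which(runif(body_len) < divergence)
          for (p in mut) ch[p] <- sample(setdiff(bases, ch[p]), 1)
          body <- paste(ch, collapse = "")
        }
        id <- sprintf("tRNA-%s-%s-%d-%d", aa, anticodons[f], f, m)
        ids <- c(ids, id); seqs <- c(seqs, paste0(body, "CCA"))
        fam_rows[[length(fam_rows) + 1L]] <-
          data.frame(id = id, family = f, anticodon = anticodons[f],
                     stringsAsFactors = FALSE)
      }
    }
    list(ref = new_reference(ids, seqs),
         families = do.call(rbind, fam_rows))
  })
}

#' Ground-truth parameters for read simulation
#'
#' @param ref a `trna_reference`.
#' @param charge named numeric (per transcript id) probability in `[0, 1]`
#'   that a molecule retains its CCA end; recycled if unnamed scalar.
#' @param abundance relative abundance weights (normalized internally).
#' @param hotspots named list: transcript id -> data.frame(`position`
#'   (0-based), `mismatch_prob`, `gap_prob`, `falloff_prob`).
#' @param falloff_prob per-position geometric RT-falloff probability.
#' @param seq_error uniform per-base sequencing error rate.
#' @param min_read_len minimum simulated tRNA-portion length.
#' @param duplicate_rate probability a molecule is emitted twice with the
#'   same UMI (PCR duplication).
#' @return a `sim_truth` list.
#' @export
sim_truth <- function(ref, charge = 0.7, abundance = NULL, hotspots = list(),
                      falloff_prob = 0.005, seq_error = 0.001,
                      min_read_len = 30L, duplicate_rate = 0) {
  n <- nrow(ref)
  if (is.null(names(charge))) charge <- setNames(rep_len(charge, n), ref$id)
  if (is.null(abundance)) abundance <- setNames(rep(1 / n, n), ref$id)
  abundance <- abundance / sum(abundance)
  stopifnot(all(charge >= 0 & charge <= 1), all(abundance >= 0))
  structure(list(charge = charge, abundance = abundance, hotspots = hotspots,
                 falloff_prob = falloff_prob, seq_error = seq_error,
                 min_read_len = min_read_len, duplicate_rate = duplicate_rate),
            class = "sim_truth")
}

.random_umi <- function(n) {
  first <- sample(c("A", "G"), n, replace = TRUE)
  rest <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = ""),
    character(1))
  paste0(first, rest)
}

.apply_seq_error <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (p in hit) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate charge tRNA-Seq reads with full ground truth
#'
#' Emulates the assay's data-generating process: each molecule picks a
#' transcript by abundance; retains its CCA end with the transcript's true
#' charge probability (else ends in CC); is 5'-truncated by per-position
#' geometric RT falloff plus any hotspot-specific falloff; acquires
#' modification-hotspot mismatches and gaps and uniform sequencing error;
#' and is emitted as `UMI (10 nt, purine-led) + tRNA portion + adapter
#' barcode + splint context`. The returned truth table records every event.
#'
#' @param ref a `trna_reference`.
#' @param truth a [sim_truth()].
#' @param n_reads number of molecules to simulate.
#' @param adapters adapter table ([read_adapters()]); one is assigned
#'   uniformly per read.
#' @param seed RNG seed.
#' @return list with `reads` (character vector of full read sequences) and
#'   `truth_table` (data.frame: transcript, true_end, adapter_id, umi,
#'   trna_start (0-based 5' index of the covered suffix), n_errors).
#' @export
simulate_reads <- function(ref, truth, n_reads, adapters, seed = 1L) {
  with_seed(seed, {
    tidx <- sample.int(nrow(ref), n_reads, replace = TRUE,
                       prob = truth$abundance[ref$id])
    aidx <- sample.int(nrow(adapters), n_reads, replace = TRUE)
    umi <- .random_umi(n_reads)
    is_cca <- runif(n_reads) < truth$charge[ref$id[tidx]]
    reads <- character(n_reads)
    trna_start <- integer(n_reads)
    n_err <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      tr <- ref$sequence[tidx[i]]
      len <- nchar(tr)
      mol <- if (is_cca[i]) tr else substr(tr, 1, len - 1L)
      mlen <- nchar(mol)
      hs <- truth$hotspots[[ref$id[tidx[i]]]]
      # RT extends 3'->5', stopping at each base with prob falloff_prob;
      # the synthesized length caps the 5' truncation, never below
      # min_read_len of covered transcript.
      max_trunc <- max(mlen - truth$min_read_len, 0L)
      trunc <- if (truth$falloff_prob > 0) {
        synth_len <- 1L + rgeom(1, truth$falloff_prob)
        min(max(mlen - synth_len, 0L), max_trunc)
      } else 0L
      # hotspot-driven RT stop: falls off 5' of the hotspot
      if (!is.null(hs)) for (h in seq_len(nrow(hs))) {
        fo <- hs$falloff_prob[h] %||% 0
        if (length(fo) && !is.na(fo) && fo > 0 && runif(1) < fo) {
          stop_at <- hs$position[h] + 1L   # 5'-most surviving index
          trunc <- max(trunc, min(stop_at, max_trunc))
        }
      }
      start0 <- trunc                       # 0-based 5' index of the portion
      portion <- substr(mol, start0 + 1L, mlen)
      # hotspot mismatches / gaps
      if (!is.null(hs)) {
        ch <- strsplit(portion, "")[[1]]
        drop <- integer(0)
        for (h in seq_len(nrow(hs))) {
          rel <- hs$position[h] - start0 + 1L
          if (rel < 1 || rel > length(ch)) next
          mp <- hs$mismatch_prob[h] %||% 0
          gp <- if ("gap_prob" %in% names(hs)) hs$gap_prob[h] else 0
          if (!is.na(mp) && mp > 0 && runif(1) < mp) {
            ch[rel] <- sample(setdiff(c("A", "C", "G", "T"), ch[rel]), 1)
            n_err[i] <- n_err[i] + 1L
          } else if (!is.na(gp) && gp > 0 && runif(1) < gp) {
            drop <- c(drop, rel)
            n_err[i] <- n_err[i] + 1L
          }
        }
        if (length(drop)) ch <- ch[-drop]
        portion <- paste(ch, collapse = "")
      }
      portion <- .apply_seq_error(portion, truth$seq_error)
      reads[i] <- paste0(umi[i], portion, adapters$search_seq[aidx[i]])
      trna_start[i] <- start0
    }
    tt <- data.frame(transcript = ref$id[tidx],
                     true_end = ifelse(is_cca, "CCA", "CC"),
                     adapter_id = adapters$adapter_id[aidx],
                     umi = umi, trna_start = trna_start, n_errors = n_err,
                     stringsAsFactors = FALSE)
    if (truth$duplicate_rate > 0) {
      dup <- which(runif(n_reads) < truth$duplicate_rate)
      reads <- c(reads, reads[dup])
      tt <- rbind(tt, tt[dup, , drop = FALSE])
      rownames(tt) <- NULL
    }
    list(reads = reads, truth_table = tt)
  })
}

#' Write simulated reads as FASTQ
#' @param reads character vector of read sequences.
#' @param path output path (`.gz` supported).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read_%06d", seq_along(reads))
  q <- Biostrings::PhredQuality(
    vapply(nchar(reads), function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Simulate a charge-titration dataset
#'
#' Measurements follow [predict_titration_charge()] with the given true F,
#' plus Gaussian noise and optional per-adapter systematic offsets, clipped
#' to `[0, 100]`. The default mixing design is the eight intact/deacylated
#' percentages 100/0, 85/15, 70/30, 55/45, 40/60, 25/75, 10/90, 0/100.
#'
#' @param transcripts transcript ids.
#' @param F_true named (or recycled) true correction factors.
#' @param T_A_true,T_B_true true endpoint charges (percent).
#' @param ratios percent-intact design points (must include 100 and 0).
#' @param n_reps replicates per ratio.
#' @param noise_sd Gaussian noise sd in percentage points.
#' @param adapter_bias optional named numeric of per-adapter offsets (pp);
#'   replicate r uses adapter `names(adapter_bias)[r]` cyclically, or
#'   adapters `I1Sp..I<n>Sp` when unnamed.
#' @param seed RNG seed.
#' @return data.frame: transcript, ratio_p, replicate, adapter,
#'   measured_charge.
#' @export
simulate_titration <- function(transcripts, F_true = 1, T_A_true = 90,
                               T_B_true = 5,
                               ratios = c(100, 85, 70, 55, 40, 25, 10, 0),
                               n_reps = 4L, noise_sd = 1,
                               adapter_bias = NULL, seed = 1L) {
  stopifnot(100 %in% ratios, 0 %in% ratios)
  nt <- length(transcripts)
  F_true <- setNames(rep_len(F_true, nt), transcripts)
  T_A_true <- setNames(rep_len(T_A_true, nt), transcripts)
  T_B_true <- setNames(rep_len(T_B_true, nt), transcripts)
  adapters <- if (!is.null(adapter_bias) && !is.null(names(adapter_bias)))
    names(adapter_bias) else sprintf("I%dSp", seq_len(n_reps))
  bias <- setNames(rep(0, length(adapters)), adapters)
  if (!is.null(adapter_bias))
    bias[names(adapter_bias) %||% adapters] <- adapter_bias
  with_seed(seed, {
    grid <- expand.grid(transcript = transcripts, ratio_p = ratios,
                        replicate = seq_len(n_reps), stringsAsFactors = FALSE)
    grid$adapter <- adapters[(grid$replicate - 1L) %% length(adapters) + 1L]
    mu <- predict_titration_charge(grid$ratio_p, T_A_true[grid$transcript],
                                   T_B_true[grid$transcript],
                                   F_true[grid$transcript])
    grid$measured_charge <- pmin(pmax(
      mu + bias[grid$adapter] + rnorm(nrow(grid), 0, noise_sd), 0), 100)
    rownames(grid) <- NULL
    grid
  })
}

#' Simulate aminoacylation decay series
#'
#' Charges follow [decay_value()] plus Gaussian noise, clipped to
#' `[0, 100]`. The default design is t = 0 plus 4, 8, 16, 32 min, 1, 2, 4,
#' 8, 16 and 40 h (11 timepoints) with 4 replicates.
#'
#' @param params data.frame with columns `group`, `N0`, `t_half`, `N_inf`.
#' @param timepoints sampling times in minutes.
#' @param n_reps replicates per timepoint.
#' @param noise_sd Gaussian noise sd (pp).
#' @param seed RNG seed.
#' @return data.frame: group, time_min, replicate, charge.
#' @export
simulate_decay <- function(params,
                           timepoints = c(0, 4, 8, 16, 32, 60, 120, 240,
                                          480, 960, 2400),
                           n_reps = 4L, noise_sd = 1, seed = 1L) {
  stopifnot(all(c("group", "N0", "t_half", "N_inf") %in% names(params)))
  with_seed(seed, {
    grid <- expand.grid(group = params$group, time_min = timepoints,
                        replicate = seq_len(n_reps), stringsAsFactors = FALSE)
    i <- match(grid$group, params$group)
    mu <- decay_value(grid$time_min, params$N0[i], params$t_half[i],
                      params$N_inf[i])
    grid$charge <- pmin(pmax(mu + rnorm(nrow(grid), 0, noise_sd), 0), 100)
    grid <- grid[order(grid$group, grid$time_min, grid$replicate), ]
    rownames(grid) <- NULL
    grid
  })
}

#' A small default adapter table for simulations and examples
#'
#' Nine adapters with 5-8 nt barcodes and a shared splint-context sequence,
#' validated to satisfy the distance-1 unambiguity requirement.
#'
#' @param n number of adapters (max 9).
#' @return adapter table as from [read_adapters()].
#' @export
example_adapters <- function(n = 4L) {
  tab <- data.frame(
    adapter_id = sprintf("I%dSp", 1:9),
    barcode = c("AACGT", "TGCAGT", "GATCGAC", "CTAGATCG",
                "CGTAC", "ACTTGA", "CTAGTCA", "GACTCGTA", "GTACA"),
    splint_context = "TGGAATTCTCG",
    stringsAsFactors = FALSE)
  read_adapters(tab[seq_len(n), , drop = FALSE])
}
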