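#' Build and validate a pipeline run configuration
#'
#' Collects every tunable of the pipeline in one validated list, serialized
#' verbatim into the output directory so a run is reproducible from its
#' artifacts. Charge is always reported on the 0-100 percent scale;
#' mismatch/gap fractions on 0-1.
#'
#' @param reference_fasta path to the mature tRNA reference FASTA.
#' @param adapter_table path to (or data.frame of) the adapter table.
#' @param output_dir output directory (created if absent).
#' @param mask optional path to a mask TSV, or a mask set list.
#' @param min_len minimum merged-read length (25 blunt-end, 39 splint).
#' @param min_score minimum alignment score to count a read as mapped.
#' @param downsample_cap per-sample read cap.
#' @param min_charge_reads minimum reads for a confident charge value.
#' @param seed RNG seed used by every stochastic step.
#' @return a validated `run_config` list.
#' @export
run_config <- function(reference_fasta, adapter_table, output_dir,
                       mask = NULL, min_len = 25L, min_score = 20L,
                       downsample_cap = 2e6, min_charge_reads = 100L,
                       seed = 1L) {
  if (!file.exists(reference_fasta))
    stop("reference FASTA not found: ", reference_fasta)
  if (is.character(adapter_table) && !file.exists(adapter_table))
    stop("adapter table not found: ", adapter_table)
  structure(list(reference_fasta = reference_fasta,
                 adapter_table = adapter_table, output_dir = output_dir,
                 mask = mask, min_len = as.integer(min_len),
                 min_score = as.integer(min_score),
                 downsample_cap = downsample_cap,
                 min_charge_reads = as.integer(min_charge_reads),
                 seed = as.integer(seed)),
            class = "run_config")
}

.out_header <- function(config) {
  c(sprintf("# trnacharge %s", as.character(utils::packageVersion("trnacharge"))),
    sprintf("# seed: %d", config$seed),
    "# charge_pct on 0-100 scale; fractions on 0-1; positions 0-based")
}

write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full charge tRNA-Seq pipeline on merged reads
#'
#' Orchestrates demultiplex -> downsample -> align (masked reference) ->
#' charge / RPM tables at all three levels -> misincorporation profiles,
#' writing per-sample TSVs and a machine-readable JSON summary (stage
#' counts, UMI QC, mapping and multi-anticodon percentages) into
#' `config$output_dir`. Reads are either given in memory (`seqs`) or read
#' from a FASTQ path.
#'
#' @param config a [run_config()].
#' @param seqs character vector of merged reads, or a FASTQ path.
#' @param sample_id sample label.
#' @return (invisibly) list with `ann`, `charge`, `rpm`, `profiles`,
#'   `summary`; files written under `config$output_dir`.
#' @export
run_pipeline <- function(config, seqs, sample_id = "sample") {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(seqs) && length(seqs) == 1 && file.exists(seqs))
    seqs <- as.character(Biostrings::readDNAStringSet(seqs, format = "fastq"))
  ref <- load_reference(config$reference_fasta)
  ref <- ensure_cca(ref)
  adapters <- read_adapters(config$adapter_table)
  mask <- if (is.null(config$mask)) list()
          else if (is.character(config$mask)) read_mask(config$mask)
          else config$mask

  dm <- demultiplex_reads(seqs, adapters, sample_id)
  reads <- downsample(dm$reads, config$downsample_cap, config$seed)
  qc <- umi_qc(reads$umi)

  ann <- align_reads(reads, apply_mask(ref, mask), align_scheme(),
                     config$min_score)
  realn <- realign_unmasked(ann, ref)
  profiles <- build_profiles(realn, ref)

  hdr <- .out_header(config)
  charge <- list(); rpm <- list()
  for (level in c("transcript", "anticodon", "amino_acid")) {
    charge[[level]] <- charge_table(ann, level, config$min_charge_reads, ref)
    rpm[[level]] <- rpm_table(ann, level, ref)
    write_tsv(charge[[level]],
              file.path(config$output_dir,
                        sprintf("%s_charge_%s.tsv", sample_id, level)), hdr)
    write_tsv(rpm[[level]],
              file.path(config$output_dir,
                        sprintf("%s_rpm_%s.tsv", sample_id, level)), hdr)
  }
  write_tsv(profiles,
            file.path(config$output_dir, sprintf("%s_profiles.tsv", sample_id)),
            hdr)

  mapped <- ann$mapped %in% TRUE
  summary <- list(
    sample = sample_id,
    seed = config$seed,
    counts = as.list(dm$counts),
    n_after_downsample = nrow(reads),
    umi_qc = as.list(qc),
    pct_mapped = 100 * mean(mapped),
    pct_multi_anticodon = if (any(mapped))
      100 * mean(!(ann$unique_anticodon[mapped] %in% TRUE)) else NA,
    mask_positions = mask_size(mask))
  jsonlite::write_json(summary,
                       file.path(config$output_dir,
                                 sprintf("%s_summary.json", sample_id)),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(ann = ann, charge = charge, rpm = rpm,
                 profiles = profiles, summary = summary))
}
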