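#' Parse a GtRNAdb-style tRNA transcript name
#'
#' Names of the form `tRNA-<AA>-<anticodon>-<family>-<copy>` (e.g.
#' `tRNA-Lys-TTT-3-1`) yield the three-letter amino-acid code and the
#' anticodon. Names that do not parse (spike-in oligos, arbitrary controls)
#' are flagged `"Und"` for both fields rather than dropped. Mitochondrial
#' transcripts are recognized by an `mt`/`MT`/`mito` prefix.
#'
#' @param id character vector of sequence names.
#' @return data.frame with columns `amino_acid`, `anticodon`, `is_mito`.
#' @examples
#' parse_trna_name("tRNA-Lys-TTT-3-1")
#' @export
parse_trna_name <- function(id) {
  m <- regmatches(id, regexec("tRNA-([A-Za-z]{3}|iMet|fMet|SeC|Sup|Und)-([ACGTacgtn]{3})", id))
  aa <- vapply(m, function(x) if (length(x) == 3) x[2] else "Und", character(1))
  ac <- vapply(m, function(x) if (length(x) == 3) toupper(x[3]) else "Und", character(1))
  data.frame(amino_acid = aa, anticodon = ac,
             is_mito = grepl("^(mt|MT|mito)", id), stringsAsFactors = FALSE)
}

new_reference <- function(id, sequence, is_spikein = FALSE,
                          name_parser = parse_trna_name) {
  sequence <- toupper(sequence)
  bad <- !grepl("^[ACGTN]+$", sequence)
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ", paste(id[bad], collapse = ", "))
  parsed <- name_parser(id)
  out <- data.frame(id = id, amino_acid = parsed$amino_acid,
                    anticodon = parsed$anticodon, sequence = sequence,
                    is_spikein = rep_len(is_spikein, length(id)),
                    is_mito = parsed$is_mito, stringsAsFactors = FALSE)
  class(out) <- c("trna_reference", "data.frame")
  out
}

#' Load and deduplicate a mature tRNA transcript reference
#'
#' Reads a FASTA of mature tRNA sequences (GtRNAdb-style names expected by
#' the default parser), deduplicates byte-identical sequences keeping the
#' first occurrence's id, and appends spike-in control sequences flagged as
#' such. Sequences are expected to be spliced/mature; no intron handling is
#' performed.
#'
#' @param fasta_path path to the reference FASTA.
#' @param spikein_fastas optional character vector of FASTA paths whose
#'   records are appended and flagged `is_spikein`.
#' @param name_parser function mapping ids to amino acid / anticodon /
#'   mitochondrial flags; defaults to [parse_trna_name()].
#' @return a `trna_reference` object (data.frame with columns `id`,
#'   `amino_acid`, `anticodon`, `sequence`, `is_spikein`, `is_mito`).
#' @export
load_reference <- function(fasta_path, spikein_fastas = character(),
                           name_parser = parse_trna_name) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0) stop("empty FASTA: ", fasta_path)
  ref <- new_reference(sub("\\s.*", "", names(seqs)), as.character(seqs),
                       is_spikein = FALSE, name_parser = name_parser)
  for (sp in spikein_fastas) {
    ss <- Biostrings::readDNAStringSet(sp)
    ref <- rbind_reference(ref, new_reference(sub("\\s.*", "", names(ss)),
                                              as.character(ss), is_spikein = TRUE,
                                              name_parser = name_parser))
  }
  dedup_reference(ref)
}

rbind_reference <- function(a, b) {
  out <- rbind(as.data.frame(a), as.data.frame(b))
  class(out) <- c("trna_reference", "data.frame")
  out
}

dedup_reference <- function(ref) {
  dup_id <- duplicated(ref$id)
  if (any(dup_id)) {
    clash <- unique(ref$id[dup_id])
    for (cid in clash) {
      if (length(unique(ref$sequence[ref$id == cid])) > 1)
        stop("duplicate id with different sequences: ", cid)
    }
    ref <- ref[!dup_id, , drop = FALSE]
  }
  keep <- !duplicated(ref$sequence)
  out <- ref[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trna_reference", "data.frame")
  out
}

#' @export
print.trna_reference <- function(x, ...) {
  cat(sprintf("tRNA reference: %d transcripts (%d spike-in, %d mitochondrial)\n",
              nrow(x), sum(x$is_spikein), sum(x$is_mito)))
  cat(sprintf("  anticodons: %d; lengths %d-%d nt\n",
              length(unique(x$anticodon[x$anticodon != "Und"])),
              min(nchar(x$sequence)), max(nchar(x$sequence))))
  invisible(x)
}

#' Ensure every reference sequence ends in the mature 3'-terminal CCA
#'
#' All molecules sequenced by the assay end in CCA (charged, protected) or CC
#' (uncharged, after removal of the terminal A); charge classification relies
#' on the reference carrying the full CCA. Sequences already ending in `CCA`
#' are untouched; others get `CCA` appended. A sequence ending in `CC` is
#' ambiguous (it may be a truncated CCA) and triggers a warning while still
#' being extended.
#'
#' @param ref a `trna_reference`.
#' @return the reference with all sequences ending in `CCA`.
#' @export
ensure_cca <- function(ref) {
  needs <- !endsWith(ref$sequence, "CCA")
  amb <- needs & endsWith(ref$sequence, "CC")
  if (any(amb))
    warning("sequence(s) ending in 'CC' extended to '...CCCCA' (ambiguous): ",
            paste(ref$id[amb], collapse = ", "))
  ref$sequence[needs] <- paste0(ref$sequence[needs], "CCA")
  ref
}

#' Apply an N-mask to a reference
#'
#' Replaces the given 0-based positions of each transcript with `N`, the
#' neutrally-scored wildcard of the alignment scheme, so that
#' modification-induced misincorporations at those positions do not penalize
#' the alignment score. The input object is not modified.
#'
#' @param ref a `trna_reference`.
#' @param mask a mask set: named list mapping transcript id to an integer
#'   vector of 0-based positions (see [read_mask()]).
#' @return the masked `trna_reference`.
#' @export
apply_mask <- function(ref, mask) {
  for (tid in names(mask)) {
    pos <- mask[[tid]]
    if (length(pos) == 0) next
    i <- match(tid, ref$id)
    if (is.na(i)) stop("mask refers to unknown transcript: ", tid)
    len <- nchar(ref$sequence[i])
    bad <- pos < 0 | pos >= len
    if (any(bad))
      stop(sprintf("mask position out of range for %s: %s (length %d)",
                   tid, paste(pos[bad], collapse = ","), len))
    s <- strsplit(ref$sequence[i], "")[[1]]
    s[pos + 1] <- "N"
    ref$sequence[i] <- paste(s, collapse = "")
  }
  ref
}

#' Read / write a mask set as TSV
#'
#' Format: `transcript_id<TAB>comma-separated 0-based positions`, one line
#' per transcript.
#'
#' @param path file path.
#' @return `read_mask`: named list of integer vectors.
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0) return(structure(list(), names = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mask <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) integer(0)
    else sort(unique(as.integer(strsplit(p[2], ",", fixed = TRUE)[[1]])))
  })
  names(mask) <- vapply(parts, `[`, character(1), 1)
  mask
}

#' @param mask named list of integer position vectors.
#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  lines <- vapply(names(mask), function(tid)
    paste0(tid, "\t", paste(sort(unique(mask[[tid]])), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference to single-line FASTA
#' @param ref a `trna_reference`.
#' @param path output path.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- ref$id
  Biostrings::writeXStringSet(x, path, width = 20001L)
  invisible(path)
}

# Total number of masked positions in a mask set.
mask_size <- function(mask) sum(lengths(mask))
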