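# Plain-text readers/writers for the pipeline's exchange formats. TSVs are
# written without quoting or row names so files diff cleanly across runs.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write genomes (or their genes) to FASTA
#'
#' @param x A `synthetic_genome`, a list of them, or a named character
#'   vector of sequences.
#' @param path Output file.
#' @param what `"genome"` or `"genes"` (coding sequences) for
#'   `synthetic_genome` input.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path, what = c("genome", "genes")) {
  what <- match.arg(what)
  seqs <- if (inherits(x, "synthetic_genome")) {
    if (what == "genome") stats::setNames(x$sequence, x$genome_id)
    else gene_sequences(x)
  } else if (is.list(x) && all(vapply(x, inherits, logical(1), "synthetic_genome"))) {
    if (what == "genome") {
      stats::setNames(vapply(x, `[[`, character(1), "sequence"),
                      vapply(x, `[[`, character(1), "genome_id"))
    } else do.call(c, lapply(x, gene_sequences))
  } else {
    unlist(x)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a coverage profile in samtools-depth dialect
#'
#' Three tab-separated columns: scaffold id, 1-based position, depth.
#'
#' @param profile A `coverage_profile` or list of them.
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_coverage_tsv <- function(profile, path) {
  profiles <- if (inherits(profile, "coverage_profile")) list(profile) else profile
  df <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(scaffold = p$genome_id, pos = seq_len(p$length),
               depth = p$depth)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read samtools-depth TSV into coverage profiles
#'
#' Accepts the headerless three-column dialect (scaffold, 1-based position,
#' depth). Positions absent from the file are taken as depth 0 up to the
#' observed maximum (or `lengths[scaffold]` when provided).
#'
#' @param path Input TSV.
#' @param lengths Optional named vector of scaffold lengths.
#' @return Named list of `coverage_profile` objects.
#' @export
read_coverage_tsv <- function(path, lengths = NULL) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          col.names = c("scaffold", "pos", "depth"),
                          stringsAsFactors = FALSE)
  out <- lapply(split(df, df$scaffold), function(d) {
    L <- if (!is.null(lengths) && d$scaffold[1] %in% names(lengths)) {
      as.integer(lengths[[d$scaffold[1]]])
    } else max(d$pos)
    depth <- numeric(L)
    depth[d$pos] <- d$depth
    structure(list(genome_id = d$scaffold[1], depth = depth, length = L),
              class = "coverage_profile")
  })
  out
}

#' Write site metadata for a synthetic panel
#' @param panel Result of [generate_site_panel()] (or its `metadata`).
#' @param path Output TSV.
#' @return The path, invisibly.
#' @export
write_site_metadata <- function(panel, path) {
  meta <- if (is.data.frame(panel)) panel else panel$metadata
  write_tsv(meta, path)
}

#' Write / read a per-protein lineage table
#'
#' Columns: protein_id, scaffold_id, then the seven canonical ranks; blank
#' cells mean unannotated.
#'
#' @param lineage_table data.frame as used by [classify_assembly()].
#' @param path TSV path.
#' @return The path (write) or the data.frame with blanks as NA (read).
#' @export
write_lineage_tsv <- function(lineage_table, path) write_tsv(lineage_table, path)

#' @rdname write_lineage_tsv
#' @export
read_lineage_tsv <- function(path) {
  df <- read_tsv(path, na.strings = c("NA", ""))
  df
}

#' Write / read a key-enzyme hit table
#' @param hits data.frame as used by [pathway_matrix()].
#' @param path TSV path.
#' @return The path (write) or the data.frame (read).
#' @export
write_enzyme_hits <- function(hits, path) write_tsv(hits, path)

#' @rdname write_enzyme_hits
#' @export
read_enzyme_hits <- function(path) read_tsv(path)
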