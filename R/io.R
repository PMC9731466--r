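# File formats: rearrangement tables as AIRR-style TSV, germline sets as
# FASTA plus an anchor side-car TSV, trees as newick, configuration as
# YAML.  TSV dialect: tab-separated, no quoting, UTF-8, semicolon-
# separated id lists; coordinates 0-based half-open.

.airr_required <- c("sequence_id", "sequence", "locus")
.airr_char_cols <- c("sequence_id", "sequence", "locus", "cell_id",
                     "droplet_id", "clone_id", "true_partner", "paired_ids",
                     "v_call", "d_call", "j_call", "naive_sequence",
                     "junction", "partner_id", "status")

#' Read an AIRR-style rearrangement TSV
#'
#' Requires columns `sequence_id`, `sequence`, `locus`; all other columns
#' are preserved as-is, so [write_airr()] then `read_airr()` round-trips
#' losslessly.
#'
#' @param path File path.
#' @return Data frame of sequence records.
#' @export
read_airr <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(.airr_required, hdr)
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  cc <- ifelse(hdr %in% .airr_char_cols, "character", NA)
  out <- read.delim(path, sep = "\t", quote = "", colClasses = cc,
                    stringsAsFactors = FALSE, na.strings = "NA")
  # empty id lists are empty strings, not missing
  if ("paired_ids" %in% names(out))
    out$paired_ids[is.na(out$paired_ids)] <- ""
  out
}

#' Write an AIRR-style rearrangement TSV
#'
#' @param records Data frame with at least `sequence_id`, `sequence`,
#'   `locus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr <- function(records, path) {
  missing <- setdiff(.airr_required, names(records))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a germline set as FASTA plus an anchor side-car TSV
#'
#' One FASTA record per allele; anchor offsets (0-based start of the CDR3
#' anchor codon) and prevalence frequencies go into `<base>_anchors.tsv`.
#'
#' @param germ A germline set.
#' @param fasta_path Path of the FASTA file to write.
#' @return `fasta_path`, invisibly.
#' @export
write_germline_set <- function(germ, fasta_path) {
  seqs <- Biostrings::DNAStringSet(setNames(germ$sequence, germ$name))
  Biostrings::writeXStringSet(seqs, fasta_path)
  side <- sub("\\.fa(sta)?$", "", fasta_path)
  write.table(germ[, c("name", "locus", "region", "anchor", "prevalence")],
              paste0(side, "_anchors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}

#' Read a germline set written by [write_germline_set()]
#'
#' @param fasta_path Path of the FASTA file.
#' @return A `germline_set` data frame.
#' @export
read_germline_set <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  side <- paste0(sub("\\.fa(sta)?$", "", fasta_path), "_anchors.tsv")
  meta <- read.delim(side, sep = "\t", stringsAsFactors = FALSE)
  out <- meta
  out$sequence <- as.character(seqs[meta$name])
  out <- out[, c("name", "locus", "region", "sequence", "anchor", "prevalence")]
  class(out) <- c("germline_set", "data.frame")
  out
}

#' Write simulation truth trees as newick
#'
#' @param events Events data frame from [simulate_paired_repertoire()].
#' @param path Output path (one newick per line, named by clone id).
#' @return `path`, invisibly.
#' @export
write_truth_trees <- function(events, path) {
  writeLines(paste0(events$newick), path)
  invisible(path)
}

#' Write a simulation configuration echo as YAML
#'
#' @param cfg A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
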