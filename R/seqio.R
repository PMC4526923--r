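# Sequence input/output and the length / C-terminal-window preprocessing
# applied to candidate small secretory peptides.

#' Read a protein FASTA file into a protein table
#'
#' Each entry becomes one row. The record ID is the first whitespace-
#' delimited token of the header; a `species=` key anywhere in the header is
#' parsed into the `species` column (empty string when absent). Sequences
#' are uppercased and trailing `*` stop characters are stripped. Splice
#' variants are ordinary independent records.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `ssp_proteins` with columns `id`,
#'   `species`, `sequence` and `length` (residues).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0)
    stop("malformed FASTA: no entries in ", path, call. = FALSE)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1L)
  if (any(!nzchar(ids)))
    stop("malformed FASTA: entry ", which(!nzchar(ids))[1L],
         " has an empty header", call. = FALSE)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ID: ", dup[1L], call. = FALSE)
  species <- vapply(headers, function(h) {
    m <- regmatches(h, regexpr("species=\\S+", h))
    if (length(m)) sub("^species=", "", m) else ""
  }, "", USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("malformed FASTA: entry '", ids[which(empty)[1L]],
         "' has an empty sequence", call. = FALSE)
  ssp_proteins(ids, species, seqs)
}

#' Construct a protein table
#'
#' @param id Character vector of unique, non-empty IDs.
#' @param species Character vector of species tags (recycled; may be empty
#'   strings).
#' @param sequence Character vector of uppercase amino-acid sequences over
#'   the 20-letter alphabet plus `X`.
#' @return A data frame of class `ssp_proteins`.
#' @export
ssp_proteins <- function(id, species = "", sequence) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  if (any(!nzchar(id))) stop("empty protein ID", call. = FALSE)
  if (anyDuplicated(id))
    stop("duplicate sequence ID: ", id[duplicated(id)][1L], call. = FALSE)
  if (any(!nzchar(sequence))) stop("empty sequence", call. = FALSE)
  bad <- grepl(paste0("[^", paste(AAX, collapse = ""), "]"), sequence)
  if (any(bad))
    stop("sequence '", id[which(bad)[1L]], "' contains non-amino-acid ",
         "characters", call. = FALSE)
  out <- data.frame(id = id, species = rep_len(as.character(species),
                                               length(id)),
                    sequence = sequence, length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("ssp_proteins", "data.frame")
  out
}

#' Write a protein table to FASTA
#'
#' @param proteins An `ssp_proteins` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins$sequence)
  names(set) <- ifelse(nzchar(proteins$species),
                       paste0(proteins$id, " species=", proteins$species),
                       proteins$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Keep proteins strictly shorter than a length cutoff
#'
#' Candidate small secretory peptides are precursors of less than 200
#' residues; the cutoff is strict (a 200-residue protein is removed).
#' Input order is preserved and the number of removed records is attached
#' as the `n_removed` attribute.
#'
#' @param proteins An `ssp_proteins` data frame.
#' @param max_len Strict upper bound on protein length (default 200).
#' @return The filtered `ssp_proteins` data frame with attribute
#'   `n_removed`.
#' @export
filter_by_length <- function(proteins, max_len = 200L) {
  stopifnot(max_len >= 1)
  keep <- proteins$length < max_len
  out <- proteins[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ssp_proteins", "data.frame")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-species report of the length filter
#'
#' @param proteins The unfiltered `ssp_proteins` data frame.
#' @param max_len Strict length cutoff.
#' @return Data frame with columns `species`, `n_input`, `n_short`,
#'   `n_removed`.
#' @export
length_filter_report <- function(proteins, max_len = 200L) {
  sp <- proteins$species
  sp[!nzchar(sp)] <- "(none)"
  short <- proteins$length < max_len
  agg <- lapply(split(short, sp), function(v)
    c(n_input = length(v), n_short = sum(v), n_removed = sum(!v)))
  out <- data.frame(species = names(agg),
                    do.call(rbind, agg), row.names = NULL,
                    stringsAsFactors = FALSE)
  out
}

#' Extract C-terminal segments
#'
#' Returns the last `window` residues of each protein (the search unit for
#' the all-against-all comparison). Proteins shorter than the window
#' contribute their whole sequence.
#'
#' @param proteins An `ssp_proteins` data frame (one or more rows).
#' @param window Window size in residues (default 50).
#' @return A data frame of class `ssp_segments` with columns `parent_id`,
#'   `sequence` and `offset` (0-based start of the suffix in the parent).
#' @export
extract_cterm <- function(proteins, window = 50L) {
  stopifnot(window >= 1)
  len <- proteins$length
  seglen <- pmin(window, len)
  offset <- len - seglen
  out <- data.frame(parent_id = proteins$id,
                    sequence = substr(proteins$sequence, offset + 1L, len),
                    offset = as.integer(offset),
                    stringsAsFactors = FALSE)
  class(out) <- c("ssp_segments", "data.frame")
  out
}
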