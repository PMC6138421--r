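#' Read sequences from a FASTA file
#'
#' Multi-record FASTA with wrapped lines is tolerated. Records are uppercased
#' on ingest and validated against the working alphabet `{A, C, G, T, N, X}`
#' ('X' is the mutation model's data-error symbol). Record ids are the header
#' token up to the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE`, reject any base outside `{A, C, G, T}` instead of
#'   accepting the ambiguity/error symbols `N` and `X`.
#' @return A named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, strict = FALSE) {
  check_string(path, "path")
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("FASTA file has no records: %s", path))
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  for (i in seq_along(seqs)) validate_bases(seqs[[i]], names(seqs)[i], strict = strict)
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("`seqs` must be a named character vector.")
  }
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

validate_bases <- function(seq, id = "sequence", strict = FALSE) {
  alphabet <- if (strict) "ACGT" else "ACGTNX"
  bad <- gsub(sprintf("[%s]", alphabet), "", seq)
  if (nzchar(bad)) {
    abort(sprintf(
      "Record '%s' contains characters outside {%s}: e.g. '%s'.",
      id, paste(strsplit(alphabet, "")[[1]], collapse = ","), substr(bad, 1, 1)
    ))
  }
  if (!nzchar(seq)) abort(sprintf("Record '%s' is empty.", id))
  invisible(seq)
}

# First `max_len` bases of over-long sequences; shorter sequences unchanged.
truncate_seq <- function(seq, max_len) {
  if (is.null(max_len) || is.na(max_len)) return(seq)
  substr(seq, 1L, max_len)
}
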