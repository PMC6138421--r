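#' Build the database index (Database Owner side)
#'
#' Sketches every database record with the Querier-provided constructor, in
#' FASTA order. Sequences longer than `truncate_len` contribute only their
#' first `truncate_len` bases. Entry ids are the FASTA header token up to the
#' first whitespace.
#'
#' @param db A FASTA path or a named character vector of sequences.
#' @param constructor The shared [lsh_constructor()] received from the Querier.
#' @param truncate_len Maximum bases per entry used for sketching, or `NULL`
#'   for no cap.
#' @return A `db_index`: entry ids, one `lsh_vector` per entry, the
#'   constructor, the pre-truncation maximum record length (`max_seq_len_raw`)
#'   and the post-cap maximum (`max_seq_len`, the value LSH sizing needs).
#' @export
build_index <- function(db, constructor, truncate_len = NULL) {
  stopifnot(inherits(constructor, "lsh_constructor"))
  seqs <- if (is.character(db) && length(db) == 1L && is.null(names(db))) {
    read_fasta(db)
  } else {
    if (is.null(names(db))) abort("`db` must be a FASTA path or a *named* character vector.")
    toupper(db)
  }
  if (!is.null(truncate_len)) truncate_len <- check_count(truncate_len, "truncate_len")
  max_raw <- max(nchar(seqs))
  used <- vapply(seqs, truncate_seq, character(1), max_len = truncate_len)
  short <- nchar(used) <= constructor$k
  if (any(short)) {
    abort(sprintf(
      "Database record(s) too short to sketch at k = %d (need length >= k + 1): %s",
      constructor$k, paste(names(seqs)[short], collapse = ", ")
    ))
  }
  lshs <- lapply(used, build_lsh, constructor = constructor)
  structure(
    list(ids = names(seqs), lshs = unname(lshs), constructor = constructor,
         max_seq_len_raw = max_raw,
         max_seq_len = if (is.null(truncate_len)) max_raw else min(max_raw, truncate_len)),
    class = "db_index"
  )
}

#' @export
print.db_index <- function(x, ...) {
  cat(sprintf("<db_index> %d entries, max_seq_len = %s (raw %s), k = %d, L = %s\n",
              length(x$ids), format(x$max_seq_len, big.mark = ","),
              format(x$max_seq_len_raw, big.mark = ","), x$constructor$k,
              format(x$constructor$L, big.mark = ",")))
  invisible(x)
}

#' Score one database entry against the encrypted query
#'
#' The encrypted intersection is the homomorphic sum of the query ciphertexts
#' at the entry's filled positions only (work is proportional to the entry's
#' popcount), re-randomized with a fresh encryption of zero so even an empty
#' entry returns a valid fresh ciphertext. Computed entirely in encrypted
#' space: the owner learns nothing about the query.
#'
#' @param enc_query An `encrypted_query`.
#' @param entry_lsh The entry's `lsh_vector`.
#' @param seed Optional integer seed for the re-randomization (fixture mode).
#' @return List with `ciphertext` (hex encrypted intersection) and
#'   `db_magnitude` (plaintext entry popcount).
#' @export
score_entry <- function(enc_query, entry_lsh, seed = NULL) {
  stopifnot(inherits(enc_query, "encrypted_query"), inherits(entry_lsh, "lsh_vector"))
  if (entry_lsh$L != length(enc_query$ciphertexts)) {
    abort("Sketch dimension mismatch between the encrypted query and the entry.")
  }
  seed <- if (is.null(seed)) -1L else check_count(seed, "seed", min = 0L)
  selected <- enc_query$ciphertexts[entry_lsh$positions + 1L]
  list(
    ciphertext = pl_sum_cpp(enc_query$public_key$n, selected, seed),
    db_magnitude = entry_lsh$magnitude
  )
}

#' Scan the whole database against an encrypted query
#'
#' Every entry is scored, in index order, with no early termination — the
#' scan-all contract that keeps execution time independent of where (or
#' whether) a match sits in the database.
#'
#' @param enc_query An `encrypted_query`.
#' @param index A `db_index`.
#' @param seed Optional integer seed for fixture-mode re-randomization.
#' @param .counter Optional environment; its `n` field is incremented once per
#'   entry scored (instrumentation hook for auditing the scan-all contract).
#' @return Tibble of score pairs (`entry_id`, `ciphertext`, `db_magnitude`),
#'   one row per entry in index order, with attribute `n_scored`.
#' @export
scan_database <- function(enc_query, index, seed = NULL, .counter = NULL) {
  stopifnot(inherits(index, "db_index"))
  seeds <- if (is.null(seed)) {
    rep(list(NULL), length(index$ids))
  } else {
    as.list(check_count(seed, "seed", min = 0L) + seq_along(index$ids) - 1L)
  }
  rows <- purrr::map2(index$lshs, seeds, function(lsh, s) {
    if (!is.null(.counter)) .counter$n <- (.counter$n %||% 0L) + 1L
    pair <- score_entry(enc_query, lsh, seed = s)
    tibble(ciphertext = pair$ciphertext, db_magnitude = pair$db_magnitude)
  })
  out <- dplyr::bind_cols(tibble(entry_id = index$ids), dplyr::bind_rows(rows))
  attr(out, "n_scored") <- length(index$ids)
  out
}
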