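#' Build the encrypted query (Querier side)
#'
#' Sketches the query sequence with the shared constructor and encrypts every
#' one of the `L` sketch positions under the Querier's public key — zeros
#' included, so the ciphertext vector reveals nothing about which positions
#' are set. The plaintext magnitude `|Q|` is retained locally for scoring and
#' is never serialized into the artifact sent to the Database Owner.
#'
#' @param seq Query sequence (single string).
#' @param constructor The shared [lsh_constructor()], sized from the Database
#'   Owner's reported maximum sequence length.
#' @param key The Querier's `paillier_public_key` or `paillier_keypair`.
#' @param seed Optional integer seed for deterministic fixture encryption
#'   (non-secure).
#' @return An `encrypted_query`: `L` hex ciphertexts, the constructor, the
#'   public key, and the local-only `q_mag`.
#' @export
build_encrypted_query <- function(seq, constructor, key, seed = NULL) {
  stopifnot(inherits(constructor, "lsh_constructor"))
  pk <- as_public_key(key)
  lsh <- build_lsh(seq, constructor)
  seed <- if (is.null(seed)) -1L else check_count(seed, "seed", min = 0L)
  ciphertexts <- pl_encrypt_bits_cpp(pk$n, lsh_bits(lsh), seed)
  structure(
    list(ciphertexts = ciphertexts, constructor = constructor,
         public_key = pk, q_mag = lsh$magnitude),
    class = "encrypted_query"
  )
}

#' @export
print.encrypted_query <- function(x, ...) {
  cat(sprintf("<encrypted_query> L = %s ciphertexts under a %d-bit key (|Q| held locally)\n",
              format(length(x$ciphertexts), big.mark = ","), x$public_key$key_size))
  invisible(x)
}

#' Similarity metrics from an intersection count
#'
#' Given the decrypted intersection `I` and the two sketch magnitudes, the
#' Querier computes
#' `IoU = I / (|Q| + |D| - I)`, `IoQ = I / |Q|`, `IoD = I / |D|`.
#' A metric with zero denominator is defined as 0. An intersection exceeding
#' `min(|Q|, |D|)` is impossible for honestly computed scores and raises an
#' integrity error rather than being clamped silently.
#'
#' @param intersection Decrypted intersection count(s).
#' @param q_mag Query sketch magnitude `|Q|`.
#' @param d_mag Database-entry sketch magnitude(s) `|D|`.
#' @return Tibble with columns `intersection`, `IoU`, `IoQ`, `IoD`.
#' @export
compute_similarity <- function(intersection, q_mag, d_mag) {
  if (any(intersection < 0) || any(q_mag < 0) || any(d_mag < 0)) {
    abort("Counts and magnitudes must be non-negative.")
  }
  if (any(intersection > pmin(q_mag, d_mag))) {
    abort(paste0(
      "Integrity error: decrypted intersection exceeds min(|Q|, |D|). ",
      "The score pairs were not computed honestly from this query."
    ))
  }
  len <- max(length(intersection), length(q_mag), length(d_mag))
  intersection <- rep_len(as.numeric(intersection), len)
  q_mag <- rep_len(as.numeric(q_mag), len)
  d_mag <- rep_len(as.numeric(d_mag), len)
  safe_div <- function(num, den) {
    out <- num / den
    out[den == 0] <- 0
    out
  }
  tibble(
    intersection = intersection,
    IoU = safe_div(intersection, q_mag + d_mag - intersection),
    IoQ = safe_div(intersection, q_mag),
    IoD = safe_div(intersection, d_mag)
  )
}

#' Decrypt returned score pairs into similarity scores (Querier side)
#'
#' One row per database entry, in the order the Database Owner returned them
#' (the number of rows — the database size — is the only structural
#' information the protocol reveals).
#'
#' @param keypair The Querier's `paillier_keypair`.
#' @param pairs Score pairs: a tibble/data.frame with columns `entry_id`,
#'   `ciphertext`, `db_magnitude`, as produced by [scan_database()] or
#'   [read_score_pairs()].
#' @param q_mag The query sketch magnitude retained by
#'   [build_encrypted_query()] (`$q_mag`).
#' @return A `sigdb_scores` tibble: `entry_id`, `db_magnitude`,
#'   `intersection`, `IoU`, `IoQ`, `IoD`.
#' @export
decrypt_scores <- function(keypair, pairs, q_mag) {
  required <- c("entry_id", "ciphertext", "db_magnitude")
  if (!is.data.frame(pairs) || !all(required %in% names(pairs))) {
    abort("`pairs` must have columns entry_id, ciphertext, db_magnitude.")
  }
  q_mag <- check_count(q_mag, "q_mag", min = 0L)
  intersection <- paillier_decrypt(keypair, pairs$ciphertext)
  out <- dplyr::bind_cols(
    tibble(entry_id = pairs$entry_id, db_magnitude = as.integer(pairs$db_magnitude)),
    compute_similarity(intersection, q_mag, as.numeric(pairs$db_magnitude))
  )
  new_sigdb_scores(out, q_mag)
}

new_sigdb_scores <- function(tbl, q_mag) {
  structure(as_tibble(tbl), q_mag = q_mag,
            class = c("sigdb_scores", class(as_tibble(tbl))))
}

#' Write similarity results as TSV
#'
#' Columns: `entry_id`, `db_magnitude`, `intersection`, `IoU`, `IoQ`, `IoD`,
#' at full float precision.
#'
#' @param scores A `sigdb_scores` tibble.
#' @param path Output path.
#' @param sort_by_iou Sort rows by decreasing IoU before writing.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(scores, path, sort_by_iou = FALSE) {
  cols <- c("entry_id", "db_magnitude", "intersection", "IoU", "IoQ", "IoD")
  out <- as.data.frame(scores)[, cols]
  if (sort_by_iou) out <- out[order(-out$IoU), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
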