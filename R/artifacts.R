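# JSON artifacts exchanged between the two parties. Each carries a schema tag
# and version; readers refuse anything else. Big integers travel as lowercase
# hex strings and are validated on read so a tampered payload fails loudly.

ARTIFACT_VERSION <- 1L

write_artifact <- function(x, path, schema) {
  payload <- c(list(schema = schema, version = ARTIFACT_VERSION), x)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_artifact <- function(path, schema) {
  if (!file.exists(path)) abort(sprintf("Artifact not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, schema)) {
    abort(sprintf("Schema mismatch: expected '%s', found '%s' in %s.",
                  schema, payload$schema %||% "<none>", path))
  }
  if (!identical(as.integer(payload$version), ARTIFACT_VERSION)) {
    abort(sprintf("Unsupported artifact version %s in %s (this build reads version %d).",
                  payload$version %||% "<none>", path, ARTIFACT_VERSION))
  }
  payload
}

check_hex <- function(x, what) {
  if (length(x) == 0L || any(is.na(x)) || any(!grepl("^[0-9a-f]+$", x))) {
    abort(sprintf("Corrupt artifact: %s is not valid lowercase hex.", what))
  }
  x
}

#' Serialize and deserialize protocol artifacts
#'
#' Byte-exact JSON round trips for everything the two parties exchange: the
#' LSH constructor, the public key, the key pair (Querier-side only), the
#' encrypted query, and the returned score pairs. The encrypted-query artifact
#' deliberately omits the query magnitude and any plaintext bit: the Database
#' Owner sees ciphertexts only. `write_query_private()` stores the magnitude
#' in a separate Querier-side file for a later [decrypt_scores()] call.
#'
#' @param x The object to serialize.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return the reconstructed
#'   object.
#' @name artifacts
NULL

#' @rdname artifacts
#' @export
write_constructor <- function(x, path) {
  stopifnot(inherits(x, "lsh_constructor"))
  write_artifact(unclass(x), path, "seqveil/lsh_constructor")
}

#' @rdname artifacts
#' @export
read_constructor <- function(path) {
  p <- read_artifact(path, "seqveil/lsh_constructor")
  if (!identical(p$hash_name, "fnv1a64")) {
    abort(sprintf("Unknown hash '%s' in constructor artifact.", p$hash_name))
  }
  lsh_constructor(k = p$k, L = p$L, hash_seed = p$hash_seed)
}

#' @rdname artifacts
#' @export
write_public_key <- function(x, path) {
  pk <- as_public_key(x)
  write_artifact(list(key_size = pk$key_size, n = pk$n), path, "seqveil/public_key")
}

#' @rdname artifacts
#' @export
read_public_key <- function(path) {
  p <- read_artifact(path, "seqveil/public_key")
  structure(list(n = check_hex(p$n, "modulus n"), key_size = as.integer(p$key_size)),
            class = "paillier_public_key")
}

#' @rdname artifacts
#' @export
write_keypair <- function(x, path) {
  stopifnot(inherits(x, "paillier_keypair"))
  write_artifact(
    list(key_size = x$public$key_size, n = x$public$n, p = x$p, q = x$q),
    path, "seqveil/keypair"
  )
}

#' @rdname artifacts
#' @export
read_keypair <- function(path) {
  p <- read_artifact(path, "seqveil/keypair")
  public <- structure(list(n = check_hex(p$n, "modulus n"),
                           key_size = as.integer(p$key_size)),
                      class = "paillier_public_key")
  structure(list(public = public, p = check_hex(p$p, "prime p"),
                 q = check_hex(p$q, "prime q"), seeded = NA),
            class = "paillier_keypair")
}

#' @rdname artifacts
#' @export
write_encrypted_query <- function(x, path) {
  stopifnot(inherits(x, "encrypted_query"))
  write_artifact(
    list(
      constructor = unclass(x$constructor),
      public_key = list(key_size = x$public_key$key_size, n = x$public_key$n),
      ciphertexts = x$ciphertexts
    ),
    path, "seqveil/encrypted_query"
  )
}

#' @rdname artifacts
#' @export
read_encrypted_query <- function(path) {
  p <- read_artifact(path, "seqveil/encrypted_query")
  ctor <- lsh_constructor(k = p$constructor$k, L = p$constructor$L,
                          hash_seed = p$constructor$hash_seed)
  cts <- check_hex(as.character(p$ciphertexts), "ciphertexts")
  if (length(cts) != ctor$L) {
    abort("Corrupt artifact: ciphertext vector length differs from the constructor's L.")
  }
  structure(
    list(ciphertexts = cts, constructor = ctor,
         public_key = structure(list(n = check_hex(p$public_key$n, "modulus n"),
                                     key_size = as.integer(p$public_key$key_size)),
                                class = "paillier_public_key"),
         q_mag = NA_integer_),
    class = "encrypted_query"
  )
}

#' @rdname artifacts
#' @export
write_query_private <- function(x, path) {
  stopifnot(inherits(x, "encrypted_query"))
  write_artifact(list(q_mag = x$q_mag), path, "seqveil/query_private")
}

#' @rdname artifacts
#' @export
read_query_private <- function(path) {
  p <- read_artifact(path, "seqveil/query_private")
  as.integer(p$q_mag)
}

#' @rdname artifacts
#' @export
write_score_pairs <- function(x, path) {
  stopifnot(is.data.frame(x))
  write_artifact(
    list(pairs = lapply(seq_len(nrow(x)), function(i) {
      list(entry_id = x$entry_id[i], ciphertext = x$ciphertext[i],
           db_magnitude = x$db_magnitude[i])
    })),
    path, "seqveil/score_pairs"
  )
}

#' @rdname artifacts
#' @export
read_score_pairs <- function(path) {
  p <- read_artifact(path, "seqveil/score_pairs")
  pairs <- p$pairs
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L) {
    abort(sprintf("Artifact %s holds no score pairs.", path))
  }
  pairs <- as_tibble(as.data.frame(pairs))
  check_hex(pairs$ciphertext, "encrypted intersection scores")
  tibble(entry_id = as.character(pairs$entry_id),
         ciphertext = as.character(pairs$ciphertext),
         db_magnitude = as.integer(pairs$db_magnitude))
}
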