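#' Generate a Paillier key pair
#'
#' Additive homomorphic cryptosystem over messages in `[0, n)`: the product of
#' two ciphertexts decrypts to the sum of their plaintexts. The generator is
#' fixed at `g = n + 1`. The default modulus size of 3072 bits targets roughly
#' 128-bit security; the small sizes exist for tests and fixtures only and
#' offer no security.
#'
#' @param key_size Modulus size in bits; one of 512, 1024, 2048, 3072, 4096.
#' @param seed Optional integer seed giving a reproducible key pair. Seeded
#'   keys are regression fixtures, not secure keys: the primes are derived
#'   from a deterministic generator. Leave `NULL` for a cryptographically
#'   random key.
#' @return A `paillier_keypair`: `$public` (a `paillier_public_key` with hex
#'   modulus `n` and `key_size`) and the private primes `p`, `q`.
#' @export
paillier_keygen <- function(key_size = 3072, seed = NULL) {
  allowed <- c(512L, 1024L, 2048L, 3072L, 4096L)
  key_size <- check_count(key_size, "key_size")
  if (!key_size %in% allowed) {
    abort(sprintf(
      "Unsupported key_size %d. Use one of %s (512/1024 are for tests only; 3072 is the security default).",
      key_size, paste(allowed, collapse = ", ")
    ))
  }
  raw <- if (is.null(seed)) {
    pl_keygen_cpp(key_size)
  } else {
    pl_keygen_seeded_cpp(key_size, check_count(seed, "seed", min = 0L))
  }
  public <- structure(
    list(n = raw$n, key_size = key_size),
    class = "paillier_public_key"
  )
  structure(
    list(public = public, p = raw$p, q = raw$q, seeded = !is.null(seed)),
    class = "paillier_keypair"
  )
}

#' @export
print.paillier_public_key <- function(x, ...) {
  cat(sprintf("<paillier_public_key> %d-bit modulus, g = n + 1\n", x$key_size))
  invisible(x)
}

#' @export
print.paillier_keypair <- function(x, ...) {
  cat(sprintf("<paillier_keypair> %d-bit modulus%s\n", x$public$key_size,
              if (isTRUE(x$seeded)) " (seeded fixture key; NOT secure)" else ""))
  invisible(x)
}

as_public_key <- function(key) {
  if (inherits(key, "paillier_keypair")) return(key$public)
  if (inherits(key, "paillier_public_key")) return(key)
  abort("Expected a `paillier_public_key` or `paillier_keypair`.")
}

as_plain_dec <- function(m) {
  if (is.character(m)) {
    if (any(!grepl("^[0-9]+$", m))) abort("Plaintexts must be non-negative integers.")
    return(m)
  }
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != floor(m))) {
    abort("Plaintexts must be non-negative integers.")
  }
  if (any(m > 2^53)) abort("Numeric plaintexts above 2^53 lose precision; pass decimal strings.")
  format(m, scientific = FALSE, trim = TRUE)
}

#' Encrypt plaintexts under a Paillier public key
#'
#' Each call draws fresh randomness, so two encryptions of the same plaintext
#' yield distinct ciphertexts (semantic security).
#'
#' @param key A `paillier_public_key` or `paillier_keypair`.
#' @param m Non-negative integer plaintexts in `[0, n)`; numerics up to 2^53
#'   or decimal strings.
#' @param seed Optional integer seed for deterministic fixture encryption
#'   (non-secure; for regression fixtures only).
#' @return Character vector of ciphertexts as lowercase hex.
#' @export
paillier_encrypt <- function(key, m, seed = NULL) {
  pk <- as_public_key(key)
  seed <- if (is.null(seed)) -1L else check_count(seed, "seed", min = 0L)
  pl_encrypt_cpp(pk$n, as_plain_dec(m), seed)
}

#' Homomorphic addition of ciphertexts
#'
#' @param key A `paillier_public_key` or `paillier_keypair` (the key both
#'   ciphertext vectors were encrypted under).
#' @param c1,c2 Hex ciphertext vectors of equal length.
#' @return Hex ciphertexts decrypting to the elementwise plaintext sums mod n.
#' @export
paillier_add <- function(key, c1, c2) {
  pk <- as_public_key(key)
  pl_add_cpp(pk$n, as.character(c1), as.character(c2))
}

#' Decrypt Paillier ciphertexts
#'
#' @param keypair A `paillier_keypair` (the private primes are required).
#' @param ciphertext Hex ciphertext vector.
#' @param as_character Return full-precision decimal strings instead of
#'   numerics (needed for plaintexts at the top of the message space).
#' @return Numeric vector of recovered plaintexts (or decimal strings).
#' @export
paillier_decrypt <- function(keypair, ciphertext, as_character = FALSE) {
  if (!inherits(keypair, "paillier_keypair")) {
    abort("Decryption requires a `paillier_keypair` holding the private primes.")
  }
  dec <- pl_decrypt_cpp(keypair$public$n, keypair$p, keypair$q, as.character(ciphertext))
  if (as_character) return(dec)
  if (any(nchar(dec) > 15L)) {
    abort("Decrypted plaintext exceeds numeric precision; call with `as_character = TRUE`.")
  }
  as.numeric(dec)
}

#' Modulus bit length of a public key
#'
#' @param key A `paillier_public_key` or `paillier_keypair`.
#' @return Integer number of bits of `n`.
#' @export
paillier_key_bits <- function(key) {
  bn_bits_cpp(as_public_key(key)$n)
}
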