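# Shared fixtures. 512-bit seeded keys are regression fixtures (fast, reproducible,
# not secure); all sequence fixtures are generated in code.

test_keypair <- function() {
  if (is.null(.fixture_env$kp)) .fixture_env$kp <- paillier_keygen(512, seed = 42)
  .fixture_env$kp
}
.fixture_env <- new.env(parent = emptyenv())

# Encrypted query assembled from explicit 0-based set positions (bypasses the
# sequence layer so protocol arithmetic can be tested on toy bit vectors).
enc_query_from_positions <- function(positions, L, keypair, k = 8, seed = 7) {
  bits <- integer(L)
  bits[positions + 1L] <- 1L
  structure(
    list(
      ciphertexts = seqveil:::pl_encrypt_bits_cpp(keypair$public$n, bits, seed),
      constructor = lsh_constructor(k = k, L = L),
      public_key = keypair$public,
      q_mag = length(positions)
    ),
    class = "encrypted_query"
  )
}

lsh_from_positions <- function(positions, L) {
  seqveil:::new_lsh_vector(as.integer(positions), L)
}

random_seqs <- function(n, len, seed) {
  withr::with_seed(seed, {
    rlang::set_names(
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
        character(1)),
      sprintf("seq%03d", seq_len(n))
    )
  })
}

# Plaintext reference pipeline: sketch both sides and score by AND/popcount.
plaintext_pipeline <- function(query_seq, db_seqs, constructor) {
  q <- build_lsh(query_seq, constructor)
  purrr::map_dfr(names(db_seqs), function(id) {
    s <- lsh_similarity(q, build_lsh(db_seqs[[id]], constructor))
    dplyr::mutate(s, entry_id = id, .before = 1)
  })
}

python_bin <- function() Sys.which("python")
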