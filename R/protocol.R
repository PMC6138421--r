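#' Protocol configuration
#'
#' Defaults are the tuned operating point: `k = 8` (most mutation-tolerant
#' k-mer size), 5:1 sketch-to-item sizing (~18% per-item collision rate),
#' 3072-bit keys (~128-bit security) and a 20,000-base cap on the bases used
#' per sequence.
#'
#' @param k k-mer length.
#' @param lsh_ratio Sketch positions per base of the longest database entry.
#' @param key_size Paillier modulus bits (512/1024 are test-only sizes).
#' @param truncate_len Use only the first `truncate_len` bases of longer
#'   sequences; `NULL` disables truncation.
#' @param hash_seed Shared seed of the position hash.
#' @param rng_seed Optional integer: when set, key generation and all
#'   encryption randomness are drawn from seeded deterministic generators so a
#'   rerun reproduces identical artifacts byte for byte. Fixture mode only —
#'   a seeded run is NOT cryptographically secure.
#' @return A `sigdb_config` list.
#' @export
sigdb_config <- function(k = 8, lsh_ratio = 5, key_size = 3072,
                         truncate_len = 20000, hash_seed = 1L, rng_seed = NULL) {
  structure(
    list(
      k = check_count(k, "k"),
      lsh_ratio = lsh_ratio,
      key_size = check_count(key_size, "key_size"),
      truncate_len = if (is.null(truncate_len)) NULL else check_count(truncate_len, "truncate_len"),
      hash_seed = check_count(hash_seed, "hash_seed", min = 0L),
      rng_seed = if (is.null(rng_seed)) NULL else check_count(rng_seed, "rng_seed", min = 0L)
    ),
    class = "sigdb_config"
  )
}

#' Run the full two-party exchange locally
#'
#' Plays both roles end to end: (1) the owner reports the longest (capped)
#' entry length; (2) the querier sizes and shares the LSH constructor;
#' (3) generates a key pair; (4) sketches and encrypts the query; (5) hands
#' the constructor, public key and encrypted query to the owner; (6) the owner
#' sketches every entry; (7) scores all of them homomorphically; (8) returns
#' the score pairs; (9) the querier decrypts; (10) computes IoU/IoQ/IoD.
#' When `out_dir` is given, every exchanged artifact plus the final TSV is
#' written there, so each half of the exchange can also be replayed from files.
#'
#' @param query Query FASTA path or a single (optionally named) sequence
#'   string. Only the first record of a multi-record FASTA is used.
#' @param db Database FASTA path or named character vector of sequences.
#' @param config A [sigdb_config()].
#' @param out_dir Optional directory for the serialized artifacts
#'   (`constructor.json`, `public_key.json`, `keypair.json`,
#'   `query_private.json`, `encrypted_query.json`, `score_pairs.json`,
#'   `results.tsv`).
#' @param quiet Suppress per-stage progress messages.
#' @return A `sigdb_scores` tibble (one row per database entry, in database
#'   order), with the constructor and config attached as attributes.
#' @export
run_exchange <- function(query, db, config = sigdb_config(), out_dir = NULL,
                         quiet = TRUE) {
  stopifnot(inherits(config, "sigdb_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Exchange failed at stage [%s]: %s", name, conditionMessage(e)),
            parent = e)
    })
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  rs <- config$rng_seed

  db_seqs <- stage("read database", {
    if (length(db) == 1L && is.null(names(db))) read_fasta(db) else toupper(db)
  })
  query_seq <- stage("read query", {
    q <- if (length(query) == 1L && is.null(names(query)) && file.exists(query)) {
      read_fasta(query)
    } else {
      toupper(query)
    }
    if (length(q) > 1L) warning("Multiple query records found; using the first.")
    truncate_seq(q[[1L]], config$truncate_len)
  })

  max_len <- stage("report max entry length", {
    raw <- max(nchar(db_seqs))
    capped <- if (is.null(config$truncate_len)) raw else min(raw, config$truncate_len)
    say("Owner reports longest entry: %d bases (raw %d)", capped, raw)
    capped
  })

  constructor <- stage("size constructor", {
    lsh_constructor(k = config$k, L = lsh_size_for(max_len, config$lsh_ratio),
                    hash_seed = config$hash_seed)
  })

  keypair <- stage("key generation", {
    paillier_keygen(config$key_size, seed = rs)
  })

  enc_query <- stage("encrypt query", {
    t0 <- Sys.time()
    eq <- build_encrypted_query(query_seq, constructor, keypair,
                                seed = if (is.null(rs)) NULL else rs + 1L)
    say("Encrypted %d positions in %.1fs", constructor$L,
        as.numeric(Sys.time() - t0, units = "secs"))
    eq
  })

  index <- stage("index database", {
    build_index(db_seqs, constructor, truncate_len = config$truncate_len)
  })

  pairs <- stage("scan database", {
    t0 <- Sys.time()
    sp <- scan_database(enc_query, index,
                        seed = if (is.null(rs)) NULL else rs + 2L)
    say("Scored %d entries in %.1fs", nrow(sp),
        as.numeric(Sys.time() - t0, units = "secs"))
    sp
  })

  results <- stage("decrypt scores", {
    decrypt_scores(keypair, pairs, enc_query$q_mag)
  })

  if (!is.null(out_dir)) {
    stage("write artifacts", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_constructor(constructor, file.path(out_dir, "constructor.json"))
      write_public_key(keypair, file.path(out_dir, "public_key.json"))
      write_keypair(keypair, file.path(out_dir, "keypair.json"))
      write_query_private(enc_query, file.path(out_dir, "query_private.json"))
      write_encrypted_query(enc_query, file.path(out_dir, "encrypted_query.json"))
      write_score_pairs(pairs, file.path(out_dir, "score_pairs.json"))
      write_results_tsv(results, file.path(out_dir, "results.tsv"))
    })
  }

  attr(results, "constructor") <- constructor
  attr(results, "config") <- config
  results
}
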