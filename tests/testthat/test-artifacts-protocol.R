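test_that("artifacts round-trip byte-exactly", {
  dir <- withr::local_tempdir()
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 9)

  write_constructor(ctor, file.path(dir, "ctor.json"))
  expect_identical(read_constructor(file.path(dir, "ctor.json")), ctor)

  write_public_key(kp, file.path(dir, "pk.json"))
  expect_identical(read_public_key(file.path(dir, "pk.json"))$n, kp$public$n)

  write_keypair(kp, file.path(dir, "kp.json"))
  kp2 <- read_keypair(file.path(dir, "kp.json"))
  expect_identical(kp2$p, kp$p)
  expect_identical(kp2$q, kp$q)

  eq <- build_encrypted_query(random_seqs(1, 100, seed = 5)[[1]], ctor, kp)
  write_encrypted_query(eq, file.path(dir, "eq.json"))
  eq2 <- read_encrypted_query(file.path(dir, "eq.json"))
  expect_identical(eq2$ciphertexts, eq$ciphertexts)
  expect_identical(eq2$constructor, eq$constructor)

  write_query_private(eq, file.path(dir, "qp.json"))
  expect_identical(read_query_private(file.path(dir, "qp.json")), eq$q_mag)

  pairs <- scan_database(eq, build_index(random_seqs(3, 100, seed = 6), ctor))
  write_score_pairs(pairs, file.path(dir, "sp.json"))
  sp2 <- read_score_pairs(file.path(dir, "sp.json"))
  expect_identical(sp2$ciphertext, pairs$ciphertext)
  expect_identical(sp2$db_magnitude, as.integer(pairs$db_magnitude))
})

test_that("tampered or mismatched artifacts fail loudly", {
  dir <- withr::local_tempdir()
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 9)
  eq <- build_encrypted_query(random_seqs(1, 100, seed = 5)[[1]], ctor, kp)
  path <- file.path(dir, "eq.json")
  write_encrypted_query(eq, path)

  # corrupt a ciphertext hex digit into a non-hex character
  txt <- readLines(path, warn = FALSE)
  writeLines(gsub(substr(eq$ciphertexts[1], 1, 16),
                  paste0("zz", substr(eq$ciphertexts[1], 3, 16)), txt, fixed = TRUE), path)
  expect_error(read_encrypted_query(path), "hex")

  # schema mismatch
  write_public_key(kp, file.path(dir, "pk.json"))
  expect_error(read_constructor(file.path(dir, "pk.json")), "Schema mismatch")

  # version mismatch
  p <- jsonlite::read_json(file.path(dir, "pk.json"), simplifyVector = TRUE)
  p$version <- 999L
  jsonlite::write_json(p, file.path(dir, "pk999.json"), auto_unbox = TRUE)
  expect_error(read_public_key(file.path(dir, "pk999.json")), "version")
})

test_that("no plaintext query material leaks into owner-bound artifacts", {
  dir <- withr::local_tempdir()
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 9)
  seq <- random_seqs(1, 100, seed = 5)[[1]]
  eq <- build_encrypted_query(seq, ctor, kp)
  path <- file.path(dir, "eq.json")
  write_encrypted_query(eq, path)
  payload <- paste(readLines(path, warn = FALSE), collapse = "")
  expect_false(grepl("q_mag", payload, fixed = TRUE))
  expect_false(grepl(seq, payload, fixed = TRUE))
  bit_pattern <- paste(lsh_bits(build_lsh(seq, ctor)), collapse = ",")
  expect_false(grepl(bit_pattern, payload, fixed = TRUE))
})

test_that("the local two-role exchange ranks an identical entry at IoU = 1", {
  dir <- withr::local_tempdir()
  seqs <- random_seqs(6, 150, seed = 81)
  write_fasta(seqs, file.path(dir, "db.fasta"))
  write_fasta(seqs[4], file.path(dir, "query.fasta"))
  cfg <- sigdb_config(key_size = 512, truncate_len = 150, rng_seed = 11)
  res <- run_exchange(file.path(dir, "query.fasta"), file.path(dir, "db.fasta"),
                      config = cfg, out_dir = file.path(dir, "run1"))
  best <- tidy(res)[1, ]
  expect_identical(best$entry_id, "seq004")
  expect_equal(best$IoU, 1.0)
  expect_equal(best$IoQ, 1.0)
  expect_equal(best$IoD, 1.0)
  expect_identical(nrow(res), 6L)

  # end-to-end equality with the plaintext pipeline on the same inputs
  ctor <- attr(res, "constructor")
  oracle <- plaintext_pipeline(seqs[[4]], seqs, ctor)
  expect_equal(res$IoU, oracle$IoU)
  expect_equal(res$intersection, oracle$intersection)

  # deterministic-fixture rerun reproduces the TSV byte for byte
  run_exchange(file.path(dir, "query.fasta"), file.path(dir, "db.fasta"),
               config = cfg, out_dir = file.path(dir, "run2"))
  expect_identical(readLines(file.path(dir, "run1", "results.tsv")),
                   readLines(file.path(dir, "run2", "results.tsv")))
  expect_true(all(file.exists(file.path(dir, "run1",
    c("constructor.json", "public_key.json", "keypair.json", "query_private.json",
      "encrypted_query.json", "score_pairs.json", "results.tsv")))))
})

test_that("the exchange can be replayed from serialized artifacts alone", {
  dir <- withr::local_tempdir()
  seqs <- random_seqs(4, 120, seed = 91)
  write_fasta(seqs, file.path(dir, "db.fasta"))
  write_fasta(seqs[2], file.path(dir, "q.fasta"))
  cfg <- sigdb_config(key_size = 512, truncate_len = 120, rng_seed = 3)
  res <- run_exchange(file.path(dir, "q.fasta"), file.path(dir, "db.fasta"),
                      config = cfg, out_dir = file.path(dir, "out"))

  # owner side, reconstructed purely from files
  ctor <- read_constructor(file.path(dir, "out", "constructor.json"))
  eq <- read_encrypted_query(file.path(dir, "out", "encrypted_query.json"))
  idx <- build_index(file.path(dir, "db.fasta"), ctor, truncate_len = 120)
  pairs <- scan_database(eq, idx)

  # querier side, reconstructed purely from files
  kp <- read_keypair(file.path(dir, "out", "keypair.json"))
  qm <- read_query_private(file.path(dir, "out", "query_private.json"))
  replay <- decrypt_scores(kp, pairs, qm)
  expect_equal(replay$IoU, res$IoU)
  expect_equal(replay$intersection, res$intersection)
})
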