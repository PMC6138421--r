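test_that("similarity metrics follow the three ratio definitions", {
  t1 <- compute_similarity(5, 5, 5)
  expect_equal(unlist(t1[, c("IoU", "IoQ", "IoD")]), c(IoU = 1, IoQ = 1, IoD = 1))
  t2 <- compute_similarity(2, 3, 3)
  expect_equal(t2$IoU, 0.5)
  expect_equal(t2$IoQ, 2 / 3)
  expect_equal(t2$IoD, 2 / 3)
  t3 <- compute_similarity(0, 4, 9)
  expect_equal(unlist(t3[, c("IoU", "IoQ", "IoD")]), c(IoU = 0, IoQ = 0, IoD = 0))
  # zero denominators are defined as 0
  t4 <- compute_similarity(0, 0, 0)
  expect_equal(unlist(t4[, c("IoU", "IoQ", "IoD")]), c(IoU = 0, IoQ = 0, IoD = 0))
  # vectorized over entries with a scalar |Q|
  tv <- compute_similarity(c(2, 0), 3, c(3, 7))
  expect_equal(tv$IoQ, c(2 / 3, 0))
  expect_equal(tv$IoD, c(2 / 3, 0))
})

test_that("an impossible intersection raises an integrity error, never a clamp", {
  expect_error(compute_similarity(5, 3, 4), "Integrity error")
  expect_error(compute_similarity(-1, 3, 4), "non-negative")
  kp <- test_keypair()
  pairs <- tibble::tibble(entry_id = "e1",
                          ciphertext = paillier_encrypt(kp, 50),
                          db_magnitude = 10L)
  expect_error(decrypt_scores(kp, pairs, q_mag = 60), "Integrity error")
})

test_that("encrypted query encrypts every position and round-trips the bits", {
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seq <- random_seqs(1, 100, seed = 31)[[1]]
  eq <- build_encrypted_query(seq, ctor, kp)
  expect_length(eq$ciphertexts, 500L)
  bits <- paillier_decrypt(kp, eq$ciphertexts)
  expect_identical(as.integer(bits), lsh_bits(build_lsh(seq, ctor)))
  expect_identical(eq$q_mag, sum(bits == 1))
  # fresh randomness: same plaintext bits, different ciphertexts
  eq2 <- build_encrypted_query(seq, ctor, kp)
  expect_false(any(eq$ciphertexts == eq2$ciphertexts))
})

test_that("entry scoring matches the AND/popcount oracle on toy vectors", {
  kp <- test_keypair()
  eq <- enc_query_from_positions(c(1, 3, 5), L = 10, keypair = kp)
  entry <- lsh_from_positions(c(3, 5, 7), L = 10)
  pair <- score_entry(eq, entry)
  expect_equal(paillier_decrypt(kp, pair$ciphertext), 2)
  expect_identical(pair$db_magnitude, 3L)
  # full overlap and empty overlap
  expect_equal(paillier_decrypt(kp, score_entry(eq, lsh_from_positions(c(1, 3, 5), 10))$ciphertext), 3)
  expect_equal(paillier_decrypt(kp, score_entry(eq, lsh_from_positions(c(0, 2), 10))$ciphertext), 0)
  # empty entry still yields a valid fresh ciphertext
  expect_equal(paillier_decrypt(kp, score_entry(eq, lsh_from_positions(integer(0), 10))$ciphertext), 0)
  expect_error(score_entry(eq, lsh_from_positions(1, L = 20)), "dimension mismatch", ignore.case = TRUE)
})

test_that("the index preserves record order, ids and truncation", {
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seqs <- random_seqs(50, 100, seed = 17)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, fa)
  idx <- build_index(fa, ctor)
  expect_identical(idx$ids, names(seqs))
  expect_length(idx$lshs, 50L)
  # identical records sketch identically
  dup <- build_index(c(a = seqs[[1]], b = seqs[[1]]), ctor)
  expect_identical(dup$lshs[[1]]$positions, dup$lshs[[2]]$positions)
  # over-long records use their first truncate_len bases only
  long <- random_seqs(1, 250, seed = 23)[[1]]
  t_idx <- build_index(c(x = long), ctor, truncate_len = 120)
  expect_identical(t_idx$lshs[[1]]$positions,
                   build_lsh(substr(long, 1, 120), ctor)$positions)
  expect_identical(t_idx$max_seq_len, 120L)
  expect_identical(t_idx$max_seq_len_raw, 250L)
  expect_error(build_index(c(tiny = "ACGTACGT"), ctor), "too short")
})

test_that("every entry is scanned, in order, with no early termination", {
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seqs <- random_seqs(7, 100, seed = 41)
  # the query equals the FIRST entry: a perfect match must not stop the scan
  eq <- build_encrypted_query(seqs[[1]], ctor, kp)
  idx <- build_index(seqs, ctor)
  counter <- new.env()
  pairs <- scan_database(eq, idx, .counter = counter)
  expect_identical(nrow(pairs), 7L)
  expect_identical(counter$n, 7L)
  expect_identical(attr(pairs, "n_scored"), 7L)
  expect_identical(pairs$entry_id, names(seqs))
  # doubling the database doubles the number of scoring calls
  idx2 <- build_index(c(seqs, rlang::set_names(seqs, paste0(names(seqs), "b"))), ctor)
  counter2 <- new.env()
  scan_database(eq, idx2, .counter = counter2)
  expect_identical(counter2$n, 14L)
})

test_that("decrypted scores equal the plaintext oracle, row for row", {
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seqs <- random_seqs(10, 100, seed = 53)
  query <- seqs[[4]]
  eq <- build_encrypted_query(query, ctor, kp)
  res <- decrypt_scores(kp, scan_database(eq, build_index(seqs, ctor)), eq$q_mag)
  oracle <- plaintext_pipeline(query, seqs, ctor)
  expect_equal(res$intersection, oracle$intersection)
  expect_equal(res$IoU, oracle$IoU)
  expect_equal(res$IoQ, oracle$IoQ)
  expect_equal(res$IoD, oracle$IoD)
  expect_identical(res$db_magnitude, as.integer(oracle$db_magnitude))
  # IoU <= min(IoQ, IoD), all in [0, 1]
  expect_true(all(res$IoU <= pmin(res$IoQ, res$IoD) + 1e-12))
  expect_true(all(unlist(res[, c("IoU", "IoQ", "IoD")]) >= 0))
  expect_true(all(unlist(res[, c("IoU", "IoQ", "IoD")]) <= 1))
})

test_that("a prefix query scores IoQ = 1 against its source entry", {
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 1000, hash_seed = 1)
  full <- random_seqs(1, 200, seed = 61)[[1]]
  eq <- build_encrypted_query(prefix_query(full, 80), ctor, kp)
  res <- decrypt_scores(kp, scan_database(eq, build_index(c(src = full), ctor)), eq$q_mag)
  expect_equal(res$IoQ, 1.0)
  expect_lt(res$IoU, 1.0)
})

test_that("tidy and glance summarise a search", {
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seqs <- random_seqs(5, 100, seed = 71)
  eq <- build_encrypted_query(seqs[[3]], ctor, kp)
  res <- decrypt_scores(kp, scan_database(eq, build_index(seqs, ctor)), eq$q_mag)
  td <- tidy(res)
  expect_identical(td$entry_id[1], "seq003")
  expect_identical(td$rank[1], 1L)
  gl <- glance(res)
  expect_identical(gl$best_entry, "seq003")
  expect_equal(gl$best_IoU, 1.0)
  expect_identical(gl$n_entries, 5L)
})
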