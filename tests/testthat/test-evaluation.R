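test_that("ani is 1 for identical sequences and for exact substrings", {
  g <- random_genome(1500, seed = 1)
  expect_equal(ani(g, g), 1.0)
  expect_equal(ani(substr(g, 200, 900), g), 1.0)
  expect_error(ani("", g), "non-empty")
})

test_that("ani of a 5% per-base mutant sits near 0.95", {
  ids <- vapply(1:10, function(s) {
    g <- random_genome(1000, seed = 100 + s)
    ani(g, mutate_bernoulli(g, 0.05, seed = 200 + s))
  }, numeric(1))
  expect_lt(abs(mean(ids) - 0.95), 0.01)
})

test_that("unrelated random pairs score far below the 0.95 label threshold", {
  ids <- vapply(1:50, function(s) {
    ani(random_genome(1000, seed = 2 * s), random_genome(1000, seed = 2 * s + 1))
  }, numeric(1))
  expect_true(all(ids < 0.8))
  # containment form: a short random query in a long random text stays low too
  ids2 <- vapply(1:10, function(s) {
    ani(random_genome(1000, seed = 500 + s), random_genome(3000, seed = 600 + s))
  }, numeric(1))
  expect_true(all(ids2 < 0.8))
})

test_that("the edit-distance kernel agrees exactly with an alignment-library oracle", {
  # Biostrings global-in-pattern / local-in-subject alignment with 0/-1 edit
  # scoring: -score is the semi-global edit distance.
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                  baseOnly = TRUE)
  for (s in 1:10) {
    p <- random_genome(60, seed = 300 + s)
    t <- random_genome(200, seed = 400 + s)
    aln <- Biostrings::pairwiseAlignment(p, t, type = "global-local",
                                         substitutionMatrix = mat,
                                         gapOpening = 0, gapExtension = 1)
    expect_identical(seqveil:::hw_edit_cpp(p, t), -as.integer(Biostrings::score(aln)))
  }
})

test_that("the threshold sweep reproduces the worked relevant-count example", {
  scores <- c(0.2, 0.33, 0.33, 0.75, 0.87)
  labels <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$threshold, c(0, 0.2, 0.33, 0.75, 0.87))
  # counts at the unique-score thresholds: [5, 4, 2, 1]
  expect_identical(roc$n_relevant[-1], c(5L, 4L, 2L, 1L))
  # threshold 0 counts every comparison as relevant: the (1,1) corner
  expect_equal(roc$tpr[1], 1)
  expect_equal(roc$fpr[1], 1)
})

test_that("AUC is 1 for perfectly separated scores and ~0.5 for random labels", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1.0)
  withr::with_seed(7, {
    scores <- runif(1000)
    labels <- sample(c(TRUE, FALSE), 1000, replace = TRUE)
    expect_lt(abs(roc_auc(scores, labels) - 0.5), 0.05)
  })
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), "Degenerate")
})

test_that("trapezoidal AUC matches the pROC reference on random data", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    scores <- runif(300)
    labels <- runif(300) < scores # informative labels
    ours <- roc_auc(scores, labels)
    ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("a small correctness experiment separates related from unrelated pairs", {
  ds <- correctness_dataset(entry_lens = 1000, entries_per_set = 8, seed = 3)
  ex <- correctness_experiment(ds, taus = 0.95)
  cmp <- tidy(ex)
  expect_identical(nrow(cmp), 24L * 8L)
  # wild-type query vs its own entry: perfect score and perfect ANI
  own_wt <- dplyr::filter(cmp, grepl("_qwt$", query_id),
                          sub("_q.*$", "", query_id) == entry_id)
  expect_true(all(own_wt$sigdb_score == 1))
  expect_true(all(own_wt$ani == 1))
  # unrelated pairs: low on both axes
  other <- dplyr::filter(cmp, sub("_q.*$", "", query_id) != entry_id)
  expect_true(all(other$ani < 0.9))
  expect_true(all(other$sigdb_score < 0.5))
  gl <- glance(ex)
  expect_identical(names(gl), c("entry_len", "tau", "auc", "n_pos", "n_comparisons"))
})

test_that("roc and scores plots build without error", {
  roc <- roc_curve(c(0.2, 0.4, 0.8), c(FALSE, TRUE, TRUE))
  expect_s3_class(autoplot(roc), "ggplot")
  kp <- test_keypair()
  ctor <- lsh_constructor(k = 8, L = 500, hash_seed = 1)
  seqs <- random_seqs(3, 100, seed = 15)
  eq <- build_encrypted_query(seqs[[1]], ctor, kp)
  res <- decrypt_scores(kp, scan_database(eq, build_index(seqs, ctor)), eq$q_mag)
  expect_s3_class(autoplot(res), "ggplot")
})
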