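#' Average nucleotide identity (containment form)
#'
#' Ground-truth pairwise similarity for evaluating the protocol as a
#' classifier. Identity is computed from the best ends-free (semi-global)
#' alignment of the shorter sequence within the longer:
#' `ani = 1 - d / len(shorter)` with `d` the alignment's edit distance. For
#' equal lengths both orientations are computed and averaged; for unequal
#' lengths the containment form is symmetric by construction, so a query that
#' is an exact substring of an entry scores 1 regardless of the length
#' difference.
#'
#' @param a,b Character vectors of sequences, recycled to a common length;
#'   `ani` is computed elementwise.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
ani <- function(a, b) {
  if (!is.character(a) || !is.character(b)) abort("`a` and `b` must be character vectors.")
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else abort("`a` and `b` must have equal length (or one of length 1).")
  }
  if (any(!nzchar(a)) || any(!nzchar(b))) abort("Sequences must be non-empty.")
  ani_pairs_cpp(a, b)
}

#' ROC curve by increasing-threshold sweep
#'
#' Thresholds are 0 (everything relevant) followed by each unique score in
#' increasing order; a comparison is called relevant when
#' `score >= threshold`. For scores `[0.2, 0.33, 0.33, 0.75, 0.87]` the
#' unique-score thresholds yield relevant counts `[5, 4, 2, 1]`.
#'
#' @param scores Numeric similarity scores.
#' @param labels Logical (or 0/1) ground-truth labels; at least one positive
#'   and one negative are required.
#' @return A `sigdb_roc` tibble: `threshold`, `n_relevant`, `tpr`, `fpr`,
#'   with the trapezoidal AUC attached as attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    abort("`scores` and `labels` must be equal-length and free of NA.")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Degenerate labels: need at least one positive and one negative.")
  }
  thresholds <- c(0, sort(unique(scores)))
  rows <- purrr::map_dfr(thresholds, function(t) {
    relevant <- scores >= t
    tibble(
      threshold = t,
      n_relevant = sum(relevant),
      tpr = sum(relevant & labels) / n_pos,
      fpr = sum(relevant & !labels) / n_neg
    )
  })
  out <- structure(rows, class = c("sigdb_roc", class(rows)))
  attr(out, "auc") <- trapezoid_auc(rows$fpr, rows$tpr)
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  out
}

# Area under the (FPR, TPR) step curve by trapezoid, with the (0,0) endpoint
# appended (the threshold-0 point already pins (1,1)).
trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- c(0, fpr[ord])
  y <- c(0, tpr[ord])
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Area under the ROC curve
#'
#' @param scores Numeric similarity scores, or a `sigdb_roc` object.
#' @param labels Ground-truth labels (ignored when `scores` is a `sigdb_roc`).
#' @return The trapezoidal AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels = NULL) {
  if (inherits(scores, "sigdb_roc")) return(attr(scores, "auc"))
  attr(roc_curve(scores, labels), "auc")
}

#' Classifier evaluation of the similarity search
#'
#' Treats the protocol as a classifier of query/entry relatedness: for every
#' same-length-set query/entry pair it computes the similarity score
#' `max(IoU, IoQ, IoD)` (the maximum accommodates query/entry length
#' mismatch) and the alignment-based [ani()] ground truth, labels pairs by
#' `ani >= tau`, and reports the ROC AUC per entry-length set and threshold.
#'
#' Scores are computed over the plaintext sketch path ([lsh_similarity()]),
#' which is provably identical to the encrypted path — the test suite asserts
#' that equivalence — keeping the evaluation desk-scale.
#'
#' @param dataset A dataset from [correctness_dataset()]; built with the
#'   defaults (plus `seed`) when omitted.
#' @param taus ANI thresholds defining ground-truth relatedness.
#' @param k k-mer length.
#' @param lsh_ratio Sketch positions per base of the entry length.
#' @param hash_seed Position-hash seed.
#' @param seed Seed for default dataset generation.
#' @return A `sigdb_correctness` list: `comparisons` (one row per
#'   query/entry pair: `entry_len`, `query_id`, `entry_id`, `ani`,
#'   `sigdb_score`) and `summary` (`entry_len`, `tau`, `auc`, `n_pos`,
#'   `n_comparisons`).
#' @export
correctness_experiment <- function(dataset = NULL, taus = c(0.95, 0.99), k = 8,
                                   lsh_ratio = 5, hash_seed = 1L, seed = 1L) {
  if (is.null(dataset)) dataset <- correctness_dataset(seed = seed)
  comparisons <- purrr::map_dfr(dataset, function(set) {
    ctor <- lsh_constructor(k = k, L = lsh_size_for(set$entry_len, lsh_ratio),
                            hash_seed = hash_seed)
    entry_lshs <- lapply(set$entries$seq, build_lsh, constructor = ctor)
    query_lshs <- lapply(set$queries$seq, build_lsh, constructor = ctor)
    grid <- expand.grid(qi = seq_len(nrow(set$queries)),
                        ei = seq_len(nrow(set$entries)))
    score <- purrr::map2_dbl(grid$qi, grid$ei, function(qi, ei) {
      s <- lsh_similarity(query_lshs[[qi]], entry_lshs[[ei]])
      max(s$IoU, s$IoQ, s$IoD)
    })
    tibble(
      entry_len = set$entry_len,
      query_id = set$queries$query_id[grid$qi],
      entry_id = set$entries$entry_id[grid$ei],
      ani = ani(set$queries$seq[grid$qi], set$entries$seq[grid$ei]),
      sigdb_score = score
    )
  })
  summary <- purrr::map_dfr(unique(comparisons$entry_len), function(len) {
    sub <- dplyr::filter(comparisons, .data$entry_len == len)
    purrr::map_dfr(taus, function(tau) {
      labels <- sub$ani >= tau
      tibble(
        entry_len = len, tau = tau,
        auc = roc_auc(sub$sigdb_score, labels),
        n_pos = sum(labels), n_comparisons = nrow(sub)
      )
    })
  })
  structure(list(comparisons = comparisons, summary = summary),
            class = "sigdb_correctness")
}

#' @export
print.sigdb_correctness <- function(x, ...) {
  cat("<sigdb_correctness>\n")
  print(x$summary)
  invisible(x)
}

#' @importFrom rlang .data
NULL
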