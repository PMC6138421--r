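#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy similarity results
#'
#' @param x A `sigdb_scores` tibble from [decrypt_scores()] or
#'   [run_exchange()].
#' @param ... Unused.
#' @return A plain tibble, one row per database entry, ranked by IoU.
#' @export
tidy.sigdb_scores <- function(x, ...) {
  out <- as_tibble(unclass(x)[names(x) != "q_mag"])
  dplyr::arrange(dplyr::mutate(out, rank = dplyr::min_rank(dplyr::desc(.data$IoU))),
                 .data$rank)
}

#' One-row summary of a search
#'
#' @inheritParams tidy.sigdb_scores
#' @return Tibble with the database size, query magnitude and the best entry.
#' @export
glance.sigdb_scores <- function(x, ...) {
  best <- which.max(x$IoU)
  tibble(
    n_entries = nrow(x),
    q_mag = attr(x, "q_mag") %||% NA_integer_,
    best_entry = x$entry_id[best],
    best_IoU = x$IoU[best],
    best_IoQ = x$IoQ[best],
    best_IoD = x$IoD[best]
  )
}

#' Tidy a ROC curve
#'
#' @param x A `sigdb_roc` from [roc_curve()].
#' @param ... Unused.
#' @return Tibble of `threshold`, `n_relevant`, `tpr`, `fpr`.
#' @export
tidy.sigdb_roc <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row ROC summary
#'
#' @inheritParams tidy.sigdb_roc
#' @return Tibble with `auc`, `n_pos`, `n_neg`, `n_thresholds`.
#' @export
glance.sigdb_roc <- function(x, ...) {
  tibble(auc = attr(x, "auc"), n_pos = attr(x, "n_pos"),
         n_neg = attr(x, "n_neg"), n_thresholds = nrow(x))
}

#' Tidy a correctness evaluation
#'
#' @param x A `sigdb_correctness` from [correctness_experiment()].
#' @param ... Unused.
#' @return The per-pair comparisons tibble.
#' @export
tidy.sigdb_correctness <- function(x, ...) x$comparisons

#' Per-set AUC summary of a correctness evaluation
#'
#' @inheritParams tidy.sigdb_correctness
#' @return The summary tibble: `entry_len`, `tau`, `auc`, `n_pos`,
#'   `n_comparisons`.
#' @export
glance.sigdb_correctness <- function(x, ...) x$summary
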