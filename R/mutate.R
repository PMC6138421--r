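# In-silico mutation models. Point mutations stand in for real divergence and
# for sequencing errors; the replacement alphabet for the fixed-count models is
# the three alternate bases plus 'X' (a data-error symbol), drawn uniformly,
# and every mutated position is guaranteed to differ from the original.

mutation_alternatives <- function(orig, include_x = TRUE) {
  pool <- c("A", "C", "G", "T", if (include_x) "X")
  vapply(orig, function(b) {
    alt <- setdiff(pool, b)
    alt[sample.int(length(alt), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Mutate a fixed fraction of positions, uniformly across the sequence
#'
#' Exactly `round(rate * n)` distinct positions are chosen uniformly without
#' replacement; each is replaced by a uniform draw from the three alternate
#' bases and `'X'`, so every mutated position differs from the original
#' (`rate = 1` gives Hamming distance `n`).
#'
#' @param seq A single sequence string.
#' @param rate Fraction of positions mutated, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @param include_x Include `'X'` in the replacement alphabet (default `TRUE`).
#' @return The mutated sequence string.
#' @export
mutate_uniform <- function(seq, rate, seed = NULL, include_x = TRUE) {
  check_string(seq, "seq")
  rate <- check_fraction(rate, "rate")
  n <- nchar(seq)
  m <- round(rate * n)
  if (m == 0) return(seq)
  with_seed_if(seed, {
    pos <- sample.int(n, m)
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases[pos] <- mutation_alternatives(bases[pos], include_x = include_x)
    paste(bases, collapse = "")
  })
}

#' Mutate a fixed fraction of positions, confined to the second half
#'
#' Models two sequences that overlap perfectly on one half: `round(rate * n)`
#' positions are mutated, all in the second half of the sequence; the first
#' half is untouched. `rate = 0.5` fully mutates the second half, i.e. two
#' sequences that match by exactly 50%.
#'
#' @inheritParams mutate_uniform
#' @param rate Fraction of *total* positions mutated, in `[0, 0.5]`.
#' @return The mutated sequence string.
#' @export
mutate_localized <- function(seq, rate, seed = NULL, include_x = TRUE) {
  check_string(seq, "seq")
  rate <- check_fraction(rate, "rate", max = 0.5)
  n <- nchar(seq)
  m <- round(rate * n)
  if (m == 0) return(seq)
  half_start <- floor(n / 2) + 1L
  with_seed_if(seed, {
    pos <- half_start - 1L + sample.int(n - half_start + 1L, m)
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases[pos] <- mutation_alternatives(bases[pos], include_x = include_x)
    paste(bases, collapse = "")
  })
}

#' Mutate each base independently with probability `p`
#'
#' The per-base Bernoulli model used to generate diverged query copies for the
#' classifier evaluation: each base is switched with probability `p` to a
#' uniform draw from the three alternate bases (no `'X'` by default, keeping
#' mutants alignable as plain DNA).
#'
#' @inheritParams mutate_uniform
#' @param p Per-base mutation probability in `[0, 1]`.
#' @param include_x Include `'X'` among the replacements (default `FALSE`).
#' @return The mutated sequence string.
#' @export
mutate_bernoulli <- function(seq, p, seed = NULL, include_x = FALSE) {
  check_string(seq, "seq")
  p <- check_fraction(p, "p")
  n <- nchar(seq)
  with_seed_if(seed, {
    hit <- which(runif(n) < p)
    if (length(hit) == 0L) return(seq)
    bases <- strsplit(seq, "", fixed = TRUE)[[1]]
    bases[hit] <- mutation_alternatives(bases[hit], include_x = include_x)
    paste(bases, collapse = "")
  })
}
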