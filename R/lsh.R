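#' LSH constructor: the shared sketching parameters
#'
#' Both protocol parties must sketch with identical parameters, so the
#' constructor travels from the Querier to the Database Owner as a JSON
#' artifact. The hash is a stable, seeded 64-bit FNV-1a reduced mod `L`;
#' identical constructors map identical k-mers to identical positions on any
#' platform.
#'
#' @param k k-mer length in bases (default 8, the setting most robust to
#'   point mutations).
#' @param L Sketch length in positions; size it with [lsh_size_for()].
#' @param hash_seed Integer seed of the position hash, shared by both parties.
#' @return An object of class `lsh_constructor`.
#' @seealso [build_lsh()], [lsh_size_for()]
#' @export
lsh_constructor <- function(k = 8, L, hash_seed = 1L) {
  k <- check_count(k, "k")
  L <- check_count(L, "L")
  hash_seed <- check_count(hash_seed, "hash_seed", min = 0L)
  structure(
    list(k = k, L = L, hash_seed = hash_seed, hash_name = "fnv1a64"),
    class = "lsh_constructor"
  )
}

#' @export
print.lsh_constructor <- function(x, ...) {
  cat(sprintf("<lsh_constructor> k = %d, L = %s, hash = %s(seed %d)\n",
              x$k, format(x$L, big.mark = ","), x$hash_name, x$hash_seed))
  invisible(x)
}

#' Extract k-mers with a sliding window of one base
#'
#' A sequence of length `n` yields `n - k` windows at offsets `0 .. n-k-1`
#' (the final base never starts a window); duplicates are retained. This
#' `n - k` convention is deliberate and is the count all sizing arithmetic in
#' the package assumes, e.g. a 20,000-base sequence has 19,992 8-mers.
#'
#' @param seq A single sequence string.
#' @param k k-mer length; must be strictly less than `nchar(seq)`.
#' @return Character vector of `n - k` k-mers, in sequence order.
#' @export
extract_kmers <- function(seq, k) {
  check_string(seq, "seq")
  k <- check_count(k, "k")
  n <- nchar(seq)
  if (n <= k) {
    abort(sprintf(
      "Sequence of length %d has no k-mers at k = %d: windows run at offsets 0..n-k-1, so n must exceed k.",
      n, k
    ))
  }
  starts <- seq_len(n - k)
  substring(seq, starts, starts + k - 1L)
}

#' Size the LSH from the longest database sequence
#'
#' The sketch is sized at `ratio` positions per base of the longest sequence
#' being compared (default 5:1), trading memory and runtime against the hash
#' collision rate; at 5:1 the per-k-mer collision probability is about 18%
#' (see [collision_probability()]). A 20,000-base maximum yields `L = 100000`.
#'
#' @param max_seq_len Length in bases of the longest sequence to be sketched.
#' @param ratio Positions per base (default 5).
#' @return Integer sketch length `L`.
#' @export
lsh_size_for <- function(max_seq_len, ratio = 5) {
  max_seq_len <- check_count(max_seq_len, "max_seq_len")
  if (!is.numeric(ratio) || length(ratio) != 1L || is.na(ratio) || ratio <= 0) {
    abort("`ratio` must be a single positive number.")
  }
  as.integer(round(ratio * max_seq_len))
}

#' Hash a k-mer to its sketch position
#'
#' Deterministic for a fixed (k-mer, seed, L) and stable across runs and
#' platforms; approximately uniform over `[0, L)`.
#'
#' @param kmer Character vector of k-mers, each of length `constructor$k`.
#' @param constructor An [lsh_constructor()].
#' @return Integer vector of 0-based positions in `[0, L)`.
#' @export
hash_kmer <- function(kmer, constructor) {
  stopifnot(inherits(constructor, "lsh_constructor"))
  if (!is.character(kmer) || length(kmer) < 1L) abort("`kmer` must be a character vector.")
  if (any(nchar(kmer) != constructor$k)) {
    abort(sprintf("All k-mers must have length k = %d.", constructor$k))
  }
  hash_kmers_cpp(kmer, constructor$L, constructor$hash_seed)
}

#' Sketch a sequence into an LSH bit vector
#'
#' Position `j` of the sketch is set iff some k-mer of `seq` hashes to `j`;
#' repeated k-mers set a bit once, so repeat content collapses. The magnitude
#' (popcount) is carried with the vector.
#'
#' @inheritParams extract_kmers
#' @param constructor An [lsh_constructor()].
#' @return An object of class `lsh_vector`: sorted 0-based set positions,
#'   the sketch length `L`, and the magnitude.
#' @export
build_lsh <- function(seq, constructor) {
  stopifnot(inherits(constructor, "lsh_constructor"))
  check_string(seq, "seq")
  if (nchar(seq) <= constructor$k) {
    abort(sprintf(
      "Sequence of length %d has no k-mers at k = %d: windows run at offsets 0..n-k-1, so n must exceed k.",
      nchar(seq), constructor$k
    ))
  }
  positions <- lsh_positions_cpp(seq, constructor$k, constructor$L, constructor$hash_seed)
  new_lsh_vector(positions, constructor$L)
}

new_lsh_vector <- function(positions, L) {
  structure(
    list(positions = as.integer(positions), L = as.integer(L),
         magnitude = length(positions)),
    class = "lsh_vector"
  )
}

#' @export
print.lsh_vector <- function(x, ...) {
  cat(sprintf("<lsh_vector> L = %s, magnitude = %s\n",
              format(x$L, big.mark = ","), format(x$magnitude, big.mark = ",")))
  invisible(x)
}

#' Expand an LSH to its full 0/1 vector
#'
#' @param x An `lsh_vector`.
#' @return Integer vector of length `L` with ones at the set positions.
#' @export
lsh_bits <- function(x) {
  stopifnot(inherits(x, "lsh_vector"))
  bits <- integer(x$L)
  bits[x$positions + 1L] <- 1L
  bits
}

#' Plaintext similarity of two sketches
#'
#' The reference (unencrypted) scoring path: the intersection is the popcount
#' of the AND of the two bit vectors. The encrypted protocol computes exactly
#' this quantity homomorphically, so this function doubles as the oracle the
#' encrypted path is tested against and as the fast scoring route for
#' large-scale evaluation.
#'
#' @param query_lsh,entry_lsh `lsh_vector`s built with a shared constructor.
#' @return One-row tibble: `db_magnitude`, `intersection`, `IoU`, `IoQ`, `IoD`.
#' @export
lsh_similarity <- function(query_lsh, entry_lsh) {
  stopifnot(inherits(query_lsh, "lsh_vector"), inherits(entry_lsh, "lsh_vector"))
  if (query_lsh$L != entry_lsh$L) {
    abort("Sketches have different lengths; both parties must share one constructor.")
  }
  i <- intersect_count_cpp(query_lsh$positions, entry_lsh$positions)
  dplyr::mutate(
    compute_similarity(i, query_lsh$magnitude, entry_lsh$magnitude),
    db_magnitude = entry_lsh$magnitude, .before = 1
  )
}

#' Closed-form hash collision probability
#'
#' Probability that a given item shares its sketch position with at least one
#' of the other `n_items - 1` items: `1 - (1 - 1/L)^(n_items - 1)`. At the
#' default 5:1 sizing (20,000 items into 100,000 positions) this is about 0.18.
#'
#' @param n_items Number of items hashed.
#' @param L Number of sketch positions.
#' @return Collision probability in `[0, 1]`.
#' @export
collision_probability <- function(n_items, L) {
  n_items <- check_count(n_items, "n_items")
  L <- check_count(L, "L")
  1 - (1 - 1 / L)^(n_items - 1)
}

#' Simulate the empirical collision fraction
#'
#' Hashes `n_items` distinct random k-mers into `L` positions with the
#' package's position hash and reports, per replicate, the fraction of items
#' that landed in a slot shared with another item.
#'
#' @inheritParams collision_probability
#' @param k k-mer length of the simulated items.
#' @param reps Number of replicates.
#' @param seed Integer seed for the simulation.
#' @return Tibble with columns `rep` and `collision_rate`.
#' @export
simulate_collision_rate <- function(n_items, L, k = 8, reps = 100, seed = 1L) {
  n_items <- check_count(n_items, "n_items")
  L <- check_count(L, "L")
  k <- check_count(k, "k")
  reps <- check_count(reps, "reps")
  seed <- check_count(seed, "seed", min = 0L)
  tibble(rep = seq_len(reps),
         collision_rate = collision_sim_cpp(n_items, L, k, reps, seed))
}
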