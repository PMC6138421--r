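# Synthetic sequence generators. They emulate the statistical shape of real
# bacterial inputs — lengths, GC content, query/entry relationships — with
# i.i.d. bases; they do not reproduce genome repeat structure, which in real
# data slightly lowers distinct k-mer counts.

#' Generate a random genome
#'
#' I.i.d. bases at the requested GC fraction; byte-for-byte reproducible under
#' `seed`.
#'
#' @param length Genome length in bases.
#' @param gc_content GC fraction in `[0, 1]` (default 0.5).
#' @param seed Optional integer seed.
#' @return A single sequence string.
#' @export
random_genome <- function(length, gc_content = 0.5, seed = NULL) {
  length <- check_count(length, "length")
  gc_content <- check_fraction(gc_content, "gc_content")
  prob <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2, (1 - gc_content) / 2)
  with_seed_if(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE, prob = prob),
          collapse = "")
  })
}

#' Take a prefix of a sequence
#'
#' The first `prefix_len` bases; a prefix's k-mer set (and hence its sketch
#' positions) is always a subset of the full sequence's.
#'
#' @param seq A single sequence string.
#' @param prefix_len Prefix length, at most `nchar(seq)`.
#' @return The prefix string.
#' @export
prefix_query <- function(seq, prefix_len) {
  check_string(seq, "seq")
  prefix_len <- check_count(prefix_len, "prefix_len")
  if (prefix_len > nchar(seq)) {
    abort(sprintf("prefix_len (%d) exceeds the sequence length (%d).",
                  prefix_len, nchar(seq)))
  }
  substr(seq, 1L, prefix_len)
}

# Non-overlapping interval sampling by random slack allocation: the unused
# bases are distributed at random among the n+1 gaps, which stays feasible at
# any packing density (plain rejection sampling stalls above ~75% occupancy).
sample_nonoverlapping <- function(genome_len, n, width) {
  if (n * width > genome_len) {
    abort(sprintf("Cannot place %d non-overlapping intervals of %d bases in %d bases.",
                  n, width, genome_len))
  }
  slack <- genome_len - n * width
  offsets <- sort(sample.int(slack + 1L, n, replace = TRUE) - 1L)
  (seq_len(n) - 1L) * width + offsets + 1L
}

#' Build a labeled query/database dataset from synthetic genomes
#'
#' For each entry length, samples `entries_per_set` non-overlapping
#' subsequences from each source genome; from every entry draws one wild-type
#' query (a random `query_len`-base subsequence of the entry) plus one
#' Bernoulli-mutated copy per rate in `mutation_rates`. Queries carry their
#' source entry in `source_entry`, and generator parameters are embedded in
#' the ids for provenance.
#'
#' @param genomes Named character vector of source genomes (default
#'   generation: two unrelated random genomes).
#' @param entry_lens Entry lengths, one database set per length.
#' @param entries_per_set Entries sampled per length set (split across
#'   genomes).
#' @param query_len Query length in bases.
#' @param mutation_rates Per-base mutation probabilities for the mutated query
#'   copies.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of per-length-set lists, each with `entry_len`, `entries`
#'   (tibble: `entry_id`, `genome`, `start`, `seq`) and `queries` (tibble:
#'   `query_id`, `source_entry`, `rate`, `seq`).
#' @export
correctness_dataset <- function(genomes = NULL, entry_lens = c(1000, 2000, 3000),
                                entries_per_set = 50, query_len = 1000,
                                mutation_rates = c(0.05, 0.10), seed = 1L) {
  seed <- check_count(seed, "seed", min = 0L)
  entries_per_set <- check_count(entries_per_set, "entries_per_set")
  query_len <- check_count(query_len, "query_len")
  if (is.null(genomes)) {
    genomes <- c(
      genomeA = random_genome(100000, seed = seed * 1000L + 1L),
      genomeB = random_genome(100000, seed = seed * 1000L + 2L)
    )
  }
  if (is.null(names(genomes))) names(genomes) <- paste0("genome", seq_along(genomes))
  withr::with_seed(seed, {
    lapply(entry_lens, function(len) {
      len <- check_count(len, "entry_lens")
      if (query_len > len) abort("query_len must not exceed the entry length.")
      per_genome <- diff(round(seq(0, entries_per_set, length.out = length(genomes) + 1L)))
      entries <- purrr::map2_dfr(names(genomes), per_genome, function(g, ng) {
        if (ng == 0L) return(tibble())
        starts <- sample_nonoverlapping(nchar(genomes[[g]]), ng, len)
        tibble(
          entry_id = sprintf("%s_len%d_s%d", g, len, starts),
          genome = g, start = starts,
          seq = substring(genomes[[g]], starts, starts + len - 1L)
        )
      })
      queries <- purrr::pmap_dfr(entries, function(entry_id, genome, start, seq) {
        qs <- sample.int(nchar(seq) - query_len + 1L, 1L)
        wt <- substring(seq, qs, qs + query_len - 1L)
        muts <- lapply(mutation_rates, function(p) mutate_bernoulli(wt, p))
        tibble(
          query_id = sprintf("%s_q%s", entry_id,
                             c("wt", sprintf("mut%g", mutation_rates))),
          source_entry = entry_id,
          rate = c(0, mutation_rates),
          seq = c(wt, unlist(muts))
        )
      })
      list(entry_len = len, entries = entries, queries = queries)
    })
  })
}

#' Write a correctness dataset to FASTA files with a manifest
#'
#' One entries FASTA and one queries FASTA per length set, plus a JSON
#' manifest recording the generator parameters.
#'
#' @param dataset Output of [correctness_dataset()].
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
write_correctness_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::map_dfr(dataset, function(set) {
    ef <- file.path(dir, sprintf("entries_len%d.fasta", set$entry_len))
    qf <- file.path(dir, sprintf("queries_len%d.fasta", set$entry_len))
    write_fasta(rlang::set_names(set$entries$seq, set$entries$entry_id), ef)
    write_fasta(rlang::set_names(set$queries$seq, set$queries$query_id), qf)
    tibble(entry_len = set$entry_len, entries_fasta = ef, queries_fasta = qf,
           n_entries = nrow(set$entries), n_queries = nrow(set$queries))
  })
  jsonlite::write_json(paths, file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(paths)
}
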