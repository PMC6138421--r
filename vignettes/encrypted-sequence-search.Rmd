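---
title: "Encrypted sequence similarity search: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encrypted sequence similarity search: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`seqveil` lets a Querier measure the similarity of a secret DNA sequence to
every entry of a Database Owner's private collection. This vignette is the
package's account of how the method works, which knobs matter, and where the
design was genuinely open.

## The protocol

Ten steps, two roles:

1. The Owner reports the length of the longest (capped) entry.
2. The Querier sizes a locality-sensitive-hash (LSH) constructor from it and
   sketches the query.
3. The Querier generates a Paillier key pair.
4. Every position of the query sketch is encrypted — zeros too.
5. Constructor, public key and encrypted query go to the Owner.
6. The Owner sketches every entry with the same constructor.
7. For each entry, the Owner homomorphically sums the query ciphertexts at the
   entry's filled positions.
8. All pairs {encrypted intersection, entry magnitude} return to the Querier.
9. The Querier decrypts the intersections.
10. The Querier computes IoU, IoQ and IoD per entry.

`run_exchange()` plays both roles locally and writes every exchanged artifact;
the JSON artifacts are the trust boundary, so each half of the exchange can
equally be replayed from files (see the `sigdb.R` command-line script).

## The sketch

A sequence of length $n$ is cut into $n-k$ k-mers by a sliding window of one
base (offsets $0$ to $n-k-1$; the last base never starts a window — this
$n-k$ convention is used consistently in all sizing arithmetic, so a
20,000-base sequence has 19,992 8-mers). Each k-mer is hashed to one of $L$
positions; the sketch is the binary occupancy vector, and its magnitude the
popcount. Identical k-mers land on identical positions, so repeats collapse
to a single set bit.

**Similarity.** For query and entry sketches $Q$ and $D$ with intersection
$I = |Q \wedge D|$:

$$\mathrm{IoU} = \frac{I}{|Q| + |D| - I}, \qquad
  \mathrm{IoQ} = \frac{I}{|Q|}, \qquad
  \mathrm{IoD} = \frac{I}{|D|}.$$

IoQ is insensitive to the query being shorter than the entry (a prefix query
scores IoQ = 1 exactly, since a prefix's sketch positions are a subset of the
full sequence's); IoD covers the mirrored case.

**Parameters.**

* `k` (default **8** bases). A point mutation corrupts every window covering
  it, i.e. about $k$ k-mers, so smaller $k$ tolerates more divergence; larger
  $k$ is more specific and slightly cheaper. The default follows the tuning
  result that $k=8$ keeps the correct entry on top of the IoU ranking to much
  higher mutation rates than $k = 16$ or $32$.
* `L` (positions), via `lsh_size_for(max_len, ratio = 5)`. Five positions per
  base of the longest compared sequence. At that ratio the chance a given
  k-mer shares its slot with another is $1-(1-1/L)^{n-1} \approx 18\%$ for
  $n = 20{,}000$, $L = 100{,}000$ (`collision_probability()`, and
  `simulate_collision_rate()` reproduces it empirically). Larger `L` lowers
  the collision floor linearly at the price of encryption and scan time, and
  `L` never needs to exceed five times $\min(4^k, n-k)$ — with 8-mers there
  are only $4^8 = 65{,}536$ distinct k-mers, so $L = 327{,}680$ suffices for
  any sequence length.
* `hash_seed`. The position hash is a seeded 64-bit FNV-1a with an avalanche
  finalizer, reduced mod $L$. A keyed, stable hash was a deliberate choice:
  both parties must agree on the map across machines and sessions, which rules
  out runtime-dependent built-in hashes; the seed travels in the constructor
  artifact. The finalizer matters because positions are taken modulo $L$ and
  raw FNV-1a has weak low bits.
* `truncate_len` (default **20,000** bases). Longer sequences contribute only
  their first `truncate_len` bases, keeping `L` and the per-query cost
  bounded; the owner reports the post-cap maximum for sizing. Full-length
  genomes work by raising the cap (and `L` with it).

## The cryptosystem

Paillier encryption with modulus $n = pq$ and the $g = n+1$ convention:
$\mathrm{Enc}(m; r) = (1+mn)\, r^n \bmod n^2$ with $r$ uniform on $(0, n)$,
fresh per ciphertext. Ciphertext products decrypt to plaintext sums, which is
the whole trick: the owner multiplies the query's ciphertexts at an entry's
filled positions without being able to read any of them. Decryption uses
$\lambda = \mathrm{lcm}(p-1, q-1)$ and $\mu = \lambda^{-1} \bmod n$. All
big-integer arithmetic is OpenSSL BIGNUM (`src/paillier.cpp`).

* **Key size** defaults to 3072 bits (~128-bit security). 512- and 1024-bit
  keys are accepted for tests and fixtures and are labelled as such; nothing
  in the package hardcodes a weak key.
* **Zeros are encrypted.** The protocol would be meaningless otherwise: a
  vector with plaintext zeros *is* the query sketch. All $L$ positions get a
  fresh ciphertext.
* **Re-randomization.** Each returned intersection is multiplied by a fresh
  $\mathrm{Enc}(0)$, so an empty entry still returns a valid ciphertext and
  returned ciphertexts never equal any function of the query ciphertexts
  alone.
* **Deterministic mode.** Every randomness consumer (`paillier_keygen()`,
  encryption, re-randomization) accepts an optional seed driving a
  deterministic generator instead of the CSPRNG. This exists for regression
  fixtures and byte-identical reruns only and is flagged as non-secure in the
  API and print methods.

**What the Querier still learns:** the number of entries (one score pair
each) and the entry sketch magnitudes, a coarse proxy for entry length and
diversity. Hiding magnitudes needs fully homomorphic encryption, which is out
of scope here.

## Degenerate inputs and numerical conventions

* A metric with a zero denominator is defined as 0 (only possible with empty
  sketches); this preserves $\mathrm{IoU} \le \min(\mathrm{IoQ},
  \mathrm{IoD})$.
* A decrypted intersection above $\min(|Q|, |D|)$ cannot arise from an honest
  scan; `decrypt_scores()` raises an integrity error instead of clamping.
* Sequences of length $\le k$ have no windows under the $n-k$ convention and
  are rejected with the convention spelled out.
* Scores are returned at full float precision; rounding (e.g. to the two
  decimals used in tabulated comparisons) is left to the caller.
* Input is uppercased; `N` and `X` are accepted as ordinary symbols (`X` is
  the mutation model's data-error mark) unless `strict = TRUE`. Reverse
  complements are *not* canonicalized — strand handling is the caller's
  responsibility.

## Mutation models

Three generators, all guaranteeing a mutated position differs from the
original:

* `mutate_uniform(seq, p)` — exactly $\mathrm{round}(p\,n)$ positions, chosen
  uniformly without replacement, each replaced by a uniform draw from the
  three alternate bases and `X`. `p = 1` gives Hamming distance $n$.
* `mutate_localized(seq, p)` — the same count, confined to the second half;
  $p = 0.5$ models two sequences overlapping perfectly on one half. Which
  half is mutated is arbitrary; the second was chosen and the first half is
  left untouched.
* `mutate_bernoulli(seq, p)` — each base independently switched with
  probability $p$ to one of the three alternate bases (no `X` by default, so
  mutants stay alignable as plain DNA). This is the model behind the
  classifier evaluation's 5%/10% mutants.

The fixed-count and per-base models are genuinely different mechanisms (exact
count vs binomial count), so both exist and are selected explicitly.
`round(p*n)` rather than `floor` was chosen for the fixed-count models so the
nominal rate is unbiased.

## Ground truth and evaluation

**ANI.** The evaluation needs a sequence-level truth independent of sketches.
`ani(a, b)` is a containment identity: the shorter sequence is aligned
ends-free (semi-global) within the longer, and
$\mathrm{ani} = 1 - d/\ell_{\min}$ with $d$ the alignment's edit distance; for
equal lengths both orientations are computed and averaged. The containment
form was a deliberate design choice over strict global-alignment identity:
the evaluation compares 1,000-bp queries against up to 3,000-bp entries, and
a query that is an exact substring of an entry should score 1, not
$\ell_{\min}/\ell_{\max}$. For a per-base mutant the measure is essentially
one minus the realized mutation fraction; for unrelated random DNA it sits
near 0.5, far below the 0.95/0.99 label thresholds. The kernel is a plain
dynamic program in C++ (`src/edit.cpp`), exact and fast enough for tens of
thousands of pairs; the test suite pins it against
`Biostrings::pairwiseAlignment` (global-in-pattern/local-in-subject, 0/−1
edit scoring) for exact agreement.

**ROC.** `roc_curve(scores, labels)` sweeps thresholds in increasing order:
0 first (everything "relevant"), then each unique score; relevant means
score ≥ threshold. TPR/FPR per threshold, AUC by trapezoid over (FPR, TPR)
with the (0, 0) endpoint appended. For scores
`[0.2, 0.33, 0.33, 0.75, 0.87]` the unique-score thresholds mark
`[5, 4, 2, 1]` comparisons relevant. The suite cross-checks the AUC against
`pROC` on random data.

**Classifier evaluation.** `correctness_experiment()` builds, per entry
length in {1000, 2000, 3000} bp, a database of non-overlapping entries
sampled from two unrelated synthetic genomes; per entry one 1,000-bp
wild-type query plus 5% and 10% per-base mutants; scores every same-set
query/entry pair by $\max(\mathrm{IoU}, \mathrm{IoQ}, \mathrm{IoD})$ (the max
absorbs the query/entry length mismatch) and labels pairs by ANI ≥ τ. The
package's default sizes — two 100-kb genomes, 50 entries and 150 queries per
length set, 7,500 scored pairs per set — are desk-scale choices that keep the
full evaluation under a few minutes on one CPU; all sizes are arguments, so a
tenfold larger replication is one call away. Scoring uses the plaintext
sketch path (`lsh_similarity()`): the test suite proves the encrypted path
computes identical intersections, so nothing is lost by evaluating in the
clear. With the defaults the evaluation reproduces (as asserted in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`) an essentially perfect classifier at τ = 0.95 and
AUC ≥ 0.97 at τ = 0.99 for every length set.

Non-overlapping entries are placed by random slack allocation — the unused
bases are distributed among the gaps — because at 3,000-bp entries the
packing density (75%) is beyond what rejection sampling can place.

## What the synthetic generator does and does not emulate

`random_genome()` draws i.i.d. bases at a chosen GC content. That matches
real bacterial sequence in length and composition but has **no repeat
structure**: real genomes contain repeated elements whose k-mers collapse
into shared sketch positions, slightly lowering distinct-k-mer counts.
Consequences worth knowing:

* Prefix-query score averages on synthetic genomes land within about 0.03 of
  values measured on real bacterial genomes (e.g. IoU ≈ 0.79 vs 0.80 for a
  15,000/20,000 prefix, 0.30 vs 0.31 for 5,000/20,000, as computed by
  `scripts/acceptance.R`).
* Two synthetic genomes share no homologous regions, so in the classifier
  evaluation cross-genome pairs are always true negatives; with two related
  bacterial strains some cross-genome pairs would be true positives and the
  τ = 0.99 AUC can dip (real-strain replications report down to 0.97).
* Passing tests on synthetic data therefore demonstrate protocol
  correctness, sizing arithmetic and score behaviour — not robustness to
  repeat-heavy genomes (plant, human), which the sketch's repeat-collapsing
  deliberately de-weights.

## Known limitations

* Entry magnitudes and the database size are revealed to the Querier by
  construction; only a fully homomorphic variant hides them.
* No network transport or authentication: the JSON artifacts are the trust
  boundary and the parties are assumed willing.
* Indels and rearrangements are not modelled by the mutation generators; the
  sketch itself is robust to rearrangements (k-mers survive) but every
  k-mer spanning an indel is corrupted.
* Single-threaded by design; the scan is embarrassingly parallel over entries
  if a caller needs it.
* ANI here is an alignment-identity stand-in, adequate for labelling clearly
  related vs unrelated pairs; it is not a drop-in replacement for
  fragment-mapping ANI tools on draft assemblies.
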