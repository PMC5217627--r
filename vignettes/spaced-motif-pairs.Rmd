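---
title: "Detecting spaced motif pairs with conserved spacer length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spaced motif pairs with conserved spacer length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacedpairs)
```

## The problem and the model

Many functional DNA elements in prokaryotic genomes are not single
over-represented words but *pairs* of short conserved motifs separated by a
spacer of variable sequence and conserved length: the two recognition
half-sites of a dimeric transcription factor, a Shine-Dalgarno sequence at
a fixed offset from its start codon, the flanks of CRISPR repeats, the two
arms of a terminator hairpin. `spacedpairs` scans a genome for every
ordered pair of k-mers (pentamers by default, `4^10` ordered pairs) and
asks, for each pair, whether its occurrences concentrate at one spacer
length far more than a uniform distance distribution would allow. Neither
motif by itself needs to be frequent; only the *distance preference*
matters.

For one ordered pair $(A, B)$, let $n$ be the total number of occurrences
of $A$ followed by $B$ with spacer length $d \in [d_{\min}, d_{\max}]$
(default $[5, 89]$, so $K = 85$ distances), and $f_{\max}$ the count at the
most frequent distance. Under the null that each occurrence falls into one
of the $K$ distance cells uniformly and independently — the classical
balls-in-urns occupancy model — the distribution of the maximum cell count
is

$$
P(f_{\max} < x) \;=\; \frac{n!}{K^n}\,
  \big[\lambda^n\big]\left(\sum_{j=0}^{x-1}\frac{\lambda^j}{j!}\right)^{K},
$$

and the test rejects when the observed maximum reaches
$f_{\mathrm{cut}}(n) = \min\{x : P(f_{\max} \ge x) \le \alpha\}$. The
per-pair level is Bonferroni-corrected over all ordered pentamer pairs,
$\alpha = 0.01 / 4^{10} \approx 9.54\times10^{-9}$; testing over the $K$
distances needs no further correction because the multinomial null already
describes the whole distance profile.

Two filters target the main sources of false structure:

* **Duplicated segments.** A segmental duplication copies motifs *and*
  spacer verbatim, so exactly repeated spacers are counted once from the
  start, and spacers at the modal distance that align at $\ge 70\%$
  identity (Needleman–Wunsch, match $+1$ / mismatch $-1$ / gap $-2$)
  are removed greedily, decrementing $f_{\max}$ each time. The cutoff
  stays fixed at $f_{\mathrm{cut}}(n)$ from the pre-reduction total; only
  the maximum is corrected.
* **Strand corroboration.** A dispersed double-stranded element should be
  over-represented in both orientations, so a pair is reported only when
  its reverse-complement pair is also significant at the same distance.
  Palindromic pairs (e.g. `CGAAA(N)19TTTCG`) corroborate themselves.

Finally, pairs of overlapping pentamers carved from one longer underlying
element are merged into a consensus pattern, and occurrences are
classified against gene annotations (gene / intergenic / overlap, with
flanking-gene orientation) to aid functional interpretation.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 5 | motif length; 6 is supported but squares the pair table |
| `dmin`, `dmax` | 5, 89 | spacer-length range (bp); `K = dmax - dmin + 1` |
| `alpha_family` | 0.01 | family-wise error before Bonferroni division |
| `n_tests` | `4^(2k)` | hypotheses for the correction |
| `n_exact_max` | 600 | largest `n` evaluated with the exact occupancy tail |
| `identity` | 0.70 | spacer-collapse threshold; 0.65/0.75 give the standard sensitivity variants |
| `min_n` | 6 | totals below this can never reach significance (`fcut(5) = 6 > 5`) |

The spacer length `d` counts the nucleotides strictly between the end of
`A` and the start of `B`, matching the `A(N)dB` pattern notation; users
who prefer start-to-start offsets can shift `dmin`/`dmax` by `k`.

## Numerical choices

**Exact occupancy tail.** The generating-function coefficient is evaluated
by conditioning cell by cell: given that the first $m-1$ cells hold $t$
occurrences, cell $m$ receives $\mathrm{Binomial}(n-t, 1/(K-m+1))$ of the
rest. Every intermediate quantity is a probability, every update adds
positive terms, so the $O(Knx)$ evaluation is cancellation-free and stable
for any $n$ (unlike a literal floating-point polynomial power, whose
coefficient range overflows doubles near $n \approx 650$). Upper tails are
$1 - \mathrm{cdf}$; below $10^{-7}$, where that complement starts losing
relative precision, `exact_pvalue()` switches to the finite
inclusion–exclusion expansion over the set of cells reaching $x$ (exact:
it terminates at $\lfloor n/x \rfloor$ terms). Tests pin the
implementation to full $K^n$ enumeration for $n \le 6, K \le 4$, to closed
forms such as $P(f_{\max} \ge n) = K^{1-n}$, and to Monte Carlo at
$n = 50, K = 85$.

**Asymptotic percentile.** For $n > 600$ the cutoff is the ceiling
(conservative rounding) of

$$
F_\alpha \approx \frac{n}{K} + \sqrt{\frac{n\log K}{K}}
 - \left(\log\log\frac{1}{1-\alpha} + 1.266\right)
   \sqrt{\frac{n}{2K\log K}},
$$

with natural logarithms — the extreme-value asymptotics behind the formula
are stated in $\ln$; with $\log_{10}$ the formula fails sanity checks such
as monotonicity calibration against the exact cutoffs. At $K = 85$ and
$\alpha \approx 10^{-8}$ the ceiled approximation sits within 3 counts of
the exact cutoff over $n = 500\ldots700$ (it undershoots slightly), which
is why the exact computation is preferred up to `n_exact_max = 600`.

**Candidate screening.** Storing unique-spacer sets for a million pairs is
infeasible, so a first pass records only raw (non-deduplicated) per-pair
summaries. A pair is carried into the exact recount only if its raw
maximum reaches `fcut(occupied)`, where `occupied` is the number of
distances with at least one occurrence. This bound is provably
conservative: each occupied distance contributes at least one distinct
spacer, so the unique-spacer total is at least `occupied`, and `fcut` is
nondecreasing in `n`; hence any pair significant after deduplication
satisfies the screen. (Screening against `fcut(n_raw)` would *not* be
sound — deduplication can shrink `n`, and with it the cutoff, faster than
it shrinks the maximum.) A test compares the screened pipeline against
exhaustive per-pair evaluation on a small genome.

**Deduplication details.** Identity is identical aligned positions over
alignment length including gap columns; among score-optimal alignments the
most-identical (then shortest) one is used, making the value
deterministic. The threshold test is `>= 0.70`, the stricter of the two
plausible readings, with the threshold exposed as a parameter. Of two
spacers above threshold the *later* (downstream) one is removed — a
deterministic choice that does not depend on alignment internals. Because
all spacers at one distance have equal length, a gapless positional
identity is offered as a fast mode; the default remains the full
alignment.

**Ties and edge cases.** All distances tying for the maximum are evaluated
and each significant one reported. `fcut` returns `n + 1` when no
attainable count is significant (all `n <= 5` at the defaults). The merge
criterion — two pairs merge when, at some offset `|o| <= k - 1`, at least
90% of the smaller pair's occurrence starts coincide with the other's
shifted starts — is this package's operationalization of "combine
overlapping pentamer pairs"; the share threshold is a parameter.
`fcut(n)` uses the unique-spacer total and is not recomputed from the
post-reduction total, matching the procedure's "reduce `fmax` by one"
reading.

## The synthetic-data generator

`generate_genome()` draws an i.i.d. background at a chosen GC content
(optionally an order-1 Markov chain) and plants motif-pair copies at
non-overlapping random positions, with three spacer regimes — independent
random spacers (genuine distance-constrained motif), one verbatim spacer
(segmental duplication), or a point-mutant family at a chosen identity
(diverged duplication) — on one or both strands, returning a truth table
of every planted locus. `generate_annotation()` adds non-overlapping
random genes. These fixtures exercise the whole pipeline through the real
FASTA/GFF3 I/O path.

What the generator deliberately does *not* emulate: real genomic
composition (codon structure, skews, repeat families), overlapping or
nested genes, and sequencing artefacts. Passing planted-recovery tests
therefore demonstrates the statistics and the bookkeeping, not robustness
to compositional confounders — on real genomes, locally repetitive
sequence is exactly what the spacer-deduplication and reverse-complement
filters are there to absorb.

Default validation conditions used by the tests and the acceptance
script: a 200 kb genome with 30 both-strand planted copies of
`AAGGA(N)6ATGAA` (a published Shine-Dalgarno-type pattern) for recovery,
the same genome with one shared spacer for the duplication control, and
five seeded 1 Mb background-only genomes for the null control, where the
family-wise level implies virtually no reports. Unit tests use 3–10 kb
toys for oracle equivalence and `n = 50, K = 85` with $10^5$ replicates
for the Monte Carlo check; these sizes make the full suite run in a few
minutes while keeping every standard error far below the asserted
margins.

## Worked example

```{r example, eval = FALSE}
syn <- generate_genome(
  length = 200000, gc = 0.5,
  plants = plant_spec("AAGGA", "ATGAA", d = 6, copies = 30,
                      spacer_mode = "distinct", strands = "both"),
  seed = 11)

res <- find_motif_pairs(syn$genome)
tidy(res)       # one row per reported pair direction
res$merged      # consensus patterns after merging overlapping pairs
autoplot(res)   # spacer-length distribution of reported pairs

h <- unique_spacer_histogram(
  collect_occurrences(syn$genome, "AAGGA", "ATGAA", scan_params()),
  scan_params(), "AAGGA", "ATGAA")
autoplot(h, cutoff = fcut(h$n))
```

## Known limitations

* Motifs are exact k-mers; degenerate or mismatched motif instances are
  fragmented across neighbouring pairs (partially recovered by the merge
  step) rather than modelled.
* The null is uniformity over distances only; sequence-composition nulls
  (Markov backgrounds for the *test*, not just the simulator) are out of
  scope.
* `k > 6` is rejected: the dense pair table grows as `4^(2k)`.
* The greedy spacer reduction is order-dependent by design (genome
  order); it reproduces the published procedure rather than an optimal
  clustering.
* Location statistics consider CDS and annotated RNA genes; feature-type
  coverage of third-party annotations varies, and the classification
  rules (full containment, strand-agnostic) are stated rather than
  configurable per feature type.
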