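---
title: "Network hub scoring of cancer genes: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network hub scoring of cancer genes: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubscore)
```

## The problem and the model

Cancer driver-gene catalogues built from mutation recurrence alone miss
genes whose importance is positional: their protein sits at the centre of a
neighbourhood of mutated interaction partners even if the gene itself is
rarely hit. `hubscore` ranks genes by exactly that quantity. For a gene $g$
with $T$ interaction partners in a protein-protein interaction network, of
which $M$ are encoded by cancer-mutated genes, the network score is

$$ S(g) \;=\; T \cdot \frac{M}{T} \;=\; M , $$

the number of mutated neighbours. The product form is kept in the code and
$T$ and $M$ are reported separately in every output, so variants that do not
collapse (for example $M^2/T$, which would reward mutated *fractions*) can
be formed downstream without rescoring. Because $S$ grows with a cohort's
overall mutation rate, scores are comparable only within one cancer; the
cross-cancer helpers therefore min-max normalise per cancer before any
comparison (see below).

Three inputs define one cancer analysis:

* a **mutation table** (MAF-like TSV, one row per mutation event) from which
  per-gene event counts and mutation locations are tallied;
* a table of **survival Meta-Z scores** (gene x cancer), a published
  meta-analysis statistic linking a gene's expression to overall survival;
  $|Z| \ge 1.96$ corresponds to 95% confidence, $|Z| \ge 2.58$ to 99%;
* an **interaction network** in BioGRID TAB3 format, reduced to an
  undirected simple graph on official gene symbols.

## Pipeline stages

1. **Classification.** Every variant label is harmonised to `ORF` (coding
   sequence) or `NON_ORF` and each gene is classed `ORF`, `NON_ORF`, `BOTH`
   or `NONE` by where its mutations fall. Synonymous changes count as `ORF`:
   they can affect transcript stability and are treated as potentially
   functional. The label map is fully configurable; unknown labels abort the
   run by default (`unknown_policy = "error"`), with `skip` and `non_orf`
   available for permissive dialects.
2. **Survival labelling.** Genes with $Z \ge 1.96$ are labelled `oncogene`,
   $Z \le -1.96$ `tumour_suppressor`, otherwise `none` (both boundaries
   inclusive). Unmutated genes labelled `none` are discarded before any
   further evaluation.
3. **Mutation-frequency filtering.** With `md` and `min` the median and
   minimum of per-gene mutation counts over the cohort's mutated genes, a
   gene with count $f$ is retained when
   * `NON_ORF` with a survival effect: $f \ge md + min$;
   * `NON_ORF` without: $f > 3\,md + min$;
   * `ORF` (label irrelevant): $f \ge md - min$;
   * `BOTH` with an effect: $f \ge md - min$;
   * `BOTH` without: $f > 3\,md$;
   * unmutated (`NONE`): rescued only when $|Z| \ge 2.58$.

   The `3 md` rule for `BOTH` genes deliberately omits `+ min`; it is
   implemented as printed above, and both multipliers are configurable
   should a user prefer a symmetric form. The even-$n$ median is the mean of
   the two middle order statistics, so `md` may be non-integer and every
   inequality is evaluated in real arithmetic. `md`/`min` are computed over
   genes with at least one mutation: letting absent genes contribute a zero
   minimum would make every threshold degenerate.
4. **Clustering.** Retained genes fall into `MUT` (mutated only), `PRECOG`
   (survival-linked only) or `MUT_PRECOG` (both); the latter two are the
   **seed** genes, `MUT` genes are **interactors**.
5. **Scoring and ranking.** Each retained gene receives $T$, $M$ and $S$,
   and the seed and interactor lists are ranked by score descending, ties
   broken by $M$ descending, then gene symbol ascending — a total,
   deterministic order. Genes absent from the network keep $S = 0$ and rank
   at the bottom; they are retained as cancer-relevant rather than dropped.

## Design choices that were genuinely open

**The mutated reference set.** "Mutated interactors" can be read against
(a) all genes mutated in the cohort, or (b) only the mutated genes that
survive the relevance filter. The two readings disagree in general; the
package implements both behind `mutated_reference` (`"filtered"`, the
default, or `"raw"`), records the choice in run metadata, and guarantees
pointwise $M_{raw} \ge M_{filtered}$. The denominator $T$ is always the full
network degree, the only reading under which "total number of interactors"
is literal.

**Survival effect in the filter.** The 1.96 level decides whether a gene
has an effect in the `NON_ORF`/`BOTH` rules; the 2.58 level is used only
for rescuing unmutated genes. Duplicate gene symbols in the Meta-Z table
keep the entry with the largest $|Z|$, preserving significance calls in
either direction.

**Outliers.** "Scores significantly above the mean" is instantiated as
$S > \bar S + k \cdot \mathrm{sd}(S)$ with sample standard deviation and
$k = 1.96$ by default; $k$ and the list used (seeds, interactors or both)
are arguments. A zero-variance score distribution yields no outliers, with
a warning.

**Min-max orientation.** Columns (cancers) of the gene x cancer score
matrix are normalised, because cross-cancer comparability is the purpose of
the normalisation; a constant column maps to all zeros. Gene-wise
normalisation would instead emphasise each gene's profile shape and can be
obtained by transposing before normalising.

**Symbols.** Gene symbols are compared case-insensitively by uppercasing at
ingest. No alias or identifier mapping is attempted; symbol synonymy is the
caller's responsibility.

## The synthetic cohort generator

`generate_cohort()` emulates the three inputs with known ground truth:
per-gene mutation counts are geometric (`1 + rgeom(p)`, right-skewed like
real per-gene counts; default $p = 0.3$ over 250 mutated genes of 500),
each event is `ORF` with probability 0.7 and carries a real MAF label, a
sparse set of 50 genes receives significant Meta-Z scores (half beyond
2.58, signs random) while the background is a truncated normal kept inside
$(-1.96, 1.96)$ so that significance ground truth is exact, and the
interactome is Erdős–Rényi with mean degree 3. Each of the 3 planted hubs
is an unmutated gene given $|Z| \ge 2.58$ — making it a clean `PRECOG` seed
whose retention does not depend on the mutation filter — and wired to 25
distinct mutated genes, so its expected score dwarfs the background
($\approx 3 \times$ the retained-mutated fraction). One seed drives
deterministic per-file sub-streams: identical configurations give
byte-identical files. Symbols are synthetic (`G000001`, ...) so overlap
tests cannot collide with real gene lists.

What the generator does **not** emulate: mutational signatures, per-sample
genotypes (counts are event counts, not patient fractions — the input
format carries no sample column), degree-correlated mutation rates, and
literature-derived network topology with its ascertainment bias toward
well-studied proteins. Passing the planted-hub benchmark therefore shows
the pipeline's plumbing and ranking are correct, not that real cohorts
will yield biologically meaningful hubs.

## Verification

The test suite checks the filter against an independently coded brute-force
rule evaluator on 500 random toy cohorts (≤ 50 genes, geometric counts,
normal Z-scores), the score against adjacency-matrix algebra on 50 random
graphs (≤ 100 nodes), the location classes against exhaustive enumeration,
each inequality at its boundary, determinism (byte-identical outputs under
identical seeds; invariance of every score, class, cluster and rank to
input row order and to swapping the interactor columns), the cross-cancer
set analytics against naive set arithmetic on 100 random fixtures, and
planted-hub recovery: over 100 default cohorts the mean fraction of the 3
planted hubs ranked in the seed top-6 is expected ≥ 0.95 (observed 1.00 in
development runs). A 10 000-gene cohort with independently drawn Z-scores,
counts and wiring keeps all pairwise correlations among mutation count,
Meta-Z and network score within ±0.05 of zero, confirming the three
quantities carry non-redundant information. These problem sizes keep the
whole suite under a minute while leaving the statistical margins wide.

## Limitations

Scores are counts, not probabilities: no significance is attached to an
individual gene's score, and comparisons across cancers require the
normalised matrix. Evidence quality in the interaction network is ignored
(one supporting line equals fifty); a `row_filter` hook on the TAB3 reader
allows, for example, restricting to physical evidence. The md/min filter
is a pragmatic range-based rule, not a calibrated statistical test; its
multipliers are exposed for sensitivity analysis.
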