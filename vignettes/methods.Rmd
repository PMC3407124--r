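---
title: "Composition-vector distances for multi-locus barcodes: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composition-vector distances for multi-locus barcodes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvbarcode)
```

## The model

`cvbarcode` treats a DNA sequence as a bag of overlapping K-strings. With
`L - K + 1` sliding windows, the observed frequency of each K-string is its
count divided by `L - K + 1`, and the sequence becomes a point on the unit
sphere of a 4^K-dimensional space (after normalization). Two sequences are
compared by the cosine of the angle between their frequency vectors — the
projection correlation `C` — and distance `D = (1 - C)/2`, which is 0 for
identical composition and 0.5 for sequences sharing no K-string. The method
needs no alignment, so indel-rich non-coding loci (the *trnH-psbA* spacer is
the motivating case) cost nothing extra.

The assumptions are the usual k-mer ones: composition at word length K is a
sufficient summary, i.e. K is large enough that shared K-strings indicate
homology rather than chance (for random sequences of length ~10^3, K >= 6
makes chance sharing rare) and small enough that related sequences still
share many strings. Both failure modes are visible in the best-K scan below.

### Combining loci

Each locus g yields its own distance matrix, possibly at its own K_g. For a
specimen pair (i, j) the per-locus distances are merged as a convex
combination with weights proportional to the pair's summed sequence length
at each locus:

$$w_g(i,j) = \frac{L_g^i + L_g^j}{\sum_h \left(L_h^i + L_h^j\right)},
\qquad D(i,j) = \sum_g w_g(i,j)\, D_g^{K_g}(i,j).$$

The weights are pairwise (a specimen with a short, partial *matK* read
down-weights *matK* only for its own pairs), sum to one, and do not involve
K — which is what makes mixing per-locus K values legitimate. **Caveat:**
the published description of this weighting is prose; the algebraic form
above is our reconstruction, the natural reading consistent with every
property stated for it (length-ratio based, per pair, normalized,
K-independent). It is isolated in `pair_weights()` so an alternative form is
a one-line change.

### Tree and evaluation

The combined matrix feeds canonical Saitou–Nei neighbor joining
(`neighbor_joining()`), a deliberate in-package implementation: the
agglomeration order is specified (smallest `(row, column)` pair on exactly
tied Q values) so runs are bit-reproducible, which stock implementations do
not document. It is the textbook O(n^3) algorithm — a 2,000-taxon matrix is
minutes of work, so no heuristics are warranted.

Grouping effectiveness is computed on the *unrooted* tree: a group "clusters"
iff one edge separates exactly that leaf set from everything else. Because NJ
output is unrooted and no rooting procedure is part of the method, formalizing
"grouped together" as an exact bipartition (a clade under some rooting) is the
only reading that does not invent a root; both metrics are consequently
invariant to rerooting, which the tests assert.

Two percentages are reported. Sequence level: a leaf is eligible (counted in
N1) if its genus has >= 2 species in the dataset or its species has >= 2
sequences; it succeeds if every applicable condition holds — genus leafset a
cluster when the genus condition applies, species leafset a cluster when the
species condition applies. Species level: among species with >= 2 sequences
(N2), the fraction whose leafset is a cluster. The sentence defining the
sequence-level rule conjoins the genus and species requirements but is
genuinely ambiguous between "both must hold" and "either suffices"; we default
to the strict AND reading and expose `semantics = "or"` for the lenient one.
Singletons are excluded from N1 yet stay in the tree, where a misplaced
singleton can still break other groups — the mechanism that depresses scores
on datasets dominated by single-taxon sequences.

## Parameters that matter

* **K (per locus), default presets matK = 14, rbcL = 14, trnH-psbA = 8.**
  Dimensionless word length. The presets are the best-K values reported for
  these regions and appear stable across datasets of the same marker; they
  are advisory defaults, not claims about new data. For other loci run
  `best_k_scan()` (default range 6–20, scored by the sequence-level metric,
  ties to the smallest K since shorter strings are cheaper).
* **mode, default `"raw"`.** Raw frequency cosine. The classic CV
  normalization — subtracting the (K−2)-order Markov expectation
  `p0 = p(prefix) p(suffix) / p(overlap)` and scoring `(p − p0)/p0` — is
  available as `"background"`. The method description this package follows
  states the plain frequency/projection form, so raw is the default; which
  variant produced any given published number is not always decidable, and
  the two can differ. Background mode requires K >= 3 and can produce a
  zero vector on degenerate input (a homopolymer), which is reported as an
  error rather than a silent fallback.
* **strict mode, default ON.** The weighted combination assumes every locus
  present for both members of a pair. The non-strict extension (weight 0 for
  a missing locus, remaining weights renormalized) exists behind
  `renormalize_missing = TRUE` but is an extension, not part of the method.
* **semantics, default `"and"`** — see above.
* **clamp_negative, default OFF.** NJ limb lengths can be negative;
  they are kept as produced (as PHYLIP's neighbor reports them), with a
  PHYLIP-compatible clamp-and-shift option.

## Numerical and representation choices

* K-strings are 2-bit packed into doubles (exact to K = 26); numeric key
  order equals lexicographic order, so sorted-key merges are canonical and
  `C(a,b)` is bit-identical to `C(b,a)`. Computed cosines are clamped to
  `[-1, 1]` before forming `D`.
* Vectors are sparse throughout: a sequence contributes at most `L - K + 1`
  keys, against 4^14 ≈ 2.7 × 10^8 possible — a dense vector is never
  allocated. A whole locus is assembled into one row-normalized sparse
  matrix and the full correlation matrix falls out of a single sparse
  cross-product.
* Windows containing a non-ACGT symbol (N, IUPAC codes, gaps) are skipped,
  while the denominator stays `L - K + 1`; frequencies then sum to < 1. This
  keeps `p` a simple function of the stated denominator and is documented so
  results are reproducible. No reverse-complement canonicalization is done:
  barcoding amplicons arrive in fixed orientation.
* In background mode the support `{p > 0 or p0 > 0}` is enumerated sparsely
  (every candidate is an observed (K−1)-mer extended by one base whose
  suffix (K−1)-mer is also observed), so entries forced to −1 by the formula
  are retained without dense allocation.
* Floating comparisons in the test suite use absolute 1e-9 unless a tighter
  oracle bound (1e-12 against dense recomputation) is the point of the test.

## The synthetic-data generator

Real multi-locus barcode compilations are large external downloads, so all
testing runs on `simulate_dataset()`: per locus, a uniform random root
sequence begets genus ancestors, species ancestors and individuals by
independent per-site substitution (uniform over the three alternatives — a
Jukes–Cantor-style process without rate heterogeneity), plus short indels
(1–5 bp, geometric run lengths) on loci configured with `indel_rate > 0`.
The *easy* preset — 5 genera × 3 species × 3 individuals; loci of 800, 550
and 450 bp with indels only on the third; divergences 0.10 / 0.02 / 0.002
per site at the genus / species / individual level — mimics the separation
of a clean plastid barcode set: roughly 10% between genera, 2% between
congeneric species, and near-identical conspecific individuals. The
*degraded* preset sets species divergence equal to individual divergence,
removing most species-level signal.

What the generator does **not** emulate: incomplete lineage sorting and
coalescent variance, rate variation among sites and lineages, hybridization
or misidentified vouchers, base-composition bias, and missing loci. Passing
the end-to-end checks therefore shows the machinery is correct and the
method behaves as designed on separable data — not that any particular real
compilation will reach the same percentages; real datasets dominated by
singleton sequences in particular score much lower for the structural
reason above.

## Problem sizes used by the checks

The packaged checks run the dense-oracle comparison at 200 pairs for each
K in 2–6, the distance-law sweep at 1,000 random pairs, NJ consistency on
50 random additive trees of 8–32 taxa, exhaustive bipartition enumeration
on 12-leaf trees plus 100 random tree/taxonomy instances, the two presets
over 20 seeds each, and one 500-taxon × 2-locus analysis at K = 14 — sizes
chosen to exercise every code path at full strength while keeping a complete
run in the order of a minute or two.

## Known limitations

* The weight formula is a documented reconstruction (see above).
* Distances are compositional, not evolutionary: `D` is not additive on a
  tree, so NJ branch lengths are descriptive, and no substitution-model
  correction is applied. Loci with very different substitution rates are
  weighted by length only; rate-aware weighting is explicitly out of scope.
* Best-K selection by exhaustive scan is the slow step of the whole method
  (it rebuilds a tree per K); the shipped presets exist precisely so routine
  analyses can skip it.
* Bootstrap support and tree rooting are out of scope; the grouping metrics
  are designed to need neither.
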