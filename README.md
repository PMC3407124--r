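# cvbarcode

Alignment-free analysis of **multi-locus plant DNA barcoding** datasets with
the composition vector (CV) method.

Plant barcoding uses several plastid markers at once — typically the coding
genes *matK* and *rbcL* plus the *trnH-psbA* intergenic spacer — because no
single locus separates all species. Combining loci is awkward for
alignment-based pipelines: the spacer is indel-rich and aligns poorly, and
sequence lengths vary between markers and specimens. `cvbarcode` sidesteps
alignment entirely: each sequence is summarised by the frequencies of its
length-K substrings, loci are compared in that vector space, and per-locus
distances are merged with weights that reflect how much sequence each locus
contributes for each pair of specimens. The package is aimed at barcoding
studies that need fast, reproducible distance trees and an objective score of
how well those trees group sequences by genus and species.

## Method

For a sequence of length *L* and a fixed string length *K*, the observed
frequency of each K-string α₁α₂…α_K is

    p(α₁α₂…α_K) = n(α₁α₂…α_K) / (L − K + 1),

where *n* counts occurrences among the L − K + 1 sliding windows. The
frequencies form a composition vector of dimension 4^K (stored sparsely).
For two sequences *A*, *B* the correlation C(A,B) is the projection (cosine)
of one vector on the other, and the CV distance is

    D = (1 − C) / 2.

For loci g = 1…m with per-specimen lengths L_g^i, the pairwise weight of
locus g for specimens *i*, *j* is

    w_g(i,j) = (L_g^i + L_g^j) / Σ_h (L_h^i + L_h^j),

which sums to 1 over loci and is independent of K, so per-locus matrices
computed at different K combine as

    D(i,j) = Σ_g w_g(i,j) · D_g^{K_g}(i,j).

A neighbor-joining (Saitou–Nei) tree is built from the combined matrix, and
grouping effectiveness is scored on the unrooted tree: the percentage of
eligible sequences whose genus and species form exclusive clusters
(denominator N1 = sequences from genera with multiple species or species
with multiple individuals), and the percentage of multi-sequence species
forming exclusive clusters (denominator N2). The best K per locus is chosen
by scanning K = 6…20 and keeping the K with the highest sequence-level
score; presets matK = 14, rbcL = 14, trnH-psbA = 8 are shipped as advisory
defaults.

## Worked example

```r
library(cvbarcode)

ds <- simulate_dataset(sim_preset("easy", seed = 42))
ds
#> Multi-locus dataset: 45 specimens, 15 species, 5 genera
#>   matK: 45 sequences, lengths 814-814
#>   rbcL: 45 sequences, lengths 546-546
#>   trnH-psbA: 45 sequences, lengths 442-455

fit <- cv_barcode(ds, K = c(matK = 14, rbcL = 14, `trnH-psbA` = 8))
summary(fit)
#> Multi-locus CV/NJ analysis
#>   loci: matK (K = 14), rbcL (K = 14), trnH-psbA (K = 8)
#>   taxa: 45; mode: raw
#> Grouping effectiveness
#>   sequences grouped to genus/species: 100.0%  (N1 = 45)
#>   multi-sequence species grouped:     100.0%  (N2 = 15)
#>   combined distances: min 0.0149, median 0.4653, max 0.4851
```

All 45 sequences are eligible (every genus has several species and every
species several individuals), and on this well-separated synthetic dataset
every genus and species is recovered as an exclusive cluster, so both
percentages are 100%. The fitted object carries the per-locus and combined
distance matrices (`fit$per_locus`, `fit$combined`), the NJ tree
(`fit$tree`, an `ape::phylo`; `plot(fit)` draws it) and the per-group detail
(`fit$report$details`).

Scanning for the best K of one locus:

```r
best_k_scan(ds, "trnH-psbA", k_range = c(6, 10))$best_K
#> [1] 6
```

(every K in the range scores 100% here, and ties resolve to the smallest K).

A command-line interface with subcommands `simulate`, `distance`, `tree`,
`evaluate`, `kscan` and `all` is installed under `inst/cli/`:

```sh
Rscript inst/cli/cv_barcode.R simulate --preset easy --seed 5 --out sim/
Rscript inst/cli/cv_barcode.R all \
  --locus matK=sim/matK.fasta --locus rbcL=sim/rbcL.fasta \
  --locus trnH-psbA=sim/trnH-psbA.fasta \
  --K matK=14,rbcL=14,trnH-psbA=8 --phylip-relaxed --out run/
```

which writes per-locus and combined PHYLIP matrices, the Newick tree, a
grouping report (TSV + JSON) and a `run_manifest.json` for provenance.

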