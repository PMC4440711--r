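---
title: "PWM-based prediction of MMP cleavage sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PWM-based prediction of MMP cleavage sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleavescan)
```

## The problem

Matrix metalloproteinases (MMPs) are extracellular zinc proteases with broad,
overlapping substrate specificities. The residues immediately surrounding the
scissile bond — in Schechter–Berger notation the P3, P2, P1 positions on the
N-terminal side and P1′, P2′ on the C-terminal side — dominate recognition by
the enzyme's active-site cleft. High-throughput phage display can select
hundreds of cleaved peptides per enzyme: each selected phage presents a
construct with constant flanks around a variable hexamer
(`ggsgXXXXXXtasgaet`), and the cleavage position within it is known. From
such a set, `cleavescan` derives a position weight matrix (PWM) and uses it
to score every peptide bond of a query protein.

## The scoring model

Substrates are aligned on their scissile bond and, for each of the five
subsites $j \in \{P3, P2, P1, P1', P2'\}$, the relative frequency
$P(a, j)$ of each residue $a$ is tabulated over all substrates that have a
complete P3–P2′ window. These are normalised by the residue frequencies
$P_{bg}(a)$ of a large set of *background* peptides drawn from the same
library without selection. The matrix entry is the log-likelihood ratio

$$M(a, j) = \log_2 \frac{P(a, j)}{P_{bg}(a)},$$

and a bond's score is the sum of the five entries picked out by its window.
Working in log space turns the product of independent per-subsite ratios
into a sum; a test verifies that $2^{\text{score}}$ equals the product of
the raw ratios whenever no substituted cell is involved.

Two enzyme-specific scalars complete the model:

* **offset** — when a residue was *never* observed at a subsite,
  $P(a, j) = 0$ and the logarithm diverges; the offset (a negative constant,
  e.g. −5) is substituted instead, acting as a finite penalty for
  never-seen residues. No pseudocounts are applied anywhere: the offset is
  the only zero-handling mechanism, so an unobserved residue costs exactly
  the same wherever it occurs.
* **threshold** — a bond is predicted cleaved when its score is at least the
  threshold. The inclusive boundary makes the threshold the minimal score a
  reported site can carry; exact ties are measure-zero for estimated
  frequencies.

The window is fixed at the five P3–P2′ subsites. Widening it adds
parameters without improving cross-validated metrics for MMPs, whose
specificity is concentrated in these positions.

### Background frequencies

Background peptides carry no cleavage alignment, so a per-subsite background
frequency is not directly observable. The default (`background_mode =
"pooled"`) uses the overall residue composition of the background set,
broadcast to all five columns — the only alignment-free reading. A
`"positional"` switch instead pools per-column counts over every complete
5-residue window of each background peptide; in practice the two differ
little because windows tile the same sequences, and all shipped defaults use
the pooled form.

## Model selection

`offset` and `threshold` are chosen by maximising the F1 score (the harmonic
mean of precision and sensitivity) on a two-dimensional grid under k-fold
cross-validation:

1. Substrates are partitioned into `k_folds = 10` folds at the substrate
   level, so a peptide's positive bond and its negative bonds always stay
   together.
2. For each fold, frequencies are re-estimated on the training substrates
   only. The held-out substrates contribute one positive (the annotated
   bond) and, as negatives, every other scorable bond of the same peptide —
   constant flanks included, since they are physically present in the phage
   construct and a scanner would encounter them.
3. For every `(offset, threshold)` grid cell the fold's confusion counts are
   computed and F1 averaged across folds; the optimum is the cell with
   maximal mean F1. Ties prefer the higher threshold and then the larger
   (less negative) offset — the more conservative model.

The default grid spans thresholds −2…3 in steps of 0.1 and offsets −8…−1 in
steps of 0.5, wide enough to bracket the optima of all trained MMP models.
A per-fold score for a bond decomposes as
(sum of observed-cell entries) + offset × (number of unobserved cells), so
the whole grid is evaluated from one pass over the held-out bonds per fold
rather than rebuilding the matrix per cell.

An *internal test* protocol is also provided: the substrate set is first
split 2:1 at random, the grid search runs on the larger part, and the chosen
parameters are evaluated once on the untouched smaller part. The final
production model is then retrained on all substrates.

Undefined metrics (for example precision when nothing is predicted
positive) are reported as 0 and flagged in the `undefined` field of the
`metric_set`, so fold averages are never silently contaminated by `NaN`.
Fold summaries report the mean and the *sample* standard deviation.

## Evaluation machinery

* **Confusion metrics** — sensitivity/TPR, specificity, FPR, precision,
  accuracy, Matthews correlation coefficient and F1, from first-principles
  count formulas (tested against hand-computed tables).
* **ROC / AUC** — a threshold sweep over the distinct observed scores; the
  AUC is computed by the rank (Mann–Whitney) formula with ties counted one
  half, which equals the trapezoid area under the swept curve. A test
  equates it with brute-force pair counting on small samples.
* **KS separation** — the two-sample Kolmogorov–Smirnov D statistic (maximal
  ECDF gap) between positive- and negative-bond score distributions,
  cross-checked against `stats::ks.test`.
* **Protein-level sampling** — for whole-protein benchmarks the annotated
  sites are the positives and negatives are sampled without replacement
  from the remaining scorable bonds at a fixed ratio (default 1:100),
  reflecting the extreme class imbalance of real proteolysis.
* **Cleavage-position refinement** — experimentally reported positions can
  be off by a few bonds (mass-spectrometry assignment ambiguity). A
  reported bond scoring below threshold is reassigned to the
  highest-scoring above-threshold bond within ±4 bonds (ties to the smaller
  shift); above-threshold reports are never moved. Refinement can only
  raise a moved site's score and never moves a site farther than the shift
  window — both are asserted as invariants.

## Virtual mass spectrometry

Predicted sites define fragment boundaries: the two protein termini plus
every above-threshold bond. Each fragment's intensity is

$$\text{Intensity} = 100 \cdot w_{s1} \cdot w_{s2},$$

where $w_{s1}, w_{s2}$ are the cleavage-efficiency weights of its N- and
C-side boundaries: the site's score rescaled linearly onto $[0, 1]$ between
the matrix's minimal and maximal achievable window scores (the sums of
per-column minima and maxima), and fixed at 1.0 for the protein termini —
so the intact full-length species always has intensity 100.

Two digestion models are offered. The default, `"partial"`, enumerates every
contiguous fragment between any ordered pair of boundaries — $\binom{n+2}{2}
= (n+1)(n+2)/2$ fragments for $n$ sites — because per-fragment boundary
weights are well-defined for any pair and a partial digest is what an
incomplete reaction produces. `"complete"` restricts to adjacent pairs
($n+1$ fragments that tile the protein; their residue masses sum to the
protein's). Masses are neutral monoisotopic values: the standard 20-residue
monoisotopic mass table (six decimal places) plus one water, 18.010565 Da.
No charge states, adducts, modifications or isotope envelopes are modelled.

## The synthetic library generator

`motif_spec()` / `generate_substrates()` / `generate_background()` emulate
the phage construct: constant flanks `ggsg` and `tasgaet` around a variable
hexamer, with the scissile bond after hexamer position 3 (as in
`PSA-LDA`) and the P3–P2′ residues of that bond drawn column-wise from a
planted probability motif; all other variable residues are uniform by
default (an empirical composition vector can be supplied). Defaults are 300
substrates and 766 background peptides per enzyme — the scale of one
enzyme's real phage-display training data.

What the generator does *not* emulate: selection-round enrichment dynamics,
cleavage kinetics ($k_{cat}/K_M$ weighting of selected clones), sequencing
errors, and correlations between subsites. Passing tests on synthetic data
therefore demonstrate correct parameter recovery and model-selection
machinery, not predictive performance on real proteomes.

Two end-to-end controls bracket the method:

* a **deterministic planted motif** must be recovered exactly (the matrix
  argmax at each subsite equals the plant) and reach mean cross-validated
  F1 ≥ 0.95;
* a **null library**, whose motif columns equal the expected composition of
  the whole scaffold (`scaffold_composition()`), gives a foreground window
  distribution identical to the background, and cross-validated F1 must
  collapse to the no-information regime — about $2p/(1+p)$ for prevalence
  $p$ (one positive among the 13 scorable bonds of a 17-mer, $p = 1/13$).
  Note that planting a *uniform* motif instead is not a null: the constant
  flanks make the background peptides G/S/T/A-rich, so a uniform variable
  window is genuinely discriminable from flank-derived windows.

## Numerical and interface choices

* Scores accumulate in double precision; PWM files round-trip to 1e−6.
* Sequences are uppercased on read; nonstandard residues (X, B, Z, U, …)
  are kept in the sequence but any scoring window touching them is skipped
  with a warning — the matrix has no values for them, and silently scoring
  0 would masquerade as evidence.
* The cleavage annotation is carried as an integer (residues before the
  bond); the reported P1 position is the 1-based index of the P1 residue,
  which equals that integer.
* All randomised steps (splits, folds, negative sampling, generators) are
  driven by one integer seed via derived streams, restored-state local RNG,
  and recorded in output headers together with input checksums.
* TSV outputs print scores at 4 decimals, masses at 6, rates at 3.
* A degenerate matrix with equal minimal and maximal achievable scores
  (possible only if foreground equals background exactly) is rejected at
  construction rather than producing 0/0 weights downstream.

Examples and tests run the grid search at 60–300 substrates against 200–766
background peptides with the full default grid; one such search completes in
well under a second, and the whole simulated train/evaluate/digest workflow
in a few seconds.

## Known limitations

* Primary-sequence specificity only: no secondary structure, disorder,
  solvent accessibility, transmembrane or signal-peptide context — in vivo
  cleavage requires site accessibility that a PWM cannot see, so
  over-prediction on folded proteins is expected.
* Subsites are treated as independent (a PWM cannot represent subsite
  coupling).
* The background composition switch accepts an empirical vector, but the
  shipped defaults assume the uniform variable-region model.
* Virtual spectra are theoretical digests, not comparable to measured
  spectra without charge, modification and instrument models.
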