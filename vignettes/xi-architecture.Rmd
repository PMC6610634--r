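---
title: "Methods: Xi architecture and allelic expression in xifold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Xi architecture and allelic expression in xifold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `xifold`. It is the package's reference for *why* each
analysis is implemented the way it is; the README shows how to run it.

## Coordinate and data conventions

All coordinates are 0-based half-open (BED convention), including bedGraph
intervals and the sparse `bin1 bin2 count` matrix dialect (0-based bin
indices, upper-triangular or full; symmetrized on read, each unordered pair
counted once). Contact matrices carry their binning, an allele tag
(`mus` = Xi, `cas` = Xa, `comp`), a per-bin unmappability mask and a
`balanced` flag. Readers are strict: malformed lines, overlapping bedGraph
intervals, out-of-range bin indices and negative counts are fatal, with the
offending line reported — silent coercion is the failure mode these formats
usually suffer, so the parsers are part of the package's contract and are
pinned by round-trip tests at full floating-point precision.

## Matrix preprocessing

**Masking.** Unmappable bins are defined operationally as the bins with the
lowest raw marginals. `mask_low_coverage(m, quantile = 0.14)` masks exactly
`ceiling(quantile * n_bins)` bins (ties broken toward the lower index, so
the rule is deterministic), plus any all-zero bin. The default 0.14 mirrors
the usual "bottom ~14% of coverage" rule for the mouse X at 100–200-kb
bins; it is a tunable fraction, not a fitted value. Masking is idempotent
and only sets flags — values are never destroyed.

**Depth matching.** `downsample()` draws contacts without replacement
(jointly multivariate hypergeometric across cells, implemented by sampling
contact indices), so the target total is hit exactly and per-cell
expectations stay proportional to the input. Comparisons of Pearson-map
intensity or megadomain fractions between samples should be run at matched
depth; the seed is recorded in the output metadata.

**Iterative correction.** `ice_balance()` is the classic bias iteration:
biases multiply until the coefficient of variation of the unmasked
marginals drops below `tol` (default 1e-6, default cap 200 iterations), and
the result is rescaled so the mean unmasked entry is unchanged — keeping
balanced matrices on the scale of the raw counts, which matters for
comparing across samples. Non-convergence warns and flags the result
rather than failing: heavily zero-inflated matrices may stall, and the
caller should see that. A fully masked matrix is an error.

**Observed/expected and Pearson maps.** Expected counts are per-diagonal
means over unmasked pairs; diagonals with zero expectation give `NA`.
The correlation map entry (i, j) is the Pearson correlation of O/E rows i
and j over unmasked columns, *excluding columns i and j*: the self-contact
and the i–j contact would otherwise leak the quantity being tested into
the correlation. Computation uses BLAS-level sufficient statistics with
per-pair corrections after row-centering (Pearson is shift-invariant, and
centering removes the catastrophic cancellation that raw-moment formulas
suffer); a brute-force loop implementation pins the result to 1e-10 in the
tests. Pairs with fewer than 3 complete columns or zero variance are `NA`.
Pearson maps are computed on O/E rather than balanced-raw matrices —
removing distance decay first is what makes the checkerboard, not the
decay, dominate the leading eigenvectors; a caller who wants the raw
variant can pass the balanced matrix directly.

## Compartments

PC1/PC2 are eigenvectors of the correlation map restricted to unmasked
bins (residual `NA` entries, rare and long-range, enter as 0). Explained
variance is the eigenvalue over the sum of positive eigenvalues. Signs are
fixed against a user-supplied reference track (Xist or H3K27me3 density for
the Xi, H3K4me3 or gene density for the Xa) so that positive values mark
the S1/A-like compartment; orientation with |r| < 0.05 warns, because a
sign fixed against an uncorrelated reference is arbitrary. Which PC
carries which structure (S1/S2 vs megadomains) is deliberately *not*
automated — it genuinely varies between samples — so both PCs are returned
with their reference correlations and `select_pc()` picks the stronger
match when automation is wanted.

Segments are maximal sign runs over unmasked bins at the calling
resolution (100 kb). Interior masked gaps are bridged when the flanking
signs agree and split at the gap midpoint when they disagree; runs shorter
than `min_run_bins = 3` are merged into the longer neighbour, shortest
first. The minimum run exists so single-bin noise flips do not inflate the
compartment count; 3 bins (300 kb) is far below any real compartment and
above one-bin noise. By construction, segment count × mean size equals the
covered span exactly.

The compartment-less test (`pc1_variance_null()`) shuffles raw counts
within each diagonal — preserving the decay profile and the count
distribution while destroying positional coherence — and re-runs the
*entire* pipeline (ICE, O/E, Pearson, eigen) per permutation. Re-running
the pipeline inside the null matters: balancing a noisy matrix alone
inflates PC1 explained variance slightly (the fitted biases act as shared
row/column factors), and a null computed without re-balancing would
mistake that artifact for structure.

## Insulation and boundaries

The raw insulation score at bin *i* is the mean unmasked contact in the
square `[i−w, i) × (i, i+w]` with `w` = 500 kb; bins within `w` of the
ends, masked bins, and bins whose window is more than half masked are
`NA`, as are windows whose mean is not positive (log-normalization needs
positivity). Normalized scores are `log2(raw / iqrMean)` where `iqrMean`
is the mean of raw scores lying within the chromosome's interquartile
range — a robust centring that makes scores comparable across chromosomes
and invariant to global scaling (a property the tests assert). The exact
semantics of this normalization and of the delta-vector boundary caller
are pinned by an independent double-loop oracle in the test suite, since
"iqrMean" is a flag name, not a published formula.

Boundaries sit at negative-to-positive zero crossings of the delta vector
(mean normalized score over the next `d` = 400 kb minus the previous `d`);
at a crossing the bin with the lower normalized score is reported, and
strength is the delta swing from the nearest local minimum before to the
nearest local maximum after. The default noise threshold is 0 (keep
everything), matching common practice; downstream comparisons re-filter by
strength. Per-region boundary scores are minima over overlapping bins
(boundaries are insulation minima), compared across sets with Wilcoxon
rank-sum tests. Compartment-border/TAD-boundary overlap uses a matching
window of ±1 bin by default; the window is exposed because published
overlap figures rarely state theirs.

## Megadomains

The inter-megadomain fraction is the contact-weighted share of long-range
interactions (bin distance > 10 Mb, about twice the largest X-linked TAD)
whose endpoints straddle the boundary (default 73 Mb, the mm9 *Dxz4*
position). Crossing is defined on bin starts: the bin containing the
boundary belongs to the proximal domain, the first bin starting at or
beyond it to the distal domain — one of several defensible conventions, so
it is documented and configurable. A pair-counted mode (`weighted =
FALSE`) is provided because "fraction of interactions" can be read either
way. Replicate-level comparisons use a one-sided unpaired Welch t test
with per-group mean ± s.d. reported; with two replicates per group this
test is honest but weak, which is inherent to the design, not the
implementation.

## Coverage tracks

Tracks are piecewise-constant signals with an exact prefix-integral
backbone, so window smoothing (1-kb windows every 500 bp by default),
region densities (length-weighted means, hence resolution-independent),
binning, and delta tracks are all closed-form and linear. Scaling to a
reference equalizes total signal mass over a region — the
chromosome-sum-equalized scaling used before differencing Xist coverage
between genotypes, justified when overall RNA abundance is known to be
equal and only the distribution changes. Input subtraction is a smoothed
IP-minus-input at matched normalization: a documented, simple windowed
equivalent of peak-caller-internal subtraction, isolated behind one
function. S1-vs-S2 density tests partition 200-kb bins by compartment sign
and use one-sided rank-sum tests with box-plot summaries (median,
quartiles, 1.5·IQR whiskers). Summit metaprofiles sample ±10 kb around
point summits at 100-bp steps, dropping and counting summits too close to
a chromosome end.

## The allelic-expression cascade

`%mus = 100·mus/(mus+cas)`, `NA` when no allele-specific reads exist. The
cascade order is fixed and each exclusion records the first filter failed:

1. **active** — FPKM > 0 in every sample;
2. **assessable** — mus+cas ≥ 13 in every sample ("at least 13" read as
   inclusive on the per-sample allele-specific total; a per-allele minimum
   is the other possible reading and would only tighten the set);
3. **miscalled SNPs** — %mus strictly greater than 9.09% (i.e. > 1 mus in
   11 informative reads) in any pure-cas control sample; skipped with a
   warning when no control table is given — in that case genes with
   spurious mus signal will surface as false escapees, which the tests
   demonstrate deliberately;
4. **escapee** — within-clone Xi/Xa expression ratio mus/cas strictly
   greater than 0.1 in at least one baseline (WT) clone. The ratio is
   computed from the same allele-specific counts as %mus;
5. **subject to XCI** — the remainder.

Reactivation requires both a mean %mus ratio of ≥3 (test condition over
baseline; a baseline of exactly 0 passes the fold criterion whenever the
test mean is positive, since the release from zero is the event of
interest) and a one-sided Welch t p < 0.1 across clones. "3-fold greater"
is implemented inclusively (≥3×); the strict reading differs only on a
measure-zero boundary and the threshold is a parameter. With two clones
per condition and zero within-group variance the t test degenerates; the
call then rests on the mean difference, which is the correct noiseless
limit. Paired cumulative-distribution comparisons use the Wilcoxon
signed-rank test — the standard paired analogue; a "paired rank-sum" is a
contradiction in terms, but a flag (`naive_paired_ranksum`) forces that
literal behaviour for comparison. Identical paired groups give p = 1
under the zero-difference normal approximation (or NA when no test is
possible).

## The synthetic-data generator

The generator defines the study conditions the package is tested under.

**Contact matrices.** Expected counts for an unmasked pair are
`C · (|i−j|+1)^(−α) · (1 + ε·same_compartment) · (1 − δ·crosses_boundary)`
with Poisson noise, `C` normalizing the expected total to the read depth.
The decay is in *bin* units — the classic `P(s) ~ s^(−1)` scaling at
analysis resolution (α = 1 by default); a base-pair-unit decay would put
essentially all mass on the diagonal at 100-kb bins and no compartment
signal would survive at any realistic depth. Defaults mirror the study
regimes: a 166-Mb chromosome (the mm9 X) at 100-kb bins, 25 planted
compartments (alternating runs with heterogeneous lengths, drawn with
uniform 10–40 relative weights and rescaled to tile the chromosome),
boundary at 73 Mb, 14% unmappable bins (never the two bins flanking the
boundary, so the megadomain statistic stays well-defined), depth 5e6.
Regime presets: `WT_Xi` (ε = 0, δ = 0.2 — compartment-less with partially
obscured megadomains), `SMCHD1_KO` (ε = 0.4, δ = 0.2), `XIST_KO` (ε = 0,
δ = 0.6 — sharpened megadomains only), `Xa` (ε = 0.4, δ = 0). Poisson
(not negative-binomial) pair counts are the standard minimal Hi-C noise
model; everything downstream is robust to modest overdispersion.

**Coverage.** Per-500-bp steps at mean `base·(1 + enrichment_S1)` in S1
bins and `base` elsewhere plus Gaussian noise (clipped at zero), the
synthetic analogue of Xist CHART or repressive-mark ChIP density following
the compartments.

**Allelic counts.** Per sample and gene, a shared Gamma factor with
variance equal to the dispersion (default 0.1) multiplies both allelic
means, and Poisson counts are drawn around `factor × mean`: each allele's
marginal is exactly negative-binomial with that dispersion, but the
allelic *ratio* carries only count-limited noise — as in real
allele-specific RNA-seq, where biological expression variation moves both
alleles together and cancels in %mus. Drawing the two alleles as
independent negative binomials instead pushes the full gene-level
dispersion into %mus and makes the two-clone t test hopeless at any depth;
the shared-factor construction is the realistic choice, not a convenience.
Defaults: 100 genes, Xa means log-normal around 800 allele-assignable
reads (a mid-expressed gene in a ~50M-read library), silenced Xi/Xa ratio
0.01, escapees 10% of genes at ratio ~0.3, miscalled SNPs 5%, planted
reactivated genes 20% of subject genes at 5× release under the combined
perturbation, plus mild global condition effects (1.4× under
demethylation alone, 1.2× under SMCHD1 loss alone, 2× combined for
non-reactivated genes) emulating mild treatment-wide destabilization;
escapees are unaffected by treatment. Setting the condition effects to 1
gives the clean "stable background" scenario used for
sensitivity/specificity measurement.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: ligation artifacts and translocation signals,
copy-number variation, fine TAD structure (blocks enter only through the
insulation tests' planted matrices), distance-dependent overdispersion,
allelic mapping bias beyond the planted miscalled-SNP mechanism, and any
polymer/phase-separation physics. Recovery results on synthetic data
certify the pipeline's correctness, not biological discovery power.

## Problem sizes and determinism

Test and acceptance runs use the full 1660-bin chromosome for compartment
recovery (where the BLAS-level Pearson map keeps a complete
simulate-balance-PCA cycle in seconds) and 100–400-bin chromosomes for
permutation nulls, power sweeps, and the bundled demo pipeline — sizes at
which a hundred full pipeline re-runs remain interactive. Every stochastic
step takes an explicit seed (`withr::with_seed`, never the global RNG
silently), the pipeline derives all stage seeds from one master seed, and
reports are written with fixed JSON formatting, so identical configs give
byte-identical outputs — asserted by the tests.

## Known limitations

* ICE assumes equal visibility is the only bias; fragment-level biases
  (GC, mappability gradients) are not modelled separately.
* The Pearson map's self-column exclusion follows common compartment
  practice but makes each entry's column set slightly different; with
  heavy masking (>50%) the maps become noisy and PCA orientation
  unreliable (warned).
* Insulation semantics ("iqrMean", delta-vector strengths) reproduce a
  flag-level description and are pinned by this package's own oracle; other
  implementations may differ in edge handling near chromosome ends.
* The two-replicate Welch t comparisons (megadomains, reactivation) have
  low power by design of the experiments they mirror; interpret their
  p-values accordingly.
* `cas`/`mus` naming assumes the hybrid-cross convention (Xi of mus
  origin); analyses of the reciprocal cross should swap the labels.
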