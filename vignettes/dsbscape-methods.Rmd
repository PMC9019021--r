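---
title: "Models and conventions of the dsbscape pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions of the dsbscape pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dsbscape` quantifies sequencing signal around sequence-specific DNA
double-strand breaks (DSBs) and implements the site-classification,
qPCR-assay and cancer-cohort statistics that typically accompany such data.
It deliberately starts *after* alignment: its inputs are aligned read
intervals (SAM/BED), cut-site catalogs (BED), Ct tables and donor tables.
Everything upstream (library preparation, alignment, peak calling) and all
imaging-based quantification are out of scope.

This vignette records the models the package implements, the conventions it
fixes where the underlying experimental literature is loose, and the design
decisions that were genuinely open.

# Coverage and windowed counts

**Read-start binning.** A coverage track holds, per contig, one value per
`bin_size` bp (default 100 bp); a read contributes to the bin containing its
leftmost coordinate. The alternative (per-base pileup of full read bodies)
smears counts across bins and breaks the identity that makes the downstream
statistics interpretable: with read-start binning, the windowed sum over any
window is *exactly* a read count, and after CPM normalization
(`value * 1e6 / total_reads`) it is exactly a normalized read count.
Fragment extension is available behind `extend_to` but defaults off.

**Coordinates.** Internally all containers are `GRanges` (1-based, closed —
the Bioconductor convention); BED's 0-based half-open coordinates are
converted by `rtracklayer` on IO and SAM's 1-based by `Rsamtools`. Bin and
window arithmetic is defined on the 0-based bin grid derived from these
(bin *i* covers `[(i-1)*bin, i*bin)`), so the window semantics below are
exact regardless of container convention.

**Window semantics.** "A window of W around a site" always means the full
span `[p − W/2, p + W/2)` centered on the cut coordinate, half-open on the
bin grid; presets that correspond to a "±x kb" phrasing therefore use
`W = 2x`. Windows are clipped at contig edges for sums; in site matrices,
cells extending past a contig are `NA` (missing), and column means exclude
them rather than zero-filling — zero-filling would fabricate edge dips in
average profiles.

**CPM.** Normalization is guarded: a track knows whether it is normalized,
normalizing twice is an error, and a zero-read track cannot be normalized.
Whole-genome CPM tracks sum to 10⁶ by construction. Windowed statistics
default to CPM inputs (matching "normalized read counts"); raw counts work
identically where the caller prefers them.

# Site classification

**Top-N by cleavage.** All aggregate analyses run on the N best-cleaved
sites (default 80) ranked by a cleavage score (point-mapping of break ends,
BLESS-like). Ties are broken by genomic order, never by input order, so
classifications are invariant to permutations of the catalog.

**Enrichment-ratio classes.** To ask which sites recruit a factor *given
equal cleavage*, the classifier scores each site as
`(factor sum in 4 kb + pc) / (cleavage sum in 1 kb + pc)`, sorts
descending, and labels the top and bottom `n_extreme` (default 20) as
high/low. The pseudocount `pc` defaults to 1 CPM unit; the source
convention is silent here, and the pseudocount prevents division by zero at
weakly-cleaved sites while leaving well-covered sites essentially
unchanged. A fully tied score vector is flagged degenerate (labels then
reflect only the tie rule).

**Quantile groups.** Occupancy groups (e.g. four pre-damage RNAPII classes)
are contiguous slices of the descending score order; with N divisible by
the group count all groups are equal (80 → 4 × 20), otherwise sizes differ
by at most one with larger groups first.

**Rank tests.** Group comparisons use the two-sided *unpaired*
Mann–Whitney–Wilcoxon test (`stats::wilcox.test` behind a guarded surface:
exact when `n₁ + n₂ ≤ 12` without ties, else normal approximation with
continuity and tie correction). Unpaired is a deliberate choice: the
compared site classes are distinct genomic subsets with no natural pairing,
even though some descriptions of such designs say "paired". A paired
signed-rank variant is available behind `paired = TRUE` for replicate
designs that do pair. Boxplot summaries use linear-interpolation quartiles
(type 7) and the 1.5 × IQR outlier fences.

**Spread width.** Reported spreading extents ("a factor spreads over ~5–10
kb") are usually read by eye; `spread_width()` fixes an artifact
definition: background = mean of the outermost 10% of bins on each side,
width = length of the contiguous run around the maximum with
`profile − background ≥ fraction × (max − background)` (default fraction
0.5, i.e. a background-corrected FWHM). A flat profile is *undefined* (`NA`
with a reason), never zero.

# qPCR assay calculators

All calculators are parameterized by the per-cycle amplification efficiency
`E` (default 2, the classic `2^−ΔCt` arithmetic) and exactly invert the
package's own Ct simulator at zero noise — a round-trip identity the tests
enforce.

* Percent input: `100 · f · E^(ct_input,adj − ct_IP)`, with the input Ct
  either measured on the diluted aliquot (`adjust_input = FALSE`) or given
  as an undiluted equivalent and adjusted by `log_E f`.
* Resection ssDNA percent: `100 / (E^(ΔCt − 1) + 0.5)` with
  `ΔCt = ct_digested − ct_undigested`. This formula is the standard
  restriction-protection assay arithmetic (a break-distal enzyme site in
  double-stranded DNA is cut and fails to amplify; ssDNA resists
  digestion); it is adopted here as the package's stated convention with
  `E` configurable. Values above 100% (ΔCt < 1) are reported as-is with a
  warning.
* Cleavage / re-cleavage: ΔΔCt against an uncut control locus and a
  calibrator condition, `E^−ΔΔCt`; the repair-fidelity readout is the same
  quantity for a second induction round referenced to the first. The
  biochemical normalization chain of capture-based kinetics assays is
  under-specified in the literature; modeling it as calibrated ΔΔCt is an
  explicit artifact convention.
* Relative quantity: `E^(ct_ref − ct_target)` (origin-normalized synthesis
  signal, translocation junction abundance).
* Replicates: mean and SEM (`sd/√n`, n ≥ 2), with a paired two-sided
  t-test for matched condition vectors — the replicate-level test, distinct
  from the site-level Wilcoxon. Zero-variance differences are flagged
  degenerate rather than producing a spurious p.

# Cancer-cohort tandem-duplication analysis

Per donor, the TD burden is the number of structural variants of
tandem-duplication type with size *strictly* below 100 kb — the signature
previously associated with break-induced replication; the strict bound
matches "shorter than 100 kb". Donors are stratified by the expression of
two genes into four groups (high/low × high/low); "high" means strictly
above the cutoff, ties go to low, and donors missing either gene are
excluded with a logged count. The cutoff rule is configurable
(median/quantile/fixed) with median as default — the underlying cohort
analyses do not state their rule, and their unequal group sizes suggest a
non-median threshold, so the rule is an explicit parameter rather than a
hidden constant.

Group contrasts use unpaired Wilcoxon tests; the interaction question
("does gene A's effect on TD burden depend on gene B?") uses a
negative-binomial GLM, `count ~ A*B` with log link and NB2 variance
`μ + μ²/θ`, fitted by `MASS::glm.nb` (θ by maximum likelihood). The
interaction p-value is a two-sided Wald test by default with a
likelihood-ratio option; non-convergence is reported in a flag, and designs
spanning fewer than three of the four cells are rejected. As θ → ∞ the fit
reduces to Poisson regression, which the tests verify on near-equidispersed
simulations, along with the optimizer sanity check that the fitted
likelihood dominates the planted truth.

# The synthetic forward model

The generator exists so that every downstream operation is exercised and
calibrated offline; its defaults define the package's study conditions and
are not tuned per analysis.

* **Genome**: one 10 Mb contig. This is a desk-scale model: the broad
  damage-marker domain is a 50 kb plateau with a central dip (a stand-in
  for megabase-wide spreading around real breaks), resection-coupled
  factors decay exponentially with a 2 kb length at early induction and
  8 kb at prolonged induction, cleavage signal is a point mass. *Shapes
  and contrasts*, not absolute widths, are the tested properties.
* **Sites**: catalogs of 120 sites with ≥ 50 kb pairwise gaps, placed by
  the order-statistics construction (sorted uniforms on the gap-deflated
  interval), which errors on infeasible packings instead of silently
  truncating. Cleavage grades are linearly spaced then shuffled, so top-N
  selection is always unique; transcription levels are log-normal(0, 1).
* **Reads**: exactly `total_reads` single-end 50 bp reads, allocated
  multinomially between a uniform background and per-site kernels with
  expected weights `amplitude · cleavage · transcription^coupling`;
  symmetric two-sided offsets; positions clipped at contig edges with
  count preserved; strand uniform. The plateau kernel's dip depth (0.25)
  is a model parameter the field phenomenology constrains only
  qualitatively (depleted, not absent, at the cut).
* **Correlated track pairs**: per-site amplitudes from a Gaussian copula
  with log-normal margins (sdlog 0.5); the latent correlation is solved in
  closed form so the amplitude-scale Pearson correlation equals the target,
  making `r = 1` give identical amplitudes and planted `r = 0.8`
  recoverable from windowed sums at n = 80 sites.
* **Ct tables**: `Ct = ct_at_unit − log_E(quantity) + N(0, σ)`.
* **Donor cohorts**: log-normal expression, median-split indicators,
  NB counts with planted `β = (log 5, 0, 0, log 2)` and θ = 2, SV tables
  containing exactly the planted small TDs plus decoy SVs (other types and
  TDs ≥ 100 kb) that a correct filter must ignore.

What the generator does **not** emulate: sequence content and alignment
error, mappability and copy-number structure, fragment-length and GC
biases, replicate-to-replicate batch effects, and any dependence between
sites beyond the planted amplitude structure. Passing recovery tests on
this model therefore demonstrates correctness of the estimators and the
pipeline's statistical calibration under its stated assumptions — not
robustness to real-data artifacts.

# Problem sizes and determinism

The recovery analyses run at 80 sites and 10⁵–2×10⁵ reads per track, where
the decay-length estimator (log-linear fit to the 0.4–6 kb profile flank)
lands within a few percent of the planted 2 kb; NB interaction recovery
uses 2000 donors and the type-I calibration 500 null cohorts of 1000
donors, sizes at which the Wald test is comfortably asymptotic. These sizes
are the package's chosen study conditions and are stated in the acceptance
script.

Every stochastic function takes an explicit integer seed and is a pure
function of (parameters, seed) via `withr::with_seed`; recipes write a
`manifest.json` (recipe, seed, parameters, version, output md5s) and replay
byte-identically — the reproducibility contract the tests enforce with file
hashes.

# Known limitations

* Ratio classification and quantile grouping assume the windowed sums are
  comparable across sites; copy-number variation or mappability holes in
  real data would need external correction.
* `spread_width` is sensitive to the window chosen relative to the signal
  extent (the flanks must reach background); the recipes size windows at
  roughly 7–8 decay lengths.
* The NB regression fits no covariates (purity, total mutation burden);
  the module surface accepts only the two indicators by design.
* bedGraph IO requires grid-aligned intervals — it is a binned-track
  interchange, not a general interval reader.
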