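# dsbscape

Break-anchored quantification and classification of sequencing signal for
studies of DNA double-strand break (DSB) repair in chromatin.

In nuclease-based DSB systems (e.g. an AsiSI–ER fusion driven into the
nucleus by tamoxifen), breaks are induced at annotated genomic positions, so
every sequencing readout — ChIP-seq of repair factors (BLM, RAD51, γH2AX,
RNAPII), BLESS cleavage mapping, DRIP-seq of RNA:DNA hybrids, EdU-seq of
repair synthesis — can be quantified *around known cut sites*. `dsbscape`
implements that analysis layer end to end:

* **Signal IO** — aligned single-end reads (SAM/BED) → deduplication →
  binned coverage by read starts → CPM normalization
  (`value × 10⁶ / total reads`) → bedGraph round trip.
* **Break-anchored quantification** — windowed read counts
  `Σ bins in [p − w/2, p + w/2)`, site × offset matrices for heatmaps
  (cleavage-ordered), average profiles, Pearson correlation of per-site
  signals, and fractional-maximum spread widths.
* **Site classification** — top-N selection by cleavage, the
  factor/cleavage enrichment-ratio classes ("high"/"low" recruitment after
  correcting for unequal nuclease activity), quantile occupancy groups, and
  two-sided Wilcoxon rank-sum comparisons with 1.5 × IQR boxplot summaries.
* **qPCR assay calculators** — ChIP percent input
  (`100·f·E^(ctᵢₙ,adj − ct_IP)`), resection ssDNA percent
  (`100 / (E^(ΔCt−1) + 0.5)`), ΔΔCt cleavage/re-cleavage fractions,
  ΔCt relative quantities, replicate mean ± SEM with paired t-tests.
* **Cancer-cohort SV analysis** — per-donor tandem-duplication counts under
  a strict < 100 kb size filter, two-gene expression stratification into
  four groups, pairwise Wilcoxon tests, and negative-binomial regression
  `count ~ NB(exp(β₀ + β₁A + β₂B + β₃AB), θ)` whose interaction term β₃
  tests whether one gene's effect on the TD burden depends on the other.
* **Synthetic data** — a forward model of every input (kernel-shaped read
  pileups around cut sites over uniform background, correlated track pairs,
  Ct tables, donor expression/SV tables with a planted interaction), so the
  whole pipeline runs and is tested with no external data.

## Worked example

Simulate a catalog of cut sites, a transcription-coupled repair-factor
track, and ask whether sites with high pre-damage transcription recruit more
factor:

```r
library(dsbscape)
genome <- genome_spec(c(sim1 = 1e7))
sites  <- make_sites(genome, n_sites = 120, min_gap = 50000, seed = 1)
top80  <- top_n_by_cleavage(sites, 80)

reads <- simulate_reads(top80, kernel_resection_early(),
                        total_reads = 2e5, seed = 2)
cov <- cpm_normalize(coverage_track(reads, bin_size = 100))
blm <- window_sum(cov, top80, window = 5000)

grp <- quantile_groups(top80, S4Vectors::mcols(top80)$transcription_score)
cmp <- wilcoxon_ranksum(blm[grp$group == 1], blm[grp$group == 4])
print(cmp)
#> <group_comparison> unpaired rank-sum (normal_approx)
#>   n: 20 vs 20  U: 400  p: 6.7956e-08

prof <- average_profile(site_matrix(cov, top80, window = 20000, bin = 200))
spread_width(prof)
#> [1] 2800
```

The rank-sum test compares the 5 kb CPM read counts of the 20
highest-transcription sites against the 20 lowest: U = 400 (complete
separation of the two groups of 20) and p ≈ 7 × 10⁻⁸ say the
transcription-coupled factor is recruited preferentially to transcribed
sites, as planted. The 2800 bp spread width is the full width at
half-maximum (above flank background) of the average profile of a kernel
with a 2 kb decay length (FWHM of a two-sided exponential ≈ 2 λ ln 2 ≈
2.8 kb).

End-to-end analyses are packaged as recipes
(`run_recipe("rnapii_groups" | "factor_heatmap" | "blm_high_low" |
"drip_edu_correlation" | "cancer_td" | "assay_suite" | "rad51_spreading")`),
each writing its tables plus a `manifest.json` that reproduces the outputs
byte-identically.

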