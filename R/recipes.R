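## per-recipe default parameters; every numeric default is a stated pipeline
## parameter (windows 1/4/5/10/40/100 kb, top N = 80, n_extreme = 20,
## TD < 100 kb) on the desk-scale toy genome
recipe_defaults <- function(name) {
  base <- list(genome = c(sim1 = 1e7), n_sites = 120, min_gap = 50000,
               bin_size = 100, read_len = 50, total_reads = 2e5,
               background_rate = 1e-5, top_n = 80)
  extra <- switch(name,
    rnapii_groups = list(occupancy_window = 10000, factor_window = 5000,
                         n_groups = 4),
    factor_heatmap = list(window = 100000, bin = 1000),
    blm_high_low = list(signal_window = 4000, cleavage_window = 1000,
                        n_extreme = 20, planted_n = 20, planted_fold = 5),
    drip_edu_correlation = list(window = 10000, target_pearson = 0.8,
                                sigma = 0.5),
    cancer_td = list(n_donors = 200, beta = c(log(5), 0, 0, log(2)),
                     dispersion = 2, max_td_size = 1e5,
                     genes = c("SETX", "POLD3")),
    assay_suite = list(efficiency = 2, ct_at_unit = 30),
    rad51_spreading = list(window = 60000, bin = 500,
                           decay_early = 2000, decay_late = 8000),
    stop("unknown recipe '", name, "'"))
  c(base, extra)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

cpm_cov <- function(reads, bin_size) cpm_normalize(coverage_track(reads, bin_size))

#' Run an end-to-end analysis recipe on synthetic data
#'
#' Each recipe chains documented operations into one panel-style analysis on
#' freshly simulated data, writing its outputs plus a `manifest.json`
#' (recipe, seed, parameters, package version, md5 of every output) to
#' `out_dir`. Outputs are a pure function of (recipe, config, seed): running
#' the same call twice produces byte-identical files, and the manifest
#' suffices to reproduce them.
#'
#' Recipes:
#' * `"rnapii_groups"`: quantile occupancy groups (pre-damage polymerase
#'   signal, 10 kb windows) vs factor recruitment (5 kb windows), with the
#'   top-vs-bottom rank-sum test.
#' * `"factor_heatmap"`: cleavage-ordered 100 kb site matrices and average
#'   profiles for a broad damage-marker and a narrow resection factor.
#' * `"blm_high_low"`: enrichment-ratio classification (factor 4 kb /
#'   cleavage 1 kb) with planted high-recruitment sites.
#' * `"drip_edu_correlation"`: two tracks with a planted per-site
#'   correlation; windowed sums (+/- 5 kb) and their Pearson r.
#' * `"cancer_td"`: simulated cohort; TD < 100 kb counts, two-gene
#'   stratification, pairwise rank-sum tests, NB interaction fit.
#' * `"assay_suite"`: noise-free Ct simulations pushed through every
#'   qPCR calculator (round-trip demonstration).
#' * `"rad51_spreading"`: early vs late induction profiles of a
#'   resection-coupled factor and their spread widths.
#'
#' @param name recipe name (see above).
#' @param config named list overriding recipe defaults, or the path to a
#'   YAML file of such overrides.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed for all randomness in the recipe.
#' @return named list of computed results (also serialized under `out_dir`),
#'   invisibly; the manifest path is attached as attribute `manifest`.
#' @export
run_recipe <- function(name, config = list(), out_dir = tempfile("recipe_"),
                       seed = 1) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("missing config file: ", config)
    config <- yaml::read_yaml(config)
  }
  params <- modifyList(recipe_defaults(name), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- genome_spec(unlist(params$genome))

  res <- switch(name,
    rnapii_groups = recipe_rnapii_groups(params, genome, out_dir, seed),
    factor_heatmap = recipe_factor_heatmap(params, genome, out_dir, seed),
    blm_high_low = recipe_blm_high_low(params, genome, out_dir, seed),
    drip_edu_correlation =
      recipe_drip_edu_correlation(params, genome, out_dir, seed),
    cancer_td = recipe_cancer_td(params, out_dir, seed),
    assay_suite = recipe_assay_suite(params, out_dir, seed),
    rad51_spreading = recipe_rad51_spreading(params, genome, out_dir, seed))

  outputs <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    recipe = name,
    seed = seed,
    package = "dsbscape",
    version = as.character(utils::packageVersion("dsbscape")),
    parameters = params[order(names(params))],
    outputs = lapply(setNames(outputs, outputs), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(res, "manifest") <- file.path(out_dir, "manifest.json")
  invisible(res)
}

recipe_sites <- function(params, genome, seed) {
  sites <- make_sites(genome, params$n_sites, params$min_gap, seed = seed)
  top_n_by_cleavage(sites, params$top_n)
}

recipe_rnapii_groups <- function(params, genome, out_dir, seed) {
  top <- recipe_sites(params, genome, seed)
  # pre-damage occupancy: transcription-coupled, cleavage-independent
  occ_kernel <- factor_kernel("exponential", decay_length_bp = 2000,
                              amplitude = 5, transcription_coupling = 1)
  occ_reads <- simulate_reads(
    top, occ_kernel, background_rate = params$background_rate,
    total_reads = params$total_reads, read_len = params$read_len,
    seed = seed + 1L,
    site_weights = mcols(top)$transcription_score)
  occ <- window_sum(cpm_cov(occ_reads, params$bin_size), top,
                    params$occupancy_window)
  grp <- quantile_groups(top, occ, params$n_groups)

  factor_reads <- simulate_reads(
    top, kernel_resection_early(), background_rate = params$background_rate,
    total_reads = params$total_reads, read_len = params$read_len,
    seed = seed + 2L)
  fac <- window_sum(cpm_cov(factor_reads, params$bin_size), top,
                    params$factor_window)
  grp$factor_signal <- unname(fac)
  top_label <- attr(grp, "group_levels")[1]
  bottom_label <- attr(grp, "group_levels")[params$n_groups]
  cmp <- wilcoxon_ranksum(fac[grp$group == 1],
                          fac[grp$group == params$n_groups])
  write_tsv(as.data.frame(grp), file.path(out_dir, "groups.tsv"))
  write_tsv(data.frame(group1 = top_label, group2 = bottom_label,
                       n1 = cmp$n[1], n2 = cmp$n[2],
                       statistic = cmp$statistic, p_value = cmp$p_value),
            file.path(out_dir, "comparison.tsv"))
  list(groups = grp, comparison = cmp)
}

recipe_factor_heatmap <- function(params, genome, out_dir, seed) {
  top <- recipe_sites(params, genome, seed)
  out <- list()
  kernels <- list(damage_marker = kernel_damage_marker(),
                  resection_factor = kernel_resection_early())
  for (nm in names(kernels)) {
    reads <- simulate_reads(
      top, kernels[[nm]], background_rate = params$background_rate,
      total_reads = params$total_reads, read_len = params$read_len,
      seed = seed + match(nm, names(kernels)))
    mat <- order_by_cleavage(site_matrix(cpm_cov(reads, params$bin_size),
                                         top, params$window, params$bin))
    prof <- average_profile(mat)
    write_matrix_tsv(mat, file.path(out_dir, paste0(nm, "_matrix.tsv")))
    write_matrix_tsv(prof, file.path(out_dir, paste0(nm, "_profile.tsv")))
    out[[nm]] <- list(matrix = mat, profile = prof)
  }
  out
}

recipe_blm_high_low <- function(params, genome, out_dir, seed) {
  top <- recipe_sites(params, genome, seed)
  n <- length(top)
  planted <- withr::with_seed(seed + 10L,
                              sort(sample(n, params$planted_n)))
  w <- rep(1, n)
  w[planted] <- params$planted_fold
  factor_reads <- simulate_reads(
    top, kernel_resection_early(), background_rate = params$background_rate,
    total_reads = params$total_reads, read_len = params$read_len,
    seed = seed + 1L, site_weights = w * mcols(top)$cleavage_score)
  cleav_reads <- simulate_reads(
    top, kernel_cleavage(), background_rate = params$background_rate,
    total_reads = params$total_reads, read_len = params$read_len,
    seed = seed + 2L)
  cls <- ratio_classify(top,
                        cpm_cov(factor_reads, params$bin_size),
                        cpm_cov(cleav_reads, params$bin_size),
                        signal_window = params$signal_window,
                        cleavage_window = params$cleavage_window,
                        n_extreme = params$n_extreme)
  cls$planted <- seq_len(n) %in% planted
  write_tsv(as.data.frame(cls), file.path(out_dir, "classification.tsv"))
  write_classification_bed(cls, file.path(out_dir, "classification.bed"))
  list(classification = cls,
       recovered = sum(cls$label == "high" & cls$planted))
}

recipe_drip_edu_correlation <- function(params, genome, out_dir, seed) {
  top <- recipe_sites(params, genome, seed)
  tr <- simulate_correlated_tracks(
    top, kernel_resection_early(), target_pearson = params$target_pearson,
    seed = seed, sigma = params$sigma, total_reads = params$total_reads,
    read_len = params$read_len)
  s1 <- window_sum(cpm_cov(tr$track1, params$bin_size), top, params$window)
  s2 <- window_sum(cpm_cov(tr$track2, params$bin_size), top, params$window)
  r <- pearson_cor(s1, s2)
  df <- data.frame(site_id = mcols(top)$site_id,
                   track1 = unname(s1), track2 = unname(s2))
  write_tsv(df, file.path(out_dir, "windowed_sums.tsv"))
  write_tsv(data.frame(n = length(s1), pearson_r = r),
            file.path(out_dir, "correlation.tsv"))
  list(sums = df, pearson_r = r)
}

recipe_cancer_td <- function(params, out_dir, seed) {
  cohort <- simulate_donors(params$n_donors, beta = unlist(params$beta),
                            dispersion = params$dispersion,
                            genes = params$genes, seed = seed)
  strat <- stratify(cohort$expression, params$genes[1], params$genes[2])
  counts <- count_td(cohort$sv, max_size = params$max_td_size,
                     donors = strat$donor_id)
  stopifnot(identical(counts$donor_id, strat$donor_id))
  cmp <- compare_groups(counts$td_count, strat$group)
  fit <- nb_interaction(counts$td_count, strat$A, strat$B)
  write_tsv(cbind(as.data.frame(strat), td_count = counts$td_count),
            file.path(out_dir, "donors.tsv"))
  write_tsv(cmp, file.path(out_dir, "comparisons.tsv"))
  jsonlite::write_json(
    list(coefficients = as.list(fit$coefficients), se = as.list(fit$se),
         theta = fit$theta, p_interaction = fit$p_interaction,
         converged = fit$converged, n = fit$n),
    file.path(out_dir, "nb_fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(stratified = strat, counts = counts, comparisons = cmp, fit = fit)
}

recipe_assay_suite <- function(params, out_dir, seed) {
  E <- params$efficiency
  c0 <- params$ct_at_unit
  ct <- function(q) c0 - log(q) / log(E)
  rows <- list(
    data.frame(assay = "percent_input", truth = 5,
               value = percent_input(ct(0.05), ct(0.01), 0.01,
                                     efficiency = E, adjust_input = FALSE)),
    data.frame(assay = "normalized_enrichment", truth = 2,
               value = normalized_enrichment(4, 2)),
    data.frame(assay = "ssdna_percent_dct1", truth = 100 / 1.5,
               value = ssdna_percent(ct(0.5), ct(1), efficiency = E)),
    data.frame(assay = "cleavage_fraction", truth = 0.5,
               value = cleavage_fraction(ct(0.5), ct(1), ct(1), ct(1),
                                         efficiency = E)),
    data.frame(assay = "relative_quantity", truth = 0.25,
               value = relative_quantity(ct(0.25), ct(1), efficiency = E)))
  out <- do.call(rbind, rows)
  out$abs_error <- abs(out$value - out$truth)
  write_tsv(out, file.path(out_dir, "assay_suite.tsv"))
  list(results = out)
}

recipe_rad51_spreading <- function(params, genome, out_dir, seed) {
  top <- recipe_sites(params, genome, seed)
  widths <- list()
  profs <- list()
  for (nm in c("early", "late")) {
    kern <- factor_kernel("exponential",
                          decay_length_bp = params[[paste0("decay_", nm)]],
                          amplitude = 5, transcription_coupling = 1)
    reads <- simulate_reads(
      top, kern, background_rate = params$background_rate,
      total_reads = params$total_reads, read_len = params$read_len,
      seed = seed + match(nm, c("early", "late")))
    mat <- site_matrix(cpm_cov(reads, params$bin_size), top,
                       params$window, params$bin)
    prof <- average_profile(mat)
    widths[[nm]] <- spread_width(prof)
    profs[[nm]] <- prof
    write_matrix_tsv(prof, file.path(out_dir, paste0("profile_", nm, ".tsv")))
  }
  write_tsv(data.frame(condition = names(widths),
                       spread_width_bp = unlist(widths)),
            file.path(out_dir, "spread_widths.tsv"))
  list(profiles = profs, widths = widths)
}
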