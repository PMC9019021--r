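#' Generate a catalog of cut sites on a toy genome
#'
#' Places `n_sites` cut positions with pairwise distance >= `min_gap`,
#' emulating an annotated nuclease-site catalog. Each site carries a planted
#' cleavage grade (linearly spaced over (0, 1] then shuffled, so "top-N by
#' cleavage" is always well defined and unique) and a pre-damage transcription
#' level drawn log-normal(meanlog 0, sdlog 1).
#'
#' Sites are distributed over contigs proportionally to contig length
#' (largest-remainder rounding) and packed by the order-statistics trick:
#' sorted uniforms on the gap-deflated interval plus the accumulated gaps,
#' which yields exact uniformity conditional on the min-gap constraint.
#'
#' @param genome a [genome_spec()].
#' @param n_sites number of sites.
#' @param min_gap minimum pairwise distance in bp.
#' @param seed integer seed; the catalog is a pure function of
#'   (genome, n_sites, min_gap, seed).
#' @return a `GRanges` of width-1 cut positions, sorted, with metadata columns
#'   `site_id`, `cleavage_score`, `transcription_score`.
#' @examples
#' sites <- make_sites(genome_spec(c(sim1 = 1e7)), n_sites = 80,
#'                     min_gap = 50000, seed = 1)
#' @export
make_sites <- function(genome, n_sites, min_gap = 50000, seed = 1) {
  genome <- genome_spec(genome)
  stopifnot(n_sites >= 1, min_gap >= 0)
  if (n_sites * min_gap >= sum(genome))
    stop("infeasible packing: n_sites * min_gap exceeds total genome length")

  # largest-remainder apportionment of sites over contigs
  quota <- n_sites * genome / sum(genome)
  n_per <- floor(quota)
  rem <- n_sites - sum(n_per)
  if (rem > 0) {
    take <- order(quota - n_per, decreasing = TRUE)[seq_len(rem)]
    n_per[take] <- n_per[take] + 1
  }
  for (i in seq_along(genome)) {
    nc <- n_per[i]
    if (nc > 0 && genome[i] - (nc - 1) * min_gap < nc)
      stop("infeasible packing on contig '", names(genome)[i],
           "': cannot place ", nc, " sites with min_gap ", min_gap,
           " on ", genome[i], " bp")
  }

  withr::with_seed(seed, {
    pos <- lapply(seq_along(genome), function(i) {
      nc <- n_per[i]
      if (nc == 0) return(numeric(0))
      slack <- genome[i] - (nc - 1) * min_gap
      u <- sort(runif(nc, 0, slack - 1))
      floor(u) + (seq_len(nc) - 1) * min_gap + 1  # 1-based cut coordinate
    })
    gr <- GRanges(
      seqnames = rep(names(genome), lengths(pos)),
      ranges = IRanges(start = unlist(pos), width = 1),
      seqinfo = as_seqinfo(genome))
    gr <- GenomicRanges::sort(gr)
    mcols(gr)$site_id <- sprintf("DSB_%03d", seq_len(n_sites))
    mcols(gr)$cleavage_score <-
      sample(seq(1, 0.05, length.out = n_sites))
    mcols(gr)$transcription_score <- rlnorm(n_sites, meanlog = 0, sdlog = 1)
    metadata(gr)$seed <- seed
    gr
  })
}

## expected read weight of each site under a kernel
site_weights_for <- function(sites, kernel) {
  w <- kernel$amplitude * mcols(sites)$cleavage_score *
    mcols(sites)$transcription_score ^ kernel$transcription_coupling
  if (any(!is.finite(w)) || any(w < 0)) stop("invalid site weights")
  w
}

## draw n signed offsets from a kernel shape
sample_kernel_offsets <- function(kernel, n) {
  if (n == 0) return(numeric(0))
  switch(kernel$shape,
    point = rep(0, n),
    exponential = {
      d <- rexp(n, rate = 1 / kernel$decay_length_bp)
      round(d) * sample(c(-1, 1), n, replace = TRUE)
    },
    plateau_with_dip = {
      ph <- kernel$plateau_halfwidth_bp
      dh <- kernel$dip_halfwidth_bp
      # mixture over the depleted core and the flanking plateau
      w_dip <- kernel$dip_depth * 2 * dh
      w_plat <- 2 * (ph - dh)
      in_dip <- runif(n) < w_dip / (w_dip + w_plat)
      off <- numeric(n)
      nd <- sum(in_dip)
      if (nd > 0) off[in_dip] <- runif(nd, -dh, dh)
      np <- n - nd
      if (np > 0) {
        d <- runif(np, dh, ph)
        off[!in_dip] <- d * sample(c(-1, 1), np, replace = TRUE)
      }
      round(off)
    })
}

#' Simulate single-end reads around cut sites over a uniform background
#'
#' Draws exactly `total_reads` read start positions from a mixture of a
#' uniform genomic background and per-site kernel-shaped pileups. The expected
#' read count of site s is proportional to
#' `amplitude * cleavage_s * transcription_s^coupling` (or to `site_weights`
#' when supplied), and the background weight to
#' `background_rate * genome length`; the realized allocation is multinomial,
#' so total read count is conserved exactly. Strand is uniform; positions
#' falling past a contig edge are clipped so the read fits the contig.
#'
#' @param sites site catalog from [make_sites()] (seqlengths required).
#' @param kernel a [factor_kernel()].
#' @param background_rate expected background reads per bp (relative weight).
#' @param total_reads total number of reads to emit.
#' @param read_len read length in bp.
#' @param seed integer seed.
#' @param site_weights optional per-site expected-count weights overriding the
#'   kernel amplitude model (used for planted-amplitude designs).
#' @return sorted `GRanges` of reads (width `read_len`, strand +/-), with
#'   `metadata()` recording seed and parameters.
#' @examples
#' sites <- make_sites(genome_spec(c(sim1 = 1e6)), 10, 20000, seed = 1)
#' reads <- simulate_reads(sites, kernel_cleavage(), total_reads = 1000,
#'                         seed = 2)
#' @export
simulate_reads <- function(sites, kernel, background_rate = 1e-5,
                           total_reads = 1e5, read_len = 50, seed = 1,
                           site_weights = NULL) {
  stopifnot(inherits(kernel, "factor_kernel"), total_reads > 0, read_len >= 1)
  genome <- genome_of(sites)
  w_site <- if (is.null(site_weights)) site_weights_for(sites, kernel)
            else {
              stopifnot(length(site_weights) == length(sites),
                        all(site_weights >= 0))
              site_weights
            }
  w_bg <- background_rate * sum(genome)
  w <- c(w_bg, w_site)
  if (sum(w) <= 0)
    stop("all mixture weights are zero: increase amplitude or background_rate")

  withr::with_seed(seed, {
    alloc <- as.vector(rmultinom(1, size = total_reads, prob = w / sum(w)))
    n_bg <- alloc[1]
    n_site <- alloc[-1]

    # background: contig by length, position uniform
    bg_contig <- if (n_bg > 0)
      sample(names(genome), n_bg, replace = TRUE, prob = genome)
    else character(0)
    bg_pos <- if (n_bg > 0)
      floor(runif(n_bg, 0, genome[bg_contig] - read_len)) + 1
    else numeric(0)

    site_contig <- rep(as.character(seqnames(sites)), n_site)
    centers <- rep(start(sites), n_site)
    offs <- sample_kernel_offsets(kernel, sum(n_site))
    site_pos <- centers + offs
    # clip so the read lies within its contig, count preserved
    lim <- genome[site_contig] - read_len + 1
    site_pos <- pmin(pmax(site_pos, 1), lim)

    gr <- GRanges(
      seqnames = c(bg_contig, site_contig),
      ranges = IRanges(start = c(bg_pos, site_pos), width = read_len),
      strand = sample(c("+", "-"), total_reads, replace = TRUE),
      seqinfo = as_seqinfo(genome))
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    names(gr) <- sprintf("read_%07d", seq_along(gr))
    metadata(gr) <- list(seed = seed, total_reads = total_reads,
                         read_len = read_len, kernel = kernel$shape,
                         background_rate = background_rate)
    gr
  })
}

#' Simulate two read tracks with a planted per-site correlation
#'
#' Plants a spatial correlation between two factors (e.g. nascent-DNA and
#' RNA:DNA-hybrid signal) by drawing per-site amplitude pairs from a Gaussian
#' copula with log-normal margins (sdlog `sigma`). The latent normal
#' correlation is chosen in closed form so that the *amplitude-scale* Pearson
#' correlation equals `target_pearson`
#' (`rho_latent = log(1 + r (exp(sigma^2)-1)) / sigma^2`), hence windowed read
#' sums at deep coverage recover r up to sampling noise. `target_pearson = 1`
#' yields identical amplitudes.
#'
#' @param sites site catalog.
#' @param base_kernel kernel shared by both tracks (shape; its amplitude model
#'   is replaced by the drawn amplitudes).
#' @param target_pearson population Pearson correlation in \[-1, 1\].
#' @param seed integer seed.
#' @param sigma sdlog of the log-normal per-site amplitudes.
#' @param total_reads reads per track.
#' @param background_rate,read_len forwarded to [simulate_reads()].
#' @return list with elements `track1`, `track2` (read `GRanges`) and
#'   `amplitudes` (data.frame site_id, a1, a2).
#' @export
simulate_correlated_tracks <- function(sites, base_kernel, target_pearson,
                                       seed = 1, sigma = 0.5,
                                       total_reads = 1e5,
                                       background_rate = 1e-6,
                                       read_len = 50) {
  if (!is.numeric(target_pearson) || length(target_pearson) != 1L ||
      abs(target_pearson) > 1)
    stop("target_pearson must be a single value in [-1, 1]")
  ev <- exp(sigma^2) - 1
  arg <- 1 + target_pearson * ev
  if (arg <= 0)
    stop("target_pearson ", target_pearson,
         " is not attainable with log-normal margins at sigma ", sigma)
  rho <- if (target_pearson == 1) 1 else log(arg) / sigma^2
  if (rho < -1 || rho > 1 + 1e-12)
    stop("latent correlation out of range; reduce |target_pearson| or sigma")
  rho <- min(rho, 1)

  n <- length(sites)
  withr::with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * rnorm(n)
    a1 <- exp(sigma * z1)
    a2 <- exp(sigma * z2)
  })
  t1 <- simulate_reads(sites, base_kernel, background_rate = background_rate,
                       total_reads = total_reads, read_len = read_len,
                       seed = seed + 1L, site_weights = a1)
  t2 <- simulate_reads(sites, base_kernel, background_rate = background_rate,
                       total_reads = total_reads, read_len = read_len,
                       seed = seed + 2L, site_weights = a2)
  list(track1 = t1, track2 = t2,
       amplitudes = data.frame(site_id = mcols(sites)$site_id,
                               a1 = a1, a2 = a2))
}

#' Simulate a qPCR Ct table from true quantities
#'
#' Maps quantities to cycle-threshold values by the exponential amplification
#' model `Ct = ct_at_unit - log_efficiency(quantity) + N(0, noise_sd)`:
#' at efficiency 2 a doubling of template lowers Ct by exactly one cycle.
#'
#' @param true_quantities positive template quantities (arbitrary units).
#' @param efficiency per-cycle amplification factor in (1, 2].
#' @param ct_at_unit Ct of a unit quantity.
#' @param noise_sd Gaussian well noise in cycles (0 = deterministic).
#' @param seed integer seed.
#' @param target,condition,replicate label columns, recycled to length.
#' @return data.frame with columns `sample`, `target`, `condition`,
#'   `replicate`, `quantity`, `ct`.
#' @examples
#' simulate_qpcr(c(1, 2, 4), efficiency = 2, ct_at_unit = 30, noise_sd = 0)
#' @export
simulate_qpcr <- function(true_quantities, efficiency = 2, ct_at_unit = 30,
                          noise_sd = 0, seed = 1, target = "amplicon",
                          condition = "ctrl", replicate = 1L) {
  if (any(true_quantities <= 0)) stop("quantities must be positive")
  if (efficiency <= 1 || efficiency > 2)
    stop("efficiency must be in (1, 2]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- length(true_quantities)
  ct <- ct_at_unit - log(true_quantities) / log(efficiency)
  if (noise_sd > 0)
    ct <- withr::with_seed(seed, ct + rnorm(n, 0, noise_sd))
  data.frame(sample = sprintf("S%03d", seq_len(n)),
             target = rep_len(target, n),
             condition = rep_len(condition, n),
             replicate = rep_len(replicate, n),
             quantity = true_quantities,
             ct = ct)
}

#' Simulate a cancer cohort with a planted expression-TD interaction
#'
#' Generates per-donor expression of two genes (log-normal), high/low
#' indicators by median split (ties to low, matching [stratify()]), and a
#' tandem-duplication count drawn negative-binomial with
#' `mean = exp(beta0 + beta1 A + beta2 B + beta3 A B)` and size `dispersion`
#' (`dispersion = Inf` gives Poisson counts). The structural-variant table
#' contains exactly that many tandem duplications with sizes < 100 kb per
#' donor, plus `n_decoys` decoy SVs per donor (deletions, inversions,
#' insertions, and tandem duplications >= 100 kb) that a correct size/type
#' filter must ignore.
#'
#' @param n_donors cohort size.
#' @param beta numeric(4): log-scale intercept, main effects, interaction.
#' @param dispersion NB size parameter (> 0, may be `Inf`).
#' @param genes names of the two stratification genes.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters, recycled
#'   to the two genes.
#' @param n_decoys decoy SVs per donor.
#' @param seed integer seed.
#' @return list with `expression` (long data.frame donor_id/gene/value),
#'   `sv` (donor_id/sv_type/size), `truth` (donor_id, A, B, td_count).
#' @examples
#' cohort <- simulate_donors(50, beta = c(log(5), 0, 0, log(2)),
#'                           dispersion = 2, seed = 1)
#' @export
simulate_donors <- function(n_donors, beta = c(log(5), 0, 0, log(2)),
                            dispersion = 2, genes = c("SETX", "POLD3"),
                            expr_meanlog = 0, expr_sdlog = 1,
                            n_decoys = 3, seed = 1) {
  stopifnot(length(beta) == 4, n_donors >= 1, length(genes) == 2)
  if (!(dispersion > 0)) stop("dispersion must be > 0")
  expr_meanlog <- rep_len(expr_meanlog, 2)
  expr_sdlog <- rep_len(expr_sdlog, 2)

  withr::with_seed(seed, {
    donor_id <- sprintf("DO%05d", seq_len(n_donors))
    ea <- rlnorm(n_donors, expr_meanlog[1], expr_sdlog[1])
    eb <- rlnorm(n_donors, expr_meanlog[2], expr_sdlog[2])
    A <- as.integer(ea > median(ea))
    B <- as.integer(eb > median(eb))
    mu <- exp(beta[1] + beta[2] * A + beta[3] * B + beta[4] * A * B)
    td_count <- if (is.infinite(dispersion)) rpois(n_donors, mu)
                else rnbinom(n_donors, mu = mu, size = dispersion)

    td <- data.frame(
      donor_id = rep(donor_id, td_count),
      sv_type = "TD",
      size = floor(runif(sum(td_count), 1000, 99999)))
    decoy_types <- c("DEL", "INV", "INS", "TD")
    nd <- n_donors * n_decoys
    decoys <- data.frame(
      donor_id = rep(donor_id, each = n_decoys),
      sv_type = sample(decoy_types, nd, replace = TRUE),
      size = floor(runif(nd, 1e5, 1e6)))  # decoy TDs are >= 100 kb
    sv <- rbind(td, decoys)
    sv <- sv[order(sv$donor_id, sv$sv_type, sv$size), , drop = FALSE]
    rownames(sv) <- NULL

    list(
      expression = data.frame(
        donor_id = rep(donor_id, 2),
        gene = rep(genes, each = n_donors),
        value = c(ea, eb)),
      sv = sv,
      truth = data.frame(donor_id = donor_id, A = A, B = B,
                         td_count = td_count))
  })
}
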