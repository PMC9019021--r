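check_efficiency <- function(efficiency) {
  if (!is.numeric(efficiency) || any(efficiency <= 1))
    stop("amplification efficiency must be > 1 (2 = perfect doubling)")
  invisible(efficiency)
}

#' ChIP efficiency as percent of input
#'
#' Converts IP and input Ct values to the fraction of input DNA
#' immunoprecipitated, on the exponential amplification model:
#' `% = 100 * input_fraction * efficiency^(ct_input_adj - ct_ip)`.
#' With `adjust_input = TRUE` (default) `ct_input` is taken as an
#' undiluted-equivalent measurement (the Ct the total chromatin would give)
#' and is mapped to the aliquot scale via
#' `ct_input_adj = ct_input - log_efficiency(input_fraction)`; the fraction
#' then cancels and the result is `100 * efficiency^(ct_input - ct_ip)`.
#' With `adjust_input = FALSE` the supplied `ct_input` is the Ct actually
#' measured on the `input_fraction` aliquot and is used as-is against the
#' stated fraction. All arguments vectorized.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction fraction of chromatin used as input (0 < f <= 1).
#' @param efficiency per-cycle amplification factor (> 1; default 2).
#' @param adjust_input see above.
#' @return percent of input, same length as the inputs.
#' @examples
#' percent_input(25, 25, input_fraction = 1)                       # 100
#' percent_input(27, 25, 0.01, adjust_input = FALSE)               # 0.25
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction, efficiency = 2,
                          adjust_input = TRUE) {
  check_efficiency(efficiency)
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop("input_fraction must be in (0, 1]")
  ct_adj <- if (adjust_input)
    ct_input - log(input_fraction) / log(efficiency)
  else ct_input
  100 * input_fraction * efficiency ^ (ct_adj - ct_ip)
}

#' Enrichment normalized to a reference
#'
#' Ratio of a test-locus quantity to a reference quantity — percent input at
#' a damage site over a control locus devoid of breaks, or one factor's ChIP
#' efficiency over another's. Scale-free: multiplying both by a constant
#' leaves the ratio unchanged.
#'
#' @param signal test-locus value(s).
#' @param reference reference value(s), > 0.
#' @return `signal / reference`.
#' @export
normalized_enrichment <- function(signal, reference) {
  if (any(reference <= 0)) stop("reference must be positive")
  signal / reference
}

#' Percent single-stranded DNA from a restriction-protection assay
#'
#' Resection readout: genomic DNA is digested with a restriction enzyme that
#' cannot cut single-stranded DNA, and the digested/undigested Ct difference
#' at a site downstream of a break measures the ssDNA fraction:
#' `%ssDNA = 100 / (efficiency^(dCt - 1) + 0.5)` with
#' `dCt = ct_digested - ct_undigested`. Strictly decreasing in dCt; values
#' above 100 (dCt < 1) are reported as-is with a warning.
#'
#' @param ct_digested,ct_undigested Ct values (vectorized).
#' @param efficiency per-cycle amplification factor (default 2).
#' @return percent ssDNA.
#' @examples
#' ssdna_percent(26, 25)  # dCt = 1 -> 66.67
#' @export
ssdna_percent <- function(ct_digested, ct_undigested, efficiency = 2) {
  check_efficiency(efficiency)
  dct <- ct_digested - ct_undigested
  out <- 100 / (efficiency ^ (dct - 1) + 0.5)
  if (any(out > 100))
    warning(sum(out > 100), " value(s) exceed 100% (dCt < 1); reported as-is")
  out
}

#' Relative cleavage by delta-delta-Ct against a calibrator
#'
#' Cleavage assays quantify unrepaired (or re-cleaved) break sites: the site
#' Ct is normalized to an uncut control locus and referenced to a calibrator
#' condition (e.g. the initial break induction as full cleavage):
#' `relative cleavage = efficiency^(-ddCt)` with
#' `ddCt = (ct_site - ct_control_locus) - (ct_calibrator_site -
#' ct_calibrator_control)`. The repair-fidelity readout is this quantity for
#' a second round of break induction relative to the first: accurate repair
#' reconstitutes the recognition site, so re-cleavage approaches 1.
#'
#' @param ct_site,ct_control_locus sample Ct at the break site and at an
#'   uncut control locus.
#' @param ct_calibrator_site,ct_calibrator_control the same pair for the
#'   calibrator condition.
#' @param efficiency per-cycle amplification factor (default 2).
#' @return relative cleavage (1 = calibrator level; may exceed 1).
#' @export
cleavage_fraction <- function(ct_site, ct_control_locus, ct_calibrator_site,
                              ct_calibrator_control, efficiency = 2) {
  check_efficiency(efficiency)
  if (anyNA(c(ct_calibrator_site, ct_calibrator_control)))
    stop("calibrator Ct values are required")
  ddct <- (ct_site - ct_control_locus) -
    (ct_calibrator_site - ct_calibrator_control)
  efficiency ^ (-ddct)
}

#' Relative quantity by delta-Ct
#'
#' Quantity of a target relative to a reference amplicon
#' (`efficiency^(ct_reference - ct_target)`): e.g. repair-synthesis signal
#' normalized to a replication origin, or translocation junction abundance
#' relative to a control locus.
#'
#' @param ct_target,ct_reference Ct values (vectorized).
#' @param efficiency per-cycle amplification factor (default 2).
#' @return relative quantity.
#' @examples
#' relative_quantity(28, 25)  # 0.125
#' @export
relative_quantity <- function(ct_target, ct_reference, efficiency = 2) {
  check_efficiency(efficiency)
  efficiency ^ (ct_reference - ct_target)
}

#' Summarize biological replicates (mean, SEM, optional paired t-test)
#'
#' The replicate convention of assay readouts: mean and standard error of the
#' mean over n independent experiments (SEM defined for n >= 2), with an
#' optional paired two-sided t-test against a matched condition vector.
#' A zero-variance difference vector (e.g. x vs x) is flagged degenerate with
#' `p_value = NA`.
#'
#' @param values per-replicate values.
#' @param paired_with optional matched vector of equal length to test
#'   against.
#' @return `assay_result` list: `n`, `mean`, `sem`, and (when tested)
#'   `p_value`, `degenerate`.
#' @examples
#' replicate_summary(c(2, 4, 6))  # mean 4, SEM 2/sqrt(3)
#' @export
replicate_summary <- function(values, paired_with = NULL) {
  if (length(values) < 1) stop("need at least one replicate")
  out <- list(n = length(values), mean = mean(values),
              sem = if (length(values) >= 2)
                sd(values) / sqrt(length(values)) else NA_real_)
  if (!is.null(paired_with)) {
    if (length(paired_with) != length(values))
      stop("paired test requires equal-length vectors")
    d <- values - paired_with
    if (sd(d) == 0 || length(d) < 2) {
      out$p_value <- NA_real_
      out$degenerate <- TRUE
    } else {
      out$p_value <- t.test(values, paired_with, paired = TRUE,
                            alternative = "two.sided")$p.value
      out$degenerate <- FALSE
    }
  }
  structure(out, class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat("<assay_result> n:", x$n, " mean:", format(x$mean),
      " SEM:", format(x$sem), "\n")
  if (!is.null(x$p_value))
    cat("  paired t-test p:", format.pval(x$p_value),
        if (isTRUE(x$degenerate)) "(degenerate: zero-variance differences)",
        "\n")
  invisible(x)
}
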