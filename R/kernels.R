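#' Describe the positional read kernel of a chromatin factor around a cut
#'
#' A factor kernel is the forward model of how reads of one ChIP/BLESS/DRIP/EdU
#' factor distribute around a DSB. Three shapes cover the phenomenology seen
#' around sequence-specific breaks:
#'
#' * `"point"`: all signal at the cut base — direct end-labeling of the break
#'   (BLESS-like cleavage signal).
#' * `"exponential"`: symmetric two-sided exponential decay away from the cut,
#'   with mean |offset| = `decay_length_bp` — resection-coupled factors (BLM,
#'   RAD51, SETX) that spread over a few to a few tens of kb. Wider decay
#'   lengths model longer break induction (nucleofilament extension).
#' * `"plateau_with_dip"`: a flat domain of half-width `plateau_halfwidth_bp`
#'   with a central depletion of half-width `dip_halfwidth_bp` where density
#'   drops to `dip_depth` of the plateau level — the broad gammaH2AX-like
#'   domain, depleted right at the cut where the phospho-acceptor
#'   nucleosomes are lost.
#'
#' `amplitude` is the expected number of reads a site of unit cleavage and
#' unit transcription contributes (relative weight among sites and against
#' background); `transcription_coupling` is the exponent with which a site's
#' transcription level scales that amplitude, so coupling 0 gives
#' transcription-independent factors and coupling 1 gives signal proportional
#' to pre-damage transcription.
#'
#' @param shape one of `"point"`, `"exponential"`, `"plateau_with_dip"`.
#' @param decay_length_bp mean absolute offset (bp) for the exponential shape.
#' @param plateau_halfwidth_bp half-width (bp) of the plateau shape.
#' @param dip_halfwidth_bp half-width (bp) of the central depletion; must be
#'   smaller than `plateau_halfwidth_bp`.
#' @param dip_depth relative read density inside the dip (0..1).
#' @param amplitude expected reads per unit-cleavage, unit-transcription site.
#' @param transcription_coupling exponent (>= 0) applied to the site
#'   transcription level when scaling the amplitude.
#' @return an object of class `factor_kernel`.
#' @examples
#' factor_kernel("exponential", decay_length_bp = 2000, amplitude = 5)
#' @export
factor_kernel <- function(shape = c("point", "exponential", "plateau_with_dip"),
                          decay_length_bp = NULL,
                          plateau_halfwidth_bp = NULL,
                          dip_halfwidth_bp = 0,
                          dip_depth = 0.25,
                          amplitude = 1,
                          transcription_coupling = 0) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("amplitude must be a single non-negative number")
  if (transcription_coupling < 0)
    stop("transcription_coupling must be >= 0")
  if (shape == "exponential") {
    if (is.null(decay_length_bp) || decay_length_bp <= 0)
      stop("exponential shape requires decay_length_bp > 0")
  }
  if (shape == "plateau_with_dip") {
    if (is.null(plateau_halfwidth_bp) || plateau_halfwidth_bp <= 0)
      stop("plateau_with_dip shape requires plateau_halfwidth_bp > 0")
    if (dip_halfwidth_bp < 0 || dip_halfwidth_bp >= plateau_halfwidth_bp)
      stop("dip_halfwidth_bp must be non-negative and < plateau_halfwidth_bp")
    if (dip_depth < 0 || dip_depth > 1)
      stop("dip_depth must be in [0, 1]")
  }
  structure(
    list(shape = shape,
         decay_length_bp = decay_length_bp,
         plateau_halfwidth_bp = plateau_halfwidth_bp,
         dip_halfwidth_bp = dip_halfwidth_bp,
         dip_depth = dip_depth,
         amplitude = amplitude,
         transcription_coupling = transcription_coupling),
    class = "factor_kernel")
}

#' @export
print.factor_kernel <- function(x, ...) {
  cat("<factor_kernel>", x$shape, "\n")
  if (x$shape == "exponential")
    cat("  decay_length_bp:", x$decay_length_bp, "\n")
  if (x$shape == "plateau_with_dip")
    cat("  plateau_halfwidth_bp:", x$plateau_halfwidth_bp,
        " dip_halfwidth_bp:", x$dip_halfwidth_bp,
        " dip_depth:", x$dip_depth, "\n")
  cat("  amplitude:", x$amplitude,
      " transcription_coupling:", x$transcription_coupling, "\n")
  invisible(x)
}

#' Preset kernels for the factors of a DSB-inducible system
#'
#' Scale-model presets used by the bundled recipes. Widths are desk-scale:
#' the broad damage-marker domain is modeled as a 50 kb plateau (a stand-in
#' for megabase-wide spreading), resection-coupled factors as ~2 kb decays
#' at early induction widening to ~8 kb at prolonged induction (so spread
#' widths land in the few-kb vs tens-of-kb regimes), and cleavage signal as
#' a point mass. Shapes and their contrasts, not absolute widths, are the
#' properties the pipeline tests.
#'
#' @param amplitude expected reads per unit site (see [factor_kernel()]).
#' @return a `factor_kernel`.
#' @name kernel_presets
NULL

#' @rdname kernel_presets
#' @export
kernel_cleavage <- function(amplitude = 5) {
  factor_kernel("point", amplitude = amplitude, transcription_coupling = 0)
}

#' @rdname kernel_presets
#' @export
kernel_damage_marker <- function(amplitude = 20) {
  factor_kernel("plateau_with_dip", plateau_halfwidth_bp = 25000,
                dip_halfwidth_bp = 1000, dip_depth = 0.25,
                amplitude = amplitude, transcription_coupling = 0)
}

#' @rdname kernel_presets
#' @export
kernel_resection_early <- function(amplitude = 5) {
  factor_kernel("exponential", decay_length_bp = 2000,
                amplitude = amplitude, transcription_coupling = 1)
}

#' @rdname kernel_presets
#' @export
kernel_resection_late <- function(amplitude = 5) {
  factor_kernel("exponential", decay_length_bp = 8000,
                amplitude = amplitude, transcription_coupling = 1)
}
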