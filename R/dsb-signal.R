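## indices of track bins whose (0-based) start lies in [lo, hi)
bins_in_range <- function(lo, hi, bin_size, nbins) {
  i1 <- ceiling(lo / bin_size) + 1
  i2 <- ceiling(hi / bin_size)
  i1 <- max(i1, 1L)
  i2 <- min(i2, nbins)
  if (i1 > i2) integer(0) else seq.int(i1, i2)
}

#' Windowed signal sum around cut sites
#'
#' Sum of the bin values whose bin start lies in
#' `[position - window/2, position + window/2)` (full window width `window`,
#' centered on the cut coordinate, half-open). Windows are clipped at contig
#' edges. This is the "normalized number of reads in a window around each
#' DSB" statistic underlying boxplots, scatter plots and ratio
#' classification; with read-start binning on a CPM track it is an exact CPM
#' read count.
#'
#' @param track a `signal_track`.
#' @param sites `GRanges` of cut sites.
#' @param window full window width in bp (>= bin size).
#' @return numeric vector of per-site sums, named by `site_id` when present.
#' @export
window_sum <- function(track, sites, window) {
  stopifnot(inherits(track, "signal_track"), window >= track$bin_size)
  contig <- as.character(seqnames(sites))
  unknown <- setdiff(unique(contig), names(track$genome))
  if (length(unknown) > 0)
    stop("site contig(s) not in track: ", paste(unknown, collapse = ", "))
  if (any(start(sites) > track$genome[contig]))
    stop("site position beyond contig end")
  out <- vapply(seq_along(sites), function(k) {
    v <- track$values[[contig[k]]]
    p0 <- start(sites)[k] - 1
    i <- bins_in_range(p0 - window / 2, p0 + window / 2,
                       track$bin_size, length(v))
    sum(v[i])
  }, numeric(1))
  if (!is.null(mcols(sites)$site_id)) names(out) <- mcols(sites)$site_id
  out
}

#' Site-by-position signal matrix
#'
#' The matrix underlying heatmaps and average profiles: row s, column k holds
#' the signal of site s at offset `(k - 1 - K/2) * bin` from its cut
#' coordinate, where `K = window / bin`. Each cell sums the track bins whose
#' start lies in the corresponding offset interval, so row sums equal
#' [window_sum()] values. Cells whose interval extends beyond the contig are
#' `NA` (missing, not zero) and are excluded from column means downstream.
#'
#' @param track a `signal_track`.
#' @param sites cut-site `GRanges`.
#' @param window full window width in bp.
#' @param bin output bin width in bp; a multiple of the track bin size
#'   (default: the track bin size). `window` must be a multiple of `bin`.
#' @return object of class `site_signal_matrix`: list with `matrix`
#'   (sites x offsets, dimnames site id / offset), `sites`, `window`, `bin`.
#' @export
site_matrix <- function(track, sites, window, bin = NULL) {
  stopifnot(inherits(track, "signal_track"))
  if (is.null(bin)) bin <- track$bin_size
  if (bin %% track$bin_size != 0)
    stop("bin must be a multiple of the track bin size")
  if (window %% bin != 0)
    stop("window must be a multiple of bin")
  K <- as.integer(window / bin)
  offsets <- (seq_len(K) - 1 - K %/% 2) * bin
  contig <- as.character(seqnames(sites))
  m <- matrix(NA_real_, nrow = length(sites), ncol = K,
              dimnames = list(mcols(sites)$site_id, offsets))
  for (s in seq_along(sites)) {
    v <- track$values[[contig[s]]]
    L <- track$genome[contig[s]]
    p0 <- start(sites)[s] - 1
    lo <- p0 + offsets
    hi <- lo + bin
    for (k in seq_len(K)) {
      if (lo[k] < 0 || hi[k] > L) next  # off-contig cell stays NA
      i <- bins_in_range(lo[k], hi[k], track$bin_size, length(v))
      m[s, k] <- sum(v[i])
    }
  }
  structure(list(matrix = m, sites = sites, window = window, bin = bin),
            class = "site_signal_matrix")
}

#' @export
print.site_signal_matrix <- function(x, ...) {
  cat("<site_signal_matrix> ", nrow(x$matrix), " sites x ", ncol(x$matrix),
      " bins (window ", x$window, " bp, bin ", x$bin, " bp)\n", sep = "")
  invisible(x)
}

#' Average signal profile over sites
#'
#' Column-wise mean of a [site_matrix()] over non-missing cells — the
#' aggregate "average profile around the best-cleaved DSBs".
#'
#' @param mat a `site_signal_matrix`.
#' @return named numeric vector (names = bp offsets) with attribute `bin`.
#' @export
average_profile <- function(mat) {
  stopifnot(inherits(mat, "site_signal_matrix"), nrow(mat$matrix) >= 1)
  p <- colMeans(mat$matrix, na.rm = TRUE)
  attr(p, "bin") <- mat$bin
  p
}

#' Order a site matrix by cleavage signal
#'
#' Rows sorted by `cleavage_score` descending (the heatmap convention:
#' best-cleaved sites on top); ties broken by genomic position ascending.
#'
#' @param mat a `site_signal_matrix` whose sites carry `cleavage_score`.
#' @return reordered `site_signal_matrix`.
#' @export
order_by_cleavage <- function(mat) {
  stopifnot(inherits(mat, "site_signal_matrix"))
  sc <- mcols(mat$sites)$cleavage_score
  if (is.null(sc)) stop("sites carry no cleavage_score")
  ord <- order(-sc, as.integer(match(as.character(seqnames(mat$sites)),
                                     seqlevels(mat$sites))),
               start(mat$sites))
  mat$matrix <- mat$matrix[ord, , drop = FALSE]
  mat$sites <- mat$sites[ord]
  mat
}

#' Pearson correlation of per-site signals
#'
#' Sample Pearson correlation between two per-site value vectors (e.g.
#' windowed counts of two factors at the same sites), with explicit guards:
#' equal length >= 3 and nonzero variance in both.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in \[-1, 1\].
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.8
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired values")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  cor(x, y, method = "pearson")
}

#' Width of the central enriched region of a profile
#'
#' Fractional-maximum width above background: background is the mean of the
#' outermost 10% of bins on each side, and the width is the length (bp) of
#' the contiguous run of bins around the profile maximum satisfying
#' `profile - background >= fraction * (max - background)`. With
#' `fraction = 0.5` this is a full width at half maximum. A profile with no
#' peak above background returns `NA` with attribute `reason = "no peak
#' above background"` (undefined, not zero).
#'
#' @param profile numeric vector from [average_profile()] (or any profile);
#'   `bin` attribute or argument gives the bp per bin.
#' @param fraction height fraction defining the width (default 0.5).
#' @param bin bp per bin (default: the profile's `bin` attribute).
#' @return width in bp, or `NA` if undefined.
#' @export
spread_width <- function(profile, fraction = 0.5, bin = attr(profile, "bin")) {
  if (is.null(bin)) stop("bin size unknown; pass bin=")
  stopifnot(fraction > 0, fraction <= 1)
  n <- length(profile)
  k <- max(1L, floor(0.1 * n))
  bg <- mean(c(profile[seq_len(k)], profile[seq.int(n - k + 1, n)]))
  pk <- max(profile)
  if (!(pk > bg)) {
    out <- NA_real_
    attr(out, "reason") <- "no peak above background"
    return(out)
  }
  thr <- bg + fraction * (pk - bg)
  above <- profile >= thr
  i <- which.max(profile)
  lo <- i
  while (lo > 1 && above[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < n && above[hi + 1]) hi <- hi + 1
  (hi - lo + 1) * bin
}

#' Export a site matrix or profile as TSV
#'
#' Matrices are written sites x offsets with a `site_id` column; profiles as
#' two columns (offset, value).
#'
#' @param x a `site_signal_matrix` or profile vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_matrix_tsv <- function(x, path) {
  if (inherits(x, "site_signal_matrix")) {
    df <- data.frame(site_id = rownames(x$matrix), x$matrix,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    df <- data.frame(offset = names(x), value = as.numeric(x))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
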