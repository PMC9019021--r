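## genomic-order rank used for all tie-breaking (input-order invariant)
genomic_rank <- function(sites) {
  order(order(as.integer(match(as.character(seqnames(sites)),
                               seqlevels(sites))), start(sites)))
}

#' Select the best-cleaved sites
#'
#' The n sites with highest cleavage score (the "N best-cleaved DSBs"
#' selection used throughout break-anchored aggregation); ties resolved by
#' genomic order. Output keeps the input (genomic) order of the retained
#' sites.
#'
#' @param sites `GRanges` with a `cleavage_score` column.
#' @param n number of sites to keep (default 80).
#' @return subset `GRanges`.
#' @export
top_n_by_cleavage <- function(sites, n = 80) {
  sc <- mcols(sites)$cleavage_score
  if (is.null(sc)) stop("sites carry no cleavage_score")
  if (n > length(sites))
    stop("n (", n, ") exceeds available sites (", length(sites), ")")
  ord <- order(-sc, genomic_rank(sites))
  sites[sort(ord[seq_len(n)])]
}

#' Classify sites by factor/cleavage enrichment ratio
#'
#' The high/low recruitment classification: for each site compute
#' `(factor windowed sum + pseudocount) / (cleavage windowed sum +
#' pseudocount)` — factor signal in a `signal_window` (default 4 kb) window,
#' cleavage signal in a `cleavage_window` (default 1 kb) window — sort sites
#' by this ratio descending, and label the first `n_extreme` "high" and the
#' last `n_extreme` "low" (the rest unlabeled). Normalizing to cleavage
#' corrects for unequal nuclease activity across sites. The pseudocount
#' (default 1 signal unit) guards weakly-cleaved sites; a zero pseudocount
#' with any zero cleavage sum is an error directing the user to set one.
#'
#' @param sites cut-site `GRanges`.
#' @param factor_track,cleavage_track `signal_track`s (factor ChIP and
#'   cleavage signal; CPM-normalized tracks recommended).
#' @param signal_window,cleavage_window full window widths in bp.
#' @param n_extreme sites per extreme class (default 20).
#' @param pseudocount added to numerator and denominator.
#' @return `site_classification` data.frame with columns `site_id`, `contig`,
#'   `position`, `score`, `label` (`high`/`low`/`unlabeled`), plus attributes
#'   `params` and `degenerate` (TRUE when all scores tie and labels are
#'   purely the genomic-order tie rule).
#' @export
ratio_classify <- function(sites, factor_track, cleavage_track,
                           signal_window = 4000, cleavage_window = 1000,
                           n_extreme = 20, pseudocount = 1) {
  if (2 * n_extreme > length(sites))
    stop("2 * n_extreme exceeds the number of sites")
  f <- window_sum(factor_track, sites, signal_window)
  cl <- window_sum(cleavage_track, sites, cleavage_window)
  if (pseudocount == 0 && any(cl == 0))
    stop("zero cleavage signal at ", sum(cl == 0),
         " site(s); set a positive pseudocount")
  score <- (f + pseudocount) / (cl + pseudocount)
  ord <- order(-score, genomic_rank(sites))
  label <- rep("unlabeled", length(sites))
  label[ord[seq_len(n_extreme)]] <- "high"
  label[rev(ord)[seq_len(n_extreme)]] <- "low"
  res <- data.frame(
    site_id = if (is.null(mcols(sites)$site_id))
      sprintf("site_%03d", seq_along(sites)) else mcols(sites)$site_id,
    contig = as.character(seqnames(sites)),
    position = start(sites),
    score = unname(score),
    label = label)
  degenerate <- length(unique(score)) == 1
  if (degenerate)
    warning("all ratio scores identical; labels follow the genomic-order ",
            "tie rule only")
  structure(res, class = c("site_classification", "data.frame"),
            params = list(signal_window = signal_window,
                          cleavage_window = cleavage_window,
                          n_extreme = n_extreme, pseudocount = pseudocount),
            degenerate = degenerate)
}

#' Split sites into quantile groups by a score
#'
#' Sites sorted by score descending (ties by genomic order) and cut into
#' `n_groups` contiguous groups — e.g. the four pre-damage RNAPII occupancy
#' classes (high / medium-high / medium-low / low) of 20 sites each on an
#' 80-site catalog. When the site count is not divisible, group sizes differ
#' by at most one with larger groups first.
#'
#' @param sites cut-site `GRanges`.
#' @param scores numeric per-site score vector, or the name of an `mcols`
#'   column of `sites`.
#' @param n_groups number of groups (>= 2, default 4).
#' @return `site_classification` data.frame with `group` (integer, 1 =
#'   highest) and `group_label`; attribute `group_levels`.
#' @export
quantile_groups <- function(sites, scores, n_groups = 4) {
  stopifnot(n_groups >= 2)
  if (is.character(scores) && length(scores) == 1) {
    nm <- scores
    scores <- mcols(sites)[[nm]]
    if (is.null(scores)) stop("no site column '", nm, "'")
  }
  stopifnot(length(scores) == length(sites))
  n <- length(sites)
  base <- n %/% n_groups
  sizes <- base + as.integer(seq_len(n_groups) <= n %% n_groups)
  ord <- order(-scores, genomic_rank(sites))
  grp <- integer(n)
  grp[ord] <- rep(seq_len(n_groups), sizes)
  levels <- if (n_groups == 4)
    c("high", "medium_high", "medium_low", "low")
  else sprintf("group_%d", seq_len(n_groups))
  res <- data.frame(
    site_id = if (is.null(mcols(sites)$site_id))
      sprintf("site_%03d", seq_along(sites)) else mcols(sites)$site_id,
    contig = as.character(seqnames(sites)),
    position = start(sites),
    score = unname(scores),
    group = grp,
    group_label = levels[grp])
  structure(res, class = c("site_classification", "data.frame"),
            group_levels = levels,
            params = list(n_groups = n_groups, sizes = sizes))
}

#' Two-sided rank-sum comparison of two groups
#'
#' Unpaired two-sided Mann-Whitney-Wilcoxon test plus the boxplot summaries
#' of both groups. `mode = "exact"` uses the exact rank-sum distribution
#' (error if ties make it unavailable), `"normal_approx"` the normal
#' approximation with continuity and tie correction, and `"auto"` picks exact
#' when `length(a) + length(b) <= 12` and there are no ties. A paired variant
#' (signed-rank) is available behind `paired = TRUE` for designs with a
#' natural pairing.
#'
#' @param a,b numeric value vectors (non-empty).
#' @param mode p-value mode, see above.
#' @param paired use the paired signed-rank test (requires equal lengths).
#' @return `group_comparison` list: `statistic` (U), `p_value`, `n`,
#'   `mode_used`, `summaries` (per-group [boxplot_stats()]).
#' @examples
#' wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
wilcoxon_ranksum <- function(a, b, mode = c("auto", "exact", "normal_approx"),
                             paired = FALSE) {
  mode <- match.arg(mode)
  if (length(a) == 0 || length(b) == 0) stop("empty group")
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- switch(mode,
    exact = {
      if (ties) stop("exact mode unavailable with ties; use normal_approx")
      TRUE
    },
    normal_approx = FALSE,
    auto = !ties && length(a) + length(b) <= 12)
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", paired = paired,
                exact = use_exact, correct = TRUE))
  structure(
    list(statistic = unname(ht$statistic),
         p_value = ht$p.value,
         n = c(a = length(a), b = length(b)),
         mode_used = if (use_exact) "exact" else "normal_approx",
         paired = paired,
         summaries = list(a = boxplot_stats(a), b = boxplot_stats(b))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>", if (x$paired) "paired signed-rank"
      else "unpaired rank-sum",
      sprintf("(%s)\n", x$mode_used))
  cat("  n:", x$n[1], "vs", x$n[2], " U:", x$statistic,
      " p:", format.pval(x$p_value), "\n")
  invisible(x)
}

#' Boxplot summary with the 1.5 IQR outlier rule
#'
#' Median, first and third quartiles (linear-interpolation quantiles),
#' whiskers at the extreme values within
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`, and the values outside those fences as
#' outliers — the plotting convention used for all group boxplots.
#'
#' @param values numeric vector (>= 1 value).
#' @return list with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
boxplot_stats <- function(values) {
  if (length(values) < 1) stop("need at least one value")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  inside <- values >= lo & values <= hi
  list(n = length(values),
       median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Export a site classification as BED
#'
#' 1 bp features at the cut positions; name = label (or group label),
#' score = classification score.
#'
#' @param cls a `site_classification`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_classification_bed <- function(cls, path) {
  lab <- if (!is.null(cls$label)) cls$label else cls$group_label
  df <- data.frame(cls$contig, cls$position - 1, cls$position, lab,
                   formatC(cls$score, digits = 6, format = "g"), ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
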