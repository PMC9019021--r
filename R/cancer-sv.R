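#' Count small tandem duplications per donor
#'
#' Number of structural variants of tandem-duplication type with size
#' strictly below `max_size` (default 100 kb) for each donor — the
#' break-induced-replication-associated genomic signature. Donors listed in
#' `donors` but absent from the SV table get a count of 0.
#'
#' @param sv data.frame with columns `donor_id`, `sv_type`, `size`.
#' @param max_size strict upper size bound in bp.
#' @param td_types `sv_type` values counted as tandem duplications.
#' @param donors optional character vector of donor ids defining the output
#'   universe (default: donors present in `sv`).
#' @return data.frame with columns `donor_id`, `td_count`.
#' @examples
#' sv <- data.frame(donor_id = "d1",
#'                  sv_type = c("TD", "TD", "DEL"),
#'                  size = c(50000, 100000, 10000))
#' count_td(sv)  # 1: the 100 kb TD fails the strict bound, the DEL the type
#' @export
count_td <- function(sv, max_size = 1e5, td_types = "TD", donors = NULL) {
  stopifnot(all(c("donor_id", "sv_type", "size") %in% names(sv)))
  if (any(sv$size <= 0, na.rm = TRUE)) stop("SV sizes must be positive")
  if (is.null(donors)) donors <- sort(unique(sv$donor_id))
  keep <- sv$sv_type %in% td_types & sv$size < max_size
  tab <- table(factor(sv$donor_id[keep], levels = donors))
  data.frame(donor_id = donors, td_count = as.integer(tab[donors]),
             row.names = NULL)
}

#' Stratify a cohort by the expression of two genes
#'
#' Each donor is classified high/low for each gene — high meaning expression
#' strictly above the cutoff, donors at exactly the cutoff going to low —
#' yielding the four groups `high_high`, `high_low`, `low_high`, `low_low`
#' (first position = `geneA`, second = `geneB`). Cutoff rules: per-gene
#' `"median"` (default), `"quantile"` at probability `q`, or `"fixed"`
#' values supplied in `cutoffs`. Donors missing either gene are excluded
#' with a message. A gene with constant expression under a data-driven rule
#' is an error (degenerate split).
#'
#' @param expression long data.frame (`donor_id`, `gene`, `value`).
#' @param geneA,geneB gene names (A listed first in group labels).
#' @param cutoff_rule `"median"`, `"quantile"` or `"fixed"`.
#' @param q quantile probability for `cutoff_rule = "quantile"`.
#' @param cutoffs named numeric (geneA, geneB) for `cutoff_rule = "fixed"`.
#' @return `stratified_cohort` data.frame: `donor_id`, `exprA`, `exprB`,
#'   `A`, `B` (0/1 high indicators), `group` (factor); attributes `cutoffs`,
#'   `genes`, `n_excluded`.
#' @export
stratify <- function(expression, geneA, geneB,
                     cutoff_rule = c("median", "quantile", "fixed"),
                     q = 0.5, cutoffs = NULL) {
  cutoff_rule <- match.arg(cutoff_rule)
  stopifnot(all(c("donor_id", "gene", "value") %in% names(expression)))
  ea <- expression[expression$gene == geneA, c("donor_id", "value")]
  eb <- expression[expression$gene == geneB, c("donor_id", "value")]
  if (anyDuplicated(ea$donor_id) || anyDuplicated(eb$donor_id))
    stop("multiple expression values per donor/gene")
  wide <- merge(ea, eb, by = "donor_id", suffixes = c(".A", ".B"))
  all_donors <- unique(expression$donor_id)
  n_excluded <- length(all_donors) - nrow(wide)
  if (n_excluded > 0)
    message("excluded ", n_excluded, " donor(s) missing ", geneA, " or ",
            geneB, " expression")
  if (nrow(wide) == 0) stop("no donor has both genes")

  cut_for <- function(v, gene) {
    switch(cutoff_rule,
      median = {
        if (length(unique(v)) == 1)
          stop("constant ", gene, " expression: median split is degenerate")
        median(v)
      },
      quantile = {
        if (length(unique(v)) == 1)
          stop("constant ", gene, " expression: quantile split is degenerate")
        unname(quantile(v, q, type = 7))
      },
      fixed = {
        if (is.null(cutoffs) || is.null(cutoffs[[gene]]))
          stop("cutoff_rule='fixed' requires cutoffs[['", gene, "']]")
        cutoffs[[gene]]
      })
  }
  ca <- cut_for(wide$value.A, geneA)
  cb <- cut_for(wide$value.B, geneB)
  A <- as.integer(wide$value.A > ca)
  B <- as.integer(wide$value.B > cb)
  group <- factor(
    paste(ifelse(A == 1, "high", "low"), ifelse(B == 1, "high", "low"),
          sep = "_"),
    levels = c("high_high", "high_low", "low_high", "low_low"))
  res <- data.frame(donor_id = wide$donor_id,
                    exprA = wide$value.A, exprB = wide$value.B,
                    A = A, B = B, group = group)
  structure(res, class = c("stratified_cohort", "data.frame"),
            cutoffs = setNames(c(ca, cb), c(geneA, geneB)),
            genes = c(geneA, geneB), n_excluded = n_excluded)
}

#' Pairwise rank-sum comparisons of group TD counts
#'
#' Unpaired two-sided Wilcoxon comparisons of per-donor counts between
#' stratification groups (delegating to [wilcoxon_ranksum()]).
#'
#' @param counts numeric per-donor counts.
#' @param groups factor/character of the same length giving group labels.
#' @param pairs list of length-2 character vectors naming the comparisons
#'   (default: all pairs of observed groups).
#' @return data.frame: `group1`, `group2`, `n1`, `n2`, `statistic`,
#'   `p_value`.
#' @export
compare_groups <- function(counts, groups, pairs = NULL) {
  stopifnot(length(counts) == length(groups))
  groups <- as.character(groups)
  lev <- unique(groups)
  if (is.null(pairs))
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- counts[groups == p[1]]
    b <- counts[groups == p[2]]
    if (length(a) == 0 || length(b) == 0)
      stop("empty group in pair ", p[1], " vs ", p[2])
    gc <- wilcoxon_ranksum(a, b)
    data.frame(group1 = p[1], group2 = p[2],
               n1 = length(a), n2 = length(b),
               statistic = gc$statistic, p_value = gc$p_value)
  })
  do.call(rbind, rows)
}

nb_loglik <- function(counts, A, B, beta, theta) {
  mu <- exp(beta[1] + beta[2] * A + beta[3] * B + beta[4] * A * B)
  sum(dnbinom(counts, mu = mu, size = theta, log = TRUE))
}

#' Negative-binomial regression with a two-gene interaction
#'
#' Maximum-likelihood fit of `count ~ NB2(mean = exp(b0 + b1 A + b2 B +
#' b3 A B), size = theta)` to per-donor tandem-duplication counts, where A
#' and B are the high-expression indicators of the two stratification genes.
#' The interaction coefficient b3 tests whether one gene's effect on the
#' counts depends on the other's expression level; its two-sided Wald
#' p-value is reported by default, with a likelihood-ratio alternative
#' (`test = "lrt"`) against the additive model. Fitting uses `MASS::glm.nb`
#' (log link, NB2 variance `mu + mu^2/theta`, theta by ML); non-convergence
#' is reported in the `converged` flag, never silently.
#'
#' @param counts non-negative integer counts.
#' @param A,B 0/1 indicators (high expression of gene A / gene B).
#' @param test `"wald"` (default) or `"lrt"` for the interaction p-value.
#' @return `nb_fit` list: `coefficients` (beta0..beta3, log scale), `se`,
#'   `theta`, `theta_se`, `p_interaction`, `test`, `converged`, `n`,
#'   `loglik`.
#' @export
nb_interaction <- function(counts, A, B, test = c("wald", "lrt")) {
  test <- match.arg(test)
  stopifnot(length(A) == length(counts), length(B) == length(counts))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(counts == 0)) stop("all counts are zero; nothing to fit")
  if (!all(A %in% 0:1) || !all(B %in% 0:1))
    stop("A and B must be 0/1 indicators")
  cells <- table(factor(A, levels = 0:1), factor(B, levels = 0:1))
  if (sum(cells > 0) < 3 || all(A == A[1]) || all(B == B[1]))
    stop("design spans ", sum(cells > 0),
         " of 4 cells; need >= 3 with both indicators varying")
  if (length(counts) < 4) stop("need at least 4 donors")

  dat <- data.frame(y = counts, A = A, B = B)
  warned <- character(0)
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(y ~ A * B, data = dat),
             error = function(e)
               stop("negative-binomial fit failed: ", conditionMessage(e))),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- isTRUE(fit$converged) &&
    !any(grepl("iteration limit", warned, ignore.case = TRUE))
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  terms <- c("(Intercept)", "A", "B", "A:B")
  beta <- setNames(coef(fit)[terms], c("beta0", "beta1", "beta2", "beta3"))
  se <- setNames(rep(NA_real_, 4), names(beta))
  present <- intersect(terms, rownames(co))
  se[match(present, terms)] <- co[present, "Std. Error"]
  p_int <- if ("A:B" %in% rownames(co) && !is.na(beta["beta3"])) {
    if (test == "wald") {
      unname(2 * pnorm(-abs(co["A:B", "Estimate"] / co["A:B", "Std. Error"])))
    } else {
      fit0 <- suppressWarnings(MASS::glm.nb(y ~ A + B, data = dat))
      lr <- 2 * (as.numeric(logLik(fit)) - as.numeric(logLik(fit0)))
      unname(stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE))
    }
  } else NA_real_

  structure(
    list(coefficients = beta, se = se,
         theta = fit$theta, theta_se = fit$SE.theta,
         p_interaction = p_int, test = test,
         converged = converged, warnings = warned,
         n = length(counts), loglik = as.numeric(logLik(fit)),
         model = fit),
    class = "nb_fit")
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("<nb_fit> n:", x$n, " theta:", format(x$theta),
      if (!x$converged) "[NOT CONVERGED]", "\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("  interaction p (", x$test, "): ", format.pval(x$p_interaction),
      "\n", sep = "")
  invisible(x)
}
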