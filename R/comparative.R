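## Cross-dataset statistics: Spearman correlation with permutation P
## values, PCA of log rates, bootstrap of medians, contingency
## chi-squared, nonparametric group comparisons and the synteny shuffling
## rate. All stochastic routines are deterministic under a fixed seed.

#' Spearman correlation with a permutation P value
#'
#' Spearman's rho (average ranks for ties) with a two-sided permutation
#' test: `P = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)` -- the
#' add-one estimator, so P is never exactly 0.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param n_perm permutation rounds (default 100000).
#' @param seed RNG seed; results are reproducible bit-for-bit.
#' @return a list with `rho`, `p_value`, `n`, `n_perm`.
#' @export
spearman_perm <- function(x, y, n_perm = 100000, seed = 1L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("constant vector: Spearman correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    rp <- cor(rx, ry[sample.int(n)])
    if (abs(rp) >= abs(rho) - 1e-12) count <- count + 1L
  }
  list(rho = rho, p_value = (1 + count) / (n_perm + 1), n = n,
       n_perm = n_perm)
}

#' PCA of log10 genome dynamics rates
#'
#' Principal component analysis of the four per-site event rates after
#' log10 transformation. The default uses the correlation matrix
#' (standardised variables); the covariance matrix is available via
#' `cor = FALSE`. The sign of PC1 is oriented so that all four loadings
#' are positive: PC1 is then the overall gene-flux axis and PC2 the
#' gain-versus-loss balance axis.
#'
#' @param rates a data frame or matrix with columns `gain`, `loss`,
#'   `expansion`, `reduction` (per-site rates, > 0), one row per dataset.
#'   Table-1-style columns (`gain_site`, ...) are also accepted.
#' @param cor logical; use the correlation (default) or covariance matrix.
#' @return a list with `variance_percent` (sums to 100), `loadings`
#'   (orthonormal, PC1 sign-fixed), `scores`.
#' @export
pca_rates <- function(rates, cor = TRUE) {
  rates <- as.data.frame(rates)
  want <- c("gain", "loss", "expansion", "reduction")
  if (!all(want %in% names(rates))) {
    alt <- paste0(want, "_site")
    if (all(alt %in% names(rates))) {
      rates <- rates[alt]
      names(rates) <- want
    } else stop("rates must have columns gain, loss, expansion, reduction")
  }
  X <- as.matrix(rates[want])
  if (nrow(X) < 3) stop("need at least 3 datasets")
  if (any(X <= 0)) stop("non-positive rate: cannot log-transform")
  pc <- stats::princomp(log10(X), cor = cor)
  vp <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  load <- unclass(pc$loadings)
  if (sum(load[, 1]) < 0) {
    load[, 1] <- -load[, 1]
    pc$scores[, 1] <- -pc$scores[, 1]
  }
  list(variance_percent = unname(vp), loadings = load, scores = pc$scores)
}

#' Bootstrap distribution of the median
#'
#' @param values numeric vector (n >= 2).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @return a list with `medians` (length `n_boot`), `mean`, `quantiles`
#'   (2.5/50/97.5%), and a `density` estimate of the medians.
#' @export
bootstrap_median <- function(values, n_boot = 1000, seed = 1L) {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  set.seed(seed)
  med <- vapply(seq_len(n_boot), function(i)
    median(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  list(medians = med, mean = mean(med),
       quantiles = quantile(med, c(0.025, 0.5, 0.975)),
       density = density(med))
}

#' Chi-squared test on a 2x2 open/closed x lifestyle table
#'
#' Pearson chi-squared without continuity correction (df = 1), as used for
#' testing whether open supergenomes are more common among free-living
#' than host-associated microbes.
#'
#' @param table 2x2 matrix of non-negative integer counts (rows:
#'   lifestyle; columns: open/closed, or vice versa).
#' @return a list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi2_open_lifestyle <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)))
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero marginal total: test undefined")
  ct <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter), expected = ct$expected)
}

#' Pairwise rank-based group comparisons of event rates
#'
#' Two-sided Mann--Whitney U (Wilcoxon rank-sum) tests between every pair
#' of groups, for every rate column. Groups with fewer than 3 members are
#' skipped with a warning.
#'
#' @param panel data frame of rates (one row per dataset); non-numeric
#'   columns are ignored.
#' @param grouping factor or character vector, one group label per row.
#' @return a data frame: `variable`, `group1`, `group2`, `n1`, `n2`,
#'   `statistic` (U), `p_value` (uncorrected).
#' @export
group_compare <- function(panel, grouping) {
  panel <- as.data.frame(panel)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == nrow(panel))
  sizes <- table(grouping)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("skipping undersized groups (< 3 members): ",
            paste(small, collapse = ", "))
  }
  groups <- names(sizes)[sizes >= 3]
  if (length(groups) < 2) stop("need at least 2 groups with >= 3 members")
  num <- names(panel)[vapply(panel, is.numeric, logical(1))]
  out <- list()
  for (v in num) {
    for (i in seq_along(groups)) {
      for (j in seq_along(groups)) {
        if (j <= i) next
        a <- panel[[v]][grouping == groups[i]]
        b <- panel[[v]][grouping == groups[j]]
        wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE))
        out[[length(out) + 1L]] <- data.frame(
          variable = v, group1 = groups[i], group2 = groups[j],
          n1 = length(a), n2 = length(b),
          statistic = unname(wt$statistic), p_value = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Genome shuffling rate from synteny decay
#'
#' Fits `log(dY) = a + b log(d_nuc)` by least squares over genome pairs,
#' where `dY = 1 - F_s` is the synteny distance (fraction of orthologs
#' outside syntenic segments) and `d_nuc` the pairwise nucleotide
#' distance, and reports the fitted `dY` at a reference distance (default
#' 0.01 substitutions/site). Non-positive values are excluded with a
#' warning.
#'
#' @param pairs data frame with columns `dY` and `d_nuc`.
#' @param at reference nucleotide distance.
#' @return a list with `rate` (fitted dY at `at`), `slope`, `intercept`,
#'   `slope_se`, `n`.
#' @export
shuffling_rate <- function(pairs, at = 0.01) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("dY", "d_nuc") %in% names(pairs)))
  if (any(pairs$dY > 1)) stop("dY must lie in [0, 1]")
  keep <- pairs$dY > 0 & pairs$d_nuc > 0
  if (any(!keep))
    warning("excluding ", sum(!keep), " pairs with non-positive dY or d_nuc")
  if (sum(keep) < 3) stop("fewer than 3 usable pairs")
  fit <- lm(log(dY) ~ log(d_nuc), data = pairs[keep, ])
  co <- coef(fit)
  list(rate = exp(unname(co[1]) + unname(co[2]) * log(at)),
       slope = unname(co[2]), intercept = unname(co[1]),
       ## a perfect fit (exact power-law input) has zero residual variance;
       ## summary() warns about it, but se = 0 is the right answer
       slope_se = suppressWarnings(summary(fit)$coefficients[2, 2]),
       n = sum(keep))
}
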