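## Supergenome (gene-pool) size estimation from repeated gene family
## gains. Two maximum-likelihood sampling models:
##  * uniform pool: P distinct families observed in K independent uniform
##    draws from a pool of S families; L = C(S, P) / S^K.
##  * power-law pool: family i is drawn with probability p_i = A / i^alpha;
##    the expected number of families gained exactly m times is
##    g_m = C(K, m) * sum_i p_i^m (1 - p_i)^(K - m), and the observed
##    multiplicity spectrum O_m is Poisson around g_m, giving
##    ln L ~ sum_m (-g_m + O_m ln g_m).
## K may be non-integer (it is a sum of posterior gain probabilities);
## binomial coefficients use the gamma-function generalisation and are
## always evaluated in log space.

#' Multiplicity spectrum of gene family gains
#'
#' Bins per-family total gain probabilities (sum of branch gain posteriors
#' plus the root-presence posterior) into integer multiplicities: a family
#' with total in `[m - 0.5, m + 0.5)` increments `O_m`. Families with total
#' below 0.5 fall into `O_0` and are excluded from the spectrum. Ancestral
#' families are those with root-presence posterior above 0.5; their count
#' is later added back to the pool-size estimate ([finalize_estimate()]).
#'
#' @details
#' Ancestral families (root posterior > 0.5) are excluded from the binned
#' spectrum and from `K_fit`: their gains predate the group's common
#' ancestor, and counting their root presence as a pool draw while also
#' adding them back afterwards would count them twice. `K` is the full sum
#' over all families (branch gains plus root presence), the quantity
#' conventionally reported alongside `P` and `M`; `K_fit` restricts the
#' sum to non-ancestral families and is what the pool estimators consume.
#'
#' @param x a [posterior_events()] result, or a numeric vector of
#'   per-family total gain probabilities.
#' @param root_posterior optional numeric vector of root-presence
#'   posteriors (used only when `x` is numeric; defaults to zero, so every
#'   family is non-ancestral and `K_fit = K`).
#' @return an object of class `gain_spectrum`: `K` (sum of all totals),
#'   `K_fit` (sum over non-ancestral families), `M` (non-ancestral
#'   families with multiplicity >= 2), `O` (named vector, `O[m]` for
#'   m >= 1, non-ancestral), `n_O0`, `A_ancestral`, `n_families`.
#' @export
build_spectrum <- function(x, root_posterior = NULL) {
  if (inherits(x, "bdi_posteriors")) {
    root_posterior <- x$p_root_present
    totals <- rowSums(x$p_gain) + root_posterior
  } else {
    totals <- as.numeric(x)
    if (is.null(root_posterior)) root_posterior <- rep(0, length(totals))
  }
  if (any(totals < 0)) stop("negative total gain probability")
  ancestral <- root_posterior > 0.5
  tna <- totals[!ancestral]
  m <- floor(tna + 0.5)              # half-open bins [m - 0.5, m + 0.5)
  pos <- m >= 1
  O <- table(m[pos])
  O <- setNames(as.numeric(O), names(O))
  out <- list(
    K = sum(totals),
    K_fit = sum(tna),
    M = sum(O[as.numeric(names(O)) >= 2]),
    O = O,
    n_O0 = sum(!pos),
    A_ancestral = sum(ancestral),
    n_families = length(totals)
  )
  class(out) <- "gain_spectrum"
  out
}

#' @export
print.gain_spectrum <- function(x, ...) {
  cat(sprintf("Gain multiplicity spectrum: K = %.2f (K_fit = %.2f), M = %d, %d families (%d ancestral)\n",
              x$K, x$K_fit, x$M, x$n_families, x$A_ancestral))
  print(x$O)
  invisible(x)
}

## ln L(S) for the uniform pool, valid for real S >= P.
uniform_loglik <- function(S, P, K) {
  lgamma(S + 1) - lgamma(S - P + 1) - lgamma(P + 1) - K * log(S)
}

#' Uniform-pool maximum-likelihood supergenome size
#'
#' Maximises `ln L(S) = ln C(S, P) - K ln S` over real `S >= P` and reports
#' the integer maximiser (the better of floor and ceiling, which equals the
#' exhaustive integer argmax because the log-likelihood is unimodal). The
#' 95% confidence interval is the profile-likelihood region
#' `{S : ln L(S) >= ln L(S_hat) - 1.92}`. The pool is declared open when
#' the likelihood keeps increasing up to `s_cap`, or is within 0.5 log
#' units of its maximum there (a flat profile carries no upper
#' information).
#'
#' @param P number of distinct families discovered (>= 1).
#' @param K total number of gains (> P for a finite estimate; `K < P` is
#'   impossible under the model and raises an error).
#' @param s_cap search cap; pools larger than this are reported open.
#' @param conf_drop log-likelihood drop defining the profile CI
#'   (1.92 = chi-squared(1)/2 at 95%).
#' @return an object of class `supergenome_estimate` with `S`,
#'   `S_continuous`, `ci_low`, `ci_high`, `open`, `P`, `K`.
#' @export
uniform_ml <- function(P, K, s_cap = 1000 * P, conf_drop = 1.92) {
  stopifnot(P >= 1, s_cap > P)
  if (K < P)
    stop("model violation: K (", K, ") < P (", P,
         "): cannot discover more families than draws")
  est <- list(model = "uniform", P = P, K = K, s_cap = s_cap,
              alpha = NA_real_, b = NA_real_)
  dll <- function(S) digamma(S + 1) - digamma(S - P + 1) - K / S
  if (K <= P || dll(s_cap) > 0) {
    ## likelihood non-decreasing through the cap: open pool
    est$open <- TRUE
    est$S <- est$S_continuous <- NA_real_
    est$ci_low <- est$ci_high <- NA_real_
    class(est) <- "supergenome_estimate"
    return(est)
  }
  S_hat <- if (dll(P) <= 0) P else uniroot(dll, c(P, s_cap), tol = 1e-9)$root
  ll_hat <- uniform_loglik(S_hat, P, K)
  ## integer maximiser: floor vs ceiling of the continuous optimum
  cand <- unique(pmax(P, c(floor(S_hat), ceiling(S_hat))))
  S_int <- cand[which.max(uniform_loglik(cand, P, K))]
  est$S_continuous <- S_hat
  est$S <- S_int
  est$open <- uniform_loglik(s_cap, P, K) >= ll_hat - 0.5
  target <- ll_hat - conf_drop
  f <- function(S) uniform_loglik(S, P, K) - target
  est$ci_low <- if (f(P) >= 0) P else uniroot(f, c(P, S_hat), tol = 1e-9)$root
  est$ci_high <- if (f(s_cap) >= 0) Inf
                 else uniroot(f, c(S_hat, s_cap), tol = 1e-9)$root
  est$loglik <- ll_hat
  class(est) <- "supergenome_estimate"
  est
}

## log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

#' Expected number of families gained exactly m times
#'
#' Direct summation of `g_m = C(K, m) sum_i p_i^m (1 - p_i)^(K - m)` for a
#' power-law pool `p_i = A / i^alpha` of size `S`. Vectorised over `m`;
#' `m > K` yields 0. Satisfies `sum_{m=0}^{K} g_m = S` exactly for integer
#' `K` (every pool family falls in exactly one multiplicity class).
#'
#' @param S pool size (positive integer).
#' @param alpha power-law exponent (>= 0; 0 is the uniform pool).
#' @param K number of draws (may be non-integer).
#' @param m multiplicities (vector of non-negative integers).
#' @return numeric vector of expectations, same length as `m`.
#' @export
powerlaw_gm <- function(S, alpha, K, m) {
  stopifnot(S >= 1, alpha >= 0, K >= 0)
  S <- as.integer(round(S))
  lia <- -alpha * log(seq_len(S))
  lp <- lia - logsumexp(lia)
  p <- exp(lp)
  l1p <- log1p(-p)
  vapply(m, function(mm) {
    if (mm > K) return(0)
    lgC <- lgamma(K + 1) - lgamma(mm + 1) - lgamma(K - mm + 1)
    exp(lgC + logsumexp(mm * lp + (K - mm) * l1p))
  }, numeric(1))
}

## Poisson spectrum log-likelihood at integer pool size S.
## ln L = -(S - g_0) + sum_m O_m ln g_m  (the full -sum g_m term uses
## sum_{m>=1} g_m = S - g_0).
powerlaw_loglik <- function(S, alpha, K, m_obs, O_obs) {
  S <- as.integer(round(S))
  lia <- -alpha * log(seq_len(S))
  lp <- lia - logsumexp(lia)
  p <- exp(lp)
  l1p <- log1p(-p)
  g0 <- sum(exp(K * l1p))
  ll <- -(S - g0)
  for (j in seq_along(m_obs)) {
    mm <- m_obs[j]
    if (mm > K) return(-Inf)          # observed multiplicity above K
    lgC <- lgamma(K + 1) - lgamma(mm + 1) - lgamma(K - mm + 1)
    lgm <- lgC + logsumexp(mm * lp + (K - mm) * l1p)
    if (!is.finite(lgm)) return(-Inf)
    ll <- ll + O_obs[j] * lgm
  }
  ll
}

## Golden-section maximisation of f over [lo, hi] (continuous argument).
golden_max <- function(f, lo, hi, tol = 1e-3, max_iter = 60) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  it <- 0
  while (abs(b - a) > tol && it < max_iter) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
    it <- it + 1
  }
  x <- if (f1 > f2) x1 else x2
  list(x = x, value = max(f1, f2))
}

#' Power-law-pool maximum-likelihood supergenome size
#'
#' Maximises the Poisson spectrum likelihood over the pool size `S` and the
#' power-law exponent `alpha`. `alpha` is searched on a grid (default
#' `[0, 3]` in steps of 0.05) and refined by golden section; `S` is
#' maximised by golden section on `log10 S` for each `alpha`, warm-started
#' from the previous exponent's optimum. The pool is declared open when the
#' maximiser hits `s_cap` or the likelihood at `s_cap` is within 0.5 log
#' units of the maximum.
#'
#' @param spectrum a [build_spectrum()] result (or a list with elements
#'   `O` -- named vector of multiplicity counts -- and `K`).
#' @param s_cap search cap for `S`; default 1000 x the number of spectrum
#'   families.
#' @param alpha_grid exponent grid; give a single value to fix `alpha`
#'   (e.g. 0 for the uniform pool).
#' @return an object of class `supergenome_estimate` with `S`, `alpha`,
#'   `open`, `loglik`, `P` (spectrum families), `K`.
#' @export
powerlaw_ml <- function(spectrum, s_cap = NULL,
                        alpha_grid = seq(0, 3, by = 0.05)) {
  O <- spectrum$O
  K <- if (!is.null(spectrum$K_fit)) spectrum$K_fit else spectrum$K
  if (is.null(O) || sum(O) < 1) stop("empty multiplicity spectrum")
  if (K < 1) stop("K must be >= 1")
  m_obs <- as.numeric(names(O))
  O_obs <- as.numeric(O)
  P_spec <- sum(O_obs)
  if (is.null(s_cap)) s_cap <- 1000 * P_spec
  l_lo <- log10(max(P_spec, 1))
  l_hi <- log10(s_cap)

  best <- list(ll = -Inf, S = NA, alpha = NA)
  warm <- NULL
  falling <- 0L
  opt_S <- function(alpha, bracket = c(l_lo, l_hi)) {
    g <- golden_max(function(ls) powerlaw_loglik(10^ls, alpha, K, m_obs,
                                                 O_obs),
                    bracket[1], bracket[2], tol = 5e-4)
    g
  }
  for (alpha in alpha_grid) {
    if (is.null(warm)) {
      ## coarse scan, then golden around the best coarse point
      grid <- seq(l_lo, l_hi, length.out = 12)
      vals <- vapply(grid, function(ls)
        powerlaw_loglik(10^ls, alpha, K, m_obs, O_obs), numeric(1))
      i <- which.max(vals)
      br <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
      g <- opt_S(alpha, br)
    } else {
      br <- c(max(l_lo, warm - 1.5), min(l_hi, warm + 1.5))
      g <- opt_S(alpha, br)
      ## re-expand if the warm bracket pinned the optimum at its edge
      if (g$x >= br[2] - 1e-3 && br[2] < l_hi)
        g <- opt_S(alpha, c(g$x - 0.5, l_hi))
      if (g$x <= br[1] + 1e-3 && br[1] > l_lo)
        g <- opt_S(alpha, c(l_lo, g$x + 0.5))
    }
    warm <- g$x
    if (g$value > best$ll) {
      best <- list(ll = g$value, S = 10^g$x, alpha = alpha, ls = g$x)
      falling <- 0L
    } else if (g$value < best$ll - 100) {
      ## profile likelihood has fallen far off its maximum: larger
      ## exponents only push S toward the cap at great cost, so stop
      falling <- falling + 1L
      if (falling >= 3L) break
    }
  }
  if (length(alpha_grid) > 1) {
    step <- diff(alpha_grid)[1]
    ref <- golden_max(function(a) {
      opt_S(a, c(max(l_lo, best$ls - 1), min(l_hi, best$ls + 1)))$value
    }, max(min(alpha_grid), best$alpha - step),
       min(max(alpha_grid), best$alpha + step), tol = 5e-3)
    if (ref$value > best$ll) {
      g <- opt_S(ref$x, c(max(l_lo, best$ls - 1), min(l_hi, best$ls + 1)))
      best <- list(ll = g$value, S = 10^g$x, alpha = ref$x, ls = g$x)
    }
  }
  ll_cap <- powerlaw_loglik(s_cap, best$alpha, K, m_obs, O_obs)
  open <- best$S >= 0.99 * s_cap || ll_cap >= best$ll - 0.5
  est <- list(model = "power-law", P = P_spec, K = K, s_cap = s_cap,
              S = if (open) NA_real_ else round(best$S),
              S_continuous = best$S,
              alpha = best$alpha, open = open, loglik = best$ll,
              ci_low = NA_real_, ci_high = NA_real_, b = NA_real_)
  class(est) <- "supergenome_estimate"
  est
}

#' Add back ancestral families and convert to genome units
#'
#' Families already present in the root genome were, by assumption, gained
#' before the group's common ancestor existed; their count is added to the
#' pool estimate. `b = S / F` expresses the supergenome in genome units.
#'
#' @param est a [uniform_ml()] or [powerlaw_ml()] result.
#' @param A_ancestral number of ancestral families (root posterior > 0.5).
#' @param F median number of families per genome (> 0).
#' @return the updated `supergenome_estimate`; open estimates pass through
#'   with `b` undefined.
#' @export
finalize_estimate <- function(est, A_ancestral, F) {
  stopifnot(inherits(est, "supergenome_estimate"))
  if (!is.finite(F) || F <= 0) stop("F must be > 0")
  if (isTRUE(est$open)) return(est)
  est$A_ancestral <- A_ancestral
  est$S <- est$S + A_ancestral
  est$S_continuous <- est$S_continuous + A_ancestral
  if (is.finite(est$ci_low)) est$ci_low <- est$ci_low + A_ancestral
  if (is.finite(est$ci_high)) est$ci_high <- est$ci_high + A_ancestral
  est$b <- est$S / F
  est
}

#' @export
print.supergenome_estimate <- function(x, ...) {
  cat(sprintf("Supergenome estimate (%s pool model)\n", x$model))
  if (isTRUE(x$open)) {
    cat("  open supergenome (no finite ML size below the search cap)\n")
  } else {
    cat(sprintf("  S = %d", as.integer(round(x$S))))
    if (is.finite(x$ci_low))
      cat(sprintf("  [95%% profile CI %.0f, %s]", x$ci_low,
                  if (is.finite(x$ci_high)) sprintf("%.0f", x$ci_high)
                  else "open"))
    if (is.finite(x$alpha)) cat(sprintf("  alpha = %.2f", x$alpha))
    if (is.finite(x$b)) cat(sprintf("  b = %.2f genome units", x$b))
    cat("\n")
  }
  cat(sprintf("  inputs: P = %d families, K = %.2f gains\n", x$P, x$K))
  invisible(x)
}
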