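test_that("spectrum binning follows the half-open rule", {
  sp <- build_spectrum(c(1.2, 0.4, 2.6, 1.5))
  expect_equal(unname(sp$O[c("1", "2", "3")]), c(1, 1, 1))
  expect_equal(sp$n_O0, 1)
  expect_equal(sp$K, 5.7)
  expect_equal(sp$K_fit, 5.7)
  expect_equal(sp$M, 2)

  ## all totals exactly 1 -> O_1 = P, no multiples
  sp1 <- build_spectrum(rep(1, 7))
  expect_equal(unname(sp1$O["1"]), 7)
  expect_equal(sp1$M, 0)

  ## ancestral families are counted but excluded from the fitted spectrum
  sp2 <- build_spectrum(c(1.2, 1.1, 2.0), root_posterior = c(0.9, 0.1, 0.8))
  expect_equal(sp2$A_ancestral, 2)
  expect_equal(unname(sp2$O["1"]), 1)
  expect_equal(sp2$K, 4.3)
  expect_equal(sp2$K_fit, 1.1)
  expect_error(build_spectrum(c(-0.1, 1)), "negative")
})

test_that("spectrum matches the simulator's true multiplicities at shallow depth", {
  sim <- simulate_dataset(simulation_config(
    n_leaves = 15, depth = 0.004, S_true = 600, kappa = 12000, lambda = 0.2,
    mu = 25, root_families = 350, seed = 13))
  fit <- fit_bdi(sim$matrix, sim$tree)
  post <- posterior_events(fit, sim$matrix, sim$tree)
  totals <- rowSums(post$p_gain) + post$p_root_present
  truth_mult <- sim$truth$gain_multiplicity[rownames(sim$matrix)] +
    as.integer(rownames(sim$matrix) %in% sim$truth$ancestral)
  agree <- abs(totals - truth_mult) <= 1
  expect_gte(mean(agree), 0.95)
})

test_that("uniform pool estimator agrees with its oracles", {
  expect_error(uniform_ml(10, 8), "model violation")
  expect_true(uniform_ml(10, 10)$open)       # K = P: no repeats

  ## P = 3, K = 5 against a brute-force scan over 3..1e6
  e <- uniform_ml(3, 5, s_cap = 1e6)
  expect_false(e$open)
  expect_equal(e$S, uniform_scan_argmax(3, 5, 1e6))

  ## spot checks across the (P, K) plane (full grid in acceptance)
  for (pk in list(c(5, 9), c(20, 30), c(50, 70), c(37, 150))) {
    e <- uniform_ml(pk[1], pk[2])
    s <- uniform_scan_argmax(pk[1], pk[2])
    if (!e$open) expect_equal(e$S, s)
  }

  ## published-scale inputs against an independent digamma bisection
  P <- 24845; K <- 38293
  f <- function(S) digamma(S + 1) - digamma(S - P + 1) - K / S
  lo <- P; hi <- 1e9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  e <- uniform_ml(P, K)
  expect_equal(e$S_continuous, (lo + hi) / 2, tolerance = 1e-6)
  expect_false(e$open)
  expect_true(e$ci_low < e$S && e$S < e$ci_high)

  ## unimodality of ln L for K > P (exhaustive over a sample of pairs)
  for (pk in list(c(4, 7), c(12, 20), c(33, 60))) {
    S <- pk[1]:(200 * pk[1])
    ll <- lgamma(S + 1) - lgamma(S - pk[1] + 1) - pk[2] * log(S)
    d <- diff(ll)
    expect_lte(sum(diff(sign(d[d != 0])) != 0), 1)  # one sign change
  }
})

test_that("power-law machinery: normalisation, consistency, monotonicity", {
  ## sum_{m=0..K} g_m = S exactly (integer K)
  g <- powerlaw_gm(200, 1, 50, 0:50)
  expect_equal(sum(g), 200, tolerance = 1e-6 * 200)
  g0 <- powerlaw_gm(120, 0, 40, 0:40)
  expect_equal(sum(g0), 120, tolerance = 1e-6 * 120)

  ## alpha = 0 reduces to the uniform pool
  set.seed(3)
  draws <- sample.int(800, 2400, replace = TRUE)
  tab <- table(table(draws))
  sp <- list(O = setNames(as.numeric(tab), names(tab)), K = 2400)
  e0 <- powerlaw_ml(sp, alpha_grid = 0)
  eu <- uniform_ml(length(unique(draws)), 2400)
  expect_false(e0$open)
  expect_lt(abs(e0$S / eu$S - 1), 0.05)

  ## more multiples at fixed P and K never increase the pool estimate
  spA <- list(O = c("1" = 16, "2" = 2), K = 21)
  spB <- list(O = c("1" = 12, "2" = 6), K = 21)
  eA <- powerlaw_ml(spA, alpha_grid = 0, s_cap = 1e5)
  eB <- powerlaw_ml(spB, alpha_grid = 0, s_cap = 1e5)
  expect_lte(eB$S_continuous, eA$S_continuous)

  ## no repeats -> open
  expect_true(powerlaw_ml(list(O = c("1" = 300), K = 300))$open)
  expect_error(powerlaw_ml(list(O = numeric(0), K = 10)), "empty")
})

test_that("power-law recovery on multinomial draws (light version)", {
  res <- t(sapply(1:3, function(seed) {
    set.seed(seed)
    p <- (1:500)^-1; p <- p / sum(p)
    draws <- sample.int(500, 5000, replace = TRUE, prob = p)
    tab <- table(table(draws))
    e <- powerlaw_ml(list(O = setNames(as.numeric(tab), names(tab)),
                          K = 5000))
    c(e$S_continuous, e$alpha)
  }))
  expect_lt(abs(median(res[, 1]) / 500 - 1), 0.25)
  expect_lt(abs(median(res[, 2]) - 1), 0.3)
})

test_that("finalize_estimate adds ancestral families and genome units", {
  e <- uniform_ml(400, 700)
  raw_S <- e$S
  fin <- finalize_estimate(e, A_ancestral = 200, F = 400)
  expect_equal(fin$S, raw_S + 200)
  expect_equal(fin$b, fin$S / 400)
  expect_equal(fin$ci_low, e$ci_low + 200)
  expect_error(finalize_estimate(e, 10, 0), "F must be")

  op <- uniform_ml(10, 10)
  fin2 <- finalize_estimate(op, 5, 100)
  expect_true(fin2$open)
  expect_true(is.na(fin2$b))

  ## worked arithmetic: S_hat 1000 + 200 ancestral at F = 400 -> b = 3
  fake <- structure(list(model = "uniform", S = 1000, S_continuous = 1000,
                         ci_low = 900, ci_high = 1100, open = FALSE,
                         P = 800, K = 1200, b = NA_real_),
                    class = "supergenome_estimate")
  expect_equal(finalize_estimate(fake, 200, 400)$b, 3)
})
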