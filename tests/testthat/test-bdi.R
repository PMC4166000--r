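test_that("transition matrix: identity at t = 0 and pure-death closed form", {
  m <- bdi_model(kappa = 3, lambda = 2, mu = 15, n_max = 4)
  expect_equal(transition_matrix(m, 0), diag(5), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(transition_matrix(m, -1), ">= 0")

  ## kappa = lambda = 0: each copy survives independently with
  ## probability exp(-mu t)
  pd <- bdi_model(kappa = 0, lambda = 0, mu = 2, n_max = 5)
  P <- transition_matrix(pd, 0.3)
  sv <- exp(-2 * 0.3)
  for (n in 1:5) for (k in 0:n)
    expect_equal(P[n + 1, k + 1], dbinom(k, n, sv), tolerance = 1e-9)
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
})

test_that("transition matrix matches event-by-event simulation", {
  m <- bdi_model(kappa = 2, lambda = 1.5, mu = 4, n_max = 12)
  t_end <- 0.25
  P <- transition_matrix(m, t_end)
  n_rep <- 20000
  for (n0 in c(0L, 2L)) {
    sim <- gillespie_single(n0, 2, 1.5, 4, t_end, n_rep, seed = 40 + n0)
    for (k in 0:6) {
      p_hat <- mean(sim == k)
      se <- sqrt(max(p_hat * (1 - p_hat), 1e-6) / n_rep)
      expect_lt(abs(P[n0 + 1, k + 1] - p_hat), 3 * se + 1e-4)
    }
  }
})

test_that("pruning likelihood equals enumeration on small trees", {
  trees <- list(
    parse_newick("(A:0.03,B:0.08);"),
    parse_newick("((A:0.02,B:0.05):0.03,C:0.04);"),
    toy_tree(),                                            # balanced 4-leaf
    parse_newick("(((A:0.02,B:0.03):0.02,C:0.04):0.01,D:0.06);")
  )
  params <- list(c(3, 2, 15), c(0.5, 0.1, 40))
  for (tr in trees) {
    tips <- tr$tip.label
    set.seed(7)
    counts <- matrix(sample(0:3, 3 * length(tips), replace = TRUE),
                     3, length(tips), dimnames = list(paste0("F", 1:3), tips))
    counts[rowSums(counts) == 0, 1] <- 1L
    for (pp in params) {
      model <- bdi_model(pp[1], pp[2], pp[3], n_max = 3)
      sk <- panflux:::tree_skeleton(tr)
      got <- panflux:::pruning_loglik(pp[1], pp[2], pp[3], 3, sk,
                                      counts[, sk$tree$tip.label],
                                      condition = TRUE)
      want <- enum_loglik_conditioned(model, tr, counts)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("posterior events equal enumeration on a 3-leaf tree", {
  tr <- parse_newick("((A:0.02,B:0.05):0.03,C:0.04);")
  counts <- rbind(F1 = c(A = 1, B = 0, C = 2), F2 = c(0, 2, 0),
                  F3 = c(1, 1, 1))
  mat <- phyletic_matrix(counts)
  model <- bdi_model(2, 1, 20, n_max = 2)
  model$root_prior <- "stationary"
  post <- posterior_events(model, mat, tr)
  for (f in 1:3) {
    oracle <- enum_posteriors(model, tr, counts[f, ])
    expect_equal(unname(post$p_gain[f, ]), oracle$p_gain, tolerance = 1e-9)
    expect_equal(unname(post$p_loss[f, ]), oracle$p_loss, tolerance = 1e-9)
    expect_equal(unname(post$p_expansion[f, ]), oracle$p_expansion,
                 tolerance = 1e-9)
    expect_equal(unname(post$p_reduction[f, ]), oracle$p_reduction,
                 tolerance = 1e-9)
    expect_equal(unname(post$p_root_present[f]), oracle$p_root_present,
                 tolerance = 1e-9)
  }
  ## probability bounds
  expect_true(all(post$p_gain >= 0 & post$p_gain <= 1))
  expect_true(all(post$p_gain + post$p_loss <= 1 + 1e-12))
})

test_that("posterior limits: singletons and universal families", {
  tr <- generate_tree(10, 0.002, seed = 21)
  counts <- matrix(0L, 2, 10,
                   dimnames = list(c("sing", "univ"), tr$tip.label))
  counts["sing", 1] <- 1L
  counts["univ", ] <- 1L
  mat <- phyletic_matrix(counts)
  model <- bdi_model(kappa = 1, lambda = 0.1, mu = 5, n_max = 3)
  model$root_prior <- "stationary"
  post <- posterior_events(model, mat, tr)
  term <- which(post$branches$terminal &
                  post$branches$child ==
                    which(post$tree$tip.label == tr$tip.label[1]))
  expect_gt(post$p_gain["sing", term], 0.95)
  expect_lt(max(post$p_gain["sing", -term]), 0.05)
  expect_gt(post$p_root_present["univ"], 0.99)
})

test_that("posteriors are invariant to family and genome order", {
  tr <- toy_tree()
  mat <- toy_matrix()
  model <- bdi_model(2, 1, 15, n_max = 4)
  model$root_prior <- "stationary"
  p1 <- posterior_events(model, mat, tr)
  perm <- unclass(mat)[c(3, 1, 4, 2), c("C", "A", "D", "B")]
  p2 <- posterior_events(model, phyletic_matrix(perm), tr)
  expect_equal(p2$p_gain[rownames(p1$p_gain), ], p1$p_gain,
               tolerance = 1e-12)
  expect_equal(p2$p_root_present[names(p1$p_root_present)],
               p1$p_root_present, tolerance = 1e-12)
})

test_that("fit_bdi: toy log-likelihood matches enumeration; no-loss limit", {
  tr <- parse_newick("((A:0.05,B:0.08):0.04,C:0.1);")
  counts <- rbind(F1 = c(A = 1, B = 1, C = 0), F2 = c(2, 0, 1))
  mat <- phyletic_matrix(counts)
  fit <- fit_bdi(mat, tr, n_max = 4)
  model <- bdi_model(fit$kappa, fit$lambda, fit$mu, 4)
  want <- sum(enum_loglik_conditioned(model, tr, counts))
  expect_equal(fit$loglik, want, tolerance = 1e-8)

  ## every family everywhere at copy 1: loss rate driven to the bound
  u <- matrix(1L, 30, 5, dimnames = list(paste0("F", 1:30),
                                         paste0("g", 1:5)))
  tru <- generate_tree(5, 0.05, seed = 2)
  fit2 <- fit_bdi(phyletic_matrix(u[, tru$tip.label, drop = FALSE] * 0 + 1L),
                  tru, n_max = 3)
  expect_lt(fit2$mu, 1e-3)   # effectively zero against mu ~ O(10) scales
})

test_that("fit and posteriors reject inconsistent inputs", {
  tr <- toy_tree()
  mat <- toy_matrix()
  bad <- unclass(mat); colnames(bad) <- c("A", "B", "C", "X")
  expect_error(fit_bdi(phyletic_matrix(bad), tr), "only in matrix")
  expect_error(fit_bdi(mat, tr, n_max = 2), "raise n_max")
  m <- bdi_model(1, 1, 1, n_max = 2)
  expect_error(posterior_events(m, mat, tr), "raise n_max")
})

test_that("two-category model: multipliers average to 1 and fit runs", {
  expect_equal(mean(gamma_multipliers(0.7)), 1)
  expect_equal(mean(gamma_multipliers(3)), 1)
  expect_lt(gamma_multipliers(1)[1], 1)
  tr <- toy_tree()
  fit <- fit_bdi(toy_matrix(), tr, n_max = 4, n_categories = 2)
  expect_s3_class(fit, "bdi_model")
  expect_true(is.finite(fit$loglik))
  ## mixture can only improve on the 1-category optimum
  fit1 <- fit_bdi(toy_matrix(), tr, n_max = 4)
  expect_gte(fit$loglik, fit1$loglik - 1e-6)
  post <- posterior_events(fit, toy_matrix(), tr)
  expect_true(all(post$p_gain >= 0 & post$p_gain <= 1))
})

test_that("count_events sums posteriors and tracks singleton gains", {
  tr <- toy_tree()
  model <- bdi_model(2, 1, 15, n_max = 4)
  model$root_prior <- "stationary"
  post <- posterior_events(model, toy_matrix(), tr)
  tot <- count_events(post)
  expect_equal(unname(tot$totals["gain"]), sum(post$p_gain))
  expect_equal(sum(tot$per_branch$gains), unname(tot$totals["gain"]))
  expect_true(all(tot$per_branch$gains_excl_singletons <=
                    tot$per_branch$gains + 1e-12))
  expect_equal(tot$total_gain_probability,
               rowSums(post$p_gain) + post$p_root_present)
  ## a zeroed posterior gives zero totals
  post0 <- post
  for (f in c("p_gain", "p_loss", "p_expansion", "p_reduction"))
    post0[[f]][] <- 0
  expect_true(all(count_events(post0)$totals == 0))
})
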