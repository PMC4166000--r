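## Helper: minimal event_totals object built directly from per-branch
## counts (bypasses inference; valid because compute_rate_table and
## genomic_clock only contract on the event_totals fields).
fake_totals <- function(lengths, gains, losses = gains, expansions = gains,
                        reductions = gains, terminal = NULL) {
  nb <- length(lengths)
  if (is.null(terminal)) terminal <- rep(FALSE, nb)
  pb <- data.frame(branch = paste0("b", seq_len(nb)), parent = NA,
                   child = NA, length = lengths, terminal = terminal,
                   midpoint_depth = cumsum(lengths) / 2,
                   gains = gains, losses = losses, expansions = expansions,
                   reductions = reductions,
                   gains_excl_singletons = gains)
  structure(list(per_branch = pb,
                 totals = c(gain = sum(gains), loss = sum(losses),
                            expansion = sum(expansions),
                            reduction = sum(reductions)),
                 tree_length = sum(lengths)),
            class = "event_totals")
}

test_that("rate table arithmetic and the published-row example", {
  ## event totals scaled to a unit tree: per-site rates equal the totals
  tot <- c(gain = 18563, loss = 50517, expansion = 1864, reduction = 4405)
  tr <- parse_newick("(A:0.5,B:0.5);")
  rt <- compute_rate_table(tot, tr, mean_gene_length_nt = 1073)
  expect_equal(unname(rt$rate_site), unname(tot))
  expect_equal(rt$rate_gene[["gain"]], 17.3, tolerance = 0.005)
  expect_equal(rt$flux_site, 75349)
  expect_equal(rt$balance, (18563 + 1864) / (50517 + 4405),
               tolerance = 1e-12)

  ## per-gene conversion never changes ratios between event types
  expect_equal(rt$rate_gene / rt$rate_gene[["gain"]],
               rt$rate_site / rt$rate_site[["gain"]], tolerance = 1e-12)

  ## linearity in the totals
  rt2 <- compute_rate_table(3 * tot, tr, mean_gene_length_nt = 1073)
  expect_equal(unname(rt2$rate_site), unname(3 * rt$rate_site))

  ## degenerate inputs
  expect_warning(
    rt0 <- compute_rate_table(c(gain = 0, loss = 0, expansion = 0,
                                reduction = 0), tr, 1000),
    "balance undefined")
  expect_true(is.nan(rt0$balance))
  expect_error(compute_rate_table(tot, parse_newick("(A:0,B:0);"), 1000),
               "> 0")
  expect_error(compute_rate_table(tot, tr, 0), "mean_gene_length_nt")
})

test_that("genomic clock: monotone limit and simulated positive clock", {
  ## events exactly proportional to branch length -> rho = 1
  lens <- seq(0.001, 0.02, length.out = 12)
  tot <- fake_totals(lens, gains = 1000 * lens)
  clk <- genomic_clock(tot, n_perm = 500, seed = 3)
  expect_true(all(clk$rho == 1))
  expect_true(all(clk$p_value < 0.05))
  expect_equal(clk$slope, rep(1, 4), tolerance = 1e-9)
  expect_error(genomic_clock(fake_totals(c(1, 2), gains = c(1, 2))),
               "3 branches")

  ## constant-rate simulation: all four types correlate with length
  sim <- simulate_dataset(simulation_config(
    n_leaves = 40, depth = 0.02, S_true = 1500, kappa = 6000, lambda = 2,
    mu = 10, root_families = 700, seed = 17))
  tb <- sim$truth$per_branch
  tot2 <- fake_totals(tb$length, gains = tb$gains, losses = tb$losses,
                      expansions = tb$expansions,
                      reductions = tb$reductions)
  clk2 <- genomic_clock(tot2, exclude_terminal_singleton_gains = FALSE,
                        n_perm = 2000, seed = 5)
  expect_true(all(clk2$rho > 0))
  expect_true(all(clk2$p_value < 0.01))
})

test_that("genomic clock permutation P is calibrated under the null", {
  set.seed(99)
  n <- 15
  hits <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    tot <- fake_totals(runif(n, 0.001, 0.02), gains = runif(n, 1, 100))
    p <- genomic_clock(tot, n_perm = 400, seed = r)$p_value[1]
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.01)
  expect_lte(hits / n_rep, 0.10)
})

test_that("depth dependence: flat and closed-form power-law cases", {
  depths <- 10^seq(-4, -1, length.out = 20)
  flat <- depth_dependence(rep(2.5, 20), depths)
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$percent_at(0.05), 100, tolerance = 1e-9)

  dd <- depth_dependence(depths^(-0.1), depths)
  expect_equal(dd$slope, -0.1, tolerance = 1e-9)
  expect_equal(dd$percent_at(0.1), 100 * (0.1 / 1e-4)^(-0.1),
               tolerance = 1e-6)
  expect_equal(dd$percent_at(0.1), 50.1, tolerance = 0.01)
  expect_error(depth_dependence(c(1, 2), c(-1, 1)), "positive")
})

test_that("category flux recovers a planted mobile-element signal", {
  tr <- generate_tree(8, 0.01, seed = 31)
  nb <- nrow(tr$edge)
  nf <- 60
  fam <- sprintf("F%03d", seq_len(nf))
  ## fabricate posteriors: families 1..10 ("X", mobilome) gain 10x more
  base <- matrix(0.02, nf, nb, dimnames = list(fam, paste0("b", 1:nb)))
  base[1:10, ] <- 0.2
  post <- structure(list(
    p_gain = base, p_loss = base * 0.5, p_expansion = base * 0.1,
    p_reduction = base * 0.05,
    p_root_present = setNames(rep(0.4, nf), fam),
    branches = data.frame(branch = paste0("b", 1:nb),
                          length = tr$edge.length,
                          terminal = tr$edge[, 2] <= 8),
    singleton = rep(FALSE, nf), family_ids = fam, tree = tr),
    class = "bdi_posteriors")
  cats <- setNames(rep(c("X", "J", "R"), c(10, 25, 25)), fam)
  cf <- category_flux(post, cats)
  expect_equal(cf$category[1], "X")          # mobilome ranks first
  expect_gt(cf$gain[cf$category == "X"], 5 * cf$gain[cf$category == "J"])

  ## a single category reproduces the whole-dataset per-gene rates
  one <- category_flux(post, setNames(rep("Q", nf), fam))
  T_tot <- sum(tr$edge.length)
  expect_equal(one$gain, sum(base) / T_tot / nf, tolerance = 1e-12)

  ## zero-gene categories are dropped with a warning
  expect_warning(
    cf2 <- category_flux(post, cats,
                         genes_per_category = c(X = 10, J = 25, R = 0)),
    "zero genes")
  expect_false("R" %in% cf2$category)
})
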