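## Independent oracles used across the suite. These deliberately avoid the
## package's fast code paths: enumeration instead of pruning, event-by-event
## simulation instead of matrix exponentials, exhaustive scans instead of
## root finding.

## Sum over all internal-node state assignments of
## prior(root) * prod_edges P[s_parent, s_child]; the likelihood of one
## family's leaf counts by direct enumeration.
enum_family_loglik <- function(model, tree, counts_row,
                               root_prior = "stationary") {
  sk <- panflux:::tree_skeleton(tree)
  k <- model$n_max + 1L
  prior <- if (identical(root_prior, "uniform")) rep(1 / k, k) else
    panflux:::bdi_stationary(model$kappa, model$lambda, model$mu,
                             model$n_max)
  mats <- lapply(sk$lens, function(l) transition_matrix(model, l))
  internals <- sort(unique(sk$parent))
  grids <- do.call(expand.grid, rep(list(0:model$n_max), length(internals)))
  tot <- 0
  for (g in seq_len(nrow(grids))) {
    st <- integer(sk$n_node)
    st[internals] <- as.integer(grids[g, ])
    st[seq_len(sk$n_tip)] <- counts_row[sk$tree$tip.label]
    pr <- prior[st[sk$root] + 1]
    for (e in seq_along(sk$lens))
      pr <- pr * mats[[e]][st[sk$parent[e]] + 1, st[sk$child[e]] + 1]
    tot <- tot + pr
  }
  log(tot)
}

## Conditioned (ascertainment-corrected) enumeration log-likelihood.
enum_loglik_conditioned <- function(model, tree, counts,
                                    root_prior = "stationary") {
  zero <- setNames(rep(0L, ape::Ntip(tree)), tree$tip.label)
  l0 <- enum_family_loglik(model, tree, zero, root_prior)
  vapply(seq_len(nrow(counts)), function(f)
    enum_family_loglik(model, tree, counts[f, ], root_prior) -
      log1p(-exp(l0)), numeric(1))
}

## Posterior event probabilities by enumeration (the same sum, tracking
## per-branch endpoint transitions).
enum_posteriors <- function(model, tree, counts_row,
                            root_prior = "stationary") {
  sk <- panflux:::tree_skeleton(tree)
  k <- model$n_max + 1L
  prior <- if (identical(root_prior, "uniform")) rep(1 / k, k) else
    panflux:::bdi_stationary(model$kappa, model$lambda, model$mu,
                             model$n_max)
  mats <- lapply(sk$lens, function(l) transition_matrix(model, l))
  internals <- sort(unique(sk$parent))
  grids <- do.call(expand.grid, rep(list(0:model$n_max), length(internals)))
  nb <- length(sk$lens)
  pg <- pl <- pe <- pr2 <- numeric(nb)
  prp <- 0; Z <- 0
  for (g in seq_len(nrow(grids))) {
    st <- integer(sk$n_node)
    st[internals] <- as.integer(grids[g, ])
    st[seq_len(sk$n_tip)] <- counts_row[sk$tree$tip.label]
    w <- prior[st[sk$root] + 1]
    for (e in seq_len(nb))
      w <- w * mats[[e]][st[sk$parent[e]] + 1, st[sk$child[e]] + 1]
    Z <- Z + w
    if (st[sk$root] >= 1) prp <- prp + w
    for (e in seq_len(nb)) {
      s <- st[sk$parent[e]]; t <- st[sk$child[e]]
      if (s == 0 && t >= 1) pg[e] <- pg[e] + w
      if (s >= 1 && t == 0) pl[e] <- pl[e] + w
      if (s >= 1 && t > s) pe[e] <- pe[e] + w
      if (s >= 1 && t >= 1 && t < s) pr2[e] <- pr2[e] + w
    }
  }
  list(p_gain = pg / Z, p_loss = pl / Z, p_expansion = pe / Z,
       p_reduction = pr2 / Z, p_root_present = prp / Z)
}

## Event-by-event simulation of the single-family birth-and-death process;
## oracle for transition_matrix().
gillespie_single <- function(n0, kappa, lambda, mu, t_end, n_rep,
                             seed = 1L) {
  set.seed(seed)
  vapply(seq_len(n_rep), function(r) {
    n <- n0; t <- 0
    repeat {
      up <- kappa + n * lambda
      down <- n * mu
      tot <- up + down
      if (tot <= 0) break
      t <- t + rexp(1, tot)
      if (t > t_end) break
      n <- if (runif(1) * tot < up) n + 1L else n - 1L
    }
    n
  }, integer(1))
}

## Exhaustive integer scan for the uniform-pool ML pool size.
uniform_scan_argmax <- function(P, K, s_max = 1000L * P) {
  S <- P:s_max
  ll <- lgamma(S + 1) - lgamma(S - P + 1) - K * log(S)
  S[which.max(ll)]
}

## Brute-force grid search for the least-squares midpoint root: variance
## of root-to-leaf distances over candidate points along every edge.
grid_midpoint_var <- function(tree, n_grid = 10000) {
  adj <- panflux:::tree_adjacency(tree)
  n_tip <- ape::Ntip(tree)
  best <- Inf
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]; len <- tree$edge.length[i]
    reach <- panflux:::node_distances(adj, v, blocked = c(u, v))
    side_v <- which(!is.na(reach[seq_len(n_tip)]))
    side_u <- setdiff(seq_len(n_tip), side_v)
    du <- panflux:::node_distances(adj, u)
    dv <- panflux:::node_distances(adj, v)
    for (x in seq(0, len, length.out = max(2, round(n_grid * len /
                                                      sum(tree$edge.length))))) {
      d <- c(dv[side_v] + x, du[side_u] + len - x)
      vr <- mean((d - mean(d))^2)
      if (vr < best) best <- vr
    }
  }
  best
}

## Small deterministic fixture: rooted 4-leaf tree and copy-number matrix.
toy_tree <- function() parse_newick(
  "((A:0.02,B:0.05):0.01,(C:0.03,D:0.04):0.02);")

toy_matrix <- function() {
  m <- rbind(F1 = c(1, 0, 2, 1), F2 = c(1, 1, 1, 1),
             F3 = c(0, 0, 0, 3), F4 = c(2, 1, 0, 1))
  colnames(m) <- c("A", "B", "C", "D")
  phyletic_matrix(m)
}
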