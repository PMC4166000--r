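## Gain--loss--duplication birth-and-death model of gene family copy-number
## evolution. A family of size n dies at rate n*mu and grows at rate
## kappa + n*lambda: kappa is the family gain (immigration) intensity,
## lambda the per-copy duplication intensity, mu the per-copy loss
## intensity, all per unit branch length (nucleotide substitutions per
## site). The copy-number state space is truncated at n_max and transition
## probabilities are obtained from the matrix exponential of the truncated
## generator.

#' Birth-and-death model of gene family copy number
#'
#' @param kappa family gain intensity per unit branch length (>= 0).
#' @param lambda per-copy duplication intensity (>= 0).
#' @param mu per-copy loss intensity (>= 0).
#' @param n_max copy-number truncation bound (>= 1). Observed copy numbers
#'   above `n_max` are an error; raise `n_max` instead.
#' @param n_categories 1 (homogeneous) or 2 (a two-point discrete-gamma
#'   family-rate multiplier shared by all three intensities; see
#'   [gamma_multipliers()]).
#' @param gamma_shape shape of the discrete gamma when `n_categories == 2`.
#' @return an object of class `bdi_model`.
#' @export
bdi_model <- function(kappa, lambda, mu, n_max,
                      n_categories = 1L, gamma_shape = NA_real_) {
  stopifnot(kappa >= 0, lambda >= 0, mu >= 0, n_max >= 1)
  n_categories <- as.integer(n_categories)
  if (!n_categories %in% c(1L, 2L)) stop("n_categories must be 1 or 2")
  if (n_categories == 2L && (!is.finite(gamma_shape) || gamma_shape <= 0))
    stop("n_categories = 2 requires a positive gamma_shape")
  structure(list(kappa = kappa, lambda = lambda, mu = mu,
                 n_max = as.integer(n_max),
                 n_categories = n_categories, gamma_shape = gamma_shape),
            class = "bdi_model")
}

#' @export
print.bdi_model <- function(x, ...) {
  cat("Gain-loss-duplication birth-and-death model\n")
  cat(sprintf("  kappa (gain): %.6g   lambda (duplication): %.6g   mu (loss): %.6g\n",
              x$kappa, x$lambda, x$mu))
  cat(sprintf("  n_max: %d   rate categories: %d\n", x$n_max, x$n_categories))
  if (!is.null(x$loglik))
    cat(sprintf("  log-likelihood: %.4f (%d families)\n", x$loglik,
                x$n_families))
  invisible(x)
}

#' Means of equal-probability discrete gamma bins
#'
#' Two-category family-rate multipliers: the means of the lower and upper
#' halves of a Gamma(shape, shape) distribution (mean 1). The multipliers
#' average to 1 by construction.
#'
#' @param shape gamma shape parameter (> 0).
#' @return numeric vector of length 2.
#' @export
gamma_multipliers <- function(shape) {
  stopifnot(shape > 0)
  q50 <- qgamma(0.5, shape, rate = shape)
  lower <- pgamma(q50, shape + 1, rate = shape) / 0.5
  c(lower, 2 - lower)
}

## Truncated generator over states 0..n_max.
bdi_generator <- function(kappa, lambda, mu, n_max) {
  k <- n_max + 1L
  Q <- matrix(0, k, k)
  n <- 0:(n_max - 1L)
  Q[cbind(n + 1L, n + 2L)] <- kappa + n * lambda       # n -> n + 1
  n <- 1:n_max
  Q[cbind(n + 1L, n)] <- n * mu                        # n -> n - 1
  diag(Q) <- -rowSums(Q)
  Q
}

## Transition matrices for a set of branch lengths, via one eigen
## decomposition of the generator (the generator is shared by all
## branches). Falls back to Matrix::expm when the eigenbasis is
## ill-conditioned. Rows are clamped to [0, 1] and renormalised to absorb
## truncation error.
bdi_branch_matrices <- function(kappa, lambda, mu, n_max, lens) {
  Q <- bdi_generator(kappa, lambda, mu, n_max)
  k <- ncol(Q)
  mats <- vector("list", length(lens))
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  ok <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      ok <- TRUE
      for (i in seq_along(lens)) {
        P <- Re(eg$vectors %*% (exp(eg$values * lens[i]) * Vi))
        if (max(abs(rowSums(P) - 1)) > 1e-6 || min(P) < -1e-6) {
          ok <- FALSE
          break
        }
        mats[[i]] <- P
      }
    }
  }
  if (!ok) {
    for (i in seq_along(lens))
      mats[[i]] <- as.matrix(Matrix::expm(Q * lens[i]))
  }
  lapply(mats, function(P) {
    P[P < 0] <- 0
    P / rowSums(P)
  })
}

#' Copy-number transition matrix
#'
#' Probability of moving from copy number `n` (row) to `k` (column) over a
#' branch of length `t`, under the truncated generator with off-diagonals
#' `Q[n, n+1] = kappa + n*lambda` and `Q[n, n-1] = n*mu`. Rows are
#' renormalised after truncation and sum to 1 within 1e-9.
#'
#' @param model a [bdi_model()].
#' @param t branch length (>= 0), substitutions per site.
#' @return a `(n_max + 1) x (n_max + 1)` row-stochastic matrix with
#'   dimnames `0:n_max`.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "bdi_model"))
  if (!is.finite(t) || t < 0) stop("branch length t must be >= 0")
  P <- bdi_branch_matrices(model$kappa, model$lambda, model$mu,
                           model$n_max, t)[[1]]
  dimnames(P) <- list(0:model$n_max, 0:model$n_max)
  P
}

## Stationary distribution of the truncated chain (detailed balance:
## pi_{n+1}/pi_n = (kappa + n*lambda) / ((n+1)*mu)). Degenerates to the
## point mass at 0 when kappa = 0 and to uniform when mu = 0.
bdi_stationary <- function(kappa, lambda, mu, n_max) {
  k <- n_max + 1L
  if (mu <= 0) return(rep(1 / k, k))
  lw <- cumsum(c(0, log(pmax(kappa + (0:(n_max - 1L)) * lambda, 0)) -
                   log((1:n_max) * mu)))
  lw[!is.finite(lw)] <- -Inf
  w <- exp(lw - max(lw))
  w / sum(w)
}

## Postorder pruning skeleton shared by the likelihood and the posterior
## pass. Returns the reordered tree plus convenience indexes.
tree_skeleton <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  n_tip <- ape::Ntip(po)
  list(tree = po, n_tip = n_tip,
       n_node = n_tip + po$Nnode,
       root = po$edge[nrow(po$edge), 1],
       parent = po$edge[, 1], child = po$edge[, 2],
       lens = po$edge.length,
       terminal = po$edge[, 2] <= n_tip)
}

## Column maxima of a small-row-count matrix.
col_max <- function(m) {
  cm <- m[1, ]
  if (nrow(m) > 1) for (r in 2:nrow(m)) cm <- pmax(cm, m[r, ])
  cm
}

## Felsenstein pruning over copy-number states, vectorised over families.
## counts: families x tips matrix aligned to sk$tree$tip.label.
## Returns log-likelihood per family (log P(leaf counts | params)).
## With condition = TRUE the likelihood is conditioned on presence in at
## least one leaf (observed matrices never contain all-absent families).
pruning_loglik <- function(kappa, lambda, mu, n_max, sk, counts,
                           root_prior = "stationary", condition = TRUE,
                           mats = NULL) {
  k <- n_max + 1L
  nf <- nrow(counts)
  if (is.null(mats))
    mats <- bdi_branch_matrices(kappa, lambda, mu, n_max, sk$lens)
  prior <- if (identical(root_prior, "uniform")) rep(1 / k, k)
           else bdi_stationary(kappa, lambda, mu, n_max)
  ## append the all-absent pseudo-family used for the ascertainment term
  F_all <- nf + 1L
  L <- vector("list", sk$n_node)
  logsc <- rep(0, F_all)
  node_logsc <- vector("list", sk$n_node)
  tipL <- function(tip) {
    m <- matrix(0, k, F_all)
    m[cbind(counts[, tip] + 1L, seq_len(nf))] <- 1
    m[1L, F_all] <- 1
    m
  }
  for (e in seq_along(sk$lens)) {
    v <- sk$child[e]; u <- sk$parent[e]
    Lv <- if (v <= sk$n_tip) tipL(v) else L[[v]]
    sc_v <- if (v <= sk$n_tip) rep(0, F_all) else node_logsc[[v]]
    M <- mats[[e]] %*% Lv
    if (is.null(L[[u]])) {
      L[[u]] <- M
      node_logsc[[u]] <- sc_v
    } else {
      L[[u]] <- L[[u]] * M
      node_logsc[[u]] <- node_logsc[[u]] + sc_v
      cm <- col_max(L[[u]])
      pos <- cm > 0
      cm[!pos] <- 1
      L[[u]] <- sweep(L[[u]], 2, cm, "/")
      node_logsc[[u]] <- node_logsc[[u]] + log(cm)
    }
  }
  Z <- colSums(prior * L[[sk$root]])
  ll <- log(Z) + node_logsc[[sk$root]]
  ll_fam <- ll[seq_len(nf)]
  if (condition) {
    p_absent <- exp(ll[F_all])
    ll_fam <- ll_fam - log1p(-min(p_absent, 1 - 1e-12))
  }
  ll_fam
}

## Mixture log-likelihood across discrete gamma categories (rates scaled
## jointly). Returns per-family log-likelihood.
mixture_loglik <- function(kappa, lambda, mu, n_max, sk, counts,
                           root_prior, n_categories, gamma_shape) {
  if (n_categories == 1L)
    return(pruning_loglik(kappa, lambda, mu, n_max, sk, counts, root_prior))
  mult <- gamma_multipliers(gamma_shape)
  lls <- vapply(mult, function(m)
    pruning_loglik(kappa * m, lambda * m, mu * m, n_max, sk, counts,
                   root_prior), numeric(nrow(counts)))
  hi <- pmax(lls[, 1], lls[, 2])
  hi + log(0.5 * exp(lls[, 1] - hi) + 0.5 * exp(lls[, 2] - hi))
}

#' Fit the birth-and-death model by maximum likelihood
#'
#' Maximises the product over gene families of the pruning-algorithm
#' likelihood of the observed leaf copy numbers, conditioned on each family
#' being present in at least one leaf (matrices never contain families that
#' were never observed, so the all-absent outcome is unobservable). The
#' root copy-number prior is the stationary distribution of the truncated
#' process (`root_prior = "uniform"` is available). Optimisation is
#' derivative-free Nelder--Mead over log-parameters from 5 fixed,
#' data-scaled starting points; the fit is deterministic.
#'
#' @param matrix a [phyletic_matrix()].
#' @param tree a rooted `phylo`; leaves must match the matrix genomes.
#' @param n_max truncation bound; default max observed copy number + 5.
#' @param n_categories 1 or 2 family-rate categories (see [bdi_model()]).
#' @param root_prior `"stationary"` or `"uniform"`.
#' @param reltol relative convergence tolerance passed to [stats::optim()].
#' @return a fitted [bdi_model()] with elements `loglik`, `n_families`,
#'   `convergence` and `starts` (the per-start objective values).
#' @export
fit_bdi <- function(matrix, tree, n_max = NULL, n_categories = 1L,
                    root_prior = c("stationary", "uniform"),
                    reltol = 1e-10) {
  stopifnot(inherits(matrix, "phyletic_matrix"))
  root_prior <- match.arg(root_prior)
  validate_tree(tree, require_rooted = TRUE)
  check_tree_matrix(tree, matrix)
  if (nrow(matrix) == 0) stop("empty matrix")
  sk <- tree_skeleton(tree)
  counts <- unclass(matrix)[, sk$tree$tip.label, drop = FALSE]
  max_obs <- max(counts)
  if (is.null(n_max)) n_max <- max_obs + 5L
  if (max_obs > n_max)
    stop("observed copy number ", max_obs, " exceeds n_max = ", n_max,
         "; raise n_max")
  ## collapse duplicate phyletic patterns; weight by multiplicity
  pat <- do.call(paste, c(as.data.frame(counts), sep = ","))
  keep <- !duplicated(pat)
  w <- as.vector(table(factor(pat, levels = pat[keep])))
  ucounts <- counts[keep, , drop = FALSE]

  T_tot <- sum(sk$lens)
  P_fam <- nrow(counts)
  F_bar <- max(mean(colSums(counts >= 1L)), 1)
  kappa0 <- P_fam / T_tot
  mu0 <- kappa0 / F_bar
  lambda0 <- 0.1 * mu0
  base <- log(c(kappa0, lambda0, mu0))
  start_mult <- list(c(1, 1, 1), c(10, 1, 1), c(0.1, 1, 1),
                     c(1, 0.1, 10), c(1, 10, 0.1))
  lb <- log(1e-8); ub <- log(1e8)
  two_cat <- n_categories == 2L

  negll <- function(par) {
    if (any(par[1:3] < lb) || any(par[1:3] > ub)) return(1e12)
    shape <- if (two_cat) exp(par[4]) else NA_real_
    if (two_cat && (shape < 1e-3 || shape > 1e3)) return(1e12)
    ll <- tryCatch(
      sum(w * mixture_loglik(exp(par[1]), exp(par[2]), exp(par[3]),
                             n_max, sk, ucounts, root_prior,
                             n_categories, shape)),
      error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  best <- NULL
  start_vals <- numeric(length(start_mult))
  for (s in seq_along(start_mult)) {
    p0 <- base + log(start_mult[[s]])
    if (two_cat) p0 <- c(p0, log(1))
    fit <- optim(p0, negll, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = reltol))
    start_vals[s] <- fit$value
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e12) {
    bad <- which(!is.finite(mixture_loglik(exp(best$par[1]), exp(best$par[2]),
                                           exp(best$par[3]), n_max, sk,
                                           ucounts, root_prior, 1L, NA)))
    stop("non-finite likelihood at optimum; first failing family pattern: ",
         rownames(ucounts)[bad[1]])
  }
  model <- bdi_model(exp(best$par[1]), exp(best$par[2]), exp(best$par[3]),
                     n_max,
                     n_categories = n_categories,
                     gamma_shape = if (two_cat) exp(best$par[4]) else NA_real_)
  model$root_prior <- root_prior
  model$loglik <- -best$value
  model$n_families <- P_fam
  model$convergence <- best$convergence
  model$starts <- start_vals
  model
}
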