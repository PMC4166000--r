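## Per-family, per-branch posterior probabilities of the four genome
## dynamics events, computed by an up--down (inside--outside) pass over the
## tree. Events are endpoint-state transitions on a branch:
##   gain       parent absent,  child present
##   loss       parent present, child absent
##   expansion  both present, child copy number > parent
##   reduction  both present, child copy number < parent
## Multiple flips within one branch are not counted separately, which is
## the source of the depth-dependent undercount the diagnostics in
## gde_rates quantify.

## One inside--outside pass at fixed rates. Returns the four probability
## matrices (families x branches), the root-presence posterior and the
## per-family (unconditioned) log-likelihood used for category weighting.
single_pass_posteriors <- function(kappa, lambda, mu, n_max, sk, counts,
                                   root_prior) {
  k <- n_max + 1L
  nf <- nrow(counts)
  nb <- length(sk$lens)
  mats <- bdi_branch_matrices(kappa, lambda, mu, n_max, sk$lens)
  prior <- if (identical(root_prior, "uniform")) rep(1 / k, k)
           else bdi_stationary(kappa, lambda, mu, n_max)

  tipL <- function(tip) {
    m <- matrix(0, k, nf)
    m[cbind(counts[, tip] + 1L, seq_len(nf))] <- 1
    m
  }
  ## --- up (inside) pass -------------------------------------------------
  L <- vector("list", sk$n_node)
  logsc <- vector("list", sk$n_node)
  M <- vector("list", nb)
  child_edges <- split(seq_len(nb), sk$parent)
  for (e in seq_len(nb)) {
    v <- sk$child[e]; u <- sk$parent[e]
    Lv <- if (v <= sk$n_tip) tipL(v) else L[[v]]
    sc_v <- if (v <= sk$n_tip) rep(0, nf) else logsc[[v]]
    M[[e]] <- mats[[e]] %*% Lv
    if (is.null(L[[u]])) {
      L[[u]] <- M[[e]]
      logsc[[u]] <- sc_v
    } else {
      L[[u]] <- L[[u]] * M[[e]]
      logsc[[u]] <- logsc[[u]] + sc_v
      cm <- col_max(L[[u]]); cm[cm <= 0] <- 1
      L[[u]] <- sweep(L[[u]], 2, cm, "/")
      logsc[[u]] <- logsc[[u]] + log(cm)
    }
  }
  rootL <- prior * L[[sk$root]]
  Zroot <- colSums(rootL)
  loglik <- log(Zroot) + logsc[[sk$root]]
  p_root_present <- 1 - rootL[1, ] / Zroot

  ## masks over (parent state s, child state t), states 0..n_max
  idx <- 0:n_max
  Mexp <- outer(idx, idx, function(s, t) as.numeric(s >= 1 & t > s))
  Mred <- outer(idx, idx, function(s, t) as.numeric(s >= 1 & t >= 1 & t < s))

  p_gain <- matrix(0, nf, nb)
  p_loss <- matrix(0, nf, nb)
  p_exp <- matrix(0, nf, nb)
  p_red <- matrix(0, nf, nb)

  ## --- down (outside) pass ----------------------------------------------
  D <- vector("list", sk$n_node)
  D[[sk$root]] <- matrix(prior, k, nf)
  for (e in rev(seq_len(nb))) {
    u <- sk$parent[e]; v <- sk$child[e]
    sib <- NULL
    for (e2 in child_edges[[as.character(u)]]) {
      if (e2 == e) next
      sib <- if (is.null(sib)) M[[e2]] else sib * M[[e2]]
    }
    A <- if (is.null(sib)) D[[u]] else D[[u]] * sib
    P <- mats[[e]]
    Lv <- if (v <= sk$n_tip) tipL(v) else L[[v]]
    N <- colSums(A * M[[e]])
    N[N <= 0] <- .Machine$double.xmin
    p_gain[, e] <- A[1, ] * as.vector(P[1, -1, drop = FALSE] %*%
                                        Lv[-1, , drop = FALSE]) / N
    p_loss[, e] <- colSums(A[-1, , drop = FALSE] * P[-1, 1]) * Lv[1, ] / N
    p_exp[, e] <- colSums(A * ((P * Mexp) %*% Lv)) / N
    p_red[, e] <- colSums(A * ((P * Mred) %*% Lv)) / N
    if (v > sk$n_tip) {
      Dv <- crossprod(P, A)
      cm <- col_max(Dv); cm[cm <= 0] <- 1
      D[[v]] <- sweep(Dv, 2, cm, "/")
    }
  }
  list(p_gain = p_gain, p_loss = p_loss, p_expansion = p_exp,
       p_reduction = p_red, p_root_present = p_root_present,
       loglik = loglik)
}

#' Posterior event probabilities for every family and branch
#'
#' Runs an inside--outside pass under a fitted [bdi_model()] to obtain, for
#' each gene family and each branch, the joint posterior distribution of
#' (parent copy number, child copy number) given the observed phyletic
#' pattern, and sums it into the four event probabilities (gain, loss,
#' expansion, reduction) plus the posterior probability of presence at the
#' root. With two rate categories the posteriors are category mixtures
#' weighted by each family's per-category likelihood.
#'
#' @param model a (typically fitted) [bdi_model()].
#' @param matrix a [phyletic_matrix()].
#' @param tree a rooted `phylo` matching the matrix genomes.
#' @return an object of class `bdi_posteriors`: families x branches
#'   matrices `p_gain`, `p_loss`, `p_expansion`, `p_reduction`; vector
#'   `p_root_present`; a `branches` table (post-order branch ids, parent
#'   and child node, length, terminal flag, midpoint depth); the logical
#'   `singleton` flag per family (present in exactly one genome).
#' @export
posterior_events <- function(model, matrix, tree) {
  stopifnot(inherits(model, "bdi_model"), inherits(matrix, "phyletic_matrix"))
  validate_tree(tree, require_rooted = TRUE)
  check_tree_matrix(tree, matrix)
  sk <- tree_skeleton(tree)
  counts <- unclass(matrix)[, sk$tree$tip.label, drop = FALSE]
  if (max(counts) > model$n_max)
    stop("observed copy number ", max(counts), " exceeds n_max = ",
         model$n_max, "; raise n_max")
  root_prior <- if (is.null(model$root_prior)) "stationary" else model$root_prior

  if (model$n_categories == 1L) {
    res <- single_pass_posteriors(model$kappa, model$lambda, model$mu,
                                  model$n_max, sk, counts, root_prior)
  } else {
    mult <- gamma_multipliers(model$gamma_shape)
    parts <- lapply(mult, function(m)
      single_pass_posteriors(model$kappa * m, model$lambda * m, model$mu * m,
                             model$n_max, sk, counts, root_prior))
    hi <- pmax(parts[[1]]$loglik, parts[[2]]$loglik)
    w1 <- exp(parts[[1]]$loglik - hi)
    w2 <- exp(parts[[2]]$loglik - hi)
    tot <- w1 + w2
    w1 <- w1 / tot; w2 <- w2 / tot
    mix <- function(fld) {
      if (is.matrix(parts[[1]][[fld]]))
        parts[[1]][[fld]] * w1 + parts[[2]][[fld]] * w2
      else parts[[1]][[fld]] * w1 + parts[[2]][[fld]] * w2
    }
    res <- list(p_gain = mix("p_gain"), p_loss = mix("p_loss"),
                p_expansion = mix("p_expansion"),
                p_reduction = mix("p_reduction"),
                p_root_present = mix("p_root_present"),
                loglik = hi + log(w1 * 0 + tot) - log(2))
  }

  fam <- rownames(counts)
  bid <- paste0("b", seq_along(sk$lens))
  for (fld in c("p_gain", "p_loss", "p_expansion", "p_reduction"))
    dimnames(res[[fld]]) <- list(fam, bid)
  names(res$p_root_present) <- fam
  branches <- data.frame(
    branch = bid,
    parent = sk$parent,
    child = sk$child,
    length = sk$lens,
    terminal = sk$terminal,
    midpoint_depth = branch_midpoint_depth(sk$tree),
    stringsAsFactors = FALSE
  )
  out <- list(p_gain = res$p_gain, p_loss = res$p_loss,
              p_expansion = res$p_expansion, p_reduction = res$p_reduction,
              p_root_present = res$p_root_present,
              branches = branches,
              singleton = rowSums(counts >= 1L) == 1L,
              family_ids = fam,
              tree = sk$tree, model = model)
  class(out) <- "bdi_posteriors"
  out
}

#' @export
print.bdi_posteriors <- function(x, ...) {
  cat(sprintf("Posterior event probabilities: %d families x %d branches\n",
              nrow(x$p_gain), ncol(x$p_gain)))
  cat(sprintf("  expected totals: gains %.1f, losses %.1f, expansions %.1f, reductions %.1f\n",
              sum(x$p_gain), sum(x$p_loss), sum(x$p_expansion),
              sum(x$p_reduction)))
  invisible(x)
}

#' Expected event counts per branch and in total
#'
#' Sums posterior event probabilities over families (per branch) and over
#' branches (dataset totals). Also reports, per branch, the gain count with
#' terminal-branch gains of singleton families removed (used by the genomic
#' clock, which excludes singletons), and the per-family total gain
#' probability consumed by the supergenome estimators.
#'
#' @param posteriors a [posterior_events()] result.
#' @return an object of class `event_totals` with elements `per_branch`
#'   (data frame), `totals` (named vector over the four event types),
#'   `per_family_total_gain` (sum of gain posteriors over branches) and
#'   `total_gain_probability` (the same plus the root-presence posterior).
#' @export
count_events <- function(posteriors) {
  stopifnot(inherits(posteriors, "bdi_posteriors"))
  pb <- posteriors$branches
  pb$gains <- colSums(posteriors$p_gain)
  pb$losses <- colSums(posteriors$p_loss)
  pb$expansions <- colSums(posteriors$p_expansion)
  pb$reductions <- colSums(posteriors$p_reduction)
  sing_term <- colSums(posteriors$p_gain[posteriors$singleton, , drop = FALSE])
  pb$gains_excl_singletons <- pb$gains - ifelse(pb$terminal, sing_term, 0)
  totals <- c(gain = sum(pb$gains), loss = sum(pb$losses),
              expansion = sum(pb$expansions), reduction = sum(pb$reductions))
  out <- list(per_branch = pb, totals = totals,
              per_family_total_gain = rowSums(posteriors$p_gain),
              total_gain_probability = rowSums(posteriors$p_gain) +
                posteriors$p_root_present,
              tree_length = sum(pb$length))
  class(out) <- "event_totals"
  out
}

#' @export
print.event_totals <- function(x, ...) {
  cat("Expected genome dynamics event counts\n")
  print(round(x$totals, 2))
  cat(sprintf("  tree length: %.6g substitutions/site\n", x$tree_length))
  invisible(x)
}

#' Export posterior probabilities as a long-format table
#'
#' @param posteriors a [posterior_events()] result.
#' @return a data frame with one row per family x branch and the four
#'   event probabilities.
#' @export
posteriors_long <- function(posteriors) {
  stopifnot(inherits(posteriors, "bdi_posteriors"))
  nf <- nrow(posteriors$p_gain); nb <- ncol(posteriors$p_gain)
  data.frame(
    family_id = rep(posteriors$family_ids, nb),
    branch = rep(posteriors$branches$branch, each = nf),
    p_gain = as.vector(posteriors$p_gain),
    p_loss = as.vector(posteriors$p_loss),
    p_expansion = as.vector(posteriors$p_expansion),
    p_reduction = as.vector(posteriors$p_reduction),
    stringsAsFactors = FALSE
  )
}
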