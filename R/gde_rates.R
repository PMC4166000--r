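## Conversion of expected event counts to genome-dynamics rates, plus the
## genomic-clock and depth-dependence diagnostics and per-functional-
## category flux. Rates are reported per nucleotide substitution per site
## (total expected events divided by total tree length) and per nucleotide
## substitution per gene (the per-site rate divided by the mean CDS length
## in nucleotides -- the divisor is metadata, never hard-coded).

#' Genome dynamics rate table
#'
#' @param totals an [count_events()] result, or a named numeric vector of
#'   the four event totals (`gain`, `loss`, `expansion`, `reduction`).
#' @param tree the rooted tree the totals were computed on (used for the
#'   total tree length); ignored when `totals` is an `event_totals` object,
#'   which carries its tree length.
#' @param mean_gene_length_nt mean CDS length in nucleotides (> 0).
#' @param dnds optional dataset-wide dN/dS, carried through as metadata.
#' @return an object of class `gde_rate_table`: `rate_site` and `rate_gene`
#'   (named vectors over the four event types), `flux_site` (sum of the
#'   four per-site rates), `balance` ((gain + expansion) / (loss +
#'   reduction); `NaN` with a warning when no loss or reduction occurred),
#'   `mean_gene_length_nt`, `total_tree_length`, `dnds`.
#' @export
compute_rate_table <- function(totals, tree = NULL,
                               mean_gene_length_nt, dnds = NA_real_) {
  if (inherits(totals, "event_totals")) {
    T_tot <- totals$tree_length
    ev <- totals$totals
  } else {
    if (is.null(tree)) stop("tree required when totals is a plain vector")
    T_tot <- total_tree_length(tree)
    ev <- totals[c("gain", "loss", "expansion", "reduction")]
  }
  if (!is.finite(T_tot) || T_tot <= 0) stop("total tree length must be > 0")
  if (!is.finite(mean_gene_length_nt) || mean_gene_length_nt <= 0)
    stop("mean_gene_length_nt must be > 0")
  rate_site <- ev / T_tot
  rate_gene <- rate_site / mean_gene_length_nt
  denom <- rate_site[["loss"]] + rate_site[["reduction"]]
  balance <- if (denom > 0) {
    (rate_site[["gain"]] + rate_site[["expansion"]]) / denom
  } else {
    warning("no loss or reduction events: balance undefined (NaN)")
    NaN
  }
  out <- list(rate_site = rate_site, rate_gene = rate_gene,
              flux_site = sum(rate_site),
              flux_gene = sum(rate_gene),
              balance = balance,
              mean_gene_length_nt = mean_gene_length_nt,
              total_tree_length = T_tot, dnds = dnds)
  class(out) <- "gde_rate_table"
  out
}

#' @export
print.gde_rate_table <- function(x, ...) {
  cat("Genome dynamics rates (events per nucleotide substitution)\n")
  df <- rbind(`per site` = x$rate_site, `per gene` = x$rate_gene)
  print(signif(df, 4))
  cat(sprintf("  flux (per site): %.6g   balance (G+E)/(L+R): %.4g\n",
              x$flux_site, x$balance))
  invisible(x)
}

#' Rate table as a one-row data frame (Table-1-like column order)
#'
#' @param x a [compute_rate_table()] result.
#' @return a one-row data frame: gain/loss/expansion/reduction, site and
#'   gene units, then flux and balance.
#' @export
rate_table_row <- function(x) {
  stopifnot(inherits(x, "gde_rate_table"))
  data.frame(
    gain_site = x$rate_site[["gain"]], gain_gene = x$rate_gene[["gain"]],
    loss_site = x$rate_site[["loss"]], loss_gene = x$rate_gene[["loss"]],
    expansion_site = x$rate_site[["expansion"]],
    expansion_gene = x$rate_gene[["expansion"]],
    reduction_site = x$rate_site[["reduction"]],
    reduction_gene = x$rate_gene[["reduction"]],
    flux_site = x$flux_site, balance = x$balance
  )
}

#' Genomic clock: event counts versus branch length
#'
#' For each event type, regresses the per-branch expected event count on
#' branch length in log--log space and reports the Spearman correlation
#' with a permutation P value. Singleton exclusion (default on, matching
#' how clock plots are drawn) removes gains of families present in exactly
#' one genome from terminal branches.
#'
#' @param totals an [count_events()] result.
#' @param exclude_terminal_singleton_gains logical.
#' @param n_perm permutation rounds for the P value.
#' @param seed RNG seed for the permutation test.
#' @return a data frame with one row per event type: log--log `slope`,
#'   `intercept`, Spearman `rho`, permutation `p_value`, `n_branches`.
#' @export
genomic_clock <- function(totals, exclude_terminal_singleton_gains = TRUE,
                          n_perm = 10000, seed = 1L) {
  stopifnot(inherits(totals, "event_totals"))
  pb <- totals$per_branch
  if (nrow(pb) < 3) stop("at least 3 branches are required")
  types <- c(gain = if (exclude_terminal_singleton_gains)
                      "gains_excl_singletons" else "gains",
             loss = "losses", expansion = "expansions",
             reduction = "reductions")
  out <- lapply(names(types), function(ty) {
    y <- pb[[types[[ty]]]]
    x <- pb$length
    keep <- x > 0 & y > 0
    slope <- intercept <- NA_real_
    if (sum(keep) >= 3) {
      fit <- lm(log(y[keep]) ~ log(x[keep]))
      slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    }
    sp <- spearman_perm(x, y, n_perm = n_perm, seed = seed)
    data.frame(type = ty, slope = slope, intercept = intercept,
               rho = sp$rho, p_value = sp$p_value, n_branches = nrow(pb),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Depth dependence of per-branch event rates
#'
#' Fits `log(rate) ~ log(depth)` and expresses the fitted rate at any depth
#' as a percentage of the fitted value at a reference depth (default 1e-4
#' substitutions per site, the normalisation depth used for reporting).
#' A negative slope reproduces the endpoint-transition undercount: deep
#' branches hide within-branch event reversals, so apparent per-length
#' rates fall with depth.
#'
#' @param rates per-branch event rates (events per unit branch length).
#' @param depths branch midpoint depths (> 0), same length.
#' @param reference_depth depth at which the normalised curve equals 100%.
#' @return an object of class `depth_fit`: `slope`, `intercept`, and
#'   `percent_at(depth)`, the fitted relative rate in percent.
#' @export
depth_dependence <- function(rates, depths, reference_depth = 1e-4) {
  stopifnot(length(rates) == length(depths))
  if (any(depths <= 0)) stop("depths must be positive")
  keep <- rates > 0
  if (sum(keep) < 2) stop("need at least 2 positive rates")
  fit <- lm(log(rates[keep]) ~ log(depths[keep]))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  out <- list(
    slope = slope, intercept = intercept,
    reference_depth = reference_depth,
    percent_at = function(depth) 100 * (depth / reference_depth)^slope
  )
  class(out) <- "depth_fit"
  out
}

#' @export
print.depth_fit <- function(x, ...) {
  cat(sprintf("log-log depth fit: slope %.4g (100%% at depth %g)\n",
              x$slope, x$reference_depth))
  invisible(x)
}

#' Gene flux by functional category
#'
#' Groups posterior event counts by COG functional category and normalises
#' per gene of that category: rate = expected events / total tree length /
#' number of genes in the category. Families without a mapping are labelled
#' `"unknown"`; categories with zero genes are omitted with a warning.
#'
#' @param posteriors a [posterior_events()] result.
#' @param categories named character vector, family id -> single-letter
#'   category; defaults to the categories attached to the matrix.
#' @param genes_per_category optional named vector of gene counts per
#'   category; defaults to the number of families per category.
#' @return a data frame, one row per category, ranked by per-gene flux:
#'   `category`, `n_genes`, `gain`, `loss`, `expansion`, `reduction`,
#'   `flux` (all per gene per substitution per site).
#' @export
category_flux <- function(posteriors, categories,
                          genes_per_category = NULL) {
  stopifnot(inherits(posteriors, "bdi_posteriors"))
  fam <- posteriors$family_ids
  cat_by_fam <- rep("unknown", length(fam))
  names(cat_by_fam) <- fam
  hit <- intersect(fam, names(categories))
  cat_by_fam[hit] <- categories[hit]
  cat_by_fam[is.na(cat_by_fam) | cat_by_fam == ""] <- "unknown"
  T_tot <- sum(posteriors$branches$length)
  lv <- sort(unique(cat_by_fam))
  grp <- factor(cat_by_fam, levels = lv)
  sums <- function(m) as.vector(rowsum(rowSums(m), grp))
  counts <- data.frame(
    category = lv,
    n_genes = if (is.null(genes_per_category)) as.vector(table(grp))
              else as.numeric(genes_per_category[lv]),
    gain = sums(posteriors$p_gain),
    loss = sums(posteriors$p_loss),
    expansion = sums(posteriors$p_expansion),
    reduction = sums(posteriors$p_reduction),
    stringsAsFactors = FALSE
  )
  empty <- !is.finite(counts$n_genes) | counts$n_genes == 0
  if (any(empty)) {
    warning("omitting categories with zero genes: ",
            paste(counts$category[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  for (cl in c("gain", "loss", "expansion", "reduction"))
    counts[[cl]] <- counts[[cl]] / T_tot / counts$n_genes
  counts$flux <- counts$gain + counts$loss + counts$expansion +
    counts$reduction
  counts[order(-counts$flux), , drop = FALSE]
}
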