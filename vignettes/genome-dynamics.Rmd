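---
title: "Genome dynamics and supergenome estimation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome dynamics and supergenome estimation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panflux)
```

This vignette is the package's account of its own methods: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator emulates, the numerical choices, and the design decisions that
were genuinely open. It states no empirical result that the test suite
does not itself compute.

## 1. The inference model

A group of closely related prokaryote genomes is summarised by a rooted
species tree (branch lengths in nucleotide substitutions per site) and a
copy-number matrix of gene families (paralogs included). Each family is
modelled as an independent birth-and-death-with-immigration process on
its copy number $n$:

$$ n \to n + 1 \text{ at rate } \kappa + n\lambda, \qquad
   n \to n - 1 \text{ at rate } n\mu, $$

per unit branch length. $\kappa$ is the family gain intensity (in
prokaryotes, dominated by horizontal gene transfer), $\lambda$ the
per-copy duplication intensity and $\mu$ the per-copy loss intensity.
Transition probabilities over a branch come from the matrix exponential
of this generator truncated at `n_max` (default: the largest observed
copy number plus 5; truncated rows are renormalised). A single
$(\kappa, \lambda, \mu)$ is shared by all families and branches —
deliberately simpler than per-family, per-edge rate schedules used by
full reconstruction programs, and honest about it: the package's claims
are about dataset-level rates and pool sizes, not per-family histories.
An optional two-point discrete-gamma family-rate multiplier (applied
jointly to all three intensities, shape estimated) is available via
`n_categories = 2`; independent per-event-type categories are not
implemented.

**Units.** $\kappa$ in `fit_bdi()` is *per family*: it is the intensity
with which one specific family arrives. The simulator's `kappa` is the
*genome-level* pool-sampling intensity; a specific family $i$ arrives at
rate $\kappa\,p_i$ (= $\kappa/S$ for a uniform pool). Recovery tests
compare in per-family units.

**Ascertainment.** Input matrices only ever contain families observed in
at least one genome, so each family's likelihood is conditioned on
non-absence (divided by $1 - P(\text{all leaves } 0)$). Families that
lived and died entirely inside the tree are invisible; this is the root
cause of the depth-dependent undercount quantified below.

**Root prior.** The stationary distribution of the truncated process
(detailed balance: $\pi_{n+1}/\pi_n = (\kappa + n\lambda)/((n+1)\mu)$);
a uniform prior is available behind a flag. When $\mu = 0$ the stationary
limit degenerates and a uniform prior is substituted.

**Optimisation.** Derivative-free Nelder–Mead over
$\log(\kappa, \lambda, \mu)$ from five fixed, data-scaled starting
points; rates are bounded to $[10^{-8}, 10^{8}]$ (a no-loss dataset
drives $\hat\mu$ to the lower bound, which is the correct degenerate
answer). No randomness is used: fits are bit-reproducible.

## 2. Event posteriors and rates

For each family, an inside–outside pass yields the joint posterior of
(parent state, child state) on every branch. Events are **endpoint
transitions**: gain = parent absent, child present; loss = the reverse;
expansion/reduction = both present with copy number up/down. A family
that flips twice within one branch contributes nothing — the method
cannot see it — so inferred event counts are a lower bound that
deteriorates with branch depth. This is a property of the method being
modelled, not a defect to be patched: `depth_dependence()` measures it
(log–log fit of per-branch rate against branch midpoint depth, curve
normalised to 100% at $10^{-4}$ substitutions/site) and the acceptance
suite asserts that the inferred/true event ratio falls with depth in
simulation. How simultaneous gain-plus-duplication within one branch
should be attributed is not decidable from endpoint states; the endpoint
convention above is declared rather than derived.

Rates are expected event counts divided by total tree length (per
substitution per site), and additionally by the mean CDS length in
nucleotides (per substitution per gene). The divisor is a required
metadata input and is never hard-coded: published per-site/per-gene rate
pairs imply a divisor close to the mean gene length (~1000–1200 nt), but
its exact per-dataset value is not recoverable, so all bundled
cross-cluster statistics use ratios or per-site values in which it
cancels. Flux is the sum of the four per-site rates; balance is
$(\text{gain} + \text{expansion})/(\text{loss} + \text{reduction})$,
reported as `NaN` with a warning when the denominator is zero.

## 3. Supergenome estimators

The per-family total gain probability (branch gains plus root presence)
is binned with half-open intervals $[m - \tfrac12, m + \tfrac12)$ into
the multiplicity spectrum $O_m$; totals below 0.5 fall into $O_0$ and
leave the spectrum.

**Ancestral families.** A family with root-presence posterior above 0.5
is ancestral: its gain predates the group's common ancestor. Ancestral
families are excluded from the fitted spectrum and their count added to
the final pool size. The alternative reading — keeping their root
presence inside $K$ *and* adding them back — double-counts them; a direct
computation with published pangenome/gain totals (`uniform_ml(24845,
38293)` gives 40822, not the published 37267 for that cluster) confirms
that the published estimates cannot be reproduced from the printed totals
alone, so the exclusion convention was adopted and the printed pool sizes
are not asserted as reproduction targets.

**Uniform pool.** $\ln L(S) = \ln C(S, P) - K \ln S$, maximised over
real $S \ge P$ via the digamma equation, then the better of
floor/ceiling (equal to the exhaustive integer argmax, since $\ln L$ is
unimodal for $K > P$ — verified by scan in the tests). The 95% interval
is the profile-likelihood region at a 1.92 log-unit drop
($\chi^2_1/2$). The published "±" intervals are of unstated type; ours
is labelled a profile CI.

**Power-law pool.** $p_i = A/i^\alpha$; the spectrum is modelled as
independent Poisson counts around $g_m = C(K, m)\sum_i p_i^m
(1-p_i)^{K-m}$, computed by direct summation over the pool in log space
($K$ may be non-integer; binomial coefficients use the gamma function).
The identity $\sum_{m \ge 1} g_m = S - g_0$ lets the full
$-\sum_m g_m$ term be evaluated without enumerating all $m$. The search
runs $\alpha$ over a 0.05-step grid on $[0, 3]$ with golden-section
maximisation of $\log_{10} S$ per exponent (warm-started from the
previous exponent) and a final golden refinement of $\alpha$; the grid
walk stops early once the profile has fallen 100 log units below its
maximum for three consecutive exponents, which only abandons exponents
that push $S$ against the cap at large cost.

**Open pools.** An estimate is open when no interior maximum exists
below the cap $S_{\text{cap}} = 10^3 P$ or the likelihood at the cap is
within 0.5 log units of the maximum. The published work reports "Open"
without a stated criterion; this rule is ours, documented and
configurable. In practice the open verdict demands an almost repeat-free
spectrum: even a handful of spuriously inferred multiple gains (posterior
ambiguity on deep branches) produces a large but finite $\hat S$.

## 4. What the simulator emulates — and what it does not

`simulate_evolution()` is an exact Gillespie simulation of the
gain–duplication–loss process along every branch, with gained identities
drawn from a finite pool (uniform or power-law). It emits the same
Newick/TSV formats the pipeline consumes plus a truth ledger (per-branch
event counts, per-family gain multiplicities, ancestral set, per-node
presence counts with a conservation invariant). Defaults and presets use
magnitudes matching published clusters: trees of 10–100 leaves at mean
root-to-leaf depths of $10^{-3}$–$10^{-1}$ substitutions/site, ~900–6500
families per genome, genome-level gain intensities of order $10^4$ per
substitution per site and per-copy loss intensities of order 10.

Deliberate simplifications: no sequences are simulated (branch lengths
stand in for substitutions); re-gain of a currently present family is an
expansion (a family cannot be "gained" while present); root genomes are
seeded with single copies by default (`root_state = "stationary"` draws
root copy numbers from the conditional stationary law — the regime in
which simulator and inference model coincide exactly, used by the
parameter-recovery tests); no rate heterogeneity across families or
branches; no gene-order or synteny structure (synteny statistics consume
externally supplied pair tables). A green recovery test therefore
establishes correctness of the estimator *under its own model
assumptions*, not robustness to the many ways real clusters violate them
(selection, episodic transfer bursts, shared mobile elements).

Preset regimes: `chlamydia-like` (small shallow genomes, pool ~1.4
genome equivalents, closed — repeated gains common), `enterobacteria-like`
(large genomes, pool ~9 equivalents) and `open-like` (pool of
$3 \times 10^6$ families; repeats essentially never drawn, verdict open).
The open-like world needs a shallow tree and a large observed pangenome:
openness under the $10^3 P$ cap requires fewer than about $P/2000$
inferred multiples, so deep trees — whose posterior ambiguity fabricates
a few multiples — bias toward large-but-closed calls.

## 5. Cross-dataset statistics

Spearman correlations use average ranks with a two-sided permutation P
value and the add-one estimator $(1 + \#\{|\rho_\pi| \ge
|\rho|\})/(n_{\text{perm}} + 1)$ (never exactly zero; 100,000 rounds by
default). Group comparisons use two-sided Mann–Whitney U — the published
analyses do not name their test, so those P values are not reproduction
targets. PCA of the four log10 per-site rates defaults to the
**correlation** matrix: on the bundled 35-cluster table the correlation
form reproduces the published variance split (~64%/~19%) while the
covariance form gives ~70%/~14%, so the correlation matrix is what the
published analysis evidently used; `cor = FALSE` restores the covariance
behaviour. PC1 is sign-oriented so all four loadings are positive (the
flux axis); PC2 then contrasts gain against loss (the balance axis).
Bootstrap medians (1000 replicates), the open-vs-lifestyle 2×2 Pearson
chi-squared without continuity correction, and the synteny shuffling
rate (log–log regression of $dY = 1 - F_s$ on nucleotide distance,
evaluated at 0.01 substitutions/site) complete the panel. No
multiple-testing correction is applied anywhere; outputs are labelled
uncorrected.

## 6. Numerical choices

* Matrix exponentials: one eigendecomposition of the generator serves
  all branches; if the eigenbasis is ill-conditioned the code falls back
  to `Matrix::expm` per branch. Rows are clamped to $[0, 1]$ and
  renormalised (row-stochastic to $10^{-9}$).
* Pruning rescales partial likelihoods per node and tracks log offsets;
  posteriors are computed from ratios in which all scale factors cancel.
* The least-squares midpoint root minimises the variance of root-to-leaf
  distances; within each edge the optimum is a clamped closed-form
  quadratic minimiser, and ties between edges break toward the first
  edge in post-order. The cited rooting method's exact algorithm is not
  published; this variance-minimising definition is our stand-in and is
  checked against a grid-search oracle.
* Binomial coefficients and spectrum terms are always evaluated through
  `lgamma`/`logsumexp`; the power-law likelihood never forms $C(K, m)$
  outside log space (doing so overflows at the $K \sim 5000$ scale of
  real spectra).
* Configuration files are JSON (the deployment environment guarantees a
  JSON parser but not YAML); flags override file values.
* Runtime scaling in the test suite: the preset band check runs 3 seeds
  (not 10) and the open-like round trip one seed; the depth-dependence
  criterion uses 25-leaf, ~1000-family simulations at five depths. These
  reduce runtime, not the stated world's parameters.

## 7. Known limitations

* Event counts are endpoint-transition lower bounds; on branches deeper
  than ~0.1 substitutions/site the undercount reaches tens of percent.
* $\lambda$ (duplication) is the weakest-identified parameter: its
  signal lives in the paralog copy-number distribution, which is thin in
  gain-dominated regimes. With ~2000 families and shallow trees, 20%
  relative error is achievable; with hundreds of families it is not.
* The supergenome estimators assume independent draws from a fixed pool;
  correlated gains (operons, mobile elements) violate this in a
  direction that is not determinable a priori.
* Open/closed is a thresholded verdict on a likelihood that can be very
  flat; near the boundary the verdict is sensitive to a few inferred
  multiples, and published open calls are not reproducible without the
  original posterior spectra.
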