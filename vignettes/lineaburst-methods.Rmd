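---
title: "Delimiting lineages and dating diversification-rate shifts with lineaburst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting lineages and dating diversification-rate shifts with lineaburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

lineaburst assembles the standard single-locus workflow used to ask when a
clade of organisms diversified: collapse redundant sequences, delimit
putative species from a barcode-style alignment and a time-calibrated tree
(chronogram), then ask whether the speciation rate shifted through time and
estimate the clade's net diversification rate.  The motivating use case is
micro-eukaryote groups such as testate amoebae, where morphospecies hide
several evolutionarily independent units and sampling is dominated by a few
heavily sequenced morphospecies — but every component is generic.  This
vignette records the models, the defaults and the numerical choices, in the
package's own words; nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## Sequence filtering and distances

**Deduplication.**  Fragments of unequal read length are aligned into a
common frame, so "the longest sequence" of a redundant set is the one with
the most determinate characters (non-N, non-gap).  Two sequences are
*compatible* when they agree at every column where both are determinate
(`A`, `C`, `G`, `T` or `-`); `N` is a wildcard.  Compatibility is not
transitive, so `dedup_longest()` collapses connected components of the
compatibility graph and keeps each component's most determinate member,
breaking ties by input order.  This is deterministic, order-stable, and a
superset of exact-duplicate removal; the collapse report lists every
member's representative.

**K2P distances.**  `k2p()` uses pairwise deletion: only columns where both
sequences carry `A/C/G/T` enter the counts.  With transition proportion
$P = s/m$ and transversion proportion $Q = v/m$ over $m$ retained sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Pairs whose log arguments are non-positive are *saturated*: the distance is
undefined, the pair is flagged, and clustering treats it as infinitely
distant (with a warning) rather than guessing.  Pairwise deletion is used
instead of complete deletion because partial-length fragments would
otherwise leave few complete columns.

**99% similarity clustering.**  `threshold_clusters()` interprets the
conventional "99% similarity" rule as K2P distance $\le 0.01$ — at 1%
divergence K2P and the uncorrected p-distance differ by about $10^{-4}$,
but the corrected distance is what barcoding studies typically compute; the
p-distance remains available via `metric = "p"`.  Single linkage (connected
components of the $d \le$ cutoff graph) is the default because
threshold-based barcoding practice chains clusters; complete linkage is
available where chaining is unwanted.  Clusters are numbered by first-seen
id so output is order-stable.

## The GMYC model

The general mixed Yule coalescent model locates a threshold age $T$ on a
chronogram separating between-species branching (speciation) from
within-species branching (coalescence).  Nodes older than $T$ are
speciation events; each subtree whose root is younger than $T$ but whose
stem crosses $T$ is one coalescent group, and its tips form one *entity*
(putative species).  A lineage belongs to the diversification process until
its first sub-threshold branching — so a species' stem stays in the
speciation process even below $T$ — and to its group's coalescent process
afterwards.

Successive branching events delimit intervals $i$ with durations $x_i$.
During interval $i$ the total branching rate is

$$b_i = \lambda_1 k_i^{p_1} + \lambda_2 \sum_j \left[n_{j,i}(n_{j,i}-1)\right]^{p_2},$$

with $k_i$ the number of diversification-process lineages and $n_{j,i}$ the
lineage count of coalescent group $j$; all groups share one
$(\lambda_2, p_2)$.  The log-likelihood is the mixed-process waiting-time
form $\sum_{\text{events}} \ln b_i - \sum_i b_i x_i$, the final interval
(ending at the present) contributing only its survival term.  The event
term uses the *total* rate $b_i$: a per-component event term would assign
zero hazard to each group's first coalescence (the group still holds a
single lineage just before it), making every informative threshold
infeasible.  The null model is a single generalized-Yule process
$b_i = \lambda_0 (i{+}1)^{p_0}$ over all lineages; the threshold model with
$T$ younger than every node reduces to it exactly, which guarantees
`logL_alt >= logL_null` at the optimum.

**Fitting.**  Candidate thresholds are the midpoints between consecutive
distinct node ages plus two degenerate extremes (older than the root: one
all-coalescent entity; younger than all nodes: all singletons).  Midpoints
rather than node ages make the older/younger classification tie-free.  At
each candidate, $(\lambda_1, p_1, \lambda_2, p_2)$ is maximized by L-BFGS-B
on $(\log \lambda, p)$ with exponents bounded in $[10^{-3}, 3]$
(unconstrained exponents diverge on small trees; $p = 1$, the linear case,
is interior) and five seeded starts jittered around a moment estimate, plus
the fitted null solution as an extra start.  The likelihood-ratio test
against the null uses $\chi^2$ with df = 3 by convention (threshold plus
one extra rate and exponent); the statistic sits on a boundary of the
parameter space, so the nominal $\chi^2_3$ reference is conservative — the
chi-bar-square refinement is documented here but deliberately not
implemented.  Singleton entities are counted as entities (`n_entities =
n_clusters + n_singletons`), with both counts reported.

**Multiple thresholds.**  `fit_gmyc_multiple()` relaxes the single global
threshold into per-group local thresholds by greedy stepwise search over
assignments of internal nodes to the speciation process, starting from the
single-threshold optimum: each step either claims one group root for the
speciation process or releases one frontier speciation node, refits the
four process parameters (incumbent parameters seed the refit), and accepts
the best AIC improvement until none exists or `max_thresholds` is reached.
The AIC charges 4 process parameters plus the *minimal number of distinct
threshold ages* consistent with the assignment, computed by greedy interval
stabbing of the (group-root age, parent age) windows; the single-threshold
state therefore counts exactly one threshold parameter.  The search is
greedy, not exhaustive (exhaustive search over rootward-closed node sets is
exponential), and is documented as an approximation.

## Diversification models

All fits consume `branching_times()` — the internal-node ages
$t_2 \ge \dots \ge t_n$ and the durations $x_k = t_k - t_{k+1}$ spent with
$k$ lineages — and all drop the same combinatorial constants so their AIC
values are comparable.

* **Pure birth.**  Conditioned on the crown,
  $\log L = (n-2)\ln\lambda - \lambda S$ with
  $S = \sum_k k\,x_k$; the MLE is $\hat\lambda = (n-2)/S$ in closed form.
* **Constant birth-death.**  Parameterized by net rate $r = \lambda - \mu$
  and extinction fraction $a = \mu/\lambda$:
  $\log L = (n-2)\ln r - rS + n\ln(1-a) - 2\sum_i \ln(1 - a e^{-r t_i})$,
  written in this overflow-safe form (the naive
  $\ln(e^{r t_i} - a)$ form overflows at large $r t$).  At $a = 0$ it
  reduces algebraically to the pure-birth expression through the identity
  $S = 2t_2 + \sum_{i \ge 3} t_i$.  Optimization is box-constrained with
  the pure-birth solution among the starts, so the fit never falls below
  the nested model.
* **2- and 3-rate pure birth.**  Shift ages are searched exhaustively over
  the observed branching times (the event at a shift age closes the older
  epoch); within an epoch the rate MLE is events / lineage-time, so the
  profile likelihood is evaluated, not optimized numerically.  Restricting
  shifts to branching times is standard for this family and makes the
  3-rate search exhaustive and deterministic via cumulative event and
  lineage-time tables.  AIC charges $2k - 1$ parameters ($k$ rates, $k-1$
  shift ages).

**$\Delta$AIC$_{rc}$.**  `delta_aic_rc()` returns AIC(best constant-rate
model) $-$ AIC(best rate-variable model); positive values favor rate
variation.  Because the shift ages are maximized over all branching-time
placements, the null distribution of $\Delta$AIC$_{rc}$ has a *positive*
median — raw AIC over-selects the shift models — which is exactly why the
decision rule calibrates a critical value by simulation:
`critical_delta_aic()` refits the best constant-rate model, simulates
`n_sim` trees (default 1000; the replicate count is this package's choice)
of the same tip count under its MLEs, and returns the 0.95 quantile of the
null $\Delta$AIC$_{rc}$.

**Ensembles.**  `ensemble_shift_analysis()` draws a seeded sample of trees
(default without replacement) from a posterior set, fits all models to
each, classifies each fitted shift by comparing the epoch rate younger than
the shift against the older one (increase vs decrease), and reports class
means with 2.5/97.5% quantile intervals plus the fraction of trees
exceeding the critical value.  Whether one pooled critical value or one per
tree is appropriate is genuinely open; pooled (simulated once under the
median constant-rate fit) is the default for cost, per-tree is a flag.

**Net diversification.**  `magallon_sanderson()` implements the stem
estimator $r = \ln(n(1-\epsilon) + \epsilon)/t$ and the crown estimator

$$\hat r = \frac1t\left[\ln\!\left(\frac{n(1-\epsilon^2)}{2} + 2\epsilon +
\frac{(1-\epsilon)\sqrt{n(n\epsilon^2 - 8\epsilon + 2n\epsilon + n)}}{2}\right) - \ln 2\right],$$

for standing diversity $n$, clade age $t$ (Myr) and relative extinction
$\epsilon = \mu/\lambda \in [0,1)$.  At $\epsilon = 0$ the crown form
reduces to $\ln(n/2)/t$.  The estimate is decreasing in $\epsilon$ and
increasing in $n$ (property-tested).

## The synthetic-data generators

Every analysis stage is exercised against generators with known truth,
seeded and bit-reproducible.

* **`sim_yule()` / `sim_yule_shift()`** produce the reconstructed
  (piecewise) pure-birth process conditioned on the tip count by an exact
  backward construction: from the present, inter-event waits have hazard
  $k\,\lambda(\text{age})$, inverted analytically across epoch boundaries,
  and each event joins two uniformly chosen lineages.  Epoch rates are
  anchored in age before present (oldest epoch first), matching how shift
  times are reported; a forward-in-time growth cannot know the present
  until it stops, whereas the backward construction has, for constant
  rates, exactly the law of forward growth conditioned on $n$ tips.
  Unconditioned, a tree may crown *after* the oldest shift age and so never
  experience the older epochs; recovery and power experiments therefore
  condition on `min_crown_age = max(shift_ages)` (simple rejection), while
  the default stays unconditioned so that equal epoch rates reproduce the
  constant-rate law exactly.
* **`sim_bd()`** grows the complete birth-death tree forward from two crown
  lineages, stops when `n_tips` lineages are simultaneously extant (plus an
  exponential stretch to the present), prunes extinct lineages and rejects
  runs that die out (cap $10^5$).  Simple rejection was chosen over
  generalized-sampling corrections for transparency; the resulting small
  stopping bias is well inside the statistical noise of the recovery checks
  (net rate inside its 95% profile interval, extinction fraction notoriously
  hard to pin down).
* **`sim_species_coalescent()`** emulates the regime GMYC assumes: samples
  coalesce within their species under a Kingman coalescent whose
  *expected pairwise coalescence time* is `coalescent_scale` (in Myr — a
  deliberately unit-free parameterization instead of an
  $N_e \times$ generation-time one, because the analysis operates on
  time-calibrated trees), and the species' single ancestral lineages join
  exactly at the species-tree node ages.  There is deliberately *no* deep
  coalescence or shared ancestral polymorphism: runs where a species fails
  to coalesce below its parent divergence are redrawn.  Consequently,
  passing recovery tests show the delimitation machinery works where its
  assumptions hold; they say nothing about robustness to incomplete lineage
  sorting, gene flow, or uneven sampling, which real data may violate.
* **`sim_sequences()`** evolves sites under GTR with discrete-Gamma rate
  heterogeneity (equal-probability categories, category means, default 4
  categories), delegating the per-site simulation to phangorn with branch
  lengths scaled by `subst_rate` (substitutions/site/Myr).  Defaults are
  COI-like: AT-rich base frequencies, transition-biased exchangeabilities,
  strong rate heterogeneity.  Optional masking replaces a contiguous run at
  a random end of each sequence with `N`, emulating partial-length
  fragments to exercise the deduplication filter; indels are out of scope.

**Experiment sizes.**  The bundled experiments use 10 species × 4 samples
for delimitation recovery, 100-tip trees for shift recovery, 50-tree
ensembles, and 1000 + 500 simulations for critical-value calibration —
sizes at which the Monte-Carlo noise of each check is comfortably below
the margins being asserted.  For the "deep divergence" delimitation regime
the within-species coalescent scale is set to 1/50 of the shallowest
species divergence: at that separation the threshold window is
unambiguous, whereas near the minimal 20× separation the single-threshold
model begins (correctly, given its likelihood) to absorb outlying shallow
speciations into the coalescent process.

## Degenerate inputs and numerical conventions

Saturated or zero-overlap sequence pairs are flagged, never silently
dropped; clustering logs them.  Trees must be rooted, binary and
ultrametric within a relative tolerance (default $10^{-6}$; BEAST exports
carry rounding noise), tips are normalized to age exactly 0, and
polytomies are resolved only on request (zero-length, seeded).  Ties among
equal node ages produce zero-length intervals that contribute no waiting
time.  Likelihood optimizations clamp infeasible parameter points to a
large penalty rather than erroring inside the optimizer, and every fit
reports which starts converged when it fails.

## Known limitations

The multiple-threshold search is greedy and can stop at a local optimum;
the single-threshold profile is exhaustive over candidates and exact given
the per-candidate optimization.  Tree uncertainty enters only at the
ensemble level (fits per sampled tree), never inside a likelihood.  The
LR test's df = 3 convention ignores the boundary problem.  No
fossilized-birth-death, serial sampling, density-dependent (SPVAR-style)
models, or Bayesian delimitation.
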