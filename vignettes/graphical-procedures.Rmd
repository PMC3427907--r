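---
title: "Graphical multiple test procedures: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphical multiple test procedures: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphMCT)
```

## The problem

A confirmatory clinical trial rarely asks one question. Two dose levels
against control, a primary and a secondary endpoint, non-inferiority and
superiority claims — each is a null hypothesis, and regulators expect the
familywise error rate (FWER), the probability of rejecting *any* true
null, to stay below a one-sided level such as $\alpha = 0.025$ no matter
which hypotheses happen to be true.

The closed testing principle turns this into a family of local tests: for
$m$ hypotheses $H_1,\dots,H_m$, reject $H_i$ only if every intersection
hypothesis $H_J = \bigcap_{j \in J} H_j$ with $i \in J$ is rejected by a
level-$\alpha$ test. Strong FWER control follows for free; the work lies
in choosing the $2^m - 1$ local tests so that they reflect the trial's
priorities and remain interpretable.

## Weighting strategies as graphs

This package separates *what the local tests weight* from *how they
test*. A weighting strategy assigns weights $w_j(J) \ge 0$,
$\sum_{j \in J} w_j(J) \le 1$, to every intersection. Rather than writing
down $m\,2^{m-1}$ numbers, the strategy is generated from a directed
weighted graph: initial weights $w_i$ on the vertices (the local level
shares for the global intersection) and a transition matrix
$G = (g_{ij})$ with $g_{ii} = 0$ and row sums at most 1, where $g_{ij}$
is the fraction of $H_i$'s level passed to $H_j$ when $H_i$ is removed.

Removing vertex $j$ updates the graph by
$$w_l \leftarrow w_l + w_j g_{jl}, \qquad
  g_{kl} \leftarrow \frac{g_{kl} + g_{kj} g_{jl}}{1 - g_{kj} g_{jk}},$$
the latter set to 0 when $g_{kj} g_{jk} \ge 1$ (a two-cycle that returns
all level to the removed pair; the guard avoids a division by zero and is
exercised by the truncated-Holm strategy at $\gamma = 1$). The weights of
any intersection $J$ are obtained by removing the complement of $J$ in
any order; order invariance is a theorem for this update rule and a
property test in the suite (`test-graph.R`). `closure_weights()`
enumerates all subsets (bitmask encoding, 0-based internally, `H1..Hm`
labels in output) and is guarded at $m \le 20$, the point where a
$2^m$-row table stops being a desk-scale object.

Hypotheses absent from an intersection have *no* weight there, and the
package represents them as `NA`, never as 0 — a weight of exactly 0 is
meaningful (a secondary hypothesis not yet reachable) and must not be
confused with absence.

```{r}
closure_weights(standard_graph("hierarchical"))
```

## Three families of local tests

**Weighted Bonferroni.** Reject $H_J$ if $p_j \le w_j(J)\alpha$ for some
$j \in J$. When the weights are monotone across nested intersections
(`check_monotonicity()`), the closed procedure is consonant and collapses
to the sequentially rejective graph algorithm: reject any vertex with
$p_j \le w_j \alpha$, remove it, repeat. `bonferroni_sequential()` takes
the smallest eligible index first; invariance of the final decisions to
this tie-break is part of the test suite, and the explicit closure
(`bonferroni_closed()`) serves as the oracle.

**Weighted parametric (min-p).** If the joint null distribution of the
one-sided $z$ statistics is known within blocks $I_1,\dots,I_l$ of a
partition (and unknown across), the Bonferroni bound can be sharpened:
reject $H_J$ if $p_j \le c_J w_j(J) \alpha$ for some $j$, where
$c_J \ge 1$ is the largest constant with
$$\sum_{h=1}^{l} P\Bigl(\bigcup_{j \in J \cap I_h}
  \{P_j \le c_J\, w_j(J)\,\alpha\}\Bigr) = \alpha .$$
With one block this is an exact min-p test; with all singleton blocks it
degrades gracefully to weighted Bonferroni. Unknown entries in the
correlation matrix are written `NA`; the pattern must be exactly
block-diagonal under some ordering, and anything else is rejected rather
than approximated, because the blockwise bound is only valid for a
partition. Zero-weight hypotheses contribute nothing to the union (for
continuous p-values $P(P_j \le 0) = 0$), which is why models with
perfectly correlated statistics still work: only the degenerate
coordinates that actually carry weight enter the orthant probability.

**Weighted Simes.** Under positive regression dependence (e.g.
multivariate normal statistics with nonnegative correlations, one-sided
tests), reject $H_J$ if some $p_j$ does not exceed $\alpha$ times the
cumulative weight $\sum_{k \in J: p_k \le p_j} w_k(J)$, ties included.
Equal weights recover the classical Simes test and the closed procedure
recovers Hommel's (cross-checked against an independent brute-force
oracle in the suite). PRD is the analyst's assertion — the package
documents it and applies the `prd_partition()` blocks, but cannot verify
it. When PRD holds only within blocks, the Simes criterion is applied per
block and the blocks are combined by Bonferroni
(`simes_closed_partitioned()`); singleton blocks again reduce to
weighted Bonferroni.

## Shortcuts, consonance, and how to restore it

A closed procedure is *consonant* when every rejected intersection
contains a rejectable elementary hypothesis; only then does a sequential
shortcut exist. For the parametric test the condition is monotonicity of
the local critical values, $c_{J'} w_j(J') \ge c_J w_j(J)$ for
$J' \subseteq J$, checked exhaustively by `check_consonance()`. The
two-dose hierarchical strategy with correlated primaries *fails* it: the
four-way intersection borrows strength from the correlation
($c_J = 1.0783$ at $\rho = 0.5$, local level 1.35%) while
$\{H_1, H_3, H_4\}$ cannot (1.25%), so `parametric_sequential()` refuses
to run and the full closure must be used.

Consonance can be bought by redirecting a fraction $\delta$ of each
primary's level to the other primary
(`standard_graph("hierarchical_delta", delta = )`).
`min_consonance_delta()` bisects for the smallest workable $\delta$
(tolerance $10^{-6}$); at $\rho = 0.5$, $\alpha = 0.025$ it returns
$\delta^* = 0.0783$, the primary-pair critical excess $c - 1$. The price
is visible in the local levels (1.15% instead of 1.25% for the secondary
in three-way intersections) and in decisions: on the worked four-vector
of p-values the plain strategy rejects $H_1$ and $H_3$, the consonant one
only $H_1$. Enforced consonance is not a free lunch, and the package
deliberately reports both routes.

The Simes closure has no full shortcut, but a partially sequential form
(`simes_sequential()`) settles the common cases first: all $p > \alpha$
(retain everything), all $p \le \alpha$ with exhaustive weights (reject
everything — this step is *skipped* when `check_exhaustive()` fails,
because its justification needs every closure row to sum to 1), then the
Bonferroni graph pass; only if more than two hypotheses survive is the
survivor closure enumerated. The two-survivor stopping rule follows from
the level bookkeeping of the Bonferroni pass: with at most two survivors
left, the Simes criterion cannot rescue either of them. Identity with the
direct closure is asserted on 500 random exhaustive strategies per run.

## Numerical choices

* All weight and probability comparisons use an absolute tolerance of
  $10^{-9}$: the quantities are pure arithmetic on fractions, with no
  statistical noise to absorb.
* Multivariate normal orthant probabilities: dimensions 2–3 use the
  deterministic TVPACK algorithm ($10^{-12}$), higher dimensions Miwa
  quadrature (4097 steps), with a quasi-Monte-Carlo fallback pinned to a
  fixed internal RNG state so every code path is reproducible to at least
  6 decimals. Perfectly correlated coordinates are merged (minimum
  threshold) before the call, so degenerate designs — e.g.
  non-inferiority and superiority statistics of the same contrast,
  $\rho = 1$ — are handled exactly rather than failing a Cholesky step.
* $c_J$ is found by `uniroot` on $[1,\ (1-10^{-9})/(\alpha \max_j w_j)]$
  at tolerance $10^{-10}$; the bracket keeps every threshold strictly
  below 1. An exactly exhausted level at $c = 1$ short-circuits to 1.
* Parametric adjusted p-values use the direct union-probability formula
  at the observed weighted min-p threshold, not nested root finding; the
  two definitions coincide (the union probability is increasing in the
  threshold) and the equivalence is itself a property test against a
  bisection oracle.
* Simes adjusted p-values use the min-ratio with cumulative weights.
  This is an extension — the closure literature defines the rejection
  rule, not an adjusted p — chosen as the unique value consistent with
  the rejection decisions at every level, which is asserted on a level
  grid in the suite.
* Division conventions: $x/0 = +\infty$ for zero weights, adjusted
  p-values capped at 1, all-zero-weight intersections get local p-value 1
  (they can never be rejected).

## What the simulator emulates, and what it does not

`simulate_pvalues()` draws $Z \sim N(\theta, R)$ with a *complete*
correlation matrix $R$ (the generating truth, as opposed to the
analyst's partial `correlation_model`) and returns one-sided p-values
$1 - \Phi(Z)$. This embodies the standard analysis-of-variance setting
with known common variance under which the parametric test is derived.
It does not emulate estimated variances (t statistics), discreteness,
model misspecification, or non-normal dependence — a passing FWER
simulation therefore validates the procedures *under their own
assumptions*, not robustness beyond them. One replicate matrix is shared
across compared procedures (paired comparison; the power-dominance checks
would otherwise need far more replicates).

Validation problem sizes: worked examples use the four-hypothesis
strategies they were published with; property suites run hundreds of
random graphs at $m \le 6$; FWER checks use $10^5$ replicates for the
headline bounds (binomial SE $\approx 0.0005$ at $\alpha = 0.025$) and
$2\times 10^4$ for the per-configuration sweep, whose purpose is bound
violation detection rather than precision.

## Limitations

* Only one-sided multivariate normal statistics are supported in the
  parametric path; Dunnett-t critical constants would need the noncentral
  t machinery and are out of scope.
* Simultaneous confidence intervals for graph procedures are not
  computed.
* Infinitesimal ("$\varepsilon$") edges are not modelled; strategies that
  need them (e.g. strict successiveness with full level recycling) must
  be approximated with small numeric weights chosen by the user.
* The closure engine enumerates all $2^m - 1$ subsets; beyond the
  $m \le 20$ guard — and practically beyond $m \approx 12$ — specialised
  shortcut implementations would be needed.
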