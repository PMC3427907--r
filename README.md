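# graphMCT

Graphical multiple comparison procedures for clinical-trial multiplicity
control: weighted Bonferroni, weighted parametric (min-p) and weighted
Simes tests built on graph-generated closed test procedures.

## What it does

Confirmatory trials test several hypotheses at once — doses against
control, primary and secondary endpoints, non-inferiority and
superiority — and must control the familywise error rate (FWER) in the
strong sense. `graphMCT` encodes the trial's testing strategy as a
directed weighted graph: vertex weights $w_i$ are shares of the
significance level, and an edge weight $g_{ij}$ is the fraction of
$H_i$'s level passed to $H_j$ once $H_i$ is rejected. The graph induces
weights $w_j(J)$ for every intersection hypothesis of the closure via the
update rule

$$w_l \leftarrow w_l + w_j g_{jl}, \qquad
  g_{kl} \leftarrow \frac{g_{kl} + g_{kj}g_{jl}}{1 - g_{kj}g_{jk}},$$

and any of three local tests can then be applied to the closure:

* **weighted Bonferroni** — reject $H_J$ if $p_j \le w_j(J)\,\alpha$ for
  some $j$; equivalent to the familiar sequentially rejective graph
  algorithm when the weights are monotone;
* **weighted parametric** — reject if
  $p_j \le c_J\, w_j(J)\,\alpha$, with $c_J \ge 1$ calibrated from the
  (fully or blockwise) known multivariate normal null distribution of the
  test statistics;
* **weighted Simes** — reject if some $p_j \le \alpha\sum_{k \in J:\,
  p_k \le p_j} w_k(J)$, valid under positive regression dependence.

The package also provides consonance, monotonicity and exhaustiveness
diagnostics, adjusted p-values, the minimal consonance-enforcing edge
weight $\delta^*$ for the two-dose hierarchical design, standard
constructors (Holm, fixed sequence, fallback, truncated-Holm
gatekeeping), Monte-Carlo FWER/power estimation, and a small CLI
(`inst/cli/graphmct`).

## Worked example

Two dose levels, each with a hierarchically ordered primary and
secondary endpoint; the primary p-values are correlated within the pairs
$\{H_1,H_2\}$ and $\{H_3,H_4\}$ ($\rho = 0.5$, unknown across):

```r
library(graphMCT)

g <- standard_graph("hierarchical")   # weights (1/2, 1/2, 0, 0)
cr <- matrix(NA_real_, 4, 4); diag(cr) <- 1
cr[1, 2] <- cr[2, 1] <- cr[3, 4] <- cr[4, 3] <- 0.5

parametric_closed(g, c(0.0131, 0.1, 0.012, 0.01), cr, alpha = 0.025)
#> closed weighted parametric (alpha = 0.025)
#>   hypothesis adjusted_p rejected
#> 1         H1     0.0243     TRUE
#> 2         H2     0.1000    FALSE
#> 3         H3     0.0243     TRUE
#> 4         H4     0.1000    FALSE

bonferroni_closed(g, c(0.0131, 0.1, 0.012, 0.01), 0.025)$rejected
#>    H1    H2    H3    H4
#> FALSE FALSE FALSE FALSE
```

Exploiting the known within-pair correlation rejects the high-dose
primary and secondary claims (adjusted p = 0.0243 ≤ 0.025), while the
correlation-agnostic Bonferroni procedure rejects nothing on the same
data. The adjusted p-value is the largest blockwise union probability
over all intersections containing the hypothesis — the smallest level at
which the closed procedure still rejects it.

The same analysis from a shell:

```sh
inst/cli/graphmct test --kind hierarchical \
  --pvalues 0.0131,0.1,0.012,0.01 --method parametric \
  --corr corr.csv --alpha 0.025
```

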