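test_that("correlation model derives the block partition and rejects bad patterns", {
  cm <- block_corr(0.5)
  expect_equal(cm$blocks, list(c(1L, 2L), c(3L, 4L)))
  expect_equal(length(correlation_model(diag(3))$blocks), 1L)

  M <- matrix(NA_real_, 3, 3); diag(M) <- 1
  expect_equal(length(correlation_model(M)$blocks), 3L)  # all singletons

  # chain 1-2 known, 2-3 known, 1-3 unknown: not block-diagonal
  M[1, 2] <- M[2, 1] <- 0.3; M[2, 3] <- M[3, 2] <- 0.3
  expect_error(correlation_model(M), "block-diagonal")

  B <- matrix(c(1, 0.5, 0.4, 1), 2, 2)
  expect_error(correlation_model(B), "symmetric")
  B2 <- matrix(c(1, -0.99, -0.99, 1), 2, 2); diag(B2) <- c(1, 2)
  expect_error(correlation_model(B2), "unit diagonal")
})

test_that("critical constant matches the Dunnett and Sidak benchmarks", {
  # two statistics, rho = 0.5, equal weights, alpha = 0.025
  cc <- critical_constant(c(0.5, 0.5), matrix(c(1, 0.5, 0.5, 1), 2, 2), 0.025)
  expect_equal(round(cc, 4), 1.0783)

  # three independent, equal weights 1/3, alpha = 0.05: per-hypothesis
  # critical value solves 1 - (1 - x)^3 = 0.05
  cc3 <- critical_constant(rep(1/3, 3), diag(3), 0.05)
  expect_equal(cc3 * (1/3) * 0.05, 1 - 0.95^(1/3), tolerance = 1e-7)
  expect_equal(round(cc3 * (1/3) * 0.05, 5), 0.01695)

  # singleton with full weight: c = 1, critical value alpha
  expect_equal(critical_constant(1, matrix(1, 1, 1), 0.025), 1)

  # unequal weights (1/3, 2/3), independent: closed form (1-a)(1-2a) = 0.95
  cc12 <- critical_constant(c(1/3, 2/3), diag(2), 0.05)
  a <- cc12 * (1/3) * 0.05
  expect_equal((1 - a) * (1 - 2 * a), 0.95, tolerance = 1e-7)
  expect_equal(a, (3 - sqrt(8.6)) / 4, tolerance = 1e-7)  # quadratic root
  expect_lt(a, 1 - 0.95^(1/3))  # below the three-way Sidak critical value

  expect_error(critical_constant(c(0, 0), diag(2), 0.025), "all weights")
  expect_gte(critical_constant(c(0.3, 0.3), diag(2), 0.025), 1 / 0.6 - 1e-6)
})

test_that("independence closed form holds for equal weights", {
  for (k in 2:4) for (alpha in c(0.025, 0.05)) {
    cc <- critical_constant(rep(1/k, k), diag(k), alpha)
    expect_equal(1 - (1 - cc * alpha / k)^k, alpha, tolerance = 1e-6)
  }
})

test_that("local parametric p-values reproduce the command-line example", {
  g <- hier_graph()
  tab <- closure_weights(g)
  p <- c(0.0131, 0.1, 0.012, 0.01)
  lp <- local_pvalue_parametric(1:4, p, tab, block_corr(0.5))
  expect_equal(round(lp, 8), 0.02431856)

  # singleton: local p is the raw p-value
  expect_equal(local_pvalue_parametric(2, p, tab, block_corr(0.5)), 0.1)

  # unknown cross-correlation collapses to the Bonferroni bound
  lp14 <- local_pvalue_parametric(c(1, 4), p, tab, block_corr(0.5))
  expect_equal(lp14, min(2 * min(p[1] / 1, p[4] / 1) * 1, 2 * 0.01))
})

test_that("local p-value equals the smallest rejecting level (root-finding oracle)", {
  set.seed(31)
  g <- hier_graph()
  tab <- closure_weights(g)
  cm <- block_corr(0.5)
  masks_all <- tab$masks
  for (rep in 1:12) {
    p <- runif(4, 0.001, 0.3)
    mk <- sample(masks_all, 1)
    J <- which(bitwAnd(mk, 2^(0:3)) > 0)
    w <- tab$weights[match(mk, tab$masks), J]
    if (all(w < 1e-9)) next
    lp <- local_pvalue_parametric(J, p, tab, cm)
    # oracle: bisect the level q at which the weighted parametric test with
    # critical constant c_J(q) first rejects H_J
    rejects_at <- function(q) {
      cc <- critical_constant(w, cm$matrix[J, J, drop = FALSE], q)
      any(p[J] <= cc * w * q + 1e-12)
    }
    lo <- 1e-6; hi <- 0.999
    if (rejects_at(lo)) { expect_lte(lp, lo + 1e-6); next }
    if (!rejects_at(hi)) { expect_gte(lp, hi - 1e-6); next }
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (rejects_at(mid)) hi <- mid else lo <- mid
    }
    expect_equal(lp, hi, tolerance = 1e-8)
  }
})

test_that("closed parametric test dominates Bonferroni and matches the example", {
  g <- hier_graph()
  p <- c(0.0131, 0.1, 0.012, 0.01)
  res <- parametric_closed(g, p, block_corr(0.5), 0.025)
  expect_equal(unname(res$rejected), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(round(res$adjusted_p, 8)),
               c(0.02431856, 0.1, 0.02431856, 0.1))
  expect_false(any(bonferroni_closed(g, p, 0.025)$rejected))

  resp1 <- parametric_closed(g, rep(1, 4), block_corr(0.5), 0.025)
  expect_false(any(resp1$rejected))
  expect_equal(unname(resp1$adjusted_p), rep(1, 4))

  # dominance on random instances
  set.seed(32)
  for (rep in 1:15) {
    m <- sample(2:4, 1)
    gg <- random_graph(m)
    cm <- correlation_model(random_block_corr(m))
    pp <- runif(m, 0, 0.2)
    rb <- unname(bonferroni_closed(gg, pp, 0.025)$rejected)
    rp <- unname(parametric_closed(gg, pp, cm, 0.025)$rejected)
    expect_true(all(rb <= rp))
  }
})

test_that("local significance levels reproduce the published table", {
  g <- hier_graph()
  ll <- local_levels(g, block_corr(0.5), 0.025)
  expect_equal(round(ll["H1 ∩ H2 ∩ H3 ∩ H4", "H1"], 2), 1.35)
  expect_equal(round(ll["H1 ∩ H3", "H1"], 2), 2.50)
  expect_equal(round(ll["H1 ∩ H3 ∩ H4", "H4"], 2), 1.25)
  expect_equal(round(ll["H3 ∩ H4", "H3"], 2), 1.35)

  lld <- local_levels(standard_graph("hierarchical_delta", delta = 0.0783),
                      block_corr(0.5), 0.025)
  expect_equal(round(lld["H1 ∩ H3 ∩ H4", "H4"], 2), 1.15)
  expect_equal(round(lld["H1 ∩ H3 ∩ H4", "H1"], 2), 1.35)
})

test_that("consonance check separates the plain and delta-modified strategies", {
  g <- hier_graph()
  res <- check_consonance(g, block_corr(0.5), 0.025)
  expect_false(res$pass)
  v <- res$violations
  expect_true(any(v$subset == "H1 ∩ H3 ∩ H4" &
                  v$superset == "H1 ∩ H2 ∩ H3 ∩ H4" & v$hypothesis == "H1"))

  gd <- standard_graph("hierarchical_delta", delta = 0.0783)
  expect_true(check_consonance(gd, block_corr(0.5), 0.025)$pass)

  # Sidak-type counter-example: cyclic propagation on three independent
  # hypotheses gives pairwise weights (2/3, 1/3) and breaks consonance
  G <- matrix(0, 3, 3); G[1, 2] <- G[2, 3] <- G[3, 1] <- 1
  cyc <- hypothesis_graph(paste0("H", 1:3), rep(1/3, 3), G)
  expect_false(check_consonance(cyc, diag(3), 0.05)$pass)
})

test_that("sequential parametric shortcut follows the known rejection path", {
  # all four correlations known: non-inferiority/superiority within dose are
  # perfectly correlated, everything else 0.5
  cm3 <- matrix(0.5, 4, 4); diag(cm3) <- 1
  cm3[1, 3] <- cm3[3, 1] <- cm3[2, 4] <- cm3[4, 2] <- 1
  g <- hier_graph()
  res <- parametric_sequential(g, c(0.01, 0.02, 0.005, 0.5), cm3, 0.025)
  expect_equal(res$trace$hypothesis, c("H1", "H3", "H2"))
  expect_equal(unname(res$rejected), c(TRUE, TRUE, TRUE, FALSE))
  # H2 is tested at the full level in the last step
  expect_equal(res$trace$local_level[3], 0.025)

  res0 <- parametric_sequential(g, rep(1, 4), cm3, 0.025)
  expect_false(any(res0$rejected))

  # consonant delta graph rejects only H1 where the plain graph rejected two
  gd <- standard_graph("hierarchical_delta", delta = 0.0783)
  resd <- parametric_sequential(gd, c(0.0131, 0.1, 0.012, 0.01),
                                block_corr(0.5), 0.025)
  expect_equal(unname(resd$rejected), c(TRUE, FALSE, FALSE, FALSE))

  # non-consonant strategy refuses the shortcut
  expect_error(parametric_sequential(g, rep(0.01, 4), block_corr(0.5), 0.025),
               "consonant")
})

test_that("sequential parametric decisions equal the closed test when consonant", {
  set.seed(33)
  cm3 <- matrix(0.5, 4, 4); diag(cm3) <- 1
  cm3[1, 3] <- cm3[3, 1] <- cm3[2, 4] <- cm3[4, 2] <- 1
  g <- hier_graph()
  for (rep in 1:10) {
    p <- runif(4, 0, 0.3)
    expect_equal(parametric_sequential(g, p, cm3, 0.025)$rejected,
                 parametric_closed(g, p, cm3, 0.025)$rejected)
  }
})

test_that("minimal consonance delta matches the published bound and is monotone in rho", {
  d05 <- min_consonance_delta(block_corr(0.5), 0.025)
  expect_equal(round(d05, 4), 0.0783)

  # independence: delta* equals the Sidak-style excess c - 1
  d0 <- min_consonance_delta(block_corr(0), 0.025)
  c0 <- critical_constant(c(0.5, 0.5), diag(2), 0.025)
  expect_equal(d0, c0 - 1, tolerance = 1e-4)
  expect_lt(d0, d05)

  # perfect correlation within the primary pair degenerates the graph
  d1 <- min_consonance_delta(block_corr(1), 0.025)
  expect_equal(d1, 1, tolerance = 1e-4)
})

test_that("dose-versus-control correlation follows the sample-size formula", {
  expect_equal(dunnett_correlation(10, 10, 10), 0.5)
  expect_equal(dunnett_correlation(100, 50, 50), 1/3)
  expect_lt(dunnett_correlation(1e7, 50, 50), 1e-2)
  expect_error(dunnett_correlation(0, 10, 10), "positive")
})
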