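## Weighted parametric (min-p) closed tests for one-sided multivariate
## normal test statistics with fully or partially known correlations.

#' Correlation model with possibly unknown entries
#'
#' Describes what is known about the joint null distribution of the
#' one-sided z statistics: entries are correlations in [-1, 1] where the
#' pairwise joint distribution is known and \code{NA} where it is not.
#' The known/unknown pattern must be block-diagonal under some ordering;
#' the induced partition into blocks is derived and stored.  Within each
#' block the weighted parametric test uses exact multivariate normal
#' probabilities; across blocks the Bonferroni inequality is applied.
#'
#' @param matrix square numeric matrix, unit diagonal, symmetric, with
#'   \code{NA} marking unknown correlations.
#' @return Object of class \code{"correlation_model"}: list with
#'   \code{matrix} and \code{blocks} (list of index vectors).
#' @examples
#' cr <- matrix(NA_real_, 4, 4); diag(cr) <- 1
#' cr[1, 2] <- cr[2, 1] <- cr[3, 4] <- cr[4, 3] <- 0.5
#' correlation_model(cr)
#' @export
correlation_model <- function(matrix) {
  M <- as.matrix(matrix)
  m <- nrow(M)
  if (m != ncol(M)) stop_validation("correlation matrix must be square")
  if (any(abs(diag(M) - 1) > .wtol, na.rm = TRUE) || anyNA(diag(M)))
    stop_validation("correlation matrix must have a unit diagonal")
  known <- !is.na(M)
  if (!isTRUE(all.equal(known, t(known))) ||
      any(abs(M - t(M)) > .wtol, na.rm = TRUE))
    stop_validation("correlation matrix must be symmetric (including the NA pattern)")
  if (any(M < -1 - .wtol | M > 1 + .wtol, na.rm = TRUE))
    stop_validation("correlations must lie in [-1, 1]")
  ## connected components of the 'known' relation give candidate blocks
  blocks <- list()
  seen <- rep(FALSE, m)
  for (i in seq_len(m)) {
    if (seen[i]) next
    comp <- i
    repeat {
      nb <- which(apply(known[comp, , drop = FALSE], 2L, any))
      nb <- setdiff(nb, comp)
      if (!length(nb)) break
      comp <- sort(c(comp, nb))
    }
    seen[comp] <- TRUE
    blocks[[length(blocks) + 1L]] <- comp
  }
  ## the pattern is block-diagonal iff every within-component pair is known
  for (b in blocks) {
    if (!all(known[b, b]))
      stop_validation(paste("the known/unknown pattern is not block-diagonal:",
                            "indices %s are linked by known correlations but some",
                            "pairwise entries among them are unknown"),
                      paste(b, collapse = ","))
    ev <- eigen(M[b, b, drop = FALSE], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop_validation("correlation block {%s} is not positive semidefinite",
                      paste(b, collapse = ","))
  }
  structure(list(matrix = M, blocks = blocks), class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("Correlation model on %d statistics, %d block(s): %s\n",
              nrow(x$matrix), length(x$blocks),
              paste(vapply(x$blocks, function(b) paste0("{", paste(b, collapse = ","), "}"),
                           ""), collapse = " ")))
  print(x$matrix, ...)
  invisible(x)
}

## restrict a correlation model to a subset of indices (keeps block structure)
restrict_corr <- function(corr, J) {
  correlation_model(corr$matrix[J, J, drop = FALSE])
}

as_corr_model <- function(corr) {
  if (inherits(corr, "correlation_model")) corr else correlation_model(corr)
}

## Deterministic lower-orthant probability P(Z_1 <= u_1, ..., Z_k <= u_k)
## for standard multivariate normal Z with correlation matrix R.
## Coordinates that are perfectly correlated (rho >= 1 - 1e-9) are merged
## (minimum threshold) so that degenerate models remain computable; dims
## 2-3 use the deterministic TVPACK algorithm, larger dims Miwa quadrature
## with a quasi-Monte-Carlo fallback under a locally fixed RNG state.
mvn_lower <- function(upper, R) {
  k <- length(upper)
  if (k == 0L) return(1)
  if (k == 1L) return(stats::pnorm(upper))
  ## merge duplicated coordinates (rho ~ 1)
  grp <- seq_len(k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
    if (R[i, j] >= 1 - 1e-9) grp[grp == grp[j]] <- grp[i]
  ug <- unique(grp)
  if (length(ug) < k) {
    upper <- vapply(ug, function(g) min(upper[grp == g]), numeric(1))
    rep_idx <- vapply(ug, function(g) which(grp == g)[1], integer(1))
    R <- R[rep_idx, rep_idx, drop = FALSE]
    k <- length(upper)
    if (k == 1L) return(stats::pnorm(upper))
  }
  if (any(!is.finite(upper))) {
    if (any(upper == -Inf)) return(0)
    fin <- is.finite(upper)
    return(mvn_lower(upper[fin], R[fin, fin, drop = FALSE]))
  }
  val <- if (k <= 3L) {
    tryCatch(mvtnorm::pmvnorm(lower = -Inf, upper = upper, corr = R,
                              algorithm = mvtnorm::TVPACK(1e-12)),
             error = function(e) NULL)
  } else {
    tryCatch(mvtnorm::pmvnorm(lower = -Inf, upper = upper, corr = R,
                              algorithm = mvtnorm::Miwa(steps = 4097)),
             error = function(e) NULL)
  }
  if (is.null(val) || is.na(val)) {
    ## quasi-Monte-Carlo fallback, made reproducible by pinning the RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
              rm(".Random.seed", envir = globalenv()), add = TRUE)
    set.seed(20110812L)
    val <- mvtnorm::pmvnorm(lower = -Inf, upper = upper, sigma = R,
                            algorithm = mvtnorm::GenzBretz(abseps = 1e-9, maxpts = 1e6))
  }
  min(max(as.numeric(val), 0), 1)
}

## P(union over active j of {P_j <= q_j}) within one block, for one-sided
## normal p-values: 1 - P(all Z_j <= Phi^{-1}(1 - q_j)).
block_union_prob <- function(q, R) {
  if (!length(q)) return(0)
  1 - mvn_lower(stats::qnorm(1 - pmin(pmax(q, 0), 1)), R)
}

## sum of blockwise union probabilities at per-hypothesis p-value
## thresholds q (length = |J|), given a correlation model on J
joint_exceedance <- function(q, corr) {
  active <- which(q > 0)
  tot <- 0
  for (b in corr$blocks) {
    ba <- intersect(b, active)
    if (!length(ba)) next
    tot <- tot + block_union_prob(q[ba], corr$matrix[ba, ba, drop = FALSE])
  }
  tot
}

#' Critical constant of the weighted parametric test
#'
#' The weighted parametric (min-p) test rejects \eqn{H_J} if some
#' \eqn{p_j \le c_J w_j(J) \alpha}.  \eqn{c_J \ge 1} is the largest
#' constant at which the probability of this event under the null --
#' computed exactly within each correlation block and combined across
#' blocks by the Bonferroni inequality -- equals \eqn{\alpha}.
#'
#' @param weights nonnegative weights over the members of \eqn{J}, summing
#'   to at most 1.
#' @param corr a \code{\link{correlation_model}} (or plain matrix with
#'   \code{NA} for unknown entries) restricted to \eqn{J}.
#' @param alpha level in (0, 1).
#' @return The critical constant \eqn{c_J} (scalar, \eqn{\ge 1}).
#' @examples
#' cr <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
#' critical_constant(c(0.5, 0.5), cr, alpha = 0.025)  # 1.0783
#' @export
critical_constant <- function(weights, corr, alpha) {
  alpha <- check_alpha(alpha)
  w <- as.numeric(weights)
  if (any(w < -.wtol)) stop_validation("weights must be nonnegative")
  if (sum(w) > 1 + .wtol) stop_validation("weights sum to %g > 1", sum(w))
  corr <- as_corr_model(corr)
  if (nrow(corr$matrix) != length(w))
    stop_validation("correlation model dimension does not match weights")
  if (all(w <= .wtol))
    stop_validation("the critical constant is undefined when all weights are zero")
  f <- function(cc) joint_exceedance(cc * w * alpha, corr) - alpha
  upper <- (1 - 1e-9) / (alpha * max(w))
  f1 <- f(1)
  if (f1 > .wtol)
    stop_numeric("level condition already exceeded at c = 1")
  if (f1 >= 0 || upper <= 1) return(1)  # level exactly exhausted at c = 1
  if (f(upper) < 0)
    stop_numeric("no sign change when bracketing the critical constant")
  max(stats::uniroot(f, c(1, upper), tol = 1e-10)$root, 1)
}

#' Local p-value of the weighted parametric test for one intersection
#'
#' The smallest level at which the weighted parametric test rejects
#' \eqn{H_J}: with \eqn{t = \min_{j \in J, w_j(J) > 0} p_j / w_j(J)}, the
#' local p-value is the blockwise union probability
#' \eqn{\sum_h P(\bigcup_{j \in J \cap I_h} \{P_j \le w_j(J)\, t\})},
#' capped at 1.  Intersections whose weights are all zero get local
#' p-value 1 (they can never be rejected).
#'
#' @param J indices of the intersection's members.
#' @param p full vector of unadjusted p-values.
#' @param table \code{\link{closure_weights}} for the graph.
#' @param corr \code{\link{correlation_model}} on all \eqn{m} hypotheses.
#' @return Local p-value in (0, 1].
#' @export
local_pvalue_parametric <- function(J, p, table, corr) {
  m <- length(table$names)
  p <- check_pvalues(p, m)
  corr <- as_corr_model(corr)
  J <- sort(unique(as.integer(J)))
  w <- closure_row(table, mask_of(J))[J]
  active <- which(w > .wtol)
  if (!length(active)) return(1)
  t0 <- min(p[J][active] / w[active])
  sub <- restrict_corr(corr, J)
  min(joint_exceedance(pmin(w * t0, 1), sub), 1)
}

#' Closed weighted parametric test
#'
#' Applies the weighted parametric test to every intersection hypothesis
#' of the closure; \eqn{H_i} is rejected iff every intersection containing
#' it has local p-value at most \eqn{\alpha}.  Adjusted p-values are the
#' maxima of the local p-values.  For a given weighting strategy this
#' procedure dominates the closed weighted Bonferroni test.
#'
#' @inheritParams bonferroni_closed
#' @param corr \code{\link{correlation_model}} (or matrix with \code{NA}
#'   for unknown entries) for the test statistics.
#' @return An \code{"mct_outcome"}.
#' @examples
#' g <- standard_graph("hierarchical")
#' cr <- matrix(NA_real_, 4, 4); diag(cr) <- 1
#' cr[1, 2] <- cr[2, 1] <- cr[3, 4] <- cr[4, 3] <- 0.5
#' parametric_closed(g, c(0.0131, 0.1, 0.012, 0.01), cr, alpha = 0.025)
#' @export
parametric_closed <- function(graph, p, corr, alpha, table = NULL) {
  m <- length(graph$names)
  p <- check_pvalues(p, m)
  alpha <- check_alpha(alpha)
  corr <- as_corr_model(corr)
  if (nrow(corr$matrix) != m)
    stop_validation("correlation model dimension does not match the graph")
  if (is.null(table)) table <- closure_weights(graph)
  localp <- vapply(table$masks, function(mk)
    local_pvalue_parametric(indices_of(mk, m), p, table, corr), numeric(1))
  adj <- vapply(seq_len(m), function(i) {
    rows <- bitwAnd(table$masks, bitwShiftL(1L, i - 1L)) > 0L
    max(localp[rows])
  }, numeric(1))
  rejected <- adj <= alpha + .wtol
  mct_outcome("closed weighted parametric", graph$names, rejected, adj, alpha)
}

#' Table of local significance levels
#'
#' For every intersection hypothesis \eqn{H_J}, the level
#' \eqn{c_J w_j(J) \alpha} at which each member's p-value is compared
#' (with \eqn{c_J = 1} for the plain Bonferroni column).
#'
#' @inheritParams parametric_closed
#' @param percent report levels in percent (default \code{TRUE}).
#' @return Data frame with one row per intersection: member columns hold
#'   local levels (\code{NA} for absent members) and \code{c} holds the
#'   critical constant.
#' @export
local_levels <- function(graph, corr, alpha, percent = TRUE, table = NULL) {
  alpha <- check_alpha(alpha)
  corr <- as_corr_model(corr)
  m <- length(graph$names)
  if (is.null(table)) table <- closure_weights(graph)
  L <- table$weights * alpha
  cs <- rep(1, length(table$masks))
  for (r in seq_along(table$masks)) {
    J <- indices_of(table$masks[r], m)
    w <- table$weights[r, J]
    if (all(w <= .wtol)) next
    cs[r] <- critical_constant(w, restrict_corr(corr, J), alpha)
    L[r, J] <- cs[r] * w * alpha
  }
  out <- as.data.frame(if (percent) 100 * L else L)
  out$c <- cs
  out
}

#' Consonance check for the weighted parametric closed test
#'
#' The parametric closed test admits a sequentially rejective shortcut iff
#' the local critical values are monotone across nested intersections:
#' \eqn{c_{J'} w_j(J') \ge c_J w_j(J)} for every \eqn{J' \subseteq J} and
#' \eqn{j \in J'}.
#'
#' @inheritParams parametric_closed
#' @return List with \code{pass} and a \code{violations} data frame of
#'   (subset, superset, hypothesis, level_subset, level_superset).
#' @export
check_consonance <- function(graph, corr, alpha, table = NULL) {
  alpha <- check_alpha(alpha)
  corr <- as_corr_model(corr)
  m <- length(graph$names)
  if (is.null(table)) table <- closure_weights(graph)
  ## per-row local critical values c_J * w_j(J) * alpha
  lev <- matrix(NA_real_, length(table$masks), m)
  for (r in seq_along(table$masks)) {
    J <- indices_of(table$masks[r], m)
    w <- table$weights[r, J]
    cr <- if (all(w <= .wtol)) 1 else
      critical_constant(w, restrict_corr(corr, J), alpha)
    lev[r, J] <- cr * w * alpha
  }
  viol <- list()
  for (ri in seq_along(table$masks)) {
    sup <- table$masks[ri]
    sub <- bitwAnd(sup - 1L, sup)
    while (sub > 0L) {
      rs <- match(sub, table$masks)
      for (j in indices_of(sub, m)) {
        if (lev[rs, j] < lev[ri, j] - .wtol) {
          viol[[length(viol) + 1L]] <- data.frame(
            subset = subset_label(sub, table$names),
            superset = subset_label(sup, table$names),
            hypothesis = table$names[j],
            level_subset = lev[rs, j], level_superset = lev[ri, j])
        }
      }
      sub <- bitwAnd(sub - 1L, sup)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(subset = character(), superset = character(),
               hypothesis = character(), level_subset = numeric(),
               level_superset = numeric())
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Sequentially rejective weighted parametric test
#'
#' The shortcut of the closed weighted parametric test, valid only when
#' the consonance condition holds (checked first; a violation is an
#' error directing the user to \code{\link{parametric_closed}}): at each
#' step, compute the critical constant for the current index set, reject
#' any hypothesis with \eqn{p_j \le c_I w_j(I) \alpha}, update the graph,
#' and repeat.
#'
#' @inheritParams parametric_closed
#' @return An \code{"mct_outcome"} with the rejection trace; adjusted
#'   p-values come from the closed test (identical decisions).
#' @export
parametric_sequential <- function(graph, p, corr, alpha) {
  m <- length(graph$names)
  p <- check_pvalues(p, m)
  alpha <- check_alpha(alpha)
  corr <- as_corr_model(corr)
  table <- closure_weights(graph)
  cons <- check_consonance(graph, corr, alpha, table = table)
  if (!cons$pass)
    stop_validation(paste("the weighting strategy is not consonant at this level;",
                          "the shortcut does not apply -- use parametric_closed()"))
  g <- graph
  keep <- seq_len(m)
  trace <- list()
  repeat {
    if (!length(keep)) break
    w <- g$weights
    if (all(w <= .wtol)) break
    cc <- critical_constant(w, restrict_corr(corr, keep), alpha)
    elig <- which(p[keep] <= cc * w * alpha + .wtol)
    if (!length(elig)) break
    j <- elig[1]
    trace[[length(trace) + 1L]] <- data.frame(
      hypothesis = g$names[j], index = keep[j], local_level = cc * w[[j]] * alpha)
    if (length(keep) == 1L) { keep <- integer(0); break }
    g <- remove_hypothesis(g, j)
    keep <- keep[-j]
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(hypothesis = character(), index = integer(), local_level = numeric())
  rejected <- graph$names %in% trace$hypothesis
  closed <- parametric_closed(graph, p, corr, alpha, table = table)
  mct_outcome("sequential weighted parametric", graph$names, rejected,
              closed$adjusted_p, alpha, trace)
}

#' Smallest consonance-enforcing delta for the hierarchical strategy
#'
#' For the two-dose hierarchical strategy, consonance of the parametric
#' closed test can be enforced by adding primary-to-primary edges of
#' weight \eqn{\delta} (see \code{\link{standard_graph}} kind
#' \code{"hierarchical_delta"}).  This function bisects for the smallest
#' \eqn{\delta \in [0, 1]} at which the consonance check passes.
#'
#' @param corr \code{\link{correlation_model}} on the four hypotheses
#'   (within-pair correlations known).
#' @param alpha level in (0, 1).
#' @param tol bisection tolerance (default 1e-6).
#' @return The minimal \eqn{\delta^*}.
#' @examples
#' cr <- matrix(NA_real_, 4, 4); diag(cr) <- 1
#' cr[1, 2] <- cr[2, 1] <- cr[3, 4] <- cr[4, 3] <- 0.5
#' min_consonance_delta(cr, 0.025)  # 0.0783
#' @export
min_consonance_delta <- function(corr, alpha, tol = 1e-6) {
  alpha <- check_alpha(alpha)
  corr <- as_corr_model(corr)
  if (nrow(corr$matrix) != 4L)
    stop_validation("the delta-modified strategy is defined for 4 hypotheses")
  ok <- function(d) check_consonance(standard_graph("hierarchical_delta", delta = d),
                                     corr, alpha)$pass
  if (ok(0)) return(0)
  if (!ok(1))
    stop_numeric("no delta in [0, 1] makes the procedure consonant")
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (ok(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Correlation of two dose-versus-control z contrasts
#'
#' Under a one-way layout with known common variance, the test statistics
#' comparing two treatment groups (sizes \eqn{n_1}, \eqn{n_2}) against a
#' shared control (size \eqn{n_0}) have correlation
#' \eqn{\sqrt{(n_1/(n_0+n_1)) \cdot (n_2/(n_0+n_2))}}; equal group sizes
#' give 0.5, and the correlation tends to 0 as the control group grows.
#'
#' @param n0 control group size.
#' @param n1,n2 treatment group sizes.
#' @return Correlation in (0, 1).
#' @export
dunnett_correlation <- function(n0, n1, n2) {
  if (any(c(n0, n1, n2) <= 0)) stop_validation("group sizes must be positive")
  sqrt((n1 / (n0 + n1)) * (n2 / (n0 + n2)))
}
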