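## Monte-Carlo validation surface: synthetic one-sided p-values under a
## multivariate normal model, and FWER / power estimation for any of the
## package's procedures.

#' Simulation specification
#'
#' The generating truth for Monte-Carlo runs: a full correlation matrix
#' (no unknown entries), a noncentrality vector on the z scale (0 = true
#' null, positive = real effect for the one-sided alternative), a
#' replicate count and a seed.
#'
#' @param correlation full \eqn{m \times m} positive-semidefinite
#'   correlation matrix with unit diagonal.
#' @param noncentrality numeric vector of effect sizes on the z scale.
#' @param nsim number of replicates (default 1e5).
#' @param seed integer seed.
#' @return Object of class \code{"simulation_spec"}.
#' @export
simulation_spec <- function(correlation, noncentrality, nsim = 1e5, seed = 1L) {
  M <- as.matrix(correlation)
  m <- nrow(M)
  if (m != ncol(M) || anyNA(M))
    stop_validation("'correlation' must be a complete square matrix")
  if (any(abs(diag(M) - 1) > .wtol))
    stop_validation("'correlation' must have a unit diagonal")
  if (any(abs(M - t(M)) > .wtol))
    stop_validation("'correlation' must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_validation("'correlation' must be positive semidefinite")
  noncentrality <- as.numeric(noncentrality)
  if (length(noncentrality) != m)
    stop_validation("'noncentrality' must have length %d", m)
  nsim <- as.integer(nsim)
  if (is.na(nsim) || nsim < 1L) stop_validation("'nsim' must be at least 1")
  structure(list(correlation = M, noncentrality = noncentrality,
                 nsim = nsim, seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Simulate one-sided p-values
#'
#' Draws \code{nsim} replicates of \eqn{Z \sim N(\theta, R)} and returns
#' \eqn{p_{ij} = 1 - \Phi(Z_{ij})}.  Reproducible under a fixed seed.
#'
#' @param spec a \code{\link{simulation_spec}}.
#' @return \code{nsim} \eqn{\times m} matrix of p-values.
#' @export
simulate_pvalues <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  Z <- mvtnorm::rmvnorm(spec$nsim, mean = spec$noncentrality,
                        sigma = spec$correlation, checkSymmetry = FALSE)
  stats::pnorm(Z, lower.tail = FALSE)
}

#' Configured multiple test procedure
#'
#' Wraps one of the package's closed test procedures as a function of a
#' p-value vector, with a vectorised batch path (a matrix of replicates
#' at once) used by \code{\link{estimate_error_rates}}.  For the
#' parametric method the critical constants \eqn{c_J} depend only on the
#' weights, correlation model and level, so they are precomputed once and
#' the batch path reduces to a Bonferroni sweep with inflated weights.
#'
#' @param method one of \code{"bonferroni"}, \code{"parametric"},
#'   \code{"simes"}, \code{"simes-partitioned"}.
#' @param graph a \code{\link{hypothesis_graph}}.
#' @param alpha level in (0, 1).
#' @param corr \code{\link{correlation_model}} (required for
#'   \code{"parametric"}: the analyst's model, which may know less than
#'   the generating truth).
#' @param partition \code{\link{prd_partition}} (required for
#'   \code{"simes-partitioned"}).
#' @return A function \code{p -> logical rejection vector}, of class
#'   \code{"mct_procedure"}, with a \code{"batch"} attribute
#'   \code{P-matrix -> logical matrix}.
#' @export
mct_procedure <- function(method = c("bonferroni", "parametric", "simes",
                                     "simes-partitioned"),
                          graph, alpha, corr = NULL, partition = NULL) {
  method <- match.arg(method)
  alpha <- check_alpha(alpha)
  table <- closure_weights(graph)
  m <- length(graph$names)
  masks <- table$masks
  member_rows <- lapply(seq_len(m), function(i)
    which(bitwAnd(masks, bitwShiftL(1L, i - 1L)) > 0L))

  ## per-row local significance thresholds for Bonferroni-type sweeps;
  ## absent members get -1 so they can never trigger a rejection
  threshold_matrix <- function(cs) {
    Th <- table$weights * alpha * cs
    Th[is.na(Th)] <- -1
    Th
  }
  batch_from_thresholds <- function(Th) {
    function(P) {
      n <- nrow(P)
      rejJ <- matrix(FALSE, n, length(masks))
      for (r in seq_along(masks)) {
        J <- which(Th[r, ] >= 0)
        E <- P[, J, drop = FALSE] <= rep(Th[r, J] + .wtol, each = n)
        rejJ[, r] <- rowSums(E) > 0L
      }
      R <- matrix(TRUE, n, m)
      for (i in seq_len(m))
        R[, i] <- rowSums(rejJ[, member_rows[[i]], drop = FALSE]) ==
          length(member_rows[[i]])
      colnames(R) <- graph$names
      R
    }
  }

  if (method == "bonferroni") {
    batch <- batch_from_thresholds(threshold_matrix(1))
    f <- function(p) unname(bonferroni_closed(graph, p, alpha, table = table)$rejected)
  } else if (method == "parametric") {
    if (is.null(corr)) stop_validation("method 'parametric' requires 'corr'")
    corr <- as_corr_model(corr)
    cs <- vapply(seq_along(masks), function(r) {
      J <- indices_of(masks[r], m)
      w <- table$weights[r, J]
      if (all(w <= .wtol)) 1 else
        critical_constant(w, restrict_corr(corr, J), alpha)
    }, numeric(1))
    batch <- batch_from_thresholds(threshold_matrix(cs))
    f <- function(p) unname(parametric_closed(graph, p, corr, alpha,
                                              table = table)$rejected)
  } else {
    if (method == "simes-partitioned") {
      if (is.null(partition))
        stop_validation("method 'simes-partitioned' requires 'partition'")
      blocks <- partition$blocks
      f <- function(p) unname(simes_closed_partitioned(graph, p, partition,
                                                       alpha, table = table)$rejected)
    } else {
      blocks <- list(seq_len(m))
      f <- function(p) unname(simes_closed(graph, p, alpha, table = table)$rejected)
    }
    W0 <- table$weights
    W0[is.na(W0)] <- 0
    batch <- function(P) {
      n <- nrow(P)
      rejJ <- matrix(FALSE, n, length(masks))
      for (r in seq_along(masks)) {
        J <- indices_of(masks[r], m)
        for (b in blocks) {
          sel <- intersect(J, b)
          if (!length(sel)) next
          for (j in sel) {
            cw <- rowSums((P[, sel, drop = FALSE] <= P[, j]) *
                            rep(W0[r, sel], each = n))
            rejJ[, r] <- rejJ[, r] | (P[, j] <= cw * alpha + .wtol)
          }
        }
      }
      R <- matrix(TRUE, n, m)
      for (i in seq_len(m))
        R[, i] <- rowSums(rejJ[, member_rows[[i]], drop = FALSE]) ==
          length(member_rows[[i]])
      colnames(R) <- graph$names
      R
    }
  }
  structure(f, batch = batch, method = method, alpha = alpha,
            hypotheses = graph$names, class = c("mct_procedure", "function"))
}

#' Monte-Carlo familywise error rate and power
#'
#' Generates p-values under \code{spec}, applies the procedure to every
#' replicate and reports the estimated FWER (probability of rejecting at
#' least one hypothesis in \code{true_nulls}), per-hypothesis rejection
#' probability (power for false nulls), expected rejection count, and
#' binomial Monte-Carlo standard errors.
#'
#' @param procedure an \code{\link{mct_procedure}} (or any function
#'   mapping a p-value vector to a logical rejection vector).
#' @param spec a \code{\link{simulation_spec}}.
#' @param true_nulls indices of the hypotheses that are true nulls
#'   (default: those with zero noncentrality).
#' @param pvalues optional precomputed p-value matrix (to share the same
#'   replicates across compared procedures).
#' @return List with \code{fwer}, \code{fwer_se}, \code{power},
#'   \code{power_se}, \code{expected_rejections}, \code{nsim},
#'   \code{true_nulls}.
#' @export
estimate_error_rates <- function(procedure, spec, true_nulls = NULL,
                                 pvalues = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(true_nulls)) true_nulls <- which(spec$noncentrality == 0)
  P <- if (is.null(pvalues)) simulate_pvalues(spec) else pvalues
  n <- nrow(P)
  batch <- attr(procedure, "batch")
  R <- if (!is.null(batch)) batch(P) else
    t(apply(P, 1L, function(p) as.logical(procedure(p))))
  fwer <- if (length(true_nulls))
    mean(rowSums(R[, true_nulls, drop = FALSE]) > 0L) else NA_real_
  power <- colMeans(R)
  list(fwer = fwer,
       fwer_se = if (is.na(fwer)) NA_real_ else sqrt(fwer * (1 - fwer) / n),
       power = power,
       power_se = sqrt(power * (1 - power) / n),
       expected_rejections = mean(rowSums(R)),
       nsim = n, true_nulls = true_nulls)
}
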