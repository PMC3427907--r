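## Weighted Bonferroni tests on the closure: the sequentially rejective
## shortcut, the explicit closed test, and adjusted p-values.

check_pvalues <- function(p, m) {
  p <- as.numeric(p)
  if (length(p) != m)
    stop_validation("length of 'p' (%d) does not match number of hypotheses (%d)",
                    length(p), m)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop_validation("p-values must lie in [0, 1]")
  p
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_validation("'alpha' must be a single number in (0, 1)")
  alpha
}

mct_outcome <- function(method, names, rejected, adjusted_p, alpha,
                        trace = NULL) {
  structure(list(method = method, names = names,
                 rejected = stats::setNames(rejected, names),
                 adjusted_p = stats::setNames(pmin(adjusted_p, 1), names),
                 alpha = alpha, trace = trace),
            class = "mct_outcome")
}

#' @export
print.mct_outcome <- function(x, digits = 4, ...) {
  cat(sprintf("%s (alpha = %s)\n", x$method, format(x$alpha)))
  df <- data.frame(hypothesis = x$names,
                   adjusted_p = round(x$adjusted_p, digits),
                   rejected = x$rejected, row.names = NULL)
  print(df, ...)
  if (!is.null(x$trace) && nrow(x$trace)) {
    cat("Rejection sequence:\n")
    print(x$trace, ...)
  }
  invisible(x)
}

#' Sequentially rejective weighted Bonferroni test
#'
#' Starting from the initial graph, repeatedly rejects any hypothesis with
#' \eqn{p_j \le w_j \alpha} (taking the smallest eligible index; the final
#' decisions do not depend on this choice), removes it and updates the
#' graph, until no hypothesis qualifies.  Equivalent to the closed test
#' with weighted Bonferroni tests on every intersection.
#'
#' @param graph a \code{\link{hypothesis_graph}}.
#' @param p unadjusted p-values, one per hypothesis.
#' @param alpha familywise significance level in (0, 1).
#' @return An object of class \code{"mct_outcome"} with rejection flags,
#'   adjusted p-values (from the closure) and the rejection trace.
#' @examples
#' g <- standard_graph("hierarchical")
#' bonferroni_sequential(g, c(0.01, 0.005, 0.1, 0.5), alpha = 0.025)
#' @export
bonferroni_sequential <- function(graph, p, alpha) {
  p <- check_pvalues(p, length(graph$names))
  alpha <- check_alpha(alpha)
  g <- graph
  trace <- list()
  repeat {
    idx <- match(g$names, graph$names)
    elig <- which(p[idx] <= g$weights * alpha + .wtol)
    if (!length(elig)) break
    j <- elig[1]
    trace[[length(trace) + 1L]] <- data.frame(
      hypothesis = g$names[j], index = idx[j], local_level = g$weights[[j]] * alpha)
    if (length(g$names) == 1L) { g <- NULL; break }
    g <- remove_hypothesis(g, j)
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(hypothesis = character(), index = integer(), local_level = numeric())
  rejected <- graph$names %in% trace$hypothesis
  mct_outcome("sequential weighted Bonferroni", graph$names, rejected,
              adjusted_p_bonferroni(graph, p), alpha, trace)
}

## local p-value of the weighted Bonferroni test for one closure row:
## min_j p_j / w_j(J), with x/0 := +Inf, over members of J
bonf_local_p <- function(w_row, p) {
  J <- which(!is.na(w_row))
  ratio <- ifelse(w_row[J] > 0, p[J] / w_row[J], Inf)
  min(ratio)
}

#' Closed weighted Bonferroni test
#'
#' Explicit closure: \eqn{H_i} is rejected iff every intersection
#' \eqn{H_J} with \eqn{i \in J} has some \eqn{j \in J} with
#' \eqn{p_j \le w_j(J)\,\alpha}.  Serves as the oracle for the
#' sequentially rejective shortcut, to which it is equivalent for
#' graph-generated weighting strategies.
#'
#' @inheritParams bonferroni_sequential
#' @param table optional precomputed \code{\link{closure_weights}}.
#' @return An \code{"mct_outcome"}.
#' @export
bonferroni_closed <- function(graph, p, alpha, table = NULL) {
  p <- check_pvalues(p, length(graph$names))
  alpha <- check_alpha(alpha)
  if (is.null(table)) table <- closure_weights(graph)
  adj <- adjusted_p_bonferroni(graph, p, table)
  ## reject via the per-intersection criterion (not via adj <= alpha) so the
  ## adjusted-p consistency is a genuine tested property
  m <- length(graph$names)
  rejJ <- apply(table$weights, 1L, function(w_row) {
    J <- which(!is.na(w_row))
    any(p[J] <= w_row[J] * alpha + .wtol)
  })
  rejected <- vapply(seq_len(m), function(i) {
    rows <- bitwAnd(table$masks, bitwShiftL(1L, i - 1L)) > 0L
    all(rejJ[rows])
  }, logical(1))
  mct_outcome("closed weighted Bonferroni", graph$names, rejected, adj, alpha)
}

#' Adjusted p-values of the closed weighted Bonferroni test
#'
#' The local p-value of \eqn{H_J} is \eqn{\min_{j \in J} p_j / w_j(J)}
#' (with \eqn{x/0 := \infty}), capped at 1; the adjusted p-value of
#' \eqn{H_i} is the maximum local p-value over all \eqn{J \ni i}.
#'
#' @inheritParams bonferroni_closed
#' @return Numeric vector of adjusted p-values in (0, 1].
#' @export
adjusted_p_bonferroni <- function(graph, p, table = NULL) {
  p <- check_pvalues(p, length(graph$names))
  if (is.null(table)) table <- closure_weights(graph)
  m <- length(graph$names)
  localp <- apply(table$weights, 1L, bonf_local_p, p = p)
  adj <- vapply(seq_len(m), function(i) {
    rows <- bitwAnd(table$masks, bitwShiftL(1L, i - 1L)) > 0L
    max(localp[rows])
  }, numeric(1))
  stats::setNames(pmin(adj, 1), graph$names)
}
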