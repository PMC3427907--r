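## Weighted Simes tests on the closure, the partially sequential shortcut,
## and the partitioned variant for partial positive regression dependence.

#' Positive-regression-dependence partition
#'
#' Asserts (it cannot be verified by the package) that within each block
#' the one-sided test statistics are positive regression dependent, e.g.
#' multivariate normal with nonnegative correlations.  The weighted Simes
#' inequality is applied within blocks and the Bonferroni inequality
#' across blocks.
#'
#' @param blocks list of disjoint integer index vectors covering
#'   \code{1:m}.
#' @param m number of hypotheses.
#' @return Object of class \code{"prd_partition"}.
#' @export
prd_partition <- function(blocks, m) {
  blocks <- lapply(blocks, function(b) sort(unique(as.integer(b))))
  all_idx <- sort(unlist(blocks))
  if (length(all_idx) != length(unique(unlist(blocks))))
    stop_validation("partition blocks must be disjoint")
  if (!identical(all_idx, seq_len(m)))
    stop_validation("partition blocks must cover exactly 1..%d", m)
  structure(list(blocks = blocks, m = as.integer(m)), class = "prd_partition")
}

#' Weighted Simes test for a single intersection hypothesis
#'
#' Rejects \eqn{H_J} iff there is a \eqn{j \in J} with
#' \eqn{p_j \le \alpha \sum_{k \in J:\, p_k \le p_j} w_k}: each p-value is
#' compared against the cumulative weight of all hypotheses with p-values
#' no larger than it (ties included).  With equal weights this reduces to
#' the classical unweighted Simes test; it is conservative under positive
#' regression dependence of the test statistics.
#'
#' @param p p-values over the members of \eqn{J}.
#' @param w nonnegative weights over \eqn{J}, summing to at most 1.
#' @param alpha level in (0, 1).
#' @return Logical: reject \eqn{H_J}?
#' @examples
#' weighted_simes_test(c(0.015, 0.022), c(0.5, 0.5), 0.025)  # TRUE
#' @export
weighted_simes_test <- function(p, w, alpha) {
  alpha <- check_alpha(alpha)
  if (length(p) != length(w))
    stop_validation("'p' and 'w' must have equal length")
  if (anyNA(p) || any(p < 0 | p > 1)) stop_validation("p-values must lie in [0, 1]")
  if (any(w < -.wtol) || sum(w) > 1 + .wtol)
    stop_validation("weights must be nonnegative with sum at most 1")
  cw <- vapply(seq_along(p), function(j) sum(w[p <= p[j]]), numeric(1))
  any(p <= cw * alpha + .wtol)
}

## local p-value of the weighted Simes test for one intersection:
## min_j p_j / (cumulative weight at p_j), with x/0 := +Inf
simes_local_p <- function(p, w) {
  cw <- vapply(seq_along(p), function(j) sum(w[p <= p[j]]), numeric(1))
  ratio <- ifelse(cw > 0, p / cw, Inf)
  min(ratio)
}

#' Closed weighted Simes test
#'
#' Applies the weighted Simes test to every intersection of the closure:
#' \eqn{H_i} is rejected iff every \eqn{J \ni i} has some \eqn{j \in J}
#' with \eqn{p_j \le \alpha \sum_{k \in J:\, p_k \le p_j} w_k(J)}.
#' Adjusted p-values use the corresponding min-ratio with cumulative
#' weights (an extension consistent with the rejection rule at every
#' level; see the methods vignette).  With equal weights the procedure
#' reduces to Hommel's.
#'
#' @inheritParams bonferroni_closed
#' @return An \code{"mct_outcome"}.
#' @export
simes_closed <- function(graph, p, alpha, table = NULL) {
  m <- length(graph$names)
  p <- check_pvalues(p, m)
  alpha <- check_alpha(alpha)
  if (is.null(table)) table <- closure_weights(graph)
  localp <- apply(table$weights, 1L, function(w_row) {
    J <- which(!is.na(w_row))
    simes_local_p(p[J], w_row[J])
  })
  adj <- vapply(seq_len(m), function(i) {
    rows <- bitwAnd(table$masks, bitwShiftL(1L, i - 1L)) > 0L
    max(localp[rows])
  }, numeric(1))
  rejected <- adj <= alpha + .wtol
  mct_outcome("closed weighted Simes", graph$names, rejected, adj, alpha)
}

#' Partially sequential weighted Simes test
#'
#' A shortcut that reproduces the closed weighted Simes decisions while
#' usually avoiding full closure enumeration.  Steps: (i) if all
#' \eqn{p_i > \alpha}, retain everything; (ii) if all \eqn{p_i \le \alpha}
#' and the weights are exhaustive (every closure row sums to 1), reject
#' everything; (iii) run the sequentially rejective Bonferroni procedure;
#' if at most two hypotheses survive, retain them; (iv) otherwise rebuild
#' the graph on the survivors and (v) apply the closed weighted Simes
#' criterion on the survivor closure.
#'
#' @inheritParams bonferroni_sequential
#' @return An \code{"mct_outcome"}; decisions identical to
#'   \code{\link{simes_closed}}.
#' @export
simes_sequential <- function(graph, p, alpha) {
  m <- length(graph$names)
  p <- check_pvalues(p, m)
  alpha <- check_alpha(alpha)
  table <- closure_weights(graph)
  exhaustive <- check_exhaustive(table)$pass
  adj <- simes_closed(graph, p, alpha, table = table)$adjusted_p
  if (all(p > alpha))   # step (i)
    return(mct_outcome("sequential weighted Simes", graph$names,
                       rep(FALSE, m), adj, alpha))
  if (exhaustive && all(p <= alpha))   # step (ii)
    return(mct_outcome("sequential weighted Simes", graph$names,
                       rep(TRUE, m), adj, alpha))
  ## step (iii): sequentially rejective Bonferroni
  bseq <- bonferroni_sequential(graph, p, alpha)
  rejected <- unname(bseq$rejected)
  surv <- which(!rejected)
  if (length(surv) > 2L) {
    ## step (iv): survivor graph = initial graph after the Bonferroni removals
    g <- graph
    for (nm in bseq$trace$hypothesis) g <- remove_hypothesis(g, nm)
    stab <- closure_weights(g)
    ## step (v): closed weighted Simes on the survivor closure
    sres <- simes_closed(g, p[surv], alpha, table = stab)
    rejected[surv] <- unname(sres$rejected)
  }
  mct_outcome("sequential weighted Simes", graph$names, rejected, adj, alpha,
              trace = bseq$trace)
}

#' Partitioned weighted Simes test for a single intersection
#'
#' When positive regression dependence holds only within the blocks of a
#' partition, the weighted Simes test is applied separately within each
#' block (cumulative weights restricted to the block) and the blocks are
#' combined by the Bonferroni inequality: reject \eqn{H_J} iff for some
#' block \eqn{h} and \eqn{j \in J \cap J_h},
#' \eqn{p_j \le \alpha \sum_{k \in J \cap J_h:\, p_k \le p_j} w_k(J)}.
#' With a single block this is the plain weighted Simes test; with all
#' singleton blocks it is the weighted Bonferroni test.
#'
#' @param p p-values over the members of \eqn{J} (in index order).
#' @param w weights over \eqn{J}.
#' @param members original indices of the members of \eqn{J} (needed to
#'   intersect with the partition blocks); defaults to
#'   \code{seq_along(p)}.
#' @param partition a \code{\link{prd_partition}}.
#' @param alpha level in (0, 1).
#' @return Logical: reject \eqn{H_J}?
#' @export
partitioned_simes_test <- function(p, w, partition, alpha,
                                   members = seq_along(p)) {
  alpha <- check_alpha(alpha)
  if (!inherits(partition, "prd_partition"))
    stop_validation("'partition' must be a prd_partition")
  if (length(p) != length(w) || length(p) != length(members))
    stop_validation("'p', 'w' and 'members' must have equal length")
  for (b in partition$blocks) {
    sel <- members %in% b
    if (!any(sel)) next
    pb <- p[sel]; wb <- w[sel]
    cw <- vapply(seq_along(pb), function(j) sum(wb[pb <= pb[j]]), numeric(1))
    if (any(pb <= cw * alpha + .wtol)) return(TRUE)
  }
  FALSE
}

#' Closed partitioned weighted Simes test
#'
#' The closed test procedure with \code{\link{partitioned_simes_test}}
#' applied to every intersection hypothesis.
#'
#' @inheritParams simes_closed
#' @param partition a \code{\link{prd_partition}} on all \eqn{m}
#'   hypotheses.
#' @return An \code{"mct_outcome"} (rejection flags and adjusted
#'   p-values; the local p-value of an intersection is the smallest
#'   blockwise min-ratio scaled by the number-free cumulative-weight rule).
#' @export
simes_closed_partitioned <- function(graph, p, partition, alpha, table = NULL) {
  m <- length(graph$names)
  p <- check_pvalues(p, m)
  alpha <- check_alpha(alpha)
  if (!inherits(partition, "prd_partition") || partition$m != m)
    stop_validation("'partition' must be a prd_partition on %d hypotheses", m)
  if (is.null(table)) table <- closure_weights(graph)
  localp <- vapply(seq_along(table$masks), function(r) {
    w_row <- table$weights[r, ]
    J <- which(!is.na(w_row))
    lp <- Inf
    for (b in partition$blocks) {
      sel <- intersect(J, b)
      if (!length(sel)) next
      lp <- min(lp, simes_local_p(p[sel], w_row[sel]))
    }
    lp
  }, numeric(1))
  adj <- vapply(seq_len(m), function(i) {
    rows <- bitwAnd(table$masks, bitwShiftL(1L, i - 1L)) > 0L
    max(localp[rows])
  }, numeric(1))
  rejected <- adj <= alpha + .wtol
  mct_outcome("closed partitioned weighted Simes", graph$names, rejected,
              adj, alpha)
}
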