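## Internal condition helpers: validation errors (bad user input) and numeric
## failures (root finding etc.) carry distinct classes so callers -- in
## particular the CLI -- can map them to stable exit codes.

stop_validation <- function(msg, ...) {
  stop(structure(class = c("mct_validation_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_numeric <- function(msg, ...) {
  stop(structure(class = c("mct_numeric_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

.wtol <- 1e-9  # absolute tolerance for all weight/probability comparisons

## ---- bitmask helpers (subsets of {1..m} as integer masks, bit i-1 <-> H_i)

mask_of <- function(idx) sum(bitwShiftL(1L, as.integer(idx) - 1L))

indices_of <- function(mask, m) which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) > 0L)

## Canonical display order: subsets sorted as binary words with H1 the most
## significant bit, descending -- H1^H2^...^Hm first, Hm last.
mask_display_order <- function(m) {
  masks <- seq_len(2L^m - 1L)
  key <- vapply(masks, function(mk) {
    sum(2^(m - indices_of(mk, m)))
  }, numeric(1))
  masks[order(-key)]
}

subset_label <- function(mask, names) {
  paste(names[indices_of(mask, length(names))], collapse = " ∩ ")
}

#' Create a hypothesis graph
#'
#' A graphical weighting strategy for \eqn{m} null hypotheses consists of
#' initial weights \eqn{w_i} (local significance-level fractions for the
#' global intersection hypothesis) and a transition matrix
#' \eqn{G = (g_{ij})}, where \eqn{g_{ij}} is the fraction of \eqn{H_i}'s
#' local level that is propagated to \eqn{H_j} once \eqn{H_i} is removed
#' (rejected).
#'
#' @param names character vector of \eqn{m} unique hypothesis labels.
#' @param weights numeric vector of \eqn{m} nonnegative weights with
#'   \eqn{\sum_i w_i \le 1}.
#' @param transition \eqn{m \times m} numeric matrix with entries in
#'   \eqn{[0,1]}, zero diagonal and row sums at most 1.
#' @return An object of class \code{"hypothesis_graph"}: a list with
#'   elements \code{names}, \code{weights} (named) and \code{transition}
#'   (with dimnames).
#' @examples
#' g <- hypothesis_graph(paste0("H", 1:2), c(0.5, 0.5),
#'                       matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
#' @export
hypothesis_graph <- function(names, weights, transition) {
  if (length(names) < 1L)
    stop_validation("at least one hypothesis is required")
  names <- as.character(names)
  m <- length(names)
  if (anyDuplicated(names))
    stop_validation("hypothesis names must be unique")
  weights <- as.numeric(weights)
  if (length(weights) != m)
    stop_validation("length of 'weights' (%d) does not match number of hypotheses (%d)",
                    length(weights), m)
  if (anyNA(weights) || !is.numeric(weights))
    stop_validation("'weights' must be numeric without missing values")
  if (any(weights < -.wtol))
    stop_validation("negative hypothesis weight: w[%d] = %g",
                    which(weights < -.wtol)[1], weights[which(weights < -.wtol)[1]])
  if (sum(weights) > 1 + .wtol)
    stop_validation("hypothesis weights sum to %g > 1", sum(weights))
  transition <- as.matrix(transition)
  if (m == 1L && length(transition) == 0L)
    transition <- matrix(0, 1, 1)
  if (!all(dim(transition) == c(m, m)))
    stop_validation("'transition' must be a %d x %d matrix", m, m)
  if (anyNA(transition))
    stop_validation("'transition' must not contain missing values")
  if (any(diag(transition) > .wtol) || any(diag(transition) < -.wtol))
    stop_validation("transition matrix must have a zero diagonal")
  if (any(transition < -.wtol) || any(transition > 1 + .wtol))
    stop_validation("transition weights must lie in [0, 1]")
  rs <- rowSums(transition)
  if (any(rs > 1 + .wtol))
    stop_validation("transition row sum for %s is %g > 1",
                    names[which(rs > 1 + .wtol)[1]], max(rs))
  weights <- pmax(weights, 0)
  transition[transition < 0] <- 0
  diag(transition) <- 0
  names(weights) <- names
  dimnames(transition) <- list(names, names)
  structure(list(names = names, weights = weights, transition = transition),
            class = "hypothesis_graph")
}

#' @export
print.hypothesis_graph <- function(x, digits = 4, ...) {
  cat(sprintf("Hypothesis graph on %d hypotheses\n", length(x$names)))
  for (i in seq_along(x$names))
    cat(sprintf("  %s: weight %s\n", x$names[i], format(x$weights[i], digits = digits)))
  ij <- which(x$transition > 0, arr.ind = TRUE)
  if (nrow(ij)) {
    cat("Edges:\n")
    for (r in seq_len(nrow(ij)))
      cat(sprintf("  %s -(%s)-> %s\n", x$names[ij[r, 1]],
                  format(x$transition[ij[r, 1], ij[r, 2]], digits = digits),
                  x$names[ij[r, 2]]))
  } else cat("No edges.\n")
  invisible(x)
}

resolve_index <- function(graph, j) {
  if (is.character(j)) {
    k <- match(j, graph$names)
    if (is.na(k)) stop_validation("hypothesis '%s' not present in graph", j)
    return(k)
  }
  j <- as.integer(j)
  if (any(j < 1L) || any(j > length(graph$names)))
    stop_validation("hypothesis index out of range")
  j
}

#' Remove a hypothesis and update the graph
#'
#' Removes hypothesis \eqn{j} and redistributes its weight along its
#' outgoing edges: for every remaining \eqn{l},
#' \eqn{w_l \leftarrow w_l + w_j g_{jl}}, and for every remaining ordered
#' pair \eqn{(k,l)},
#' \eqn{g_{kl} \leftarrow (g_{kl} + g_{kj} g_{jl})/(1 - g_{kj} g_{jk})}
#' when \eqn{g_{kj} g_{jk} < 1} and 0 otherwise.
#'
#' @param graph a \code{\link{hypothesis_graph}}.
#' @param j index or name of the hypothesis to remove.
#' @return The updated \code{hypothesis_graph} on \eqn{m-1} hypotheses.
#' @export
remove_hypothesis <- function(graph, j) {
  j <- resolve_index(graph, j)
  stopifnot(length(j) == 1L)
  m <- length(graph$names)
  if (m == 1L)
    stop_validation("cannot remove the last remaining hypothesis")
  keep <- setdiff(seq_len(m), j)
  w <- graph$weights[keep] + graph$weights[j] * graph$transition[j, keep]
  G <- graph$transition
  newG <- matrix(0, m - 1L, m - 1L)
  for (a in seq_along(keep)) for (b in seq_along(keep)) {
    if (a == b) next
    k <- keep[a]; l <- keep[b]
    loop <- G[k, j] * G[j, k]
    newG[a, b] <- if (loop < 1 - .wtol) (G[k, l] + G[k, j] * G[j, l]) / (1 - loop) else 0
  }
  ## guard against accumulated round-off pushing a row sum over 1
  rs <- rowSums(newG)
  over <- rs > 1
  if (any(over)) newG[over, ] <- newG[over, ] / rs[over]
  hypothesis_graph(graph$names[keep], pmin(w, 1), newG)
}

#' Weights of an intersection hypothesis
#'
#' Computes the weight vector \eqn{w_j(J)}, \eqn{j \in J}, by removing the
#' hypotheses outside \code{J} one at a time and updating the graph.  The
#' result does not depend on the removal order.
#'
#' @param graph a \code{\link{hypothesis_graph}}.
#' @param J integer indices (or names) of the hypotheses retained.
#' @param order optional explicit removal order for the complement
#'   (indices into the original graph); used mainly for testing the
#'   order-invariance property.
#' @return Named numeric weight vector over the members of \code{J}.
#' @export
subset_weights <- function(graph, J, order = NULL) {
  J <- sort(unique(resolve_index(graph, J)))
  if (length(J) == 0L) stop_validation("'J' must be a non-empty subset")
  comp <- setdiff(seq_along(graph$names), J)
  if (!is.null(order)) {
    order <- resolve_index(graph, order)
    if (!setequal(order, comp))
      stop_validation("'order' must be a permutation of the complement of J")
    comp <- order
  }
  g <- graph
  for (j in comp) g <- remove_hypothesis(g, graph$names[j])
  g$weights[match(graph$names[J], g$names)]
}

#' Closure weight table
#'
#' Generates the weights \eqn{w_j(J)} for every non-empty subset
#' \eqn{J \subseteq \{1,\dots,m\}} of the closure by repeated application
#' of the removal/update rule.  Hypotheses outside \eqn{J} have no weight
#' (reported as \code{NA}, printed as \dQuote{--}).
#'
#' @param graph a \code{\link{hypothesis_graph}}.
#' @param max_m guard on the number of hypotheses (table size is
#'   \eqn{2^m - 1}); default 20.
#' @return Object of class \code{"closure_weights"}: list with
#'   \code{names}, \code{masks} (bitmask per row, bit \eqn{i-1} set iff
#'   \eqn{H_i \in J}) and \code{weights} (\eqn{(2^m-1) \times m} matrix,
#'   \code{NA} for absent members).
#' @export
closure_weights <- function(graph, max_m = 20L) {
  m <- length(graph$names)
  if (m > max_m)
    stop_validation("closure enumeration limited to %d hypotheses (got %d)", max_m, m)
  full <- 2L^m - 1L
  graphs <- vector("list", full)
  graphs[[full]] <- graph
  masks <- mask_display_order(m)
  ## fill by decreasing subset size: each subset's graph is obtained from the
  ## superset with one extra member (the smallest absent index) removed
  for (mk in masks[order(-vapply(masks, function(z) length(indices_of(z, m)), numeric(1)))]) {
    if (mk == full) next
    j <- indices_of(bitwAnd(bitwNot(mk), full), m)[1]
    parent <- bitwOr(mk, bitwShiftL(1L, j - 1L))
    graphs[[mk]] <- remove_hypothesis(graphs[[parent]], graph$names[j])
  }
  W <- matrix(NA_real_, length(masks), m, dimnames = list(
    vapply(masks, subset_label, "", names = graph$names), graph$names))
  for (r in seq_along(masks)) {
    J <- indices_of(masks[r], m)
    W[r, J] <- graphs[[masks[r]]]$weights[match(graph$names[J], graphs[[masks[r]]]$names)]
  }
  structure(list(names = graph$names, masks = masks, weights = W),
            class = "closure_weights")
}

#' @export
print.closure_weights <- function(x, digits = 4, ...) {
  M <- format(round(x$weights, digits))
  M[is.na(x$weights)] <- "-"
  cat(sprintf("Closure weights (%d intersection hypotheses)\n", nrow(x$weights)))
  print(as.data.frame(M), ...)
  invisible(x)
}

## weight vector for a given mask (row lookup)
closure_row <- function(table, mask) {
  r <- match(mask, table$masks)
  if (is.na(r)) stop_validation("subset not present in closure table")
  table$weights[r, ]
}

#' Check the monotonicity condition of a closure weight table
#'
#' Monotonicity requires \eqn{w_j(J') \ge w_j(J)} for every
#' \eqn{J' \subseteq J} and \eqn{j \in J'}; it guarantees consonance of the
#' closed weighted Bonferroni procedure and hence the validity of the
#' sequentially rejective shortcut.
#'
#' @param table a \code{\link{closure_weights}} object.
#' @return List with \code{pass} (logical) and \code{violations}, a data
#'   frame of triples (subset, superset, hypothesis) with their weights.
#' @export
check_monotonicity <- function(table) {
  m <- length(table$names)
  viol <- list()
  for (sup in table$masks) {
    wsup <- closure_row(table, sup)
    sub <- bitwAnd(sup - 1L, sup)  # iterate proper non-empty submasks
    while (sub > 0L) {
      wsub <- closure_row(table, sub)
      for (j in indices_of(sub, m)) {
        if (wsub[j] < wsup[j] - .wtol) {
          viol[[length(viol) + 1L]] <- data.frame(
            subset = subset_label(sub, table$names),
            superset = subset_label(sup, table$names),
            hypothesis = table$names[j],
            w_subset = wsub[j], w_superset = wsup[j])
        }
      }
      sub <- bitwAnd(sub - 1L, sup)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(subset = character(), superset = character(),
               hypothesis = character(), w_subset = numeric(),
               w_superset = numeric())
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' Check that closure weights are exhaustive
#'
#' Exhaustive weights satisfy \eqn{\sum_{j \in J} w_j(J) = 1} for every
#' non-empty subset \eqn{J}; several shortcut arguments (notably step (ii)
#' of the partially sequential Simes procedure) require this.
#'
#' @param table a \code{\link{closure_weights}} object.
#' @return List with \code{pass} and \code{first_failing} (label of the
#'   first subset whose weights do not sum to 1, or \code{NA}).
#' @export
check_exhaustive <- function(table) {
  sums <- rowSums(table$weights, na.rm = TRUE)
  bad <- which(abs(sums - 1) > .wtol)
  list(pass = length(bad) == 0L,
       first_failing = if (length(bad)) rownames(table$weights)[bad[1]] else NA_character_,
       sums = sums)
}

#' Standard graphical test procedures
#'
#' Constructors for common weighting strategies.
#'
#' \describe{
#'   \item{\code{"holm"}}{weighted Holm: weights \code{w} (default equal),
#'     each hypothesis passes its weight to the others proportionally to
#'     their weights; for equal weights, \eqn{g_{ij} = 1/(m-1)}.}
#'   \item{\code{"fixed_sequence"}}{hierarchical testing in the order
#'     given: full weight on the first hypothesis, each passes everything
#'     to its successor.}
#'   \item{\code{"fallback"}}{fallback procedure with weights \code{w}:
#'     each hypothesis passes its level to the next in sequence.}
#'   \item{\code{"truncated_holm"}}{two primary and two secondary
#'     hypotheses; the primary family is tested by a Holm procedure
#'     truncated at \code{gamma}: weights (1/2, 1/2, 0, 0), edges
#'     H1<->H2 with weight \code{gamma}, each primary sends
#'     \code{(1-gamma)/2} to each secondary, and H3<->H4 with weight 1.}
#'   \item{\code{"hierarchical"}}{two dose levels with a primary and a
#'     secondary endpoint each, secondary tested only after its primary:
#'     weights (1/2, 1/2, 0, 0), edges H1->H3, H2->H4, H3->H2, H4->H1 all
#'     of weight 1.}
#'   \item{\code{"hierarchical_delta"}}{the same strategy with extra
#'     primary-to-primary edges of weight \code{delta} (used to enforce
#'     consonance of the parametric procedure): edges H1->H2 and H2->H1
#'     of weight \code{delta}, H1->H3 and H2->H4 of weight
#'     \code{1-delta}, H3->H2 and H4->H1 of weight 1.}
#' }
#'
#' @param kind one of \code{"holm"}, \code{"fixed_sequence"},
#'   \code{"fallback"}, \code{"truncated_holm"}, \code{"hierarchical"},
#'   \code{"hierarchical_delta"}.
#' @param m number of hypotheses (kinds without a fixed size; default 4
#'   where applicable).
#' @param w initial weights where configurable.
#' @param gamma truncation parameter in [0, 1] (\code{"truncated_holm"}).
#' @param delta primary-to-primary edge weight in [0, 1]
#'   (\code{"hierarchical_delta"}).
#' @param names hypothesis labels (default H1..Hm).
#' @return A \code{\link{hypothesis_graph}}.
#' @export
standard_graph <- function(kind, m = NULL, w = NULL, gamma = NULL, delta = NULL,
                           names = NULL) {
  kind <- match.arg(kind, c("holm", "fixed_sequence", "fallback",
                            "truncated_holm", "hierarchical",
                            "hierarchical_delta"))
  if (kind %in% c("truncated_holm", "hierarchical", "hierarchical_delta")) {
    if (!is.null(m) && m != 4L)
      stop_validation("kind '%s' is defined for m = 4 hypotheses", kind)
    m <- 4L
  }
  if (is.null(m)) m <- if (!is.null(w)) length(w) else
    stop_validation("supply 'm' or 'w' for kind '%s'", kind)
  if (is.null(names)) names <- paste0("H", seq_len(m))
  G <- matrix(0, m, m)
  switch(kind,
    holm = {
      if (is.null(w)) w <- rep(1 / m, m)
      if (length(w) != m) stop_validation("'w' must have length %d", m)
      for (i in seq_len(m)) {
        rest <- setdiff(seq_len(m), i)
        s <- sum(w[rest])
        G[i, rest] <- if (s > 0) w[rest] / s else if (m > 1) 1 / (m - 1) else 0
      }
      hypothesis_graph(names, w, G)
    },
    fixed_sequence = {
      w <- c(1, rep(0, m - 1))
      if (m > 1) for (i in seq_len(m - 1)) G[i, i + 1] <- 1
      hypothesis_graph(names, w, G)
    },
    fallback = {
      if (is.null(w)) w <- rep(1 / m, m)
      if (length(w) != m) stop_validation("'w' must have length %d", m)
      if (m > 1) for (i in seq_len(m - 1)) G[i, i + 1] <- 1
      hypothesis_graph(names, w, G)
    },
    truncated_holm = {
      if (is.null(gamma)) stop_validation("kind 'truncated_holm' requires 'gamma'")
      if (gamma < 0 || gamma > 1) stop_validation("'gamma' must lie in [0, 1]")
      G[1, 2] <- G[2, 1] <- gamma
      G[1, 3] <- G[1, 4] <- G[2, 3] <- G[2, 4] <- (1 - gamma) / 2
      G[3, 4] <- G[4, 3] <- 1
      hypothesis_graph(names, c(0.5, 0.5, 0, 0), G)
    },
    hierarchical = {
      G[1, 3] <- G[2, 4] <- G[3, 2] <- G[4, 1] <- 1
      hypothesis_graph(names, c(0.5, 0.5, 0, 0), G)
    },
    hierarchical_delta = {
      if (is.null(delta)) stop_validation("kind 'hierarchical_delta' requires 'delta'")
      if (delta < 0 || delta > 1) stop_validation("'delta' must lie in [0, 1]")
      G[1, 2] <- G[2, 1] <- delta
      G[1, 3] <- G[2, 4] <- 1 - delta
      G[3, 2] <- G[4, 1] <- 1
      hypothesis_graph(names, c(0.5, 0.5, 0, 0), G)
    })
}

#' Read / write a hypothesis graph as JSON
#'
#' The file holds an object with fields \code{names}, \code{weights} and
#' \code{transition} (row-major matrix).
#'
#' @param path file path.
#' @param graph a \code{\link{hypothesis_graph}}.
#' @return \code{read_graph} returns a validated
#'   \code{\link{hypothesis_graph}}; \code{write_graph} returns
#'   \code{path} invisibly.
#' @export
read_graph <- function(path) {
  if (!file.exists(path)) stop_validation("graph file '%s' not found", path)
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) stop_validation("malformed graph file '%s': %s",
                                                      path, conditionMessage(e)))
  if (!all(c("names", "weights", "transition") %in% names(obj)))
    stop_validation("graph file must contain 'names', 'weights' and 'transition'")
  hypothesis_graph(obj$names, obj$weights, as.matrix(obj$transition))
}

#' @rdname read_graph
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "hypothesis_graph"))
  jsonlite::write_json(
    list(names = graph$names, weights = unname(graph$weights),
         transition = unname(graph$transition)),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
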