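# Fixture builders shared across test files.

# Two-dose hierarchical strategy: weights (1/2, 1/2, 0, 0), unit edges
# H1->H3, H2->H4, H3->H2, H4->H1.
hier_graph <- function() standard_graph("hierarchical")

# Correlation model with rho known within {H1,H2} and {H3,H4}, unknown across.
block_corr <- function(rho = 0.5) {
  M <- matrix(NA_real_, 4, 4)
  diag(M) <- 1
  M[1, 2] <- M[2, 1] <- M[3, 4] <- M[4, 3] <- rho
  correlation_model(M)
}

# The 15-row closure weight table of the hierarchical strategy, frozen from
# independent hand evaluation of the removal/update rule (row order: subsets
# as binary words with H1 most significant, descending).
hier_closure_expected <- function() {
  M <- rbind(
    c(0.5, 0.5,  0,   0),    # H1 H2 H3 H4
    c(0.5, 0.5,  0,  NA),    # H1 H2 H3
    c(0.5, 0.5, NA,   0),    # H1 H2 H4
    c(0.5, 0.5, NA,  NA),    # H1 H2
    c(0.5,  NA,  0, 0.5),    # H1 H3 H4
    c(1,    NA,  0,  NA),    # H1 H3
    c(0.5,  NA, NA, 0.5),    # H1 H4
    c(1,    NA, NA,  NA),    # H1
    c(NA,  0.5, 0.5,  0),    # H2 H3 H4
    c(NA,  0.5, 0.5, NA),    # H2 H3
    c(NA,  1,   NA,   0),    # H2 H4
    c(NA,  1,   NA,  NA),    # H2
    c(NA,  NA, 0.5, 0.5),    # H3 H4
    c(NA,  NA,  1,   NA),    # H3
    c(NA,  NA, NA,    1))    # H4
  colnames(M) <- paste0("H", 1:4)
  M
}

# Random valid hypothesis graph.  exhaustive = TRUE forces sum(w) = 1 and all
# transition row sums = 1, which makes every closure row sum to 1.
random_graph <- function(m, exhaustive = FALSE) {
  w <- stats::runif(m)
  w <- w / sum(w) * (if (exhaustive) 1 else stats::runif(1, 0.3, 1))
  G <- matrix(stats::runif(m * m), m, m)
  diag(G) <- 0
  for (i in seq_len(m)) {
    s <- sum(G[i, ])
    if (s > 0) G[i, ] <- G[i, ] / s * (if (exhaustive) 1 else stats::runif(1))
  }
  hypothesis_graph(paste0("H", seq_len(m)), w, G)
}

# Random full correlation matrix with a block structure (equicorrelated
# within randomly chosen blocks, zero across) -- PSD by construction.
random_block_corr <- function(m, known_only = TRUE) {
  k <- sample(seq_len(m), 1)
  blocks <- split(seq_len(m), sort(rep_len(seq_len(k), m)))
  M <- matrix(if (known_only) NA_real_ else 0, m, m)
  diag(M) <- 1
  for (b in blocks) {
    rho <- stats::runif(1, 0, 0.9)
    M[b, b] <- rho
    diag(M) <- 1
  }
  M
}

# Independent closure oracle for the unweighted Simes procedure (Hommel):
# used as the cross-check for the equal-weight reduction.
hommel_oracle <- function(p, alpha) {
  m <- length(p)
  rejected <- rep(TRUE, m)
  for (mask in seq_len(2^m - 1)) {
    J <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    ps <- sort(p[J])
    k <- length(J)
    rejJ <- any(ps <= seq_len(k) / k * alpha + 1e-12)
    if (!rejJ) rejected[J] <- FALSE
  }
  rejected
}
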