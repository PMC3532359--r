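# Small graph fixtures and independent dense-matrix oracles used across tests.

k3_graph <- function() weighted_graph(1 - diag(3), c("a", "b", "c"))

path3_graph <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  weighted_graph(A, c("a", "b", "c"))
}

# connected Erdos-Renyi graph (resamples until connected)
random_graph <- function(n, p = 0.15, seed = 1, weighted = FALSE) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- (runif(sum(up)) < p) * (if (weighted) runif(sum(up), 0.5, 2) else 1)
    A <- A + t(A)
    g <- weighted_graph(A, sprintf("v%03d", seq_len(n)))
    if (igraph::is_connected(igraph::graph_from_adjacency_matrix(
          unname(g$A > 0), mode = "undirected"))) return(g)
  }
}

# dense-matrix oracles, written independently of the package internals
dense_S <- function(g) {
  A <- as.matrix(g$A); d <- rowSums(A)
  diag(1 / sqrt(d)) %*% A %*% diag(1 / sqrt(d))
}
dense_P <- function(g) {
  A <- as.matrix(g$A); d <- rowSums(A)
  diag(1 / d) %*% A
}
dense_glp <- function(M, y, lam) solve(diag(nrow(M)) - lam * M, y)

dense_walk_features <- function(M, y, R) {
  X <- matrix(0, length(y), R)
  Mr <- diag(length(y))
  for (r in seq_len(R)) {
    Mr <- Mr %*% M
    X[, r] <- Mr %*% y
  }
  X
}

# O(n^2) pair-counting AUROC oracle (ties count one half)
brute_auroc <- function(scores, labels) {
  sp <- scores[labels > 0]; sn <- scores[labels == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# exhaustive precision-at-each-positive-rank oracle with lexicographic ties
brute_ap <- function(scores, labels, ids = NULL) {
  if (is.null(ids)) ids <- seq_along(scores)
  ord <- order(-scores, ids)
  lab <- labels[ord] > 0
  mean(cumsum(lab)[lab] / which(lab))
}
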