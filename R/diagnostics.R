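# connectivity / bipartiteness preconditions for walk-convergence claims;
# bipartite = FALSE checks connectivity only (pi^T P = pi^T holds on any
# connected graph even when the walk itself oscillates)
check_ergodic <- function(graph, lazy = FALSE, bipartite = TRUE) {
  # unnamed vertices: igraph's bipartite check mishandles names
  ig <- igraph::graph_from_adjacency_matrix(unname(graph$A > 0), mode = "undirected")
  comp <- igraph::components(ig)
  if (comp$no > 1)
    stop(sprintf("graph has %d connected components; restrict to the largest component first",
                 comp$no))
  if (bipartite && !lazy && igraph::bipartite_mapping(ig)$res)
    stop("graph is bipartite: the random walk has no unique limiting distribution (use lazy = TRUE)")
  invisible(TRUE)
}

#' Stationary distribution of the random walk on a graph
#'
#' On a connected, non-bipartite weighted graph the simple random walk (one
#' step: move to a neighbour with probability proportional to link weight)
#' converges to the stationary distribution \eqn{\pi_i = d_i / \sum_j d_j},
#' the degree distribution. This limit is what makes long random walks
#' uninformative for node labelling: once the walk has mixed, its end-point
#' distribution no longer depends on where it started.
#'
#' The balance equation \eqn{\pi^T P = \pi^T} holds on any connected
#' weighted graph; bipartite graphs satisfy it too but the walk itself
#' oscillates rather than converging, so the convergence diagnostics
#' (\code{\link{tv_curve}}, \code{\link{mixing_report}}) additionally reject
#' bipartite inputs.
#'
#' @param graph a connected \code{prop_graph}.
#' @param lazy unused here (accepted for interface symmetry with
#'   \code{\link{tv_curve}}).
#' @return Named probability vector \eqn{\pi} with
#'   \eqn{\pi^T P = \pi^T} exactly (to floating point).
#' @export
stationary_distribution <- function(graph, lazy = FALSE) {
  check_ergodic(graph, lazy = lazy, bipartite = FALSE)
  d <- degree_vector(graph)
  d / sum(d)
}

#' Total variation distance of a random walk to stationarity
#'
#' Starting a walk at \code{start_node}, computes for each length
#' \eqn{r = 0 \ldots r_{max}} the total variation distance
#' \eqn{TV(r) = \frac{1}{2} \sum_j |(e_i^T P^r)_j - \pi_j|} between the
#' length-\eqn{r} walk distribution and the stationary distribution, by
#' iterated sparse vector-matrix products. At \eqn{r = 0} this is
#' \eqn{1 - \pi_i}. Fast decay of this curve is the topological reason
#' walks beyond a few steps carry no label information.
#'
#' @param graph a connected, non-bipartite \code{prop_graph}.
#' @param start_node node identifier to start from.
#' @param r_max maximum walk length (default 10).
#' @param lazy use the lazy walk \eqn{(I + P)/2} (and skip the bipartiteness
#'   check). Default FALSE.
#' @return Data frame with columns \code{r} and \code{tv}.
#' @export
tv_curve <- function(graph, start_node, r_max = 10L, lazy = FALSE) {
  check_ergodic(graph, lazy = lazy)
  pi_ <- stationary_distribution(graph)
  i <- match(start_node, graph$nodes)
  if (is.na(i)) stop(sprintf("unknown start node '%s'", start_node))
  P <- normalize_graph(graph, "asymmetric")$M
  Pt <- Matrix::t(P)
  p <- numeric(length(pi_)); p[i] <- 1
  tv <- numeric(r_max + 1L)
  tv[1L] <- 0.5 * sum(abs(p - pi_))
  for (r in seq_len(r_max)) {
    step <- as.numeric(Pt %*% p)         # row-vector step: p <- p P
    p <- if (lazy) 0.5 * (p + step) else step
    tv[r + 1L] <- 0.5 * sum(abs(p - pi_))
  }
  data.frame(r = 0:r_max, tv = tv)
}

#' Walk-mixing summary over random start nodes
#'
#' Repeats \code{\link{tv_curve}} from \code{n_starts} seeded random start
#' nodes and summarizes the total variation distance per walk length by its
#' median and quartiles — a compact picture of how fast walks on the network
#' forget their origin.
#'
#' @param graph a connected, non-bipartite \code{prop_graph} (restrict to the
#'   largest component first if needed).
#' @param n_starts number of random start nodes (default 100; capped at the
#'   node count).
#' @param r_max maximum walk length (default 10).
#' @param seed integer seed for start-node sampling.
#' @param lazy passed to \code{\link{tv_curve}}.
#' @return Data frame with columns \code{r}, \code{median}, \code{q25},
#'   \code{q75}.
#' @export
mixing_report <- function(graph, n_starts = 100L, r_max = 10L, seed = 1L,
                          lazy = FALSE) {
  check_ergodic(graph, lazy = lazy)
  n_starts <- min(n_starts, length(graph$nodes))
  starts <- with_seed(seed, sample(graph$nodes, n_starts))
  curves <- vapply(starts,
                   function(s) tv_curve(graph, s, r_max, lazy = lazy)$tv,
                   numeric(r_max + 1L))
  curves <- matrix(curves, nrow = r_max + 1L)
  data.frame(r = 0:r_max,
             median = apply(curves, 1, stats::median),
             q25 = apply(curves, 1, stats::quantile, 0.25),
             q75 = apply(curves, 1, stats::quantile, 0.75))
}
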