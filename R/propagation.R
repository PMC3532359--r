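#' Random-walk feature matrix
#'
#' Column \eqn{r} of the returned matrix is \eqn{x^{(r)} = M^r y}, computed by
#' successive sparse matrix-vector products (the matrix power is never
#' formed). Under the asymmetric normalization and a binary label vector,
#' entry \eqn{(i, r)} is the probability that a length-\eqn{r} random walk
#' started at node \eqn{i} ends in a positive node.
#'
#' @param norm a \code{prop_norm} (see \code{\link{normalize_graph}}).
#' @param y numeric label vector over the graph's node ordering.
#' @param R number of walk lengths (columns), \code{R >= 1}.
#' @return \code{n x R} dense matrix with columns \code{x1 ... xR}.
#' @export
walk_features <- function(norm, y, R) {
  stopifnot(inherits(norm, "prop_norm"), R >= 1)
  if (length(y) != nrow(norm$M)) stop("label vector length does not match graph")
  X <- matrix(0, length(y), R, dimnames = list(norm$nodes, paste0("x", seq_len(R))))
  v <- y
  for (r in seq_len(R)) {
    v <- as.numeric(norm$M %*% v)
    X[, r] <- v
  }
  X
}

#' Truncated label-propagation scores
#'
#' Computes the length-\code{R} truncation of the propagation series
#' \eqn{f^{(R)} = \sum_{r=0}^{R} \lambda^r M^r y} incrementally (the
#' \eqn{r = 0} term is \eqn{y} itself).
#'
#' @param norm a \code{prop_norm}.
#' @param y numeric label vector.
#' @param lambda propagation strength, in (0, 1).
#' @param R truncation length, \code{R >= 0} (\code{R = 0} returns \code{y}).
#' @return Named score vector.
#' @export
glp_truncated <- function(norm, y, lambda, R) {
  stopifnot(inherits(norm, "prop_norm"), lambda > 0, lambda < 1, R >= 0)
  if (length(y) != nrow(norm$M)) stop("label vector length does not match graph")
  f <- y
  v <- y
  lr <- 1
  for (r in seq_len(R)) {
    v <- as.numeric(norm$M %*% v)
    lr <- lr * lambda
    f <- f + lr * v
  }
  names(f) <- norm$nodes
  f
}

# Conjugate gradient for a symmetric positive-definite operator given as a
# function v -> Av. Plain CG suffices at the problem sizes this package
# targets; spectral radius of S is <= 1 so I - lambda*S is SPD for
# lambda in (0,1).
cg_solve <- function(apply_A, b, tol = 1e-10, max_iter = 1000L) {
  x <- numeric(length(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  bnorm <- sqrt(sum(b * b))
  if (bnorm == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (sqrt(rs_new) <= tol * bnorm) return(x)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  stop(sprintf("conjugate gradient did not converge in %d iterations (relative residual %.3g)",
               max_iter, sqrt(rs) / bnorm))
}

#' Exact label-propagation scores
#'
#' Solves the fixed point \eqn{(I - \lambda M) f = y} of the propagation
#' update, i.e. the limit of the series computed by
#' \code{\link{glp_truncated}}, using conjugate gradient on the sparse
#' system. The asymmetric system \eqn{(I - \lambda P)} is solved through its
#' symmetric similarity transform
#' \eqn{I - \lambda P = D^{-1/2} (I - \lambda S) D^{1/2}}, so both
#' normalizations use the symmetric solver. Isolated nodes have
#' \eqn{f_i = y_i}.
#'
#' @param norm a \code{prop_norm}.
#' @param y numeric label vector.
#' @param lambda propagation strength, in (0, 1).
#' @param tol relative residual tolerance of the solver.
#' @param max_iter iteration cap.
#' @return Named score vector \code{f} with
#'   \code{(I - lambda M) f = y} up to \code{tol}.
#' @export
glp_exact <- function(norm, y, lambda, tol = 1e-10, max_iter = 1000L) {
  stopifnot(inherits(norm, "prop_norm"), lambda > 0, lambda < 1)
  if (length(y) != nrow(norm$M)) stop("label vector length does not match graph")
  d <- norm$d
  live <- d > 0
  f <- as.numeric(y)            # isolated nodes: (I - lam M) f = y gives f = y
  if (any(live)) {
    if (norm$kind == "symmetric") {
      S <- norm$M[live, live, drop = FALSE]
      b <- y[live]
      g <- cg_solve(function(v) v - lambda * as.numeric(S %*% v), b,
                    tol = tol, max_iter = max_iter)
      f[live] <- g
    } else {
      # (I - lam P) f = y  <=>  (I - lam S) D^{1/2} f = D^{1/2} y
      A_live <- norm$M[live, live, drop = FALSE]   # P restricted to live nodes
      s <- sqrt(d[live])
      S <- Matrix::Diagonal(x = s) %*% A_live %*% Matrix::Diagonal(x = 1 / s)
      b <- s * y[live]
      g <- cg_solve(function(v) v - lambda * as.numeric(S %*% v), b,
                    tol = tol, max_iter = max_iter)
      f[live] <- g / s
    }
  }
  names(f) <- norm$nodes
  f
}

#' Symmetric propagation scores computed through the asymmetric variant
#'
#' The symmetric (SLP) and asymmetric (ALP) propagation solutions are related
#' exactly: running ALP with the modified label vector
#' \eqn{y'_i = \sqrt{d_i}} for positives (0 otherwise) and rescaling the
#' resulting scores elementwise by \eqn{1/\sqrt{d_i}} reproduces the SLP
#' scores. This function computes SLP by that route; it agrees with
#' \code{glp_exact(normalize_graph(g, "symmetric"), y, lambda)} to solver
#' tolerance.
#'
#' Here "ALP" propagates label mass outward from the positives (the
#' distribution-evolution form \eqn{f = \sum_r \lambda^r (P^T)^r y'}, the
#' fixed point of \eqn{f \leftarrow \lambda P^T f + y'}), which is the form
#' whose correspondence with SLP is exact. The fixed point is computed by
#' iterating that update to tolerance — the classic label-propagation
#' iteration, a route computationally independent of the conjugate-gradient
#' solve used by \code{\link{glp_exact}}.
#'
#' @param graph a \code{prop_graph}.
#' @param y binary label vector.
#' @param lambda propagation strength, in (0, 1).
#' @param tol max-norm tolerance on the fixed-point update.
#' @param max_iter iteration cap (the update contracts at rate
#'   \code{lambda}, so convergence is geometric).
#' @return Named score vector.
#' @export
slp_via_alp <- function(graph, y, lambda, tol = 1e-10, max_iter = 100000L) {
  stopifnot(lambda > 0, lambda < 1)
  norm <- normalize_graph(graph, "asymmetric")
  d <- norm$d
  y_mod <- ifelse(y > 0, sqrt(d), 0)
  Pt <- Matrix::t(norm$M)
  f_alp <- y_mod
  for (it in seq_len(max_iter)) {
    f_new <- lambda * as.numeric(Pt %*% f_alp) + y_mod
    delta <- max(abs(f_new - f_alp))
    f_alp <- f_new
    if (delta <= tol * (1 - lambda) / max(lambda, .Machine$double.eps)) break
  }
  f <- ifelse(d > 0, f_alp / sqrt(pmax(d, .Machine$double.xmin)), y)
  names(f) <- graph$nodes
  f
}
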