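#' Fit a 3Prop / NProp node-labelling model
#'
#' 3Prop scores every node of an undirected network as a weighted sum of its
#' length-1, -2 and -3 random-walk probabilities into positively labelled
#' nodes, \eqn{f = w_1 M y + w_2 M^2 y + w_3 M^3 y}, where \eqn{M} is either
#' the symmetric normalization \eqn{S = D^{-1/2} A D^{-1/2}} (default) or the
#' row-stochastic \eqn{P = D^{-1} A}. Unlike classic label propagation, the
#' three weights are free, real-valued and possibly negative, which lets the
#' model adapt to assortative, disassortative and shared-neighbour labelling
#' patterns. \code{NProp} is the same model with walks up to length \code{R}.
#'
#' The weights are estimated by linear discriminant analysis,
#' \eqn{w = C^{-1}(\mu_+ - \mu_-)}: the difference of the class means of the
#' walk-feature rows, whitened by the feature covariance. To avoid a
#' positive's own label inflating its features, the training positives are
#' split: a random fraction (\code{propagation_fraction}, default 2/3) of
#' them populates the label vector inside the walk features, while the class
#' means and covariance are estimated from the remaining positives plus the
#' non-positive nodes.
#'
#' @param graph a \code{prop_graph} (see \code{\link{weighted_graph}},
#'   \code{\link{read_edge_list}}).
#' @param positives character vector of positive node identifiers, or a
#'   binary 0/1 label vector over the graph's nodes.
#' @param R maximum walk length (number of weights). Default 3.
#' @param variant \code{"symmetric"} (default; performs better in practice)
#'   or \code{"asymmetric"}.
#' @param propagation_fraction fraction of training positives whose labels
#'   drive the walk features; the rest enter the estimation set. Default 2/3.
#' @param split_seed integer seed for the random positive split (required for
#'   reproducibility; recorded in the fit).
#' @param ridge ridge added to the covariance before inversion. Default
#'   \code{1e-8 * mean(diag(C))}; pass 0 to disable.
#' @param covariance \code{"pooled"} (default): pooled within-class sample
#'   covariance; \code{"total"}: single sample covariance of all estimation
#'   rows.
#' @return An object of class \code{threeprop}: list with \code{weights}
#'   (canonically normalized: unit Euclidean norm, oriented so the fitted
#'   direction increases the mean positive score), \code{fit} (class means,
#'   covariance, counts, split membership, seed), \code{variant}, \code{R},
#'   \code{positives}, and the graph. Use \code{\link{predict.threeprop}} to
#'   score nodes.
#' @examples
#' sim <- synth_network(pattern = "assortative", seed = 1)
#' fit <- threeprop(sim$graph, sim$positives, split_seed = 1)
#' coef(fit)
#' head(sort(predict(fit), decreasing = TRUE))
#' @seealso \code{\link{score_nprop}}, \code{\link{cross_validate}}
#' @export
threeprop <- function(graph, positives, R = 3L,
                      variant = c("symmetric", "asymmetric"),
                      propagation_fraction = 2 / 3,
                      split_seed,
                      ridge = NULL,
                      covariance = c("pooled", "total")) {
  variant <- match.arg(variant)
  covariance <- match.arg(covariance)
  stopifnot(inherits(graph, "prop_graph"), R >= 1,
            propagation_fraction > 0, propagation_fraction < 1)
  if (missing(split_seed)) stop("split_seed is required (logged for reproducibility)")
  if (is.numeric(positives) && length(positives) == length(graph$nodes))
    positives <- graph$nodes[positives > 0]
  positives <- intersect(positives, graph$nodes)
  n_pos_total <- length(positives)
  if (n_pos_total < 3)
    stop(sprintf("need at least 3 training positives (got %d)", n_pos_total))

  norm <- normalize_graph(graph, variant)
  # split training positives: propagation set drives y, the rest are scored
  n_prop <- ceiling(propagation_fraction * n_pos_total)
  if (n_prop >= n_pos_total) n_prop <- n_pos_total - 1L
  prop_set <- with_seed(as.integer(split_seed), sample(positives, n_prop))
  est_pos <- setdiff(positives, prop_set)

  y_prop <- label_vector(graph, prop_set)
  X <- walk_features(norm, y_prop, R)

  is_est_pos <- graph$nodes %in% est_pos
  is_neg <- !(graph$nodes %in% positives)   # non-positives act as negatives
  Xp <- X[is_est_pos, , drop = FALSE]
  Xn <- X[is_neg, , drop = FALSE]
  n_pos <- nrow(Xp); n_neg <- nrow(Xn)
  if (n_pos < 1 || n_neg < 2)
    stop(sprintf("estimation set too small (%d positives, %d non-positives)", n_pos, n_neg))

  lda <- lda_weights(Xp, Xn, ridge = ridge, covariance = covariance)
  w <- lda$w
  mu_pos <- lda$mu_pos; mu_neg <- lda$mu_neg; C <- lda$C; ridge <- lda$ridge

  structure(list(
    weights = w,
    fit = list(mu_pos = mu_pos, mu_neg = mu_neg, C = C,
               n_pos = n_pos, n_neg = n_neg,
               propagation_set = sort(prop_set), estimation_positives = sort(est_pos),
               split_seed = as.integer(split_seed),
               propagation_fraction = propagation_fraction,
               ridge = ridge, covariance = covariance),
    variant = variant, R = as.integer(R),
    positives = sort(positives), graph = graph,
    call = match.call()
  ), class = "threeprop")
}

# closed-form LDA on walk-feature rows: w = (C + ridge I)^{-1} (mu+ - mu-),
# with C either the pooled within-class or the total sample covariance
lda_weights <- function(Xp, Xn, ridge = NULL,
                        covariance = c("pooled", "total")) {
  covariance <- match.arg(covariance)
  n_pos <- nrow(Xp); n_neg <- nrow(Xn); R <- ncol(Xp)
  mu_pos <- colMeans(Xp)
  mu_neg <- colMeans(Xn)
  C <- if (covariance == "pooled") {
    Cp <- if (n_pos > 1) stats::cov(Xp) * (n_pos - 1) else matrix(0, R, R)
    Cn <- if (n_neg > 1) stats::cov(Xn) * (n_neg - 1) else matrix(0, R, R)
    (Cp + Cn) / (max(n_pos - 1, 0) + max(n_neg - 1, 0))
  } else {
    stats::cov(rbind(Xp, Xn))
  }
  if (is.null(ridge)) ridge <- 1e-8 * mean(diag(C))
  w <- tryCatch(solve(C + diag(ridge, R), mu_pos - mu_neg),
                error = function(e)
                  stop("covariance matrix is singular; supply ridge > 0",
                       call. = FALSE))
  list(w = canonicalize_weights(w, mu_pos - mu_neg),
       mu_pos = mu_pos, mu_neg = mu_neg, C = C, ridge = ridge)
}

# unit Euclidean norm, oriented so that w . (mu+ - mu-) > 0
canonicalize_weights <- function(w, direction = w) {
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("degenerate fit: all weights zero")
  w <- w / nrm
  if (sum(w * direction) < 0) w <- -w
  names(w) <- paste0("w", seq_along(w))
  w
}

#' NProp scores for given walk weights
#'
#' Computes \eqn{f = \sum_{r=1}^{R} w_r M^r y}; there is no \eqn{r = 0}
#' self-term, so only network structure contributes. With geometric weights
#' \eqn{(\lambda, \lambda^2, \lambda^3)} this reproduces the truncated
#' propagation series at \eqn{R = 3} minus \eqn{y}.
#'
#' @param norm a \code{prop_norm}.
#' @param y numeric label vector (at prediction time: all training positives).
#' @param w numeric weight vector; its length sets the number of walk steps.
#' @return Named score vector.
#' @export
score_nprop <- function(norm, y, w) {
  X <- walk_features(norm, y, length(w))
  f <- as.numeric(X %*% w)
  names(f) <- norm$nodes
  f
}

#' Score nodes with a fitted 3Prop model
#'
#' @param object a \code{threeprop} fit.
#' @param newdata optional \code{prop_graph} with the same node set (e.g. the
#'   same network re-weighted); defaults to the training graph.
#' @param positives optional replacement set of positive identifiers to
#'   propagate from; defaults to the full training positives (both halves of
#'   the fitting split).
#' @param ... ignored.
#' @return Named numeric score vector over all nodes (higher = more likely
#'   positive; only the ranking is meaningful).
#' @export
predict.threeprop <- function(object, newdata = NULL, positives = NULL, ...) {
  graph <- if (is.null(newdata)) object$graph else newdata
  if (is.null(positives)) positives <- object$positives
  norm <- normalize_graph(graph, object$variant)
  score_nprop(norm, label_vector(graph, positives), object$weights)
}

#' @export
coef.threeprop <- function(object, ...) object$weights

#' @export
print.threeprop <- function(x, ...) {
  cat(sprintf("%dProp fit (%s normalization)\n", x$R, x$variant))
  cat("Walk weights (unit norm):\n")
  print(round(x$weights, 4))
  cat(sprintf("Training: %d positives (%d propagation / %d estimation), %d non-positives; split_seed = %d\n",
              length(x$positives), length(x$fit$propagation_set),
              x$fit$n_pos, x$fit$n_neg, x$fit$split_seed))
  invisible(x)
}

#' @export
summary.threeprop <- function(object, ...) {
  out <- list(weights = object$weights, mu_pos = object$fit$mu_pos,
              mu_neg = object$fit$mu_neg, C = object$fit$C,
              n_pos = object$fit$n_pos, n_neg = object$fit$n_neg,
              variant = object$variant, R = object$R)
  class(out) <- "summary.threeprop"
  out
}

#' @export
print.summary.threeprop <- function(x, ...) {
  cat(sprintf("%dProp (%s) LDA fit\n", x$R, x$variant))
  cat("Weights:\n"); print(round(x$weights, 4))
  cat("Class means of walk features (estimation set):\n")
  print(rbind(positive = x$mu_pos, `non-positive` = x$mu_neg))
  cat("Pooled covariance:\n"); print(signif(x$C, 4))
  invisible(x)
}

#' Weight profile plot for a 3Prop fit
#'
#' Bar plot of the fitted (canonically normalized) weight per walk length;
#' the sign pattern is the model's reading of the labelling regime (all
#' positive: assortative; negative first step: disassortative / shared
#' neighbour).
#'
#' @param x a \code{threeprop} fit.
#' @param ... passed to \code{barplot}.
#' @export
plot.threeprop <- function(x, ...) {
  graphics::barplot(x$weights, names.arg = paste("length", seq_len(x$R)),
                    ylab = "weight", main = sprintf("%dProp walk weights", x$R), ...)
  graphics::abline(h = 0)
  invisible(x)
}

#' Serialize a 3Prop fit report to JSON
#'
#' Writes weights, class means, covariance, counts and the split seed, so the
#' learned weights can be reused for other labelling tasks on the same
#' network. Read back with \code{\link{read_fit_report}}.
#'
#' @param object a \code{threeprop} fit.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_fit_report <- function(object, path) {
  stopifnot(inherits(object, "threeprop"))
  rep <- list(weights = as.numeric(object$weights),
              R = object$R, variant = object$variant,
              mu_pos = as.numeric(object$fit$mu_pos),
              mu_neg = as.numeric(object$fit$mu_neg),
              C = unname(as.matrix(object$fit$C)),
              n_pos = object$fit$n_pos, n_neg = object$fit$n_neg,
              split_seed = object$fit$split_seed,
              propagation_fraction = object$fit$propagation_fraction,
              ridge = object$fit$ridge, covariance = object$fit$covariance)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_report
#' @param path path of a JSON fit report.
#' @return For \code{read_fit_report}: the parsed report as a list with a
#'   numeric \code{weights} vector.
#' @export
read_fit_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep$weights <- as.numeric(rep$weights)
  rep
}
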