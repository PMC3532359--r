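#' Area under the ROC curve
#'
#' Rank-based AUROC with midrank tie handling: equals the probability that a
#' uniformly chosen positive scores higher than a uniformly chosen negative,
#' ties counting one half.
#'
#' @param scores numeric score vector.
#' @param labels binary label vector (1 = positive), same length.
#' @param eval_mask optional logical vector or integer index subset; the
#'   metric is computed only over these nodes. Must contain at least one
#'   positive and one negative.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels, eval_mask = NULL) {
  if (!is.null(eval_mask)) { scores <- scores[eval_mask]; labels <- labels[eval_mask] }
  pos <- labels > 0
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("evaluation set must contain at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Average precision
#'
#' Mean of the precision values at the rank of each positive (the precision
#' of the top-\eqn{k} list whenever a positive sits at rank \eqn{k}),
#' averaged over positives. Ties are broken deterministically by the score
#' vector's names (node identifiers) or, unnamed, by position.
#'
#' @inheritParams auroc
#' @param method \code{"mean_precision"} (default) or \code{"trapezoid"}
#'   (trapezoidal area under the precision-recall curve).
#' @return Average precision in [0, 1].
#' @export
average_precision <- function(scores, labels, eval_mask = NULL,
                              method = c("mean_precision", "trapezoid")) {
  method <- match.arg(method)
  if (!is.null(eval_mask)) { scores <- scores[eval_mask]; labels <- labels[eval_mask] }
  pos <- labels > 0
  n1 <- sum(pos)
  if (n1 == 0 || sum(!pos) == 0)
    stop("evaluation set must contain at least one positive and one negative")
  tie_break <- if (!is.null(names(scores))) names(scores) else seq_along(scores)
  ord <- order(-scores, tie_break)
  hit <- pos[ord]
  prec_at_pos <- cumsum(hit)[hit] / which(hit)
  if (method == "mean_precision") return(mean(prec_at_pos))
  recall <- cumsum(hit)[hit] / n1
  # trapezoid over the PR steps, anchored at recall 0 with the first precision
  sum(diff(c(0, recall)) * (prec_at_pos + c(prec_at_pos[1], utils::head(prec_at_pos, -1))) / 2)
}

default_lambda_grid <- function() c(0.01, 0.1, 0.25, 0.5, 0.75, 0.9, 0.99)

# deterministic stratified partition of ids into k folds
make_folds <- function(ids, k, seed) {
  idx <- with_seed(seed, sample(seq_along(ids)))
  split(ids[idx], rep_len(seq_len(k), length(ids)))
}

#' Nested cross-validated evaluation of 3Prop / NProp and label propagation
#'
#' Evaluates a labelling method by outer k-fold cross-validation over the
#' positive nodes (default 3-fold): in each outer fold the held-out
#' positives' labels are zeroed in the training label vector, the method is
#' trained on the remaining positives, and AUROC and average precision are
#' computed over the held-out positives against all never-positive nodes
#' (which are never removed — non-positives act as negatives throughout).
#' For \code{method = "glp"} the propagation strength \eqn{\lambda} is chosen
#' per outer fold by an inner cross-validation (default 2-fold) over
#' \code{lambda_grid}, maximizing mean average precision. For
#' \code{method = "nprop"} the walk weights are fitted per outer fold by
#' \code{\link{threeprop}}.
#'
#' @param graph a \code{prop_graph}.
#' @param positives character vector of positive node ids (or binary vector).
#' @param method \code{"nprop"} (default) or \code{"glp"}.
#' @param R maximum walk length for nprop.
#' @param variant normalization, \code{"symmetric"} (default) or
#'   \code{"asymmetric"}.
#' @param outer_folds,inner_folds fold counts (defaults 3 and 2).
#' @param lambda_grid candidate \eqn{\lambda} values for glp.
#' @param seed integer seed controlling fold assignment and the nprop fitting
#'   split.
#' @param ... passed to \code{\link{threeprop}} (e.g. \code{covariance}).
#' @return An object of class \code{threeprop_cv}: list with \code{per_fold}
#'   (data frame: fold, parameter, auroc, aup, n_test_pos), \code{auroc} and
#'   \code{aup} (means over folds), \code{method}, and the protocol settings.
#' @examples
#' sim <- synth_network(pattern = "assortative", seed = 1)
#' cross_validate(sim$graph, sim$positives, method = "nprop", seed = 1)
#' @export
cross_validate <- function(graph, positives, method = c("nprop", "glp"),
                           R = 3L, variant = c("symmetric", "asymmetric"),
                           outer_folds = 3L, inner_folds = 2L,
                           lambda_grid = default_lambda_grid(),
                           seed = 1L, ...) {
  method <- match.arg(method)
  variant <- match.arg(variant)
  stopifnot(inherits(graph, "prop_graph"), outer_folds >= 2, inner_folds >= 2)
  if (is.numeric(positives) && length(positives) == length(graph$nodes))
    positives <- graph$nodes[positives > 0]
  positives <- intersect(positives, graph$nodes)
  if (length(positives) < outer_folds)
    stop(sprintf("need at least %d positives for %d outer folds (got %d)",
                 outer_folds, outer_folds, length(positives)))
  norm <- normalize_graph(graph, variant)
  never_pos <- !(graph$nodes %in% positives)
  folds <- make_folds(positives, outer_folds, seed)

  rows <- vector("list", outer_folds)
  for (k in seq_len(outer_folds)) {
    test_pos <- folds[[k]]
    train_pos <- setdiff(positives, test_pos)
    eval_mask <- never_pos | (graph$nodes %in% test_pos)
    y_eval <- as.numeric(graph$nodes %in% test_pos)

    if (method == "glp") {
      lam <- select_lambda(graph, norm, train_pos, never_pos, inner_folds,
                           lambda_grid, seed = seed * 131L + k)
      f <- glp_exact(norm, label_vector(graph, train_pos), lam)
      param <- sprintf("lambda=%g", lam)
    } else {
      fit <- threeprop(graph, train_pos, R = R, variant = variant,
                       split_seed = seed * 131L + k, ...)
      f <- score_nprop(norm, label_vector(graph, train_pos), fit$weights)
      param <- paste0("w=(", paste(sprintf("%.3f", fit$weights), collapse = ","), ")")
    }
    rows[[k]] <- data.frame(
      fold = k, parameter = param,
      auroc = auroc(f, y_eval, eval_mask),
      aup = average_precision(f, y_eval, eval_mask),
      n_test_pos = length(test_pos))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 auroc = mean(per_fold$auroc), aup = mean(per_fold$aup),
                 method = method, variant = variant, R = R,
                 outer_folds = outer_folds, inner_folds = inner_folds,
                 lambda_grid = lambda_grid, seed = seed,
                 n_pos = length(positives), n_neg = sum(never_pos)),
            class = "threeprop_cv")
}

# inner CV: pick lambda maximizing mean held-out average precision
select_lambda <- function(graph, norm, train_pos, never_pos, inner_folds,
                          lambda_grid, seed) {
  if (length(train_pos) < inner_folds) return(lambda_grid[1])
  inner <- make_folds(train_pos, inner_folds, seed)
  mean_aup <- vapply(lambda_grid, function(lam) {
    mean(vapply(seq_along(inner), function(j) {
      held <- inner[[j]]
      y_tr <- label_vector(graph, setdiff(train_pos, held))
      f <- glp_exact(norm, y_tr, lam)
      mask <- never_pos | (graph$nodes %in% held)
      average_precision(f, as.numeric(graph$nodes %in% held), mask)
    }, 0))
  }, 0)
  lambda_grid[which.max(mean_aup)]
}

#' @export
print.threeprop_cv <- function(x, ...) {
  cat(sprintf("%s (%s), %d-fold outer / %d-fold inner CV, %d positives vs %d non-positives\n",
              toupper(x$method), x$variant, x$outer_folds, x$inner_folds,
              x$n_pos, x$n_neg))
  print(x$per_fold, row.names = FALSE)
  cat(sprintf("Mean AUROC = %.4f, mean AUP = %.4f\n", x$auroc, x$aup))
  invisible(x)
}

#' Cross-validated performance as a function of maximum walk length
#'
#' Runs \code{\link{cross_validate}} with \code{method = "nprop"} for each
#' walk length in \code{R_values}, returning one row per length — useful for
#' checking whether walks longer than three add predictive signal.
#'
#' @inheritParams cross_validate
#' @param R_values integer vector of maximum walk lengths (default 1:6).
#' @return Data frame with columns R, auroc, aup.
#' @export
nprop_sweep <- function(graph, positives, R_values = 1:6,
                        variant = c("symmetric", "asymmetric"), seed = 1L, ...) {
  variant <- match.arg(variant)
  rows <- lapply(R_values, function(R) {
    cv <- cross_validate(graph, positives, method = "nprop", R = R,
                         variant = variant, seed = seed, ...)
    data.frame(R = R, auroc = cv$auroc, aup = cv$aup)
  })
  do.call(rbind, rows)
}
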