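# exhaustive direction search on the unit sphere: the independent oracle for
# the LDA direction (maximizes training AUROC of X w over ~2600 directions)
sphere_grid_direction <- function(X, labels, step_deg = 5) {
  th <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  ph <- seq(0, 360 - step_deg, by = step_deg) * pi / 180
  best <- NULL; best_auc <- -Inf
  for (t in th) for (p in ph) {
    w <- c(sin(t) * cos(p), sin(t) * sin(p), cos(t))
    a <- brute_auroc(as.numeric(X %*% w), labels)
    if (a > best_auc) { best_auc <- a; best <- w }
  }
  best
}
angle_deg <- function(u, v)
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi

test_that("LDA reduces to the mean difference under identity covariance", {
  set.seed(1)
  Xn <- matrix(rnorm(600 * 3), 600, 3)
  Xp <- matrix(rnorm(600 * 3), 600, 3)
  Xp[, 1] <- Xp[, 1] + 3
  lda <- threeprop:::lda_weights(Xp, Xn)
  expect_gt(lda$w[1], 0.95)                       # w ~ (1, 0, 0) after norm
  expect_lt(max(abs(lda$w[2:3])), 0.25)
  expect_equal(sqrt(sum(lda$w^2)), 1)
  # canonical orientation increases the mean positive score
  expect_gt(sum(lda$w * (colMeans(Xp) - colMeans(Xn))), 0)
})

test_that("pooled covariance is the size-weighted within-class combination", {
  set.seed(2)
  Xp <- matrix(rnorm(30), 10, 3); Xn <- matrix(rnorm(60), 20, 3)
  C <- threeprop:::lda_weights(Xp, Xn)$C
  expect_equal(C, (9 * cov(Xp) + 19 * cov(Xn)) / 28)
  Ct <- threeprop:::lda_weights(Xp, Xn, covariance = "total")$C
  expect_equal(Ct, cov(rbind(Xp, Xn)))
})

test_that("nprop scoring is the weighted walk-feature combination", {
  g <- random_graph(25, seed = 3, weighted = TRUE)
  M <- normalize_graph(g)
  set.seed(31); y <- as.numeric(runif(25) < 0.3)
  X <- walk_features(M, y, 3)
  expect_equal(score_nprop(M, y, c(1, 0, 0)), stats::setNames(X[, 1], g$nodes))
  # geometric weights + y reproduce the truncated series at R = 3 exactly
  lam <- 0.37
  expect_equal(unname(score_nprop(M, y, c(lam, lam^2, lam^3)) + y),
               unname(glp_truncated(M, y, lam, 3)), tolerance = 1e-14)
})

test_that("metrics are invariant to positive rescaling of the weights", {
  sim <- synth_network(pattern = "assortative", seed = 3)
  M <- normalize_graph(sim$graph)
  fit <- threeprop(sim$graph, sim$positives, split_seed = 3)
  f1 <- score_nprop(M, sim$y, fit$weights)
  f2 <- score_nprop(M, sim$y, 17.3 * fit$weights)
  expect_equal(auroc(f1, sim$y), auroc(f2, sim$y))
  expect_equal(average_precision(f1, sim$y), average_precision(f2, sim$y))
})

test_that("the fitting split separates propagation and estimation positives", {
  sim <- synth_network(pattern = "assortative", seed = 4)
  fit <- threeprop(sim$graph, sim$positives, split_seed = 11)
  expect_length(fit$fit$propagation_set, ceiling(2 / 3 * length(sim$positives)))
  expect_setequal(c(fit$fit$propagation_set, fit$fit$estimation_positives),
                  sim$positives)
  expect_length(intersect(fit$fit$propagation_set,
                          fit$fit$estimation_positives), 0)
  # same seed, same split; fit is deterministic
  fit2 <- threeprop(sim$graph, sim$positives, split_seed = 11)
  expect_identical(fit$weights, fit2$weights)
  expect_error(threeprop(sim$graph, sim$positives[1:2], split_seed = 1),
               "at least 3")
})

test_that("fitted direction agrees with the sphere-grid AUROC oracle", {
  sim <- synth_network(pattern = "assortative", seed = 5)
  fit <- threeprop(sim$graph, sim$positives, split_seed = 5)
  # oracle on the same estimation-set features the fit used
  M <- normalize_graph(sim$graph)
  X <- walk_features(M, label_vector(sim$graph, fit$fit$propagation_set), 3)
  est <- sim$graph$nodes %in% fit$fit$estimation_positives |
    !(sim$graph$nodes %in% sim$positives)
  lab <- as.numeric(sim$graph$nodes %in% fit$fit$estimation_positives)[est]
  w_star <- sphere_grid_direction(X[est, ], lab)
  expect_lt(angle_deg(fit$weights, w_star), 30)
  expect_gt(fit$weights[1], 0)                     # assortative: direct links help
})

test_that("shared-neighbor fits discount or invert the direct-link weight", {
  for (seed in 1:5) {
    sim <- synth_network(pattern = "shared_neighbor", seed = seed)
    w <- coef(threeprop(sim$graph, sim$positives, split_seed = seed))
    expect_true(sign(w[1]) != sign(w[2]) || abs(w[1]) < abs(w[2]) / 3)
  }
})

test_that("symmetric and asymmetric variants behave as documented", {
  sim <- synth_network(pattern = "assortative", seed = 6)
  fit <- threeprop(sim$graph, sim$positives, split_seed = 6)
  expect_identical(fit$variant, "symmetric")       # default variant
  g <- k3_graph()
  X <- walk_features(normalize_graph(g, "asymmetric"), c(1, 1, 0), 3)
  expect_true(all(X >= 0 & X <= 1))
  # regular graph: both variants give identical rankings
  y <- c(1, 0, 0)
  fS <- score_nprop(normalize_graph(g, "symmetric"), y, c(0.2, 0.5, -0.1))
  fP <- score_nprop(normalize_graph(g, "asymmetric"), y, c(0.2, 0.5, -0.1))
  expect_equal(order(fS), order(fP))
})

test_that("fit reports round-trip through JSON", {
  sim <- synth_network(pattern = "assortative", seed = 7)
  fit <- threeprop(sim$graph, sim$positives, split_seed = 7)
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, path)
  rep <- read_fit_report(path)
  expect_equal(rep$weights, unname(fit$weights), tolerance = 1e-12)
  expect_equal(rep$split_seed, 7)
  expect_equal(rep$C, unname(as.matrix(fit$fit$C)), tolerance = 1e-12)
  # reusing stored weights reproduces the model's scores
  M <- normalize_graph(sim$graph, rep$variant)
  expect_equal(score_nprop(M, sim$y, rep$weights), predict(fit),
               tolerance = 1e-12)
})
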