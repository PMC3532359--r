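test_that("walk features match hand steps and the dense matrix-power oracle", {
  P <- normalize_graph(path3_graph(), "asymmetric")
  X <- walk_features(P, c(1, 0, 0), 2)
  expect_equal(unname(X[, 1]), c(0, 1 / 2, 0))
  expect_equal(unname(X[, 2]), c(1 / 2, 0, 1 / 2))   # P^2 y, dense oracle value

  expect_equal(unname(walk_features(P, c(0, 0, 0), 3)), matrix(0, 3, 3))

  g <- random_graph(30, seed = 2, weighted = TRUE)
  set.seed(9); y <- as.numeric(runif(30) < 0.2)
  for (kind in c("symmetric", "asymmetric")) {
    M <- normalize_graph(g, kind)
    Md <- if (kind == "symmetric") dense_S(g) else dense_P(g)
    expect_equal(unname(walk_features(M, y, 3)), dense_walk_features(Md, y, 3),
                 tolerance = 1e-10)
  }
})

test_that("asymmetric walk features of a binary label vector are probabilities", {
  for (seed in 1:5) {
    g <- random_graph(25, p = 0.2, seed = seed, weighted = TRUE)
    set.seed(seed + 100); y <- as.numeric(runif(25) < 0.3)
    X <- walk_features(normalize_graph(g, "asymmetric"), y, 5)
    expect_true(all(X >= -1e-12 & X <= 1 + 1e-12))
  }
})

test_that("truncated propagation follows the incremental series", {
  P <- normalize_graph(path3_graph(), "asymmetric")
  y <- c(1, 0, 0)
  expect_equal(unname(glp_truncated(P, y, 0.5, 0)), y)   # R = 0: just y
  # y + 0.5 * Py + 0.25 * P^2 y, dense-oracle expansion
  expect_equal(unname(glp_truncated(P, y, 0.5, 2)), c(1.125, 0.25, 0.125))
})

test_that("truncated series converges to the exact fixed point", {
  g <- random_graph(30, seed = 4, weighted = TRUE)
  set.seed(44); y <- as.numeric(runif(30) < 0.2)
  for (kind in c("symmetric", "asymmetric")) {
    M <- normalize_graph(g, kind)
    f_tr <- glp_truncated(M, y, 0.9, 200)
    f_ex <- glp_exact(M, y, 0.9, tol = 1e-12)
    expect_lt(max(abs(f_tr - f_ex)), 1e-6)
  }
})

test_that("exact solver matches the dense direct solve", {
  S <- normalize_graph(k3_graph(), "symmetric")
  y <- c(1, 0, 0)
  expect_equal(unname(glp_exact(S, y, 0.5, tol = 1e-12)),
               dense_glp(dense_S(k3_graph()), y, 0.5), tolerance = 1e-10)

  g <- random_graph(40, seed = 6, weighted = TRUE)
  set.seed(66); y <- as.numeric(runif(40) < 0.15)
  for (kind in c("symmetric", "asymmetric")) {
    M <- normalize_graph(g, kind)
    Md <- if (kind == "symmetric") dense_S(g) else dense_P(g)
    for (lam in c(0.1, 0.5, 0.9)) {
      expect_equal(unname(glp_exact(M, y, lam, tol = 1e-12)),
                   unname(dense_glp(Md, y, lam)), tolerance = 1e-8)
    }
  }
  # lambda -> 0 limit is the identity
  expect_equal(unname(glp_exact(M, y, 1e-12)), y, tolerance = 1e-9)
})

test_that("truncation error decays to zero and is non-increasing at large R", {
  for (seed in 1:10) {
    g <- random_graph(20, p = 0.25, seed = seed)
    set.seed(seed); y <- as.numeric(runif(20) < 0.25)
    if (sum(y) == 0) y[1] <- 1
    for (lam in c(0.1, 0.5, 0.9)) {
      M <- normalize_graph(g, "symmetric")
      f_ex <- glp_exact(M, y, lam, tol = 1e-13)
      errs <- vapply(c(5, 10, 20, 40, 160),
                     function(R) max(abs(glp_truncated(M, y, lam, R) - f_ex)), 0)
      expect_true(all(diff(errs) <= 1e-12))
      expect_lt(errs[length(errs)], 1e-3)
    }
  }
})

test_that("symmetric scores via the asymmetric route reproduce the direct solve", {
  g <- k3_graph()
  y <- c(1, 0, 0)
  expect_equal(slp_via_alp(g, y, 0.5),
               glp_exact(normalize_graph(g, "symmetric"), y, 0.5),
               tolerance = 1e-8)
  # regular graph: asymmetric and symmetric scores proportional
  f_alp <- glp_exact(normalize_graph(g, "asymmetric"), y, 0.5)
  f_slp <- glp_exact(normalize_graph(g, "symmetric"), y, 0.5)
  expect_equal(stats::sd(f_alp / f_slp), 0, tolerance = 1e-10)

  g2 <- random_graph(50, seed = 8, weighted = TRUE)
  set.seed(88); y2 <- as.numeric(seq_len(50) %in% sample(50, 5))
  f_direct <- glp_exact(normalize_graph(g2, "symmetric"), y2, 0.7, tol = 1e-12)
  f_via <- slp_via_alp(g2, y2, 0.7, tol = 1e-12)
  expect_lt(max(abs(f_direct - f_via)), 1e-8)
  expect_equal(cor(f_direct, f_via, method = "spearman"), 1.0)
})

test_that("propagation scores are equivariant under node relabeling", {
  g <- random_graph(20, seed = 10, weighted = TRUE)
  set.seed(20); y <- as.numeric(runif(20) < 0.3)
  perm <- sample(20)
  gp <- weighted_graph(g$A[perm, perm], g$nodes[perm])
  for (kind in c("symmetric", "asymmetric")) {
    f <- glp_exact(normalize_graph(g, kind), y, 0.6, tol = 1e-12)
    fp <- glp_exact(normalize_graph(gp, kind), y[perm], 0.6, tol = 1e-12)
    expect_equal(unname(fp), unname(f[perm]), tolerance = 1e-9)
  }
})
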