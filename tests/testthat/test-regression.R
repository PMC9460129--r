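test_that("specification enumeration matches the combinatorial counts", {
  cand <- c("D_SAISAIIFAI", "D_ALL", "D_SAISAIIFAII", "D_FAII",
            "D_SAIIFAII", "mu_prime")
  expect_length(enumerate_specs("interaction", cand), 15L)     # choose(6, 2)
  expect_length(enumerate_specs("linear", cand, p_max = 5), 62L)
  expect_length(enumerate_specs("logarithmic", cand, p_max = 5), 62L)
  expect_length(enumerate_specs("polynomial", cand, a_max = 3), 6L)
  expect_warning(enumerate_specs("linear", cand[1:2], p_max = 5), "clamped")
  expect_error(model_spec("interaction", cand[1:3]), "exactly 2")
})

test_that("design matrices implement the four family structures", {
  d <- data.frame(x1 = c(2, 4, 8), x2 = c(3, 9, 27), x3 = c(1, 1, 2))
  X <- design_matrix(model_spec("linear", c("x1", "x2")), d)
  expect_equal(dim(X), c(3L, 3L))
  expect_equal(unname(X[, 1]), rep(1, 3))
  Xl <- design_matrix(model_spec("logarithmic", c("x1", "x2")), d)
  expect_equal(unname(Xl[2, ]), c(1, log10(4), log10(9)))
  Xi <- design_matrix(model_spec("interaction", c("x1", "x2")), d)
  expect_equal(unname(Xi[1, ]), c(1, 2, 3, 6))                 # product term
  Xp <- design_matrix(model_spec("polynomial", "x1", degree = 3), d)
  expect_equal(unname(Xp[3, ]), c(1, 8, 64, 512))
  # log of a non-positive value: infeasible sentinel, not an error
  d0 <- d; d0$x1[2] <- 0
  expect_null(design_matrix(model_spec("logarithmic", c("x1", "x2")), d0))
  expect_error(design_matrix(model_spec("linear", "nope"), d), "missing")
})

test_that("OLS fitting matches the normal-equation oracle and closed forms", {
  # noiseless line
  d <- data.frame(x = c(1, 2, 3, 4, 5, 6, 7, 8))
  y <- 2 * d$x + 1
  fit <- fit_model(model_spec("linear", "x"), d, y)
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # standardized coefficient of a single regressor equals Pearson r
  set.seed(31)
  d2 <- data.frame(x = rnorm(20))
  y2 <- 0.6 * d2$x + rnorm(20, 0, 0.5)
  fit2 <- fit_model(model_spec("linear", "x"), d2, y2)
  expect_equal(unname(fit2$std_coefficients), cor(d2$x, y2), tolerance = 1e-12)
  # random 8 x 3 problem against solve(X'X, X'y)
  set.seed(37)
  d3 <- data.frame(a = runif(8, 1, 5), b = runif(8, 1, 5))
  y3 <- rnorm(8)
  fit3 <- fit_model(model_spec("linear", c("a", "b")), d3, y3)
  X <- cbind(1, d3$a, d3$b)
  expect_equal(unname(fit3$coefficients), drop(oracle_ols(X, y3)),
               tolerance = 1e-10)
  # infeasibility: more coefficients than rows, rank deficiency
  expect_null(fit_model(model_spec("linear", c("a", "b")), d3[1:3, ], y3[1:3]))
  d4 <- data.frame(a = 1:8, b = 2 * (1:8))
  expect_null(fit_model(model_spec("linear", c("a", "b")), d4, rnorm(8)))
})

test_that("refitting on z-scored columns reproduces standardized betas", {
  set.seed(41)
  d <- data.frame(a = runif(12, 1, 9), b = rexp(12))
  y <- 1 + 0.5 * d$a - 2 * d$b + rnorm(12, 0, 0.3)
  fit <- fit_model(model_spec("linear", c("a", "b")), d, y)
  dz <- as.data.frame(scale(d))
  fitz <- fit_model(model_spec("linear", c("a", "b")), dz, as.numeric(scale(y)))
  expect_equal(unname(fitz$coefficients[-1]), unname(fit$std_coefficients),
               tolerance = 1e-8)
})

test_that("adding a regressor never lowers in-sample R2 but can hurt LOSO", {
  set.seed(43)
  d <- data.frame(x = seq(1, 8), z = rnorm(8))
  y <- 2 + 0.7 * d$x + rnorm(8, 0, 0.4)
  f1 <- fit_model(model_spec("linear", "x"), d, y)
  f2 <- fit_model(model_spec("linear", c("x", "z")), d, y)
  expect_gte(f2$r_squared + 1e-12, f1$r_squared)
  cv1 <- loso_error(model_spec("linear", "x"), d, y)
  cv2 <- loso_error(model_spec("linear", c("x", "z")), d, y)
  expect_gt(cv2$error, cv1$error)   # irrelevant regressor inflates CV error
})

test_that("leave-one-sample-out error is exact, invariant and well-formed", {
  d <- data.frame(x = c(1, 2, 4, 8, 16, 32, 64, 128),
                  row.names = sprintf("S%d", 1:8))
  y <- 3 - 0.25 * d$x
  cv <- loso_error(model_spec("linear", "x"), d, y)
  expect_length(cv$fold_errors, 8L)
  expect_lt(cv$error, 1e-20)                       # noiseless: zero error
  # permutation invariance
  set.seed(47)
  noisy <- y + rnorm(8, 0, 0.2)
  cv_a <- loso_error(model_spec("linear", "x"), d, noisy)
  perm <- sample(8)
  cv_b <- loso_error(model_spec("linear", "x"), d[perm, , drop = FALSE],
                     noisy[perm])
  expect_equal(cv_b$error, cv_a$error, tolerance = 1e-12)
  expect_equal(sqrt(cv_a$error),
               loso_error(model_spec("linear", "x"), d, noisy,
                          metric = "rmse")$error)
  # a fold with a non-positive value makes a logarithmic spec infeasible
  d0 <- d; d0$x[3] <- 0
  expect_null(loso_error(model_spec("logarithmic", "x"), d0, y))
})

test_that("a planted logarithmic law beats the linear family in selection", {
  ft <- simulate_feature_table(seed = 53)
  y <- 2 + 1.5 * log10(ft$D_ALL)
  set.seed(54)
  y <- y + rnorm(8, 0, 0.05)
  targets <- data.frame(sample_id = ft$sample_id, pc = y)
  sel <- select_models(list(B = ft), targets,
                       candidates = list(B = c("D_ALL", "mu_prime")))
  expect_equal(sel$best$cell, "B-2")
  expect_equal(sel$best$family, "logarithmic")
  expect_equal(dim(sel$grid), c(1L, 4L))
})

test_that("the selection grid has 8 cells and A/B symmetry when tables match", {
  ft <- simulate_feature_table(seed = 59)
  set.seed(60)
  targets <- data.frame(sample_id = ft$sample_id,
                        pc1 = rnorm(8), pc2 = rnorm(8))
  sel <- select_models(list(A = ft, B = ft), targets,
                       candidates = list(A = c("D_ALL", "mu_prime"),
                                         B = c("D_ALL", "mu_prime")))
  expect_equal(colnames(sel$grid), c("A-1", "A-2", "A-3", "A-4",
                                     "B-1", "B-2", "B-3", "B-4"))
  expect_equal(sel$grid[, 1:4], sel$grid[, 5:8],
               ignore_attr = TRUE)                 # identical inputs, identical minima
  expect_equal(nrow(sel$best), 2L)
  # deterministic under re-run
  sel2 <- select_models(list(A = ft, B = ft), targets,
                        candidates = list(A = c("D_ALL", "mu_prime"),
                                          B = c("D_ALL", "mu_prime")))
  expect_identical(sel$grid, sel2$grid)
  expect_identical(sel$best, sel2$best)
})

test_that("selected-model coefficients converge as planted noise shrinks", {
  ft <- simulate_feature_table(seed = 61)
  clean <- 2 + 1.5 * log10(ft$D_ALL)
  set.seed(62)
  eps <- rnorm(8)
  rel_err <- vapply(c(0.1, 0.01, 0.001), function(s) {
    fit <- fit_model(model_spec("logarithmic", "D_ALL"), ft, clean + s * eps)
    max(abs(fit$coefficients - c(2, 1.5)) / c(2, 1.5))
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 1e-3)
})

test_that("frozen published equations evaluate verbatim", {
  expect_equal(evaluate_frozen("C1PC2", c(D_SAIIFAII = 0)), 0)
  expect_equal(evaluate_frozen("C2PC1", c(D_SAISAIIFAI = 1, mu_prime = 1)),
               -16.88)
  expect_equal(evaluate_frozen("C2PC2", c(D_SAISAIIFAII = 0, D_ALL = 0,
                                          D_SAIIFAII = 0)), -94.98)
  # structural spot checks of the remaining terms
  expect_equal(evaluate_frozen("C1PC2", c(D_SAIIFAII = 100)),
               1.828 * 100 - 3.5e-4 * 1e4 + 1.69e-8 * 1e6)
  expect_equal(evaluate_frozen("C2PC3", c(D_SAISAIIFAII = 1, D_SAIIFAII = 2,
                                          D_SAISAIIFAI = 3)),
               4911 - 2.237 - 0.8546 + 2.151e-4 * 6)
  expect_equal(evaluate_frozen("C1PC1",
                               c(D_SAISAIIFAI = 10, D_SAIIFAII = 10,
                                 D_FAII = 10, mu_prime = 1)),
               -4136 + 5.544 - 98.20 + 466.3)
  expect_error(evaluate_frozen("C2PC1", c(mu_prime = 1)), "D_SAISAIIFAI")
  expect_error(evaluate_frozen("C2PC1", c(D_SAISAIIFAI = 0, mu_prime = 1)),
               "positive")
  expect_error(evaluate_frozen("nope", c(D_ALL = 1)))
})
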