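test_that("relative error matches the published convention", {
  expect_equal(round(relative_error(-32.347, -32.025), 2), 1.00)
  expect_equal(round(relative_error(-66.480, -56.925), 2), 14.37)
  expect_equal(relative_error(-50, -50), 0)
  expect_error(relative_error(0, 1), "undefined")
})

test_that("R2 matches brute-force sums of squares", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    obs <- rnorm(n); pred <- obs + rnorm(n, sd = 0.3)
    brute <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
    expect_equal(r_squared(obs, pred), brute, tolerance = 1e-12)
  }
  obs <- rnorm(5)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 5)), 0)
  expect_error(r_squared(rep(1, 4), rnorm(4)), "constant")
})

test_that("one-component PLS on rank-1 descriptors reproduces OLS", {
  set.seed(3)
  v <- rnorm(12)
  X <- cbind(v, 2 * v, -0.5 * v)       # rank 1
  y <- 3 + 2 * v + rnorm(12, sd = 0.2)
  fit <- pls_fit(X, y, ncomp = 1)
  ols <- lm(y ~ v)
  expect_equal(unname(fitted(fit)), unname(fitted(ols)), tolerance = 1e-9)
  expect_error(pls_fit(X, y, ncomp = 2), "rank")
})

test_that("PLS predictions are deterministic and invariant to row order", {
  set.seed(4)
  X <- matrix(rnorm(60), 12, 5)
  y <- X %*% c(1, -2, 0.5, 0, 0) + rnorm(12, sd = 0.1)
  f1 <- pls_fit(X, y, ncomp = 3)
  f2 <- pls_fit(X, y, ncomp = 3)
  expect_identical(f1$coefficients, f2$coefficients)
  perm <- sample(12)
  f3 <- pls_fit(X[perm, ], y[perm], ncomp = 3)
  expect_equal(predict(f3, X), predict(f1, X), tolerance = 1e-9)
})

test_that("duplicating a descriptor column leaves full-rank predictions unchanged", {
  set.seed(5)
  X <- matrix(rnorm(48), 12, 4)
  y <- drop(X %*% c(1, -1, 2, 0.3)) + rnorm(12, sd = 0.2)
  f_base <- pls_fit(X, y, ncomp = 4)
  f_dup <- pls_fit(cbind(X, X[, 1]), y, ncomp = 4)
  expect_equal(predict(f_dup, cbind(X, X[, 1])), predict(f_base, X),
               tolerance = 1e-8)
})

test_that("PLS agrees with an independent implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(6)
  X <- matrix(rnorm(80), 16, 5,
              dimnames = list(NULL, paste0("d", 1:5)))
  y <- drop(X %*% c(2, -1, 0.5, 0, 1)) + rnorm(16, sd = 0.3)
  mine <- pls_fit(X, y, ncomp = 3)
  theirs <- mixOmics::pls(X, y, ncomp = 3, scale = FALSE,
                          mode = "regression")
  pred <- predict(theirs, X)$predict[, 1, 3]
  expect_equal(unname(fitted(mine)), unname(pred), tolerance = 1e-6)
})

test_that("LOO Q2 equals an explicit hold-one-out OLS loop on one descriptor", {
  set.seed(7)
  v <- rnorm(6)
  y <- 1 + 0.8 * v + rnorm(6, sd = 0.4)
  X <- matrix(v, ncol = 1)
  press <- 0
  for (i in 1:6) {
    m <- lm(y[-i] ~ v[-i])
    pred_i <- coef(m)[1] + coef(m)[2] * v[i]
    press <- press + (y[i] - pred_i)^2
  }
  brute <- 1 - as.numeric(press) / sum((y - mean(y))^2)
  expect_equal(loo_q2(X, y, ncomp = 1), brute, tolerance = 1e-9)
})

test_that("Q2 approaches 1 on an exactly linear response", {
  set.seed(8)
  v <- seq(-2, 2, length.out = 10)
  X <- cbind(v, rnorm(10, sd = 0.01))
  y <- -40 - 12 * v
  expect_gte(loo_q2(X, y, ncomp = 1), 0.99)
})

test_that("Q2 is non-positive in expectation under response permutation", {
  set.seed(9)
  X <- matrix(rnorm(27), 9, 3)
  y <- rnorm(9)
  q2 <- vapply(1:20, function(i) loo_q2(X, sample(y), ncomp = 1),
               numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("Q2 never exceeds R2 on the same training data", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% rnorm(3)) + rnorm(n, sd = 0.5)
    fit <- pls_fit(X, y, ncomp = 2)
    expect_lte(loo_q2(X, y, ncomp = 2),
               r_squared(y, fitted(fit)) + 1e-12)
  }
})

test_that("determination coefficients are invariant to a response unit change", {
  set.seed(11)
  X <- matrix(rnorm(36), 12, 3)
  y <- drop(X %*% c(1, 2, -1)) + rnorm(12, sd = 0.3)
  kcal <- y * 0.239006 + 5          # kJ/mol -> shifted kcal/mol
  f1 <- pls_fit(X, y, ncomp = 2); f2 <- pls_fit(X, kcal, ncomp = 2)
  expect_equal(r_squared(kcal, fitted(f2)), r_squared(y, fitted(f1)),
               tolerance = 1e-10)
  expect_equal(loo_q2(X, kcal, ncomp = 2), loo_q2(X, y, ncomp = 2),
               tolerance = 1e-10)
})

test_that("external R2_pred variants match brute-force sums", {
  set.seed(12)
  tr_obs <- rnorm(10, -60, 8)
  te_obs <- rnorm(5, -60, 8)
  te_pred <- te_obs + rnorm(5, sd = 2)
  std <- 1 - sum((te_obs - te_pred)^2) / sum((te_obs - mean(tr_obs))^2)
  alt <- 1 - sum((te_obs - te_pred)^2) / sum((te_obs - mean(te_obs))^2)
  expect_equal(as.numeric(external_r2_pred(tr_obs, te_obs, te_pred)),
               std, tolerance = 1e-12)
  expect_equal(as.numeric(external_r2_pred(tr_obs, te_obs, te_pred,
                                           "sd_testmean")),
               alt, tolerance = 1e-12)
  expect_equal(as.numeric(external_r2_pred(tr_obs, te_obs, te_pred,
                                           "pearson2")),
               cor(te_obs, te_pred)^2, tolerance = 1e-12)
  expect_equal(as.numeric(external_r2_pred(tr_obs, te_obs, te_obs)), 1)
  expect_equal(as.numeric(external_r2_pred(tr_obs, te_obs,
                                           rep(mean(tr_obs), 5))), 0)
  expect_error(external_r2_pred(tr_obs, te_obs[1:2], te_pred[1:2]),
               "3 matched")
})

test_that("SEE and F follow the latent-component conventions", {
  set.seed(13)
  obs <- rnorm(12); pred <- obs + rnorm(12, sd = 0.4)
  nc <- 3
  sf <- see_and_f(obs, pred, nc)
  df <- 12 - nc - 1
  expect_equal(sf$SEE, sqrt(sum((obs - pred)^2) / df), tolerance = 1e-12)
  r2 <- r_squared(obs, pred)
  expect_equal(sf$F, (r2 / nc) / ((1 - r2) / df), tolerance = 1e-12)
  # doubled residuals double SEE
  pred2 <- obs - 2 * (obs - pred)
  expect_equal(see_and_f(obs, pred2, nc)$SEE, 2 * sf$SEE,
               tolerance = 1e-12)
  perfect <- see_and_f(obs, obs, nc)
  expect_equal(perfect$SEE, 0)
  expect_identical(perfect$F, Inf)
  expect_error(see_and_f(obs[1:3], pred[1:3], 3), "degrees of freedom")
})

test_that("the full validation report is internally consistent", {
  set.seed(14)
  n <- 20
  X <- matrix(rnorm(n * 4), n, 4)
  y <- drop(X %*% c(-3, 1, 0.5, 0)) + rnorm(n, sd = 0.4)
  split <- rep(c("training", "test"), c(15, 5))
  rep_ <- qsar_validation_report(X, y, split, ncomp = 2)
  expect_lte(rep_$Q2, rep_$R2)
  expect_gte(rep_$SEE, 0)
  expect_equal(rep_$N, 2)
  expect_length(rep_$R2_pred, 3)
  expect_length(rep_$relative_errors, n)
  expect_gt(rep_$R2, 0.9)
})
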