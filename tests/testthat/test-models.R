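test_that("R2 and RMSE follow their definitions", {
  y <- c(0, 1, 2)
  expect_equal(r2(y, y), 1)
  expect_equal(r2(y, rep(mean(y), 3)), 0)
  expect_equal(r2(y, c(0, 1, 3)), 0.5)
  expect_equal(rmse(y, y), 0)
  expect_equal(rmse(c(0, 2), c(1, 1)), 1)
  set.seed(5)
  a <- rnorm(40); b <- rnorm(40)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 40), tolerance = 1e-12)
  expect_error(r2(rep(1, 5), rnorm(5)), "constant")
  expect_error(rmse(numeric(), numeric()), "non-empty")
})

test_that("the calibration curve matches the normal equations", {
  x <- c(1, 2, 3, 4)
  m <- fit_curve(x, 3 * x + 1)
  expect_equal(m$a, 3); expect_equal(m$b, 1)
  set.seed(9)
  xn <- runif(30, 0, 100)
  yn <- 0.8 * xn + 5 + rnorm(30)
  mn <- fit_curve(xn, yn)
  # closed-form slope/intercept oracle
  a_hat <- sum((xn - mean(xn)) * (yn - mean(yn))) / sum((xn - mean(xn))^2)
  expect_equal(mn$a, a_hat, tolerance = 1e-10)
  expect_equal(mn$b, mean(yn) - a_hat * mean(xn), tolerance = 1e-10)
  # univariate R2 equals squared Pearson correlation
  expect_equal(r2(yn, predict(mn, xn)), cor(xn, yn)^2, tolerance = 1e-10)
  expect_error(fit_curve(rep(2, 5), rnorm(5)), "variance")
})

test_that("MLR agrees with the OLS oracle", {
  set.seed(2)
  X <- matrix(rnorm(25 * 3), 25, 3, dimnames = list(NULL, c("p", "q", "s")))
  y <- as.numeric(X %*% c(1, -1, 2) + 4 + rnorm(25, 0, 0.1))
  m <- fit_mlr(X, y)
  o <- ols_oracle(X, y)
  expect_equal(unname(m$coefficients), unname(o$coef[-1]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(o$coef[1]), tolerance = 1e-10)
  expect_error(predict(m, X[, c(2, 1, 3)]), "feature names")
})

test_that("PLSR with full components reproduces OLS predictions", {
  set.seed(4)
  X <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("w", 1:4)))
  y <- as.numeric(X %*% c(2, 1, 0, -1) + 3 + rnorm(30, 0, 0.2))
  m <- fit_plsr(X, y, ncomp = 4)
  ols_pred <- as.numeric(cbind(1, X) %*% ols_oracle(X, y)$coef)
  expect_lt(max(abs(predict(m, X) - ols_pred) / pmax(abs(ols_pred), 1)),
            1e-6)
  expect_error(fit_plsr(X, y, ncomp = 10), "ncomp")
})

test_that("PLSR matches an independent implementation at fixed components", {
  skip_if_not_installed("mixOmics")
  set.seed(14)
  X <- matrix(rnorm(25 * 8), 25, 8, dimnames = list(NULL, paste0("w", 1:8)))
  y <- as.numeric(X[, 1] * 2 - X[, 3] + rnorm(25, 0, 0.3))
  for (a in c(1, 2, 3)) {
    ours <- predict(fit_plsr(X, y, ncomp = a), X)
    mo <- mixOmics::pls(X, y, ncomp = a, mode = "regression", scale = FALSE)
    theirs <- as.numeric(predict(mo, X)$predict[, , a])
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("the LSSVM solve satisfies its KKT system", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1.5, -2, 0.5) + 3 + rnorm(n, 0, 0.3))
  m <- fit_lssvm(X, y, gamma = 10, sigma = 2)
  K <- craterspec:::.lssvm_kernel(m$Z, m$Z, m$sigma, m$kernel)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / m$gamma))
  expect_lt(max(abs(A %*% c(m$b, m$alpha) - c(0, y))), 1e-8)
  # sum of dual weights is zero (the equality constraint)
  expect_lt(abs(sum(m$alpha)), 1e-8)
})

test_that("a barely regularized linear LSSVM approaches OLS", {
  set.seed(6)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- as.numeric(X %*% c(1.5, -2, 0.5) + 3 + rnorm(n, 0, 0.3))
  m <- fit_lssvm(X, y, gamma = 1e8, kernel = "linear")
  ols_pred <- as.numeric(cbind(1, X) %*% ols_oracle(X, y)$coef)
  expect_lt(max(abs(predict(m, X) - ols_pred) / pmax(abs(ols_pred), 1e-9)),
            1e-3)
})

test_that("seeded models are exactly reproducible", {
  set.seed(31)
  X <- matrix(runif(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- as.numeric(X %*% runif(5) + rnorm(40, 0, 0.05))
  r1 <- predict(fit_rf(X, y, n_trees = 100, seed = 77), X)
  r2_ <- predict(fit_rf(X, y, n_trees = 100, seed = 77), X)
  expect_identical(r1, r2_)
  l1 <- fit_lssvm(X, y, seed = 5)
  l2 <- fit_lssvm(X, y, seed = 5)
  expect_identical(l1$alpha, l2$alpha)
  expect_identical(c(l1$gamma, l1$sigma), c(l2$gamma, l2$sigma))
})

test_that("LOD and LOQ follow the 3-sigma and 10-sigma convention", {
  # noiseless line: zero residual sd, zero detection limit
  x <- seq(10, 100, by = 10)
  y <- (x - 5) / 2
  m <- fit_curve(x, y)
  ll <- lod_loq(m)
  expect_equal(ll$lod, 0, tolerance = 1e-10)
  expect_equal(ll$loq, 0, tolerance = 1e-10)
  # noisy line: the ratio LOQ/LOD is exactly 10/3 and values match the
  # slope/residual construction
  set.seed(77)
  conc <- rep(seq(0, 70, length.out = 8), 3)
  intens <- 2 * conc + 10 + rnorm(24, 0, 1)
  mc <- fit_curve(intens, conc)
  ll2 <- lod_loq(mc)
  expect_equal(ll2$loq / ll2$lod, 10 / 3, tolerance = 1e-12)
  fit <- lm(intens ~ conc)
  expect_equal(ll2$lod, 3 * sd(residuals(fit)) / coef(fit)[[2]],
               tolerance = 1e-12)
  # concentration-space alternative keeps the ratio identity
  ll3 <- lod_loq(mc, sigma_space = "concentration")
  expect_equal(ll3$loq / ll3$lod, 10 / 3, tolerance = 1e-12)
  # a negative-slope curve has no detection limit
  mneg <- fit_curve(x, -2 * x + 300)
  expect_error(lod_loq(mneg), "slope")
})

test_that("evaluate composes the individual metrics", {
  x <- seq(1, 20)
  y <- 2 * x + 1
  m <- fit_curve(x, y)
  rep_ <- evaluate(m, cal = list(features = x, y = y),
                   pred = list(features = x + 0.0, y = y))
  expect_equal(rep_$Rc2, 1); expect_equal(rep_$Rp2, 1)
  expect_equal(rep_$RMSEC, 0); expect_equal(rep_$RMSEP, 0)
  set.seed(10)
  xp <- runif(10, 1, 20); yp <- 2 * xp + 1 + rnorm(10)
  rep2 <- evaluate(m, cal = list(features = x, y = y),
                   pred = list(features = xp, y = yp))
  expect_equal(rep2$Rp2, r2(yp, predict(m, xp)))
  expect_equal(rep2$RMSEP, rmse(yp, predict(m, xp)))
})

test_that("PCA scores expose variance structure and ordering", {
  # points exactly on a line through the centroid: one component carries all
  wl <- seq(210, 211, by = 0.1)
  t_par <- seq(-2, 2, length.out = 9)
  dir <- runif(length(wl))
  X <- 5 + outer(t_par, dir)
  ss <- spectrum_set(X, wl, sprintf("s%d", 1:9))
  out <- pca_scores(ss, 2)
  expect_equal(out$explained[1], 1, tolerance = 1e-10)
  expect_true(all(diff(out$explained) <= 1e-12))
  expect_lte(sum(out$explained), 1 + 1e-12)
  expect_error(pca_scores(ss, 50), "min")
})

test_that("benchmark PCA clusters by brand more than by spike level", {
  ds <- generate_dataset(benchmark_config(seed = 3))
  sc <- pca_scores(ds$spectra, 3)$scores
  d <- dist(sc)
  sil <- function(lab) mean(cluster::silhouette(as.integer(factor(lab)),
                                                d)[, 3])
  expect_gt(sil(ds$brand), sil(ds$level))
})
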