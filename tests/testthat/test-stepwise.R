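test_that("stepwise keeps the true predictor and drops independent noise", {
  set.seed(42)
  n <- 30
  x1 <- runif(n, 0, 10)
  x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n, 0, 0.5)
  sw <- stepwise_backward(cbind(x1 = x1, x2 = x2), y)
  expect_identical(sw$retained, "x1")
  expect_identical(sw$elimination_order$variable, "x2")
  # the recorded p-values equal the textbook OLS t-test p-values
  oracle_full <- ols_oracle(cbind(x1 = x1, x2 = x2), y)
  expect_equal(unname(sw$p_table[, 1]),
               unname(oracle_full$p[c("x1", "x2")]), tolerance = 1e-10)
  oracle_red <- ols_oracle(cbind(x1 = x1), y)
  expect_equal(unname(sw$p_table["x1", 2]), unname(oracle_red$p["x1"]),
               tolerance = 1e-10)
  expect_equal(unname(sw$final_model$coefficients["x1"]),
               unname(oracle_red$coef["x1"]), tolerance = 1e-10)
})

test_that("a single perfectly correlated feature is retained with p near zero", {
  x <- 1:20
  y <- 3 * x + rnorm(20, 0, 1e-8)
  sw <- stepwise_backward(cbind(only = x), y)
  expect_identical(sw$retained, "only")
  expect_lt(sw$final_model$p_values[["only"]], 1e-12)
})

test_that("p-value trajectories match the OLS oracle across random problems", {
  set.seed(8)
  for (case in 1:5) {
    n <- 25; k <- 4
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("v", 1:k)))
    y <- as.numeric(X %*% c(1, 0, 0.5, 0) + rnorm(n))
    sw <- stepwise_backward(X, y)
    # replay the elimination path with the oracle
    current <- colnames(X)
    it <- 0L
    repeat {
      it <- it + 1L
      pv <- ols_oracle(X[, current, drop = FALSE], y)$p[current]
      expect_equal(unname(sw$p_table[current, it]), unname(pv),
                   tolerance = 1e-10)
      if (max(pv) <= sw$alpha || length(current) == 1L) break
      current <- current[-which.max(pv)]
    }
    # determinism: bit-for-bit reproducible trajectory
    sw2 <- stepwise_backward(X, y)
    expect_identical(sw$p_table, sw2$p_table)
  }
})

test_that("residual sum of squares never improves when a variable is dropped", {
  set.seed(15)
  n <- 40
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- as.numeric(X[, 1] * 2 + rnorm(n))
  sw <- stepwise_backward(X, y)
  dropped <- sw$elimination_order$variable
  current <- colnames(X)
  rss <- function(v) {
    fit <- lm(y ~ ., data = data.frame(X[, v, drop = FALSE], y = y))
    sum(residuals(fit)^2)
  }
  for (d in dropped) {
    before <- rss(current)
    current <- setdiff(current, d)
    expect_gte(rss(current), before - 1e-10)
  }
})

test_that("collinear features raise a named error", {
  set.seed(3)
  x <- rnorm(20)
  X <- cbind(a = x, b = 2 * x, c = rnorm(20))
  expect_error(stepwise_backward(X, rnorm(20)), "rank deficiency")
  expect_error(stepwise_backward(X[1:3, ], rnorm(3)), "n > k")
})

test_that("crater summaries compute min/max/mean/RSD per parameter", {
  ds <- generate_dataset(benchmark_config(seed = 6, replicates = 1))
  cr <- ds$craters
  # two identical craters: zero dispersion
  twin <- rbind(cr[1, ], cr[1, ])
  twin$sample_id <- c("a", "b")
  s0 <- summarize_craters(twin)
  expect_equal(s0$rsd_pct, rep(0, 9))
  # forced two-point case: mean 2, sd sqrt(2) -> RSD 70.71%
  two <- twin
  two$volume <- c(1, 3)
  sv <- summarize_craters(two)
  expect_equal(sv$rsd_pct[sv$parameter == "volume"], 100 * sqrt(2) / 2,
               tolerance = 1e-12)
  expect_error(summarize_craters(cr[1, , drop = FALSE]), "at least 2")
})

test_that("generated crater dispersions sit in the strong-matrix-effect regime", {
  ds <- generate_dataset(benchmark_config(seed = 12))
  s <- summarize_craters(ds$craters)
  vol_rsd <- s$rsd_pct[s$parameter == "volume"]
  expect_gt(vol_rsd, 20)         # "RSD beyond 20%" regime
  expect_lt(vol_rsd, 120)
  expect_true(all(s$rsd_pct > 10))
  expect_true(all(s$mean > 0))
})
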