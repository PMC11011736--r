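# Fixtures are generated in code; nothing is read from disk.

# a small spectrum set with Gaussian peaks on a flat background
tiny_spectra <- function(n = 4, wl = seq(225, 231, by = 0.02),
                         peak_nm = 228.80, heights = NULL, background = 10,
                         scale = rep(1, n)) {
  if (is.null(heights)) heights <- seq_len(n) * 5
  X <- t(vapply(seq_len(n), function(i)
    scale[i] * (background + heights[i] * dnorm(wl, peak_nm, 0.05) * 0.05 *
                  sqrt(2 * pi)),
    numeric(length(wl))))
  spectrum_set(X, wl, sprintf("S%d", seq_len(n)))
}

# the standard synthetic benchmark conditions (six brands with factors drawn
# from U[0.5, 1.5], ten levels 0-70 ug/g, four replicates, 2% noise)
benchmark_config <- function(seed, ...) synthetic_config(seed = seed, ...)

# feature-level simulation for stepwise recovery: three emission lines and
# three crater parameters (volume + both depths) carry signal, the six
# remaining crater parameters are pure noise
stepwise_sim_run <- function(n = 40) {
  pars <- crater_parameters()
  signal_cr <- c("volume", "average_depth", "maximum_depth")
  lines_nm <- c("Cd_II_214.44", "Cd_II_226.50", "Cd_I_228.80")
  F <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, c(pars, lines_nm)))
  beta <- setNames(rep(0, 12), colnames(F))
  beta[signal_cr] <- c(2, 1.5, 1.2)
  beta[lines_nm] <- c(3, 2.5, 4)
  y <- as.numeric(F %*% beta + rnorm(n))
  list(features = F, y = y, signal = c(signal_cr, lines_nm),
       noise = setdiff(pars, signal_cr))
}

# textbook OLS with coefficient t-tests from the normal equations; the
# independent oracle for stepwise_backward and fit_mlr
ols_oracle <- function(X, y) {
  X <- as.matrix(X)
  A <- cbind(`(Intercept)` = 1, X)
  XtX_inv <- solve(crossprod(A))
  beta <- XtX_inv %*% crossprod(A, y)
  res <- y - A %*% beta
  df <- nrow(A) - ncol(A)
  s2 <- sum(res^2) / df
  se <- sqrt(diag(XtX_inv) * s2)
  tval <- beta / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  list(coef = drop(beta), se = se, t = drop(tval), p = drop(pval))
}

# naive Pearson correlation, written out elementwise
pearson_oracle <- function(b, y) {
  num <- sum((b - mean(b)) * (y - mean(y)))
  den <- sqrt(sum((b - mean(b))^2) * sum((y - mean(y))^2))
  num / den
}

rmsep_ladder <- function(ds, seed) {
  specs <- list(
    fusion_spec(cd_lines()["Cd_I_228.80"], NULL, "none", "curve",
                label = "raw"),
    fusion_spec(cd_lines()["Cd_I_228.80"], "stepwise", "none", "mlr",
                label = "crater_mlr"),
    fusion_spec(cd_lines()["Cd_I_228.80"], NULL, "cprc", "curve",
                label = "cprc"),
    fusion_spec(cd_lines(), "stepwise", "cprc", "lssvm",
                label = "fused_lssvm"))
  r <- run_grid(ds, specs, seed = seed)$report
  setNames(r$RMSEP, r$Variables)
}
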