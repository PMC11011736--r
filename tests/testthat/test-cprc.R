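# direct check of the ratio-correlation, on ratios injected via a crafted
# spectrum set: the peak bin carries x_N, one background bin carries z so
# that B = x_N / z takes the prescribed values
make_ratio_fixture <- function(B, y, z_bin_value = NULL) {
  wl <- seq(228, 231, by = 0.5)
  n <- length(B)
  X <- matrix(1, n, length(wl))
  X[, 2] <- 10                      # peak bin (228.5): x_N = 10
  X[, 5] <- 10 / B                  # bin at 230.0: z = x_N / B
  ss <- spectrum_set(X, wl, sprintf("S%d", seq_len(n)))
  refs <- reference_values(y, ss$sample_ids)
  list(ss = ss, refs = refs,
       peak = emission_line("Cd", "I", 228.5), bin = 5L)
}

test_that("ratio candidates reproduce the Pearson correlation of B with y", {
  fx <- make_ratio_fixture(c(1, 2, 3), c(10, 20, 30))
  cand <- ratio_candidates(fx$ss, fx$refs, fx$peak, peak_window_nm = 0.1)
  expect_equal(cand$r[fx$bin], 1)
  fx2 <- make_ratio_fixture(c(1, 2, 3), c(30, 20, 10))
  cand2 <- ratio_candidates(fx2$ss, fx2$refs, fx2$peak, peak_window_nm = 0.1)
  expect_equal(cand2$r[fx2$bin], -1)
  fx3 <- make_ratio_fixture(c(1, 2, 4), c(1, 2, 3))
  cand3 <- ratio_candidates(fx3$ss, fx3$refs, fx3$peak, peak_window_nm = 0.1)
  expect_equal(cand3$r[fx3$bin], 3 / sqrt(28 / 3), tolerance = 1e-12)
  # constant-B bins are invalid; the peak's own window is invalid
  expect_false(cand$valid[2])      # the peak's own window
  expect_false(cand$valid[1])      # B constant across samples there
  expect_error(
    ratio_candidates(fx$ss, reference_values(rep(2, 3), fx$ss$sample_ids),
                     fx$peak),
    "constant")
})

test_that("r-values agree with a brute-force Pearson implementation", {
  set.seed(7)
  wl <- seq(210, 212, by = 0.02)
  n <- 12
  X <- matrix(runif(n * length(wl), 1, 100), n, length(wl))
  ss <- spectrum_set(X, wl, sprintf("S%d", 1:n))
  y <- runif(n, 0, 70)
  refs <- reference_values(y, ss$sample_ids)
  peak <- emission_line("Cd", "II", 211.00)
  cand <- ratio_candidates(ss, refs, peak, peak_window_nm = 0.1)
  xN <- extract_peak(ss, peak, 0.1)$intensity
  for (j in which(cand$valid)) {
    expect_equal(cand$r[j], pearson_oracle(xN / X[, j], y),
                 tolerance = 1e-12)
  }
})

test_that("a noiseless background bin proportional to the matrix factor is found with m = 1", {
  # construct spectra where exactly one bin equals the per-sample factor and
  # the peak is factor * concentration: dividing by that bin is an exact
  # correction, so the CV-RMSE path must attain its minimum at m = 1
  set.seed(21)
  wl <- seq(228, 231, by = 0.02)
  n <- 30
  conc <- rep(seq(5, 70, length.out = 10), 3)
  fac <- runif(n, 0.5, 1.5)
  X <- matrix(runif(n * length(wl), 40, 60), n, length(wl)) # irrelevant noise
  peak_bin <- which(abs(wl - 228.80) < 1e-9)
  magic_bin <- which(abs(wl - 230.50) < 1e-9)
  X[, peak_bin] <- 100 * conc * fac
  # make the peak a window maximum
  X[, peak_bin + c(-1, 1)] <- 0.5 * X[, peak_bin]
  X[, magic_bin] <- 50 * fac
  ss <- spectrum_set(X, wl, sprintf("S%d", 1:n))
  refs <- reference_values(conc, ss$sample_ids)
  model <- fit_cprc(ss, refs, emission_line("Cd", "I", 228.80),
                    folds = 5, seed = 3)
  expect_identical(model$selected$bin[1], magic_bin)
  expect_identical(model$m, 1L)
  expect_identical(which.min(model$cv_rmse_path), 1L)
})

test_that("forcing max_m = 1 keeps only the top-ranked candidate", {
  ds <- generate_dataset(benchmark_config(seed = 5, replicates = 1))
  model <- fit_cprc(ds$spectra, ds$references, cd_lines()[["Cd_I_228.80"]],
                    max_m = 1, folds = 5, seed = 1)
  expect_identical(model$m, 1L)
  expect_identical(nrow(model$selected), 1L)
})

test_that("CPRC application matches the closed-form division", {
  wl <- c(228.0, 228.5)
  ss <- spectrum_set(matrix(c(2, 4), 1, 2), wl, "s1")
  model <- structure(list(
    peak = emission_line("Cd", "I", 228.0), peak_window_nm = 0.1,
    selected = data.frame(wavelength_nm = 228.5, bin = 2L, r = 1),
    m = 1L, cv_rmse_path = 0, folds = 2L, ncomp = 1L, seed = 1L),
    class = "cprc_model")
  out <- apply_cprc(model, ss)
  expect_equal(out$X[1, ], c(0.5, 1.0))
  # selected intensities all equal to 1 -> identity
  ss1 <- spectrum_set(matrix(c(3, 1), 1, 2), wl, "s1")
  expect_equal(apply_cprc(model, ss1)$X, ss1$X)
  # a spectrum that is 2x another corrects to the same thing
  ss2 <- spectrum_set(rbind(c(2, 4), c(4, 8)), wl, c("a", "b"))
  out2 <- apply_cprc(model, ss2)
  expect_equal(out2$X[1, ], out2$X[2, ])
  # non-positive divisor is a hard error naming the sample
  ss3 <- spectrum_set(rbind(c(2, 0)), wl, "badone")
  expect_error(apply_cprc(model, ss3), "badone")
})

test_that("CPRC is exactly invariant to per-sample multiplicative factors", {
  set.seed(99)
  ds <- generate_dataset(benchmark_config(seed = 99, replicates = 1))
  model <- fit_cprc(ds$spectra, ds$references, cd_lines()[["Cd_I_228.80"]],
                    folds = 5, seed = 1)
  n <- 100
  wl <- ds$spectra$wavelengths
  for (rep in 1:4) {
    X <- matrix(runif(n * length(wl), 1, 1000), n, length(wl))
    ss <- spectrum_set(X, wl, sprintf("R%d", 1:n))
    c_fac <- runif(n, 0.1, 10)
    ss_scaled <- spectrum_set(X * c_fac, wl, ss$sample_ids)
    expect_lt(max(abs(apply_cprc(model, ss_scaled)$X -
                        apply_cprc(model, ss)$X)), 1e-10)
  }
})

test_that("corrected intensities average to one over the selected bins", {
  ds <- generate_dataset(benchmark_config(seed = 2, replicates = 1))
  model <- fit_cprc(ds$spectra, ds$references, cd_lines()[["Cd_I_228.80"]],
                    folds = 5, seed = 1)
  corr <- apply_cprc(model, ds$spectra)
  means <- rowMeans(corr$X[, model$selected$bin, drop = FALSE])
  expect_equal(means, rep(1, n_samples(ds)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are rejected", {
  wl <- seq(228, 229, by = 0.1)
  ss <- spectrum_set(matrix(runif(2 * length(wl)), 2), wl, c("a", "b"))
  refs <- reference_values(c(1, 2), c("a", "b"))
  expect_error(ratio_candidates(ss, refs, emission_line("Cd", "I", 228.5)),
               "n >= 3")
  cand <- data.frame(bin = 1L, wavelength_nm = 228, r = NA_real_,
                     valid = FALSE)
  ss3 <- spectrum_set(matrix(runif(3 * length(wl)), 3), wl, c("a", "b", "c"))
  refs3 <- reference_values(1:3, c("a", "b", "c"))
  expect_error(select_matrix_variables(cand, ss3, refs3,
                                       emission_line("Cd", "I", 228.5)),
               "no valid")
  expect_error(fit_cprc(ss3, refs3, emission_line("Cd", "I", 228.5),
                        folds = 10), "folds exceed")
})

test_that("CPRC models serialize to JSON and back", {
  ds <- generate_dataset(benchmark_config(seed = 4, replicates = 1))
  model <- fit_cprc(ds$spectra, ds$references, cd_lines()[["Cd_I_228.80"]],
                    folds = 5, seed = 8)
  path <- tempfile(fileext = ".json")
  write_cprc_model(model, path)
  back <- read_cprc_model(path)
  expect_equal(back$selected$wavelength_nm, model$selected$wavelength_nm)
  expect_equal(back$cv_rmse_path, model$cv_rmse_path)
  expect_identical(back$m, model$m)
  expect_equal(apply_cprc(back, ds$spectra)$X,
               apply_cprc(model, ds$spectra)$X)
})
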