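#' Ratio candidates for characteristic peak ratio correction
#'
#' For the chosen characteristic peak, computes per wavelength bin j the
#' ratio B_j = x_N / z_j (characteristic-peak intensity over the intensity at
#' bin j, per sample) and its Pearson correlation r_j with the reference
#' concentrations. Bins where any sample has z_j = 0, where B_j has zero
#' variance, or that lie inside the peak's own extraction window are flagged
#' invalid and can never be selected as matrix variables.
#'
#' @param ss Calibration [spectrum_set].
#' @param refs [reference_values] aligned to `ss`.
#' @param peak The characteristic [emission_line] (e.g. Cd I 228.80 nm).
#' @param peak_window_nm Half-width for peak extraction and for the excluded
#'   self-window. Default 0.1.
#' @return data.frame with columns `bin`, `wavelength_nm`, `r`, `valid`.
#' @export
ratio_candidates <- function(ss, refs, peak, peak_window_nm = 0.1) {
  stopifnot(inherits(ss, "spectrum_set"), inherits(refs, "reference_values"))
  if (!identical(ss$sample_ids, refs$sample_ids))
    stop("sample_id mismatch between spectra and references")
  y <- refs$values
  n <- length(y)
  if (n < 3L) stop("ratio candidates need n >= 3 samples")
  if (stats::var(y) == 0)
    stop("reference values are constant; correlation undefined")
  xN <- extract_peak(ss, peak, peak_window_nm)$intensity
  wl <- ss$wavelengths
  p <- length(wl)
  B <- xN / ss$X                      # n x p, column j = x_N / z_j
  zero_z <- apply(ss$X == 0, 2L, any)
  in_peak <- abs(wl - peak$wavelength) <= peak_window_nm
  # column sds of B; zero-variance columns carry no correlation information
  sdB <- apply(B, 2L, stats::sd)
  valid <- !zero_z & !in_peak & is.finite(sdB) & sdB > 0
  r <- rep(NA_real_, p)
  if (any(valid))
    r[valid] <- as.numeric(stats::cor(B[, valid, drop = FALSE], y))
  data.frame(bin = seq_len(p), wavelength_nm = wl, r = r, valid = valid)
}

#' Select matrix-related variables and fit a CPRC model
#'
#' Candidates are ranked by signed r descending (ties: lower wavelength).
#' For every prefix of the ranking up to `max_m` variables, the full spectrum
#' is corrected by dividing each sample by the mean intensity of the prefix
#' bins, a PLSR model on the corrected spectrum is cross-validated against
#' the references, and the prefix minimizing CV-RMSE is retained (ties:
#' smaller m). Fold assignment is shuffled once from `seed` and shared across
#' prefixes.
#'
#' @param candidates Output of [ratio_candidates()].
#' @param ss Calibration [spectrum_set].
#' @param refs [reference_values].
#' @param peak Characteristic [emission_line].
#' @param max_m Maximum number of matrix variables (default 10).
#' @param folds Cross-validation folds for m selection (default 10).
#' @param ncomp PLSR components inside the CV (default 5, capped at rank).
#' @param seed Integer seed for the CV shuffle, recorded in the model.
#' @param peak_window_nm Half-width for peak extraction. Default 0.1.
#' @return Object of class `cprc_model` with fields `peak`,
#'   `peak_window_nm`, `selected` (data.frame wavelength_nm/bin/r for the m
#'   retained variables), `ranking` (full candidate ranking used), `m`,
#'   `cv_rmse_path`, `folds`, `ncomp`, `seed`.
#' @export
select_matrix_variables <- function(candidates, ss, refs, peak,
                                    max_m = 10L, folds = 10L, ncomp = 5L,
                                    seed = 1L, peak_window_nm = 0.1) {
  cand <- candidates[candidates$valid & is.finite(candidates$r), , drop = FALSE]
  if (!nrow(cand)) stop("no valid ratio candidates to select from")
  y <- refs$values
  n <- length(y)
  if (folds > n) stop("cross-validation folds exceed the number of samples")
  ord <- order(-cand$r, cand$wavelength_nm)
  cand <- cand[ord, , drop = FALSE]
  m_max <- min(max_m, nrow(cand))
  fold_id <- .cv_folds(n, folds, seed)
  path <- rep(NA_real_, m_max)
  for (m in seq_len(m_max)) {
    bins <- cand$bin[seq_len(m)]
    Zbar <- rowMeans(ss$X[, bins, drop = FALSE])
    if (any(Zbar <= 0)) { path[m] <- Inf; next }
    Xc <- ss$X / Zbar
    path[m] <- .cv_rmse_pls(Xc, y, ncomp, fold_id)
  }
  if (all(!is.finite(path)))
    stop("every candidate prefix produced a non-positive divisor")
  m <- which.min(path)               # first minimum -> smallest m on ties
  structure(list(
    peak = peak, peak_window_nm = peak_window_nm,
    selected = cand[seq_len(m), c("wavelength_nm", "bin", "r")],
    ranking = cand[seq_len(m_max), c("wavelength_nm", "bin", "r")],
    m = m, cv_rmse_path = path,
    folds = folds, ncomp = ncomp, seed = seed),
    class = "cprc_model")
}

#' Fit a CPRC correction on a calibration set
#'
#' Composite of [ratio_candidates()] and [select_matrix_variables()]: ranks
#' every wavelength bin by the correlation of the peak/bin intensity ratio
#' with the reference concentrations and keeps the prefix (at most `max_m`
#' variables) whose full-spectrum correction minimizes the cross-validated
#' PLSR RMSE. The fitted model is reusable on any spectrum set sharing the
#' same wavelength axis.
#'
#' @inheritParams select_matrix_variables
#' @return A `cprc_model` (see [select_matrix_variables()]).
#' @export
fit_cprc <- function(ss, refs, peak, max_m = 10L, folds = 10L, ncomp = 5L,
                     seed = 1L, peak_window_nm = 0.1) {
  cand <- ratio_candidates(ss, refs, peak, peak_window_nm)
  select_matrix_variables(cand, ss, refs, peak, max_m = max_m, folds = folds,
                          ncomp = ncomp, seed = seed,
                          peak_window_nm = peak_window_nm)
}

#' @export
print.cprc_model <- function(x, ...) {
  cat(sprintf("CPRC model for %s: m = %d matrix variables\n",
              format(x$peak), x$m))
  cat("  selected (nm):",
      paste(sprintf("%.2f", x$selected$wavelength_nm), collapse = "; "), "\n")
  cat(sprintf("  CV-RMSE at m: %.4f (path over 1..%d)\n",
              x$cv_rmse_path[x$m], length(x$cv_rmse_path)))
  invisible(x)
}

#' Apply a fitted CPRC model to a spectrum set
#'
#' Per sample, the mean intensity over the model's m matrix-variable bins is
#' computed and the whole spectrum is divided by it. Any per-sample constant
#' multiplier therefore cancels exactly, which is the mechanism by which CPRC
#' removes multiplicative matrix and shot effects.
#'
#' @param model A `cprc_model`.
#' @param ss A [spectrum_set] on the same wavelength axis as the fit.
#' @return The corrected [spectrum_set] (dimensionless intensities).
#' @export
apply_cprc <- function(model, ss) {
  stopifnot(inherits(model, "cprc_model"), inherits(ss, "spectrum_set"))
  bins <- match_wavelengths(model$selected$wavelength_nm, ss$wavelengths)
  Zbar <- rowMeans(ss$X[, bins, drop = FALSE])
  bad <- which(Zbar <= 0)
  if (length(bad))
    stop("non-positive matrix-variable mean for sample(s): ",
         paste(ss$sample_ids[bad], collapse = ", "))
  spectrum_set(ss$X / Zbar, ss$wavelengths, ss$sample_ids)
}

#' Match nominal wavelengths onto an axis
#'
#' @param wl Wavelengths to locate (nm).
#' @param axis Ascending axis (nm).
#' @param tol Matching tolerance in nm (default 1e-6).
#' @return Integer bin indices; errors if any wavelength is absent.
#' @export
match_wavelengths <- function(wl, axis, tol = 1e-6) {
  idx <- vapply(wl, function(w) {
    i <- which.min(abs(axis - w))
    if (abs(axis[i] - w) > tol)
      stop(sprintf("wavelength %.4f nm not on the axis", w))
    i
  }, 0L)
  idx
}

#' Extract the CPRC-corrected characteristic peak
#'
#' @param model A `cprc_model`.
#' @param ss A [spectrum_set].
#' @return data.frame as in [extract_peak()], computed on the corrected
#'   spectra at the model's own peak and window.
#' @export
corrected_peak <- function(model, ss) {
  extract_peak(apply_cprc(model, ss), model$peak, model$peak_window_nm)
}

#' Serialize a CPRC model to JSON
#' @param model A `cprc_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cprc_model <- function(model, path) {
  obj <- list(
    peak = list(element = model$peak$element, stage = model$peak$stage,
                wavelength = model$peak$wavelength),
    peak_window_nm = model$peak_window_nm,
    selected = model$selected, m = model$m,
    cv_rmse_path = model$cv_rmse_path,
    folds = model$folds, ncomp = model$ncomp, seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read a CPRC model from JSON
#' @param path JSON path written by [write_cprc_model()].
#' @return A `cprc_model`.
#' @export
read_cprc_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    peak = emission_line(o$peak$element, o$peak$stage, o$peak$wavelength),
    peak_window_nm = o$peak_window_nm,
    selected = as.data.frame(o$selected),
    ranking = NULL,
    m = o$m, cv_rmse_path = o$cv_rmse_path,
    folds = o$folds, ncomp = o$ncomp, seed = o$seed),
    class = "cprc_model")
}
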