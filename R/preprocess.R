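#' Asymmetric least squares (AsLS) baseline estimation
#'
#' Whittaker-smoother baseline with asymmetric weights: the baseline b
#' minimizes sum(w * (x - b)^2) + smoothness * sum(diff(b, 2)^2), where points
#' above the running baseline receive weight `asymmetry` and points below
#' receive `1 - asymmetry`. Weights are re-estimated until they stop changing
#' or `max_iter` is reached. Emission peaks (far above baseline) are thereby
#' almost ignored while the slowly varying continuum is tracked.
#'
#' @param intensities Numeric intensity vector (one spectrum), length >= 3.
#' @param smoothness Positive penalty on the second difference of the
#'   baseline (larger = stiffer baseline). Default 1e5.
#' @param asymmetry Weight for points above the baseline, in (0, 1).
#'   Default 0.01.
#' @param max_iter Maximum reweighting iterations. Default 20.
#' @return List with numeric vectors `baseline` and `corrected`;
#'   `corrected + baseline` equals the input exactly.
#' @export
baseline_asls <- function(intensities, smoothness = 1e5, asymmetry = 0.01,
                          max_iter = 20L) {
  x <- as.numeric(intensities)
  p <- length(x)
  if (p < 3L) stop("baseline_asls needs at least 3 points")
  if (any(!is.finite(x))) stop("non-finite intensities")
  stopifnot(smoothness > 0, asymmetry > 0, asymmetry < 1, max_iter >= 1)
  D <- Matrix::bandSparse(p - 2L, p,
                          k = 0:2,
                          diagonals = list(rep(1, p - 2L), rep(-2, p - 2L),
                                           rep(1, p - 2L)))
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, p)
  z <- x
  for (it in seq_len(max_iter)) {
    W <- Matrix::Diagonal(p, w)
    z <- as.numeric(Matrix::solve(W + P, w * x))
    w_new <- ifelse(x > z, asymmetry, 1 - asymmetry)
    if (identical(w_new, w)) break
    w <- w_new
  }
  list(baseline = z, corrected = x - z)
}

#' Apply AsLS baseline correction to every spectrum in a set
#'
#' @param ss A [spectrum_set].
#' @inheritParams baseline_asls
#' @return A [spectrum_set] of baseline-corrected spectra.
#' @export
baseline_correct_set <- function(ss, smoothness = 1e5, asymmetry = 0.01,
                                 max_iter = 20L) {
  stopifnot(inherits(ss, "spectrum_set"))
  Xc <- t(apply(ss$X, 1L, function(row)
    baseline_asls(row, smoothness, asymmetry, max_iter)$corrected))
  spectrum_set(Xc, ss$wavelengths, ss$sample_ids)
}

#' Total-area normalization
#'
#' Rescales a spectrum so its intensities sum to 1, removing global
#' multiplicative throughput differences between shots. Invariant under
#' positive rescaling of the input.
#'
#' @param intensities Numeric intensity vector with positive total.
#' @return Numeric vector summing to 1.
#' @export
total_area_normalize <- function(intensities) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("non-finite intensities")
  s <- sum(x)
  if (!(s > 0)) stop("total area must be positive for normalization")
  x / s
}

#' Apply total-area normalization to every spectrum in a set
#' @param ss A [spectrum_set].
#' @return A normalized [spectrum_set]; every row sums to 1.
#' @export
area_normalize_set <- function(ss) {
  stopifnot(inherits(ss, "spectrum_set"))
  spectrum_set(t(apply(ss$X, 1L, total_area_normalize)),
               ss$wavelengths, ss$sample_ids)
}

#' Extract characteristic peak intensities at an emission line
#'
#' For every sample, returns the maximum intensity within +/- `window_nm` of
#' the line's nominal wavelength, together with the winning bin. Ties are
#' broken toward the bin nearest the nominal wavelength, then the lower
#' wavelength. With `window_nm = 0` the intensity at the single bin closest
#' to the nominal wavelength is returned.
#'
#' @param ss A [spectrum_set].
#' @param line An [emission_line] within the axis.
#' @param window_nm Half-width of the search window in nm. Default 0.1.
#' @return data.frame with columns `sample_id`, `bin`, `wavelength_nm`,
#'   `intensity`.
#' @export
extract_peak <- function(ss, line, window_nm = 0.1) {
  stopifnot(inherits(ss, "spectrum_set"), inherits(line, "emission_line"),
            window_nm >= 0)
  wl <- ss$wavelengths
  lo <- line$wavelength - window_nm
  hi <- line$wavelength + window_nm
  if (line$wavelength < wl[1L] || line$wavelength > wl[length(wl)])
    stop(format(line), " is outside the wavelength axis")
  idx <- which(wl >= lo & wl <= hi)
  if (!length(idx)) idx <- which.min(abs(wl - line$wavelength))
  # tie-break ordering: nearest to nominal first, lower wavelength on equal
  # distance; which.max then returns the preferred bin among equal maxima
  ord <- idx[order(abs(wl[idx] - line$wavelength), wl[idx])]
  sub <- ss$X[, ord, drop = FALSE]
  win <- apply(sub, 1L, which.max)
  bins <- ord[win]
  data.frame(sample_id = ss$sample_ids,
             bin = bins,
             wavelength_nm = wl[bins],
             intensity = ss$X[cbind(seq_len(nrow(ss$X)), bins)],
             stringsAsFactors = FALSE)
}

#' Extract a named intensity matrix for several emission lines
#'
#' @param ss A [spectrum_set].
#' @param lines List of [emission_line]s (named; names become columns).
#' @param window_nm Half-width per line, recycled.
#' @return n x length(lines) matrix of peak intensities, rownames =
#'   sample_ids.
#' @export
extract_lines <- function(ss, lines, window_nm = 0.1) {
  if (inherits(lines, "emission_line")) lines <- list(lines)
  window_nm <- rep_len(window_nm, length(lines))
  cols <- lapply(seq_along(lines), function(i)
    extract_peak(ss, lines[[i]], window_nm[i])$intensity)
  M <- do.call(cbind, cols)
  nm <- names(lines)
  if (is.null(nm))
    nm <- vapply(lines, function(l)
      sprintf("%s_%s_%.2f", l$element, l$stage, l$wavelength), "")
  dimnames(M) <- list(ss$sample_ids, nm)
  M
}
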