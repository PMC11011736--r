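#' Backward stepwise multiple linear regression
#'
#' Starts from an ordinary least squares fit of the references on all k
#' features (crater morphology parameters in um-based units and emission-line
#' intensities in counts, unstandardized: coefficient t-tests are
#' scale-invariant). At each iteration the two-sided coefficient t-test
#' p-value (t = b/SE, df = n - k_current - 1) is computed for every surviving
#' feature; the single feature with the highest p-value above `alpha` is
#' removed and the model refit, until all p-values are at or below `alpha` or
#' one feature remains. The full p-value trajectory is recorded, so
#' non-monotone paths (a variable significant early, insignificant mid-path,
#' significant again at the end) are visible rather than corrected.
#'
#' @param features n x k numeric matrix or data.frame with column names.
#' @param refs [reference_values] or numeric vector of length n.
#' @param alpha Significance level for retention. Default 0.05.
#' @return Object of class `stepwise_result` with fields `retained` (names,
#'   in original column order), `elimination_order` (data.frame variable /
#'   iteration / p_value), `p_table` (k x iterations matrix of p-values, NA
#'   once eliminated), `final_model` (list coefficients / intercept /
#'   p_values / sigma), `alpha`.
#' @export
stepwise_backward <- function(features, refs, alpha = 0.05) {
  y <- if (inherits(refs, "reference_values")) refs$values else as.numeric(refs)
  Xf <- as.data.frame(features)
  if (is.null(names(Xf)) || any(!nzchar(names(Xf))))
    stop("features must have column names")
  k <- ncol(Xf); n <- nrow(Xf)
  if (length(y) != n) stop("features and references are misaligned")
  if (n <= k + 1L)
    stop("backward stepwise needs n > k + 1 (", n, " <= ", k + 1L, ")")
  vars <- names(Xf)
  p_table <- matrix(NA_real_, k, 0L, dimnames = list(vars, NULL))
  elim <- data.frame(variable = character(), iteration = integer(),
                     p_value = numeric(), stringsAsFactors = FALSE)
  current <- vars
  it <- 0L
  repeat {
    it <- it + 1L
    fit <- stats::lm(y ~ ., data = cbind(Xf[current], y = y))
    cf <- stats::coef(fit)
    if (anyNA(cf))
      stop("rank deficiency among features: ",
           paste(names(cf)[is.na(cf)], collapse = ", "))
    sm <- summary(fit)$coefficients
    pv <- sm[match(current, rownames(sm)), 4L]
    names(pv) <- current
    col <- rep(NA_real_, k); names(col) <- vars
    col[current] <- pv
    p_table <- cbind(p_table, col)
    worst <- which.max(pv)
    if (pv[worst] <= alpha || length(current) == 1L) {
      final <- list(coefficients = cf[current],
                    intercept = unname(cf["(Intercept)"]),
                    p_values = pv,
                    sigma = summary(fit)$sigma)
      break
    }
    elim <- rbind(elim, data.frame(variable = current[worst],
                                   iteration = it,
                                   p_value = unname(pv[worst]),
                                   stringsAsFactors = FALSE))
    current <- current[-worst]
  }
  colnames(p_table) <- seq_len(ncol(p_table))
  structure(list(retained = vars[vars %in% current],
                 elimination_order = elim,
                 p_table = p_table,
                 final_model = final,
                 alpha = alpha),
            class = "stepwise_result")
}

#' @export
print.stepwise_result <- function(x, ...) {
  cat("Backward stepwise MLR (alpha =", x$alpha, ")\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$elimination_order))
    cat("  eliminated:",
        paste(sprintf("%s (it %d, p=%.4f)", x$elimination_order$variable,
                      x$elimination_order$iteration,
                      x$elimination_order$p_value), collapse = "; "), "\n")
  invisible(x)
}

#' Summarize crater morphology parameters
#'
#' Min, max, mean and relative standard deviation (RSD, percent of the mean,
#' sample sd) for each of the nine crater parameters — the dispersion table
#' used to judge how strongly the sample matrix modulates laser ablation.
#'
#' @param craters Crater table (see [validate_craters()]); >= 2 rows.
#' @return data.frame with columns `parameter`, `min`, `max`, `mean`,
#'   `rsd_pct`.
#' @export
summarize_craters <- function(craters) {
  craters <- validate_craters(craters)
  if (nrow(craters) < 2L) stop("crater summary needs at least 2 craters")
  pars <- crater_parameters()
  out <- lapply(pars, function(p) {
    v <- craters[[p]]
    m <- mean(v)
    if (m == 0) stop("zero mean for ", p, "; RSD undefined")
    data.frame(parameter = p, min = min(v), max = max(v), mean = m,
               rsd_pct = 100 * stats::sd(v) / m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
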