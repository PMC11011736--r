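#' Coefficient of determination
#'
#' R2 = 1 - sum((yhat - y)^2) / sum((mean(y) - y)^2).
#'
#' @param y Reference values (ug/g).
#' @param yhat Predicted values (ug/g), same length.
#' @return Dimensionless R2 (<= 1; negative when worse than the mean model).
#' @export
r2 <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) < 2L)
    stop("r2 needs two equal-length vectors with n >= 2")
  ss_tot <- sum((mean(y) - y)^2)
  if (ss_tot == 0) stop("constant reference values; R2 undefined")
  1 - sum((yhat - y)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @inheritParams r2
#' @return RMSE in the units of `y` (ug/g).
#' @export
rmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat) || length(y) == 0L)
    stop("rmse needs two equal-length non-empty vectors")
  sqrt(mean((y - yhat)^2))
}

.as_feature_matrix <- function(features) {
  M <- as.matrix(as.data.frame(features))
  storage.mode(M) <- "double"
  if (is.null(colnames(M))) colnames(M) <- paste0("V", seq_len(ncol(M)))
  if (any(!is.finite(M))) stop("non-finite feature values")
  M
}

.check_features <- function(model, features) {
  M <- .as_feature_matrix(features)
  if (!identical(colnames(M), model$feature_names))
    stop("feature names do not match the fitted model: expected ",
         paste(model$feature_names, collapse = ", "))
  M
}

#' Fit a univariate calibration curve
#'
#' Least-squares straight line predicting concentration from a single
#' intensity variable (the working direction of all model evaluations here:
#' concentration is the response).
#'
#' @param x Intensities (counts, or dimensionless after correction).
#' @param y Reference concentrations (ug/g).
#' @return `cs_model` of kind `"curve"` with slope `a` and intercept `b`
#'   (y = a x + b).
#' @export
fit_curve <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L)
    stop("fit_curve needs n >= 3 aligned points")
  if (stats::var(x) == 0) stop("zero intensity variance; curve undefined")
  fit <- stats::lm(y ~ x)
  structure(list(kind = "curve",
                 a = unname(stats::coef(fit)[2L]),
                 b = unname(stats::coef(fit)[1L]),
                 feature_names = "x",
                 x_cal = x, y_cal = y),
            class = "cs_model")
}

#' Fit multiple linear regression (OLS with intercept)
#'
#' @param features n x k named feature matrix/data.frame.
#' @param y Reference concentrations (ug/g).
#' @return `cs_model` of kind `"mlr"` with `coefficients` and `intercept`.
#' @export
fit_mlr <- function(features, y) {
  M <- .as_feature_matrix(features)
  y <- as.numeric(y)
  if (nrow(M) <= ncol(M) + 1L) stop("fit_mlr needs n > k + 1")
  fit <- stats::lm(y ~ ., data = data.frame(M, y = y, check.names = FALSE))
  cf <- stats::coef(fit)
  if (anyNA(cf)) stop("rank-deficient feature matrix in fit_mlr")
  structure(list(kind = "mlr",
                 coefficients = cf[colnames(M)],
                 intercept = unname(cf["(Intercept)"]),
                 feature_names = colnames(M)),
            class = "cs_model")
}

#' Fit partial least squares regression (SIMPLS)
#'
#' Single-response SIMPLS on mean-centered (unscaled) data. When `ncomp` is
#' `NULL` the component count is chosen by seeded k-fold cross-validation
#' over 1..`max_ncomp`.
#'
#' @param features n x p named matrix.
#' @param y Reference concentrations.
#' @param ncomp Number of latent components, or `NULL` to choose by CV.
#' @param max_ncomp Upper bound for the CV search. Default 10 (capped at
#'   rank).
#' @param folds CV folds when selecting `ncomp`. Default 10.
#' @param seed Seed for the CV shuffle. Default 1.
#' @return `cs_model` of kind `"plsr"` with the regression vector on the raw
#'   scale, the centering constants and the chosen component count.
#' @export
fit_plsr <- function(features, y, ncomp = NULL, max_ncomp = 10L,
                     folds = 10L, seed = 1L) {
  M <- .as_feature_matrix(features)
  y <- as.numeric(y)
  cap <- min(nrow(M) - 1L, ncol(M))
  if (!is.null(ncomp)) {
    if (ncomp < 1L || ncomp > cap)
      stop("ncomp must lie in 1..", cap)
    a <- ncomp
  } else {
    grid <- seq_len(min(max_ncomp, cap))
    fold_id <- .cv_folds(nrow(M), folds, seed)
    cv <- vapply(grid, function(a) .cv_rmse_pls(M, y, a, fold_id), 0)
    a <- grid[which.min(cv)]
  }
  fit <- .simpls_fit(M, y, a)
  structure(list(kind = "plsr", coef = fit$coef, mx = fit$mx, my = fit$my,
                 ncomp = fit$ncomp, feature_names = colnames(M),
                 seed = seed),
            class = "cs_model")
}

#' Fit a least-squares support vector machine (regression)
#'
#' Solves the LSSVM dual saddle system
#' \deqn{[[0, 1^T], [1, K + I/\gamma]] [b; \alpha] = [0; y]}
#' with an RBF (or linear) kernel; prediction is
#' f(x) = sum_i alpha_i k(x, x_i) + b. Features are standardized internally
#' (kernel methods are scale-sensitive) and the transform is stored in the
#' model. When `gamma`/`sigma` are `NULL` they are chosen by a seeded k-fold
#' CV grid: gamma in 10^(0..6), sigma in {0.1, 1, 10} x the median pairwise
#' distance of the standardized calibration features.
#'
#' @param features n x k named matrix.
#' @param y Reference concentrations.
#' @param gamma Regularization (larger = less regularized), or `NULL`.
#' @param sigma RBF kernel width on the standardized scale, or `NULL`.
#'   Ignored for `kernel = "linear"`.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param folds CV folds for the hyperparameter grid. Default 5.
#' @param seed Seed for the CV shuffle. Default 1.
#' @param standardize Standardize features internally. Default TRUE.
#' @return `cs_model` of kind `"lssvm"` with dual weights `alpha`, bias `b`,
#'   kernel parameters, standardization constants and the stored support
#'   (calibration) features.
#' @export
fit_lssvm <- function(features, y, gamma = NULL, sigma = NULL,
                      kernel = c("rbf", "linear"), folds = 5L, seed = 1L,
                      standardize = TRUE) {
  kernel <- match.arg(kernel)
  M <- .as_feature_matrix(features)
  y <- as.numeric(y)
  n <- nrow(M)
  if (n < 3L) stop("fit_lssvm needs n >= 3")
  if (standardize) {
    ctr <- colMeans(M)
    scl <- apply(M, 2L, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(M)); scl <- rep(1, ncol(M))
  }
  Z <- sweep(sweep(M, 2L, ctr), 2L, scl, "/")
  med_d <- stats::median(stats::dist(Z))
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  gammas <- if (is.null(gamma)) 10^(0:6) else gamma
  sigmas <- if (kernel == "linear") NA_real_
            else if (is.null(sigma)) c(0.1, 1, 10) * med_d else sigma
  grid <- expand.grid(gamma = gammas, sigma = sigmas)
  if (nrow(grid) > 1L) {
    fold_id <- .cv_folds(n, folds, seed)
    cv <- vapply(seq_len(nrow(grid)), function(i) {
      pred <- numeric(n)
      for (f in unique(fold_id)) {
        tr <- fold_id != f
        sol <- .lssvm_solve(Z[tr, , drop = FALSE], y[tr],
                            grid$gamma[i], grid$sigma[i], kernel)
        pred[!tr] <- .lssvm_eval(sol, Z[tr, , drop = FALSE],
                                 Z[!tr, , drop = FALSE],
                                 grid$sigma[i], kernel)
      }
      sqrt(mean((y - pred)^2))
    }, 0)
    best <- grid[which.min(cv), ]
  } else best <- grid[1L, ]
  sol <- .lssvm_solve(Z, y, best$gamma, best$sigma, kernel)
  structure(list(kind = "lssvm", alpha = sol$alpha, b = sol$b,
                 gamma = best$gamma, sigma = best$sigma, kernel = kernel,
                 center = ctr, scale = scl, Z = Z, y = y,
                 feature_names = colnames(M), seed = seed),
            class = "cs_model")
}

.lssvm_kernel <- function(A, B, sigma, kernel) {
  if (kernel == "linear") return(tcrossprod(A, B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

.lssvm_solve <- function(Z, y, gamma, sigma, kernel) {
  n <- nrow(Z)
  K <- .lssvm_kernel(Z, Z, sigma, kernel)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(n) / gamma))
  sol <- tryCatch(solve(A, c(0, y)),
                  error = function(e) stop("singular LSSVM system: ",
                                           conditionMessage(e)))
  list(b = sol[1L], alpha = sol[-1L], A = A)
}

.lssvm_eval <- function(sol, Ztrain, Znew, sigma, kernel) {
  Knew <- .lssvm_kernel(Znew, Ztrain, sigma, kernel)
  as.numeric(Knew %*% sol$alpha + sol$b)
}

#' Fit a random forest regression
#'
#' Seeded wrapper around [randomForest::randomForest()] with mtry = max(1,
#' floor(k/3)).
#'
#' @param features n x k named matrix.
#' @param y Reference concentrations.
#' @param n_trees Number of trees. Default 500.
#' @param seed RNG seed, recorded in the model. Default 1.
#' @return `cs_model` of kind `"rf"`.
#' @export
fit_rf <- function(features, y, n_trees = 500L, seed = 1L) {
  M <- .as_feature_matrix(features)
  y <- as.numeric(y)
  forest <- .with_seed(seed,
    randomForest::randomForest(M, y, ntree = n_trees,
                               mtry = max(1L, floor(ncol(M) / 3))))
  structure(list(kind = "rf", forest = forest, seed = seed,
                 n_trees = n_trees, feature_names = colnames(M)),
            class = "cs_model")
}

#' Predict concentrations from a fitted calibration model
#'
#' @param object A `cs_model`.
#' @param newdata Feature matrix/data.frame with the model's feature names
#'   (for curve models: a numeric vector or one-column input).
#' @param ... Unused.
#' @return Numeric vector of predicted concentrations (ug/g).
#' @export
predict.cs_model <- function(object, newdata, ...) {
  switch(object$kind,
    curve = {
      x <- if (is.numeric(newdata) && is.null(dim(newdata))) newdata
           else .as_feature_matrix(newdata)[, 1L]
      object$a * as.numeric(x) + object$b
    },
    mlr = {
      M <- .check_features(object, newdata)
      as.numeric(M %*% object$coefficients + object$intercept)
    },
    plsr = {
      M <- .check_features(object, newdata)
      as.numeric(sweep(M, 2L, object$mx) %*% object$coef + object$my)
    },
    lssvm = {
      M <- .check_features(object, newdata)
      Z <- sweep(sweep(M, 2L, object$center), 2L, object$scale, "/")
      .lssvm_eval(list(alpha = object$alpha, b = object$b),
                  object$Z, Z, object$sigma, object$kernel)
    },
    rf = {
      M <- .check_features(object, newdata)
      as.numeric(stats::predict(object$forest, M))
    },
    stop("unknown model kind: ", object$kind))
}

#' @export
print.cs_model <- function(x, ...) {
  cat("cs_model kind =", x$kind)
  if (x$kind == "curve") cat(sprintf(": y = %.4g x + %.4g", x$a, x$b))
  if (x$kind == "plsr") cat(sprintf(" (%d components)", x$ncomp))
  if (x$kind == "lssvm")
    cat(sprintf(" (%s kernel, gamma=%.3g, sigma=%.3g)",
                x$kernel, x$gamma, x$sigma))
  cat("\n")
  invisible(x)
}

#' Limit of detection and quantification of a calibration curve
#'
#' Classical 3-sigma / 10-sigma convention: the intensity-on-concentration
#' regression of the calibration data gives the sensitivity slope A
#' (counts per ug/g) and the residual standard deviation sigma in intensity
#' space; LOD = 3 sigma / |A|, LOQ = 10 sigma / |A|. With
#' `sigma_space = "concentration"` sigma is instead the residual sd of the
#' concentration predictions and LOD = 3 sigma directly (alternative
#' convention).
#'
#' @param model A fitted curve `cs_model` (stores its calibration data).
#' @param sigma_space `"intensity"` (default) or `"concentration"`.
#' @return Named list with `lod` and `loq` in ug/g; `loq/lod` is always
#'   10/3.
#' @export
lod_loq <- function(model, sigma_space = c("intensity", "concentration")) {
  sigma_space <- match.arg(sigma_space)
  if (!inherits(model, "cs_model") || model$kind != "curve")
    stop("lod_loq requires a univariate curve model")
  if (model$a <= 0)
    stop("non-positive calibration slope; LOD undefined")
  x <- model$x_cal; y <- model$y_cal
  if (sigma_space == "intensity") {
    fit <- stats::lm(x ~ y)                       # intensity on concentration
    A <- unname(stats::coef(fit)[2L])
    if (A <= 0) stop("non-positive sensitivity slope; LOD undefined")
    s <- stats::sd(stats::residuals(fit))
    list(lod = 3 * s / abs(A), loq = 10 * s / abs(A))
  } else {
    res <- y - (model$a * x + model$b)
    s <- stats::sd(res)
    list(lod = 3 * s, loq = 10 * s)
  }
}

#' Evaluate a model on calibration and prediction sets
#'
#' @param model A fitted `cs_model`.
#' @param cal List with `features` and `y` for the calibration set.
#' @param pred List with `features` and `y` for the prediction set.
#' @return Object of class `evaluation_report`: `Rc2`, `RMSEC`, `Rp2`,
#'   `RMSEP` (ug/g), plus `LOD`/`LOQ` for curve models (NA otherwise).
#' @export
evaluate <- function(model, cal, pred) {
  yc_hat <- stats::predict(model, cal$features)
  yp_hat <- stats::predict(model, pred$features)
  lodloq <- if (model$kind == "curve" && model$a > 0) lod_loq(model)
            else list(lod = NA_real_, loq = NA_real_)
  structure(list(Rc2 = r2(cal$y, yc_hat), RMSEC = rmse(cal$y, yc_hat),
                 Rp2 = r2(pred$y, yp_hat), RMSEP = rmse(pred$y, yp_hat),
                 LOD = lodloq$lod, LOQ = lodloq$loq,
                 kind = model$kind),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Rc2=%.4f RMSEC=%.4f  Rp2=%.4f RMSEP=%.4f",
              x$Rc2, x$RMSEC, x$Rp2, x$RMSEP))
  if (!is.na(x$LOD)) cat(sprintf("  LOD=%.2f LOQ=%.2f", x$LOD, x$LOQ))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.evaluation_report <- function(x, ...) {
  data.frame(Rc2 = x$Rc2, RMSEC = x$RMSEC, Rp2 = x$Rp2, RMSEP = x$RMSEP,
             LOD = x$LOD, LOQ = x$LOQ)
}

#' Principal component scores of a spectrum set
#'
#' Mean-centered (unscaled) SVD-based PCA for qualitative inspection of
#' brand/level structure.
#'
#' @param ss A [spectrum_set].
#' @param k Number of components, 1 <= k <= min(n, p).
#' @return List with `scores` (n x k) and `explained` (length-k variance
#'   fractions, descending, summing to <= 1).
#' @export
pca_scores <- function(ss, k) {
  stopifnot(inherits(ss, "spectrum_set"))
  n <- nrow(ss$X); p <- ncol(ss$X)
  if (k < 1L || k > min(n, p)) stop("k must lie in 1..min(n, p)")
  pc <- stats::prcomp(ss$X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)])
}
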