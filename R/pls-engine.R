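# SIMPLS for a single response (de Jong 1993). Kept internal and minimal:
# it backs fit_plsr() and the CV loop of the CPRC m-selection, where many
# thousands of fits on ~200 x ~1000 matrices must stay in the millisecond
# range. Centering only, no scaling (raw-intensity convention).

.simpls_fit <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  ncomp <- min(ncomp, n - 1L, p)
  if (ncomp < 1L) stop("ncomp must be >= 1 after rank capping")
  mx <- colMeans(X); my <- mean(y)
  Xc <- sweep(X, 2L, mx)
  yc <- y - my
  S <- crossprod(Xc, yc)            # p x 1
  W <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  V <- matrix(0, p, ncomp)
  a_used <- 0L
  for (a in seq_len(ncomp)) {
    r <- S
    t <- Xc %*% r
    nt <- sqrt(sum(t^2))
    if (!is.finite(nt) || nt < 1e-12) break   # rank exhausted
    t <- t / nt
    w <- r / nt
    pa <- crossprod(Xc, t)          # loading
    qa <- sum(yc * t)
    v <- pa
    if (a > 1L) {
      Vp <- V[, seq_len(a - 1L), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pa)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12) break
    v <- v / nv
    S <- S - v * sum(v * S)
    W[, a] <- w; Q[a] <- qa; V[, a] <- v
    a_used <- a
  }
  if (a_used == 0L) stop("PLS extracted no components (X has no variance)")
  coef <- W[, seq_len(a_used), drop = FALSE] %*% Q[seq_len(a_used)]
  list(coef = as.numeric(coef), mx = mx, my = my, ncomp = a_used)
}

.simpls_predict <- function(fit, X) {
  X <- as.matrix(X)
  as.numeric(sweep(X, 2L, fit$mx) %*% fit$coef + fit$my)
}

# Evaluate an expression under a temporary RNG state; the caller's stream is
# untouched.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Shuffled k-fold assignment, deterministic in `seed`.
.cv_folds <- function(n, k, seed) {
  if (k > n) stop("cross-validation folds (", k, ") exceed n (", n, ")")
  .with_seed(seed, sample(rep_len(seq_len(k), n)))
}

# RMSE of k-fold cross-validated SIMPLS predictions.
.cv_rmse_pls <- function(X, y, ncomp, fold_id) {
  pred <- numeric(length(y))
  for (f in unique(fold_id)) {
    tr <- fold_id != f
    fit <- .simpls_fit(X[tr, , drop = FALSE], y[tr], ncomp)
    pred[!tr] <- .simpls_predict(fit, X[!tr, , drop = FALSE])
  }
  sqrt(mean((y - pred)^2))
}
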