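#' Fit a multi-response partial least squares model
#'
#' NIPALS-style PLS2 fitted by successive singular value decompositions of the
#' cross-product matrix. Per component: form S = E'F from the current deflated
#' predictor and response matrices; take the leading singular pair (w, q) as
#' weight vectors; score t = E w, normalized to unit length; loadings
#' p = E't and q = F't; deflate E <- E - t p', F <- F - t q'. After `a`
#' components the rotation R = W (P'W)^-1 maps the original (scaled)
#' predictors to scores T = X R, the inner regression is b = (T'T)^-1 T'Y,
#' and the coefficient matrix on the scaled predictors is B = R b. Columns of
#' X and Y are centered and scaled to unit variance before fitting;
#' predictions are returned on the original response scale. With a
#' single-column Y the algorithm reduces to univariate PLS unchanged.
#'
#' @param X n x m predictor matrix.
#' @param Y n x nT response matrix (a vector is treated as one column).
#' @param a Number of latent variables, `1 <= a <= min(n - 1, m)`. If the
#'   predictor rank is exhausted earlier, fitting stops with a warning and a
#'   smaller `a`.
#' @return A `pls_fit` object holding the scaling statistics, the weight
#'   (`W`), loading (`P`, `Q`), score (`T`, `U`) and rotation (`Rrot`)
#'   matrices, the inner coefficients `b` and the coefficient matrix `B` on
#'   the standardized scale.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' Y <- X %*% matrix(rnorm(6), 3, 2) + 0.01 * matrix(rnorm(40), 20, 2)
#' fit <- fit_pls(X, Y, a = 3)
#' head(predict(fit, X))
fit_pls <- function(X, Y, a) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  m <- ncol(X)
  nT <- ncol(Y)
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (n < 2) stop("need at least 2 rows")
  a_lim <- min(n - 1L, m)
  if (a < 1 || a > a_lim) {
    stop("a must be between 1 and min(n - 1, m) = ", a_lim)
  }
  sc <- scale_columns(X, Y)
  E <- sc$Xs
  F_ <- sc$Ys

  W <- P <- matrix(0, m, a)
  Q <- matrix(0, nT, a)
  Tm <- U <- matrix(0, n, a)
  a_used <- 0L
  for (k in seq_len(a)) {
    S <- crossprod(E, F_)
    if (max(abs(S)) < 1e-12) break
    sv <- svd(S, nu = 1, nv = 1)
    w <- sv$u[, 1]
    qw <- sv$v[, 1]
    # reproducible sign: largest-magnitude weight entry positive
    sgn <- sign(w[which.max(abs(w))])
    if (sgn < 0) { w <- -w; qw <- -qw }
    t <- E %*% w
    tn <- sqrt(sum(t^2))
    if (tn < 1e-12) break
    t <- t / tn
    u <- F_ %*% qw   # kept for interpretation; unused in the regression
    p <- crossprod(E, t)
    qload <- crossprod(F_, t)
    E <- E - t %*% t(p)
    F_ <- F_ - t %*% t(qload)
    a_used <- k
    W[, k] <- w; P[, k] <- p; Q[, k] <- qload
    Tm[, k] <- t; U[, k] <- u
  }
  if (a_used == 0L) stop("predictor matrix has no usable variance")
  if (a_used < a) {
    warning("rank exhausted after ", a_used, " of ", a,
            " requested components")
    W <- W[, seq_len(a_used), drop = FALSE]
    P <- P[, seq_len(a_used), drop = FALSE]
    Q <- Q[, seq_len(a_used), drop = FALSE]
    Tm <- Tm[, seq_len(a_used), drop = FALSE]
    U <- U[, seq_len(a_used), drop = FALSE]
  }
  rot <- pls_rotation(W, P)
  Tfull <- sc$Xs %*% rot                       # scores from the original scaled X
  b <- solve(crossprod(Tfull), crossprod(Tfull, sc$Ys))
  B <- rot %*% b
  resid <- sweep(sc$Ys - Tfull %*% b, 2, sc$y_sds, "*")
  structure(list(
    x_means = sc$x_means, x_sds = sc$x_sds,
    y_means = sc$y_means, y_sds = sc$y_sds,
    scaled_x_cols = sc$scaled_x_cols,
    W = W, P = P, Q = Q, T = Tfull, U = U,
    Rrot = rot, b = b, B = B,
    a = a_used, a_requested = as.integer(a),
    rmse_train = sqrt(mean(resid^2)),
    E_residual = E,
    dims = c(n = n, m = m, nT = nT),
    trait_names = colnames(Y)
  ), class = "pls_fit")
}

# R = W (P'W)^-1, with a pseudo-inverse fallback near rank exhaustion
pls_rotation <- function(W, P) {
  PtW <- crossprod(P, W)
  cond <- tryCatch(kappa(PtW, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e12) {
    warning("P'W is ill-conditioned (kappa ", format(cond, digits = 3),
            "); using pseudo-inverse")
    W %*% MASS::ginv(PtW)
  } else {
    W %*% solve(PtW)
  }
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("<pls_fit> ", x$dims["n"], " obs, ", x$dims["m"], " predictors, ",
      x$dims["nT"], " response(s), ", x$a, " latent variable(s)\n", sep = "")
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' New predictors are standardized with the training statistics, multiplied
#' by the coefficient matrix B, and rescaled to the original response units,
#' so observed and predicted values share the same scale. Equivalent to the
#' score route `T_new b` with `T_new = X_new R`.
#'
#' @param object A `pls_fit`.
#' @param newdata Matrix with the same number of columns as the training X.
#' @param ... Unused.
#' @return A matrix of predictions, one column per response.
#' @export
predict.pls_fit <- function(object, newdata, ...) {
  Xnew <- as.matrix(newdata)
  if (ncol(Xnew) != object$dims["m"]) {
    stop("newdata has ", ncol(Xnew), " columns; model expects ",
         object$dims["m"])
  }
  Xs <- sweep(sweep(Xnew, 2, object$x_means, "-"), 2, object$x_sds, "/")
  Ys <- Xs %*% object$B
  out <- sweep(sweep(Ys, 2, object$y_sds, "*"), 2, object$y_means, "+")
  colnames(out) <- object$trait_names
  out
}

#' @rdname predict.pls_fit
#' @export
predict_pls <- function(object, newdata, ...) predict.pls_fit(object, newdata, ...)

#' Choose the number of latent variables by cross-validated RMSEP
#'
#' Rows are partitioned at random (seeded) into `folds` folds. For each fold
#' the model is fitted on the remaining rows with `a_max` components — PLS
#' components are nested, so every smaller model is read off the same fit —
#' and held-out predictions for each a in 1..a_max are scored by the root
#' mean squared error of prediction, pooled over folds and responses on the
#' original response scale. The chosen a minimizes RMSEP, ties going to the
#' smallest a.
#'
#' @param X,Y Training predictors and responses.
#' @param a_max Largest number of components to consider (capped at the
#'   smallest fold's limit).
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return A `component_selection`: list with `rmsep_by_a`, `chosen_a`,
#'   `folds`, `seed`.
#' @export
select_components <- function(X, Y, a_max, folds = 5, seed = 1) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2) stop("folds must be >= 2")
  if (a_max < 1) stop("a_max must be >= 1")
  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  sizes <- tabulate(fold_id, folds)
  if (any(sizes < 2)) stop("each fold needs at least 2 rows; reduce folds")
  a_cap <- min(a_max, min(n - sizes) - 1L, ncol(X))
  sse <- numeric(a_cap)
  n_pred <- 0L
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- suppressWarnings(fit_pls(X[tr, , drop = FALSE],
                                    Y[tr, , drop = FALSE], a = a_cap))
    Xs <- sweep(sweep(X[!tr, , drop = FALSE], 2, fit$x_means, "-"),
                2, fit$x_sds, "/")
    for (a in seq_len(a_cap)) {
      B_a <- if (a == fit$a) fit$B else truncated_coef(fit, min(a, fit$a))
      pred <- sweep(sweep(Xs %*% B_a, 2, fit$y_sds, "*"), 2, fit$y_means, "+")
      sse[a] <- sse[a] + sum((Y[!tr, , drop = FALSE] - pred)^2)
    }
    n_pred <- n_pred + sum(!tr) * ncol(Y)
  }
  rmsep <- sqrt(sse / n_pred)
  structure(list(rmsep_by_a = rmsep,
                 chosen_a = which.min(rmsep),
                 folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "component_selection")
}

# coefficients of the nested a-component model from an a_max-component fit
truncated_coef <- function(fit, a) {
  W <- fit$W[, seq_len(a), drop = FALSE]
  P <- fit$P[, seq_len(a), drop = FALSE]
  rot <- pls_rotation(W, P)
  # scores are mutually orthogonal and nested (the a-component fit's scores
  # are the first a columns of the full fit's), so the inner coefficients of
  # the truncated model are the first a rows of b
  b <- fit$b[seq_len(a), , drop = FALSE]
  rot %*% b
}

#' @export
print.component_selection <- function(x, ...) {
  cat("<component_selection> chosen a = ", x$chosen_a, " of ",
      length(x$rmsep_by_a), " (", x$folds, "-fold, RMSEP ",
      format(min(x$rmsep_by_a), digits = 5), ")\n", sep = "")
  invisible(x)
}

# column standardization shared by fit and predict; zero-variance predictor
# columns are centered but not scaled (their sd is set to 1 and flagged)
scale_columns <- function(X, Y) {
  x_means <- colMeans(X)
  x_sds <- apply(X, 2, stats::sd)
  scaled <- x_sds > 1e-12
  if (!all(scaled)) x_sds[!scaled] <- 1
  y_means <- colMeans(Y)
  y_sds <- apply(Y, 2, stats::sd)
  if (any(y_sds <= 1e-12)) stop("zero-variance response column")
  list(
    Xs = sweep(sweep(X, 2, x_means, "-"), 2, x_sds, "/"),
    Ys = sweep(sweep(Y, 2, y_means, "-"), 2, y_sds, "/"),
    x_means = x_means, x_sds = x_sds, scaled_x_cols = scaled,
    y_means = y_means, y_sds = y_sds
  )
}
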