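test_that("full-component PLS reproduces exact fits and the OLS solution", {
  # exact linear map: fitted values reproduce Y
  set.seed(21)
  X <- matrix(rnorm(30), 10, 3)
  Y <- X %*% matrix(c(1, -2, 0.5, 3, 1, -1), 3, 2)
  fit <- fit_pls(X, Y, a = 3)
  expect_lt(max(abs(predict(fit, X) - Y)), 1e-9)

  # with a = m = rank, B on the standardized scale equals OLS
  set.seed(22)
  X <- matrix(rnorm(250), 50, 5)
  Y <- X %*% matrix(rnorm(10), 5, 2) + matrix(rnorm(100), 50, 2)
  fit <- fit_pls(X, Y, a = 5)
  Xs <- scale(X); Ys <- scale(Y)
  B_ols <- solve(crossprod(Xs), crossprod(Xs, Ys))
  expect_lt(max(abs(fit$B - B_ols)), 1e-8)
})

test_that("first weight vector is the dominant singular direction of X'Y", {
  for (s in 1:5) {
    set.seed(300 + s)
    X <- matrix(rnorm(40 * 7), 40, 7)
    Y <- matrix(rnorm(40 * 3), 40, 3)
    fit <- fit_pls(X, Y, a = 2)
    sv <- svd(crossprod(scale(X), scale(Y)))
    cosine <- abs(sum(fit$W[, 1] * sv$u[, 1]))
    expect_gte(cosine, 1 - 1e-10)
  }
})

test_that("internal identities hold: orthogonality, rotation, dual routes", {
  set.seed(23)
  X <- matrix(rnorm(40 * 8), 40, 8)
  Y <- matrix(rnorm(40 * 2), 40, 2)
  fit <- fit_pls(X, Y, a = 5)
  TtT <- crossprod(fit$T)
  expect_lt(max(abs(TtT - diag(diag(TtT)))), 1e-8)
  expect_lt(max(abs(fit$Rrot -
                      fit$W %*% solve(crossprod(fit$P, fit$W)))), 1e-8)
  expect_identical(fit$B, fit$Rrot %*% fit$b)

  # deflation conservation: X_scaled = T P' + E_residual
  Xs <- scale(X)
  expect_lt(max(abs(Xs - fit$T %*% t(fit$P) - fit$E_residual)), 1e-8)

  # prediction: coefficient route equals score route
  Xnew <- matrix(rnorm(10 * 8), 10, 8)
  Xns <- sweep(sweep(Xnew, 2, fit$x_means, "-"), 2, fit$x_sds, "/")
  via_B <- Xns %*% fit$B
  via_T <- (Xns %*% fit$Rrot) %*% fit$b
  expect_lt(max(abs(via_B - via_T)), 1e-10)

  # predicting at the training means returns the response means
  at_mean <- predict(fit, matrix(fit$x_means, 1))
  expect_lt(max(abs(at_mean - fit$y_means)), 1e-10)

  # training predictions equal fitted values
  expect_equal(predict(fit, X),
               sweep(sweep(fit$T %*% fit$b, 2, fit$y_sds, "*"),
                     2, fit$y_means, "+"))
})

test_that("training RMSE is non-increasing in the number of components", {
  set.seed(24)
  X <- matrix(rnorm(30 * 6), 30, 6)
  Y <- matrix(rnorm(30 * 2), 30, 2)
  rmse <- vapply(1:6, function(a) fit_pls(X, Y, a)$rmse_train, numeric(1))
  expect_true(all(diff(rmse) <= 1e-12))
})

test_that("component-1 covariance dominates random weight directions", {
  set.seed(25)
  X <- matrix(rnorm(50 * 10), 50, 10)
  Y <- matrix(rnorm(50 * 2), 50, 2)
  fit <- fit_pls(X, Y, a = 1)
  S <- crossprod(scale(X), scale(Y))
  attained <- sqrt(sum((t(S) %*% fit$W[, 1])^2))
  wr <- matrix(rnorm(10 * 1000), 10, 1000)
  wr <- sweep(wr, 2, sqrt(colSums(wr^2)), "/")
  best_random <- max(sqrt(colSums((t(S) %*% wr)^2)))
  expect_gte(attained, best_random)
})

test_that("rank exhaustion stops early with a warning; guards fire", {
  X <- cbind(1:10, (1:10) * 2, 11:20)  # rank 2 after centering
  Y <- matrix(rnorm(20), 10, 2)
  expect_warning(fit <- fit_pls(X, Y, a = 3), "rank exhausted")
  expect_lt(fit$a, 3)
  expect_error(fit_pls(X, Y, a = 10), "min\\(n - 1, m\\)")
  expect_error(fit_pls(X, matrix(1, 10, 2), a = 2), "zero-variance")
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("nT = 1 fitting equals the independent univariate implementation", {
  set.seed(26)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- X %*% rnorm(8) + rnorm(30)
  for (a in c(1, 3, 5)) {
    fit <- fit_pls(X, y, a = a)
    ora <- ut_pls_oracle(X, y, a)
    expect_lt(max(abs(fit$W - ora$W)), 1e-10)
    expect_lt(max(abs(fit$B - ora$B)), 1e-10)
    expect_lt(max(abs(predict(fit, X) - ora$fitted)), 1e-10)
  }
})

test_that("a fitted model round-trips through its JSON container", {
  set.seed(28)
  X <- matrix(rnorm(25 * 6), 25, 6)
  Y <- matrix(rnorm(25 * 2), 25, 2)
  for (resp in list(Y, Y[, 1, drop = FALSE])) {
    fit <- fit_pls(X, resp, a = 3)
    f <- tempfile(fileext = ".json")
    write_pls_model(fit, f)
    fit2 <- read_pls_model(f)
    expect_equal(fit2$B, unname(fit$B), tolerance = 1e-12)
    expect_equal(predict(fit2, X), unname(predict(fit, X)),
                 tolerance = 1e-12)
    expect_identical(fit2$a, fit$a)
  }
})

test_that("component selection minimizes a reproducible RMSEP curve", {
  set.seed(27)
  X <- matrix(rnorm(80 * 10), 80, 10)
  Y <- matrix(rnorm(80 * 2), 80, 2)

  sel <- select_components(X, Y, a_max = 6, folds = 5, seed = 3)
  expect_equal(sel$chosen_a, which.min(sel$rmsep_by_a))

  # deterministic under the seed
  sel2 <- select_components(X, Y, a_max = 6, folds = 5, seed = 3)
  expect_identical(sel$rmsep_by_a, sel2$rmsep_by_a)
  expect_identical(sel$chosen_a, sel2$chosen_a)

  # singleton grid
  expect_equal(select_components(X, Y, a_max = 1, folds = 4,
                                 seed = 1)$chosen_a, 1L)

  # brute force: refit each a from scratch on the same fold partition
  set.seed(3)
  fold_id <- sample(rep(1:5, length.out = 80))
  sse <- numeric(6); npred <- 0
  for (f in 1:5) {
    tr <- fold_id != f
    for (a in 1:6) {
      fit <- fit_pls(X[tr, ], Y[tr, ], a)
      sse[a] <- sse[a] + sum((Y[!tr, ] - predict(fit, X[!tr, ]))^2)
    }
    npred <- npred + sum(!tr) * 2
  }
  expect_lt(max(abs(sel$rmsep_by_a - sqrt(sse / npred))), 1e-8)
})
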