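# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# univariate PLS, written directly from the scalar recursions (weight vector
# proportional to E'f, no SVD call): the single-response reduction oracle
ut_pls_oracle <- function(X, y, a) {
  Xs <- scale(X)
  ys <- scale(y)
  E <- Xs
  f <- ys
  m <- ncol(X)
  W <- P <- matrix(0, m, a)
  Tm <- matrix(0, nrow(X), a)
  for (k in seq_len(a)) {
    w <- as.vector(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) w <- -w
    t <- as.vector(E %*% w)
    t <- t / sqrt(sum(t^2))
    p <- as.vector(crossprod(E, t))
    q <- sum(f * t)
    E <- E - t %o% p
    f <- f - t * q
    W[, k] <- w; P[, k] <- p; Tm[, k] <- t
  }
  R <- W %*% solve(crossprod(P, W))
  Tfull <- Xs %*% R
  b <- solve(crossprod(Tfull), crossprod(Tfull, ys))
  B <- R %*% b
  list(W = W, B = B,
       fitted = as.vector(Xs %*% B) * attr(ys, "scaled:scale") +
         attr(ys, "scaled:center"))
}

# dense covariance-form ("kriging") BLUP oracle for the multi-trait mixed
# model at fixed covariances: builds the full n*nT phenotypic covariance and
# reads effects off Cov(effect, y) V^{-1} y. Independent of the whitened
# mixed-model-equations route used by solve_mme().
dense_blup_oracle <- function(ds, G, H, predictor, Sigma_T, R_res,
                              fixed_var = 1e6) {
  Y <- ds$Y
  n <- nrow(Y); nT <- ncol(Y)
  I <- length(ds$env_ids); J <- length(ds$line_ids)
  des <- build_design(ds)
  Ffix <- matrix(1, n, 1)
  if (predictor != "G+GE") Ffix <- cbind(Ffix, des$X_E)
  ZG <- des$Z_L %*% G %*% t(des$Z_L)
  V <- kronecker(Sigma_T, ZG) + kronecker(R_res, diag(n)) +
    fixed_var * kronecker(diag(nT), tcrossprod(Ffix))
  has_ge <- predictor %in% c("E+G+GE", "G+GE")
  if (has_ge) {
    K <- kronecker(H, G)  # environment-major cell covariance
    ZKZ <- des$Z_EL %*% K %*% t(des$Z_EL)
    V <- V + kronecker(Sigma_T, ZKZ)
  }
  Vi_y <- solve(V, as.vector(Y))
  g_hat <- matrix(kronecker(Sigma_T, G %*% t(des$Z_L)) %*% Vi_y, J, nT)
  gE_hat <- if (has_ge) {
    matrix(kronecker(Sigma_T, K %*% t(des$Z_EL)) %*% Vi_y, I * J, nT)
  } else matrix(0, I * J, nT)
  theta <- matrix(fixed_var * kronecker(diag(nT), t(Ffix)) %*% Vi_y,
                  ncol(Ffix), nT)
  mu <- theta[1, ]
  beta_E <- if (predictor != "G+GE") theta[-1, , drop = FALSE] else
    matrix(0, I, nT)
  list(mu = mu, beta_E = beta_E, g_hat = g_hat, gE_hat = gE_hat)
}

# small balanced dataset simulated from the generator, shared by tests
make_small_sim <- function(J = 40, I = 3, nT = 2, p = 300, h2 = 0.5,
                           ge_fraction = 0.2, gencor = 0.5, seed = 1,
                           covs = FALSE) {
  mk <- simulate_markers(J, p, seed = seed)
  Sigma <- matrix(gencor, nT, nT); diag(Sigma) <- 1
  cv <- if (covs) simulate_env_covariates(I, 6, seed = seed + 1) else NULL
  sim <- simulate_dataset(mk, covs = cv, Sigma_T = Sigma, h2 = h2,
                          ge_fraction = ge_fraction, I = I, seed = seed + 2)
  sim$markers <- mk
  sim$covs <- cv
  sim
}

# delimited fixture writers
write_pheno_file <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
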