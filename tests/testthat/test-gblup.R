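test_that("solve_mme matches the dense covariance-form BLUP oracle", {
  sim <- make_small_sim(J = 12, I = 3, p = 100, seed = 31, covs = TRUE)
  ds <- sim$dataset
  G <- sim$truth$G; H <- sim$truth$H
  St <- matrix(c(1, 0.4, 0.4, 0.8), 2, 2)
  Rr <- matrix(c(0.6, 0.1, 0.1, 0.9), 2, 2)
  for (pc in c("E+G", "E+G+GE", "G+GE")) {
    mme <- solve_mme(ds, G, H, pc, Sigma_T = St, R_res = Rr)
    ora <- dense_blup_oracle(ds, G, H, pc, St, Rr)
    expect_lt(max(abs(mme$g_hat - ora$g_hat)), 1e-6)
    expect_lt(max(abs(mme$gE_hat - ora$gE_hat)), 1e-6)
    env_mme <- sweep(mme$beta_E, 2, mme$mu, "+")
    env_ora <- sweep(ora$beta_E, 2, ora$mu, "+")
    expect_lt(max(abs(env_mme - env_ora)), 1e-6)
  }
})

test_that("solve_mme limits: infinite shrinkage and environment means", {
  sim <- make_small_sim(J = 10, I = 3, p = 80, seed = 32)
  ds <- sim$dataset
  G <- sim$truth$G
  # zero genetic variance: line effects shrink to zero
  mme <- solve_mme(ds, G, NULL, "E+G", Sigma_T = diag(1e-10, 2),
                   R_res = diag(2))
  expect_lt(max(abs(mme$g_hat)), 1e-6)

  # balanced design, G = I, H = I, negligible genetic variance:
  # the environment-level fixed effect recovers the environment means
  Gi <- identity_kernel(ds$line_ids)
  mme2 <- solve_mme(ds, Gi, NULL, "E+G", Sigma_T = diag(1e-10, 2),
                    R_res = diag(2))
  envfit <- sweep(mme2$beta_E, 2, mme2$mu, "+")
  for (i in seq_along(ds$env_ids)) {
    mu_i <- colMeans(ds$Y[ds$env_index == i, , drop = FALSE])
    expect_lt(max(abs(envfit[i, ] - mu_i)), 1e-4)
  }

  # single trait, H = I, no GE: equals the closed-form ridge/GBLUP solve
  ds1 <- ds; ds1$Y <- ds$Y[, 1, drop = FALSE]; ds1$trait_names <- "t1"
  s2g <- 0.7; s2e <- 1.3
  mme3 <- solve_mme(ds1, G, NULL, "E+G", Sigma_T = matrix(s2g),
                    R_res = matrix(s2e))
  des <- build_design(ds1)
  Ffix <- cbind(1, des$X_E)
  V <- s2g * des$Z_L %*% G %*% t(des$Z_L) + s2e * diag(nrow(ds1$Y)) +
    1e6 * tcrossprod(Ffix)
  ghat_ref <- s2g * G %*% t(des$Z_L) %*% solve(V, ds1$Y)
  expect_lt(max(abs(mme3$g_hat - ghat_ref)), 1e-6)
})

test_that("the Gibbs sampler is reproducible and respects the predictor", {
  sim <- make_small_sim(J = 15, I = 3, p = 100, seed = 33)
  ds <- sim$dataset
  G <- sim$truth$G
  ctrl <- gblup_control(n_iter = 400, burn_in = 100, thin = 2, seed = 5)
  f1 <- fit_mt_gblup(ds, G, NULL, "E+G+GE", ctrl)
  f2 <- fit_mt_gblup(ds, G, NULL, "E+G+GE", ctrl)
  expect_identical(f1$g_hat, f2$g_hat)
  expect_identical(f1$Sigma_T, f2$Sigma_T)
  expect_equal(f1$samples_kept, 150L)

  # E+G: no interaction effects; G+GE: no environment fixed effects
  fe <- fit_mt_gblup(ds, G, NULL, "E+G", ctrl)
  expect_true(all(fe$gE_hat == 0))
  fg <- fit_mt_gblup(ds, G, NULL, "G+GE", ctrl)
  expect_true(all(fg$beta_E == 0))
  expect_true(all(is.finite(fg$mu)))

  # kept covariance draws stay symmetric positive definite
  for (k in seq_len(f1$samples_kept)) {
    S <- f1$Sigma_draws[k, , ]
    expect_equal(S, t(S))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("with fixed covariances the sampler converges on the MME solution", {
  sim <- make_small_sim(J = 25, I = 3, p = 200, seed = 34)
  ds <- sim$dataset
  G <- sim$truth$G; H <- sim$truth$H
  St <- matrix(c(1, 0.5, 0.5, 1), 2, 2)
  Rr <- diag(c(1, 1.2))
  mme <- solve_mme(ds, G, H, "E+G+GE", Sigma_T = St, R_res = Rr)
  err <- function(n_iter) {
    fit <- fit_mt_gblup(ds, G, H, "E+G+GE",
                        gblup_control(n_iter, 500, 1, seed = 11,
                                      fix_Sigma_T = St, fix_R_res = Rr))
    max(max(abs(fit$g_hat - mme$g_hat)),
        max(abs(fit$gE_hat - mme$gE_hat)))
  }
  e_short <- err(2500)
  e_long <- err(8500)
  expect_lt(e_long, 0.05)
  expect_lt(e_long, e_short)
})

test_that("a null genetic signal shrinks the trait covariance", {
  mk <- simulate_markers(60, 400, seed = 37)
  sim <- simulate_dataset(mk, Sigma_T = matrix(c(1, .5, .5, 1), 2),
                          h2 = 0.03, ge_fraction = 0, I = 3, seed = 38)
  fit <- fit_mt_gblup(sim$dataset, sim$truth$G, NULL, "E+G",
                      gblup_control(1500, 500, 2, seed = 9))
  expect_true(all(diag(fit$Sigma_T) < 0.2 * diag(fit$R_res)))
})

test_that("single-trait fitting reduces every update to its scalar form", {
  sim <- make_small_sim(J = 15, I = 3, p = 100, seed = 35)
  ds <- sim$dataset
  ds$Y <- ds$Y[, 1, drop = FALSE]
  ds$trait_names <- "t1"
  fit <- fit_mt_gblup(ds, sim$truth$G, NULL, "E+G+GE",
                      gblup_control(400, 100, 2, seed = 6))
  expect_equal(dim(fit$Sigma_T), c(1L, 1L))
  expect_equal(ncol(fit$g_hat), 1L)
  expect_true(all(is.finite(fit$g_hat)))
})

test_that("held-out environment prediction follows the Kronecker logic", {
  sim <- make_small_sim(J = 8, I = 4, p = 80, seed = 36, covs = TRUE)
  ds <- sim$dataset
  G <- sim$truth$G; H <- sim$truth$H
  train <- subset_environments(ds, ds$env_ids[1:3])
  Htr <- H[train$env_ids, train$env_ids]
  St <- diag(2) + 0.3; Rr <- diag(2)
  fit <- fit_mt_gblup(train, G, Htr, "E+G+GE",
                      gblup_control(600, 200, 1, seed = 7,
                                    unseen_env = "zero",
                                    fix_Sigma_T = St, fix_R_res = Rr))
  test_env <- ds$env_ids[4]

  # GE contribution = prediction minus (intercept + line effect)
  p <- predict_gblup(fit, ds$line_ids, test_env, H)
  base <- rep(1, 8) %o% fit$mu + fit$g_hat
  ge_contrib <- p - base

  # dense conditional-Gaussian oracle on the full (I*J)-dim Kronecker
  # covariance, per trait: E[gE_test | gE_train]
  K_tr <- kronecker(Htr, G)
  K_xt <- kronecker(H[test_env, train$env_ids, drop = FALSE], G)
  cond <- K_xt %*% MASS::ginv(K_tr) %*% fit$gE_hat
  expect_lt(max(abs(ge_contrib - cond)), 1e-6)

  # identity H: the unseen environment gets exactly zero GE transfer
  fit_id <- fit_mt_gblup(train, G, NULL, "E+G+GE",
                         gblup_control(300, 100, 1, seed = 8,
                                       unseen_env = "zero"))
  Hbig <- identity_kernel(ds$env_ids)
  p_id <- predict_gblup(fit_id, ds$line_ids, test_env, Hbig)
  expect_identical(unname(p_id),
                   unname(rep(1, 8) %o% fit_id$mu + fit_id$g_hat))

  # zeroed effects predict the intercept row
  fit0 <- fit_id
  fit0$g_hat[] <- 0; fit0$gE_hat[] <- 0
  p0 <- predict_gblup(fit0, ds$line_ids[1:3], test_env, NULL)
  expect_equal(unname(p0), matrix(rep(fit0$mu, each = 3), 3, 2))

  # unknown line errors
  expect_error(predict_gblup(fit, "nope", test_env, H), "nope")
})
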