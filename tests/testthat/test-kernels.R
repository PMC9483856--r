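test_that("VanRaden GRM matches hand and brute-force evaluation", {
  # 2 lines, 1 marker, codes (0, 2): p = 0.5, W = (-1, 1), denom = 0.5
  mk <- marker_matrix(c("A", "B"), matrix(c(0, 2), 2, 1))
  expect_equal(unname(vanraden_grm(mk)),
               matrix(c(2, -2, -2, 2), 2, 2))

  # centering identity: zero row sums
  mk2 <- simulate_markers(30, 200, seed = 8)
  G <- vanraden_grm(mk2)
  expect_lt(max(abs(rowSums(G))), 1e-10)
  expect_equal(G, t(G))

  # brute-force double-loop oracle on a simulated panel
  mk3 <- simulate_markers(50, 500, seed = 9)
  G3 <- vanraden_grm(mk3)
  codes <- mk3$codes
  p <- colMeans(codes) / 2
  poly <- p > 0 & p < 1
  codes <- codes[, poly, drop = FALSE]; p <- p[poly]
  denom <- 2 * sum(p * (1 - p))
  Gref <- matrix(0, 50, 50)
  for (i in 1:50) for (j in 1:50) {
    Gref[i, j] <- sum((codes[i, ] - 2 * p) * (codes[j, ] - 2 * p)) / denom
  }
  expect_lt(max(abs(unname(G3) - Gref)), 1e-10)

  # all-monomorphic panel has a zero denominator
  mono <- marker_matrix(c("A", "B"), matrix(c(2, 2, 0, 0), 2, 2))
  expect_error(vanraden_grm(mono), "monomorphic")
})

test_that("environmental kernel is the standardized Gram matrix", {
  # I = 3, q = 2 hand table
  cv <- env_covariates(c("E1", "E2", "E3"),
                       matrix(c(1, 2, 3, 10, 30, 20), 3, 2))
  H <- env_kernel(cv)
  W <- scale(cv$values)
  expect_equal(unname(H), unname(tcrossprod(W) / 2))
  expect_true(all(eigen(H, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))

  # duplicated environment rows give off-diagonal equal to the diagonals
  cv2 <- env_covariates(c("E1", "E2", "E3"),
                        rbind(c(1, 5), c(1, 5), c(4, 2)))
  H2 <- env_kernel(cv2)
  expect_equal(H2["E1", "E2"], H2["E1", "E1"])
  expect_equal(H2["E1", "E2"], H2["E2", "E2"])

  # constant covariates are dropped with a warning; all-constant errors
  cv3 <- env_covariates(c("E1", "E2"), cbind(c(1, 2), c(7, 7)))
  expect_warning(env_kernel(cv3), "constant")
  cv4 <- env_covariates(c("E1", "E2"), cbind(c(7, 7)))
  expect_error(suppressWarnings(env_kernel(cv4)), "constant")
})

test_that("matrix square root reconstructs, clips and rejects", {
  expect_equal(matrix_sqrt(diag(3)), diag(3))
  expect_equal(unname(matrix_sqrt(diag(c(4, 9)))), diag(c(2, 3)))

  set.seed(10)
  A <- matrix(rnorm(400), 20, 20)
  K <- crossprod(A) / 20
  L <- matrix_sqrt(K)
  expect_lt(max(abs(tcrossprod(L) - K)), 1e-8)
  expect_equal(L, t(L))
  # idempotent under re-factorization
  L2 <- matrix_sqrt(tcrossprod(L))
  expect_lt(max(abs(L2 - L)), 1e-8)

  # rank-deficient PSD is fine; indefinite is not
  K1 <- tcrossprod(matrix(rnorm(60), 20, 3))
  expect_lt(max(abs(tcrossprod(matrix_sqrt(K1)) - K1)), 1e-8)
  expect_error(matrix_sqrt(diag(c(1, -1))), "semidefinite")

  # identity kernel: sqrt of identity is identity
  expect_equal(matrix_sqrt(identity_kernel(letters[1:4])),
               identity_kernel(letters[1:4]))
})

test_that("design matrices follow the environment-major cell convention", {
  sim <- make_small_sim(J = 3, I = 2, p = 30, seed = 5)
  ds <- sim$dataset
  des <- build_design(ds)
  expect_equal(dim(des$X_E), c(6L, 2L))
  expect_equal(dim(des$Z_L), c(6L, 3L))
  expect_equal(dim(des$Z_EL), c(6L, 6L))
  # balanced complete layout: Z_EL is the identity under this ordering
  expect_equal(unname(des$Z_EL), diag(6))
  expect_true(all(rowSums(des$X_E) == 1))
  expect_true(all(rowSums(des$Z_L) == 1))
  expect_true(all(rowSums(des$Z_EL) == 1))
  expect_equal(unname(crossprod(des$X_E)), diag(c(3, 3)))
})

test_that("PLS predictor blocks concatenate the kernel square roots", {
  sim <- make_small_sim(J = 3, I = 2, p = 40, seed = 6)
  ds <- sim$dataset
  des <- build_design(ds)
  G <- sim$truth$G
  H <- matrix(c(1, .4, .4, 1), 2, 2,
              dimnames = list(ds$env_ids, ds$env_ids))
  Lg <- matrix_sqrt(G)
  LE <- matrix_sqrt(H)

  pm <- build_pls_inputs(des, Lg, LE, "E+G+GE")
  expect_equal(ncol(pm$X), 2 + 3 + 6)
  expect_equal(lengths(pm$block_spans), c(E = 2L, G = 3L, GE = 6L))

  # identity factors reproduce the raw indicator matrices
  pid <- build_pls_inputs(des, diag(3), diag(2), "E+G+GE")
  expect_equal(unname(pid$X),
               unname(cbind(des$X_E, des$Z_L, des$Z_EL)))

  # row contents match the direct matrix products, incl. the Kronecker block
  direct <- cbind(des$X_E %*% LE, des$Z_L %*% Lg,
                  des$Z_EL %*% kronecker(LE, Lg))
  expect_lt(max(abs(unname(pm$X) - unname(direct))), 1e-12)
  r <- 5  # row for (env 2, line 2)
  i <- ds$env_index[r]; j <- ds$line_index[r]
  expect_equal(unname(pm$X[r, pm$block_spans$E]), unname(LE[i, ]))
  expect_equal(unname(pm$X[r, pm$block_spans$G]), unname(Lg[j, ]))
  expect_equal(unname(pm$X[r, pm$block_spans$GE]),
               unname(kronecker(LE, Lg)[(i - 1) * 3 + j, ]))

  # Gram matrix of the G-block carries the GBLUP kernel
  Xg <- pm$X[, pm$block_spans$G]
  expect_lt(max(abs(tcrossprod(Xg) - des$Z_L %*% G %*% t(des$Z_L))), 1e-8)

  # E+G columns are a prefix of E+G+GE
  peg <- build_pls_inputs(des, Lg, LE, "E+G")
  expect_equal(peg$X, pm$X[, 1:5])

  # G+GE drops the environment block; absent factor errors
  pgg <- build_pls_inputs(des, Lg, LE, "G+GE")
  expect_equal(ncol(pgg$X), 3 + 6)
  expect_error(build_pls_inputs(des, Lg, NULL, "E+G"), "LE")
})
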