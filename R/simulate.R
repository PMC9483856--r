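#' Simulate a 0/1/2 marker panel
#'
#' Per marker an allele frequency is drawn uniformly in `maf_range`, then the
#' J line codes are Binomial(2, freq) draws — unlinked loci in
#' Hardy-Weinberg proportions, which is all the relationship-matrix
#' machinery needs (linkage disequilibrium and structure are deliberately
#' not modeled).
#'
#' @param J Number of lines (>= 2).
#' @param p Number of markers (>= 1).
#' @param maf_range Length-2 numeric in (0, 0.5], lower <= upper.
#' @param seed Integer seed.
#' @return A `marker_matrix` with line ids `L001, L002, ...`.
#' @export
simulate_markers <- function(J, p, maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(J >= 2, p >= 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be within (0, 0.5] with lower <= upper")
  }
  set.seed(as.integer(seed))
  freqs <- stats::runif(p, maf_range[1], maf_range[2])
  codes <- vapply(freqs, function(f) stats::rbinom(J, 2, f), numeric(J))
  marker_matrix(sprintf("L%03d", seq_len(J)), codes,
                sprintf("M%05d", seq_len(p)))
}

#' Simulate an environment x covariate table
#'
#' Independent standard-normal covariates, mimicking (in shape only) the
#' weather-covariate tables of multi-environment trials.
#'
#' @param I Number of environments (>= 2).
#' @param q Number of covariates (>= 1).
#' @param seed Integer seed.
#' @return An `env_covariates` object with ids `Env1, Env2, ...`.
#' @export
simulate_env_covariates <- function(I, q = 18, seed = 1) {
  stopifnot(I >= 2, q >= 1)
  set.seed(as.integer(seed))
  env_covariates(paste0("Env", seq_len(I)),
                 matrix(stats::rnorm(I * q), I, q,
                        dimnames = list(NULL, paste0("ec", seq_len(q)))))
}

#' Simulate a balanced multi-environment, multi-trait dataset
#'
#' Generates phenotypes from the multi-trait mixed model
#' `Y = 1 mu' + X_E beta_E + Z_L g + Z_EL gE + e` with
#' `g ~ MN(0, G, (1 - ge_fraction) * Sigma_T)` and
#' `gE ~ MN(0, K, ge_fraction * Sigma_T)`, where G is the VanRaden kernel of
#' the supplied markers, K the environment-major Kronecker kernel of the
#' environmental and genomic relationship matrices, and the residual
#' covariance is diagonal, chosen per trait so that the marginal
#' heritability — genetic (line + interaction) variance over total — equals
#' `h2`. Every line appears once in every environment (balanced layout, as
#' in the groundnut-style mid-sized trial the defaults mirror: J around 300,
#' I = 4, nT = 4). Environment main effects are drawn with standard
#' deviation `env_sd` times the genetic standard deviation; intercepts
#' default to 10 so that NRMSE (which divides by the observed mean) is
#' well-defined.
#'
#' @param markers A `marker_matrix` (provides J and G).
#' @param covs Optional `env_covariates` (provides I and H); when `NULL`,
#'   `I` environments with an identity H are used.
#' @param Sigma_T nT x nT PSD genetic trait covariance.
#' @param h2 Per-trait heritabilities in (0, 1) (recycled to nT).
#' @param ge_fraction Share of genetic variance allocated to the
#'   genotype-by-environment term, in [0, 1).
#' @param I Number of environments when `covs` is `NULL`.
#' @param mu Trait intercepts (recycled to nT).
#' @param env_sd Environment-effect standard deviation, as a multiple of the
#'   genetic standard deviation per trait.
#' @param seed Integer seed.
#' @return A list with `dataset` (an `aligned_dataset`) and `truth` (a
#'   `sim_truth` list: `Sigma_T_true`, `beta_E_true`, `g_true`, `gE_true`,
#'   `R_res_true`, `heritabilities`, `ge_fraction`, `mu_true`, `G`, `H`,
#'   `seed`).
#' @export
simulate_dataset <- function(markers, covs = NULL, Sigma_T, h2 = 0.5,
                             ge_fraction = 0.2, I = 4, mu = 10,
                             env_sd = 0.5, seed = 1) {
  stopifnot(inherits(markers, "marker_matrix"))
  Sigma_T <- as.matrix(Sigma_T)
  nT <- ncol(Sigma_T)
  if (max(abs(Sigma_T - t(Sigma_T))) > 1e-10) stop("Sigma_T must be symmetric")
  if (min(eigen(Sigma_T, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-8 * max(diag(Sigma_T))) {
    stop("Sigma_T must be positive semidefinite")
  }
  h2 <- rep_len(h2, nT)
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)")
  if (ge_fraction < 0 || ge_fraction >= 1) stop("ge_fraction must be in [0, 1)")
  mu <- rep_len(mu, nT)

  G <- vanraden_grm(markers)
  J <- length(markers$line_ids)
  if (is.null(covs)) {
    stopifnot(I >= 2)
    env_ids <- paste0("Env", seq_len(I))
    H <- identity_kernel(env_ids)
  } else {
    stopifnot(inherits(covs, "env_covariates"))
    env_ids <- covs$env_ids
    I <- length(env_ids)
    H <- env_kernel(covs)
  }

  set.seed(as.integer(seed))
  LG <- matrix_sqrt(G)
  LH <- matrix_sqrt(H)
  chol_psd <- function(S) {
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  }
  Lt <- chol_psd(Sigma_T)

  # g = L_G Z L_t' scaled by the main-effect share of Sigma_T
  g_true <- sqrt(1 - ge_fraction) *
    LG %*% matrix(stats::rnorm(J * nT), J, nT) %*% t(Lt)
  if (ge_fraction > 0) {
    Zmat <- matrix(stats::rnorm(I * J * nT), I * J, nT)
    # row-covariance factor of H (x) G applied blockwise: kron(LH, LG) Z
    gE_true <- matrix(0, I * J, nT)
    Zb <- lapply(seq_len(I), function(b)
      seq.int((b - 1L) * J + 1L, b * J))
    for (i in seq_len(I)) {
      acc <- matrix(0, J, nT)
      for (b in seq_len(I)) {
        if (abs(LH[i, b]) > 1e-14) {
          acc <- acc + LH[i, b] * (LG %*% Zmat[Zb[[b]], , drop = FALSE])
        }
      }
      gE_true[Zb[[i]], ] <- acc
    }
    gE_true <- sqrt(ge_fraction) * gE_true %*% t(Lt)
  } else {
    gE_true <- matrix(0, I * J, nT)
  }

  # residual variances set so each trait's marginal h2 holds on the
  # realized kernel scale (mean kernel diagonal = average effect variance)
  mdG <- mean(diag(G))
  mdK <- mean(diag(H)) * mdG
  gen_var <- (1 - ge_fraction) * diag(Sigma_T) * mdG +
    ge_fraction * diag(Sigma_T) * mdK
  res_var <- gen_var * (1 - h2) / h2
  R_res <- diag(res_var, nT)

  beta_E <- matrix(stats::rnorm(I * nT), I, nT) %*% diag(env_sd * sqrt(gen_var), nT)

  env_index <- rep(seq_len(I), each = J)
  line_index <- rep(seq_len(J), times = I)
  cell <- (env_index - 1L) * J + line_index
  eps <- matrix(stats::rnorm(I * J * nT), I * J, nT) %*% diag(sqrt(res_var), nT)
  Y <- matrix(rep(mu, each = I * J), I * J, nT) +
    beta_E[env_index, , drop = FALSE] +
    g_true[line_index, , drop = FALSE] +
    gE_true[cell, , drop = FALSE] + eps
  trait_names <- paste0("trait", seq_len(nT))
  dimnames(Y) <- list(NULL, trait_names)

  ds <- structure(list(
    Y = Y, env_index = env_index, line_index = line_index,
    env_ids = env_ids, line_ids = markers$line_ids,
    trait_names = trait_names, n_dropped = 0L
  ), class = "aligned_dataset")

  truth <- structure(list(
    Sigma_T_true = Sigma_T,
    beta_E_true = beta_E, g_true = g_true, gE_true = gE_true,
    R_res_true = R_res, heritabilities = h2, ge_fraction = ge_fraction,
    mu_true = mu, G = G, H = H, seed = as.integer(seed)
  ), class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> nT = ", ncol(x$Sigma_T_true), ", h2 = ",
      paste(format(x$heritabilities, digits = 2), collapse = ", "),
      ", ge_fraction = ", x$ge_fraction, "\n", sep = "")
  invisible(x)
}
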