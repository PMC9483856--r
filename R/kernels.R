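#' VanRaden genomic relationship matrix
#'
#' G = W W' / (2 * sum_k p_k (1 - p_k)), where W is the 0/1/2 marker matrix
#' with each column centered at twice its allele frequency p_k (column mean /
#' 2). Monomorphic markers carry no information and are excluded from both W
#' and the denominator; missing calls are mean-imputed per marker column
#' before centering. Columns of W are centered, so G has zero row sums.
#'
#' @param markers A `marker_matrix`.
#' @return A J x J labeled genomic relationship matrix.
#' @export
vanraden_grm <- function(markers) {
  stopifnot(inherits(markers, "marker_matrix"))
  codes <- markers$codes
  if (nrow(codes) < 2) stop("need at least 2 lines to build a GRM")
  # mean-impute missing calls per marker
  if (anyNA(codes)) {
    mu <- colMeans(codes, na.rm = TRUE)
    idx <- which(is.na(codes), arr.ind = TRUE)
    codes[idx] <- mu[idx[, 2]]
  }
  p <- colMeans(codes) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all markers are monomorphic; GRM denominator is zero")
  codes <- codes[, poly, drop = FALSE]
  p <- p[poly]
  W <- sweep(codes, 2, 2 * p, "-")
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(markers$line_ids, markers$line_ids)
  G
}

#' Environmental relationship matrix from covariates
#'
#' The environment-level analogue of the VanRaden kernel: each covariate is
#' standardized to mean 0, sd 1 across environments, and H = W_E W_E' / q'
#' where q' counts the non-constant covariates. Constant covariates are
#' dropped with a warning.
#'
#' @param covs An `env_covariates` object.
#' @return An I x I labeled environmental relationship matrix.
#' @export
env_kernel <- function(covs) {
  stopifnot(inherits(covs, "env_covariates"))
  vals <- covs$values
  if (nrow(vals) < 2) stop("need at least 2 environments")
  sds <- apply(vals, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) stop("all environmental covariates are constant")
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " constant covariate(s): ",
            paste(colnames(vals)[!keep], collapse = ", "))
  }
  W <- scale(vals[, keep, drop = FALSE])
  H <- tcrossprod(W) / ncol(W)
  dimnames(H) <- list(covs$env_ids, covs$env_ids)
  H
}

#' Identity kernel
#'
#' Used as the environmental relationship matrix when no environmental
#' covariates are available: environments are treated as mutually unrelated.
#'
#' @param labels Character vector of labels (e.g. environment ids).
#' @return A labeled identity matrix.
#' @export
identity_kernel <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1) stop("labels must be nonempty")
  K <- diag(length(labels))
  dimnames(K) <- list(labels, labels)
  K
}

#' Symmetric positive semidefinite square root of a kernel
#'
#' Spectral square root: K = U diag(lambda) U', L = U diag(sqrt(lambda)) U'.
#' Eigenvalues below `tol * max(lambda)` are clipped to zero, which keeps the
#' factorization defined for the rank-deficient relationship matrices typical
#' of line panels with fewer markers than lines (or centered GRMs, which are
#' always singular). A Cholesky factor would fail there; the spectral root is
#' also symmetric, so L L' = L'L = K.
#'
#' @param K Symmetric PSD matrix.
#' @param tol Relative eigenvalue clipping threshold.
#' @return The symmetric square root L, with `K`'s dimnames.
#' @export
matrix_sqrt <- function(K, tol = 1e-10) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K) || max(abs(K - t(K))) > 1e-10 * max(1, max(abs(K)))) {
    stop("K must be symmetric")
  }
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lam <- eig$values
  top <- max(lam, 0)
  if (any(lam < -tol * max(top, 1))) {
    stop("K is not positive semidefinite (eigenvalue ",
         format(min(lam)), ")")
  }
  lam[lam < tol * top] <- 0
  L <- eig$vectors %*% (sqrt(lam) * t(eig$vectors))
  dimnames(L) <- dimnames(K)
  L
}

#' Indicator design matrices for an aligned dataset
#'
#' Builds the 0/1 design matrices of the multi-environment model: `X_E`
#' (n x I, environments), `Z_L` (n x J, lines) and `Z_EL` (n x I*J, one
#' column per environment x line cell). Cells are indexed environment-major:
#' the (env i, line j) cell maps to column (i - 1) * J + j, the same
#' convention used for the Kronecker kernels.
#'
#' @param ds An `aligned_dataset`.
#' @return A list with `X_E`, `Z_L`, `Z_EL`.
#' @export
build_design <- function(ds) {
  stopifnot(inherits(ds, "aligned_dataset"))
  n <- nrow(ds$Y)
  I <- length(ds$env_ids)
  J <- length(ds$line_ids)
  X_E <- matrix(0, n, I, dimnames = list(NULL, ds$env_ids))
  X_E[cbind(seq_len(n), ds$env_index)] <- 1
  Z_L <- matrix(0, n, J, dimnames = list(NULL, ds$line_ids))
  Z_L[cbind(seq_len(n), ds$line_index)] <- 1
  cell <- (ds$env_index - 1L) * J + ds$line_index
  Z_EL <- matrix(0, n, I * J)
  Z_EL[cbind(seq_len(n), cell)] <- 1
  colnames(Z_EL) <- paste(rep(ds$env_ids, each = J),
                          rep(ds$line_ids, times = I), sep = ":")
  list(X_E = X_E, Z_L = Z_L, Z_EL = Z_EL)
}

#' Kernel-augmented predictor matrix for PLS
#'
#' Concatenates up to three blocks: the environment block `X_E L_E`, the
#' genomic block `Z_L L_g` and the interaction block `Z_EL (L_E o L_g)`
#' (Kronecker product, environment-major), where `L_g` and `L_E` are the
#' symmetric square roots of the genomic and environmental relationship
#' matrices. PLS takes a single predictor matrix, so the covariance structure
#' the GBLUP model encodes through kernels is injected by multiplying the
#' indicator designs with the kernel square roots: the Gram matrix of each
#' block then reproduces the corresponding kernel term.
#'
#' @param design Design list from [build_design()].
#' @param Lg J x J square root of the genomic relationship matrix (required
#'   for the G and GE blocks).
#' @param LE I x I square root of the environmental relationship matrix
#'   (required for the E and GE blocks).
#' @param config Predictor configuration: `"E+G"`, `"E+G+GE"` or `"G+GE"`.
#' @return A `predictor_matrix`: list with `X` (n x m), `block_spans` (named
#'   list of column index vectors) and `config`.
#' @export
build_pls_inputs <- function(design, Lg = NULL, LE = NULL,
                             config = c("E+G+GE", "E+G", "G+GE")) {
  config <- match.arg(config)
  blocks <- predictor_blocks(config)
  I <- ncol(design$X_E)
  J <- ncol(design$Z_L)
  if (any(c("E", "GE") %in% blocks) && is.null(LE)) {
    stop("config ", config, " requires the environmental factor LE")
  }
  if (any(c("G", "GE") %in% blocks) && is.null(Lg)) {
    stop("config ", config, " requires the genomic factor Lg")
  }
  if (!is.null(LE) && !all(dim(LE) == c(I, I))) stop("LE must be I x I")
  if (!is.null(Lg) && !all(dim(Lg) == c(J, J))) stop("Lg must be J x J")

  parts <- list()
  if ("E" %in% blocks) parts$E <- design$X_E %*% LE
  if ("G" %in% blocks) parts$G <- design$Z_L %*% Lg
  if ("GE" %in% blocks) {
    # row r of Z_EL %*% (LE %x% Lg) is kron(LE[env_r, ], Lg[line_r, ]):
    # build it by row-wise outer products instead of forming the I*J square
    env_index <- max.col(design$X_E)
    line_index <- max.col(design$Z_L)
    parts$GE <- LE[env_index, rep(seq_len(I), each = J), drop = FALSE] *
      Lg[line_index, rep(seq_len(J), times = I), drop = FALSE]
    colnames(parts$GE) <- colnames(design$Z_EL)
  }
  X <- do.call(cbind, parts)
  rownames(X) <- NULL
  widths <- vapply(parts, ncol, integer(1))
  ends <- cumsum(widths)
  spans <- Map(function(w, e) seq.int(e - w + 1L, e), widths, ends)
  structure(list(X = X, block_spans = spans, config = config),
            class = "predictor_matrix")
}

#' @export
print.predictor_matrix <- function(x, ...) {
  cat("<predictor_matrix> ", nrow(x$X), " x ", ncol(x$X),
      " (", x$config, "; blocks: ",
      paste(sprintf("%s=%d", names(x$block_spans),
                    lengths(x$block_spans)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

predictor_blocks <- function(config) {
  switch(config,
         "E+G"    = c("E", "G"),
         "E+G+GE" = c("E", "G", "GE"),
         "G+GE"   = c("G", "GE"),
         stop("unknown predictor configuration: ", config))
}
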