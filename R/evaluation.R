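#' Leave-one-environment-out folds
#'
#' One fold per environment: that environment's rows form the test set, the
#' remaining `I - 1` environments the training set. Together the test sets
#' partition the dataset.
#'
#' @param ds An `aligned_dataset` with at least two environments.
#' @return A list of length I; each element has `env` (held-out environment
#'   id), `train` and `test` (both `aligned_dataset`s).
#' @export
loeo_split <- function(ds) {
  stopifnot(inherits(ds, "aligned_dataset"))
  I <- length(ds$env_ids)
  if (I < 2) stop("leave-one-environment-out needs at least 2 environments")
  lapply(ds$env_ids, function(e) {
    list(env = e,
         train = subset_environments(ds, setdiff(ds$env_ids, e)),
         test = subset_environments(ds, e))
  })
}

#' Normalized root mean squared error
#'
#' `NRMSE = RMSE / mean(observed)`: the root mean squared prediction error
#' scaled by the mean of the observed values, making accuracies comparable
#' across traits measured in different units. Undefined when the observed
#' mean is (numerically) zero.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @return A single nonnegative number.
#' @export
#' @examples
#' nrmse(c(1, 2, 3), c(1, 2, 4))  # sqrt(1/3) / 2
nrmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 1) stop("empty input")
  ybar <- mean(observed)
  if (abs(ybar) <= 1e-12) {
    stop("mean of observed values is (near) zero; NRMSE undefined")
  }
  sqrt(mean((observed - predicted)^2)) / ybar
}

#' Relative efficiency of two NRMSE values
#'
#' `RE = nrmse_num / nrmse_den`. Values above 1 favor the denominator
#' method (it achieved the smaller error); equal inputs give 1, meaning the
#' two methods were equally efficient.
#'
#' @param nrmse_num,nrmse_den Positive NRMSE values (numerator and
#'   denominator of the ratio).
#' @return The quotient.
#' @export
relative_efficiency <- function(nrmse_num, nrmse_den) {
  if (any(c(nrmse_num, nrmse_den) <= 0)) {
    stop("relative efficiency requires strictly positive NRMSE values")
  }
  nrmse_num / nrmse_den
}

#' Benchmark settings
#'
#' @param tune_folds Folds of the nested cross-validation used to tune the
#'   number of PLS components on each training fold (default 5, the nested
#'   80/20 scheme; 10 reproduces plain 10-fold RMSEP tuning).
#' @param a_max Largest number of latent variables considered; `NULL` means
#'   `min(n_train - 1, m, 100)`.
#' @param gblup [gblup_control()] for the samplers (seed is re-derived per
#'   fold from `seed`).
#' @param seed Master seed; every source of randomness in the benchmark is
#'   derived from it deterministically.
#' @return A list of class `benchmark_settings`.
#' @export
benchmark_settings <- function(tune_folds = 5, a_max = NULL,
                               gblup = gblup_control(), seed = 1) {
  structure(list(tune_folds = as.integer(tune_folds), a_max = a_max,
                 gblup = gblup, seed = as.integer(seed)),
            class = "benchmark_settings")
}

#' Leave-one-environment-out benchmark of PLS and GBLUP predictors
#'
#' For every LOEO fold, predictor configuration and method: the PLS variants
#' tune the number of latent variables by nested cross-validation on the
#' training fold, refit on the whole training fold and predict the held-out
#' environment; the GBLUP variants fit the Gibbs sampler on the training
#' fold and predict the held-out environment. Multi-trait (MT) methods fit
#' all traits jointly; uni-trait (UT) methods fit one trait at a time with
#' the same predictor matrix (and per-trait tuning for UT-PLS). NRMSE is
#' computed per (environment, trait) on the test set; "AcrossTraits" rows
#' average the per-trait NRMSE of an environment and "Global" rows average
#' across environments, so every aggregate is re-derivable from the cell
#' rows. The efficiency table holds the GBLUP/PLS ratio within each
#' framework and the UT/MT ratio within each method family.
#'
#' @param ds An `aligned_dataset`.
#' @param markers A `marker_matrix` covering the dataset lines (used for the
#'   genomic relationship matrix).
#' @param covs Optional `env_covariates` for the environmental kernel;
#'   identity when `NULL`.
#' @param methods Subset of `c("MT-PLS", "UT-PLS", "MT-GBLUP", "UT-GBLUP")`.
#' @param predictors Subset of `c("E+G", "E+G+GE", "G+GE")`.
#' @param settings A [benchmark_settings()] list.
#' @return A `benchmark_result`: list with tibbles `results` (method,
#'   predictor, environment, trait, nrmse) and `efficiency` (comparison,
#'   predictor, environment, trait, re), plus a `manifest` of all settings.
#' @export
run_benchmark <- function(ds, markers, covs = NULL,
                          methods = c("MT-PLS", "UT-PLS",
                                      "MT-GBLUP", "UT-GBLUP"),
                          predictors = c("E+G", "E+G+GE", "G+GE"),
                          settings = benchmark_settings()) {
  stopifnot(inherits(ds, "aligned_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  predictors <- match.arg(predictors, several.ok = TRUE)
  I <- length(ds$env_ids)
  if (I < 2) stop("benchmark needs at least 2 environments")
  traits <- ds$trait_names

  # kernels over the full panel (marker data and environment covariates are
  # line-/environment-level inputs, not phenotypes: no test-set leakage)
  sub <- markers$line_ids %in% ds$line_ids
  mk <- marker_matrix(markers$line_ids[sub],
                      markers$codes[sub, , drop = FALSE])
  # reorder to dataset line order
  ord <- match(ds$line_ids, mk$line_ids)
  mk <- marker_matrix(mk$line_ids[ord], mk$codes[ord, , drop = FALSE])
  G <- vanraden_grm(mk)
  H <- if (is.null(covs)) identity_kernel(ds$env_ids) else env_kernel(covs)
  H <- H[ds$env_ids, ds$env_ids]
  Lg <- matrix_sqrt(G)
  LE <- matrix_sqrt(H)
  design_full <- build_design(ds)

  folds <- loeo_split(ds)
  rows <- list()
  for (pc in predictors) {
    Xfull <- build_pls_inputs(design_full, Lg = Lg, LE = LE, config = pc)$X
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      tr_rows <- ds$env_index != match(fold$env, ds$env_ids)
      Ytr <- ds$Y[tr_rows, , drop = FALSE]
      Yte <- ds$Y[!tr_rows, , drop = FALSE]
      te_lines <- ds$line_ids[ds$line_index[!tr_rows]]
      fold_seed <- as.integer((as.numeric(settings$seed) * 1009 + fi * 37 +
                                 match(pc, c("E+G", "E+G+GE", "G+GE"))) %%
                                2147483000)

      preds <- list()
      if (any(c("MT-PLS", "UT-PLS") %in% methods)) {
        Xtr <- Xfull[tr_rows, , drop = FALSE]
        Xte <- Xfull[!tr_rows, , drop = FALSE]
        a_cap <- if (is.null(settings$a_max)) {
          min(nrow(Xtr) - 1L, ncol(Xtr), 100L)
        } else settings$a_max
        if ("MT-PLS" %in% methods) {
          sel <- select_components(Xtr, Ytr, a_max = a_cap,
                                   folds = settings$tune_folds,
                                   seed = fold_seed)
          fit <- suppressWarnings(fit_pls(Xtr, Ytr, a = sel$chosen_a))
          preds[["MT-PLS"]] <- predict(fit, Xte)
        }
        if ("UT-PLS" %in% methods) {
          out <- matrix(NA_real_, nrow(Yte), ncol(Yte))
          for (k in seq_along(traits)) {
            yk <- Ytr[, k, drop = FALSE]
            sel <- select_components(Xtr, yk, a_max = a_cap,
                                     folds = settings$tune_folds,
                                     seed = fold_seed + k)
            fit <- suppressWarnings(fit_pls(Xtr, yk, a = sel$chosen_a))
            out[, k] <- predict(fit, Xte)
          }
          preds[["UT-PLS"]] <- out
        }
      }
      if (any(c("MT-GBLUP", "UT-GBLUP") %in% methods)) {
        Htr <- H[fold$train$env_ids, fold$train$env_ids, drop = FALSE]
        ctrl <- settings$gblup
        if ("MT-GBLUP" %in% methods) {
          ctrl$seed <- fold_seed + 101L
          fit <- fit_mt_gblup(fold$train, G, Htr, predictor = pc,
                              control = ctrl)
          preds[["MT-GBLUP"]] <- predict_gblup(fit, te_lines, fold$env, H)
        }
        if ("UT-GBLUP" %in% methods) {
          out <- matrix(NA_real_, nrow(Yte), ncol(Yte))
          for (k in seq_along(traits)) {
            ctrl$seed <- fold_seed + 200L + k
            ds_k <- fold$train
            ds_k$Y <- ds_k$Y[, k, drop = FALSE]
            ds_k$trait_names <- traits[k]
            fit <- fit_mt_gblup(ds_k, G, Htr, predictor = pc,
                                control = ctrl)
            out[, k] <- predict_gblup(fit, te_lines, fold$env, H)
          }
          preds[["UT-GBLUP"]] <- out
        }
      }
      for (mth in names(preds)) {
        for (k in seq_along(traits)) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            method = mth, predictor = pc, environment = fold$env,
            trait = traits[k],
            nrmse = nrmse(Yte[, k], preds[[mth]][, k]))
        }
      }
    }
  }
  cells <- dplyr::bind_rows(rows)

  # aggregates: AcrossTraits = mean over traits per environment;
  # Global = mean over environments (per trait, and of AcrossTraits cells)
  across <- cells |>
    dplyr::group_by(.data$method, .data$predictor, .data$environment) |>
    dplyr::summarise(nrmse = mean(.data$nrmse), .groups = "drop") |>
    dplyr::mutate(trait = "AcrossTraits")
  global_tr <- cells |>
    dplyr::group_by(.data$method, .data$predictor, .data$trait) |>
    dplyr::summarise(nrmse = mean(.data$nrmse), .groups = "drop") |>
    dplyr::mutate(environment = "Global")
  global_all <- across |>
    dplyr::group_by(.data$method, .data$predictor, .data$trait) |>
    dplyr::summarise(nrmse = mean(.data$nrmse), .groups = "drop") |>
    dplyr::mutate(environment = "Global")
  results <- dplyr::bind_rows(cells, across, global_tr, global_all) |>
    dplyr::select("method", "predictor", "environment", "trait", "nrmse") |>
    dplyr::arrange(.data$method, .data$predictor, .data$environment,
                   .data$trait)

  efficiency <- efficiency_table(results)
  manifest <- list(methods = methods, predictors = predictors,
                   seed = settings$seed, tune_folds = settings$tune_folds,
                   a_max = settings$a_max,
                   gblup = unclass(settings$gblup),
                   I = I, J = length(ds$line_ids), nT = length(traits),
                   n = nrow(ds$Y))
  structure(list(results = results, efficiency = efficiency,
                 manifest = manifest),
            class = "benchmark_result")
}

# relative-efficiency table from a results table: GBLUP/PLS within each
# framework (MT, UT) and UT/MT within each method family (PLS, GBLUP)
efficiency_table <- function(results) {
  pairs <- list(
    list(comparison = "GBLUP/PLS", scope = "MT",
         num = "MT-GBLUP", den = "MT-PLS"),
    list(comparison = "GBLUP/PLS", scope = "UT",
         num = "UT-GBLUP", den = "UT-PLS"),
    list(comparison = "UT/MT", scope = "PLS",
         num = "UT-PLS", den = "MT-PLS"),
    list(comparison = "UT/MT", scope = "GBLUP",
         num = "UT-GBLUP", den = "MT-GBLUP")
  )
  out <- list()
  for (p in pairs) {
    have <- results$method %in% c(p$num, p$den)
    if (length(unique(results$method[have])) < 2) next
    wide <- results |>
      dplyr::filter(.data$method %in% c(p$num, p$den)) |>
      tidyr::pivot_wider(names_from = "method", values_from = "nrmse")
    if (!all(c(p$num, p$den) %in% names(wide))) next
    out[[length(out) + 1L]] <- wide |>
      dplyr::mutate(comparison = p$comparison, scope = p$scope,
                    re = relative_efficiency(.data[[p$num]],
                                             .data[[p$den]])) |>
      dplyr::select("comparison", "scope", "predictor", "environment",
                    "trait", "re")
  }
  if (length(out) == 0) {
    return(tibble::tibble(comparison = character(), scope = character(),
                          predictor = character(), environment = character(),
                          trait = character(), re = numeric()))
  }
  dplyr::bind_rows(out)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat("<benchmark_result> ", nrow(x$results), " NRMSE cells (",
      paste(x$manifest$methods, collapse = ", "), "; ",
      paste(x$manifest$predictors, collapse = ", "), ")\n", sep = "")
  glob <- dplyr::filter(x$results, .data$environment == "Global",
                        .data$trait == "AcrossTraits")
  print(glob, n = nrow(glob))
  invisible(x)
}
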