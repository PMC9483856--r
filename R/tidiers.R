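#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted PLS model
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return A tibble with one row per (predictor column, response): `term`,
#'   `response`, `estimate` (coefficient on the standardized scale).
#' @export
tidy.pls_fit <- function(x, ...) {
  B <- x$B
  terms <- rownames(B) %||% paste0("x", seq_len(nrow(B)))
  resp <- x$trait_names %||% paste0("y", seq_len(ncol(B)))
  tibble::tibble(
    term = rep(terms, times = ncol(B)),
    response = rep(resp, each = nrow(B)),
    estimate = as.vector(B)
  )
}

#' Summarize a fitted PLS model
#'
#' @param x A `pls_fit`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, number of latent variables and the
#'   training RMSE on the original response scale.
#' @export
glance.pls_fit <- function(x, ...) {
  tibble::tibble(
    n = unname(x$dims["n"]), m = unname(x$dims["m"]),
    n_traits = unname(x$dims["nT"]), a = x$a,
    rmse_train = x$rmse_train
  )
}

#' Tidy a fitted Bayesian multi-trait GBLUP model
#'
#' @param x An `mt_gblup`.
#' @param ... Unused.
#' @return A tibble of posterior-mean effects: `effect` (intercept,
#'   environment, line, interaction), `level`, `trait`, `estimate`.
#' @export
tidy.mt_gblup <- function(x, ...) {
  nT <- length(x$mu)
  traits <- x$trait_names %||% paste0("trait", seq_len(nT))
  long <- function(M, effect, levels) {
    tibble::tibble(
      effect = effect,
      level = rep(levels, times = ncol(M)),
      trait = rep(traits, each = nrow(M)),
      estimate = as.vector(M)
    )
  }
  dplyr::bind_rows(
    tibble::tibble(effect = "intercept", level = traits, trait = traits,
                   estimate = unname(x$mu)),
    long(x$beta_E, "environment", x$env_ids),
    long(x$g_hat, "line", x$line_ids),
    long(x$gE_hat, "interaction", rownames(x$gE_hat))
  )
}

#' Summarize a fitted Bayesian multi-trait GBLUP model
#'
#' @param x An `mt_gblup`.
#' @param ... Unused.
#' @return One-row tibble: kept samples, predictor, per-trait posterior-mean
#'   genetic and residual variances and (for nT >= 2) the mean genetic
#'   correlation.
#' @export
glance.mt_gblup <- function(x, ...) {
  nT <- length(x$mu)
  gcor <- if (nT >= 2) {
    cm <- stats::cov2cor(x$Sigma_T)
    mean(cm[upper.tri(cm)])
  } else NA_real_
  tibble::tibble(
    samples_kept = x$samples_kept,
    predictor = x$predictor,
    mean_genetic_var = mean(diag(x$Sigma_T)),
    mean_residual_var = mean(diag(x$R_res)),
    mean_genetic_cor = gcor
  )
}

#' Tidy a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return The results tibble (method, predictor, environment, trait, nrmse).
#' @export
tidy.benchmark_result <- function(x, ...) x$results

#' Summarize a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return One row per (method, predictor) with the Global across-trait NRMSE.
#' @export
glance.benchmark_result <- function(x, ...) {
  x$results |>
    dplyr::filter(.data$environment == "Global",
                  .data$trait == "AcrossTraits") |>
    dplyr::select("method", "predictor", global_nrmse = "nrmse")
}

#' Plot benchmark NRMSE by environment and method
#'
#' Bar chart of per-environment NRMSE, faceted by trait and predictor
#' configuration. Aggregate rows ("Global", "AcrossTraits") are excluded.
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, ...) {
  dat <- object$results |>
    dplyr::filter(.data$environment != "Global",
                  .data$trait != "AcrossTraits")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$environment, y = .data$nrmse,
                                    fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_grid(trait ~ predictor) +
    ggplot2::labs(x = "held-out environment", y = "NRMSE", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the component-selection RMSEP curve
#'
#' @param object A `component_selection` from [select_components()].
#' @param ... Unused.
#' @return A ggplot object: RMSEP versus number of latent variables, with
#'   the chosen number marked.
#' @export
autoplot.component_selection <- function(object, ...) {
  dat <- tibble::tibble(a = seq_along(object$rmsep_by_a),
                        rmsep = object$rmsep_by_a)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$a, y = .data$rmsep)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_a, linetype = 2) +
    ggplot2::labs(x = "latent variables", y = "cross-validated RMSEP") +
    ggplot2::theme_minimal()
}
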