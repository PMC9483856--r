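#' Read a long-format phenotype table
#'
#' Reads a delimited text file (comma or tab, sniffed from the header line)
#' with one row per environment x line combination and one numeric column per
#' trait. Non-numeric trait cells (and the tokens in `na_tokens`) become
#' missing values; rows carrying missing traits are dropped later, at
#' alignment time.
#'
#' @param path Path to a delimited text file.
#' @param trait_columns Character vector naming the trait columns to keep.
#' @param env_col,line_col Names of the environment and line id columns.
#' @param na_tokens Strings treated as missing values.
#' @return A tibble with columns `env`, `line` and one column per trait,
#'   carrying the attribute `trait_names`. Duplicate (env, line) pairs are an
#'   error.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("env,line,yield,height",
#'              "E1,L1,5.1,98", "E1,L2,4.3,91", "E2,L1,6.0,99"), tf)
#' read_phenotypes(tf, c("yield", "height"))
read_phenotypes <- function(path, trait_columns, env_col = "env",
                            line_col = "line", na_tokens = c("NA", "")) {
  stopifnot(is.character(trait_columns), length(trait_columns) >= 1)
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- read_delimited(path, na_tokens)
  need <- c(env_col, line_col, trait_columns)
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    stop("phenotype file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tibble::tibble(
    env  = as.character(tab[[env_col]]),
    line = as.character(tab[[line_col]])
  )
  for (tr in trait_columns) {
    out[[tr]] <- suppressWarnings(as.numeric(as.character(tab[[tr]])))
  }
  dup <- duplicated(out[, c("env", "line")])
  if (any(dup)) {
    d <- out[which(dup)[1], ]
    stop("duplicated (env, line) pair in phenotype file: ",
         d$env, "/", d$line)
  }
  attr(out, "trait_names") <- trait_columns
  out
}

#' Read a line x marker genotype matrix coded 0/1/2
#'
#' @param path Path to a delimited file. For `dialect = "csv"` the first
#'   column holds line ids and the remaining columns marker codes. For
#'   `dialect = "plink_raw"` the six PLINK metadata columns
#'   (FID, IID, PAT, MAT, SEX, PHENOTYPE) lead; IID becomes the line id.
#' @param dialect Input dialect, `"csv"` or `"plink_raw"`.
#' @param na_tokens Strings treated as missing marker calls.
#' @return A `marker_matrix`: list with `line_ids` (character) and `codes`
#'   (integer matrix, entries in 0/1/2 or NA). Any other entry is an error
#'   reported with its row/column position.
#' @export
read_markers <- function(path, dialect = c("csv", "plink_raw"),
                         na_tokens = c("NA", "")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("marker file not found: ", path)
  tab <- read_delimited(path, na_tokens)
  if (dialect == "plink_raw") {
    if (ncol(tab) < 7) stop("plink_raw file must have > 6 columns")
    line_ids <- as.character(tab[[2]])
    codes <- as.matrix(tab[, -(1:6)])
  } else {
    line_ids <- as.character(tab[[1]])
    codes <- as.matrix(tab[, -1, drop = FALSE])
  }
  marker_names <- colnames(codes)
  codes <- suppressWarnings(matrix(as.numeric(codes), nrow = nrow(tab)))
  bad <- which(!is.na(codes) & !(codes %in% c(0, 1, 2)))
  if (length(bad) > 0) {
    i <- ((bad[1] - 1) %% nrow(codes)) + 1
    j <- ((bad[1] - 1) %/% nrow(codes)) + 1
    stop("marker code outside {0,1,2} at line ", line_ids[i],
         " (row ", i, "), marker column ", j)
  }
  marker_matrix(line_ids, codes, marker_names)
}

#' Construct a marker matrix object
#'
#' @param line_ids Character vector of unique line ids (length J).
#' @param codes J x p numeric matrix with entries in 0/1/2 or NA.
#' @param marker_names Optional marker names.
#' @return A `marker_matrix` object.
#' @export
marker_matrix <- function(line_ids, codes, marker_names = NULL) {
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("line ids must be unique")
  codes <- as.matrix(codes)
  if (nrow(codes) != length(line_ids)) {
    stop("codes must have one row per line id")
  }
  if (any(!is.na(codes) & !(codes %in% c(0, 1, 2)))) {
    stop("marker codes must be 0, 1, 2 or missing")
  }
  storage.mode(codes) <- "double"
  rownames(codes) <- line_ids
  if (!is.null(marker_names)) colnames(codes) <- marker_names
  structure(list(line_ids = line_ids, codes = codes),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("<marker_matrix> ", length(x$line_ids), " lines x ",
      ncol(x$codes), " markers; ", sum(is.na(x$codes)),
      " missing calls\n", sep = "")
  invisible(x)
}

#' Read an environment x covariate table
#'
#' First column holds environment ids; remaining columns are numeric
#' covariates. Missing values are an error after validation.
#'
#' @param path Path to a delimited text file.
#' @param na_tokens Strings treated as missing values.
#' @return An `env_covariates` object: list with `env_ids`, `values`
#'   (I x q matrix) and `covariate_names`.
#' @export
read_env_covariates <- function(path, na_tokens = c("NA", "")) {
  if (!file.exists(path)) stop("covariate file not found: ", path)
  tab <- read_delimited(path, na_tokens)
  env_ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[, -1, drop = FALSE])
  nm <- colnames(vals)
  vals <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(tab)))
  colnames(vals) <- nm
  env_covariates(env_ids, vals)
}

#' Construct an environment-covariate object
#'
#' @param env_ids Character vector of unique environment ids.
#' @param values I x q numeric matrix with no missing values.
#' @return An `env_covariates` object.
#' @export
env_covariates <- function(env_ids, values) {
  env_ids <- as.character(env_ids)
  if (anyDuplicated(env_ids)) stop("environment ids must be unique")
  values <- as.matrix(values)
  if (nrow(values) != length(env_ids)) {
    stop("values must have one row per environment")
  }
  if (anyNA(values)) stop("environmental covariates contain missing values")
  storage.mode(values) <- "double"
  rownames(values) <- env_ids
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("cov", seq_len(ncol(values)))
  }
  structure(list(env_ids = env_ids, values = values,
                 covariate_names = colnames(values)),
            class = "env_covariates")
}

#' Align phenotypes with markers into the canonical row ordering
#'
#' Rows are ordered first by environment, then by line ("environment-major"):
#' environments in order of first appearance in the phenotype table (or an
#' explicit `env_order`), lines in marker-file order. Records with any missing
#' trait value are dropped (listwise deletion; the count is messaged) so that
#' the phenotype matrix Y is complete, as both the PLS and the GBLUP model
#' require.
#'
#' @param pheno Tibble from [read_phenotypes()] (columns `env`, `line`,
#'   traits).
#' @param markers A `marker_matrix`; every phenotyped line must be present.
#' @param covs Optional `env_covariates`; every environment must be present.
#' @param env_order Optional explicit environment ordering.
#' @param trait_columns Optional trait column names; defaults to the
#'   `trait_names` attribute of `pheno`, else all non-id columns.
#' @return An `aligned_dataset`: list with `Y` (n x nT matrix), `env_index`,
#'   `line_index` (1-based into `env_ids` / `line_ids`), `env_ids`,
#'   `line_ids`, `trait_names`, `n_dropped`.
#' @export
align_dataset <- function(pheno, markers, covs = NULL, env_order = NULL,
                          trait_columns = NULL) {
  stopifnot(inherits(markers, "marker_matrix"))
  if (is.null(trait_columns)) {
    trait_columns <- attr(pheno, "trait_names")
  }
  if (is.null(trait_columns)) {
    trait_columns <- setdiff(names(pheno), c("env", "line"))
  }
  if (length(trait_columns) < 1) stop("no trait columns found")

  missing_lines <- setdiff(unique(pheno$line), markers$line_ids)
  if (length(missing_lines) > 0) {
    stop("phenotyped line(s) absent from marker data: ",
         paste(utils::head(missing_lines, 5), collapse = ", "))
  }
  env_ids <- if (is.null(env_order)) unique(pheno$env) else as.character(env_order)
  if (!all(pheno$env %in% env_ids)) {
    stop("env_order does not cover all environments in the phenotypes")
  }
  if (!is.null(covs)) {
    stopifnot(inherits(covs, "env_covariates"))
    missing_envs <- setdiff(env_ids, covs$env_ids)
    if (length(missing_envs) > 0) {
      stop("environment(s) absent from covariate table: ",
           paste(missing_envs, collapse = ", "))
    }
  }
  # lines in marker-file order, restricted to phenotyped lines
  line_ids <- markers$line_ids[markers$line_ids %in% unique(pheno$line)]

  Y <- as.matrix(pheno[, trait_columns, drop = FALSE])
  storage.mode(Y) <- "double"
  keep <- stats::complete.cases(Y)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("align_dataset: dropped ", n_dropped,
            " record(s) with missing trait values")
  }
  pheno <- pheno[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (nrow(Y) == 0) stop("no complete phenotype records remain after filtering")

  env_index <- match(pheno$env, env_ids)
  line_index <- match(pheno$line, line_ids)
  ord <- order(env_index, line_index)
  structure(list(
    Y = Y[ord, , drop = FALSE],
    env_index = env_index[ord],
    line_index = line_index[ord],
    env_ids = env_ids,
    line_ids = line_ids,
    trait_names = trait_columns,
    n_dropped = n_dropped
  ), class = "aligned_dataset")
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("<aligned_dataset> n = ", nrow(x$Y), " records, I = ",
      length(x$env_ids), " environments, J = ", length(x$line_ids),
      " lines, nT = ", ncol(x$Y), " trait(s)\n", sep = "")
  cat("  traits: ", paste(x$trait_names, collapse = ", "), "\n", sep = "")
  if (x$n_dropped > 0) cat("  dropped records:", x$n_dropped, "\n")
  invisible(x)
}

#' Tabular view of an aligned dataset
#'
#' @param x An `aligned_dataset`.
#' @param ... Unused.
#' @return A tibble with `env`, `line` and one column per trait, in the
#'   canonical environment-major row order.
#' @export
as_tibble.aligned_dataset <- function(x, ...) {
  out <- tibble::tibble(
    env = x$env_ids[x$env_index],
    line = x$line_ids[x$line_index]
  )
  for (k in seq_along(x$trait_names)) out[[x$trait_names[k]]] <- x$Y[, k]
  out
}

#' Subset an aligned dataset to a set of environments
#'
#' Keeps the canonical ordering; `env_ids` and environment indices are
#' re-numbered to the kept environments (order preserved), `line_ids` are
#' kept as-is so line effects remain comparable across subsets.
#'
#' @param ds An `aligned_dataset`.
#' @param envs Character vector of environment ids to keep.
#' @return An `aligned_dataset` restricted to `envs`.
#' @export
subset_environments <- function(ds, envs) {
  stopifnot(inherits(ds, "aligned_dataset"))
  envs <- as.character(envs)
  if (!all(envs %in% ds$env_ids)) stop("unknown environment id(s)")
  keep_env <- ds$env_ids[ds$env_ids %in% envs]  # preserve declared order
  rows <- ds$env_index %in% match(keep_env, ds$env_ids)
  structure(list(
    Y = ds$Y[rows, , drop = FALSE],
    env_index = match(ds$env_ids[ds$env_index[rows]], keep_env),
    line_index = ds$line_index[rows],
    env_ids = keep_env,
    line_ids = ds$line_ids,
    trait_names = ds$trait_names,
    n_dropped = 0L
  ), class = "aligned_dataset")
}

#' Write a results or phenotype table as CSV
#'
#' @param x A data frame (e.g. the results table of [run_benchmark()] or the
#'   tibble view of an aligned dataset).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  readr::write_csv(as.data.frame(x), path)
  invisible(path)
}

# comma/tab sniffing on the header line; returns a data.frame of characters
read_delimited <- function(path, na_tokens) {
  header <- readLines(path, n = 1L)
  delim <- if (lengths(regmatches(header, gregexpr("\t", header))) >
               lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  as.data.frame(readr::read_delim(
    path, delim = delim, na = na_tokens, col_types = readr::cols(.default = "c"),
    progress = FALSE, show_col_types = FALSE, trim_ws = TRUE
  ))
}
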