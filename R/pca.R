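#' Summarize a trait block by correlation-matrix PCA
#'
#' Principal component analysis on standardized variables (the correlation
#' matrix), with Kaiser retention (every retained eigenvalue > 1) or a fixed
#' number of components, a deterministic sign convention (each component is
#' oriented so its largest-magnitude loading is positive), and per-component
#' internal-consistency reliability (Cronbach's alpha over the variables
#' loading at least `alpha_loading` in absolute value).
#'
#' @param data A data frame.
#' @param vars Character vector of variable columns (default: all numeric
#'   columns).
#' @param retention `"kaiser"` (default) or `"fixed"`.
#' @param k Number of components when `retention = "fixed"`.
#' @param alpha_loading Absolute-loading threshold assigning variables to a
#'   component for the alpha computation (default 0.5).
#' @param labeller Optional function `f(loadings)` returning one display
#'   label per retained component (e.g. a sign-pattern rule naming a
#'   "Size" axis); default labels are `PC1`, `PC2`, ...
#' @return Object of class `pca_fit` with elements `eigenvalues` (all
#'   components), `loadings` and `scores` (retained, sign-fixed),
#'   `variance_explained` (percent, retained), `alpha` (per-component
#'   tibble), `component_names`, `vars`, `n`.
#' @export
fit_pca <- function(data, vars = NULL, retention = c("kaiser", "fixed"),
                    k = NULL, alpha_loading = 0.5, labeller = NULL) {
  retention <- match.arg(retention)
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort_schema(paste0("Unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  if (length(vars) < 2) abort_validation("PCA needs at least two variables.")
  x <- as.matrix(data[vars])
  if (anyNA(x)) abort_validation("PCA input contains missing values.")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    abort_validation(paste0("Constant variable(s): ",
                            paste(vars[sds == 0], collapse = ", ")))
  }
  if (nrow(x) <= length(vars)) {
    rlang::warn("Fewer observations than variables + 1; loadings are unstable.")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pc$sdev^2
  n_retain <- switch(retention,
    kaiser = max(1L, sum(ev > 1)),
    fixed = {
      if (is.null(k)) abort_validation("retention = \"fixed\" requires `k`.")
      min(as.integer(k), length(ev))
    }
  )
  idx <- seq_len(n_retain)
  load <- pc$rotation[, idx, drop = FALSE]
  scores <- pc$x[, idx, drop = FALSE]
  # orient each component so its largest-magnitude loading is positive
  for (j in idx) {
    top <- which.max(abs(load[, j]))
    if (load[top, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  comp_names <- if (!is.null(labeller)) labeller(load) else colnames(load)
  colnames(load) <- comp_names
  colnames(scores) <- comp_names

  alpha_tbl <- purrr::map_dfr(seq_len(n_retain), function(j) {
    items <- vars[abs(load[, j]) >= alpha_loading]
    a <- if (length(items) >= 2) cronbach_alpha(data, items) else NA_real_
    tibble::tibble(component = comp_names[j], n_items = length(items),
                   alpha = a)
  })

  structure(
    list(eigenvalues = ev,
         loadings = load,
         scores = scores,
         variance_explained = 100 * sum(ev[idx]) / length(ev),
         alpha = alpha_tbl,
         component_names = comp_names,
         vars = vars,
         center = pc$center,
         scale = pc$scale,
         n = nrow(x)),
    class = "pca_fit"
  )
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf(
    "Correlation-matrix PCA: %d variables, %d individuals, %d component(s) retained (%.1f%% of variance)\n",
    length(x$vars), x$n, length(x$component_names), x$variance_explained))
  cat("Eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items,
#' \eqn{\alpha = k/(k-1)\,(1 - \sum_i s_i^2 / s_{tot}^2)} where
#' \eqn{s_{tot}^2} is the variance of the item sum.
#'
#' @param data A data frame.
#' @param vars Character vector of >= 2 item columns (default: all numeric
#'   columns).
#' @return The alpha coefficient (scalar).
#' @export
cronbach_alpha <- function(data, vars = NULL) {
  if (is.null(vars)) vars <- names(data)[vapply(data, is.numeric, logical(1))]
  if (length(vars) < 2) abort_validation("Cronbach's alpha needs >= 2 items.")
  x <- as.matrix(data[vars])
  total_var <- stats::var(rowSums(x))
  if (total_var == 0) abort_validation("Zero total variance across items.")
  k <- ncol(x)
  k / (k - 1) * (1 - sum(apply(x, 2, stats::var)) / total_var)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a PCA summary
#'
#' `tidy()` returns the retained loadings in long form; `glance()` a one-row
#' model summary; `augment()` binds the retained scores to the original data.
#'
#' @param x A `pca_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pca_fit <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "variable") |>
    tidyr::pivot_longer(-"variable", names_to = "component",
                        values_to = "loading")
}

#' @rdname tidy.pca_fit
#' @exportS3Method generics::glance
glance.pca_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_vars = length(x$vars),
                 n_retained = length(x$component_names),
                 variance_explained = x$variance_explained,
                 min_alpha = suppressWarnings(min(x$alpha$alpha, na.rm = TRUE)))
}

#' @rdname tidy.pca_fit
#' @param data Data frame the scores are bound to (default: scores only).
#' @exportS3Method generics::augment
augment.pca_fit <- function(x, data = NULL, ...) {
  sc <- tibble::as_tibble(x$scores)
  names(sc) <- paste0(".", x$component_names)
  if (is.null(data)) return(sc)
  if (nrow(data) != nrow(sc)) {
    abort_validation("`data` must have the same rows as the fitted scores.")
  }
  dplyr::bind_cols(tibble::as_tibble(data), sc)
}
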