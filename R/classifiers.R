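# Wilks' lambda det(W)/det(T) for a variable set; returns NA on singular W/T.
wilks_lambda <- function(x, g) {
  x <- as.matrix(x)
  tot <- sweep(x, 2, colMeans(x))
  T_ <- crossprod(tot)
  W <- matrix(0, ncol(x), ncol(x))
  for (l in levels(g)) {
    xi <- x[g == l, , drop = FALSE]
    ci <- sweep(xi, 2, colMeans(xi))
    W <- W + crossprod(ci)
  }
  dT <- det(T_)
  dW <- det(W)
  if (dT <= 0) return(NA_real_)
  dW / dT
}

#' Stepwise discriminant-variable selection by Wilks' lambda
#'
#' Greedy forward selection with backward checks: at each step the candidate
#' minimizing \eqn{\Lambda = |W|/|T|} enters if its partial F-to-enter meets
#' the threshold; after every entry, any selected variable whose F-to-remove
#' falls below the removal threshold leaves again. A visited-set guard
#' enforces termination. The final discriminant function is summarized by
#' Bartlett's chi-squared, \eqn{\chi^2 = -(n - 1 - (p + k)/2)\ln\Lambda} on
#' `p` degrees of freedom (`p` selected variables, `k` groups).
#'
#' @param data A data frame.
#' @param vars Candidate variable columns.
#' @param label Unquoted two-class label column.
#' @param f_enter,f_remove Partial-F thresholds (defaults 3.84 / 2.71, the
#'   conventional stepwise defaults; `f_remove` must be < `f_enter`).
#' @return Object of class `stepwise_wilks`: `selected` (in entry order),
#'   `lambda`, `chi_square`, `df`, `p_value`, `steps` (per-step tibble with
#'   action, variable, lambda and partial F), `empty` flag.
#' @export
stepwise_wilks <- function(data, vars, label, f_enter = 3.84, f_remove = 2.71) {
  g <- factor(dplyr::pull(data, {{ label }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort_validation("Need >= 2 classes.")
  if (f_remove >= f_enter) {
    abort_validation("f_remove must be smaller than f_enter (termination).")
  }
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort_schema(paste0("Unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[vars])
  n <- nrow(x)
  k <- nlevels(g)

  lam_of <- function(set) {
    if (length(set) == 0) return(1)
    l <- unname(wilks_lambda(x[, set, drop = FALSE], g))
    if (is.na(l)) {
      abort_validation(paste0("Singular within-group SSCP for variable set {",
                              paste(set, collapse = ", "), "}."))
    }
    l
  }
  partial_f <- function(lam_small, lam_big, p_small) {
    # F for adding one variable to a p_small-variable model
    ((n - k - p_small) / (k - 1)) * (lam_small / lam_big - 1)
  }

  selected <- character(0)
  steps <- list()
  visited <- character(0)
  lam <- 1
  repeat {
    state <- paste(sort(selected), collapse = "|")
    if (state %in% visited) break
    visited <- c(visited, state)

    # entry phase
    cands <- setdiff(vars, selected)
    moved <- FALSE
    if (length(cands) > 0 && n - k - length(selected) > 0) {
      lams <- vapply(cands, function(v) lam_of(c(selected, v)), numeric(1))
      fs <- partial_f(lam, lams, length(selected))
      ok <- fs >= f_enter & lams < lam
      if (any(ok)) {
        best <- cands[ok][which.min(lams[ok])]
        lam_new <- unname(lams[cands == best])
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "enter", variable = best,
          lambda = lam_new, partial_f = unname(fs[cands == best]))
        selected <- c(selected, best)
        lam <- lam_new
        moved <- TRUE
      }
    }
    # removal phase
    if (length(selected) > 1) {
      repeat {
        lams_wo <- vapply(selected, function(v) lam_of(setdiff(selected, v)),
                          numeric(1))
        fs_rm <- partial_f(lam, lams_wo, length(selected) - 1)
        if (all(fs_rm >= f_remove)) break
        worst <- selected[which.min(fs_rm)]
        lam <- unname(lams_wo[selected == worst])
        steps[[length(steps) + 1]] <- tibble::tibble(
          step = length(steps) + 1L, action = "remove", variable = worst,
          lambda = lam, partial_f = min(fs_rm))
        selected <- setdiff(selected, worst)
        moved <- TRUE
        if (length(selected) <= 1) break
      }
    }
    if (!moved) break
  }

  p <- length(selected)
  chi <- if (p > 0) -(n - 1 - (p + k) / 2) * log(lam) else NA_real_
  structure(
    list(selected = selected,
         lambda = lam,
         chi_square = chi,
         df = p,
         p_value = if (p > 0) stats::pchisq(chi, p, lower.tail = FALSE)
                   else NA_real_,
         steps = if (length(steps)) dplyr::bind_rows(steps) else
           tibble::tibble(step = integer(), action = character(),
                          variable = character(), lambda = double(),
                          partial_f = double()),
         empty = p == 0,
         candidates = vars, n = n, k = k,
         f_enter = f_enter, f_remove = f_remove),
    class = "stepwise_wilks"
  )
}

#' @export
print.stepwise_wilks <- function(x, ...) {
  if (x$empty) {
    cat("Stepwise Wilks' lambda: no variable passed the entry threshold.\n")
  } else {
    cat(sprintf(
      "Stepwise Wilks' lambda: selected %s; lambda = %.4f, chi-squared(%d) = %.3f, p = %.4g\n",
      paste(x$selected, collapse = " + "), x$lambda, x$df, x$chi_square,
      x$p_value))
  }
  invisible(x)
}

#' @rdname tidy.pca_fit
#' @exportS3Method generics::tidy
tidy.stepwise_wilks <- function(x, ...) x$steps

#' @rdname tidy.pca_fit
#' @exportS3Method generics::glance
glance.stepwise_wilks <- function(x, ...) {
  tibble::tibble(n_selected = x$df, lambda = x$lambda,
                 chi_square = x$chi_square, df = x$df, p_value = x$p_value,
                 n = x$n)
}

# Assemble a classification report from per-individual predictions.
make_classification_report <- function(per_individual, engine, trait_set,
                                       details = list()) {
  pi <- per_individual
  classes <- sort(unique(pi$truth))
  per_class <- purrr::map_dfr(classes, function(cl) {
    sel <- pi$truth == cl
    tibble::tibble(class = cl, n = sum(sel), n_correct = sum(pi$correct[sel]),
                   rate = 100 * mean(pi$correct[sel]))
  })
  structure(
    list(engine = engine,
         trait_set = trait_set,
         hybrids_included = any(pi$is_hybrid),
         per_individual = pi,
         per_class = per_class,
         rate_global = 100 * mean(pi$correct),
         n = nrow(pi),
         n_misclassified = sum(!pi$correct),
         n_misclassified_hybrids = sum(!pi$correct & pi$is_hybrid),
         details = details),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf(
    "%s classification report (%s, hybrids %s): global rate %.1f%% (n = %d, %d misclassified, %d hybrid)\n",
    x$engine, x$trait_set, if (x$hybrids_included) "included" else "excluded",
    x$rate_global, x$n, x$n_misclassified, x$n_misclassified_hybrids))
  print(x$per_class)
  invisible(x)
}

#' @rdname tidy.pca_fit
#' @exportS3Method generics::tidy
tidy.classification_report <- function(x, ...) x$per_class

#' @rdname tidy.pca_fit
#' @exportS3Method generics::glance
glance.classification_report <- function(x, ...) {
  tibble::tibble(engine = x$engine, trait_set = x$trait_set,
                 hybrids_included = x$hybrids_included,
                 rate_global = x$rate_global, n = x$n,
                 n_misclassified = x$n_misclassified,
                 n_misclassified_hybrids = x$n_misclassified_hybrids)
}

#' Per-class correct-classification rate
#'
#' @param report A `classification_report`.
#' @param class Class label (e.g. `"isabellinus"`).
#' @return Percentage of that class's individuals classified correctly.
#' @export
class_rate <- function(report, class) {
  pc <- report$per_class
  if (!class %in% pc$class) abort_validation(paste0("No class `", class, "`."))
  pc$rate[pc$class == class]
}

#' Quadratic discriminant classification with leave-one-out cross-validation
#'
#' Each individual is classified by quadratic discriminant scores fitted on
#' all other individuals (via [MASS::qda()] with `CV = TRUE`). Priors are
#' equal by default; proportional priors are available.
#'
#' @param data A data frame containing `vars`, the label column, and
#'   (optionally) `individual_id` and `is_hybrid`.
#' @param vars Predictor variable columns.
#' @param label Unquoted class-label column (the molecular species label).
#' @param priors `"equal"` (default) or `"proportional"`.
#' @param trait_set Display label stored in the report.
#' @return A `classification_report` with `engine = "DFA"`.
#' @export
qda_crossval <- function(data, vars, label, priors = c("equal", "proportional"),
                         trait_set = "morphometry") {
  priors <- match.arg(priors)
  g <- factor(dplyr::pull(data, {{ label }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort_validation("Need >= 2 classes.")
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort_schema(paste0("Unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[vars])
  ns <- table(g)
  if (any(ns <= length(vars))) {
    abort_validation(paste0(
      "QDA needs every class size > number of predictors; offending class(es): ",
      paste(names(ns)[ns <= length(vars)], collapse = ", ")))
  }
  prior <- if (priors == "equal") rep(1 / nlevels(g), nlevels(g)) else
    as.numeric(ns / sum(ns))
  fit <- tryCatch(
    MASS::qda(x, g, prior = prior, CV = TRUE),
    error = function(e) {
      abort_validation(paste0("QDA failed (singular class covariance in a ",
                              "leave-one-out fold?): ", conditionMessage(e)))
    }
  )
  pred <- as.character(fit$class)
  pi <- tibble::tibble(
    individual_id = if ("individual_id" %in% names(data))
      as.character(data$individual_id) else as.character(seq_along(g)),
    truth = as.character(g),
    predicted = pred,
    correct = pred == as.character(g),
    is_hybrid = if ("is_hybrid" %in% names(data))
      as.logical(data$is_hybrid) else FALSE
  )
  make_classification_report(pi, engine = "DFA", trait_set = trait_set,
                             details = list(vars = vars, priors = priors,
                                            cv = "leave-one-out"))
}

#' Configure the SVM ensemble
#'
#' @param gamma Radial-kernel gamma grid (default `c(0.1, 1, 10, 100, 1000)`).
#' @param n_restarts Reinitializations per gamma (default 20).
#' @param cost Soft-margin cost C (default 1).
#' @param restart_scheme What varies between restarts: `"bootstrap"`
#'   (stratified bootstrap resample of the training set, default),
#'   `"subsample"` (stratified random 80% subsample) or `"none"`
#'   (every restart fits the full data; deterministic members).
#' @param seed Integer seed for the restart stream.
#' @return Object of class `svm_config`.
#' @export
svm_config <- function(gamma = c(0.1, 1, 10, 100, 1000), n_restarts = 20,
                       cost = 1, restart_scheme = c("bootstrap", "subsample",
                                                    "none"),
                       seed = 1L) {
  restart_scheme <- match.arg(restart_scheme)
  if (any(gamma <= 0)) abort_validation("gamma values must be positive.")
  if (n_restarts < 1) abort_validation("n_restarts must be >= 1.")
  if (cost <= 0) abort_validation("cost must be positive.")
  structure(list(gamma = gamma, n_restarts = as.integer(n_restarts),
                 cost = cost, restart_scheme = restart_scheme,
                 seed = as.integer(seed)),
            class = "svm_config")
}

# Stratified resample indices for one restart.
restart_rows <- function(y, scheme) {
  idx <- switch(scheme,
    none = seq_along(y),
    bootstrap = unlist(lapply(levels(y), function(l) {
      w <- which(y == l)
      sample(w, length(w), replace = TRUE)
    }), use.names = FALSE),
    subsample = unlist(lapply(levels(y), function(l) {
      w <- which(y == l)
      sample(w, max(1L, floor(0.8 * length(w))))
    }), use.names = FALSE)
  )
  sort(idx)
}

# Combine per-class ensemble claims into the single-claim correctness rule:
# an individual is correct iff exactly one class claims it and that class is
# the molecular label; zero or multiple claims count as misclassified.
combine_claims <- function(claims, truth, is_hybrid, individual_id = NULL) {
  stopifnot(is.matrix(claims), nrow(claims) == length(truth))
  n_claims <- rowSums(claims)
  predicted <- ifelse(n_claims == 1,
                      colnames(claims)[apply(claims, 1, function(r)
                        if (sum(r) == 1) which(r) else NA_integer_)],
                      NA_character_)
  tibble::tibble(
    individual_id = if (is.null(individual_id)) as.character(seq_along(truth))
                    else as.character(individual_id),
    truth = as.character(truth),
    predicted = predicted,
    n_claims = as.integer(n_claims),
    correct = n_claims == 1 & !is.na(predicted) & predicted == as.character(truth),
    is_hybrid = as.logical(is_hybrid)
  )
}

#' Radial-kernel SVM ensemble with a single-claim acceptance rule
#'
#' For each class, one-vs-rest support vector machines with a radial basis
#' kernel are trained over the full gamma grid crossed with `n_restarts`
#' stochastic reinitializations (see [svm_config()]). A class ensemble
#' "claims" an individual when strictly more than half of its member
#' classifiers predict that class. An individual is counted as classified
#' correctly only if exactly one class claims it and that class matches the
#' molecular label; individuals claimed by zero or several classes are
#' misclassified.
#'
#' @param data A data frame containing `vars` (typically retained PCA
#'   scores), the label column, and optionally `individual_id`/`is_hybrid`.
#' @param vars Predictor columns.
#' @param label Unquoted class-label column.
#' @param config An [svm_config()].
#' @param trait_set Display label stored in the report.
#' @return A `classification_report` with `engine = "SVM"` and a
#'   `per_individual` table including the number of claiming classes.
#' @export
svm_ensemble <- function(data, vars, label, config = svm_config(),
                         trait_set = "morphometry") {
  stopifnot(inherits(config, "svm_config"))
  g <- factor(dplyr::pull(data, {{ label }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort_validation("Need >= 2 classes.")
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort_schema(paste0("Unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(data[vars])
  if (!all(is.finite(x))) abort_validation("Predictors must be finite.")
  classes <- levels(g)
  n_members <- length(config$gamma) * config$n_restarts

  set.seed(config$seed)
  claims <- matrix(FALSE, nrow(x), length(classes),
                   dimnames = list(NULL, classes))
  for (cl in classes) {
    yc <- factor(ifelse(g == cl, cl, ".rest"), levels = c(cl, ".rest"))
    votes <- integer(nrow(x))
    for (gamma in config$gamma) {
      for (r in seq_len(config$n_restarts)) {
        rows <- restart_rows(yc, config$restart_scheme)
        fit <- e1071::svm(x[rows, , drop = FALSE], yc[rows],
                          type = "C-classification", kernel = "radial",
                          gamma = gamma, cost = config$cost, scale = FALSE)
        pred <- stats::predict(fit, x)
        votes <- votes + as.integer(pred == cl)
      }
    }
    claims[, cl] <- votes > n_members / 2
  }
  pi <- combine_claims(
    claims, truth = g,
    is_hybrid = if ("is_hybrid" %in% names(data))
      as.logical(data$is_hybrid) else FALSE,
    individual_id = if ("individual_id" %in% names(data))
      data$individual_id else NULL
  )
  make_classification_report(pi, engine = "SVM", trait_set = trait_set,
                             details = list(vars = vars, config = config,
                                            n_members_per_class = n_members))
}
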