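#' Kruskal-Wallis rank test with tie correction
#'
#' Omnibus non-parametric comparison of a trait across groups. The statistic
#' is the midrank H divided by the tie-correction factor
#' \eqn{1 - \sum (t^3 - t)/(N^3 - N)}; the p-value uses the chi-squared
#' approximation on \eqn{k - 1} degrees of freedom.
#'
#' @param data A data frame.
#' @param value,group Unquoted columns holding the measurement and the
#'   group label.
#' @return One-row tibble: `statistic`, `statistic_name`, `df1`, `df2`,
#'   `p_value`, `n`, `method`.
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  check_two_groups(v, g, min_total = 3)
  if (length(unique(v)) == 1L) {
    rlang::abort("All values identical: tie correction degenerates, H undefined.",
                 class = "morphoverlap_degenerate_data")
  }
  res <- stats::kruskal.test(v, g)
  test_row(unname(res$statistic), "H", df1 = unname(res$parameter), df2 = NA_real_,
           p_value = res$p.value, n = length(v),
           method = "Kruskal-Wallis rank sum test, tie-corrected")
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA, F = MSB/MSW on (k-1, N-k)
#' degrees of freedom.
#'
#' @inheritParams kruskal_wallis
#' @return One-row tibble as in [kruskal_wallis()].
#' @export
one_way_anova <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  check_two_groups(v, g)
  if (length(v) - nlevels(g) < 1) {
    abort_validation("Residual degrees of freedom must be >= 1.")
  }
  a <- stats::anova(stats::lm(v ~ g))
  f <- a$`F value`[1]
  if (is.nan(f)) {
    # no between- and no within-group variation
    if (a$`Sum Sq`[1] < 1e-12 && a$`Sum Sq`[2] < 1e-12) {
      rlang::abort("F undefined: zero between- and within-group variance.",
                   class = "morphoverlap_degenerate_data")
    }
  }
  test_row(f, "F", df1 = a$Df[1], df2 = a$Df[2], p_value = a$`Pr(>F)`[1],
           n = length(v), method = "One-way ANOVA")
}

#' Pairwise post-hoc comparisons
#'
#' All unordered group pairs after an omnibus test. `method = "LSD"` is
#' Fisher's least significant difference: unadjusted two-sided t tests on the
#' pooled within-group variance (the ANOVA mean square error). Applied with
#' `scale = "ranks"` it operates on midranks (Conover-style follow-up to a
#' Kruskal-Wallis omnibus). `method = "TukeyHSD"` uses the studentized-range
#' adjustment via [stats::TukeyHSD()].
#'
#' @inheritParams kruskal_wallis
#' @param method `"LSD"` or `"TukeyHSD"`.
#' @param scale Analyse raw values (default) or midranks.
#' @return Tibble with one row per group pair: `group_a`, `group_b`,
#'   `estimate` (mean difference a - b on the analysis scale), `p_value`,
#'   `adjustment`.
#' @export
posthoc <- function(data, value, group, method = c("LSD", "TukeyHSD"),
                    scale = c("raw", "ranks")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  check_two_groups(v, g)
  if (any(table(g) < 2)) {
    abort_validation("Every group needs >= 2 observations for variance-based post hocs.")
  }
  if (scale == "ranks") v <- rank(v)
  k <- nlevels(g)
  n <- length(v)
  means <- tapply(v, g, mean)
  ns <- tapply(v, g, length)
  msw <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / (n - k)
  pairs <- utils::combn(levels(g), 2)
  if (method == "LSD") {
    out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      est <- means[[a]] - means[[b]]
      se <- sqrt(msw * (1 / ns[[a]] + 1 / ns[[b]]))
      p <- if (se == 0) as.numeric(est == 0) else
        2 * stats::pt(-abs(est / se), df = n - k)
      tibble::tibble(group_a = a, group_b = b, estimate = est,
                     p_value = p, adjustment = "LSD")
    })
  } else {
    fit <- stats::aov(v ~ g)
    tk <- stats::TukeyHSD(fit)$g
    out <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      key <- if (paste0(a, "-", b) %in% rownames(tk)) paste0(a, "-", b)
             else paste0(b, "-", a)
      sgn <- if (startsWith(key, a)) 1 else -1
      tibble::tibble(group_a = a, group_b = b,
                     estimate = sgn * tk[key, "diff"],
                     p_value = tk[key, "p adj"], adjustment = "TukeyHSD")
    })
  }
  out
}

#' Box's M test of covariance homogeneity
#'
#' Tests equality of the group covariance matrices,
#' \eqn{M = (N-k)\ln|S_p| - \sum_i (n_i-1)\ln|S_i|}, with Box's F
#' approximation (fractional denominator df) by default or the chi-squared
#' approximation on request.
#'
#' @param data A data frame.
#' @param group Unquoted grouping column.
#' @param vars Character vector of variable columns (default: all numeric
#'   columns except the group).
#' @param approx `"F"` (default) or `"chisq"`.
#' @return One-row tibble: `statistic` (M), `statistic_name`, `f_statistic`
#'   (or chi-squared value), `df1`, `df2`, `p_value`, `n`, `method`.
#' @export
box_m <- function(data, group, vars = NULL, approx = c("F", "chisq")) {
  approx <- match.arg(approx)
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  vars <- resolve_vars(data, {{ group }}, vars)
  x <- as.matrix(data[vars])
  k <- nlevels(g)
  p <- ncol(x)
  ns <- tapply(seq_along(g), g, length)
  if (any(ns <= p)) {
    abort_validation(paste0(
      "Box's M needs every group size > number of variables; offending group(s): ",
      paste(names(ns)[ns <= p], collapse = ", ")))
  }
  n <- nrow(x)
  covs <- lapply(levels(g), function(l) stats::cov(x[g == l, , drop = FALSE]))
  names(covs) <- levels(g)
  logdets <- vapply(levels(g), function(l) {
    d <- determinant(covs[[l]], logarithm = TRUE)
    if (d$sign <= 0) {
      abort_validation(paste0("Singular covariance matrix in group `", l, "`."))
    }
    as.numeric(d$modulus)
  }, numeric(1))
  pooled <- Reduce(`+`, Map(function(S, ni) (ni - 1) * S, covs, ns)) / (n - k)
  dp <- determinant(pooled, logarithm = TRUE)
  if (dp$sign <= 0) abort_validation("Singular pooled covariance matrix.")
  M <- (n - k) * as.numeric(dp$modulus) - sum((ns - 1) * logdets)
  M <- max(M, 0)

  c1 <- (sum(1 / (ns - 1)) - 1 / (n - k)) *
    (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1))
  df1 <- p * (p + 1) * (k - 1) / 2
  if (approx == "chisq") {
    chi <- M * (1 - c1)
    return(test_row(M, "M", df1 = df1, df2 = NA_real_,
                    p_value = stats::pchisq(chi, df1, lower.tail = FALSE),
                    n = n, method = "Box's M, chi-squared approximation",
                    f_statistic = chi))
  }
  c2 <- (sum(1 / (ns - 1)^2) - 1 / (n - k)^2) *
    (p - 1) * (p + 2) / (6 * (k - 1))
  df2 <- (df1 + 2) / abs(c2 - c1^2)
  if (c2 > c1^2) {
    a1 <- df1 / (1 - c1 - df1 / df2)
    f <- M / a1
  } else {
    b <- df2 / (1 - c1 + 2 / df2)
    f <- df2 * M / (df1 * (b - M))
  }
  test_row(M, "M", df1 = df1, df2 = df2,
           p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
           n = n, method = "Box's M, F approximation", f_statistic = f)
}

#' Permutation MANOVA on Euclidean distances
#'
#' Non-parametric multivariate comparison of group centroids: the total
#' squared Euclidean distance is partitioned into between- and within-group
#' components, the pseudo-F is
#' \eqn{(SS_B/(k-1)) / (SS_W/(N-k))}, and significance comes from random
#' relabellings, \eqn{p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})}. With
#' `exhaustive = TRUE` (two groups only) every distinct relabelling is
#' enumerated and the p-value is exact.
#'
#' @inheritParams box_m
#' @param n_perm Number of random permutations (>= 99; default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param exhaustive Enumerate all relabellings (two-group designs only).
#' @return One-row tibble: pseudo-F, df, `p_value`, `n`, `method`.
#' @export
permutation_manova <- function(data, group, vars = NULL, n_perm = 9999,
                               seed = 1L, exhaustive = FALSE) {
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  vars <- resolve_vars(data, {{ group }}, vars)
  x <- as.matrix(data[vars])
  if (nlevels(g) < 2) abort_validation("Need >= 2 groups.")
  if (!exhaustive && n_perm < 99) abort_validation("n_perm must be >= 99.")
  n <- nrow(x)
  k <- nlevels(g)

  pseudo_f <- function(labels) {
    ssw <- 0
    for (l in levels(labels)) {
      xi <- x[labels == l, , drop = FALSE]
      ssw <- ssw + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    sst <- sum(sweep(x, 2, colMeans(x))^2)
    ssb <- sst - ssw
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- pseudo_f(g)

  if (exhaustive) {
    if (k != 2) abort_validation("Exhaustive enumeration supports two groups only.")
    n1 <- sum(g == levels(g)[1])
    sets <- utils::combn(n, n1)
    f_all <- apply(sets, 2, function(idx) {
      lab <- factor(ifelse(seq_len(n) %in% idx, levels(g)[1], levels(g)[2]),
                    levels = levels(g))
      pseudo_f(lab)
    })
    p <- mean(f_all >= f_obs - 1e-12)
    return(test_row(f_obs, "pseudo-F", df1 = k - 1, df2 = n - k, p_value = p,
                    n = n, method = sprintf(
                      "Permutation MANOVA (Euclidean), exhaustive (%d relabellings)",
                      ncol(sets))))
  }
  set.seed(seed)
  f_perm <- vapply(seq_len(n_perm), function(i) {
    pseudo_f(factor(sample(as.character(g)), levels = levels(g)))
  }, numeric(1))
  p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
  test_row(f_obs, "pseudo-F", df1 = k - 1, df2 = n - k, p_value = p, n = n,
           method = sprintf(
             "Permutation MANOVA (Euclidean), %d permutations, seed %d",
             n_perm, seed))
}

#' Classical MANOVA (Wilks' lambda)
#'
#' Parametric multivariate comparison of group mean vectors, reporting
#' Wilks' \eqn{\Lambda = |W|/|T|} and its F approximation. Intended for
#' retained PCA axes; covariance homogeneity should be screened with
#' [box_m()] first (a warning-level gate, not enforced).
#'
#' @inheritParams box_m
#' @return One-row tibble: `statistic` (approximating F), `wilks`, `df1`,
#'   `df2`, `p_value`, `n`, `method`.
#' @export
classical_manova <- function(data, group, vars = NULL) {
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  vars <- resolve_vars(data, {{ group }}, vars)
  x <- as.matrix(data[vars])
  if (nlevels(g) < 2) abort_validation("Need >= 2 groups.")
  if (nrow(x) < ncol(x) + nlevels(g)) {
    abort_validation("Too few observations for the number of components and groups.")
  }
  if (ncol(x) == 1) {
    # single response: Wilks reduces to SSW/SST and F to the one-way ANOVA F
    a <- stats::anova(stats::lm(x[, 1] ~ g))
    out <- test_row(a$`F value`[1], "F", df1 = a$Df[1], df2 = a$Df[2],
                    p_value = a$`Pr(>F)`[1], n = nrow(x),
                    method = "MANOVA, Wilks' lambda F approximation")
    out$wilks <- a$`Sum Sq`[2] / sum(a$`Sum Sq`)
    return(out)
  }
  fit <- stats::manova(x ~ g)
  s <- summary(fit, test = "Wilks")$stats
  out <- test_row(unname(s["g", "approx F"]), "F",
                  df1 = unname(s["g", "num Df"]), df2 = unname(s["g", "den Df"]),
                  p_value = unname(s["g", "Pr(>F)"]), n = nrow(x),
                  method = "MANOVA, Wilks' lambda F approximation")
  out$wilks <- unname(s["g", "Wilks"])
  out
}

# ---- internal helpers -------------------------------------------------------

test_row <- function(statistic, statistic_name, df1, df2, p_value, n, method,
                     f_statistic = NULL) {
  out <- tibble::tibble(statistic = statistic, statistic_name = statistic_name,
                        df1 = df1, df2 = df2, p_value = p_value,
                        n = as.integer(n), method = method)
  if (!is.null(f_statistic)) out$f_statistic <- f_statistic
  out
}

check_two_groups <- function(v, g, min_total = 2) {
  if (nlevels(g) < 2) {
    abort_validation("Need at least two groups.")
  }
  if (length(v) < min_total) {
    abort_validation(paste0("Need at least ", min_total, " observations."))
  }
  if (any(tapply(v, g, length) < 1)) {
    abort_validation("Every group needs at least one observation.")
  }
  invisible(NULL)
}

resolve_vars <- function(data, group, vars) {
  gname <- rlang::as_name(rlang::enquo(group))
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
    vars <- setdiff(vars, gname)
  }
  missing <- setdiff(vars, names(data))
  if (length(missing)) {
    abort_schema(paste0("Unknown variable(s): ", paste(missing, collapse = ", ")))
  }
  vars
}
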