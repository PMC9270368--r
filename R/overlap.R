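#' Overlap and hybrid contribution from a classification report
#'
#' Overlap between the two species in sympatry is defined as
#' `100 - rate_global` of a with-hybrids classification run. The hybrids'
#' contribution to that overlap is the percentage of molecularly confirmed
#' hybrids among the misclassified individuals of the same run.
#'
#' @param report A `classification_report` with hybrids included.
#' @return A percentage.
#' @export
overlap_from_report <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  100 - report$rate_global
}

#' @rdname overlap_from_report
#' @export
hybrid_contribution <- function(report) {
  stopifnot(inherits(report, "classification_report"))
  if (!report$hybrids_included) {
    abort_validation("Hybrid contribution requires a with-hybrids run.")
  }
  if (report$n_misclassified == 0) {
    rlang::warn("No misclassified individuals: hybrid contribution undefined, returning 0.")
    return(0)
  }
  100 * report$n_misclassified_hybrids / report$n_misclassified
}

#' Mean and sample standard deviation
#'
#' The cross-method aggregation used for overlap and contribution values:
#' arithmetic mean with the n-1 sample standard deviation.
#'
#' @param values Numeric vector (>= 2 values for the sd).
#' @return One-row tibble: `mean`, `sd`, `n`.
#' @export
aggregate_rates <- function(values) {
  if (length(values) < 2) {
    abort_validation("Aggregation needs >= 2 values for a sample sd.")
  }
  tibble::tibble(mean = mean(values), sd = stats::sd(values),
                 n = length(values))
}

#' Published classification rates for the Iberian Eptesicus contact zone
#'
#' The reference engine x trait-set grid of correct-classification rates,
#' overlap and hybrid-contribution percentages for sympatric *E. isabellinus*
#' and *E. serotinus* (DFA and SVM on morphometry and colour, with and
#' without hybrids), shipped as plain CSV. Used to validate the aggregation
#' and comparison arithmetic against the published summary statistics.
#'
#' @return Tibble with columns `trait_set`, `engine`, the four per-species
#'   rates (with/without hybrids), both global rates and the published
#'   hybrid-contribution value.
#' @export
reference_rates <- function() {
  path <- system.file("extdata", "eptesicus_reference_rates.csv",
                      package = "morphoverlap", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Summarize a rates grid into an overlap report
#'
#' Takes an engine x trait-set grid of classification rates (as produced by
#' [run_overlap_study()] or shipped via [reference_rates()]), derives the
#' overlap column (`100 - rate_global`), the cross-method aggregates
#' (mean +/- sample sd of overlap and contribution, overall and per trait
#' set) and the comparison tests: tie-corrected Kruskal-Wallis and one-way
#' ANOVA of all per-species rates by species (N = 16), and one-way ANOVA of
#' the contribution values by trait set.
#'
#' @param grid Tibble with columns `trait_set`, `engine`,
#'   `rate_isabellinus`, `rate_serotinus`, `rate_isabellinus_no_hybrids`,
#'   `rate_serotinus_no_hybrids`, `rate_global`, `rate_global_no_hybrids`,
#'   `hybrid_contribution`.
#' @return Object of class `overlap_report` with `grid` (plus `overlap`
#'   column), `aggregates` and `comparisons` tibbles.
#' @export
overlap_summary <- function(grid) {
  need <- c("trait_set", "engine", "rate_isabellinus", "rate_serotinus",
            "rate_isabellinus_no_hybrids", "rate_serotinus_no_hybrids",
            "rate_global", "rate_global_no_hybrids", "hybrid_contribution")
  missing <- setdiff(need, names(grid))
  if (length(missing)) {
    abort_schema(paste0("Rates grid is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  grid <- dplyr::mutate(grid, overlap = 100 - .data$rate_global)

  agg <- function(label, values) {
    dplyr::mutate(aggregate_rates(values), quantity = label, .before = 1)
  }
  aggregates <- dplyr::bind_rows(
    agg("overlap", grid$overlap),
    agg("hybrid_contribution", grid$hybrid_contribution),
    agg("hybrid_contribution_morphometry",
        grid$hybrid_contribution[grid$trait_set == "morphometry"]),
    agg("hybrid_contribution_colour",
        grid$hybrid_contribution[grid$trait_set == "colour"])
  )

  # the 16 per-species rates (species x engine x trait set x with/without)
  rates_long <- tidyr::pivot_longer(
    grid,
    cols = c("rate_isabellinus", "rate_serotinus",
             "rate_isabellinus_no_hybrids", "rate_serotinus_no_hybrids"),
    names_to = "measure", values_to = "rate")
  rates_long$species <- ifelse(grepl("isabellinus", rates_long$measure),
                               "isabellinus", "serotinus")
  comparisons <- dplyr::bind_rows(
    dplyr::mutate(kruskal_wallis(rates_long, rate, species),
                  comparison = "per-species rates by species", .before = 1),
    dplyr::mutate(one_way_anova(rates_long, rate, species),
                  comparison = "per-species rates by species", .before = 1),
    dplyr::mutate(one_way_anova(grid, hybrid_contribution, trait_set),
                  comparison = "hybrid contribution by trait set", .before = 1)
  )

  structure(list(grid = grid, aggregates = aggregates,
                 comparisons = comparisons),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Overlap report (engine x trait-set grid):\n")
  print(dplyr::select(x$grid, "trait_set", "engine", "rate_global",
                      "rate_global_no_hybrids", "overlap",
                      "hybrid_contribution"))
  cat("\nAggregates (mean +/- sample sd):\n")
  print(x$aggregates)
  cat("\nComparisons:\n")
  print(dplyr::select(x$comparisons, "comparison", "statistic_name",
                      "statistic", "df1", "df2", "p_value", "n"))
  invisible(x)
}

#' @rdname tidy.pca_fit
#' @exportS3Method generics::tidy
tidy.overlap_report <- function(x, ...) x$grid

#' @rdname tidy.pca_fit
#' @exportS3Method generics::glance
glance.overlap_report <- function(x, ...) {
  a <- x$aggregates
  tibble::tibble(
    overlap_mean = a$mean[a$quantity == "overlap"],
    overlap_sd = a$sd[a$quantity == "overlap"],
    contribution_mean = a$mean[a$quantity == "hybrid_contribution"],
    contribution_sd = a$sd[a$quantity == "hybrid_contribution"],
    contribution_mean_morpho =
      a$mean[a$quantity == "hybrid_contribution_morphometry"],
    contribution_sd_morpho =
      a$sd[a$quantity == "hybrid_contribution_morphometry"],
    contribution_mean_colour = a$mean[a$quantity == "hybrid_contribution_colour"],
    contribution_sd_colour = a$sd[a$quantity == "hybrid_contribution_colour"]
  )
}

# One engine/trait-set cell of the study grid: with- and without-hybrid runs.
run_study_cell <- function(sym, engine, trait_set, svm_cfg, f_enter, f_remove,
                           priors) {
  vars <- trait_vars(if (trait_set == "morphometry") "morpho" else "colour")
  fit_one <- function(tab, hybrids) {
    if (engine == "DFA") {
      sw <- stepwise_wilks(tab, vars, species, f_enter = f_enter,
                           f_remove = f_remove)
      use <- if (sw$empty) vars else sw$selected
      rep <- qda_crossval(tab, use, species, priors = priors,
                          trait_set = trait_set)
      rep$details$stepwise <- sw
      rep$details$stepwise_fallback <- sw$empty
      rep
    } else {
      pca <- fit_pca(tab, vars)
      scored <- augment(pca, tab)
      score_cols <- paste0(".", pca$component_names)
      svm_ensemble(scored, score_cols, species, config = svm_cfg,
                   trait_set = trait_set)
    }
  }
  with_h <- fit_one(sym, hybrids = TRUE)
  without_h <- fit_one(dplyr::filter(sym, !.data$is_hybrid), hybrids = FALSE)
  list(with_hybrids = with_h, without_hybrids = without_h)
}

#' Run the full overlap study on a cohort
#'
#' Executes the 2 x 2 x 2 design on the sympatric subset of a trait table:
#' both classification engines (stepwise-Wilks QDA with leave-one-out
#' cross-validation on raw selected variables; the SVM ensemble on retained
#' PCA scores) on both trait sets (morphometry, colour), each with and
#' without the molecularly confirmed hybrids. Fills the rates grid, derives
#' overlap and hybrid contribution per cell, and aggregates and compares
#' across cells via [overlap_summary()]. Hybrids carry their molecular
#' backcross species label as classification truth.
#'
#' @param data A trait table covering the sympatric zone (other zones are
#'   dropped).
#' @param svm An [svm_config()].
#' @param f_enter,f_remove Stepwise thresholds passed to [stepwise_wilks()].
#' @param priors QDA priors, `"equal"` or `"proportional"`.
#' @return An `overlap_report` whose `grid` also holds the secondary
#'   contribution definition
#'   `100 * (overlap_with - overlap_without) / overlap_with`
#'   (`contribution_rate_change`), a `stepwise_fallback` flag, and whose
#'   `reports` element keeps all eight `classification_report`s.
#' @export
run_overlap_study <- function(data, svm = svm_config(), f_enter = 3.84,
                              f_remove = 2.71,
                              priors = c("equal", "proportional")) {
  priors <- match.arg(priors)
  sym <- filter_cohort(data, zone = "sympatric", include_hybrids = TRUE)
  if (!any(sym$is_hybrid)) {
    abort_validation("Overlap study needs a nonempty hybrid group in sympatry.")
  }
  if (length(unique(sym$species[!sym$is_hybrid])) < 2) {
    abort_validation("Overlap study needs both parental species in sympatry.")
  }

  cells <- tidyr::expand_grid(trait_set = c("morphometry", "colour"),
                              engine = c("DFA", "SVM"))
  reports <- list()
  grid <- purrr::pmap_dfr(cells, function(trait_set, engine) {
    cell <- run_study_cell(sym, engine, trait_set, svm, f_enter, f_remove,
                           priors)
    reports[[paste(engine, trait_set, sep = "_")]] <<- cell
    w <- cell$with_hybrids
    wo <- cell$without_hybrids
    ov_w <- overlap_from_report(w)
    ov_wo <- 100 - wo$rate_global
    tibble::tibble(
      trait_set = trait_set, engine = engine,
      rate_isabellinus = class_rate(w, "isabellinus"),
      rate_serotinus = class_rate(w, "serotinus"),
      rate_isabellinus_no_hybrids = class_rate(wo, "isabellinus"),
      rate_serotinus_no_hybrids = class_rate(wo, "serotinus"),
      rate_global = w$rate_global,
      rate_global_no_hybrids = wo$rate_global,
      hybrid_contribution = suppressWarnings(hybrid_contribution(w)),
      contribution_rate_change =
        if (ov_w > 0) 100 * (ov_w - ov_wo) / ov_w else NA_real_,
      stepwise_fallback = isTRUE(w$details$stepwise_fallback) ||
        isTRUE(wo$details$stepwise_fallback)
    )
  })
  out <- overlap_summary(grid)
  out$reports <- reports
  out
}
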