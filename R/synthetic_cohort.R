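#' Default morphometric calibration of the synthetic cohort
#'
#' Per-group medians and observed ranges (mm) of the seven wing and dentition
#' variables for the five experimental groups, as published for the Iberian
#' *Eptesicus* contact-zone cohort (31/33/8/19/35 individuals). Locations are
#' medians; `lower`/`upper` are the observed extremes and act as hard
#' truncation bounds for the generator.
#'
#' @return Tibble with columns `group`, `variable`, `location`, `lower`, `upper`.
#' @export
default_morpho_params <- function() {
  rows <- list(
    #           FA                D3_MC             D3_F1             D5_MC             D5_F1             C1_C1          CM3
    Eisa_allo = c(51.6, 49.9, 55.7, 47.1, 44.0, 52.0, 17.8, 12.2, 19.8, 44.1, 41.3, 48.0, 10.9, 10.0, 12.0, 6.7, 6.3, 7.2, 7.2, 6.8, 7.7),
    Eisa_sym  = c(51.6, 48.6, 54.3, 46.1, 42.6, 48.6, 18.0, 16.5, 20.5, 43.0, 40.1, 48.5, 11.3, 10.2, 12.6, 6.9, 6.3, 7.4, 7.2, 6.5, 8.4),
    Hybrid    = c(52.6, 49.7, 53.7, 46.8, 42.7, 47.7, 18.8, 16.8, 19.1, 43.4, 39.9, 45.9, 12.0, 11.0, 13.3, 6.7, 6.5, 6.9, 7.4, 7.1, 7.5),
    Eser_sym  = c(52.8, 49.7, 55.2, 47.5, 44.7, 49.7, 17.8, 16.8, 20.4, 44.5, 40.5, 47.2, 11.7,  9.9, 13.1, 6.9, 6.6, 7.5, 7.6, 7.3, 8.5),
    Eser_allo = c(52.6, 48.8, 56.1, 49.0, 41.4, 51.6, 18.0, 13.2, 19.5, 46.5, 41.6, 49.6, 11.3, 10.0, 12.5, 6.9, 6.6, 7.5, 7.7, 7.4, 8.7)
  )
  purrr::map_dfr(group_levels(), function(g) {
    m <- matrix(rows[[g]], ncol = 3, byrow = TRUE)
    tibble::tibble(group = g, variable = morpho_vars(),
                   location = m[, 1], lower = m[, 2], upper = m[, 3])
  })
}

#' Default colour calibration of the synthetic cohort (ASSUMED)
#'
#' The published colour descriptives exist only as a figure, so these CIELAB
#' centroids are declared assumptions, chosen to match the qualitative
#' pattern: allopatric *E. serotinus* darkest and greyest (lowest L*, a*, b*),
#' the other groups along the brown palette (higher a*, b*), hybrids the
#' brightest of all, and ventral fur brighter than dorsal. Ranges span
#' location +/- two of the implied within-group standard deviations (the
#' generator's sd is range/4), with L* clipped to its [0, 100] gamut.
#'
#' @return Tibble with columns `group`, `variable`, `location`, `lower`, `upper`.
#' @export
default_colour_params <- function() {
  centre <- list( # L_d, a_d, b_d, L_v, a_v, b_v
    Eisa_allo = c(32, 6.0, 16.0, 42, 4.5, 14.0),
    Eisa_sym  = c(31, 6.2, 16.5, 41, 4.7, 14.5),
    Hybrid    = c(34, 6.5, 17.0, 44, 5.0, 15.0),
    Eser_sym  = c(27, 6.8, 17.5, 37, 5.2, 15.5),
    Eser_allo = c(26, 3.5, 12.0, 36, 2.5, 10.0)
  )
  spread <- c(4, 1.6, 3, 4, 1.6, 3) # half-ranges (= 2 sd)
  purrr::map_dfr(group_levels(), function(g) {
    loc <- centre[[g]]
    lo <- loc - spread
    hi <- loc + spread
    isL <- grepl("^L_", colour_vars())
    lo[isL] <- pmax(lo[isL], 0)
    hi[isL] <- pmin(hi[isL], 100)
    tibble::tibble(group = g, variable = colour_vars(),
                   location = loc, lower = lo, upper = hi)
  })
}

#' Specify a synthetic five-group cohort
#'
#' Bundles everything the generator needs: group sizes, per-group per-variable
#' locations and truncation bounds, the within-group dispersion scale, the
#' hybrid-intermediacy dial, the wing-trait correlation and the seed.
#'
#' Each variable is drawn from a normal distribution centred at `location`
#' with sd `spread_fraction * (upper - lower) / 4`, truncated hard at
#' `[lower, upper]`; wing lengths share a common positive correlation via a
#' Gaussian copula so that a "Size" axis emerges in PCA.
#'
#' @param group_sizes Named integer vector over [group_levels()]
#'   (default `c(31, 33, 8, 19, 35)`).
#' @param morpho_params,colour_params Calibration tibbles
#'   (`group`, `variable`, `location`, `lower`, `upper`).
#' @param spread_fraction Scales within-group sd relative to `range/4`
#'   (default 1: about 95% of the untruncated mass lies inside the range).
#' @param hybrid_intermediacy `NULL` (default) keeps the calibrated hybrid
#'   locations. A value `h` in \eqn{[0, 1]} instead places the hybrid group at
#'   `(1 - h) * anchor + h * midpoint` of the two sympatric parental groups:
#'   0 = identical to the anchor parent, 1 = exact parental midpoint.
#' @param hybrid_anchor Parent group anchoring `h = 0` (default `"Eser_sym"`,
#'   the dominant backcross direction).
#' @param hybrid_species Molecular species label carried by hybrids
#'   (default `"serotinus"`).
#' @param wing_correlation Common pairwise correlation among the five wing
#'   variables (default 0.6).
#' @param seed Integer seed; each group consumes its own derived stream so
#'   resizing one group never perturbs another group's draws.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = default_group_sizes(),
                        morpho_params = default_morpho_params(),
                        colour_params = default_colour_params(),
                        spread_fraction = 1,
                        hybrid_intermediacy = NULL,
                        hybrid_anchor = "Eser_sym",
                        hybrid_species = "serotinus",
                        wing_correlation = 0.6,
                        seed = 1L) {
  spec <- structure(
    list(group_sizes = group_sizes,
         params = dplyr::bind_rows(morpho_params, colour_params),
         spread_fraction = spread_fraction,
         hybrid_intermediacy = hybrid_intermediacy,
         hybrid_anchor = hybrid_anchor,
         hybrid_species = hybrid_species,
         wing_correlation = wing_correlation,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  gs <- spec$group_sizes
  if (is.null(names(gs)) && length(gs) == 5) {
    names(gs) <- group_levels()
    spec$group_sizes <- gs
  }
  if (!all(group_levels() %in% names(gs))) {
    abort_validation("group_sizes must be named over all five group levels.")
  }
  if (any(gs < 0) || any(gs != round(gs))) {
    abort_validation("group_sizes must be nonnegative integers.")
  }
  small <- setdiff(names(gs)[gs < 2 & gs > 0], "Hybrid")
  if (length(small)) {
    abort_validation(paste0("Non-hybrid groups need n >= 2 (or 0): ",
                            paste(small, collapse = ", ")))
  }
  p <- spec$params
  need <- tidyr::expand_grid(group = group_levels(), variable = trait_vars("both"))
  if (nrow(dplyr::anti_join(need, p, by = c("group", "variable"))) > 0) {
    abort_validation("params must cover every group x variable combination.")
  }
  if (any(p$lower >= p$upper)) {
    abort_validation("Every variable needs lower < upper bounds.")
  }
  if (any(p$location < p$lower | p$location > p$upper)) {
    abort_validation("Every location must lie within its bounds.")
  }
  if (!is.null(spec$hybrid_intermediacy)) {
    h <- spec$hybrid_intermediacy
    if (!is.numeric(h) || h < 0 || h > 1) {
      abort_validation("hybrid_intermediacy must be NULL or in [0, 1].")
    }
  }
  if (spec$spread_fraction <= 0 || spec$spread_fraction > 1) {
    abort_validation("spread_fraction must lie in (0, 1].")
  }
  if (abs(spec$wing_correlation) >= 1) {
    abort_validation("wing_correlation must lie in (-1, 1).")
  }
  spec
}

# Resolve the hybrid row of the parameter table under the intermediacy dial.
resolve_params <- function(spec) {
  p <- spec$params
  h <- spec$hybrid_intermediacy
  if (is.null(h)) return(p)
  anchor <- p[p$group == spec$hybrid_anchor, ]
  isa <- p[p$group == "Eisa_sym", ]
  ser <- p[p$group == "Eser_sym", ]
  stopifnot(identical(anchor$variable, isa$variable),
            identical(isa$variable, ser$variable))
  mid_loc <- (isa$location + ser$location) / 2
  mid_lo <- (isa$lower + ser$lower) / 2
  mid_hi <- (isa$upper + ser$upper) / 2
  hy <- anchor
  hy$group <- "Hybrid"
  hy$location <- (1 - h) * anchor$location + h * mid_loc
  hy$lower <- pmin((1 - h) * anchor$lower + h * mid_lo, hy$location)
  hy$upper <- pmax((1 - h) * anchor$upper + h * mid_hi, hy$location)
  dplyr::bind_rows(p[p$group != "Hybrid", ], hy)
}

# Inverse-CDF truncated-normal transform of uniform draws.
qtruncnorm <- function(u, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(x, lower), upper)
}

#' Simulate a synthetic cohort
#'
#' Draws a complete trait table from a [cohort_spec()]: per group, each
#' variable follows a truncated normal centred at its calibrated location
#' (hard truncation at the published range), wing variables share a common
#' correlation through a Gaussian copula, and hybrids sit where the
#' intermediacy dial places them. Identical seeds give identical tables.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer overriding `spec$seed`.
#' @return A validated trait table with groups assigned.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  spec <- validate_cohort_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  params <- resolve_params(spec)
  vars <- trait_vars("both")
  wing <- c("FA", "D3_MC", "D3_F1", "D5_MC", "D5_F1")

  # exchangeable correlation among wing variables, identity elsewhere
  R <- diag(length(vars))
  dimnames(R) <- list(vars, vars)
  R[wing, wing] <- spec$wing_correlation
  diag(R) <- 1
  L <- chol(R)

  tables <- purrr::imap(stats::setNames(group_levels(), group_levels()),
                        function(g, nm) NULL)
  for (gi in seq_along(group_levels())) {
    g <- group_levels()[gi]
    n <- spec$group_sizes[[g]]
    if (n == 0) next
    # derived per-group stream: independent of the other groups' sizes
    set.seed((spec$seed %% 100003L) + 1000L * gi)
    z <- matrix(stats::rnorm(n * length(vars)), nrow = n) %*% L
    u <- stats::pnorm(z)
    colnames(u) <- vars
    pg <- params[params$group == g, ]
    draws <- purrr::map(vars, function(v) {
      row <- pg[pg$variable == v, ]
      sd <- spec$spread_fraction * (row$upper - row$lower) / 4
      qtruncnorm(u[, v], row$location, sd, row$lower, row$upper)
    })
    names(draws) <- vars
    tab <- tibble::as_tibble(draws)
    tab <- dplyr::mutate(
      tab,
      individual_id = sprintf("%s_%03d", g, seq_len(n)),
      species = if (g == "Hybrid") spec$hybrid_species else
        if (startsWith(g, "Eisa")) "isabellinus" else "serotinus",
      is_hybrid = g == "Hybrid",
      zone = if (endsWith(g, "allo")) "allopatric" else "sympatric",
      .before = 1
    )
    tables[[g]] <- tab
  }
  assign_groups(dplyr::bind_rows(tables))
}

#' Shift one group's location for a sensitivity study
#'
#' Returns a copy of the spec with `location` shifted by `delta` for one
#' variable in one group, widening the truncation bounds if the shift would
#' otherwise leave the location outside them.
#'
#' @param spec A [cohort_spec()].
#' @param variable Trait variable name.
#' @param group Group label, or a character vector of groups.
#' @param delta Additive shift.
#' @return The modified spec.
#' @export
perturb_effect <- function(spec, variable, group, delta) {
  spec <- validate_cohort_spec(spec)
  p <- spec$params
  hit <- p$variable == variable & p$group %in% group
  if (!any(hit)) {
    abort_validation(paste0("No parameter row for variable `", variable,
                            "` in group(s) ", paste(group, collapse = ", ")))
  }
  p$location[hit] <- p$location[hit] + delta
  p$lower[hit] <- pmin(p$lower[hit], p$location[hit])
  p$upper[hit] <- pmax(p$upper[hit], p$location[hit])
  spec$params <- p
  validate_cohort_spec(spec)
}
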