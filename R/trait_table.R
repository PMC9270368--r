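#' Trait variable names
#'
#' The seven wing and dentition measurements (mm) and the six CIELAB colour
#' variables (dorsal and ventral L*, a*, b*) that make up a trait table.
#'
#' @return Character vector of column names.
#' @export
morpho_vars <- function() {
  c("FA", "D3_MC", "D3_F1", "D5_MC", "D5_F1", "C1_C1", "CM3")
}

#' @rdname morpho_vars
#' @export
colour_vars <- function() {
  c("L_dorsal", "a_dorsal", "b_dorsal", "L_ventral", "a_ventral", "b_ventral")
}

#' @rdname morpho_vars
#' @param trait_set `"morpho"`, `"colour"` or `"both"`.
#' @export
trait_vars <- function(trait_set = c("both", "morpho", "colour")) {
  trait_set <- match.arg(trait_set)
  switch(trait_set,
    morpho = morpho_vars(),
    colour = colour_vars(),
    both   = c(morpho_vars(), colour_vars())
  )
}

#' Five-group experimental scheme
#'
#' Ordered group labels of the allopatry/sympatry design: allopatric
#' *E. isabellinus*, sympatric *E. isabellinus*, hybrids, sympatric
#' *E. serotinus*, allopatric *E. serotinus*, with the default cohort sizes.
#'
#' @return `group_levels()` returns the five ordered labels;
#'   `default_group_sizes()` a named integer vector.
#' @export
group_levels <- function() {
  c("Eisa_allo", "Eisa_sym", "Hybrid", "Eser_sym", "Eser_allo")
}

#' @rdname group_levels
#' @export
default_group_sizes <- function() {
  stats::setNames(c(31L, 33L, 8L, 19L, 35L), group_levels())
}

meta_cols <- function() c("individual_id", "species", "is_hybrid", "zone")

required_cols <- function() c(meta_cols(), trait_vars("both"))

abort_schema <- function(msg, ...) {
  rlang::abort(msg, class = "morphoverlap_schema_error", ...)
}

abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "morphoverlap_validation_error", ...)
}

#' Validate a per-individual trait table
#'
#' Checks the column contract (id, 13 trait columns, `species`, `is_hybrid`,
#' `zone`), value ranges (strictly positive morphometry, L* within
#' \eqn{[0, 100]}), uniqueness of individual ids and the constraint that
#' hybrids occur only in the sympatric contact zone.
#'
#' @param data A data frame of individuals.
#' @param na_action `"error"` rejects missing trait cells (default);
#'   `"drop"` removes the affected rows (listwise deletion).
#' @return The validated table as a tibble (invisibly identical content),
#'   with `species`/`zone` as character and `is_hybrid` logical.
#' @export
validate_trait_table <- function(data, na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (!is.data.frame(data)) abort_schema("`data` must be a data frame.")
  missing_cols <- setdiff(required_cols(), names(data))
  if (length(missing_cols) > 0) {
    abort_schema(
      paste0("Trait table is missing required column(s): ",
             paste(missing_cols, collapse = ", ")),
      missing = missing_cols
    )
  }
  out <- tibble::as_tibble(data)
  out$individual_id <- as.character(out$individual_id)
  out$species <- as.character(out$species)
  out$zone <- as.character(out$zone)
  out$is_hybrid <- as.logical(out$is_hybrid)

  for (v in trait_vars("both")) {
    if (!is.numeric(out[[v]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(out[[v]])))) &
                     !is.na(out[[v]]))
      abort_schema(paste0(
        "Column `", v, "` is not numeric",
        if (length(bad)) paste0(" (first offending row: ", bad[1], ")"), "."
      ))
    }
  }

  has_na <- !stats::complete.cases(out[trait_vars("both")])
  if (any(has_na)) {
    if (na_action == "error") {
      abort_validation(paste0(
        "Missing trait values in row(s): ",
        paste(utils::head(which(has_na), 5), collapse = ", "),
        if (sum(has_na) > 5) " ...", ". Use na_action = \"drop\" for listwise deletion."
      ))
    }
    out <- out[!has_na, , drop = FALSE]
  }

  if (anyDuplicated(out$individual_id)) {
    dup <- unique(out$individual_id[duplicated(out$individual_id)])
    abort_validation(paste0("Duplicate individual_id: ",
                            paste(utils::head(dup, 5), collapse = ", ")))
  }
  bad_species <- setdiff(unique(out$species), c("isabellinus", "serotinus"))
  if (length(bad_species)) {
    abort_validation(paste0("Unknown species label(s): ",
                            paste(bad_species, collapse = ", ")))
  }
  bad_zone <- setdiff(unique(out$zone), c("allopatric", "sympatric"))
  if (length(bad_zone)) {
    abort_validation(paste0("Unknown zone label(s): ",
                            paste(bad_zone, collapse = ", ")))
  }
  if (any(is.na(out$is_hybrid))) abort_validation("`is_hybrid` contains NA.")

  for (v in morpho_vars()) {
    if (any(out[[v]] <= 0)) {
      abort_validation(paste0("Morphometric variable `", v,
                              "` must be strictly positive (row ",
                              which(out[[v]] <= 0)[1], ")."))
    }
  }
  for (v in c("L_dorsal", "L_ventral")) {
    if (any(out[[v]] < 0 | out[[v]] > 100)) {
      abort_validation(paste0("CIELAB lightness `", v,
                              "` must lie in [0, 100] (row ",
                              which(out[[v]] < 0 | out[[v]] > 100)[1], ")."))
    }
  }
  if (any(out$is_hybrid & out$zone != "sympatric")) {
    abort_validation(paste0(
      "Hybrids occur only in the sympatric contact zone; offending row(s): ",
      paste(utils::head(which(out$is_hybrid & out$zone != "sympatric"), 5),
            collapse = ", ")
    ))
  }
  out
}

#' Assign the five-group experimental labels
#'
#' `group` is a pure function of (`species`, `is_hybrid`, `zone`): hybrids
#' form their own group regardless of their backcross species label;
#' non-hybrids are split by species crossed with zone.
#'
#' @param data A validated trait table (see [validate_trait_table()]).
#' @return The table with a `group` factor column (levels [group_levels()]).
#' @export
assign_groups <- function(data) {
  data <- validate_trait_table(data)
  grp <- ifelse(
    data$is_hybrid, "Hybrid",
    paste0(
      ifelse(data$species == "isabellinus", "Eisa", "Eser"),
      ifelse(data$zone == "allopatric", "_allo", "_sym")
    )
  )
  data$group <- factor(grp, levels = group_levels())
  data
}

#' Read and write trait tables as delimited text
#'
#' Plain UTF-8 delimited text with a header row and `"."` decimal separator.
#' A header alias map allows field labels such as `"D3 MC"` to be mapped onto
#' the canonical identifiers.
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @param aliases Named character vector mapping file headers to canonical
#'   column names, e.g. `c("D3 MC" = "D3_MC")`.
#' @param na_action Passed to [validate_trait_table()].
#' @return A validated trait table with groups assigned.
#' @export
read_trait_table <- function(path, delim = ",", aliases = NULL,
                             na_action = c("error", "drop")) {
  if (!file.exists(path)) abort_schema(paste0("File not found: ", path))
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(aliases)) {
    hit <- names(raw) %in% names(aliases)
    names(raw)[hit] <- unname(aliases[names(raw)[hit]])
  }
  assign_groups(validate_trait_table(raw, na_action = na_action))
}

#' @rdname read_trait_table
#' @param data A trait table.
#' @export
write_trait_table <- function(data, path, delim = ",") {
  data <- validate_trait_table(data)
  keep <- intersect(c(meta_cols(), trait_vars("both"), "group"), names(data))
  readr::write_delim(data[keep], path, delim = delim)
  invisible(path)
}

#' Filter a cohort by zone, hybrid status and trait set
#'
#' Restricts a trait table to a geographic zone, optionally removes the
#' molecularly confirmed hybrids, and optionally drops one trait block.
#'
#' @param data A validated trait table.
#' @param zone `NULL` (keep all), `"sympatric"` or `"allopatric"`. Hybrids
#'   belong to the sympatric zone.
#' @param include_hybrids Keep hybrid individuals? Default `TRUE`.
#' @param trait_set Which trait columns to retain: `"both"`, `"morpho"`
#'   or `"colour"`.
#' @return The restricted tibble. An empty selection is an error.
#' @export
filter_cohort <- function(data, zone = NULL, include_hybrids = TRUE,
                          trait_set = c("both", "morpho", "colour")) {
  trait_set <- match.arg(trait_set)
  data <- assign_groups(data)
  if (!is.null(zone)) {
    zone <- match.arg(zone, c("sympatric", "allopatric"))
    data <- data[data$zone == zone, , drop = FALSE]
  }
  if (!include_hybrids) data <- data[!data$is_hybrid, , drop = FALSE]
  if (nrow(data) == 0) {
    rlang::abort("Cohort filter selected zero individuals.",
                 class = "morphoverlap_empty_selection")
  }
  keep <- c(meta_cols(), trait_vars(trait_set), "group")
  data[keep]
}

#' Per-group counts
#'
#' @param data A trait table.
#' @return Tibble with one row per experimental group and its size.
#' @export
group_counts <- function(data) {
  data <- assign_groups(data)
  dplyr::count(data, .data$group, name = "n", .drop = FALSE)
}
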