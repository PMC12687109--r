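#' Suitable area of a species in one year
#'
#' The suitable area combines a binary climate state with fractional habitat
#' suitability: SA = sum over range cells of
#' \[cell climatically suitable\] x preferred-habitat fraction x cell area.
#' Under `driver_mode = "climate_only"` the habitat fractions are frozen at
#' their 2015 values, so only climate moves the trajectory; under
#' `"landuse_only"` every cell counts as climatically suitable.
#'
#' @param habitat_frac Numeric vector: the year's preferred-habitat fraction
#'   per range cell.
#' @param climate_flags Logical vector per range cell (`TRUE` = suitable),
#'   typically the ensemble flags; ignored under `"landuse_only"`.
#' @param cell_area_km2 Area of one grid cell (km2).
#' @param driver_mode One of `"combined"`, `"climate_only"`, `"landuse_only"`.
#' @param habitat_frac_2015 Baseline-year fractions; required for
#'   `"climate_only"`.
#' @return Suitable area in km2.
#' @export
suitable_area_year <- function(habitat_frac, climate_flags, cell_area_km2,
                               driver_mode = c("combined", "climate_only",
                                               "landuse_only"),
                               habitat_frac_2015 = NULL) {
  driver_mode <- match.arg(driver_mode)
  w <- switch(driver_mode,
    combined = habitat_frac * climate_flags,
    climate_only = {
      if (is.null(habitat_frac_2015))
        stop("climate_only mode needs the 2015 habitat fractions", call. = FALSE)
      habitat_frac_2015 * climate_flags
    },
    landuse_only = habitat_frac
  )
  sum(w) * cell_area_km2
}

#' Baseline suitable area in 2015
#'
#' The 2015 suitable area assumes a suitable climate throughout the range:
#' it is the cell-area-weighted sum of the preferred-habitat fractions with
#' no climate masking. Species with zero 2015 suitable area cannot enter
#' percent-change statistics and must be excluded upstream.
#'
#' @param habitat_frac_2015 Numeric vector of 2015 preferred-habitat
#'   fractions per range cell.
#' @param cell_area_km2 Cell area (km2).
#' @return Area in km2.
#' @export
sa_2015 <- function(habitat_frac_2015, cell_area_km2) {
  sum(habitat_frac_2015) * cell_area_km2
}

#' Apply the absorbing extinction rule
#'
#' Once a species' suitable area hits zero in any year, it is treated as
#' having no suitable cells from that year onwards, even if conditions later
#' turn suitable again. Recolonisation before the first zero is free: values
#' may fall and rise arbitrarily. The rule is absorbing and idempotent.
#'
#' @param sa Numeric vector of suitable areas over consecutive years
#'   (optionally named by year).
#' @return List with `sa` (the corrected vector) and `extinct_year` (the
#'   name or index of the first zero year, or `NA` if never extinct).
#' @export
#' @examples
#' apply_extinction_rule(c(`2015` = 5, `2016` = 0, `2017` = 3))
apply_extinction_rule <- function(sa) {
  if (any(sa < 0)) stop("suitable areas must be non-negative", call. = FALSE)
  z <- which(sa == 0)
  if (length(z) == 0L)
    return(list(sa = sa, extinct_year = NA))
  first <- z[1L]
  sa[first:length(sa)] <- 0
  yr <- if (!is.null(names(sa))) as.integer(names(sa)[first]) else first
  list(sa = sa, extinct_year = yr)
}

#' Percent change in suitable area and the 0-200 index
#'
#' Gains are scored relative to the future area, losses relative to the 2015
#' baseline: if SA_y > SA_2015 the change is (1 - SA_2015/SA_y) x 100, which
#' approaches but never reaches +100; if SA_y < SA_2015 it is
#' (SA_y/SA_2015 - 1) x 100, bounded below by -100 (total loss); equal areas
#' give 0. The shifted index (percent change + 100) therefore lies in
#' \[0, 200): 0 = total loss, 100 = no change, values towards 200 = gain.
#'
#' @param sa_y Numeric vector of future suitable areas (km2), >= 0.
#' @param sa_2015 Baseline suitable area (km2), > 0 (recycled).
#' @return Tibble with `pct_change`, `index_0_200` and `exposure_fraction`
#'   (the loss side as a 0-1 fraction: max(0, -pct_change)/100).
#' @export
#' @examples
#' percent_change(c(0, 10, 20), 10)
percent_change <- function(sa_y, sa_2015) {
  if (any(sa_2015 <= 0))
    stop("invalid baseline: sa_2015 must be positive (species with no ",
         "initial habitat are excluded upstream)", call. = FALSE)
  if (any(sa_y < 0)) stop("sa_y must be non-negative", call. = FALSE)
  pct <- unname(ifelse(sa_y > sa_2015, (1 - sa_2015 / sa_y) * 100,
                       (sa_y / sa_2015 - 1) * 100))
  tibble::tibble(
    pct_change = pct,
    index_0_200 = pct + 100,
    exposure_fraction = pmax(0, -pct) / 100
  )
}

#' Annual suitable-area trajectory of one species
#'
#' Builds the 2015-2100 suitable-area series of a species under one scenario
#' and driver mode, applies the absorbing extinction rule and derives the
#' percent-change exposure records. Climate is assumed suitable everywhere
#' before `climate_start` (2020): the first five years are a land-use-only
#' spin-up, and 2015 itself is the baseline.
#'
#' @param hf_mat Numeric matrix of preferred-habitat fractions, range cells x
#'   years, columns named by calendar year and including the baseline year.
#' @param flags_mat Logical matrix of ensemble climate suitability with the
#'   same shape (`TRUE` = suitable); may be `NULL` for `"landuse_only"`.
#' @param cell_area_km2 Cell area (km2).
#' @param driver_mode See [suitable_area_year()].
#' @param base_year Baseline year (default 2015).
#' @param climate_start First year climate masking applies (default 2020).
#' @return List with `trajectory` (tibble: year, sa_km2, pct_change,
#'   index_0_200, exposure_fraction), `sa_2015` and `extinct_year`.
#' @export
sa_trajectory <- function(hf_mat, flags_mat, cell_area_km2,
                          driver_mode = c("combined", "climate_only",
                                          "landuse_only"),
                          base_year = 2015L, climate_start = 2020L) {
  driver_mode <- match.arg(driver_mode)
  years <- as.integer(colnames(hf_mat))
  if (is.null(years) || anyNA(years))
    stop("hf_mat columns must be named by calendar year", call. = FALSE)
  if (!as.character(base_year) %in% colnames(hf_mat))
    stop("missing data: no habitat layer for the baseline year", call. = FALSE)
  hf0 <- hf_mat[, as.character(base_year)]
  base <- sa_2015(hf0, cell_area_km2)
  if (base <= 0)
    stop("no-initial-habitat: species has zero suitable area in ", base_year,
         call. = FALSE)
  if (driver_mode != "landuse_only") {
    if (is.null(flags_mat))
      stop("missing data: climate flags required for mode ", driver_mode,
           call. = FALSE)
    if (!identical(dim(flags_mat), dim(hf_mat)))
      stop("flags_mat must match hf_mat in shape", call. = FALSE)
  }
  sa <- vapply(seq_along(years), function(j) {
    fl <- if (driver_mode == "landuse_only" || years[j] < climate_start)
      rep(TRUE, nrow(hf_mat)) else flags_mat[, j]
    suitable_area_year(hf_mat[, j], fl, cell_area_km2, driver_mode,
                       habitat_frac_2015 = hf0)
  }, numeric(1))
  names(sa) <- years
  ext <- apply_extinction_rule(sa)
  pc <- percent_change(ext$sa, base)
  list(
    trajectory = tibble::tibble(year = years, sa_km2 = unname(ext$sa)) |>
      dplyr::bind_cols(pc),
    sa_2015 = base,
    extinct_year = ext$extinct_year
  )
}

#' Attribute a species' exposure to its drivers
#'
#' For a species whose combined-driver exposure reaches the threshold, the
#' single-driver counterfactual runs decide the attribution class: `heat`
#' when extreme heat alone already reaches the threshold but land use alone
#' does not; `landuse` for the reverse; `both` when each driver alone
#' suffices; `combined_only` when neither does and only their union reaches
#' the threshold.
#'
#' @param combined,climate_only,landuse_only Exposure fractions in \[0,1\]
#'   at the evaluation year under the three driver modes.
#' @param threshold Exposure threshold in (0, 1\] (default 0.5).
#' @return Character scalar: one of `"heat"`, `"landuse"`, `"both"`,
#'   `"combined_only"`.
#' @export
attribute_driver <- function(combined, climate_only, landuse_only,
                             threshold = 0.5) {
  if (combined < threshold)
    stop("not applicable: combined exposure below the threshold", call. = FALSE)
  heat <- climate_only >= threshold
  lu <- landuse_only >= threshold
  if (heat && lu) "both"
  else if (heat) "heat"
  else if (lu) "landuse"
  else "combined_only"
}

#' Count species crossing exposure thresholds
#'
#' Tabulates, per group (taxon or Red List category) and threshold, how many
#' species face unsuitable conditions in at least that fraction of their 2015
#' suitable area, and the within-group percentage. Empty groups report a
#' count of 0 with `pct` 0 and `empty_group = TRUE`.
#'
#' @param exposures Tibble with one row per species at the evaluation year,
#'   containing `exposure_fraction` and the grouping column.
#' @param thresholds Numeric thresholds (default `c(0.5, 1)`).
#' @param group_by Name of the grouping column (e.g. `"taxon"`,
#'   `"redlist"`), or `NULL` for an overall count.
#' @return Tibble with `group`, `threshold`, `n_species`, `n_over`, `pct`,
#'   `empty_group`.
#' @export
threshold_counts <- function(exposures, thresholds = c(0.5, 1),
                             group_by = NULL) {
  grp <- if (is.null(group_by)) rep("all", nrow(exposures))
         else as.character(exposures[[group_by]])
  purrr::map_dfr(thresholds, function(th) {
    tibble::tibble(group = grp, over = exposures$exposure_fraction >= th) |>
      dplyr::summarise(n_species = dplyr::n(), n_over = sum(.data$over),
                       .by = "group") |>
      dplyr::mutate(
        threshold = th,
        empty_group = .data$n_species == 0L,
        pct = ifelse(.data$n_species > 0L,
                     100 * .data$n_over / .data$n_species, 0)
      )
  }) |>
    dplyr::select("group", "threshold", "n_species", "n_over", "pct",
                  "empty_group")
}

#' Write an exposure summary table to CSV
#'
#' @param exposures Tibble of per-species exposure records (one evaluation
#'   year), e.g. the `exposure` element of [run_pipeline()] output.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposure_summary <- function(exposures, path) {
  utils::write.csv(exposures, path, row.names = FALSE)
  invisible(path)
}
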