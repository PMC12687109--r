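# Per-cell percent change of a habitat fraction, on the asymmetric
# gain/loss scale used for suitable areas. Zero-baseline cells: no habitat
# then and none later is no change; habitat appearing from nothing is scored
# as the gain limit (+100, the supremum of the gain equation).
cell_pct_change <- function(new, base) {
  dplyr::case_when(
    base == 0 & new == 0 ~ 0,
    base == 0 & new > 0 ~ 100,
    new > base ~ (1 - base / new) * 100,
    .default = (new / base - 1) * 100
  )
}

#' Mean land-use-driven suitability change of one cell
#'
#' For every species whose range includes the cell, the percent change of its
#' preferred-habitat fraction in that cell (window mean against the 2015
#' baseline), averaged over species. Positive values flag potential habitat
#' gain, negative values loss.
#'
#' @param hf_window Numeric vector: per-species mean preferred-habitat
#'   fraction in the cell over the evaluation window.
#' @param hf_base Numeric vector: per-species 2015 fraction in the cell.
#' @return Mean percent change, or `NA` if no species is present.
#' @export
cell_landuse_change <- function(hf_window, hf_base) {
  if (length(hf_window) == 0L) return(NA_real_)
  mean(cell_pct_change(hf_window, hf_base))
}

#' Proportion of a cell's species exposed to unsuitable climate
#'
#' @param exposed Logical vector: one flag per species present in the cell,
#'   `TRUE` when the species' ensemble climate flag for this cell is
#'   unsuitable in at least one window year (or the species went extinct
#'   before the window closed).
#' @return Fraction in \[0,1\], or `NA` if no species is present.
#' @export
cell_climate_exposure <- function(exposed) {
  if (length(exposed) == 0L) return(NA_real_)
  mean(exposed)
}

#' Bivariate map class of a cell
#'
#' Assigns the 3x3 bivariate bin crossing land-use-driven suitability change
#' (columns) with the proportion of climate-exposed species (rows). Bin
#' edges are open on the left: a value exactly on an edge falls in the lower
#' bin. Default edges: climate \{0.25, 0.5\}, land use \{-5, +5\} percent,
#' so land-use change 0 sits in the neutral centre column.
#'
#' @param mean_landuse_change Percent change (see [cell_landuse_change()]).
#' @param prop_climate_exposed Fraction in \[0,1\].
#' @param landuse_edges,climate_edges Increasing length-2 numeric edges.
#' @return Integer vector `c(row, col)`, each in 1..3 (1 = lowest bin).
#' @export
#' @examples
#' bivariate_class(40, 0.6)   # gain column, high-exposure row
#' bivariate_class(-5, 0.25)  # boundary values fall in the lower bins
bivariate_class <- function(mean_landuse_change, prop_climate_exposed,
                            landuse_edges = c(-5, 5),
                            climate_edges = c(0.25, 0.5)) {
  if (is.unsorted(landuse_edges, strictly = TRUE) ||
      is.unsorted(climate_edges, strictly = TRUE))
    stop("invalid config: bin edges must be strictly increasing", call. = FALSE)
  c(row = 1L + sum(prop_climate_exposed > climate_edges),
    col = 1L + sum(mean_landuse_change > landuse_edges))
}

#' Per-cell summaries of species-level results
#'
#' Aggregates species results to grid cells for one scenario: the number of
#' species whose (2015) range includes the cell, the mean land-use-driven
#' percent change of their preferred-habitat fraction in the cell (window
#' mean vs. 2015), the proportion of those species climatically exposed in
#' the cell during the window, and the resulting 3x3 bivariate class. A
#' species counts as exposed in a cell when the cell's ensemble flag is
#' unsuitable in at least one window year, or when the species' extinction
#' year precedes the end of the window (its current range is mapped as
#' exposed even after the trajectory hits zero).
#'
#' @param species Species tibble (columns `species_id`, `habitat_classes`).
#' @param ranges Named list: species_id -> integer range cell ids.
#' @param lu5 Three-dimensional array cell x habitat class x year of
#'   five-class land-use fractions, with year dimnames.
#' @param flags Named list: species_id -> logical matrix (range cells x
#'   years, dimnames set) of ensemble climate suitability; `NULL` entries
#'   mean never unsuitable.
#' @param extinct_years Named numeric vector: species_id -> extinction year
#'   (`NA` if never extinct).
#' @param window Evaluation years (default 2091:2100).
#' @param base_year Baseline year (default 2015).
#' @param landuse_edges,climate_edges Bin edges, see [bivariate_class()].
#' @return Tibble: `cell_id`, `n_species`, `mean_landuse_change`,
#'   `prop_climate_exposed`, `bivariate_row`, `bivariate_col`. Cells with no
#'   species are absent.
#' @export
cell_summaries <- function(species, ranges, lu5, flags = NULL,
                           extinct_years = NULL, window = 2091:2100,
                           base_year = 2015L,
                           landuse_edges = c(-5, 5),
                           climate_edges = c(0.25, 0.5)) {
  yrs <- dimnames(lu5)[[3]]
  wy <- intersect(as.character(window), yrs)
  if (length(wy) == 0L)
    stop("evaluation window outside the land-use years", call. = FALSE)
  base_slice <- lu5[, , as.character(base_year)]
  win_slice <- apply(lu5[, , wy, drop = FALSE], c(1, 2), mean)

  rows <- purrr::map_dfr(seq_len(nrow(species)), function(i) {
    sid <- species$species_id[i]
    cells <- ranges[[sid]]
    prefs <- species$habitat_classes[[i]]
    hf_base <- habitat_fraction(prefs, base_slice, cells)
    hf_win <- habitat_fraction(prefs, win_slice, cells)
    ext <- if (!is.null(extinct_years)) extinct_years[[sid]] else NA
    gone <- !is.na(ext) && ext <= max(window)
    fl <- if (!is.null(flags)) flags[[sid]] else NULL
    exposed <- if (gone) {
      rep(TRUE, length(cells))
    } else if (is.null(fl)) {
      rep(FALSE, length(cells))
    } else {
      wcols <- intersect(as.character(window), colnames(fl))
      apply(!fl[as.character(cells), wcols, drop = FALSE], 1, any)
    }
    tibble::tibble(cell_id = cells,
                   change = cell_pct_change(hf_win, hf_base),
                   exposed = unname(exposed))
  })

  rows |>
    dplyr::summarise(
      n_species = dplyr::n(),
      mean_landuse_change = mean(.data$change),
      prop_climate_exposed = mean(.data$exposed),
      .by = "cell_id"
    ) |>
    dplyr::arrange(.data$cell_id) |>
    dplyr::mutate(
      bivariate_row = 1L + vapply(.data$prop_climate_exposed,
                                  function(p) sum(p > climate_edges), 0L),
      bivariate_col = 1L + vapply(.data$mean_landuse_change,
                                  function(x) sum(x > landuse_edges), 0L)
    )
}
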