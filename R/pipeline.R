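#' Per-cell baseline 99th-percentile temperatures
#'
#' @param world A `heat_world`.
#' @param cells Integer cell ids (default: union of all species ranges).
#' @param prob Percentile (default 0.99).
#' @return Numeric matrix, pseudo-GCMs x cells (colnames = cell ids).
#' @export
compute_cell_p99 <- function(world, cells = NULL, prob = 0.99) {
  cfg <- world$config
  if (is.null(cells)) cells <- sort(unique(unlist(world$ranges)))
  idx <- days_in_years(cfg$years[1], 1950:2005)
  out <- matrix(NA_real_, cfg$n_gcms, length(cells),
                dimnames = list(NULL, cells))
  for (g in seq_len(cfg$n_gcms))
    for (j in seq_along(cells))
      out[g, j] <- stats::quantile(world$tmax_base(cells[j], g)[idx],
                                   probs = prob, type = 7, names = FALSE)
  out
}

#' Species realised thermal limits across the ensemble
#'
#' @param world A `heat_world`.
#' @param p99 Optional precomputed matrix from [compute_cell_p99()].
#' @return Tibble `species_id`, `gcm`, `t_star` (the spatial maximum of the
#'   per-cell baseline 99th percentiles over the species range).
#' @export
compute_thermal_limits <- function(world, p99 = NULL) {
  if (is.null(p99)) p99 <- compute_cell_p99(world)
  purrr::map_dfr(world$species$species_id, function(sid) {
    cc <- as.character(world$ranges[[sid]])
    tibble::tibble(species_id = sid, gcm = seq_len(nrow(p99)),
                   t_star = apply(p99[, cc, drop = FALSE], 1, max))
  })
}

#' Climate suitability flags for one scenario
#'
#' Streams over the needed (cell, pseudo-GCM) daily series once, computes
#' per-year event metrics against each resident species' thermal limit,
#' derives each species' baseline (1950-2005) maxima of frequency, duration
#' and intensity over its whole range, scores every future cell-year against
#' those maxima per model, and combines the per-model verdicts with the
#' binary ensemble-median (strict majority) rule. Years before
#' `climate_start` count as suitable.
#'
#' @param world A `heat_world`.
#' @param scenario Scenario name.
#' @param min_run Minimum qualifying run length in days (default 6).
#' @param duration_rule,intensity_rule See [event_metrics()].
#' @return List: `thermal_limits` (tibble), `baseline` (tibble per species x
#'   gcm), `flags` (named list species_id -> logical matrix range cells x
#'   years 2015-2100, `TRUE` = suitable, dimnames set), `p99`.
#' @export
compute_climate <- function(world, scenario, min_run = 6L,
                            duration_rule = "longest",
                            intensity_rule = "max") {
  cfg <- world$config
  stopifnot(scenario %in% cfg$scenarios)
  cells <- sort(unique(unlist(world$ranges)))
  p99 <- compute_cell_p99(world, cells)
  tl <- compute_thermal_limits(world, p99)
  tl_mat <- matrix(tl$t_star, nrow = cfg$n_gcms,
                   dimnames = list(NULL, unique(tl$species_id)))

  fut_years <- cfg$base_year:max(cfg$years)
  n_fut <- length(fut_years)
  base_years <- 1950:2005
  species_ids <- world$species$species_id
  sp_index <- stats::setNames(seq_along(species_ids), species_ids)

  # invert ranges: which species sit on each cell
  by_cell <- vector("list", max(cells))
  for (sid in species_ids)
    for (cl in world$ranges[[sid]])
      by_cell[[cl]] <- c(by_cell[[cl]], sid)

  # accumulators: baseline maxima per species x gcm x metric, and future
  # metrics per species (range cells x future years x metric x gcm)
  base_max <- array(0, dim = c(length(species_ids), cfg$n_gcms, 3L),
                    dimnames = list(species_ids, NULL,
                                    c("frequency", "duration", "intensity")))
  fut <- lapply(species_ids, function(sid) {
    rc <- world$ranges[[sid]]
    array(0, dim = c(length(rc), n_fut, 3L, cfg$n_gcms),
          dimnames = list(rc, fut_years, NULL, NULL))
  })
  names(fut) <- species_ids

  base_rows <- match(base_years, cfg$years)
  fut_rows <- match(fut_years, cfg$years)
  for (cl in cells) {
    res <- by_cell[[cl]]
    if (is.null(res)) next
    for (g in seq_len(cfg$n_gcms)) {
      series <- world$tmax_series(cl, g, scenario)
      for (sid in res) {
        mm <- year_metrics_core(series, tl_mat[g, sid], min_run,
                                duration_rule, intensity_rule)
        i <- sp_index[[sid]]
        base_max[i, g, ] <- pmax(base_max[i, g, ],
                                 apply(mm[base_rows, , drop = FALSE], 2, max))
        fut[[sid]][as.character(cl), , , g] <- mm[fut_rows, , drop = FALSE]
      }
    }
  }

  # per-model suitability then strict-majority ensemble
  flags <- lapply(species_ids, function(sid) {
    i <- sp_index[[sid]]
    f <- fut[[sid]]
    unsuit_count <- matrix(0L, dim(f)[1], n_fut)
    for (g in seq_len(cfg$n_gcms)) {
      suit <- !(f[, , 1L, g] > base_max[i, g, 1L] |
                  f[, , 2L, g] > base_max[i, g, 2L] |
                  f[, , 3L, g] > base_max[i, g, 3L])
      unsuit_count <- unsuit_count + !suit
    }
    ens <- unsuit_count < (cfg$n_gcms + 1L) / 2L  # combine_gcms, vectorised
    ens[, fut_years < cfg$climate_start] <- TRUE
    dimnames(ens) <- list(world$ranges[[sid]], fut_years)
    ens
  })
  names(flags) <- species_ids

  baseline <- purrr::map_dfr(species_ids, function(sid) {
    i <- sp_index[[sid]]
    tibble::tibble(species_id = sid, gcm = seq_len(cfg$n_gcms),
                   max_frequency = base_max[i, , 1L],
                   max_duration = base_max[i, , 2L],
                   max_intensity = base_max[i, , 3L])
  })

  list(thermal_limits = tl, baseline = baseline, flags = flags, p99 = p99)
}

# five-class land-use array [cell x class x year] for one scenario
reclassify_scenario <- function(world, scenario) {
  arr12 <- world$landuse[[scenario]]
  yrs <- dimnames(arr12)[[3]]
  out <- array(0, dim = c(dim(arr12)[1], 5L, length(yrs)),
               dimnames = list(NULL, habitat_classes(), yrs))
  for (t in seq_along(yrs)) out[, , t] <- reclassify_luh2(arr12[, , t])
  out
}

# habitat-fraction matrix (range cells x years) of one species
species_hf_matrix <- function(prefs, lu5, cells) {
  sel <- intersect(habitat_classes(), unlist(prefs))
  sub <- lu5[cells, sel, , drop = FALSE]
  hf <- apply(sub, c(1, 3), sum)
  if (length(cells) == 1L) hf <- matrix(hf, nrow = 1L,
                                        dimnames = list(NULL, dimnames(lu5)[[3]]))
  rownames(hf) <- cells
  hf
}

#' Run the full exposure pipeline on a world
#'
#' Executes every stage end-to-end for each requested scenario: thermal
#' limits and ensemble climate flags; suitable-area trajectories 2015-2100
#' under the combined, climate-only and land-use-only driver modes with the
#' absorbing extinction rule; per-species exposure records at the evaluation
#' year; driver attribution for species over the threshold; species counts
#' over the exposure thresholds by taxon and Red List category; per-cell
#' summaries with bivariate classes; and the zero-one inflated beta
#' regression of exposure on log10 range size and Red List category (fitted
#' over species whose suitable area decreased by the evaluation year).
#' Species with no suitable habitat in the baseline year are excluded from
#' percent-change statistics and listed in the manifest.
#'
#' @param world A `heat_world`.
#' @param scenarios Scenario subset (default: all in the config).
#' @param eval_year Evaluation year for species counts (default 2100).
#' @param window Cell-summary window (default 2091:2100).
#' @param thresholds Exposure thresholds (default `c(0.5, 1)`).
#' @param attribution_threshold Threshold for driver attribution (default 0.5).
#' @param min_run,duration_rule,intensity_rule Event definition knobs.
#' @param fit_zoib_model Fit the exposure regression (default `TRUE`).
#' @return List with `scenarios` (named per-scenario result lists:
#'   `trajectories`, `exposure`, `attribution`, `counts_taxon`,
#'   `counts_redlist`, `cells`, `zoib`, `climate`), `species`, `excluded`
#'   and a `manifest` describing the run.
#' @export
run_pipeline <- function(world, scenarios = world$config$scenarios,
                         eval_year = 2100L, window = 2091:2100,
                         thresholds = c(0.5, 1),
                         attribution_threshold = 0.5,
                         min_run = 6L, duration_rule = "longest",
                         intensity_rule = "max",
                         fit_zoib_model = TRUE) {
  cfg <- world$config
  stopifnot(all(scenarios %in% cfg$scenarios))
  if (any(thresholds <= 0 | thresholds > 1))
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  area <- world$grid$cell_area_km2
  res <- list()
  excluded <- character()

  for (sc in scenarios) {
    lu5 <- reclassify_scenario(world, sc)
    climate <- compute_climate(world, sc, min_run = min_run,
                               duration_rule = duration_rule,
                               intensity_rule = intensity_rule)
    modes <- c("combined", "climate_only", "landuse_only")
    traj_rows <- list()
    expo_rows <- list()
    extinct <- stats::setNames(rep(NA_real_, nrow(world$species)),
                               world$species$species_id)
    for (i in seq_len(nrow(world$species))) {
      sid <- world$species$species_id[i]
      cells <- world$ranges[[sid]]
      hf <- species_hf_matrix(world$species$habitat_classes[[i]], lu5, cells)
      if (sum(hf[, as.character(cfg$base_year)]) <= 0) {
        excluded <- unique(c(excluded, sid))
        next
      }
      fl <- climate$flags[[sid]]
      per_mode <- lapply(stats::setNames(modes, modes), function(md)
        sa_trajectory(hf, fl, area, driver_mode = md,
                      base_year = cfg$base_year,
                      climate_start = cfg$climate_start))
      extinct[[sid]] <- per_mode$combined$extinct_year
      traj_rows[[sid]] <- purrr::map_dfr(modes, function(md)
        dplyr::mutate(per_mode[[md]]$trajectory, species_id = sid,
                      scenario = sc, driver_mode = md, .before = 1))
      at_eval <- function(md)
        per_mode[[md]]$trajectory$exposure_fraction[
          per_mode[[md]]$trajectory$year == eval_year]
      expo_rows[[sid]] <- tibble::tibble(
        species_id = sid, scenario = sc,
        taxon = world$species$taxon[i],
        redlist = world$species$redlist[i],
        sa_2015 = per_mode$combined$sa_2015,
        polygon_area_km2 = world$species$polygon_area_km2[i],
        extinct_year = per_mode$combined$extinct_year,
        pct_change = per_mode$combined$trajectory$pct_change[
          per_mode$combined$trajectory$year == eval_year],
        index_0_200 = pct_change + 100,
        exposure_fraction = at_eval("combined"),
        exposure_climate_only = at_eval("climate_only"),
        exposure_landuse_only = at_eval("landuse_only")
      )
    }
    trajectories <- dplyr::bind_rows(traj_rows)
    exposure <- dplyr::bind_rows(expo_rows)

    attribution <- exposure |>
      dplyr::filter(.data$exposure_fraction >= attribution_threshold) |>
      dplyr::mutate(
        threshold = attribution_threshold,
        cls = purrr::pmap_chr(
          list(.data$exposure_fraction, .data$exposure_climate_only,
               .data$exposure_landuse_only),
          attribute_driver, threshold = attribution_threshold)
      ) |>
      dplyr::select("species_id", "scenario", "threshold", "cls")

    cells_tbl <- cell_summaries(
      world$species[world$species$species_id %in% exposure$species_id, ],
      world$ranges, lu5, climate$flags, extinct, window = window,
      base_year = cfg$base_year)

    zfit <- NULL
    if (fit_zoib_model) {
      losers <- exposure[exposure$pct_change < 0, ]
      if (nrow(losers) >= 10) {
        X <- zoib_design(losers)
        zfit <- fit_zoib(losers$exposure_fraction, X)
      }
    }

    res[[sc]] <- list(
      trajectories = trajectories,
      exposure = exposure,
      attribution = attribution,
      counts_taxon = threshold_counts(exposure, thresholds, "taxon"),
      counts_redlist = threshold_counts(exposure, thresholds, "redlist"),
      counts_all = threshold_counts(exposure, thresholds),
      cells = cells_tbl,
      zoib = zfit,
      climate = climate
    )
  }

  list(
    scenarios = res,
    species = world$species,
    excluded = excluded,
    manifest = list(
      seed = cfg$seed, scenarios = scenarios, eval_year = eval_year,
      window = range(window), thresholds = thresholds,
      n_species = nrow(world$species), n_excluded = length(excluded),
      n_gcms = cfg$n_gcms, grid = c(cfg$n_rows, cfg$n_cols),
      min_run = min_run, duration_rule = duration_rule,
      intensity_rule = intensity_rule
    )
  )
}

#' Attribution summary of suitable-area losses
#'
#' Tabulates the attribution classes of species over the exposure threshold
#' and the share attributable to extreme heat alone (`heat` class over all
#' attributed species), the quantity reported alongside the threshold
#' counts; `both` is tabulated separately rather than folded into either
#' driver.
#'
#' @param attribution Attribution tibble from [run_pipeline()].
#' @return Tibble `cls`, `n`, `pct`.
#' @export
attribution_summary <- function(attribution) {
  if (nrow(attribution) == 0L)
    return(tibble::tibble(cls = character(), n = integer(), pct = numeric()))
  attribution |>
    dplyr::count(.data$cls, name = "n") |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n))
}
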