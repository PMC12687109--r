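# Deterministic child-stream seed for one (gcm, cell) weather stream; kept
# below 2^31 so it is a valid R integer seed.
stream_seed <- function(seed, gcm, cell) {
  as.integer((abs(seed) %% 100000L) * 10007 + gcm * 1009 + cell) %% 2147483629L + 1L
}

# Run `expr` under its own RNG stream without disturbing the caller's state.
with_rng <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Configuration of a synthetic world
#'
#' Collects every tunable of the synthetic-world generator: grid size,
#' species numbers and range-size distribution per taxon, the SSP-RCP
#' scenario set with per-scenario warming rates (degC per decade, applied
#' from 2015) and annual land-conversion rates (fraction of remaining natural
#' land converted per year; negative = recovery of natural land from
#' agriculture), the pseudo-GCM ensemble size and its noise, and the
#' mandatory seed. The scenario defaults encode the qualitative ordering of
#' the SSP-RCP family: strongest warming under SSP5-RCP8.5, strongest
#' natural-habitat loss under SSP3-RCP7.0, land recovery under SSP1-RCP2.6.
#'
#' @param seed Integer seed; mandatory, all randomness derives from it.
#' @param n_rows,n_cols Grid dimensions (default 30 x 30).
#' @param n_species Total species count, split evenly over the taxa.
#' @param scenarios Scenario names (default [ssp_scenarios()]).
#' @param years Calendar span of the daily climate (default 1950:2100).
#' @param lu_years Years with land-use layers (default 2015:2100).
#' @param n_gcms Pseudo-GCM ensemble size; odd, so the binary median rule is
#'   defined (default 3; use 5 for full-scale runs).
#' @param gcm_noise_sd Marginal s.d. of the daily temperature noise (degC).
#' @param ar1 Lag-1 autocorrelation of the daily noise.
#' @param seasonal_amplitude Amplitude of the sinusoidal season (degC).
#' @param warming_rate Named per-scenario warming (degC/decade from 2015).
#' @param landuse_trend Named per-scenario annual conversion rate.
#' @param range_meanlog,range_sdlog Log-normal range-size (cells) parameters;
#'   `range_meanlog` named per taxon, smaller for amphibians and reptiles.
#' @param recycle_weather If `TRUE`, the 1950-2005 noise block is recycled
#'   cyclically over the whole span, so every future year replays a baseline
#'   year; used by [make_null_world()] as a negative control.
#' @return An object of class `world_config`.
#' @export
world_config <- function(seed,
                         n_rows = 30L, n_cols = 30L,
                         n_species = 200L,
                         scenarios = ssp_scenarios(),
                         years = 1950:2100,
                         lu_years = 2015:2100,
                         n_gcms = 3L,
                         gcm_noise_sd = 2.5,
                         ar1 = 0.7,
                         seasonal_amplitude = 8,
                         warming_rate = c("SSP1-RCP2.6" = 0.10,
                                          "SSP2-RCP4.5" = 0.25,
                                          "SSP3-RCP7.0" = 0.35,
                                          "SSP5-RCP8.5" = 0.55),
                         landuse_trend = c("SSP1-RCP2.6" = -0.0020,
                                           "SSP2-RCP4.5" = 0.0015,
                                           "SSP3-RCP7.0" = 0.0060,
                                           "SSP5-RCP8.5" = 0.0025),
                         range_meanlog = c(amphibian = 1.3, bird = 2.4,
                                           mammal = 2.1, reptile = 1.5),
                         range_sdlog = 0.7,
                         recycle_weather = FALSE) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("seed is mandatory", call. = FALSE)
  if (n_gcms %% 2L == 0L)
    stop("invalid config: n_gcms must be odd for the ensemble median rule",
         call. = FALSE)
  if (n_rows * n_cols < 4L)
    stop("invalid config: grid too small", call. = FALSE)
  if (!all(scenarios %in% names(warming_rate)) ||
      !all(scenarios %in% names(landuse_trend)))
    stop("invalid config: every scenario needs a warming and land-use rate",
         call. = FALSE)
  if (any(!is.finite(warming_rate)) || any(!is.finite(landuse_trend)))
    stop("invalid config: rates must be finite", call. = FALSE)
  max_range <- max(1L, floor(n_rows * n_cols / 4))
  if (exp(min(range_meanlog)) > n_rows * n_cols)
    stop("invalid config: typical range larger than the grid", call. = FALSE)
  structure(
    list(seed = as.integer(seed), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols), n_species = as.integer(n_species),
         scenarios = scenarios, years = years, lu_years = lu_years,
         base_year = 2015L, climate_start = 2020L,
         n_gcms = as.integer(n_gcms), gcm_noise_sd = gcm_noise_sd,
         ar1 = ar1, seasonal_amplitude = seasonal_amplitude,
         warming_rate = warming_rate, landuse_trend = landuse_trend,
         range_meanlog = range_meanlog, range_sdlog = range_sdlog,
         max_range_cells = max_range,
         recycle_weather = isTRUE(recycle_weather)),
    class = "world_config"
  )
}

# Grow a contiguous blob of `size` cells from a start cell by random
# accretion over the 4-neighbourhood.
grow_blob <- function(grid, start_cell, size) {
  nr <- grid$n_rows; nc <- grid$n_cols
  member <- logical(nr * nc)
  member[start_cell] <- TRUE
  cells <- start_cell
  neighbours <- function(cell) {
    r <- (cell - 1L) %/% nc; c <- (cell - 1L) %% nc
    out <- c(if (r > 0L) cell - nc, if (r < nr - 1L) cell + nc,
             if (c > 0L) cell - 1L, if (c < nc - 1L) cell + 1L)
    out
  }
  frontier <- setdiff(neighbours(start_cell), cells)
  while (length(cells) < size && length(frontier) > 0L) {
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    member[nxt] <- TRUE
    cells <- c(cells, nxt)
    frontier <- unique(c(frontier, neighbours(nxt)))
    frontier <- frontier[!member[frontier]]
  }
  sort(cells)
}

# Initial 12-state land-use composition per cell: Dirichlet-like draws with
# a west-east forest gradient, scaled to a land total below 1 (water/ice
# remainder).
init_landuse <- function(grid) {
  n <- length(grid$cell_ids)
  colfrac <- (cell_rowcol(grid)$col - 1) / max(1, grid$n_cols - 1)
  alpha_base <- c(primf = 2.4, primn = 1.6, secdf = 1.2, secdn = 0.8,
                  urban = 0.08, c3ann = 0.7, c4ann = 0.3, c3per = 0.12,
                  c4per = 0.12, c3nfx = 0.12, pastr = 1.0, range = 0.7)
  m <- matrix(0, n, 12L, dimnames = list(NULL, luh2_states()))
  for (j in seq_along(alpha_base)) {
    a <- alpha_base[j]
    # forested west, open east
    a <- a * switch(names(alpha_base)[j],
                    primf = , secdf = 1.6 - 1.1 * colfrac,
                    primn = , secdn = , range = 0.6 + 1.0 * colfrac,
                    1)
    m[, j] <- stats::rgamma(n, shape = a, rate = 1)
  }
  land_total <- stats::runif(n, 0.88, 1.0)
  m * (land_total / rowSums(m))
}

# Evolve the 12-state composition over lu_years at annual conversion rate r:
# positive r moves natural land (primf/primn/secdf/secdn) into cropland,
# pasture and urban; negative r returns agriculture and pasture to secondary
# vegetation. Sum per cell is conserved.
evolve_landuse <- function(init, lu_years, r) {
  nat <- c("primf", "primn", "secdf", "secdn")
  sinks <- c(c3ann = 0.60, pastr = 0.25, urban = 0.15)
  agr <- c("c3ann", "c4ann", "c3per", "c4per", "c3nfx", "pastr")
  back <- c(secdf = 0.5, secdn = 0.5)
  n_years <- length(lu_years)
  arr <- array(0, dim = c(nrow(init), 12L, n_years),
               dimnames = list(NULL, luh2_states(), lu_years))
  arr[, , 1L] <- init
  if (n_years == 1L) return(arr)
  for (t in 2:n_years) {
    cur <- arr[, , t - 1L]
    if (r > 0) {
      lost <- cur[, nat, drop = FALSE] * r
      cur[, nat] <- cur[, nat] - lost
      tot <- rowSums(lost)
      for (s in names(sinks)) cur[, s] <- cur[, s] + tot * sinks[[s]]
    } else if (r < 0) {
      rec <- cur[, agr, drop = FALSE] * (-r)
      cur[, agr] <- cur[, agr] - rec
      tot <- rowSums(rec)
      for (s in names(back)) cur[, s] <- cur[, s] + tot * back[[s]]
    }
    arr[, , t] <- cur
  }
  arr
}

#' Generate a complete synthetic world
#'
#' Builds a deterministic synthetic counterpart of the pipeline's global
#' inputs: an equal-area grid; per-scenario annual 12-state fractional
#' land-use arrays with scenario-dependent conversion trends; a lazily
#' evaluated daily-maximum-temperature generator per pseudo-GCM and cell
#' (latitudinal mean gradient + sinusoidal season + AR(1) noise + a linear
#' post-2015 warming ramp at the scenario rate); and a species table with
#' contiguous blob-shaped ranges (log-normal sizes, smaller for amphibians
#' and reptiles), per-cell overlap fractions, habitat preferences and Red
#' List labels. All randomness derives from the config seed; two runs with
#' the same config are identical.
#'
#' @param config A [world_config()].
#' @return An object of class `heat_world`: list with `grid`, `config`,
#'   `species` (tibble), `overlaps` (per-species named overlap vectors),
#'   `ranges` (per-species rasterized cell ids), `landuse` (per-scenario
#'   arrays cell x 12 x year), `tmax_base(cell, gcm)` and
#'   `tmax_series(cell, gcm, scenario)` closures, and a `ground_truth`
#'   sidecar recording the design parameters.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  cfg <- config
  grid <- build_grid(cfg$n_rows, cfg$n_cols)
  taxa <- names(cfg$range_meanlog)

  world <- with_rng(cfg$seed, {
    lu_init <- init_landuse(grid)
    landuse <- lapply(stats::setNames(cfg$scenarios, cfg$scenarios),
                      function(sc)
                        evolve_landuse(lu_init, cfg$lu_years,
                                       cfg$landuse_trend[[sc]]))

    n <- cfg$n_species
    ids <- sprintf("sp%04d", seq_len(n))
    taxon <- rep_len(taxa, n)
    redlist <- sample(redlist_levels(), n, replace = TRUE,
                      prob = c(0.55, 0.08, 0.10, 0.09, 0.05, 0.13))
    pref_prob <- c(forest = 0.65, non_forest = 0.55, agriculture = 0.25,
                   managed = 0.30, urban = 0.08)
    overlaps <- vector("list", n)
    prefs <- vector("list", n)
    sizes <- integer(n)
    for (i in seq_len(n)) {
      p <- habitat_classes()[stats::runif(5) < pref_prob]
      if (length(p) == 0L) p <- "non_forest"
      prefs[[i]] <- p
      size <- round(stats::rlnorm(1, cfg$range_meanlog[[taxon[i]]],
                                  cfg$range_sdlog))
      size <- min(max(size, 1L), cfg$max_range_cells)
      sizes[i] <- size
      start <- sample(grid$cell_ids, 1L)
      blob <- grow_blob(grid, start, size)
      fr <- stats::runif(length(blob), 0.15, 1)
      # sub-threshold fringe cells exercise the <10% exclusion rule
      fringe <- setdiff(unlist(lapply(blob, function(cl) {
        r <- (cl - 1L) %/% grid$n_cols; cc <- (cl - 1L) %% grid$n_cols
        c(if (r > 0L) cl - grid$n_cols,
          if (r < grid$n_rows - 1L) cl + grid$n_cols,
          if (cc > 0L) cl - 1L, if (cc < grid$n_cols - 1L) cl + 1L)
      })), blob)
      fringe <- fringe[stats::runif(length(fringe)) < 0.4]
      ov <- c(stats::setNames(fr, blob),
              stats::setNames(stats::runif(length(fringe), 0.005, 0.095),
                              fringe))
      overlaps[[i]] <- ov
    }
    names(overlaps) <- ids
    species <- tibble::tibble(
      species_id = ids, taxon = taxon, redlist = redlist,
      habitat_classes = prefs,
      polygon_area_km2 = vapply(overlaps, sum, 0) * grid$cell_area_km2
    )
    list(landuse = landuse, species = species, overlaps = overlaps,
         sizes = sizes)
  })

  ranges <- lapply(world$species$species_id, function(sid) {
    suppressWarnings(rasterize_range(
      list(species_id = sid, cell_overlaps = world$overlaps[[sid]],
           polygon_area_km2 =
             world$species$polygon_area_km2[world$species$species_id == sid]),
      grid))
  })
  names(ranges) <- world$species$species_id

  # climate generator: deterministic per (gcm, cell) stream
  n_years <- length(cfg$years)
  n_days <- n_years * 365L
  doy <- rep(1:365, n_years)
  season <- cfg$seasonal_amplitude * sin(2 * pi * (doy - 120) / 365)
  rowfrac <- (cell_rowcol(grid)$row - 1) / max(1, grid$n_rows - 1)
  mean_t <- 10 + 24 * rowfrac
  gcm_offsets <- (seq_len(cfg$n_gcms) - (cfg$n_gcms + 1) / 2) * 0.3
  innov_sd <- cfg$gcm_noise_sd * sqrt(1 - cfg$ar1^2)
  start_year <- cfg$years[1]
  day_frac <- rep(cfg$years, each = 365L) + (doy - 0.5) / 365 # decimal year

  tmax_base <- function(cell, gcm) {
    noise <- with_rng(stream_seed(cfg$seed, gcm, cell), {
      if (cfg$recycle_weather) {
        block <- (2005L - start_year + 1L) * 365L
        x <- stats::filter(stats::rnorm(block, sd = innov_sd), cfg$ar1,
                           method = "recursive")
        rep_len(as.numeric(x), n_days)
      } else {
        as.numeric(stats::filter(stats::rnorm(n_days, sd = innov_sd),
                                 cfg$ar1, method = "recursive"))
      }
    })
    mean_t[cell] + season + noise + gcm_offsets[gcm]
  }
  tmax_series <- function(cell, gcm, scenario) {
    rate <- cfg$warming_rate[[scenario]]
    tmax_base(cell, gcm) + rate / 10 * pmax(0, day_frac - cfg$base_year)
  }

  structure(
    list(grid = grid, config = cfg, species = world$species,
         overlaps = world$overlaps, ranges = ranges,
         landuse = world$landuse,
         tmax_base = tmax_base, tmax_series = tmax_series,
         ground_truth = list(seed = cfg$seed,
                             warming_rate = cfg$warming_rate,
                             landuse_trend = cfg$landuse_trend,
                             range_cells = stats::setNames(
                               world$sizes, world$species$species_id),
                             recycle_weather = cfg$recycle_weather)),
    class = "heat_world"
  )
}

#' @export
print.heat_world <- function(x, ...) {
  cat(sprintf(paste0("<heat_world> %dx%d grid, %d species, %d pseudo-GCMs, ",
                     "%d scenarios, seed %d\n"),
              x$grid$n_rows, x$grid$n_cols, nrow(x$species),
              x$config$n_gcms, length(x$config$scenarios), x$config$seed))
  invisible(x)
}

#' Generate a null world with zero trends
#'
#' A negative control: warming and land-conversion rates are forced to zero
#' and the historical (1950-2005) weather-noise block is recycled cyclically
#' over the whole 1950-2100 span, so every future year replays a baseline
#' year exactly. No future cell-year can then exceed the baseline event
#' maxima, land use never changes, and every species' percent change is 0.
#'
#' @param config A [world_config()]; its trend fields are overridden.
#' @return A `heat_world`.
#' @export
make_null_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  config$warming_rate[] <- 0
  config$landuse_trend[] <- 0
  config$recycle_weather <- TRUE
  generate_world(config)
}
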