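# Shared fixtures: small synthetic worlds, generated once per test run, and
# an independent brute-force event oracle.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .world_cache)) assign(key, build(), envir = .world_cache)
  get(key, envir = .world_cache)
}

# general-purpose small world
tiny_world <- function() {
  cached("tiny", function()
    generate_world(world_config(seed = 42, n_rows = 8, n_cols = 8,
                                n_species = 12, n_gcms = 3)))
}

# world whose species all prefer natural (declining) habitat: the loss-only
# regime in which combined suitability is dominated by both single drivers
decline_world <- function() {
  cached("decline", function() {
    w <- generate_world(world_config(seed = 7, n_rows = 8, n_cols = 8,
                                     n_species = 12, n_gcms = 3))
    w$species$habitat_classes <- rep(list(c("forest", "non_forest")),
                                     nrow(w$species))
    w
  })
}

# zero-trend negative control
null_world <- function() {
  cached("null", function()
    make_null_world(world_config(seed = 5, n_rows = 8, n_cols = 8,
                                 n_species = 10, n_gcms = 3)))
}

# Independent oracle: day-by-day scan for runs of > min_run - 1 consecutive
# exceedance days. Deliberately naive; no shared code with detect_events.
brute_force_events <- function(x, t_star, min_run = 6L) {
  starts <- integer(); lens <- integer(); exs <- numeric()
  len <- 0L
  for (i in seq_along(x)) {
    if (x[i] > t_star) {
      len <- len + 1L
    } else if (len > 0L) {
      if (len >= min_run) {
        starts <- c(starts, i - len); lens <- c(lens, len)
        exs <- c(exs, max(x[(i - len):(i - 1L)]) - t_star)
      }
      len <- 0L
    }
  }
  if (len >= min_run) {
    n <- length(x)
    starts <- c(starts, n - len + 1L); lens <- c(lens, len)
    exs <- c(exs, max(x[(n - len + 1L):n]) - t_star)
  }
  data.frame(start = starts, length = lens, max_exceedance = exs)
}

# random 12-state land-use composition rows summing to <= 1
random_luh2 <- function(n_cells) {
  m <- matrix(stats::rgamma(n_cells * 12, 0.5), n_cells, 12,
              dimnames = list(NULL, luh2_states()))
  m * stats::runif(n_cells, 0.5, 1) / rowSums(m)
}
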