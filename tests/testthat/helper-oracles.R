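# Independent oracles and fixture builders shared across tests.

# Exhaustive-enumeration k-means oracle: minimum total within-cluster
# squared distance over every assignment of n points to k labels.
# Independent of the Lloyd implementation; only feasible for tiny n.
brute_force_inertia <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 9, k <= 4)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- grid[i, ]
    wss <- 0
    for (j in unique(lab)) {
      pts <- X[lab == j, , drop = FALSE]
      ctr <- colMeans(pts)
      wss <- wss + sum(sweep(pts, 2, ctr)^2)
    }
    if (wss < best) best <- wss
  }
  best
}

# polar_features built directly from coordinates (bypasses the wind/table
# plumbing so clustering tests control the geometry exactly)
features_from_xyz <- function(x, y, c) {
  r <- sqrt(x^2 + y^2)
  wd <- (atan2(x, y) * 180 / pi) %% 360
  ts <- as.POSIXct("2018-01-01", tz = "UTC") + 3600 * (seq_along(x) - 1)
  structure(list(data = data.frame(timestamp = ts, x = x, y = y, r = r,
                                   wd = wd, c = c),
                 kept_idx = seq_along(x), n_dropped = 0L,
                 radial_variable = "wind_speed", pollutant = "pm10",
                 standardized = FALSE, center = NULL, scale = NULL,
                 z = NULL),
            class = "polar_features")
}

# small well-formed hourly table
tiny_hourly_table <- function(n = 48, seed = 42) {
  withr::with_seed(seed, {
    ts <- as.POSIXct("2018-01-01", tz = "UTC") + 3600 * (seq_len(n) - 1)
    data.frame(timestamp = ts,
               ws = round(runif(n, 0, 8), 2),
               wd = round(runif(n, 0, 359.9), 1),
               temp = round(rnorm(n, 12, 4), 1),
               rh = round(runif(n, 30, 95), 1),
               pm25 = round(runif(n, 2, 40), 1),
               pm10 = round(runif(n, 5, 80), 1),
               nox = round(runif(n, 5, 90), 1),
               no2 = round(runif(n, 2, 40), 1),
               co = round(runif(n, 100, 900), 0),
               so2 = round(runif(n, 0.5, 9), 2))
  })
}

# minimal single-regime scenario for generator unit tests
flat_scenario <- function(n_days, seed = 1, ...) {
  met_scenario(n_days = n_days, temp_seasonal_amp = 0, temp_diurnal_amp = 0,
               temp_noise_sd = 0, rh_noise_sd = 0,
               wind_regimes = list(wind_regime(180, 0, speed_scale = 2)),
               seed = seed, ...)
}
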