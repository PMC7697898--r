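#' Define a surface wind regime
#'
#' A wind regime is a directional/speed mode of the local circulation that is
#' active during given hours of day and months of year, e.g. a daytime
#' anabatic (upslope) flow or a nocturnal drainage calm. Hourly wind is
#' simulated by sampling one active regime per hour (probability proportional
#' to `weight`), then drawing direction ~ N(`direction_center`,
#' `direction_spread`) (mod 360) and speed ~ Weibull(`speed_shape`,
#' scale = `speed_scale`).
#'
#' @param direction_center mean wind direction, degrees in `[0, 360)`
#'   (direction the wind blows from).
#' @param direction_spread circular sd of direction, degrees; 0 gives a fixed
#'   direction.
#' @param speed_scale Weibull scale of wind speed, m/s; 0 gives calm air.
#' @param speed_shape Weibull shape of wind speed (default 2, Rayleigh-like).
#' @param hours hours of day (0-23) during which the regime is active.
#' @param months calendar months (1-12) during which the regime is active.
#' @param weight non-negative sampling weight among co-active regimes.
#' @return a `wind_regime` list.
#' @export
wind_regime <- function(direction_center, direction_spread = 20,
                        speed_scale = 3, speed_shape = 2,
                        hours = 0:23, months = 1:12, weight = 1) {
  if (direction_center < 0 || direction_center >= 360)
    stopf("direction_center must lie in [0, 360), got %s", direction_center)
  if (weight < 0) stopf("regime weight must be non-negative")
  structure(list(direction_center = direction_center,
                 direction_spread = direction_spread,
                 speed_scale = speed_scale, speed_shape = speed_shape,
                 hours = as.integer(hours), months = as.integer(months),
                 weight = weight),
            class = "wind_regime")
}

#' Specify a synthetic meteorological scenario
#'
#' Encodes the seasonal and diurnal temperature climate, relative-humidity
#' cycle, and wind regimes of an urban site. Temperature is
#' `temp_mean_annual` minus a seasonal cosine with amplitude
#' `temp_seasonal_amp` (minimum mid-way through `coldest_month`) plus a
#' diurnal cosine with amplitude `temp_diurnal_amp` (maximum at 14:00,
#' minimum at 02:00) plus Gaussian noise. The simulated calendar is naive
#' local time, hourly, starting Monday 2018-01-01 00:00 with no daylight
#' saving, so weekday/weekend logic is unambiguous.
#'
#' @param n_days number of simulated days (>= 1).
#' @param coldest_month month index (1-12) of the coldest month (7 for a
#'   Southern-Hemisphere site).
#' @param temp_mean_annual annual mean temperature, deg C.
#' @param temp_seasonal_amp seasonal half-range of daily-mean temperature, deg C.
#' @param temp_diurnal_amp diurnal half-range of temperature, deg C.
#' @param temp_noise_sd sd of hourly temperature noise, deg C.
#' @param wind_regimes list of [wind_regime()] objects; together they must
#'   cover every (hour, month) combination with positive total weight.
#' @param rh_mean,rh_amp mean and diurnal amplitude of relative humidity, %.
#' @param rh_noise_sd sd of hourly RH noise, %.
#' @param start first calendar day ("YYYY-MM-DD"); the default is a Monday.
#' @param seed integer seed making the generated series reproducible.
#' @return a `met_scenario` list.
#' @export
met_scenario <- function(n_days, coldest_month = 7, temp_mean_annual = 12,
                         temp_seasonal_amp = 6, temp_diurnal_amp = 5,
                         temp_noise_sd = 1,
                         wind_regimes = list(wind_regime(270)),
                         rh_mean = 70, rh_amp = 15, rh_noise_sd = 5,
                         start = "2018-01-01", seed = 1L) {
  if (n_days < 1) stopf("n_days must be >= 1")
  if (!length(wind_regimes)) stopf("at least one wind regime is required")
  w <- vapply(wind_regimes, `[[`, numeric(1), "weight")
  if (any(w < 0) || sum(w) <= 0)
    stopf("regime weights must be non-negative with positive sum")
  structure(list(n_days = as.integer(n_days), coldest_month = coldest_month,
                 temp_mean_annual = temp_mean_annual,
                 temp_seasonal_amp = temp_seasonal_amp,
                 temp_diurnal_amp = temp_diurnal_amp,
                 temp_noise_sd = temp_noise_sd,
                 wind_regimes = wind_regimes,
                 rh_mean = rh_mean, rh_amp = rh_amp, rh_noise_sd = rh_noise_sd,
                 start = start, seed = as.integer(seed)),
            class = "met_scenario")
}

#' Generate an hourly meteorological series from a scenario
#'
#' @param scenario a [met_scenario()].
#' @return an `hourly_table` data frame with columns `timestamp`, `ws`, `wd`,
#'   `temp`, `rh`. Identical scenarios (including seed) give bit-identical
#'   tables.
#' @export
generate_meteorology <- function(scenario) {
  stopifnot(inherits(scenario, "met_scenario"))
  n <- scenario$n_days * 24L
  t0 <- as.POSIXct(paste(scenario$start, "00:00"), tz = "UTC")
  ts <- t0 + 3600 * (seq_len(n) - 1L)
  hour <- as.integer(format(ts, "%H"))
  month <- as.integer(format(ts, "%m"))
  yday <- as.integer(format(ts, "%j"))

  coldest_doy <- 15 + 30.44 * (scenario$coldest_month - 1)
  seas <- -scenario$temp_seasonal_amp * cos(2 * pi * (yday - coldest_doy) / 365.25)
  diur <- scenario$temp_diurnal_amp * cos(2 * pi * (hour - 14) / 24)

  withr::with_seed(scenario$seed, {
    temp <- scenario$temp_mean_annual + seas + diur +
      stats::rnorm(n, 0, scenario$temp_noise_sd)

    # regime sampling: group hours by (hour, month) so each group draws from
    # the regimes active there
    ws <- numeric(n); wd <- numeric(n)
    regs <- scenario$wind_regimes
    active <- matrix(FALSE, length(regs), 288)  # (hour, month) combos
    combo <- hour + 24L * (month - 1L) + 1L
    for (r in seq_along(regs)) {
      hm <- outer(0:23 %in% regs[[r]]$hours, 1:12 %in% regs[[r]]$months, "&")
      active[r, ] <- as.vector(hm)
    }
    wts <- vapply(regs, `[[`, numeric(1), "weight")
    for (cb in unique(combo)) {
      idx <- which(combo == cb)
      act <- which(active[, cb] & wts > 0)
      if (!length(act))
        stopf("no active wind regime for hour %d, month %d",
              (cb - 1L) %% 24L, (cb - 1L) %/% 24L + 1L)
      pick <- if (length(act) == 1L) rep(act, length(idx)) else
        sample(act, length(idx), replace = TRUE, prob = wts[act])
      for (r in unique(pick)) {
        i <- idx[pick == r]
        rg <- regs[[r]]
        wd[i] <- (rg$direction_center +
                    stats::rnorm(length(i), 0, rg$direction_spread)) %% 360
        ws[i] <- if (rg$speed_scale > 0)
          stats::rweibull(length(i), rg$speed_shape, rg$speed_scale) else 0
      }
    }

    rh <- scenario$rh_mean + scenario$rh_amp * cos(2 * pi * (hour - 5) / 24) +
      stats::rnorm(n, 0, scenario$rh_noise_sd)
    rh <- pmin(pmax(rh, 2), 100)
  })

  out <- data.frame(timestamp = ts, ws = ws, wd = wd, temp = temp, rh = rh)
  class(out) <- c("hourly_table", "data.frame")
  out
}

# default diurnal emission profiles (24 weights, approx. mean 1)
.traffic_diurnal <- c(0.25, 0.15, 0.10, 0.10, 0.15, 0.35, 0.80, 1.60, 2.00,
                      1.40, 1.00, 0.95, 0.95, 0.90, 0.95, 1.05, 1.20, 1.60,
                      1.90, 1.95, 1.30, 0.90, 0.60, 0.40)
.rwb_diurnal <- c(1.90, 1.40, 1.00, 0.70, 0.55, 0.50, 0.50, 0.55, 0.55, 0.45,
                  0.35, 0.30, 0.25, 0.25, 0.25, 0.30, 0.40, 0.65, 0.95, 1.20,
                  1.55, 1.90, 2.20, 2.35)

#' Define a source archetype
#'
#' An archetype is a statistical emulator of one emission-source category:
#'
#' * `traffic`: diurnal rush-hour cycle, weekend decrease, diluted at high
#'   wind speed (contribution times `1 / (1 + ws_dilution * ws)`).
#' * `rwb` (residential wood burning): heating-degree driver
#'   `base_level + temp_sensitivity * max(0, temp_threshold - T)`, evening /
#'   near-midnight diurnal peak, mild weekend decrease, amplified at low wind
#'   speed; emitted regardless of wind direction.
#' * `industrial`: stack fumigation, nonzero only when the wind blows from
#'   `stack_sector` at speeds >= `ws_activation`, increasing with wind speed.
#' * `aeolian`: wind-blown dust, zero below `ws_threshold` and growing as
#'   `(ws - ws_threshold)^ws_exponent` above it; coarse-dominated.
#' * `regional`: steady background, no weekly or diurnal cycle.
#'
#' Contributions to PM2.5 are `fine_coarse_ratio` times the PM10
#' contribution; gases are emitted in proportion to PM10 via `gas_ratios`.
#'
#' @param name one of `"traffic"`, `"rwb"`, `"industrial"`, `"aeolian"`,
#'   `"regional"`.
#' @param base_level emission scale, ug/m3 (for aeolian, the coefficient of
#'   the above-threshold power law).
#' @param diurnal_profile 24 non-negative weights (hour 0 first).
#' @param weekend_factor multiplier applied on Saturdays and Sundays, in
#'   `(0, 1.5]`.
#' @param temp_sensitivity ug/m3 per deg C below `temp_threshold` (rwb only).
#' @param temp_threshold heating threshold, deg C (rwb only; default 15).
#' @param ws_exponent,ws_threshold power and threshold (m/s) of the aeolian
#'   wind-speed law.
#' @param stack_sector numeric length-2 `(from, to)` wind-direction arc in
#'   degrees for industrial plumes.
#' @param ws_activation minimum wind speed (m/s) bringing stack plumes to the
#'   ground.
#' @param fine_coarse_ratio mean PM2.5/PM10 ratio of emitted particles, in
#'   (0, 1].
#' @param fcr_range optional `c(low, high)`: the source is a per-hour
#'   mixture of a fine end-member (ratio `high`, e.g. exhaust) and a coarse
#'   one (ratio `low`, e.g. resuspended road dust), with the hourly mix
#'   drawn from a Beta law whose mean preserves `fine_coarse_ratio`. This
#'   reproduces the two limiting edge lines of a fine-vs-coarse scatter;
#'   `NULL` (default) keeps the ratio fixed.
#' @param gas_ratios named vector: mass of `co`, `nox`, `no2`, `so2` emitted
#'   per unit PM10 contribution (units pass through).
#' @param ws_dilution ventilation coefficient for traffic/rwb/regional
#'   dilution `1 / (1 + ws_dilution * ws)`.
#' @param day_cv sd (log scale) of day-to-day emission variability for
#'   traffic/rwb/regional archetypes.
#' @return a `source_archetype` list.
#' @export
source_archetype <- function(name, base_level,
                             diurnal_profile = rep(1, 24),
                             weekend_factor = 1,
                             temp_sensitivity = 0, temp_threshold = 15,
                             ws_exponent = 2, ws_threshold = 5,
                             stack_sector = c(45, 135), ws_activation = 6,
                             fine_coarse_ratio = 0.6, fcr_range = NULL,
                             gas_ratios = c(co = 0, nox = 0, no2 = 0, so2 = 0),
                             ws_dilution = 0.35, day_cv = 0.1) {
  kinds <- c("traffic", "rwb", "industrial", "aeolian", "regional")
  if (!name %in% kinds)
    stopf("unknown archetype name '%s' (must be one of %s)", name,
          paste(kinds, collapse = ", "))
  if (fine_coarse_ratio <= 0 || fine_coarse_ratio > 1)
    stopf("fine_coarse_ratio must lie in (0, 1]")
  if (weekend_factor <= 0 || weekend_factor > 1.5)
    stopf("weekend_factor must lie in (0, 1.5]")
  if (length(diurnal_profile) != 24 || any(diurnal_profile < 0))
    stopf("diurnal_profile must be 24 non-negative weights")
  if (!is.null(fcr_range)) {
    if (length(fcr_range) != 2 || fcr_range[1] >= fcr_range[2] ||
        fine_coarse_ratio <= fcr_range[1] ||
        fine_coarse_ratio >= fcr_range[2])
      stopf("fcr_range must bracket fine_coarse_ratio")
  }
  gr <- c(co = 0, nox = 0, no2 = 0, so2 = 0)
  gr[names(gas_ratios)] <- gas_ratios
  structure(list(name = name, base_level = base_level,
                 diurnal_profile = diurnal_profile,
                 weekend_factor = weekend_factor,
                 temp_sensitivity = temp_sensitivity,
                 temp_threshold = temp_threshold,
                 ws_exponent = ws_exponent, ws_threshold = ws_threshold,
                 stack_sector = stack_sector, ws_activation = ws_activation,
                 fine_coarse_ratio = fine_coarse_ratio,
                 fcr_range = fcr_range, gas_ratios = gr,
                 ws_dilution = ws_dilution, day_cv = day_cv),
            class = "source_archetype")
}

#' Generate noise-free per-source contributions (the truth panel)
#'
#' Applies each archetype's emission law to the meteorological series,
#' producing the per-hour, per-source contributions to PM2.5, PM10 and each
#' gas that the observed concentrations are later assembled from. All
#' contributions are deterministic functions of the meteorology except a
#' seeded day-level lognormal emission variability (traffic/rwb/regional).
#'
#' @param met an `hourly_table` with at least `timestamp`, `ws`, `wd`, `temp`.
#' @param archetypes list of [source_archetype()] objects with unique names.
#' @param seed integer seed for the day-level variability.
#' @return a `truth_panel`: list with `timestamp`, `met`, `sources`, and one
#'   hours x sources matrix per pollutant (`pm25`, `pm10`, `co`, `nox`,
#'   `no2`, `so2`).
#' @export
generate_source_contributions <- function(met, archetypes, seed = 1L) {
  nm <- vapply(archetypes, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stopf("archetype names must be unique")
  n <- nrow(met)
  hour <- as.integer(format(met$timestamp, "%H"))
  day <- as.integer(format(met$timestamp, "%j")) +
    366L * (as.integer(format(met$timestamp, "%Y")) - 2000L)
  day_id <- match(day, unique(day))
  wknd <- is_weekend(met$timestamp)

  pm10 <- matrix(0, n, length(archetypes), dimnames = list(NULL, nm))
  pm25 <- pm10
  gases <- list(co = pm10, nox = pm10, no2 = pm10, so2 = pm10)

  withr::with_seed(as.integer(seed), {
    for (j in seq_along(archetypes)) {
      a <- archetypes[[j]]
      dayfac <- if (a$day_cv > 0 && a$name %in% c("traffic", "rwb", "regional"))
        exp(stats::rnorm(max(day_id), 0, a$day_cv))[day_id] else rep(1, n)
      base <- switch(a$name,
        traffic = a$base_level * a$diurnal_profile[hour + 1L] *
          ifelse(wknd, a$weekend_factor, 1) / (1 + a$ws_dilution * met$ws),
        rwb = {
          hdd <- pmax(0, a$temp_threshold - met$temp)
          (a$base_level + a$temp_sensitivity * hdd) *
            a$diurnal_profile[hour + 1L] *
            ifelse(wknd, a$weekend_factor, 1) / (1 + a$ws_dilution * met$ws)
        },
        regional = a$base_level * a$diurnal_profile[hour + 1L] /
          (1 + a$ws_dilution * met$ws),
        aeolian = a$base_level * pmax(0, met$ws - a$ws_threshold)^a$ws_exponent,
        industrial = {
          in_sector <- if (a$stack_sector[1] <= a$stack_sector[2])
            met$wd >= a$stack_sector[1] & met$wd <= a$stack_sector[2]
          else met$wd >= a$stack_sector[1] | met$wd <= a$stack_sector[2]
          a$base_level * ifelse(in_sector & met$ws >= a$ws_activation,
                                met$ws / a$ws_activation, 0)
        })
      pm10[, j] <- base * dayfac
      fcr <- if (is.null(a$fcr_range)) a$fine_coarse_ratio else {
        # hourly fine/coarse end-member mixing, mean-preserving
        mu <- (a$fine_coarse_ratio - a$fcr_range[1]) / diff(a$fcr_range)
        mix <- stats::rbeta(n, 2 * mu, 2 * (1 - mu))
        a$fcr_range[1] + diff(a$fcr_range) * mix
      }
      pm25[, j] <- fcr * pm10[, j]
      for (g in names(gases)) gases[[g]][, j] <- a$gas_ratios[[g]] * pm10[, j]
    }
  })

  structure(list(timestamp = met$timestamp, met = met, sources = nm,
                 pm25 = pm25, pm10 = pm10,
                 co = gases$co, nox = gases$nox, no2 = gases$no2,
                 so2 = gases$so2),
            class = "truth_panel")
}

#' Multiplicative measurement-noise factors
#'
#' Lognormal-type noise: Gaussian in log space truncated at +/- 4 sd, scaled
#' so the factor has mean 1 and coefficient of variation `cv` (positive
#' concentrations stay positive).
#' @noRd
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  z <- stats::rnorm(n, 0, sdlog)
  z <- pmin(pmax(z, -4 * sdlog), 4 * sdlog)
  exp(z - sdlog^2 / 2)
}

#' Assemble observed concentrations from a truth panel
#'
#' Observed pollutant = (sum of per-source truth) x (1 + noise), with
#' multiplicative lognormal-type noise of coefficient of variation
#' `noise_cv` applied independently per pollutant and hour. PM2.5 is clipped
#' to PM10 after noise; the number of clipped hours is recorded in
#' `attr(, "n_pm25_clipped")`.
#'
#' @param truth a `truth_panel`.
#' @param noise_cv measurement noise coefficient of variation (>= 0).
#' @param seed integer seed.
#' @return an `hourly_table` with met columns plus `pm25`, `pm10`, `nox`,
#'   `no2`, `co`, `so2`.
#' @export
assemble_observations <- function(truth, noise_cv = 0.25, seed = 1L) {
  stopifnot(inherits(truth, "truth_panel"))
  if (noise_cv < 0) stopf("noise_cv must be >= 0")
  n <- length(truth$timestamp)
  out <- truth$met
  withr::with_seed(as.integer(seed), {
    for (p in c("pm25", "pm10", "nox", "no2", "co", "so2"))
      out[[p]] <- rowSums(truth[[p]]) * noise_factor(n, noise_cv)
  })
  clipped <- out$pm25 > out$pm10
  out$pm25 <- pmin(out$pm25, out$pm10)
  attr(out, "n_pm25_clipped") <- sum(clipped)
  class(out) <- c("hourly_table", "data.frame")
  out
}

#' Build a weekly sampling schedule
#'
#' Mimics a filter-based campaign that samples the same `days_per_week`
#' weekdays (Monday-first) every week: each period collects the 24 hourly
#' rows of each sampled day.
#'
#' @param timestamp POSIXct vector of the hourly series being sampled.
#' @param n_weeks number of weekly periods.
#' @param days_per_week number of sampling days (1-7), taken Monday onwards.
#' @param start_week 1-based index of the first sampled week.
#' @return list of integer row-index vectors, one per period, with names
#'   `"week 1"`, ...
#' @export
weekly_schedule <- function(timestamp, n_weeks, days_per_week = 5,
                            start_week = 1) {
  if (n_weeks < 1) stopf("empty schedule")
  wd <- weekday_num(timestamp)
  day0 <- as.numeric(difftime(timestamp, timestamp[1], units = "days"))
  week <- floor(day0 / 7) + 1L
  periods <- lapply(seq_len(n_weeks), function(w) {
    which(week == (w + start_week - 1L) & wd <= days_per_week)
  })
  names(periods) <- paste("week", seq_len(n_weeks))
  if (any(!lengths(periods)))
    stopf("schedule periods lie outside the series span")
  periods
}

#' Generate speciated filter samples from a truth panel
#'
#' Forward mass-balance model: the species concentration in sample i is
#' `X[i, j] = sum_k gbar[i, k] * F[k, j]` where `gbar` holds period-mean
#' PM2.5 source contributions over the scheduled hours and `F` the species
#' mass fractions of each source profile, plus Gaussian noise of sd
#' `sigma[i, j] = max(noise_cv * X_true[i, j], sigma_floor)`.
#'
#' @param truth a `truth_panel`.
#' @param profiles sources x species matrix of mass fractions (rownames are
#'   source names matching the truth panel; each row sums to <= 1).
#' @param schedule list of hour-index vectors (see [weekly_schedule()]).
#' @param noise_cv relative measurement uncertainty of species
#'   concentrations.
#' @param seed integer seed.
#' @param sigma_floor lower bound on reported uncertainties (keeps
#'   `sigma > 0` for zero-valued species).
#' @return a `speciated_samples` list with `X`, `sigma` (samples x species),
#'   `periods`, and the period-mean true contributions in
#'   `attr(, "g_true")`.
#' @export
generate_speciated_samples <- function(truth, profiles, schedule,
                                       noise_cv = 0.05, seed = 1L,
                                       sigma_floor = 1e-3) {
  stopifnot(inherits(truth, "truth_panel"), is.matrix(profiles))
  if (!length(schedule)) stopf("empty schedule")
  if (is.null(rownames(profiles)) ||
      !all(rownames(profiles) %in% truth$sources))
    stopf("profile rownames must name sources present in the truth panel")
  if (any(profiles < 0) || any(rowSums(profiles) > 1 + 1e-8))
    stopf("profiles must be non-negative mass fractions with row sums <= 1")
  src <- rownames(profiles)
  gt <- vapply(schedule, function(idx) {
    if (!length(idx)) stopf("schedule period with no hours")
    colMeans(truth$pm25[idx, src, drop = FALSE])
  }, numeric(length(src)))
  g_true <- if (is.matrix(gt)) t(gt) else matrix(gt, ncol = 1)
  colnames(g_true) <- src
  x_true <- g_true %*% profiles
  sigma <- pmax(noise_cv * abs(x_true), sigma_floor)
  withr::with_seed(as.integer(seed), {
    noise <- if (noise_cv > 0)
      matrix(stats::rnorm(length(x_true), 0, sigma), nrow(x_true)) else 0
  })
  X <- x_true + noise
  structure(list(X = X, sigma = sigma,
                 periods = data.frame(period = names(schedule),
                                      n_hours = lengths(schedule))),
            g_true = g_true, class = "speciated_samples")
}

#' Default chemical source profiles
#'
#' Species mass fractions (of PM2.5 mass) for the five source archetypes,
#' loosely patterned on urban receptor-modelling practice: traffic rich in
#' elemental carbon, wood smoke in organic carbon/levoglucosan/potassium,
#' dust in crustal elements, industry and regional background in sulfate.
#'
#' @param sources character vector of archetype names to include.
#' @return sources x species matrix of mass fractions (row sums < 1; the
#'   remainder is unspeciated mass).
#' @export
default_profiles <- function(sources = c("traffic", "rwb")) {
  species <- c("OC", "EC", "levoglucosan", "K", "Si", "Ca", "NO3", "SO4")
  all <- rbind(
    traffic    = c(0.25, 0.35, 0.000, 0.005, 0.050, 0.030, 0.060, 0.050),
    rwb        = c(0.48, 0.08, 0.120, 0.040, 0.005, 0.005, 0.020, 0.030),
    industrial = c(0.08, 0.05, 0.000, 0.005, 0.020, 0.020, 0.030, 0.450),
    aeolian    = c(0.05, 0.01, 0.000, 0.015, 0.280, 0.120, 0.010, 0.020),
    regional   = c(0.20, 0.04, 0.000, 0.010, 0.020, 0.010, 0.120, 0.350))
  colnames(all) <- species
  bad <- setdiff(sources, rownames(all))
  if (length(bad)) stopf("no default profile for: %s", paste(bad, collapse = ", "))
  all[sources, , drop = FALSE]
}

#' Scenario preset: wood-smoke-dominated city (Temuco-like)
#'
#' Two simulated years at a cool, wet mid-latitude site: a strong residential
#' wood burning source driven by heating demand (peaking near midnight in
#' cold months, emitted under calm meandering winds from all directions) plus
#' a traffic source sampled under two directional wind corridors. Clustered
#' with temperature as the radial variable, a three-cluster solution should
#' produce one central wood-smoke cluster and two directional traffic
#' clusters.
#'
#' @param n_days simulated days (default two years).
#' @param seed integer seed propagated to met, truth and noise generation.
#' @return list with `scenario`, `archetypes`, and the recommended
#'   clustering settings (`pollutant`, `radial_variable`, `k`).
#' @export
temuco_like_scenario <- function(n_days = 730, seed = 1L) {
  scen <- met_scenario(
    n_days = n_days, coldest_month = 7, temp_mean_annual = 12,
    temp_seasonal_amp = 6, temp_diurnal_amp = 5, temp_noise_sd = 1.2,
    wind_regimes = list(
      # daytime westerly valley flow
      wind_regime(250, 25, speed_scale = 3.5, hours = 9:19, weight = 1),
      # easterly corridor (daytime) and morning drainage flow
      wind_regime(70, 25, speed_scale = 3.0, weight = 0.6),
      # calm nights with meandering directions, ending before dawn
      wind_regime(0, 180, speed_scale = 0.9, hours = c(20:23, 0:5),
                  weight = 1.4)),
    rh_mean = 75, rh_amp = 15, seed = seed)
  arch <- list(
    source_archetype("traffic", base_level = 9,
                     diurnal_profile = .traffic_diurnal,
                     weekend_factor = 0.6, fine_coarse_ratio = 0.6,
                     fcr_range = c(0.1, 0.95),
                     gas_ratios = c(co = 8, nox = 6, no2 = 1.2, so2 = 0.3)),
    source_archetype("rwb", base_level = 1, temp_sensitivity = 2.8,
                     temp_threshold = 12, diurnal_profile = .rwb_diurnal,
                     weekend_factor = 0.95, fine_coarse_ratio = 0.9,
                     ws_dilution = 0.25,
                     gas_ratios = c(co = 6, nox = 0.8, no2 = 0.2, so2 = 0.15)))
  list(scenario = scen, archetypes = arch,
       pollutant = "pm25", radial_variable = "temperature", k = 3L)
}

#' Scenario preset: desert mining city (Calama-like)
#'
#' Two simulated years at an arid site where PM10 is the pollutant of
#' concern: a traffic source (coarse-rich, road dust) sampled under three
#' wind corridors (morning calm easterlies, daytime anabatic westerlies, a
#' seasonal north-westerly), and an aeolian dust source active only above a
#' wind-speed threshold under the two high-wind regimes. A five-cluster
#' solution on wind-speed radial coordinates should resolve three traffic
#' and two aeolian clusters.
#'
#' @inheritParams temuco_like_scenario
#' @return list with `scenario`, `archetypes`, `pollutant`,
#'   `radial_variable`, `k`.
#' @export
calama_like_scenario <- function(n_days = 730, seed = 1L) {
  scen <- met_scenario(
    n_days = n_days, coldest_month = 7, temp_mean_annual = 12,
    temp_seasonal_amp = 5, temp_diurnal_amp = 8, temp_noise_sd = 1,
    wind_regimes = list(
      # daytime anabatic upslope westerlies, year-round
      wind_regime(280, 20, speed_scale = 7, hours = 11:18, weight = 1),
      # winter-season strong NNW synoptic winds
      wind_regime(340, 12, speed_scale = 9, hours = 12:19, months = 5:8,
                  weight = 0.7),
      # calm nights and mornings, easterly drainage
      wind_regime(100, 35, speed_scale = 1.6, hours = c(19:23, 0:10),
                  weight = 1.2),
      # southerly corridor at moderate speed
      wind_regime(180, 25, speed_scale = 2.8, weight = 0.5)),
    rh_mean = 30, rh_amp = 10, seed = seed)
  arch <- list(
    source_archetype("traffic", base_level = 30,
                     diurnal_profile = .traffic_diurnal,
                     weekend_factor = 0.65, fine_coarse_ratio = 0.3,
                     fcr_range = c(0.08, 0.9), ws_dilution = 0.5,
                     gas_ratios = c(co = 6, nox = 5, no2 = 1, so2 = 0.4)),
    source_archetype("aeolian", base_level = 5, ws_threshold = 5,
                     ws_exponent = 2, fine_coarse_ratio = 0.15))
  list(scenario = scen, archetypes = arch,
       pollutant = "pm10", radial_variable = "wind_speed", k = 5L)
}

#' Run a scenario preset end to end
#'
#' Generates meteorology, the truth panel, and the observed hourly table in
#' one call.
#'
#' @param preset list from [temuco_like_scenario()] or
#'   [calama_like_scenario()] (or a custom list with `scenario` and
#'   `archetypes`).
#' @param noise_cv measurement noise coefficient of variation.
#' @param seed integer seed; defaults to the scenario's own seed.
#' @return list with `met`, `truth`, `table` plus the preset's clustering
#'   settings.
#' @export
simulate_scenario <- function(preset, noise_cv = 0.25, seed = NULL) {
  scen <- preset$scenario
  if (!is.null(seed)) scen$seed <- as.integer(seed)
  met <- generate_meteorology(scen)
  truth <- generate_source_contributions(met, preset$archetypes,
                                         seed = scen$seed + 1L)
  table <- assemble_observations(truth, noise_cv = noise_cv,
                                 seed = scen$seed + 2L)
  list(met = met, truth = truth, table = table,
       pollutant = preset$pollutant %||% "pm25",
       radial_variable = preset$radial_variable %||% "wind_speed",
       k = preset$k %||% 3L)
}
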