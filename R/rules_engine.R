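#' Diurnal, weekday and monthly time-variation profiles
#'
#' Stratified means with standard errors (`sd/sqrt(n)`) of each cluster or
#' source series: by hour of day, by weekday (Monday first) and by calendar
#' month. Empty strata are flagged with `n = 0`.
#'
#' @param series a `contribution_series` or `source_series`.
#' @return list with data frames `diurnal`, `weekday`, `monthly`.
#' @export
time_variation <- function(series) {
  list(diurnal = aggregate_contributions(series, "hour"),
       weekday = aggregate_contributions(series, "weekday"),
       monthly = aggregate_contributions(series, "calendar_month"))
}

#' Weekend-to-weekday contribution ratio
#'
#' `(Saturday-Sunday mean) / (Monday-Friday mean)` per series column.
#' Traffic contributions universally drop on weekends (ratios well below 1),
#' wood smoke drops less, industrial and wind-driven sources stay near 1.
#'
#' @param series a `contribution_series` or `source_series`.
#' @return named numeric vector of ratios; `NA` (flagged via attribute
#'   `"undefined"`) where the weekday mean is zero.
#' @export
weekend_ratio <- function(series) {
  wk <- is_weekend(series$timestamp)
  if (!any(wk) || all(wk)) stopf("both weekday and weekend hours are required")
  cols <- setdiff(names(series), "timestamp")
  ratios <- vapply(cols, function(cn) {
    wd_mean <- mean(series[[cn]][!wk], na.rm = TRUE)
    we_mean <- mean(series[[cn]][wk], na.rm = TRUE)
    if (wd_mean == 0) NA_real_ else we_mean / wd_mean
  }, numeric(1))
  attr(ratios, "undefined") <- names(ratios)[is.na(ratios)]
  ratios
}

#' Limiting edge-line slopes of a fine-vs-coarse scatter
#'
#' The upper and lower bounding slopes of a PM2.5 vs PM10 point cloud are
#' read as the fine/coarse ratios of two mixing end-members (e.g. exhaust
#' near 1:1 versus road dust near 0.1). They are estimated as empirical
#' quantiles of the per-hour PM2.5/PM10 ratio rather than regressions
#' through the origin: simpler, monotone and robust.
#'
#' @param pm25,pm10 paired concentrations within one cluster.
#' @param tau_low,tau_high ratio quantiles for the lower/upper edges.
#' @param pm10_floor exclude hours with PM10 below this (ratio unstable).
#' @param min_pairs minimum retained pairs; fewer marks the diagnostic
#'   unavailable (`NA`s).
#' @return named numeric `c(lower, upper)`.
#' @export
edge_slopes <- function(pm25, pm10, tau_low = 0.05, tau_high = 0.95,
                        pm10_floor = 5, min_pairs = 30) {
  ok <- !is.na(pm25) & !is.na(pm10) & pm10 >= pm10_floor
  if (sum(ok) < min_pairs) return(c(lower = NA_real_, upper = NA_real_))
  q <- stats::quantile(pm25[ok] / pm10[ok], c(tau_low, tau_high),
                       names = FALSE)
  c(lower = q[1], upper = q[2])
}

#' Dependence of a contribution on a meteorological variable
#'
#' Ordinary least-squares slope of the contribution on the met variable over
#' the paired hours, with Pearson correlation and r-squared. Negative
#' wind-speed slopes indicate ventilation-limited area sources (traffic,
#' wood smoke); positive slopes indicate fumigating stacks or wind-blown
#' dust; negative temperature slopes indicate heating-driven sources.
#'
#' @param contribution numeric vector (the cluster's concentrations).
#' @param met paired met-variable vector.
#' @param min_pairs minimum complete pairs.
#' @return list `slope`, `cor`, `r2`, `n`; `NA`s when unavailable (too few
#'   pairs or zero met variance).
#' @export
met_dependence <- function(contribution, met, min_pairs = 30) {
  ok <- !is.na(contribution) & !is.na(met)
  n <- sum(ok)
  if (n < min_pairs || stats::var(met[ok]) == 0)
    return(list(slope = NA_real_, cor = NA_real_, r2 = NA_real_, n = n))
  x <- met[ok]; y <- contribution[ok]
  slope <- stats::cov(x, y) / stats::var(x)
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  list(slope = slope, cor = r, r2 = r^2, n = n)
}

#' Apportion gaseous co-pollutants across clusters
#'
#' For each gas, the share of total gas mass observed during the hours of
#' each cluster (shares sum to 1 over clusters), plus the mean NO2/NOx
#' ratio within the cluster (aged regional air shows elevated ratios; fresh
#' traffic emissions low ones). CO follows traffic and wood smoke; SO2
#' traces large industrial point sources.
#'
#' @param table the source `hourly_table`.
#' @param solution a `cluster_solution`.
#' @param gases gas columns to apportion; all-missing gases are omitted.
#' @return list with `shares` (clusters x gases matrix) and `no2_nox_ratio`
#'   (per-cluster vector); omitted gases recorded in `attr(, "omitted")`.
#' @export
gas_apportionment <- function(table, solution,
                              gases = c("co", "nox", "no2", "so2")) {
  stopifnot(inherits(solution, "cluster_solution"))
  gases <- intersect(gases, names(table))
  k <- solution$k
  assign <- solution$assignment
  idx <- solution$kept_idx
  omitted <- character(0)
  shares <- matrix(NA_real_, k, length(gases),
                   dimnames = list(paste0("C", seq_len(k)), gases))
  for (g in gases) {
    v <- table[[g]][idx]
    tot <- sum(v, na.rm = TRUE)
    if (all(is.na(v)) || tot == 0) { omitted <- c(omitted, g); next }
    shares[, g] <- vapply(seq_len(k), function(j)
      sum(v[assign == j], na.rm = TRUE) / tot, numeric(1))
  }
  shares <- shares[, setdiff(gases, omitted), drop = FALSE]
  no2_nox <- rep(NA_real_, k)
  if (all(c("no2", "nox") %in% names(table))) {
    no2 <- table$no2[idx]; nox <- table$nox[idx]
    no2_nox <- vapply(seq_len(k), function(j) {
      mn <- mean(nox[assign == j], na.rm = TRUE)
      if (!is.finite(mn) || mn == 0) NA_real_
      else mean(no2[assign == j], na.rm = TRUE) / mn
    }, numeric(1))
  }
  structure(list(shares = shares, no2_nox_ratio = no2_nox),
            omitted = omitted)
}

#' Four coldest and four warmest calendar months of a table
#'
#' Derived from the input's own temperature climatology, so the seasonality
#' rules are hemisphere-agnostic.
#' @noRd
cold_warm_months <- function(table) {
  mo <- as.integer(format(table$timestamp, "%m"))
  clim <- vapply(1:12, function(m) {
    v <- table$temp[mo == m]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  ord <- order(clim)
  list(cold = ord[1:4], warm = rev(ord)[1:4])
}

#' Compute the full identification diagnostics for every cluster
#'
#' Assembles, per cluster, every metric the source-identification rules
#' consume: diurnal profile and top-2 peak hours, weekend ratio, cold/warm
#' seasonal ratio (4 coldest vs 4 warmest calendar months of the input's
#' own temperature climatology), fine/coarse edge-line slopes, least-squares
#' slopes of contribution on wind speed, temperature and relative humidity,
#' polar geometry (sector coverage below the median radius, convex hull
#' containing the origin, number of sectors holding at least 5% of the
#' cluster's points), the fraction of contribution occurring below a
#' wind-speed threshold, gas shares and the NO2/NOx ratio.
#'
#' @param table the source `hourly_table`.
#' @param solution a `cluster_solution`.
#' @param features the `polar_features` the solution was fitted on.
#' @param config rule configuration, see [default_rule_config()] (supplies
#'   the aeolian wind-speed threshold and sector occupancy cutoffs).
#' @return a `cluster_diagnostics` object: list of per-cluster lists.
#' @export
cluster_diagnostics <- function(table, solution, features,
                                config = default_rule_config()) {
  series <- contribution_series(table, solution)
  tv <- time_variation(series)
  wr <- weekend_ratio(series)
  geom <- central_cluster_candidates(solution, features)
  geom <- geom[order(geom$cluster), ]
  gas <- gas_apportionment(table, solution)

  idx <- attr(series, "kept_idx")
  assign <- attr(series, "assignment")
  ts <- series$timestamp
  mo <- as.integer(format(ts, "%m"))
  cw <- cold_warm_months(table)
  ws <- table$ws[idx]; temp <- table$temp[idx]; rh <- table$rh[idx]
  pm25 <- if ("pm25" %in% names(table)) table$pm25[idx] else NULL
  pm10 <- if ("pm10" %in% names(table)) table$pm10[idx] else NULL
  wd_sector <- sector_index(features$data$wd)[match(idx, attr(series, "kept_idx"))]

  k <- solution$k
  diag <- lapply(seq_len(k), function(j) {
    cn <- paste0("C", j)
    in_j <- assign == j
    contrib <- series[[cn]]
    diurnal <- tv$diurnal[tv$diurnal$source == cn, ]
    peak_hours <- diurnal$period[order(diurnal$mean,
                                       decreasing = TRUE)][1:2]
    cold_mean <- mean(contrib[mo %in% cw$cold], na.rm = TRUE)
    warm_mean <- mean(contrib[mo %in% cw$warm], na.rm = TRUE)
    cold_warm <- if (is.finite(warm_mean) && warm_mean > 0)
      cold_mean / warm_mean else NA_real_
    edges <- if (!is.null(pm25) && !is.null(pm10))
      edge_slopes(pm25[in_j], pm10[in_j],
                  pm10_floor = config$edge_pm10_floor)
    else c(lower = NA_real_, upper = NA_real_)
    conc_j <- contrib[in_j]
    sect <- table(sector_index(table$wd[idx][in_j]))
    occupancy <- sum(sect / sum(sect) >= config$sector_min_share)
    tot <- sum(conc_j, na.rm = TRUE)
    low_ws_frac <- if (tot > 0)
      sum(conc_j[ws[in_j] < config$aeolian_ws_threshold], na.rm = TRUE) / tot
    else NA_real_
    list(cluster = j,
         diurnal_profile = diurnal$mean,
         peak_hours = peak_hours,
         weekend_ratio = unname(wr[cn]),
         cold_warm_ratio = cold_warm,
         fine_coarse_lower = unname(edges["lower"]),
         fine_coarse_upper = unname(edges["upper"]),
         ws_slope = met_dependence(conc_j, ws[in_j])$slope,
         temp_slope = met_dependence(conc_j, temp[in_j])$slope,
         rh_slope = met_dependence(conc_j, rh[in_j])$slope,
         sector_coverage = geom$coverage[j],
         hull_contains_origin = geom$hull_contains_origin[j],
         sector_occupancy = occupancy,
         low_ws_frac = low_ws_frac,
         gas_shares = if (ncol(gas$shares)) gas$shares[j, ] else NULL,
         so2_share = if ("so2" %in% colnames(gas$shares))
           gas$shares[j, "so2"] else NA_real_,
         so2_enrichment = if ("so2" %in% colnames(gas$shares))
           gas$shares[j, "so2"] / (sum(in_j) / length(assign))
         else NA_real_,
         so2_cold_warm = {
           if ("so2" %in% names(table)) {
             so2 <- table$so2[idx]
             cm <- mean(so2[in_j & mo %in% cw$cold], na.rm = TRUE)
             wm <- mean(so2[in_j & mo %in% cw$warm], na.rm = TRUE)
             if (is.finite(wm) && wm > 0 && is.finite(cm)) cm / wm
             else NA_real_
           } else NA_real_
         },
         no2_nox_ratio = gas$no2_nox_ratio[j],
         n_hours = sum(in_j))
  })
  structure(diag, k = k, pollutant = attr(series, "pollutant"),
            cold_months = cw$cold, warm_months = cw$warm,
            class = "cluster_diagnostics")
}

#' Default source-identification rule configuration
#'
#' Each identification rule clause is a named, thresholded predicate; every
#' threshold lives here so it is visible and overridable. The fine-particle
#' cutoff of 0.7 for wood smoke is the one value fixed by receptor-modelling
#' practice; the remaining cut-points are declared implementation defaults.
#' Clause weights are 1 (unweighted counts) unless overridden via `weights`.
#'
#' @param ... named overrides of any listed default.
#' @return configuration list consumed by [classify_clusters()] and
#'   [cluster_diagnostics()].
#' @export
default_rule_config <- function(...) {
  cfg <- list(
    rwb_upper_edge = 0.7,        # PM2.5/PM10 upper edge for wood smoke
    rwb_cold_warm = 2,           # cold/warm seasonal contribution ratio
    rwb_peak_hours = c(22, 23, 0, 1),
    central_coverage_min = 0.75,  # sectors occupied below median radius
    rush_morning = 6:10,
    rush_evening = 17:21,
    traffic_weekend_max = 0.85,
    traffic_lower_edge = 0.3,    # road-dust lower edge
    steady_weekend = c(0.9, 1.1),
    confined_sectors_max = 6,    # of 16; "hot spot" directionality
    sector_min_share = 0.05,     # a sector counts as occupied at >= 5% of pts
    so2_enrichment_min = 1.5,    # industrial: SO2 share / hour share
    so2_year_round = c(0.5, 2),  # regional: cold/warm SO2 ratio window
    aeolian_ws_threshold = 4,    # m/s
    aeolian_low_ws_frac = 0.1,
    aeolian_upper_edge = 0.7,    # upper edge below the combustion divider
    no2_nox_elevated = 0.5,
    edge_pm10_floor = 5,
    score_floor = 2,             # min fired clauses before labelling
    # SO2 is the defining industrial tracer, so its clause carries double
    # weight: wind-driven coarse sources share the other industrial
    # signatures (ws-positive, confined sector, weekend-steady) but not the
    # SO2 enrichment
    weights = list(industrial = c(ws_positive = 1, confined_sector = 1,
                                  so2_rich = 2, weekend_steady = 1)))
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' @noRd
rule_clauses <- function(d, cfg, k) {
  between <- function(x, lim) !is.na(x) & x >= lim[1] & x <= lim[2]
  ge <- function(x, v) if (is.na(x)) NA else x >= v
  le <- function(x, v) if (is.na(x)) NA else x <= v
  lt <- function(x, v) if (is.na(x)) NA else x < v
  gt <- function(x, v) if (is.na(x)) NA else x > v
  list(
    rwb = c(
      upper_edge_high = ge(d$fine_coarse_upper, cfg$rwb_upper_edge),
      cold_season_peak = ge(d$cold_warm_ratio, cfg$rwb_cold_warm),
      central_cluster = if (is.na(d$hull_contains_origin)) NA
        else isTRUE(d$hull_contains_origin) &&
          d$sector_coverage >= cfg$central_coverage_min,
      temp_negative = lt(d$temp_slope, 0),
      midnight_peak = if (anyNA(d$peak_hours)) NA
        else any(d$peak_hours %in% cfg$rwb_peak_hours)),
    traffic = c(
      weekend_drop = le(d$weekend_ratio, cfg$traffic_weekend_max),
      rush_hour_peaks = if (anyNA(d$peak_hours)) NA
        else any(d$peak_hours %in% cfg$rush_morning) &&
          any(d$peak_hours %in% cfg$rush_evening),
      ws_negative = lt(d$ws_slope, 0),
      road_dust_edge = le(d$fine_coarse_lower, cfg$traffic_lower_edge)),
    industrial = c(
      ws_positive = gt(d$ws_slope, 0),
      confined_sector = le(d$sector_occupancy, cfg$confined_sectors_max),
      so2_rich = ge(d$so2_enrichment, cfg$so2_enrichment_min),
      weekend_steady = if (is.na(d$weekend_ratio)) NA
        else between(d$weekend_ratio, cfg$steady_weekend)),
    aeolian = c(
      ws_threshold = le(d$low_ws_frac, cfg$aeolian_low_ws_frac),
      ws_positive = gt(d$ws_slope, 0),
      coarse_dominated = le(d$fine_coarse_upper, cfg$aeolian_upper_edge)),
    regional = c(
      confined_sector = le(d$sector_occupancy, cfg$confined_sectors_max),
      weekend_steady = if (is.na(d$weekend_ratio)) NA
        else between(d$weekend_ratio, cfg$steady_weekend),
      so2_year_round = if (is.na(d$so2_enrichment) || is.na(d$so2_cold_warm)) NA
        else d$so2_enrichment >= 1 &&
          between(d$so2_cold_warm, cfg$so2_year_round),
      aged_air = ge(d$no2_nox_ratio, cfg$no2_nox_elevated)))
}

#' Map clusters to source archetypes with the identification rules
#'
#' Evaluates every rule clause per cluster; each archetype's score is the
#' weighted fraction of its evaluable clauses that fired (unavailable
#' diagnostics are excluded from both numerator and denominator, so
#' degenerate inputs lower scores but never crash). A cluster is labeled
#' with the top-scoring archetype, or `unidentified` when fewer than
#' `score_floor` clauses fired for it or the top score is tied. The
#' rationale lists every fired clause. Deterministic and invariant to
#' cluster numbering.
#'
#' @param diagnostics a `cluster_diagnostics` object.
#' @param config rule configuration, see [default_rule_config()].
#' @return a `source_label_map`: data frame (`cluster`, `label`, `score`,
#'   `n_fired`) with per-archetype score matrix in `attr(, "scores")` and
#'   fired-clause rationale in `attr(, "rationale")`.
#' @export
classify_clusters <- function(diagnostics, config = default_rule_config()) {
  stopifnot(inherits(diagnostics, "cluster_diagnostics"))
  k <- attr(diagnostics, "k")
  archetypes <- c("rwb", "traffic", "industrial", "aeolian", "regional")
  scores <- matrix(0, k, length(archetypes),
                   dimnames = list(paste0("C", seq_len(k)), archetypes))
  fired_n <- scores
  rationale <- vector("list", k)
  for (j in seq_len(k)) {
    cl <- rule_clauses(diagnostics[[j]], config, k)
    fired_names <- character(0)
    for (a in archetypes) {
      v <- cl[[a]]
      w <- config$weights[[a]] %||% rep(1, length(v))
      ok <- !is.na(v)
      scores[j, a] <- if (any(ok)) sum(w[ok] * v[ok]) / sum(w[ok]) else 0
      fired_n[j, a] <- sum(v[ok])
      if (any(ok & v))
        fired_names <- c(fired_names,
                         paste0(a, ":", names(v)[ok & v == 1]))
    }
    rationale[[j]] <- fired_names
  }
  label <- vapply(seq_len(k), function(j) {
    s <- scores[j, ]
    top <- which(s == max(s))
    if (max(s) == 0 || fired_n[j, top[1]] < config$score_floor ||
        length(top) > 1) "unidentified" else archetypes[top]
  }, character(1))
  out <- data.frame(cluster = seq_len(k), label = label,
                    score = apply(scores, 1, max),
                    n_fired = fired_n[cbind(seq_len(k),
                                            max.col(scores,
                                                    ties.method = "first"))],
                    row.names = NULL)
  structure(out, scores = scores, rationale = rationale,
            class = c("source_label_map", "data.frame"))
}
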