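# build a contribution_series-like frame directly
series_of <- function(values_by_cluster, start = "2018-01-01") {
  n <- length(values_by_cluster[[1]])
  ts <- as.POSIXct(start, tz = "UTC") + 3600 * (seq_len(n) - 1)
  out <- data.frame(timestamp = ts)
  for (nm in names(values_by_cluster)) out[[nm]] <- values_by_cluster[[nm]]
  class(out) <- c("contribution_series", "data.frame")
  out
}

test_that("time variation of a constant series is flat with zero standard error", {
  ser <- series_of(list(C1 = rep(4, 24 * 14)))
  tv <- time_variation(ser)
  expect_equal(tv$diurnal$mean, rep(4, 24))
  expect_equal(tv$diurnal$se, rep(0, 24))
  expect_equal(tv$weekday$period, 1:7)  # Monday-first
  expect_equal(tv$weekday$mean, rep(4, 7))
})

test_that("a series nonzero only at hour 0 has a single diurnal spike", {
  v <- rep(0, 24 * 7)
  v[seq(1, length(v), by = 24)] <- 12
  tv <- time_variation(series_of(list(C1 = v)))
  expect_equal(tv$diurnal$mean[tv$diurnal$period == 0], 12)
  expect_equal(tv$diurnal$mean[tv$diurnal$period != 0], rep(0, 23))
})

test_that("weekend ratio is the weekend mean over the weekday mean", {
  # 2018-01-01 is a Monday: hours 0-119 weekdays, 120-167 weekend
  v <- c(rep(10, 120), rep(6, 48))
  expect_equal(unname(weekend_ratio(series_of(list(C1 = v)))["C1"]), 0.6)
  expect_equal(unname(weekend_ratio(series_of(list(C1 = rep(3, 168))))["C1"]), 1)
  wr <- weekend_ratio(series_of(list(C1 = c(rep(0, 120), rep(1, 48)))))
  expect_true(is.na(wr["C1"]))
  expect_equal(attr(wr, "undefined"), "C1")
})

test_that("edge slopes recover constructed fine/coarse ratio quantiles", {
  pm10 <- rep(20, 200)
  expect_equal(edge_slopes(0.8 * pm10, pm10), c(lower = 0.8, upper = 0.8))
  expect_equal(edge_slopes(pm10, pm10), c(lower = 1, upper = 1))
  mixed <- rep(c(0.9, 0.1), each = 100) * pm10
  es <- edge_slopes(mixed, pm10)
  expect_equal(unname(es), c(0.1, 0.9), tolerance = 1e-9)
  # too few qualifying pairs marks the diagnostic unavailable
  expect_true(all(is.na(edge_slopes(rep(4, 10), rep(6, 10)))))
  expect_true(all(is.na(edge_slopes(rep(1, 100), rep(2, 100),
                                    pm10_floor = 5))))
})

test_that("met dependence recovers exact slopes and flags degenerate inputs", {
  ws <- runif(100, 0, 10)
  md <- met_dependence(2 * ws, ws)
  expect_equal(md$slope, 2, tolerance = 1e-10)
  expect_equal(md$r2, 1, tolerance = 1e-10)
  flat <- met_dependence(rep(5, 100), ws)
  expect_equal(flat$slope, 0, tolerance = 1e-10)
  expect_true(is.na(met_dependence(ws, rep(1, 100))$slope))
  expect_true(is.na(met_dependence(ws[1:5], ws[1:5])$slope))
})

test_that("gas shares sum to one per gas and isolate single-cluster gases", {
  tab <- tiny_hourly_table(200)
  f <- standardize(to_polar_features(tab, "pm25"))
  sol <- kmeans_cluster(f, k = 3, seed = 2)
  ga <- gas_apportionment(tab, sol)
  expect_equal(unname(colSums(ga$shares)), rep(1, ncol(ga$shares)),
               tolerance = 1e-9)
  # single cluster holds every share
  sol1 <- kmeans_cluster(f, k = 1, seed = 2)
  ga1 <- gas_apportionment(tab, sol1)
  expect_equal(unname(ga1$shares[1, ]), rep(1, 4))
  # a gas present only during one cluster's hours is fully apportioned there
  tab2 <- tab
  tab2$so2 <- ifelse(sol$assignment == 2, 5, 0)
  ga2 <- gas_apportionment(tab2, sol)
  expect_equal(unname(ga2$shares[, "so2"]), c(0, 1, 0))
})

test_that("textbook diagnostic profiles classify to the expected archetypes", {
  base <- list(cluster = 1, diurnal_profile = rep(1, 24),
               peak_hours = c(12, 13), weekend_ratio = 1,
               cold_warm_ratio = 1, fine_coarse_lower = 0.5,
               fine_coarse_upper = 0.6, ws_slope = 0, temp_slope = 0,
               rh_slope = 0, sector_coverage = 0.5,
               hull_contains_origin = FALSE, sector_occupancy = 8,
               low_ws_frac = 0.5, gas_shares = NULL, so2_share = 0.2,
               so2_enrichment = 1, so2_cold_warm = 1, no2_nox_ratio = 0.3,
               n_hours = 1000)
  mk <- function(...) {
    d <- utils::modifyList(base, list(...))
    structure(list(d), k = 1L, class = "cluster_diagnostics")
  }
  # wood smoke: high fine edge, strong cold-season peak, central geometry,
  # colder-is-more, near-midnight peak
  rwb <- mk(fine_coarse_upper = 0.85, cold_warm_ratio = 4,
            hull_contains_origin = TRUE, sector_coverage = 1,
            temp_slope = -0.8, peak_hours = c(23, 22))
  expect_equal(classify_clusters(rwb)$label, "rwb")
  # traffic: weekend drop, rush peaks both windows, ventilation-limited,
  # road-dust lower edge
  traffic <- mk(weekend_ratio = 0.6, peak_hours = c(8, 19),
                ws_slope = -1.2, fine_coarse_lower = 0.08,
                fine_coarse_upper = 0.95)
  expect_equal(classify_clusters(traffic)$label, "traffic")
  # industrial: fumigation, confined sector, SO2-enriched, weekday-steady
  indus <- mk(ws_slope = 2, sector_occupancy = 3, so2_enrichment = 3,
              weekend_ratio = 1)
  expect_equal(classify_clusters(indus)$label, "industrial")
  # aeolian: nothing below the wind threshold, wind-driven, coarse
  aeol <- mk(low_ws_frac = 0, ws_slope = 3, fine_coarse_upper = 0.3,
             weekend_ratio = 0.99, sector_occupancy = 8)
  expect_equal(classify_clusters(aeol)$label, "aeolian")
  # regional: confined, steady, SO2 year-round, aged NO2/NOx
  reg <- mk(sector_occupancy = 4, weekend_ratio = 1, so2_enrichment = 1.2,
            so2_cold_warm = 1, no2_nox_ratio = 0.8)
  expect_equal(classify_clusters(reg)$label, "regional")
})

test_that("all-unavailable diagnostics yield an unidentified cluster", {
  d <- list(cluster = 1, diurnal_profile = rep(NA_real_, 24),
            peak_hours = c(NA_integer_, NA_integer_),
            weekend_ratio = NA_real_, cold_warm_ratio = NA_real_,
            fine_coarse_lower = NA_real_, fine_coarse_upper = NA_real_,
            ws_slope = NA_real_, temp_slope = NA_real_, rh_slope = NA_real_,
            sector_coverage = NA_real_, hull_contains_origin = NA,
            sector_occupancy = NA_integer_, low_ws_frac = NA_real_,
            gas_shares = NULL, so2_share = NA_real_,
            so2_enrichment = NA_real_, so2_cold_warm = NA_real_,
            no2_nox_ratio = NA_real_, n_hours = 0L)
  dd <- structure(list(d), k = 1L, class = "cluster_diagnostics")
  res <- classify_clusters(dd)
  expect_equal(res$label, "unidentified")
  expect_equal(res$score, 0)
})

test_that("classification is deterministic and invariant to cluster numbering", {
  sim <- simulate_scenario(temuco_like_scenario(n_days = 365, seed = 6))
  f <- to_polar_features(sim$table, "pm25", "temperature")
  sol <- kmeans_cluster(f, k = 3, seed = 6)
  diag <- cluster_diagnostics(sim$table, sol, f)
  l1 <- classify_clusters(diag)
  l2 <- classify_clusters(diag)
  expect_identical(l1$label, l2$label)
  # renumber clusters: labels must follow their clusters
  perm <- c(3, 1, 2)
  diag_p <- structure(lapply(perm, function(j) diag[[j]]),
                      k = 3L, class = "cluster_diagnostics")
  lp <- classify_clusters(diag_p)
  expect_equal(lp$label, l1$label[perm])
})

test_that("cluster diagnostics carry coherent per-cluster rule metrics", {
  sim <- simulate_scenario(temuco_like_scenario(n_days = 365, seed = 9))
  f <- to_polar_features(sim$table, "pm25", "temperature")
  sol <- kmeans_cluster(f, k = 3, seed = 9)
  diag <- cluster_diagnostics(sim$table, sol, f)
  expect_length(diag, 3)
  for (d in diag) {
    expect_length(d$diurnal_profile, 24)
    expect_true(d$fine_coarse_lower <= d$fine_coarse_upper)
    expect_gte(d$weekend_ratio, 0)
    expect_true(d$sector_occupancy >= 1 && d$sector_occupancy <= 16)
  }
  # wood smoke carries a strongly negative temperature slope; its seasonal
  # cold/warm ratio dwarfs the traffic clusters'
  rwb_cl <- which.max(vapply(diag, `[[`, numeric(1), "cold_warm_ratio"))
  expect_lt(diag[[rwb_cl]]$temp_slope, 0)
  expect_gt(diag[[rwb_cl]]$cold_warm_ratio, 2)
})
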