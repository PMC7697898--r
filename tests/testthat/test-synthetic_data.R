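test_that("degenerate amplitudes give constant temperature and fixed wind direction", {
  met <- generate_meteorology(flat_scenario(3, temp_mean_annual = 9.5))
  expect_equal(met$temp, rep(9.5, 72))
  expect_equal(met$wd, rep(180, 72))
  expect_true(all(met$ws >= 0))
})

test_that("meteorology is reproducible for a fixed seed and differs across seeds", {
  sc1 <- met_scenario(5, seed = 11)
  sc2 <- met_scenario(5, seed = 11)
  sc3 <- met_scenario(5, seed = 12)
  expect_identical(generate_meteorology(sc1), generate_meteorology(sc2))
  expect_false(isTRUE(all.equal(generate_meteorology(sc1),
                                generate_meteorology(sc3))))
})

test_that("scenario validation rejects bad regimes", {
  expect_error(met_scenario(0), "n_days")
  expect_error(wind_regime(400), "direction_center")
  expect_error(wind_regime(10, weight = -1), "non-negative")
  # a regime set with an uncovered hour fails at generation time
  sc <- met_scenario(2, wind_regimes = list(wind_regime(90, hours = 0:11)))
  expect_error(generate_meteorology(sc), "no active wind regime")
})

test_that("zeroed wood-burning and sub-threshold winds give identically zero truth", {
  met <- generate_meteorology(flat_scenario(4))
  arch <- list(
    source_archetype("rwb", base_level = 0, temp_sensitivity = 0),
    # flat scenario winds are Weibull(scale 2): force all below threshold
    source_archetype("aeolian", base_level = 3, ws_threshold = 99))
  truth <- generate_source_contributions(met, arch, seed = 1)
  expect_equal(unname(truth$pm10[, "rwb"]), rep(0, nrow(met)))
  expect_equal(unname(truth$pm10[, "aeolian"]), rep(0, nrow(met)))
})

test_that("aeolian contributions vanish below threshold and follow the power law above", {
  met <- generate_meteorology(met_scenario(
    10, wind_regimes = list(wind_regime(270, 10, speed_scale = 6)),
    seed = 4))
  a <- source_archetype("aeolian", base_level = 2, ws_threshold = 4,
                        ws_exponent = 2)
  truth <- generate_source_contributions(met, list(a), seed = 1)
  v <- truth$pm10[, "aeolian"]
  expect_equal(unname(v), 2 * pmax(0, met$ws - 4)^2)
  expect_true(all(v[met$ws < 4] == 0))
})

test_that("industrial contributions appear only in-sector at activating wind speeds", {
  met <- generate_meteorology(met_scenario(
    20, wind_regimes = list(wind_regime(90, 60, speed_scale = 5)), seed = 6))
  a <- source_archetype("industrial", base_level = 4,
                        stack_sector = c(45, 135), ws_activation = 5)
  truth <- generate_source_contributions(met, list(a), seed = 1)
  v <- truth$pm10[, "industrial"]
  active <- met$wd >= 45 & met$wd <= 135 & met$ws >= 5
  expect_true(all(v[!active] == 0))
  expect_true(all(v[active] > 0))
})

test_that("traffic weekend/weekday truth ratio recovers the configured factor", {
  # two simulated years; ratio recomputed directly from the truth panel
  met <- generate_meteorology(met_scenario(730, seed = 21))
  a <- source_archetype("traffic", base_level = 10, weekend_factor = 0.6)
  truth <- generate_source_contributions(met, list(a), seed = 2)
  wknd <- format(met$timestamp, "%u") >= "6"
  ratio <- mean(truth$pm10[wknd, 1]) / mean(truth$pm10[!wknd, 1])
  expect_equal(ratio, 0.6, tolerance = 0.02 / 0.6)
})

test_that("wood-burning truth is driven by heating degrees below the threshold only", {
  met <- generate_meteorology(met_scenario(365, seed = 8))
  a <- source_archetype("rwb", base_level = 1, temp_sensitivity = 2,
                        temp_threshold = 15, day_cv = 0)
  truth <- generate_source_contributions(met, list(a), seed = 1)
  v <- truth$pm10[, "rwb"]
  hdd <- pmax(0, 15 - met$temp)
  # above threshold: no temperature sensitivity (constant given hour and ws)
  expect_equal(unname(v), (1 + 2 * hdd) *
                 a$diurnal_profile[as.integer(format(met$timestamp, "%H")) + 1] /
                 (1 + a$ws_dilution * met$ws) *
                 ifelse(format(met$timestamp, "%u") >= "6", a$weekend_factor, 1))
})

test_that("raising wood-burning temperature sensitivity never lowers winter PM2.5", {
  preset <- temuco_like_scenario(n_days = 365, seed = 3)
  met <- generate_meteorology(preset$scenario)
  arch_lo <- preset$archetypes
  arch_hi <- preset$archetypes
  arch_hi[[2]]$temp_sensitivity <- arch_hi[[2]]$temp_sensitivity + 1
  t_lo <- generate_source_contributions(met, arch_lo, seed = 5)
  t_hi <- generate_source_contributions(met, arch_hi, seed = 5)
  winter <- as.integer(format(met$timestamp, "%m")) %in% 5:8
  expect_true(all(rowSums(t_hi$pm25)[winter] >= rowSums(t_lo$pm25)[winter]))
})

test_that("generated traffic truth peaks inside the rush-hour windows", {
  preset <- temuco_like_scenario(n_days = 365, seed = 13)
  met <- generate_meteorology(preset$scenario)
  truth <- generate_source_contributions(met, preset$archetypes, seed = 13)
  hour <- as.integer(format(met$timestamp, "%H"))
  diurnal <- tapply(truth$pm10[, "traffic"], hour, mean)
  top2 <- as.integer(names(sort(diurnal, decreasing = TRUE)[1:2]))
  expect_true(all(top2 %in% c(6:10, 17:21)))
})

test_that("noise-free observations equal summed truth and preserve fine = coarse", {
  met <- generate_meteorology(flat_scenario(5))
  arch <- list(source_archetype("traffic", base_level = 8,
                                fine_coarse_ratio = 1))
  truth <- generate_source_contributions(met, arch, seed = 1)
  obs <- assemble_observations(truth, noise_cv = 0, seed = 1)
  expect_equal(obs$pm25, unname(rowSums(truth$pm25)))
  expect_equal(obs$pm10, unname(rowSums(truth$pm10)))
  expect_equal(obs$pm25, obs$pm10)  # single source with ratio 1
  expect_equal(attr(obs, "n_pm25_clipped"), 0L)
})

test_that("measurement noise has the configured coefficient of variation", {
  met <- generate_meteorology(met_scenario(420, seed = 31))  # ~10,000 h
  arch <- list(source_archetype("regional", base_level = 12, day_cv = 0))
  truth <- generate_source_contributions(met, arch, seed = 1)
  obs <- assemble_observations(truth, noise_cv = 0.10, seed = 7)
  rel <- obs$pm10 / rowSums(truth$pm10) - 1
  expect_equal(sd(rel), 0.10, tolerance = 0.01 / 0.10)
  expect_lt(abs(mean(rel)), 0.01)
})

test_that("observations always satisfy PM2.5 <= PM10", {
  sim <- simulate_scenario(temuco_like_scenario(n_days = 60, seed = 2),
                           noise_cv = 0.4)
  expect_true(all(sim$table$pm25 <= sim$table$pm10 + 1e-12))
})

test_that("speciated samples reproduce period-mean truth exactly without noise", {
  met <- generate_meteorology(met_scenario(70, seed = 17))
  arch <- list(source_archetype("traffic", base_level = 10))
  truth <- generate_source_contributions(met, arch, seed = 1)
  prof <- matrix(c(1, 0, 0, 0), 1, 4,
                 dimnames = list("traffic", c("s1", "s2", "s3", "s4")))
  sched <- weekly_schedule(truth$timestamp, 8, days_per_week = 5)
  samp <- generate_speciated_samples(truth, prof, sched, noise_cv = 0, seed = 1)
  expect_equal(nrow(samp$X), 8)
  # every weekly sample averages exactly 5 x 24 hourly truth values
  expect_equal(unname(samp$periods$n_hours), rep(120L, 8))
  manual <- vapply(sched, function(idx) mean(truth$pm25[idx, "traffic"]),
                   numeric(1))
  expect_equal(unname(samp$X[, "s1"]), unname(manual))
  expect_true(all(samp$X[, c("s2", "s3", "s4")] == 0))
  expect_true(all(samp$sigma > 0))
})

test_that("two disjoint-tracer sources round-trip exactly through the mass-balance fit", {
  met <- generate_meteorology(met_scenario(70, seed = 19))
  arch <- list(source_archetype("traffic", base_level = 10),
               source_archetype("rwb", base_level = 3, temp_sensitivity = 1))
  truth <- generate_source_contributions(met, arch, seed = 2)
  prof <- rbind(traffic = c(0.6, 0, 0.2, 0),
                rwb = c(0, 0.7, 0, 0.1))
  colnames(prof) <- c("s1", "s2", "s3", "s4")
  sched <- weekly_schedule(truth$timestamp, 9)
  samp <- generate_speciated_samples(truth, prof, sched, noise_cv = 0, seed = 1)
  fit <- cmb_fit(samp, prof)
  expect_equal(fit$G, attr(samp, "g_true"), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("truth generation is deterministic and rejects duplicate archetypes", {
  met <- generate_meteorology(flat_scenario(3))
  arch <- list(source_archetype("traffic", base_level = 5))
  expect_identical(generate_source_contributions(met, arch, seed = 9),
                   generate_source_contributions(met, arch, seed = 9))
  expect_error(generate_source_contributions(
    met, c(arch, arch), seed = 1), "unique")
  expect_error(source_archetype("volcano", 1), "unknown archetype")
})
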