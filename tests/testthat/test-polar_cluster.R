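test_that("k = 1 puts every hour in one cluster with the total-scatter inertia", {
  f <- standardize(features_from_xyz(x = rnorm(20), y = rnorm(20),
                                     c = runif(20)))
  sol <- kmeans_cluster(f, k = 1, seed = 1)
  expect_equal(sol$assignment, rep(1L, 20))
  expect_equal(sol$inertia, sum(sweep(f$z, 2, colMeans(f$z))^2))
})

test_that("k equal to the number of distinct points gives zero inertia", {
  f <- features_from_xyz(x = c(0, 1, 5, 9), y = c(0, 2, 5, 1),
                         c = c(1, 4, 9, 16))
  sol <- kmeans_cluster(f, k = 4, n_restarts = 10, seed = 2)
  expect_equal(sol$inertia, 0)
  expect_equal(sort(sol$assignment), 1:4)
  expect_error(kmeans_cluster(f, k = 5), "exceeds")
})

test_that("two well-separated triplets are split optimally at k = 2", {
  f <- features_from_xyz(x = c(0, 0.1, -0.1, 10, 10.1, 9.9),
                         y = c(0, 0.1, 0.1, 10, 10.2, 9.9),
                         c = c(1, 1.1, 0.9, 8, 8.1, 7.9))
  f <- standardize(f)
  sol <- kmeans_cluster(f, k = 2, n_restarts = 20, seed = 3)
  expect_equal(sol$assignment[1:3], rep(sol$assignment[1], 3))
  expect_equal(sol$assignment[4:6], rep(sol$assignment[4], 3))
  expect_equal(sol$inertia, brute_force_inertia(f$z, 2), tolerance = 1e-10)
})

test_that("best-of-restarts matches the exhaustive-partition optimum on random fixtures", {
  for (i in 1:6) {
    n <- 5 + (i %% 4)
    f <- withr::with_seed(100 + i,
      features_from_xyz(x = rnorm(n), y = rnorm(n), c = runif(n, 1, 10)))
    f <- standardize(f)
    for (k in 2:3) {
      sol <- kmeans_cluster(f, k = k, n_restarts = 20, seed = i)
      expect_equal(sol$inertia, brute_force_inertia(f$z, k),
                   tolerance = 1e-8)
    }
  }
})

test_that("clustering is deterministic for a fixed seed and relabels by mean concentration", {
  f <- withr::with_seed(7, features_from_xyz(rnorm(60), rnorm(60),
                                             runif(60, 0, 50)))
  s1 <- kmeans_cluster(f, k = 3, seed = 11)
  s2 <- kmeans_cluster(f, k = 3, seed = 11)
  expect_identical(s1$assignment, s2$assignment)
  mean_c <- tapply(f$data$c, s1$assignment, mean)
  expect_true(all(diff(mean_c) <= 0))  # cluster 1 has the highest mean c
})

test_that("agreement with a reference implementation on a clean fixture", {
  # independent cross-check: stats::kmeans from many restarts reaches the
  # same optimum partition on well-separated data
  f <- withr::with_seed(15, features_from_xyz(
    x = c(rnorm(40, -4), rnorm(40, 4)),
    y = c(rnorm(40, -4), rnorm(40, 4)),
    c = c(runif(40, 0, 2), runif(40, 8, 10))))
  f <- standardize(f)
  sol <- kmeans_cluster(f, k = 2, seed = 5)
  ref <- withr::with_seed(5, stats::kmeans(f$z, 2, nstart = 25,
                                           algorithm = "Lloyd"))
  expect_equal(sol$inertia, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(mclust::adjustedRandIndex(sol$assignment, ref$cluster), 1)
})

test_that("the k sweep has nonincreasing inertia and reports consecutive agreement", {
  f <- withr::with_seed(23, features_from_xyz(rnorm(120), rnorm(120),
                                              runif(120, 0, 30)))
  sw <- sweep_k(f, 1, 6, n_restarts = 5, seed = 2)
  expect_equal(sw$summary$k, 1:6)
  expect_true(all(diff(sw$summary$inertia) <= 1e-9))
  expect_true(all(is.finite(sw$summary$ari_prev[-1])))
})

test_that("sweep agreement on a two-blob fixture beats the random-relabeling baseline", {
  f <- withr::with_seed(31, features_from_xyz(
    x = c(rnorm(50, -5), rnorm(50, 5)),
    y = c(rnorm(50, -5), rnorm(50, 5)),
    c = c(runif(50, 0, 3), runif(50, 7, 10))))
  sw <- sweep_k(f, 2, 3, n_restarts = 10, seed = 4)
  ari_23 <- sw$summary$ari_prev[2]
  # permutation baseline computed by the test itself
  base <- withr::with_seed(99, {
    a <- sw$solutions[["2"]]$assignment
    mean(replicate(50, mclust::adjustedRandIndex(sample(a), a)))
  })
  expect_gt(ari_23, base)
})

test_that("central-cluster geometry ranks an origin-enclosing low-radius cluster first", {
  # cluster A: ring around the origin at small radius covering all sectors;
  # cluster B: confined to one narrow sector far from the origin
  th_a <- seq(0, 2 * pi, length.out = 64)[-64]
  xa <- 1.5 * sin(th_a); ya <- 1.5 * cos(th_a)
  xb <- rnorm(40, 8, 0.3); yb <- rnorm(40, 0.5, 0.2)
  f <- features_from_xyz(c(xa, xb), c(ya, yb),
                         c = c(rep(10, 63), rep(5, 40)))
  sol <- kmeans_cluster(standardize(f), k = 2, seed = 6)
  cc <- central_cluster_candidates(sol, f)
  ring_cluster <- sol$assignment[1]
  top <- cc[cc$rank == 1, ]
  expect_equal(top$cluster, ring_cluster)
  expect_equal(top$coverage, 1.0)
  expect_true(top$hull_contains_origin)
  side <- cc[cc$cluster != ring_cluster, ]
  expect_false(side$hull_contains_origin)
  expect_lte(side$coverage, 2 / 16)
})

test_that("hull test is skipped and flagged for clusters with under three points", {
  f <- features_from_xyz(x = c(0, 0.1, -0.1, 9), y = c(0, 0.1, 0.1, 9),
                         c = c(1, 1, 1, 50))
  sol <- kmeans_cluster(standardize(f), k = 2, n_restarts = 10, seed = 1)
  cc <- central_cluster_candidates(sol, f)
  lone <- cc[cc$n_points < 3, ]
  expect_equal(nrow(lone), 1)
  expect_true(lone$few_points)
  expect_true(is.na(lone$hull_contains_origin))
})

test_that("contribution series are additive and aggregate as defined", {
  tab <- tiny_hourly_table(4)
  tab$pm10 <- c(10, 20, 30, 40)
  tab$wd <- c(10, 20, 200, 210)
  tab$ws <- c(1, 1.2, 5, 5.5)
  f <- standardize(to_polar_features(tab, "pm10"))
  sol <- kmeans_cluster(f, k = 2, n_restarts = 10, seed = 1)
  # force the worked example's labels: hours 1-2 vs hours 3-4
  expect_setequal(sol$assignment[1:2], sol$assignment[1])
  ser <- contribution_series(tab, sol)
  expect_equal(rowSums(ser[, c("C1", "C2")]), tab$pm10)
  agg <- aggregate_contributions(ser, "month")
  expect_equal(sum(agg$mean), mean(tab$pm10))  # 7.5 + 17.5 = 25
  expect_setequal(agg$mean, c(7.5, 17.5))
})

test_that("a single cluster's contribution series equals the concentration series", {
  tab <- tiny_hourly_table(30)
  f <- standardize(to_polar_features(tab, "pm25"))
  sol <- kmeans_cluster(f, k = 1, seed = 1)
  ser <- contribution_series(tab, sol)
  expect_equal(ser$C1, tab$pm25)
})

test_that("hours with missing pollutant are dropped from the series and counted", {
  tab <- tiny_hourly_table(30)
  f <- standardize(to_polar_features(tab, "pm25"))
  sol <- kmeans_cluster(f, k = 2, seed = 3)
  tab2 <- tab
  tab2$pm25[4] <- NA  # goes missing after clustering
  ser <- contribution_series(tab2, sol)
  expect_equal(nrow(ser), 29)
  expect_equal(attr(ser, "n_dropped"), 1L)
})
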