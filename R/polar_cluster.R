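#' Lloyd iterations from one set of initial centroids
#'
#' Nearest-centroid ties break to the lowest cluster index; an emptied
#' cluster is reseeded with the point farthest from its current centroid.
#' Stops at an assignment fixed point or `max_iter` sweeps.
#' @noRd
lloyd <- function(X, centers, max_iter = 300) {
  n <- nrow(X); k <- nrow(centers)
  d2 <- matrix(0, n, k)
  assign_prev <- integer(n)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k))
      d2[, j] <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2 +
        (X[, 3] - centers[j, 3])^2
    assign <- max.col(-d2, ties.method = "first")
    # repair empty clusters with the point farthest from its own centroid
    repeat {
      empty <- setdiff(seq_len(k), unique(assign))
      if (!length(empty)) break
      own <- d2[cbind(seq_len(n), assign)]
      far <- which.max(own)
      centers[empty[1], ] <- X[far, ]
      for (j in seq_len(k))
        d2[, j] <- (X[, 1] - centers[j, 1])^2 + (X[, 2] - centers[j, 2])^2 +
          (X[, 3] - centers[j, 3])^2
      assign <- max.col(-d2, ties.method = "first")
    }
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    cnt <- tabulate(assign, k)
    centers <- rowsum(X, assign, reorder = TRUE) / cnt
  }
  inertia <- sum(d2[cbind(seq_len(n), assign)])
  list(assign = assign, centers = centers, inertia = inertia, iter = it)
}

#' k-means++ initial centroids: first centre uniform, later centres sampled
#' with probability proportional to squared distance from the nearest
#' chosen centre
#' @noRd
init_pp <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[idx, ])^2)
  for (j in seq_len(k - 1)) {
    pick <- if (all(d2 <= 0)) sample.int(n, 1)
            else sample.int(n, 1, prob = d2)
    idx <- c(idx, pick)
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[pick, ])^2))
  }
  X[idx, , drop = FALSE]
}

#' @noRd
kmeans_engine <- function(X, k, n_restarts, extra_inits = list()) {
  best <- NULL
  # tiny inputs: random restarts can miss the global optimum, and the
  # candidate initialisations are few -- seed from every distinct k-subset
  # of points instead (still Lloyd, but the search is exhaustive over
  # point-seeded starts)
  if (nrow(X) <= 12 && choose(nrow(X), k) <= 250) {
    subsets <- utils::combn(nrow(X), k)
    for (s in seq_len(ncol(subsets))) {
      fit <- lloyd(X, X[subsets[, s], , drop = FALSE])
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  }
  for (r in seq_len(n_restarts)) {
    fit <- lloyd(X, init_pp(X, k))
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  for (init in extra_inits) {
    fit <- lloyd(X, init)
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  best
}

#' k-means clustering of standardized polar features
#'
#' Best-of-`n_restarts` seeded Lloyd runs on the standardized `(x, y, c)`
#' triplets, each restart initialised from `k` data points by k-means++
#' (D-squared) seeding. Clusters
#' are relabeled in decreasing order of mean concentration, so cluster 1 is
#' always the highest-concentration one regardless of restart order. Fixed
#' `seed` gives identical assignments across runs.
#'
#' @param features a `polar_features` object; standardized automatically if
#'   not already.
#' @param k number of clusters (1 <= k <= rows).
#' @param n_restarts number of random restarts.
#' @param seed integer seed.
#' @return a `cluster_solution`: `k`, `assignment` (per retained hour, in
#'   1..k), `centroids` (k x 3, standardized space), `inertia`, `sizes`,
#'   plus the retained timestamps and row index into the source table.
#' @export
kmeans_cluster <- function(features, k, n_restarts = 20, seed = 1L) {
  stopifnot(inherits(features, "polar_features"))
  if (!features$standardized) features <- standardize(features)
  X <- features$z
  if (k < 1) stopf("k must be >= 1")
  if (k > nrow(X)) stopf("k = %d exceeds the %d retained rows", k, nrow(X))
  best <- withr::with_seed(as.integer(seed),
                           kmeans_engine(X, k, n_restarts))
  sol <- relabel_by_concentration(best, features$data$c, k)
  structure(list(k = as.integer(k), assignment = sol$assign,
                 centroids = sol$centers, inertia = best$inertia,
                 sizes = tabulate(sol$assign, k),
                 n_restarts = n_restarts, seed = as.integer(seed),
                 iterations = best$iter,
                 timestamp = features$data$timestamp,
                 kept_idx = features$kept_idx,
                 pollutant = features$pollutant,
                 radial_variable = features$radial_variable),
            class = "cluster_solution")
}

#' @noRd
relabel_by_concentration <- function(fit, conc, k) {
  mean_c <- vapply(seq_len(k), function(j) {
    v <- conc[fit$assign == j]
    if (length(v)) mean(v) else -Inf
  }, numeric(1))
  ord <- order(mean_c, decreasing = TRUE)  # new label 1 = highest mean c
  relab <- integer(k); relab[ord] <- seq_len(k)
  list(assign = relab[fit$assign],
       centers = fit$centers[ord, , drop = FALSE])
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("k-means solution: k = %d, %d hours, inertia = %.2f\n",
              x$k, length(x$assignment), x$inertia))
  cat("cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Sweep a range of cluster counts
#'
#' Fits one solution per `k`. Besides the random restarts, each `k > k_min`
#' also tries an initialisation nested from the previous best solution (its
#' centroids plus the point farthest from them), which guarantees the
#' reported inertia is nonincreasing in `k`. The number of clusters is a
#' user decision: the sweep reports inertia and the adjusted Rand agreement
#' between consecutive solutions but never auto-picks `k`.
#'
#' @param features a `polar_features` object.
#' @param k_min,k_max inclusive range of cluster counts.
#' @param n_restarts random restarts per `k`.
#' @param seed integer seed.
#' @return a `k_sweep`: list of solutions plus a summary data frame with
#'   columns `k`, `inertia`, `ari_prev` (agreement with the previous `k`).
#' @export
sweep_k <- function(features, k_min = 2, k_max = 10, n_restarts = 20,
                    seed = 1L) {
  if (k_min < 1 || k_min > k_max) stopf("need 1 <= k_min <= k_max")
  if (!features$standardized) features <- standardize(features)
  X <- features$z
  solutions <- list()
  prev_centers <- NULL
  for (k in k_min:k_max) {
    extra <- list()
    if (!is.null(prev_centers)) {
      d2 <- vapply(seq_len(nrow(prev_centers)), function(j)
        rowSums(sweep(X, 2, prev_centers[j, ])^2), numeric(nrow(X)))
      far <- which.max(apply(d2, 1, min))
      extra <- list(rbind(prev_centers, X[far, ]))
    }
    best <- withr::with_seed(as.integer(seed) + k,
                             kmeans_engine(X, k, n_restarts, extra))
    sol <- relabel_by_concentration(best, features$data$c, k)
    prev_centers <- sol$centers
    solutions[[as.character(k)]] <- structure(
      list(k = as.integer(k), assignment = sol$assign,
           centroids = sol$centers, inertia = best$inertia,
           sizes = tabulate(sol$assign, k), n_restarts = n_restarts,
           seed = as.integer(seed), iterations = best$iter,
           timestamp = features$data$timestamp,
           kept_idx = features$kept_idx, pollutant = features$pollutant,
           radial_variable = features$radial_variable),
      class = "cluster_solution")
  }
  ks <- k_min:k_max
  inertia <- vapply(solutions, `[[`, numeric(1), "inertia")
  ari <- c(NA, vapply(seq_along(ks)[-1], function(i)
    mclust::adjustedRandIndex(solutions[[i - 1]]$assignment,
                              solutions[[i]]$assignment), numeric(1)))
  structure(list(solutions = solutions,
                 summary = data.frame(k = ks, inertia = inertia,
                                      ari_prev = ari, row.names = NULL)),
            class = "k_sweep")
}

#' Rank clusters as central-cluster candidates
#'
#' A central cluster — the polar signature of a ubiquitous calm-condition
#' source such as residential wood burning — occupies low radial values in
#' every wind direction, enclosing the origin of the polar plane. For each
#' cluster this computes the fraction of the 16 compass sectors occupied by
#' its points below the median radius of the whole data set, and whether the
#' convex hull of its `(x, y)` points contains the origin, then ranks by
#' (hull contains origin, sector coverage).
#'
#' @param solution a `cluster_solution`.
#' @param features the `polar_features` the solution was fitted on.
#' @return data frame with one row per cluster: `cluster`, `coverage`,
#'   `hull_contains_origin`, `n_points`, `few_points` flag, `rank`.
#' @export
central_cluster_candidates <- function(solution, features) {
  stopifnot(inherits(solution, "cluster_solution"),
            inherits(features, "polar_features"))
  dat <- features$data
  if (nrow(dat) != length(solution$assignment))
    stopf("solution and features are not aligned")
  r_med <- stats::median(dat$r)
  res <- lapply(seq_len(solution$k), function(j) {
    in_j <- solution$assignment == j
    low <- in_j & dat$r <= r_med
    # a sector counts as occupied at >= 2% of the cluster's low-radius
    # points, so stray single points do not inflate coverage
    sect <- table(sector_index(dat$wd[low]))
    coverage <- sum(sect >= max(1, 0.02 * sum(low))) / 16
    few <- sum(in_j) < 3
    hull <- if (few) NA else hull_contains_origin(dat$x[in_j], dat$y[in_j])
    data.frame(cluster = j, coverage = coverage,
               hull_contains_origin = hull, n_points = sum(in_j),
               few_points = few)
  })
  out <- do.call(rbind, res)
  out <- out[order(!out$hull_contains_origin %in% TRUE, -out$coverage), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Hourly cluster-contribution series
#'
#' The contribution of cluster `j` at hour `t` is the observed concentration
#' if the hour is assigned to `j` and zero otherwise, so the per-cluster
#' series sum exactly to the observed concentration at every retained hour,
#' and period-mean contributions sum to the period-mean concentration. Hours
#' whose pollutant value is missing in `table` are dropped and counted in
#' `attr(, "n_dropped")`.
#'
#' @param table the source `hourly_table`.
#' @param solution a `cluster_solution` fitted on features from `table`.
#' @param pollutant concentration column; defaults to the solution's.
#' @return a `contribution_series` data frame: `timestamp`, `C1` ... `Ck`,
#'   with the assignment in `attr(, "assignment")`.
#' @export
contribution_series <- function(table, solution,
                                pollutant = solution$pollutant) {
  stopifnot(inherits(solution, "cluster_solution"))
  if (!pollutant %in% names(table))
    stopf("pollutant column '%s' not found", pollutant)
  conc <- table[[pollutant]][solution$kept_idx]
  ok <- !is.na(conc)
  k <- solution$k
  m <- matrix(0, sum(ok), k,
              dimnames = list(NULL, paste0("C", seq_len(k))))
  assign_ok <- solution$assignment[ok]
  m[cbind(seq_len(sum(ok)), assign_ok)] <- conc[ok]
  out <- data.frame(timestamp = solution$timestamp[ok])
  out <- cbind(out, as.data.frame(m))
  attr(out, "assignment") <- assign_ok
  attr(out, "pollutant") <- pollutant
  attr(out, "kept_idx") <- solution$kept_idx[ok]
  attr(out, "n_dropped") <- sum(!ok)
  class(out) <- c("contribution_series", "data.frame")
  out
}

#' Aggregate a contribution series over calendar periods
#'
#' Periodic means with standard errors `sd/sqrt(n)` over the period's
#' retained hours; cluster means per period sum to the period-mean
#' concentration.
#'
#' @param series a `contribution_series` (or `source_series`).
#' @param by `"month"` (calendar year-month), `"week"` (7-day blocks from
#'   the first timestamp), `"hour"` (0-23), `"weekday"` (Monday-first 1-7),
#'   or `"calendar_month"` (1-12 across years).
#' @return long data frame: `period`, `source`, `mean`, `se`, `n`.
#' @export
aggregate_contributions <- function(series,
                                    by = c("month", "week", "hour",
                                           "weekday", "calendar_month")) {
  by <- match.arg(by)
  ts <- series$timestamp
  key <- switch(by,
    month = format(ts, "%Y-%m"),
    week = paste("week", floor(as.numeric(difftime(ts, ts[1],
                                                   units = "days")) / 7) + 1),
    hour = as.integer(format(ts, "%H")),
    weekday = weekday_num(ts),
    calendar_month = as.integer(format(ts, "%m")))
  cols <- setdiff(names(series), "timestamp")
  out <- do.call(rbind, lapply(cols, function(cn) {
    agg <- t(vapply(split(series[[cn]], key), mean_se, numeric(3)))
    data.frame(period = rownames(agg), source = cn,
               mean = agg[, "mean"], se = agg[, "se"], n = agg[, "n"],
               row.names = NULL)
  }))
  if (by %in% c("hour", "weekday", "calendar_month"))
    out$period <- as.integer(out$period)
  out[order(out$source, out$period), , drop = FALSE]
}
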