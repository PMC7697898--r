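.ht_columns <- c("timestamp", "ws", "wd", "temp", "rh",
                 "pm25", "pm10", "nox", "no2", "co", "so2")

#' Read an hourly air-quality table from CSV
#'
#' Expects a header row and ISO 8601 timestamps (`"YYYY-MM-DD HH:MM"`,
#' seconds optional). Recognised columns are `timestamp`, `ws` (m/s), `wd`
#' (degrees), `temp` (deg C), `rh` (%), and the pollutant concentrations
#' `pm25`, `pm10`, `nox`, `no2`, `co`, `so2`; units pass through unchanged.
#' Unparseable numeric cells become missing values and are counted in
#' `attr(, "qc_parse")`.
#'
#' @param path CSV file path.
#' @param column_map optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(pm25 = "PM2.5", ws = "WSPD")`.
#' @return an `hourly_table` data frame ordered by timestamp.
#' @export
read_hourly_table <- function(path, column_map = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  if (!"timestamp" %in% names(raw))
    stopf("missing timestamp column in %s", path)
  ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%dT%H:%M"))
  if (anyNA(ts))
    stopf("unparseable timestamps: %s",
          paste(utils::head(raw$timestamp[is.na(ts)], 5), collapse = ", "))
  if (anyDuplicated(ts))
    stopf("duplicate timestamps: %s",
          paste(format(unique(ts[duplicated(ts)]), "%Y-%m-%d %H:%M"),
                collapse = ", "))
  keep <- intersect(.ht_columns, names(raw))
  out <- data.frame(timestamp = ts)
  parse_fail <- integer(0)
  for (cn in setdiff(keep, "timestamp")) {
    v <- raw[[cn]]
    v[v %in% c("", "NA", "NaN")] <- NA
    num <- suppressWarnings(as.numeric(v))
    n_bad <- sum(!is.na(v) & is.na(num))
    if (n_bad) parse_fail[cn] <- n_bad
    out[[cn]] <- num
  }
  out <- out[order(out$timestamp), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_parse") <- parse_fail
  class(out) <- c("hourly_table", "data.frame")
  out
}

#' Write an hourly table to CSV
#'
#' Inverse of [read_hourly_table()]: a write/read round trip preserves all
#' values including missing cells.
#'
#' @param table an `hourly_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hourly_table <- function(table, path) {
  out <- as.data.frame(table)
  out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Default outlier-screening rules
#'
#' Physical caps per column (violations are set missing, not row-deleted)
#' and a spike rule (value exceeding `spike_k` times the centred 24-h
#' rolling median is flagged but retained).
#'
#' @param pm25_max,pm10_max,ws_max upper caps (ug/m3, ug/m3, m/s).
#' @param spike_k spike multiplier over the rolling median.
#' @param spike_window rolling-median window, hours.
#' @return a rules list for [screen_outliers()].
#' @export
default_qc_rules <- function(pm25_max = 1000, pm10_max = 2000, ws_max = 60,
                             spike_k = 10, spike_window = 24) {
  list(caps = list(pm25 = c(0, pm25_max), pm10 = c(0, pm10_max),
                   nox = c(0, Inf), no2 = c(0, Inf), co = c(0, Inf),
                   so2 = c(0, Inf), ws = c(0, ws_max), rh = c(0, 100),
                   temp = c(-40, 55)),
       spike_k = spike_k, spike_window = spike_window)
}

#' Screen an hourly table for obvious outliers
#'
#' Cells violating per-column physical caps are set missing (whole rows are
#' never deleted, so valid meteorology survives a bad pollutant cell).
#' Negative concentrations are itemised separately from above-cap values.
#' Spikes relative to the rolling median are flagged only.
#'
#' @param table an `hourly_table`.
#' @param rules rules list, see [default_qc_rules()].
#' @return list with `table` (screened) and `report` (a `qc_report` with
#'   per-rule counts and per-column missingness).
#' @export
screen_outliers <- function(table, rules = default_qc_rules()) {
  counts <- data.frame(column = character(0), rule = character(0),
                       n = integer(0))
  add <- function(column, rule, n) {
    if (n > 0)
      counts <<- rbind(counts, data.frame(column = column, rule = rule, n = n))
    invisible(NULL)
  }
  conc_cols <- c("pm25", "pm10", "nox", "no2", "co", "so2")
  for (cn in intersect(names(rules$caps), names(table))) {
    cap <- rules$caps[[cn]]
    v <- table[[cn]]
    low <- !is.na(v) & v < cap[1]
    high <- !is.na(v) & v > cap[2]
    add(cn, if (cn %in% conc_cols) "negative concentration" else "below minimum",
        sum(low))
    add(cn, "above maximum", sum(high))
    v[low | high] <- NA
    table[[cn]] <- v
  }
  spikes <- integer(0)
  for (cn in intersect(conc_cols, names(table))) {
    v <- table[[cn]]
    ok <- !is.na(v)
    if (sum(ok) < rules$spike_window) next
    med <- zoo::rollapply(zoo::zoo(v), rules$spike_window,
                          function(z) stats::median(z, na.rm = TRUE),
                          partial = TRUE, align = "center")
    flag <- ok & !is.na(med) & med > 0 & v > rules$spike_k * as.numeric(med)
    if (any(flag)) spikes[cn] <- sum(flag)
  }
  report <- structure(list(counts = counts,
                           n_removed = sum(counts$n),
                           spikes_flagged = spikes,
                           missing = vapply(table[setdiff(names(table),
                                                          "timestamp")],
                                            function(v) sum(is.na(v)),
                                            integer(1)),
                           n_rows = nrow(table)),
                      class = "qc_report")
  list(table = table, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:", x$n_rows, "rows,", x$n_removed, "cells set missing\n")
  if (nrow(x$counts)) print(x$counts, row.names = FALSE)
  if (length(x$spikes_flagged))
    cat("spikes flagged (retained):",
        paste(names(x$spikes_flagged), x$spikes_flagged, collapse = ", "),
        "\n")
  invisible(x)
}

#' Build bivariate polar features for clustering
#'
#' Embeds each retained hour as `(x, y, c)`: the radial variable `r` (wind
#' speed, or temperature shifted by its minimum so `r >= 0`) placed at the
#' compass bearing of the wind direction (`x = r sin(theta)` east,
#' `y = r cos(theta)` north, `theta` = direction the wind blows from), and
#' the target pollutant concentration `c`. Hours missing any of wind
#' direction, the radial variable, or the pollutant are dropped and indexed.
#'
#' @param table an `hourly_table`.
#' @param pollutant name of the concentration column to cluster.
#' @param radial_variable `"wind_speed"` or `"temperature"`.
#' @return a `polar_features` object: `data` (timestamp, x, y, r, wd, c),
#'   `kept_idx` (row index into `table`), `n_dropped`, `radial_variable`,
#'   `pollutant`, and after [standardize()] a matrix `z` of standardized
#'   coordinates.
#' @export
to_polar_features <- function(table, pollutant,
                              radial_variable = c("wind_speed",
                                                  "temperature")) {
  radial_variable <- match.arg(radial_variable)
  if (!pollutant %in% names(table))
    stopf("pollutant column '%s' not found", pollutant)
  r <- if (radial_variable == "wind_speed") {
    table$ws
  } else {
    if (!"temp" %in% names(table)) stopf("temperature column not found")
    table$temp - min(table$temp, na.rm = TRUE)
  }
  cc <- table[[pollutant]]
  keep <- which(!is.na(table$wd) & !is.na(r) & !is.na(cc))
  if (!length(keep)) stopf("zero retained rows after dropping missing values")
  th <- table$wd[keep] * pi / 180
  dat <- data.frame(timestamp = table$timestamp[keep],
                    x = r[keep] * sin(th), y = r[keep] * cos(th),
                    r = r[keep], wd = table$wd[keep], c = cc[keep])
  structure(list(data = dat, kept_idx = keep,
                 n_dropped = nrow(table) - length(keep),
                 radial_variable = radial_variable, pollutant = pollutant,
                 standardized = FALSE, center = NULL, scale = NULL,
                 z = NULL),
            class = "polar_features")
}

#' Standardize polar features
#'
#' Scales each of the `x`, `y`, `c` coordinates to mean 0 and sample
#' standard deviation 1 over the retained rows (the three coordinates have
#' different natural scales, so clustering requires a common one). The
#' transform parameters are stored for inverse mapping; applying
#' [standardize()] twice is a no-op up to rounding.
#'
#' @param features a `polar_features` object with at least 2 rows.
#' @return the features with a standardized coordinate matrix in `$z`.
#' @export
standardize <- function(features) {
  stopifnot(inherits(features, "polar_features"))
  m <- as.matrix(features$data[, c("x", "y", "c")])
  if (!is.null(features$z)) m <- features$z
  if (nrow(m) < 2) stopf("need at least 2 rows to standardize")
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero))
    stopf("zero variance: %s", paste(colnames(m)[zero], collapse = ", "))
  features$z <- sweep(sweep(m, 2, ctr), 2, scl, "/")
  features$center <- ctr
  features$scale <- scl
  features$standardized <- TRUE
  features
}
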