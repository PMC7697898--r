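#' Merge labeled clusters into per-source hourly series
#'
#' Clusters sharing a source label are summed, producing the final hourly
#' source-apportionment series. Since labels partition the clusters, the
#' per-source series still sum exactly to the observed concentration at
#' every retained hour.
#'
#' @param contribs a `contribution_series`.
#' @param labels a `source_label_map` from [classify_clusters()], or a
#'   character vector of labels (one per cluster).
#' @return a `source_series` data frame: `timestamp` plus one column per
#'   distinct label.
#' @export
merge_labeled_clusters <- function(contribs, labels) {
  if (inherits(labels, "source_label_map")) labels <- labels$label
  cols <- setdiff(names(contribs), "timestamp")
  if (length(labels) != length(cols))
    stopf("labels must cover all %d clusters", length(cols))
  order_ref <- c("traffic", "rwb", "industrial", "aeolian", "regional",
                 "unidentified")
  lv <- unique(labels[order(match(labels, order_ref, nomatch = 99L))])
  out <- data.frame(timestamp = contribs$timestamp)
  for (l in lv)
    out[[l]] <- rowSums(contribs[, cols[labels == l], drop = FALSE])
  attr(out, "pollutant") <- attr(contribs, "pollutant")
  attr(out, "cluster_labels") <- stats::setNames(labels, cols)
  class(out) <- c("source_series", "data.frame")
  out
}

#' Align a source series to a sampling schedule
#'
#' Period means over only the scheduled hours — emulating a filter campaign
#' that samples a subset of days — with standard errors `sd/sqrt(n)` of
#' those hours. Periods whose scheduled hours are all missing are flagged
#' with `n = 0`.
#'
#' @param series a `source_series` (or `contribution_series`).
#' @param schedule list of row-index vectors into `series`, one per period
#'   (see [weekly_schedule()]).
#' @return long data frame: `period`, `source`, `mean`, `se`, `n`.
#' @export
align_to_schedule <- function(series, schedule) {
  cols <- setdiff(names(series), "timestamp")
  bad <- vapply(schedule, function(idx)
    length(idx) && max(idx) > nrow(series), logical(1))
  if (any(bad)) stopf("schedule days outside the series span")
  do.call(rbind, lapply(names(schedule), function(pd) {
    idx <- schedule[[pd]]
    do.call(rbind, lapply(cols, function(cn) {
      ms <- mean_se(series[[cn]][idx])
      data.frame(period = pd, source = cn, mean = ms[["mean"]],
                 se = ms[["se"]], n = ms[["n"]], row.names = NULL)
    }))
  }))
}

#' Side-by-side comparison of CA and RM period estimates
#'
#' Joins cluster-analysis (CA) and receptor-model (RM) period means on
#' (period, source), appends a footer row of column averages (standard
#' errors combined in quadrature, `sqrt(sum se^2)/n`), and flags per-row
#' agreement where `|CA - RM| <= 2 sqrt(se_CA^2 + se_RM^2)`.
#'
#' @param ca,rm long data frames with columns `period`, `source`, `mean`,
#'   `se` (as from [align_to_schedule()] / [rm_period_summary()]). Periods
#'   must match between the two.
#' @return a `comparison_table`: wide data frame with columns
#'   `<source>_ca`, `<source>_ca_se`, `<source>_rm`, `<source>_rm_se`,
#'   `<source>_agree`; the footer averages are in `attr(, "footer")` (raw)
#'   and `attr(, "footer_printed")` (one decimal, half away from zero,
#'   matching reporting convention).
#' @export
build_comparison <- function(ca, rm) {
  periods <- unique(ca$period)
  miss <- union(setdiff(periods, rm$period), setdiff(rm$period, ca$period))
  if (length(miss))
    stopf("mismatched periods: %s", paste(miss, collapse = ", "))
  sources <- intersect(unique(ca$source), unique(rm$source))
  if (!length(sources)) stopf("no common sources between CA and RM")
  out <- data.frame(period = periods)
  for (s in sources) {
    ca_s <- ca[ca$source == s, ][match(periods, ca$period[ca$source == s]), ]
    rm_s <- rm[rm$source == s, ][match(periods, rm$period[rm$source == s]), ]
    out[[paste0(s, "_ca")]] <- ca_s$mean
    out[[paste0(s, "_ca_se")]] <- ca_s$se
    out[[paste0(s, "_rm")]] <- rm_s$mean
    out[[paste0(s, "_rm_se")]] <- rm_s$se
    tol <- 2 * sqrt(ifelse(is.na(ca_s$se), 0, ca_s$se)^2 +
                      ifelse(is.na(rm_s$se), 0, rm_s$se)^2)
    out[[paste0(s, "_agree")]] <- abs(ca_s$mean - rm_s$mean) <= tol
  }
  value_cols <- grep("_(ca|rm)$", names(out), value = TRUE)
  se_cols <- grep("_se$", names(out), value = TRUE)
  footer <- vapply(value_cols, function(cn) mean(out[[cn]]), numeric(1))
  footer_se <- vapply(se_cols, function(cn)
    sqrt(sum(out[[cn]]^2, na.rm = TRUE)) / sum(!is.na(out[[cn]])),
    numeric(1))
  structure(out,
            footer = footer,
            footer_se = footer_se,
            footer_printed = round_half_up(footer, 1),
            sources = sources,
            class = c("comparison_table", "data.frame"))
}

#' @export
print.comparison_table <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = 1)
  print(df, row.names = FALSE)
  cat("Average:",
      paste(names(attr(x, "footer_printed")),
            format(attr(x, "footer_printed"), nsmall = 1), collapse = "  "),
      "\n")
  invisible(x)
}

#' Monthly source-contribution table
#'
#' Means per calendar month and source. For an hourly `source_series` (or
#' `contribution_series`) the means are computed from the retained hours;
#' a plain data frame whose first column is the month is taken as an
#' already-aggregated table (e.g. published values).
#'
#' @param x a `source_series`, `contribution_series`, or months x sources
#'   data frame.
#' @param year optional calendar year to restrict an hourly series to.
#' @return a `monthly_table` data frame: `month` plus one column per source.
#' @export
monthly_table <- function(x, year = NULL) {
  if (inherits(x, "source_series") || inherits(x, "contribution_series")) {
    if (!is.null(year))
      x <- x[format(x$timestamp, "%Y") == as.character(year), , drop = FALSE]
    if (!nrow(x)) stopf("series does not span the requested year")
    mo <- as.integer(format(x$timestamp, "%m"))
    cols <- setdiff(names(x), "timestamp")
    out <- data.frame(month = sort(unique(mo)))
    for (cn in cols)
      out[[cn]] <- vapply(out$month, function(m)
        mean(x[[cn]][mo == m], na.rm = TRUE), numeric(1))
  } else {
    out <- as.data.frame(x)
    names(out)[1] <- "month"
  }
  class(out) <- c("monthly_table", "data.frame")
  out
}

#' Subset-sum average of a monthly table
#'
#' Sums the selected source columns per month and averages those sums over
#' the selected months — the summary used when comparing a subset of
#' resolved sources against a receptor-model total over a season.
#'
#' @param mt a [monthly_table()].
#' @param sources column names to sum.
#' @param months month numbers to average over (default: all rows).
#' @return list with `monthly_sums` (data frame `month`, `sum`), `average`
#'   (raw), and `printed` (one decimal, half away from zero).
#' @export
subset_average <- function(mt, sources, months = mt$month) {
  stopifnot(inherits(mt, "monthly_table"))
  bad <- setdiff(sources, names(mt))
  if (length(bad)) stopf("unknown sources: %s", paste(bad, collapse = ", "))
  rows <- mt$month %in% months
  sums <- rowSums(mt[rows, sources, drop = FALSE])
  avg <- mean(sums)
  list(monthly_sums = data.frame(month = mt$month[rows], sum = sums,
                                 row.names = NULL),
       average = avg, printed = round_half_up(avg, 1))
}
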