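#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used when reporting concentrations in printed tables
#' (base [round()] rounds halves to even, so e.g. 2.15 would print as 2.1).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Index of the 22.5-degree compass sector containing a bearing
#' @noRd
sector_index <- function(wd, n_sectors = 16) {
  width <- 360 / n_sectors
  floor(((wd + width / 2) %% 360) / width) + 1L
}

#' Test whether the origin lies inside the convex hull of a point cloud
#'
#' Vertices are taken from [grDevices::chull()]; a point on the boundary
#' counts as inside. Needs at least 3 non-collinear points.
#' @noRd
hull_contains_origin <- function(x, y) {
  if (length(x) < 3) return(NA)
  h <- grDevices::chull(x, y)
  if (length(h) < 3) return(NA)  # collinear cloud
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  j <- c(2:nh, 1)
  cross <- (hx[j] - hx) * (0 - hy) - (hy[j] - hy) * (0 - hx)
  all(cross <= 1e-12) || all(cross >= -1e-12)
}

#' Weekday number, Monday = 1 ... Sunday = 7
#' @noRd
weekday_num <- function(timestamp) as.integer(format(timestamp, "%u"))

is_weekend <- function(timestamp) weekday_num(timestamp) >= 6L

#' Mean and standard error (sd/sqrt(n)) of a vector, NA-safe
#' @noRd
mean_se <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(c(mean = NA_real_, se = NA_real_, n = 0))
  se <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  c(mean = mean(x), se = se, n = n)
}
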