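#' Reference weekly comparison values: Temuco winter 2014 campaign
#'
#' Weekly PM2.5 source-apportionment estimates (mean +/- standard error,
#' ug/m3) for Temuco, Chile, July-September 2014: cluster-analysis (CA)
#' estimates from the long-term hourly record alongside chemical mass
#' balance receptor-model (RM) estimates from the co-located 8-week
#' molecular-marker filter campaign. Residential wood burning (RWB)
#' dominates; traffic is the minor resolved source. Bundled for validating
#' comparison-table arithmetic and as a worked example.
#'
#' @return data frame with columns `period`, and for each of `rwb` and
#'   `traffic` the CA and RM means and standard errors.
#' @export
temuco_weekly_campaign <- function() {
  data.frame(
    period = paste("week", 1:8),
    rwb_ca = c(35.3, 64.3, 15.2, 47.9, 52.9, 43.7, 23.1, 57.6),
    rwb_ca_se = c(4.1, 7.1, 2.8, 5.6, 6.6, 4.4, 4.2, 9.0),
    rwb_rm = c(42.7, 75.9, 18.6, 52.6, 56.9, 42.8, 23.5, 48.6),
    rwb_rm_se = c(5.9, 7.1, 5.0, 6.3, 6.7, 6.1, 5.0, 7.8),
    traffic_ca = c(0.9, 0.5, 3.2, 0.0, 3.7, 2.7, 5.1, 1.1),
    traffic_ca_se = c(0.5, 0.5, 1.0, 0.0, 1.1, 1.0, 1.1, 0.3),
    traffic_rm = c(2.2, 2.4, 1.4, 2.3, 2.6, 2.5, 1.5, 2.8),
    traffic_rm_se = c(0.2, 0.5, 0.1, 0.2, 0.2, 0.2, 0.1, 0.2))
}

#' Reference monthly cluster contributions: Santiago Las Condes 2004
#'
#' Monthly mean PM2.5 contributions (ug/m3) of the eight-cluster solution
#' at the Las Condes site, Santiago, for calendar year 2004. Clusters 3 and
#' 4 are traffic corridors, cluster 7 the residential wood burning source,
#' cluster 6 the regional background.
#'
#' @return data frame: `month` (1-12), `C1` ... `C8`.
#' @export
santiago_monthly_clusters <- function() {
  data.frame(
    month = 1:12,
    C1 = c(2.1, 2.7, 1.8, 1.7, 0.4, 0.1, 0.0, 0.2, 0.4, 1.0, 1.5, 2.4),
    C2 = c(0.3, 0.6, 0.3, 0.2, 0.1, 0.0, 0.0, 0.0, 0.0, 0.1, 0.3, 0.5),
    C3 = c(10.4, 11.4, 11.0, 5.8, 5.7, 4.0, 3.1, 4.7, 6.3, 6.3, 7.7, 10.4),
    C4 = c(5.8, 9.1, 10.7, 13.3, 17.4, 16.7, 16.0, 9.2, 10.8, 8.0, 6.0, 5.7),
    C5 = c(0.0, 0.0, 0.0, 0.02, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0),
    C6 = c(0.9, 1.8, 2.4, 3.7, 6.6, 5.9, 4.7, 3.2, 3.1, 2.8, 3.2, 1.5),
    C7 = c(0.0, 0.0, 0.0, 0.7, 6.5, 4.5, 3.9, 6.8, 2.1, 0.6, 0.1, 0.0),
    C8 = c(0.1, 0.0, 0.2, 0.5, 0.4, 1.3, 0.9, 0.4, 0.4, 0.3, 0.4, 0.3))
}

#' Reference seasonal comparison: Santiago Las Condes, May-August 2004
#'
#' Monthly PM2.5 source-apportionment estimates (mean +/- standard error,
#' ug/m3) for the cold season at Las Condes: cluster-analysis estimates
#' (traffic = clusters 3+4, RWB = cluster 7, regional = cluster 6) against
#' positive matrix factorization receptor-model estimates from the
#' co-located elemental-speciation campaign.
#'
#' @return data frame with columns `month` (5-8) and CA/RM means and
#'   standard errors for `traffic`, `rwb`, `regional`.
#' @export
santiago_monthly_comparison <- function() {
  data.frame(
    month = 5:8,
    traffic_ca = c(25.2, 20.8, 21.6, 14.8),
    traffic_ca_se = c(2.5, 1.9, 2.1, 1.8),
    traffic_rm = c(14.7, 17.6, 16.8, 9.3),
    traffic_rm_se = c(1.2, 1.7, 1.5, 0.8),
    rwb_ca = c(7.4, 6.4, 4.0, 8.1),
    rwb_ca_se = c(2.4, 2.1, 1.6, 2.3),
    rwb_rm = c(15.1, 13.8, 12.7, 7.3),
    rwb_rm_se = c(1.6, 1.2, 1.3, 0.7),
    regional_ca = c(6.3, 7.9, 6.7, 4.0),
    regional_ca_se = c(1.2, 1.3, 1.7, 1.1),
    regional_rm = c(17.7, 11.6, 12.7, 12.3),
    regional_rm_se = c(2.2, 1.1, 1.7, 1.3))
}

#' Long format helper for the bundled comparison tables
#'
#' Reshapes a bundled wide table into the long `(period, source, mean, se)`
#' format consumed by [build_comparison()].
#'
#' @param wide data frame from [temuco_weekly_campaign()] or
#'   [santiago_monthly_comparison()].
#' @param method `"ca"` or `"rm"`.
#' @return long data frame: `period`, `source`, `mean`, `se`.
#' @export
campaign_long <- function(wide, method = c("ca", "rm")) {
  method <- match.arg(method)
  period <- wide[[1]]
  src <- unique(sub("_(ca|rm)(_se)?$", "",
                    grep("_(ca|rm)(_se)?$", names(wide), value = TRUE)))
  do.call(rbind, lapply(src, function(s) {
    data.frame(period = period, source = s,
               mean = wide[[paste0(s, "_", method)]],
               se = wide[[paste0(s, "_", method, "_se")]],
               row.names = NULL)
  }))
}
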