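#' Site-wide UTCI extremes per timestamp
#'
#' @param grids list of UTCI matrices, one per timestamp, or a 3-d array
#'   `[time, row, col]`.
#' @param time POSIXct vector aligned with the grids.
#' @return data frame with `time`, `utci_max`, `utci_min`.
#' @export
site_extremes <- function(grids, time) {
  if (is.array(grids) && length(dim(grids)) == 3) {
    grids <- lapply(seq_len(dim(grids)[1]), function(i) grids[i, , ])
  }
  stopifnot(length(grids) == length(time))
  mx <- vapply(grids, function(g) {
    if (all(is.na(g))) stop("all-missing UTCI grid", call. = FALSE)
    max(g, na.rm = TRUE)
  }, numeric(1))
  mn <- vapply(grids, function(g) min(g, na.rm = TRUE), numeric(1))
  data.frame(time = time, utci_max = mx, utci_min = mn)
}

# (hour, doy) factors in numeric order, covering all 24 x 365 cells.
hour_doy_factors <- function(groups) {
  list(hour = factor(groups$hour, levels = 0:23),
       doy = factor(groups$block, levels = 1:365))
}

# Period change per (hour, doy) for one ensemble member.
member_hour_doy_change <- function(hist, fut, value_col = "tair") {
  gh <- hour_doy_factors(build_time_groups(hist$time, "daily"))
  gf <- hour_doy_factors(build_time_groups(fut$time, "daily"))
  mh <- tapply(hist[[value_col]], gh, mean)
  mf <- tapply(fut[[value_col]], gf, mean)
  if (!all(dim(mh) == dim(mf))) stop("mismatched (hour, doy) coverage", call. = FALSE)
  mf - mh
}

#' Ensemble change field by hour of day and day of year
#'
#' Per (hour, day-of-year) cell: each member's future-period mean minus
#' historic-period mean, then the ensemble mean or sample standard deviation
#' (n - 1) of those changes.
#'
#' @param ens_hist,ens_fut lists of [met_series()] (or data frames with
#'   `time` and the value column), one element per ensemble member, matching
#'   names/order.
#' @param statistic `"mean"` or `"sd"`.
#' @param value_col column to analyse (default `tair`).
#' @return 24 x 365 matrix (hours 0-23 by day of year), with attribute
#'   `hour_month` giving the 24 x 12 calendar-month aggregation.
#' @export
change_by_hour_doy <- function(ens_hist, ens_fut, statistic = c("mean", "sd"),
                               value_col = "tair") {
  statistic <- match.arg(statistic)
  if (length(ens_hist) != length(ens_fut)) {
    stop("ensembles must have matching members", call. = FALSE)
  }
  if (statistic == "sd" && length(ens_hist) < 2) {
    stop("sd requires >= 2 members", call. = FALSE)
  }
  changes <- mapply(member_hour_doy_change, ens_hist, ens_fut,
                    MoreArgs = list(value_col = value_col), SIMPLIFY = FALSE)
  arr <- simplify2array(changes)            # 24 x 365 x members
  field <- apply(arr, c(1, 2), if (statistic == "mean") mean else sd)
  doy_month <- doy_to_month()
  hm <- t(apply(field, 1, function(row) tapply(row, doy_month, mean)))
  attr(field, "hour_month") <- hm
  field
}

# Calendar month of each day of a fixed 365-day year.
doy_to_month <- function() {
  rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
}

#' Future medians expressed as historic percentiles
#'
#' For each (hour, day-of-year) group, the percentile rank (0-100) of the
#' future median within the historic empirical distribution of the same
#' group, by linear interpolation of the type-7 quantile curve; future
#' medians outside the historic range report 0 or 100.
#'
#' @param hist,fut data frames with `time` and the value column.
#' @param value_col column to analyse.
#' @return 24 x 365 matrix of percentiles.
#' @export
median_as_historic_percentile <- function(hist, fut, value_col = "tair") {
  gh <- hour_doy_factors(build_time_groups(hist$time, "daily"))
  gf <- hour_doy_factors(build_time_groups(fut$time, "daily"))
  fmed <- tapply(fut[[value_col]], gf, median)
  out <- matrix(NA_real_, 24, 365, dimnames = dimnames(fmed))
  hsplit <- split(hist[[value_col]], gh, sep = "|")
  for (h in 1:24) for (d in 1:365) {
    key <- paste(rownames(fmed)[h], colnames(fmed)[d], sep = "|")
    hv <- hsplit[[key]]
    if (is.null(hv) || length(hv) == 0 || is.na(fmed[h, d])) next
    out[h, d] <- percentile_rank(hv, fmed[h, d])
  }
  out
}

# Percentile rank (0-100) of x0 in sample v under the type-7 quantile curve.
percentile_rank <- function(v, x0) {
  sv <- sort(v)
  if (x0 <= sv[1]) return(if (x0 < sv[1]) 0 else 0)
  if (x0 >= sv[length(sv)]) return(100)
  tau <- seq(0, 1, length.out = length(sv))
  100 * approx(sv, tau, xout = x0, ties = "mean")$y
}

#' Percentile bands of site-wide extremes by hour of day
#'
#' @param extremes data frame from [site_extremes()].
#' @param levels percentile levels (default 5, 50, 95).
#' @param value_col `"utci_max"` or `"utci_min"`.
#' @return data frame with `hour` and one column per level.
#' @export
percentile_bands_by_hour <- function(extremes, levels = c(5, 50, 95),
                                     value_col = "utci_max") {
  hour <- as.POSIXlt(extremes$time)$hour
  counts <- table(hour)
  if (any(counts < 20) && any(levels %in% c(5, 95))) {
    warning("fewer than 20 values in some hours: tail percentiles unstable")
  }
  out <- data.frame(hour = sort(unique(hour)))
  for (lv in levels) {
    out[[sprintf("p%g", lv)]] <- as.numeric(
      tapply(extremes[[value_col]], hour, quantile, probs = lv / 100, type = 7))
  }
  out
}

#' Stress flags from site-wide extremes
#'
#' Scope semantics: "any-cell" heat needs one hot cell (`utci_max` crosses
#' the threshold), "site-wide" heat needs every cell hot (`utci_min`
#' crosses); cold mirrors with the opposite extreme.
#'
#' @param extremes data frame from [site_extremes()].
#' @param rollup `"heat"`, `"cold"` or `"no_stress"`.
#' @param scope `"any_cell"` or `"site_wide"`.
#' @param scale a [utci_stress_scale()].
#' @return logical vector per timestamp.
#' @export
stress_flags <- function(extremes, rollup = c("heat", "cold", "no_stress"),
                         scope = c("any_cell", "site_wide"),
                         scale = utci_stress_scale()) {
  rollup <- match.arg(rollup)
  scope <- match.arg(scope)
  hb <- scale$heat_breaks[1]; cb <- scale$cold_breaks[1]
  mx <- extremes$utci_max; mn <- extremes$utci_min
  switch(rollup,
    heat = if (scope == "any_cell") mx > hb else mn > hb,
    cold = if (scope == "any_cell") mn < cb else mx < cb,
    no_stress = if (scope == "any_cell") !(mn > hb) & !(mx < cb)
                else mx <= hb & mn >= cb)
}

#' Annual mean stress hours by month and by hour of day
#'
#' Counts flagged hours aggregated by calendar month and, separately, by
#' hour of day, divided by the number of calendar years spanned.
#'
#' @param time POSIXct vector.
#' @param flags logical vector aligned with `time`.
#' @return list with `by_month` (length 12), `by_hour` (length 24),
#'   `annual_total` and `n_years`.
#' @export
stress_hours <- function(time, flags) {
  stopifnot(length(time) == length(flags))
  lt <- as.POSIXlt(time)
  n_years <- length(unique(lt$year))
  by_month <- vapply(1:12, function(m) sum(flags[lt$mon + 1 == m]), numeric(1)) / n_years
  by_hour <- vapply(0:23, function(h) sum(flags[lt$hour == h]), numeric(1)) / n_years
  names(by_month) <- month.abb
  names(by_hour) <- sprintf("%02d", 0:23)
  list(by_month = by_month, by_hour = by_hour,
       annual_total = sum(flags) / n_years, n_years = n_years)
}

#' Cumulative stress hours over June-to-May spans
#'
#' Splits the record into spans running 1 June through 31 May (labelled by
#' the starting year), accumulates flagged hours within each span, and
#' records the first flagged timestamp (if any).
#'
#' @param time POSIXct vector at hourly steps.
#' @param flags logical vector aligned with `time`.
#' @param complete_only drop spans not fully covered by the record.
#' @return data frame with one row per span: `span_start_year`, `total`,
#'   `first_occurrence` (POSIXct, NA when the span has none); attribute
#'   `cumulative` holds the running series per span.
#' @export
cumulative_stress_june_may <- function(time, flags, complete_only = TRUE) {
  lt <- as.POSIXlt(time)
  year <- lt$year + 1900
  span <- ifelse(lt$mon + 1 >= 6, year, year - 1)
  spans <- sort(unique(span))
  if (complete_only) {
    keep <- vapply(spans, function(s) {
      i <- span == s
      any(i & lt$mon + 1 == 6 & lt$mday == 1 & lt$hour == 0) &&
        any(i & lt$mon + 1 == 5 & lt$mday == 31 & lt$hour == 23)
    }, logical(1))
    spans <- spans[keep]
  }
  if (length(spans) == 0) stop("no complete June-May span in record", call. = FALSE)
  cum <- list()
  out <- data.frame(span_start_year = spans, total = NA_real_)
  tzv <- attr(time, "tzone")
  if (is.null(tzv) || !nzchar(tzv[1])) tzv <- "UTC"
  out$first_occurrence <- as.POSIXct(rep(NA_real_, length(spans)),
                                     origin = "1970-01-01", tz = tzv[1])
  for (i in seq_along(spans)) {
    idx <- which(span == spans[i])
    f <- flags[idx]
    cum[[as.character(spans[i])]] <- cumsum(f)
    out$total[i] <- sum(f)
    if (any(f)) out$first_occurrence[i] <- time[idx[which(f)[1]]]
  }
  attr(out, "cumulative") <- cum
  out
}

#' Period summary table with net changes and change factors
#'
#' Reproduces the structure of an ensemble summary over two periods:
#' per-variable period means and net change (future minus historic), the
#' percentage of hours in each stress rollup per period, and the change
#' factor (future percentage / historic percentage). Values are additionally
#' reported rounded to the conventional precision (means 1 decimal,
#' percentages 2, change factors 2).
#'
#' @param hist,fut [met_series()] for the two periods.
#' @param hist_extremes,fut_extremes data frames from [site_extremes()]
#'   (site-wide UTCI max/min per timestamp), aligned with the series.
#' @param hist_utci,fut_utci optional site-mean UTCI per timestamp; when
#'   given a UTCI row is included in the means block.
#' @param scale a [utci_stress_scale()].
#' @return list with data frames `means` (`variable`, `hist`, `fut`,
#'   `net_change`, rounded columns) and `stress` (`condition`, `hist_pct`,
#'   `fut_pct`, `change_factor`, rounded columns).
#' @export
summary_table <- function(hist, fut, hist_extremes, fut_extremes,
                          hist_utci = NULL, fut_utci = NULL,
                          scale = utci_stress_scale()) {
  vars <- MET_VARS
  means <- data.frame(
    variable = vars,
    hist = vapply(vars, function(v) mean(hist[[v]]), numeric(1)),
    fut = vapply(vars, function(v) mean(fut[[v]]), numeric(1)))
  if (!is.null(hist_utci)) {
    means <- rbind(means, data.frame(variable = "utci",
                                     hist = mean(hist_utci), fut = mean(fut_utci)))
  }
  means$net_change <- means$fut - means$hist
  means$hist_r <- round(means$hist, 1)
  means$fut_r <- round(means$fut, 1)
  means$net_change_r <- round(means$net_change, 1)

  conds <- expand.grid(rollup = c("heat", "no_stress", "cold"),
                       scope = c("any_cell", "site_wide"),
                       stringsAsFactors = FALSE)
  conds <- conds[order(match(conds$rollup, c("heat", "no_stress", "cold"))), ]
  pct <- function(ex, rollup, scope) {
    100 * mean(stress_flags(ex, rollup, scope, scale))
  }
  stress <- data.frame(
    condition = paste(conds$scope, conds$rollup, sep = "_"),
    hist_pct = mapply(function(r, s) pct(hist_extremes, r, s),
                      conds$rollup, conds$scope),
    fut_pct = mapply(function(r, s) pct(fut_extremes, r, s),
                     conds$rollup, conds$scope))
  stress$change_factor <- ifelse(stress$hist_pct > 0,
                                 stress$fut_pct / stress$hist_pct, NA_real_)
  stress$hist_pct_r <- round(stress$hist_pct, 2)
  stress$fut_pct_r <- round(stress$fut_pct, 2)
  stress$change_factor_r <- round(stress$change_factor, 2)
  rownames(stress) <- NULL
  list(means = means, stress = stress)
}

#' Net changes and change factors from printed period statistics
#'
#' Arithmetic used by the summary table, exposed for recomputing a published
#' table's derived columns from its printed period entries: net change =
#' future mean - historic mean (rounded to 1 decimal), change factor =
#' future percentage / historic percentage (rounded to 2).
#'
#' @param hist_mean,fut_mean period means (or `NULL`).
#' @param hist_pct,fut_pct period percentages of hours (or `NULL`).
#' @return list with `net_change` and `change_factor` (NA where inputs
#'   are `NULL`).
#' @export
summary_arithmetic <- function(hist_mean = NULL, fut_mean = NULL,
                               hist_pct = NULL, fut_pct = NULL) {
  net <- if (is.null(hist_mean)) NA_real_ else round(fut_mean - hist_mean, 1)
  cf <- if (is.null(hist_pct)) NA_real_ else {
    if (any(hist_pct == 0)) stop("undefined change factor: zero historic percentage",
                                 call. = FALSE)
    round(fut_pct / hist_pct, 2)
  }
  list(net_change = net, change_factor = cf)
}
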