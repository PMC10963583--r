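#' Bias-correction configuration
#'
#' @param n_quantiles number of evenly spaced quantile levels (>= 10).
#' @param trace_threshold smallest value treated as nonzero when forming
#'   multiplicative adjustment factors (absolute units of the variable).
#' @param mbcn_max_iter maximum MBCn rotation iterations.
#' @param mbcn_min_iter iterations run before the convergence test applies
#'   (guards against spurious plateaus in the subsampled energy estimate).
#' @param mbcn_tol convergence tolerance on the change in energy distance
#'   between corrected historical data and the reference.
#' @param rotation_seed seed controlling the random rotations (recorded so a
#'   run is reproducible).
#' @param energy_sample rows subsampled when estimating the energy distance.
#' @return object of class `correction_config`.
#' @export
correction_config <- function(n_quantiles = 100, trace_threshold = 1e-6,
                              mbcn_max_iter = 30, mbcn_min_iter = 10,
                              mbcn_tol = 1e-4,
                              rotation_seed = 4242, energy_sample = 500) {
  if (n_quantiles < 10) stop("n_quantiles must be >= 10", call. = FALSE)
  if (trace_threshold <= 0) stop("trace_threshold must be > 0", call. = FALSE)
  structure(list(n_quantiles = n_quantiles, trace_threshold = trace_threshold,
                 mbcn_max_iter = mbcn_max_iter, mbcn_min_iter = mbcn_min_iter,
                 mbcn_tol = mbcn_tol,
                 rotation_seed = rotation_seed, energy_sample = energy_sample),
            class = "correction_config")
}

#' Replace invalid multiplicative adjustment factors
#'
#' Division by (near-)zero model quantiles yields non-finite adjustment
#' factors. For downwelling shortwave these are set to zero (a cell the model
#' keeps dark stays dark); 0/0 cases are likewise defined as zero. For other
#' variables non-finite factors are left in place with a warning, since they
#' indicate a configuration problem (e.g. multiplicative correction across a
#' sign change).
#'
#' @param factors numeric vector of raw adjustment factors.
#' @param variable variable tag; replacement applies when `"swdown"`.
#' @return the factors, with an attribute `n_replaced` giving the count of
#'   replacements.
#' @export
sanitize_factors <- function(factors, variable = "swdown") {
  bad <- !is.finite(factors)
  n <- sum(bad)
  if (n > 0) {
    if (identical(variable, "swdown")) {
      factors[bad] <- 0
    } else {
      warning(sprintf("%d non-finite adjustment factors for '%s' left in place",
                      n, variable))
      n <- 0L
    }
  }
  attr(factors, "n_replaced") <- as.integer(n)
  factors
}

# Empirical quantile function on evenly spaced tau levels (type 7). When the
# group has no more members than levels, the exact type-7 knots (the sorted
# sample) represent the same piecewise-linear curve with no resampling error.
qdm_quantiles <- function(x, nq) {
  n <- length(x)
  if (n == 1) return(list(tau = c(0, 1), q = c(x, x)))
  if (n <= nq) return(list(tau = seq(0, 1, length.out = n), q = sort(x)))
  tau <- seq(0, 1, length.out = nq)
  list(tau = tau, q = quantile(x, probs = tau, type = 7, names = FALSE))
}

# Inverse lookup: tau of x0 under the type-7 quantile curve; plateaus (tied
# quantile values) interpolate to the plateau midpoint; values beyond the
# range clamp to tau 0/1, which makes the edge adjustment factor constant.
qdm_tau_of <- function(qs, x0) {
  if (diff(range(qs$q)) == 0) return(rep(0.5, length(x0)))
  approx(qs$q, qs$tau, xout = x0, rule = 2, ties = "mean")$y
}

qdm_value_at <- function(qs, tau0) {
  approx(qs$tau, qs$q, xout = tau0, rule = 2, ties = "ordered")$y
}

# Core QDM on one group of values.
qdm_group <- function(ref, mod_hist, x, kind, config, variable) {
  nq <- config$n_quantiles
  qr <- qdm_quantiles(ref, nq)
  qh <- qdm_quantiles(mod_hist, nq)
  qp <- qdm_quantiles(x, nq)
  tau0 <- qdm_tau_of(qp, x)
  rq <- qdm_value_at(qr, tau0)
  hq <- qdm_value_at(qh, tau0)
  if (kind == "additive") {
    out <- rq + (x - hq)
    attr(out, "n_replaced") <- 0L
    return(out)
  }
  tr <- config$trace_threshold
  fac <- ifelse(abs(hq) > tr, rq / hq, ifelse(abs(rq) > tr, Inf, NaN))
  fac <- sanitize_factors(fac, variable)
  out <- fac * x
  out[!is.finite(out)] <- 0
  attr(out, "n_replaced") <- attr(fac, "n_replaced")
  out
}

#' Grouped quantile delta mapping
#'
#' Corrects a model-projected series against a reference using the model's
#' historical run, within (hour, block) time groups. For each projected value
#' `x`, `tau` is its level under the group's empirical model-projected
#' quantile curve; the multiplicative output is
#' `ref_q(tau) * x / mod_hist_q(tau)` and the additive output
#' `ref_q(tau) + (x - mod_hist_q(tau))`, so the model's projected relative
#' (resp. absolute) change at each quantile is preserved.
#'
#' @param ref,mod_hist,mod_proj numeric vectors (reference, model historical,
#'   model projected).
#' @param groups `NULL` for a single group, or a list with character key
#'   vectors `ref`, `hist`, `proj` (e.g. the `key` column of
#'   [build_time_groups()]) aligned with the three series.
#' @param config a [correction_config()].
#' @param kind `"multiplicative"` or `"additive"`.
#' @param variable variable tag forwarded to [sanitize_factors()].
#' @return corrected projected series, with attribute `n_replaced` (total
#'   factor replacements).
#' @export
qdm_correct <- function(ref, mod_hist, mod_proj, groups = NULL,
                        config = correction_config(),
                        kind = c("multiplicative", "additive"),
                        variable = "generic") {
  kind <- match.arg(kind)
  for (v in list(ref, mod_hist, mod_proj)) {
    if (any(!is.finite(v))) stop("non-finite values in input series", call. = FALSE)
  }
  if (kind == "multiplicative" &&
      (any(ref < 0) || any(mod_hist < 0) || any(mod_proj < 0))) {
    stop("multiplicative QDM requires non-negative data", call. = FALSE)
  }
  if (is.null(groups)) {
    return(qdm_group(ref, mod_hist, mod_proj, kind, config, variable))
  }
  iref <- split(seq_along(ref), groups$ref)
  ihist <- split(seq_along(mod_hist), groups$hist)
  iproj <- split(seq_along(mod_proj), groups$proj)
  out <- numeric(length(mod_proj))
  n_rep <- 0L
  for (g in names(iproj)) {
    if (is.null(iref[[g]]) || is.null(ihist[[g]])) {
      stop(sprintf("time group '%s' empty in reference or historical series", g),
           call. = FALSE)
    }
    res <- qdm_group(ref[iref[[g]]], mod_hist[ihist[[g]]],
                     mod_proj[iproj[[g]]], kind, config, variable)
    out[iproj[[g]]] <- res
    n_rep <- n_rep + attr(res, "n_replaced")
  }
  attr(out, "n_replaced") <- n_rep
  out
}

#' Univariate QDM of all four driver variables of a met series
#'
#' Applies multiplicative QDM within (hour, week-of-year) groups to each
#' variable. Air temperature is shifted to kelvin before the multiplicative
#' correction and back afterwards, keeping ratios positive across 0 degC.
#' Relative humidity is clamped to `[0, 100]` after correction (count
#' reported).
#'
#' @param ref,mod_hist,mod_proj [met_series()] objects.
#' @param config a [correction_config()].
#' @param mode time-group mode, default `"weekly"`.
#' @return corrected projected [met_series()]; attribute `diagnostics` lists
#'   factor replacements and clamp counts per variable.
#' @export
qdm_correct_met <- function(ref, mod_hist, mod_proj,
                            config = correction_config(), mode = "weekly") {
  gr <- list(ref = build_time_groups(ref$time, mode)$key,
             hist = build_time_groups(mod_hist$time, mode)$key,
             proj = build_time_groups(mod_proj$time, mode)$key)
  mr <- met_matrix(ref); mh <- met_matrix(mod_hist); mp <- met_matrix(mod_proj)
  out <- mp
  diag <- list()
  for (v in MET_VARS) {
    shift <- if (v == "tair") 273.15 else 0
    cor_v <- qdm_correct(mr[, v] + shift, mh[, v] + shift, mp[, v] + shift,
                         groups = gr, config = config,
                         kind = "multiplicative", variable = v)
    diag[[v]] <- list(n_replaced = attr(cor_v, "n_replaced"))
    out[, v] <- as.numeric(cor_v) - shift
  }
  n_clamp <- sum(out[, "rh"] < 0 | out[, "rh"] > 100)
  out[, "rh"] <- pmin(100, pmax(0, out[, "rh"]))
  out[, "wind10"] <- pmax(0, out[, "wind10"])
  out[, "swdown"] <- pmax(0, out[, "swdown"])
  diag$rh_clamped <- n_clamp
  res <- met_replace(mod_proj, out)
  attr(res, "diagnostics") <- diag
  res
}
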