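#' Haar-distributed random orthogonal matrix
#'
#' QR decomposition of a standard-Gaussian matrix with the signs of the
#' diagonal of R fixed, giving a rotation drawn from the Haar measure.
#'
#' @param dim matrix dimension (>= 2).
#' @param seed integer seed; the same seed reproduces the same matrix.
#' @return `dim` x `dim` orthogonal matrix.
#' @export
random_rotation <- function(dim, seed) {
  stopifnot(dim >= 2)
  withr_seed(seed, {
    m <- matrix(rnorm(dim * dim), dim, dim)
    qrm <- qr(m)
    q <- qr.Q(qrm)
    d <- sign(diag(qr.R(qrm)))
    d[d == 0] <- 1
    q %*% diag(d)
  })
}

#' Energy distance between two multivariate samples
#'
#' `2 E||X - Y|| - E||X - X'|| - E||Y - Y'||` with Euclidean distances,
#' estimated on (sub)samples.
#'
#' @param x,y numeric matrices with matching column count.
#' @param max_n rows to subsample from each (deterministic, seeded).
#' @param seed subsampling seed.
#' @return non-negative scalar.
#' @export
energy_distance <- function(x, y, max_n = 500, seed = 1) {
  sub <- function(m, s) {
    if (nrow(m) <= max_n) return(m)
    withr_seed(s, m[sample.int(nrow(m), max_n), , drop = FALSE])
  }
  x <- sub(x, seed); y <- sub(y, seed + 1)
  mean_pdist <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    mean(sqrt(pmax(d2, 0)))
  }
  2 * mean_pdist(x, y) - mean_pdist(x, x) - mean_pdist(y, y)
}

# Group bookkeeping for the vectorised inner QDM: integer group ids shared
# across the three datasets plus per-dataset sizes and sorted-block offsets.
mbcn_group_index <- function(keys_ref, keys_hist, keys_proj) {
  lev <- sort(unique(keys_proj))
  gid <- function(k) match(k, lev)
  g <- list(ref = gid(keys_ref), hist = gid(keys_hist), proj = gid(keys_proj),
            n_groups = length(lev))
  for (nm in c("ref", "hist")) {
    if (anyNA(g[[nm]])) g[[nm]] <- g[[nm]]  # extra groups in ref/hist are unused
  }
  sizes <- function(idx) tabulate(idx[!is.na(idx)], g$n_groups)
  g$sizes_ref <- sizes(g$ref); g$sizes_hist <- sizes(g$hist)
  g$sizes_proj <- sizes(g$proj)
  if (any(g$sizes_ref == 0) || any(g$sizes_hist == 0)) {
    bad <- lev[which(g$sizes_ref == 0 | g$sizes_hist == 0)[1]]
    stop(sprintf("time group '%s' empty in reference or historical series", bad),
         call. = FALSE)
  }
  g$starts_ref <- cumsum(g$sizes_ref) - g$sizes_ref
  g$starts_hist <- cumsum(g$sizes_hist) - g$sizes_hist
  g
}

# Within-group ranks via one sort; tau at the type-7 knots (rank-1)/(m-1).
group_tau <- function(x, gid, sizes) {
  keep <- !is.na(gid)
  o <- order(gid[keep], x[keep])
  pos <- sequence(sizes[sizes > 0])
  rk <- numeric(sum(keep))
  rk[o] <- pos
  m <- sizes[gid[keep]]
  tau <- ifelse(m == 1, 0.5, (rk - 1) / pmax(m - 1, 1))
  out <- rep(NA_real_, length(x))
  out[keep] <- tau
  out
}

# Evaluate per-group piecewise-linear quantile curves (sorted sample knots)
# at tau, vectorised over all groups at once.
group_quantile <- function(x, gid, sizes, starts, gid_out, tau) {
  keep <- !is.na(gid)
  o <- order(gid[keep], x[keep])
  xs <- x[keep][o]
  m <- sizes[gid_out]
  pos <- 1 + tau * (m - 1)
  lo <- pmin(floor(pos), m)
  hi <- pmin(lo + 1, m)
  frac <- pos - lo
  xs[starts[gid_out] + lo] * (1 - frac) + xs[starts[gid_out] + hi] * frac
}

# Additive QDM of hist and proj against ref within groups, vectorised.
# Equivalent to per-group qdm_group on the exact type-7 knots; ties are
# broken by position (continuous rotated coordinates in practice).
mbcn_qdm_pair <- function(ref, hist, proj, gx) {
  tau_h <- group_tau(hist, gx$hist, gx$sizes_hist)
  tau_p <- group_tau(proj, gx$proj, gx$sizes_proj)
  qr_h <- group_quantile(ref, gx$ref, gx$sizes_ref, gx$starts_ref, gx$hist, tau_h)
  qr_p <- group_quantile(ref, gx$ref, gx$sizes_ref, gx$starts_ref, gx$proj, tau_p)
  qh_p <- group_quantile(hist, gx$hist, gx$sizes_hist, gx$starts_hist, gx$proj, tau_p)
  # hist's own quantile at its own knots is itself, so its correction is qr_h
  list(hist = qr_h, proj = qr_p + proj - qh_p)
}

#' N-dimensional multivariate bias correction (MBCn)
#'
#' Iteratively applies a random orthogonal rotation to the reference,
#' historical and projected matrices, additive QDM on each rotated coordinate
#' within time groups, and the inverse rotation, until the energy distance
#' between the corrected historical data and the reference stops improving.
#' The final output reorders the supplied univariate-QDM marginals to the
#' rank order of the converged iterate, within each group and variable, so
#' every corrected marginal is exactly its univariate-QDM marginal while the
#' rank dependence structure comes from the MBCn iterate.
#'
#' @param ref,mod_hist,mod_proj numeric matrices, one column per variable.
#' @param qdm_marginals matrix aligned with `mod_proj`: the univariate
#'   QDM-corrected projected values to be reordered.
#' @param groups `NULL` for a single group, or list of key vectors
#'   `ref`/`hist`/`proj` as in [qdm_correct()] (daily mode in the pipeline).
#' @param config a [correction_config()].
#' @param qdm_marginals_hist optional matrix aligned with `mod_hist`; when
#'   given, the corrected historical matrix is returned as well.
#' @return matrix of corrected projected values; attributes: `energy_trace`
#'   (energy distance per iteration), `converged`, and (if requested)
#'   `historical` (corrected historical matrix).
#' @export
mbcn_correct <- function(ref, mod_hist, mod_proj, qdm_marginals,
                         groups = NULL, config = correction_config(),
                         qdm_marginals_hist = NULL) {
  ref <- as.matrix(ref); mod_hist <- as.matrix(mod_hist)
  mod_proj <- as.matrix(mod_proj); qdm_marginals <- as.matrix(qdm_marginals)
  p <- ncol(ref)
  if (ncol(mod_hist) != p || ncol(mod_proj) != p || ncol(qdm_marginals) != p) {
    stop("all inputs must share the same variable columns", call. = FALSE)
  }
  if (nrow(qdm_marginals) != nrow(mod_proj)) {
    stop("qdm_marginals must align row-wise with mod_proj", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- list(ref = rep("all", nrow(ref)), hist = rep("all", nrow(mod_hist)),
                   proj = rep("all", nrow(mod_proj)))
  }
  gx <- mbcn_group_index(groups$ref, groups$hist, groups$proj)
  ihist <- split(seq_len(nrow(mod_hist)), groups$hist)
  iproj <- split(seq_len(nrow(mod_proj)), groups$proj)

  # standardise by the reference marginals for rotation conditioning
  mu <- colMeans(ref)
  sg <- apply(ref, 2, sd)
  sg[sg == 0] <- 1
  std <- function(m) sweep(sweep(m, 2, mu), 2, sg, "/")
  r0 <- std(ref); h <- std(mod_hist); pr <- std(mod_proj)

  trace <- numeric(0)
  best <- list(e = Inf, hist = h, proj = pr)
  converged <- FALSE
  for (it in seq_len(config$mbcn_max_iter)) {
    rot <- random_rotation(p, config$rotation_seed + it)
    rR <- r0 %*% rot; hR <- h %*% rot; pR <- pr %*% rot
    for (j in seq_len(p)) {
      res <- mbcn_qdm_pair(rR[, j], hR[, j], pR[, j], gx)
      hR[, j] <- res$hist
      pR[, j] <- res$proj
    }
    h <- hR %*% t(rot); pr <- pR %*% t(rot)
    e <- energy_distance(h, r0, max_n = config$energy_sample,
                         seed = config$rotation_seed)
    trace <- c(trace, e)
    if (e < best$e) best <- list(e = e, hist = h, proj = pr)
    min_it <- if (is.null(config$mbcn_min_iter)) 10 else config$mbcn_min_iter
    if (it >= min_it && abs(trace[it - 1] - e) < config$mbcn_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning(sprintf(
      "MBCn did not converge in %d iterations (last energy-distance change %.3g); best iterate used",
      config$mbcn_max_iter,
      if (length(trace) > 1) abs(diff(tail(trace, 2))) else NA_real_))
  }

  reorder <- function(target, marg, idx) {
    out <- marg
    for (g in names(idx)) {
      for (j in seq_len(p)) {
        rk <- rank(target[idx[[g]], j], ties.method = "first")
        out[idx[[g]], j] <- sort(marg[idx[[g]], j])[rk]
      }
    }
    out
  }
  out <- reorder(best$proj, qdm_marginals, iproj)
  attr(out, "energy_trace") <- trace
  attr(out, "converged") <- converged
  if (!is.null(qdm_marginals_hist)) {
    attr(out, "historical") <- reorder(best$hist, as.matrix(qdm_marginals_hist), ihist)
  }
  out
}

#' Full multivariate correction of a model pair against a reference
#'
#' The complete correction chain: univariate multiplicative QDM per variable
#' within (hour, week) groups — applied to the historical run (mapping it
#' onto the reference) and to the projected run (preserving its change
#' signal) — followed by MBCn within (hour, day-of-year) groups, whose output
#' reorders the QDM marginals.
#'
#' @param ref reference [met_series()].
#' @param mod_hist,mod_proj model historical and projected [met_series()].
#' @param config a [correction_config()].
#' @param mbcn_mode time-group mode for the MBCn stage (`"daily"`, the
#'   default, or `"weekly"` for small samples).
#' @param mbcn whether to run the MBCn stage at all (`FALSE` leaves the
#'   univariate QDM output).
#' @return list with corrected `historical` and `future` [met_series()] and a
#'   `diagnostics` list (factor replacements, energy-distance trace).
#' @export
correct_met_pair <- function(ref, mod_hist, mod_proj,
                             config = correction_config(),
                             mbcn_mode = "daily", mbcn = TRUE) {
  qdm_hist <- qdm_correct_met(ref, mod_hist, mod_hist, config)
  qdm_proj <- qdm_correct_met(ref, mod_hist, mod_proj, config)
  diagnostics <- list(qdm_hist = attr(qdm_hist, "diagnostics"),
                      qdm_proj = attr(qdm_proj, "diagnostics"))
  if (!mbcn) {
    return(list(historical = qdm_hist, future = qdm_proj,
                diagnostics = diagnostics))
  }
  gr <- list(ref = build_time_groups(ref$time, mbcn_mode)$key,
             hist = build_time_groups(mod_hist$time, mbcn_mode)$key,
             proj = build_time_groups(mod_proj$time, mbcn_mode)$key)
  out <- mbcn_correct(met_matrix(ref), met_matrix(mod_hist),
                      met_matrix(mod_proj), met_matrix(qdm_proj),
                      groups = gr, config = config,
                      qdm_marginals_hist = met_matrix(qdm_hist))
  diagnostics$energy_trace <- attr(out, "energy_trace")
  diagnostics$converged <- attr(out, "converged")
  hist_m <- attr(out, "historical")
  list(historical = met_replace(mod_hist, hist_m),
       future = met_replace(mod_proj, structure(as.numeric(out), dim = dim(out),
                                                dimnames = dimnames(out))),
       diagnostics = diagnostics)
}
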