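## -------------------------------------------------------------------------
## Partitioning NEE into ecosystem respiration (RECO) and GPP
## -------------------------------------------------------------------------

#' Lloyd-Taylor respiration model
#'
#' \eqn{RECO(T) = R_{ref} \exp(E_0 (1/(T_{ref}-T_0) - 1/(T-T_0)))} with
#' a reference temperature of 15 degC and \eqn{T_0 = -46.02} degC.
#'
#' @param ta air temperature, degC.
#' @param rref base respiration at the reference temperature,
#'   umolCO2 m-2 s-1.
#' @param e0 temperature sensitivity, K.
#' @param tref,t0 model constants, degC.
#' @export
lloyd_taylor <- function(ta, rref, e0, tref = 15, t0 = -46.02) {
  rref * exp(e0 * (1 / (tref - t0) - 1 / (ta - t0)))
}

## Closed-form Rref given fixed E0 (model linear in Rref):
## minimises sum (y - Rref g)^2  =>  Rref = sum(y g) / sum(g^2)
.rref_given_e0 <- function(nee_night, ta_night, e0, tref = 15, t0 = -46.02) {
  g <- lloyd_taylor(ta_night, 1, e0, tref, t0)
  s <- sum(g^2)
  if (s == 0) return(NA_real_)
  sum(nee_night * g) / s
}

## Estimate the short-term temperature sensitivity E0 from nighttime
## windows: fit (Rref, E0) per window (enough points, adequate
## temperature range) and take the median of the window estimates.  The
## median is used rather than a precision-weighted mean because under
## heavy flux noise the per-window standard error scales roughly with
## the absolute error, so any relative-precision acceptance rule selects
## for large E0 and biases the average high; the median over all
## successfully fitted windows is close to unbiased.  The final value
## must fall in the plausible range, else no estimate.
.estimate_e0 <- function(nee, ta, night_measured, timestamps,
                         window_days = 14, stride_days = 7,
                         e0_range = c(50, 400), min_points = 10,
                         min_ta_range = 5) {
  t0 <- as.numeric(timestamps[1L])
  day <- (as.numeric(timestamps) - t0) / 86400
  centers <- seq(window_days / 2, max(day), by = stride_days)
  e0s <- numeric(0)
  for (cen in centers) {
    sel <- which(night_measured & abs(day - cen) <= window_days / 2 &
                   !is.na(nee) & !is.na(ta))
    if (length(sel) < min_points) next
    if (diff(range(ta[sel])) < min_ta_range) next
    df <- data.frame(y = nee[sel], x = ta[sel])
    fit <- try(minpack.lm::nlsLM(
      y ~ lloyd_taylor(x, rref, e0),
      data = df, start = list(rref = 2, e0 = 100),
      lower = c(0.01, 10), upper = c(100, 600),
      control = minpack.lm::nls.lm.control(maxiter = 50)),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    e0s <- c(e0s, stats::coef(fit)[["e0"]])
  }
  if (length(e0s) == 0L) return(NA_real_)
  e0 <- stats::median(e0s)
  if (e0 < e0_range[1L] || e0 > e0_range[2L]) return(NA_real_)
  e0
}

## Linear interpolation of window parameters to every record.
.interp_param <- function(centers, values, day) {
  ok <- !is.na(values)
  if (sum(ok) == 0L) return(rep(NA_real_, length(day)))
  if (sum(ok) == 1L) return(rep(values[ok], length(day)))
  stats::approx(centers[ok], values[ok], xout = day, rule = 2)$y
}

#' Nighttime-method partitioning of one NEE series
#'
#' A respiration-temperature model (Lloyd-Taylor) is parameterized on
#' nighttime data in short (14-day) sliding windows: the temperature
#' sensitivity E0 is first estimated from windows with an adequate
#' temperature range and then fixed at their precision-weighted average;
#' the base respiration Rref is re-fit per window in closed form and
#' linearly interpolated between window centres.  The model extrapolates
#' RECO to all records; GPP = RECO - NEE.  Negative GPP values are kept
#' to preserve distributions.
#'
#' @param nee gap-filled NEE member series.
#' @param ta gap-filled air temperature.
#' @param night nighttime mask (potential radiation at or below
#'   12 W m-2).
#' @param measured mask of measured (non-filled) NEE records.
#' @param timestamps POSIXct record start times.
#' @param window_days,stride_days Rref window length and stride.
#' @return list with \code{reco}, \code{gpp}, \code{rref} (per record),
#'   \code{e0}, \code{n_windows}; or \code{NULL} when no window could be
#'   parameterized.
#' @export
nighttime_partition <- function(nee, ta, night, measured, timestamps,
                                window_days = 14, stride_days = 7) {
  night_meas <- night & measured
  e0 <- .estimate_e0(nee, ta, night_meas, timestamps)
  if (is.na(e0)) return(NULL)
  t0 <- as.numeric(timestamps[1L])
  day <- (as.numeric(timestamps) - t0) / 86400
  centers <- seq(window_days / 2, max(day), by = stride_days)
  rrefs <- rep(NA_real_, length(centers))
  for (w in seq_along(centers)) {
    sel <- which(night_meas & abs(day - centers[w]) <= window_days / 2 &
                   !is.na(nee) & !is.na(ta))
    if (length(sel) < 5L) next
    r <- .rref_given_e0(nee[sel], ta[sel], e0)
    if (!is.na(r) && r > 0) rrefs[w] <- r
  }
  if (all(is.na(rrefs))) return(NULL)
  rref_t <- .interp_param(centers, rrefs, day)
  reco <- lloyd_taylor(ta, rref_t, e0)
  list(reco = reco, gpp = reco - nee, rref = rref_t, e0 = e0,
       n_windows = sum(!is.na(rrefs)))
}

## Daytime model: NEE = RECO(T) - alpha beta Rg / (alpha Rg + beta),
## with beta reduced exponentially above a VPD threshold.
.lasslop_nee <- function(sw_in, ta, vpd, rref, e0, alpha, beta0, kvpd,
                         vpd0 = 10) {
  beta <- ifelse(!is.na(vpd) & vpd > vpd0,
                 beta0 * exp(-kvpd * (vpd - vpd0)), beta0)
  gpp <- alpha * beta * sw_in / (alpha * sw_in + beta)
  gpp[!is.finite(gpp)] <- 0
  lloyd_taylor(ta, rref, e0) - gpp
}

#' Daytime-method partitioning of one NEE series
#'
#' NEE is modelled as respiration (Lloyd-Taylor, E0 fixed from the
#' nighttime estimate) minus a rectangular-hyperbola light response whose
#' plateau is reduced exponentially above a VPD threshold.  Parameters
#' (Rref, alpha, beta, VPD sensitivity) are fit per 8-day window on
#' daytime and nighttime data together and linearly interpolated between
#' window centres; GPP and RECO are the model components per record.
#'
#' @inheritParams nighttime_partition
#' @param sw_in,vpd gap-filled drivers.
#' @param e0 temperature sensitivity; NA re-estimates it from the
#'   nighttime data.
#' @param window_days,stride_days fitting window length and stride.
#' @param min_windows minimum convergent windows; below it NULL is
#'   returned.
#' @return list with \code{reco}, \code{gpp}, \code{params} (per-window
#'   matrix), \code{e0}; or NULL.
#' @export
daytime_partition <- function(nee, ta, sw_in, vpd, night, measured,
                              timestamps, e0 = NA, window_days = 8,
                              stride_days = 4, min_windows = 2) {
  if (is.na(e0)) {
    e0 <- .estimate_e0(nee, ta, night & measured, timestamps)
    if (is.na(e0)) return(NULL)
  }
  t0 <- as.numeric(timestamps[1L])
  day <- (as.numeric(timestamps) - t0) / 86400
  centers <- seq(window_days / 2, max(day), by = stride_days)
  par <- matrix(NA_real_, length(centers), 4L,
                dimnames = list(NULL, c("rref", "alpha", "beta0", "kvpd")))
  for (w in seq_along(centers)) {
    sel <- which(measured & abs(day - centers[w]) <= window_days / 2 &
                   !is.na(nee) & !is.na(ta) & !is.na(sw_in) & !is.na(vpd))
    if (length(sel) < 20L || sum(sw_in[sel] > 100) < 5L) next
    df <- data.frame(y = nee[sel], rg = sw_in[sel], ta = ta[sel],
                     vpd = vpd[sel])
    ## the VPD-limitation parameter has zero gradient unless the window
    ## actually samples the high-VPD regime; fix it at 0 otherwise
    fit_vpd <- sum(df$vpd > 10, na.rm = TRUE) >= 10L
    fit <- if (fit_vpd) {
      try(minpack.lm::nlsLM(
        y ~ .lasslop_nee(rg, ta, vpd, rref, e0, alpha, beta0, kvpd),
        data = df,
        start = list(rref = 2, alpha = 0.05, beta0 = 20, kvpd = 0.05),
        lower = c(0.01, 1e-4, 0.5, 0), upper = c(100, 1, 400, 1),
        control = minpack.lm::nls.lm.control(maxiter = 60)),
        silent = TRUE)
    } else {
      try(minpack.lm::nlsLM(
        y ~ .lasslop_nee(rg, ta, vpd, rref, e0, alpha, beta0, 0),
        data = df,
        start = list(rref = 2, alpha = 0.05, beta0 = 20),
        lower = c(0.01, 1e-4, 0.5), upper = c(100, 1, 400),
        control = minpack.lm::nls.lm.control(maxiter = 60)),
        silent = TRUE)
    }
    if (inherits(fit, "try-error")) next
    co <- stats::coef(fit)
    par[w, ] <- c(co[["rref"]], co[["alpha"]], co[["beta0"]],
                  if (fit_vpd) co[["kvpd"]] else 0)
  }
  if (sum(!is.na(par[, "rref"])) < min_windows) return(NULL)
  p <- lapply(colnames(par), function(cn)
    .interp_param(centers, par[, cn], day))
  names(p) <- colnames(par)
  beta <- ifelse(!is.na(vpd) & vpd > 10,
                 p$beta0 * exp(-p$kvpd * (vpd - 10)), p$beta0)
  gpp <- p$alpha * beta * sw_in / (p$alpha * sw_in + beta)
  gpp[!is.finite(gpp) | sw_in <= 0] <- 0
  reco <- lloyd_taylor(ta, p$rref, e0)
  list(reco = reco, gpp = gpp, params = par, e0 = e0)
}

#' Ensemble products for partitioned fluxes
#'
#' Applies one partitioning method to every usable ensemble member and
#' assembles the per-record percentiles, MEAN and model-efficiency REF
#' products, re-using the same reference-selection machinery as NEE.
#' Daytime and nighttime results are never merged.
#'
#' @param ensemble a [build_ensemble()] result.
#' @param method \code{"NT"} or \code{"DT"}.
#' @param ta,sw_in,vpd gap-filled drivers.
#' @param night nighttime mask.
#' @param timestamps POSIXct record start times.
#' @return list with \code{reco} and \code{gpp}, each holding
#'   \code{members}, \code{mean}, \code{percentiles}, \code{ref_index},
#'   \code{ref}; plus \code{failed} member indices.
#' @export
partition_products <- function(ensemble, method = c("NT", "DT"), ta, sw_in,
                               vpd, night, timestamps) {
  method <- match.arg(method)
  nm <- ncol(ensemble$members)
  n <- nrow(ensemble$members)
  reco_m <- matrix(NA_real_, n, nm)
  gpp_m <- matrix(NA_real_, n, nm)
  ok <- logical(nm)
  e0s <- rep(NA_real_, nm)
  for (p in seq_len(nm)) {
    if (!ensemble$usable[p]) next
    nee <- ensemble$members[, p]
    measured <- !is.na(ensemble$qc[, p]) & ensemble$qc[, p] == 0L
    res <- if (method == "NT") {
      nighttime_partition(nee, ta, night, measured, timestamps)
    } else {
      daytime_partition(nee, ta, sw_in, vpd, night, measured, timestamps)
    }
    if (is.null(res)) next
    reco_m[, p] <- res$reco
    gpp_m[, p] <- res$gpp
    e0s[p] <- res$e0
    ok[p] <- TRUE
  }
  if (sum(ok) < 2L)
    return(list(reco = NULL, gpp = NULL, failed = which(!ok)))
  wrap <- function(m) {
    ref <- select_reference(m, usable = ok)
    list(members = m, mean = rowMeans(m[, ok, drop = FALSE]),
         percentiles = ensemble_percentiles(m[, ok, drop = FALSE]),
         ref_index = ref, ref = m[, ref])
  }
  list(reco = wrap(reco_m), gpp = wrap(gpp_m), e0 = e0s,
       failed = which(!ok))
}
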