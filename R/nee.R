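## -------------------------------------------------------------------------
## NEE construction, ensemble products, random and joint uncertainty
## -------------------------------------------------------------------------

#' Net ecosystem exchange from turbulent and storage fluxes
#'
#' NEE = FC + SC.  Where SC is missing: for short canopies with the
#' analyzer below 3 m the storage term is taken as zero; for taller
#' towers a discrete one-point storage estimate is computed from the top
#' CO2 concentration, \eqn{SC = (dCO2/dt) (P h)/(R T)} with P the
#' air pressure, h the analyzer height, T air temperature in kelvin and
#' R the gas constant.  Records where no estimate is possible stay
#' missing.
#'
#' @param fc turbulent CO2 flux, umolCO2 m-2 s-1.
#' @param sc storage flux, umolCO2 m-2 s-1 (NA where missing).
#' @param metadata a [site_metadata()].
#' @param co2 CO2 mole fraction at the top level, umol mol-1.
#' @param pa air pressure, kPa.
#' @param ta air temperature, degC.
#' @param step record length in minutes.
#' @return NEE series, umolCO2 m-2 s-1.
#' @export
compute_nee <- function(fc, sc = NULL, metadata, co2 = NULL, pa = NULL,
                        ta = NULL, step = 30) {
  n <- length(fc)
  if (is.null(sc)) sc <- rep(NA_real_, n)
  miss <- is.na(sc)
  if (any(miss)) {
    if (metadata$canopy_class == "short" && metadata$analyzer_height < 3) {
      sc[miss] <- 0
    } else if (!is.null(co2)) {
      dt <- step * 60
      dco2 <- rep(NA_real_, n)
      if (n >= 3L)
        dco2[2:(n - 1L)] <- (co2[3:n] - co2[1:(n - 2L)]) / (2 * dt)
      pa_pa <- if (is.null(pa)) rep(101.325, n) * 1000 else pa * 1000
      tk <- if (is.null(ta)) rep(288.15, n) else ta + 273.15
      sc_est <- dco2 * pa_pa * metadata$analyzer_height / (8.314 * tk)
      sc[miss] <- sc_est[miss]
    }
  }
  fc + sc
}

#' Nash-Sutcliffe model efficiency
#'
#' \eqn{ME = 1 - \sum (sim - obs)^2 / \sum (obs - \bar{obs})^2} over the
#' complete pairs; undefined (NA) with fewer than two pairs or zero
#' observed variance.
#'
#' @param sim,obs aligned numeric series.
#' @export
nash_sutcliffe <- function(sim, obs) {
  ok <- !is.na(sim) & !is.na(obs)
  if (sum(ok) < 2L) return(NA_real_)
  den <- sum((obs[ok] - mean(obs[ok]))^2)
  if (den == 0) return(NA_real_)
  1 - sum((sim[ok] - obs[ok])^2) / den
}

#' Select the reference ensemble member by model-efficiency sum
#'
#' For each member the Nash-Sutcliffe efficiency against each of the
#' other members is summed; the member most similar to the rest (highest
#' sum) is the reference.  Ties break toward the lowest percentile rank.
#' Because the comparison can be made on aggregated series, the selected
#' member may differ between temporal resolutions.
#'
#' @param members numeric matrix, records x members.
#' @param usable logical per member; unusable members are excluded.
#' @return index of the reference member.
#' @export
select_reference <- function(members, usable = NULL) {
  if (!is.matrix(members)) members <- matrix(members, nrow = 1L)
  m <- ncol(members)
  if (is.null(usable)) usable <- rep(TRUE, m)
  if (sum(usable) < 2L) return(which(usable)[1L])
  sums <- rep(-Inf, m)
  for (i in which(usable)) {
    s <- 0
    for (j in which(usable)) {
      if (i == j) next
      me <- nash_sutcliffe(members[, i], members[, j])
      if (!is.na(me)) s <- s + me
    }
    sums[i] <- s
  }
  which.max(sums)      # first maximum = lowest rank on ties
}

#' Build the filtered and gap-filled NEE ensemble
#'
#' Each of the 40 extracted USTAR thresholds produces one ensemble
#' member: the despiked NEE series is filtered at that threshold
#' ([apply_ustar_filter()]) and gap-filled by MDS with the SW_IN, TA and
#' VPD drivers.  The member filtered at the pool median (USTAR50) is
#' built the same way.
#'
#' @param nee despiked NEE series (unfiltered).
#' @param ustar friction velocity series.
#' @param thresholds length-40 vector (CUT) or 40 x years matrix (VUT).
#' @param ustar50 scalar (CUT) or per-year vector (VUT).
#' @param sw_in,ta,vpd gap-filled driver series.
#' @param timestamps POSIXct record start times.
#' @param step record length in minutes.
#' @param max_masked_frac members with a larger masked fraction are
#'   flagged unusable and excluded from REF selection.
#' @return object of class \code{nee_ensemble}: list with
#'   \code{members} (records x 40), \code{qc} (records x 40),
#'   \code{ustar50_member}, \code{ustar50_qc}, \code{usable},
#'   \code{thresholds}, \code{threshold_by_record} (records x 40).
#' @export
build_ensemble <- function(nee, ustar, thresholds, ustar50, sw_in, ta, vpd,
                           timestamps, step = 30, max_masked_frac = 0.95) {
  n <- length(nee)
  yrs <- as.integer(format(timestamps, "%Y", tz = "UTC"))
  year_index <- match(yrs, sort(unique(yrs)))
  thr_record <- function(th) {          # per-record threshold vector
    if (is.matrix(th)) th[, year_index, drop = FALSE] else th
  }
  nthr <- if (is.matrix(thresholds)) nrow(thresholds) else length(thresholds)
  members <- matrix(NA_real_, n, nthr)
  qc <- matrix(NA_integer_, n, nthr)
  thr_by_rec <- matrix(NA_real_, n, nthr)
  usable <- rep(TRUE, nthr)
  for (p in seq_len(nthr)) {
    thr <- if (is.matrix(thresholds))
      thresholds[p, year_index] else thresholds[p]
    thr_by_rec[, p] <- thr
    filtered <- apply_ustar_filter(nee, ustar, thr)
    if (mean(is.na(filtered)) > max_masked_frac) {
      usable[p] <- FALSE
      next
    }
    fit <- mds_fill(filtered, sw_in, ta, vpd, timestamps, step)
    members[, p] <- fit$filled
    qc[, p] <- fit$qc
  }
  u50_thr <- if (length(ustar50) > 1L) ustar50[year_index] else ustar50
  u50_filtered <- apply_ustar_filter(nee, ustar, u50_thr)
  u50 <- mds_fill(u50_filtered, sw_in, ta, vpd, timestamps, step)
  structure(list(members = members, qc = qc,
                 ustar50_member = u50$filled, ustar50_qc = u50$qc,
                 usable = usable, thresholds = thresholds,
                 threshold_by_record = thr_by_rec),
            class = "nee_ensemble")
}

#' @export
print.nee_ensemble <- function(x, ...) {
  cat(sprintf("<nee_ensemble>  %d records x %d members (%d usable)\n",
              nrow(x$members), ncol(x$members), sum(x$usable)))
  invisible(x)
}

#' Per-record percentiles of an ensemble
#'
#' @param members records x members matrix.
#' @param probs percentile levels in percent (default the seven
#'   representative ones: 5, 16, 25, 50, 75, 84, 95).
#' @return matrix records x length(probs), columns named by level.
#' @export
ensemble_percentiles <- function(members,
                                 probs = c(5, 16, 25, 50, 75, 84, 95)) {
  out <- t(apply(members, 1L, stats::quantile, probs = probs / 100,
                 names = FALSE, type = 7, na.rm = TRUE))
  colnames(out) <- sprintf("%02d", probs)
  out
}

#' Random uncertainty of half-hourly fluxes
#'
#' Method 1 (direct standard deviation): for each record, the standard
#' deviation of the measured fluxes within a sliding window of
#' \code{window_days} and one hour of the time of day, under similar
#' meteorological conditions (the MDS tolerances); at least five values
#' are required.  Method 2 (median standard deviation): where Method 1 is
#' not possible, the median of the Method-1 uncertainties of similar
#' fluxes (magnitude within 20 percent, with an absolute floor) inside a
#' window of \code{window_days_m2} and one hour.
#'
#' @param flux gap-filled flux series (used for Method-2 similarity).
#' @param measured measured-record mask (pre-fill).
#' @param sw_in,ta,vpd gap-filled drivers.
#' @param timestamps POSIXct record start times.
#' @param step record length in minutes.
#' @param window_days Method-1 half-window (7 for NEE, 5 for H/LE).
#' @param window_days_m2 Method-2 half-window (5).
#' @param floor similarity floor (2 umolCO2 m-2 s-1 for NEE,
#'   10 W m-2 for H and LE).
#' @param tolerances MDS similarity tolerances.
#' @return list with \code{randunc} and \code{method} (1, 2 or NA).
#' @export
flux_randunc <- function(flux, measured, sw_in, ta, vpd, timestamps,
                         step = 30, window_days = 7, window_days_m2 = 5,
                         floor = 2, tolerances = mds_tolerances()) {
  n <- length(flux)
  rpd <- as.integer(1440 / step)
  rph <- as.integer(60 / step)
  offs1 <- as.vector(outer(seq(-window_days, window_days) * rpd,
                           seq(-rph, rph), "+"))
  offs2 <- as.vector(outer(seq(-window_days_m2, window_days_m2) * rpd,
                           seq(-rph, rph), "+"))
  randunc <- rep(NA_real_, n)
  method <- rep(NA_integer_, n)
  meas_flux <- ifelse(measured, flux, NA_real_)
  for (i in seq_len(n)) {
    j <- i + offs1
    j <- j[j >= 1L & j <= n & j != i]
    ok <- !is.na(meas_flux[j])
    if (!is.na(sw_in[i])) {
      tol_sw <- if (sw_in[i] < tolerances$swin_low_cut)
        tolerances$swin_low else tolerances$swin
      ok <- ok & !is.na(sw_in[j]) & abs(sw_in[j] - sw_in[i]) <= tol_sw
    }
    if (!is.na(ta[i])) ok <- ok & !is.na(ta[j]) &
        abs(ta[j] - ta[i]) <= tolerances$ta
    if (!is.na(vpd[i])) ok <- ok & !is.na(vpd[j]) &
        abs(vpd[j] - vpd[i]) <= tolerances$vpd
    if (sum(ok, na.rm = TRUE) >= 5L) {
      randunc[i] <- stats::sd(meas_flux[j][which(ok)])
      method[i] <- 1L
    }
  }
  ## Method 2 for the rest: median Method-1 uncertainty of similar fluxes
  need <- which(is.na(method) & !is.na(flux))
  for (i in need) {
    j <- i + offs2
    j <- j[j >= 1L & j <= n & j != i]
    sim <- !is.na(randunc[j]) & method[j] == 1L & !is.na(flux[j]) &
      abs(flux[j] - flux[i]) <= pmax(0.2 * abs(flux[i]), floor)
    if (any(sim, na.rm = TRUE)) {
      randunc[i] <- stats::median(randunc[j][which(sim)])
      method[i] <- 2L
    }
  }
  list(randunc = randunc, method = method)
}

#' Joint uncertainty by quadrature
#'
#' \eqn{\sqrt{randunc^2 + ((upper - lower)/denom)^2}}.  For NEE the 16th
#' and 84th ensemble percentiles with denominator 2 (they bracket one
#' standard deviation under normality); for the energy-balance corrected
#' fluxes the 25th and 75th correction percentiles with denominator
#' 1.349 (the interquartile range of the standard normal).
#'
#' @param randunc random uncertainty series.
#' @param upper,lower percentile series.
#' @param denom spread-to-sigma denominator.
#' @return joint uncertainty series (NA where any input is missing).
#' @export
joint_uncertainty <- function(randunc, upper, lower, denom = 2) {
  sqrt(randunc^2 + ((upper - lower) / denom)^2)
}
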