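## -------------------------------------------------------------------------
## Automated quality control
## -------------------------------------------------------------------------

#' Potential (top-of-atmosphere) incoming shortwave radiation
#'
#' Solar geometry from the Spencer Fourier-series ephemeris (declination,
#' eccentricity factor, equation of time), evaluated at 1-minute
#' sub-steps and averaged over each record, so each value is a period
#' average rather than an instantaneous sample.  Zero whenever the sun is
#' below the horizon.
#'
#' @param metadata a [site_metadata()] (latitude, longitude, utc_offset).
#' @param timestamps POSIXct record start times (local standard time).
#' @param step record length in minutes.
#' @param solar_constant W m-2 at mean Earth-Sun distance.
#' @return numeric vector, W m-2.
#' @export
potential_radiation <- function(metadata, timestamps, step = 30,
                                solar_constant = 1361) {
  lat <- metadata$latitude * pi / 180
  nsub <- as.integer(step)            # 1-minute sub-steps
  off <- (seq_len(nsub) - 0.5) * 60   # centre of each minute
  n <- length(timestamps)
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  doy0 <- lt$yday + 1L
  sec0 <- lt$hour * 3600 + lt$min * 60 + lt$sec
  acc <- numeric(n)
  for (k in seq_len(nsub)) {
    sec <- sec0 + off[k]
    doy <- doy0 + (sec >= 86400)      # sub-step may roll past midnight
    hour <- (sec %% 86400) / 3600
    g <- 2 * pi * (doy - 1 + (hour - 12) / 24) / 365
    decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
      0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
      0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
    ecc <- 1.000110 + 0.034221 * cos(g) + 0.001280 * sin(g) +
      0.000719 * cos(2 * g) + 0.000077 * sin(2 * g)
    eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                          0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
    solar_min <- hour * 60 + eqtime +
      4 * (metadata$longitude - 15 * metadata$utc_offset)
    ha <- (solar_min / 4 - 180) * pi / 180
    sin_elev <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(ha)
    acc <- acc + solar_constant * ecc * pmax(sin_elev, 0)
  }
  acc / nsub
}

#' Night mask used throughout the pipeline
#'
#' A record is nighttime when potential radiation is at or below
#' \code{cutoff} (default 12 W m-2).
#'
#' @param sw_in_pot potential radiation series.
#' @param cutoff W m-2.
#' @export
is_night <- function(sw_in_pot, cutoff = 12) sw_in_pot <= cutoff

#' Spike detection by double-differenced median absolute deviation
#'
#' The statistic \eqn{d_i = (x_i - x_{i-1}) - (x_{i+1} - x_i)} is
#' computed on consecutive valid records; within each block (default 13
#' days), separately for day and night, records with
#' \eqn{d_i} outside \eqn{Md \pm z \cdot MAD / 0.6745} are flagged as
#' spikes.  A zero MAD (e.g. constant series) flags nothing.
#'
#' @param x numeric series with NA for missing.
#' @param sw_in_pot potential radiation, used to split day and night;
#'   NULL treats all records as one subset.
#' @param z rejection factor (default 5.5).
#' @param timestamps record start times (needed for blocking).
#' @param block_days block length for the local statistics.
#' @return integer vector: 0 ok (or missing), 2 spike.
#' @export
despike_mad <- function(x, sw_in_pot = NULL, timestamps = NULL, z = 5.5,
                        block_days = 13) {
  stopifnot(z > 0)
  n <- length(x)
  flag <- integer(n)
  if (sum(!is.na(x)) < 3L) {
    warning("fewer than 3 valid points; no despiking applied")
    return(flag)
  }
  night <- if (is.null(sw_in_pot)) rep(TRUE, n) else is_night(sw_in_pot)
  block <- if (is.null(timestamps)) rep(1L, n) else {
    day0 <- floor(as.numeric(timestamps) / 86400)
    (day0 - day0[1L]) %/% block_days
  }
  for (b in unique(block)) {
    for (nt in c(TRUE, FALSE)) {
      sel <- which(block == b & night == nt & !is.na(x))
      if (length(sel) < 3L) next
      xv <- x[sel]
      m <- length(xv)
      d <- (xv[2:(m - 1)] - xv[1:(m - 2)]) - (xv[3:m] - xv[2:(m - 1)])
      md <- stats::median(d)
      mad <- stats::median(abs(d - md))
      lim <- z * mad / 0.6745            # 0 when MAD = 0: any deviation
      cand <- d > md + lim | d < md - lim
      ## a spike perturbs the neighbouring double differences too; only
      ## the local |d| extremum is the spike itself
      ad <- abs(d - md)
      adl <- c(0, ad[-length(ad)]); adr <- c(ad[-1L], 0)
      spikes <- which(cand & ad >= adl & ad >= adr)
      flag[sel[spikes + 1L]] <- 2L
    }
  }
  flag
}

#' Fill incoming shortwave radiation from photon flux density
#'
#' Where SW_IN is missing and PPFD_IN is present, SW_IN is estimated as
#' \code{factor * PPFD_IN}.  The factor is the zero-intercept regression
#' slope over the overlapping valid pairs; with no overlap the standard
#' 0.48 J per micromole photon is assumed.
#'
#' @param sw_in,ppfd_in numeric series.
#' @param min_overlap minimum valid pairs to fit a site-specific factor.
#' @return list with \code{sw_in} (filled series), \code{factor},
#'   \code{n_overlap}, \code{n_filled}.
#' @export
swin_from_ppfd <- function(sw_in, ppfd_in, min_overlap = 10) {
  if (is.null(sw_in)) sw_in <- rep(NA_real_, length(ppfd_in))
  ok <- !is.na(sw_in) & !is.na(ppfd_in) & ppfd_in > 0
  if (sum(ok) >= min_overlap && sum(ppfd_in[ok]^2) > 0) {
    fac <- sum(sw_in[ok] * ppfd_in[ok]) / sum(ppfd_in[ok]^2)
  } else {
    fac <- 0.48
  }
  fill <- is.na(sw_in) & !is.na(ppfd_in)
  sw_in[fill] <- fac * ppfd_in[fill]
  list(sw_in = sw_in, factor = fac,
       n_overlap = sum(ok), n_filled = sum(fill))
}

#' Default physical range limits per variable
#'
#' @return named list of \code{c(lo, hi)} pairs.
#' @export
default_range_limits <- function() {
  list(RH = c(0, 100), SWC = c(0, 100), USTAR = c(0, 10),
       PA = c(40, 110), SW_IN = c(0, 1500), PPFD_IN = c(0, 3000),
       TA = c(-60, 60), WS = c(0, 50), P = c(0, 100),
       LW_IN = c(50, 650), CO2 = c(200, 1200))
}

#' Apply range controls to a flux table
#'
#' Out-of-range records are flagged and masked (set missing) so that no
#' downstream step sees them.
#'
#' @param table a [flux_table()].
#' @param limits named list of \code{c(lo, hi)}; see
#'   [default_range_limits()].
#' @return list with \code{table} (masked) and \code{n_flagged} per
#'   variable.
#' @export
apply_range_flags <- function(table, limits = default_range_limits()) {
  n_flagged <- integer(0)
  for (v in names(limits)) {
    if (!v %in% names(table)) next
    x <- table[[v]]
    bad <- !is.na(x) & (x < limits[[v]][1L] | x > limits[[v]][2L])
    n_flagged[[v]] <- sum(bad)
    if (any(bad)) {
      x[bad] <- NA_real_
      table[[v]] <- x
    }
  }
  unknown <- setdiff(names(limits), names(table))
  list(table = table, n_flagged = n_flagged, unknown = unknown)
}
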