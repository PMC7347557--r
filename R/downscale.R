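## -------------------------------------------------------------------------
## Debiased linear downscaling of a coarse reference meteorological series
## -------------------------------------------------------------------------

#' Align a coarse reference series onto the tower time axis
#'
#' States (temperature, radiation, ...) are linearly interpolated to the
#' record centres, preserving the diurnal cycle present in the reference;
#' precipitation-like per-period totals are instead split evenly across
#' the tower records each coarse period covers.
#'
#' @param ref_timestamps POSIXct start times of the coarse series.
#' @param ref_values numeric values of the coarse series.
#' @param axis POSIXct tower record start times.
#' @param step tower record length in minutes.
#' @param kind \code{"state"} (interpolate) or \code{"total"} (split).
#' @return numeric series on the tower axis.
#' @export
align_reference <- function(ref_timestamps, ref_values, axis, step = 30,
                            kind = c("state", "total")) {
  kind <- match.arg(kind)
  tr <- as.numeric(ref_timestamps)
  ta <- as.numeric(axis) + step * 30     # record centre
  if (kind == "state") {
    ref_step <- if (length(tr) > 1L) stats::median(diff(tr)) else step * 60
    stats::approx(tr + ref_step / 2, ref_values, xout = ta, rule = 2)$y
  } else {
    idx <- findInterval(as.numeric(axis), tr)
    idx[idx < 1L] <- 1L
    per <- tabulate(idx, nbins = length(tr))
    out <- ref_values[idx] / per[idx]
    out[is.na(out)] <- 0
    out
  }
}

#' Fit the debiasing regression between tower and reference series
#'
#' Ordinary least squares of the site measurement on the aligned
#' reference over their overlap; the fit statistics are the AUXMETEO
#' parameters (ERA_SLOPE, ERA_INTERCEPT, ERA_RMSE, ERA_CORRELATION).
#'
#' @param site_series measured series on the tower axis.
#' @param reference_series reference aligned to the tower axis.
#' @param min_overlap minimum valid pairs for a usable fit.
#' @return object of class \code{downscale_fit}: list with \code{slope},
#'   \code{intercept}, \code{rmse}, \code{correlation}, \code{n},
#'   \code{available}.  With insufficient overlap the fit is marked
#'   unavailable and downscaling falls back to the identity.
#' @export
fit_debias <- function(site_series, reference_series, min_overlap = 200) {
  ok <- !is.na(site_series) & !is.na(reference_series)
  n <- sum(ok)
  if (n < min_overlap || stats::var(reference_series[ok]) == 0) {
    warning(sprintf(
      "insufficient overlap (%d pairs) for debiasing; identity fallback", n))
    return(structure(list(slope = 1, intercept = 0, rmse = NA_real_,
                          correlation = NA_real_, n = n, available = FALSE),
                     class = "downscale_fit"))
  }
  x <- reference_series[ok]; y <- site_series[ok]
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  resid <- y - (slope * x + intercept)
  fit <- structure(list(slope = slope, intercept = intercept,
                        rmse = sqrt(mean(resid^2)),
                        correlation = stats::cor(x, y), n = n,
                        available = TRUE),
                   class = "downscale_fit")
  if (!is.na(fit$correlation) && fit$correlation < 0.5)
    warning(sprintf(
      "low site/reference correlation (%.2f); possible coordinate or time mismatch",
      fit$correlation))
  fit
}

#' @export
print.downscale_fit <- function(x, ...) {
  cat(sprintf(
    "<downscale_fit>  slope %.4f  intercept %.4f  rmse %.3f  r %.3f  n %d\n",
    x$slope, x$intercept, x$rmse, x$correlation, x$n))
  invisible(x)
}

#' Physical bounds applied after downscaling
#' @export
downscale_bounds <- function() {
  list(TA = c(-80, 60), PA = c(40, 110), VPD = c(0, 120), WS = c(0, 60),
       P = c(0, Inf), SW_IN = c(0, Inf), LW_IN = c(0, Inf))
}

#' Apply a debiasing fit to the full reference record
#'
#' \code{slope * reference + intercept} over the whole record, clipped to
#' the physical bounds of the variable; gap-free by construction.
#'
#' @param fit a [fit_debias()] result.
#' @param reference_series aligned reference on the tower axis.
#' @param bounds \code{c(lo, hi)} physical clip range, or NULL.
#' @param sw_in_pot optional potential-radiation ceiling (for SW_IN).
#' @return numeric gap-free series.
#' @export
downscale_series <- function(fit, reference_series, bounds = NULL,
                             sw_in_pot = NULL) {
  out <- fit$slope * reference_series + fit$intercept
  if (!is.null(bounds)) out <- pmin(pmax(out, bounds[1L]), bounds[2L])
  if (!is.null(sw_in_pot)) out <- pmin(out, sw_in_pot)
  out
}

#' Downscale the standard meteorological variable set
#'
#' Fits and applies the debiasing for every downscalable variable present
#' in both the tower table and the reference table (TA, PA, VPD, WS, P,
#' SW_IN, LW_IN), returning the gap-free downscaled series and the
#' AUXMETEO parameter table.
#'
#' @param table tower [flux_table()].
#' @param reference named list of coarse series, each a list with
#'   \code{timestamps} and \code{values} (see [generate_site()]).
#' @param sw_in_pot potential radiation on the tower axis.
#' @return list with \code{series} (named list), \code{fits},
#'   \code{auxmeteo} (data frame of VARIABLE/PARAMETER/VALUE rows).
#' @export
downscale_meteo <- function(table, reference, sw_in_pot = NULL) {
  vars <- intersect(c("TA", "PA", "VPD", "WS", "P", "SW_IN", "LW_IN"),
                    intersect(names(reference), names(table)))
  axis <- table$TIMESTAMP_START
  step <- flux_step(table)
  bounds <- downscale_bounds()
  series <- list(); fits <- list(); rows <- list()
  for (v in vars) {
    kind <- if (v == "P") "total" else "state"
    ref <- align_reference(reference[[v]]$timestamps,
                           reference[[v]]$values, axis, step, kind)
    fit <- fit_debias(table[[v]], ref)
    series[[v]] <- downscale_series(fit, ref, bounds[[v]],
                                    if (v == "SW_IN") sw_in_pot else NULL)
    fits[[v]] <- fit
    rows[[v]] <- data.frame(
      VARIABLE = v,
      PARAMETER = c("ERA_SLOPE", "ERA_INTERCEPT", "ERA_RMSE",
                    "ERA_CORRELATION"),
      VALUE = c(fit$slope, fit$intercept, fit$rmse, fit$correlation))
  }
  list(series = series, fits = fits,
       auxmeteo = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' Saturation vapour pressure (hPa) and VPD helper
#'
#' Magnus-form saturation vapour pressure over water; VPD is the
#' saturation deficit given relative humidity.
#'
#' @param ta air temperature, degC.
#' @param rh relative humidity, percent.
#' @return VPD in hPa.
#' @export
vpd_from_rh <- function(ta, rh) {
  esat <- 6.1078 * exp(17.269 * ta / (237.3 + ta))
  esat * (1 - rh / 100)
}
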