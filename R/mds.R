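## -------------------------------------------------------------------------
## Marginal Distribution Sampling (MDS) gap-filling
## -------------------------------------------------------------------------

#' Default MDS similarity tolerances
#'
#' 50 W m-2 for incoming shortwave (20 when the target record's SW_IN is
#' below 50 W m-2), 2.5 degC for air temperature, 5 hPa for vapour
#' pressure deficit.
#' @export
mds_tolerances <- function() {
  list(swin = 50, swin_low = 20, swin_low_cut = 50, ta = 2.5, vpd = 5)
}

## Window schedule per driver-availability scenario.  Half-widths in
## days; qc class: scenario (i) <= 14 d -> 1; (ii) <= 14 d or (i) <= 28 d
## -> 2; anything larger, and the mean-diurnal-course fallback -> 3.
.mds_schedule <- function(scenario) {
  full <- rbind(
    data.frame(type = "full", w = c(7, 14), qc = 1L),
    data.frame(type = "full", w = c(21, 28), qc = 2L),
    data.frame(type = "full", w = c(35, 42, 56, 70), qc = 3L))
  swo <- rbind(
    data.frame(type = "sw", w = c(7, 14), qc = 2L),
    data.frame(type = "sw", w = c(21, 28, 42, 56, 70), qc = 3L))
  mdc <- data.frame(type = "mdc", w = c(0, 1, 2, 7, 14, 28, 70, 140),
                    qc = 3L)
  switch(scenario,
         full = rbind(full, mdc),
         sw = rbind(swo, mdc),
         none = mdc)
}

#' Gap-fill a series by Marginal Distribution Sampling
#'
#' For every missing record the method seeks records under physically and
#' temporally similar meteorological conditions, in the smallest possible
#' window, and fills with their mean.  Three scenarios apply depending on
#' driver availability at the gap: (i) SW_IN, TA and VPD all present
#' (similarity within the full tolerances), (ii) only SW_IN present
#' (SW_IN tolerance alone), (iii) no drivers (mean diurnal course, i.e.
#' records within one hour of the same time of day).  The search window
#' expands until at least one candidate is found.  Quality classes:
#' 0 measured, 1 high confidence (full drivers, window at most 14 days),
#' 2 medium, 3 low.
#'
#' @param target numeric series with NA gaps.
#' @param sw_in,ta,vpd driver series (any may be NULL or partly missing).
#' @param timestamps POSIXct record start times.
#' @param step record length in minutes.
#' @param tolerances see [mds_tolerances()].
#' @return object of class \code{mds_result}: list with \code{filled},
#'   \code{qc} (0-3), \code{scenario}, \code{window_days} per record.
#' @export
mds_fill <- function(target, sw_in = NULL, ta = NULL, vpd = NULL,
                     timestamps, step = 30,
                     tolerances = mds_tolerances()) {
  n <- length(target)
  if (n == 0L) stop("empty target series", call. = FALSE)
  if (is.null(sw_in)) sw_in <- rep(NA_real_, n)
  if (is.null(ta)) ta <- rep(NA_real_, n)
  if (is.null(vpd)) vpd <- rep(NA_real_, n)
  rpd <- as.integer(1440 / step)            # records per day
  rph <- as.integer(60 / step)              # records per hour
  measured <- !is.na(target)
  tod <- as.numeric(timestamps) %% 86400
  filled <- target
  qc <- integer(n)
  scen_out <- character(n)
  wdays <- rep(NA_real_, n)
  scen_out[measured] <- "measured"
  gaps <- which(!measured)
  schedules <- list(full = .mds_schedule("full"),
                    sw = .mds_schedule("sw"),
                    none = .mds_schedule("none"))
  for (i in gaps) {
    has_sw <- !is.na(sw_in[i]); has_ta <- !is.na(ta[i])
    has_vpd <- !is.na(vpd[i])
    scen <- if (has_sw && has_ta && has_vpd) "full"
            else if (has_sw) "sw" else "none"
    sched <- schedules[[scen]]
    tol_sw <- if (has_sw && sw_in[i] < tolerances$swin_low_cut)
      tolerances$swin_low else tolerances$swin
    for (r in seq_len(nrow(sched))) {
      w <- sched$w[r]
      lo <- max(1L, i - w * rpd); hi <- min(n, i + w * rpd)
      j <- lo:hi
      cand <- measured[j]
      type <- sched$type[r]
      if (type == "full") {
        cand <- cand &
          !is.na(sw_in[j]) & abs(sw_in[j] - sw_in[i]) <= tol_sw &
          !is.na(ta[j]) & abs(ta[j] - ta[i]) <= tolerances$ta &
          !is.na(vpd[j]) & abs(vpd[j] - vpd[i]) <= tolerances$vpd
      } else if (type == "sw") {
        cand <- cand &
          !is.na(sw_in[j]) & abs(sw_in[j] - sw_in[i]) <= tol_sw
      } else {                               # mean diurnal course +-1 h
        dt <- abs(((tod[j] - tod[i] + 43200) %% 86400) - 43200)
        cand <- cand & dt <= 3600
      }
      if (any(cand)) {
        filled[i] <- mean(target[j][cand])
        qc[i] <- sched$qc[r]
        scen_out[i] <- type
        wdays[i] <- w
        break
      }
    }
    if (is.na(filled[i])) { qc[i] <- NA_integer_; scen_out[i] <- "unfilled" }
  }
  structure(list(filled = filled, qc = qc, scenario = scen_out,
                 window_days = wdays),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  tab <- table(factor(x$qc, levels = 0:3), useNA = "ifany")
  cat(sprintf("<mds_result>  %d records; qc counts 0:%s 1:%s 2:%s 3:%s\n",
              length(x$filled), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Merge MDS fills with a downscaled reference into the final product
#'
#' Measured records and high-confidence MDS fills (MDS QC below 2) go
#' into the final gap-filled series; low-quality fills are replaced by
#' the downscaled reference value with final flag 2.  The final quality
#' flag is therefore 0 (measured), 1 (high-quality MDS) or 2
#' (downscaled); no record carries flag 3.
#'
#' @param mds an [mds_fill()] result.
#' @param downscaled gap-free downscaled series on the same axis (from
#'   [downscale_series()]); NULL keeps the MDS fills with their flags
#'   capped at 3.
#' @return list with \code{value} and \code{qc}.
#' @export
merge_final_gapfill <- function(mds, downscaled = NULL) {
  value <- mds$filled
  qc <- mds$qc
  if (is.null(downscaled)) return(list(value = value, qc = qc))
  low <- !is.na(qc) & qc >= 2L | is.na(qc)
  have <- !is.na(downscaled)
  value[low & have] <- downscaled[low & have]
  qc[low & have] <- 2L
  if (any(low & !have)) {
    value[low & !have] <- NA_real_
    qc[low & !have] <- NA_integer_
    warning("downscaled series missing where needed; records left missing")
  }
  list(value = value, qc = qc)
}
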