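## -------------------------------------------------------------------------
## Energy-balance-closure corrected H and LE
## -------------------------------------------------------------------------

#' Half-hourly energy-balance-closure correction factors
#'
#' \eqn{EBC\_CF = (NETRAD - G)/(H + LE)} at every record where NETRAD and
#' G are measured and H and LE are measured or good-quality gap-filled
#' (MDS QC at most 1).  To avoid transient conditions the series is then
#' filtered by removing values outside 1.5 times its own interquartile
#' range.
#'
#' @param netrad,g measured series (NA where missing).
#' @param h_f,le_f gap-filled H and LE.
#' @param h_qc,le_qc MDS quality flags of H and LE.
#' @param iqr_mult IQR filter width.
#' @return list with \code{cf} (filtered series, NA where ineligible or
#'   removed), \code{cf_raw}, \code{n_removed}.
#' @export
ebc_cf_series <- function(netrad, g, h_f, le_f, h_qc = NULL, le_qc = NULL,
                          iqr_mult = 1.5) {
  n <- length(netrad)
  if (is.null(h_qc)) h_qc <- integer(n)
  if (is.null(le_qc)) le_qc <- integer(n)
  eligible <- !is.na(netrad) & !is.na(g) & !is.na(h_f) & !is.na(le_f) &
    !is.na(h_qc) & h_qc <= 1L & !is.na(le_qc) & le_qc <= 1L &
    (h_f + le_f) != 0
  cf_raw <- rep(NA_real_, n)
  cf_raw[eligible] <- (netrad[eligible] - g[eligible]) /
    (h_f[eligible] + le_f[eligible])
  q <- stats::quantile(cf_raw, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  iqr <- q[2L] - q[1L]
  keep <- !is.na(cf_raw) & cf_raw >= q[1L] - iqr_mult * iqr &
    cf_raw <= q[2L] + iqr_mult * iqr
  cf <- ifelse(keep, cf_raw, NA_real_)
  list(cf = cf, cf_raw = cf_raw, n_removed = sum(!is.na(cf_raw)) - sum(keep))
}

## time-of-day band membership: [22:00, 02:30] wrapping midnight and
## [10:00, 14:30], edges inclusive, judged on the record start time.
.in_ebc_band <- function(timestamps) {
  tod <- as.numeric(timestamps) %% 86400
  (tod >= 22 * 3600 | tod <= 2.5 * 3600) |
    (tod >= 10 * 3600 & tod <= 14.5 * 3600)
}

#' Energy-balance corrected H and LE at half-hourly resolution
#'
#' Three methods applied hierarchically per record.  Method 1: the
#' correction factors within a sliding window of 15 days restricted to
#' the 22:00-02:30 and 10:00-14:30 time-of-day bands (excluding sunrise
#' and sunset transients) form a pool; with at least five factors the
#' flux is multiplied by every factor and the 25th, 50th and 75th
#' percentiles of the corrected pool become _CORR25, _CORR, _CORR75.
#' Method 2: the factor is the mean of the pooled factors within 5 days
#' and one hour of the time of day; no percentiles.  Method 3: as Method
#' 2 but looking at the same half-hour within 5 days in the previous and
#' next years.  When all fail the corrected fluxes stay missing.
#'
#' @param cf filtered correction-factor series ([ebc_cf_series()]).
#' @param h_f,le_f gap-filled fluxes.
#' @param timestamps POSIXct record start times.
#' @param step record length in minutes.
#' @param window_days Method-1 half-window (15 at HH resolution).
#' @return object of class \code{ebc_products}: per-flux lists with
#'   \code{corr}, \code{corr25}, \code{corr75}, plus \code{method}
#'   (1, 2, 3 or NA) and \code{cf_used}.
#' @export
corrected_fluxes <- function(cf, h_f, le_f, timestamps, step = 30,
                             window_days = 15) {
  n <- length(cf)
  rpd <- as.integer(1440 / step)
  rph <- as.integer(60 / step)
  band <- .in_ebc_band(timestamps)
  has_cf <- !is.na(cf)
  method <- rep(NA_integer_, n)
  cf_used <- rep(NA_real_, n)
  res <- list(
    H = list(corr = rep(NA_real_, n), corr25 = rep(NA_real_, n),
             corr75 = rep(NA_real_, n)),
    LE = list(corr = rep(NA_real_, n), corr25 = rep(NA_real_, n),
              corr75 = rep(NA_real_, n)))
  offs2 <- as.vector(outer(seq(-5, 5) * rpd, seq(-rph, rph), "+"))
  yr_off <- round(365.25 * 86400)
  t_num <- as.numeric(timestamps)
  for (i in seq_len(n)) {
    if (is.na(h_f[i]) && is.na(le_f[i])) next
    lo <- max(1L, i - window_days * rpd)
    hi <- min(n, i + window_days * rpd)
    j <- lo:hi
    pool <- cf[j][band[j] & has_cf[j]]
    if (length(pool) >= 5L) {
      method[i] <- 1L
      cf_used[i] <- stats::median(pool)
      for (v in c("H", "LE")) {
        fx <- if (v == "H") h_f[i] else le_f[i]
        if (is.na(fx)) next
        q <- stats::quantile(fx * pool, c(0.25, 0.5, 0.75), names = FALSE,
                             type = 7)
        if (fx < 0) q <- sort(q)    # percentiles of the corrected pool
        res[[v]]$corr25[i] <- q[1L]
        res[[v]]$corr[i] <- q[2L]
        res[[v]]$corr75[i] <- q[3L]
      }
      next
    }
    ## Method 2: mean CF within +-5 d, +-1 h
    j2 <- i + offs2
    j2 <- j2[j2 >= 1L & j2 <= n]
    pool2 <- cf[j2][band[j2] & has_cf[j2]]
    if (length(pool2) >= 1L) {
      method[i] <- 2L
      cf_used[i] <- mean(pool2)
    } else {
      ## Method 3: same half-hour, +-5 d, previous and next year
      cand <- c(t_num[i] - yr_off, t_num[i] + yr_off)
      j3 <- integer(0)
      for (tc in cand) {
        k <- which(abs(t_num - tc) <= 5 * 86400)
        if (length(k)) {
          tod_match <- abs(((t_num[k] - t_num[i]) %% 86400)) < step * 60 / 2 |
            abs(((t_num[k] - t_num[i]) %% 86400) - 86400) < step * 60 / 2
          j3 <- c(j3, k[tod_match])
        }
      }
      pool3 <- cf[j3][has_cf[j3]]
      if (length(pool3) >= 1L) {
        method[i] <- 3L
        cf_used[i] <- mean(pool3)
      }
    }
    if (!is.na(cf_used[i])) {
      res$H$corr[i] <- h_f[i] * cf_used[i]
      res$LE$corr[i] <- le_f[i] * cf_used[i]
    }
  }
  structure(list(H = res$H, LE = res$LE, method = method, cf_used = cf_used),
            class = "ebc_products")
}

#' @export
print.ebc_products <- function(x, ...) {
  tab <- table(factor(x$method, levels = 1:3), useNA = "ifany")
  cat(sprintf(
    "<ebc_products>  %d records; method counts 1:%s 2:%s 3:%s none:%s\n",
    length(x$method), tab[1], tab[2], tab[3], tab[4]))
  invisible(x)
}

#' Joint uncertainty of energy-balance corrected fluxes
#'
#' Quadrature combination of the random uncertainty and the
#' correction-factor spread,
#' \eqn{\sqrt{RANDUNC^2 + ((CORR75 - CORR25)/1.349)^2}}; where the
#' percentile variants are absent (Method 2 or 3 records) the joint
#' uncertainty equals the random uncertainty.  Produced at HH and DD
#' resolutions only.
#'
#' @param randunc random uncertainty series.
#' @param corr25,corr75 corrected-flux percentile series.
#' @export
hle_jointunc <- function(randunc, corr25, corr75) {
  out <- joint_uncertainty(randunc, corr75, corr25, denom = 1.349)
  no_pct <- is.na(corr25) | is.na(corr75)
  out[no_pct] <- randunc[no_pct]
  out
}

#' Energy-balance correction at coarser resolutions
#'
#' The correction factor is computed from the period-average component
#' fluxes.  For daily resolution a sliding window of 7 days of daily
#' averages is pooled (Method-1 analogue, five factors minimum, with the
#' 25th/50th/75th percentile variants); for WW, MM and YY the factor of
#' each period is taken directly from that period's average NETRAD, G, H
#' and LE without percentiles.  A period only qualifies when at least
#' half of its records have all four components measured.
#'
#' @param period factor/integer grouping of HH records into periods.
#' @param netrad,g,h_f,le_f HH series.
#' @param eligible logical: all four components measured at the record.
#' @param h_agg,le_agg period-aggregated gap-filled fluxes to correct.
#' @param window Method-1 half-window in periods (7 for DD, 0 to use the
#'   period's own factor only).
#' @param min_coverage measured-coverage fraction required per period.
#' @return list of per-period \code{H} and \code{LE} lists (corr,
#'   corr25, corr75) plus \code{cf}.
#' @export
corrected_fluxes_coarse <- function(period, netrad, g, h_f, le_f, eligible,
                                    h_agg, le_agg, window = 7,
                                    min_coverage = 0.5) {
  periods <- sort(unique(period))
  np <- length(periods)
  avg <- function(x) as.numeric(tapply(x, factor(period, periods), mean,
                                       na.rm = TRUE))
  cov <- as.numeric(tapply(eligible, factor(period, periods), mean))
  nr <- avg(netrad); gg <- avg(g); hh <- avg(h_f); le <- avg(le_f)
  cf <- (nr - gg) / (hh + le)
  cf[!is.finite(cf) | cov < min_coverage] <- NA_real_
  out <- list(H = list(corr = rep(NA_real_, np), corr25 = rep(NA_real_, np),
                       corr75 = rep(NA_real_, np)),
              LE = list(corr = rep(NA_real_, np),
                        corr25 = rep(NA_real_, np),
                        corr75 = rep(NA_real_, np)),
              cf = cf)
  for (p in seq_len(np)) {
    j <- max(1L, p - window):min(np, p + window)
    pool <- cf[j][!is.na(cf[j])]
    if (window > 0 && length(pool) >= 5L) {
      for (v in c("H", "LE")) {
        fx <- if (v == "H") h_agg[p] else le_agg[p]
        if (is.na(fx)) next
        q <- stats::quantile(fx * pool, c(0.25, 0.5, 0.75), names = FALSE)
        if (fx < 0) q <- sort(q)
        out[[v]]$corr25[p] <- q[1L]; out[[v]]$corr[p] <- q[2L]
        out[[v]]$corr75[p] <- q[3L]
      }
    } else if (!is.na(cf[p])) {
      out$H$corr[p] <- h_agg[p] * cf[p]
      out$LE$corr[p] <- le_agg[p] * cf[p]
    }
  }
  out
}
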