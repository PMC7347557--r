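## -------------------------------------------------------------------------
## USTAR (friction velocity) threshold estimation and filtering
## -------------------------------------------------------------------------

## Equal-count binning: bin sizes differ by at most one record.
.equal_count_bins <- function(x, k) {
  n <- length(x)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- integer(n)
  bin[order(x)] <- rep.int(seq_len(k), sizes)
  bin
}

#' Season (three-month period) of each timestamp
#'
#' Calendar quarters anchored at January: Jan-Mar = 1, ..., Oct-Dec = 4.
#' @param timestamps POSIXct vector.
#' @export
season_of <- function(timestamps)
  (as.integer(format(timestamps, "%m", tz = "UTC")) - 1L) %/% 3L + 1L

#' Bin one year of nighttime data into season/temperature/USTAR classes
#'
#' Nighttime records of a year are divided into four three-month seasons
#' and, within each season, 7 air-temperature classes of equal record
#' count; each season-temperature group is divided into 20 USTAR classes
#' (also equal count) and the mean NEE and mean USTAR per USTAR class are
#' computed.  A group is skipped when it has fewer than
#' \code{min_records} records or when temperature and USTAR are strongly
#' correlated within it (confounding guard).
#'
#' @param nee,ustar,ta aligned nighttime vectors (NA allowed).
#' @param season season index per record (see [season_of()]).
#' @param n_temp,n_ustar class counts (7 and 20).
#' @param min_records minimum records per season-temperature group.
#' @param cor_guard groups with |cor(TA, USTAR)| above this are skipped.
#' @return list of groups, each with \code{season}, \code{temp_class},
#'   \code{ustar_mean}, \code{nee_mean} (length \code{n_ustar}).
#' @export
build_night_classes <- function(nee, ustar, ta, season, n_temp = 7,
                                n_ustar = 20, min_records = 20,
                                cor_guard = 0.4) {
  ok <- !is.na(nee) & !is.na(ustar) & !is.na(ta)
  groups <- list()
  for (s in sort(unique(season[ok]))) {
    sel <- which(ok & season == s)
    if (length(sel) < n_temp * min_records) next
    tbin <- .equal_count_bins(ta[sel], n_temp)
    for (tc in seq_len(n_temp)) {
      g <- sel[tbin == tc]
      if (length(g) < max(min_records, n_ustar)) next
      if (stats::sd(ta[g]) > 0 && stats::sd(ustar[g]) > 0 &&
          abs(stats::cor(ta[g], ustar[g])) > cor_guard) next
      ubin <- .equal_count_bins(ustar[g], n_ustar)
      um <- as.numeric(tapply(ustar[g], ubin, mean))
      nm <- as.numeric(tapply(nee[g], ubin, mean))
      groups[[length(groups) + 1L]] <-
        list(season = s, temp_class = tc, ustar_mean = um, nee_mean = nm)
    }
  }
  groups
}

#' Moving-point USTAR threshold from class means
#'
#' Scans the USTAR classes from low to high and selects the first class
#' whose mean NEE exceeds 99 percent of the mean NEE of the following ten
#' classes, confirmed by requiring the same condition to hold at the next
#' class as well (robustness over noisy data); when no class qualifies no
#' threshold is returned.  The threshold value is the mean USTAR of the
#' selected class.
#'
#' @param nee_mean,ustar_mean per-class means, low to high USTAR.
#' @param ratio plateau ratio (0.99).
#' @param n_above classes averaged above the candidate (10).
#' @return threshold (m s-1) or NA.
#' @export
mp_threshold <- function(nee_mean, ustar_mean, ratio = 0.99, n_above = 10) {
  n <- length(nee_mean)
  if (n < n_above + 1L) return(NA_real_)
  cond <- function(x) {
    hi <- x + n_above
    if (hi > n) return(NA)
    nee_mean[x] > ratio * mean(nee_mean[(x + 1L):hi])
  }
  for (x in seq_len(n - n_above)) {
    c1 <- cond(x)
    if (!isTRUE(c1)) next
    c2 <- cond(x + 1L)
    if (is.na(c2) || isTRUE(c2)) return(ustar_mean[x])
  }
  NA_real_
}

#' Change-point USTAR threshold from class means
#'
#' For every candidate change point the model consists of two linear
#' regressions between NEE and USTAR: a free-slope segment below the
#' change point and a zero-slope segment above it, constrained to meet
#' at the change point (the abscissa where the two lines cross).  Given
#' a candidate abscissa the model is linear,
#' \eqn{y = b_0 + b_1 \min(u - u_c, 0)}, and the candidate minimising
#' the sum of squared errors wins.  The two-segment model must be a
#' significant improvement (F-test) over a single straight line and the
#' lower segment must rise; otherwise no clear change point can be
#' identified and NA is returned.
#'
#' @param nee_mean,ustar_mean per-class means, low to high USTAR.
#' @param alpha significance level of the F-test.
#' @return threshold (m s-1) or NA.
#' @export
cp_threshold <- function(nee_mean, ustar_mean, alpha = 0.05) {
  n <- length(nee_mean)
  if (n < 6L || stats::sd(nee_mean) == 0 || stats::sd(ustar_mean) == 0)
    return(NA_real_)
  u <- ustar_mean; y <- nee_mean
  best_c <- NA_integer_; best_b1 <- NA_real_; best_sse <- Inf
  for (c in 2:(n - 1L)) {
    x <- pmin(u - u[c], 0)
    vx <- stats::var(x)
    if (vx == 0) next
    b1 <- stats::cov(x, y) / vx
    b0 <- mean(y) - b1 * mean(x)
    sse <- sum((y - (b0 + b1 * x))^2)
    if (sse < best_sse) { best_sse <- sse; best_c <- c; best_b1 <- b1 }
  }
  if (is.na(best_c) || best_b1 <= 0) return(NA_real_)
  ## single-line reduced model
  b0 <- stats::cov(u, y) / stats::var(u)
  a0 <- mean(y) - b0 * mean(u)
  sse0 <- sum((y - (a0 + b0 * u))^2)
  df2 <- n - 3L
  if (best_sse <= 0) {
    p <- 0
  } else {
    f <- (sse0 - best_sse) / (best_sse / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  }
  if (is.na(p) || p > alpha) return(NA_real_)
  u[best_c]
}

## One full season/temperature/class run for one method on one year of
## night data.  Returns the year threshold or NA.
.ustar_year_threshold <- function(nee, ustar, ta, season,
                                  method = c("MP", "CP"),
                                  min_seasons = 2, ...) {
  method <- match.arg(method)
  groups <- build_night_classes(nee, ustar, ta, season, ...)
  if (length(groups) == 0L) return(NA_real_)
  fn <- if (method == "MP") mp_threshold else cp_threshold
  thr <- vapply(groups, function(g) fn(g$nee_mean, g$ustar_mean), 0.0)
  seas <- vapply(groups, function(g) g$season, 0L)
  med <- tapply(thr, seas, function(v)
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  med <- med[!is.na(med)]
  if (length(med) < min_seasons) return(NA_real_)
  max(med)
}

#' Bootstrap USTAR threshold estimation (MP and CP)
#'
#' For each year the valid nighttime records are re-sampled with
#' replacement \code{n_boot} times; each resample is run through the full
#' season/temperature/USTAR-class pipeline for both the moving-point and
#' change-point methods, giving up to \code{2 * n_boot} threshold
#' estimates per year.  An un-resampled run per method records the
#' SUCCESS_RUN indicator.
#'
#' @param table a [flux_table()] carrying NEE (despiked), USTAR, TA.
#' @param sw_in_pot potential radiation (defines night).
#' @param n_boot bootstrap replicates per method (default 100).
#' @param seed RNG seed for reproducibility.
#' @param nee_col column holding the (despiked, unfilled) NEE series.
#' @param ... passed to [build_night_classes()].
#' @return object of class \code{ustar_thresholds}: list with
#'   \code{years}, matrices \code{mp} and \code{cp}
#'   (years x \code{n_boot}, NA where a replicate failed), and
#'   \code{success_run} (years x 2, 1 threshold found / 0 failed).
#' @export
bootstrap_thresholds <- function(table, sw_in_pot, n_boot = 100, seed = 1,
                                 nee_col = "NEE", ...) {
  years <- flux_years(table)
  yr <- as.integer(format(table$TIMESTAMP_START, "%Y", tz = "UTC"))
  night <- is_night(sw_in_pot)
  season <- season_of(table$TIMESTAMP_START)
  mp <- matrix(NA_real_, length(years), n_boot,
               dimnames = list(years, NULL))
  cp <- mp
  success <- matrix(0L, length(years), 2L,
                    dimnames = list(years, c("MP", "CP")))
  set.seed(seed)
  for (k in seq_along(years)) {
    sel <- which(yr == years[k] & night & !is.na(table[[nee_col]]) &
                   !is.na(table$USTAR) & !is.na(table$TA))
    if (length(sel) == 0L) next
    nee <- table[[nee_col]][sel]; us <- table$USTAR[sel]
    ta <- table$TA[sel]; se <- season[sel]
    for (m in c("MP", "CP")) {
      t0 <- .ustar_year_threshold(nee, us, ta, se, method = m, ...)
      success[k, m] <- as.integer(!is.na(t0))
    }
    for (b in seq_len(n_boot)) {
      i <- sample.int(length(sel), replace = TRUE)
      mp[k, b] <- .ustar_year_threshold(nee[i], us[i], ta[i], se[i],
                                        method = "MP", ...)
      cp[k, b] <- .ustar_year_threshold(nee[i], us[i], ta[i], se[i],
                                        method = "CP", ...)
    }
  }
  structure(list(years = years, mp = mp, cp = cp, success_run = success,
                 n_boot = n_boot),
            class = "ustar_thresholds")
}

#' @export
print.ustar_thresholds <- function(x, ...) {
  cat(sprintf("<ustar_thresholds>  years %s; %d bootstrap replicates/method\n",
              paste(x$years, collapse = ", "), x$n_boot))
  for (k in seq_along(x$years)) {
    cat(sprintf("  %d: MP %3d found (median %.3f), CP %3d found (median %.3f)\n",
                x$years[k], sum(!is.na(x$mp[k, ])),
                stats::median(x$mp[k, ], na.rm = TRUE),
                sum(!is.na(x$cp[k, ])),
                stats::median(x$cp[k, ], na.rm = TRUE)))
  }
  invisible(x)
}

#' The 40 percentile ranks used for threshold extraction
#' @export
ustar_percentile_ranks <- function() seq(1.25, 98.75, by = 2.5)

#' Extract the 40 representative thresholds (VUT or CUT)
#'
#' Variable USTAR threshold (VUT): for each year, the bootstrap
#' thresholds of that year and of the years immediately before and after
#' (when available) are pooled, and the 40 percentiles 1.25, 3.75, ...,
#' 98.75 of the pooled empirical distribution are extracted.  Constant
#' USTAR threshold (CUT): all years' thresholds are pooled once.  The
#' 50th percentile of the pool is the USTAR50 threshold.
#'
#' @param set a [bootstrap_thresholds()] result.
#' @param mode \code{"VUT"} or \code{"CUT"}.
#' @return for VUT a list with \code{thresholds} (40 x years matrix),
#'   \code{ustar50} (per year), \code{ranks}; for CUT \code{thresholds}
#'   is a length-40 vector and \code{ustar50} a scalar.
#' @export
extract_percentiles <- function(set, mode = c("VUT", "CUT")) {
  mode <- match.arg(mode)
  ranks <- ustar_percentile_ranks()
  pool_of <- function(ks) {
    v <- c(set$mp[ks, , drop = FALSE], set$cp[ks, , drop = FALSE])
    v[!is.na(v)]
  }
  if (mode == "CUT") {
    pool <- pool_of(seq_along(set$years))
    if (length(pool) == 0L)
      return(list(mode = mode, thresholds = rep(NA_real_, 40L),
                  ustar50 = NA_real_, ranks = ranks))
    thr <- stats::quantile(pool, ranks / 100, names = FALSE, type = 7)
    return(list(mode = mode, thresholds = thr,
                ustar50 = stats::median(pool), ranks = ranks))
  }
  ny <- length(set$years)
  thr <- matrix(NA_real_, 40L, ny, dimnames = list(NULL, set$years))
  u50 <- rep(NA_real_, ny)
  for (k in seq_len(ny)) {
    ks <- intersect(c(k - 1L, k, k + 1L), seq_len(ny))
    pool <- pool_of(ks)
    if (length(pool) == 0L) next
    thr[, k] <- stats::quantile(pool, ranks / 100, names = FALSE, type = 7)
    u50[k] <- stats::median(pool)
  }
  list(mode = mode, thresholds = thr, ustar50 = u50, ranks = ranks)
}

#' Filter NEE for low-turbulence conditions
#'
#' NEE is masked wherever USTAR is below the threshold or missing, for
#' daytime and nighttime records alike, and additionally at the first
#' high-turbulence record following one or more sub-threshold records
#' (false emission pulses from CO2 accumulated under the canopy).  H and
#' LE are never filtered this way.
#'
#' @param nee NEE series.
#' @param ustar friction velocity series.
#' @param threshold m s-1; may be a per-record vector (VUT).
#' @return NEE with filtered records set to NA.
#' @export
apply_ustar_filter <- function(nee, ustar, threshold) {
  low <- !is.na(ustar) & ustar < threshold
  drop <- low | is.na(ustar)
  recover <- c(FALSE, low[-length(low)]) & !low & !is.na(ustar)
  nee[drop | recover] <- NA_real_
  nee
}
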