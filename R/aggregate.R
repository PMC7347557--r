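## -------------------------------------------------------------------------
## Temporal aggregation (DD / WW / MM / YY)
## -------------------------------------------------------------------------

#' Weekly period boundaries for a calendar year
#'
#' 52 seven-day periods anchored at January 1; the final period absorbs
#' the remaining one (normal year) or two (leap year) days.
#'
#' @param year calendar year.
#' @return data frame with \code{start} and \code{end} POSIXct period
#'   bounds (end exclusive).
#' @export
weekly_axis <- function(year) {
  t0 <- parse_flux_timestamp(sprintf("%04d01010000", year))
  t1 <- parse_flux_timestamp(sprintf("%04d01010000", year + 1L))
  starts <- t0 + (0:51) * 7 * 86400
  ends <- c(starts[-1L], t1)
  data.frame(start = starts, end = ends)
}

## Period id for every record at a given resolution; WW ids are
## "YYYY-WW" strings, DD "YYYYMMDD", MM "YYYYMM", YY "YYYY".
.period_id <- function(timestamps, resolution) {
  switch(resolution,
         DD = format(timestamps, "%Y%m%d", tz = "UTC"),
         MM = format(timestamps, "%Y%m", tz = "UTC"),
         YY = format(timestamps, "%Y", tz = "UTC"),
         WW = {
           yr <- as.integer(format(timestamps, "%Y", tz = "UTC"))
           doy <- as.integer(format(timestamps, "%j", tz = "UTC"))
           wk <- pmin((doy - 1L) %/% 7L + 1L, 52L)
           sprintf("%04d-W%02d", yr, wk)
         },
         stop("resolution must be one of DD, WW, MM, YY", call. = FALSE))
}

#' Aggregate a half-hourly series to a coarser resolution
#'
#' Kinds: \code{"average"} for state variables (TA, SW_IN, ...);
#' \code{"sum"} for per-record totals like precipitation; and
#' \code{"carbon"} for CO2 fluxes in umolCO2 m-2 s-1, converted to grams
#' of carbon (12.011 ug per umol times the record length in seconds).
#' Following the published unit conventions, sums and carbon fluxes are
#' reported as per-day amounts at DD, WW and MM resolution (mm d-1,
#' gC m-2 d-1) and as period totals at YY (mm y-1, gC m-2 y-1).
#' The QC fraction of a period is the share of underlying records whose
#' flag qualifies as measured or good fill (flag at most \code{good_max}).
#'
#' @param x numeric HH/HR series.
#' @param timestamps POSIXct record start times.
#' @param resolution DD, WW, MM or YY.
#' @param kind aggregation kind.
#' @param step record length in minutes.
#' @param qc optional per-record quality flags for the QC fraction.
#' @param good_max largest flag still counting as good.
#' @return data frame with \code{TIMESTAMP} (period label), \code{value},
#'   and \code{qc} fraction (NA when no flags given).
#' @export
aggregate_series <- function(x, timestamps, resolution,
                             kind = c("average", "sum", "carbon"),
                             step = 30, qc = NULL, good_max = 1) {
  kind <- match.arg(kind)
  resolution <- match.arg(resolution, c("DD", "WW", "MM", "YY"))
  pid <- .period_id(timestamps, resolution)
  days <- .period_id(timestamps, "DD")
  f <- factor(pid, unique(pid))
  per_sec <- step * 60
  if (kind == "average") {
    value <- as.numeric(tapply(x, f, function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)))
  } else {
    mult <- if (kind == "carbon") 12.011e-6 * per_sec else 1
    daily <- tapply(x * mult, factor(days, unique(days)), function(v)
      if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE))
    day_of <- tapply(pid, factor(days, unique(days)), `[`, 1L)
    fd <- factor(day_of, unique(pid))
    value <- if (resolution %in% c("DD", "YY")) {
      as.numeric(tapply(as.numeric(daily), fd, sum))
    } else {
      as.numeric(tapply(as.numeric(daily), fd, mean))
    }
  }
  qcf <- if (is.null(qc)) rep(NA_real_, nlevels(f)) else
    as.numeric(tapply(qc, f, function(v)
      mean(!is.na(v) & v <= good_max)))
  data.frame(TIMESTAMP = levels(f), value = value, qc = qcf,
             stringsAsFactors = FALSE)
}

#' Aggregate a set of columns of a flux table
#'
#' Convenience wrapper mapping standard variable names to their
#' aggregation kind (precipitation summed, carbon fluxes converted and
#' summed, everything else averaged); wind direction and relative
#' humidity are not aggregated.
#'
#' @param table a [flux_table()].
#' @param resolution DD, WW, MM or YY.
#' @param vars columns to aggregate (default: all numeric).
#' @param qc_table optional named list of per-record flags.
#' @return data frame, one row per period, first column TIMESTAMP.
#' @export
aggregate_table <- function(table, resolution, vars = NULL,
                            qc_table = list()) {
  if (is.null(vars))
    vars <- setdiff(names(table), c("TIMESTAMP_START", "TIMESTAMP_END"))
  vars <- setdiff(vars, c("WD", "RH"))
  ts <- table$TIMESTAMP_START
  step <- flux_step(table)
  out <- NULL
  for (v in vars) {
    base <- sub("_.*$", "", v)
    kind <- if (base == "P") "sum"
    else if (base %in% c("NEE", "GPP", "RECO", "FC", "SC")) "carbon"
    else "average"
    agg <- aggregate_series(table[[v]], ts, resolution, kind, step,
                            qc = qc_table[[v]])
    if (is.null(out)) {
      out <- data.frame(TIMESTAMP = agg$TIMESTAMP,
                        stringsAsFactors = FALSE)
    }
    out[[v]] <- agg$value
    if (!is.null(qc_table[[v]])) out[[paste0(v, "_QC")]] <- agg$qc
  }
  out
}
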