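#' @keywords internal
"_PACKAGE"

## -------------------------------------------------------------------------
## Timestamps (YYYYMMDDHHMM dialect, local standard time, no DST)
## -------------------------------------------------------------------------

.ts_width <- c(HH = 12L, HR = 12L, DD = 8L, WW = 8L, MM = 6L, YY = 4L)

#' Parse a FLUXNET-dialect timestamp
#'
#' Timestamps use the format \code{YYYYMMDDHHMM}, truncated at the
#' resolution of the file (\code{YYYYMMDD} for daily, \code{YYYYMM} for
#' monthly, \code{YYYY} for yearly).  All times are local standard time;
#' internally they are held as POSIXct in the UTC timezone so that no
#' daylight-saving jumps can occur.
#'
#' @param x character vector of timestamps.
#' @param resolution one of \code{"HH"}, \code{"HR"}, \code{"DD"},
#'   \code{"WW"}, \code{"MM"}, \code{"YY"}.
#' @return POSIXct vector (UTC-encoded local standard time).
#' @export
parse_flux_timestamp <- function(x, resolution = "HH") {
  resolution <- match.arg(resolution, names(.ts_width))
  x <- as.character(x)
  w <- .ts_width[[resolution]]
  bad <- !grepl("^[0-9]+$", x) | nchar(x) != w
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("malformed %s timestamp (expect %d digits): '%s'",
                 resolution, w, x[which(bad)[1L]]), call. = FALSE)
  }
  full <- paste0(x, substr("000101010000", nchar(x) + 1L, 12L))
  out <- as.POSIXct(strptime(full, "%Y%m%d%H%M", tz = "UTC"))
  if (anyNA(out) && !anyNA(x)) {
    stop(sprintf("invalid calendar timestamp: '%s'", x[which(is.na(out))[1L]]),
         call. = FALSE)
  }
  out
}

#' Render a timestamp in the FLUXNET dialect
#'
#' Inverse of [parse_flux_timestamp()]; truncates to the width of the
#' requested resolution.
#'
#' @inheritParams parse_flux_timestamp
#' @param t POSIXct vector.
#' @return character vector.
#' @export
format_flux_timestamp <- function(t, resolution = "HH") {
  resolution <- match.arg(resolution, names(.ts_width))
  substr(format(t, "%Y%m%d%H%M", tz = "UTC"), 1L, .ts_width[[resolution]])
}

#' Build a regular half-hourly (or hourly) time axis
#'
#' @param first_year,last_year calendar years covered (inclusive).
#' @param step record length in minutes, 30 or 60.
#' @return POSIXct vector of record start times.
#' @export
flux_time_axis <- function(first_year, last_year = first_year, step = 30) {
  stopifnot(step %in% c(30, 60))
  t0 <- parse_flux_timestamp(sprintf("%04d01010000", first_year))
  t1 <- parse_flux_timestamp(sprintf("%04d01010000", last_year + 1L))
  seq(t0, by = step * 60, to = t1 - step * 60)
}

## -------------------------------------------------------------------------
## Site metadata
## -------------------------------------------------------------------------

#' Site metadata required by the pipeline
#'
#' @param site_id FLUXNET site id, \code{CC-SSS} (two-letter country code,
#'   three-character site code), e.g. \code{"US-Ha1"}.
#' @param latitude,longitude WGS84 decimal degrees.
#' @param utc_offset local standard time offset from UTC in hours.
#' @param analyzer_height gas-analyzer measurement height in metres.
#' @param igbp IGBP vegetation class code.
#' @param canopy_class \code{"short"} or \code{"tall"}; with a missing
#'   storage flux, short canopies below 3 m assume zero storage while tall
#'   towers use a discrete one-point storage estimate.
#' @return object of class \code{site_metadata}.
#' @export
site_metadata <- function(site_id, latitude, longitude, utc_offset = 0,
                          analyzer_height = 3, igbp = "DBF",
                          canopy_class = c("short", "tall")) {
  canopy_class <- match.arg(canopy_class)
  if (!grepl("^[A-Z]{2}-[A-Za-z0-9]{3}$", site_id))
    stop("site_id must have the form CC-SSS, e.g. 'US-Ha1'", call. = FALSE)
  stopifnot(latitude >= -90, latitude <= 90,
            longitude >= -180, longitude <= 180)
  structure(list(site_id = site_id, latitude = latitude,
                 longitude = longitude, utc_offset = utc_offset,
                 analyzer_height = analyzer_height, igbp = igbp,
                 canopy_class = canopy_class),
            class = "site_metadata")
}

#' @export
print.site_metadata <- function(x, ...) {
  cat(sprintf("<site %s>  lat %.4f  lon %.4f  UTC%+g  analyzer %.1f m  %s/%s\n",
              x$site_id, x$latitude, x$longitude, x$utc_offset,
              x$analyzer_height, x$igbp, x$canopy_class))
  invisible(x)
}

## -------------------------------------------------------------------------
## flux_table: the universal currency of the pipeline
## -------------------------------------------------------------------------

#' Construct a half-hourly flux table
#'
#' A \code{flux_table} is a data frame whose first two columns are
#' \code{TIMESTAMP_START} and \code{TIMESTAMP_END} (POSIXct, strictly
#' increasing, equally spaced) followed by numeric data columns.  Missing
#' values are plain \code{NA} internally; the -9999 sentinel exists only
#' in files.
#'
#' @param timestamps POSIXct record start times (regular axis).
#' @param data named list or data frame of numeric columns.
#' @param step record length in minutes.
#' @return a \code{flux_table}.
#' @export
flux_table <- function(timestamps, data = list(), step = 30) {
  stopifnot(step %in% c(30, 60))
  n <- length(timestamps)
  if (n > 1L) {
    d <- diff(as.numeric(timestamps))
    if (any(d != step * 60))
      stop("timestamps must be strictly increasing and equally spaced by step",
           call. = FALSE)
  }
  out <- data.frame(TIMESTAMP_START = timestamps,
                    TIMESTAMP_END = timestamps + step * 60)
  for (nm in names(data)) out[[nm]] <- as.numeric(data[[nm]])
  attr(out, "step") <- step
  class(out) <- c("flux_table", "data.frame")
  out
}

#' @export
print.flux_table <- function(x, ...) {
  cat(sprintf("<flux_table>  %d records @ %d min, %s .. %s, %d variables\n",
              nrow(x), flux_step(x),
              format_flux_timestamp(x$TIMESTAMP_START[1L]),
              format_flux_timestamp(x$TIMESTAMP_START[nrow(x)]),
              ncol(x) - 2L))
  NextMethod()
}

#' Record length of a flux table in minutes
#' @param table a \code{flux_table}.
#' @export
flux_step <- function(table) attr(table, "step", exact = TRUE)

#' Calendar years spanned by a flux table
#' @param table a \code{flux_table}.
#' @export
flux_years <- function(table)
  sort(unique(as.integer(format(table$TIMESTAMP_START, "%Y", tz = "UTC"))))

## -------------------------------------------------------------------------
## CSV reading / writing
## -------------------------------------------------------------------------

#' Read a FLUXNET-dialect CSV into a flux table
#'
#' Columns are located by label, never by position (only the TIMESTAMP
#' columns are guaranteed to come first in files).  -9999 becomes
#' \code{NA}.  Records missing from the time axis are re-inserted as
#' all-missing rows so that the table is always regular.
#'
#' @param path CSV file path.
#' @param step record length in minutes (30 or 60).
#' @return a [flux_table()].
#' @export
read_fluxnet_csv <- function(path, step = 30) {
  raw <- utils::read.csv(path, check.names = FALSE,
                         colClasses = "character")
  if (!"TIMESTAMP_START" %in% names(raw))
    stop("no TIMESTAMP_START column in ", path, call. = FALSE)
  ts <- parse_flux_timestamp(raw$TIMESTAMP_START, "HH")
  if (anyDuplicated(ts)) stop("duplicated timestamps in ", path, call. = FALSE)
  if (is.unsorted(as.numeric(ts), strictly = TRUE))
    stop("non-monotone timestamps in ", path, call. = FALSE)
  axis <- seq(ts[1L], ts[length(ts)], by = step * 60)
  idx <- match(as.numeric(axis), as.numeric(ts))
  vars <- setdiff(names(raw), c("TIMESTAMP_START", "TIMESTAMP_END"))
  cols <- lapply(raw[vars], function(col) {
    v <- suppressWarnings(as.numeric(col))
    v[!is.na(v) & v == -9999] <- NA_real_
    v[idx]
  })
  names(cols) <- vars
  flux_table(axis, cols, step = step)
}

## Truncate toward zero: <=9 decimals for |v| < 1, <=5 otherwise,
## integers without decimal point, missing -> "-9999".
.format_flux_number <- function(v) {
  out <- character(length(v))
  out[is.na(v)] <- "-9999"
  ok <- !is.na(v)
  x <- v[ok]
  dig <- ifelse(abs(x) < 1, 9L, 5L)
  ## floor toward zero in the scaled space, with a nudge so that values
  ## sitting on the decimal grid (e.g. re-read output) are not knocked
  ## one unit down by float representation error
  tr <- sign(x) * floor(abs(x) * 10^dig + 1e-6) / 10^dig
  s <- vapply(seq_along(x), function(i)
    formatC(tr[i], format = "f", digits = dig[i]), "")
  s <- sub("0+$", "", s)
  s <- sub("\\.$", "", s)
  s[s %in% c("-0", "")] <- "0"
  out[ok] <- s
  out
}

#' Render a product file name
#'
#' \code{FLX_[SITE_ID]_FLUXNET2015_[DATA_PRODUCT]_[RESOLUTION]_}
#' \code{[FIRST_YEAR]-[LAST_YEAR]_[SITE_VERSION]-[CODE_VERSION].[EXT]}.
#' AUXMETEO and AUXNEE files carry no resolution field.
#'
#' @param site_id site id \code{CC-SSS}.
#' @param product one of SUBSET, FULLSET, AUXMETEO, AUXNEE, ERAI.
#' @param resolution HH/HR/DD/WW/MM/YY (ignored for AUX products).
#' @param first_year,last_year year range of the flux record.
#' @param site_version,code_version integer version tags.
#' @param ext file extension, csv or zip.
#' @export
product_filename <- function(site_id, product, resolution, first_year,
                             last_year, site_version = 1, code_version = 1,
                             ext = "csv") {
  product <- match.arg(product,
                       c("SUBSET", "FULLSET", "AUXMETEO", "AUXNEE", "ERAI"))
  ext <- match.arg(ext, c("csv", "zip"))
  if (product %in% c("AUXMETEO", "AUXNEE")) {
    sprintf("FLX_%s_FLUXNET2015_%s_%d-%d_%d-%d.%s", site_id, product,
            first_year, last_year, site_version, code_version, ext)
  } else {
    resolution <- match.arg(resolution, names(.ts_width))
    sprintf("FLX_%s_FLUXNET2015_%s_%s_%d-%d_%d-%d.%s", site_id, product,
            resolution, first_year, last_year, site_version, code_version, ext)
  }
}

## Variable list for the reduced SUBSET product (kept ones that exist).
.subset_variables <- function(vars) {
  keep <- c("TA_F", "TA_F_QC", "SW_IN_POT", "SW_IN_F", "SW_IN_F_QC",
            "LW_IN_F", "LW_IN_F_QC", "VPD_F", "VPD_F_QC", "PA_F", "PA_F_QC",
            "P_F", "P_F_QC", "WS_F", "WS_F_QC", "USTAR", "NETRAD", "PPFD_IN",
            "CO2_F_MDS", "CO2_F_MDS_QC",
            "LE_F", "LE_F_QC", "LE_CORR", "LE_CORR_25", "LE_CORR_75",
            "LE_RANDUNC", "H_F", "H_F_QC", "H_CORR", "H_CORR_25",
            "H_CORR_75", "H_RANDUNC", "G_F",
            "NEE_VUT_REF", "NEE_VUT_REF_QC", "NEE_VUT_REF_RANDUNC",
            "NEE_VUT_REF_JOINTUNC",
            "NEE_VUT_25", "NEE_VUT_50", "NEE_VUT_75",
            "RECO_NT_VUT_REF", "GPP_NT_VUT_REF",
            "RECO_DT_VUT_REF", "GPP_DT_VUT_REF")
  intersect(keep, vars)
}

#' Write a data product CSV in FLUXNET2015 conventions
#'
#' Values are truncated toward zero (up to nine decimals for numbers of
#' magnitude below one, up to five otherwise), missing values become
#' -9999 without decimal point, and the file is named by the Table-style
#' template.  The SUBSET product emits only the reduced variable list.
#'
#' @param table a [flux_table()] or a coarser-resolution data frame whose
#'   first column(s) are timestamps.
#' @param metadata a [site_metadata()].
#' @inheritParams product_filename
#' @param dest destination directory.
#' @return the file name written (invisibly its full path as attribute).
#' @export
write_product <- function(table, metadata, product, resolution, dest = ".",
                          first_year = NULL, last_year = NULL,
                          site_version = 1, code_version = 1) {
  product <- match.arg(product,
                       c("SUBSET", "FULLSET", "AUXMETEO", "AUXNEE", "ERAI"))
  ts_cols <- intersect(c("TIMESTAMP_START", "TIMESTAMP_END", "TIMESTAMP"),
                       names(table))
  if (is.null(first_year) || is.null(last_year)) {
    if (length(ts_cols) == 0L)
      stop("first_year/last_year required for tables without timestamps",
           call. = FALSE)
    tc <- table[[ts_cols[1L]]]
    if (inherits(tc, "POSIXct")) {
      yrs <- as.integer(format(range(tc), "%Y", tz = "UTC"))
    } else {
      yrs <- as.integer(substr(range(as.character(tc)), 1L, 4L))
    }
    if (is.null(first_year)) first_year <- yrs[1L]
    if (is.null(last_year)) last_year <- yrs[2L]
  }
  fname <- product_filename(metadata$site_id, product, resolution,
                            first_year, last_year, site_version, code_version)
  vars <- setdiff(names(table), ts_cols)
  if (product == "SUBSET") vars <- .subset_variables(vars)
  out <- list()
  for (cn in ts_cols) {
    tc <- table[[cn]]
    out[[cn]] <- if (inherits(tc, "POSIXct"))
      format_flux_timestamp(tc, resolution) else as.character(tc)
  }
  for (cn in vars) {
    out[[cn]] <- if (is.numeric(table[[cn]]))
      .format_flux_number(table[[cn]]) else as.character(table[[cn]])
  }
  path <- file.path(dest, fname)
  utils::write.csv(as.data.frame(out, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  structure(fname, path = path)
}
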