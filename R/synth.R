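## -------------------------------------------------------------------------
## Synthetic-site generator with known ground truth
## -------------------------------------------------------------------------

#' Configuration of the synthetic site
#'
#' Defaults describe a mid-latitude deciduous site with a moderate
#' advection problem: a true friction-velocity threshold of 0.25 m s-1
#' below which nighttime fluxes lose half their magnitude, a 20 percent
#' energy-balance closure gap, temperature sensitivity and base
#' respiration typical of temperate forests, ten percent random gaps per
#' variable and a small residual spike rate.
#'
#' @param years number of calendar years (starting at
#'   \code{first_year}).
#' @param first_year first calendar year.
#' @param latitude,longitude,utc_offset site location.
#' @param step record length in minutes.
#' @param true_ustar_threshold m s-1 below which nighttime advection
#'   losses occur.
#' @param night_suppression_fraction fraction of the flux lost below the
#'   threshold (0-1).
#' @param closure_gap energy-balance closure factor alpha; measured H
#'   and LE are the true fluxes divided by alpha.
#' @param rref,e0 respiration parameters (Lloyd-Taylor).
#' @param lrc_alpha,lrc_beta light-response initial slope
#'   (umolCO2 J-1) and plateau (umolCO2 m-2 s-1).
#' @param gap_fraction random missing fraction applied per variable.
#' @param spike_rate fraction of FC records hit by a spike.
#' @param nee_noise_sd flux noise, umolCO2 m-2 s-1.
#' @param seed RNG seed; fixes the full realization.
#' @export
synth_config <- function(years = 2, first_year = 2010, latitude = 45,
                         longitude = 8, utc_offset = 1, step = 30,
                         true_ustar_threshold = 0.25,
                         night_suppression_fraction = 0.5,
                         closure_gap = 1.25, rref = 2, e0 = 200,
                         lrc_alpha = 0.04, lrc_beta = 25,
                         gap_fraction = 0.1, spike_rate = 0.002,
                         nee_noise_sd = 1.5, seed = 42) {
  stopifnot(night_suppression_fraction >= 0,
            night_suppression_fraction <= 1,
            gap_fraction >= 0, gap_fraction <= 1)
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic half-hourly site with known ground truth
#'
#' Builds a complete half-hourly record driven by the site's potential
#' radiation: incoming shortwave with autocorrelated cloud attenuation,
#' air temperature with seasonal and diurnal cycles, humidity-derived
#' VPD, lognormal friction velocity with calm nights, true NEE from a
#' Lloyd-Taylor respiration plus rectangular-hyperbola light response,
#' advection losses below the true USTAR threshold, sensible and latent
#' heat from an available-energy split with an imposed closure gap, plus
#' precipitation, pressure, CO2 and soil variables.  Gaps and spikes are
#' injected last.  A coarse (3-hourly) biased reference series is also
#' produced for the downscaling step, and every generative quantity is
#' kept in the truth record.
#'
#' @param config a [synth_config()].
#' @return list with \code{table} (a [flux_table()]), \code{metadata},
#'   \code{reference} (named list of coarse series) and \code{truth}.
#' @export
generate_site <- function(config = synth_config()) {
  set.seed(config$seed)
  meta <- site_metadata("XX-Syn", config$latitude, config$longitude,
                        config$utc_offset, analyzer_height = 2,
                        igbp = "DBF", canopy_class = "short")
  axis <- flux_time_axis(config$first_year,
                         config$first_year + config$years - 1L,
                         step = config$step)
  n <- length(axis)
  rpd <- as.integer(1440 / config$step)
  sw_pot <- potential_radiation(meta, axis, config$step)
  doy <- as.integer(format(axis, "%j", tz = "UTC"))
  hour <- as.integer(format(axis, "%H", tz = "UTC")) +
    as.integer(format(axis, "%M", tz = "UTC")) / 60

  ## cloud attenuation: slow AR(1) in [0.25, 1]
  ar <- stats::filter(stats::rnorm(n, 0, 0.08), 0.98, "recursive")
  cloud <- pmin(pmax(0.75 + as.numeric(ar), 0.25), 1)
  sw_in <- sw_pot * cloud

  ## air temperature: seasonal + diurnal + AR noise
  seas <- 10 - 12 * cos(2 * pi * (doy - 15) / 365.25)
  diur <- 5 * sin(2 * pi * (hour - 9) / 24) * (0.5 + 0.5 * cloud)
  ta <- seas + diur + as.numeric(
    stats::filter(stats::rnorm(n, 0, 0.3), 0.95, "recursive"))

  rh <- pmin(pmax(75 - 0.02 * sw_in + stats::rnorm(n, 0, 6), 20), 100)
  vpd <- pmax(vpd_from_rh(ta, rh), 0)

  ## friction velocity: lognormal, suppressed at night
  u_mu <- ifelse(is_night(sw_pot), -1.45, -0.85)
  ustar <- stats::rlnorm(n, u_mu, 0.6)

  ## true fluxes
  reco <- lloyd_taylor(ta, config$rref, config$e0)
  gpp <- config$lrc_alpha * config$lrc_beta * sw_in /
    (config$lrc_alpha * sw_in + config$lrc_beta)
  gpp[sw_in <= 0] <- 0
  nee_true <- reco - gpp
  night <- is_night(sw_pot)
  advected <- night & ustar < config$true_ustar_threshold
  nee_obs <- nee_true
  nee_obs[advected] <- nee_true[advected] *
    (1 - config$night_suppression_fraction)
  sc <- stats::rnorm(n, 0, 0.2)
  fc <- nee_obs - sc + stats::rnorm(n, 0, config$nee_noise_sd)

  ## energy balance: available energy split, closure gap alpha
  netrad <- 0.85 * sw_in - 55 + stats::rnorm(n, 0, 8)
  g <- 0.12 * netrad + stats::rnorm(n, 0, 4)
  avail <- netrad - g
  ef <- 0.55 + 0.1 * sin(2 * pi * (doy - 150) / 365.25)   # evap fraction
  le_true <- ef * avail
  h_true <- (1 - ef) * avail
  h <- h_true / config$closure_gap + stats::rnorm(n, 0, 6)
  le <- le_true / config$closure_gap + stats::rnorm(n, 0, 6)

  p <- ifelse(stats::runif(n) < 0.01, stats::rexp(n, 1), 0)
  pa <- 98 + stats::rnorm(n, 0, 0.3)
  co2 <- 400 + 8 * cos(2 * pi * hour / 24) + stats::rnorm(n, 0, 2)
  lw_in <- 280 + 4.2 * ta + stats::rnorm(n, 0, 10)
  ws <- ustar / 0.12 + stats::rnorm(n, 0, 0.3)
  swc <- pmin(pmax(30 + as.numeric(
    stats::filter(stats::rnorm(n, 0, 0.1), 0.995, "recursive")), 5), 60)
  ts_soil <- seas + 2 * sin(2 * pi * (hour - 14) / 24) +
    stats::rnorm(n, 0, 0.2)
  ppfd <- sw_in / 0.48 + stats::rnorm(n, 0, 10)
  ppfd[ppfd < 0] <- 0

  cols <- list(FC = fc, SC = sc, H = h, LE = le, WS = ws, USTAR = ustar,
               TA = ta, RH = rh, PA = pa, SW_IN = sw_in,
               SW_IN_POT = sw_pot, PPFD_IN = ppfd, P = p, LW_IN = lw_in,
               NETRAD = netrad, G = g, CO2 = co2, SWC = swc, TS = ts_soil,
               VPD = vpd)

  ## spike injection on FC, then random gaps per variable
  spikes <- which(stats::runif(n) < config$spike_rate)
  cols$FC[spikes] <- cols$FC[spikes] +
    sample(c(-1, 1), length(spikes), TRUE) * stats::runif(length(spikes),
                                                          15, 40)
  gap_mask <- list()
  if (config$gap_fraction > 0) {
    for (v in setdiff(names(cols), "SW_IN_POT")) {
      m <- stats::runif(n) < config$gap_fraction
      gap_mask[[v]] <- m
      cols[[v]][m] <- NA_real_
    }
  }

  ## coarse 3-hourly reference with bias and noise (reanalysis stand-in)
  cstep <- as.integer(180 / config$step)   # records per 3 h
  cidx <- rep(seq_len(ceiling(n / cstep)), each = cstep)[seq_len(n)]
  coarse <- function(x, bias = 0, sd = 0, scale = 1) {
    v <- as.numeric(tapply(x, cidx, mean))
    list(timestamps = axis[seq(1L, n, by = cstep)],
         values = scale * v + bias + stats::rnorm(length(v), 0, sd))
  }
  reference <- list(
    TA = coarse(ta, bias = -1.2, sd = 0.8),
    SW_IN = coarse(sw_in, sd = 15, scale = 0.95),
    VPD = coarse(vpd, bias = 0.5, sd = 0.6),
    WS = coarse(ws, bias = 0.4, sd = 0.3),
    PA = coarse(pa, bias = 0.8, sd = 0.1),
    LW_IN = coarse(lw_in, bias = -5, sd = 5),
    P = {
      tot <- as.numeric(tapply(p, cidx, sum))
      list(timestamps = axis[seq(1L, n, by = cstep)], values = tot)
    })

  truth <- list(nee = nee_true, reco = reco, gpp = gpp,
                nee_observed = nee_obs,
                ustar_threshold = config$true_ustar_threshold,
                suppression = config$night_suppression_fraction,
                closure_gap = config$closure_gap,
                rref = config$rref, e0 = config$e0,
                lrc_alpha = config$lrc_alpha, lrc_beta = config$lrc_beta,
                cloud = cloud, spikes = spikes, gap_mask = gap_mask,
                advected = advected, sw_in_pot = sw_pot)
  list(table = flux_table(axis, cols, step = config$step),
       metadata = meta, reference = reference, truth = truth,
       config = config)
}

#' Recovery metrics of a pipeline run against the generative truth
#'
#' Compares pipeline outputs with the stored generative quantities:
#' USTAR-threshold recovery (USTAR50 versus the true cutoff), closure
#' factor recovery (median EBC_CF versus alpha), respiration-parameter
#' recovery, gap-fill RMSE, and annual NEE bias.
#'
#' @param site a [generate_site()] result.
#' @param outputs a [process_site()] result (components may be missing;
#'   the report is then partial).
#' @return named list of metrics.
#' @export
truth_report <- function(site, outputs) {
  truth <- site$truth
  out <- list()
  if (!is.null(outputs$ustar_vut)) {
    out$ustar50_error <- mean(outputs$ustar_vut$ustar50, na.rm = TRUE) -
      truth$ustar_threshold
  }
  if (!is.null(outputs$ebc$cf)) {
    out$median_ebc_cf <- stats::median(outputs$ebc$cf, na.rm = TRUE)
    out$closure_gap_error <- out$median_ebc_cf - truth$closure_gap
  }
  pnt <- outputs$partition_nt_vut
  if (!is.null(pnt) && any(!is.na(pnt$e0))) {
    out$e0_recovered <- stats::median(pnt$e0, na.rm = TRUE)
    out$e0_error_frac <- abs(out$e0_recovered - truth$e0) / truth$e0
  }
  if (!is.null(pnt) && !is.null(pnt$reco)) {
    ok <- !is.na(pnt$reco$ref) & !is.na(truth$reco)
    out$reco_rmse <- sqrt(mean((pnt$reco$ref[ok] - truth$reco[ok])^2))
  }
  if (!is.null(outputs$nee_ref)) {
    ok <- !is.na(outputs$nee_ref)
    out$annual_nee_bias <- mean(outputs$nee_ref[ok] - truth$nee[ok])
    out$fill_rmse <- sqrt(mean((outputs$nee_ref[ok] - truth$nee[ok])^2))
  }
  out
}
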