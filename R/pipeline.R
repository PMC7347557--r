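## -------------------------------------------------------------------------
## Whole-site orchestration
## -------------------------------------------------------------------------

#' Run the full post-processing pipeline on one site
#'
#' Executes, in order: automated QC (range controls, NEE despiking,
#' potential radiation, SW_IN from PPFD_IN), meteorological gap-filling
#' (MDS plus, when a coarse reference is supplied, debiased downscaling
#' and the merged final product), USTAR threshold bootstrapping with the
#' moving-point and change-point methods, extraction of the 40
#' representative thresholds (VUT always; CUT when more than two years
#' are available), construction of the filtered and gap-filled NEE
#' ensemble with percentile/MEAN/USTAR50/REF products, random and joint
#' NEE uncertainty, energy-balance-corrected H and LE with their
#' uncertainties, nighttime and daytime partitioning into RECO and GPP
#' across the ensemble, and daily-to-yearly aggregation.
#'
#' @param site_table a [flux_table()] with the standard input variables
#'   (FC, SC, H, LE, WS, USTAR, TA, RH, PA, SW_IN, PPFD_IN, P, LW_IN,
#'   NETRAD, G, CO2, SWC, TS; VPD optional).
#' @param metadata a [site_metadata()].
#' @param reference optional named list of coarse reference series for
#'   downscaling (as produced by [generate_site()]).
#' @param n_boot bootstrap replicates per USTAR method.
#' @param seed RNG seed for the bootstrap.
#' @param modes USTAR threshold schemes to run (\code{"VUT"},
#'   \code{"CUT"}); defaults to VUT, plus CUT when the record exceeds
#'   two years.
#' @param partitioning run the NT/DT flux partitioning.
#' @param randunc compute the record-level random uncertainties (the
#'   slowest optional step).
#' @param resolutions coarse resolutions to aggregate to.
#' @return object of class \code{flux_pipeline}: a list of all
#'   intermediate and final products (see the vignette for the map).
#' @export
process_site <- function(site_table, metadata, reference = NULL,
                         n_boot = 100, seed = 1, modes = NULL,
                         partitioning = TRUE, randunc = TRUE,
                         resolutions = c("DD", "WW", "MM", "YY")) {
  step <- flux_step(site_table)
  axis <- site_table$TIMESTAMP_START
  years <- flux_years(site_table)
  out <- list(metadata = metadata, years = years, step = step)

  ## ---- QC ----------------------------------------------------------------
  rc <- apply_range_flags(site_table)
  tab <- rc$table
  if (!"SW_IN_POT" %in% names(tab) || all(is.na(tab$SW_IN_POT)))
    tab$SW_IN_POT <- potential_radiation(metadata, axis, step)
  sw_pot <- tab$SW_IN_POT
  night <- is_night(sw_pot)
  ppfd <- swin_from_ppfd(tab$SW_IN, tab$PPFD_IN)
  tab$SW_IN <- ppfd$sw_in
  if (!"VPD" %in% names(tab) || all(is.na(tab$VPD)))
    tab$VPD <- vpd_from_rh(tab$TA, tab$RH)
  out$qc <- list(range = rc$n_flagged, ppfd_factor = ppfd$factor)

  ## ---- NEE construction and despiking ------------------------------------
  nee_raw <- compute_nee(tab$FC, tab$SC, metadata, co2 = tab$CO2,
                         pa = tab$PA, ta = tab$TA, step = step)
  spike_flag <- despike_mad(nee_raw, sw_pot, axis, z = 5.5)
  nee <- ifelse(spike_flag == 2L, NA_real_, nee_raw)
  tab$NEE <- nee
  out$n_spikes <- sum(spike_flag == 2L)

  ## ---- meteorological products -------------------------------------------
  ds <- if (!is.null(reference))
    downscale_meteo(tab, reference, sw_pot) else list(series = list())
  out$auxmeteo <- ds$auxmeteo
  meteo <- list()
  for (v in c("TA", "VPD", "SW_IN", "PA", "WS", "P", "LW_IN", "CO2")) {
    if (!v %in% names(tab) || all(is.na(tab[[v]]))) next
    m <- mds_fill(tab[[v]], tab$SW_IN, tab$TA, tab$VPD, axis, step)
    fin <- merge_final_gapfill(m, ds$series[[v]])
    meteo[[v]] <- list(mds = m, value = fin$value, qc = fin$qc)
  }
  out$meteo <- meteo
  ta_f <- meteo$TA$value; vpd_f <- meteo$VPD$value
  sw_f <- meteo$SW_IN$value

  ## ---- USTAR thresholds ---------------------------------------------------
  uset <- bootstrap_thresholds(tab, sw_pot, n_boot = n_boot, seed = seed)
  out$ustar_set <- uset
  if (is.null(modes))
    modes <- if (length(years) > 2L) c("VUT", "CUT") else "VUT"
  modes <- intersect(c("VUT", "CUT"), modes)

  ## ---- per-mode NEE / partitioning products ------------------------------
  for (mode in modes) {
    pct <- extract_percentiles(uset, mode)
    out[[paste0("ustar_", tolower(mode))]] <- pct
    if (all(is.na(pct$thresholds))) next
    ens <- build_ensemble(nee, tab$USTAR, pct$thresholds, pct$ustar50,
                          sw_f, ta_f, vpd_f, axis, step)
    prods <- list(ensemble = ens,
                  mean = rowMeans(ens$members[, ens$usable, drop = FALSE]),
                  percentiles = ensemble_percentiles(
                    ens$members[, ens$usable, drop = FALSE]))
    ref_hh <- select_reference(ens$members, ens$usable)
    prods$ref_index <- c(HH = ref_hh)
    for (res in resolutions) {
      agg <- apply(ens$members, 2L, function(x)
        aggregate_series(x, axis, res, "average", step)$value)
      prods$ref_index[[res]] <- select_reference(agg, ens$usable)
    }
    prods$ref <- ens$members[, ref_hh]
    prods$ref_qc <- ens$qc[, ref_hh]
    if (randunc) {
      ru <- flux_randunc(prods$ref,
                         measured = !is.na(ens$qc[, ref_hh]) &
                           ens$qc[, ref_hh] == 0L,
                         sw_f, ta_f, vpd_f, axis, step,
                         window_days = 7, floor = 2)
      prods$randunc <- ru$randunc
      prods$randunc_method <- ru$method
      prods$jointunc <- joint_uncertainty(
        ru$randunc, prods$percentiles[, "84"], prods$percentiles[, "16"],
        denom = 2)
    }
    out[[paste0("nee_", tolower(mode))]] <- prods
    if (partitioning) {
      for (alg in c("NT", "DT")) {
        pp <- partition_products(ens, alg, ta_f, sw_f, vpd_f, night, axis)
        out[[paste0("partition_", tolower(alg), "_",
                    tolower(mode))]] <- pp
      }
    }
  }
  out$nee_ref <- out$nee_vut$ref

  ## ---- energy products ----------------------------------------------------
  h_m <- mds_fill(tab$H, tab$SW_IN, tab$TA, tab$VPD, axis, step)
  le_m <- mds_fill(tab$LE, tab$SW_IN, tab$TA, tab$VPD, axis, step)
  cfres <- ebc_cf_series(tab$NETRAD, tab$G, h_m$filled, le_m$filled,
                         h_m$qc, le_m$qc)
  corr <- corrected_fluxes(cfres$cf, h_m$filled, le_m$filled, axis, step)
  out$ebc <- list(cf = cfres$cf, cf_raw = cfres$cf_raw, corrected = corr,
                  h_f = h_m$filled, h_qc = h_m$qc,
                  le_f = le_m$filled, le_qc = le_m$qc)
  if (randunc) {
    for (v in c("H", "LE")) {
      m <- if (v == "H") h_m else le_m
      ru <- flux_randunc(m$filled, measured = m$qc == 0L, sw_f, ta_f,
                         vpd_f, axis, step, window_days = 5, floor = 10)
      out$ebc[[paste0(tolower(v), "_randunc")]] <- ru$randunc
      out$ebc[[paste0(tolower(v), "_jointunc")]] <- hle_jointunc(
        ru$randunc, corr[[v]]$corr25, corr[[v]]$corr75)
    }
  }

  ## ---- aggregated products ------------------------------------------------
  hh <- data.frame(TIMESTAMP_START = axis,
                   TIMESTAMP_END = axis + step * 60)
  hh$SW_IN_POT <- sw_pot
  for (v in names(meteo)) {
    hh[[paste0(v, "_F")]] <- meteo[[v]]$value
    hh[[paste0(v, "_F_QC")]] <- meteo[[v]]$qc
  }
  hh$USTAR <- tab$USTAR
  hh$NEE <- nee
  if (!is.null(out$nee_vut)) {
    hh$NEE_VUT_REF <- out$nee_vut$ref
    hh$NEE_VUT_REF_QC <- out$nee_vut$ref_qc
    hh$NEE_VUT_USTAR50 <- out$nee_vut$ensemble$ustar50_member
    hh$NEE_VUT_MEAN <- out$nee_vut$mean
    pctm <- out$nee_vut$percentiles
    for (cn in colnames(pctm)) hh[[paste0("NEE_VUT_", cn)]] <- pctm[, cn]
    if (!is.null(out$nee_vut$randunc)) {
      hh$NEE_VUT_REF_RANDUNC <- out$nee_vut$randunc
      hh$NEE_VUT_REF_JOINTUNC <- out$nee_vut$jointunc
    }
  }
  hh$H_F <- h_m$filled; hh$H_F_QC <- h_m$qc
  hh$LE_F <- le_m$filled; hh$LE_F_QC <- le_m$qc
  hh$EBC_CF <- cfres$cf
  hh$EBC_CF_METHOD <- as.numeric(corr$method)
  hh$H_CORR <- corr$H$corr; hh$H_CORR_25 <- corr$H$corr25
  hh$H_CORR_75 <- corr$H$corr75
  hh$LE_CORR <- corr$LE$corr; hh$LE_CORR_25 <- corr$LE$corr25
  hh$LE_CORR_75 <- corr$LE$corr75
  for (alg in c("nt", "dt")) {
    pp <- out[[paste0("partition_", alg, "_vut")]]
    if (is.null(pp) || is.null(pp$reco)) next
    hh[[sprintf("RECO_%s_VUT_REF", toupper(alg))]] <- pp$reco$ref
    hh[[sprintf("GPP_%s_VUT_REF", toupper(alg))]] <- pp$gpp$ref
    hh[[sprintf("RECO_%s_VUT_MEAN", toupper(alg))]] <- pp$reco$mean
    hh[[sprintf("GPP_%s_VUT_MEAN", toupper(alg))]] <- pp$gpp$mean
  }
  attr(hh, "step") <- step
  class(hh) <- c("flux_table", "data.frame")
  out$hh <- hh
  qc_cols <- list()
  for (v in grep("_F$", names(hh), value = TRUE))
    qc_cols[[v]] <- hh[[paste0(v, "_QC")]]
  if (!is.null(hh$NEE_VUT_REF))
    qc_cols$NEE_VUT_REF <- hh$NEE_VUT_REF_QC
  out$aggregated <- list()
  agg_vars <- setdiff(names(hh),
                      c("TIMESTAMP_START", "TIMESTAMP_END",
                        grep("_QC$|_METHOD$", names(hh), value = TRUE)))
  for (res in resolutions)
    out$aggregated[[res]] <- aggregate_table(hh, res, agg_vars, qc_cols)

  ## ---- AUXNEE -------------------------------------------------------------
  out$auxnee <- .build_auxnee(out, modes, resolutions)
  class(out) <- "flux_pipeline"
  out
}

.build_auxnee <- function(out, modes, resolutions) {
  rows <- list()
  add <- function(variable, parameter, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      VARIABLE = variable, PARAMETER = parameter, VALUE = value)
  sr <- out$ustar_set$success_run
  for (k in seq_along(out$ustar_set$years)) {
    add("USTAR_MP_METHOD", "SUCCESS_RUN", sr[k, "MP"])
    add("USTAR_CP_METHOD", "SUCCESS_RUN", sr[k, "CP"])
  }
  ranks <- ustar_percentile_ranks()
  for (mode in modes) {
    pct <- out[[paste0("ustar_", tolower(mode))]]
    if (is.null(pct)) next
    thr <- pct$thresholds
    if (is.matrix(thr)) thr <- rowMeans(thr, na.rm = TRUE)
    for (r in seq_along(ranks)) {
      add(paste0("NEE_", mode), "USTAR_PERCENTILE", ranks[r])
      add(paste0("NEE_", mode), "USTAR_THRESHOLD", thr[r])
    }
    add(paste0("NEE_USTAR50_", mode), "USTAR_THRESHOLD",
        mean(pct$ustar50, na.rm = TRUE))
    prods <- out[[paste0("nee_", tolower(mode))]]
    if (!is.null(prods)) {
      for (res in names(prods$ref_index)) {
        idx <- prods$ref_index[[res]]
        add(paste0("NEE_", mode, "_REF"),
            paste0(res, "_USTAR_PERCENTILE"), ranks[idx])
        add(paste0("NEE_", mode, "_REF"),
            paste0(res, "_USTAR_THRESHOLD"), thr[idx])
      }
    }
    for (alg in c("NT", "DT")) {
      pp <- out[[paste0("partition_", tolower(alg), "_",
                        tolower(mode))]]
      if (is.null(pp) || is.null(pp$reco)) next
      for (prod in c("RECO", "GPP")) {
        idx <- pp[[tolower(prod)]]$ref_index
        add(sprintf("%s_%s_%s_REF", prod, alg, mode),
            "USTAR_PERCENTILE", ranks[idx])
        add(sprintf("%s_%s_%s_REF", prod, alg, mode),
            "USTAR_THRESHOLD", thr[idx])
      }
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.flux_pipeline <- function(x, ...) {
  cat(sprintf("<flux_pipeline>  %s, years %s, %d records\n",
              x$metadata$site_id,
              paste(range(x$years), collapse = "-"), nrow(x$hh)))
  cat(sprintf("  spikes removed: %d; PPFD factor: %.3f\n",
              x$n_spikes, x$qc$ppfd_factor))
  if (!is.null(x$nee_vut))
    cat(sprintf("  NEE_VUT_REF member: percentile %.2f\n",
                ustar_percentile_ranks()[x$nee_vut$ref_index[["HH"]]]))
  invisible(x)
}
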