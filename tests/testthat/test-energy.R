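test_that("closure correction factors follow the defining ratio", {
  r <- ebc_cf_series(netrad = c(450, 300), g = c(50, 100),
                     h_f = c(80, 100), le_f = c(120, 100))
  expect_equal(r$cf_raw, c(2, 1))
  ## undefined when the turbulent fluxes cancel
  r2 <- ebc_cf_series(400, 50, 100, -100)
  expect_true(is.na(r2$cf_raw))
})

test_that("the IQR filter removes exactly the brute-force outlier set", {
  set.seed(61)
  n <- 500
  netrad <- runif(n, 300, 500); g <- runif(n, 20, 60)
  h <- runif(n, 50, 150); le <- runif(n, 80, 200)
  r <- ebc_cf_series(netrad, g, h, le)
  cf <- r$cf_raw
  q <- quantile(cf, c(0.25, 0.75), na.rm = TRUE)
  lim <- c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q))
  oracle_keep <- which(cf >= lim[1] & cf <= lim[2])
  expect_identical(which(!is.na(r$cf)), oracle_keep)
  expect_identical(r$n_removed, length(cf) - length(oracle_keep))
})

test_that("Method 1 pools percentiles; thin windows fall back to Method 2", {
  axis <- flux_time_axis(2014)[1:(48 * 40)]
  n <- length(axis)
  cf <- rep(NA_real_, n)
  band <- fluxproc:::.in_ebc_band(axis)
  ## exactly five factors of 2 near the centre record, inside the bands
  centre <- 48 * 20
  spots <- which(band & abs(seq_len(n) - centre) <= 15 * 48)[1:5]
  cf[spots] <- 2
  h <- rep(50, n); le <- rep(100, n)
  r <- corrected_fluxes(cf, h, le, axis)
  expect_identical(r$method[centre], 1L)
  expect_equal(r$H$corr[centre], 100)
  expect_equal(r$H$corr25[centre], 100)
  expect_equal(r$H$corr75[centre], 100)
  ## Bowen ratio preserved under the shared factor
  expect_equal(r$H$corr[centre] / r$LE$corr[centre], 50 / 100)
  ## with four factors, Method 2 and no percentile variants
  cf2 <- rep(NA_real_, n)
  cf2[spots[1:4]] <- 2
  r2 <- corrected_fluxes(cf2, h, le, axis)
  far <- which(r2$method == 1L)
  expect_length(far, 0L)
  m2 <- which(r2$method == 2L)
  expect_true(all(is.na(r2$H$corr25[m2])))
  expect_true(all(!is.na(r2$H$corr[m2])))
})

test_that("Method-1 percentiles equal a sort-based oracle", {
  axis <- flux_time_axis(2014)[1:(48 * 40)]
  n <- length(axis)
  set.seed(62)
  cf <- rep(NA_real_, n)
  band <- fluxproc:::.in_ebc_band(axis)
  cf[band] <- rnorm(sum(band), 1.3, 0.2)
  h <- rep(80, n); le <- rep(120, n)
  r <- corrected_fluxes(cf, h, le, axis)
  i <- 48 * 20
  j <- max(1, i - 15 * 48):min(n, i + 15 * 48)
  pool <- cf[j][band[j] & !is.na(cf[j])]
  oracle <- quantile(80 * pool, c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(c(r$H$corr25[i], r$H$corr[i], r$H$corr75[i]), oracle,
               tolerance = 1e-12)
})

test_that("H/LE joint uncertainty has its closed forms", {
  expect_equal(hle_jointunc(3, 0, 1.349), sqrt(10))
  expect_equal(hle_jointunc(0, 0, 2.698), 2)
  ## percentiles absent: joint equals random
  expect_equal(hle_jointunc(3, NA, NA), 3)
  set.seed(63)
  r <- runif(10, 1, 3); lo <- runif(10); hi <- lo + runif(10)
  expect_equal(hle_jointunc(r, lo, hi),
               sqrt(r^2 + ((hi - lo) / 1.349)^2), tolerance = 1e-12)
})

test_that("the imposed closure gap is recovered from synthetic data", {
  site <- cached_site("ebc_site", years = 1, gap_fraction = 0.05,
                      seed = 23)
  tab <- site$table
  h_m <- mds_fill(tab$H, tab$SW_IN, tab$TA, tab$VPD, tab$TIMESTAMP_START)
  le_m <- mds_fill(tab$LE, tab$SW_IN, tab$TA, tab$VPD,
                   tab$TIMESTAMP_START)
  r <- ebc_cf_series(tab$NETRAD, tab$G, h_m$filled, le_m$filled,
                     h_m$qc, le_m$qc)
  alpha <- site$truth$closure_gap
  expect_lt(abs(median(r$cf, na.rm = TRUE) - alpha) / alpha, 0.05)
  ## Bowen-ratio preservation through the correction
  corr <- corrected_fluxes(r$cf, h_m$filled, le_m$filled,
                           tab$TIMESTAMP_START)
  both <- which(!is.na(corr$H$corr) & !is.na(corr$LE$corr) &
                  abs(le_m$filled) > 20)
  expect_all_equal(corr$H$corr[both] / corr$LE$corr[both],
                   h_m$filled[both] / le_m$filled[both], tol = 1e-9)
})

test_that("coarse-resolution correction applies coverage and windows", {
  ## 30 daily periods, closure factor 1.25, full coverage
  period <- rep(1:30, each = 48)
  n <- length(period)
  netrad <- rep(400, n); g <- rep(40, n)
  h <- rep(120, n); le <- rep(168, n)     # (400-40)/(120+168) = 1.25
  eligible <- rep(TRUE, n)
  r <- corrected_fluxes_coarse(period, netrad, g, h, le, eligible,
                               h_agg = rep(120, 30), le_agg = rep(168, 30))
  expect_all_equal(r$cf, 1.25, tol = 1e-12)
  expect_all_equal(r$H$corr, 150, tol = 1e-9)
  expect_all_equal(r$H$corr25, 150, tol = 1e-9)
  ## low coverage disqualifies the period
  eligible[period == 5] <- FALSE
  r2 <- corrected_fluxes_coarse(period, netrad, g, h, le, eligible,
                                h_agg = rep(120, 30),
                                le_agg = rep(168, 30))
  expect_true(is.na(r2$cf[5]))
})
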