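test_that("NEE is the sum of turbulent and storage fluxes", {
  meta_short <- site_metadata("XX-Sht", 45, 8, 1, analyzer_height = 2,
                              canopy_class = "short")
  expect_equal(compute_nee(-5, 1, meta_short), -4)
  ## short canopy, missing storage: SC = 0
  expect_equal(compute_nee(c(-5, 2), c(NA, NA), meta_short), c(-5, 2))
  ## tall tower, constant concentration: discrete storage is zero
  meta_tall <- site_metadata("XX-Tll", 45, 8, 1, analyzer_height = 30,
                             canopy_class = "tall")
  nee <- compute_nee(rep(1, 5), rep(NA_real_, 5), meta_tall,
                     co2 = rep(400, 5), pa = rep(100, 5), ta = rep(15, 5))
  expect_equal(nee[2:4], rep(1, 3))
  ## tall tower, no SC and no CO2: missing
  expect_true(all(is.na(compute_nee(rep(1, 3), rep(NA_real_, 3),
                                    meta_tall))))
  ## rising concentration gives positive storage of the expected size
  co2 <- 400 + 0.5 * (0:4)            # umol/mol per half hour
  nee2 <- compute_nee(rep(0, 5), rep(NA_real_, 5), meta_tall, co2 = co2,
                      pa = rep(100, 5), ta = rep(15, 5))
  oracle <- (0.5 / 1800) * (100 * 1000) * 30 / (8.314 * 288.15)
  expect_equal(nee2[3], oracle, tolerance = 1e-12)
})

test_that("Nash-Sutcliffe efficiency has its textbook fixed points", {
  set.seed(51)
  obs <- rnorm(100, 2, 3)
  expect_equal(nash_sutcliffe(obs, obs), 1)
  expect_equal(nash_sutcliffe(rep(mean(obs), 100), obs), 0)
  sim <- obs + rnorm(100, 0, 1)
  oracle <- 1 - sum((sim - obs)^2) / sum((obs - mean(obs))^2)
  expect_equal(nash_sutcliffe(sim, obs), oracle, tolerance = 1e-12)
  expect_true(is.na(nash_sutcliffe(1:5, rep(2, 5))))   # zero variance
})

test_that("reference selection equals the exhaustive pairwise table", {
  set.seed(52)
  base <- rnorm(300)
  members <- sapply(1:5, function(i) base + rnorm(300, 0, 0.2 * i))
  got <- select_reference(members)
  me_sum <- sapply(1:5, function(i)
    sum(sapply(setdiff(1:5, i), function(j)
      nash_sutcliffe(members[, i], members[, j]))))
  expect_identical(got, which.max(me_sum))
  ## an outlier member cannot win against 39 near-identical ones
  members2 <- cbind(sapply(1:9, function(i) base + rnorm(300, 0, 0.01)),
                    base + 50)
  expect_lt(select_reference(members2), 10L)
})

test_that("ensemble percentiles match a per-record sort oracle", {
  set.seed(53)
  m <- matrix(rnorm(50 * 40), 50, 40)
  p <- ensemble_percentiles(m)
  for (i in c(1, 25, 50)) {
    oracle <- quantile(m[i, ], c(5, 16, 25, 50, 75, 84, 95) / 100,
                       names = FALSE, type = 7)
    expect_equal(unname(p[i, ]), oracle, tolerance = 1e-12)
  }
  ## ordering invariant per record
  expect_true(all(p[, "05"] <= p[, "16"] & p[, "16"] <= p[, "50"] &
                    p[, "50"] <= p[, "84"] & p[, "84"] <= p[, "95"]))
})

test_that("identical thresholds give identical members and zero spread", {
  site <- cached_site("ens_small", years = 1, gap_fraction = 0.03,
                      seed = 19)
  tab <- site$table
  idx <- 1:(48 * 40)                       # 40 days
  ts <- tab$TIMESTAMP_START[idx]
  nee <- compute_nee(tab$FC, tab$SC, site$metadata)[idx]
  thr <- rep(0.25, 5)
  ens <- build_ensemble(nee, tab$USTAR[idx], thr, 0.25,
                        site$truth$sw_in_pot[idx] * 0.8, tab$TA[idx],
                        tab$VPD[idx], ts)
  expect_identical(ncol(ens$members), 5L)
  for (p in 2:5) expect_identical(ens$members[, p], ens$members[, 1])
  pct <- ensemble_percentiles(ens$members)
  expect_all_equal(pct[, "95"] - pct[, "05"], 0, tol = 1e-12)
  ## filtering+filling never changes measured above-threshold records
  us <- tab$USTAR[idx]
  prev_low <- c(FALSE, !is.na(us[-length(us)]) & us[-length(us)] < 0.25)
  keep <- which(!is.na(nee) & !is.na(us) & us >= 0.25 & !prev_low)
  expect_identical(ens$members[keep, 1], nee[keep])
  expect_true(all(ens$qc[keep, 1] == 0L))
})

test_that("random uncertainty follows the two-method hierarchy", {
  ## build a 15-day axis with a deterministic diurnal flux
  axis <- flux_time_axis(2014)[1:(48 * 15)]
  n <- length(axis)
  hour <- as.integer(format(axis, "%H"))
  flux <- rep(5, n)
  sw <- rep(400, n); ta <- rep(15, n); vpd <- rep(8, n)
  measured <- rep(TRUE, n)
  r <- flux_randunc(flux, measured, sw, ta, vpd, axis, floor = 2)
  ## identical matched fluxes: Method-1 uncertainty 0
  expect_equal(unique(r$method[!is.na(r$method)]), 1L)
  expect_all_equal(r$randunc, 0, tol = 1e-12)
  ## method-1 value equals a brute-force windowed stdev oracle
  set.seed(54)
  flux2 <- rnorm(n, 5, 2)
  r2 <- flux_randunc(flux2, measured, sw, ta, vpd, axis, floor = 2)
  i <- 400
  j <- i + as.vector(outer(seq(-7, 7) * 48, -2:2, "+"))
  j <- j[j >= 1 & j <= n & j != i]
  expect_equal(r2$randunc[i], sd(flux2[j]), tolerance = 1e-12)
  ## starve Method 1 (fewer than five measured values) -> Method 2
  measured3 <- rep(FALSE, n)
  measured3[c(300, 348, 396)] <- TRUE        # three matched records only
  flux3 <- rep(5, n)
  r3 <- flux_randunc(flux3, measured3, sw, ta, vpd, axis, floor = 2)
  expect_false(any(r3$method == 1L, na.rm = TRUE))
})

test_that("joint uncertainty reduces to its closed forms", {
  expect_equal(joint_uncertainty(0, 4, 0, denom = 2), 2)
  expect_equal(joint_uncertainty(3, 0, 0, denom = 2), 3)
  expect_equal(joint_uncertainty(3, 8, 0, denom = 2), 5)   # 3-4-5
  set.seed(55)
  r <- runif(20); u <- runif(20, 1, 2); l <- -runif(20)
  expect_equal(joint_uncertainty(r, u, l, 2),
               sqrt(r^2 + ((u - l) / 2)^2), tolerance = 1e-12)
  expect_true(is.na(joint_uncertainty(NA, 1, 0, 2)))
})
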