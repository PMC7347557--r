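test_that("night classes are equal-count with group-mean oracle", {
  set.seed(31)
  n <- 5600
  ta <- runif(n, -5, 25)
  us <- rlnorm(n, -1.2, 0.6)
  nee <- 2 + 0.5 * ta / 10 + rnorm(n)
  season <- rep(1L, n)
  g <- build_night_classes(nee, us, ta, season)
  expect_length(g, 7L)                       # 7 temp classes, one season
  ## each temp class holds 800 records -> 20 USTAR classes of 40
  expect_true(all(vapply(g, function(x) length(x$ustar_mean), 0L) == 20L))
  ## brute-force group-by oracle for one group
  tbin <- fluxproc:::.equal_count_bins(ta, 7)
  g1 <- which(tbin == 1L)
  expect_length(g1, 800L)
  ubin <- fluxproc:::.equal_count_bins(us[g1], 20)
  oracle_nee <- as.numeric(tapply(nee[g1], ubin, mean))
  k <- which(vapply(g, function(x) x$temp_class, 0L) == 1L)
  expect_equal(g[[k]]$nee_mean, oracle_nee, tolerance = 1e-12)
  ## USTAR class means are increasing by construction
  expect_true(all(diff(g[[k]]$ustar_mean) > 0))
})

## Brute-force evaluation of the plateau criterion over all classes
mp_oracle <- function(nee, us, ratio = 0.99) {
  n <- length(nee)
  for (x in seq_len(n - 10)) {
    c1 <- nee[x] > ratio * mean(nee[(x + 1):(x + 10)])
    if (!c1) next
    if (x + 11 <= n) {
      c2 <- nee[x + 1] > ratio * mean(nee[(x + 2):(x + 11)])
      if (!c2) next
    }
    return(us[x])
  }
  NA_real_
}

test_that("moving-point threshold matches the exhaustive criterion scan", {
  ## flat series: plateau from the start
  flat <- two_regime_classes(threshold = 0, plateau = 2)
  expect_equal(mp_threshold(flat$nee_mean, flat$ustar_mean),
               flat$ustar_mean[1])
  ## ramp to a plateau
  f <- two_regime_classes(threshold = 0.3, plateau = 3, slope = 10)
  expect_equal(mp_threshold(f$nee_mean, f$ustar_mean),
               mp_oracle(f$nee_mean, f$ustar_mean))
  ## noisy cases, many seeds: always equal to the oracle
  for (s in 1:25) {
    f <- two_regime_classes(noise_sd = 0.3, seed = s)
    expect_identical(mp_threshold(f$nee_mean, f$ustar_mean),
                     mp_oracle(f$nee_mean, f$ustar_mean))
  }
  expect_true(is.na(mp_threshold(1:5, 1:5)))   # fewer than 11 classes
})

test_that("a single-class violation is rejected and the search continues", {
  f <- two_regime_classes(threshold = 0.3, plateau = 3, slope = 10)
  y <- f$nee_mean
  ## poke a false plateau at class 3: passes the first condition only
  y[3] <- 3.2
  got <- mp_threshold(y, f$ustar_mean)
  expect_gt(got, f$ustar_mean[3])
  expect_identical(got, mp_oracle(y, f$ustar_mean))
})

test_that("change-point threshold finds exact two-segment structure", {
  f <- two_regime_classes(threshold = 0.3, plateau = 3, slope = 10)
  thr <- cp_threshold(f$nee_mean, f$ustar_mean)
  ## grid-search SSE oracle over all candidate change points
  oracle <- {
    u <- f$ustar_mean; y <- f$nee_mean
    sses <- sapply(2:(length(u) - 1), function(c) {
      x <- pmin(u - u[c], 0)
      sum(resid(lm(y ~ x))^2)
    })
    u[(2:(length(u) - 1))[which.min(sses)]]
  }
  expect_equal(thr, oracle, tolerance = 1e-12)
  expect_lt(abs(thr - 0.3), diff(f$ustar_mean)[1] + 1e-9)
})

test_that("change-point declines flat and structure-free data", {
  flat <- list(ustar_mean = seq(0.05, 0.8, length.out = 20),
               nee_mean = rep(2, 20))
  expect_true(is.na(cp_threshold(flat$nee_mean, flat$ustar_mean)))
  set.seed(40)
  declines <- sum(vapply(1:20, function(i) {
    is.na(cp_threshold(rnorm(20), seq(0.05, 0.8, length.out = 20)))
  }, TRUE))
  expect_gt(declines, 14)        # pure noise rarely shows a change point
})

test_that("MP and CP agree on noiseless two-regime class means", {
  f <- two_regime_classes(threshold = 0.3, plateau = 3, slope = 10)
  mp <- mp_threshold(f$nee_mean, f$ustar_mean)
  cp <- cp_threshold(f$nee_mean, f$ustar_mean)
  width <- mean(diff(f$ustar_mean))
  expect_lt(abs(mp - cp), 2 * width)
})

test_that("the low-turbulence filter follows the recovery rule", {
  us <- c(0.3, 0.1, 0.1, 0.4, 0.5)
  nee <- 1:5
  out <- apply_ustar_filter(nee, us, 0.2)
  expect_identical(which(is.na(out)), 2:4)   # 4 = first recovery record
  ## threshold 0: only missing-USTAR records affected
  us2 <- c(0.3, NA, 0.2)
  expect_identical(which(is.na(apply_ustar_filter(1:3, us2, 0))), 2L)
  ## all above: untouched
  expect_identical(apply_ustar_filter(nee, rep(1, 5), 0.2),
                   as.numeric(1:5))
})

test_that("a higher threshold masks a superset of records", {
  set.seed(41)
  us <- rlnorm(2000, -1.2, 0.5)
  nee <- rnorm(2000)
  m1 <- which(is.na(apply_ustar_filter(nee, us, 0.15)))
  m2 <- which(is.na(apply_ustar_filter(nee, us, 0.30)))
  expect_true(all(m1 %in% m2))
})

test_that("percentile extraction is a sort-and-interpolate with 40 ranks", {
  ranks <- ustar_percentile_ranks()
  expect_length(ranks, 40L)
  expect_equal(ranks[1], 1.25)
  expect_equal(ranks[40], 98.75)
  expect_equal(unique(round(diff(ranks), 10)), 2.5)
  ## degenerate pool
  set <- list(years = 2010L,
              mp = matrix(0.1, 1, 100), cp = matrix(0.1, 1, 100),
              success_run = matrix(1L, 1, 2))
  p <- extract_percentiles(set, "VUT")
  expect_all_equal(p$thresholds[, 1], 0.1, tol = 1e-12)
  ## uniform pool vs interpolation oracle
  set2 <- list(years = 2010L,
               mp = matrix(1:100, 1), cp = matrix(101:200, 1),
               success_run = matrix(1L, 1, 2))
  p2 <- extract_percentiles(set2, "VUT")
  oracle <- quantile(1:200, ranks / 100, names = FALSE, type = 7)
  expect_equal(p2$thresholds[, 1], oracle, tolerance = 1e-12)
})

test_that("CUT pools all years; VUT pools adjacent years only", {
  set <- list(years = 2010:2013,
              mp = matrix(rep(c(0.1, 0.2, 0.3, 0.4), 10), 4),
              cp = matrix(rep(c(0.1, 0.2, 0.3, 0.4), 10), 4),
              success_run = matrix(1L, 4, 2))
  cut <- extract_percentiles(set, "CUT")
  expect_equal(cut$ustar50, median(c(0.1, 0.2, 0.3, 0.4)))
  ## CUT invariant to year ordering
  setr <- set
  perm <- c(3, 1, 4, 2)
  setr$mp <- set$mp[perm, ]; setr$cp <- set$cp[perm, ]
  setr$years <- set$years[perm]
  expect_equal(extract_percentiles(setr, "CUT")$thresholds,
               cut$thresholds)
  ## VUT for 2011 pools 2010-2012 exactly
  vut <- extract_percentiles(set, "VUT")
  oracle <- quantile(rep(c(0.1, 0.2, 0.3), 20),
                     ustar_percentile_ranks() / 100,
                     names = FALSE, type = 7)
  expect_equal(vut$thresholds[, 2], oracle, tolerance = 1e-12)
})

test_that("bootstrap is reproducible and recovers the imposed threshold", {
  site <- clean_year()
  tab <- site$table
  tab$NEE <- compute_nee(tab$FC, tab$SC, site$metadata)
  a <- bootstrap_thresholds(tab, tab$SW_IN_POT, n_boot = 8, seed = 99)
  b <- bootstrap_thresholds(tab, tab$SW_IN_POT, n_boot = 8, seed = 99)
  expect_identical(a$mp, b$mp)
  expect_identical(a$cp, b$cp)
  expect_identical(a$success_run, matrix(1L, 1, 2,
                                         dimnames = list("2010",
                                                         c("MP", "CP"))))
  ## pooled median near the generative cutoff (one class width ~ 0.05)
  pool <- c(a$mp, a$cp)
  expect_lt(abs(median(pool, na.rm = TRUE) - site$truth$ustar_threshold),
            0.06)
})
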