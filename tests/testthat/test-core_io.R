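test_that("timestamps parse, render and round-trip at every resolution", {
  t <- parse_flux_timestamp("199201010000")
  expect_s3_class(t, "POSIXct")
  expect_identical(format_flux_timestamp(t, "HH"), "199201010000")
  for (pair in list(c("202001", "MM"), c("20200115", "DD"),
                    c("2020", "YY"), c("202007081330", "HH"))) {
    expect_identical(
      format_flux_timestamp(parse_flux_timestamp(pair[1], pair[2]),
                            pair[2]),
      pair[1])
  }
  expect_error(parse_flux_timestamp("2020-01-01", "HH"), "malformed")
  expect_error(parse_flux_timestamp("202001", "HH"), "malformed")
  expect_error(parse_flux_timestamp("202013", "MM"), "invalid")
})

test_that("time axis has the correct yearly record counts", {
  expect_length(flux_time_axis(2014), 17520)       # normal year, HH
  expect_length(flux_time_axis(2012), 17568)       # leap year, HH
  expect_length(flux_time_axis(2014, step = 60), 8760)
  expect_length(flux_time_axis(2010, 2011), 2 * 17520)
})

test_that("site metadata validates its fields", {
  m <- site_metadata("US-Ha1", 42.5378, -72.1715, -5, 30, "DBF", "tall")
  expect_identical(m$site_id, "US-Ha1")
  expect_error(site_metadata("USHa1", 42, -72), "CC-SSS")
  expect_error(site_metadata("US-Ha1", 95, 0))
})

test_that("missing rows are restored and -9999 becomes NA on read", {
  axis <- flux_time_axis(2014)[1:200]
  set.seed(1)
  tab <- flux_table(axis, list(FC = rnorm(200), TA = rnorm(200, 10)))
  tab$FC[5] <- NA
  dir <- withr::local_tempdir()
  meta <- site_metadata("XX-Tst", 45, 8, 1)
  fn <- write_product(tab, meta, "FULLSET", "HH", dir)
  txt <- readLines(file.path(dir, fn))
  expect_true(any(grepl(",-9999,", txt[6])))       # row 5 data line
  ## drop some rows and re-read: reinserted as all-missing
  keep <- setdiff(seq_len(200), c(10, 11, 50))
  writeLines(txt[c(1L, keep + 1L)], file.path(dir, "gappy.csv"))
  rt <- read_fluxnet_csv(file.path(dir, "gappy.csv"))
  expect_identical(nrow(rt), 200L)
  expect_true(all(is.na(rt$FC[c(10, 11, 50)])))
  expect_true(all(is.na(rt$TA[c(10, 11, 50)])))
  ## brute-force reindex oracle: non-deleted rows keep their values
  expect_all_equal(rt$TA[keep], tab$TA[keep], tol = 1e-5)
  expect_true(is.na(rt$FC[5]))
})

test_that("column order does not matter, labels do", {
  axis <- flux_time_axis(2014)[1:10]
  dir <- withr::local_tempdir()
  a <- file.path(dir, "a.csv"); b <- file.path(dir, "b.csv")
  ts <- format_flux_timestamp(axis)
  te <- format_flux_timestamp(axis + 1800)
  writeLines(c("TIMESTAMP_START,TIMESTAMP_END,FC,TA",
               paste(ts, te, 1:10, 21:30, sep = ",")), a)
  writeLines(c("TIMESTAMP_START,TIMESTAMP_END,TA,FC",
               paste(ts, te, 21:30, 1:10, sep = ",")), b)
  ta <- read_fluxnet_csv(a); tb <- read_fluxnet_csv(b)
  expect_identical(ta$FC, tb$FC)
  expect_identical(ta$TA, tb$TA)
})

test_that("read-write-read is idempotent (bit-identical second pass)", {
  site <- cached_site("io_small", years = 1, seed = 5)
  tab <- site$table[1:500, ]
  attr(tab, "step") <- 30
  class(tab) <- c("flux_table", "data.frame")
  dir <- withr::local_tempdir()
  meta <- site$metadata
  f1 <- write_product(tab, meta, "FULLSET", "HH", dir)
  r1 <- read_fluxnet_csv(file.path(dir, f1))
  dir2 <- withr::local_tempdir()
  f2 <- write_product(r1, meta, "FULLSET", "HH", dir2)
  r2 <- read_fluxnet_csv(file.path(dir2, f2))
  f3 <- write_product(r2, meta, "FULLSET", "HH", dir)
  expect_identical(readLines(file.path(dir2, f2)),
                   readLines(file.path(dir, f3)))
})

test_that("numeric codec truncates toward zero at the printed precision", {
  expect_identical(fluxproc:::.format_flux_number(0.123456789123),
                   "0.123456789")
  expect_identical(fluxproc:::.format_flux_number(123.9999999), "123.99999")
  expect_identical(fluxproc:::.format_flux_number(-0.9999999999),
                   "-0.999999999")
  expect_identical(fluxproc:::.format_flux_number(NA_real_), "-9999")
  expect_identical(fluxproc:::.format_flux_number(5), "5")
  expect_identical(fluxproc:::.format_flux_number(0), "0")
})

test_that("product file names follow the naming template", {
  expect_identical(
    product_filename("US-Ha1", "FULLSET", "HH", 1992, 2012, 1, 3),
    "FLX_US-Ha1_FLUXNET2015_FULLSET_HH_1992-2012_1-3.csv")
  expect_identical(
    product_filename("US-Ha1", "AUXNEE", NULL, 1992, 2012, 1, 3),
    "FLX_US-Ha1_FLUXNET2015_AUXNEE_1992-2012_1-3.csv")
  expect_error(product_filename("US-Ha1", "BOGUS", "HH", 2000, 2001))
})
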