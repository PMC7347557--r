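# Shared fixtures, generated once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

cached_site <- function(key, ...) {
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_site(synth_config(...))
  .fixtures[[key]]
}

# one clean year: low noise, few gaps, no spikes -- used by the USTAR and
# despiking tests
clean_year <- function()
  cached_site("clean_year", years = 1, gap_fraction = 0.02, spike_rate = 0,
              nee_noise_sd = 0.5, seed = 3)

# the canonical two-year site under default study conditions
default_site <- function() cached_site("default_site", years = 2, seed = 42)

# class-mean fixture with a rising lower regime and a flat plateau,
# optionally exact (no noise)
two_regime_classes <- function(threshold = 0.3, plateau = 3, slope = 10,
                               n = 20, noise_sd = 0, seed = 1) {
  set.seed(seed)
  u <- seq(0.05, 0.8, length.out = n)
  y <- ifelse(u <= threshold, slope * u, plateau) +
    stats::rnorm(n, 0, noise_sd)
  list(ustar_mean = u, nee_mean = y)
}

expect_all_equal <- function(x, y, tol = 1e-12)
  expect_true(all(abs(x - y) < tol, na.rm = TRUE))
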