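---
title: "Processing eddy-covariance tower data with fluxproc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing eddy-covariance tower data with fluxproc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fluxproc` post-processes half-hourly (or hourly) eddy-covariance tower
records into standardized flux and meteorological data products: quality
control, gap-filling, low-turbulence filtering with bootstrap
uncertainty, energy-balance-corrected heat fluxes, partitioning of the
net CO2 flux into respiration and photosynthesis, and multi-resolution
aggregation. This vignette explains the scientific procedure each module
implements, the tunable parameters and their defaults, the numerical
choices made where the published methods leave the details open, and
what the synthetic-site validation can and cannot show.

## The data model

All processing operates on a `flux_table`: a regular half-hourly axis in
local standard time (never daylight-saving time), with `TIMESTAMP_START`
and `TIMESTAMP_END` columns and numeric variables named by the standard
basenames (FC, SC, H, LE, USTAR, TA, RH, PA, SW_IN, PPFD_IN, P, LW_IN,
NETRAD, G, CO2, SWC, TS). Missing values are plain `NA` internally; the
`-9999` sentinel exists only at the file boundary, which prevents
sentinel values from ever leaking into arithmetic. On output, numbers of
magnitude below one are truncated (toward zero, as distributed files do)
at nine decimals and larger numbers at five, and files are named by the
`FLX_[SITE]_FLUXNET2015_[PRODUCT]_[RESOLUTION]_[YEARS]_[VERSIONS]`
template. Hourly sites are handled by `step = 60`; every window used by
the algorithms below is defined in physical time (days, hours), not in
record counts, so both resolutions run through identical code.

Weekly aggregation uses 7-day periods anchored at January 1 with the
final period absorbing the remaining one or two days; weekly rows carry
a start/end timestamp pair since a 7-day period is not self-describing
from a single timestamp.

## Quality control

Range controls (`apply_range_flags()`) mask physically impossible
values; the default limits (RH in 0-100 %, SWC in 0-100 %, USTAR at or
above 0, PA in a plausible band, and so on) are a configurable list.

Spike detection (`despike_mad()`) uses the double-differenced statistic
$d_i = (x_i - x_{i-1}) - (x_{i+1} - x_i)$, computed within 13-day blocks
separately for day and night, and flags records whose $d_i$ deviates
from the block median by more than $z \cdot MAD / 0.6745$ with
$z = 5.5$. Two details are our own: when the MAD is zero the limit
degenerates to "any deviation", which keeps constant series unflagged
while still catching an isolated spike in an otherwise clean series; and
because one spike perturbs the neighbouring double differences as well,
only the local extremum of $|d_i - Md|$ within a run of candidates is
flagged. Day and night are split at potential radiation above
12 W m^-2^ -- this cutoff also defines "nighttime" for the USTAR and
partitioning steps, where the published descriptions say nighttime
without a number.

Potential top-of-atmosphere radiation (`potential_radiation()`) uses the
Spencer Fourier-series ephemeris (declination, eccentricity, equation of
time) evaluated at 1-minute sub-steps and averaged per record, so values
are period averages rather than instantaneous samples; the annual
maximum stays below the solar constant times the maximum eccentricity
factor (about 1450 W m^-2^).

Incoming shortwave is reconstructed from photon flux density where
missing: the conversion factor is the zero-intercept regression slope
over overlapping valid pairs, or the standard 0.48 J per micromole of
photons when the two sensors never ran in parallel.

## Gap-filling

`mds_fill()` implements marginal distribution sampling: a gap is filled
with the mean of records measured under similar meteorological
conditions (|dSW_IN| <= 50 W m^-2^, or 20 when the gap's SW_IN is below
50 W m^-2^; |dTA| <= 2.5 degC; |dVPD| <= 5 hPa) in the smallest window
that contains at least one candidate. Three scenarios apply, depending
on which drivers exist at the gap: all three, only SW_IN, or none (mean
diurnal course, records within one hour of the same time of day). The
window schedule and quality classes are code-defined in the reference
implementations rather than printed; ours, configurable, is: scenario
(i) at +-7 or +-14 days gives quality 1 (high confidence); scenario (i)
at +-21/28 days or scenario (ii) at +-7/14 days gives 2; everything
larger, and every diurnal-course fill, gives 3. Measured records are
never altered (flag 0).

When a coarse reference meteorological series is available (a reanalysis
product in production use; any coarse series here), `fit_debias()`
regresses the tower measurement on the reference aligned to the tower
axis, and `downscale_series()` applies the fitted line to the whole
reference record, clipped to physical bounds (precipitation at or above
zero, shortwave between zero and the potential ceiling). State variables
are interpolated to record centres, preserving the diurnal cycle;
precipitation totals are split across the covered records. The fit
statistics (slope, intercept, RMSE, correlation) form the AUXMETEO
parameters; a correlation below 0.5 triggers a warning, our reduction of
the published mismatch diagnostics to a single check. The final
gap-filled product (`merge_final_gapfill()`) keeps measured records and
high-quality MDS fills (flag < 2) and takes the downscaled value
elsewhere with final flag 2 -- so no final record carries flag 3, and the
series is gap-free whenever a reference exists. Seven variables are
downscaled: TA, PA, VPD, WS, P, SW_IN, LW_IN. CO2 concentration has no
reference companion and keeps its MDS fill.

## USTAR threshold estimation

Under weak turbulence, nighttime fluxes are underestimated because part
of the transport escapes both the eddy system and the storage profile.
The remedy is to discard records below a site-specific friction-velocity
threshold. One year of nighttime data is divided into four three-month
seasons (calendar quarters anchored at January), each season into 7
equal-count temperature classes, and each season-temperature group into
20 equal-count USTAR classes; the group contributes its class means of
NEE and USTAR. A group is discarded when |cor(TA, USTAR)| > 0.4 within
it (temperature-turbulence confounding guard, as in the cited methods)
or when it has fewer than 20 records.

Two detectors run on each group's class means:

* **MP (moving point)**: the first class whose mean NEE exceeds 99 % of
  the mean of the ten classes above it, confirmed at the next class as
  well; the threshold is the mean USTAR of the selected class.
* **CP (change point)**: two linear regressions between NEE and USTAR --
  a free-slope segment below the candidate change point and a zero-slope
  segment above it, meeting at the change point. Given the candidate
  abscissa the model is linear, so each candidate is solved by ordinary
  least squares and the minimum-SSE candidate wins. The two-segment
  model must beat a single straight line in an F-test at alpha = 0.05
  (our choice of significance rule, where the published description
  defers to the change-point literature) and the lower segment must
  rise; otherwise no clear change point exists and the run records a
  failure.

Per method and year, season values are the median over temperature
classes and the year's threshold is the maximum over seasons; we require
at least two seasons with a valid median, else the replicate fails (the
published text is silent here). Each year is bootstrapped 100 times
(resampling records with replacement), giving up to 200 thresholds per
year across the two methods. From the pooled thresholds, 40
representative values are extracted at percentile ranks 1.25, 3.75, ...,
98.75: per year with the neighbouring years pooled (VUT, variable
threshold) and across all years at once (CUT, constant threshold; only
produced for records longer than two years, since below that both
schemes coincide). The pool median is the USTAR50 threshold.

Filtering (`apply_ustar_filter()`) masks NEE -- daytime and nighttime
alike -- where USTAR is below the threshold or missing, plus the first
high-turbulence record after a low-turbulence run (a venting-burst
guard). H and LE are never USTAR-filtered.

## NEE products

NEE = FC + SC. With SC missing, short canopies measured below 3 m assume
zero storage; taller towers use a discrete one-point estimate
$SC = (d[CO_2]/dt) \, P h / (R T)$ from the top CO2 concentration, the
ideal-gas molar density, and the analyzer height (our formula choice for
the cited discrete approach).

Each of the 40 thresholds yields one ensemble member: despiked NEE,
filtered, then MDS-filled with the gap-filled SW_IN/TA/VPD drivers.
Per-record percentiles (05/16/25/50/75/84/95), the member mean (MEAN),
the member filtered at the pool median (USTAR50), and a reference member
(REF) summarize the ensemble. REF is the member with the highest sum of
Nash-Sutcliffe efficiencies against the other 39 -- the most typical
member -- selected independently per temporal resolution, with ties
broken toward the lowest percentile rank. Members with more than 95 %
of records masked are excluded from REF selection. The efficiency sums
are computed over all records of the gap-free members (measured and
filled alike); this is a documented choice, flagged for sensitivity
testing.

Random uncertainty follows the two-method hierarchy: the standard
deviation of measured fluxes within +-7 days and +-1 hour under similar
meteorological conditions (at least five values), else the median of
those uncertainties among similar-magnitude fluxes (within +-20 %, with
a 2 umol CO2 m^-2^ s^-1^ floor) within +-5 days. Joint uncertainty
combines random uncertainty with the ensemble spread,
$\sqrt{RANDUNC^2 + ((NEE_{84} - NEE_{16})/2)^2}$, the 16th/84th
percentiles bracketing one standard deviation under normality.

## Energy balance correction

The closure factor $EBC\_CF = (NETRAD - G)/(H + LE)$ is computed where
net radiation and ground heat flux are measured and H and LE are
measured or good-quality fills (MDS flag <= 1, our reading of
"good-quality"), then filtered to 1.5 interquartile ranges of the whole
series (we read "its own interquartile range" as a global filter, not a
windowed one). Three correction methods apply hierarchically: (1)
factors within +-15 days restricted to the 22:00-02:30 and 10:00-14:30
bands (edges inclusive, judged on the record start) -- at least five
factors; multiplying the flux by each pooled factor gives the corrected
pool whose 25th/50th/75th percentiles become `_CORR25/_CORR/_CORR75`;
(2) the mean factor within +-5 days and +-1 hour, no percentiles; (3)
as (2) but around the same half-hour of the previous and next years.
Because one shared factor multiplies both fluxes, the Bowen ratio
H/LE is preserved wherever both corrected values exist. Random
uncertainty uses the same hierarchy as NEE with +-5 days and a
10 W m^-2^ floor, and joint uncertainty divides the percentile spread by
1.349 (the interquartile range of the standard normal), falling back to
the random term alone where percentiles are absent. At daily resolution
the factor pool is built from +-7 days of daily-average components; at
weekly and coarser resolutions the factor comes from the period-average
fluxes directly, requiring at least half of the period's records to
have all four components measured, without percentile variants.

## Partitioning

The nighttime method fits the Lloyd-Taylor respiration model
$RECO(T) = R_{ref} \exp(E_0 (1/(T_{ref} - T_0) - 1/(T - T_0)))$
(Tref = 15 degC, T0 = -46.02 degC) on nighttime NEE in 14-day windows
stepped by 7 days. The temperature sensitivity E0 is estimated first:
windows need at least 10 nighttime records and a temperature range of
at least 5 degC, and E0 is fixed at the median of the per-window
estimates, which must fall within 50-400 K. The median is a deliberate
numerical choice: under heavy flux noise the per-window standard error
of E0 scales with the absolute error, so any relative-precision
acceptance rule (accept windows whose standard error is a small
fraction of E0) systematically selects high-E0 windows and biases the
average upward; the median over all fitted windows recovers the
generative sensitivity nearly unbiased. The base respiration Rref is re-fit
per window in closed form (the model is linear in Rref once E0 is
fixed) and interpolated linearly between window centres. GPP is
RECO - NEE; negative GPP values are kept to preserve distributions. If
no window is accepted the member's partition is unavailable.

The daytime method models NEE jointly as Lloyd-Taylor respiration minus
a rectangular-hyperbola light response whose plateau decays
exponentially above a 10 hPa VPD threshold, fit per 8-day window
(stepped by 4 days) on day and night data together with E0 fixed from
the nighttime estimate and bounded Levenberg-Marquardt for the
remaining four parameters; non-convergent windows inherit interpolated
parameters, and a member needs at least two convergent windows. Both
methods run over all 40 members per threshold scheme, and the resulting
GPP/RECO ensembles get the same percentile/MEAN/REF treatment as NEE;
daytime and nighttime results are never merged -- their difference is
itself an uncertainty estimate.

## Aggregation

States average; precipitation sums; carbon fluxes convert by
12.011 ug C per umol times the record length and sum. Following the
published unit conventions, daily values are per-day totals, weekly and
monthly values are mean daily rates, and yearly values are annual
totals, which makes the carbon sum conserved from daily through yearly
to numerical precision. Each aggregate carries a quality fraction: the
share of underlying records that are measured or good-quality fills;
downstream screening typically requires it above 0.5.

## The synthetic site

`generate_site()` builds a two-year (by default) mid-latitude site in
which every quantity the pipeline estimates is known: true NEE from the
same respiration and light-response forms the partitioners fit (Rref =
2 umol m^-2^ s^-1^, E0 = 200 K, plateau 25 umol m^-2^ s^-1^), a hard
advection rule (night records below USTAR = 0.25 m s^-1^ lose 50 % of
their flux), an energy-balance gap of alpha = 1.25 imposed by dividing
the true H and LE, autocorrelated cloud attenuation over the potential
radiation, 10 % random gaps per variable and a 0.2 % spike rate. These
defaults are the package's canonical study conditions; they were chosen
once as field-realistic values and the validation suite runs against
them as-is. A coarse 3-hourly, deliberately biased copy of the
meteorology serves as the downscaling reference.

What the synthetic fixture shows: that the estimators recover known
generative parameters (threshold, closure factor, E0/Rref) and that the
structural contracts hold (ensemble cardinalities, flag ceilings,
conservation, identities). What it cannot show: performance under
instrument drift, non-stationary advection, heteroscedastic real-world
noise, or storage-profile errors -- the generator draws independent
lognormal turbulence and Gaussian noise, which is kinder than nature.
Two further caveats follow from the generator's hard suppression step:
the MP detector, built for a gradual flux recovery below the threshold,
is biased low on step-shaped data, while CP sits slightly high; their
pooled median is what recovers the truth. Problem sizes in the test
suite (one 2-year site at 100 bootstrap replicates, single years for
module tests) were chosen as the smallest sizes at which these
statistical checks are stable.

## Worked example

```{r, eval = FALSE}
library(fluxproc)

site <- generate_site(synth_config(years = 2, seed = 42))
res <- process_site(site$table, site$metadata, site$reference,
                    n_boot = 100, seed = 7)
print(res)
truth_report(site, res)

# write the standard product files
dir.create("out")
write_product(res$hh, site$metadata, "FULLSET", "HH", "out")
write_product(res$aggregated$DD, site$metadata, "FULLSET", "DD", "out")
```

## Known limitations

Sundown-based partitioning (a third method applicable to sites with
high-quality storage profiles) is not implemented. Visual/manual QC,
actual reanalysis retrieval, metadata spreadsheets beyond the critical
fields, and archive packaging are out of scope. The Method-2/3
energy-correction fallbacks at weekly and coarser resolutions are
simplified to the period-average factor, as documented above.
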