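---
title: "Methods: detection QC, survival proxies, residency and gridded HMM geolocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection QC, survival proxies, residency and gridded HMM geolocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagtrack)
```

This vignette is the package's own account of its models and of the
design choices that were genuinely open: what is assumed, what is
tunable and why the defaults are what they are, what the synthetic-data
generator does and does not emulate, and where the methods' limits lie.

## The data and their conventions

Four tabular inputs (detections, receiver deployments, 90-s archival
records, fish metadata) and one gridded input (reference fields) drive
everything. Conventions are fixed once, package-wide: WGS84 decimal
degrees with longitude negative west of Greenwich, all great-circle
distances on a sphere of radius 6371.0 km, UTC timestamps, clock-aligned
half-open hour bins `[h, h+1)`, and depth positive downward in records,
bathymetry and level depths alike. Maturity is classified from total
length against the length at 50% maturity for pollack (43.7 cm).

Archival records arrive at a 90-s cadence and the geolocation model
works hourly, so each occupied hour is reduced to the maximum depth
(`z_max`), mean depth (`z̄`) and mean temperature. The reduction rule is
a design choice: the maximum is the most informative depth statistic
against bathymetry (a fish that touched 50 m cannot be in 30 m of
water), while the mean depth is the right argument for the temperature
profile since the tag's mean temperature approximates the profile at
the mean depth when the profile is near-linear across the hour's range.

## Detection quality control

False detections arise from ping collisions and noise. Each detection
is scored on two *hard* criteria — recorded before the fish was
released, or outside the logging receiver's deployment interval — and
four *soft* criteria: isolation (no same-tag detection within ±24 h
anywhere in the network), implied speed to the nearest-in-time
neighbouring detection above `vmax`, distance from the release point
exceeding `vmax ×` time since release, and SNR below 6 dB when SNR is
recorded. A hard flag invalidates a detection outright; one soft flag
marks it *suspect* (retained); two or more invalidate it. The graded
two-tier scheme mirrors published QC practice for acoustic telemetry
while remaining fully reproducible; the thresholds (`vmax` = 2 m/s for
a slow bentho-demersal gadid, 24 h isolation window, 6 dB) are
configurable through `analysis_config()`.

Two deliberate asymmetries: velocity is computed from station
positions, so same-station pairs imply zero speed; and the strictness
of the downstream use decides the filter — summaries use everything
non-invalid, whereas the geolocation model's acoustic likelihood is a
hard constraint and receives only unflagged (`keep = "valid"`)
detections. `geolocate()` additionally drops detections in hours whose
combined emission likelihood would otherwise have no feasible cell:
a detection incompatible with the fish's own depth record (for
example, a plausible-SNR false detection at a shallow receiver while
the tag logged 30 m) is a residual false positive, not evidence.

## Survival proxies

*Short-term*: fish released inside a monitored bay pass two temporary
stations in sequence on their way out. A tag pinging continuously
(median gap at most twice the nominal 3-min ping interval) at one
station until the end of its series marks a carcass; any other
detection history — sequential passage, gate detections that cease, or
appearance elsewhere in the network later — marks a survivor, on the
argument that a fish in post-surgical distress dies at the release
site rather than swimming away. Fish never detected are unassessed.

*Long-term*: a fish survives in the long term if it is detected by the
permanent network (temporary gate stations excluded, since their
detections reflect the tagging event) or recaptured at least
`survival_week` (7) days after release; otherwise its fate is unknown.
Percentages are rounded half-up to integers, the reporting convention
of field studies.

## Residency, effort and movement graphs

Consecutive same-station detections closer than the threshold belong
to one residency period; a gap of at least the threshold starts a new
one. A single detection is a period of duration zero. The default 24-h
threshold is conventional, so `residency_summary()` always carries a
1–24 h sensitivity sweep; period counts are non-increasing in the
threshold by construction, which the tests assert. Terminal mortality
runs and temporary stations are excluded before the analysis.

Listening effort is the calendar-month sum over receivers of
deployment overlap, in days; detection and distinct-fish counts divided
by it are comparable across months with different network sizes.
Movement graphs connect consecutive distinct located events (release,
station detections, recapture) per fish, attribute each edge to the
season of the later event (Winter = DJF, Spring = MAM, Summer = JJA,
Fall = SON) and to the fish's maturity class, and weight edges by the
number of distinct fish. Stations, not receivers, are the spatial
unit.

## The gridded hidden Markov geolocation model

The hidden state is the fish's cell on a regular longitude/latitude
grid (~2 × 2 km here). Movement is an isotropic discrete Gaussian with
standard deviation σ cells per √hour, truncated at 4σ on a square
support (hence separable, applied as two banded matrix products), and
renormalised *per source cell* after land masking:

P(j | i) = K(j − i) · sea(j) / Σ_j′ K(j′ − i) · sea(j′).

Mask-and-renormalise (rather than absorbing) conserves probability at
coasts and grid edges; the smoother's exactness under this law is
tested against full path enumeration on small grids to 1e-10.

The three emission likelihoods are described in the README; the two
tolerances deserve comment. σ_z (depth slack) absorbs tide-model error
and sensor calibration; σ_T absorbs reference-field error, sensor
noise and within-cell temperature variation. For field data the
defaults are σ_T = 1 °C, σ_z = 5 m. For *synthetic* data the correct
values are the generator's own noise scales (σ_T = 0.05 °C, σ_z = 2 m):
maximum-likelihood estimation of σ is consistent only when the assumed
observation law matches the generating one, and deliberately
overdispersed likelihoods centred on the truth shrink the σ estimate
noticeably. The synthetic experiments and `run_pipeline()` therefore
default to the matched values.

σ is estimated by maximising the forward log marginal likelihood with
Brent's method (tolerance 1e-3 cells) inside user bounds, alongside a
coarse profile; a flat or monotone profile (uninformative data) warns
and returns the boundary. Scale-invariance of the estimate under
rescaled likelihoods is tested. σ is reported both in cell units per
√hour and in km per √hour via the mean cell size.

Track extraction: the mean track is the posterior-weighted centroid of
sea-cell centres; the mode track is the argmax cell (ties broken
towards the lowest latitude, then longitude, index); the positional
spread is the RMS great-circle distance about the mean. Distance
travelled sums consecutive great-circle steps on the *daily* mean
track by default — hourly centroid jitter inflates path length — with
hourly resolution available. Track sensitivity compares mean tracks
fitted with and without the acoustic stack on a common time axis and
reports mean, minimum and maximum per-hour distances.

Degenerate inputs are handled explicitly: an hourly slice with no
positive sea cell aborts with the slice named; simultaneous detections
with disjoint footprints are infeasible; σ small enough to truncate to
a delta kernel is allowed (the identity transition); dead-at-sea tags
can be truncated at a user-supplied death time or at the onset of a
sustained (<1 m for ≥24 h) surface signature detected by
`detect_tag_death()`.

One acoustic subtlety: with a ~400-m detection range inside ~2.2-km
cells, a non-detection must *not* zero the whole cell containing a
silent receiver — the fish can be in the cell yet out of range. Hours
without detections therefore only zero cells whose centre lies within
the range, while detection hours use the receiver's cell itself as the
indicator support.

## The synthetic-data generator

`simulate_scenario()` generates the study the tests and the acceptance
script validate against: a shelf domain of ~2 × 2 km cells with a
straight coast and linearly deepening bathymetry (130 m per degree of
latitude, with a gentle longitudinal ripple), an M2 tide (2 m
amplitude, 12.42 h), and a temperature field with a 0.5 °C/degree
zonal gradient, seasonal (2 °C) and diel (0.3 °C) cycles, a linear
0.04 °C/m decrease with depth and a 1.5 °C coastal-warming component
decaying over 40 m of bathymetry — the bathymetry-linked thermal
signal of a summer shelf, without which tag temperature would carry no
information about water-column depth. Fish are released at the
receiver stations (as in real tagging operations), move as Brownian
walks with σ_true = 1.2 cells/√h (the middle of the range reported for
recaptured pollack), hold a Beta(4, 2) fraction of the water column
each hour, and are recorded every 90 s with 0.3 m / 0.05 °C sensor
noise. Receivers ping-sample with exponential 3-min gaps inside a hard
400-m disk; false detections are injected at 0.5 per receiver-day with
low SNR (4 ± 1.5 dB against 12 ± 3 dB for genuine ones). Default
scenario sizes (14 days, 6 fish, 6 receivers; 9-day tracks for the
20-seed recovery experiments) are chosen to exercise every code path
at pilot-study scale.

What the generator does *not* emulate: hydrodynamic structure (fronts,
internal tides), behavioural modes (no diel vertical migration or
state switching), receiver-range stochasticity (a logistic range curve
is available but the default is a hard disk), tag clock drift, and
post-mortem drift trajectories (only the sensor signature of a
floating tag). Passing tests therefore demonstrate correctness of the
estimators under the model's own assumptions and robustness to
injected noise — not skill against unmodelled ocean physics.

## Numerical choices

Posterior slices are renormalised at every step; the backward variable
is rescaled by its maximum to avoid underflow; likelihood products
that underflow to an empty slice raise an infeasibility error rather
than silently renormalising noise. The text serialisation of gridded
fields stores coordinates at 1e-6° and values at 9 significant digits,
enough for lossless round-trips at the precision the models use.
Timestamps round-trip at 1 s.

## Known limitations

Regular latitude/longitude grids only; no light-based or
tidal-harmonic geolocation; no behavioural-state HMM; the QC scheme is
a re-design in the spirit of published graded criteria, not a
transcription of any specific scoring table; and the σ estimate
inherits the usual pseudo-likelihood caveat — when the emission model
is much wider than the real observation error, σ is biased low, which
is why tolerance choices are documented above and configurable.
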