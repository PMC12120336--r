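# tagtrack

Tools for analysing coastal fish tracked with two complementary tag
types at once: **acoustic transmitters**, whose coded pings are logged
by moored receivers whenever the fish swims within a few hundred
metres, and **archival data-storage tags (DSTs)**, which record depth
and temperature every 90 s and give up their data only when the fish is
recaptured. The package was built for double-tagging studies of
pollack (*Pollachius pollachius*) on the north-east Atlantic shelf, but
nothing in it is species-specific.

It covers the full analysis chain:

* **Detection quality control** — score every acoustic detection on
  six criteria (pre-release timing, deployment window, isolation,
  implied swimming speed, distance from release, signal-to-noise
  ratio) and filter the false detections that signal collisions and
  background noise create.
* **Post-tagging survival** — short-term survival from a two-station
  "gate" at the release site (a fish that dies after surgery pings
  continuously from one spot; a survivor passes the gate and leaves),
  and long-term survival from detections or recaptures at least a week
  after release.
* **Residency and effort** — maximal runs of same-station detections
  separated by less than a threshold (default 24 h) form residency
  periods; listening effort (receiver-days per month) normalises
  detection counts; seasonal movement graphs summarise transitions
  between stations.
* **Hidden Markov geolocation** — the core of the package. The sea is
  discretised on a regular ~2 x 2 km longitude/latitude grid. The
  fish's hourly position is a hidden state evolving by an isotropic
  Brownian kernel with diffusion parameter σ (cells · h^-1/2). Each
  hour emits three observations compared against gridded reference
  fields (bathymetry, hourly sea-surface height, hourly temperature
  profiles):

  * depth: a cell is feasible when `bathymetry + ssh ≥ z_max − σ_z`,
    with a Gaussian penalty `exp(−(z_max − D)² / 2σ_z²)` on the
    shortfall otherwise;
  * temperature: an unnormalised Gaussian
    `exp(−(T_tag − T_ref(z̄))² / 2σ_T²)`, with `T_ref` interpolated in
    depth at the hour's mean tag depth;
  * acoustics: an indicator of the detecting receiver's cells in hours
    with a detection, and a mask ruling out covered cells in hours
    without one.

  Tracks are anchored at the release (and recapture, when known)
  position, σ is estimated by maximising the forward log marginal
  likelihood (Brent search), the forward–backward recursions give
  smoothed hourly position distributions, and mean/mode tracks with
  positional spread are extracted. The **track sensitivity** — the
  per-hour distance between tracks estimated with and without the
  acoustic detections — is the model-consistency diagnostic reported
  per fish.
* **Synthetic data** — a generator producing the complete study with
  known ground truth (environment, Brownian tracks, 90-s DST records,
  receiver network, genuine and injected false detections), used by the
  test suite and the acceptance script.

## Worked example

A complete simulated study — three tagged fish, twelve days, six
receivers — through QC, survival, residency and geolocation:

```r
library(tagtrack)
run <- run_pipeline(list(n_fish = 3, n_days = 12, seed = 42,
                         n_geolocate = 2), out_dir = "demo")
run$survival
#> # A tibble: 2 × 5
#>   cohort   group      n survivors rate_pct
#>   <chr>    <chr>  <int>     <int>    <dbl>
#> 1 all      all        3         3      100
#> 2 maturity mature     3         3      100
run$geolocation
#> # A tibble: 2 × 7
#>   tag_id n_hours sigma_hat sigma_hat_km log_lik distance_km use_acoustic
#>   <chr>    <int>     <dbl>        <dbl>   <dbl>       <dbl> <lgl>
#> 1 T0001      288      1.01         2.25   -320.       103.  TRUE
#> 2 T0002      288      1.02         2.27   -264.        93.7 TRUE
run$sensitivity
#> # A tibble: 2 × 4
#>   tag_id mean_km min_km max_km
#>   <chr>    <dbl>  <dbl>  <dbl>
#> 1 T0001   0.0409      0  0.632
#> 2 T0002   0           0  0
```

All three fish are classified long-term survivors (each was detected
by the network more than a week after release). The estimated
diffusion coefficients (1.01 and 1.02 cells · h^-1/2, i.e. ≈2.3
km · h^-1/2) recover the generator's true value of 1.2 within the
expected tolerance, and the reconstructed 12-day paths cover ≈100 km.
Track sensitivity is small because these simulated fish stay close to
the receiver line, so the acoustic constraint and the sensor-only
model agree — exactly the behaviour expected of well-detected fish.

Per-fish geolocation of real inputs follows the same path explicitly:

```r
dets  <- read_detections("detections.csv")
recv  <- read_receivers("receivers.csv")
fish  <- read_fish("fish.csv")
dst   <- read_sensor_series("dst_A0001.csv", tag_id = "T0001")
flds  <- read_fields("fields.csv")

scores <- score_detections(dets, recv, fish)
clean  <- filter_detections(dets, scores, keep = "valid")
fit    <- geolocate(dst, flds, fish[1, ], dets = clean, recv = recv)
glance(fit)      # sigma_hat, log-likelihood, distance travelled
tidy(fit)        # hourly mean/mode track with positional sd
autoplot(fit)    # track map coloured by season
```

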