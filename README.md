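# mlcqa

Quantitative multi-leaf collimator (MLC) quality assurance from EPID
picket-fence images anchored to linac delivery log files — with a synthetic
linac so the whole calibration and validation loop runs without hardware.

## The problem and who this is for

Modulated radiotherapy relies on sub-millimetre MLC leaf positioning; the
picket-fence test is the standard periodic check. A sequence of abutting
step-and-shoot segments is delivered onto the portal imager, and the narrow
under-dosed strip between adjacent segments — the abutment — encodes the
positions of the two leaves that bound it. This package is for medical
physicists and QA-tool developers who want that test to produce *numbers*
(per-leaf position errors in mm) rather than a visual impression, and who
want the analysis anchored to the delivery log rather than to a fresh MLC
hardware calibration.

## The method

For each leaf pair and abutment strip, the open-field-normalized profile
along the leaf-motion axis (`I_norm = dI_raw / dI_open`, with raw values
decoded as `65535 - stored`) is averaged over the central 5 rows of the
pair's band and interpolated to a 0.01 mm grid. Three scalar features of
the abutment valley are measured:

* **FWHM** — distance between the two half-level crossings,
  `FWHM = (P^r - P^l) / 100` grid steps, with per-side half level
  `(peak + valley)/2`;
* **valley area** — summed deficit of the profile below the flanking peak
  levels;
* **valley depth** — the valley value itself.

Each feature is calibrated against the *actual* abutment width parsed from
the delivery log (the per-segment mean of the 40 ms leaf records) over 13
fields of 2–14 mm nominal width, averaged over 8 sessions, with a quintic

```
W_abu = c0 + c1*W_F + c2*W_F^2 + c3*W_F^3 + c4*W_F^4 + c5*W_F^5
```

fitted per (strip, leaf pair) — Scheme C; strip-averaged (A) and
TPS-width-based (B) schemes are provided for comparison. A measured feature
inverts to a width, the leaf positions follow from the abutment centre
(`P_l = P_peak - W/2`, `P_r = P_peak + W/2`), and per leaf the **integration
method** keeps whichever of the three estimates has the smallest absolute
error against the log-derived actual position.

The synthetic linac module (`simulate_picket_fence()`,
`simulate_open_field()`) generates matched portal images (DICOM-writable)
and delivery logs (documented CSV dialect) with controllable penumbra,
transmission, per-pair response variation, session output fluctuation,
pixel noise, leaf jitter and injected leaf position errors.

## A worked example

```r
library(mlcqa)

# calibrate a synthetic machine: 8 sessions x 13 field widths (2-14 mm)
campaign <- run_calibration_study(seed = 1, n_pairs = 6)

# deliver a 5 mm validation field carrying known +/-0.6..2.4 mm displacements
errors <- validation_error_map(pattern = "single", n_pairs = 6)
qa <- analyze_validation_field(campaign, width = 5, error_map = errors,
                               seed = 2)
summarize_qa(qa)
#> # A tibble: 4 x 9
#>   method           n     mean     sd mean_abs  sd_abs max_abs within_0.1 within_0.2
#> 1 fwhm            60 -0.00196 0.0627  0.0463  0.0419   0.152       0.85           1
#> 2 integration     60 -0.00139 0.0116  0.00777 0.00865  0.0484      1              1
#> 3 valley_area     60 -0.00196 0.0343  0.0227  0.0256   0.131       0.967          1
#> 4 valley_depth    60 -0.00196 0.0148  0.0114  0.00953  0.0484      1              1
```

Read: across the 60 analyzed leaves of this field (including ten leaves
deliberately displaced by up to 2.4 mm), the integrated estimate deviates
from the log-recorded actual position by 0.008 mm on average and never by
more than 0.05 mm — every leaf inside the 0.1 mm action level — while each
single method is worse, which is precisely why the integration rule exists.

Calibration curves are ordinary tidy objects:

```r
cv <- dplyr::filter(campaign$calibration, scheme == "C", method == "fwhm",
                    strip == 4, pair == 2)$curve[[1]]
cv
#> <mlc_curve> fwhm / scheme C / strip 4 pair 2: quintic over features
#> [8.602, 14.516], 13 points, max |resid| 8.18e-02 mm
tidy(cv)      # c0..c5
glance(cv)    # fit diagnostics
autoplot(cv)  # curve with its calibration points
```

A thin command-line front end wraps the same functions
(`inst/cli/mlcqa.R`; subcommands `simulate`, `calibrate`, `analyze`,
`logstats`) for shell-driven use on DICOM images, CSV logs, calibration
JSON and plan YAML files.

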