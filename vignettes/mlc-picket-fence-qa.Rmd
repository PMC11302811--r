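---
title: "Log-file-anchored picket-fence MLC QA from EPID images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-file-anchored picket-fence MLC QA from EPID images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlcqa)
library(dplyr)
```

## The measurement problem

A multi-leaf collimator (MLC) shapes every modulated radiotherapy field, and
millimetre-scale leaf position errors translate directly into dose errors,
especially where opposing leaves nearly abut. The picket-fence test is the
standard periodic check: a sequence of abutting step-and-shoot segments is
delivered onto the portal imager (EPID), and the narrow under-dosed strips
between segments — the abutments — reveal each leaf pair's positioning.

`mlcqa` implements a quantitative version of this test that anchors the
image analysis to the linac's own delivery log. The log records every leaf
position once per 40 ms during delivery, so the *actual* (jitter-averaged)
leaf positions are known independently of the image. Calibrating image
features against log-derived abutment widths, rather than against the
planned widths, removes the need for a fresh MLC hardware calibration before
each analysis session and makes leaf position errors well beyond 1 mm
measurable.

## The analysis chain

A QA field is processed in five stages.

1. **Raw decoding and normalization.** Portal images are stored inverted in
   16 bits: the delivered signal is `65535 - stored`. Each picket-fence
   image is divided pixel-wise by a matching open-field image from the same
   session, `I_norm = dI_raw / dI_open`, which cancels session-to-session
   beam output and energy drift.
2. **Profile extraction.** For each leaf pair and abutment strip, the
   central 5 image rows of the pair's projected band (a 5 mm leaf projects
   to 20 rows of the 0.4 mm panel at 1.6 magnification) are averaged to
   suppress interleaf leakage, then resampled by cubic-spline interpolation
   onto an exact 0.01 mm grid around the strip's nominal centre. All
   positions are expressed in mm at the isocenter plane (0.25 mm per pixel).
3. **Feature measurement.** The abutment valley is the most prominent local
   minimum of the profile; the flanking peaks are the highest values on
   each side. Three scalar features describe the valley:
   the **FWHM** (distance between the two half-level crossings, where each
   side's half level is the mean of that side's peak and the valley value),
   the **valley area** (summed deficit of the profile below the peak levels
   between the two peaks), and the **valley depth** (the valley value
   itself).
4. **Calibration and inversion.** Thirteen calibration fields with nominal
   abutment widths of 2-14 mm are delivered in each of 8 sessions. Per
   (strip, leaf pair), the session-averaged feature is paired with the
   session-averaged log-derived width, and a fifth-order polynomial
   `W_abu = c0 + c1 W_F + ... + c5 W_F^5` is fitted to the 13 points
   (abscissae are centred and scaled internally; a raw quintic design is
   numerically ill-conditioned). A measured feature then maps directly to a
   width estimate, and the two leaf positions follow from the abutment
   centre: `P_l = P_peak - W/2`, `P_r = P_peak + W/2`.
5. **Integration.** Each leaf therefore gets three independent position
   estimates. The integrated result is the one with the smallest absolute
   error against the log-derived actual position (exact ties resolved by
   the fixed priority FWHM, then valley area, then valley depth).

Three data-processing schemes control how the calibration points are
assembled: **Scheme A** fits one curve per strip from pair-averaged features
and log widths; **Scheme B** fits per (strip, pair) against the *planned*
(TPS) widths; **Scheme C** fits per (strip, pair) against the log-derived
widths. Scheme C is the default: per-pair curves absorb the panel's
pair-to-pair response differences, and log widths absorb each leaf's
persistent calibration offset.

### The abutment centre

The leaf-position decomposition needs the abutment centre `P_peak`. The raw
valley-minimum location is exact on noiseless profiles, but for wide
abutments the profile bottom is nearly flat, so pixel noise moves the
interpolated minimum by the order of 0.1 mm. The two half-level boundary
crossings, by contrast, sit on the steep flanks at every width, where the
same noise moves them by only a few thousandths of a millimetre. `mlcqa`
therefore uses the midpoint of the two FWHM boundaries as `P_peak`; the two
estimators coincide for symmetric noiseless profiles, and the valley
position is still reported for inspection.

### Half-level convention

The half level is computed per side as `(side peak + valley)/2`, which
tolerates asymmetric shoulders. Walking outward from the valley on the
0.01 mm grid, the boundary is the first sample at or above the half level;
the grid already bounds the quantization error at 0.005 mm per side, so no
sub-sample interpolation is applied.

## The synthetic linac

The package ships a simulator that generates matched picket-fence images,
open fields and delivery logs, so the full calibration/validation loop runs
without hardware. Its components:

* **Collimated edges.** Each leaf edge is a two-component spread: a sharp
  error-function core (`penumbra_sigma`, default 3.6 mm at the isocenter)
  plus a broad low-amplitude tail (`glare_sigma` 5 mm, weight 10%)
  representing portal-imager glare and in-beam scatter. An abutment profile
  is the sum of the two facing edge tails plus the transmission floor
  (0.4% per closed segment). The defaults were fixed by the recorded sweep
  in `scripts/tune_penumbra.R`: across core sigmas of 3.0-4.2 mm the
  two-segment piecewise-linear breakpoint of the FWHM-versus-width curve
  rounds to 8 mm, the published turning point for this test; 3.6 mm, whose
  fitted breakpoint is nearest 8 mm, is shipped. With a Gaussian edge
  family this choice makes the valley-depth saturation gradual rather than
  complete by 4 mm — the sensitivity ratio between 12 mm and 2 mm widths is
  about 0.29 — which the feature tests assert as computed from the
  closed-form edge model.
* **Field layout.** Eight abutting 20 mm x 240 mm segments of 100 MU each,
  separated by the nominal abutment width; the central five of the seven
  strips are analyzed. 48 leaf pairs of 5 mm projected width tile the field.
* **Per-machine traits.** Multiplicative per-leaf-pair response factors
  (SD 2%, switchable off) and persistent per-leaf position offsets
  (SD 0.022 mm) are drawn once per simulated machine and reused across all
  of its sessions. Persistence is what distinguishes Scheme C from Scheme B:
  per-delivery-only offsets would average out of the 8-session nominal
  values.
* **Delivery log.** One record per 40 ms; 272 beam-on records per 100 MU
  segment; per-record leaf jitter of SD 0.064 mm on top of the persistent
  offsets. The marginal per-record position error then has SD
  `sqrt(0.064^2 + 0.022^2) = 0.068 mm` and mean absolute value
  `sqrt(2/pi) * 0.068 = 0.054 mm`, the reported magnitude for this class of
  machine; the implied abutment-width error statistics
  (SD about 0.096 mm, mean absolute about 0.076 mm) follow without further
  tuning. A few flagged beam-off transition records separate segments and
  are excluded from averaging ("useful records" are defined as beam-on).
* **Image rendering.** The image is rendered from the per-segment *mean*
  delivered leaf positions, so image and log describe the same geometry;
  session output fluctuation (SD 2%) multiplies field and open image alike,
  and multiplicative Gaussian pixel noise (SD 0.2%, a realistic figure for
  an integrated portal acquisition) is applied per pixel. Penumbra
  broadening by intra-delivery jitter (about 0.06 mm in quadrature with a
  3.6 mm sigma) is negligible and not modelled.
* **Error injection.** Planned leaf displacements are applied to both the
  commanded positions (hence the log) and the image, as TPS-introduced
  errors are real displacements. Single-bank offsets move one abutment edge
  (width and centre change); both-bank offsets translate the gap. A
  separate `epid_only` flag injects image-only shifts to exercise
  leaf-versus-log discrepancy detection.

### What the simulator does not emulate

Tongue-and-groove structure (absent on the modelled MLC design), rounded
leaf-tip transmission shapes, panel sag or alignment drift, dead pixels,
beam profile asymmetry beyond a global output factor, and Poisson counting
statistics (noise is Gaussian multiplicative; for ratio images at this
signal level the difference is immaterial). Passing tests therefore
demonstrate the correctness and internal consistency of the analysis chain
under a controlled, physically plausible image model — not detector-specific
behaviour of any particular clinical EPID.

## Numerical choices and degenerate inputs

* Valley prominence threshold 0.02 (about 10% of the valley depth of an
  ideal 2 mm strip under the default beam); profiles with no sufficiently
  prominent minimum raise "no abutment detected" and degrade to a flagged
  per-pair failure rather than aborting the field.
* Abutment search window: nominal width/2 + 3 x max(core, glare sigma)
  + 2 mm around the nominal strip centre.
* Tie-breaks: equal-prominence valleys resolve towards the window centre;
  plateau peaks resolve towards the valley; the valley sample belongs to
  the left summand of the valley area.
* Quintic fits require at least 6 distinct abscissae; the full 13-width
  series is required by default (configurable down to 7). Feature values
  beyond 10% outside the fitted feature range are refused as uncalibrated
  extrapolation.
* An injected offset that closes a gap is rejected as a degenerate
  abutment at plan construction.
* Derived seeds are kept below 2^31 (R integers are 32-bit).

## Problem sizes used in tests and the acceptance script

Simulation studies in the test-suite and in `scripts/acceptance.R` cover 6
leaf pairs per field (the full 1024-column motion axis is retained), 8
sessions x 13 widths per calibration campaign, 10 replicate campaigns for
the error-injection study, and a 24-pair field (over 10^5 leaf-records) for
jitter statistics. These sizes were chosen so a full run completes in a few
minutes while every statistic quoted here is computed, not assumed; the
simulator defaults remain the full-size conditions (48 pairs, 1024 x 1024
panel).

With those sizes, the shipped acceptance run reports a mean absolute
integrated leaf-position error of about 0.009 mm against the log-derived
actuals across the +/-0.6 to +/-2.4 mm injection grid — comfortably inside
the 0.1 mm action level used for the tolerance verdicts (a second 0.2 mm
"investigate" level is configurable). The synthetic setting is cleaner than
a physical machine: there is no panel sag, no residual alignment error and
no detector glare mismatch between calibration and test sessions, so
clinical errors would be larger.

## Known limitations

* The quintic has an approximation floor of a few hundredths of a mm near
  the strongly curved low-width end of the FWHM relation; single-method
  errors grow towards large injected displacements there, which is exactly
  what the integration rule compensates.
* With the Gaussian-edge beam model, valley-depth accuracy does not
  deteriorate at 11 mm the way saturated measured curves suggest, because
  multiplicative noise shrinks along with the valley signal. The mechanism
  — the inverse calibration slope |dW/d(feature)| growing with width — is
  present and tested; the outcome-level degradation would appear with an
  additive read-noise floor.
* Scheme A's accuracy penalty is driven by the per-pair response SD; at
  the default 2% it is substantially larger than on a well-matched
  clinical panel, which exaggerates (but correctly orders) the A-to-C gap.

## A worked example

```{r example, eval = FALSE}
library(mlcqa)

# calibrate a synthetic machine: 8 sessions x 13 widths, schemes A/B/C
campaign <- run_calibration_study(seed = 1, n_pairs = 6)

# deliver a 5 mm validation field carrying known displacements
errors <- validation_error_map(pattern = "single", n_pairs = 6)
qa <- analyze_validation_field(campaign, width = 5, error_map = errors,
                               seed = 2)
summarize_qa(qa)
autoplot(qa)

# how well were the injected displacements recovered?
val <- run_validation_study(campaign, seeds = 1:3)
recovery_stats(val)
```
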