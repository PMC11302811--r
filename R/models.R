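#' Beam and imaging response model for the synthetic linac
#'
#' Describes the parts of the beam/EPID chain that shape a picket-fence
#' portal image: the penumbra width of a collimated edge, leaf transmission,
#' interleaf leakage, per-leaf-pair response variation, session-to-session
#' output fluctuation, and per-pixel noise.
#'
#' @param penumbra_sigma Gaussian sigma of the sharp (collimation core)
#'   component of a leaf-edge penumbra, in mm at the isocenter plane.
#' @param glare_sigma Gaussian sigma of the broad low-amplitude tail of the
#'   edge (panel glare and in-beam scatter), mm at the isocenter plane. A
#'   megavoltage portal edge is well described by such a two-component
#'   spread; `glare_fraction = 0` recovers a pure single-sigma erf edge.
#' @param glare_fraction Weight of the glare component in `[0, 1)`. The
#'   penumbra defaults are fixed by a recorded tuning sweep
#'   (`scripts/tune_penumbra.R`) so that the FWHM-vs-width calibration
#'   curve's piecewise-linear turning point falls at 8 mm, the primary
#'   curve-shape anchor of measured picket-fence series; the valley value
#'   then saturates gradually towards the top calibration widths.
#' @param transmission Fraction of the open-beam signal transmitted through a
#'   closed leaf, in `[0, 1)`.
#' @param interleaf_leakage_amp Amplitude (fraction of the open signal) of the
#'   narrow leakage ridges at leaf-pair boundaries.
#' @param pair_response_sd Standard deviation of the multiplicative
#'   per-leaf-pair response perturbation (default 2%). Set to 0 to switch
#'   response heterogeneity off.
#' @param pair_response Optional numeric vector of realized per-pair response
#'   factors (one per leaf pair, values in (0.8, 1.2)). When supplied it is
#'   used as-is, which keeps the response fixed across all sessions of a
#'   simulated machine; when `NULL` the simulator draws factors from
#'   `N(1, pair_response_sd)`.
#' @param output_fluctuation_sd Standard deviation of the per-session beam
#'   output factor (unitless fraction). Open-field normalization is designed
#'   to cancel this component.
#' @param noise_sd Standard deviation of the multiplicative Gaussian per-pixel
#'   noise (unitless fraction).
#' @param open_signal Decoded in-field signal level (detector counts) produced
#'   by a 100 MU open-field delivery.
#'
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(penumbra_sigma = 3.6,
                       glare_sigma = 5,
                       glare_fraction = 0.1,
                       transmission = 0.004,
                       interleaf_leakage_amp = 0.002,
                       pair_response_sd = 0.02,
                       pair_response = NULL,
                       output_fluctuation_sd = 0.02,
                       noise_sd = 0.002,
                       open_signal = 20000) {
  stopifnot_scalar_number(penumbra_sigma, "penumbra_sigma", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(glare_sigma, "glare_sigma", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(glare_fraction, "glare_fraction", min = 0,
                          max = 1 - 1e-12)
  stopifnot_scalar_number(transmission, "transmission", min = 0, max = 1 - 1e-12)
  stopifnot_scalar_number(interleaf_leakage_amp, "interleaf_leakage_amp", min = 0)
  stopifnot_scalar_number(pair_response_sd, "pair_response_sd", min = 0)
  stopifnot_scalar_number(output_fluctuation_sd, "output_fluctuation_sd", min = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", min = 0)
  stopifnot_scalar_number(open_signal, "open_signal", min = 1)
  if (!is.null(pair_response)) {
    if (!is.numeric(pair_response) || any(!is.finite(pair_response)) ||
        any(pair_response <= 0.8) || any(pair_response >= 1.2)) {
      abort_mlcqa("`pair_response` values must lie strictly inside (0.8, 1.2).",
                  "mlcqa_invalid_model")
    }
  }
  structure(
    list(
      penumbra_sigma = penumbra_sigma,
      glare_sigma = glare_sigma,
      glare_fraction = glare_fraction,
      transmission = transmission,
      interleaf_leakage_amp = interleaf_leakage_amp,
      pair_response_sd = pair_response_sd,
      pair_response = pair_response,
      output_fluctuation_sd = output_fluctuation_sd,
      noise_sd = noise_sd,
      open_signal = open_signal
    ),
    class = "beam_model"
  )
}

#' Panel geometry and pixel-to-isocenter mapping
#'
#' The default geometry is a 1024 x 1024 amorphous-silicon panel with 0.4 mm
#' pixel pitch at a source-to-detector distance of 160 cm and
#' source-to-axis distance of 100 cm, so the magnification is 1.6 and one
#' pixel projects to 0.25 mm at the isocenter plane. Pixel indices are
#' 0-based with pixel centers at integer indices; the beam axis crosses the
#' panel at the (possibly fractional) `origin` index.
#'
#' @param sdd_cm Source-to-detector distance, cm.
#' @param sad_cm Source-to-axis distance, cm.
#' @param pixel_pitch_panel_mm Physical pixel pitch on the panel, mm.
#' @param rows,cols Panel dimensions in pixels. Smaller panels are useful for
#'   reduced-size simulations covering only the leaf pairs under analysis.
#' @param origin Length-2 numeric `(row, col)` 0-based index of the beam axis;
#'   defaults to the panel center.
#'
#' @return An object of class `geometry_model` with derived fields
#'   `magnification` and `pixel_pitch_iso_mm`.
#' @export
geometry_model <- function(sdd_cm = 160, sad_cm = 100,
                           pixel_pitch_panel_mm = 0.4,
                           rows = 1024, cols = 1024,
                           origin = c((rows - 1) / 2, (cols - 1) / 2)) {
  stopifnot_scalar_number(sdd_cm, "sdd_cm", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(sad_cm, "sad_cm", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(pixel_pitch_panel_mm, "pixel_pitch_panel_mm",
                          min = 0, strict_min = TRUE)
  magnification <- sdd_cm / sad_cm
  if (magnification <= 1) {
    abort_mlcqa("magnification (sdd/sad) must exceed 1.", "mlcqa_invalid_model")
  }
  if (length(origin) != 2L || any(!is.finite(origin))) {
    abort_mlcqa("`origin` must be a finite (row, col) pair.",
                "mlcqa_invalid_model")
  }
  structure(
    list(
      sdd_cm = sdd_cm, sad_cm = sad_cm,
      pixel_pitch_panel_mm = pixel_pitch_panel_mm,
      magnification = magnification,
      pixel_pitch_iso_mm = pixel_pitch_panel_mm / magnification,
      rows = as.integer(rows), cols = as.integer(cols),
      origin = as.numeric(origin)
    ),
    class = "geometry_model"
  )
}

#' Leaf jitter model for delivery-log simulation
#'
#' The delivery log records every leaf position once per `record_interval_ms`.
#' Recorded positions deviate from the commanded ones by a persistent per-leaf
#' systematic offset (drawn once per simulated machine) plus independent
#' per-record jitter. The defaults reproduce the per-record leaf-position
#' error statistics of a step-and-shoot Elekta delivery: per-record SD of
#' 0.064 mm, with a 0.022 mm systematic component so the marginal error
#' ensemble has mean absolute value `sqrt(2/pi) * sqrt(0.064^2 + 0.022^2)
#' = 0.054 mm`.
#'
#' @param record_interval_ms Time between log records, ms.
#' @param records_per_100mu Number of beam-on records generated per 100 MU of
#'   a segment delivery (default 272).
#' @param per_record_sd SD of the independent per-record leaf jitter, mm.
#' @param systematic_offset_sd SD of the persistent per-leaf offset, mm.
#' @param beam_off_records Number of beam-off (transition) records inserted
#'   before each segment; these are flagged `beam_on = 0` and excluded from
#'   segment averaging.
#'
#' @return An object of class `jitter_model`.
#' @export
jitter_model <- function(record_interval_ms = 40,
                         records_per_100mu = 272,
                         per_record_sd = 0.064,
                         systematic_offset_sd = 0.022,
                         beam_off_records = 3) {
  stopifnot_scalar_number(record_interval_ms, "record_interval_ms", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(records_per_100mu, "records_per_100mu", min = 1)
  stopifnot_scalar_number(per_record_sd, "per_record_sd", min = 0)
  stopifnot_scalar_number(systematic_offset_sd, "systematic_offset_sd", min = 0)
  stopifnot_scalar_number(beam_off_records, "beam_off_records", min = 0)
  structure(
    list(
      record_interval_ms = record_interval_ms,
      records_per_100mu = records_per_100mu,
      per_record_sd = per_record_sd,
      systematic_offset_sd = systematic_offset_sd,
      beam_off_records = as.integer(beam_off_records)
    ),
    class = "jitter_model"
  )
}

#' Marginal per-record position-error SD implied by a jitter model
#'
#' @param jitter A [jitter_model()].
#' @return SD in mm of `recorded - commanded` pooled over leaves and records.
#' @export
jitter_marginal_sd <- function(jitter) {
  sqrt(jitter$per_record_sd^2 + jitter$systematic_offset_sd^2)
}

#' Picket-fence field plan
#'
#' Describes one picket-fence test: `n_segments` abutting step-and-shoot
#' segments of `segment_width_mm` (motion direction) by `field_y_mm`
#' (across the leaves), separated by an intentional gap of
#' `nominal_width_mm` — the nominal abutment width. The central
#' `n_strips_analyzed` abutment strips are analyzed. Optional leaf position
#' errors are listed in `error_map`.
#'
#' @param nominal_width_mm Nominal abutment (gap) width, mm, typically 2-14.
#' @param n_segments Number of segments (default 8, giving 7 strips).
#' @param segment_width_mm Segment width along the leaf-motion axis, mm.
#' @param segment_mu Monitor units delivered per segment.
#' @param leaf_width_mm Projected leaf width at the isocenter, mm.
#' @param field_y_mm Field extent across the leaves, mm; the number of leaf
#'   pairs is `field_y_mm / leaf_width_mm`.
#' @param n_strips_analyzed Number of central strips used for analysis
#'   (default 5, capped at the number of strips).
#' @param error_map `NULL` or a data frame with columns `strip`, `pair`,
#'   `bank` (`"A"`, `"B"` or `"both"`), `offset_mm` and optionally
#'   `epid_only` (logical; when `TRUE` the displacement is applied to the
#'   image only, not to the delivery log — a leaf-versus-log discrepancy).
#'   Offsets are displacements along the +x motion axis of the named leaf
#'   tip(s) bounding that strip: bank A is the right-hand boundary (the
#'   following segment's left bank), bank B the left-hand boundary.
#'
#' @return An object of class `field_plan`.
#' @export
field_plan <- function(nominal_width_mm,
                       n_segments = 8,
                       segment_width_mm = 20,
                       segment_mu = 100,
                       leaf_width_mm = 5,
                       field_y_mm = 240,
                       n_strips_analyzed = NULL,
                       error_map = NULL) {
  stopifnot_scalar_number(nominal_width_mm, "nominal_width_mm", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(n_segments, "n_segments", min = 2)
  stopifnot_scalar_number(segment_width_mm, "segment_width_mm", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(segment_mu, "segment_mu", min = 0, strict_min = TRUE)
  stopifnot_scalar_number(leaf_width_mm, "leaf_width_mm", min = 0,
                          strict_min = TRUE)
  stopifnot_scalar_number(field_y_mm, "field_y_mm", min = leaf_width_mm)
  n_strips <- as.integer(n_segments) - 1L
  if (is.null(n_strips_analyzed)) n_strips_analyzed <- min(5L, n_strips)
  stopifnot_scalar_number(n_strips_analyzed, "n_strips_analyzed", min = 1,
                          max = n_strips)
  n_pairs <- as.integer(floor(field_y_mm / leaf_width_mm + 1e-9))

  if (!is.null(error_map)) {
    error_map <- tibble::as_tibble(error_map)
    required <- c("strip", "pair", "bank", "offset_mm")
    missing <- setdiff(required, names(error_map))
    if (length(missing) > 0) {
      abort_mlcqa(sprintf("`error_map` is missing column(s): %s",
                          paste(missing, collapse = ", ")),
                  "mlcqa_invalid_plan")
    }
    if (!"epid_only" %in% names(error_map)) error_map$epid_only <- FALSE
    if (any(!is.finite(error_map$offset_mm))) {
      abort_mlcqa("`error_map$offset_mm` must be finite.", "mlcqa_invalid_plan")
    }
    if (any(!error_map$bank %in% c("A", "B", "both"))) {
      abort_mlcqa("`error_map$bank` must be 'A', 'B' or 'both'.",
                  "mlcqa_invalid_plan")
    }
    if (any(error_map$strip < 1 | error_map$strip > n_strips)) {
      abort_mlcqa("`error_map$strip` targets a strip outside the field.",
                  "mlcqa_invalid_plan")
    }
    if (any(error_map$pair < 1 | error_map$pair > n_pairs)) {
      abort_mlcqa("`error_map$pair` targets a leaf pair outside the field.",
                  "mlcqa_invalid_plan")
    }
  } else {
    error_map <- tibble::tibble(strip = integer(), pair = integer(),
                                bank = character(), offset_mm = numeric(),
                                epid_only = logical())
  }

  plan <- structure(
    list(
      nominal_width_mm = nominal_width_mm,
      n_segments = as.integer(n_segments),
      segment_width_mm = segment_width_mm,
      segment_mu = segment_mu,
      leaf_width_mm = leaf_width_mm,
      field_y_mm = field_y_mm,
      n_pairs = n_pairs,
      n_strips = n_strips,
      n_strips_analyzed = as.integer(n_strips_analyzed),
      error_map = error_map
    ),
    class = "field_plan"
  )
  # reject plans whose injected offsets close an abutment completely
  ab <- plan_abutments(plan, which = "imaged")
  if (any(ab$width <= 0)) {
    abort_mlcqa("degenerate abutment: an injected offset closes the gap.",
                "mlcqa_degenerate_abutment")
  }
  plan
}

#' Indices of the analyzed central strips
#' @param plan A [field_plan()].
#' @return Integer vector of strip indices (1 = strip between segments 1 and 2).
#' @export
analyzed_strips <- function(plan) {
  first <- (plan$n_strips - plan$n_strips_analyzed) %/% 2L + 1L
  seq.int(first, first + plan$n_strips_analyzed - 1L)
}

#' Leaf-pair center coordinates across the field
#' @param plan A [field_plan()].
#' @return Tibble with `pair` and `y_mm` (isocenter-plane center of the pair).
#' @export
plan_pairs <- function(plan) {
  tibble::tibble(
    pair = seq_len(plan$n_pairs),
    y_mm = -plan$field_y_mm / 2 + (seq_len(plan$n_pairs) - 0.5) * plan$leaf_width_mm
  )
}

# nominal aperture edges common to all leaf pairs (before any error offsets)
plan_segment_edges <- function(plan) {
  w <- plan$nominal_width_mm
  sw <- plan$segment_width_mm
  total <- plan$n_segments * sw + (plan$n_segments - 1L) * w
  a <- -total / 2 + (seq_len(plan$n_segments) - 1L) * (sw + w)
  tibble::tibble(segment = seq_len(plan$n_segments), a_mm = a, b_mm = a + sw)
}

#' Commanded per-leaf aperture edges of every segment
#'
#' Expands the nominal layout and the plan's `error_map` into one aperture
#' edge per (segment, pair, bank). `which` selects the reference frame:
#' `"nominal"` ignores all injected errors, `"commanded"` applies every
#' error that the machine actually executes (i.e. not `epid_only`), and
#' `"imaged"` applies all errors including image-only discrepancies.
#'
#' @param plan A [field_plan()].
#' @param which One of `"nominal"`, `"commanded"`, `"imaged"`.
#' @return Tibble with `segment`, `pair`, `bank` and `position_mm`.
#' @export
plan_positions <- function(plan, which = c("commanded", "nominal", "imaged")) {
  which <- match.arg(which)
  edges <- plan_segment_edges(plan)
  pos <- tidyr::expand_grid(segment = edges$segment,
                            pair = seq_len(plan$n_pairs),
                            bank = c("A", "B"))
  pos$position_mm <- ifelse(pos$bank == "A",
                            edges$a_mm[pos$segment], edges$b_mm[pos$segment])
  em <- plan$error_map
  if (which == "nominal" || nrow(em) == 0) return(tibble::as_tibble(pos))
  if (which == "commanded") em <- em[!em$epid_only, , drop = FALSE]
  for (i in seq_len(nrow(em))) {
    s <- em$strip[i]; p <- em$pair[i]; off <- em$offset_mm[i]
    if (em$bank[i] %in% c("A", "both")) {
      sel <- pos$segment == s + 1L & pos$pair == p & pos$bank == "A"
      pos$position_mm[sel] <- pos$position_mm[sel] + off
    }
    if (em$bank[i] %in% c("B", "both")) {
      sel <- pos$segment == s & pos$pair == p & pos$bank == "B"
      pos$position_mm[sel] <- pos$position_mm[sel] + off
    }
  }
  tibble::as_tibble(pos)
}

#' Per-strip, per-pair abutment geometry of a plan
#'
#' @param plan A [field_plan()].
#' @param which Reference frame, see [plan_positions()].
#' @param strips Strip indices; defaults to the analyzed central strips.
#' @return Tibble with `strip`, `pair`, `p_left`, `p_right`, `width`,
#'   `center` (all mm at the isocenter plane). The left boundary of strip
#'   `s` is the bank-B edge of segment `s`; the right boundary is the bank-A
#'   edge of segment `s + 1`.
#' @export
plan_abutments <- function(plan, which = "commanded", strips = NULL) {
  if (is.null(strips)) strips <- analyzed_strips(plan)
  pos <- plan_positions(plan, which)
  left <- pos[pos$bank == "B" & pos$segment %in% strips, ]
  right <- pos[pos$bank == "A" & pos$segment %in% (strips + 1L), ]
  out <- tibble::tibble(
    strip = left$segment,
    pair = left$pair,
    p_left = left$position_mm,
    p_right = right$position_mm[match(
      paste(left$segment + 1L, left$pair),
      paste(right$segment, right$pair))]
  )
  out$width <- out$p_right - out$p_left
  out$center <- (out$p_left + out$p_right) / 2
  dplyr::arrange(out, strip, pair)
}

#' @export
print.field_plan <- function(x, ...) {
  cat(sprintf(
    "<field_plan> %g mm nominal abutment, %d segments x %g MU, %d leaf pairs, %d/%d strips analyzed\n",
    x$nominal_width_mm, x$n_segments, x$segment_mu, x$n_pairs,
    x$n_strips_analyzed, x$n_strips))
  if (nrow(x$error_map) > 0) {
    cat(sprintf("  %d injected leaf position error(s)\n", nrow(x$error_map)))
  }
  invisible(x)
}

#' Rising edge response of the beam model
#'
#' Fraction of the open signal delivered at a signed distance `d_mm` past a
#' collimated edge (positive = into the open side): a weighted sum of the
#' core and glare normal CDFs.
#'
#' @param d_mm Signed distances from the edge, mm at the isocenter plane.
#' @param beam A [beam_model()].
#' @return Numeric vector in `[0, 1]`.
#' @export
beam_edge <- function(d_mm, beam) {
  g <- beam$glare_fraction
  (1 - g) * stats::pnorm(d_mm / beam$penumbra_sigma) +
    g * stats::pnorm(d_mm / beam$glare_sigma)
}

# length scale bounding where an edge still varies appreciably
penumbra_span <- function(beam) {
  max(beam$penumbra_sigma,
      if (beam$glare_fraction > 0) beam$glare_sigma else 0)
}

#' @export
print.beam_model <- function(x, ...) {
  cat(sprintf(
    "<beam_model> core sigma %.2f mm + %.0f%% glare sigma %.2f mm, transmission %.3f, noise %.4f, pair response SD %.3f\n",
    x$penumbra_sigma, 100 * x$glare_fraction, x$glare_sigma, x$transmission,
    x$noise_sd, x$pair_response_sd))
  invisible(x)
}

#' @export
print.geometry_model <- function(x, ...) {
  cat(sprintf(
    "<geometry_model> %d x %d px, %.2f mm pitch, magnification %.2f (%.3f mm/px at iso)\n",
    x$rows, x$cols, x$pixel_pitch_panel_mm, x$magnification,
    x$pixel_pitch_iso_mm))
  invisible(x)
}

#' @export
print.jitter_model <- function(x, ...) {
  cat(sprintf(
    "<jitter_model> %g ms records, %g/100MU, per-record SD %.3f mm, systematic SD %.3f mm\n",
    x$record_interval_ms, x$records_per_100mu, x$per_record_sd,
    x$systematic_offset_sd))
  invisible(x)
}

#' Write a field plan to a YAML file
#'
#' @param plan A [field_plan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_field_plan <- function(plan, path) {
  yaml::write_yaml(list(
    nominal_width_mm = plan$nominal_width_mm,
    n_segments = plan$n_segments,
    segment_width_mm = plan$segment_width_mm,
    segment_mu = plan$segment_mu,
    leaf_width_mm = plan$leaf_width_mm,
    field_y_mm = plan$field_y_mm,
    n_strips_analyzed = plan$n_strips_analyzed,
    error_map = if (nrow(plan$error_map) == 0) list() else
      lapply(seq_len(nrow(plan$error_map)), \(i) as.list(plan$error_map[i, ]))
  ), path)
  invisible(path)
}

#' Read a field plan written by [write_field_plan()]
#'
#' @param path YAML file path.
#' @return A [field_plan()].
#' @export
read_field_plan <- function(path) {
  x <- yaml::read_yaml(path)
  em <- if (length(x$error_map) == 0) NULL else
    dplyr::bind_rows(lapply(x$error_map, tibble::as_tibble))
  field_plan(
    nominal_width_mm = x$nominal_width_mm,
    n_segments = x$n_segments,
    segment_width_mm = x$segment_width_mm,
    segment_mu = x$segment_mu,
    leaf_width_mm = x$leaf_width_mm,
    field_y_mm = x$field_y_mm,
    n_strips_analyzed = x$n_strips_analyzed,
    error_map = em
  )
}
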