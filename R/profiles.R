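#' Extract a per-leaf-pair abutment profile from a normalized image
#'
#' Averages the central 5 image rows of the leaf pair's projected band
#' (reducing interleaf leakage), then interpolates the averaged row with a
#' cubic spline onto a uniform 0.01 mm grid spanning the abutment search
#' window around the strip's nominal center.
#'
#' @param norm An [normalize_epid()] result.
#' @param plan A [field_plan()].
#' @param strip Strip index (see [analyzed_strips()]).
#' @param pair Leaf-pair index.
#' @param beam A [beam_model()]; its penumbra scale sets the default window.
#' @param window_mm Half-width of the abutment window, mm. Defaults to
#'   `nominal_width/2 + 3 * max(penumbra_sigma, glare_sigma) + 2`.
#' @return A tibble of class `mlc_profile` with `position_mm` (uniform
#'   0.01 mm step) and `value`; attributes `strip`, `pair`, `center_nominal`.
#' @export
extract_profile <- function(norm, plan, strip, pair, beam = beam_model(),
                            window_mm = NULL) {
  geometry <- norm$geometry
  if (is.null(window_mm)) {
    window_mm <- plan$nominal_width_mm / 2 + 3 * penumbra_span(beam) + 2
  }
  ab <- plan_abutments(plan, "nominal", strips = strip)
  center <- ab$center[ab$pair == pair]
  if (length(center) != 1) {
    abort_mlcqa("strip/pair not covered by the plan.", "mlcqa_invalid_plan")
  }
  y_pair <- plan_pairs(plan)$y_mm[pair]
  core <- profile_core(norm$values, geometry, y_pair, center, window_mm)
  out <- tibble::tibble(position_mm = core$x, value = core$v)
  class(out) <- c("mlc_profile", class(out))
  attr(out, "strip") <- strip
  attr(out, "pair") <- pair
  attr(out, "center_nominal") <- center
  attr(out, "coarse") <- tibble::tibble(position_mm = core$xc,
                                        value = core$averaged)
  out
}

# numeric kernel shared by extract_profile and extract_features: 5-row band
# average + cubic-spline resampling onto the exact 0.01 mm grid
profile_core <- function(values, geometry, y_pair, center, window_mm) {
  row_c <- iso_to_pixel(y_pair, geometry, "row")
  rows0 <- round(row_c) + (-2:2) # 0-based central 5 rows of the band
  if (any(rows0 < 0 | rows0 > geometry$rows - 1)) {
    abort_mlcqa("leaf-pair band lies outside the image.", "mlcqa_out_of_image")
  }
  col_lo <- floor(iso_to_pixel(center - window_mm, geometry, "col"))
  col_hi <- ceiling(iso_to_pixel(center + window_mm, geometry, "col"))
  if (col_lo < 0 || col_hi > geometry$cols - 1) {
    abort_mlcqa("abutment window lies outside the image.", "mlcqa_out_of_image")
  }
  cols0 <- col_lo:col_hi
  band <- values[rows0 + 1L, cols0 + 1L, drop = FALSE]
  if (anyNA(band)) {
    abort_mlcqa("masked pixels inside the abutment window.",
                "mlcqa_masked_pixels")
  }
  averaged <- colMeans(band)
  xc <- pixel_to_iso(cols0, geometry, "col")
  k <- seq.int(ceiling((center - window_mm) * 100),
               floor((center + window_mm) * 100))
  x <- k / 100
  x <- x[x >= xc[1] & x <= xc[length(xc)]]
  sp <- stats::splinefun(xc, averaged, method = "fmm")
  list(x = x, v = sp(x), xc = xc, averaged = averaged)
}

# extrema on plain vectors; returns integer indices (valley, left, right)
extrema_core <- function(v, prominence) {
  n <- length(v)
  if (n < 5) abort_mlcqa("profile too short.", "mlcqa_no_abutment")
  interior <- 2:(n - 1)
  is_min <- v[interior] < v[interior - 1] & v[interior] <= v[interior + 1]
  cand <- interior[is_min]
  if (length(cand) == 0) {
    abort_mlcqa("no abutment detected: profile has no interior minimum.",
                "mlcqa_no_abutment")
  }
  cummax_l <- cummax(v)
  cummax_r <- rev(cummax(rev(v)))
  prom <- pmin(cummax_l[cand], cummax_r[cand]) - v[cand]
  keep <- prom >= prominence
  if (!any(keep)) {
    abort_mlcqa("no abutment detected: no minimum with sufficient prominence.",
                "mlcqa_no_abutment")
  }
  cand <- cand[keep]; prom <- prom[keep]
  best <- prom == max(prom)
  if (sum(best) > 1) { # tie-break: closest to the window center
    center_idx <- (n + 1) / 2
    d <- abs(cand - center_idx)
    best <- best & d == min(d[best])
  }
  vi <- cand[which(best)[1]]
  lv <- v[seq_len(vi - 1)]
  li <- length(lv) + 1L - which.max(rev(lv)) # last max = nearest the valley
  ri <- vi + which.max(v[(vi + 1):n]) # first max = nearest the valley
  c(valley = vi, left = li, right = ri)
}

# FWHM boundaries on plain vectors; returns indices (left, right)
fwhm_core <- function(v, idx) {
  vv <- v[idx[["valley"]]]
  half_l <- (v[idx[["left"]]] + vv) / 2
  half_r <- (v[idx[["right"]]] + vv) / 2
  left_run <- rev(seq_len(idx[["valley"]]))
  li <- left_run[which(v[left_run] >= half_l)[1]]
  right_run <- idx[["valley"]]:length(v)
  ri <- right_run[which(v[right_run] >= half_r)[1]]
  if (is.na(li) || is.na(ri)) {
    abort_mlcqa("half level not crossed on one side of the valley.",
                "mlcqa_no_half_crossing")
  }
  c(left = li, right = ri)
}

area_core <- function(v, idx) {
  left <- sum(v[idx[["left"]]] - v[idx[["left"]]:idx[["valley"]]])
  right <- if (idx[["right"]] > idx[["valley"]]) {
    sum(v[idx[["right"]]] - v[(idx[["valley"]] + 1):idx[["right"]]])
  } else 0
  left + right
}

#' Locate the abutment valley and its flanking peaks
#'
#' The valley is the most prominent local minimum of the profile (prominence
#' = lower of the two highest bounding values minus the minimum); ties are
#' broken deterministically towards the window center. The peaks are the
#' highest values on each side of the valley, ties broken towards the
#' valley.
#'
#' @param profile An [extract_profile()] result (or any tibble with
#'   `position_mm` and `value`).
#' @param prominence Minimum prominence for a minimum to count as an
#'   abutment valley. The default, 0.02, is about 10% of the valley depth of
#'   an ideal 2 mm strip under the default beam model.
#' @return A list of class `mlc_extrema` with elements `valley`,
#'   `left_peak`, `right_peak`, each a list with `index`, `position`,
#'   `value`.
#' @export
find_extrema <- function(profile, prominence = 0.02) {
  idx <- extrema_core(profile$value, prominence)
  pt <- function(i) list(index = i, position = profile$position_mm[i],
                         value = profile$value[i])
  structure(list(valley = pt(idx[["valley"]]), left_peak = pt(idx[["left"]]),
                 right_peak = pt(idx[["right"]])),
            class = "mlc_extrema")
}

#' Full-width half-maximum of an abutment valley
#'
#' The half level on each side is the mean of that side's peak value and the
#' valley value. Walking outward from the valley on the 0.01 mm grid, the
#' boundary is the first sample whose value reaches the half level; the
#' FWHM is the millimetre distance between the right and left boundaries.
#'
#' @param profile An [extract_profile()] result.
#' @param extrema A [find_extrema()] result for the same profile.
#' @return A list with `fwhm` (mm), `boundary_left`, `boundary_right` (mm)
#'   and `center` (midpoint of the two boundaries, mm).
#' @export
profile_fwhm <- function(profile, extrema) {
  idx <- c(valley = extrema$valley$index, left = extrema$left_peak$index,
           right = extrema$right_peak$index)
  b <- fwhm_core(profile$value, idx)
  bl <- profile$position_mm[b[["left"]]]
  br <- profile$position_mm[b[["right"]]]
  list(fwhm = br - bl, boundary_left = bl, boundary_right = br,
       center = (bl + br) / 2)
}

#' Valley area of an abutment profile
#'
#' Sum over the fine-grid samples from the left peak to the valley of
#' (left peak value - sample) plus the sum from just right of the valley to
#' the right peak of (right peak value - sample). The valley sample is
#' counted once, on the left side. Units: unitless signal deficit times
#' number of 0.01 mm samples.
#'
#' @inheritParams profile_fwhm
#' @return Numeric valley area (>= 0).
#' @export
profile_valley_area <- function(profile, extrema) {
  area_core(profile$value,
            c(valley = extrema$valley$index, left = extrema$left_peak$index,
              right = extrema$right_peak$index))
}

#' Valley depth feature
#'
#' The valley depth method uses the valley value itself as the observed
#' feature; deeper valleys give smaller values.
#'
#' @param extrema A [find_extrema()] result.
#' @return The valley value (unitless).
#' @export
valley_depth <- function(extrema) {
  extrema$valley$value
}

#' All three abutment features of one leaf-pair profile
#'
#' @inheritParams extract_profile
#' @param prominence Passed to [find_extrema()].
#' @return A one-row tibble with the extrema positions/values, the
#'   half-level boundaries, the abutment `center_mm` (boundary midpoint) and
#'   the three scalar features `fwhm`, `valley_area`, `valley_depth`.
#'   When no abutment is detected the feature columns are `NA` and `status`
#'   records the failure.
#' @export
profile_features <- function(norm, plan, strip, pair, beam = beam_model(),
                             window_mm = NULL, prominence = 0.02) {
  extract_features(norm, plan, beam, strips = strip, pairs = pair,
                   window_mm = window_mm, prominence = prominence)
}

# one profile's feature record as a plain named list (fast path)
features_core <- function(x, v, prominence) {
  idx <- extrema_core(v, prominence)
  b <- fwhm_core(v, idx)
  list(
    status = "ok",
    valley_pos = x[idx[["valley"]]], valley_value = v[idx[["valley"]]],
    left_peak_pos = x[idx[["left"]]], left_peak_value = v[idx[["left"]]],
    right_peak_pos = x[idx[["right"]]], right_peak_value = v[idx[["right"]]],
    boundary_left = x[b[["left"]]], boundary_right = x[b[["right"]]],
    center_mm = (x[b[["left"]]] + x[b[["right"]]]) / 2,
    fwhm = x[b[["right"]]] - x[b[["left"]]],
    valley_area = area_core(v, idx),
    valley_depth = v[idx[["valley"]]]
  )
}

#' Feature table of every analyzed (strip, leaf pair) of a field
#'
#' @inheritParams extract_profile
#' @param strips Strip indices; defaults to the analyzed central strips.
#' @param pairs Leaf-pair indices; defaults to all pairs of the plan.
#' @param prominence Passed to [find_extrema()].
#' @return Tibble with one row per (strip, pair): the extrema positions and
#'   values, the half-level boundaries, the abutment `center_mm` (boundary
#'   midpoint) and the three scalar features `fwhm`, `valley_area`,
#'   `valley_depth`. Rows where no abutment was detected carry `NA` features
#'   and the failure message in `status`.
#' @export
extract_features <- function(norm, plan, beam = beam_model(), strips = NULL,
                             pairs = NULL, window_mm = NULL,
                             prominence = 0.02) {
  if (is.null(strips)) strips <- analyzed_strips(plan)
  if (is.null(pairs)) pairs <- seq_len(plan$n_pairs)
  if (is.null(window_mm)) {
    window_mm <- plan$nominal_width_mm / 2 + 3 * penumbra_span(beam) + 2
  }
  ab <- plan_abutments(plan, "nominal", strips = strips)
  y_of_pair <- plan_pairs(plan)$y_mm
  grid <- tidyr::expand_grid(strip = strips, pair = pairs)
  na_rec <- list(
    status = NA_character_, valley_pos = NA_real_, valley_value = NA_real_,
    left_peak_pos = NA_real_, left_peak_value = NA_real_,
    right_peak_pos = NA_real_, right_peak_value = NA_real_,
    boundary_left = NA_real_, boundary_right = NA_real_, center_mm = NA_real_,
    fwhm = NA_real_, valley_area = NA_real_, valley_depth = NA_real_
  )
  recs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- grid$strip[i]; p <- grid$pair[i]
    center <- ab$center[ab$strip == s & ab$pair == p]
    recs[[i]] <- tryCatch({
      core <- profile_core(norm$values, norm$geometry, y_of_pair[p], center,
                           window_mm)
      features_core(core$x, core$v, prominence)
    }, mlcqa_error = function(e) {
      rec <- na_rec
      rec$status <- conditionMessage(e)
      rec
    })
  }
  cols <- names(na_rec)
  out <- tibble::as_tibble(lapply(stats::setNames(cols, cols), \(cn) {
    unlist(lapply(recs, `[[`, cn), use.names = FALSE)
  }))
  dplyr::bind_cols(grid, out)
}
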