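#' Average per-session tables into nominal calibration values
#'
#' Each calibration session contributes, per (nominal width, strip, leaf
#' pair), the three measured features and the log-derived actual abutment
#' geometry. The nominal value of every quantity is its arithmetic mean over
#' the sessions (8 sessions by default in a full campaign).
#'
#' @param sessions Tibble with one row per
#'   (session, nominal_width, strip, pair) and columns `fwhm`,
#'   `valley_area`, `valley_depth`, `center_mm`, `actual_width`,
#'   `actual_p_left`, `actual_p_right`.
#' @return Tibble of class `mlc_nominal` keyed by
#'   (nominal_width, strip, pair) with the per-cell means and `n_sessions`.
#' @export
build_nominal_values <- function(sessions) {
  required <- c("session", "nominal_width", "strip", "pair", "fwhm",
                "valley_area", "valley_depth", "actual_width")
  missing <- setdiff(required, names(sessions))
  if (length(missing) > 0) {
    abort_mlcqa(sprintf("`sessions` is missing column(s): %s",
                        paste(missing, collapse = ", ")),
                "mlcqa_invalid_sessions")
  }
  counts <- dplyr::count(sessions, nominal_width, strip, pair)
  n_sessions <- length(unique(sessions$session))
  bad <- counts[counts$n != n_sessions, ]
  if (nrow(bad) > 0) {
    abort_mlcqa(sprintf(
      "incomplete session grid: width %g strip %d pair %d present in %d/%d sessions.",
      bad$nominal_width[1], bad$strip[1], bad$pair[1], bad$n[1], n_sessions),
      "mlcqa_invalid_sessions")
  }
  if (any(!is.finite(sessions$fwhm))) {
    abort_mlcqa("sessions contain failed feature extractions (NA features).",
                "mlcqa_invalid_sessions")
  }
  num_cols <- intersect(
    c("fwhm", "valley_area", "valley_depth", "center_mm",
      "actual_width", "actual_p_left", "actual_p_right"),
    names(sessions))
  out <- sessions |>
    dplyr::group_by(nominal_width, strip, pair) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(num_cols), mean),
                     .groups = "drop") |>
    dplyr::mutate(n_sessions = n_sessions)
  class(out) <- c("mlc_nominal", class(out))
  out
}

#' Assemble calibration point sets under a data-processing scheme
#'
#' Scheme A builds one point set per strip: features and log-derived widths
#' are averaged over all leaf pairs of the strip. Schemes B and C build one
#' point set per (strip, leaf pair); B takes the planned (TPS) nominal
#' widths as the ordinate, C the log-derived nominal actual widths. Each set
#' holds one point per calibration field width.
#'
#' @param nominal A [build_nominal_values()] result.
#' @param scheme `"A"`, `"B"` or `"C"`.
#' @param method `"fwhm"`, `"valley_area"` or `"valley_depth"` — which
#'   feature supplies the abscissa.
#' @param min_widths Minimum number of calibration field widths required
#'   (default 13, the full 2-14 mm series; may be lowered to no less
#'   than 7).
#' @return Tibble with `scheme`, `method`, `strip`, `pair` (`NA` for scheme
#'   A), `w_feature`, `w_abutment`.
#' @export
assemble_calibration_points <- function(nominal, scheme = c("C", "A", "B"),
                                        method = c("fwhm", "valley_area",
                                                   "valley_depth"),
                                        min_widths = 13) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  if (min_widths < 7) {
    abort_mlcqa("`min_widths` may not be lowered below 7.",
                "mlcqa_invalid_calibration")
  }
  n_widths <- length(unique(nominal$nominal_width))
  if (n_widths < min_widths) {
    abort_mlcqa(sprintf(
      "only %d calibration field widths present; %d required.",
      n_widths, min_widths), "mlcqa_invalid_calibration")
  }
  feature <- nominal[[method]]
  if (scheme == "A") {
    out <- nominal |>
      dplyr::mutate(.feature = feature) |>
      dplyr::group_by(strip, nominal_width) |>
      dplyr::summarise(w_feature = mean(.feature),
                       w_abutment = mean(actual_width), .groups = "drop") |>
      dplyr::mutate(pair = NA_integer_)
  } else {
    out <- nominal |>
      dplyr::mutate(
        w_feature = feature,
        w_abutment = if (scheme == "B") nominal_width else actual_width
      )
  }
  out |>
    dplyr::transmute(scheme = scheme, method = method, strip, pair,
                     w_feature, w_abutment) |>
    dplyr::arrange(strip, pair, w_abutment)
}

# expand a polynomial in z = (x - center)/scale into raw powers of x
expand_scaled_poly <- function(coef_scaled, center, scale) {
  deg <- length(coef_scaled) - 1L
  raw <- numeric(deg + 1L)
  for (k in 0:deg) {
    ak <- coef_scaled[k + 1L] / scale^k
    for (i in 0:k) {
      raw[i + 1L] <- raw[i + 1L] + ak * choose(k, i) * (-center)^(k - i)
    }
  }
  raw
}

#' Fit a fifth-order calibration curve to (feature, width) points
#'
#' Least-squares quintic `W_abu = c0 + c1*W_F + ... + c5*W_F^5`. The
#' abscissa is centered and scaled internally before fitting (a raw-unit
#' quintic design is ill-conditioned); the returned object carries both the
#' stable scaled coefficients used for evaluation and the equivalent raw
#' coefficients `c0..c5`.
#'
#' @param points Tibble with `w_feature` and `w_abutment` (one calibration
#'   point set, e.g. one group of [assemble_calibration_points()]).
#' @param method,scheme,strip,pair Optional provenance fields stored on the
#'   curve (taken from `points` when present).
#' @return An object of class `mlc_curve`.
#' @export
fit_calibration_curve <- function(points, method = NULL, scheme = NULL,
                                  strip = NULL, pair = NULL) {
  grab <- function(field, arg) {
    if (!is.null(arg)) return(arg)
    if (field %in% names(points) && length(unique(points[[field]])) == 1) {
      return(points[[field]][1])
    }
    NA
  }
  x <- points$w_feature
  y <- points$w_abutment
  if (length(x) < 6) {
    abort_mlcqa("at least 6 calibration points are required.",
                "mlcqa_invalid_calibration")
  }
  if (length(unique(x)) < 6) {
    abort_mlcqa("fewer than 6 distinct feature abscissae.",
                "mlcqa_invalid_calibration")
  }
  center <- mean(x)
  scale <- stats::sd(x)
  if (!is.finite(scale) || scale <= 0) {
    abort_mlcqa("degenerate feature abscissae.", "mlcqa_invalid_calibration")
  }
  z <- (x - center) / scale
  design <- outer(z, 0:5, "^")
  qr_d <- qr(design)
  if (qr_d$rank < 6) {
    abort_mlcqa(
      "ill-conditioned quintic design even after centering the features.",
      "mlcqa_invalid_calibration")
  }
  coef_scaled <- as.numeric(qr.coef(qr_d, y))
  fitted <- as.numeric(design %*% coef_scaled)
  structure(
    list(
      method = grab("method", method),
      scheme = grab("scheme", scheme),
      strip = grab("strip", strip),
      pair = grab("pair", pair),
      center = center, scale = scale,
      coef_scaled = coef_scaled,
      coefficients = expand_scaled_poly(coef_scaled, center, scale),
      fit_domain = range(x),
      n_points = length(x),
      residuals = y - fitted,
      r_squared = if (stats::var(y) > 0) {
        1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
      } else NA_real_
    ),
    class = "mlc_curve"
  )
}

#' Estimate an abutment width from a feature value
#'
#' Evaluates the calibration quintic at the feature value. Features outside
#' the fitted feature range trigger a warning; beyond 10% of the range past
#' either end the estimate is refused as uncalibrated extrapolation.
#'
#' @param curve An [fit_calibration_curve()] result.
#' @param feature Numeric vector of feature values.
#' @param extrapolation Allowed fractional extrapolation beyond the fit
#'   domain (default 0.1).
#' @return Numeric vector of estimated abutment widths, mm.
#' @export
estimate_width <- function(curve, feature, extrapolation = 0.1) {
  dom <- curve$fit_domain
  span <- diff(dom)
  lo <- dom[1] - extrapolation * span
  hi <- dom[2] + extrapolation * span
  if (any(feature < lo | feature > hi)) {
    abort_mlcqa(sprintf(
      "feature %g outside calibrated range [%g, %g] (+/- %g%%).",
      feature[which(feature < lo | feature > hi)[1]], dom[1], dom[2],
      100 * extrapolation), "mlcqa_outside_calibration")
  }
  if (any(feature < dom[1] | feature > dom[2])) {
    rlang::warn("feature outside the fit domain; extrapolating the quintic.",
                class = "mlcqa_extrapolation")
  }
  z <- (feature - curve$center) / curve$scale
  as.numeric(outer(z, 0:5, "^") %*% curve$coef_scaled)
}

#' Decompose an abutment into its two leaf positions
#'
#' Given the abutment center (extremum position of the abutment profile) and
#' its width, the left and right leaf positions are `center - W/2` and
#' `center + W/2`.
#'
#' @param p_peak Abutment center position(s), mm.
#' @param width Abutment width(s), mm.
#' @return Tibble with `p_left` and `p_right` (mm).
#' @export
leaf_positions <- function(p_peak, width) {
  if (any(width <= 0)) {
    abort_mlcqa("abutment width must be positive.", "mlcqa_invalid_width")
  }
  tibble::tibble(p_left = p_peak - width / 2, p_right = p_peak + width / 2)
}

#' Fit the full calibration set of a campaign
#'
#' Builds every curve for the requested schemes and methods from the nominal
#' values and returns them as one tidy table.
#'
#' @param nominal A [build_nominal_values()] result.
#' @param schemes Subset of `c("A", "B", "C")`.
#' @param methods Subset of `c("fwhm", "valley_area", "valley_depth")`.
#' @inheritParams assemble_calibration_points
#' @return Tibble of class `mlc_calibration` with `scheme`, `method`,
#'   `strip`, `pair` and a `curve` list-column of [fit_calibration_curve()]
#'   objects.
#' @export
fit_calibration <- function(nominal, schemes = c("A", "B", "C"),
                            methods = c("fwhm", "valley_area", "valley_depth"),
                            min_widths = 13) {
  combos <- tidyr::expand_grid(scheme = schemes, method = methods)
  out <- purrr::pmap(combos, \(scheme, method) {
    sch <- scheme
    mth <- method
    pts <- assemble_calibration_points(nominal, sch, mth, min_widths)
    pts |>
      dplyr::group_by(strip, pair) |>
      tidyr::nest() |>
      dplyr::ungroup() |>
      dplyr::mutate(
        scheme = sch, method = mth,
        curve = purrr::pmap(list(data, strip, pair), \(d, s, p) {
          fit_calibration_curve(d, method = mth, scheme = sch,
                                strip = s, pair = p)
        })
      ) |>
      dplyr::select(scheme, method, strip, pair, curve)
  }) |>
    purrr::list_rbind()
  class(out) <- c("mlc_calibration", class(out))
  attr(out, "n_sessions") <- nominal$n_sessions[1]
  attr(out, "widths") <- sort(unique(nominal$nominal_width))
  out
}

# fast curve lookup used by analyze_field
calibration_lookup <- function(calibration) {
  key <- ifelse(is.na(calibration$pair),
                paste(calibration$scheme, calibration$method,
                      calibration$strip, sep = "/"),
                paste(calibration$scheme, calibration$method,
                      calibration$strip, calibration$pair, sep = "/"))
  stats::setNames(calibration$curve, key)
}

#' @export
print.mlc_curve <- function(x, ...) {
  scope <- if (is.na(x$pair)) sprintf("strip %s", x$strip) else {
    sprintf("strip %s pair %s", x$strip, x$pair)
  }
  cat(sprintf(
    "<mlc_curve> %s / scheme %s / %s: quintic over features [%.3f, %.3f], %d points, max |resid| %.2e mm\n",
    x$method, x$scheme, scope, x$fit_domain[1], x$fit_domain[2], x$n_points,
    max(abs(x$residuals))))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mlc_curve <- function(x, ...) {
  tibble::tibble(term = paste0("c", 0:5), estimate = x$coefficients)
}

#' @export
glance.mlc_curve <- function(x, ...) {
  tibble::tibble(
    method = x$method, scheme = x$scheme, strip = x$strip, pair = x$pair,
    n_points = x$n_points, r_squared = x$r_squared,
    max_abs_residual = max(abs(x$residuals)),
    feature_min = x$fit_domain[1], feature_max = x$fit_domain[2]
  )
}

#' @export
tidy.mlc_calibration <- function(x, ...) {
  x |>
    dplyr::mutate(coef = purrr::map(curve, tidy)) |>
    dplyr::select(-curve) |>
    tidyr::unnest(coef) |>
    tidyr::pivot_wider(names_from = "term", values_from = "estimate")
}

#' @export
glance.mlc_calibration <- function(x, ...) {
  purrr::list_rbind(purrr::map(x$curve, glance))
}

#' Serialize a calibration set to JSON
#'
#' Every curve record stores its scheme, method, scope, the centering
#' transform, the raw coefficients `c0..c5` and the fit domain, so a QA run
#' is fully auditable from the file alone.
#'
#' @param calibration An [fit_calibration()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calibration, path) {
  records <- purrr::map(calibration$curve, \(cv) {
    list(scheme = cv$scheme, method = cv$method,
         strip = if (is.na(cv$strip)) NULL else cv$strip,
         pair = if (is.na(cv$pair)) NULL else cv$pair,
         center = cv$center, scale = cv$scale,
         coef_scaled = cv$coef_scaled,
         coefficients = cv$coefficients,
         fit_domain = cv$fit_domain, n_points = cv$n_points)
  })
  jsonlite::write_json(
    list(n_sessions = attr(calibration, "n_sessions"),
         widths = attr(calibration, "widths"),
         curves = records),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a calibration set written by [write_calibration()]
#'
#' @param path JSON file path.
#' @return An `mlc_calibration` tibble.
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  curves <- purrr::map(obj$curves, \(r) {
    structure(
      list(method = r$method, scheme = r$scheme,
           strip = if (is.null(r$strip)) NA else r$strip,
           pair = if (is.null(r$pair)) NA_integer_ else r$pair,
           center = r$center, scale = r$scale,
           coef_scaled = as.numeric(r$coef_scaled),
           coefficients = as.numeric(r$coefficients),
           fit_domain = as.numeric(r$fit_domain),
           n_points = r$n_points,
           residuals = NA_real_, r_squared = NA_real_),
      class = "mlc_curve")
  })
  out <- tibble::tibble(
    scheme = purrr::map_chr(curves, "scheme"),
    method = purrr::map_chr(curves, "method"),
    strip = purrr::map_int(curves, \(cv) as.integer(cv$strip)),
    pair = purrr::map_int(curves, \(cv) as.integer(cv$pair)),
    curve = curves
  )
  class(out) <- c("mlc_calibration", class(out))
  attr(out, "n_sessions") <- obj$n_sessions
  attr(out, "widths") <- as.numeric(obj$widths)
  out
}

#' Continuous two-segment piecewise-linear fit
#'
#' Fits `y = b0 + b1*x + b2*(x - bp)+` by least squares, scanning the
#' breakpoint `bp` over a fine grid between the second and second-to-last
#' abscissae. Used to locate the slope turning point of the FWHM-versus-
#' width calibration curve.
#'
#' @param x,y Numeric vectors.
#' @param grid_step Breakpoint scan step (default 0.01 in x units).
#' @return List with `breakpoint`, `coefficients` (b0, b1, b2), `sse` and
#'   `fitted`.
#' @export
piecewise_linear_fit <- function(x, y, grid_step = 0.01) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  if (n < 5) abort_mlcqa("need at least 5 points.", "mlcqa_invalid_fit")
  grid <- seq(x[2], x[n - 1], by = grid_step)
  best <- NULL
  best_sse <- Inf
  for (bp in grid) {
    design <- cbind(1, x, pmax(x - bp, 0))
    fit <- stats::lm.fit(design, y)
    sse <- sum(fit$residuals^2)
    if (sse < best_sse) {
      best_sse <- sse
      best <- list(breakpoint = bp, coefficients = fit$coefficients,
                   sse = sse, fitted = fit$fitted.values)
    }
  }
  best
}
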