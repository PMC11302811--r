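#' Integrate the three method errors for one leaf
#'
#' The integrated output is the value with the smallest absolute error among
#' the available method results. Exact ties are broken by the fixed priority
#' fwhm > valley_area > valley_depth (the methods' typical accuracy
#' ordering).
#'
#' @param errors Named numeric vector of signed errors, names among
#'   `"fwhm"`, `"valley_area"`, `"valley_depth"`; `NA` marks a failed
#'   method.
#' @return List with `method` and `error`; both `NA` when every method
#'   failed.
#' @export
integrate_errors <- function(errors) {
  priority <- c("fwhm", "valley_area", "valley_depth")
  errors <- errors[intersect(priority, names(errors))]
  ok <- !is.na(errors)
  if (!any(ok)) return(list(method = NA_character_, error = NA_real_))
  errors <- errors[ok]
  best <- names(errors)[abs(errors) == min(abs(errors))]
  chosen <- priority[priority %in% best][1]
  list(method = chosen, error = unname(errors[chosen]))
}

#' Analyze a measured picket-fence field against a calibration set
#'
#' For every analyzed (strip, leaf pair) and each of the three feature
#' methods: the profile feature is mapped through the calibration curve to
#' an estimated abutment width, the width is decomposed about the measured
#' abutment center into the two leaf positions, and each leaf position is
#' compared against the log-derived actual position (`error`) and against
#' the nominal error-free layout (`deviation`, which recovers injected
#' displacements). The integration rows pick, per leaf, the method with the
#' smallest absolute error.
#'
#' @param norm A [normalize_epid()] result for the field.
#' @param calibration An [fit_calibration()] (or [read_calibration()])
#'   result covering the plan's strips/pairs for all three methods.
#' @param records Parsed delivery log of the same field.
#' @param plan The field's [field_plan()].
#' @param scheme Which calibration scheme to apply (`"A"`, `"B"` or `"C"`).
#' @param beam A [beam_model()] (window default for profile extraction).
#' @param prominence Valley prominence threshold, see [find_extrema()].
#' @param action_levels Two increasing action thresholds in mm (default
#'   0.1 "action" and 0.2 "investigate").
#' @return A tibble of class `mlc_qa`, one row per (strip, pair, method,
#'   side) with `w_est`, `p_est`, `p_actual`, `p_nominal`, `error` (vs log),
#'   `deviation` (vs nominal layout) and `status`. Integration rows carry
#'   the chosen method in `chosen`. Attributes: `scheme`, `action_levels`.
#' @export
analyze_field <- function(norm, calibration, records, plan, scheme = "C",
                          beam = beam_model(), prominence = 0.02,
                          action_levels = c(0.1, 0.2)) {
  states <- segment_leaf_states(records)
  actual <- log_abutments(states, plan)
  nominal <- plan_abutments(plan, "nominal") |>
    dplyr::rename(nominal_p_left = p_left, nominal_p_right = p_right)
  feats <- extract_features(norm, plan, beam, prominence = prominence)
  lookup <- calibration_lookup(calibration)
  methods <- c("fwhm", "valley_area", "valley_depth")
  if (!scheme %in% calibration$scheme) {
    abort_mlcqa(sprintf("calibration has no scheme %s curves.", scheme),
                "mlcqa_missing_calibration")
  }

  rows <- purrr::pmap(feats, function(strip, pair, status, center_mm, fwhm,
                                      valley_area, valley_depth, ...) {
    act <- actual[actual$strip == strip & actual$pair == pair, ]
    nom <- nominal[nominal$strip == strip & nominal$pair == pair, ]
    feature_of <- c(fwhm = fwhm, valley_area = valley_area,
                    valley_depth = valley_depth)
    per_method <- purrr::map(methods, function(m) {
      out <- tibble::tibble(
        strip = strip, pair = pair, method = m,
        side = c("left", "right"),
        w_est = NA_real_, p_est = NA_real_,
        p_actual = c(act$actual_p_left, act$actual_p_right),
        p_nominal = c(nom$nominal_p_left, nom$nominal_p_right),
        error = NA_real_, deviation = NA_real_,
        chosen = NA_character_, status = status
      )
      if (status != "ok") return(out)
      curve <- lookup[[paste(scheme, m, strip, pair, sep = "/")]]
      if (is.null(curve)) curve <- lookup[[paste(scheme, m, strip, sep = "/")]]
      if (is.null(curve)) {
        abort_mlcqa(sprintf(
          "calibration lacks a scheme %s %s curve for strip %d pair %d.",
          scheme, m, strip, pair), "mlcqa_missing_calibration")
      }
      w <- tryCatch(
        suppressWarnings(estimate_width(curve, feature_of[[m]])),
        mlcqa_outside_calibration = function(e) NA_real_)
      if (is.na(w) || w <= 0) {
        out$status <- "outside calibrated range"
        return(out)
      }
      lp <- leaf_positions(center_mm, w)
      out$w_est <- w
      out$p_est <- c(lp$p_left, lp$p_right)
      out$error <- out$p_est - out$p_actual
      out$deviation <- out$p_est - out$p_nominal
      out
    })
    per_method <- purrr::list_rbind(per_method)

    integ <- per_method |>
      dplyr::group_by(side) |>
      dplyr::group_modify(\(d, key) {
        errs <- stats::setNames(d$error, d$method)
        pick <- integrate_errors(errs)
        row <- d[1, ]
        if (is.na(pick$method)) {
          row$w_est <- NA_real_; row$p_est <- NA_real_
          row$error <- NA_real_; row$deviation <- NA_real_
          row$chosen <- NA_character_
          row$status <- if (row$status == "ok") "indeterminate" else row$status
        } else {
          src <- d[d$method == pick$method, ]
          row[, c("w_est", "p_est", "error", "deviation", "status")] <-
            src[, c("w_est", "p_est", "error", "deviation", "status")]
          row$chosen <- pick$method
        }
        row$method <- "integration"
        row
      }) |>
      dplyr::ungroup() |>
      dplyr::select(dplyr::all_of(names(per_method)))
    dplyr::bind_rows(per_method, integ)
  })

  out <- purrr::list_rbind(rows) |>
    dplyr::arrange(strip, pair, factor(method, levels = c(methods, "integration")),
                   side)
  class(out) <- c("mlc_qa", class(out))
  attr(out, "scheme") <- scheme
  attr(out, "action_levels") <- action_levels
  attr(out, "nominal_width_mm") <- plan$nominal_width_mm
  out
}

#' Summary statistics of QA leaf-position errors
#'
#' Reports, per group, the mean/SD of the signed errors, the mean/SD of the
#' absolute errors, the maximum absolute error and the fraction of leaves
#' within each action level.
#'
#' @param qa An `mlc_qa` tibble (or several row-bound together), or any
#'   tibble with `method` and `error` columns.
#' @param by Grouping columns (default `"method"`).
#' @param value Which column to summarize: `"error"` (vs log actuals) or
#'   `"deviation"` (vs nominal layout).
#' @param action_levels Thresholds in mm for the within-tolerance fractions.
#' @return Tibble with one row per group: `n`, `mean`, `sd`, `mean_abs`,
#'   `sd_abs`, `max_abs` and `within_<level>` columns.
#' @export
summarize_qa <- function(qa, by = "method", value = "error",
                         action_levels = attr(qa, "action_levels") %||% c(0.1, 0.2)) {
  x <- tibble::as_tibble(qa)
  x$.err <- x[[value]]
  x <- x[!is.na(x$.err), ]
  out <- x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.err),
      sd = stats::sd(.err),
      mean_abs = mean(abs(.err)),
      sd_abs = stats::sd(abs(.err)),
      max_abs = max(abs(.err)),
      .groups = "drop"
    )
  for (lvl in action_levels) {
    frac <- x |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(f = mean(abs(.err) <= lvl), .groups = "drop")
    out[[sprintf("within_%g", lvl)]] <- frac$f
  }
  out
}

#' @export
print.mlc_qa <- function(x, ...) {
  cat(sprintf("<mlc_qa> scheme %s, %g mm nominal abutment, %d leaf pairs\n",
              attr(x, "scheme"), attr(x, "nominal_width_mm"),
              length(unique(x$pair))))
  print(summarize_qa(x))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
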