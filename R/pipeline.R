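#' Panel geometry covering only the leaf pairs under study
#'
#' Full-panel simulations are rarely needed for method studies: this helper
#' returns a geometry whose rows cover `n_pairs` projected leaf bands plus a
#' small margin, with the full-width motion axis retained.
#'
#' @param n_pairs Number of leaf pairs to cover.
#' @param leaf_width_mm Projected leaf width at the isocenter, mm.
#' @param cols Panel columns (motion axis), default 1024.
#' @param margin_rows Extra rows added beyond the bands (total).
#' @return A [geometry_model()].
#' @export
study_geometry <- function(n_pairs, leaf_width_mm = 5, cols = 1024,
                           margin_rows = 24) {
  rows_per_pair <- leaf_width_mm / geometry_model()$pixel_pitch_iso_mm
  geometry_model(rows = n_pairs * rows_per_pair + margin_rows, cols = cols)
}

# derived sub-seed, kept well below 2^31 for 32-bit R integers
sub_seed <- function(seed, session, field) {
  (as.integer(seed) %% 20000L) * 100000L + session * 1000L + field
}

# one session's feature + log-actual table across the calibration widths
measure_session <- function(machine, widths, session, seed, beam, jitter,
                            geometry, field_y_mm, plan_args, prominence) {
  set.seed(sub_seed(seed, session, 0L))
  output_factor <- stats::rnorm(1, 1, beam$output_fluctuation_sd)
  open <- simulate_open_field(beam, geometry, seed = sub_seed(seed, session, 99L),
                              output_factor = output_factor)
  purrr::imap(widths, \(w, i) {
    plan <- do.call(field_plan, c(list(nominal_width_mm = w,
                                       field_y_mm = field_y_mm), plan_args))
    sim <- simulate_picket_fence(plan, beam, jitter, geometry,
                                 seed = sub_seed(seed, session, i),
                                 machine = machine,
                                 output_factor = output_factor)
    norm <- normalize_epid(sim$image, open)
    feats <- extract_features(norm, plan, beam, prominence = prominence)
    act <- log_abutments(segment_leaf_states(sim$log), plan)
    feats |>
      dplyr::left_join(act, by = c("strip", "pair")) |>
      dplyr::mutate(session = session, nominal_width = w, .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Run a full synthetic calibration campaign
#'
#' Simulates `n_sessions` picket-fence sessions of one machine across the
#' calibration field widths (2-14 mm by default), extracts the per-pair
#' abutment features and log-derived actual widths, averages them into
#' nominal values and fits the calibration curves for the requested
#' schemes.
#'
#' @param seed Integer seed for the whole campaign.
#' @param widths Calibration field nominal abutment widths, mm.
#' @param n_sessions Number of sessions averaged into the nominal values.
#' @param n_pairs Number of leaf pairs simulated and analyzed.
#' @param beam,jitter A [beam_model()] and [jitter_model()].
#' @param geometry A [geometry_model()]; defaults to a reduced panel
#'   covering `n_pairs` ([study_geometry()]).
#' @param schemes Calibration schemes to fit.
#' @param prominence Valley prominence threshold.
#' @param plan_args Extra arguments passed to [field_plan()] (e.g.
#'   `segment_mu`).
#' @return A list of class `mlc_campaign`: `machine`, `sessions` (per-session
#'   measurements), `nominal`, `calibration`, plus the models used.
#' @export
run_calibration_study <- function(seed, widths = 2:14, n_sessions = 8,
                                  n_pairs = 12,
                                  beam = beam_model(),
                                  jitter = jitter_model(),
                                  geometry = NULL,
                                  schemes = c("A", "B", "C"),
                                  prominence = 0.02,
                                  plan_args = list()) {
  if (is.null(geometry)) geometry <- study_geometry(n_pairs)
  field_y_mm <- n_pairs * (plan_args$leaf_width_mm %||% 5)
  machine <- simulate_machine(n_pairs, beam, jitter,
                              seed = sub_seed(seed, 0L, 0L))
  sessions <- purrr::map(seq_len(n_sessions), \(s) {
    measure_session(machine, widths, s, seed, beam, jitter, geometry,
                    field_y_mm, plan_args, prominence)
  }) |>
    purrr::list_rbind()
  nominal <- build_nominal_values(sessions)
  calibration <- fit_calibration(nominal, schemes = schemes,
                                 min_widths = min(13, length(widths)))
  structure(
    list(machine = machine, sessions = sessions, nominal = nominal,
         calibration = calibration, beam = beam, jitter = jitter,
         geometry = geometry, n_pairs = n_pairs, field_y_mm = field_y_mm,
         widths = widths, seed = seed, plan_args = plan_args,
         prominence = prominence),
    class = "mlc_campaign"
  )
}

#' @export
print.mlc_campaign <- function(x, ...) {
  cat(sprintf(
    "<mlc_campaign> %d sessions x %d widths (%g-%g mm), %d leaf pairs, schemes %s\n",
    length(unique(x$sessions$session)), length(x$widths), min(x$widths),
    max(x$widths), x$n_pairs,
    paste(unique(x$calibration$scheme), collapse = "/")))
  invisible(x)
}

#' Build the error map of a validation field
#'
#' Distributes signed error magnitudes over the analyzed strips and leaf
#' pairs. In the `"single"` pattern each error displaces one bank-A leaf of
#' a unique (strip, pair); in the `"both"` pattern each error displaces
#' both facing leaves of two consecutive adjacent pairs (same signed
#' offset, i.e. a gap translation).
#'
#' @param magnitudes Positive error magnitudes, mm; both signs are injected.
#' @param pattern `"single"` or `"both"`.
#' @param n_pairs Leaf pairs available per strip.
#' @param strips Strip indices to distribute over.
#' @param signs Signs applied to each magnitude (default both).
#' @return An `error_map` tibble for [field_plan()], with an extra
#'   `error_id` column.
#' @export
validation_error_map <- function(magnitudes = c(0.6, 0.8, 1.2, 1.8, 2.4),
                                 pattern = c("single", "both"),
                                 n_pairs = 12, strips = 2:6,
                                 signs = c(1, -1)) {
  pattern <- match.arg(pattern)
  offsets <- as.numeric(outer(magnitudes, signs))
  block <- if (pattern == "single") 1L else 2L
  next_pair <- stats::setNames(rep(1L, length(strips)), strips)
  rows <- list()
  for (i in seq_along(offsets)) {
    placed <- FALSE
    for (s_i in seq_along(strips)) {
      s <- strips[((i - 1L + s_i - 1L) %% length(strips)) + 1L]
      p0 <- next_pair[[as.character(s)]]
      if (p0 + block - 1L <= n_pairs) {
        pairs <- p0:(p0 + block - 1L)
        rows[[i]] <- tibble::tibble(
          error_id = i, strip = s, pair = pairs,
          bank = if (pattern == "single") "A" else "both",
          offset_mm = offsets[i], epid_only = FALSE)
        next_pair[[as.character(s)]] <- p0 + block
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      abort_mlcqa("not enough leaf pairs to place every validation error.",
                  "mlcqa_invalid_plan")
    }
  }
  purrr::list_rbind(rows)
}

# (strip, pair, side) -> injected displacement implied by an error map
expected_deviations <- function(error_map) {
  if (nrow(error_map) == 0) {
    return(tibble::tibble(strip = integer(), pair = integer(),
                          side = character(), injected_mm = numeric()))
  }
  purrr::pmap(error_map, \(strip, pair, bank, offset_mm, ...) {
    sides <- switch(bank, A = "right", B = "left", both = c("left", "right"))
    tibble::tibble(strip = strip, pair = pair, side = sides,
                   injected_mm = offset_mm)
  }) |>
    purrr::list_rbind()
}

#' Simulate and analyze one validation field
#'
#' @param campaign A [run_calibration_study()] result.
#' @param width Nominal abutment width of the validation field, mm.
#' @param error_map Injected leaf displacements (see [field_plan()]).
#' @param seed Integer seed.
#' @param scheme Calibration scheme to apply.
#' @return An `mlc_qa` tibble with an `injected_mm` column (`NA` for
#'   undisturbed leaves).
#' @export
analyze_validation_field <- function(campaign, width, error_map, seed,
                                     scheme = "C") {
  plan <- do.call(field_plan, c(
    list(nominal_width_mm = width, field_y_mm = campaign$field_y_mm,
         error_map = error_map[, setdiff(names(error_map), "error_id")]),
    campaign$plan_args))
  set.seed(seed)
  output_factor <- stats::rnorm(1, 1, campaign$beam$output_fluctuation_sd)
  open <- simulate_open_field(campaign$beam, campaign$geometry,
                              seed = seed + 7L, output_factor = output_factor)
  sim <- simulate_picket_fence(plan, campaign$beam, campaign$jitter,
                               campaign$geometry, seed = seed + 13L,
                               machine = campaign$machine,
                               output_factor = output_factor)
  norm <- normalize_epid(sim$image, open)
  qa <- analyze_field(norm, campaign$calibration, sim$log, plan,
                      scheme = scheme, beam = campaign$beam,
                      prominence = campaign$prominence)
  inj <- expected_deviations(error_map)
  out <- dplyr::left_join(qa, inj, by = c("strip", "pair", "side"))
  class(out) <- class(qa)
  for (a in c("scheme", "action_levels", "nominal_width_mm")) {
    attr(out, a) <- attr(qa, a)
  }
  out
}

#' Replicate the error-injection validation design synthetically
#'
#' For each seed, nominal width and error pattern, simulates a picket-fence
#' field carrying the signed error magnitudes (default +/-0.6, 0.8, 1.2,
#' 1.8, 2.4 mm) distributed over the analyzed strips, analyzes it against
#' the campaign's calibration and tags every leaf with its injected
#' displacement.
#'
#' @param campaign A [run_calibration_study()] result.
#' @param widths Validation field widths, mm (default 5, 8, 11).
#' @param magnitudes Error magnitudes, mm.
#' @param patterns Subset of `c("single", "both")`.
#' @param seeds Integer seeds, one validation round each.
#' @param scheme Calibration scheme to apply.
#' @return A tibble of class `mlc_validation`: all QA rows with `seed`,
#'   `width`, `pattern` and `injected_mm` columns.
#' @export
run_validation_study <- function(campaign, widths = c(5, 8, 11),
                                 magnitudes = c(0.6, 0.8, 1.2, 1.8, 2.4),
                                 patterns = c("single", "both"),
                                 seeds = 1:10, scheme = "C") {
  grid <- tidyr::expand_grid(seed = seeds, width = widths, pattern = patterns)
  out <- purrr::pmap(grid, \(seed, width, pattern) {
    em <- validation_error_map(magnitudes, pattern,
                               n_pairs = campaign$n_pairs,
                               strips = analyzed_strips(
                                 do.call(field_plan, c(
                                   list(nominal_width_mm = width,
                                        field_y_mm = campaign$field_y_mm),
                                   campaign$plan_args))))
    qa <- analyze_validation_field(
      campaign, width, em,
      seed = sub_seed(campaign$seed, 50L + seed, match(width, widths) * 10L +
                        match(pattern, patterns)),
      scheme = scheme)
    dplyr::mutate(qa, seed = seed, width = width, pattern = pattern,
                  .before = 1)
  }) |>
    purrr::list_rbind()
  class(out) <- c("mlc_validation", class(out))
  out
}

#' Recovery statistics of a validation study
#'
#' @param validation A [run_validation_study()] result.
#' @param methods Methods to report (default all four).
#' @return Tibble per (method): accuracy versus the log-derived actual
#'   positions over the injected leaves (`mean_abs_error`), and recovery of
#'   the injected displacement (`mean_abs_recovery_residual`, where the
#'   residual is `deviation - injected`).
#' @export
recovery_stats <- function(validation,
                           methods = c("fwhm", "valley_area", "valley_depth",
                                       "integration")) {
  validation |>
    dplyr::filter(!is.na(injected_mm), method %in% methods) |>
    dplyr::group_by(method) |>
    dplyr::summarise(
      n = sum(!is.na(error)),
      mean_abs_error = mean(abs(error), na.rm = TRUE),
      max_abs_error = max(abs(error), na.rm = TRUE),
      mean_abs_recovery_residual = mean(abs(deviation - injected_mm),
                                        na.rm = TRUE),
      .groups = "drop"
    )
}
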