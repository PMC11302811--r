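#' Realize the fixed per-machine properties of a simulated linac
#'
#' A simulated machine has two persistent traits that stay fixed across all
#' sessions and fields delivered on it: the multiplicative per-leaf-pair
#' response factors and the per-leaf systematic position offsets. Realizing
#' them once and passing the result to every [simulate_picket_fence()] call
#' of a campaign is what makes per-leaf-pair calibration (Scheme C)
#' meaningful.
#'
#' @param n_pairs Number of leaf pairs in the simulated field.
#' @param beam A [beam_model()].
#' @param jitter A [jitter_model()].
#' @param seed Integer seed.
#' @return A list of class `sim_machine` with `pair_response` (numeric
#'   vector) and `offset_a`, `offset_b` (per-leaf systematic offsets, mm).
#' @export
simulate_machine <- function(n_pairs, beam, jitter, seed) {
  set.seed(seed)
  machine <- draw_machine_traits(n_pairs, beam, jitter)
  machine$seed <- seed
  machine
}

# draws from the current RNG stream (no reseeding)
draw_machine_traits <- function(n_pairs, beam, jitter) {
  resp <- if (!is.null(beam$pair_response)) {
    if (length(beam$pair_response) != n_pairs) {
      abort_mlcqa("`beam$pair_response` length does not match `n_pairs`.",
                  "mlcqa_invalid_model")
    }
    beam$pair_response
  } else {
    pmin(pmax(stats::rnorm(n_pairs, 1, beam$pair_response_sd), 0.801), 1.199)
  }
  structure(
    list(
      n_pairs = n_pairs,
      pair_response = resp,
      offset_a = stats::rnorm(n_pairs, 0, jitter$systematic_offset_sd),
      offset_b = stats::rnorm(n_pairs, 0, jitter$systematic_offset_sd),
      seed = NA_integer_
    ),
    class = "sim_machine"
  )
}

# aperture-edge matrices [n_segments x n_pairs] for one reference frame
edge_matrices <- function(plan, which) {
  pos <- plan_positions(plan, which)
  a <- matrix(pos$position_mm[pos$bank == "A"], nrow = plan$n_segments,
              byrow = TRUE)
  b <- matrix(pos$position_mm[pos$bank == "B"], nrow = plan$n_segments,
              byrow = TRUE)
  list(a = a, b = b)
}

#' Simulate an open-field EPID acquisition
#'
#' Produces a raw-encoded portal image of a square open field: decoded
#' in-field signal near `beam$open_signal * mu / 100` (times the session
#' output factor and pixel noise) and near the transmission level outside.
#'
#' @param beam A [beam_model()].
#' @param geometry A [geometry_model()].
#' @param seed Integer seed.
#' @param mu Delivered monitor units.
#' @param field_xy_mm Open-field size `(x, y)` at the isocenter plane, mm.
#' @param output_factor Session beam-output factor; drawn from
#'   `N(1, output_fluctuation_sd)` when `NULL`. Pass the factor shared with
#'   the session's picket-fence fields so that normalization cancels it.
#' @return An [epid_image()].
#' @export
simulate_open_field <- function(beam, geometry, seed, mu = 100,
                                field_xy_mm = c(260, 260),
                                output_factor = NULL) {
  set.seed(seed)
  if (is.null(output_factor)) {
    output_factor <- stats::rnorm(1, 1, beam$output_fluctuation_sd)
  }
  x <- pixel_to_iso(0:(geometry$cols - 1), geometry, "col")
  y <- pixel_to_iso(0:(geometry$rows - 1), geometry, "row")
  ex <- beam_edge(x + field_xy_mm[1] / 2, beam) *
    beam_edge(field_xy_mm[1] / 2 - x, beam)
  ey <- beam_edge(y + field_xy_mm[2] / 2, beam) *
    beam_edge(field_xy_mm[2] / 2 - y, beam)
  fluence <- beam$transmission + (1 - beam$transmission) * outer(ey, ex)
  signal <- beam$open_signal * (mu / 100) * output_factor * fluence
  if (beam$noise_sd > 0) {
    signal <- signal * (1 + stats::rnorm(length(signal), 0, beam$noise_sd))
  }
  encode_signal(signal, geometry,
                meta = list(kind = "open_field", seed = seed, mu = mu,
                            output_factor = output_factor,
                            origin = geometry$origin,
                            field_xy_mm = field_xy_mm))
}

#' Simulate a picket-fence EPID image and its delivery log
#'
#' Delivers the plan's step-and-shoot segments on a synthetic linac. Each
#' collimated edge follows the [beam_edge()] penumbra (error-function core
#' plus glare tail); a closed leaf transmits `beam$transmission` of the
#' open signal; at each abutment the profile is the sum of the two facing
#' penumbra tails plus the transmission floor. The delivery log gets one
#' record per 40 ms (272 beam-on records per 100 MU segment by default) with
#' per-record leaf jitter and the machine's persistent offsets. The image is
#' rendered from the per-segment mean delivered leaf positions, so image and
#' log describe the same delivered geometry; injected `error_map`
#' displacements are real leaf displacements recorded by both (unless marked
#' `epid_only`).
#'
#' @param plan A [field_plan()].
#' @param beam A [beam_model()].
#' @param jitter A [jitter_model()].
#' @param geometry A [geometry_model()].
#' @param seed Integer seed for the per-field randomness (log jitter, pixel
#'   noise, and — when `machine`/`output_factor` are not supplied — the
#'   machine traits and session output factor).
#' @param machine A [simulate_machine()] result, or `NULL` to realize one
#'   from `seed`.
#' @param output_factor Session beam-output factor; drawn when `NULL`.
#' @return A list of class `pf_simulation`: `image` ([epid_image()]), `log`
#'   (delivery-log tibble in the CSV dialect of [write_delivery_log()]),
#'   `plan`, `machine`, `output_factor`.
#' @export
simulate_picket_fence <- function(plan, beam, jitter, geometry, seed,
                                  machine = NULL, output_factor = NULL) {
  n_pairs <- plan$n_pairs
  set.seed(seed)
  if (is.null(machine)) {
    machine <- draw_machine_traits(n_pairs, beam, jitter)
    machine$seed <- seed
  }
  if (machine$n_pairs != n_pairs) {
    abort_mlcqa("`machine` was realized for a different number of leaf pairs.",
                "mlcqa_invalid_model")
  }
  if (is.null(output_factor)) {
    output_factor <- stats::rnorm(1, 1, beam$output_fluctuation_sd)
  }

  cmd <- edge_matrices(plan, "commanded")
  img_frame <- edge_matrices(plan, "imaged")
  n_on <- as.integer(round(jitter$records_per_100mu * plan$segment_mu / 100))
  if (n_on < 1) {
    abort_mlcqa("segment MU too small: no beam-on records.", "mlcqa_invalid_plan")
  }
  n_off <- jitter$beam_off_records

  # --- delivery log -------------------------------------------------------
  rec_list <- vector("list", plan$n_segments)
  mean_a <- matrix(0, plan$n_segments, n_pairs)
  mean_b <- matrix(0, plan$n_segments, n_pairs)
  for (k in seq_len(plan$n_segments)) {
    n_tot <- n_off + n_on
    ja <- matrix(stats::rnorm(n_tot * n_pairs, 0, jitter$per_record_sd),
                 n_tot, n_pairs)
    jb <- matrix(stats::rnorm(n_tot * n_pairs, 0, jitter$per_record_sd),
                 n_tot, n_pairs)
    rec_a <- sweep(ja, 2, cmd$a[k, ] + machine$offset_a, "+")
    rec_b <- sweep(jb, 2, cmd$b[k, ] + machine$offset_b, "+")
    beam_on <- rep(c(0L, 1L), c(n_off, n_on))
    on <- beam_on == 1L
    mean_a[k, ] <- colMeans(rec_a[on, , drop = FALSE])
    mean_b[k, ] <- colMeans(rec_b[on, , drop = FALSE])
    rec_list[[k]] <- cbind(segment = k, beam_on = beam_on, rec_a, rec_b)
  }
  rec <- do.call(rbind, rec_list)
  log <- tibble::as_tibble(as.data.frame(rec[, 3:ncol(rec), drop = FALSE]),
                           .name_repair = "minimal")
  names(log) <- c(leaf_columns("A", n_pairs), leaf_columns("B", n_pairs))
  log <- dplyr::bind_cols(
    tibble::tibble(
      time_ms = (seq_len(nrow(rec)) - 1L) * jitter$record_interval_ms,
      segment = as.integer(rec[, "segment"]),
      beam_on = as.integer(rec[, "beam_on"])
    ),
    log
  )

  # --- image --------------------------------------------------------------
  # edges delivered on the image: per-segment log means, plus any image-only
  # discrepancy relative to the commanded frame
  edge_a <- mean_a + (img_frame$a - cmd$a)
  edge_b <- mean_b + (img_frame$b - cmd$b)

  tr <- beam$transmission
  x <- pixel_to_iso(0:(geometry$cols - 1), geometry, "col")
  y <- pixel_to_iso(0:(geometry$rows - 1), geometry, "row")
  mu_frac <- plan$segment_mu / 100

  prof <- matrix(0, n_pairs, geometry$cols)
  for (j in seq_len(n_pairs)) {
    acc <- numeric(geometry$cols)
    for (k in seq_len(plan$n_segments)) {
      acc <- acc + tr + (1 - tr) *
        beam_edge(x - edge_a[k, j], beam) *
        beam_edge(edge_b[k, j] - x, beam)
    }
    prof[j, ] <- mu_frac * acc * machine$pair_response[j]
  }

  half_y <- plan$field_y_mm / 2
  ey <- beam_edge(y + half_y, beam) * beam_edge(half_y - y, beam)
  pair_of_row <- pmin(pmax(floor((y + half_y) / plan$leaf_width_mm) + 1, 1),
                      n_pairs)
  fluence <- prof[pair_of_row, , drop = FALSE] * ey

  if (beam$interleaf_leakage_amp > 0 && n_pairs > 1) {
    yb <- -half_y + seq_len(n_pairs - 1) * plan$leaf_width_mm
    ridge <- rowSums(outer(y, yb, function(yy, b) {
      exp(-(yy - b)^2 / (2 * 0.2^2))
    }))
    x_in <- x >= min(img_frame$a) & x <= max(img_frame$b)
    fluence <- fluence + beam$interleaf_leakage_amp * plan$n_segments *
      mu_frac * outer(ridge * ey, as.numeric(x_in))
  }

  signal <- beam$open_signal * output_factor * fluence
  if (beam$noise_sd > 0) {
    signal <- signal * (1 + stats::rnorm(length(signal), 0, beam$noise_sd))
  }
  image <- encode_signal(
    signal, geometry,
    meta = list(kind = "picket_fence", seed = seed,
                nominal_width_mm = plan$nominal_width_mm,
                segment_mu = plan$segment_mu,
                output_factor = output_factor, origin = geometry$origin))

  structure(list(image = image, log = log, plan = plan, machine = machine,
                 output_factor = output_factor),
            class = "pf_simulation")
}

#' @export
print.pf_simulation <- function(x, ...) {
  cat(sprintf(
    "<pf_simulation> %g mm abutment, %d log records (%d beam-on), %d x %d px image\n",
    x$plan$nominal_width_mm, nrow(x$log), sum(x$log$beam_on == 1L),
    nrow(x$image$stored), ncol(x$image$stored)))
  invisible(x)
}
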