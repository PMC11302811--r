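#' EPID portal image container
#'
#' Raw-encoded 16-bit portal image: the delivered signal at a pixel is
#' `65535 - stored`. The container keeps the stored values, the panel
#' geometry and free-form acquisition metadata.
#'
#' @param stored Integer matrix of stored pixel values in `[0, 65535]`,
#'   `geometry$rows` x `geometry$cols`.
#' @param geometry A [geometry_model()].
#' @param meta Named list of acquisition metadata (seed, plan summary, ...).
#'
#' @return An object of class `epid_image`.
#' @export
epid_image <- function(stored, geometry, meta = list()) {
  if (!is.matrix(stored)) {
    abort_mlcqa("`stored` must be a matrix.", "mlcqa_invalid_image")
  }
  if (nrow(stored) != geometry$rows || ncol(stored) != geometry$cols) {
    abort_mlcqa("image dimensions do not match the geometry.",
                "mlcqa_invalid_image")
  }
  if (any(stored < 0 | stored > 65535)) {
    abort_mlcqa("stored pixel values must lie in [0, 65535].",
                "mlcqa_invalid_image")
  }
  storage.mode(stored) <- "integer"
  structure(list(stored = stored, geometry = geometry, meta = meta),
            class = "epid_image")
}

# encode a signal matrix into the raw 16-bit representation
encode_signal <- function(signal, geometry, meta = list()) {
  stored <- 65535 - round(signal)
  stored[stored < 0] <- 0L
  stored[stored > 65535] <- 65535L
  epid_image(stored, geometry, meta)
}

#' Decode the delivered signal of a raw EPID image
#'
#' The raw encoding stores `65535 - signal`, so decoding subtracts the
#' stored values from 65535 element-wise.
#'
#' @param image An [epid_image()].
#' @return Numeric matrix of decoded signal values.
#' @export
decode_signal <- function(image) {
  65535 - image$stored
}

#' Open-field normalization of a picket-fence image
#'
#' Divides the decoded picket-fence signal by the decoded open-field signal
#' pixel-wise, which cancels session-to-session beam output and energy
#' fluctuations. Pixels whose open-field signal falls below `floor` are
#' masked (`NA`) rather than producing unbounded ratios.
#'
#' @param field An [epid_image()] of the picket-fence delivery.
#' @param open An [epid_image()] of the matching open field from the same
#'   session.
#' @param floor Signal floor below which the open field is considered
#'   unexposed. Defaults to 5% of the median in-field open signal (pixels
#'   above half the open-field maximum).
#' @return An object of class `epid_norm`: list with `values` (matrix of
#'   unitless ratios, `NA` where masked), `geometry` and `meta`.
#' @export
normalize_epid <- function(field, open, floor = NULL) {
  if (!identical(dim(field$stored), dim(open$stored))) {
    abort_mlcqa("field and open-field images have different shapes.",
                "mlcqa_shape_mismatch")
  }
  raw_sig <- decode_signal(field)
  open_sig <- decode_signal(open)
  if (is.null(floor)) {
    in_field <- open_sig > max(open_sig) / 2
    if (!any(in_field)) {
      abort_mlcqa("open field contains no exposed pixels.", "mlcqa_bad_open_field")
    }
    floor <- 0.05 * stats::median(open_sig[in_field])
  }
  ok <- open_sig > floor
  if (!any(ok)) {
    abort_mlcqa("entire open field is below the signal floor.",
                "mlcqa_bad_open_field")
  }
  values <- matrix(NA_real_, nrow(raw_sig), ncol(raw_sig))
  values[ok] <- raw_sig[ok] / open_sig[ok]
  structure(list(values = values, geometry = field$geometry,
                 meta = c(field$meta, list(norm_floor = floor))),
            class = "epid_norm")
}

#' Map 0-based pixel indices to isocenter-plane millimetres
#'
#' Positions are `(index - origin) * pixel_pitch_iso_mm` per axis, with
#' pixel centers at integer indices.
#'
#' @param index Numeric vector of 0-based pixel indices.
#' @param geometry A [geometry_model()].
#' @param axis `"col"` (leaf-motion axis, x) or `"row"` (cross-leaf axis, y).
#' @return Numeric vector of positions in mm.
#' @export
pixel_to_iso <- function(index, geometry, axis = c("col", "row")) {
  axis <- match.arg(axis)
  origin <- if (axis == "col") geometry$origin[2] else geometry$origin[1]
  (index - origin) * geometry$pixel_pitch_iso_mm
}

#' Inverse of [pixel_to_iso()]
#' @param position_mm Numeric vector of isocenter-plane positions, mm.
#' @inheritParams pixel_to_iso
#' @return Numeric vector of fractional 0-based pixel indices.
#' @export
iso_to_pixel <- function(position_mm, geometry, axis = c("col", "row")) {
  axis <- match.arg(axis)
  origin <- if (axis == "col") geometry$origin[2] else geometry$origin[1]
  position_mm / geometry$pixel_pitch_iso_mm + origin
}

#' @export
print.epid_image <- function(x, ...) {
  sig <- 65535 - range(x$stored)
  cat(sprintf("<epid_image> %d x %d px (raw 16-bit), decoded signal %d..%d\n",
              nrow(x$stored), ncol(x$stored), sig[2], sig[1]))
  invisible(x)
}

#' @export
print.epid_norm <- function(x, ...) {
  cat(sprintf("<epid_norm> %d x %d px, %d masked, in-field ratio ~%.3f\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              stats::median(x$values, na.rm = TRUE)))
  invisible(x)
}
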