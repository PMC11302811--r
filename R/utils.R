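# internal helpers shared across modules

abort_mlcqa <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "mlcqa_error"), ...)
}

stopifnot_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                    strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_mlcqa(sprintf("`%s` must be a single finite number.", name),
                "mlcqa_invalid_model")
  }
  lo_ok <- if (strict_min) x > min else x >= min
  if (!lo_ok || x > max) {
    abort_mlcqa(sprintf("`%s` = %g is outside its valid range.", name, x),
                "mlcqa_invalid_model")
  }
  invisible(x)
}

# zero-padded leaf column names of the delivery-log CSV dialect
leaf_columns <- function(bank, n) sprintf("bank%s_leaf_%03d", bank, seq_len(n))

utils::globalVariables(c(
  ".", ".err", ".feature", "actual_p_left", "actual_p_right", "actual_width",
  "bank", "beam_on", "center_mm", "chosen", "coef", "curve", "data",
  "deviation", "error", "fwhm", "injected_mm", "kind", "method", "n",
  "n_records", "nominal_width", "p_left", "p_right", "pair", "position_mm",
  "position_mm_cmd", "quantity", "scheme", "segment", "session", "side",
  "status", "strip", "threshold_mm", "time_ms", "valley_area", "valley_depth",
  "value", "w_abutment", "w_feature", "width", "x", "y"
))
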