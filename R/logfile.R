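#' Write a delivery log in the documented CSV dialect
#'
#' One row per record (every 40 ms by default). Columns: `time_ms`,
#' `segment`, `beam_on`, then `bankA_leaf_001..N` and `bankB_leaf_001..N`
#' with leaf positions in mm at the isocenter plane.
#'
#' @param log Delivery-log tibble as produced by [simulate_picket_fence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_delivery_log <- function(log, path) {
  readr::write_csv(log, path)
  invisible(path)
}

#' Parse a delivery log from the CSV dialect
#'
#' Validates the dialect and returns the records as a tibble, one row per
#' 40 ms snapshot. Beam-off records are kept but flagged so downstream
#' averaging can exclude them.
#'
#' @param source Path to a CSV delivery log, or a data frame already in the
#'   dialect (useful for in-memory round trips).
#' @return Tibble of records sorted as recorded, with attribute `n_pairs`.
#' @export
parse_log <- function(source) {
  log <- if (is.data.frame(source)) {
    tibble::as_tibble(source)
  } else {
    readr::read_csv(source, show_col_types = FALSE, progress = FALSE)
  }
  for (col in c("time_ms", "segment", "beam_on")) {
    if (!col %in% names(log)) {
      abort_mlcqa(sprintf("delivery log is missing column `%s`.", col),
                  "mlcqa_log_parse")
    }
  }
  a_cols <- grep("^bankA_leaf_\\d+$", names(log), value = TRUE)
  b_cols <- grep("^bankB_leaf_\\d+$", names(log), value = TRUE)
  if (length(a_cols) == 0 && length(b_cols) == 0) {
    abort_mlcqa("delivery log has no leaf position columns.", "mlcqa_log_parse")
  }
  if (length(a_cols) != length(b_cols)) {
    miss <- if (length(a_cols) > length(b_cols)) {
      setdiff(sub("bankA", "bankB", a_cols), b_cols)
    } else {
      setdiff(sub("bankB", "bankA", b_cols), a_cols)
    }
    abort_mlcqa(sprintf("bank A/B leaf columns mismatch; missing: %s",
                        paste(miss, collapse = ", ")),
                "mlcqa_log_parse")
  }
  expected <- c(leaf_columns("A", length(a_cols)),
                leaf_columns("B", length(b_cols)))
  missing <- setdiff(expected, names(log))
  if (length(missing) > 0) {
    abort_mlcqa(sprintf("delivery log is missing column(s): %s",
                        paste(missing, collapse = ", ")),
                "mlcqa_log_parse")
  }
  if (any(diff(log$time_ms) <= 0)) {
    row <- which(diff(log$time_ms) <= 0)[1] + 1L
    abort_mlcqa(sprintf("non-monotonic `time_ms` at row %d.", row),
                "mlcqa_log_parse")
  }
  bad <- which(!stats::complete.cases(log[, expected]))
  if (length(bad) > 0) {
    abort_mlcqa(sprintf("missing leaf positions at row %d.", bad[1]),
                "mlcqa_log_parse")
  }
  attr(log, "n_pairs") <- length(a_cols)
  log
}

# long view of the leaf position columns
log_long <- function(records, beam_on_only = TRUE) {
  n_pairs <- length(grep("^bankA_leaf_\\d+$", names(records)))
  if (beam_on_only) records <- records[records$beam_on == 1L, ]
  records |>
    tidyr::pivot_longer(
      cols = dplyr::matches("^bank[AB]_leaf_\\d+$"),
      names_to = c("bank", "pair"),
      names_pattern = "bank([AB])_leaf_(\\d+)",
      values_to = "position_mm"
    ) |>
    dplyr::mutate(pair = as.integer(pair))
}

#' Per-segment mean leaf positions from a delivery log
#'
#' The leaf positions recorded for each segment are averaged over that
#' segment's beam-on records; the mean is the actual leaf position, and
#' opposing-edge differences of these means are the actual abutment widths.
#'
#' @param records Parsed delivery log ([parse_log()] output or the tibble
#'   from [simulate_picket_fence()]).
#' @param segments Segments to average; default all present.
#' @return Tibble with `segment`, `bank`, `pair`, `position_mm` (mean over
#'   beam-on records) and `n_records`.
#' @export
segment_leaf_states <- function(records, segments = NULL) {
  on <- records[records$beam_on == 1L, ]
  if (is.null(segments)) segments <- sort(unique(records$segment))
  missing <- setdiff(segments, unique(on$segment))
  if (length(missing) > 0) {
    abort_mlcqa(sprintf("no beam-on records for segment(s): %s",
                        paste(missing, collapse = ", ")),
                "mlcqa_log_empty_segment")
  }
  n_pairs <- length(grep("^bankA_leaf_\\d+$", names(records)))
  cols <- c(leaf_columns("A", n_pairs), leaf_columns("B", n_pairs))
  out <- lapply(segments, function(s) {
    m <- as.matrix(on[on$segment == s, cols, drop = FALSE])
    tibble::tibble(
      segment = as.integer(s),
      bank = rep(c("A", "B"), each = n_pairs),
      pair = rep(seq_len(n_pairs), 2L),
      position_mm = unname(colMeans(m)),
      n_records = nrow(m)
    )
  })
  dplyr::arrange(purrr::list_rbind(out), segment, bank, pair)
}

#' Mean leaf positions of a single segment
#'
#' Convenience wrapper around [segment_leaf_states()] for one segment.
#'
#' @inheritParams segment_leaf_states
#' @param segment Segment index.
#' @return Tibble with `bank`, `pair`, `position_mm`, `n_records`.
#' @export
average_segment_positions <- function(records, segment) {
  st <- segment_leaf_states(records, segments = segment)
  st[, c("bank", "pair", "position_mm", "n_records")]
}

#' Actual abutment geometry from per-segment leaf states
#'
#' For strip `s`, the left boundary of pair `j`'s abutment is segment `s`'s
#' bank-B mean position and the right boundary is segment `s + 1`'s bank-A
#' mean position; the actual abutment width is their difference.
#'
#' @param states Output of [segment_leaf_states()].
#' @param plan A [field_plan()] (defines the analyzed strips).
#' @param strips Strip indices; defaults to the analyzed central strips.
#' @return Tibble with `strip`, `pair`, `actual_p_left`, `actual_p_right`,
#'   `actual_width` (mm).
#' @export
log_abutments <- function(states, plan, strips = NULL) {
  if (is.null(strips)) strips <- analyzed_strips(plan)
  key <- function(seg, bank) paste(seg, bank, sep = "/")
  idx <- split(seq_len(nrow(states)), key(states$segment, states$bank))
  out <- tidyr::expand_grid(strip = strips, pair = seq_len(plan$n_pairs))
  left <- right <- numeric(nrow(out))
  for (i in seq_len(nrow(out))) {
    s <- out$strip[i]; p <- out$pair[i]
    bi <- idx[[key(s, "B")]]
    ai <- idx[[key(s + 1L, "A")]]
    if (is.null(bi) || is.null(ai)) {
      abort_mlcqa(sprintf("log states do not cover strip %d.", s),
                  "mlcqa_log_empty_segment")
    }
    left[i] <- states$position_mm[bi][match(p, states$pair[bi])]
    right[i] <- states$position_mm[ai][match(p, states$pair[ai])]
  }
  out$actual_p_left <- left
  out$actual_p_right <- right
  out$actual_width <- right - left
  out
}

#' Leaf-position and abutment-width error statistics of a delivery log
#'
#' Per-record signed leaf position errors are `recorded - commanded`; the
#' per-record abutment width error of strip `s` pairs the r-th beam-on
#' record of segment `s + 1` (bank A) with the r-th beam-on record of
#' segment `s` (bank B). Reported are mean/SD/max of the signed and
#' absolute errors plus the fraction of errors beyond each threshold.
#'
#' @param records Parsed delivery log.
#' @param plan A [field_plan()] supplying the commanded positions.
#' @param thresholds Exceedance thresholds in mm (default 0.1 and 0.2).
#' @return A list of class `mlc_log_stats`: `stats` (tibble with rows
#'   `leaf_position`, `abs_leaf_position`, `abutment_width`,
#'   `abs_abutment_width` and columns `mean`, `sd`, `max`) and `exceedance`
#'   (tibble with `quantity`, `threshold_mm`, `fraction`).
#' @export
log_error_stats <- function(records, plan, thresholds = c(0.1, 0.2)) {
  n_pairs <- length(grep("^bankA_leaf_\\d+$", names(records)))
  if (n_pairs != plan$n_pairs) {
    abort_mlcqa("leaf-pair count of log and plan differ.", "mlcqa_log_parse")
  }
  cmd <- plan_positions(plan, "commanded")
  long <- log_long(records) |>
    dplyr::left_join(cmd, by = c("segment", "pair", "bank"),
                     suffix = c("", "_cmd")) |>
    dplyr::mutate(error = position_mm - position_mm_cmd)
  pos_err <- long$error

  # record-aligned width errors across the analyzed strips
  on <- records[records$beam_on == 1L, ]
  width_err <- list()
  cmd_a <- edge_matrices(plan, "commanded")$a
  cmd_b <- edge_matrices(plan, "commanded")$b
  for (s in analyzed_strips(plan)) {
    lb <- on[on$segment == s, leaf_columns("B", n_pairs)]
    ra <- on[on$segment == s + 1L, leaf_columns("A", n_pairs)]
    n <- min(nrow(lb), nrow(ra))
    if (n == 0) next
    w <- as.matrix(ra[seq_len(n), ]) - as.matrix(lb[seq_len(n), ])
    w_cmd <- matrix(cmd_a[s + 1L, ] - cmd_b[s, ], n, n_pairs, byrow = TRUE)
    width_err[[as.character(s)]] <- as.numeric(w - w_cmd)
  }
  width_err <- unlist(width_err, use.names = FALSE)

  row_stats <- function(x) c(mean = mean(x), sd = stats::sd(x), max = max(x))
  stats_tbl <- tibble::tibble(
    quantity = c("leaf_position", "abs_leaf_position",
                 "abutment_width", "abs_abutment_width"),
    mean = c(mean(pos_err), mean(abs(pos_err)),
             mean(width_err), mean(abs(width_err))),
    sd = c(stats::sd(pos_err), stats::sd(abs(pos_err)),
           stats::sd(width_err), stats::sd(abs(width_err))),
    max = c(max(pos_err), max(abs(pos_err)),
            max(width_err), max(abs(width_err)))
  )
  exceed <- tidyr::expand_grid(
    quantity = c("leaf_position", "abutment_width"),
    threshold_mm = sort(thresholds)
  ) |>
    dplyr::mutate(fraction = purrr::map2_dbl(quantity, threshold_mm, \(q, t) {
      x <- if (q == "leaf_position") pos_err else width_err
      mean(abs(x) > t)
    }))
  structure(list(stats = stats_tbl, exceedance = exceed),
            class = "mlc_log_stats")
}

#' @export
print.mlc_log_stats <- function(x, ...) {
  cat("Delivery-log error statistics (mm):\n")
  print(as.data.frame(x$stats), row.names = FALSE, digits = 3)
  cat("\nExceedance fractions:\n")
  print(as.data.frame(x$exceedance), row.names = FALSE, digits = 3)
  invisible(x)
}
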