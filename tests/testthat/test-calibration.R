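# synthetic session tables without any simulation
fake_sessions <- function(n_sessions = 2, widths = 2:14, strips = 2:3,
                          pairs = 1:2, feature_noise = 0) {
  grid <- tidyr::expand_grid(session = seq_len(n_sessions),
                             nominal_width = widths, strip = strips,
                             pair = pairs)
  set.seed(99)
  grid |>
    dplyr::mutate(
      fwhm = nominal_width + 1.5 +
        stats::rnorm(dplyr::n(), 0, feature_noise),
      valley_area = 90 * nominal_width,
      valley_depth = exp(-nominal_width / 4),
      center_mm = 0,
      actual_width = nominal_width + 0.01 * pair,
      actual_p_left = -nominal_width / 2,
      actual_p_right = nominal_width / 2
    )
}

test_that("nominal values are per-cell session means", {
  one <- fake_sessions(n_sessions = 1)
  nom1 <- build_nominal_values(one)
  expect_equal(nom1$fwhm, one$fwhm[order(one$nominal_width, one$strip,
                                         one$pair)])
  expect_true(all(nom1$n_sessions == 1))

  two <- fake_sessions(n_sessions = 2)
  two$fwhm <- rep(c(5.0, 5.2), each = nrow(two) / 2)
  nom2 <- build_nominal_values(two)
  expect_true(all(abs(nom2$fwhm - 5.1) < 1e-12))

  incomplete <- two[-1, ]
  expect_error(build_nominal_values(incomplete),
               class = "mlcqa_invalid_sessions")
})

test_that("session averaging shrinks the nominal feature spread", {
  # 8-session nominal features should scatter ~ 1/sqrt(8) of single-session
  # features across repeated campaigns of the same machine
  beam <- beam_model()
  jit <- jitter_model()
  geom <- study_geometry(2)
  machine <- simulate_machine(2, beam, jit, seed = 55)
  plan <- field_plan(5, field_y_mm = 10)
  one_session <- function(seed) {
    set.seed(seed)
    of <- rnorm(1, 1, beam$output_fluctuation_sd)
    sim <- simulate_picket_fence(plan, beam, jit, geom, seed = seed,
                                 machine = machine, output_factor = of)
    open <- simulate_open_field(beam, geom, seed = seed + 50000,
                                output_factor = of)
    norm <- normalize_epid(sim$image, open)
    extract_features(norm, plan, beam, strips = 4L, pairs = 1L)$fwhm
  }
  singles <- vapply(1:20, \(r) one_session(3000 + r), numeric(1))
  means8 <- vapply(1:20, \(r) {
    mean(vapply(1:8, \(s) one_session(10000 + r * 10 + s * 2000), numeric(1)))
  }, numeric(1))
  ratio <- sd(means8) / sd(singles)
  expect_lt(ratio, 0.6) # ~ 1/sqrt(8) = 0.354, allow sampling slack
})

test_that("scheme assembly follows the three data-processing definitions", {
  sessions <- fake_sessions(n_sessions = 2)
  nominal <- build_nominal_values(sessions)

  b <- assemble_calibration_points(nominal, "B", "fwhm")
  expect_setequal(unique(b$w_abutment), 2:14) # TPS widths exactly
  expect_equal(nrow(b), 13 * 2 * 2)

  a <- assemble_calibration_points(nominal, "A", "fwhm")
  expect_equal(nrow(a), 13 * 2) # 13 points per strip, pairs averaged out
  expect_true(all(is.na(a$pair)))
  expect_equal(sort(unique(a$w_abutment)),
               sort(unique(2:14 + 0.015))) # mean of per-pair log widths

  # scheme C: ordinate is each pair's log-derived width (nominal + 0.01*pair)
  cc <- assemble_calibration_points(nominal, "C", "fwhm")
  expect_equal(cc$w_abutment, (cc$w_feature - 1.5) + 0.01 * cc$pair)
})

test_that("schemes B and C coincide when the log equals the plan", {
  sessions <- fake_sessions(n_sessions = 1)
  sessions$actual_width <- sessions$nominal_width # zero jitter, zero offset
  nominal <- build_nominal_values(sessions)
  b <- assemble_calibration_points(nominal, "B", "valley_area")
  cc <- assemble_calibration_points(nominal, "C", "valley_area")
  expect_equal(b$w_abutment, cc$w_abutment)
  expect_equal(b$w_feature, cc$w_feature)
})

test_that("too few calibration widths are refused", {
  short <- fake_sessions(widths = 2:9)
  nominal <- build_nominal_values(short)
  expect_error(assemble_calibration_points(nominal, "C", "fwhm"),
               class = "mlcqa_invalid_calibration")
  expect_silent(assemble_calibration_points(nominal, "C", "fwhm",
                                            min_widths = 8))
  expect_error(assemble_calibration_points(nominal, "C", "fwhm",
                                           min_widths = 5),
               class = "mlcqa_invalid_calibration")
})

test_that("an exact quintic is recovered from 13 points", {
  coefs <- c(0.5, 1.2, -0.3, 0.05, -0.002, 0.0001)
  x <- seq(3, 15, length.out = 13)
  y <- as.numeric(outer(x, 0:5, "^") %*% coefs)
  curve <- fit_calibration_curve(tibble::tibble(w_feature = x, w_abutment = y))
  expect_lt(max(abs(curve$residuals)), 1e-8)
  expect_equal(curve$coefficients, coefs, tolerance = 1e-6)
  expect_equal(estimate_width(curve, x), y, tolerance = 1e-8)

  # 6 points: interpolating square system
  x6 <- 1:6
  y6 <- as.numeric(outer(x6, 0:5, "^") %*% coefs)
  c6 <- fit_calibration_curve(tibble::tibble(w_feature = x6, w_abutment = y6))
  expect_lt(max(abs(c6$residuals)), 1e-8)

  dup <- tibble::tibble(w_feature = c(1, 1, 2, 3, 4, 5),
                        w_abutment = 1:6)
  expect_error(fit_calibration_curve(dup), class = "mlcqa_invalid_calibration")
  expect_error(fit_calibration_curve(dup[1:4, ]),
               class = "mlcqa_invalid_calibration")
})

test_that("width estimation evaluates the polynomial with domain guards", {
  pts <- tibble::tibble(w_feature = 0:6, w_abutment = 1 + 2 * (0:6))
  curve <- fit_calibration_curve(pts)
  expect_equal(estimate_width(curve, 3), 7, tolerance = 1e-9)
  expect_warning(estimate_width(curve, 6.3), class = "mlcqa_extrapolation")
  expect_error(suppressWarnings(estimate_width(curve, 7)),
               class = "mlcqa_outside_calibration")

  # round-trip at the calibration points themselves
  expect_lt(max(abs(estimate_width(curve, pts$w_feature) - pts$w_abutment)),
            1e-6)
})

test_that("leaf positions decompose the abutment about its center", {
  expect_equal(leaf_positions(0, 5), tibble::tibble(p_left = -2.5,
                                                    p_right = 2.5))
  expect_equal(leaf_positions(1.2, 8), tibble::tibble(p_left = -2.8,
                                                      p_right = 5.2))
  set.seed(2)
  p <- rnorm(20); w <- runif(20, 0.1, 20)
  lp <- leaf_positions(p, w)
  expect_equal(lp$p_right - lp$p_left, w)
  expect_equal((lp$p_right + lp$p_left) / 2, p)
  expect_error(leaf_positions(0, -1), class = "mlcqa_invalid_width")
})

test_that("fitted curves are monotone over the domain on noiseless data", {
  sessions <- fake_sessions(n_sessions = 1)
  nominal <- build_nominal_values(sessions)
  cal <- fit_calibration(nominal, schemes = "C",
                         methods = c("fwhm", "valley_area"))
  for (cv in cal$curve) {
    grid <- seq(cv$fit_domain[1], cv$fit_domain[2], length.out = 200)
    expect_true(all(diff(estimate_width(cv, grid)) > 0))
  }
})

test_that("calibration sets serialize to JSON and back", {
  sessions <- fake_sessions(n_sessions = 2, feature_noise = 0.01)
  nominal <- build_nominal_values(sessions)
  cal <- fit_calibration(nominal)
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, path)
  back <- read_calibration(path)
  expect_equal(nrow(back), nrow(cal))
  expect_equal(attr(back, "widths"), 2:14)
  i <- which(cal$scheme == "C" & cal$method == "fwhm")[1]
  j <- which(back$scheme == "C" & back$method == "fwhm" &
               back$strip == cal$strip[i] & back$pair == cal$pair[i])
  expect_equal(back$curve[[j]]$coefficients, cal$curve[[i]]$coefficients)
  feats <- seq(cal$curve[[i]]$fit_domain[1], cal$curve[[i]]$fit_domain[2],
               length.out = 7)
  expect_equal(estimate_width(back$curve[[j]], feats),
               estimate_width(cal$curve[[i]], feats), tolerance = 1e-12)
})

test_that("tidy and glance expose coefficients and fit quality", {
  sessions <- fake_sessions(n_sessions = 1)
  nominal <- build_nominal_values(sessions)
  cal <- fit_calibration(nominal, schemes = "C", methods = "fwhm")
  td <- tidy(cal$curve[[1]])
  expect_equal(td$term, paste0("c", 0:5))
  gl <- glance(cal)
  expect_equal(nrow(gl), nrow(cal))
  expect_true(all(gl$n_points == 13))
  wide <- tidy(cal)
  expect_true(all(paste0("c", 0:5) %in% names(wide)))
})

test_that("the piecewise-linear fit recovers a known breakpoint", {
  x <- seq(2, 14, by = 1)
  y <- 1 + 0.4 * pmin(x, 7.3) + 1.0 * pmax(x - 7.3, 0)
  fit <- piecewise_linear_fit(x, y)
  expect_lt(abs(fit$breakpoint - 7.3), 0.02)
  expect_lt(fit$sse, 1e-12)
})
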