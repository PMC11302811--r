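# hand-built normalized image whose band rows are constant down each row
manual_norm <- function(row_values, geom, plan) {
  y_pair <- plan_pairs(plan)$y_mm[1]
  rc <- round(iso_to_pixel(y_pair, geom, "row"))
  values <- matrix(1, geom$rows, geom$cols)
  for (i in seq_along(row_values)) {
    values[rc - 2 + i, ] <- row_values[i] # 0-based rc; R index rc+1 -2..+2
  }
  structure(list(values = values, geometry = geom, meta = list()),
            class = "epid_norm")
}

test_that("the central five band rows are averaged", {
  plan <- field_plan(5, field_y_mm = 5)
  geom <- study_geometry(1)
  norm <- manual_norm(c(1, 2, 3, 4, 5), geom, plan)
  prof <- extract_profile(norm, plan, strip = analyzed_strips(plan)[1],
                          pair = 1)
  expect_true(all(abs(prof$value - 3) < 1e-9))
  # flat profile: no abutment detectable
  expect_error(find_extrema(prof), class = "mlcqa_no_abutment")
})

test_that("the fine grid is uniform 0.01 mm and reproduces the samples", {
  # integer beam-axis origin puts the coarse pixel centers on the fine grid
  geom <- geometry_model(rows = 64, cols = 1024, origin = c(31, 512))
  beam <- beam_model(noise_sd = 0.002, output_fluctuation_sd = 0)
  plan <- field_plan(7, field_y_mm = 10)
  sim <- simulate_picket_fence(plan, beam, jitter_model(), geom, seed = 6)
  open <- simulate_open_field(beam, geom, seed = 7,
                              output_factor = sim$output_factor)
  prof <- extract_profile(normalize_epid(sim$image, open), plan,
                          strip = 4, pair = 1, beam)
  steps <- diff(prof$position_mm)
  expect_lt(max(abs(steps - 0.01)), 1e-9)
  coarse <- attr(prof, "coarse")
  interp <- prof$value[match(round(coarse$position_mm * 100),
                             round(prof$position_mm * 100))]
  inside <- !is.na(interp)
  expect_gt(sum(inside), 50)
  expect_lt(max(abs(interp[inside] - coarse$value[inside])), 1e-9)
})

test_that("a leaf pair projects to 20 panel rows with the default geometry", {
  geom <- geometry_model()
  expect_equal(5 * geom$magnification / geom$pixel_pitch_panel_mm, 20)
})

test_that("extrema are located on simple synthetic profiles", {
  x <- seq(-5, 5, by = 0.01)
  v_shape <- 1 - 0.6 * pmax(0, 1 - abs(x) / 3)
  prof <- tibble::tibble(position_mm = x, value = v_shape)
  ex <- find_extrema(prof)
  expect_equal(ex$valley$position, 0)
  expect_equal(ex$valley$value, 0.4)
  expect_lt(ex$left_peak$position, 0)
  expect_gt(ex$right_peak$position, 0)

  flat <- tibble::tibble(position_mm = x, value = rep(1, length(x)))
  expect_error(find_extrema(flat), class = "mlcqa_no_abutment")
  shallow <- tibble::tibble(position_mm = x,
                            value = 1 - 0.005 * pmax(0, 1 - abs(x) / 3))
  expect_error(find_extrema(shallow), class = "mlcqa_no_abutment")
})

test_that("FWHM of linear flanks follows the half-level geometry", {
  # peaks 1.0, valley 0.4, linear flanks over 3 mm: half level 0.7 at the
  # flank midpoints, so the boundaries sit 1.5 mm either side of the valley
  x <- seq(-5, 5, by = 0.01)
  v <- 1 - 0.6 * pmax(0, 1 - abs(x) / 3)
  prof <- tibble::tibble(position_mm = x, value = v)
  ex <- find_extrema(prof)
  fw <- profile_fwhm(prof, ex)
  expect_equal(fw$fwhm, 3.00)
  expect_equal(fw$boundary_left, -1.5)
  expect_equal(fw$boundary_right, 1.5)
  expect_equal(fw$center, 0)
  # the distance is the fine-grid index difference over 100
  i_l <- which(prof$position_mm == fw$boundary_left)
  i_r <- which(prof$position_mm == fw$boundary_right)
  expect_equal((i_r - i_l) / 100, fw$fwhm)
})

test_that("noiseless FWHM matches a brute-force scan of the continuous model", {
  beam <- noiseless_beam()
  g <- beam$glare_fraction
  edge <- function(d) {
    (1 - g) * pnorm(d / beam$penumbra_sigma) + g * pnorm(d / beam$glare_sigma)
  }
  for (w in c(3, 5, 9)) {
    f <- quiet_field(width = w, n_pairs = 2, seed = 8, beam = beam)
    prof <- extract_profile(f$norm, f$plan, strip = 4, pair = 1, beam)
    ex <- find_extrema(prof)
    fw <- profile_fwhm(prof, ex)

    # oracle: evaluate the continuous all-segment fluence model on a very
    # fine grid over the same window and apply the half-level definitions
    edges <- plan_positions(f$plan, "nominal")
    a_k <- edges$position_mm[edges$bank == "A" & edges$pair == 1]
    b_k <- edges$position_mm[edges$bank == "B" & edges$pair == 1]
    ped <- function(x) {
      acc <- 0
      for (k in seq_along(a_k)) {
        acc <- acc + beam$transmission +
          (1 - beam$transmission) * edge(x - a_k[k]) * edge(b_k[k] - x)
      }
      acc
    }
    xs <- seq(min(prof$position_mm), max(prof$position_mm), by = 0.001)
    vs <- ped(xs)
    vi <- which.min(vs)
    peak_l <- max(vs[1:(vi - 1)]); peak_r <- max(vs[(vi + 1):length(vs)])
    lo <- xs[max(which(vs[1:vi] >= (peak_l + vs[vi]) / 2))]
    hi <- xs[vi - 1 + min(which(vs[vi:length(vs)] >= (peak_r + vs[vi]) / 2))]
    expect_lt(abs(fw$fwhm - (hi - lo)), 0.02)
  }
})

test_that("valley area follows its sample-sum definition", {
  prof <- tibble::tibble(position_mm = seq(0, 0.04, by = 0.01),
                         value = c(1.0, 0.8, 0.4, 0.7, 1.0))
  ex <- structure(list(valley = list(index = 3L, position = 0.02, value = 0.4),
                       left_peak = list(index = 1L, position = 0, value = 1.0),
                       right_peak = list(index = 5L, position = 0.04,
                                         value = 1.0)),
                  class = "mlc_extrema")
  expect_equal(profile_valley_area(prof, ex), 1.1)
  # profile equal to its peak plateau (no dip): zero area
  prof0 <- tibble::tibble(position_mm = seq(0, 0.04, by = 0.01),
                          value = rep(1, 5))
  expect_equal(profile_valley_area(prof0, ex), 0)
})

test_that("valley area agrees with trapezoid quadrature on smooth profiles", {
  f <- quiet_field(width = 6, n_pairs = 2, seed = 9)
  prof <- extract_profile(f$norm, f$plan, strip = 4, pair = 1, f$beam)
  ex <- find_extrema(prof)
  area <- profile_valley_area(prof, ex)
  li <- ex$left_peak$index; ri <- ex$right_peak$index; vi <- ex$valley$index
  xs <- prof$position_mm[li:ri]
  deficit <- ifelse(seq_along(xs) + li - 1 <= vi,
                    ex$left_peak$value, ex$right_peak$value) -
    prof$value[li:ri]
  trap <- sum((deficit[-1] + deficit[-length(deficit)]) / 2)
  expect_lt(abs(area - trap) / trap, 0.01)
})

test_that("valley depth passes the valley value through and saturates", {
  ex <- structure(list(valley = list(index = 3L, position = 0, value = 0.4),
                       left_peak = list(index = 1L, position = -1, value = 1),
                       right_peak = list(index = 5L, position = 1, value = 1)),
                  class = "mlc_extrema")
  expect_equal(valley_depth(ex), 0.4)

  # sensitivity d(feature)/d(width) decays towards wide gaps; the expected
  # ratio comes from the closed-form edge model (independent oracle)
  beam <- noiseless_beam()
  widths <- c(2, 3, 11, 13)
  vd <- vapply(widths, function(w) {
    f <- quiet_field(width = w, n_pairs = 2, seed = 10, beam = beam)
    extract_features(f$norm, f$plan, beam, strips = 4L, pairs = 1L)$valley_depth
  }, numeric(1))
  meas_ratio <- abs((vd[4] - vd[3]) / 2) / abs(vd[2] - vd[1])
  g <- beam$glare_fraction
  v_model <- function(w) {
    2 * ((1 - g) * pnorm(-w / 2 / beam$penumbra_sigma) +
           g * pnorm(-w / 2 / beam$glare_sigma)) * (1 - beam$transmission)
  }
  oracle_ratio <- abs((v_model(13) - v_model(11)) / 2) /
    abs(v_model(3) - v_model(2))
  expect_lt(abs(meas_ratio - oracle_ratio) / oracle_ratio, 0.15)
  expect_lt(meas_ratio, 0.5) # sensitivity has decayed substantially by 12 mm
})

test_that("features are scale-invariant up to their homogeneity degree", {
  f <- quiet_field(width = 6, n_pairs = 2, seed = 11)
  prof <- extract_profile(f$norm, f$plan, strip = 4, pair = 1, f$beam)
  k <- 1.7
  scaled <- prof
  scaled$value <- k * prof$value
  ex1 <- find_extrema(prof); ex2 <- find_extrema(scaled, prominence = 0.02 * k)
  expect_identical(profile_fwhm(scaled, ex2)$fwhm, profile_fwhm(prof, ex1)$fwhm)
  expect_equal(profile_valley_area(scaled, ex2),
               k * profile_valley_area(prof, ex1))
  expect_equal(valley_depth(ex2), k * valley_depth(ex1))
})

test_that("feature extraction is translation-equivariant", {
  f <- quiet_field(width = 6, n_pairs = 2, seed = 12)
  prof <- extract_profile(f$norm, f$plan, strip = 4, pair = 1, f$beam)
  delta <- 0.37
  shifted <- prof
  shifted$position_mm <- prof$position_mm + delta
  ex1 <- find_extrema(prof); ex2 <- find_extrema(shifted)
  fw1 <- profile_fwhm(prof, ex1); fw2 <- profile_fwhm(shifted, ex2)
  expect_equal(ex2$valley$position, ex1$valley$position + delta)
  expect_equal(fw2$boundary_left, fw1$boundary_left + delta)
  expect_equal(fw2$boundary_right, fw1$boundary_right + delta)
  expect_identical(fw2$fwhm, fw1$fwhm)
  expect_identical(profile_valley_area(shifted, ex2),
                   profile_valley_area(prof, ex1))
})

test_that("fwhm and valley area increase strictly with gap width (noiseless)", {
  beam <- noiseless_beam()
  widths <- seq(2, 14, by = 2)
  feats <- purrr::map(widths, \(w) {
    f <- quiet_field(width = w, n_pairs = 2, seed = 13, beam = beam)
    extract_features(f$norm, f$plan, beam, strips = 4L, pairs = 1L)
  }) |> purrr::list_rbind()
  expect_true(all(diff(feats$fwhm) > 0))
  expect_true(all(diff(feats$valley_area) > 0))
  expect_true(all(diff(feats$valley_depth) < 0)) # deepens towards saturation
})

test_that("failures surface per pair without aborting the table", {
  f <- quiet_field(width = 5, n_pairs = 4, seed = 14)
  # mask one pair's band: that pair fails, the rest survive
  y <- plan_pairs(f$plan)$y_mm[2]
  rc <- round(iso_to_pixel(y, f$geom, "row"))
  f$norm$values[rc + 1, ] <- NA
  feats <- extract_features(f$norm, f$plan, f$beam)
  expect_true(all(feats$status[feats$pair == 2] != "ok"))
  expect_true(all(feats$status[feats$pair != 2] == "ok"))
  expect_true(all(is.na(feats$fwhm[feats$pair == 2])))
})
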