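test_that("noiseless open field delivers the configured level exactly in-field", {
  beam <- noiseless_beam()
  geom <- study_geometry(4)
  img <- simulate_open_field(beam, geom, seed = 1, output_factor = 1)
  sig <- decode_signal(img)
  # central region is deep inside the 26 x 26 cm field
  center <- sig[30:80, 400:600]
  expect_true(all(center == beam$open_signal))
})

test_that("images and logs are byte-identical under a fixed seed", {
  beam <- beam_model()
  jit <- jitter_model()
  geom <- study_geometry(4)
  plan <- field_plan(5, field_y_mm = 20)
  s1 <- simulate_picket_fence(plan, beam, jit, geom, seed = 7)
  s2 <- simulate_picket_fence(plan, beam, jit, geom, seed = 7)
  expect_identical(s1$image$stored, s2$image$stored)
  expect_identical(s1$log, s2$log)
  o1 <- simulate_open_field(beam, geom, seed = 3)
  o2 <- simulate_open_field(beam, geom, seed = 3)
  expect_identical(o1$stored, o2$stored)
})

test_that("pixel noise reproduces its configured relative SD", {
  beam <- beam_model(noise_sd = 0.01, output_fluctuation_sd = 0)
  # a field larger than the panel keeps every pixel deep in-field
  img <- simulate_open_field(beam, geometry_model(), seed = 42,
                             field_xy_mm = c(300, 300), output_factor = 1)
  sig <- decode_signal(img)
  in_field <- sig > beam$open_signal / 2
  expect_gt(sum(in_field), 1e6)
  rel_sd <- stats::sd(sig[in_field]) / mean(sig[in_field])
  expect_lt(abs(rel_sd - 0.01) / 0.01, 0.05)
})

test_that("decoded in-field signal scales linearly with segment MU", {
  beam <- noiseless_beam()
  jit <- zero_jitter()
  geom <- study_geometry(2)
  mk <- function(mu) {
    plan <- field_plan(5, field_y_mm = 10, segment_mu = mu)
    sim <- simulate_picket_fence(plan, beam, jit, geom, seed = 1)
    decode_signal(sim$image)
  }
  full <- mk(100)
  half <- mk(50)
  mid <- full > 0.5 * max(full) # plateau pixels only (avoid rounding at 0)
  expect_lt(max(abs(half[mid] / full[mid] - 0.5)), 1e-3)
})

test_that("a symmetric noiseless abutment profile is mirror-symmetric", {
  f <- quiet_field(width = 6, n_pairs = 2, seed = 1)
  prof <- extract_profile(f$norm, f$plan, strip = 4, pair = 1, f$beam)
  center <- attr(prof, "center_nominal")
  v <- prof$value
  # positions are symmetric about the strip center by construction
  expect_equal(prof$position_mm + rev(prof$position_mm),
               rep(2 * center, nrow(prof)))
  expect_lt(max(abs(v - rev(v))), 1e-9)
})

test_that("the delivery log has 272 records per 100 MU at 40 ms spacing", {
  f <- quiet_field(width = 5, n_pairs = 2, seed = 2)
  log <- f$sim$log
  on_counts <- table(log$segment[log$beam_on == 1L])
  expect_true(all(on_counts == 272))
  expect_true(all(diff(log$time_ms) == 40))
  plan150 <- field_plan(5, field_y_mm = 10, segment_mu = 150)
  s150 <- simulate_picket_fence(plan150, noiseless_beam(), zero_jitter(),
                                study_geometry(2), seed = 1)
  expect_true(all(table(s150$log$segment[s150$log$beam_on == 1L]) == 408))
})

test_that("per-record jitter reproduces the configured marginal SD within 2%", {
  jit <- jitter_model()
  beam <- noiseless_beam()
  geom <- study_geometry(24)
  plan <- field_plan(5, field_y_mm = 120)
  sim <- simulate_picket_fence(plan, beam, jit, geom, seed = 5)
  cmd <- plan_positions(plan, "commanded")
  errs <- log_error_stats(sim$log, plan)
  n_leaf_records <- sum(sim$log$beam_on == 1L) * 2L * plan$n_pairs
  expect_gt(n_leaf_records, 1e5)
  measured_sd <- errs$stats$sd[errs$stats$quantity == "leaf_position"]
  expect_lt(abs(measured_sd - jitter_marginal_sd(jit)) / jitter_marginal_sd(jit),
            0.02)
})

test_that("noiseless valleys sit at the planned abutment centers", {
  f <- quiet_field(width = 5, n_pairs = 4, seed = 1)
  feats <- extract_features(f$norm, f$plan, f$beam)
  ab <- plan_abutments(f$plan, "nominal")
  joined <- dplyr::left_join(feats, ab, by = c("strip", "pair"))
  expect_true(all(joined$status == "ok"))
  expect_lt(max(abs(joined$valley_pos - joined$center)), 0.0100001)
  expect_lt(max(abs(joined$center_mm - joined$center)), 0.0100001)
})

test_that("a single bank-A displacement widens the gap and shifts the valley", {
  em <- tibble::tibble(strip = 4L, pair = 2L, bank = "A", offset_mm = 2.4)
  f0 <- quiet_field(width = 5, n_pairs = 4, seed = 1)
  f1 <- quiet_field(width = 5, n_pairs = 4, seed = 1, error_map = em)
  r0 <- extract_features(f0$norm, f0$plan, f0$beam, strips = 4L, pairs = 2L)
  r1 <- extract_features(f1$norm, f1$plan, f1$beam, strips = 4L, pairs = 2L)
  # valley center moves by half the single-edge displacement
  expect_lt(abs((r1$valley_pos - r0$valley_pos) - 1.2), 0.011)
  # the delivered gap width grows by the full displacement (log view)
  st <- segment_leaf_states(f1$sim$log)
  ab <- log_abutments(st, f1$plan)
  expect_equal(ab$actual_width[ab$strip == 4 & ab$pair == 2], 7.4)
})

test_that("segment means in the log reflect the realized systematic offsets", {
  jit <- jitter_model(per_record_sd = 0.064, systematic_offset_sd = 0.05)
  beam <- noiseless_beam()
  geom <- study_geometry(2)
  plan <- field_plan(5, field_y_mm = 10)
  machine <- simulate_machine(2, beam, jit, seed = 9)
  sim <- simulate_picket_fence(plan, beam, jit, geom, seed = 10,
                               machine = machine)
  st <- segment_leaf_states(sim$log)
  cmd <- plan_positions(plan, "commanded")
  joined <- dplyr::left_join(st, cmd, by = c("segment", "pair", "bank"),
                             suffix = c("", "_cmd"))
  joined$offset <- ifelse(joined$bank == "A", machine$offset_a[joined$pair],
                          machine$offset_b[joined$pair])
  resid <- joined$position_mm - joined$position_mm_cmd - joined$offset
  # residual = mean of 272 iid jitters: SE = 0.064 / sqrt(272)
  expect_lt(max(abs(resid)), 4 * 0.064 / sqrt(272) + 1e-6)
})

test_that("segment averaging beats the per-record jitter (standard error bound)", {
  jit <- jitter_model(systematic_offset_sd = 0) # isolate the averaging
  se <- jit$per_record_sd / sqrt(jit$records_per_100mu)
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    machine <- list(n_pairs = 1L, pair_response = 1, offset_a = 0, offset_b = 0,
                    seed = s)
    class(machine) <- "sim_machine"
    plan <- field_plan(5, n_segments = 2, field_y_mm = 5)
    sim <- simulate_picket_fence(plan, noiseless_beam(), jit,
                                 study_geometry(1, cols = 256), seed = s,
                                 machine = machine)
    st <- segment_leaf_states(sim$log, segments = 1L)
    cmd <- plan_positions(plan, "commanded")
    err <- st$position_mm - cmd$position_mm[match(
      paste(st$segment, st$bank, st$pair),
      paste(cmd$segment, cmd$bank, cmd$pair))]
    all(abs(err) <= 4 * se)
  }, logical(1))
  expect_gte(mean(inside), 0.99)
})
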