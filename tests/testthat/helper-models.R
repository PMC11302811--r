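# deterministic building blocks shared across test files

noiseless_beam <- function(...) {
  beam_model(noise_sd = 0, output_fluctuation_sd = 0, pair_response_sd = 0,
             interleaf_leakage_amp = 0, ...)
}

zero_jitter <- function(...) {
  jitter_model(per_record_sd = 0, systematic_offset_sd = 0, ...)
}

# noiseless field + matching open field, normalized; small panel
quiet_field <- function(width = 5, n_pairs = 4, seed = 1, error_map = NULL,
                        beam = noiseless_beam(), jitter = zero_jitter()) {
  geom <- study_geometry(n_pairs)
  plan <- field_plan(width, field_y_mm = n_pairs * 5, error_map = error_map)
  sim <- simulate_picket_fence(plan, beam, jitter, geom, seed = seed)
  open <- simulate_open_field(beam, geom, seed = seed + 1, output_factor = 1)
  list(sim = sim, plan = plan, geom = geom, beam = beam,
       norm = normalize_epid(sim$image, open))
}

# closed-form two-component edge profile of one abutment (independent of the
# simulator's rendering path; used as numeric oracle)
model_abutment <- function(x, p_left, p_right, beam) {
  g <- beam$glare_fraction
  edge <- function(d) {
    (1 - g) * pnorm(d / beam$penumbra_sigma) + g * pnorm(d / beam$glare_sigma)
  }
  edge(p_left - x) + edge(x - p_right)
}
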