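# shared builders for synthetic fixtures (all generated in code at test time)

quiet_noise <- function() noise_spec(wander_amp_mv = 0, white_sd_mv = 0,
                                     emg_sd_mv = 0)

no_artifacts <- function() artifact_spec(rate_per_min = 0)

# clean (noise- and artifact-free) simulation config
clean_config <- function(duration_s = 30, seed = 1L, ...) {
  sim_config(duration_s = duration_s, seed = seed, noise = quiet_noise(),
             artifacts = no_artifacts(), ...)
}

# reference annotations from simulator ground truth
truth_beats <- function(sim, rate = 2000) {
  beat_annotations(sim$truth$sample, rate, source = "reference")
}

# a tiny deterministic record for I/O tests
toy_record <- function(n = 400, rate = 2000) {
  t <- (seq_len(n) - 1) / rate
  ecg_record(list(I = 0.2 * sin(2 * pi * 7 * t),
                  II = 0.5 * sin(2 * pi * 7 * t) + 0.05 * cos(2 * pi * 3 * t)),
             sample_rate = rate)
}
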