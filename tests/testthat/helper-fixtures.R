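# Shared fixtures built in code: small schedules, recordings and montages.

slow_condition <- function() condition_by_label("AUD-ISO-1Hz")
fast_condition <- function() condition_by_label("AUD-ISO-3Hz")

# a small synthetic recording with a given per-channel signal matrix
toy_recording <- function(data_uv, fs = 256, montage = default_montage()) {
  n <- nrow(data_uv)
  eeg_recording(data_uv * 1e-6, fs, montage$label[seq_len(n)],
                channel_positions = as.matrix(montage[seq_len(n), c("x", "y", "z")]))
}

# run the full single-recording beta chain on synthetic EEG; returns the
# per-channel window averages in dB
measure_planted_db <- function(condition, around_db, after_db, seed = 4,
                               n_sequences = 5, spread_rad = Inf,
                               reference = "laplacian") {
  sch <- generate_cue_schedule(condition, n_sequences)
  sim <- simulate_taps(sch, tap_ground_truth(mean_phase_deg = 0, kappa = Inf),
                       seed = seed)
  spec <- beta_effect_spec(around_db = around_db, after_db = after_db,
                           spread_rad = spread_rad)
  rec <- simulate_eeg(sch, sim$tap_times, spec, seed = seed + 1)
  rec <- rereference_average(rec)
  if (reference == "laplacian") rec <- surface_laplacian(rec)
  fam <- build_wavelet_family(rec$sample_rate)
  tfl <- tf_power(rec, fam)
  base <- segment_baseline(tfl, baseline_epoch_defs(rec$sample_rate,
                                                    sch$baseline_window))
  ep <- epoch_around_taps(tfl, unlist(sim$tap_times), condition$isi)
  wa <- window_average(db_normalize(ep, base), condition$isi)
  attr(wa, "n_epochs") <- dim(ep$power)[1]
  wa
}
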