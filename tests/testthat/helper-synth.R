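# shared fixtures, built in code at test time

# trajectory-level multi-session dataset for specificity/slope analyses
make_traj_data <- function(transfer = 0, n_sessions = 10, n_stimuli = 6,
                           reps = 15, n_sites = 3, noise_sd = 0.2,
                           seed = 1, truth = NULL) {
  truth <- truth %||% ground_truth(sprintf("img%02d", seq_len(n_stimuli)),
                                   specificity_transfer = transfer,
                                   seed = seed)
  out <- lapply(seq_len(n_sessions), function(s) {
    tr <- generate_natural_sequence(n_stimuli, reps, 3, 4,
                                    seed = seed * 100 + s,
                                    p_error_early = 0, p_error_late = 0,
                                    session_id = sprintf("ses%02d", s))
    synthesize_band_responses(tr, truth, n_sites = n_sites,
                              noise_sd = noise_sd, seed = seed * 1000 + s)
  })
  d <- dplyr::bind_rows(out)
  tibble::tibble(session_id = d$session_id, site_id = d$site_id,
                 stimulus_id = d$stimulus_id,
                 repetition = d$repetition_number,
                 gamma = d$gamma_ratio, dmua = d$dmua)
}

# small full-signal recording with controllable gamma parameters
make_recording <- function(n_stimuli = 2, reps = 6, n_sites = 4,
                           gamma_peak_hz = 60, gamma_base_power = 3,
                           gamma_early_slope = 0, gamma_late_slope = 0,
                           gamma_freq_shift_hz = 0, seed = 1, ...) {
  tr <- generate_natural_sequence(n_stimuli, reps, min(2, n_stimuli), 4,
                                  seed = seed,
                                  p_error_early = 0, p_error_late = 0)
  truth <- ground_truth(sprintf("img%02d", seq_len(n_stimuli)),
                        gamma_peak_hz = gamma_peak_hz,
                        gamma_base_power = gamma_base_power,
                        gamma_early_slope = gamma_early_slope,
                        gamma_late_slope = gamma_late_slope,
                        gamma_freq_shift_hz = gamma_freq_shift_hz,
                        seed = seed, ...)
  synthesize_recording(tr, truth, n_sites = n_sites, seed = seed + 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
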