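#' Ground-truth effect parameters for synthetic sessions
#'
#' Collects the per-stimulus and global parameters that drive
#' [synthesize_recording()] and [synthesize_band_responses()]. Defaults
#' emulate V1 responses to natural images: stimulus-specific gamma peak
#' frequencies in the 35-75 Hz range, gamma power a few-fold above the 1/f
#' background, early repetition slopes that vary in sign across stimuli with
#' a negative mean, a weakly positive late gamma slope, and multi-unit rates
#' that decay most strongly over the first few repetitions.
#'
#' @param stimuli Character vector of stimulus ids.
#' @param gamma_peak_hz Per-stimulus gamma peak frequency (recycled).
#' @param gamma_base_power Gamma-band power at repetition 1, as a multiple of
#'   the local 1/f background (must be > 0; set 0 to inject no oscillation).
#' @param gamma_early_slope,gamma_late_slope Change in the gamma power
#'   multiplier per repetition for repetitions 1-4 and 5+ (used when
#'   `x_transform = "repetition"`), or per log10 trial-in-block for
#'   `gamma_late_slope` (used when `x_transform = "log10_trial"`).
#' @param gamma_freq_shift_hz Peak-frequency drift per log10 repetition.
#' @param mua_base Sustained multi-unit rate at repetition 1 (a.u.).
#' @param mua_decay_early,mua_decay_late Change in the rate multiplier per
#'   repetition for early/late repetitions (or per log10 trial for
#'   `mua_decay_late` under `x_transform = "log10_trial"`).
#' @param specificity_transfer Fraction in `[0, 1]` of each stimulus's
#'   repetition trajectory replaced by the stimulus-average trajectory:
#'   0 = fully stimulus-specific effects, 1 = fully shared.
#' @param persistence Fraction in `[0, 1]` of accumulated repetition change
#'   retained when the same stimulus (or location) returns after an
#'   intervening block.
#' @param x_transform `"repetition"` for piecewise-linear early/late
#'   trajectories over repetition number (natural-image style) or
#'   `"log10_trial"` for log-linear trajectories over trial-in-block
#'   (block-design style).
#' @param noise_1f_exponent Spectral exponent of the LFP background.
#' @param mua_noise_floor Per-site additive noise floor (recycled over sites
#'   at synthesis time).
#' @param seed Seed recorded for reproducibility.
#'
#' @return An object of class `ground_truth`: a list with a per-stimulus
#'   tibble (`$stimulus`) and global parameters.
#' @export
ground_truth <- function(stimuli,
                         gamma_peak_hz = NULL,
                         gamma_base_power = 3,
                         gamma_early_slope = NULL,
                         gamma_late_slope = NULL,
                         gamma_freq_shift_hz = 2,
                         mua_base = 10,
                         mua_decay_early = -0.04,
                         mua_decay_late = -0.006,
                         specificity_transfer = 0.2,
                         persistence = 0.5,
                         x_transform = c("repetition", "log10_trial"),
                         noise_1f_exponent = 1.5,
                         mua_noise_floor = 5,
                         seed = NULL) {
  x_transform <- match.arg(x_transform)
  n <- length(stimuli)
  with_seed(seed, {
    if (is.null(gamma_peak_hz)) gamma_peak_hz <- runif(n, 35, 75)
    if (is.null(gamma_early_slope)) gamma_early_slope <- rnorm(n, -0.04, 0.06)
    if (is.null(gamma_late_slope)) {
      gamma_late_slope <- if (x_transform == "repetition")
        rnorm(n, 0.012, 0.008) else rnorm(n, 0.25, 0.05)
    }
    if (any(gamma_base_power < 0)) abort("gamma_base_power must be >= 0.")
    if (specificity_transfer < 0 || specificity_transfer > 1) {
      abort("specificity_transfer must lie in [0, 1].")
    }
    stim_tbl <- tibble::tibble(
      stimulus_id = stimuli,
      gamma_peak_hz = rep_len(gamma_peak_hz, n),
      gamma_base_power = rep_len(gamma_base_power, n),
      gamma_early_slope = rep_len(gamma_early_slope, n),
      gamma_late_slope = rep_len(gamma_late_slope, n),
      gamma_freq_shift_hz = rep_len(gamma_freq_shift_hz, n),
      mua_base = rep_len(mua_base, n),
      mua_decay_early = rep_len(mua_decay_early, n),
      mua_decay_late = rep_len(mua_decay_late, n)
    )
    structure(list(stimulus = stim_tbl,
                   specificity_transfer = specificity_transfer,
                   persistence = persistence,
                   x_transform = x_transform,
                   noise_1f_exponent = noise_1f_exponent,
                   mua_noise_floor = mua_noise_floor,
                   seed = seed),
              class = "ground_truth")
  })
}

# Repetition-trajectory multipliers for every trial of a trial table, mixed
# across stimuli by specificity_transfer. Returns a list with gamma and mua
# multiplier vectors (one per trial) plus the drifted gamma frequency.
trajectory_multipliers <- function(trials, truth) {
  st <- truth$stimulus
  idx <- match(trials$stimulus_id, st$stimulus_id)
  if (anyNA(idx)) abort("trial table contains stimuli absent from truth.")
  if (truth$x_transform == "repetition") {
    r <- if ("presentation_number" %in% names(trials))
      trials$presentation_number else trials$repetition_number
    x_e <- pmin(r, 4) - 1
    x_l <- pmax(r - 4, 0)
    gm <- 1 + st$gamma_early_slope[idx] * x_e + st$gamma_late_slope[idx] * x_l
    mm <- 1 + st$mua_decay_early[idx] * x_e + st$mua_decay_late[idx] * x_l
    # shared component: the same trajectory under stimulus-average slopes
    gm_sh <- 1 + mean(st$gamma_early_slope) * x_e +
      mean(st$gamma_late_slope) * x_l
    mm_sh <- 1 + mean(st$mua_decay_early) * x_e + mean(st$mua_decay_late) * x_l
    xlog <- log10(pmax(r, 1))
  } else {
    tib <- if ("trial_in_block" %in% names(trials))
      trials$trial_in_block else NULL
    if (is.null(tib)) abort("log10_trial transform needs `trial_in_block`.")
    prior <- prior_same_condition_trials(trials)
    n_eff <- tib + truth$persistence * prior
    xl <- log10(pmax(n_eff, 1))
    gm <- 1 + st$gamma_late_slope[idx] * xl
    mm <- 1 + st$mua_decay_late[idx] * xl
    gm_sh <- 1 + mean(st$gamma_late_slope) * xl
    mm_sh <- 1 + mean(st$mua_decay_late) * xl
    xlog <- xl
  }
  tau <- truth$specificity_transfer
  list(
    gamma = pmax((1 - tau) * gm + tau * gm_sh, 0),
    mua = pmax((1 - tau) * mm + tau * mm_sh, 0),
    freq = st$gamma_peak_hz[idx] + st$gamma_freq_shift_hz[idx] * xlog,
    base_power = st$gamma_base_power[idx],
    mua_base = st$mua_base[idx]
  )
}

# number of same-stimulus (or same-location) trials in earlier blocks
prior_same_condition_trials <- function(trials) {
  key <- if ("location" %in% names(trials) &&
             any(trials$location %in% "In")) {
    paste(trials$stimulus_id, trials$location)
  } else {
    trials$stimulus_id
  }
  bi <- if ("block_index" %in% names(trials)) trials$block_index else
    rep(1L, nrow(trials))
  out <- numeric(nrow(trials))
  for (k in unique(key)) {
    sel <- key == k
    for (b in unique(bi[sel])) {
      out[sel & bi == b] <- sum(sel & bi < b)
    }
  }
  out
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise
pink_noise <- function(n, fs, exponent = 1.5, sd = 1) {
  f <- seq(0, fs / 2, by = fs / n)
  nf <- length(f)
  mag <- c(0, f[-1]^(-exponent / 2))
  spec <- complex(modulus = mag * rnorm(nf, 1, 0.25),
                  argument = runif(nf, 0, 2 * pi))
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(fft(full, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Synthesize a multi-site LFP + MUA recording session
#'
#' Generates site x trial x time LFP and MUA-envelope arrays with the
#' statistical structure the analysis pipeline assumes: LFP is 1/f background
#' noise plus a stimulus-gated narrowband gamma oscillation (Brownian-phase
#' oscillator) whose power follows each stimulus's repetition trajectory and
#' whose center frequency drifts with log repetition; MUA is a non-negative
#' envelope with an onset transient and a sustained rate that decays with
#' repetition, riding on a per-site noise floor, and is gamma-phase modulated
#' so that MUA-LFP pairwise phase consistency is positive by construction.
#' For location designs, stimulus-driven components are injected only on
#' trials with `location == "In"` (receptive field stimulated).
#'
#' @param trials A trial table from [generate_natural_sequence()] or
#'   [generate_block_sequence()].
#' @param truth A [ground_truth()] object covering the table's stimuli.
#' @param n_sites Number of recording sites (>= 2; sites form a chain graph
#'   of array neighbors).
#' @param fs Sampling rate in Hz; must exceed 4x the largest gamma frequency.
#' @param time_window Peri-stimulus window in seconds (stimulus onset at 0).
#' @param gamma_linewidth_hz Approximate FWHM of the injected gamma bump.
#' @param locking MUA gamma-phase modulation depth in `[0, 1)` (drives PPC).
#' @param seed Integer seed; synthesis is bit-reproducible given the seed.
#'
#' @return An object of class `recording`: list with `lfp` and `mua`
#'   (site x trial x time arrays), `fs`, `time`, `sites`, `neighbors`
#'   (chain-graph edge list), `trials`, `truth`, `seed`.
#' @export
synthesize_recording <- function(trials, truth, n_sites = 4, fs = 500,
                                 time_window = c(-1.3, 1.5),
                                 gamma_linewidth_hz = 6,
                                 locking = 0.4, seed = NULL) {
  if (n_sites < 2) abort("`n_sites` must be >= 2.")
  fmax <- max(truth$stimulus$gamma_peak_hz + abs(truth$stimulus$gamma_freq_shift_hz) * 2)
  if (fs < 4 * fmax) abort("`fs` too low for the requested gamma frequencies (aliasing guard).")
  if (locking < 0 || locking >= 1) abort("`locking` must lie in [0, 1).")
  n_trials <- nrow(trials)
  tm <- trajectory_multipliers(trials, truth)
  with_seed(seed, {
    tax <- seq(time_window[1], time_window[2] - 1 / fs, by = 1 / fs)
    n_t <- length(tax)
    stim_on <- tax >= 0
    ramp <- pmin(pmax(tax / 0.05, 0), 1) # 50 ms onset ramp
    transient <- exp(-(tax - 0.06)^2 / (2 * 0.02^2)) * 1.5
    lfp <- array(0, dim = c(n_sites, n_trials, n_t))
    mua <- array(0, dim = c(n_sites, n_trials, n_t))
    floors <- rep_len(truth$mua_noise_floor, n_sites)
    site_gain <- runif(n_sites, 0.8, 1.2)
    drive <- if (!"location" %in% names(trials)) rep(TRUE, n_trials) else
      trials$location != "Out"
    sd_phase <- sqrt(2 * pi * gamma_linewidth_hz / fs)
    # calibrate oscillation amplitude against the analytic 1/f background
    # density so that `gamma_base_power` is the excess gamma-band power in
    # units of the background power within +-16 Hz of the peak
    alpha <- truth$noise_1f_exponent
    f1 <- 1 / (time_window[2] - time_window[1])
    bg_norm <- if (abs(alpha - 1) < 1e-9) log(fs / 2) - log(f1) else
      ((fs / 2)^(1 - alpha) - f1^(1 - alpha)) / (1 - alpha)
    s_bg <- function(f0) f0^(-alpha) / bg_norm
    for (i in seq_len(n_trials)) {
      # one gamma phase path per trial, shared across sites (volume conduction
      # within an array patch); per-site gain and independent 1/f background
      pow_mult <- tm$base_power[i] * tm$gamma[i]
      amp2 <- 2 * pow_mult * 32 * s_bg(tm$freq[i])
      has_gamma <- drive[i] && pow_mult > 0
      if (has_gamma) {
        phase <- 2 * pi * tm$freq[i] * tax +
          cumsum(rnorm(n_t, 0, sd_phase))
        gamma_wave <- sqrt(amp2) * cos(phase) * ramp * stim_on
      } else {
        gamma_wave <- numeric(n_t)
      }
      rate_mult <- tm$mua[i]
      for (s in seq_len(n_sites)) {
        bg <- pink_noise(n_t, fs, truth$noise_1f_exponent, sd = 1)
        lfp[s, i, ] <- bg + site_gain[s] * gamma_wave
        rate <- floors[s] +
          (if (drive[i]) site_gain[s] * tm$mua_base[i] * rate_mult *
             (1 + transient) * stim_on else 0)
        if (has_gamma) rate <- rate * (1 + locking * cos(phase) * stim_on)
        mua[s, i, ] <- pmax(rate + rnorm(n_t, 0, 0.15 * floors[s]), 0)
      }
    }
    structure(list(
      lfp = lfp, mua = mua, fs = fs, time = tax,
      sites = sprintf("site%02d", seq_len(n_sites)),
      neighbors = if (n_sites >= 2)
        cbind(seq_len(n_sites - 1), seq_len(n_sites - 1) + 1L) else
        matrix(integer(0), 0, 2),
      trials = trials, truth = truth, seed = seed
    ), class = "recording")
  })
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d sites x %d trials x %d samples @ %g Hz\n",
              dim(x$lfp)[1], dim(x$lfp)[2], dim(x$lfp)[3], x$fs))
  cat(sprintf("  time %g .. %g s; %d stimuli; seed %s\n",
              min(x$time), max(x$time) + 1 / x$fs,
              length(unique(x$trials$stimulus_id)),
              x$seed %||% "unset"))
  invisible(x)
}

#' Synthesize per-trial band-level responses directly
#'
#' Feature-level counterpart of [synthesize_recording()]: instead of raw
#' signals, emits the analysis-level per-trial, per-site features the signal
#' model induces - the gamma-band stimulation/baseline power ratio and the
#' sustained dMUA rate - with multiplicative log-normal noise. Used for
#' statistic-level simulations (power/calibration studies) where synthesizing
#' and spectrally decomposing full LFP traces adds cost but no information.
#'
#' @param trials Trial table.
#' @param truth A [ground_truth()] object.
#' @param n_sites Number of sites.
#' @param noise_sd SD of log-normal measurement noise on each feature.
#' @param seed Integer seed.
#' @return A tibble with one row per trial x site: the trial-table columns
#'   plus `site_id`, `gamma_ratio` and `dmua`.
#' @export
synthesize_band_responses <- function(trials, truth, n_sites = 4,
                                      noise_sd = 0.2, seed = NULL) {
  tm <- trajectory_multipliers(trials, truth)
  n <- nrow(trials)
  with_seed(seed, {
    site_gain <- runif(n_sites, 0.8, 1.2)
    drive <- if (!"location" %in% names(trials)) rep(TRUE, n) else
      trials$location != "Out"
    out <- tidyr::expand_grid(trials, site_id = sprintf("site%02d",
                                                        seq_len(n_sites)))
    si <- match(out$site_id, sprintf("site%02d", seq_len(n_sites)))
    g_mean <- 1 + rep(tm$base_power * tm$gamma * drive, each = n_sites) *
      site_gain[si]
    m_mean <- rep_len(truth$mua_noise_floor, n_sites)[si] +
      rep(tm$mua_base * tm$mua * drive, each = n_sites) * site_gain[si]
    out$gamma_ratio <- g_mean * exp(rnorm(nrow(out), 0, noise_sd))
    out$dmua <- m_mean * exp(rnorm(nrow(out), 0, noise_sd))
    out
  })
}

#' Synthesize eye-position and pupil traces
#'
#' Emits fixational gaze traces (degrees of visual angle) with Gaussian
#' jitter, injected microsaccade-like steps at random times (recorded in
#' `$events` for detector validation), and a stimulus-locked pupil
#' constriction with configurable latency and amplitude.
#'
#' @param trials Trial table (one trace per trial).
#' @param fs Sampling rate, >= 100 Hz.
#' @param events_per_trial Number of injected microsaccade-like steps.
#' @param jitter_dva SD of fixational jitter (dva); 0 gives flat traces.
#' @param event_amplitude_dva Step amplitude of injected events.
#' @param pupil_constriction Constriction amplitude (a.u., in units of the
#'   baseline noise SD when `pupil_noise_sd = 1`).
#' @param pupil_latency Seconds from stimulus onset to peak constriction.
#' @param pupil_noise_sd SD of pupil measurement noise.
#' @param time_window Peri-stimulus window (s).
#' @param seed Integer seed.
#' @return An object of class `eye_trace`: list with `gaze_x`, `gaze_y`,
#'   `pupil` (trial x time matrices), `fs`, `time`, and `events` (tibble
#'   of injected events: `trial`, `onset`, `amplitude`).
#' @export
synthesize_eye_traces <- function(trials, fs = 500, events_per_trial = 2,
                                  jitter_dva = 0.02,
                                  event_amplitude_dva = 1,
                                  pupil_constriction = 2,
                                  pupil_latency = 0.4,
                                  pupil_noise_sd = 1,
                                  time_window = c(-1.3, 1.5),
                                  seed = NULL) {
  if (fs < 100) abort("`fs` must be >= 100 Hz.")
  n_trials <- nrow(trials)
  with_seed(seed, {
    tax <- seq(time_window[1], time_window[2] - 1 / fs, by = 1 / fs)
    n_t <- length(tax)
    gx <- matrix(rnorm(n_trials * n_t, 0, jitter_dva), n_trials, n_t)
    gy <- matrix(rnorm(n_trials * n_t, 0, jitter_dva), n_trials, n_t)
    events <- list()
    # 20 ms raised-cosine step profile (saccade-like velocity pulse)
    n_ramp <- max(round(0.02 * fs), 2)
    prof <- (1 - cos(seq(0, pi, length.out = n_ramp))) / 2
    for (i in seq_len(n_trials)) {
      if (events_per_trial > 0) {
        onsets <- sort(runif(events_per_trial, time_window[1] + 0.2,
                             time_window[2] - 0.2))
        # enforce >= 100 ms separation so injected events stay resolvable
        while (any(diff(onsets) < 0.1)) {
          onsets <- sort(runif(events_per_trial, time_window[1] + 0.2,
                               time_window[2] - 0.2))
        }
        for (on in onsets) {
          theta <- runif(1, 0, 2 * pi)
          k0 <- which.min(abs(tax - on))
          idx <- k0:min(k0 + n_ramp - 1, n_t)
          step <- c(prof[seq_along(idx)],
                    rep(1, n_t - idx[length(idx)])) * event_amplitude_dva
          span <- k0:n_t
          gx[i, span] <- gx[i, span] + cos(theta) * step[seq_along(span)]
          gy[i, span] <- gy[i, span] + sin(theta) * step[seq_along(span)]
          events[[length(events) + 1]] <-
            tibble::tibble(trial = i, onset = tax[k0],
                           amplitude = event_amplitude_dva)
        }
      }
    }
    kern <- exp(-(tax - pupil_latency)^2 / (2 * 0.12^2))
    pupil <- matrix(rnorm(n_trials * n_t, 0, pupil_noise_sd), n_trials, n_t)
    pupil <- sweep(pupil, 2, pupil_constriction * kern * (tax >= 0), `-`)
    structure(list(
      gaze_x = gx, gaze_y = gy, pupil = pupil, fs = fs, time = tax,
      events = if (length(events)) dplyr::bind_rows(events) else
        tibble::tibble(trial = integer(), onset = numeric(),
                       amplitude = numeric())
    ), class = "eye_trace")
  })
}
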