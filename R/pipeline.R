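#' Configuration for a natural-image (Dataset-1 style) experiment
#'
#' Bundles generator and analysis parameters for [run_dataset1_analysis()].
#' Defaults reproduce the study conditions: 25 natural images repeated 20
#' times per session under constrained-lag interleaving (max lag 4, rolling
#' subset of 3), analysis restricted to the first 15 correct repetitions,
#' 250 ms multitaper epochs with +-10 Hz smoothing, s = 100 session splits
#' and 1000 permutations. Simulation studies typically scale `n_sessions`,
#' `n_stimuli` and `n_sites` down; every stage honors the config.
#'
#' @param n_stimuli,reps_per_stim,subset_size,max_lag Sequence parameters.
#' @param n_sessions,n_sites,fs Recording parameters.
#' @param max_rep Analysis cap on correct repetitions.
#' @param s,n_perm,n_boot Resampling parameters.
#' @param signal_level `"lfp"` synthesizes and spectrally decomposes full
#'   recordings; `"band"` synthesizes gamma-band/dMUA features directly
#'   (statistic-level simulations).
#' @param compute_spectrum Also run the per-frequency correlation spectrum
#'   (the permutation cost center).
#' @param truth Optional [ground_truth()]; generated from the seed if
#'   `NULL`.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
dataset1_config <- function(n_stimuli = 25, reps_per_stim = 20,
                            subset_size = 3, max_lag = 4,
                            n_sessions = 10, n_sites = 4, fs = 500,
                            max_rep = 15, s = 100, n_perm = 1000,
                            n_boot = 1000,
                            signal_level = c("lfp", "band"),
                            compute_spectrum = FALSE,
                            truth = NULL, seed = 1) {
  structure(list(n_stimuli = n_stimuli, reps_per_stim = reps_per_stim,
                 subset_size = subset_size, max_lag = max_lag,
                 n_sessions = n_sessions, n_sites = n_sites, fs = fs,
                 max_rep = max_rep, s = s, n_perm = n_perm, n_boot = n_boot,
                 signal_level = match.arg(signal_level),
                 compute_spectrum = compute_spectrum,
                 truth = truth, seed = seed),
            class = "run_config")
}

# gamma-band + dMUA per-trial features for one synthesized session
session_features <- function(trials, truth, cfg, session_seed) {
  if (cfg$signal_level == "band") {
    feats <- synthesize_band_responses(trials, truth, n_sites = cfg$n_sites,
                                       seed = session_seed)
    return(list(features = feats, spectra = NULL))
  }
  rec <- synthesize_recording(trials, truth, n_sites = cfg$n_sites,
                              fs = cfg$fs, seed = session_seed)
  dmua <- baseline_normalize(compute_dmua(rec))
  resp_bins <- dmua$time >= 0.05 & dmua$time < 1
  onset_bins <- dmua$time >= 0.05 & dmua$time < 0.15
  stim_ps <- taper_power(epoch_signal(rec, "lfp", c(0.5, 1.5), 0.25))
  base_ps <- taper_power(epoch_signal(rec, "lfp", c(-1, 0), 0.25))
  rel <- baseline_normalize(stim_ps, base_ps)
  n_sites <- dim(rel$power)[2]
  feats <- tidyr::expand_grid(trials,
                              site_id = sprintf("site%02d", seq_len(n_sites)))
  si <- match(feats$site_id, sprintf("site%02d", seq_len(n_sites)))
  ti <- match(feats$trial_index, trials$trial_index)
  feats$dmua <- vapply(seq_len(nrow(feats)), function(k)
    mean(dmua$data[si[k], ti[k], resp_bins]), numeric(1))
  feats$dmua_onset <- vapply(seq_len(nrow(feats)), function(k)
    mean(dmua$data[si[k], ti[k], onset_bins]), numeric(1))
  # site-mean relative spectrum per trial feeds peak detection downstream
  site_mean <- apply(rel$power, c(1, 3), mean)
  list(features = feats, spectra = list(trial_power = site_mean,
                                        rel = rel, freq = rel$freq))
}

#' Run the natural-image repetition analysis end-to-end
#'
#' Executes the full Dataset-1 style pipeline on synthetic sessions:
#' sequence generation, recording synthesis, dMUA and relative LFP power
#' extraction, per-stimulus gamma peak detection and permutation validation,
#' early/late repetition slopes with sign-flip tests and RRC, the
#' cross-validated drive-dependence correlation, and the split-half
#' stimulus-specificity test (optionally resolved per frequency bin).
#' Deterministic under the config seed.
#'
#' @param cfg A [dataset1_config()].
#' @return A list of class `dataset1_report`: `peaks`, `slopes`, `tests`,
#'   `rrc`, `drive`, `specificity`, `spectrum` (or `NULL`), `exclusions`,
#'   `cfg`.
#' @export
run_dataset1_analysis <- function(cfg = dataset1_config()) {
  stopifnot(inherits(cfg, "run_config"))
  stim_ids <- sprintf("img%02d", seq_len(cfg$n_stimuli))
  truth <- cfg$truth %||% ground_truth(stim_ids, seed = cfg$seed)
  sessions <- lapply(seq_len(cfg$n_sessions), function(i) {
    trials <- generate_natural_sequence(
      cfg$n_stimuli, cfg$reps_per_stim, cfg$subset_size, cfg$max_lag,
      seed = cfg$seed + i, session_id = sprintf("ses%02d", i))
    session_features(trials, truth, cfg, session_seed = cfg$seed + 10000 + i)
  })
  feats <- dplyr::bind_rows(lapply(sessions, `[[`, "features"))
  exclusions <- list()

  # --- gamma peak per stimulus (trials pooled across sessions) ---
  if (cfg$signal_level == "lfp") {
    freq <- sessions[[1]]$spectra$freq
    pooled <- dplyr::bind_rows(lapply(sessions, function(s) {
      tp <- s$spectra$trial_power
      tibble::tibble(stimulus_id = s$features$stimulus_id[
        !duplicated(s$features$trial_index)],
        row = seq_len(nrow(tp)))
    }))
    all_power <- do.call(rbind, lapply(sessions, function(s)
      s$spectra$trial_power))
    peaks <- lapply(stim_ids, function(st) {
      rows <- which(pooled$stimulus_id == st)
      spec <- colMeans(all_power[rows, , drop = FALSE])
      pk <- find_gamma_peaks(spec, freq)
      if (nrow(pk) == 0) {
        return(tibble::tibble(stimulus_id = st, freq_hz = NA_real_,
                              rank = NA_integer_, p = NA_real_,
                              validated = FALSE))
      }
      v <- validate_gamma_peak(all_power[rows, , drop = FALSE], freq,
                               pk$freq_hz[1], n_perm = cfg$n_perm,
                               seed = cfg$seed + 500)
      tibble::tibble(stimulus_id = st, freq_hz = pk$freq_hz[1],
                     rank = 1L, p = v$p, validated = v$validated)
    })
    peaks <- dplyr::bind_rows(peaks)
    exclusions$stimuli_without_peak <-
      peaks$stimulus_id[!peaks$validated]
    # gamma-band scalar per trial and site around the stimulus peak
    gam <- rep(NA_real_, nrow(feats))
    offset <- 0
    for (s in sessions) {
      rel <- s$spectra$rel
      tr <- s$features
      pk <- peaks$freq_hz[match(tr$stimulus_id, peaks$stimulus_id)]
      ok <- which(peaks$validated[match(tr$stimulus_id,
                                        peaks$stimulus_id)] & !is.na(pk))
      si <- match(tr$site_id, sprintf("site%02d", seq_len(cfg$n_sites)))
      ti <- match(tr$trial_index, unique(tr$trial_index))
      for (k in ok) {
        gam[offset + k] <- gamma_band_mean(rel$power[ti[k], si[k], ],
                                           rel$freq, pk[k], band_hz = 16)
      }
      offset <- offset + nrow(tr)
    }
    feats$gamma_ratio <- gam
  } else {
    peaks <- tibble::tibble(stimulus_id = stim_ids,
                            freq_hz = truth$stimulus$gamma_peak_hz,
                            rank = 1L, p = NA_real_, validated = TRUE)
  }

  # --- repetition trajectories (correct trials, capped repetitions) ---
  traj <- feats |>
    dplyr::filter(.data$correct, !is.na(.data$repetition_number),
                  .data$repetition_number <= cfg$max_rep) |>
    dplyr::select(dplyr::any_of(c("session_id", "stimulus_id", "site_id",
                                  "repetition_number", "gamma_ratio",
                                  "dmua", "dmua_onset"))) |>
    dplyr::rename(repetition = "repetition_number")
  elig <- eligibility(dplyr::distinct(
    feats, .data$session_id, .data$stimulus_id, .data$trial_index,
    .data$correct))
  exclusions$sequences_below_min_trials <-
    sum(!elig$eligible_all)

  site_avg <- traj |>
    dplyr::group_by(.data$session_id, .data$stimulus_id,
                    .data$repetition) |>
    dplyr::summarise(gamma = mean(.data$gamma_ratio, na.rm = TRUE),
                     dmua = mean(.data$dmua, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::semi_join(elig[elig$eligible_all, ],
                     by = c("session_id", "stimulus_id"))

  slope_tbl <- site_avg |>
    tidyr::pivot_longer(c("gamma", "dmua"), names_to = "feature") |>
    dplyr::group_by(.data$feature, .data$session_id, .data$stimulus_id) |>
    dplyr::reframe(dplyr::bind_rows(lapply(c("early", "late"), function(sg)
      glance(fit_slopes(.data$value, .data$repetition, segment = sg,
                        max_rep = cfg$max_rep))))) |>
    dplyr::filter(!.data$omitted)

  tests <- slope_tbl |>
    dplyr::group_by(.data$feature, .data$segment) |>
    dplyr::summarise(
      mean_slope = mean(.data$slope),
      mean_rrc = mean(.data$rrc, na.rm = TRUE),
      p = signflip_test(.data$slope, n_perm = cfg$n_perm,
                        seed = cfg$seed + 71)$p,
      .groups = "drop")
  exclusions$rrc_degenerate <- sum(is.na(slope_tbl$rrc))

  drive <- tryCatch(
    drive_dependence(
      traj |> dplyr::mutate(response = if (cfg$signal_level == "lfp")
        .data$dmua_onset else .data$dmua),
      segment = "all", max_rep = cfg$max_rep),
    error = function(e) NULL)

  spec_data <- site_avg |>
    dplyr::transmute(.data$session_id, .data$stimulus_id,
                     site_id = "siteavg", .data$repetition,
                     value = .data$gamma)
  specificity <- specificity_test(spec_data, s = cfg$s,
                                  n_perm = cfg$n_perm,
                                  n_reps = cfg$max_rep,
                                  seed = cfg$seed + 99)
  spectrum <- NULL
  if (cfg$compute_spectrum && cfg$signal_level == "lfp") {
    freq <- sessions[[1]]$spectra$freq
    keep_f <- freq >= 20 & freq <= 100
    long <- list()
    offset <- 0
    for (s in sessions) {
      tp <- s$spectra$trial_power[, keep_f, drop = FALSE]
      tr <- s$features[!duplicated(s$features$trial_index), ]
      keep <- tr$correct & !is.na(tr$repetition_number) &
        tr$repetition_number <= cfg$max_rep
      long[[length(long) + 1]] <- tibble::tibble(
        session_id = rep(tr$session_id[keep], sum(keep_f)),
        stimulus_id = rep(tr$stimulus_id[keep], sum(keep_f)),
        site_id = "siteavg",
        repetition = rep(tr$repetition_number[keep], sum(keep_f)),
        bin = rep(freq[keep_f], each = sum(keep)),
        value = as.vector(tp[keep, , drop = FALSE]))
    }
    spectrum <- correlation_spectrum(dplyr::bind_rows(long),
                                     s = cfg$s, n_perm = cfg$n_perm,
                                     n_reps = cfg$max_rep,
                                     seed = cfg$seed + 1234)
  }
  structure(list(peaks = peaks, slopes = slope_tbl, tests = tests,
                 drive = drive, specificity = specificity,
                 spectrum = spectrum, exclusions = exclusions, cfg = cfg),
            class = "dataset1_report")
}

#' Configuration for block-design (Dataset-2/3 style) experiments
#'
#' @param designs Character vector of block designs presented across
#'   sessions (recycled); Dataset-2 grating defaults `c("ABA", "BBA")`,
#'   Dataset-3 location sequences e.g.
#'   `c("InIn", "OutIn", "InOutIn", "OutOutIn")`.
#' @param trials_per_block Trials per block (100 gratings, 50 locations).
#' @param n_sessions,n_sites,fs,s,n_perm Scale parameters.
#' @param signal_level `"band"` (default: block analyses consume gamma-band
#'   features) or `"lfp"`.
#' @param truth Optional [ground_truth()] (built with
#'   `x_transform = "log10_trial"` if `NULL`).
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
block_config <- function(designs = c("ABA", "BBA"), trials_per_block = 100,
                         n_sessions = 20, n_sites = 4, fs = 500,
                         s = 100, n_perm = 1000,
                         signal_level = c("band", "lfp"),
                         truth = NULL, seed = 1) {
  structure(list(designs = designs, trials_per_block = trials_per_block,
                 n_sessions = n_sessions, n_sites = n_sites, fs = fs,
                 s = s, n_perm = n_perm,
                 signal_level = match.arg(signal_level),
                 truth = truth, seed = seed),
            class = "run_config")
}

# +-3-trial centered binning within each block
bin_pm3 <- function(value, trial_in_block, half = 3) {
  vapply(trial_in_block, function(t0)
    mean(value[abs(trial_in_block - t0) <= half]), numeric(1))
}

#' Run a block-design persistence/specificity analysis
#'
#' Builds grating (`dataset = 2`) or location (`dataset = 3`) block
#' sequences, synthesizes responses, fits `r(trlNum) = a + b * log10(trlNum)`
#' per block (excluding the first 4 trials, as for the natural images),
#' derives RRC and initial-response intercepts per block type, and runs the
#' exchange-test contrasts: stimulus/location specificity (`A[B]A` vs
#' `B[B]A`), between-session persistence (`AB[A]` vs `BB[A]`) and
#' within-session persistence (`AB[A]` vs `[A]BA`), plus the multiple
#' regression model with block indicators. Dataset-3 responses are averaged
#' in +-3-trial bins before the block contrasts.
#'
#' @param cfg A [block_config()].
#' @param dataset 2 (gratings) or 3 (locations).
#' @return A list of class `block_report`: `fits` (per session x block),
#'   `contrasts` (tidy exchange tests), `regression`, `cfg`.
#' @export
run_block_analysis <- function(cfg = block_config(), dataset = 2) {
  stopifnot(inherits(cfg, "run_config"))
  if (dataset == 3 && !any(grepl("In|Out", cfg$designs))) {
    abort("dataset 3 requires In/Out designs.")
  }
  if (any(vapply(cfg$designs, function(d)
    length(strsplit(gsub("In|Out", "L", d), "")[[1]]) < 2 &&
      !grepl("In|Out", d) && nchar(d) < 2, logical(1)))) {
    abort("designs must contain at least 2 blocks for contrasts.")
  }
  stim_ids <- if (dataset == 2) c("gratingA", "gratingB") else "grating"
  truth <- cfg$truth %||% ground_truth(stim_ids,
                                       x_transform = "log10_trial",
                                       seed = cfg$seed)
  sessions <- lapply(seq_len(cfg$n_sessions), function(i) {
    des <- cfg$designs[(i - 1) %% length(cfg$designs) + 1]
    # counterbalance which grating serves as A across sessions
    stim_map <- if (dataset == 2) {
      if (i %% 2 == 0) c(A = "gratingA", B = "gratingB") else
        c(A = "gratingB", B = "gratingA")
    } else "grating"
    trials <- generate_block_sequence(des, cfg$trials_per_block,
                                      stimuli = stim_map,
                                      seed = cfg$seed + i,
                                      session_id = sprintf("ses%02d", i))
    f <- session_features(trials, truth, cfg,
                          session_seed = cfg$seed + 10000 + i)$features
    f$design <- des
    f
  })
  feats <- dplyr::bind_rows(sessions)
  site_avg <- feats |>
    dplyr::group_by(.data$session_id, .data$design, .data$block_index,
                    .data$block_type, .data$stimulus_id, .data$location,
                    .data$trial_in_block) |>
    dplyr::summarise(gamma = mean(.data$gamma_ratio), .groups = "drop")
  if (dataset == 3) {
    site_avg <- site_avg |>
      dplyr::group_by(.data$session_id, .data$block_index) |>
      dplyr::mutate(gamma = bin_pm3(.data$gamma, .data$trial_in_block)) |>
      dplyr::ungroup()
  }
  fits <- site_avg |>
    dplyr::group_by(.data$session_id, .data$design, .data$block_index,
                    .data$block_type, .data$stimulus_id, .data$location) |>
    dplyr::reframe(glance(fit_slopes(
      .data$gamma, .data$trial_in_block, segment = "late",
      x_transform = "log10_trial", max_rep = Inf)))

  contrast <- function(type_a, type_b, metric) {
    a <- fits |> dplyr::filter(.data$block_type == type_a)
    b <- fits |> dplyr::filter(.data$block_type == type_b)
    if (nrow(a) < 2 || nrow(b) < 2) return(NULL)
    n <- min(nrow(a), nrow(b))
    tst <- exchange_test(a[[metric]][seq_len(n)], b[[metric]][seq_len(n)],
                         n_perm = cfg$n_perm, seed = cfg$seed + 333)
    tibble::tibble(contrast = paste(type_a, "vs", type_b),
                   metric = metric, observed = tst$observed, p = tst$p)
  }
  pairs <- if (dataset == 2) {
    list(c("A[B]A", "B[B]A"), c("AB[A]", "BB[A]"), c("AB[A]", "[A]BA"))
  } else {
    list(c("Out[In]", "In[In]"), c("InOut[In]", "OutOut[In]"))
  }
  contrasts <- dplyr::bind_rows(unlist(lapply(pairs, function(p)
    lapply(c("intercept", "rrc"), function(m) contrast(p[1], p[2], m))),
    recursive = FALSE))

  reg_data <- feats |>
    dplyr::group_by(.data$session_id, .data$design, .data$trial_index,
                    .data$block_index, .data$block_type,
                    .data$stimulus_id, .data$location,
                    .data$trial_in_block, .data$repetition_number,
                    .data$local_rep) |>
    dplyr::summarise(gamma = mean(.data$gamma_ratio), .groups = "drop") |>
    block_indicators()
  regression <- if (dataset == 2) {
    fit_block_regression(reg_data, "gamma",
                         continuous = c("log_rep", "log_trial"),
                         categorical = "session_id")
  } else {
    d3 <- reg_data |>
      dplyr::filter(.data$location == "In",
                    .data$block_type %in% c("Out[In]", "In[In]",
                                            "InOut[In]", "OutOut[In]")) |>
      dplyr::mutate(log_local_rep = log10(pmax(.data$local_rep, 1)))
    if (nrow(d3) > 10) {
      fit_block_regression(d3, "gamma",
                           continuous = c("log_local_rep", "log_trial"),
                           categorical = "session_id",
                           block_terms = character(),
                           interact_with = NULL)
    } else NULL
  }
  structure(list(fits = fits, contrasts = contrasts,
                 regression = regression, cfg = cfg),
            class = "block_report")
}
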