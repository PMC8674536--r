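#' Detect microsaccades by robust velocity threshold
#'
#' Smooths horizontal and vertical gaze signals with a rectangular +-5 ms
#' window, differentiates across time points separated by ~10 ms to obtain
#' robust eye velocities, and marks samples where either axis exceeds
#' `lambda * c`, with the criterion `c = sqrt(median(v^2) - median(v)^2)` -
#' a median-based robust SD in velocity units, computed per trial and axis.
#' Consecutive threshold crossings (and crossings separated by less than
#' `min_sep_ms`) are merged into single events.
#'
#' @param eye An `eye_trace` from [synthesize_eye_traces()].
#' @param lambda Threshold multiplier (6 by default; 5-7 give qualitatively
#'   similar results).
#' @param smooth_ms Half-width of the rectangular smoothing window (ms).
#' @param diff_ms Separation of the samples used for differentiation (ms).
#' @param min_sep_ms Crossing runs closer than this merge into one event.
#' @return A tibble with one row per detected event: `trial`, `onset` (s),
#'   `offset` (s), `peak_velocity` (dva/s).
#' @export
detect_microsaccades <- function(eye, lambda = 6, smooth_ms = 5,
                                 diff_ms = 10, min_sep_ms = 10) {
  fs <- eye$fs
  n_t <- length(eye$time)
  half_sm <- max(round(smooth_ms / 1000 * fs), 1)
  if (n_t < 4 * half_sm + 4) abort("trace shorter than the smoothing support.")
  half_d <- max(round(diff_ms / 2000 * fs), 1)
  min_sep <- max(round(min_sep_ms / 1000 * fs), 1)
  boxcar <- function(x) {
    k <- rep(1 / (2 * half_sm + 1), 2 * half_sm + 1)
    pad <- c(x[half_sm:1], x, x[n_t:(n_t - half_sm + 1)])
    as.numeric(stats::filter(pad, k, sides = 2))[(half_sm + 1):(half_sm + n_t)]
  }
  vel <- function(x) {
    v <- rep(0, n_t)
    idx <- (half_d + 1):(n_t - half_d)
    v[idx] <- (x[idx + half_d] - x[idx - half_d]) / (2 * half_d / fs)
    v
  }
  crit <- function(v) sqrt(max(median(v^2) - median(v)^2, 0))
  out <- list()
  for (i in seq_len(nrow(eye$gaze_x))) {
    vx <- vel(boxcar(eye$gaze_x[i, ]))
    vy <- vel(boxcar(eye$gaze_y[i, ]))
    cross <- abs(vx) > lambda * crit(vx) | abs(vy) > lambda * crit(vy)
    if (!any(cross)) next
    r <- rle(cross)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    ev <- cbind(starts[r$values], ends[r$values])
    # merge events separated by short gaps
    if (nrow(ev) > 1) {
      keep <- ev[1, , drop = FALSE]
      for (j in 2:nrow(ev)) {
        if (ev[j, 1] - keep[nrow(keep), 2] <= min_sep) {
          keep[nrow(keep), 2] <- ev[j, 2]
        } else {
          keep <- rbind(keep, ev[j, ])
        }
      }
      ev <- keep
    }
    speed <- pmax(abs(vx), abs(vy))
    out[[length(out) + 1]] <- tibble::tibble(
      trial = i,
      onset = eye$time[ev[, 1]],
      offset = eye$time[ev[, 2]],
      peak_velocity = vapply(seq_len(nrow(ev)), function(j)
        max(speed[ev[j, 1]:ev[j, 2]]), numeric(1))
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(trial = integer(), onset = numeric(),
                          offset = numeric(), peak_velocity = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Per-trial microsaccade rate
#'
#' Counts detected events per trial inside a window and converts to Hz.
#'
#' @param events Output of [detect_microsaccades()].
#' @param n_trials Total number of trials.
#' @param window Counting window (s).
#' @return Numeric vector of rates (events/s), one per trial.
#' @export
microsaccade_rate <- function(events, n_trials, window = c(0, 1.5)) {
  counts <- rep(0, n_trials)
  sel <- events$onset >= window[1] & events$onset < window[2]
  tb <- table(events$trial[sel])
  counts[as.integer(names(tb))] <- as.integer(tb)
  counts / (window[2] - window[1])
}

#' Baseline-normalized pupil response
#'
#' Z-scores each trial's pupil trace against that trial's own pre-stimulus
#' baseline window (single-trial baseline), returning time-resolved z values
#' per trial; trials whose baseline has zero variance are flagged and
#' returned as `NA`.
#'
#' @param eye An `eye_trace`.
#' @param baseline_window Pre-stimulus window (s).
#' @return A list: `z` (trial x time matrix), `time`, `flagged_trials`,
#'   and `trial_mean` (per-trial average z over the post-stimulus period).
#' @export
pupil_response <- function(eye, baseline_window = c(-1, 0)) {
  sel <- eye$time >= baseline_window[1] & eye$time < baseline_window[2]
  z <- eye$pupil
  flagged <- integer()
  for (i in seq_len(nrow(z))) {
    b <- eye$pupil[i, sel]
    s <- sd(b)
    if (!is.finite(s) || s == 0) {
      z[i, ] <- NA_real_
      flagged <- c(flagged, i)
    } else {
      z[i, ] <- (eye$pupil[i, ] - mean(b)) / s
    }
  }
  post <- eye$time >= 0
  list(z = z, time = eye$time, flagged_trials = flagged,
       trial_mean = rowMeans(z[, post, drop = FALSE]))
}
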