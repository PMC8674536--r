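#' Denoised multi-unit activity (dMUA)
#'
#' Bins the MUA envelope in fixed windows (default 10 ms) over the analysis
#' span and subtracts, per site, the minimum binned value observed across all
#' bins and trials of the session. The minimal observable activity of a site
#' is the best available estimate of its noise floor, so after subtraction
#' the per-site minimum is exactly zero.
#'
#' @param rec A `recording` from [synthesize_recording()].
#' @param bin_s Bin width in seconds.
#' @param window Analysis span (s, half-open bins `[start, stop)`).
#' @return An object of class `binned_rate`: list with `data` (site x trial
#'   x bin array), `time` (bin start times), `bin_s`, `trials`, and
#'   `noise_floor` (the subtracted per-site minima).
#' @export
compute_dmua <- function(rec, bin_s = 0.01, window = c(-1, 1.5)) {
  if (dim(rec$mua)[2] == 0) abort("empty trial set.")
  if (min(rec$time) > window[1] || max(rec$time) + 1 / rec$fs < window[2]) {
    abort("recording does not cover the requested analysis window.")
  }
  br <- bin_rate(rec$mua, rec$time, rec$fs, bin_s, window)
  mins <- apply(br$data, 1, min)
  br$data <- sweep(br$data, 1, mins, `-`)
  br$noise_floor <- mins
  br$trials <- rec$trials
  br
}

# mean within half-open bins [start, start + bin_s) along the time axis
bin_rate <- function(x, time, fs, bin_s, window) {
  starts <- seq(window[1], window[2] - bin_s / 2, by = bin_s)
  per_bin <- round(bin_s * fs)
  i0 <- round((starts - time[1]) * fs) + 1
  d <- dim(x)
  out <- array(0, dim = c(d[1], d[2], length(starts)))
  for (b in seq_along(starts)) {
    idx <- i0[b]:(i0[b] + per_bin - 1)
    out[, , b] <- apply(x[, , idx, drop = FALSE], c(1, 2), mean)
  }
  structure(list(data = out, time = starts, bin_s = bin_s),
            class = "binned_rate")
}

#' Gaussian-smooth binned rates
#'
#' Convolves rate time courses with a Gaussian kernel (default SD 20 ms)
#' along the time axis, using reflection padding at the edges. Analyses that
#' are latency-sensitive (first-significant-bin tests) should use the
#' unsmoothed input, since smoothing shifts apparent onset times.
#'
#' @param br A `binned_rate` (or a numeric vector/matrix with time along the
#'   last dimension).
#' @param sd_s Kernel SD in seconds (> 0).
#' @param dt Sample spacing in seconds; taken from `br$bin_s` when `br` is a
#'   `binned_rate`.
#' @return Same shape/class as the input, smoothed.
#' @export
smooth_rate <- function(br, sd_s = 0.02, dt = NULL) {
  if (sd_s <= 0) abort("`sd_s` must be > 0.")
  if (inherits(br, "binned_rate")) {
    out <- br
    d <- dim(br$data)
    for (s in seq_len(d[1])) for (i in seq_len(d[2])) {
      out$data[s, i, ] <- gauss_smooth(br$data[s, i, ], sd_s, br$bin_s)
    }
    return(out)
  }
  if (is.null(dt)) abort("`dt` required for plain numeric input.")
  if (is.matrix(br)) {
    t(apply(br, 1, gauss_smooth, sd_s = sd_s, dt = dt))
  } else {
    gauss_smooth(br, sd_s, dt)
  }
}

gauss_smooth <- function(x, sd_s, dt) {
  half <- max(ceiling(3 * sd_s / dt), 1)
  k <- dnorm(seq(-half, half) * dt, sd = sd_s)
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half, n):1], x, x[n:pmax(n - half + 1, 1)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Baseline-normalize responses
#'
#' Divides trial-wise responses by a session-average baseline computed per
#' site over **all** trials (never per trial), returning unitless
#' stimulation/baseline ratios. For `binned_rate` input the baseline is the
#' mean rate in `baseline_window` (default -0.95 to 0 s); for
#' `power_spectrum` input supply the baseline-period spectrum and each
#' trial's stimulation spectrum is divided by the trial-averaged baseline
#' spectrum per site and frequency.
#'
#' @param x A `binned_rate` or `power_spectrum`.
#' @param ... Method arguments.
#' @return Same class as `x` with normalized values; per-site baseline kept
#'   in `$baseline_stat`. Sites with non-positive baseline are flagged in
#'   `$flagged_sites` and filled with `NA`.
#' @export
baseline_normalize <- function(x, ...) UseMethod("baseline_normalize")

#' @rdname baseline_normalize
#' @param baseline_window Window (s) over which the rate baseline is taken.
#' @export
baseline_normalize.binned_rate <- function(x, baseline_window = c(-0.95, 0),
                                           ...) {
  sel <- x$time >= baseline_window[1] &
    (x$time + x$bin_s) <= baseline_window[2] + 1e-9
  base <- apply(x$data[, , sel, drop = FALSE], 1, mean)
  normalize_by_site(x, base)
}

#' @rdname baseline_normalize
#' @param baseline A `power_spectrum` computed on the pre-stimulus baseline
#'   period of the same session.
#' @export
baseline_normalize.power_spectrum <- function(x, baseline, ...) {
  if (!inherits(baseline, "power_spectrum")) {
    abort("`baseline` must be a power_spectrum.")
  }
  if (!isTRUE(all.equal(x$freq, baseline$freq))) {
    abort("stimulus and baseline spectra are on different frequency grids.")
  }
  base <- apply(baseline$power, c(2, 3), mean) # site x freq, over all trials
  out <- x
  flagged <- which(apply(base <= 0, 1, any))
  for (s in seq_len(dim(x$power)[2])) {
    out$power[, s, ] <- if (s %in% flagged) NA_real_ else
      sweep(x$power[, s, , drop = FALSE][, 1, ], 2, base[s, ], `/`)
  }
  out$normalized <- TRUE
  out$baseline_stat <- base
  out$flagged_sites <- flagged
  out
}

normalize_by_site <- function(x, base) {
  flagged <- which(base <= 0)
  out <- x
  out$data <- sweep(x$data, 1, ifelse(base <= 0, NA_real_, base), `/`)
  out$baseline_stat <- base
  out$flagged_sites <- flagged
  out
}

#' Cut trials into non-overlapping epochs
#'
#' Cuts each trial's signal within `window` into `floor(window / epoch_len)`
#' non-overlapping, left-aligned epochs (half-open sample bins).
#'
#' @param rec A `recording`.
#' @param signal Which array to epoch: `"lfp"` or `"mua"`.
#' @param window Window (s) relative to stimulus onset; defaults to the
#'   0.5-1.5 s stimulation period. Use `c(-1, 0)` for the baseline period.
#' @param epoch_len Epoch length in seconds; `epoch_len * fs` must be a
#'   whole number of samples and fit inside `window`.
#' @return An object of class `epoch_set`: list with `data` (epoch x site x
#'   sample array), `trial` (parent trial index per epoch), `epoch_len`,
#'   `fs`, `origin` window.
#' @export
epoch_signal <- function(rec, signal = c("lfp", "mua"),
                         window = c(0.5, 1.5), epoch_len = 0.25) {
  signal <- match.arg(signal)
  span <- window[2] - window[1]
  if (epoch_len > span + 1e-9) abort("`epoch_len` exceeds the window.")
  n_samp <- round(epoch_len * rec$fs)
  if (abs(n_samp - epoch_len * rec$fs) > 1e-9) {
    abort("`epoch_len * fs` must be an integer number of samples.")
  }
  n_ep <- floor(span / epoch_len + 1e-9)
  x <- rec[[signal]]
  d <- dim(x)
  i0 <- round((window[1] - rec$time[1]) * rec$fs) + 1
  data <- array(0, dim = c(d[2] * n_ep, d[1], n_samp))
  trial <- integer(d[2] * n_ep)
  k <- 0
  for (i in seq_len(d[2])) {
    for (e in seq_len(n_ep)) {
      k <- k + 1
      idx <- (i0 + (e - 1) * n_samp):(i0 + e * n_samp - 1)
      data[k, , ] <- x[, i, idx]
      trial[k] <- i
    }
  }
  structure(list(data = data, trial = trial, epoch_len = epoch_len,
                 fs = rec$fs, origin = window),
            class = "epoch_set")
}

#' Re-reference LFP sites
#'
#' Derives unipolar (identity), common-average (subtract the cross-site mean
#' per sample) or bipolar (sample-by-sample time-domain difference between
#' neighboring sites, each unipolar channel used at most once) LFP signals.
#'
#' @param rec A `recording`.
#' @param mode `"unipolar"`, `"common_average"` or `"bipolar"`.
#' @param pairs For bipolar: 2-column integer matrix of site index pairs;
#'   defaults to consecutive disjoint neighbor pairs (1-2, 3-4, ...).
#' @return A `recording` with the derived `lfp` (and matching `sites`).
#' @export
derive_sites <- function(rec, mode = c("unipolar", "common_average",
                                       "bipolar"), pairs = NULL) {
  mode <- match.arg(mode)
  out <- rec
  if (mode == "unipolar") return(out)
  d <- dim(rec$lfp)
  if (mode == "common_average") {
    for (i in seq_len(d[2])) {
      m <- rec$lfp[, i, , drop = TRUE]
      if (is.null(dim(m))) m <- matrix(m, nrow = 1)
      out$lfp[, i, ] <- sweep(m, 2, colMeans(m), `-`)
    }
    return(out)
  }
  if (is.null(pairs)) {
    k <- floor(d[1] / 2)
    pairs <- cbind(2 * seq_len(k) - 1L, 2 * seq_len(k))
  }
  if (anyDuplicated(as.vector(pairs))) {
    abort("a unipolar channel may be used in at most one bipolar pair.")
  }
  bip <- array(0, dim = c(nrow(pairs), d[2], d[3]))
  for (p in seq_len(nrow(pairs))) {
    bip[p, , ] <- rec$lfp[pairs[p, 1], , ] - rec$lfp[pairs[p, 2], , ]
  }
  out$lfp <- bip
  out$sites <- sprintf("bip%02d", seq_len(nrow(pairs)))
  out$neighbors <- if (nrow(pairs) >= 2)
    cbind(seq_len(nrow(pairs) - 1), seq_len(nrow(pairs) - 1) + 1L) else
    matrix(integer(0), 0, 2)
  out
}
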