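#' Find gamma-band peaks in a relative power spectrum
#'
#' Returns up to `n_peaks` strict local maxima of the spectrum between 20
#' and 190 Hz, ranked by height with ties broken toward the lower frequency.
#' Monotone spectra yield an empty result.
#'
#' @param power Numeric vector: one (relative) power spectrum.
#' @param freq Frequency grid (Hz), spacing <= 4 Hz recommended.
#' @param range Search range in Hz.
#' @param n_peaks Maximum number of peaks to return.
#' @return A tibble with `freq_hz`, `height`, `rank` (possibly 0 rows).
#' @export
find_gamma_peaks <- function(power, freq, range = c(20, 190), n_peaks = 2) {
  stopifnot(length(power) == length(freq))
  inside <- which(freq >= range[1] & freq <= range[2])
  is_max <- vapply(inside, function(i) {
    i > 1 && i < length(power) &&
      power[i] > power[i - 1] && power[i] > power[i + 1]
  }, logical(1))
  cand <- inside[is_max]
  if (length(cand) == 0) {
    return(tibble::tibble(freq_hz = numeric(), height = numeric(),
                          rank = integer()))
  }
  ord <- order(-power[cand], freq[cand])
  keep <- cand[ord][seq_len(min(n_peaks, length(cand)))]
  tibble::tibble(freq_hz = freq[keep], height = power[keep],
                 rank = seq_along(keep))
}

#' Validate a gamma peak against high-frequency activity
#'
#' One-sided permutation test of the trial-mean relative power in the band
#' `peak_hz +- band_hz` against the reference band `ref_hz +- band_hz`
#' (default 190 Hz, so that validated peaks stand reliably above any
#' spike-bleed plateau rather than merely above the pre-stimulus baseline).
#' Trials are pooled across sessions; each permutation re-assigns the two
#' band labels within every trial (equivalent to flipping the sign of the
#' per-trial band difference).
#'
#' @param trial_power Trial x frequency matrix of relative power.
#' @param freq Frequency grid (Hz).
#' @param peak_hz Candidate peak frequency.
#' @param band_hz Half-width of both bands (bins fully inside are used).
#' @param ref_hz Center of the reference band.
#' @param n_perm Number of permutations.
#' @param alpha Validation threshold on the one-sided p value.
#' @param seed Integer seed.
#' @return A list with `validated`, `p`, `observed` (mean band difference),
#'   `n_trials`.
#' @export
validate_gamma_peak <- function(trial_power, freq, peak_hz, band_hz = 8,
                                ref_hz = 190, n_perm = 1000, alpha = 0.05,
                                seed = NULL) {
  pk <- band_bins(freq, peak_hz, band_hz)
  rf <- band_bins(freq, ref_hz, band_hz)
  if (length(intersect(pk, rf)) > 0) {
    abort("peak band overlaps the reference band; cannot validate.")
  }
  if (length(pk) == 0 || length(rf) == 0) abort("empty comparison band.")
  d <- rowMeans(trial_power[, pk, drop = FALSE]) -
    rowMeans(trial_power[, rf, drop = FALSE])
  obs <- mean(d)
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    null <- as.vector(signs %*% d) / length(d)
    p <- max(sum(null >= obs), 1) / n_perm
    list(validated = p < alpha, p = p, observed = obs, n_trials = length(d))
  })
}

# bins fully inside center +- half (inclusive)
band_bins <- function(freq, center, half) {
  which(freq >= center - half - 1e-9 & freq <= center + half + 1e-9)
}

#' Group recording sites by shared gamma peak
#'
#' Groups sites whose largest (validated) peaks agree within `+-tol_hz`.
#' Groups are formed greedily around the most common peak frequency (ties
#' broken toward the lower frequency), mirroring how a dominant
#' stimulus-induced gamma peak recruits most of an array.
#'
#' @param peaks Tibble with `site_id` and `freq_hz` (one row per site:
#'   its largest validated peak).
#' @param tol_hz Grouping tolerance.
#' @return The input with a `group` integer column (1 = largest group).
#' @export
group_peak_sites <- function(peaks, tol_hz = 16) {
  remaining <- peaks
  remaining$group <- NA_integer_
  g <- 0L
  while (anyNA(remaining$group)) {
    g <- g + 1L
    open <- which(is.na(remaining$group))
    tab <- sort(table(remaining$freq_hz[open]), decreasing = TRUE)
    modal <- as.numeric(names(tab))
    seed_f <- modal[order(-as.vector(tab), modal)][1]
    hit <- open[abs(remaining$freq_hz[open] - seed_f) <= tol_hz + 1e-9]
    remaining$group[hit] <- g
  }
  # renumber so group 1 is the largest
  sizes <- table(remaining$group)
  remap <- setNames(seq_along(sizes), names(sort(sizes, decreasing = TRUE)))
  remaining$group <- as.integer(remap[as.character(remaining$group)])
  remaining
}

#' Align spectra to their individual gamma peaks
#'
#' Shifts each spectrum by a whole number of frequency bins so that its peak
#' sits at relative frequency 0, allowing averaging across stimuli with
#' different peak frequencies. Shifts are exact on the grid; out-of-range
#' bins are `NA`.
#'
#' @param spectra Matrix (row per stimulus/site) of spectra on `freq`.
#' @param peak_hz Peak frequency per row; must lie on the grid (the nearest
#'   bin is used).
#' @param freq Frequency grid (Hz).
#' @return A list with `aligned` (same-size matrix on the relative grid) and
#'   `rel_freq` (Hz relative to each peak).
#' @export
align_spectra <- function(spectra, peak_hz, freq) {
  spectra <- as.matrix(spectra)
  stopifnot(nrow(spectra) == length(peak_hz))
  n_f <- length(freq)
  mid <- floor(n_f / 2) + 1
  rel_freq <- (seq_len(n_f) - mid) * (freq[2] - freq[1])
  aligned <- matrix(NA_real_, nrow(spectra), n_f)
  for (i in seq_len(nrow(spectra))) {
    pk_bin <- which.min(abs(freq - peak_hz[i]))
    shift <- mid - pk_bin
    src <- seq_len(n_f) - shift
    ok <- src >= 1 & src <= n_f
    aligned[i, ok] <- spectra[i, src[ok]]
  }
  list(aligned = aligned, rel_freq = rel_freq)
}

#' Gamma-band scalar response around a peak
#'
#' Mean (relative) power over the bins fully inside `peak_hz +- band_hz`
#' (+-16 Hz for the natural-image analyses, +-8 Hz for block designs).
#'
#' @param power Vector or trial x frequency matrix.
#' @param freq Frequency grid (Hz).
#' @param peak_hz Peak frequency.
#' @param band_hz Band half-width.
#' @return Scalar (or per-trial vector) band mean.
#' @export
gamma_band_mean <- function(power, freq, peak_hz, band_hz = 16) {
  bins <- band_bins(freq, peak_hz, band_hz)
  if (length(bins) == 0) abort("no frequency bins inside the band.")
  if (is.matrix(power)) rowMeans(power[, bins, drop = FALSE]) else
    mean(power[bins])
}

#' Trial-selection eligibility for repetition analyses
#'
#' Applies the minimum-data thresholds used before slope and specificity
#' analyses: a (session, stimulus) sequence needs at least `min_correct`
#' correct trials (at least `min_early` for early-repetition fits), and a
#' stimulus enters gamma analyses only when at least `min_sites` sites show
#' a validated gamma peak for it.
#'
#' @param trials Trial table.
#' @param peak_sites Optional tibble with `stimulus_id`, `site_id`,
#'   `validated` from peak validation.
#' @param min_correct,min_early,min_sites Thresholds.
#' @return A tibble per (session_id, stimulus_id): `n_correct`,
#'   `eligible_all`, `eligible_early`, `eligible_gamma`.
#' @export
eligibility <- function(trials, peak_sites = NULL, min_correct = 8,
                        min_early = 4, min_sites = 5) {
  out <- trials |>
    dplyr::group_by(.data$session_id, .data$stimulus_id) |>
    dplyr::summarise(n_correct = sum(.data$correct), .groups = "drop") |>
    dplyr::mutate(eligible_all = .data$n_correct >= min_correct,
                  eligible_early = .data$n_correct >= min_early)
  if (!is.null(peak_sites)) {
    ok <- peak_sites |>
      dplyr::filter(.data$validated) |>
      dplyr::count(.data$stimulus_id, name = "n_peak_sites")
    out <- out |>
      dplyr::left_join(ok, by = "stimulus_id") |>
      dplyr::mutate(eligible_gamma =
                      !is.na(.data$n_peak_sites) &
                      .data$n_peak_sites >= min_sites)
  } else {
    out$eligible_gamma <- NA
  }
  out
}
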