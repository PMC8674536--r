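#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers for `n` samples and half-bandwidth `w`
#' (in cycles per sample) via the standard symmetric tridiagonal eigenvector
#' formulation. Tapers are unit-energy and sign-fixed so that the element of
#' largest magnitude is positive.
#'
#' @param n Samples per epoch.
#' @param nw Time-half-bandwidth product `n * w` (e.g. 2.5 for 250 ms epochs
#'   and 10 Hz half-bandwidth at 500 Hz).
#' @param k Number of tapers (>= 1; must not exceed `n`).
#' @return An `n` x `k` matrix, one taper per column.
#' @export
dpss_tapers <- function(n, nw, k) {
  if (k < 1) abort("taper count K must be >= 1.")
  if (2 * nw >= n) abort("epoch too short for the requested bandwidth.")
  w <- nw / n
  t0 <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
  diag_off <- t0[-1] * (n - t0[-1]) / 2
  tri <- matrix(0, n, n)
  tri[cbind(seq_len(n), seq_len(n))] <- diag_main
  tri[cbind(seq_len(n - 1), seq(2, n))] <- diag_off
  tri[cbind(seq(2, n), seq_len(n - 1))] <- diag_off
  ev <- eigen(tri, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    v <- tap[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    tap[, j] <- v / sqrt(sum(v^2))
  }
  tap
}

#' Taper configuration for spectral estimation
#'
#' Two standard configurations are used throughout: 500 ms Hann-tapered
#' epochs (2 Hz resolution; grating-response and low-frequency analyses) and
#' 250 ms multitaper epochs with +-10 Hz spectral smoothing (gamma-band
#' analyses of natural images). Under the convention `K = 2 T W`, 250 ms
#' epochs with 10 Hz half-bandwidth yield 5 DPSS tapers. The alternative
#' reading `K = 2 T W - 1` is available via `k_rule`.
#'
#' @param type `"hann"` or `"dpss"`.
#' @param epoch_len Epoch length T in seconds.
#' @param w_hz DPSS half-bandwidth W in Hz (ignored for Hann).
#' @param k_rule `"2TW"` (default) or `"2TW-1"`.
#' @return A list of class `taper_cfg` with `type`, `epoch_len`, `w_hz` and
#'   `n_tapers`.
#' @export
#' @examples
#' taper_cfg("dpss", 0.25, 10)$n_tapers # 5
taper_cfg <- function(type = c("dpss", "hann"), epoch_len = 0.25,
                      w_hz = 10, k_rule = c("2TW", "2TW-1")) {
  type <- match.arg(type)
  k_rule <- match.arg(k_rule)
  n_tapers <- if (type == "hann") 1L else {
    k <- 2 * epoch_len * w_hz
    k <- if (k_rule == "2TW") floor(k + 1e-9) else floor(k + 1e-9) - 1
    if (k < 1) abort("K < 1: epoch too short for the requested smoothing.")
    as.integer(k)
  }
  structure(list(type = type, epoch_len = epoch_len,
                 w_hz = if (type == "dpss") w_hz else NA_real_,
                 n_tapers = n_tapers),
            class = "taper_cfg")
}

taper_matrix <- function(cfg, n, fs) {
  if (cfg$type == "hann") {
    h <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
    matrix(h / sqrt(sum(h^2)), ncol = 1)
  } else {
    dpss_tapers(n, cfg$epoch_len * cfg$w_hz, cfg$n_tapers)
  }
}

#' Tapered power spectra per trial
#'
#' Computes, for every epoch, the tapered FFT magnitude-squared averaged
#' across tapers, then averages epochs within each trial, yielding one
#' spectrum per trial and site. No zero padding is used, so the frequency
#' grid spacing is `1 / epoch_len` (4 Hz for 250 ms epochs, 2 Hz for 500 ms
#' epochs). Power is scaled as one-sided spectral density (unit-energy
#' tapers, divided by `fs`, doubled off DC/Nyquist) so that the integral of
#' the spectrum over frequency tracks signal variance.
#'
#' @param ep An `epoch_set` from [epoch_signal()].
#' @param cfg A [taper_cfg()]; its `epoch_len` must match the epochs.
#' @return An object of class `power_spectrum`: list with `power` (trial x
#'   site x frequency array), `freq` (Hz), `cfg`, `normalized = FALSE`.
#' @export
taper_power <- function(ep, cfg = taper_cfg("dpss", ep$epoch_len, 10)) {
  if (abs(cfg$epoch_len - ep$epoch_len) > 1e-9) {
    abort("taper_cfg epoch_len does not match the epoch set.")
  }
  n <- dim(ep$data)[3]
  tap <- taper_matrix(cfg, n, ep$fs)
  n_f <- floor(n / 2) + 1
  freq <- (seq_len(n_f) - 1) * ep$fs / n
  scale <- c(1, rep(2, n_f - 2), if (n %% 2 == 0) 1 else 2)[seq_len(n_f)]
  n_sites <- dim(ep$data)[2]
  trials <- sort(unique(ep$trial))
  pow <- array(0, dim = c(length(trials), n_sites, n_f))
  for (s in seq_len(n_sites)) {
    x <- t(ep$data[, s, , drop = TRUE])            # samples x epochs
    if (is.null(dim(x))) x <- matrix(x, nrow = n)
    ep_pow <- matrix(0, n_f, ncol(x))
    for (j in seq_len(ncol(tap))) {
      xf <- stats::mvfft(x * tap[, j])[seq_len(n_f), , drop = FALSE]
      ep_pow <- ep_pow + (Mod(xf)^2) * scale / ep$fs
    }
    ep_pow <- ep_pow / ncol(tap)
    for (ti in seq_along(trials)) {
      sel <- ep$trial == trials[ti]
      pow[ti, s, ] <- rowMeans(ep_pow[, sel, drop = FALSE])
    }
  }
  structure(list(power = pow, freq = freq, cfg = cfg, trial = trials,
                 normalized = FALSE),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d trials x %d sites x %d freqs (%g-%g Hz)%s\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              min(x$freq), max(x$freq),
              if (isTRUE(x$normalized)) ", baseline-normalized" else ""))
  invisible(x)
}

#' Turn a power spectrum into a tidy tibble
#'
#' @param x A `power_spectrum`.
#' @param ... Unused.
#' @return A tibble with `trial`, `site`, `freq`, `power`.
#' @export
tidy.power_spectrum <- function(x, ...) {
  d <- dim(x$power)
  tibble::tibble(
    trial = rep(x$trial, times = d[2] * d[3]),
    site = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    freq = rep(x$freq, each = d[1] * d[2]),
    power = as.vector(x$power)
  )
}

#' Unit-magnitude MUA-LFP cross-spectra per epoch
#'
#' Computes, per epoch and taper, the cross-spectrum between an MUA site and
#' an LFP site and normalizes it by its magnitude, retaining phase-only
#' complex values. Zero-magnitude bins are excluded (set `NA`) and counted.
#'
#' @param mua_ep,lfp_ep `epoch_set`s with identical epoching (the MUA set is
#'   indexed by `mua_site`, the LFP set by `lfp_site`).
#' @param mua_site,lfp_site Site indices within the two epoch sets.
#' @param cfg A [taper_cfg()].
#' @return A list of class `cross_phases`: `z` (epoch-taper x frequency
#'   complex matrix, unit magnitude), `freq`, `n_excluded`.
#' @export
cross_spectral_phases <- function(mua_ep, lfp_ep, mua_site, lfp_site,
                                  cfg = taper_cfg("dpss", mua_ep$epoch_len,
                                                  10)) {
  if (!identical(dim(mua_ep$data)[c(1, 3)], dim(lfp_ep$data)[c(1, 3)])) {
    abort("MUA and LFP epoch sets must share epoching.")
  }
  n <- dim(mua_ep$data)[3]
  tap <- taper_matrix(cfg, n, mua_ep$fs)
  n_f <- floor(n / 2) + 1
  xm <- t(mua_ep$data[, mua_site, , drop = TRUE])
  xl <- t(lfp_ep$data[, lfp_site, , drop = TRUE])
  if (is.null(dim(xm))) { xm <- matrix(xm, nrow = n); xl <- matrix(xl, nrow = n) }
  zs <- vector("list", ncol(tap))
  for (j in seq_len(ncol(tap))) {
    fm <- stats::mvfft(xm * tap[, j])[seq_len(n_f), , drop = FALSE]
    fl <- stats::mvfft(xl * tap[, j])[seq_len(n_f), , drop = FALSE]
    zs[[j]] <- t(fm * Conj(fl))
  }
  z <- do.call(rbind, zs)
  m <- Mod(z)
  excluded <- m == 0
  z[excluded] <- NA_complex_
  z[!excluded] <- z[!excluded] / m[!excluded]
  structure(list(z = z, freq = (seq_len(n_f) - 1) * mua_ep$fs / n,
                 trial = rep(mua_ep$trial, times = ncol(tap)),
                 n_excluded = sum(excluded)),
            class = "cross_phases")
}

#' Pairwise phase consistency (PPC)
#'
#' The PPC over `N` phase observations is the average cosine of all pairwise
#' phase differences, \deqn{PPC = \frac{2}{N(N-1)} \sum_{j<k}
#' \cos(\theta_j - \theta_k),} computed here through the closed form
#' \eqn{(|\sum_j z_j|^2 - N) / (N (N-1))} on unit-magnitude complex values
#' \eqn{z_j}. Unlike the resultant-length, the PPC is unbiased by the number
#' of observations.
#'
#' @param z Complex matrix (observations x frequency) of unit-magnitude
#'   cross-spectral values, or a `cross_phases` object.
#' @return Numeric vector of PPC values per frequency (`NA` when fewer than
#'   2 observations are available in a bin).
#' @export
ppc <- function(z) {
  if (inherits(z, "cross_phases")) z <- z$z
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  apply(z, 2, function(col) {
    col <- col[!is.na(col)]
    n <- length(col)
    if (n < 2) return(NA_real_)
    (Mod(sum(col))^2 - n) / (n * (n - 1))
  })
}

#' MUA-LFP PPC spectra over neighboring sites
#'
#' For each MUA site, computes the PPC against every LFP site that is a
#' direct array neighbor (same-electrode pairs are excluded to avoid
#' spike-bleed artifacts) and averages the PPC across those neighboring LFP
#' sites. Phases are pooled over all stimulus-window epochs of the supplied
#' trial group.
#'
#' @param rec A `recording` (its `neighbors` edge list defines adjacency).
#' @param trials_idx Trial indices forming the group (default: all).
#' @param window,epoch_len Stimulus window and epoch length (s).
#' @param cfg A [taper_cfg()].
#' @return A tibble with `site`, `freq`, `ppc`, `n_epochs`; sites without an
#'   eligible neighbor are omitted with a warning.
#' @export
ppc_spectrum <- function(rec, trials_idx = NULL, window = c(0.5, 1.5),
                         epoch_len = 0.25,
                         cfg = taper_cfg("dpss", epoch_len, 10)) {
  sub <- rec
  if (!is.null(trials_idx)) {
    sub$lfp <- rec$lfp[, trials_idx, , drop = FALSE]
    sub$mua <- rec$mua[, trials_idx, , drop = FALSE]
    sub$trials <- rec$trials[trials_idx, ]
  }
  lfp_ep <- epoch_signal(sub, "lfp", window, epoch_len)
  mua_ep <- epoch_signal(sub, "mua", window, epoch_len)
  n_sites <- dim(sub$lfp)[1]
  nb <- rec$neighbors
  out <- list()
  for (s in seq_len(n_sites)) {
    partners <- c(nb[nb[, 1] == s, 2], nb[nb[, 2] == s, 1])
    partners <- setdiff(partners, s) # same-electrode pairs excluded
    if (length(partners) == 0) {
      warn(sprintf("site %d has no eligible neighbor; omitted.", s))
      next
    }
    cps <- lapply(partners, function(p)
      cross_spectral_phases(mua_ep, lfp_ep, s, p, cfg))
    vals <- vapply(cps, ppc, numeric(length(cps[[1]]$freq)))
    out[[length(out) + 1]] <- tibble::tibble(
      site = s,
      freq = cps[[1]]$freq,
      ppc = rowMeans(as.matrix(vals)),
      n_epochs = dim(mua_ep$data)[1] * cfg$n_tapers
    )
  }
  dplyr::bind_rows(out)
}
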