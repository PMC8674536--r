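test_that("DPSS tapers match an independent reference implementation", {
  # reference values computed once with scipy.signal.windows.dpss(125, 2.5, 5)
  # at samples 1, 31, 63, 91, 125 (sign aligned to largest-|value| positive)
  ref <- list(
    c(0.0007231987, 0.05830527, 0.15688046, 0.07445513, 0.0007231987),
    c(0.0049015830, 0.12049824, 0.00000000, -0.13201711, -0.0049015830),
    c(0.0216675900, 0.12553223, -0.10316355, 0.10494515, 0.0216675900),
    c(-0.0682338079, -0.03664963, 0.00000000, -0.00749060, 0.0682338079),
    c(0.1485793400, -0.06831020, 0.07892889, -0.08569240, 0.1485793400)
  )
  tap <- dpss_tapers(125, 2.5, 5)
  idx <- c(1, 31, 63, 91, 125)
  for (k in 1:5) {
    v <- tap[, k]
    if (sum(v[idx] * ref[[k]]) < 0) v <- -v # sign is a free convention
    expect_equal(v[idx], ref[[k]], tolerance = 1e-6)
  }
  # orthonormal family
  expect_equal(crossprod(tap), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("the 2TW rule gives five tapers for 250 ms and 10 Hz smoothing", {
  expect_equal(taper_cfg("dpss", 0.25, 10)$n_tapers, 5L)
  expect_equal(taper_cfg("dpss", 0.25, 10, k_rule = "2TW-1")$n_tapers, 4L)
  expect_equal(taper_cfg("hann", 0.5)$n_tapers, 1L)
  expect_error(taper_cfg("dpss", 0.02, 10), "K < 1")
})

test_that("multitaper power concentrates a sinusoid with little leakage", {
  fs <- 500
  tr <- generate_natural_sequence(1, 4, 1, 0, seed = 1,
                                  p_error_early = 0, p_error_late = 0)
  truth <- ground_truth("img01", gamma_base_power = 0, seed = 1)
  rec <- synthesize_recording(tr, truth, n_sites = 2, seed = 2)
  tone <- sin(2 * pi * 60 * rec$time)
  for (s in 1:2) for (i in seq_len(dim(rec$lfp)[2]))
    rec$lfp[s, i, ] <- tone
  ps <- taper_power(epoch_signal(rec, "lfp", c(0.5, 1.5), 0.25))
  spec <- colMeans(apply(ps$power, c(1, 3), mean))
  # energy confined to the +-10 Hz design band plus one resolution bin
  inband <- abs(ps$freq - 60) <= 14
  expect_lt(max(spec[!inband]) / max(spec), 0.01)
  expect_lte(abs(ps$freq[which.max(spec)] - 60), 10)
  expect_equal(diff(ps$freq)[1], 4) # no zero padding: 4 Hz grid
})

test_that("zero signal has zero power and white noise obeys Parseval", {
  tr <- generate_natural_sequence(1, 3, 1, 0, seed = 1,
                                  p_error_early = 0, p_error_late = 0)
  truth <- ground_truth("img01", gamma_base_power = 0, seed = 1)
  rec <- synthesize_recording(tr, truth, n_sites = 2, seed = 2)
  rec$lfp[] <- 0
  ps <- taper_power(epoch_signal(rec, "lfp", c(0.5, 1.5), 0.25))
  expect_true(all(ps$power == 0))

  set.seed(4)
  rec$lfp <- array(rnorm(length(rec$lfp)), dim = dim(rec$lfp))
  hp <- taper_power(epoch_signal(rec, "lfp", c(0.5, 1.5), 0.5),
                    taper_cfg("hann", 0.5))
  total <- mean(apply(hp$power, c(1, 2), function(v) sum(v) * hp$freq[2]))
  expect_lt(abs(total - 1), 0.05)
})

test_that("cross-spectral phases are unit magnitude and track delays", {
  fs <- 500
  tr <- generate_natural_sequence(1, 3, 1, 0, seed = 1,
                                  p_error_early = 0, p_error_late = 0)
  truth <- ground_truth("img01", gamma_base_power = 0, seed = 1)
  rec <- synthesize_recording(tr, truth, n_sites = 2, seed = 2)
  delta <- 0.008 # seconds
  tone <- function(t) cos(2 * pi * 60 * t)
  for (i in seq_len(dim(rec$lfp)[2])) {
    rec$mua[1, i, ] <- tone(rec$time)
    rec$lfp[1, i, ] <- tone(rec$time)
    rec$lfp[2, i, ] <- tone(rec$time - delta)
  }
  me <- epoch_signal(rec, "mua", c(0.5, 1.5), 0.25)
  le <- epoch_signal(rec, "lfp", c(0.5, 1.5), 0.25)
  # symmetric taper so an exact-bin tone keeps its analytic phase
  hann <- taper_cfg("hann", 0.25)
  same <- cross_spectral_phases(me, le, 1, 1, cfg = hann)
  expect_true(all(abs(Mod(same$z[!is.na(same$z)]) - 1) < 1e-9))
  bin60 <- which(same$freq == 60)
  expect_true(all(abs(Arg(same$z[, bin60])) < 1e-8))
  # delayed copy: phase 2*pi*f*delta at the tone frequency
  del <- cross_spectral_phases(me, le, 1, 2, cfg = hann)
  expected <- (2 * pi * 60 * delta + pi) %% (2 * pi) - pi
  expect_equal(unname(Arg(del$z[, bin60])),
               rep(expected, nrow(del$z)), tolerance = 1e-4)
})

test_that("closed-form PPC equals the brute-force pairwise sum", {
  brute <- function(theta) {
    n <- length(theta)
    s <- 0
    for (j in 1:(n - 1)) for (k in (j + 1):n) s <- s + cos(theta[j] - theta[k])
    2 * s / (n * (n - 1))
  }
  set.seed(5)
  for (n in c(4, 11, 50)) {
    th <- runif(n, 0, 2 * pi)
    expect_equal(ppc(matrix(exp(1i * th), ncol = 1)), brute(th),
                 tolerance = 1e-12)
  }
})

test_that("PPC is 1 for identical phases and invariant to global rotation", {
  z <- matrix(exp(1i * rep(0.7, 20)), ncol = 1)
  expect_equal(ppc(z), 1, tolerance = 1e-12)
  set.seed(6)
  th <- runif(15, 0, 2 * pi)
  base <- ppc(matrix(exp(1i * th), ncol = 1))
  rot <- ppc(matrix(exp(1i * (th + 1.234)), ncol = 1))
  expect_equal(base, rot, tolerance = 1e-12)
  expect_true(is.na(ppc(matrix(exp(1i * 0.2), ncol = 1))))
})

test_that("PPC of uniform phases is unbiased by observation count", {
  set.seed(7)
  for (n in c(10, 100)) {
    vals <- replicate(400, ppc(matrix(exp(1i * runif(n, 0, 2 * pi)),
                                      ncol = 1)))
    expect_lt(abs(mean(vals)), 0.02)
  }
})

test_that("PPC spectrum averages neighboring LFP sites and peaks at gamma", {
  rec <- make_recording(n_stimuli = 1, reps = 6, n_sites = 3,
                        gamma_peak_hz = 60, seed = 3)
  pp <- ppc_spectrum(rec)
  expect_true(all(pp$ppc <= 1 + 1e-12))
  top <- pp |> dplyr::group_by(site) |>
    dplyr::slice_max(ppc, n = 1) |> dplyr::ungroup()
  expect_true(all(abs(top$freq - 60) <= 8))
  # no-neighbor warning path (one warning per omitted site)
  rec$neighbors <- matrix(integer(0), 0, 2)
  msgs <- capture_warnings(out <- ppc_spectrum(rec))
  expect_match(msgs, "no eligible neighbor", all = TRUE)
  expect_equal(nrow(out), 0)
})
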