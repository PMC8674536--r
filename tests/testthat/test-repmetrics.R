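test_that("trajectory z-scores use the population SD and ignore affine scale", {
  z <- zscore_trajectory(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.224745, 0, 1.224745), tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  # affine invariance
  x <- c(2.5, -1, 4, 0.3, 7)
  expect_equal(as.numeric(zscore_trajectory(3 * x + 10)),
               as.numeric(zscore_trajectory(x)), tolerance = 1e-12)
  # constant input flagged, missing entries stay missing
  zc <- zscore_trajectory(c(5, 5, 5))
  expect_true(attr(zc, "constant"))
  expect_equal(as.numeric(zc), c(0, 0, 0))
  zm <- zscore_trajectory(c(1, NA, 3))
  expect_true(is.na(zm[2]))
  expect_error(zscore_trajectory(c(1, NA, NA)), "2 finite")
})

test_that("slope fits are exact on linear data and segment-faithful", {
  f <- fit_slopes(10 - 0.5 * (1:4), 1:4, segment = "early")
  expect_equal(f$slope, -0.5, tolerance = 1e-12)
  expect_equal(f$intercept, 10, tolerance = 1e-12)
  expect_equal(f$r_first, 9.5, tolerance = 1e-12)
  expect_equal(f$r_last, 8, tolerance = 1e-12)
  fc <- fit_slopes(rep(3, 10), 1:10, segment = "all")
  expect_equal(fc$slope, 0, tolerance = 1e-12)
  # early uses repetitions 1-4 exactly; late 5..max_rep
  y <- c(1:4 * 0, 10 - (5:15))
  fl <- fit_slopes(c(rep(0, 4), 10 - (5:15)), 1:15, segment = "late")
  expect_equal(fl$slope, -1, tolerance = 1e-12)
  expect_equal(fl$n, 11)
  # insufficient points are omitted, not fabricated
  fo <- fit_slopes(c(1, 2), c(1, 2), segment = "early")
  expect_true(fo$omitted)
  # log-transform fit: exact on log-linear data
  tvals <- 5:100
  flog <- fit_slopes(2 + 0.3 * log10(tvals), tvals, segment = "late",
                     x_transform = "log10_trial", max_rep = Inf)
  expect_equal(flog$slope, 0.3, tolerance = 1e-10)
  expect_equal(flog$intercept, 2, tolerance = 1e-10)
})

test_that("slope estimator is unbiased on noisy linear trajectories", {
  set.seed(20)
  errs <- replicate(400, {
    y <- 5 - 0.3 * (1:15) + rnorm(15, 0, 0.5)
    fit_slopes(y, 1:15, segment = "all")$slope + 0.3
  })
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)))
})

test_that("RRC identities hold exactly", {
  expect_equal(rrc(2, 2), 1, tolerance = 1e-12)
  expect_equal(rrc(2, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(rrc(1, 1.5), 1.2, tolerance = 1e-12)
  # slope zero -> RRC exactly 1 through the fit path
  f0 <- fit_slopes(rep(2.5, 8), 1:8)
  expect_equal(rrc(f0), 1, tolerance = 1e-12)
  # strictly increasing in r_last for fixed positive r_first
  rl <- seq(0.5, 3, by = 0.25)
  expect_true(all(diff(rrc(rep(1, length(rl)), rl)) > 0))
  # degenerate denominator excluded
  expect_true(is.na(rrc(1, -1)))
})

test_that("drive dependence recovers planted intercept-slope coupling", {
  set.seed(21)
  make_dd <- function(k) {
    rows <- list()
    for (st in 1:5) for (si in 1:4) {
      int0 <- runif(1, 5, 15)
      sl <- -k * int0 + rnorm(1, 0, 0.02)
      for (ses in 1:6) {
        y <- int0 + sl * (1:15) + rnorm(15, 0, 0.5)
        rows[[length(rows) + 1]] <- tibble::tibble(
          stimulus_id = st, site_id = si, session_id = ses,
          repetition = 1:15, response = y)
      }
    }
    dplyr::bind_rows(rows)
  }
  dd <- drive_dependence(make_dd(0.08))
  expect_lt(dd$rho, -0.5)
  # independent slopes and intercepts: near-zero correlation
  null_rhos <- replicate(20, drive_dependence(make_dd(0))$rho)
  expect_lt(abs(mean(null_rhos)), 0.2)
  expect_error(drive_dependence(make_dd(0)[1:30, ]), ">= 3")
})

test_that("interleaved halves remove the mean-slope coupling bias", {
  # naive same-data fits couple slope and intercept estimates negatively:
  # cov(intercept_hat, slope_hat) < 0 for OLS on the same points. Using the
  # same half for both inflates |cor|; interleaved cross-halves do not.
  set.seed(22)
  n_combo <- 60
  naive <- numeric(0)
  crossed <- numeric(0)
  for (rep in 1:40) {
    ints <- slopes <- ints2 <- slopes2 <- numeric(n_combo)
    for (i in 1:n_combo) {
      y <- 10 + 0 * (1:15) + rnorm(15, 0, 2) # no true coupling, no true slope
      f1 <- stats::coef(lm(y[seq(1, 15, 2)] ~ seq(1, 15, 2)))
      f2 <- stats::coef(lm(y[seq(2, 15, 2)] ~ seq(2, 15, 2)))
      ints[i] <- f1[1]; slopes[i] <- f1[2]
      ints2[i] <- f2[1]; slopes2[i] <- f2[2]
    }
    naive <- c(naive, cor(slopes, ints, method = "spearman"))
    crossed <- c(crossed, mean(c(cor(slopes, ints2, method = "spearman"),
                                 cor(slopes2, ints, method = "spearman"))))
  }
  expect_lt(mean(naive), -0.3)        # built-in coupling on shared data
  expect_lt(abs(mean(crossed)), 0.1)  # removed by cross-validation
})

test_that("median split keeps a global effect and drops a floor artifact", {
  set.seed(23)
  build <- function(floor_artifact) {
    rows <- list()
    for (st in 1:6) for (si in 1:5) {
      int0 <- runif(1, 2, 20)
      sl <- if (floor_artifact) {
        if (int0 < 11) 0 else rnorm(1, 0, 0.05) # slope clipped at low drive
      } else -0.05 * int0 + rnorm(1, 0, 0.02)
      for (ses in 1:5) {
        y <- pmax(int0 + sl * (1:15) + rnorm(15, 0, 0.3), 0)
        rows[[length(rows) + 1]] <- tibble::tibble(
          stimulus_id = st, site_id = si, session_id = ses,
          repetition = 1:15, response = y)
      }
    }
    dd <- drive_dependence(dplyr::bind_rows(rows))
    combos <- dd$combos
    combos$animal_id <- "m1"
    combos
  }
  global <- median_split_control(build(FALSE), n_perm = 400, seed = 1)
  expect_true(all(global$significant))
  artifact <- median_split_control(build(TRUE), n_perm = 400, seed = 1)
  expect_false(artifact$significant[artifact$half == "high"])
  expect_error(median_split_control(build(FALSE)[1:2, ]), ">= 4")
})
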