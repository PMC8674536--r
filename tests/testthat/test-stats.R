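test_that("sign-flip test honors trivial cases and the two-sided floor", {
  z <- signflip_test(rep(0, 10), seed = 1)
  expect_equal(z$p, 1)
  # all-equal positive values with many sessions: p at the 0.002 floor
  s <- signflip_test(rep(0.7, 20), n_perm = 1000, seed = 2)
  expect_equal(s$p, 0.002)
  expect_equal(s$observed, 0.7)
  expect_length(s$null_draws, 1000)
  expect_error(signflip_test(1), ">= 2")
})

test_that("exchange test is symmetric and exact on identical conditions", {
  set.seed(3)
  a <- rnorm(12)
  same <- exchange_test(a, a, seed = 4)
  expect_equal(same$p, 1)
  b <- a + rnorm(12, 0.2)
  t1 <- exchange_test(a, b, seed = 5)
  t2 <- exchange_test(b, a, seed = 5)
  expect_equal(t1$observed, -t2$observed)
  expect_equal(t1$p, t2$p)
  expect_error(exchange_test(a, a[1:5]), "paired")
})

test_that("permutation tests are calibrated and powered", {
  set.seed(6)
  # type-I: fraction of p < 0.05 under the null within the binomial CI
  p_null <- replicate(300, signflip_test(rnorm(15), n_perm = 400)$p)
  ci <- 1.96 * sqrt(0.05 * 0.95 / 300)
  expect_lt(abs(mean(p_null < 0.05) - 0.05), ci + 0.01)
  # power: 1 SD difference across 20 sessions detected > 90% of the time
  hits <- replicate(100, {
    a <- rnorm(20)
    b <- a + 1 + rnorm(20) # paired difference of 1 SD
    exchange_test(a, b, n_perm = 400)$p < 0.05
  })
  expect_gt(mean(hits), 0.9)
})

test_that("bootstrap SEM matches the analytic standard error", {
  expect_equal(bootstrap_sem(rep(2, 10), seed = 1)$sem, 0)
  set.seed(7)
  x <- rnorm(25)
  bs <- bootstrap_sem(x, n_boot = 1000, seed = 8)
  expect_lt(abs(bs$sem - sd(x) / sqrt(25)) / (sd(x) / sqrt(25)), 0.15)
  # scale equivariance
  bs2 <- bootstrap_sem(2 * x, n_boot = 1000, seed = 8)
  expect_equal(bs2$sem, 2 * bs$sem, tolerance = 1e-12)
  # grouped averaging: stimuli then animals
  d <- tidyr::expand_grid(animal_id = c("m1", "m2"),
                          stimulus_id = c("s1", "s2"),
                          session_id = 1:6) |>
    dplyr::mutate(value = rnorm(dplyr::n()))
  bsg <- bootstrap_sem(d, n_boot = 500, seed = 9)
  expect_true(is.finite(bsg$sem) && bsg$sem > 0)
})

test_that("BH step-up controls the false discovery proportion", {
  expect_true(all(fdr_correct(rep(0.001, 20))$significant))
  expect_equal(fdr_correct(0.04)$significant, TRUE) # single p = alpha test
  expect_equal(fdr_correct(0.06)$significant, FALSE)
  set.seed(10)
  fdp <- replicate(300, mean(fdr_correct(runif(100))$significant))
  expect_lte(mean(fdp), 0.05)
})

test_that("block regression recovers planted persistence intercepts", {
  set.seed(11)
  recover <- replicate(30, {
    trials <- generate_block_sequence("ABA", 60, seed = sample.int(1e6, 1))
    trials <- block_indicators(trials)
    y <- 0.5 + 0.3 * trials$log_rep + 0.1 * trials$delayed_rep +
      rnorm(nrow(trials), 0, 0.05)
    d <- dplyr::mutate(trials, resp = 10^y)
    fit <- fit_block_regression(d, "resp", continuous = "log_rep",
                                block_terms = "delayed_rep",
                                interact_with = NULL)
    fit$terms$estimate[fit$terms$term == "delayed_repTRUE"]
  })
  expect_lt(abs(mean(recover) - 0.1), 2 * sd(recover) / sqrt(30))
})

test_that("block regression reports interactions, aliasing and scale identity", {
  trials <- block_indicators(generate_block_sequence("ABA", 50, seed = 1))
  set.seed(12)
  trials$resp <- 10^(1 + 0.2 * trials$log_rep + rnorm(nrow(trials), 0, 0.1))
  fit <- fit_block_regression(trials, "resp")
  expect_true("log_rep:delayed_repTRUE" %in% fit$terms$term)
  # multiplying the response by a constant shifts only the intercept
  trials$resp2 <- trials$resp * 100
  fit2 <- fit_block_regression(trials, "resp2")
  keep <- fit$terms$term != "(Intercept)"
  expect_equal(fit$terms$estimate[keep], fit2$terms$estimate[keep],
               tolerance = 1e-9)
  expect_equal(unname(fit2$terms$estimate[fit2$terms$term == "(Intercept)"] -
                        fit$terms$estimate[fit$terms$term == "(Intercept)"]),
               2, tolerance = 1e-9)
  # duplicated regressor is reported as aliased
  trials$log_rep_copy <- trials$log_rep
  fit3 <- fit_block_regression(trials, "resp",
                               continuous = c("log_rep", "log_rep_copy"),
                               block_terms = character(),
                               interact_with = NULL)
  expect_true("log_rep_copy" %in% fit3$aliased)
})

test_that("microsaccade detection recovers injected events at 6c", {
  tr <- generate_natural_sequence(2, 4, 1, 0, seed = 1,
                                  p_error_early = 0, p_error_late = 0)
  eye <- synthesize_eye_traces(tr, events_per_trial = 2, jitter_dva = 0,
                               seed = 2)
  ev <- detect_microsaccades(eye)
  matched <- vapply(seq_len(nrow(eye$events)), function(i)
    any(ev$trial == eye$events$trial[i] &
          abs(ev$onset - eye$events$onset[i]) <= 0.012), logical(1))
  expect_gte(mean(matched), 0.95)
  expect_equal(nrow(ev), nrow(eye$events)) # no false alarms on clean traces

  # constant gaze produces no events
  flat <- synthesize_eye_traces(tr, events_per_trial = 0, jitter_dva = 0,
                                seed = 3)
  expect_equal(nrow(detect_microsaccades(flat)), 0)

  # thresholds 5-7 x c give the same detections on injected events
  for (lam in c(5, 7)) {
    evl <- detect_microsaccades(eye, lambda = lam)
    expect_equal(nrow(evl), nrow(eye$events))
  }
  short <- flat
  short$time <- flat$time[1:4]
  short$gaze_x <- flat$gaze_x[, 1:4, drop = FALSE]
  short$gaze_y <- flat$gaze_y[, 1:4, drop = FALSE]
  expect_error(detect_microsaccades(short), "shorter")
})

test_that("the velocity criterion c scales linearly with velocity scale", {
  set.seed(13)
  v <- rnorm(2000, 0.3, 1)
  crit <- function(v) sqrt(max(median(v^2) - median(v)^2, 0))
  expect_equal(crit(3 * v), 3 * crit(v), tolerance = 1e-12)
})

test_that("pupil responses are z-scored against the single-trial baseline", {
  tr <- generate_natural_sequence(1, 4, 1, 0, seed = 1,
                                  p_error_early = 0, p_error_late = 0)
  eye <- synthesize_eye_traces(tr, events_per_trial = 0,
                               pupil_constriction = 0, seed = 2)
  # pupil equal to its baseline mean gives 0
  eye$pupil[1, ] <- c(rnorm(sum(eye$time < 0)),
                      rep(NA, sum(eye$time >= 0)))
  base_mean <- mean(eye$pupil[1, eye$time >= -1 & eye$time < 0])
  eye$pupil[1, eye$time >= 0] <- base_mean
  pr <- pupil_response(eye)
  expect_true(all(abs(pr$z[1, pr$time >= 0]) < 1e-9))
  # zero-variance baseline flagged
  eye$pupil[2, ] <- 1
  pr2 <- pupil_response(eye)
  expect_true(2 %in% pr2$flagged_trials)
  expect_true(all(is.na(pr2$z[2, ])))
})

test_that("microsaccade rate counts events inside the window", {
  ev <- tibble::tibble(trial = c(1, 1, 2), onset = c(0.1, 0.9, 2.0),
                       offset = c(0.11, 0.91, 2.01), peak_velocity = 1)
  r <- microsaccade_rate(ev, n_trials = 3, window = c(0, 1.5))
  expect_equal(r, c(2, 0, 0) / 1.5)
})
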