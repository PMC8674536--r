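make_sv <- function(patterns, n_reps = 5) {
  # patterns: list of per-session lists of per-stimulus trajectories
  rows <- list()
  for (s in seq_along(patterns)) {
    for (st in seq_along(patterns[[s]])) {
      y <- patterns[[s]][[st]]
      if (is.null(y)) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        session_id = sprintf("ses%02d", s), site_id = "site01",
        stimulus_id = sprintf("img%02d", st),
        repetition = seq_along(y), value = y)
    }
  }
  build_session_vectors(dplyr::bind_rows(rows), n_reps = n_reps)
}

test_that("session vectors concatenate stimuli in a fixed canonical order", {
  pats <- lapply(1:4, function(s) list(1:5 + s, 5:1 - s))
  sv <- make_sv(pats)
  expect_equal(dim(sv$vectors), c(4, 10)) # 2 stimuli x 5 reps
  expect_equal(sv$slot_stimulus, rep(c("img01", "img02"), each = 5))
  # z-scoring makes the per-session additive offsets vanish
  expect_equal(sv$vectors[1, ], sv$vectors[2, ], tolerance = 1e-12)
})

test_that("coverage thresholding keeps 75% sessions and drops 40% ones", {
  pats <- list(list(1:5, 5:1, 2:6, c(3, 1, 4, 1, 5)),
               list(1:5, 5:1, 2:6, NULL),          # 75% coverage
               list(1:5, NULL, NULL, NULL))        # 25% coverage
  sv <- make_sv(pats)
  expect_equal(sv$sessions, c("ses01", "ses02"))
  expect_equal(sv$dropped, "ses03")
  # five stimuli overall, each session covering only two (40%)
  low <- list(list(1:5, 1:5, NULL, NULL, NULL),
              list(NULL, NULL, 1:5, 1:5, NULL),
              list(1:5, NULL, NULL, NULL, 1:5))
  expect_error(make_sv(low), "coverage")
})

test_that("identical noiseless patterns correlate perfectly across halves", {
  pats <- lapply(1:6, function(s) list(c(5, 3, 2, 1.5, 1), c(1, 2, 3, 4, 5)))
  sv <- make_sv(pats)
  sh <- split_half_correlation(sv, s = 20, seed = 1)
  expect_equal(sh$r, 1, tolerance = 1e-12)
  # odd session counts split floor/ceiling
  pats7 <- lapply(1:7, function(s) list(c(5, 3, 2, 1.5, 1), 1:5))
  sv7 <- make_sv(pats7)
  sh7 <- split_half_correlation(sv7, s = 5, seed = 1)
  sizes <- vapply(sh7$splits, function(sp)
    c(length(sp$h1), length(sp$h2)), numeric(2))
  expect_true(all(sizes[1, ] == 3 & sizes[2, ] == 4))
  expect_error(split_half_correlation(make_sv(list(list(1:5)))), ">= 2")
})

test_that("independent noise vectors give near-zero split-half correlation", {
  set.seed(2)
  rs <- replicate(60, {
    pats <- lapply(1:10, function(s) list(rnorm(5), rnorm(5), rnorm(5)))
    split_half_correlation(make_sv(pats), s = 20)$r
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("fast block-permutation correlations equal the naive computation", {
  set.seed(3)
  n_stim <- 5; n_rep <- 6
  h1 <- rnorm(n_stim * n_rep)
  h2 <- rnorm(n_stim * n_rep)
  naive <- function(h1, h2, ord) {
    idx <- rep((ord - 1) * n_rep, each = n_rep) + rep(1:n_rep, n_stim)
    cor(h1, h2[idx])
  }
  set.seed(42)
  ords <- replicate(50, sample.int(n_stim))
  fast <- gammarep:::perm_cors(h1, h2, n_stim, ords)
  ref <- apply(ords, 2, function(o) naive(h1, h2, o))
  expect_equal(fast, ref, tolerance = 1e-12)
  # NA path agrees with pairwise-complete naive correlation
  h2[3] <- NA
  set.seed(42)
  ords <- replicate(10, sample.int(n_stim))
  fast_na <- gammarep:::perm_cors(h1, h2, n_stim, ords)
  ref_na <- apply(ords, 2, function(o) {
    idx <- rep((o - 1) * n_rep, each = n_rep) + rep(1:n_rep, n_stim)
    v <- h2[idx]; ok <- !is.na(v)
    cor(h1[ok], v[ok])
  })
  expect_equal(fast_na, ref_na, tolerance = 1e-12)
})

test_that("the permutation null is centered for fully exchangeable stimuli", {
  set.seed(7)
  null_means <- replicate(25, {
    pats <- lapply(1:10, function(s) lapply(1:6, function(st) rnorm(10)))
    mean(specificity_permutation(make_sv(pats, n_reps = 10),
                                 s = 30, n_perm = 200)$null)
  })
  # zero within ~3 Monte-Carlo SEs of the realization-to-realization spread
  expect_lt(abs(mean(null_means)), 3 * sd(null_means) / 5)
})

test_that("stimulus-specific trajectories are detected against the null", {
  d <- make_traj_data(transfer = 0, n_sessions = 10, n_stimuli = 5,
                      seed = 7)
  res <- specificity_test(
    dplyr::transmute(d, session_id, site_id, stimulus_id, repetition,
                     value = gamma),
    s = 50, n_perm = 400, seed = 8)
  expect_true(res$significant)
  expect_gt(res$observed_r, quantile(attr(res, "null"), 0.975))
})

test_that("observed statistic is invariant to session order and stimulus offsets", {
  d <- make_traj_data(transfer = 0, n_sessions = 8, n_stimuli = 4, seed = 9)
  d <- dplyr::transmute(d, session_id, site_id, stimulus_id, repetition,
                        value = gamma)
  r1 <- specificity_test(d, s = 30, n_perm = 100, seed = 10)
  # shuffle row order / relabel sessions in reverse
  d2 <- d[sample.int(nrow(d)), ]
  d2$session_id <- factor(d2$session_id,
                          levels = rev(sort(unique(d2$session_id))))
  d2$session_id <- as.character(d2$session_id)
  r2 <- specificity_test(d2, s = 30, n_perm = 100, seed = 10)
  expect_equal(r1$observed_r, r2$observed_r, tolerance = 1e-12)
  # constant per-stimulus offsets are absorbed by the z-score
  d3 <- d
  d3$value <- d3$value + 10 * as.integer(factor(d3$stimulus_id))
  r3 <- specificity_test(d3, s = 30, n_perm = 100, seed = 10)
  expect_equal(r1$observed_r, r3$observed_r, tolerance = 1e-12)
})

test_that("rejection power increases as trajectories become stimulus-specific", {
  # >= 5 stimuli: the permutation orbit of fewer stimuli is too small for
  # a two-sided test at alpha 0.05 (4! = 24 orders)
  hits <- vapply(c(1, 0.5, 0), function(tau) {
    mean(vapply(1:12, function(k) {
      d <- make_traj_data(transfer = tau, n_sessions = 10, n_stimuli = 8,
                          seed = 100 * k + tau * 7)
      res <- specificity_test(
        dplyr::transmute(d, session_id, site_id, stimulus_id, repetition,
                         value = gamma),
        s = 30, n_perm = 200, seed = k)
      res$significant
    }, logical(1)))
  }, numeric(1))
  expect_true(hits[3] >= hits[2] && hits[2] >= hits[1]) # monotone trend
  expect_gt(hits[3], 0.8)
})

test_that("degenerate inputs are rejected", {
  pats <- lapply(1:4, function(s) list(1:5))
  sv <- make_sv(pats)
  expect_error(specificity_permutation(sv), "2 stimuli")
})

test_that("the correlation spectrum localizes a band-limited effect", {
  bins <- seq(20, 80, by = 20)
  run_one <- function(run) {
    set.seed(30 + run)
    rows <- list()
    for (s in 1:8) for (st in 1:6) {
      shape <- sin((1:10) / 2 + st) # stimulus-specific trajectory
      for (b in bins) {
        y <- if (b %in% c(40, 60)) shape + rnorm(10, 0, 0.3) else rnorm(10)
        rows[[length(rows) + 1]] <- tibble::tibble(
          session_id = sprintf("ses%02d", s), site_id = "site01",
          stimulus_id = sprintf("img%02d", st), repetition = 1:10,
          bin = b, value = y)
      }
    }
    correlation_spectrum(dplyr::bind_rows(rows), s = 30, n_perm = 200,
                         seed = 31 + run)
  }
  runs <- lapply(1:5, run_one)
  expect_s3_class(runs[[1]], "correlation_result")
  in_band <- vapply(runs, function(cs)
    all(cs$significant[cs$bin %in% c(40, 60)]), logical(1))
  false_bins <- vapply(runs, function(cs)
    sum(cs$significant[!cs$bin %in% c(40, 60)]), numeric(1))
  expect_gte(sum(in_band), 4)              # planted band found
  expect_lte(sum(false_bins), 2)           # null bins essentially clean
})
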