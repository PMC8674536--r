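#' Generate a constrained-lag natural-image trial sequence
#'
#' Builds one pseudo-random block of interleaved stimulus presentations in
#' which each stimulus is shown a fixed number of times and the lag between
#' two presentations of the same stimulus (the number of intervening
#' other-stimulus trials) never exceeds `max_lag`. On every trial a stimulus
#' is drawn at random from a rolling subset of `subset_size` stimuli; a
#' stimulus whose pending lag has reached `max_lag` is presented immediately,
#' and a stimulus that has exhausted its repetitions is replaced in the
#' subset by a randomly drawn unused stimulus.
#'
#' Trial correctness is simulated as an independent Bernoulli draw with a
#' higher error rate on the first three presentations of a stimulus (rapid
#' fixation breaks are most common when a stimulus is new). The repetition
#' number counts correct trials only and is `NA` on error trials.
#'
#' @param n_stimuli Number of distinct stimuli in the set.
#' @param reps_per_stim Presentations per stimulus.
#' @param subset_size Size of the rolling subset stimuli are drawn from.
#' @param max_lag Maximum allowed number of intervening other-stimulus trials
#'   between two presentations of the same stimulus.
#' @param seed Integer seed; the caller's RNG state is restored on exit.
#' @param dummy_prefix If `TRUE`, the sequence starts with two unchanging
#'   "dummy" stimuli (reduced, randomly drawn repetition counts) interleaved
#'   with the first stimulus of the set, so that set stimuli do not all start
#'   their sequences simultaneously.
#' @param p_error_early,p_error_late Bernoulli error probabilities for
#'   presentations 1-3 and 4+ of each stimulus.
#' @param session_id,animal_id Labels stored with every trial.
#'
#' @return A tibble with one row per trial: `trial_index`, `stimulus_id`,
#'   `presentation_number` (1-based count over all trials of that stimulus),
#'   `correct`, `repetition_number` (1-based count over correct trials, `NA`
#'   when incorrect), `lag` (`NA` on first presentation), `change_time`
#'   (seconds post stimulus onset), `block_id`, `block_type`, `location`,
#'   `session_id`, `animal_id`.
#' @export
#' @examples
#' trials <- generate_natural_sequence(25, 20, seed = 1)
#' nrow(trials) # 500
generate_natural_sequence <- function(n_stimuli, reps_per_stim,
                                      subset_size = 3, max_lag = 4,
                                      seed = NULL, dummy_prefix = FALSE,
                                      p_error_early = 0.2,
                                      p_error_late = 0.05,
                                      session_id = "ses01",
                                      animal_id = "animal1") {
  stopifnot_scalar_pos(n_stimuli, "n_stimuli")
  stopifnot_scalar_pos(reps_per_stim, "reps_per_stim")
  stopifnot_scalar_pos(subset_size, "subset_size")
  if (max_lag < 0) abort("`max_lag` must be >= 0.")
  if (subset_size > n_stimuli) {
    abort("`subset_size` cannot exceed `n_stimuli`.")
  }
  with_seed(seed, {
    stim_ids <- sprintf("img%02d", seq_len(n_stimuli))
    reps <- setNames(rep(as.integer(reps_per_stim), n_stimuli), stim_ids)
    if (dummy_prefix) {
      if (reps_per_stim < 3) abort("dummy prefix needs reps_per_stim >= 3.")
      dummy_ids <- c("dummy1", "dummy2")
      dummy_reps <- sample(seq(ceiling(reps_per_stim / 4),
                               reps_per_stim - 1), 2, replace = TRUE)
      reps <- c(setNames(as.integer(dummy_reps), dummy_ids), reps)
      # dummies plus the first set stimulus seed the subset
      first <- c(dummy_ids, stim_ids[1])[seq_len(min(subset_size, 3))]
      unused <- setdiff(names(reps), first)
    } else {
      first <- sample(stim_ids, subset_size)
      unused <- setdiff(stim_ids, first)
    }
    n_trials <- sum(reps)
    seq_out <- character(n_trials)
    remaining <- reps
    subset <- first
    # pending[s]: trials since s was last shown; NA_real_ if never shown
    pending <- setNames(rep(NA_real_, length(reps)), names(reps))
    for (t in seq_len(n_trials)) {
      forced <- subset[!is.na(pending[subset]) & pending[subset] >= max_lag]
      if (length(forced) > 1L) {
        abort("infeasible lag constraint: multiple stimuli due simultaneously.")
      }
      pick <- if (length(forced) == 1L) forced else
        subset[sample.int(length(subset), 1L)]
      seq_out[t] <- pick
      shown <- !is.na(pending)
      pending[shown] <- pending[shown] + 1
      pending[pick] <- 0
      remaining[pick] <- remaining[pick] - 1L
      if (remaining[pick] == 0L) {
        subset <- setdiff(subset, pick)
        if (length(unused) > 0L) {
          repl <- unused[sample.int(length(unused), 1L)]
          subset <- c(subset, repl)
          unused <- setdiff(unused, repl)
        }
      }
    }
    pres <- stats::ave(seq_along(seq_out), seq_out, FUN = seq_along)
    lag <- lag_from_sequence(seq_out)
    p_err <- ifelse(pres <= 3, p_error_early, p_error_late)
    correct <- runif(n_trials) >= p_err
    rep_num <- rep(NA_integer_, n_trials)
    for (s in unique(seq_out)) {
      idx <- which(seq_out == s & correct)
      rep_num[idx] <- seq_along(idx)
    }
    tibble::tibble(
      trial_index = seq_len(n_trials),
      stimulus_id = seq_out,
      presentation_number = as.integer(pres),
      correct = correct,
      repetition_number = rep_num,
      lag = lag,
      change_time = 1.5 + sample_change_time(n_trials),
      block_id = "block1",
      block_type = "natural",
      location = "n/a",
      session_id = session_id,
      animal_id = animal_id
    )
  })
}

# intervening other-stimulus trials since the previous same-stimulus trial
lag_from_sequence <- function(stimulus) {
  last_seen <- new.env(parent = emptyenv())
  out <- rep(NA_integer_, length(stimulus))
  for (t in seq_along(stimulus)) {
    s <- stimulus[t]
    prev <- get0(s, envir = last_seen, ifnotfound = NA_integer_)
    if (!is.na(prev)) out[t] <- t - prev - 1L
    assign(s, t, envir = last_seen)
  }
  out
}

#' Sample change times from a Weibull hazard
#'
#' Draws the variable interval between stimulus onset and the behaviorally
#' relevant stimulus change from a standard Weibull distribution with scale
#' `a` and shape `b`, i.e. hazard \eqn{h(t) = (b/a)(t/a)^{b-1}}. With shape
#' `b = 2` the hazard rate increases linearly in time, making the change
#' onset progressively more expected within a trial.
#'
#' @param n Number of draws.
#' @param scale,shape Weibull scale `a` and shape `b`, both > 0.
#' @param seed Optional seed.
#' @return A numeric vector of `n` positive change times (seconds).
#' @export
sample_change_time <- function(n, scale = 0.27, shape = 2, seed = NULL) {
  stopifnot_scalar_pos(scale, "scale")
  stopifnot_scalar_pos(shape, "shape")
  with_seed(seed, rweibull(n, shape = shape, scale = scale))
}

#' Generate a block-design trial sequence
#'
#' Builds sequences of direct-repetition blocks: grating designs over the
#' alphabet `{A, B}` (e.g. `"ABA"`, 100-trial blocks) and location designs
#' over `{In, Out}` (e.g. `"InOutIn"`, 50-trial blocks). Within a block all
#' trials share the same stimulus (and location); block labels use bracket
#' notation, e.g. the second block of `"ABA"` is tagged `"A[B]A"`.
#'
#' @param design Design string over `{A, B}` (e.g. `"ABA"`, `"BBA"`) or over
#'   `{In, Out}` (e.g. `"OutIn"`, `"InOutIn"`).
#' @param trials_per_block Trials per block.
#' @param stimuli Named map from design letter to stimulus label for grating
#'   designs (counterbalancing hook: swap the mapping across sessions), or a
#'   single stimulus label for location designs.
#' @param seed Optional seed (only used for change-time draws).
#' @param session_id,animal_id Labels stored with every trial.
#'
#' @return A tibble with one row per trial: `trial_index`, `stimulus_id`,
#'   `location`, `block_id`, `block_index`, `block_type` (bracket notation),
#'   `trial_in_block`, `repetition_number` (consecutive same-stimulus count,
#'   continuing across boundaries when adjacent blocks share the stimulus),
#'   `local_rep` (consecutive same-location count, location designs), `lag`,
#'   `correct`, `change_time`, `session_id`, `animal_id`.
#' @export
#' @examples
#' aba <- generate_block_sequence("ABA", 100)
#' table(aba$block_type)
generate_block_sequence <- function(design, trials_per_block,
                                    stimuli = c(A = "gratingA", B = "gratingB"),
                                    seed = NULL,
                                    session_id = "ses01",
                                    animal_id = "animal1") {
  stopifnot_scalar_pos(trials_per_block, "trials_per_block")
  if (grepl("^(In|Out)+$", design)) {
    tokens <- regmatches(design, gregexpr("In|Out", design))[[1]]
    location_design <- TRUE
  } else if (grepl("^[AB]+$", design)) {
    tokens <- strsplit(design, "")[[1]]
    location_design <- FALSE
  } else {
    abort(sprintf("unknown design token in '%s' (use A/B or In/Out).", design))
  }
  n_blocks <- length(tokens)
  block_type <- vapply(seq_len(n_blocks), function(i) {
    paste0(paste(tokens[seq_len(i - 1)], collapse = ""),
           "[", tokens[i], "]",
           paste(tokens[seq(i + 1, length.out = n_blocks - i)], collapse = ""))
  }, character(1))
  with_seed(seed, {
    n <- n_blocks * trials_per_block
    bi <- rep(seq_len(n_blocks), each = trials_per_block)
    tok <- tokens[bi]
    if (location_design) {
      stim <- rep(if (is.null(names(stimuli))) stimuli[1] else
        unname(stimuli[1]), n)
      loc <- tok
    } else {
      if (!all(tokens %in% names(stimuli))) {
        abort("`stimuli` must name every design letter.")
      }
      stim <- unname(stimuli[tok])
      loc <- rep("n/a", n)
    }
    run_id <- cumsum(c(TRUE, tok[-1] != tok[-n]))
    consec <- stats::ave(seq_len(n), run_id, FUN = seq_along)
    tibble::tibble(
      trial_index = seq_len(n),
      stimulus_id = stim,
      location = loc,
      block_id = sprintf("block%d", bi),
      block_index = bi,
      block_type = block_type[bi],
      trial_in_block = as.integer(stats::ave(seq_len(n), bi, FUN = seq_along)),
      repetition_number = if (location_design)
        as.integer(stats::ave(seq_len(n), stim, FUN = seq_along)) else
        as.integer(consec),
      local_rep = if (location_design) as.integer(consec) else NA_integer_,
      lag = lag_from_sequence(if (location_design) paste(stim, loc) else stim),
      correct = TRUE,
      change_time = runif(n, 1.5, 2.3),
      session_id = session_id,
      animal_id = animal_id
    )
  })
}
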