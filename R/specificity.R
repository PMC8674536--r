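#' Build per-session concatenated trajectory vectors
#'
#' For each session, z-scores the repetition trajectory of every stimulus at
#' every site (see [zscore_trajectory()]), averages the z-scored
#' trajectories across sites, and concatenates the per-stimulus trajectories
#' into one vector using a fixed (lexicographic) stimulus order, irrespective
#' of the actual presentation order in the session. Sessions where fewer
#' than `min_coverage` of the vector entries contain data are excluded.
#'
#' @param data Tibble with `session_id`, `site_id`, `stimulus_id`,
#'   `repetition`, `value` (one response per repetition).
#' @param n_reps Repetitions per stimulus slot (default: the maximum
#'   repetition present).
#' @param min_coverage Minimum fraction of non-missing vector entries.
#' @return An object of class `session_vectors`: list with `vectors`
#'   (session x slot matrix), `slot_stimulus` (stimulus of each slot),
#'   `sessions`, `dropped` (session ids under coverage), `n_reps`.
#' @export
build_session_vectors <- function(data, n_reps = NULL, min_coverage = 0.5) {
  if (is.null(n_reps)) n_reps <- max(data$repetition)
  stimuli <- sort(unique(data$stimulus_id))
  z <- data |>
    dplyr::filter(.data$repetition >= 1, .data$repetition <= n_reps,
                  is.finite(.data$value)) |>
    dplyr::group_by(.data$session_id, .data$site_id, .data$stimulus_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::mutate(z = as.numeric(zscore_trajectory(.data$value))) |>
    dplyr::group_by(.data$session_id, .data$stimulus_id,
                    .data$repetition) |>
    dplyr::summarise(z = mean(.data$z), .groups = "drop")
  sessions <- sort(unique(z$session_id))
  n_slots <- length(stimuli) * n_reps
  vec <- matrix(NA_real_, length(sessions), n_slots)
  slot <- (match(z$stimulus_id, stimuli) - 1L) * n_reps + z$repetition
  vec[cbind(match(z$session_id, sessions), slot)] <- z$z
  coverage <- rowMeans(!is.na(vec))
  keep <- coverage >= min_coverage
  if (!any(keep)) abort("no session passes the coverage threshold.")
  structure(list(vectors = vec[keep, , drop = FALSE],
                 slot_stimulus = rep(stimuli, each = n_reps),
                 sessions = sessions[keep],
                 dropped = sessions[!keep],
                 n_reps = n_reps),
            class = "session_vectors")
}

# s random equal-size splits of n sessions (odd n: floor/ceil halves)
make_splits <- function(n, s) {
  lapply(seq_len(s), function(k) {
    h1 <- sample.int(n, floor(n / 2))
    list(h1 = h1, h2 = setdiff(seq_len(n), h1))
  })
}

pairwise_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  cor(a[ok], b[ok])
}

#' Split-half correlation of session trajectory vectors
#'
#' Draws `s` random equal-size splits of the sessions, averages the
#' concatenated trajectory vectors within each half, correlates the two
#' half averages (Pearson, over entries present in both halves), and
#' returns the mean correlation over splits. Stimulus-specific repetition
#' trajectories that are consistent across sessions yield positive values.
#'
#' @param sv A `session_vectors` object.
#' @param s Number of random splits.
#' @param seed Integer seed.
#' @param splits Optional explicit list of splits (used internally to share
#'   splits between observed statistic and permutation null).
#' @return A list: `r` (mean over splits), `r_split` (per split), `splits`.
#' @export
split_half_correlation <- function(sv, s = 100, seed = NULL, splits = NULL) {
  n <- nrow(sv$vectors)
  if (n < 2) abort("need >= 2 sessions.")
  with_seed(seed, {
    if (is.null(splits)) splits <- make_splits(n, s)
    r_split <- vapply(splits, function(sp) {
      h1 <- colMeans(sv$vectors[sp$h1, , drop = FALSE], na.rm = TRUE)
      h2 <- colMeans(sv$vectors[sp$h2, , drop = FALSE], na.rm = TRUE)
      pairwise_cor(h1, h2)
    }, numeric(1))
    list(r = mean(r_split, na.rm = TRUE), r_split = r_split, splits = splits)
  })
}

# correlations of h1 with block-permuted h2 for the given stimulus orders
# (one order per column of `perms`); exact fast path when both halves are
# complete
perm_cors <- function(h1, h2, n_stim, perms) {
  n_perm <- ncol(perms)
  n_rep <- length(h1) / n_stim
  if (!anyNA(h1) && !anyNA(h2)) {
    m1 <- mean(h1); m2 <- mean(h2)
    s1 <- sqrt(mean(h1^2) - m1^2)
    s2 <- sqrt(mean(h2^2) - m2^2)
    if (s1 == 0 || s2 == 0) return(rep(NA_real_, n_perm))
    H1 <- matrix(h1, n_rep, n_stim) # col per stimulus
    H2 <- matrix(h2, n_rep, n_stim)
    cc <- crossprod(H1, H2)         # cc[i, j] = sum_r H1[, i] * H2[, j]
    idx <- (as.vector(perms) - 1L) * n_stim +
      rep.int(seq_len(n_stim), n_perm)
    sums <- colSums(matrix(cc[idx], n_stim, n_perm))
    (sums / length(h1) - m1 * m2) / (s1 * s2)
  } else {
    vapply(seq_len(n_perm), function(i) {
      ord <- perms[, i]
      blocks <- rep((ord - 1L) * n_rep, each = n_rep) +
        rep.int(seq_len(n_rep), n_stim)
      pairwise_cor(h1, h2[blocks])
    }, numeric(1))
  }
}

#' Stimulus-reshuffling permutation null for the split-half correlation
#'
#' Each of `n_perm` iterations draws one random stimulus order and, for
#' every one of the `s` session splits used by the observed statistic,
#' correlates the intact half-1 average vector with the half-2 average
#' re-ordered by that iteration's stimulus order; the `s` values are then
#' averaged exactly as for the observed data, yielding `n_perm` null
#' correlations. Sharing one stimulus order per iteration across splits
#' makes the observed statistic the identity member of the permutation
#' orbit, so the test is exact-level under stimulus exchangeability (an
#' order drawn independently per split would shrink the null variance by
#' roughly the number of splits and grossly inflate false positives).
#'
#' @param sv A `session_vectors` object.
#' @param s Number of splits.
#' @param n_perm Number of permutations per split.
#' @param seed Integer seed.
#' @return A list: `observed` (mean split-half r), `null` (length `n_perm`),
#'   `p` (two-sided), `n_sessions`.
#' @export
specificity_permutation <- function(sv, s = 100, n_perm = 1000,
                                    seed = NULL) {
  n_stim <- length(unique(sv$slot_stimulus))
  if (n_stim < 2) abort("permutation degenerate with < 2 stimuli.")
  with_seed(seed, {
    obs <- split_half_correlation(sv, s = s)
    perms <- vapply(seq_len(n_perm), function(i) sample.int(n_stim),
                    integer(n_stim))
    null_acc <- matrix(0, n_perm, length(obs$splits))
    for (k in seq_along(obs$splits)) {
      sp <- obs$splits[[k]]
      h1 <- colMeans(sv$vectors[sp$h1, , drop = FALSE], na.rm = TRUE)
      h2 <- colMeans(sv$vectors[sp$h2, , drop = FALSE], na.rm = TRUE)
      h1[is.nan(h1)] <- NA_real_
      h2[is.nan(h2)] <- NA_real_
      null_acc[, k] <- perm_cors(h1, h2, n_stim, perms)
    }
    null <- rowMeans(null_acc, na.rm = TRUE)
    list(observed = obs$r, null = null,
         p = perm_p_two_sided(obs$r, null), n_sessions = nrow(sv$vectors))
  })
}

#' Stimulus-specificity test, averaged across animals
#'
#' Runs [build_session_vectors()] and [specificity_permutation()] per
#' animal, then averages the observed correlation and, iteration-wise, the
#' permutation null across animals before the two-sided comparison - the
#' grand statistic is one correlation value per animal average.
#'
#' @param data Tibble with `animal_id`, `session_id`, `site_id`,
#'   `stimulus_id`, `repetition`, `value`.
#' @param s,n_perm,min_coverage,n_reps See the component functions.
#' @param alpha Two-sided significance level.
#' @param seed Integer seed.
#' @return A tibble of class `specificity_result` with one row: `observed_r`,
#'   `p`, `significant`, `n_animals`, `n_sessions`; the averaged null draws
#'   are kept in `attr(, "null")`.
#' @export
specificity_test <- function(data, s = 100, n_perm = 1000,
                             min_coverage = 0.5, n_reps = NULL,
                             alpha = 0.05, seed = NULL) {
  if (!"animal_id" %in% names(data)) data$animal_id <- "animal1"
  with_seed(seed, {
    per_animal <- lapply(split(data, data$animal_id), function(d) {
      sv <- build_session_vectors(d, n_reps = n_reps,
                                  min_coverage = min_coverage)
      specificity_permutation(sv, s = s, n_perm = n_perm)
    })
    obs <- mean(vapply(per_animal, `[[`, numeric(1), "observed"))
    null <- rowMeans(vapply(per_animal, `[[`, numeric(length(
      per_animal[[1]]$null)), "null"))
    p <- perm_p_two_sided(obs, null)
    out <- tibble::tibble(
      observed_r = obs, p = p, significant = p <= alpha,
      n_animals = length(per_animal),
      n_sessions = sum(vapply(per_animal, `[[`, numeric(1), "n_sessions"))
    )
    attr(out, "null") <- null
    class(out) <- c("specificity_result", class(out))
    out
  })
}

#' Specificity correlation spectrum or time course
#'
#' Runs the full split-half specificity procedure independently for every
#' bin of a frequency- or time-resolved feature (LFP power per frequency,
#' peak-aligned PPC, dMUA per time bin), then applies Benjamini-Hochberg
#' FDR correction across bins. Repetition subsets (all / early / late) are
#' selected before calling.
#'
#' @param data Tibble as for [specificity_test()] plus a `bin` column
#'   (frequency in Hz or peri-stimulus time in s).
#' @param ... Passed to [specificity_test()].
#' @param fdr FDR level across bins.
#' @param seed Integer seed (advanced per bin).
#' @return A tibble of class `correlation_result`: per bin `bin`,
#'   `observed_r`, `p`, `p_adj`, `significant`.
#' @export
correlation_spectrum <- function(data, ..., fdr = 0.05, seed = NULL) {
  bins <- sort(unique(data$bin))
  res <- purrr::map2_dfr(bins, seq_along(bins), function(b, i) {
    r <- specificity_test(data[data$bin == b, ], ...,
                          seed = if (is.null(seed)) NULL else seed + i)
    tibble::tibble(bin = b, observed_r = r$observed_r, p = r$p)
  })
  adj <- fdr_correct(res$p, fdr = fdr)
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant
  class(res) <- c("correlation_result", class(res))
  res
}
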