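# two-sided permutation p: double the smaller tail, with the count floored
# at 1 so the minimal attainable p with 1000 permutations is 0.002
perm_p_two_sided <- function(obs, null) {
  n <- length(null)
  lo <- sum(null <= obs)
  hi <- sum(null >= obs)
  min(1, 2 * max(min(lo, hi), 1) / n)
}

new_perm_test <- function(observed, null, n_perm, type) {
  structure(list(observed = observed, null_draws = null,
                 p = perm_p_two_sided(observed, null),
                 n_perm = n_perm, type = type),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("<perm_test %s> observed %.4g, p = %.4g (%d permutations)\n",
              x$type, x$observed, x$p, x$n_perm))
  invisible(x)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(observed = x$observed, p = x$p, n_perm = x$n_perm,
                 type = x$type)
}

#' Sign-flip permutation test across sessions
#'
#' Tests whether the mean of per-session values (e.g. repetition slopes,
#' already averaged over stimuli and animals upstream) differs from zero.
#' The null distribution is built by randomly flipping the sign of each
#' session's value and recomputing the mean, 1000 times by default; the
#' two-sided p doubles the smaller tail, so its floor is 2 / n_perm.
#'
#' @param values Numeric vector, one value per session.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test` object (`observed`, `null_draws`, `p`, `n_perm`).
#' @export
signflip_test <- function(values, n_perm = 1000, seed = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2) abort("need >= 2 sessions.")
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(values), replace = TRUE),
                    n_perm, length(values))
    null <- as.vector(signs %*% values) / length(values)
    new_perm_test(mean(values), null, n_perm, "signflip")
  })
}

#' Exchange permutation test for paired conditions
#'
#' Tests the mean difference between two paired condition values (one pair
#' per session, e.g. early vs late slopes, or A[B]A vs B[B]A responses).
#' Each permutation makes an independent random decision per session to
#' exchange the two condition values, then recomputes the mean difference.
#'
#' @param a,b Paired numeric vectors (one entry per session).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return A `perm_test` object.
#' @export
exchange_test <- function(a, b, n_perm = 1000, seed = NULL) {
  if (length(a) != length(b)) abort("`a` and `b` must be paired.")
  ok <- is.finite(a) & is.finite(b)
  d <- (a - b)[ok]
  if (length(d) < 2) abort("need >= 2 paired sessions.")
  with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * length(d), replace = TRUE),
                    n_perm, length(d))
    null <- as.vector(signs %*% d) / length(d)
    new_perm_test(mean(d), null, n_perm, "exchange")
  })
}

#' Bootstrap standard error of the mean
#'
#' Resamples sessions with replacement (1000 times by default) within each
#' animal-stimulus cell, averages across sessions, then stimuli, then
#' animals, and returns the SD of the resampled grand means - the bootstrap
#' SEM. Plots conventionally show +- 2 SEM. A plain numeric vector is
#' treated as one animal, one stimulus.
#'
#' @param data Tibble with `animal_id`, `stimulus_id`, `session_id`,
#'   `value`, or a plain numeric vector of per-session values.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return A list: `sem`, `mean`, `boot_means` (length `n_boot`).
#' @export
bootstrap_sem <- function(data, n_boot = 1000, seed = NULL) {
  if (is.numeric(data)) {
    data <- tibble::tibble(animal_id = "a", stimulus_id = "s",
                           session_id = seq_along(data), value = data)
  }
  cells <- split(data$value,
                 list(data$animal_id, data$stimulus_id), drop = TRUE)
  animal_of <- vapply(strsplit(names(cells), "\\."), `[`, "", 1)
  with_seed(seed, {
    boot <- replicate(n_boot, {
      cell_means <- vapply(cells, function(v) {
        mean(v[sample.int(length(v), replace = TRUE)])
      }, numeric(1))
      mean(tapply(cell_means, animal_of, mean))
    })
    list(sem = sd(boot), mean = mean(data$value), boot_means = boot)
  })
}

#' Benjamini-Hochberg FDR correction across bins
#'
#' Step-up false discovery rate control across the multiple tests of a
#' frequency- or time-resolved analysis, at a rate of 0.05 by default.
#'
#' @param p Vector of per-bin p values.
#' @param fdr Target false discovery rate.
#' @return A tibble with `p`, `p_adj` and logical `significant`.
#' @export
fdr_correct <- function(p, fdr = 0.05) {
  adj <- p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = adj, significant = adj <= fdr)
}
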