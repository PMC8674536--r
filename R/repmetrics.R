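#' Z-score a repetition trajectory
#'
#' Standardizes a per-stimulus response trajectory across its available
#' repetitions to mean 0 and SD 1, using the population (N-denominator) SD:
#' the repetitions of one stimulus in one session are the full population of
#' that trajectory, not a sample from a longer one. Missing repetitions stay
#' missing; a zero-variance trajectory returns all zeros with attribute
#' `constant = TRUE`.
#'
#' @param x Numeric trajectory (response per repetition; may contain `NA`).
#' @return Z-scored vector, same length; attribute `constant` flags
#'   zero-variance input.
#' @export
zscore_trajectory <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) abort("need >= 2 finite repetitions to z-score.")
  m <- mean(x[ok])
  s <- sqrt(mean((x[ok] - m)^2))
  out <- x
  if (s == 0) {
    out[ok] <- 0
    attr(out, "constant") <- TRUE
  } else {
    out[ok] <- (x[ok] - m) / s
    attr(out, "constant") <- FALSE
  }
  out
}

#' Fit a linear repetition slope
#'
#' Ordinary least squares fit of responses against repetition number (or
#' against log10 trial-in-block for block designs), over one of three
#' segments: `"early"` (repetitions 1-4), `"late"` (5 up to `max_rep`), or
#' `"all"`. Fitted endpoint responses `r_first` and `r_last` are evaluated
#' from the fit at the segment endpoints (not from raw trials) and feed the
#' repetition-related change metric [rrc()].
#'
#' @param response Numeric responses.
#' @param repetition Repetition numbers (or trial-in-block), same length.
#' @param segment `"all"`, `"early"` or `"late"`.
#' @param x_transform `"repetition"` (fit against the raw repetition
#'   number) or `"log10_trial"` (fit against `log10(repetition)`, the block
#'   design convention; combined with `segment = "late"` this excludes the
#'   first 4 trials as in the natural-image analyses).
#' @param early_n Last repetition of the early segment.
#' @param max_rep Last repetition of the late segment for repetition-indexed
#'   fits (`Inf` to use all available trials, the block-design case).
#' @return An object of class `rep_fit`: list with `slope`, `intercept`,
#'   `r_first`, `r_last`, `segment`, `x_transform`, `n`, `omitted`.
#' @export
fit_slopes <- function(response, repetition,
                       segment = c("all", "early", "late"),
                       x_transform = c("repetition", "log10_trial"),
                       early_n = 4, max_rep = 15) {
  segment <- match.arg(segment)
  x_transform <- match.arg(x_transform)
  keep <- is.finite(response) & is.finite(repetition)
  keep <- keep & switch(segment,
    all = repetition <= max_rep,
    early = repetition <= early_n,
    late = repetition > early_n & repetition <= max_rep
  )
  min_n <- if (segment == "early") early_n else 2L
  out <- list(slope = NA_real_, intercept = NA_real_, r_first = NA_real_,
              r_last = NA_real_, segment = segment,
              x_transform = x_transform, n = sum(keep), omitted = TRUE)
  class(out) <- "rep_fit"
  if (sum(keep) < min_n) return(out)
  r <- repetition[keep]
  y <- response[keep]
  x <- if (x_transform == "repetition") r else log10(r)
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  out$slope <- b[2]
  out$intercept <- b[1]
  out$r_first <- b[1] + b[2] * min(x)
  out$r_last <- b[1] + b[2] * max(x)
  out$omitted <- FALSE
  out
}

#' @export
print.rep_fit <- function(x, ...) {
  cat(sprintf("<rep_fit %s/%s> slope %.4g, intercept %.4g (n = %d%s)\n",
              x$segment, x$x_transform, x$slope, x$intercept, x$n,
              if (x$omitted) ", omitted" else ""))
  invisible(x)
}

#' @export
tidy.rep_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope))
}

#' @export
glance.rep_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r_first = x$r_first, r_last = x$r_last,
                 rrc = rrc(x), segment = x$segment,
                 x_transform = x$x_transform, n = x$n, omitted = x$omitted)
}

#' Repetition-related change (RRC)
#'
#' RRC = r_last / (0.5 * (r_last + r_first)), with `r_first` and `r_last`
#' the fitted responses at the segment endpoints. RRC equals 1 when the
#' response does not change, exceeds 1 for increases, and normalizes for
#' stimulus-induced power differences. The more direct ratio
#' r_last / r_first is avoided because it degenerates when both responses
#' are near zero; when `|r_first + r_last|` falls below `eps` the RRC is
#' undefined and `NA` is returned.
#'
#' @param fit A `rep_fit`, or `r_first` as a number.
#' @param r_last Fitted last response (numeric method).
#' @param eps Degenerate-denominator guard.
#' @return Unitless RRC (NA when degenerate).
#' @export
rrc <- function(fit, r_last = NULL, eps = 1e-6) {
  if (inherits(fit, "rep_fit")) {
    r_first <- fit$r_first
    r_last <- fit$r_last
  } else {
    r_first <- fit
  }
  denom <- 0.5 * (r_last + r_first)
  ifelse(abs(r_last + r_first) < eps, NA_real_, r_last / denom)
}

# interleaved cross-validated half fits: one OLS on every second repetition
# starting with the first, one on every second starting with the second
interleaved_fits <- function(response, repetition) {
  ord <- order(repetition)
  r <- repetition[ord]
  y <- response[ord]
  halves <- lapply(c(1, 2), function(start) {
    sel <- seq(start, length(r), by = 2)
    if (length(sel) < 2) return(c(NA_real_, NA_real_))
    unname(coef(lm(y[sel] ~ r[sel])))
  })
  tibble::tibble(int_h1 = halves[[1]][1], slope_h1 = halves[[1]][2],
                 int_h2 = halves[[2]][1], slope_h2 = halves[[2]][2])
}

#' Cross-validated drive dependence of repetition effects
#'
#' Tests whether a stimulus-site combination's initial response strength
#' (intercept) predicts its repetition-related change (slope). To remove
#' the built-in coupling between a fitted mean and slope, two independent
#' OLS fits are computed per stimulus, site and session - one on every
#' second repetition starting with the first, one starting with the second.
#' Slopes and intercepts are medianed across sessions per stimulus-site
#' combination, and Spearman's rank correlation is computed between the
#' slope of one half and the independently estimated intercept of the other
#' half, in both directions, then averaged.
#'
#' @param data Tibble with `stimulus_id`, `site_id`, `session_id`,
#'   `repetition`, `response`.
#' @param segment,early_n,max_rep Segment selection as in [fit_slopes()].
#' @return A list of class `drive_dependence`: `rho` (averaged Spearman),
#'   `rho_12`, `rho_21`, and `combos` (per stimulus-site tibble of median
#'   half-fit slopes and intercepts).
#' @export
drive_dependence <- function(data, segment = c("all", "early", "late"),
                             early_n = 4, max_rep = 15) {
  segment <- match.arg(segment)
  sel <- switch(segment,
    all = data$repetition <= max_rep,
    early = data$repetition <= early_n,
    late = data$repetition > early_n & data$repetition <= max_rep
  )
  d <- data[sel & is.finite(data$response), ]
  fits <- d |>
    dplyr::group_by(.data$stimulus_id, .data$site_id, .data$session_id) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::reframe(interleaved_fits(.data$response, .data$repetition))
  combos <- fits |>
    dplyr::group_by(.data$stimulus_id, .data$site_id) |>
    dplyr::summarise(dplyr::across(c("int_h1", "slope_h1",
                                     "int_h2", "slope_h2"),
                                   ~ median(.x, na.rm = TRUE)),
                     .groups = "drop")
  combos <- combos[complete.cases(combos), ]
  if (nrow(combos) < 3) abort("need >= 3 stimulus-site combinations.")
  rho_12 <- cor(combos$slope_h1, combos$int_h2, method = "spearman")
  rho_21 <- cor(combos$slope_h2, combos$int_h1, method = "spearman")
  structure(list(rho = mean(c(rho_12, rho_21)), rho_12 = rho_12,
                 rho_21 = rho_21, combos = combos),
            class = "drive_dependence")
}

#' @export
glance.drive_dependence <- function(x, ...) {
  tibble::tibble(rho = x$rho, rho_12 = x$rho_12, rho_21 = x$rho_21,
                 n_combos = nrow(x$combos))
}

#' Median-split floor-effect control for drive dependence
#'
#' Splits stimulus-site combinations at the median intercept (response
#' strength) per animal - the lower half receiving the extra point when the
#' count is odd - and computes the cross-validated intercept-slope
#' correlation separately in each half. If the overall correlation derived
#' only from a floor effect in weakly driven combinations, the strongly
#' driven half would lose it. Significance per half comes from a permutation
#' distribution that randomizes intercepts within animal and half, averaged
#' across animals, with Benjamini-Hochberg correction across the two halves.
#'
#' @param combos Tibble with `animal_id`, `int_h1`, `slope_h1`, `int_h2`,
#'   `slope_h2` (from `drive_dependence()$combos`, plus an animal column).
#' @param n_perm Number of permutations.
#' @param alpha FDR level across halves.
#' @param seed Integer seed.
#' @return A tibble per half (`low`, `high`): `rho`, `p`, `p_adj`,
#'   `significant`, `n`.
#' @export
median_split_control <- function(combos, n_perm = 1000, alpha = 0.05,
                                 seed = NULL) {
  if (nrow(combos) < 4) abort("need >= 4 combinations for a median split.")
  if (!"animal_id" %in% names(combos)) combos$animal_id <- "animal1"
  combos$drive <- (combos$int_h1 + combos$int_h2) / 2
  split_tbl <- combos |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::mutate(half = ifelse(rank(.data$drive, ties.method = "first") <=
                                  ceiling(dplyr::n() / 2), "low", "high")) |>
    dplyr::ungroup()
  xv_rho <- function(d) {
    mean(c(cor(d$slope_h1, d$int_h2, method = "spearman"),
           cor(d$slope_h2, d$int_h1, method = "spearman")))
  }
  with_seed(seed, {
    res <- lapply(c("low", "high"), function(h) {
      dh <- split_tbl[split_tbl$half == h, ]
      obs <- mean(vapply(split(dh, dh$animal_id), xv_rho, numeric(1)))
      null <- replicate(n_perm, {
        mean(vapply(split(dh, dh$animal_id), function(d) {
          d$int_h1 <- sample(d$int_h1)
          d$int_h2 <- sample(d$int_h2)
          xv_rho(d)
        }, numeric(1)))
      })
      tibble::tibble(half = h, rho = obs,
                     p = perm_p_two_sided(obs, null), n = nrow(dh))
    })
    out <- dplyr::bind_rows(res)
    out$p_adj <- p.adjust(out$p, method = "BH")
    out$significant <- out$p_adj <= alpha
    out
  })
}
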