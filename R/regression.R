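#' Add block-indicator regressors to a block-design trial table
#'
#' Derives, per block, whether it is an *immediate repetition block* (its
#' stimulus equals the previous block's, e.g. the middle block of BBA) or a
#' *delayed repetition block* (its stimulus returns after an intervening
#' different block, e.g. the last block of ABA), plus the log10-transformed
#' consecutive-repetition count. For location designs the same logic applies
#' to the `location` column (`local_rep` as the repetition count).
#'
#' @param trials A tibble from [generate_block_sequence()].
#' @return The input with columns `immediate_rep`, `delayed_rep`, `log_rep`
#'   and `log_trial` added.
#' @export
block_indicators <- function(trials) {
  key_col <- if (any(trials$location %in% c("In", "Out"))) "location" else
    "stimulus_id"
  blocks <- trials |>
    dplyr::distinct(.data$block_index, key = .data[[key_col]]) |>
    dplyr::arrange(.data$block_index)
  imm <- c(FALSE, blocks$key[-1] == blocks$key[-nrow(blocks)])
  del <- vapply(seq_len(nrow(blocks)), function(i) {
    i >= 3 && !imm[i] && blocks$key[i] %in% blocks$key[seq_len(i - 2)]
  }, logical(1))
  rep_col <- if (key_col == "location") trials$local_rep else
    trials$repetition_number
  trials |>
    dplyr::mutate(
      immediate_rep = imm[.data$block_index],
      delayed_rep = del[.data$block_index],
      log_rep = log10(pmax(rep_col, 1)),
      log_trial = log10(pmax(.data$trial_index, 1))
    )
}

#' Multiple regression model for block-design responses
#'
#' Fits an OLS multiple regression of log-transformed, site-averaged
#' responses on repetition and block-structure terms. Responses are
#' log-transformed so the fit is not dominated by stimuli with strong
#' responses. Main effects of the block indicators test intercept shifts
#' (persistence / specificity of the repetition state), while their
#' interactions with the log repetition term test slope changes.
#'
#' @param data Tibble with one row per trial containing the response and all
#'   regressor columns (see [block_indicators()] for the standard ones).
#' @param response Name of the response column (log10 applied when
#'   `log_response = TRUE`; values must then be positive).
#' @param continuous Names of continuous regressors.
#' @param categorical Names of categorical regressors (converted to factors;
#'   e.g. animal, session per animal, stimulus per animal).
#' @param block_terms Names of logical block-indicator regressors whose main
#'   effects test intercept shifts.
#' @param interact_with Name of the regressor whose interaction with each
#'   block term tests slope changes (`NULL` for none).
#' @param log_response Log10-transform the response first.
#' @return An object of class `block_regression`: list with `model` (the
#'   `lm` fit), `terms` (tidy tibble: term, estimate, std.error, p.value),
#'   `partial_var` (per-term fraction of total SS from marginality-
#'   respecting single-term deletions), `aliased` (rank-deficient terms).
#' @export
fit_block_regression <- function(data, response,
                                 continuous = "log_rep",
                                 categorical = character(),
                                 block_terms = c("immediate_rep",
                                                 "delayed_rep"),
                                 interact_with = "log_rep",
                                 log_response = TRUE) {
  d <- as.data.frame(data)
  if (log_response) {
    if (any(d[[response]] <= 0, na.rm = TRUE)) {
      abort("non-positive responses cannot be log-transformed.")
    }
    d[[".y"]] <- log10(d[[response]])
  } else {
    d[[".y"]] <- d[[response]]
  }
  for (v in categorical) d[[v]] <- factor(d[[v]])
  block_terms <- block_terms[vapply(block_terms, function(v)
    length(unique(d[[v]])) > 1, logical(1))]
  rhs <- c(continuous, categorical, block_terms,
           if (!is.null(interact_with) && length(block_terms))
             paste0(interact_with, ":", block_terms))
  if (length(rhs) == 0) abort("no regressors supplied.")
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- lm(form, data = d)
  cf <- summary(fit)$coefficients
  terms_tbl <- tibble::tibble(
    term = rownames(cf),
    estimate = cf[, 1], std.error = cf[, 2], p.value = cf[, 4]
  )
  aliased <- names(coef(fit))[is.na(coef(fit))]
  ss_total <- sum((d$.y - mean(d$.y))^2)
  dr <- drop1(fit, test = "F")
  partial <- tibble::tibble(
    term = rownames(dr)[-1],
    partial_var = dr$`Sum of Sq`[-1] / ss_total,
    p.value = dr$`Pr(>F)`[-1]
  )
  structure(list(model = fit, terms = terms_tbl, partial_var = partial,
                 aliased = aliased),
            class = "block_regression")
}

#' @export
print.block_regression <- function(x, ...) {
  cat("<block_regression>\n")
  print(x$partial_var)
  if (length(x$aliased)) {
    cat("aliased terms:", paste(x$aliased, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.block_regression <- function(x, ...) x$terms

#' @export
glance.block_regression <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, df.residual = x$model$df.residual,
                 n_aliased = length(x$aliased))
}
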