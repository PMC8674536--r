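#' Read and write trial tables as CSV
#'
#' One trial per row with a header; round-trips all trial-table columns.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns a tibble; `write_trials()` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a recording session to a directory container
#'
#' Writes the session as a directory of plain-text datasets mirroring a
#' chunked-array container layout: `manifest.json` (dimensions, sampling
#' rate, seed), `lfp.txt` / `mua.txt` (one row per site-trial, samples as
#' columns, trial index varying slowest), `time.txt`, `trials.csv` and
#' `truth.json`.
#'
#' @param rec A `recording`.
#' @param dir Target directory (created if missing).
#' @return `read_recording()` returns a `recording`; `write_recording()`
#'   the directory, invisibly.
#' @export
write_recording <- function(rec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(rec$lfp)
  manifest <- list(n_sites = d[1], n_trials = d[2], n_samples = d[3],
                   fs = rec$fs, seed = rec$seed, sites = rec$sites,
                   neighbors = rec$neighbors)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  flat <- function(a) {
    m <- matrix(aperm(a, c(3, 1, 2)), nrow = d[1] * d[2], byrow = TRUE)
    m
  }
  utils::write.table(flat(rec$lfp), file.path(dir, "lfp.txt"),
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(flat(rec$mua), file.path(dir, "mua.txt"),
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(rec$time, digits = 17), file.path(dir, "time.txt"))
  write_trials(rec$trials, file.path(dir, "trials.csv"))
  if (!is.null(rec$truth)) {
    tr <- rec$truth
    jsonlite::write_json(
      list(stimulus = tr$stimulus,
           specificity_transfer = tr$specificity_transfer,
           persistence = tr$persistence, x_transform = tr$x_transform,
           noise_1f_exponent = tr$noise_1f_exponent,
           mua_noise_floor = tr$mua_noise_floor, seed = tr$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  d <- c(manifest$n_sites, manifest$n_trials, manifest$n_samples)
  unflat <- function(path) {
    m <- as.matrix(utils::read.table(path))
    aperm(array(t(m), dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth.json"))) {
    tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
    truth <- structure(list(
      stimulus = tibble::as_tibble(tj$stimulus),
      specificity_transfer = tj$specificity_transfer,
      persistence = tj$persistence, x_transform = tj$x_transform,
      noise_1f_exponent = tj$noise_1f_exponent,
      mua_noise_floor = tj$mua_noise_floor, seed = tj$seed),
      class = "ground_truth")
  }
  structure(list(
    lfp = unflat(file.path(dir, "lfp.txt")),
    mua = unflat(file.path(dir, "mua.txt")),
    fs = manifest$fs,
    time = as.numeric(readLines(file.path(dir, "time.txt"))),
    sites = manifest$sites,
    neighbors = if (is.null(manifest$neighbors))
      matrix(integer(0), 0, 2) else as.matrix(manifest$neighbors),
    trials = read_trials(file.path(dir, "trials.csv")),
    truth = truth, seed = manifest$seed
  ), class = "recording")
}

#' Read and write run configurations as JSON
#'
#' @param cfg A `run_config` from [dataset1_config()] or [block_config()].
#' @param path File path.
#' @return `read_config()` returns a `run_config`; `write_config()` its
#'   path, invisibly.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_config")
}
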