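#' Read and write trial tables
#'
#' Trial tables are tab-separated with a header row and one row per
#' completed trial: `session_id`, `trial_index`, `iti_ms`, `stimulus`
#' (`s`/`l`), `difficulty` (`easy`/`difficult`), `choice` (`s`/`l`),
#' `outcome` (+1/-1), `x` (+1/-1), and the four event timestamps in ms.
#' The round trip is lossless.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `read_trials()` returns the trial tibble; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      session_id = readr::col_character(),
      trial_index = readr::col_integer(),
      iti_ms = readr::col_double(),
      stimulus = readr::col_character(),
      difficulty = readr::col_character(),
      choice = readr::col_character(),
      outcome = readr::col_integer(),
      x = readr::col_integer(),
      t_center_poke_ms = readr::col_double(),
      t_tone1_ms = readr::col_double(),
      t_tone2_ms = readr::col_double(),
      t_side_poke_ms = readr::col_double()
    )
  )
}

#' Read and write spike-count tables
#'
#' Long tab-separated tables: `neuron_id`, `ensemble_id`, `trial_index`,
#' `period`, `count`.
#'
#' @param counts A long counts tibble.
#' @param path File path.
#' @param duration_ms Window length stored alongside (re-attached on read
#'   as attribute when passed).
#' @return `read_counts()` returns the tibble; `write_counts()` returns
#'   `path` invisibly.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, duration_ms = 150) {
  out <- readr::read_tsv(
    path,
    col_types = readr::cols(
      neuron_id = readr::col_character(),
      ensemble_id = readr::col_integer(),
      trial_index = readr::col_integer(),
      period = readr::col_character(),
      count = readr::col_integer()
    )
  )
  attr(out, "duration_ms") <- duration_ms
  out
}

#' Read and write spike-time tables
#'
#' Long tab-separated tables: `neuron_id`, `t_ms`.
#'
#' @param spikes A spike-times tibble.
#' @param path File path.
#' @return `read_spikes()` returns the tibble; `write_spikes()` returns
#'   `path` invisibly.
#' @export
write_spikes <- function(spikes, path) {
  readr::write_tsv(spikes, path)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  readr::read_tsv(
    path,
    col_types = readr::cols(
      neuron_id = readr::col_character(),
      t_ms = readr::col_double()
    )
  )
}
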