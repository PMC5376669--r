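#' Stimulus set for the interval categorization task
#'
#' Defines the discrete inter-tone intervals (ITIs) used in the task, their
#' short/long category assignment, the easy/difficult split by distance from
#' the category boundary, and the boundary itself. The default reproduces the
#' task's printed design: short intervals 50--200 ms, long intervals
#' 350--500 ms, easy intervals far from the boundary (50, 100, 450, 500 ms),
#' and a boundary at the midpoint between the longest short and the shortest
#' long interval (275 ms).
#'
#' @param short_ms Durations (ms) of the short-category ITIs.
#' @param long_ms Durations (ms) of the long-category ITIs.
#' @param easy_ms Subset of ITIs counted as easy (far from the boundary);
#'   every remaining ITI is difficult.
#' @param boundary_ms Category boundary (ms). When `NULL` it is computed as
#'   the midpoint between `max(short_ms)` and `min(long_ms)`.
#'
#' @return An object of class `stimulus_set`: a list with elements
#'   `short_ms`, `long_ms`, `easy_ms`, `difficult_ms`, `boundary_ms`.
#' @examples
#' ss <- stimulus_set()
#' ss$boundary_ms # 275
#' @export
stimulus_set <- function(short_ms = c(50, 100, 150, 200),
                         long_ms = c(350, 400, 450, 500),
                         easy_ms = c(50, 100, 450, 500),
                         boundary_ms = NULL) {
  short_ms <- sort(unique(short_ms))
  long_ms <- sort(unique(long_ms))
  if (length(intersect(short_ms, long_ms)) > 0L) {
    stop("short and long ITI sets must be disjoint")
  }
  all_itis <- sort(c(short_ms, long_ms))
  if (!all(easy_ms %in% all_itis)) {
    stop("easy_ms must be a subset of the ITIs")
  }
  difficult_ms <- setdiff(all_itis, easy_ms)
  if (is.null(boundary_ms)) {
    boundary_ms <- (max(short_ms) + min(long_ms)) / 2
  }
  if (!(boundary_ms > max(short_ms) && boundary_ms < min(long_ms))) {
    stop("boundary_ms must lie strictly between max(short_ms) and min(long_ms)")
  }
  structure(
    list(
      short_ms = short_ms,
      long_ms = long_ms,
      easy_ms = sort(easy_ms),
      difficult_ms = difficult_ms,
      boundary_ms = boundary_ms
    ),
    class = "stimulus_set"
  )
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat("<stimulus_set>\n")
  cat("  short (ms):    ", paste(x$short_ms, collapse = ", "), "\n")
  cat("  long (ms):     ", paste(x$long_ms, collapse = ", "), "\n")
  cat("  easy (ms):     ", paste(x$easy_ms, collapse = ", "), "\n")
  cat("  difficult (ms):", paste(x$difficult_ms, collapse = ", "), "\n")
  cat("  boundary (ms): ", x$boundary_ms, "\n")
  invisible(x)
}

#' Categorize ITIs into stimulus category and difficulty
#'
#' Maps each ITI to its stimulus category `S` (+1 short, -1 long) and
#' difficulty `D` (+1 easy, -1 difficult) under a stimulus set.
#'
#' @param iti_ms Vector of ITI durations (ms); each must be a member of the
#'   stimulus set (the boundary itself is not a stimulus).
#' @param stim_set A [stimulus_set()].
#' @return A tibble with one row per input: `iti_ms`, `S`, `D`, and the
#'   labels `stimulus` (`"s"`/`"l"`) and `difficulty`
#'   (`"easy"`/`"difficult"`).
#' @examples
#' categorize_stimulus(c(150, 500))
#' @export
categorize_stimulus <- function(iti_ms, stim_set = stimulus_set()) {
  all_itis <- c(stim_set$short_ms, stim_set$long_ms)
  bad <- setdiff(unique(iti_ms), all_itis)
  if (length(bad) > 0L) {
    stop(
      "unknown ITI value(s): ", paste(bad, collapse = ", "),
      "; stimulus set is {", paste(sort(all_itis), collapse = ", "), "}"
    )
  }
  s <- ifelse(iti_ms %in% stim_set$short_ms, 1L, -1L)
  d <- ifelse(iti_ms %in% stim_set$easy_ms, 1L, -1L)
  tibble::tibble(
    iti_ms = iti_ms,
    S = s,
    D = d,
    stimulus = ifelse(s == 1L, "s", "l"),
    difficulty = ifelse(d == 1L, "easy", "difficult")
  )
}

#' Second-order prior
#'
#' The second-order prior is the interaction between choice and outcome,
#' `X = C * R`. On every completed trial it equals the stimulus category,
#' because the outcome is `R = +1` exactly when `C = S`.
#'
#' @param C Choice code(s), +1 short / -1 long.
#' @param R Outcome code(s), +1 correct / -1 incorrect.
#' @return `C * R` as an integer vector.
#' @examples
#' second_order_prior(+1, -1) # -1
#' @export
second_order_prior <- function(C, R) {
  if (!all(C %in% c(-1, 1)) || !all(R %in% c(-1, 1))) {
    stop("C and R must be coded +1/-1")
  }
  as.integer(C * R)
}
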