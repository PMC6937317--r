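#' Behavioral scoring and learning-criterion session labeling
#'
#' The task is a two-alternative choice odor discrimination: per trial the
#' animal samples one of two odors and chooses a side; a no-response trial
#' counts as incorrect. Learning criterion (LC) is >= 80% correct on two
#' consecutive 30-trial blocks on three consecutive days. Sessions before
#' criterion are labeled S1..Sn; the session just before the criterion run
#' is LC0, and the days at criterion are LC1, LC2, ...
#'
#' @name behavior
NULL

#' Whole-session performance
#'
#' @param trials trial table with a logical `correct` column (no-response
#'   already encoded as incorrect).
#' @return fraction of correct trials in `[0, 1]`.
#' @export
session_performance <- function(trials) {
  if (nrow(trials) < 1L) stop("session_performance needs at least one trial")
  mean(trials$correct)
}

#' Block-wise performance over consecutive trials
#'
#' @param trials trial table.
#' @param block_size trials per block, default 30.
#' @param sliding if `TRUE`, a sliding window with step 1; otherwise the
#'   default non-overlapping partition (blocks 1-30, 31-60, ...), dropping
#'   a partial trailing block.
#' @return numeric vector of per-block fractions correct (empty when
#'   fewer than `block_size` trials).
#' @export
rolling_block_performance <- function(trials, block_size = 30L, sliding = FALSE) {
  n <- nrow(trials)
  if (n < block_size) return(numeric(0))
  x <- as.numeric(trials$correct)
  if (sliding) {
    cum <- c(0, cumsum(x))
    (cum[(block_size + 1L):(n + 1L)] - cum[1L:(n - block_size + 1L)]) / block_size
  } else {
    n_blocks <- n %/% block_size
    vapply(seq_len(n_blocks), function(b) {
      mean(x[((b - 1L) * block_size + 1L):(b * block_size)])
    }, numeric(1))
  }
}

#' Day-wise learning-criterion detection
#'
#' A day satisfies the within-day condition iff some two consecutive
#' blocks both reach >= `threshold`; the criterion is achieved at the
#' first day that ends a run of three consecutive satisfying days.
#'
#' @param day_blocks list of per-day block performance vectors (from
#'   [rolling_block_performance()]).
#' @param threshold block performance threshold, default 0.80.
#' @return list: `day_satisfies` (logical per day), `criterion_day` (index
#'   of the third satisfying day, or `NA` if never reached).
#' @export
criterion_reached <- function(day_blocks, threshold = 0.80) {
  sat <- vapply(day_blocks, function(b) {
    if (length(b) < 2L) return(FALSE)
    any(b[-length(b)] >= threshold & b[-1L] >= threshold)
  }, logical(1))
  crit <- NA_integer_
  run <- 0L
  for (d in seq_along(sat)) {
    run <- if (sat[d]) run + 1L else 0L
    if (run == 3L) { crit <- d; break }
  }
  list(day_satisfies = sat, criterion_day = crit)
}

#' Label sessions relative to learning-criterion achievement
#'
#' Days up to two before the criterion run are S1..Sn; the day just prior
#' to the run is LC0; the days from the start of the three-day criterion
#' run onward are LC1, LC2, LC3, ... When the criterion is reached on the
#' earliest possible day there are no S (and possibly no LC0) labels.
#'
#' @param criterion a [criterion_reached()] result (or a list with
#'   `criterion_day` and the number of days inferred from
#'   `day_satisfies`).
#' @param phase phase tag prefixed to labels, e.g. `"P1"`; `NULL` for
#'   bare labels.
#' @return character vector of labels, one per day.
#' @export
label_sessions <- function(criterion, phase = NULL) {
  n <- length(criterion$day_satisfies)
  crit <- criterion$criterion_day
  labels <- paste0("S", seq_len(n))
  if (!is.na(crit)) {
    lc1 <- crit - 2L # first day of the criterion run
    at <- lc1:n
    labels[at] <- paste0("LC", seq_along(at))
    if (lc1 > 1L) {
      labels[lc1 - 1L] <- "LC0"
      if (lc1 > 2L) labels[seq_len(lc1 - 2L)] <- paste0("S", seq_len(lc1 - 2L))
    }
  }
  if (!is.null(phase)) labels <- paste(phase, labels, sep = "-")
  labels
}

#' Last pre-learning session of a reversal sequence
#'
#' The "pre-learning" session is the last session whose whole-session
#' performance is below 60%.
#'
#' @param performances numeric vector of session performances, in session
#'   order.
#' @param threshold default 0.60.
#' @return index of the last session with performance `< threshold`.
#' @export
detect_pre_learning <- function(performances, threshold = 0.60) {
  below <- which(performances < threshold)
  if (!length(below)) stop("no session with performance below ", threshold)
  max(below)
}

#' Performer / non-performer split for recall tests
#'
#' An animal counts as a performer on a recall session when its
#' performance over trials 11-20 reaches at least 80%.
#'
#' @param trials trial table of the recall session.
#' @return logical.
#' @export
is_performer <- function(trials) {
  if (nrow(trials) < 20L) stop("need at least 20 trials for the performer split")
  mean(trials$correct[11L:20L]) >= 0.80
}
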