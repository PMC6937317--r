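#' Group-level aggregation and tidy exports
#'
#' Group summaries always aggregate per rat first (medians), then across
#' rats (means with bootstrap confidence intervals); trials are never
#' pooled across animals.
#'
#' @name stats_report
NULL

#' Percentile bootstrap confidence interval of the mean
#'
#' @param values per-rat statistics (numeric, length >= 2).
#' @param n_boot bootstrap resamples, default 1000.
#' @param level confidence level, default 0.95.
#' @param seed RNG seed; the interval is deterministic given the seed.
#' @return named numeric `(mean, low, high)`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000L, level = 0.95, seed = 1L) {
  n <- length(values)
  if (n < 2L) stop("bootstrap_ci needs at least 2 values")
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
    rowMeans(matrix(values[idx], nrow = n_boot))
  })
  a <- (1 - level) / 2
  q <- stats::quantile(means, c(a, 1 - a), names = FALSE, type = 7)
  c(mean = mean(values), low = q[1L], high = q[2L])
}

#' Spearman rank correlation between hub index and beta amplitude
#'
#' @param hub_index per-session hub indices.
#' @param median_beta per-session median beta amplitudes.
#' @return Spearman correlation (midrank ties).
#' @export
hub_amplitude_correlation <- function(hub_index, median_beta) {
  if (length(hub_index) < 4L) stop("need >= 4 sessions for a rank correlation")
  stats::cor(hub_index, median_beta, method = "spearman")
}

#' Session summary table across rats
#'
#' @param measures long `data.frame` with columns `rat`, `session`,
#'   `structure`, `beta_amplitude`.
#' @param n_boot,level,seed bootstrap parameters (see [bootstrap_ci()]).
#' @return `data.frame` with one row per (session, structure): across-rat
#'   mean of per-rat medians with 95% CI and `n_rats`.
#' @export
group_summary <- function(measures, n_boot = 1000L, level = 0.95, seed = 1L) {
  key <- interaction(measures$session, measures$structure, drop = TRUE)
  rows <- lapply(split(measures, key), function(d) {
    per_rat <- tapply(d$beta_amplitude, d$rat, stats::median, na.rm = TRUE)
    per_rat <- per_rat[!is.na(per_rat)]
    ci <- if (length(per_rat) >= 2L) {
      bootstrap_ci(as.numeric(per_rat), n_boot, level, seed)
    } else {
      c(mean = as.numeric(per_rat)[1L] %||% NA_real_, low = NA_real_, high = NA_real_)
    }
    data.frame(session = d$session[1L], structure = d$structure[1L],
               mean = ci[["mean"]], ci_low = ci[["low"]], ci_high = ci[["high"]],
               n_rats = length(per_rat), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis-ready long table
#'
#' Plain CSV (UTF-8, header always written) whose write -> read round
#' trip is lossless for the standard measure tables.
#'
#' @param table `data.frame` (list columns are dropped with a note).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_tidy <- function(table, path) {
  is_list <- vapply(table, is.list, logical(1))
  if (any(is_list)) table <- table[, !is_list, drop = FALSE]
  data.table::fwrite(table, path, na = "NA")
  invisible(path)
}

#' Read a table written by [export_tidy()]
#' @param path CSV path.
#' @return `data.frame`.
#' @export
read_tidy <- function(path) {
  as.data.frame(data.table::fread(path, na.strings = "NA", encoding = "UTF-8"))
}
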