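# Global corrections for multiple testing over time: count, duration and
# Fisher-combined statistics on TANOVA p-series, recycling the permutation
# null run by run.

#' Per-run null p-value series
#'
#' Re-uses the randomization runs retained by [tanova()]: for run r and time
#' t, the p-value is computed by comparing that run's statistic with those of
#' all other runs and the observed data, exactly as the observed series is
#' compared with all runs. Observed and run series thus share the
#' (1 + b)/(n + 1) scale and are exchangeable under the null hypothesis,
#' which keeps the overall statistics exactly calibrated despite the discrete
#' p-value grid.
#'
#' @param result a [TanovaResult-class].
#' @param effect one of its effects.
#' @return matrix (run x time) of leave-one-out p-values.
#' @export
nullPMatrix <- function(result, effect) {
  e <- match(effect, result@effects)
  if (is.na(e)) stop(sprintf("effect '%s' not in result", effect))
  S <- result@null[, , e, drop = FALSE]
  dim(S) <- dim(result@null)[1:2]
  n <- nrow(S)
  if (n < 20L) warning("fewer than 20 runs: overall statistics are unstable")
  obs <- result@observed[, e]
  # p_rt = (1 + #{s != r : stat_st >= stat_rt} + [obs_t >= stat_rt]) / (n + 1)
  vapply(seq_len(ncol(S)), function(t) {
    x <- S[, t]
    (1 + (n - rank(x, ties.method = "min")) + (obs[t] >= x)) / (n + 1)
  }, numeric(n))
}

#' Count of sub-threshold p-values
#'
#' @param p a p-value series.
#' @param theta significance threshold in (0, 1).
#' @return number of time points with p < theta.
#' @export
countStatistic <- function(p, theta) {
  stopifnot(theta > 0, theta < 1)
  sum(p < theta)
}

#' Longest duration of contiguous sub-threshold p-values
#'
#' @param p a p-value series (time-ordered).
#' @param theta significance threshold.
#' @param dtMs inter-sample interval in ms.
#' @return longest run of consecutive sub-threshold points, in ms.
#' @export
durationStatistic <- function(p, theta, dtMs) {
  stopifnot(theta > 0, theta < 1)
  r <- rle(p < theta)
  len <- r$lengths[r$values]
  if (!length(len)) return(0)
  max(len) * dtMs
}

#' Fisher's combined probability statistic
#'
#' \eqn{-2 \sum_t \ln p_t} over the whole series ("p-AUC" statistic).
#'
#' @param p a p-value series; all values must be positive (guaranteed by the
#'   add-one convention).
#' @return scalar.
#' @export
fisherStatistic <- function(p) {
  if (any(p <= 0)) stop("Fisher's method requires all p > 0")
  -2 * sum(log(p))
}

#' Overall significance over time
#'
#' Computes one of the three global statistics (count of sub-threshold
#' p-values, longest sub-threshold duration, Fisher's combined p) on the
#' observed p-series and on every randomization run's null p-series (via
#' [nullPMatrix()]); the overall p is the add-one proportion of runs whose
#' statistic reaches the observed one. For `kind = "duration"` the
#' (1 - theta)-quantile of the null durations is reported as the shortest
#' duration a contiguous significant period must exceed.
#'
#' @param result a [TanovaResult-class] (its retained permutations are
#'   recycled, so no new randomization is performed).
#' @param effect effect to correct.
#' @param kind `"count"`, `"duration"` or `"fisher"`.
#' @param theta sub-threshold criterion for counting/segmenting the p-series;
#'   defaults to the p-threshold of the run.
#' @param level overall significance level used for the duration-threshold
#'   quantile (defaults to `theta`).
#' @return an [OverallResult-class].
#' @export
overallTest <- function(result, effect,
                        kind = c("count", "duration", "fisher"),
                        theta = result@cfg@pThreshold, level = theta) {
  kind <- match.arg(kind)
  e <- match(effect, result@effects)
  if (is.na(e)) stop(sprintf("effect '%s' not in result", effect))
  dtMs <- if (length(result@time) > 1L) diff(result@time[1:2]) else 1
  P <- nullPMatrix(result, effect)   # run x time
  pObs <- result@p[, e]
  stat <- switch(kind,
                 count = function(p) countStatistic(p, theta),
                 duration = function(p) durationStatistic(p, theta, dtMs),
                 fisher = fisherStatistic)
  observed <- stat(pObs)
  nullSamples <- apply(P, 1L, stat)
  n <- length(nullSamples)
  p <- (1 + sum(nullSamples >= observed)) / (n + 1)
  thr <- NA_real_
  if (kind == "duration")
    thr <- as.numeric(stats::quantile(nullSamples, 1 - level, type = 1L))
  new("OverallResult", effect = effect, kind = kind, observed = observed,
      nullSamples = as.numeric(nullSamples), p = p,
      durationThresholdMs = thr, theta = theta)
}
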