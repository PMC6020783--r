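# Topographic consistency test.

#' Topographic consistency test
#'
#' Tests, per condition and time point, whether the subjects share a common
#' scalp-field topography. The effect size is the GFP of the grand-mean map
#' across subjects, which is large only when the individual maps agree
#' spatially. The null distribution is built by shuffling, separately and
#' freshly for each subject, time point and run, the measured potentials of
#' each map across channels — which preserves every subject's GFP while
#' destroying any spatial communality. The p-value is the add-one proportion
#' of runs whose shuffled grand-mean GFP reaches the observed one.
#'
#' @param ds an average-referenced [ErpDataset-class].
#' @param conditions condition tags to test (default all).
#' @param cfg a [RandConfig-class]; `normalize` and `interaction` do not
#'   apply here.
#' @return a [TctResult-class] with per-time-point observed grand-mean GFP and
#'   p-values per condition.
#' @export
tct <- function(ds, conditions = conditionTags(ds), cfg = randConfig()) {
  if (nSubjects(ds) < 2L) stop("the TCT needs at least 2 subjects")
  bad <- setdiff(conditions, ds@conditionTags)
  if (length(bad))
    stop("condition(s) not in dataset: ", paste(bad, collapse = ", "))
  d <- dim(ds@data)
  tp <- d[1L]; nch <- d[2L]; ns <- d[3L]
  nRuns <- as.integer(cfg@nRuns)
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  obs <- matrix(NA_real_, tp, length(conditions),
                dimnames = list(NULL, conditions))
  p <- obs
  for (ci in seq_along(conditions)) {
    co <- match(conditions[ci], ds@conditionTags)
    A <- ds@data[, , , co, drop = FALSE]
    dim(A) <- c(tp, nch, ns)
    obs[, ci] <- gfp(apply(A, c(1L, 2L), mean))
    nullGfp <- matrix(NA_real_, nRuns, tp)
    rowIdx <- rep(seq_len(tp), each = nch)
    Asub <- lapply(seq_len(ns), function(s) A[, , s])
    for (r in seq_len(nRuns)) {
      acc <- matrix(0, nch, tp)
      for (s in seq_len(ns)) {
        # independent channel permutation of every time point's map
        ord <- apply(matrix(stats::runif(tp * nch), tp, nch), 1L, order)
        acc <- acc + matrix(Asub[[s]][rowIdx + (as.integer(ord) - 1L) * tp],
                            nrow = nch)
      }
      acc <- acc / ns
      mu <- colMeans(acc)
      nullGfp[r, ] <- sqrt(colMeans(acc^2) - mu^2)
    }
    b <- colSums(nullGfp >= matrix(obs[, ci], nRuns, tp, byrow = TRUE))
    p[, ci] <- if (cfg@legacyP) b / nRuns else (1 + b) / (nRuns + 1)
  }
  new("TctResult", observedGfp = obs, p = p, time = sampleTimes(ds),
      nRuns = as.numeric(nRuns), threshold = cfg@pThreshold)
}
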