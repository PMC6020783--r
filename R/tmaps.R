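# Post-hoc channel-wise t-maps on window-averaged contrasts.

#' Define a selection for a t-map contrast
#'
#' @param conditions condition tags averaged within each subject.
#' @param subjects subject ids or indices (default all).
#' @return a selection list consumed by [tMap()].
#' @export
erpSelection <- function(conditions, subjects = NULL) {
  list(conditions = conditions, subjects = subjects)
}

.resolveSelection <- function(ds, sel) {
  if (is.character(sel) || is.null(sel$conditions)) sel <- erpSelection(sel)
  co <- match(sel$conditions, ds@conditionTags)
  if (anyNA(co)) stop("unknown condition in selection")
  s <- sel$subjects
  if (is.null(s)) s <- seq_len(nSubjects(ds))
  if (is.character(s)) s <- match(s, ds@subjectIds)
  if (anyNA(s) || !length(s)) stop("unknown or empty subject selection")
  list(conditions = co, subjects = sort(s))
}

#' Channel-wise t-map of a window-averaged contrast
#'
#' Averages each subject's maps over the analysis window (and over the
#' selected conditions), then computes, per channel, how much the two
#' selections differ on average relative to the variance of the differences:
#' a paired t when the selections share the same subjects, a two-sample t
#' otherwise (the test type is set automatically, or can be forced). The map
#' of `b` is subtracted from the map of `a`, so the caller states minuend and
#' subtrahend explicitly. A TANOVA p-value for the identical contrast and
#' window accompanies the map.
#'
#' Channels with zero variance are reported as a signed infinite sentinel
#' (with a warning) so the output map stays rectangular.
#'
#' @param ds an [ErpDataset-class].
#' @param a,b selections from [erpSelection()] (or bare condition tags).
#' @param window `c(from, to)` ms.
#' @param paired `"auto"`, `TRUE` or `FALSE`.
#' @param cfg [RandConfig-class] for the accompanying TANOVA.
#' @return a [TMapResult-class].
#' @export
tMap <- function(ds, a, b, window = NULL, paired = "auto",
                 cfg = randConfig()) {
  sa <- .resolveSelection(ds, a)
  sb <- .resolveSelection(ds, b)
  avg <- .windowAverageArray(ds, window)        # channel x subject x condition
  selMean <- function(sel) {
    m <- avg[, sel$subjects, sel$conditions, drop = FALSE]
    apply(m, c(1L, 2L), mean)                   # channel x subject
  }
  A <- selMean(sa)
  B <- selMean(sb)
  if (identical(paired, "auto"))
    paired <- identical(sa$subjects, sb$subjects)
  nch <- nrow(A)
  if (paired) {
    if (ncol(A) < 2L) stop("paired t needs at least 2 subjects")
    D <- A - B
    n <- ncol(D)
    m <- rowMeans(D)
    s <- sqrt(rowSums((D - m)^2) / (n - 1))
    tval <- m / (s / sqrt(n))
    df <- n - 1
  } else {
    n1 <- ncol(A); n2 <- ncol(B)
    if (n1 < 2L || n2 < 2L) stop("unpaired t needs at least 2 subjects per side")
    m1 <- rowMeans(A); m2 <- rowMeans(B)
    v1 <- rowSums((A - m1)^2) / (n1 - 1)
    v2 <- rowSums((B - m2)^2) / (n2 - 1)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    tval <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    m <- m1 - m2
  }
  bad <- !is.finite(tval)
  if (any(bad)) {
    tval[bad] <- sign(m[bad]) * Inf
    tval[bad & m == 0] <- 0
    warning(sprintf("%d channel(s) with zero variance: t set to signed Inf",
                    sum(bad)))
  }
  contrastP <- .contrastTanovaP(ds, A, B, paired, cfg)
  new("TMapResult", t = as.numeric(tval), meanA = rowMeans(A),
      meanB = rowMeans(B), df = df, paired = paired, contrastP = contrastP,
      channels = ds@channelLabels)
}

# TANOVA p for a two-selection contrast on window-averaged maps. For a paired
# contrast the two selections form a 1 x 2 within design; for unpaired, a
# between design over the union of subjects.
.contrastTanovaP <- function(ds, A, B, paired, cfg) {
  nch <- nrow(A)
  if (paired) {
    arr <- array(NA_real_, c(1L, nch, ncol(A), 2L))
    arr[1L, , , 1L] <- A
    arr[1L, , , 2L] <- B
    ds2 <- erpDataset(arr, dtMs = ds@dt,
                      subjectIds = paste0("s", seq_len(ncol(A))),
                      conditionTags = c("a", "b"),
                      averageReferenced = ds@averageReferenced)
    des <- erpDesign(list(contrast = c(a = 1, b = 2)),
                     conditionTags = c("a", "b"))
  } else {
    arr <- array(NA_real_, c(1L, nch, ncol(A) + ncol(B), 1L))
    arr[1L, , , 1L] <- cbind(A, B)
    ids <- paste0("s", seq_len(ncol(A) + ncol(B)))
    ds2 <- erpDataset(arr, dtMs = ds@dt, subjectIds = ids,
                      conditionTags = "x",
                      averageReferenced = ds@averageReferenced)
    des <- erpDesign(list(), conditionTags = "x",
                     betweenFactor = stats::setNames(
                       rep(c("a", "b"), c(ncol(A), ncol(B))), ids))
  }
  res <- tanova(ds2, des, cfg)
  as.numeric(res@p[1L, 1L])
}
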