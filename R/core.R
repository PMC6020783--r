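# Core scalp-field arithmetic: GFP, referencing, normalization, grand means.

#' Global field power
#'
#' GFP is the standard deviation of the potential values across channels at
#' one time point (population form, i.e. divided by the number of channels):
#' the reference-free overall strength of a scalp field. For a time x channel
#' matrix a GFP time series is returned.
#'
#' @param x numeric vector (one scalp map) or time x channel matrix.
#' @return scalar or per-time-point numeric vector, in uV.
#' @examples
#' gfp(c(1, -1))            # 1
#' gfp(c(2, 0, -2, 0))      # sqrt(2)
#' @export
gfp <- function(x) {
  if (is.matrix(x)) {
    if (ncol(x) < 2L) stop("GFP needs at least 2 channels")
    mu <- rowMeans(x)
    return(sqrt(rowMeans((x - mu)^2)))
  }
  if (length(x) < 2L) stop("GFP needs at least 2 channels")
  sqrt(mean((x - mean(x))^2))
}

#' @rdname averageReference
setMethod("averageReference", "matrix", function(x) x - rowMeans(x))

#' @rdname averageReference
setMethod("averageReference", "numeric", function(x) x - mean(x))

#' @rdname averageReference
setMethod("averageReference", "ErpDataset", function(x) {
  mu <- apply(x@data, c(1L, 3L, 4L), mean)
  x@data <- x@data - aperm(
    array(mu, c(dim(x@data)[c(1L, 3L, 4L)], dim(x@data)[2L])),
    c(1L, 4L, 2L, 3L))
  x@averageReferenced <- TRUE
  validObject(x)
  x
})

#' Normalize maps by their GFP
#'
#' Divides every time point's map by its GFP so that each non-degenerate map
#' has unit field strength; this removes purely quantitative (scaling)
#' differences and leaves topographic (qualitative) structure. Maps whose GFP
#' does not exceed `eps` are returned as zeros and counted in one warning, so
#' randomization loops stay total.
#'
#' @param m time x channel matrix (average referenced).
#' @param eps degenerate-map threshold in uV (default 1e-12).
#' @return matrix of the same shape; every retained time point has GFP 1.
#' @export
normalizeByGfp <- function(m, eps = 1e-12) {
  g <- gfp(m)
  bad <- g <= eps
  g[bad] <- 1
  out <- m / g
  if (any(bad)) {
    out[bad, ] <- 0
    warning(sprintf("%d time point(s) with GFP <= %g set to zero", sum(bad),
                    eps))
  }
  out
}

.normalizeArray <- function(a, eps = 1e-12) {
  # per subject x condition x time-point GFP normalization of a 4-D array
  d <- dim(a)
  mu <- apply(a, c(1L, 3L, 4L), mean)
  g <- sqrt(apply((a - aperm(array(mu, c(d[c(1L, 3L, 4L)], d[2L])),
                             c(1L, 4L, 2L, 3L)))^2, c(1L, 3L, 4L), mean))
  nbad <- sum(g <= eps)
  gs <- g
  gs[g <= eps] <- Inf   # degenerate maps -> zeros
  a <- a / aperm(array(gs, c(d[c(1L, 3L, 4L)], d[2L])), c(1L, 4L, 2L, 3L))
  if (nbad > 0L)
    warning(sprintf("%d degenerate map(s) (GFP <= %g) set to zero during normalization",
                    nbad, eps))
  a
}

#' Grand-mean ERP matrix
#'
#' Pointwise weighted mean over selected subjects and conditions.
#'
#' @param ds an [ErpDataset-class].
#' @param subjects subject ids or indices (default all).
#' @param conditionWeights per-condition weights, summing to 1 (a one-hot
#'   vector selects a single condition); default equal weights.
#' @return time x channel matrix of the grand mean (uV).
#' @export
grandMean <- function(ds, subjects = NULL, conditionWeights = NULL) {
  stopifnot(is(ds, "ErpDataset"))
  d <- dim(ds@data)
  if (is.null(subjects)) subjects <- seq_len(d[3L])
  if (is.character(subjects)) subjects <- match(subjects, ds@subjectIds)
  if (length(subjects) == 0L || anyNA(subjects))
    stop("empty or unknown subject subset")
  if (is.null(conditionWeights)) conditionWeights <- rep(1 / d[4L], d[4L])
  if (length(conditionWeights) != d[4L])
    stop("need one weight per condition")
  if (abs(sum(conditionWeights) - 1) > 1e-8)
    stop("condition weights must sum to 1")
  sub <- ds@data[, , subjects, , drop = FALSE]
  m <- apply(sub, c(1L, 2L, 4L), mean)           # time x channel x condition
  out <- matrix(0, d[1L], d[2L])
  for (co in seq_len(d[4L]))
    if (conditionWeights[co] != 0)
      out <- out + conditionWeights[co] * m[, , co]
  dimnames(out) <- list(NULL, ds@channelLabels)
  out
}

# ---------------------------------------------------------------------------
# time window helpers
# ---------------------------------------------------------------------------

# analysis windows are inclusive [from, to] in ms, endpoints mapped to the
# nearest sample
.windowSamples <- function(times, window) {
  if (is.null(window)) return(seq_along(times))
  if (length(window) != 2L || window[2L] < window[1L])
    stop("window must be c(from, to) in ms with from <= to")
  i1 <- which.min(abs(times - window[1L]))
  i2 <- which.min(abs(times - window[2L]))
  if (i2 < i1) stop("empty analysis window")
  i1:i2
}

#' Map a time window in ms to sample indices
#'
#' @param ds an [ErpDataset-class].
#' @param window `c(from, to)` in ms, inclusive; endpoints are mapped to the
#'   nearest sample.
#' @return integer vector of sample indices.
#' @export
windowSamples <- function(ds, window) .windowSamples(sampleTimes(ds), window)

# dataset restricted/averaged over a window; used by window tests and t-maps
.windowAverageArray <- function(ds, window) {
  idx <- windowSamples(ds, window)
  a <- ds@data[idx, , , , drop = FALSE]
  apply(a, c(2L, 3L, 4L), mean)    # channel x subject x condition
}
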