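# Data screening: baseline correction, zero-phase IIR filtering, and
# MDS-based outlier detection with a Wilks/Mahalanobis auto-select.

#' Baseline correction
#'
#' Subtracts, per channel and per subject x condition matrix, the mean over a
#' baseline window from the whole epoch.
#'
#' @param ds an [ErpDataset-class].
#' @param window `c(from, to)` in ms, inside the recording.
#' @return the corrected dataset.
#' @export
baselineCorrect <- function(ds, window) {
  idx <- windowSamples(ds, window)
  base <- apply(ds@data[idx, , , , drop = FALSE], c(2L, 3L, 4L), mean)
  d <- dim(ds@data)
  ds@data <- ds@data - aperm(array(base, c(d[2:4], d[1L])), c(4L, 1:3))
  ds
}

#' Zero-phase IIR filtering
#'
#' Applies Butterworth high-cut/low-cut band filters and/or a notch filter
#' (default 2nd order) forward and backward, so the phase is untouched. The
#' unfiltered data are retained when `undoable`, and every application is
#' recorded for the filter-specs report.
#'
#' @param ds an [ErpDataset-class].
#' @param lowCut high-pass edge in Hz, or `NULL`.
#' @param highCut low-pass edge in Hz, or `NULL`.
#' @param notch notch center frequency in Hz, or `NULL`.
#' @param order Butterworth order (default 2).
#' @param notchWidthHz half-width of the notch stop band (default 2 Hz).
#' @param undoable keep the original data so [undoFilter()] can restore them.
#' @return the filtered dataset.
#' @export
applyFilter <- function(ds, lowCut = NULL, highCut = NULL, notch = NULL,
                        order = 2, notchWidthHz = 2, undoable = TRUE) {
  fs <- 1000 / ds@dt
  nyq <- fs / 2
  for (f in c(lowCut, highCut, notch))
    if (f >= nyq)
      stop(sprintf("cutoff %g Hz is at or above the Nyquist frequency (%g Hz)",
                   f, nyq))
  filters <- list()
  if (!is.null(lowCut) && !is.null(highCut))
    filters <- c(filters, list(signal::butter(order,
      c(lowCut, highCut) / nyq, type = "pass")))
  else if (!is.null(lowCut))
    filters <- c(filters, list(signal::butter(order, lowCut / nyq,
                                              type = "high")))
  else if (!is.null(highCut))
    filters <- c(filters, list(signal::butter(order, highCut / nyq,
                                              type = "low")))
  if (!is.null(notch))
    filters <- c(filters, list(signal::butter(order,
      c(notch - notchWidthHz, notch + notchWidthHz) / nyq, type = "stop")))
  if (!length(filters)) return(ds)
  orig <- ds@data
  d <- dim(ds@data)
  for (s in seq_len(d[3L])) for (co in seq_len(d[4L])) {
    m <- ds@data[, , s, co]
    for (fl in filters)
      m <- apply(m, 2L, function(x) signal::filtfilt(fl, x))
    ds@data[, , s, co] <- m
  }
  if (undoable) ds@original <- orig
  ds@filterLog <- c(ds@filterLog, list(list(
    low_cut_hz = lowCut, high_cut_hz = highCut, notch_hz = notch,
    order = order, type = "butterworth zero-phase", undoable = undoable)))
  ds
}

#' Undo the last undoable filter
#'
#' @param ds a filtered [ErpDataset-class].
#' @return the dataset with the pre-filter data restored, bit-identically.
#' @export
undoFilter <- function(ds) {
  if (is.null(ds@original)) stop("no undoable filter to undo")
  ds@data <- ds@original
  ds@original <- NULL
  ds@filterLog <- c(ds@filterLog, list(list(type = "undo")))
  ds
}

#' Filter specification report
#'
#' @param ds an [ErpDataset-class].
#' @return list of the filter settings applied so far.
#' @export
filterSpecs <- function(ds) ds@filterLog

#' Between-subject similarity matrix
#'
#' Arranges each subject's data (all channels, time points and conditions) in
#' one vector and computes the matrix of Pearson correlations between these
#' vectors.
#'
#' @param ds an [ErpDataset-class] with at least 3 subjects.
#' @return symmetric subject x subject correlation matrix with unit diagonal.
#' @export
subjectSimilarity <- function(ds) {
  ns <- nSubjects(ds)
  if (ns < 3L) stop("similarity screening needs at least 3 subjects")
  V <- vapply(seq_len(ns), function(s) as.numeric(ds@data[, , s, ]),
              numeric(length(ds@data) / ns))
  sds <- apply(V, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance data vector for subject(s): ",
         paste(ds@subjectIds[sds == 0], collapse = ", "))
  r <- stats::cor(V)
  dimnames(r) <- list(ds@subjectIds, ds@subjectIds)
  r
}

#' Metric MDS embedding of subject similarity
#'
#' Classical (metric) multidimensional scaling of the chord distance
#' d = sqrt(2 (1 - r)), so that Euclidean distances between subjects'
#' coordinates represent their ERP correlation, higher correlations giving
#' smaller distances. Coordinates are centered: the origin is the mean of all
#' subjects' data.
#'
#' @param similarity correlation matrix from [subjectSimilarity()].
#' @param dims embedding dimension (default 2).
#' @return an [MdsEmbedding-class].
#' @export
mdsEmbed <- function(similarity, dims = 2) {
  d <- sqrt(pmax(2 * (1 - similarity), 0))
  fit <- stats::cmdscale(d, k = dims)
  if (ncol(fit) < dims) fit <- cbind(fit, matrix(0, nrow(fit), dims - ncol(fit)))
  fit <- sweep(fit, 2L, colMeans(fit))
  dhat <- as.matrix(stats::dist(fit))
  stress <- sqrt(sum((dhat - d)^2) / max(sum(d^2), .Machine$double.eps))
  rownames(fit) <- rownames(similarity)
  new("MdsEmbedding", coords = fit, stress = stress)
}

#' Auto-select outliers (Wilks / Mahalanobis)
#'
#' Sequential single-outlier testing on the embedded points: the point with
#' the largest sample Mahalanobis distance is tested with the F form of the
#' single-outlier statistic and a Bonferroni-corrected p-value; while it is
#' significant at `alpha` it is flagged, removed, and the test repeats.
#' The flag set is advisory — the decision to exclude stays with the user.
#'
#' @param embedding an [MdsEmbedding-class] (or a coordinate matrix) of at
#'   least 5 subjects.
#' @param alpha significance level of the auto-select (default 0.05).
#' @return integer vector of flagged subject indices (possibly empty), with
#'   attributes `mahalanobis` (distances at first evaluation) and `pValues`.
#' @export
flagOutliers <- function(embedding, alpha = 0.05) {
  X <- if (is(embedding, "MdsEmbedding")) embedding@coords else as.matrix(embedding)
  n0 <- nrow(X)
  p <- ncol(X)
  if (n0 < 5L) stop("outlier auto-select needs at least 5 subjects")
  active <- seq_len(n0)
  flagged <- integer(0)
  pvals <- numeric(0)
  d2first <- NULL
  repeat {
    n <- length(active)
    if (n <= p + 2L) break
    Xa <- X[active, , drop = FALSE]
    mu <- colMeans(Xa)
    S <- stats::cov(Xa)
    d2 <- stats::mahalanobis(Xa, mu, S)
    if (is.null(d2first)) d2first <- stats::setNames(d2, active)
    i <- which.max(d2)
    nd2 <- n * d2[i] / (n - 1)^2          # Wilks' one-outlier statistic
    if (nd2 >= 1) pv <- 0
    else {
      Fv <- (n - p - 1) / p * nd2 / (1 - nd2)
      pv <- min(1, n * stats::pf(Fv, p, n - p - 1, lower.tail = FALSE))
    }
    if (pv < alpha) {
      flagged <- c(flagged, active[i])
      pvals <- c(pvals, pv)
      active <- active[-i]
    } else break
  }
  full <- rep(NA_real_, n0)
  full[as.integer(names(d2first))] <- d2first
  structure(flagged, mahalanobis = full, pValues = pvals)
}

#' Subject screening table
#'
#' One-call screening: similarity, 2-D MDS, Mahalanobis distances and outlier
#' flags as a per-subject table.
#'
#' @param ds an [ErpDataset-class].
#' @param alpha auto-select significance level.
#' @return data frame: id, mds_x, mds_y, mahalanobis, flagged.
#' @export
screenSubjects <- function(ds, alpha = 0.05) {
  emb <- mdsEmbed(subjectSimilarity(ds))
  fl <- tryCatch(flagOutliers(emb, alpha), error = function(e) {
    warning(conditionMessage(e))
    structure(integer(0),
              mahalanobis = rep(NA_real_, nSubjects(ds)), pValues = numeric(0))
  })
  data.frame(id = subjectIds(ds),
             mds_x = emb@coords[, 1L], mds_y = emb@coords[, 2L],
             mahalanobis = attr(fl, "mahalanobis"),
             flagged = seq_len(nSubjects(ds)) %in% as.integer(fl),
             row.names = NULL)
}
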