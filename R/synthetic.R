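# Synthetic ERP datasets with known ground truth: a small set of orthonormal
# source maps activated in sequence, per-condition topographic / amplitude /
# latency effects, per-subject variability, and channel noise.

#' Deterministic quasi-uniform hemispheric montage
#'
#' Places n electrodes on the upper unit hemisphere along a Fibonacci spiral;
#' repeated calls are identical.
#'
#' @param nChannels number of electrodes (>= 2).
#' @return a [Montage-class] with labels `E1..En`.
#' @export
makeMontage <- function(nChannels) {
  if (nChannels < 2L) stop("a montage needs at least 2 channels")
  i <- seq_len(nChannels)
  z <- (i - 0.5) / nChannels            # heights, strictly inside (0, 1)
  r <- sqrt(1 - z^2)
  phi <- i * pi * (3 - sqrt(5))         # golden angle
  montage(cbind(r * cos(phi), r * sin(phi), z), paste0("E", i))
}

#' Orthonormal source maps
#'
#' Generates k mutually orthogonal, zero-mean, unit-GFP scalp maps (random
#' directions orthogonal to the constant vector). Uses the current RNG
#' stream.
#'
#' @param k number of maps (k <= nChannels - 1).
#' @param nChannels channels per map.
#' @return k x nChannels matrix; any pair has spatial correlation 0.
#' @export
makeTemplates <- function(k, nChannels) {
  if (k > nChannels - 1L)
    stop("at most nChannels - 1 zero-mean orthogonal maps exist")
  R <- matrix(stats::rnorm(nChannels * (k + 1L)), nChannels)
  R[, 1L] <- 1                           # project out the constant map
  Q <- qr.Q(qr(R))[, -1L, drop = FALSE]
  t(Q) * sqrt(nChannels)                 # unit population SD per row
}

#' Specify a synthetic ERP study
#'
#' See [SyntheticSpec-class] for the meaning of every field. Defaults emulate
#' a 16-subject, 74-channel, 250-sample (4 ms) study with four conditions in
#' a 2 x 2 within-subject design, seven sequentially active source maps of
#' 5 uV peak amplitude, 1 uV independent channel noise (20\% of signal),
#' 10\% per-subject amplitude variability and 10 ms latency jitter.
#'
#' @param nSubjects,nChannels,nTimepoints,dtMs,t0Ms recording geometry.
#' @param conditionTags condition labels.
#' @param nClasses source maps in the default sequence.
#' @param amplitude peak source amplitude (uV).
#' @param rampMs envelope on/off cosine ramp (ms).
#' @param sequence per-condition activation tables (see class docs) or `NULL`.
#' @param templates optional k x channel template matrix.
#' @param conditionScale,conditionRotationDeg,conditionShiftMs per-condition
#'   effects (named vectors; unnamed conditions default to 1 / 0 / 0).
#' @param rotationClass template index the rotation applies to.
#' @param noiseSd,correlatedNoiseSd noise levels (uV).
#' @param subjectAmpSd,subjectLatencySd subject variability (relative, ms),
#'   drawn per subject and condition.
#' @param boundaryJitterSd per-subject, per-condition, per-activation
#'   onset/offset jitter SD (ms).
#' @param groups optional per-subject group labels.
#' @param seed RNG seed.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nSubjects = 16, nChannels = 74, nTimepoints = 250,
                          dtMs = 4, t0Ms = 0,
                          conditionTags = c("C1", "C2", "F1", "F2"),
                          nClasses = 7, amplitude = 5, rampMs = 20,
                          sequence = NULL, templates = NULL,
                          conditionScale = numeric(0),
                          conditionRotationDeg = numeric(0),
                          conditionShiftMs = numeric(0), rotationClass = 1,
                          noiseSd = 1, correlatedNoiseSd = 0,
                          subjectAmpSd = 0.1, subjectLatencySd = 10,
                          boundaryJitterSd = 0, groups = NULL, seed = 1) {
  fill <- function(x, default) {
    out <- stats::setNames(rep(default, length(conditionTags)), conditionTags)
    out[names(x)] <- x
    out
  }
  new("SyntheticSpec", nSubjects = nSubjects, nChannels = nChannels,
      nTimepoints = nTimepoints, dtMs = dtMs, t0Ms = t0Ms,
      conditionTags = conditionTags, nClasses = nClasses,
      amplitude = amplitude, rampMs = rampMs, sequence = sequence,
      templates = templates, conditionScale = fill(conditionScale, 1),
      conditionRotationDeg = fill(conditionRotationDeg, 0),
      conditionShiftMs = fill(conditionShiftMs, 0),
      rotationClass = rotationClass, noiseSd = noiseSd,
      correlatedNoiseSd = correlatedNoiseSd, subjectAmpSd = subjectAmpSd,
      subjectLatencySd = subjectLatencySd,
      boundaryJitterSd = boundaryJitterSd, groups = groups, seed = seed)
}

#' Canonical simulation scenarios
#'
#' Frozen study definitions used throughout the validation suite:
#' \describe{
#'   \item{`null`}{two conditions, identical generation (no condition
#'     effect): the calibration scenario.}
#'   \item{`amplitude`}{condition B is a x1.5 scaled copy of the same source
#'     configuration: a purely quantitative effect (GFP test territory).}
#'   \item{`duration`}{six sequential classes; the third stays on 80 ms
#'     longer in condition B, the remaining five classes each yielding 16 ms
#'     (time is conserved, so a longer microstate must displace its
#'     neighbours; spreading the displacement thinly keeps the other classes
#'     within their permutation-null spread).}
#' }
#' All scenarios use 12 subjects, 30 channels, 4 ms sampling, 5 uV peak
#' sources with 1 uV channel noise (20\%), 10\% subject amplitude
#' variability and latency jitter (10 ms; 15 ms for `duration`).
#'
#' @param name scenario name.
#' @param seed RNG seed of the generated dataset.
#' @param nSubjects,nChannels overridable geometry.
#' @return a [SyntheticSpec-class].
#' @export
syntheticScenario <- function(name = c("null", "amplitude", "duration"),
                              seed = 1, nSubjects = 12, nChannels = 30) {
  name <- match.arg(name)
  base <- list(nSubjects = nSubjects, nChannels = nChannels,
               conditionTags = c("A", "B"), amplitude = 5, noiseSd = 1,
               subjectAmpSd = 0.1, subjectLatencySd = 10, seed = seed)
  if (name == "null")
    return(do.call(syntheticSpec, c(base, list(nTimepoints = 60,
                                               nClasses = 3, dtMs = 4))))
  if (name == "amplitude")
    return(do.call(syntheticSpec, c(base, list(nTimepoints = 60,
                                               nClasses = 3, dtMs = 4,
                                               conditionScale = c(B = 1.5)))))
  # duration: explicit per-condition sequences over a 600 ms epoch
  segTab <- function(durations) {
    b <- cumsum(c(0, durations))
    data.frame(class = seq_along(durations), onsetMs = b[-length(b)],
               offsetMs = b[-1L], amplitude = 5)
  }
  durA <- c(100, 100, 96, 100, 100, 100)
  durB <- c(84, 84, 176, 84, 84, 84)          # class 3 gains 80 ms
  base$subjectLatencySd <- 15
  do.call(syntheticSpec, c(base, list(
    nTimepoints = 150, dtMs = 4, nClasses = 6, boundaryJitterSd = 30,
    sequence = list(A = segTab(durA), B = segTab(durB)))))
}

# trapezoidal activation envelope with cosine ramps, on [onset, offset] ms
.envelope <- function(times, onset, offset, rampMs) {
  env <- numeric(length(times))
  inside <- times >= onset & times <= offset
  env[inside] <- 1
  if (rampMs > 0) {
    up <- inside & times < onset + rampMs
    down <- inside & times > offset - rampMs
    env[up] <- sin(pi / 2 * (times[up] - onset) / rampMs)^2
    env[down] <- sin(pi / 2 * (offset - times[down]) / rampMs)^2
  }
  env
}

# default sequence: nClasses equal contiguous segments spanning the epoch
.defaultSequence <- function(spec) {
  tEnd <- spec@t0Ms + (spec@nTimepoints - 1) * spec@dtMs
  bounds <- seq(spec@t0Ms, tEnd, length.out = spec@nClasses + 1L)
  tab <- data.frame(class = seq_len(spec@nClasses),
                    onsetMs = bounds[-length(bounds)], offsetMs = bounds[-1L],
                    amplitude = spec@amplitude)
  stats::setNames(rep(list(tab), length(spec@conditionTags)),
                  spec@conditionTags)
}

#' Generate a synthetic ERP dataset with ground truth
#'
#' Builds, per subject and condition, the sum of amplitude-enveloped source
#' templates with the condition effects applied (amplitude scale; rotation of
#' one template within the plane it spans with an extra orthogonal map, a
#' purely topographic effect preserving GFP; latency shift), multiplied by the
#' subject's amplitude factor, shifted by the subject's latency jitter, plus
#' independent and optionally spatially correlated Gaussian channel noise.
#' Everything is average referenced. Identical spec (including seed) gives a
#' bit-identical dataset.
#'
#' @param spec a [SyntheticSpec-class].
#' @return an [ErpDataset-class]; attribute `groundTruth` holds the true
#'   templates, the rotation target map, the per-condition true class label
#'   series (0 where no source is on) and the generating [SyntheticSpec-class].
#' @export
generateDataset <- function(spec) {
  set.seed(spec@seed)
  ns <- spec@nSubjects
  nch <- spec@nChannels
  tp <- spec@nTimepoints
  conds <- spec@conditionTags
  times <- spec@t0Ms + (seq_len(tp) - 1) * spec@dtMs
  seqs <- if (is.null(spec@sequence)) .defaultSequence(spec) else spec@sequence
  k <- max(vapply(seqs, function(s) max(s$class), numeric(1L)))
  if (is.null(spec@templates)) {
    all <- makeTemplates(k + 4L, nch)   # + rotation target + 3 noise bases
    Tm <- all[seq_len(k), , drop = FALSE]
    rotTarget <- all[k + 1L, ]
    noiseBasis <- all[k + 2:4, , drop = FALSE]
  } else {
    Tm <- spec@templates
    extra <- makeTemplates(4L, nch)     # not orthogonal to user templates
    rotTarget <- extra[1L, ]
    noiseBasis <- extra[2:4, , drop = FALSE]
  }
  # per-condition effective templates and envelope tables
  condTemplates <- list()
  trueLabels <- list()
  for (co in conds) {
    Tc <- Tm
    th <- spec@conditionRotationDeg[[co]] * pi / 180
    if (th != 0) {
      rc <- spec@rotationClass
      Tc[rc, ] <- cos(th) * Tm[rc, ] + sin(th) * rotTarget
    }
    condTemplates[[co]] <- Tc
    sq <- seqs[[co]]
    env <- vapply(seq_len(nrow(sq)), function(i)
      .envelope(times, sq$onsetMs[i] + spec@conditionShiftMs[[co]],
                sq$offsetMs[i] + spec@conditionShiftMs[[co]], spec@rampMs),
      numeric(tp))
    lab <- integer(tp)
    on <- apply(env, 1L, max) > 0.05
    lab[on] <- sq$class[apply(env[on, , drop = FALSE], 1L, which.max)]
    trueLabels[[co]] <- lab
  }
  # amplitude and latency variability are drawn per subject AND condition:
  # each condition average is a finite-trial measurement of the subject's
  # response, so its gain and latency wobble independently around the
  # subject's values even in the absence of any condition effect
  ampFac <- 1 + matrix(stats::rnorm(ns * length(conds), 0,
                                    spec@subjectAmpSd), ns)
  latJit <- matrix(stats::rnorm(ns * length(conds), 0,
                                spec@subjectLatencySd), ns)
  arr <- array(NA_real_, c(tp, nch, ns, length(conds)))
  for (s in seq_len(ns)) for (ci in seq_along(conds)) {
    co <- conds[ci]
    sq <- seqs[[co]]
    sig <- matrix(0, tp, nch)
    for (i in seq_len(nrow(sq))) {
      on <- sq$onsetMs[i] + spec@conditionShiftMs[[co]] + latJit[s, ci]
      off <- sq$offsetMs[i] + spec@conditionShiftMs[[co]] + latJit[s, ci]
      if (spec@boundaryJitterSd > 0) {
        on <- on + stats::rnorm(1, 0, spec@boundaryJitterSd)
        off <- off + stats::rnorm(1, 0, spec@boundaryJitterSd)
        if (off < on + 2 * spec@dtMs) off <- on + 2 * spec@dtMs
      }
      env <- .envelope(times, on, off, spec@rampMs)
      sig <- sig + (sq$amplitude[i] * ampFac[s, ci] * env) %o%
        condTemplates[[co]][sq$class[i], ]
    }
    noise <- matrix(stats::rnorm(tp * nch, 0, spec@noiseSd), tp, nch)
    if (spec@correlatedNoiseSd > 0)
      noise <- noise + matrix(stats::rnorm(tp * 3L, 0,
                                           spec@correlatedNoiseSd), tp) %*%
        noiseBasis
    # the amplitude effect scales the whole measured field (all active
    # sources proportionally), so it is exactly removed by normalization
    arr[, , s, ci] <- spec@conditionScale[[co]] * (sig + noise)
  }
  ds <- erpDataset(arr, dtMs = spec@dtMs, t0Ms = spec@t0Ms,
                   subjectIds = sprintf("S%02d", seq_len(ns)),
                   conditionTags = conds, montage = makeMontage(nch))
  ds <- averageReference(ds)
  attr(ds, "groundTruth") <- list(templates = Tm, rotationTarget = rotTarget,
                                  trueLabels = trueLabels, spec = spec)
  ds
}
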