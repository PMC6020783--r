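# Shared fixtures and independent oracles, all built in code.

# all permutations of 1..n (tiny n only)
allPerms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPerms(n - 1L)) for (i in seq_len(n)) {
    out <- c(out, list(append(p, n, after = i - 1L)))
  }
  out
}

# small average-referenced dataset from explicit per-cell matrices
tinyDataset <- function(cells, dtMs = 4, t0Ms = 0) {
  # cells: list (subjects) of lists (conditions) of time x channel matrices
  ds <- erpDataset(cells, dtMs = dtMs, t0Ms = t0Ms)
  averageReference(ds)
}

# random average-referenced dataset
randomDataset <- function(ns = 4, nc = 2, tp = 6, nch = 5, sd = 1,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  arr <- array(rnorm(tp * nch * ns * nc, sd = sd), c(tp, nch, ns, nc))
  averageReference(erpDataset(arr, dtMs = 4, conditionTags = LETTERS[1:nc]))
}

twoLevelDesign <- function(tags = c("A", "B"))
  erpDesign(list(cond = stats::setNames(seq_along(tags), tags)),
            conditionTags = tags)

# Exact TANOVA p for 2 conditions: enumerate all 2^ns within-subject swaps.
# Independent of the package's permutation path (direct arithmetic).
exactTanovaP <- function(ds) {
  a <- ds@data
  d <- dim(a)
  stopifnot(d[4L] == 2L)
  obs <- exhDgfp(a, rep(FALSE, d[3L]))
  stats <- sapply(0:(2^d[3L] - 1L), function(mask) {
    swap <- as.logical(bitwAnd(mask, 2^(seq_len(d[3L]) - 1L)))
    exhDgfp(a, swap)
  })
  # stats: time x combos; exact p per time point, identity included
  rowMeans(stats >= obs)
}

exhDgfp <- function(a, swap) {
  d <- dim(a)
  m1 <- apply(a[, , !swap, 1L, drop = FALSE], c(1L, 2L), sum) +
    apply(a[, , swap, 2L, drop = FALSE], c(1L, 2L), sum)
  m2 <- apply(a[, , !swap, 2L, drop = FALSE], c(1L, 2L), sum) +
    apply(a[, , swap, 1L, drop = FALSE], c(1L, 2L), sum)
  m1 <- m1 / d[3L]; m2 <- m2 / d[3L]
  g <- (m1 + m2) / 2
  sqrt((rowSums((m1 - g)^2) + rowSums((m2 - g)^2)) / d[2L])
}

# Exact TCT p for tiny data: enumerate all channel-permutation combinations
# across subjects (one map per subject). maps: subject x channel matrix.
exactTctP <- function(maps) {
  ns <- nrow(maps); nch <- ncol(maps)
  perms <- allPerms(nch)
  combos <- expand.grid(rep(list(seq_along(perms)), ns))
  gm <- colMeans(maps)
  obs <- sqrt(mean((gm - mean(gm))^2))
  stats <- apply(combos, 1L, function(ix) {
    pm <- sapply(seq_len(ns), function(s) maps[s, perms[[ix[s]]]])
    g <- rowMeans(pm)
    sqrt(mean((g - mean(g))^2))
  })
  mean(stats >= obs)
}
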