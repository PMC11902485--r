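# Shared fixtures, built in code and memoized per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small isointense cohort with jitter and voids (default spec conditions)
smallCohort <- function(n = 4) {
  fixture(paste0("cohort", n), function()
    generateCohort(n, phantomSpec(seed = 301L)))
}

# one easy-regime phantom (well-separated GM/WM)
easyPhantom <- function() {
  fixture("easy", function()
    generatePhantom(phantomSpec(gmWmSeparation = 6, seed = 101L)))
}

# a tiny random multi-channel tensor
randArray <- function(dims, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(prod(dims)), dim = dims)
}

randLabels <- function(dims, nClasses = 4L, seed = 1) {
  set.seed(seed)
  array(sample.int(nClasses, prod(dims), replace = TRUE) - 1L, dim = dims)
}

# Independent brute-force metric oracle: direct voxel-set counting from
# the sensitivity/precision/Dice/accuracy definitions, no confusion matrix.
oracleMetrics <- function(pred, truth, nClasses = 4L) {
  p <- as.integer(pred); y <- as.integer(truth)
  perClass <- lapply(seq_len(nClasses) - 1L, function(cl) {
    gamma <- which(y == cl)          # ground-truth voxel set
    lambda <- which(p == cl)         # assigned voxel set
    inter <- length(intersect(gamma, lambda))
    list(tpr = if (length(gamma)) inter / length(gamma) else NA_real_,
         ppv = if (length(lambda)) inter / length(lambda) else NA_real_,
         dsc = if (length(gamma) + length(lambda))
           2 * inter / (length(gamma) + length(lambda)) else NA_real_)
  })
  list(perClass = perClass, acc = mean(p == y))
}

# Independent quantile oracle: sort + interpolate between order statistics.
oracleQuantile <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Independent piecewise-linear map oracle, one voxel at a time.
oraclePiecewiseMap <- function(v, src, dst) {
  vapply(v, function(x) {
    if (x <= src[1]) return(dst[1])
    if (x >= src[length(src)]) return(dst[length(dst)])
    k <- max(which(src <= x))
    if (src[k + 1] == src[k]) return(dst[k])
    dst[k] + (x - src[k]) / (src[k + 1] - src[k]) * (dst[k + 1] - dst[k])
  }, numeric(1))
}

# Independent iterative neighborhood-median fill oracle.
oracleFill <- function(values, valid) {
  d <- dim(values)
  while (any(!valid)) {
    voids <- which(!valid, arr.ind = TRUE)
    newV <- values; newM <- valid
    progress <- FALSE
    for (i in seq_len(nrow(voids))) {
      s <- voids[i, 1]; r <- voids[i, 2]; cl <- voids[i, 3]
      vals <- c()
      for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
        if (ds == 0 && dr == 0 && dc == 0) next
        ss <- s + ds; rr <- r + dr; cc <- cl + dc
        if (ss >= 1 && ss <= d[1] && rr >= 1 && rr <= d[2] &&
            cc >= 1 && cc <= d[3] && valid[ss, rr, cc])
          vals <- c(vals, values[ss, rr, cc])
      }
      if (length(vals)) {
        newV[s, r, cl] <- stats::median(vals)
        newM[s, r, cl] <- TRUE
        progress <- TRUE
      }
    }
    if (!progress) stop("oracle stuck")
    values <- newV; valid <- newM
  }
  values
}

reportedMetricsPath <- function() {
  system.file("extdata", "iseg2017_reported_metrics.csv", package = "IsoSeg")
}
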