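#' BCa bootstrap confidence interval for a mean
#'
#' Bias-corrected and accelerated percentile bootstrap: resamples with
#' replacement (each resample the size of the original data), computes the
#' bias-correction z0 from the fraction of bootstrap means below the
#' observed mean, and the acceleration from the jackknife skewness of the
#' mean.
#'
#' @param samples numeric vector (>= 2 values).
#' @param nBoot number of bootstrap resamples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed for the resampling.
#' @return list with `low`, `high`, `mean` and `degenerate` (TRUE when all
#'   samples are identical, in which case the interval is a point).
#' @export
bootstrapBcaCi <- function(samples, nBoot = 10000L, level = 0.95,
                           seed = 1L) {
  stopifnot(length(samples) >= 2L, nBoot >= 1000L)
  n <- length(samples)
  obs <- mean(samples)
  if (all(samples == samples[1L]))
    return(list(low = obs, high = obs, mean = obs, degenerate = TRUE))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * nBoot, replace = TRUE), nBoot, n)
  boots <- rowMeans(matrix(samples[idx], nBoot, n))
  prop <- mean(boots < obs) + 0.5 * mean(boots == obs)
  prop <- min(max(prop, 1 / (nBoot + 1)), nBoot / (nBoot + 1))
  z0 <- stats::qnorm(prop)
  jack <- (sum(samples) - samples) / (n - 1)
  dj <- mean(jack) - jack
  acc <- sum(dj^3) / (6 * sum(dj^2)^1.5)
  alpha <- (1 - level) / 2
  za <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + za) / (1 - acc * (z0 + za)))
  ci <- stats::quantile(boots, probs = adj, names = FALSE, type = 6)
  list(low = ci[1L], high = ci[2L], mean = obs, degenerate = FALSE)
}

#' Cohen's d with pooled standard deviation
#'
#' (mean(a) - mean(b)) / s_pooled, where the pooled SD weights the group
#' variances by their degrees of freedom (n - 1).
#'
#' @param a,b numeric vectors with at least 2 values each.
#' @return effect size d.
#' @export
cohensDPooled <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 == 0) stop("zero pooled standard deviation: effect size undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benchmark connectivity criteria I-III
#'
#' Evaluates a cohort of band-averaged connectivity arrays (one per subject)
#' against three criteria for a known dominant driver:
#' I - the driver's total driving, at each subject's driver-peak latency,
#' exceeds the second-largest driver's (lower BCa bound of the per-subject
#' differences > 0);
#' II - the mean driver-peak latency falls in a physiologically plausible
#' window;
#' III - driving from the driver toward each designated target exceeds
#' driving toward its paired control (lower BCa bounds > 0 for every pair).
#' Cohen's d (pooled SD) accompanies every comparison.
#'
#' @param bandConn list of arrays (receiver, sender, time), one per subject,
#'   e.g. from [bandAverage()].
#' @param times time axis in seconds, relative to stimulus onset.
#' @param driverNode index of the expected dominant driver.
#' @param targets integer vector of expected target nodes.
#' @param controls integer vector of control nodes paired with `targets`.
#' @param latencyWindowMs criterion-II window in ms (default c(8, 14)).
#' @param searchWindowMs window in which the driver peak is searched
#'   (default c(0, 50) ms).
#' @param nBoot,seed bootstrap settings.
#' @return data.frame with one row per criterion (criterion III also gets
#'   one row per target/control pair), columns criterion, comparison,
#'   passed, ciLow, ciHigh, effectSizeD, peakLatencyMs.
#' @export
evaluateCriteria <- function(bandConn, times, driverNode, targets, controls,
                             latencyWindowMs = c(8, 14),
                             searchWindowMs = c(0, 50),
                             nBoot = 10000L, seed = 1L) {
  stopifnot(length(bandConn) >= 2L, length(targets) == length(controls))
  win <- which(times * 1000 >= searchWindowMs[1L] &
               times * 1000 <= searchWindowMs[2L])
  if (!length(win)) stop("peak search window lies outside the time axis")
  nsub <- length(bandConn)
  d <- dim(bandConn[[1L]])[1L]

  peakIdx <- integer(nsub)
  drvTD <- secTD <- numeric(nsub)
  tgtDrive <- matrix(0, nsub, length(targets))
  ctlDrive <- matrix(0, nsub, length(controls))
  for (s in seq_len(nsub)) {
    conn <- bandConn[[s]]
    td <- vapply(seq_len(d), function(nd) totalDriving(conn, nd),
                 numeric(dim(conn)[3L]))            # time x node
    peakIdx[s] <- win[which.max(td[win, driverNode])]
    atPeak <- td[peakIdx[s], ]
    drvTD[s] <- atPeak[driverNode]
    secTD[s] <- max(atPeak[-driverNode])
    tgtDrive[s, ] <- conn[targets, driverNode, peakIdx[s]]
    ctlDrive[s, ] <- conn[controls, driverNode, peakIdx[s]]
  }

  rows <- list()
  ci <- bootstrapBcaCi(drvTD - secTD, nBoot = nBoot, seed = seed)
  rows[[1L]] <- data.frame(criterion = "I",
    comparison = sprintf("driver %d vs second-largest", driverNode),
    passed = ci$low > 0, ciLow = ci$low, ciHigh = ci$high,
    effectSizeD = cohensDPooled(drvTD, secTD),
    peakLatencyMs = mean(times[peakIdx]) * 1000)

  lat <- mean(times[peakIdx]) * 1000
  rows[[2L]] <- data.frame(criterion = "II",
    comparison = sprintf("peak latency in [%g, %g] ms",
                         latencyWindowMs[1L], latencyWindowMs[2L]),
    passed = lat >= latencyWindowMs[1L] && lat <= latencyWindowMs[2L],
    ciLow = NA_real_, ciHigh = NA_real_, effectSizeD = NA_real_,
    peakLatencyMs = lat)

  for (j in seq_along(targets)) {
    diffs <- tgtDrive[, j] - ctlDrive[, j]
    ci <- bootstrapBcaCi(diffs, nBoot = nBoot, seed = seed + j)
    rows[[2L + j]] <- data.frame(criterion = "III",
      comparison = sprintf("%d->%d vs %d->%d", driverNode, targets[j],
                           driverNode, controls[j]),
      passed = ci$low > 0, ciLow = ci$low, ciHigh = ci$high,
      effectSizeD = cohensDPooled(tgtDrive[, j], ctlDrive[, j]),
      peakLatencyMs = NA_real_)
  }
  # criterion III as a whole passes when every target/control row passes
  do.call(rbind, rows)
}
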