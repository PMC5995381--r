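#' Goodness-of-fit of a tvMVAR model
#'
#' One-step predictions yhat(n) = sum_r A_r(n) y(n - r) are formed for every
#' n > p over all trials; the relative error variance (REV) is the mean
#' squared prediction error normalized by the variance of the observed
#' signal, and GOF = (1 - REV) * 100. REV is computed per channel and
#' averaged ("overall"); a pooled variant (total error power over total
#' signal power) is reported alongside.
#'
#' For single-trial modeling pass the list of per-trial fits
#' (`fitTvMvar(..., perTrial = TRUE)`): each trial is then scored against its
#' own model and the percentages are averaged across trials.
#'
#' @param trials a [TrialSet-class].
#' @param coeffs a [TVMVARCoefficients-class] fitted to those trials, or a
#'   list of per-trial fits (one per trial).
#' @return list with elements `gof` (overall percent), `perChannel`
#'   (percent per channel) and `pooled` (percent).
#' @export
goodnessOfFit <- function(trials, coeffs) {
  if (is.list(coeffs)) return(.per_trial_metric(trials, coeffs, goodnessOfFit))
  stopifnot(is(trials, "TrialSet"), is(coeffs, "TVMVARCoefficients"))
  if (nChannels(trials) != nChannels(coeffs) ||
      nSamples(trials) != nSamples(coeffs))
    stop("trials and coefficients are dimensionally inconsistent")
  p <- modelOrder(coeffs); d <- nChannels(trials)
  res <- .onestep_sse(.flat_coeffs(coeffs), .as_cube(trials), p)
  sse <- drop(res$sse)
  x <- trialArray(trials)
  v <- vapply(seq_len(d), function(ch) stats::var(as.vector(x[, ch, ])), 0)
  if (any(v == 0)) stop("zero-variance channel: GOF is undefined")
  rev_ch <- (sse / res$n) / v
  list(gof = mean((1 - rev_ch) * 100),
       perChannel = (1 - rev_ch) * 100,
       pooled = (1 - sum(sse) / (res$n * sum(v))) * 100)
}

# score each trial against its own model, average the results
.per_trial_metric <- function(trials, fits, metric, ...) {
  stopifnot(is(trials, "TrialSet"), length(fits) == nTrials(trials))
  x <- trialArray(trials)
  vals <- lapply(seq_along(fits), function(k)
    metric(trialSet(x[k, , , drop = FALSE], samplingRate(trials)),
           fits[[k]], ...))
  if (is.list(vals[[1L]]))
    return(lapply(stats::setNames(names(vals[[1L]]), names(vals[[1L]])),
                  function(nm) Reduce(`+`, lapply(vals, `[[`, nm)) /
                    length(vals)))
  mean(unlist(vals))
}

# coefficient array (N, p, d, d) -> cube (d, dp, N) used by the C++ helpers
.flat_coeffs <- function(coeffs) {
  cf <- coefArray(coeffs)
  N <- dim(cf)[1L]; p <- dim(cf)[2L]; d <- dim(cf)[3L]
  out <- aperm(cf, c(3, 4, 2, 1))   # (receiver, sender, lag, time)
  dim(out) <- c(d, d * p, N)
  out
}

#' Percent consistency of a tvMVAR model
#'
#' Simulates surrogate trials from the fitted coefficients (innovations
#' matched to the per-channel one-step residual standard deviations), then
#' compares the stacked cross-correlation structure (all channel pairs, lags
#' 0..p) of real and surrogate data:
#' consistency = (1 - ||Rs - Rr|| / ||Rr||) * 100 with Euclidean norms.
#'
#' A list of per-trial fits scores each trial against its own model and
#' averages, as in [goodnessOfFit()].
#'
#' @inheritParams goodnessOfFit
#' @param seed integer seed for the surrogate innovations.
#' @return consistency in percent (<= 100; can be negative for very poor
#'   models).
#' @export
percentConsistency <- function(trials, coeffs, seed = 1L) {
  if (is.list(coeffs))
    return(.per_trial_metric(trials, coeffs, percentConsistency,
                             seed = seed))
  stopifnot(is(trials, "TrialSet"), is(coeffs, "TVMVARCoefficients"))
  p <- modelOrder(coeffs)
  res <- .onestep_sse(.flat_coeffs(coeffs), .as_cube(trials), p)
  sdres <- sqrt(drop(res$sse) / res$n)
  surr <- .simulate_with_sd(coeffs, nTrials(trials), sdres, seed)
  Rr <- .xcorr_vector(trialArray(trials), p)
  if (sqrt(sum(Rr^2)) == 0)
    stop("data cross-correlation structure is degenerate (zero norm)")
  Rs <- .xcorr_vector(trialArray(surr), p)
  (1 - sqrt(sum((Rs - Rr)^2)) / sqrt(sum(Rr^2))) * 100
}

# simulate with per-channel innovation sds (percent-consistency surrogates)
.simulate_with_sd <- function(model, nTrials, sds, seed) {
  d <- nChannels(model)
  cf <- coefArray(model)
  set.seed(seed)
  N <- dim(cf)[1L]; p <- dim(cf)[2L]
  burnIn <- 10L * p
  Alist <- vector("list", N)
  for (n in seq_len(N))
    Alist[[n]] <- matrix(aperm(cf[n, , , , drop = FALSE], c(3, 4, 2, 1)), d, d * p)
  A0 <- Alist[[1L]]
  Ntot <- burnIn + N
  out <- array(0, dim = c(nTrials, d, N))
  for (k in seq_len(nTrials)) {
    e <- matrix(stats::rnorm(d * Ntot), d, Ntot) * sds
    x <- matrix(0, d, Ntot)
    x[, seq_len(p)] <- e[, seq_len(p)]
    xlag <- as.vector(x[, p:1, drop = FALSE])
    for (m in (p + 1):Ntot) {
      A <- if (m > burnIn) Alist[[m - burnIn]] else A0
      xn <- drop(A %*% xlag) + e[, m]
      x[, m] <- xn
      xlag <- c(xn, xlag[seq_len(d * (p - 1))])
    }
    out[k, , ] <- x[, (burnIn + 1):Ntot]
  }
  new("TrialSet", data = out, samplingRate = samplingRate(model),
      channelLabels = character(0))
}

# stacked cross-correlations: all ordered channel pairs, lags 0..p, pooled
# across trials
.xcorr_vector <- function(x, p) {
  k <- dim(x)[1L]; d <- dim(x)[2L]; N <- dim(x)[3L]
  out <- NULL
  for (l in 0:p) {
    for (i in seq_len(d)) for (j in seq_len(d)) {
      if (l == 0 && j < i) next              # lag-0 matrix is symmetric
      a <- as.vector(x[, i, (l + 1):N])
      b <- as.vector(x[, j, 1:(N - l)])
      out <- c(out, stats::cor(a, b))
    }
  }
  out
}

#' Miss and false-alarm connectivity errors
#'
#' Normalized mean squared differences between estimated and ground-truth
#' squared PDC: squared differences per time-frequency point are averaged
#' over points and then over edges with a simulated connection (misses) and
#' edges without one (false alarms); both are divided by the mean squared
#' ground-truth PDC on the connected edges.
#'
#' @param est a [TFConnectivity-class] from an estimated model.
#' @param true a [TFConnectivity-class] from the generating coefficients, on
#'   the same grids.
#' @param partition an [EdgePartition-class].
#' @return named vector c(misses =, falseAlarms =).
#' @export
missesFalseAlarms <- function(est, true, partition) {
  stopifnot(is(est, "TFConnectivity"), is(true, "TFConnectivity"),
            is(partition, "EdgePartition"))
  if (!isTRUE(all.equal(frequencies(est), frequencies(true))) ||
      !isTRUE(all.equal(timePoints(est), timePoints(true))))
    stop("estimated and ground-truth connectivity grids differ")
  ce <- partition@connectedEdges; ne <- partition@nullEdges
  if (!nrow(ce))
    stop("empty connected-edge set: normalization is undefined")
  pe <- pdcArray(est); pt <- pdcArray(true)
  edge_mse <- function(edges)
    vapply(seq_len(nrow(edges)), function(r) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      mean((pe[i, j, , ] - pt[i, j, , ])^2)
    }, 0)
  norm <- mean(vapply(seq_len(nrow(ce)), function(r)
    mean(pt[ce[r, 1L], ce[r, 2L], , ]^2), 0))
  if (norm == 0)
    stop("ground-truth PDC is zero on all connected edges; cannot normalize")
  fa <- if (nrow(ne)) mean(edge_mse(ne)) / norm else NA_real_
  c(misses = mean(edge_mse(ce)) / norm, falseAlarms = fa)
}

#' Peak-delay of estimated causal influences
#'
#' For every connected edge, the latency of the maximum of the
#' frequency-averaged PDC time course is located in estimated and
#' ground-truth connectivity; the signed differences (estimated minus true,
#' seconds) are averaged across connected edges. Flat time courses break
#' ties to the earliest index and are flagged.
#'
#' @inheritParams missesFalseAlarms
#' @return list with `delay` (seconds, signed), `perEdge` (seconds) and
#'   `tieFlag` (logical per edge).
#' @export
peakDelay <- function(est, true, partition) {
  stopifnot(is(est, "TFConnectivity"), is(true, "TFConnectivity"),
            is(partition, "EdgePartition"))
  ce <- partition@connectedEdges
  if (!nrow(ce)) stop("no connected edges to evaluate")
  tax <- timePoints(est)
  one <- function(conn, i, j) {
    tc <- apply(pdcArray(conn)[i, j, , , drop = FALSE], 4, mean)
    idx <- which.max(tc)                 # ties -> earliest index
    list(t = tax[idx], tie = sum(tc == max(tc)) > 1L)
  }
  per <- numeric(nrow(ce)); tie <- logical(nrow(ce))
  for (r in seq_len(nrow(ce))) {
    i <- ce[r, 1L]; j <- ce[r, 2L]
    a <- one(est, i, j); b <- one(true, i, j)
    per[r] <- a$t - b$t
    tie[r] <- a$tie || b$tie
  }
  list(delay = mean(per), perEdge = per, tieFlag = tie)
}

#' AIC / BIC model-order selection on pooled stationary fits
#'
#' For every candidate order p a stationary MVAR is fitted by least squares
#' to all trials pooled; with residual covariance Sigma and effective sample
#' count Ne = k (N - p):
#' AIC(p) = ln det(Sigma) + 2 d^2 p / Ne,
#' BIC(p) = ln det(Sigma) + ln(Ne) d^2 p / Ne.
#' An argmin at the upper grid edge is flagged as non-converged.
#'
#' @param trials a [TrialSet-class].
#' @param pGrid integer vector of candidate orders.
#' @return list with `table` (data.frame p, aic, bic), `aicOrder`,
#'   `bicOrder`, and logical flags `aicConverged`, `bicConverged`.
#' @export
informationCriteria <- function(trials, pGrid) {
  stopifnot(is(trials, "TrialSet"))
  pGrid <- sort(unique(as.integer(pGrid)))
  x <- trialArray(trials)
  k <- dim(x)[1L]; d <- dim(x)[2L]; N <- dim(x)[3L]
  if (max(pGrid) >= N) stop("largest candidate order must be < trial length")
  aic <- bic <- numeric(length(pGrid))
  for (gi in seq_along(pGrid)) {
    p <- pGrid[gi]
    ne <- k * (N - p)
    X <- matrix(0, ne, d * p); Yt <- matrix(0, ne, d)
    row <- 0L
    for (tr in seq_len(k)) {
      for (r in seq_len(p))
        X[row + seq_len(N - p), (r - 1) * d + seq_len(d)] <-
          t(x[tr, , (p + 1 - r):(N - r), drop = FALSE][1, , ])
      Yt[row + seq_len(N - p), ] <- t(x[tr, , (p + 1):N, drop = FALSE][1, , ])
      row <- row + (N - p)
    }
    fit <- stats::lm.fit(X, Yt)
    E <- as.matrix(fit$residuals)
    Sig <- crossprod(E) / ne
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev))
      stop("singular residual covariance (rank deficiency)")
    ld <- sum(log(ev))
    aic[gi] <- ld + 2 * d^2 * p / ne
    bic[gi] <- ld + log(ne) * d^2 * p / ne
  }
  list(table = data.frame(p = pGrid, aic = aic, bic = bic),
       aicOrder = pGrid[which.min(aic)],
       bicOrder = pGrid[which.min(bic)],
       aicConverged = which.min(aic) < length(pGrid),
       bicConverged = which.min(bic) < length(pGrid))
}
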