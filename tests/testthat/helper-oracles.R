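# Independent reference implementations used as oracles. These are written
# for clarity, not speed, and deliberately share no code with the package
# internals they check.

# plain-R RLS recursion that materializes C explicitly (pseudo-inverse for
# the gain) and records C at every step
refRls <- function(x, p, lambda) {
  d <- nrow(x); N <- ncol(x); dp <- d * p
  C <- matrix(0, dp, dp)
  A <- matrix(0, d, dp)
  Ahist <- array(0, dim = c(N, d, dp))
  Chist <- vector("list", N)
  for (n in (p + 1):N) {
    X <- matrix(0, 1, dp)
    for (r in 1:p) X[1, (r - 1) * d + 1:d] <- x[, n - r]
    C <- (1 - lambda) * C + crossprod(X)
    K <- X %*% MASS::ginv(C + 1e-8 * mean(diag(C)) * diag(dp))
    Z <- matrix(x[, n], 1, d) - X %*% t(A)
    A <- A + t(Z) %*% K
    Ahist[n, , ] <- A
    Chist[[n]] <- C
  }
  list(A = Ahist, C = Chist)
}

# pooled least-squares MVAR fit on the lag design (the stationary-limit
# oracle); x is channels x samples, possibly a list of trials
refLeastSquares <- function(x, p) {
  if (!is.list(x)) x <- list(x)
  d <- nrow(x[[1]])
  X <- NULL; Y <- NULL
  for (tr in x) {
    N <- ncol(tr)
    for (n in (p + 1):N) {
      row <- numeric(0)
      for (r in 1:p) row <- c(row, tr[, n - r])
      X <- rbind(X, row)
      Y <- rbind(Y, tr[, n])
    }
  }
  t(qr.solve(X, Y))        # d x dp, lag-major columns
}

# scalar-loop evaluation of the spectral coefficient matrix
refSpectral <- function(coeffs, freqs, fs) {
  dm <- dim(coeffs)
  N <- dm[1]; p <- dm[2]; d <- dm[3]
  out <- array(0i, dim = c(d, d, length(freqs), N))
  for (n in 1:N) for (fi in seq_along(freqs)) for (i in 1:d) for (j in 1:d) {
    acc <- if (i == j) 1 + 0i else 0i
    for (r in 1:p)
      acc <- acc - coeffs[n, r, i, j] * exp(-2i * pi * freqs[fi] * r / fs)
    out[i, j, fi, n] <- acc
  }
  out
}

# naive double-loop miss / false-alarm computation
refMissesFa <- function(estPdc, truePdc, connected, nulls) {
  mse_of <- function(edges) {
    tot <- 0
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      s <- 0; cnt <- 0
      for (fi in seq_len(dim(estPdc)[3])) for (n in seq_len(dim(estPdc)[4])) {
        s <- s + (estPdc[i, j, fi, n] - truePdc[i, j, fi, n])^2
        cnt <- cnt + 1
      }
      tot <- tot + s / cnt
    }
    tot / nrow(edges)
  }
  norm <- 0
  for (r in seq_len(nrow(connected))) {
    i <- connected[r, 1]; j <- connected[r, 2]
    norm <- norm + mean(truePdc[i, j, , ]^2)
  }
  norm <- norm / nrow(connected)
  c(mse_of(connected) / norm, mse_of(nulls) / norm)
}

# lag-0 stationary covariance of a constant-coefficient MVAR via fixed-point
# iteration of the discrete Lyapunov equation on the companion form
refLyapunovCov <- function(Alist, sigma2 = 1, iter = 4000) {
  p <- length(Alist); d <- nrow(Alist[[1]])
  Fm <- matrix(0, d * p, d * p)
  for (r in 1:p) Fm[1:d, (r - 1) * d + 1:d] <- Alist[[r]]
  if (p > 1) Fm[(d + 1):(d * p), 1:(d * (p - 1))] <- diag(d * (p - 1))
  Q <- matrix(0, d * p, d * p)
  Q[1:d, 1:d] <- sigma2 * diag(d)
  S <- Q
  for (it in seq_len(iter)) S <- Fm %*% S %*% t(Fm) + Q
  S[1:d, 1:d]
}

# shared small simulated dataset for estimator tests
makeStationaryTrials <- function(d = 2, p = 2, N = 5000, k = 1, seed = 7,
                                 fs = 500) {
  A1 <- matrix(c(1.3, 0.2, 0, 1.1), 2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.64, 0, 0.15, -0.5), 2, 2, byrow = TRUE)
  cf <- array(0, dim = c(N, 2, 2, 2))
  cf[, 1, , ] <- rep(1, N) %o% A1
  cf[, 2, , ] <- rep(1, N) %o% A2
  model <- tvmvarCoefficients(cf, fs)
  simulateTvMvar(model, k, seed = seed)
}
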