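# shared stationary fixture: strongly resonant bivariate AR(2) with weak
# bidirectional coupling, spectral radius ~0.94
statModel <- local({
  th1 <- 2 * pi * 30 / 500; th2 <- 2 * pi * 70 / 500
  A1 <- matrix(c(2 * 0.95 * cos(th1), 0.15, 0, 2 * 0.93 * cos(th2)),
               2, 2, byrow = TRUE)
  A2 <- matrix(c(-0.95^2, 0, 0.1, -0.93^2), 2, 2, byrow = TRUE)
  N <- 5000
  cf <- array(0, dim = c(N, 2, 2, 2))
  cf[, 1, , ] <- rep(1, N) %o% A1
  cf[, 2, , ] <- rep(1, N) %o% A2
  tvmvarCoefficients(cf, 500)
})

terminalA <- function(fit) {
  cf <- coefArray(fit); N <- dim(cf)[1]; p <- dim(cf)[2]; d <- dim(cf)[3]
  matrix(aperm(cf[N, , , , drop = FALSE], c(3, 4, 2, 1)), d, d * p)
}

test_that("estimator configuration enforces its invariants", {
  expect_error(estimatorConfig("rls", orderP = 3, adaptation = 1.5),
               "between")
  expect_error(estimatorConfig("rls", orderP = 3, adaptation = 0),
               "between")
  expect_error(estimatorConfig("mvaar", "multi_trial", orderP = 3,
                               adaptation = 0.02), "RLS and GLKF")
  expect_error(estimatorConfig("dekf", "multi_trial", orderP = 3,
                               adaptation = 0.02), "RLS and GLKF")
  cfg <- estimatorConfig("GLKF", orderP = 5, adaptation = c(0.02, 0.05))
  expect_identical(cfg@algorithm, "glkf")
})

test_that("RLS agrees with the plain-R reference recursion and keeps C PSD", {
  skip_if_not_installed("MASS")
  tr <- makeStationaryTrials(N = 300, seed = 21)
  x <- trialArray(tr)[1, , ]
  ref <- refRls(x / sqrt(mean(x^2)), p = 2, lambda = 0.05)
  fit <- fitRls(tr, estimatorConfig("rls", orderP = 2, adaptation = 0.05))
  cf <- coefArray(fit)
  for (n in c(150L, 300L)) {
    got <- matrix(aperm(cf[n, , , , drop = FALSE], c(3, 4, 2, 1)), 2, 4)
    expect_lt(max(abs(got - ref$A[n, , ])), 1e-4)
  }
  for (n in seq(10, 300, by = 37)) {
    C <- ref$C[[n]]
    expect_lt(max(abs(C - t(C))), 1e-10)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8 * mean(diag(C)))
  }
})

test_that("GLKF single-trial matches a plain-R Kalman mirror with PSD covariances", {
  tr <- makeStationaryTrials(N = 200, seed = 22)
  x <- trialArray(tr)[1, , ]
  xs <- x / sqrt(mean(x^2))
  d <- 2; p <- 2; dp <- d * p; c1 <- 0.03; c2 <- 0.03
  Q <- matrix(0, dp, d); P <- diag(dp); W <- diag(d)
  ref <- array(0, dim = c(200, p, d, d))
  for (n in (p + 1):200) {
    H <- matrix(c(xs[, n - 1], xs[, n - 2]), 1, dp)
    P <- P + c2 * mean(diag(P)) * diag(dp)
    E <- matrix(xs[, n], 1, d) - H %*% Q
    W <- (1 - c1) * W + c1 * crossprod(E)
    wbar <- mean(diag(W))
    S <- drop(H %*% P %*% t(H)) + wbar + 1e-12 * (drop(H %*% P %*% t(H)) + 1)
    K <- P %*% t(H) / S
    Q <- Q + K %*% E
    P <- P - K %*% (H %*% P)
    P <- (P + t(P)) / 2
    expect_gt(min(eigen(P, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
    for (r in 1:p) ref[n, r, , ] <- t(Q[(r - 1) * d + 1:d, ])
  }
  fit <- fitGlkf(tr, estimatorConfig("glkf", orderP = 2, adaptation = 0.03))
  expect_lt(max(abs(coefArray(fit) - ref)), 1e-8)
})

test_that("constant zero signal leaves every estimator at its initialization", {
  tr <- trialSet(array(0, dim = c(2, 2, 80)), 100)
  for (alg in c("rls", "glkf", "mvaar", "dekf")) {
    fit <- fitTvMvar(tr, estimatorConfig(alg, orderP = 2, adaptation = 0.05))
    expect_identical(max(abs(coefArray(fit))), 0)
  }
})

test_that("estimators converge to the pooled least-squares oracle on stationary data", {
  tr1 <- simulateTvMvar(statModel, 1, seed = 7)
  ls1 <- refLeastSquares(trialArray(tr1)[1, , ], p = 2)
  # multi-trial RLS pools five trials of information at lambda = 0.01
  tr5 <- simulateTvMvar(statModel, 5, seed = 7)
  x5 <- lapply(1:5, function(k) trialArray(tr5)[k, , ])
  ls5 <- refLeastSquares(x5, p = 2)
  fit <- fitRls(tr5, estimatorConfig("rls", "multi_trial", orderP = 2,
                                     adaptation = 0.01))
  expect_lt(max(abs(terminalA(fit) - ls5)), 0.05)
  fit <- fitMvaar(tr1, estimatorConfig("mvaar", orderP = 2,
                                       adaptation = 0.01))
  expect_lt(max(abs(terminalA(fit) - ls1)), 0.05)
  fit <- fitGlkf(tr1, estimatorConfig("glkf", orderP = 2,
                                      adaptation = 0.005))
  expect_lt(max(abs(terminalA(fit) - ls1)), 0.1)
  fit <- fitDekf(tr1, estimatorConfig("dekf", orderP = 2,
                                      adaptation = 0.001))
  expect_lt(max(abs(terminalA(fit) - ls1)), 0.1)
})

test_that("MVAAR process noise is the squared constant of the GLKF variant", {
  # V_mvaar(c2) = c2 * V_glkf(c2): on identical data MVAAR at constant c2
  # injects the same process noise as GLKF at constant c2^2
  tr <- makeStationaryTrials(N = 400, seed = 23)
  fm <- fitMvaar(tr, estimatorConfig("mvaar", orderP = 2,
                                     adaptation = c(0.2, 0.2)))
  fg <- fitGlkf(tr, estimatorConfig("glkf", orderP = 2,
                                    adaptation = c(0.2, 0.04)))
  expect_lt(max(abs(coefArray(fm) - coefArray(fg))), 0.15)
  expect_false(identical(coefArray(fm), coefArray(fg)))
})

test_that("fits are deterministic and single-trial lists combine correctly", {
  tr <- makeStationaryTrials(N = 300, k = 3, seed = 24)
  cfg <- estimatorConfig("glkf", orderP = 2, adaptation = 0.02)
  expect_identical(coefArray(fitGlkf(tr, cfg)), coefArray(fitGlkf(tr, cfg)))
  fits <- fitGlkf(tr, cfg, perTrial = TRUE)
  expect_length(fits, 3L)
  avg <- combineSingleTrial(fits)
  expect_equal(coefArray(avg),
               (coefArray(fits[[1]]) + coefArray(fits[[2]]) +
                coefArray(fits[[3]])) / 3)
  # single fit is the identity under combination
  expect_identical(coefArray(combineSingleTrial(fits[1])),
                   coefArray(fits[[1]]))
  # A and -A average to exact zero
  neg <- fits[[1]]
  neg@coeffs <- -coefArray(fits[[1]])
  expect_identical(max(abs(coefArray(combineSingleTrial(list(fits[[1]],
                                                             neg))))), 0)
  # mixed dimensions are rejected
  small <- fitGlkf(makeStationaryTrials(N = 100, seed = 1), cfg,
                   perTrial = TRUE)
  expect_error(combineSingleTrial(c(fits[1], small[1])), "mixed")
})

test_that("averaged-PDC combination keeps rows normalized and reduces variance", {
  model <- twoNodeNetwork(N = 600)
  tr <- addMeasurementNoise(simulateTvMvar(model, 8, seed = 31), 20,
                            seed = 32)
  fits <- fitGlkf(tr, estimatorConfig("glkf", orderP = 8,
                                      adaptation = 0.05), perTrial = TRUE)
  freqs <- seq(0, 500, by = 20)
  conn <- combineSingleTrial(fits, "average_pdc", freqs = freqs)
  expect_s4_class(conn, "TFConnectivity")
  rs <- apply(pdcArray(conn), c(1, 3, 4), sum)
  expect_lt(max(abs(rs - 1)), 1e-10)
  # averaging across trials smooths the per-trial PDC time course
  perTrialPdc <- lapply(fits, function(f) pdcSquared(f, freqs))
  tc <- vapply(perTrialPdc,
               function(p) stats::var(pdcArray(p)[2, 1, 3, ]), 0)
  expect_lt(stats::var(pdcArray(conn)[2, 1, 3, ]), mean(tc))
})

test_that("adaptation speed rises monotonically with the coefficient", {
  N <- 1000
  cf <- array(0, dim = c(N, 1, 2, 2))
  cf[, 1, 1, 1] <- 0.9; cf[, 1, 2, 2] <- 0.9
  cf[501:N, 1, 2, 1] <- 0.5
  mstep <- tvmvarCoefficients(cf, 500)
  tr <- simulateTvMvar(mstep, 10, seed = 31)
  rise <- function(ac) {
    fit <- fitGlkf(tr, estimatorConfig("glkf", "multi_trial", orderP = 1,
                                       adaptation = ac))
    r <- which(coefArray(fit)[500:N, 1, 2, 1] >= 0.45)[1]
    if (is.na(r)) 501 else r     # censored at trial end
  }
  rts <- vapply(c(0.001, 0.003, 0.01, 0.03, 0.1), rise, 0)
  expect_true(all(diff(rts) <= 0))
  expect_lt(rts[5], 60)
  expect_gt(rts[3], rts[5])
})

test_that("multi-trial modeling yields lower-variance trajectories than single trials", {
  tr <- makeStationaryTrials(N = 1500, k = 10, seed = 25)
  cfg <- estimatorConfig("glkf", "multi_trial", orderP = 2,
                         adaptation = 0.02)
  mt <- fitGlkf(tr, cfg)
  st <- fitGlkf(tr, estimatorConfig("glkf", orderP = 2, adaptation = 0.02),
                perTrial = TRUE)
  win <- 800:1500    # steady state
  vMT <- stats::var(coefArray(mt)[win, 1, 1, 1])
  vST <- mean(vapply(st, function(f) stats::var(coefArray(f)[win, 1, 1, 1]),
                     0))
  expect_lt(vMT, vST)
})

test_that("multi-trial GLKF requires at least two trials", {
  tr <- makeStationaryTrials(N = 200, k = 1, seed = 26)
  expect_error(fitGlkf(tr, estimatorConfig("glkf", "multi_trial",
                                           orderP = 2, adaptation = 0.02)),
               "at least 2 trials")
})

test_that("DEKF on a larger network either returns finite output or a clear diagnostic", {
  net <- buildNetwork(list(), d = 6, p = 8, N = 300, fs = 500)
  tr <- addMeasurementNoise(simulateTvMvar(net, 1, seed = 41), 20, seed = 42)
  res <- tryCatch(fitDekf(tr, estimatorConfig("dekf", orderP = 8,
                                              adaptation = 0.05)),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "diverged")
  } else {
    expect_true(all(is.finite(coefArray(res))))
  }
})
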