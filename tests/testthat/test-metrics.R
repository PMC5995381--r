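test_that("GOF is 100 for noise-free data reproduced exactly by the model", {
  # deterministic decaying AR(1): predictions are exact
  N <- 60
  x <- array(0, dim = c(1, 1, N))
  x[1, 1, ] <- 0.9^(0:(N - 1))
  cf <- array(0.9, dim = c(N, 1, 1, 1))
  g <- goodnessOfFit(trialSet(x, 100), tvmvarCoefficients(cf, 100))
  expect_equal(g$gof, 100)
  expect_equal(g$pooled, 100)
})

test_that("GOF is near zero for an all-zero model on zero-mean data", {
  set.seed(2)
  x <- array(stats::rnorm(2 * 2 * 4000), dim = c(2, 2, 4000))
  cf <- array(0, dim = c(4000, 1, 2, 2))
  g <- goodnessOfFit(trialSet(x, 100), tvmvarCoefficients(cf, 100))
  expect_lt(abs(g$gof), 3)
})

test_that("GOF and consistency are invariant under joint global rescaling", {
  tr <- makeStationaryTrials(N = 800, seed = 51)
  fit <- fitGlkf(tr, estimatorConfig("glkf", orderP = 2, adaptation = 0.02))
  scaled <- trialSet(trialArray(tr) * 7.3, samplingRate(tr))
  g1 <- goodnessOfFit(tr, fit); g2 <- goodnessOfFit(scaled, fit)
  expect_equal(g1$gof, g2$gof, tolerance = 1e-10)
  c1 <- percentConsistency(tr, fit, seed = 5)
  # consistency surrogates scale with the residual sd, so the comparison is
  # already scale-free; the statistic must match up to surrogate noise
  c2 <- percentConsistency(scaled, fit, seed = 5)
  expect_equal(c1, c2, tolerance = 0.05)
})

test_that("consistency approaches 100 when the model is the generator", {
  N <- 10000
  th <- 2 * pi * 30 / 500
  cf <- array(0, dim = c(N, 2, 2, 2))
  cf[, 1, 1, 1] <- 2 * 0.9 * cos(th); cf[, 2, 1, 1] <- -0.81
  cf[, 1, 2, 2] <- 0.8
  cf[, 1, 2, 1] <- 0.4
  model <- tvmvarCoefficients(cf, 500)
  tr <- simulateTvMvar(model, 1, seed = 52)
  cons <- percentConsistency(tr, model, seed = 53)
  expect_gt(cons, 90)
  expect_lte(cons, 100)
})

test_that("misses and false alarms match hand arithmetic and the loop oracle", {
  # tiny 2-node instance: one frequency, two time points, hand-listed PDC
  mk <- function(v21, v12) {
    p <- array(0, dim = c(2, 2, 1, 2))
    p[1, 1, 1, ] <- 1 - v12; p[1, 2, 1, ] <- v12
    p[2, 2, 1, ] <- 1 - v21; p[2, 1, 1, ] <- v21
    new("TFConnectivity", pdc = p, spectralMatrix = array(0i, dim = dim(p)),
        freqs = 10, times = c(0, 0.1))
  }
  est <- mk(c(0.5, 0.7), c(0.1, 0.3))
  tru <- mk(c(0.4, 0.9), c(0, 0))
  part <- new("EdgePartition", connectedEdges = rbind(c(2L, 1L)),
              nullEdges = rbind(c(1L, 2L)))
  got <- missesFalseAlarms(est, tru, part)
  norm <- mean(c(0.4, 0.9)^2)
  expect_equal(unname(got["misses"]),
               mean(c(0.1, 0.2)^2) / norm, tolerance = 1e-12)
  expect_equal(unname(got["falseAlarms"]),
               mean(c(0.1, 0.3)^2) / norm, tolerance = 1e-12)
  expect_identical(unname(missesFalseAlarms(tru, tru, part)),
                   c(0, 0))
})

test_that("misses/false alarms equal the naive double-loop oracle on random instances", {
  set.seed(12)
  for (rep in 1:3) {
    d <- 3; Fn <- 4; N <- 6
    raw <- array(stats::runif(d * d * Fn * N), dim = c(d, d, Fn, N))
    norm <- function(a) {
      for (i in 1:d) for (fi in 1:Fn) for (n in 1:N)
        a[i, , fi, n] <- a[i, , fi, n] / sum(a[i, , fi, n])
      a
    }
    mk <- function(a) new("TFConnectivity", pdc = norm(a),
                          spectralMatrix = array(0i, dim = dim(a)),
                          freqs = 1:Fn, times = (1:N) / 10)
    est <- mk(raw); tru <- mk(array(stats::runif(d^2 * Fn * N),
                                    dim = dim(raw)))
    conn <- rbind(c(2L, 1L), c(3L, 1L)); nul <- rbind(c(1L, 2L), c(1L, 3L))
    part <- new("EdgePartition", connectedEdges = conn, nullEdges = nul)
    got <- missesFalseAlarms(est, tru, part)
    want <- refMissesFa(pdcArray(est), pdcArray(tru), conn, nul)
    expect_lt(max(abs(got - want)), 1e-12)
  }
})

test_that("the two-node partition computes misses on 1->2 and false alarms on 2->1", {
  part <- edgePartition(twoNodeNetwork(N = 100))
  expect_identical(part@connectedEdges, rbind(c(2L, 1L)))  # receiver 2, sender 1
  expect_identical(part@nullEdges, rbind(c(1L, 2L)))
})

test_that("peak delay recovers constructed latency shifts", {
  mkbump <- function(center) {
    N <- 500; tt <- seq_len(N)
    bump <- 0.6 * exp(-0.5 * ((tt - center) / 30)^2)
    p <- array(0, dim = c(2, 2, 3, N))
    p[1, 1, , ] <- 1
    for (fi in 1:3) { p[2, 1, fi, ] <- bump; p[2, 2, fi, ] <- 1 - bump }
    new("TFConnectivity", pdc = p, spectralMatrix = array(0i, dim = dim(p)),
        freqs = c(0, 10, 20), times = (tt - 1) / 500)
  }
  part <- new("EdgePartition", connectedEdges = rbind(c(2L, 1L)),
              nullEdges = rbind(c(1L, 2L)))
  pd <- peakDelay(mkbump(425), mkbump(400), part)
  expect_equal(pd$delay, 25 / 500, tolerance = 1e-12)
  expect_false(any(pd$tieFlag))
  expect_identical(peakDelay(mkbump(400), mkbump(400), part)$delay, 0)
})

test_that("flat time courses are tie-broken to the earliest index and flagged", {
  N <- 50
  p <- array(0, dim = c(2, 2, 1, N))
  p[1, 1, 1, ] <- 1; p[2, 1, 1, ] <- 0.5; p[2, 2, 1, ] <- 0.5
  flat <- new("TFConnectivity", pdc = p,
              spectralMatrix = array(0i, dim = dim(p)),
              freqs = 1, times = (seq_len(N) - 1) / 100)
  part <- new("EdgePartition", connectedEdges = rbind(c(2L, 1L)),
              nullEdges = rbind(c(1L, 2L)))
  pd <- peakDelay(flat, flat, part)
  expect_identical(pd$delay, 0)
  expect_true(all(pd$tieFlag))
})

test_that("white noise drives BIC to the smallest candidate order", {
  set.seed(3)
  x <- array(stats::rnorm(5 * 2 * 800), dim = c(5, 2, 800))
  ic <- informationCriteria(trialSet(x, 100), c(1, 2, 4, 8))
  expect_identical(ic$bicOrder, 1L)
  expect_true(ic$bicConverged)
})

test_that("BIC never selects a larger order than AIC on the same fits", {
  tr <- makeStationaryTrials(N = 1500, k = 2, seed = 54)
  ic <- informationCriteria(tr, 1:10)
  expect_lte(ic$bicOrder, ic$aicOrder)
  expect_true(all(diff(ic$table$bic - ic$table$aic) > 0))  # BIC penalty grows faster
})

test_that("rank-deficient data raises a covariance error", {
  set.seed(4)
  v <- matrix(stats::rnorm(400), 1)
  x <- array(0, dim = c(1, 2, 400))
  x[1, 1, ] <- v; x[1, 2, ] <- 2 * v          # perfectly collinear channels
  expect_error(informationCriteria(trialSet(x, 100), 1:3), "singular")
})
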