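#' Build a sweep configuration
#'
#' Describes one generation-estimation-evaluation experiment: a generating
#' network, one swept parameter with its grid, the algorithms to fit, fixed
#' fitting parameters, the number of repetitions, and a seed. The swept
#' parameter is one of "adaptation", "order", "rate" (downsampling target)
#' or "trials".
#'
#' @param network "five_node" or "two_node".
#' @param networkArgs list of arguments for [fiveNodeNetwork()] /
#'   [twoNodeNetwork()].
#' @param sweep name of the swept parameter.
#' @param grid numeric vector of swept values.
#' @param algorithms character vector like c("glkf_mt", "rls_st"); suffix
#'   `_st` / `_mt` selects the trial strategy.
#' @param order fixed model order (ignored when sweeping "order"; when
#'   sweeping "rate" the order is rescaled to keep the lag in ms constant if
#'   `matchLagMs` is set).
#' @param adaptation fixed adaptation coefficient (ignored when sweeping
#'   "adaptation").
#' @param nTrialsSim trials per dataset (ignored when sweeping "trials").
#' @param snrDb measurement-noise SNR in dB.
#' @param repetitions generation-estimation repetitions per grid value.
#' @param freqStep frequency-grid spacing (Hz) for the PDC evaluation.
#' @param fMax upper frequency limit of the PDC evaluation (Hz); default is
#'   the Nyquist frequency. Rate sweeps use a fixed limit (e.g. the Nyquist
#'   at the lowest rate) so grids stay comparable across rates.
#' @param matchLagMs when sweeping "rate": lag in ms that the model order
#'   must match at every rate.
#' @param metrics metrics to compute, subset of c("gof", "consistency",
#'   "misses", "false_alarms", "peak_delay").
#' @param seed base seed; repetition r of grid value g uses a seed derived
#'   from it deterministically.
#' @return a `"sweepConfig"` list.
#' @export
sweepConfig <- function(network = c("two_node", "five_node"),
                        networkArgs = list(),
                        sweep = c("adaptation", "order", "rate", "trials"),
                        grid, algorithms = c("rls_st", "rls_mt", "glkf_st",
                                             "glkf_mt", "mvaar_st",
                                             "dekf_st"),
                        order = 3L, adaptation = 0.02, nTrialsSim = 20L,
                        snrDb = 20, repetitions = 50L, freqStep = 5,
                        fMax = NULL, matchLagMs = NULL,
                        metrics = c("gof", "misses", "false_alarms",
                                    "peak_delay"),
                        seed = 1L) {
  cfg <- list(network = match.arg(network), networkArgs = networkArgs,
              sweep = match.arg(sweep), grid = grid,
              algorithms = algorithms, order = as.integer(order),
              adaptation = adaptation, nTrialsSim = as.integer(nTrialsSim),
              snrDb = snrDb, repetitions = as.integer(repetitions),
              freqStep = freqStep, fMax = fMax, matchLagMs = matchLagMs,
              metrics = metrics, seed = as.integer(seed))
  if (!length(cfg$grid)) stop("empty sweep grid")
  known <- c("rls_st", "rls_mt", "glkf_st", "glkf_mt", "mvaar_st", "dekf_st")
  if (!all(cfg$algorithms %in% known))
    stop("unknown algorithm label(s): ",
         paste(setdiff(cfg$algorithms, known), collapse = ", "))
  class(cfg) <- "sweepConfig"
  cfg
}

#' Read a sweep configuration from JSON or YAML
#'
#' @param path file ending in .json, .yaml or .yml.
#' @return a `"sweepConfig"` list.
#' @export
readSweepConfig <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = , yml = yaml::read_yaml(path),
    stop("config must be a .json, .yaml or .yml file"))
  do.call(sweepConfig, lst)
}

.algo_config <- function(label, order, adaptation) {
  parts <- strsplit(label, "_", fixed = TRUE)[[1L]]
  estimatorConfig(parts[1L],
                  if (parts[2L] == "mt") "multi_trial" else "single_trial",
                  orderP = order, adaptation = adaptation)
}

#' Run a generation-estimation-evaluation sweep
#'
#' For every grid value and repetition: simulate the configured network, add
#' measurement noise, fit every configured algorithm, compute the requested
#' metrics against the ground truth, and collect everything in a long
#' table. Deterministic given the config seed; fits that diverge are
#' recorded as flagged rows (metric NA, diverged TRUE), not crashes.
#'
#' @param config a [sweepConfig()].
#' @return data.frame with columns algorithm, strategy, sweep, value,
#'   repetition, metric, result, diverged.
#' @export
runSweep <- function(config) {
  stopifnot(inherits(config, "sweepConfig"))
  rows <- list()
  for (gi in seq_along(config$grid)) {
    g <- config$grid[gi]
    for (rep in seq_len(config$repetitions)) {
      seed <- config$seed + 7919L * (gi - 1L) + rep
      rows[[length(rows) + 1L]] <- .sweep_cell(config, g, rep, seed)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.sweep_cell <- function(config, g, rep, seed) {
  na <- config$networkArgs
  nTr <- if (config$sweep == "trials") as.integer(g) else config$nTrialsSim
  model <- switch(config$network,
                  two_node = do.call(twoNodeNetwork, na),
                  five_node = do.call(fiveNodeNetwork, na))
  trials <- simulateTvMvar(model, nTr, seed = seed)
  trials <- addMeasurementNoise(trials, config$snrDb, seed = seed + 1L)

  fs <- samplingRate(trials)
  order <- config$order
  if (config$sweep == "order") order <- as.integer(g)
  if (config$sweep == "rate") {
    trials <- antialiasDownsample(trials, g)
    fs <- g
    if (!is.null(config$matchLagMs))
      order <- max(1L, as.integer(round(config$matchLagMs * g / 1000)))
    # decimate the ground truth coefficients' time axis for the comparison
  }
  ac <- if (config$sweep == "adaptation") g else config$adaptation

  fTop <- if (is.null(config$fMax)) fs / 2 else min(config$fMax, fs / 2)
  freqs <- seq(0, fTop, by = config$freqStep)
  part <- edgePartition(model)
  needPdc <- any(c("misses", "false_alarms", "peak_delay") %in%
                 config$metrics)
  truePdc <- NULL
  if (needPdc) {
    trueModel <- if (config$sweep == "rate") .decimate_model(model, fs)
                 else model
    truePdc <- pdcSquared(trueModel, freqs)
  }

  out <- list()
  for (label in config$algorithms) {
    cfgA <- .algo_config(label, order, ac)
    strategy <- cfgA@strategy
    st <- strategy == "single_trial"
    # single-trial: keep the per-trial fits (model quality is scored per
    # trial against its own model), combine them for the PDC metrics
    raw <- tryCatch(fitTvMvar(trials, cfgA, perTrial = st),
                    error = function(e) e)
    diverged <- inherits(raw, "error")
    vals <- stats::setNames(rep(NA_real_, length(config$metrics)),
                            config$metrics)
    if (!diverged) {
      fit <- if (st) combineSingleTrial(raw) else raw
      quality <- if (st) raw else fit
      if ("gof" %in% config$metrics)
        vals["gof"] <- goodnessOfFit(trials, quality)$gof
      if ("consistency" %in% config$metrics)
        vals["consistency"] <- percentConsistency(trials, quality,
                                                  seed = seed + 2L)
      if (needPdc) {
        estPdc <- pdcSquared(fit, freqs)
        if (any(c("misses", "false_alarms") %in% config$metrics)) {
          mf <- missesFalseAlarms(estPdc, truePdc, part)
          if ("misses" %in% config$metrics) vals["misses"] <- mf["misses"]
          if ("false_alarms" %in% config$metrics)
            vals["false_alarms"] <- mf["falseAlarms"]
        }
        if ("peak_delay" %in% config$metrics)
          vals["peak_delay"] <- peakDelay(estPdc, truePdc, part)$delay
      }
    }
    out[[label]] <- data.frame(
      algorithm = sub("_(st|mt)$", "", label),
      strategy = if (strategy == "multi_trial") "MT" else "ST",
      sweep = config$sweep, value = g, repetition = rep,
      metric = config$metrics, result = unname(vals), diverged = diverged)
  }
  do.call(rbind, out)
}

# ground-truth model on a decimated time axis (sample-and-hold of the
# coefficient waveforms; the lag structure is re-expressed at the new rate)
.decimate_model <- function(model, targetFs) {
  fs <- samplingRate(model)
  q <- as.integer(round(fs / targetFs))
  cf <- coefArray(model)
  N <- dim(cf)[1L]; p <- dim(cf)[2L]; d <- dim(cf)[3L]
  keep <- seq(1L, by = q, length.out = N %/% q)
  pNew <- max(1L, as.integer(ceiling(p / q)))
  out <- array(0, dim = c(length(keep), pNew, d, d))
  for (r in seq_len(p)) {
    rNew <- max(1L, as.integer(round(r / q)))
    out[, rNew, , ] <- out[, rNew, , ] + cf[keep, r, , ]
  }
  new("TVMVARCoefficients", coeffs = out, samplingRate = targetFs)
}
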