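#' Write a TrialSet to a self-describing text container
#'
#' Serializes a [TrialSet-class] to a single CSV file whose leading comment
#' lines (prefix `#`) carry the sampling rate, dimensions and channel
#' labels, followed by a long-format table (trial, channel, sample, value).
#' Values are printed with 17 significant digits, so a write/read round trip
#' is bit-exact for float64 payloads.
#'
#' @param trials a [TrialSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTrialSet <- function(trials, path) {
  stopifnot(is(trials, "TrialSet"))
  x <- trialArray(trials)
  k <- dim(x)[1L]; d <- dim(x)[2L]; N <- dim(x)[3L]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# tvmvar TrialSet v1"),
    sprintf("# fs: %s", sprintf("%.17g", samplingRate(trials))),
    sprintf("# dims: %d,%d,%d", k, d, N),
    sprintf("# labels: %s", paste(channelLabels(trials), collapse = ",")),
    "trial,channel,sample,value"), con)
  idx <- expand.grid(sample = seq_len(N), channel = seq_len(d),
                     trial = seq_len(k))
  vals <- sprintf("%.17g", aperm(x, c(3, 2, 1)))
  writeLines(paste(idx$trial, idx$channel, idx$sample, vals, sep = ","), con)
  invisible(path)
}

#' Read a TrialSet written by [writeTrialSet()]
#'
#' @param path file path.
#' @return a [TrialSet-class].
#' @export
readTrialSet <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(name) {
    line <- grep(sprintf("^# %s:", name), hdr, value = TRUE)
    if (!length(line))
      stop(sprintf("not a TrialSet container: missing '%s' header", name))
    trimws(sub(sprintf("^# %s:", name), "", line[1L]))
  }
  fs <- as.numeric(get_field("fs"))
  dims <- as.integer(strsplit(get_field("dims"), ",")[[1L]])
  labels <- get_field("labels")
  labels <- if (nzchar(labels)) strsplit(labels, ",")[[1L]] else character(0)
  tab <- utils::read.csv(path, comment.char = "#")
  if (!all(c("trial", "channel", "sample", "value") %in% names(tab)))
    stop("not a TrialSet container: missing data columns")
  if (any(!is.finite(tab$value)))
    stop("TrialSet payload contains non-finite values")
  x <- array(0, dim = dims)
  x[cbind(tab$trial, tab$channel, tab$sample)] <- tab$value
  new("TrialSet", data = x, samplingRate = fs, channelLabels = labels)
}

#' Export band-averaged connectivity to long-format CSV
#'
#' @param band array (receiver, sender, time) from [bandAverage()].
#' @param times time axis in seconds.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeBandCsv <- function(band, times, path) {
  d <- dim(band)[1L]
  idx <- expand.grid(receiver = seq_len(d), sender = seq_len(d),
                     time = times)
  idx$value <- as.vector(band)
  utils::write.csv(idx[, c("time", "sender", "receiver", "value")], path,
                   row.names = FALSE)
  invisible(path)
}
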