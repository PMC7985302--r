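## Plain-text serialisation: recordings and trial sets as CSV, estimates as
## JSON/CSV, simulator configs as key=value files, query batches as JSON.

#' Read and write recordings as CSV
#'
#' Wide format: a `time` column (seconds, uniform spacing encodes fs)
#' followed by one column per channel.
#'
#' @param rec a [MultiChannelRecording-class].
#' @param path file path.
#' @return `readRecordingCSV` returns a [MultiChannelRecording-class];
#'   `writeRecordingCSV` returns `path` invisibly.
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "MultiChannelRecording"))
  df <- data.frame(time = (seq_len(nSamples(rec)) - 1) / rec@fs,
                   t(rec@data), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecordingCSV
#' @export
readRecordingCSV <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (!"time" %in% names(df)) stop("missing 'time' column", call. = FALSE)
  dt <- diff(df$time)
  if (length(dt) < 1L || max(abs(dt - dt[1L])) > 1e-8 * dt[1L])
    stop("time column must be uniformly spaced", call. = FALSE)
  chans <- setdiff(names(df), "time")
  multiChannelRecording(t(as.matrix(df[chans])), fs = 1 / dt[1L],
                        channelNames = chans)
}

#' Read and write trial sets as long-format CSV
#'
#' Columns: trial, channel, time, value. Intended for small cases; large
#' trial sets should be regenerated from their simulator config and seed.
#'
#' @param ts a [TrialSet-class].
#' @param path file path.
#' @export
writeTrialSetCSV <- function(ts, path) {
  stopifnot(is(ts, "TrialSet"))
  d <- dim(ts@data)
  tgrid <- (seq_len(d[3L]) - 1) / ts@fs
  df <- expand.grid(time = tgrid, channel = ts@channelNames,
                    trial = seq_len(d[1L]), stringsAsFactors = FALSE)
  df$value <- as.vector(aperm(ts@data, c(3L, 2L, 1L)))
  write.csv(df[c("trial", "channel", "time", "value")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname writeTrialSetCSV
#' @export
readTrialSetCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  trials <- sort(unique(df$trial))
  chans <- unique(df$channel)
  times <- sort(unique(df$time))
  fs <- 1 / diff(times)[1L]
  arr <- array(NA_real_, dim = c(length(trials), length(chans),
                                 length(times)))
  df <- df[order(df$trial, match(df$channel, chans), df$time), ]
  arr[] <- aperm(array(df$value, dim = c(length(times), length(chans),
                                         length(trials))), c(3L, 2L, 1L))
  trialSet(arr, fs = fs, channelNames = chans)
}

#' Parse a flat key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored;
#' numeric-looking values are coerced to numeric.
#'
#' @param path file path.
#' @return Named list.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line: ", ln, call. = FALSE)
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Serialise a CouplingEstimate to JSON for audit
#'
#' Records the value, bootstrap trace, estimator identity, selections and
#' seed so the estimate can be reconstructed.
#'
#' @param est a [CouplingEstimate-class].
#' @param path file path.
#' @export
writeCouplingEstimateJSON <- function(est, path) {
  stopifnot(is(est, "CouplingEstimate"))
  selTxt <- lapply(est@selections, function(s)
    list(channels = s@channels, frequencies = s@frequencies))
  obj <- list(value = est@value, iterations = est@iterations,
              estimator = est@estimator, terms = as.list(est@terms),
              selections = selTxt, seed = est@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a batch of PGC/MIF queries from JSON
#'
#' The file holds a list of objects with fields `x`, `y` (each
#' `{channels, frequencies}`), optional `cond`, and optional `estimator`,
#' `iterations`, `k`, `seed`.
#'
#' @param path file path.
#' @return List of [pgcQuery()] objects.
#' @export
readQueriesJSON <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  lapply(raw, function(q) {
    mkSel <- function(s) incrementSelection(s$channels, s$frequencies)
    pgcQuery(mkSel(q$x), mkSel(q$y),
             cond = if (!is.null(q$cond)) mkSel(q$cond) else NULL,
             estimator = if (!is.null(q$estimator)) q$estimator else "auto",
             bspec = bootstrapSpec(
               iterations = if (!is.null(q$iterations)) q$iterations else 20),
             k = if (!is.null(q$k)) q$k else 5,
             seed = if (!is.null(q$seed)) q$seed else 1)
  })
}

#' Read and write spectral sample sets as long-format CSV
#'
#' Columns: channel, frequency, window, re, im, plus the window length
#' recorded in a `windowLength` column (constant).
#'
#' @param sss a [SpectralSampleSet-class].
#' @param path file path.
#' @export
writeSampleSetCSV <- function(sss, path) {
  stopifnot(is(sss, "SpectralSampleSet"))
  rows <- list()
  for (ch in sss@channels) for (f in sss@frequencies[[ch]]) {
    m <- incrementSamples(sss, ch, f)
    rows[[length(rows) + 1L]] <- data.frame(
      channel = ch, frequency = f, window = seq_len(nrow(m)),
      re = m[, 1L], im = m[, 2L], windowLength = sss@windowLength)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSampleSetCSV
#' @export
readSampleSetCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  wl <- df$windowLength[1L]
  chans <- unique(df$channel)
  samples <- list(); freqs <- stats::setNames(vector("list", length(chans)), chans)
  for (ch in chans) {
    sub <- df[df$channel == ch, ]
    for (f in sort(unique(sub$frequency))) {
      s2 <- sub[sub$frequency == f, ]
      s2 <- s2[order(s2$window), ]
      samples[[.incKey(ch, f)]] <- cbind(Re = s2$re, Im = s2$im)
      freqs[[ch]] <- c(freqs[[ch]], f)
    }
  }
  .newSpectralSampleSet(samples, windowLength = wl, freqResolution = 1 / wl,
                        channels = chans, frequencies = freqs)
}
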