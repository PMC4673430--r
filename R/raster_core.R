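#' Voltage recording container
#'
#' Holds a multichannel extracellular voltage trace as a dense channels x
#' time matrix sampled at `sampling_rate_hz`. The downstream MUA pipeline
#' expects 1 kHz data (one column per millisecond); recordings acquired at a
#' higher rate should first pass through [downsample_recording()].
#'
#' @param signal numeric matrix, channels x samples, in microvolts.
#' @param channel_ids identifiers, one per row; defaults to `0:(n-1)`.
#' @param sampling_rate_hz sampling rate of the columns, in Hz.
#' @return an object of class `voltage_recording`.
#' @export
voltage_recording <- function(signal, channel_ids = NULL,
                              sampling_rate_hz = 1000) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("`signal` must be a numeric matrix (channels x time)")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number")
  }
  channel_ids <- channel_ids %||% (seq_len(nrow(signal)) - 1L)
  if (length(channel_ids) != nrow(signal)) {
    stop("`channel_ids` must have one entry per channel")
  }
  structure(
    list(signal = signal, channel_ids = as.character(channel_ids),
         sampling_rate_hz = sampling_rate_hz),
    class = "voltage_recording"
  )
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("<voltage_recording> %d channels x %d samples @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate_hz))
  invisible(x)
}

#' Downsample a voltage recording to the analysis rate
#'
#' Reduces the sampling rate by an integer factor (default 5, e.g. 5 kHz
#' acquisition down to the 1 kHz analysis rate). `"subsample"` keeps every
#' `factor`-th sample; `"mean"` averages each block of `factor` samples.
#'
#' @param rec a [voltage_recording()].
#' @param factor positive integer decimation factor.
#' @param method `"subsample"` (default) or `"mean"`.
#' @return a [voltage_recording()] at `sampling_rate_hz / factor`.
#' @export
downsample_recording <- function(rec, factor = 5,
                                 method = c("subsample", "mean")) {
  stopifnot(inherits(rec, "voltage_recording"))
  method <- match.arg(method)
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1")
  if (factor == 1L) return(rec)
  n_keep <- floor(ncol(rec$signal) / factor)
  if (n_keep < 1L) stop("recording shorter than one decimation block")
  sig <- if (method == "subsample") {
    rec$signal[, seq_len(n_keep) * factor - factor + 1L, drop = FALSE]
  } else {
    grp <- rep(seq_len(n_keep), each = factor)
    t(rowsum(t(rec$signal[, seq_len(n_keep * factor), drop = FALSE]), grp)) /
      factor
  }
  voltage_recording(sig, rec$channel_ids, rec$sampling_rate_hz / factor)
}

#' Binary MUA raster
#'
#' Channels x milliseconds 0/1 event matrix produced by threshold crossing
#' of the filtered voltage (or by the branching simulator).
#'
#' @param events 0/1 matrix, channels x time bins (1 ms).
#' @param channel_ids identifiers, one per row.
#' @param duration_ms recording duration; defaults to `ncol(events)`.
#' @return an object of class `mua_raster`.
#' @export
mua_raster <- function(events, channel_ids = NULL, duration_ms = NULL) {
  if (!is_binary_matrix(events)) stop("`events` must be a 0/1 matrix")
  storage.mode(events) <- "integer"
  duration_ms <- duration_ms %||% ncol(events)
  if (duration_ms != ncol(events)) {
    stop("`duration_ms` must equal the number of columns")
  }
  channel_ids <- channel_ids %||% (seq_len(nrow(events)) - 1L)
  if (length(channel_ids) != nrow(events)) {
    stop("`channel_ids` must have one entry per channel")
  }
  structure(
    list(events = events, channel_ids = as.character(channel_ids),
         duration_ms = as.integer(duration_ms)),
    class = "mua_raster"
  )
}

#' @export
print.mua_raster <- function(x, ...) {
  cat(sprintf("<mua_raster> %d channels x %d ms, %d events\n",
              nrow(x$events), x$duration_ms, sum(x$events)))
  invisible(x)
}

#' Per-channel mean firing rate in Hz
#'
#' @param raster an [mua_raster()].
#' @return named numeric vector, events per second over the full duration.
#' @export
channel_rates <- function(raster) {
  stopifnot(inherits(raster, "mua_raster"))
  r <- rowSums(raster$events) / (raster$duration_ms / 1000)
  names(r) <- raster$channel_ids
  r
}

#' Read an MUA raster from disk
#'
#' Two plain-text dialects are supported. `event_list`: a two-column CSV with
#' header `channel,time_ms`, 0-based channel indices and integer millisecond
#' times. `dense`: a header line of channel ids followed by one
#' comma-separated 0/1 row per channel.
#'
#' @param path file to read.
#' @param format `"event_list"` or `"dense"`.
#' @param n_channels,duration_ms override the shape inferred from the data
#'   (`max(channel)+1` channels, `max(time)+1` ms); required to represent
#'   trailing silent channels/time in event lists.
#' @return an [mua_raster()]. Duplicate (channel, time) pairs collapse to a
#'   single event with a warning.
#' @seealso [save_raster()]
#' @export
load_raster <- function(path, format = c("event_list", "dense"),
                        n_channels = NULL, duration_ms = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "event_list") {
    lines <- readLines(path)
    if (length(lines) == 0L || lines[1] != "channel,time_ms") {
      stop("parse error at line 1: expected header 'channel,time_ms'")
    }
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) > 0L) {
      parts <- strsplit(body, ",", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) != 2L)
      if (length(bad) > 0L) {
        stop("parse error at line ", bad[1] + 1L, ": expected 'channel,time_ms'")
      }
      ch <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
      tm <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
      bad <- which(is.na(ch) | is.na(tm) | ch < 0L | tm < 0L)
      if (length(bad) > 0L) {
        stop("parse error at line ", bad[1] + 1L,
             ": channel and time_ms must be non-negative integers")
      }
    } else {
      ch <- integer(0)
      tm <- integer(0)
    }
    n_channels <- as.integer(n_channels %||% (max(ch, -1L) + 1L))
    duration_ms <- as.integer(duration_ms %||% (max(tm, -1L) + 1L))
    if (n_channels < 1L || duration_ms < 1L) {
      stop("empty event list needs explicit `n_channels` and `duration_ms`")
    }
    if (length(ch) > 0L && max(ch) >= n_channels) {
      stop("channel index exceeds declared `n_channels`")
    }
    if (length(tm) > 0L && max(tm) >= duration_ms) {
      stop("event time exceeds declared `duration_ms`")
    }
    key <- ch * as.double(duration_ms) + tm
    if (anyDuplicated(key)) {
      warning("duplicate (channel, time) pairs collapsed to single events")
      keep <- !duplicated(key)
      ch <- ch[keep]
      tm <- tm[keep]
    }
    m <- matrix(0L, n_channels, duration_ms)
    m[cbind(ch + 1L, tm + 1L)] <- 1L
    mua_raster(m, seq_len(n_channels) - 1L, duration_ms)
  } else {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("parse error: dense file needs header + rows")
    ids <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    rows <- strsplit(lines[-1], ",", fixed = TRUE)
    if (length(rows) != length(ids)) {
      stop("parse error: ", length(ids), " channel ids but ",
           length(rows), " data rows")
    }
    widths <- vapply(rows, length, 1L)
    if (length(unique(widths)) != 1L) {
      stop("parse error at line ", which(widths != widths[1])[1] + 1L,
           ": ragged row width")
    }
    m <- matrix(suppressWarnings(as.integer(unlist(rows))),
                nrow = length(ids), byrow = TRUE)
    if (anyNA(m) || !all(m %in% c(0L, 1L))) {
      stop("parse error: dense raster entries must be 0 or 1")
    }
    mua_raster(m, ids, ncol(m))
  }
}

#' Write an MUA raster to disk
#'
#' Inverse of [load_raster()]; the round trip is bit-exact for both dialects.
#'
#' @param raster an [mua_raster()].
#' @param path destination file.
#' @param format `"event_list"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
save_raster <- function(raster, path, format = c("event_list", "dense")) {
  stopifnot(inherits(raster, "mua_raster"))
  format <- match.arg(format)
  if (format == "event_list") {
    idx <- which(raster$events != 0L, arr.ind = TRUE)
    ord <- order(idx[, 1L], idx[, 2L])
    lines <- c("channel,time_ms",
               sprintf("%d,%d", idx[ord, 1L] - 1L, idx[ord, 2L] - 1L))
    writeLines(lines, path)
  } else {
    body <- apply(raster$events, 1L, paste, collapse = ",")
    writeLines(c(paste(raster$channel_ids, collapse = ","), body), path)
  }
  invisible(path)
}

#' High-pass filter a recording
#'
#' Per-channel Butterworth high-pass (default 2nd order, 200 Hz cut-off) to
#' isolate the fast extracellular deflections that carry multi-unit activity.
#' The default is a causal forward pass, matching online acquisition;
#' `zero_phase = TRUE` applies forward-backward filtering instead.
#'
#' @param rec a [voltage_recording()] at its final analysis rate.
#' @param cutoff_hz cut-off frequency; must be below Nyquist.
#' @param order filter order.
#' @param zero_phase use `signal::filtfilt()` instead of a causal pass.
#' @return the filtered [voltage_recording()].
#' @export
highpass_filter <- function(rec, cutoff_hz = 200, order = 2,
                            zero_phase = FALSE) {
  stopifnot(inherits(rec, "voltage_recording"))
  nyquist <- rec$sampling_rate_hz / 2
  if (cutoff_hz >= nyquist) {
    stop("`cutoff_hz` must be below the Nyquist frequency (",
         nyquist, " Hz)")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "high")
  run <- if (zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- t(apply(rec$signal, 1L, run))
  voltage_recording(out, rec$channel_ids, rec$sampling_rate_hz)
}

#' Detect multi-unit activity by negative threshold crossing
#'
#' Sets a per-channel negative threshold from that channel's noise level and
#' marks a 1 at every millisecond where the filtered voltage is at or below
#' it. The default noise estimate is the robust
#' `median(|x|)/0.6745` (an SD estimate insensitive to the spikes
#' themselves); `noise = "sd"` uses the plain standard deviation. Crossings
#' within `dead_time_ms` of an accepted event are suppressed so a single
#' waveform is not counted multiple times; `dead_time_ms = 0` disables this.
#'
#' @param rec a high-pass filtered [voltage_recording()] at 1 kHz.
#' @param k positive threshold multiplier; the threshold is `-k * noise_i`.
#' @param dead_time_ms refractory suppression window after each event.
#' @param noise `"mad"` (default) or `"sd"`.
#' @return an [mua_raster()]; per-channel thresholds are attached as the
#'   `thresholds` element.
#' @export
detect_mua <- function(rec, k = 5, dead_time_ms = 2, noise = c("mad", "sd")) {
  stopifnot(inherits(rec, "voltage_recording"))
  noise <- match.arg(noise)
  if (!is.numeric(k) || k <= 0) stop("`k` must be positive")
  dead_time_ms <- as.integer(dead_time_ms)
  n <- nrow(rec$signal)
  t_ms <- ncol(rec$signal)
  theta <- numeric(n)
  events <- matrix(0L, n, t_ms)
  for (i in seq_len(n)) {
    x <- rec$signal[i, ]
    sigma_i <- if (noise == "mad") stats::median(abs(x)) / 0.6745 else
      stats::sd(x)
    theta[i] <- -k * sigma_i
    idx <- which(x <= theta[i] & theta[i] < 0)
    if (length(idx) > 0L && dead_time_ms > 0L) {
      keep <- logical(length(idx))
      last <- -Inf
      for (j in seq_along(idx)) {
        if (idx[j] - last > dead_time_ms) {
          keep[j] <- TRUE
          last <- idx[j]
        }
      }
      idx <- idx[keep]
    }
    events[i, idx] <- 1L
  }
  out <- mua_raster(events, rec$channel_ids, t_ms)
  out$thresholds <- stats::setNames(theta, rec$channel_ids)
  out
}

#' Channel quality control
#'
#' Removes channels with fewer than two MUA events and channels whose firing
#' rate exceeds the across-channel mean by more than five standard
#' deviations. Both rules are evaluated against the single pre-removal rate
#' distribution and applied once; QC is not meant to be iterated on its own
#' output.
#'
#' @param raster an [mua_raster()] with at least two channels.
#' @param min_events minimum event count to keep a channel.
#' @param sd_limit rate outlier cut in standard deviations above the mean.
#' @return list with elements `raster` (channels removed) and `report`, a
#'   `channel_qc_report` with `removed_low_count`, `removed_rate_outlier`
#'   and `kept` channel ids.
#' @export
qc_channels <- function(raster, min_events = 2, sd_limit = 5) {
  stopifnot(inherits(raster, "mua_raster"))
  if (nrow(raster$events) < 2L) stop("QC needs at least two channels")
  counts <- rowSums(raster$events)
  rates <- counts / (raster$duration_ms / 1000)
  mu <- mean(rates)
  sd_r <- stats::sd(rates)
  low <- counts < min_events
  outlier <- if (is.finite(sd_r) && sd_r > 0) {
    rates > mu + sd_limit * sd_r
  } else {
    rep(FALSE, length(rates))
  }
  drop <- low | outlier
  if (all(drop)) stop("all channels removed by QC: unusable recording")
  report <- structure(
    list(removed_low_count = raster$channel_ids[low],
         removed_rate_outlier = raster$channel_ids[outlier],
         kept = raster$channel_ids[!drop],
         rate_mean_hz = mu, rate_sd_hz = sd_r),
    class = "channel_qc_report"
  )
  kept <- mua_raster(raster$events[!drop, , drop = FALSE],
                     raster$channel_ids[!drop], raster$duration_ms)
  list(raster = kept, report = report)
}

#' @export
print.channel_qc_report <- function(x, ...) {
  cat(sprintf(
    "<channel_qc_report> kept %d | low-count %d | rate-outlier %d (mean %.3g Hz, sd %.3g Hz)\n",
    length(x$kept), length(x$removed_low_count),
    length(x$removed_rate_outlier), x$rate_mean_hz, x$rate_sd_hz))
  invisible(x)
}

#' Bin a raster into coarse presence bins
#'
#' Groups consecutive `B` columns into one bin whose entry is 1 iff the
#' channel has at least one event in the bin (presence, not a count). A
#' trailing partial bin is dropped. `B = 1` returns the input matrix
#' unchanged apart from the container class.
#'
#' @param raster an [mua_raster()].
#' @param B bin width in ms.
#' @return a [binned_raster()] with `floor(T/B)` bins.
#' @export
bin_raster <- function(raster, B = 10) {
  stopifnot(inherits(raster, "mua_raster"))
  B <- as.integer(B)
  if (B < 1L) stop("`B` must be >= 1")
  t_ms <- ncol(raster$events)
  if (B > t_ms) stop("`B` exceeds the recording length")
  nb <- t_ms %/% B
  if (B == 1L) {
    pres <- raster$events
  } else {
    grp <- rep(seq_len(nb), each = B)
    counts <- t(rowsum(t(raster$events[, seq_len(nb * B), drop = FALSE]), grp))
    pres <- (counts > 0L) * 1L
    dimnames(pres) <- NULL
  }
  binned_raster(pres, bin_ms = B, channel_ids = raster$channel_ids)
}
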