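#' Binned presence raster
#'
#' Channels x bins 0/1 matrix where an entry marks the presence of at least
#' one MUA event in a `bin_ms`-wide bin (default 10 ms). Produced by
#' [bin_raster()].
#'
#' @param presence 0/1 matrix, channels x bins.
#' @param bin_ms bin width in ms.
#' @param channel_ids identifiers, one per row.
#' @return an object of class `binned_raster`.
#' @export
binned_raster <- function(presence, bin_ms = 10, channel_ids = NULL) {
  if (!is_binary_matrix(presence)) stop("`presence` must be a 0/1 matrix")
  storage.mode(presence) <- "integer"
  bin_ms <- as.integer(bin_ms)
  if (bin_ms < 1L) stop("`bin_ms` must be >= 1")
  channel_ids <- channel_ids %||% (seq_len(nrow(presence)) - 1L)
  if (length(channel_ids) != nrow(presence)) {
    stop("`channel_ids` must have one entry per channel")
  }
  structure(
    list(presence = presence, bin_ms = bin_ms,
         channel_ids = as.character(channel_ids)),
    class = "binned_raster"
  )
}

#' @export
print.binned_raster <- function(x, ...) {
  cat(sprintf("<binned_raster> %d channels x %d bins of %d ms\n",
              nrow(x$presence), ncol(x$presence), x$bin_ms))
  invisible(x)
}

# One rate-preserving surrogate: each channel's presence bins are moved to
# uniformly random positions (a random permutation of its time axis), and
# the permuted rows are summed across channels.
perm_colsums <- function(presence) {
  nb <- ncol(presence)
  out <- integer(nb)
  for (r_i in rowSums(presence)) {
    if (r_i > 0L) out <- out + tabulate(sample.int(nb, r_i), nbins = nb)
  }
  out
}

#' Detect network bursts against a permutation null
#'
#' Sums activity across channels per bin and compares this population count
#' against surrogates in which every channel's firing times are randomly
#' permuted while its firing rate is preserved. The burst threshold is, by
#' default, one scalar: the `percentile`-th percentile of all surrogate
#' population counts pooled across bins and permutations (the surrogate
#' counts are stationary, so a flat threshold is appropriate);
#' `pooled = FALSE` instead takes the percentile per bin across
#' permutations. Bins strictly exceeding the threshold are supra-threshold,
#' and maximal runs of consecutive supra-threshold bins form bursts whose
#' onset is the start of the run.
#'
#' @param z a [binned_raster()].
#' @param n_permutations number of surrogates.
#' @param percentile threshold percentile (strict exceedance, `>`).
#' @param seed RNG seed for the surrogates; fixed seed gives bit-identical
#'   output.
#' @param pooled pooled scalar threshold (default) or per-bin thresholds.
#' @return a `burst_set`: list with `onsets_ms`, `intervals` (half-open
#'   `[start_ms, end_ms)` matrix), `threshold`, `n_permutations`,
#'   `percentile`, `seed`, `bin_ms`, `n_bins`, `duration_ms`. A raster with
#'   zero events yields an empty burst set with threshold 0.
#' @export
detect_network_bursts <- function(z, n_permutations = 100, percentile = 95,
                                  seed = NULL, pooled = TRUE) {
  stopifnot(inherits(z, "binned_raster"))
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("`n_permutations` must be >= 1")
  nb <- ncol(z$presence)
  s <- colSums(z$presence)
  if (sum(s) == 0) {
    return(new_burst_set(integer(0), matrix(numeric(0), 0, 2), 0,
                         n_permutations, percentile, seed, z$bin_ms, nb))
  }
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) perm_colsums(z$presence),
           numeric(nb))
  })
  threshold <- if (pooled) {
    stats::quantile(as.numeric(perm), percentile / 100, names = FALSE)
  } else {
    apply(perm, 1L, stats::quantile, probs = percentile / 100, names = FALSE)
  }
  supra <- s > threshold
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values)
  intervals <- cbind(start_ms = (starts[hit] - 1L) * z$bin_ms,
                     end_ms = ends[hit] * z$bin_ms)
  new_burst_set(intervals[, 1L], intervals,
                if (pooled) threshold else max(threshold),
                n_permutations, percentile, seed, z$bin_ms, nb,
                per_bin_threshold = if (pooled) NULL else threshold)
}

new_burst_set <- function(onsets_ms, intervals, threshold, n_permutations,
                          percentile, seed, bin_ms, n_bins,
                          per_bin_threshold = NULL) {
  structure(
    list(onsets_ms = as.numeric(onsets_ms), intervals = intervals,
         threshold = as.numeric(threshold),
         per_bin_threshold = per_bin_threshold,
         n_permutations = n_permutations, percentile = percentile,
         seed = seed, bin_ms = bin_ms, n_bins = n_bins,
         duration_ms = n_bins * bin_ms),
    class = "burst_set"
  )
}

#' @export
print.burst_set <- function(x, ...) {
  cat(sprintf("<burst_set> %d bursts over %d ms (threshold %.3g, %d permutations, %g%%)\n",
              length(x$onsets_ms), x$duration_ms, x$threshold,
              x$n_permutations, x$percentile))
  invisible(x)
}

#' Number of bursts in a burst set
#' @param bursts a `burst_set`.
#' @return integer count.
#' @export
n_bursts <- function(bursts) {
  stopifnot(inherits(bursts, "burst_set"))
  length(bursts$onsets_ms)
}

#' Culture-level quality control
#'
#' A baseline recording must contain at least `min_bursts` network bursts to
#' be usable for burst-predictor analysis.
#'
#' @param bursts a `burst_set` from a full baseline session.
#' @param min_bursts inclusion threshold (default 5; fewer are excluded).
#' @return `TRUE` to keep the culture, `FALSE` to exclude it.
#' @export
qc_culture <- function(bursts, min_bursts = 5) {
  n_bursts(bursts) >= min_bursts
}

#' Burst-prediction (BP) scores
#'
#' For every channel, counts the network bursts preceded by at least one of
#' that channel's presence bins within `window_ms` strictly before the burst
#' onset (the onset bin itself is excluded: prediction must precede the
#' burst). The hit fraction is divided by the channel's mean rate so that
#' tonically active channels are not mistaken for specific predictors:
#' `score = (hits / n_bursts) / rate_hz`. Channels with zero rate score 0.
#'
#' @param z the [binned_raster()] the bursts were detected on.
#' @param bursts a non-empty `burst_set`.
#' @param window_ms pre-burst window; must be a positive multiple of the bin
#'   width.
#' @param strong_cutoff score above which a channel is flagged a strong
#'   burst predictor (default 20).
#' @return a `bp_score_table` data frame with columns `channel`,
#'   `pre_burst_hit_count`, `n_bursts`, `mean_rate_hz`, `bp_score`,
#'   `strong`.
#' @export
compute_bp_scores <- function(z, bursts, window_ms = 50, strong_cutoff = 20) {
  stopifnot(inherits(z, "binned_raster"), inherits(bursts, "burst_set"))
  if (n_bursts(bursts) == 0L) {
    stop("empty burst set: BP scores are undefined (culture should have been excluded)")
  }
  if (window_ms <= 0 || window_ms %% z$bin_ms != 0) {
    stop("`window_ms` must be a positive multiple of the bin width")
  }
  w <- window_ms %/% z$bin_ms
  nb <- ncol(z$presence)
  n_ch <- nrow(z$presence)
  onset_bins <- bursts$onsets_ms %/% z$bin_ms + 1L
  hits <- integer(n_ch)
  for (ob in onset_bins) {
    lo <- max(1L, ob - w)
    if (lo > ob - 1L) next
    sub <- z$presence[, lo:(ob - 1L), drop = FALSE]
    hits <- hits + (rowSums(sub) > 0L)
  }
  nB <- n_bursts(bursts)
  rate <- rowSums(z$presence) / (nb * z$bin_ms / 1000)
  score <- ifelse(rate > 0, (hits / nB) / rate, 0)
  out <- data.frame(
    channel = z$channel_ids,
    pre_burst_hit_count = hits,
    n_bursts = nB,
    mean_rate_hz = rate,
    bp_score = score,
    strong = score > strong_cutoff,
    stringsAsFactors = FALSE
  )
  class(out) <- c("bp_score_table", "data.frame")
  out
}
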