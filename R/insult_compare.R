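# Pre/post-insult comparison: rate changes, predictor stability, emergent
# predictors, score-stability PCA, and association statistics.

#' Pair two analyzed sessions for comparison
#'
#' Reconciles the channel sets of a baseline and a post-insult session.
#' Channels absent from one session are retained with rate 0 and BP score 0
#' and flagged inactive, so rate differences and inactive-electrode
#' percentages stay computable.
#'
#' @param pre_raster,post_raster [mua_raster()] objects.
#' @param pre_bp,post_bp matching `bp_score_table`s (see
#'   [compute_bp_scores()]).
#' @param condition label: `"control"`, `"low_kill"`, or `"high_kill"`.
#' @return a `session_pair`: list with `channel_ids`, `pre`, `post` (each a
#'   list of `raster`, `bp`, `rate_hz`), `condition`.
#' @export
session_pair <- function(pre_raster, post_raster, pre_bp, post_bp,
                         condition = c("control", "low_kill", "high_kill")) {
  condition <- match.arg(condition)
  stopifnot(inherits(pre_raster, "mua_raster"),
            inherits(post_raster, "mua_raster"))
  ids <- union(pre_raster$channel_ids, post_raster$channel_ids)
  if (length(intersect(pre_raster$channel_ids, post_raster$channel_ids)) == 0L) {
    stop("no matched channels between sessions")
  }
  align <- function(raster, bp) {
    rate <- stats::setNames(numeric(length(ids)), ids)
    score <- stats::setNames(numeric(length(ids)), ids)
    r <- channel_rates(raster)
    rate[names(r)] <- r
    score[as.character(bp$channel)] <- bp$bp_score
    list(raster = raster, bp = bp, rate_hz = rate, bp_score = score)
  }
  structure(
    list(channel_ids = ids,
         pre = align(pre_raster, pre_bp),
         post = align(post_raster, post_bp),
         condition = condition),
    class = "session_pair"
  )
}

#' Per-channel firing-rate change
#'
#' Subtracts each channel's baseline mean rate from its post-insult mean
#' rate; negative values indicate a post-insult decrease. With
#' `normalize = TRUE`, rates are additionally min-max scaled to `[0, 1]`
#' within each session and the normalized difference reported alongside
#' (the raw `delta` column is always `rate_post - rate_pre` in Hz).
#'
#' @param pair a [session_pair()].
#' @param normalize also report min-max normalized rates and their
#'   difference.
#' @return a `delta_rate_table` data frame: `channel`, `rate_pre_hz`,
#'   `rate_post_hz`, `delta`, `strong_flag` (baseline BP score > 20),
#'   `inactive_post` (no events post-insult), and when `normalize` the
#'   `*_norm` columns.
#' @export
delta_rate <- function(pair, normalize = FALSE) {
  stopifnot(inherits(pair, "session_pair"))
  pre <- pair$pre$rate_hz
  post <- pair$post$rate_hz
  out <- data.frame(
    channel = pair$channel_ids,
    rate_pre_hz = as.numeric(pre),
    rate_post_hz = as.numeric(post),
    delta = as.numeric(post - pre),
    strong_flag = as.numeric(pair$pre$bp_score) > 20,
    inactive_post = as.numeric(post) == 0,
    stringsAsFactors = FALSE
  )
  if (normalize) {
    mm <- function(x) {
      rng <- range(x)
      if (diff(rng) == 0) return(rep(0, length(x)))
      (x - rng[1]) / diff(rng)
    }
    out$rate_pre_norm <- mm(out$rate_pre_hz)
    out$rate_post_norm <- mm(out$rate_post_hz)
    out$delta_norm <- out$rate_post_norm - out$rate_pre_norm
  }
  class(out) <- c("delta_rate_table", "data.frame")
  out
}

# Deterministic ranking for the high/low split: score descending, baseline
# rate ascending, channel id ascending.
rank_by_bp <- function(pair) {
  score <- as.numeric(pair$pre$bp_score)
  rate <- as.numeric(pair$pre$rate_hz)
  order(-score, rate, pair$channel_ids)
}

#' Compare high-BP and low-BP electrode groups
#'
#' Ranks channels by baseline BP score, takes the top `k_top` as the "high
#' BP" group and the rest as "low BP", and tests whether the high group
#' retains higher scores after the insult. For a single culture the default
#' is a two-sample t test of post-insult scores between groups; for a list
#' of cultures the per-culture group means are compared with a paired t
#' test across cultures. Ties spanning the group boundary are broken
#' deterministically (score descending, baseline rate ascending, channel id
#' ascending) and noted in the report.
#'
#' @param x a [session_pair()] or a list of them.
#' @param k_top size of the high-BP group (default 5).
#' @param var_equal assume equal variances in the two-sample test.
#' @return a `bp_group_report`: list with `groups` (per-group pre/post mean
#'   and SEM), `statistic`, `df`, `p_value`, `mode`, `degenerate`,
#'   `boundary_tie`.
#' @export
compare_high_low_bp <- function(x, k_top = 5, var_equal = TRUE) {
  pairs <- if (inherits(x, "session_pair")) list(x) else x
  stopifnot(all(vapply(pairs, inherits, TRUE, "session_pair")))
  k_top <- as.integer(k_top)
  split_one <- function(pair) {
    n <- length(pair$channel_ids)
    if (n < k_top + 2L) stop("need at least k_top + 2 channels")
    ord <- rank_by_bp(pair)
    hi <- ord[seq_len(k_top)]
    lo <- ord[-seq_len(k_top)]
    score <- as.numeric(pair$pre$bp_score)
    tie <- score[ord[k_top]] == score[ord[k_top + 1L]]
    list(pre_hi = as.numeric(pair$pre$bp_score)[hi],
         pre_lo = as.numeric(pair$pre$bp_score)[lo],
         post_hi = as.numeric(pair$post$bp_score)[hi],
         post_lo = as.numeric(pair$post$bp_score)[lo],
         tie = tie)
  }
  parts <- lapply(pairs, split_one)
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  agg <- function(f) lapply(parts, `[[`, f)
  groups <- data.frame(
    group = c("high", "low"),
    n = c(length(unlist(agg("post_hi"))), length(unlist(agg("post_lo")))),
    mean_pre = c(mean(unlist(agg("pre_hi"))), mean(unlist(agg("pre_lo")))),
    sem_pre = c(sem(unlist(agg("pre_hi"))), sem(unlist(agg("pre_lo")))),
    mean_post = c(mean(unlist(agg("post_hi"))), mean(unlist(agg("post_lo")))),
    sem_post = c(sem(unlist(agg("post_hi"))), sem(unlist(agg("post_lo"))))
  )
  mode <- if (length(parts) == 1L) "between_groups" else "paired_cultures"
  post_hi <- unlist(agg("post_hi"))
  post_lo <- unlist(agg("post_lo"))
  degenerate <- stats::sd(c(post_hi, post_lo)) == 0
  if (degenerate) {
    stat <- df <- p <- NA_real_
  } else if (mode == "between_groups") {
    tt <- stats::t.test(post_hi, post_lo, var.equal = var_equal)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  } else {
    hi_means <- vapply(parts, function(p_) mean(p_$post_hi), 1)
    lo_means <- vapply(parts, function(p_) mean(p_$post_lo), 1)
    tt <- stats::t.test(hi_means, lo_means, paired = TRUE)
    stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
  }
  structure(
    list(groups = groups, statistic = stat, df = df, p_value = p,
         mode = mode, degenerate = degenerate,
         boundary_tie = any(vapply(parts, `[[`, TRUE, "tie"))),
    class = "bp_group_report"
  )
}

#' @export
print.bp_group_report <- function(x, ...) {
  print(x$groups)
  if (x$degenerate) {
    cat("test degenerate (no score variance); no p value reported\n")
  } else {
    cat(sprintf("%s t = %.3f, df = %.3g, p = %.4g%s\n", x$mode, x$statistic,
                x$df, x$p_value,
                if (x$boundary_tie) " [tie at group boundary]" else ""))
  }
  invisible(x)
}

#' Find emergent burst predictors
#'
#' Channels whose baseline BP score is exactly zero but whose post-insult
#' score is positive: predictors that emerged after the insult.
#'
#' @param pair a [session_pair()].
#' @return character vector of channel ids.
#' @export
find_emergent_predictors <- function(pair) {
  stopifnot(inherits(pair, "session_pair"))
  pre <- as.numeric(pair$pre$bp_score)
  post <- as.numeric(pair$post$bp_score)
  pair$channel_ids[pre == 0 & post > 0]
}

#' PCA of BP-score stability across sessions
#'
#' Principal components analysis of a channels x sessions score matrix
#' (columns mean-centered, unscaled). A dominant first component whose
#' channel scores track per-channel mean BP indicates that the ranking of
#' burst predictors is stable across recordings. PC1 is oriented so that
#' its correlation with the per-channel mean score is non-negative (the
#' sign of an eigenvector is arbitrary).
#'
#' @param scores numeric matrix, channels x sessions (>= 3 channels,
#'   >= 2 sessions).
#' @return list with `components` (loadings), `scores` (channel scores),
#'   `variance_fractions` (sums to 1), `pc1_mean_cor`.
#' @export
bp_stability_pca <- function(scores) {
  if (!is.matrix(scores) || nrow(scores) < 3L || ncol(scores) < 2L) {
    stop("`scores` must be a channels x sessions matrix (>= 3 x >= 2)")
  }
  if (all(apply(scores, 2L, stats::sd) == 0)) stop("no variance in scores")
  pr <- stats::prcomp(scores, center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  pc1 <- pr$x[, 1L]
  mean_bp <- rowMeans(scores)
  r <- stats::cor(pc1, mean_bp)
  if (is.finite(r) && r < 0) {
    pc1 <- -pc1
    pr$x[, 1L] <- pc1
    pr$rotation[, 1L] <- -pr$rotation[, 1L]
    r <- -r
  }
  list(components = pr$rotation, scores = pr$x, variance_fractions = vf,
       pc1_mean_cor = r)
}

#' Association statistics across channels and cultures
#'
#' Computes the correlation-style summaries used to relate burst prediction
#' to firing rate and cell loss: (a) Pearson correlation of BP score vs
#' firing rate across channels; (b) Pearson correlation of the percentage
#' of electrodes inactive post-insult vs the mean BP score across cultures;
#' (c) a Wilcoxon signed-rank comparison (normal approximation) of
#' pre vs post BP-score distributions. Any section with fewer than 3
#' observations is an error; pass `NULL` to skip a section.
#'
#' @param bp_rate data frame with columns `bp_score` and `rate_hz` (one row
#'   per channel), or `NULL`.
#' @param cultures data frame with columns `pct_inactive` and `mean_bp`
#'   (one row per culture), or `NULL`.
#' @param pre_scores,post_scores paired per-channel score vectors, or
#'   `NULL`.
#' @return an `association_report`: list with `bp_vs_rate`,
#'   `inactive_vs_mean_bp` (each `r`, `df`, `p`), and `pre_vs_post`
#'   (`statistic` V, `z`, `p`).
#' @export
association_report <- function(bp_rate = NULL, cultures = NULL,
                               pre_scores = NULL, post_scores = NULL) {
  pearson <- function(x, y, what) {
    if (length(x) < 3L) stop(what, ": need at least 3 observations")
    ct <- stats::cor.test(x, y, method = "pearson")
    list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
  }
  out <- list()
  if (!is.null(bp_rate)) {
    out$bp_vs_rate <- pearson(bp_rate$bp_score, bp_rate$rate_hz,
                              "bp_rate")
  }
  if (!is.null(cultures)) {
    out$inactive_vs_mean_bp <- pearson(cultures$pct_inactive,
                                       cultures$mean_bp, "cultures")
  }
  if (!is.null(pre_scores)) {
    if (is.null(post_scores) || length(post_scores) != length(pre_scores)) {
      stop("`pre_scores` and `post_scores` must be paired vectors")
    }
    if (length(pre_scores) < 3L) stop("pre/post: need at least 3 observations")
    wt <- stats::wilcox.test(pre_scores, post_scores, paired = TRUE,
                             exact = FALSE, correct = TRUE)
    z <- stats::qnorm(wt$p.value / 2, lower.tail = FALSE)
    d <- pre_scores - post_scores
    z <- z * sign(sum(rank(abs(d[d != 0])) * sign(d[d != 0])))
    out$pre_vs_post <- list(statistic = unname(wt$statistic), z = z,
                            p = wt$p.value)
  }
  if (length(out) == 0L) stop("nothing to compute: all inputs NULL")
  structure(out, class = "association_report")
}
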