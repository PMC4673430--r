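# Small deterministic session pairs built directly from rasters and score
# tables, so the comparison stage is tested independently of the generator.
make_bp <- function(ids, scores, rates = NULL, n_bursts = 10) {
  rates <- rates %||% rep(1, length(ids))
  out <- data.frame(channel = as.character(ids),
                    pre_burst_hit_count = 0L, n_bursts = n_bursts,
                    mean_rate_hz = rates, bp_score = scores,
                    strong = scores > 20, stringsAsFactors = FALSE)
  class(out) <- c("bp_score_table", "data.frame")
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

make_pair <- function(pre_scores, post_scores, pre_events = NULL,
                      post_events = NULL, condition = "low_kill",
                      duration_ms = 1000) {
  n <- length(pre_scores)
  evm <- function(ev) {
    m <- matrix(0L, n, duration_ms)
    if (!is.null(ev)) m[ev] <- 1L
    m
  }
  pre_m <- if (is.null(pre_events)) {
    m <- matrix(0L, n, duration_ms)
    m[, 1:2] <- 1L
    m
  } else evm(pre_events)
  post_m <- if (is.null(post_events)) {
    m <- matrix(0L, n, duration_ms)
    m[, 1:2] <- 1L
    m
  } else evm(post_events)
  ids <- seq_len(n) - 1L
  session_pair(mua_raster(pre_m, ids), mua_raster(post_m, ids),
               make_bp(ids, pre_scores), make_bp(ids, post_scores),
               condition)
}

test_that("delta rate has the documented sign convention and flags", {
  n <- 4
  pre_m <- matrix(0L, n, 10000)
  post_m <- matrix(0L, n, 10000)
  pre_m[1, 1:5] <- 1L; post_m[1, 1:3] <- 1L  # 0.5 -> 0.3 Hz
  pre_m[2, 1:7] <- 1L; post_m[2, 1:7] <- 1L  # unchanged
  pre_m[3, 1:9] <- 1L                        # silent post
  ids <- 0:3
  pair <- session_pair(mua_raster(pre_m, ids), mua_raster(post_m, ids),
                       make_bp(ids, c(25, 1, 1, 0)),
                       make_bp(ids, c(30, 1, 0, 0)), "high_kill")
  dr <- delta_rate(pair)
  expect_equal(dr$delta[1], -0.2)
  expect_equal(dr$delta[2], 0)
  expect_equal(dr$delta[3], -0.9)            # = -rate_pre
  expect_true(dr$inactive_post[3])
  expect_true(dr$strong_flag[1])             # baseline BP 25 > 20
  expect_false(any(dr$strong_flag[-1]))

  # identical rasters -> all deltas zero
  pair0 <- session_pair(mua_raster(pre_m, ids), mua_raster(pre_m, ids),
                        make_bp(ids, rep(1, 4)), make_bp(ids, rep(1, 4)),
                        "control")
  expect_true(all(delta_rate(pair0)$delta == 0))

  # antisymmetry under role swap
  swapped <- session_pair(mua_raster(post_m, ids), mua_raster(pre_m, ids),
                          make_bp(ids, c(30, 1, 0, 0)),
                          make_bp(ids, c(25, 1, 1, 0)), "high_kill")
  expect_equal(delta_rate(swapped)$delta, -dr$delta)
})

test_that("normalized deltas use per-session min-max scaling", {
  pre_m <- matrix(0L, 3, 1000)
  pre_m[1, 1:4] <- 1L
  pre_m[2, 1:2] <- 1L
  post_m <- pre_m
  ids <- 0:2
  p <- session_pair(mua_raster(pre_m, ids), mua_raster(post_m, ids),
                    make_bp(ids, rep(1, 3)), make_bp(ids, rep(1, 3)),
                    "control")
  dn <- delta_rate(p, normalize = TRUE)
  expect_equal(dn$rate_pre_norm, c(1, 0.5, 0))
  expect_equal(dn$delta, dn$rate_post_hz - dn$rate_pre_hz)
})

test_that("high/low BP grouping partitions channels and computes the t test", {
  # 59 channels: exactly 5 high, 54 low
  set.seed(71)
  scores <- c(100, 90, 80, 70, 60, runif(54, 0, 10))
  pair <- make_pair(scores, scores * 0.9 + rnorm(59, 0, 0.5))
  rep_ <- compare_high_low_bp(pair, k_top = 5)
  expect_equal(rep_$groups$n, c(5L, 54L))
  expect_equal(sum(rep_$groups$n), 59L)
  expect_false(rep_$degenerate)
  expect_gt(rep_$groups$mean_post[1], rep_$groups$mean_post[2])
  expect_lt(rep_$p_value, 0.01)

  # degenerate: identical scores everywhere -> flagged, no p
  flat <- make_pair(rep(2, 10), rep(2, 10))
  rep0 <- compare_high_low_bp(flat, k_top = 5)
  expect_true(rep0$degenerate)
  expect_true(is.na(rep0$p_value))
  expect_error(compare_high_low_bp(make_pair(1:6, 1:6), k_top = 5), "k_top")
})

test_that("two-sample t statistic matches the closed form on constructed numbers", {
  post_hi <- c(10, 12, 14, 11, 13)
  post_lo <- c(5, 6, 7, 5.5, 6.5, 6, 7.5)
  pre <- c(50, 40, 30, 20, 15, rep(1, 7))
  pair <- make_pair(pre, c(post_hi, post_lo))
  rep_ <- compare_high_low_bp(pair, k_top = 5)
  n1 <- 5; n2 <- 7
  sp2 <- ((n1 - 1) * var(post_hi) + (n2 - 1) * var(post_lo)) / (n1 + n2 - 2)
  t_hand <- (mean(post_hi) - mean(post_lo)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  expect_equal(rep_$statistic, t_hand)
  expect_equal(rep_$df, n1 + n2 - 2)
})

test_that("boundary ties are broken deterministically and reported", {
  scores <- c(9, 8, 7, 6, 5, 5, 1, 1, 1, 1)
  rates <- c(rep(1, 4), 0.2, 0.1, rep(1, 4))   # tie at rank 5/6: lower rate wins
  n <- 10
  pre_m <- matrix(0L, n, 1000)
  for (i in 1:n) pre_m[i, seq_len(round(rates[i] * 10))] <- 1L
  ids <- 0:9
  pair <- session_pair(mua_raster(pre_m, ids), mua_raster(pre_m, ids),
                       make_bp(ids, scores, rates),
                       make_bp(ids, scores, rates), "low_kill")
  rep_ <- compare_high_low_bp(pair, k_top = 5)
  expect_true(rep_$boundary_tie)
  ord <- burstnet:::rank_by_bp(pair)
  expect_equal(ord[5], 6L)              # channel id 5 (rate 0.1) enters high
})

test_that("emergent predictors are exactly the pre-zero, post-positive set", {
  pair <- make_pair(c(0, 0, 3), c(2, 0, 3))
  expect_equal(find_emergent_predictors(pair), "0")
  none <- make_pair(c(1, 2, 3), c(0, 5, 1))
  expect_length(find_emergent_predictors(none), 0)
})

test_that("BP stability PCA recovers known eigenstructure", {
  # rank-1: scores proportional across sessions -> PC1 fraction 1
  base <- c(1, 5, 2, 8, 3)
  m1 <- cbind(base, 2 * base, 0.5 * base)
  p1 <- bp_stability_pca(m1)
  expect_equal(p1$variance_fractions[1], 1, tolerance = 1e-12)

  # constructed 2-session data with centered crossprod eigenvalues (3, 1)
  m2 <- cbind(sqrt(3) / 2 * c(-1, -1, 1, 1), 0.5 * c(-1, 1, -1, 1))
  p2 <- bp_stability_pca(m2)
  expect_equal(unname(p2$variance_fractions), c(0.75, 0.25))

  # stable planted scores: PC1 tracks the per-channel mean
  set.seed(81)
  mean_bp <- c(rep(30, 3), runif(20, 0, 5))
  m3 <- sapply(1:5, function(s) mean_bp * runif(1, 0.8, 1.2) +
                 rnorm(23, 0, 0.3))
  p3 <- bp_stability_pca(m3)
  expect_gt(p3$pc1_mean_cor, 0.9)
  expect_error(bp_stability_pca(matrix(1, 5, 3)), "variance")
})

test_that("association report computes correlations with exact df", {
  x <- seq(1, 40, length.out = 23)
  rep1 <- association_report(bp_rate = data.frame(bp_score = x,
                                                  rate_hz = 2 * x + 1))
  expect_equal(rep1$bp_vs_rate$r, 1)
  expect_equal(rep1$bp_vs_rate$df, 21)

  set.seed(91)
  rep2 <- association_report(bp_rate = data.frame(bp_score = rnorm(400),
                                                  rate_hz = rnorm(400)))
  expect_lt(abs(rep2$bp_vs_rate$r), 0.1)

  # 23-culture fixture with hand-computable correlation
  cult <- data.frame(pct_inactive = x, mean_bp = -3 * x + 100)
  rep3 <- association_report(cultures = cult)
  expect_equal(rep3$inactive_vs_mean_bp$r, -1)
  expect_equal(rep3$inactive_vs_mean_bp$df, 21)

  set.seed(92)
  pre <- rexp(30); post <- pre + rnorm(30, 0.5, 0.2)
  rep4 <- association_report(pre_scores = pre, post_scores = post)
  expect_lt(rep4$pre_vs_post$p, 0.01)
  expect_lt(rep4$pre_vs_post$z, 0)       # post > pre -> negative shift sign
  expect_error(association_report(bp_rate = data.frame(bp_score = 1:2,
                                                       rate_hz = 1:2)),
               "at least 3")
})

test_that("high-kill fixtures reproduce the headline pattern end to end", {
  fx <- generate_session_pair("high_kill", seed = 55, n_units = 40,
                              duration_ms = 120000)
  analyze <- function(raster, seed) {
    z <- bin_raster(raster, 10)
    b <- detect_network_bursts(z, 50, 95, seed = seed)
    compute_bp_scores(z, b)
  }
  pair <- session_pair(fx$pre, fx$post,
                       analyze(fx$pre, 1), analyze(fx$post, 2), "high_kill")
  dr <- delta_rate(pair)
  planted <- dr$channel %in% fx$ground_truth$planted
  expect_gt(median(abs(dr$delta[!planted])),
            median(abs(dr$delta[planted])))
  # planted predictors top the baseline ranking
  ord <- burstnet:::rank_by_bp(pair)
  expect_setequal(pair$channel_ids[ord[1:3]], fx$ground_truth$planted)
})
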