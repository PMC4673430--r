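# Probabilistic branching network model and auxiliary generators. This is
# the package's synthetic-data engine: it produces rasters with near-critical
# avalanche statistics, planted burst predictors, and matched pre/post
# "insult" session pairs so every pipeline stage can be exercised without
# recordings.

#' Build a branching network
#'
#' All-to-all network of `n_units` binary units. Each unit's incoming
#' propagation probabilities are drawn uniformly and rescaled so that the
#' sum of its presynaptic connections equals `sigma`, the branching
#' parameter: a lone active ancestor then activates `sigma` descendants in
#' expectation. Entries that exceed 1 after rescaling (possible for large
#' `sigma`) are clipped with their excess mass redistributed over the
#' remaining entries, with a warning.
#'
#' @param n_units number of units (default 100).
#' @param sigma target branching parameter, `>= 0`.
#' @param seed RNG seed; same seed gives an identical network.
#' @return a `branching_net`: list with `n_units`, `prob_matrix` (entry
#'   `[i, j]` is the probability that activity in unit `i` propagates to
#'   unit `j`; every column sums to `sigma`), `sigma`, `seed`.
#' @export
build_network <- function(n_units = 100, sigma, seed = NULL) {
  n_units <- as.integer(n_units)
  if (n_units < 2L) stop("`n_units` must be >= 2")
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  if (sigma > n_units) stop("`sigma` cannot exceed `n_units` (probabilities would exceed 1)")
  p <- with_seed(seed, {
    if (sigma == 0) {
      matrix(0, n_units, n_units)
    } else {
      u <- matrix(stats::runif(n_units * n_units), n_units, n_units)
      p <- sweep(u, 2L, colSums(u) / sigma, "/")
      if (any(p > 1)) {
        warning("propagation probabilities clipped at 1; excess mass redistributed")
        for (j in which(colSums(p > 1) > 0)) {
          col <- pmin(p[, j], 1)
          excess <- sigma - sum(col)
          # refill proportionally to headroom: exact in one pass since the
          # total headroom is at least the excess whenever sigma <= n_units
          headroom <- 1 - col
          col <- col + excess * headroom / sum(headroom)
          p[, j] <- col
        }
      }
      p
    }
  })
  structure(
    list(n_units = n_units, prob_matrix = p, sigma = sigma, seed = seed),
    class = "branching_net"
  )
}

#' @export
print.branching_net <- function(x, ...) {
  cat(sprintf("<branching_net> %d units, all-to-all, sigma = %g\n",
              x$n_units, x$sigma))
  invisible(x)
}

#' Simulate branching network dynamics
#'
#' Binary dynamics with independent-synapse noisy-OR activation: unit `j`
#' is active at `t + 1` with probability
#' `1 - prod_{i active at t} (1 - p[i, j])`. By default a unit that fired
#' at `t` is refractory at `t + 1` and cannot fire again immediately
#' (`refractory = TRUE`); this keeps supercritical activity from settling
#' into a saturated steady state and matches the refractoriness that the
#' branching-parameter estimator corrects for. Under the default
#' `seed_on_silence` drive, whenever the network is fully silent one
#' uniformly chosen unit is activated at the next step, so avalanches are
#' cleanly delimited by single silent steps; `drive = "poisson"` instead
#' adds independent spontaneous activations at `drive_rate` per unit per
#' step for ongoing background activity.
#'
#' @param net a [build_network()] result.
#' @param steps number of time steps (nominally 1 ms each).
#' @param seed RNG seed; fixed `(net, seed, steps)` gives a bit-identical
#'   raster.
#' @param drive `"seed_on_silence"` (default) or `"poisson"`.
#' @param drive_rate activation probability per unit per step for the
#'   Poisson drive.
#' @param refractory disallow immediate re-firing (default `TRUE`).
#' @return a `sim_raster`, which is also an [mua_raster()] (fields
#'   `events`, `channel_ids`, `duration_ms`) with provenance fields
#'   `sigma`, `seed`, `steps`, `step_ms = 1`.
#' @export
simulate_network <- function(net, steps, seed = NULL,
                             drive = c("seed_on_silence", "poisson"),
                             drive_rate = 0.001, refractory = TRUE) {
  stopifnot(inherits(net, "branching_net"))
  drive <- match.arg(drive)
  steps <- as.integer(steps)
  if (steps < 1L) stop("`steps` must be >= 1")
  n <- net$n_units
  lq <- log1p(-net$prob_matrix)          # log(1 - p), -Inf where p = 1
  events <- with_seed(seed, {
    out <- matrix(0L, n, steps)
    act <- integer(0)
    for (t in seq_len(steps)) {
      if (length(act) == 0L && drive == "seed_on_silence") {
        act <- sample.int(n, 1L)
      } else {
        nxt <- if (length(act) == 0L) {
          integer(0)
        } else {
          l <- if (length(act) == 1L) lq[act, ] else
            colSums(lq[act, , drop = FALSE])
          which(stats::runif(n) < -expm1(l))
        }
        if (drive == "poisson") {
          spont <- which(stats::runif(n) < drive_rate)
          nxt <- union(nxt, spont)
        }
        if (refractory) nxt <- setdiff(nxt, act)
        act <- nxt
      }
      if (length(act) > 0L) out[act, t] <- 1L
    }
    out
  })
  r <- mua_raster(events, seq_len(n) - 1L, steps)
  r$step_ms <- 1L
  r$sigma <- net$sigma
  r$seed <- seed
  r$steps <- steps
  class(r) <- c("sim_raster", class(r))
  r
}

#' @export
print.sim_raster <- function(x, ...) {
  cat(sprintf("<sim_raster> %d units x %d steps (sigma = %g), %d events\n",
              nrow(x$events), x$steps, x$sigma, sum(x$events)))
  invisible(x)
}

#' Sample from a bounded discrete power law
#'
#' Exact inverse-CDF draws with `P(k) proportional to k^(-alpha)` on the
#' integer support `[x_min, x_max]`. Used as the independent sampler for
#' power-law parameter-recovery checks.
#'
#' @param alpha exponent.
#' @param x_min,x_max integer support bounds.
#' @param n number of draws.
#' @param seed RNG seed.
#' @return integer vector of length `n`.
#' @export
sample_bounded_power_law <- function(alpha, x_min, x_max, n, seed = NULL) {
  if (x_min < 1 || x_min > x_max) stop("need 1 <= x_min <= x_max")
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1")
  support <- seq.int(x_min, x_max)
  p <- support^(-alpha)
  cdf <- cumsum(p / sum(p))
  with_seed(seed, {
    u <- stats::runif(n)
    support[pmin(findInterval(u, cdf) + 1L, length(support))]
  })
}

# Run one branching cascade from `init` active units until extinction or
# `max_steps`, with 1-step refractoriness. Returns the N x L event matrix.
run_cascade <- function(net, init, max_steps = 500L) {
  n <- net$n_units
  lq <- log1p(-net$prob_matrix)
  cols <- vector("list", max_steps)
  act <- init
  t <- 0L
  while (length(act) > 0L && t < max_steps) {
    t <- t + 1L
    col <- integer(n)
    col[act] <- 1L
    cols[[t]] <- col
    l <- if (length(act) == 1L) lq[act, ] else colSums(lq[act, , drop = FALSE])
    nxt <- which(stats::runif(n) < -expm1(l))
    act <- setdiff(nxt, act)
  }
  matrix(unlist(cols[seq_len(t)]), nrow = n)
}

#' Simulate a session with planted burst predictors
#'
#' Emulates an MEA recording: sparse independent background spiking on
#' every channel, rare network bursts, and a handful of planted units that
#' fire almost exclusively in the 50 ms preceding those bursts - the rare,
#' low-rate, high-specificity burst predictors seen in cortical cultures.
#' Population events are scheduled as a Poisson process at `event_rate_hz`
#' (with a 2 s minimum separation) and each is realized by seeding several
#' units of the branching network and running the cascade until extinction;
#' cascades are re-drawn (up to 20 attempts) until they recruit at least
#' `burst_frac` of the units, so every scheduled event is a genuine
#' network-wide burst. Planted units are silent except for a pre-burst
#' event placed 10-50 ms before each onset with probability `hit_prob` and
#' sparse background at `predictor_bg_rate_hz`.
#'
#' @param net a [build_network()] result, typically at `sigma = 1`.
#' @param duration_ms session length in ms (default 20 min, one full
#'   recording session).
#' @param seed RNG seed.
#' @param n_predictors number of planted predictor units.
#' @param predictor_ids which units (1-based) to plant; defaults to a
#'   seeded draw.
#' @param event_rate_hz rate of scheduled network bursts.
#' @param background_rate_hz background rate of ordinary units.
#' @param predictor_bg_rate_hz unspecific background rate of planted units.
#' @param burst_frac fraction of units a cascade must recruit.
#' @param hit_prob probability a planted unit fires before a given event.
#' @param predictor_window_ms `c(min, max)` lead time of planted events.
#' @param n_seed_units units seeded to trigger each cascade.
#' @return list with `raster` (an [mua_raster()]), `planted` (unit ids,
#'   0-based, as characters matching `channel_ids`), and `event_onsets_ms`.
#' @export
simulate_planted_session <- function(net, duration_ms = 1200000, seed = NULL,
                                     n_predictors = 3, predictor_ids = NULL,
                                     event_rate_hz = 0.05,
                                     background_rate_hz = 0.5,
                                     predictor_bg_rate_hz = 0.02,
                                     burst_frac = 0.5, hit_prob = 0.9,
                                     predictor_window_ms = c(10, 50),
                                     n_seed_units = NULL) {
  stopifnot(inherits(net, "branching_net"))
  n <- net$n_units
  duration_ms <- as.integer(duration_ms)
  n_seed_units <- as.integer(n_seed_units %||% max(2L, ceiling(0.1 * n)))
  w_lo <- predictor_window_ms[1]
  w_hi <- predictor_window_ms[2]
  with_seed(seed, {
    planted <- predictor_ids %||% sample.int(n, n_predictors)
    ordinary <- setdiff(seq_len(n), planted)
    m <- matrix(0L, n, duration_ms)
    # sparse independent background on ordinary units
    p_bg <- background_rate_hz / 1000
    for (u in ordinary) {
      n_ev <- stats::rbinom(1L, duration_ms, p_bg)
      if (n_ev > 0L) m[u, sample.int(duration_ms, n_ev)] <- 1L
    }
    # scheduled population events, >= 2 s apart, clear of the session edges
    gaps <- stats::rexp(max(10L, ceiling(duration_ms / 1000 * event_rate_hz * 3)),
                        event_rate_hz / 1000) + 2000
    onsets <- cumsum(gaps) + w_hi
    onsets <- floor(onsets[onsets < duration_ms - 600])
    for (on in onsets) {
      best <- NULL
      for (try in seq_len(20L)) {
        casc <- run_cascade(net, sample.int(n, n_seed_units))
        if (is.null(best) || sum(rowSums(casc) > 0) > sum(rowSums(best) > 0)) {
          best <- casc
        }
        if (sum(rowSums(best) > 0) >= burst_frac * n) break
      }
      len <- min(ncol(best), duration_ms - on)
      blk <- on + seq_len(len)
      m[, blk] <- pmax(m[, blk, drop = FALSE], best[, seq_len(len), drop = FALSE])
    }
    # planted predictors: pre-burst events + sparse background
    for (u in planted) {
      fire <- onsets[stats::runif(length(onsets)) < hit_prob]
      t_ev <- fire - floor(stats::runif(length(fire), w_lo, w_hi + 1))
      n_bg <- stats::rbinom(1L, duration_ms, predictor_bg_rate_hz / 1000)
      bg <- if (n_bg > 0L) sample.int(duration_ms, n_bg) else integer(0)
      m[u, unique(c(t_ev + 1L, bg))] <- 1L
    }
    list(
      raster = mua_raster(m, seq_len(n) - 1L, duration_ms),
      planted = as.character(planted - 1L),
      event_onsets_ms = onsets
    )
  })
}

#' Generate a matched pre/post insult session pair
#'
#' Produces two sessions from the same near-critical branching network with
#' planted strong burst predictors (see [simulate_planted_session()]), then
#' applies a profile-dependent perturbation to the post session that
#' emulates an excitotoxic insult: a fraction of the non-predictor ("weak")
#' units is silenced outright, the surviving weak units' rates are thinned
#' and jittered, and the planted predictors are left untouched. The
#' `control` profile silences nothing and applies only the jitter.
#'
#' @param profile `"control"`, `"low_kill"`, or `"high_kill"`.
#' @param seed master RNG seed (network, sessions and perturbations derive
#'   from it deterministically).
#' @param n_units number of units.
#' @param sigma branching parameter of the generating network.
#' @param duration_ms session length in ms (default 20 min, a full
#'   recording session).
#' @param n_predictors number of planted predictors.
#' @param silence_frac fraction of weak units silenced post-insult;
#'   defaults per profile to 0 / 0.2 / 0.5.
#' @param rate_factor post-insult event-retention probability for surviving
#'   weak units; defaults per profile to 1 / 0.9 / 0.6.
#' @param jitter_sd multiplicative rate jitter (s.d.) applied to surviving
#'   weak units.
#' @param ... further arguments passed to [simulate_planted_session()].
#' @return list of class `insult_fixture` with `pre` and `post` rasters,
#'   and `ground_truth`: `planted` ids, `silenced` ids, realized
#'   `delta_rate_hz` per unit, and the profile parameters.
#' @export
generate_session_pair <- function(profile = c("control", "low_kill", "high_kill"),
                                  seed, n_units = 60, sigma = 1.0,
                                  duration_ms = 1200000, n_predictors = 3,
                                  silence_frac = NULL, rate_factor = NULL,
                                  jitter_sd = 0.05, ...) {
  profile <- match.arg(profile)
  silence_frac <- silence_frac %||%
    switch(profile, control = 0, low_kill = 0.2, high_kill = 0.5)
  rate_factor <- rate_factor %||%
    switch(profile, control = 1, low_kill = 0.9, high_kill = 0.6)
  net <- build_network(n_units, sigma, seed = seed)
  pre <- simulate_planted_session(net, duration_ms, seed = seed + 1L,
                                  n_predictors = n_predictors, ...)
  post <- simulate_planted_session(net, duration_ms, seed = seed + 101L,
                                   n_predictors = n_predictors,
                                   predictor_ids = as.integer(pre$planted) + 1L,
                                   ...)
  m_post <- post$raster$events
  weak <- setdiff(seq_len(n_units), as.integer(pre$planted) + 1L)
  silenced <- with_seed(seed + 201L, {
    n_sil <- floor(silence_frac * length(weak))
    sil <- if (n_sil > 0L) sample(weak, n_sil) else integer(0)
    m_post[sil, ] <- 0L
    for (u in setdiff(weak, sil)) {
      keep_p <- min(1, rate_factor * exp(stats::rnorm(1, 0, jitter_sd)))
      if (keep_p < 1) {
        idx <- which(m_post[u, ] == 1L)
        drop <- idx[stats::runif(length(idx)) >= keep_p]
        m_post[u, drop] <- 0L
      }
    }
    sil
  })
  post_raster <- mua_raster(m_post, post$raster$channel_ids, duration_ms)
  dur_s <- duration_ms / 1000
  structure(
    list(
      pre = pre$raster, post = post_raster,
      ground_truth = list(
        profile = profile,
        planted = pre$planted,
        silenced = as.character(silenced - 1L),
        delta_rate_hz = stats::setNames(
          (rowSums(post_raster$events) - rowSums(pre$raster$events)) / dur_s,
          post_raster$channel_ids),
        silence_frac = silence_frac, rate_factor = rate_factor,
        sigma = sigma, seed = seed
      )
    ),
    class = "insult_fixture"
  )
}
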