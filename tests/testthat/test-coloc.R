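coincident_pair <- function(n_coloc = 10, n_total = 12, sep = 0,
                            state2 = NULL, dt = 0.0305) {
  # channel-2 track rides on channel 1 for the first n_coloc frames,
  # then jumps far away
  x1 <- seq(0, 1, length.out = n_total)
  x2 <- x1 + c(rep(sep, n_coloc), rep(5, n_total - n_coloc))
  ts <- make_track_set(track_rows("a", x1, rep(0, n_total), channel = 1),
                       track_rows("b", x2, rep(0, n_total), channel = 2),
                       dt = dt)
  lab <- labels_for(ts)
  if (!is.null(state2))
    lab$state[lab$channel == 2] <- state2
  list(ts = ts, lab = lab)
}

test_that("distance and state criteria define events", {
  p <- coincident_pair()
  ev <- detect_coloc(p$ts, p$lab)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_frame, 0L)
  expect_equal(ev$end_frame, 9L)
  expect_equal(ev$duration_s, 10 * 0.0305)
  expect_false(ev$censored)

  # constant separation beyond the radius: nothing
  far <- coincident_pair(sep = 0.15)
  expect_equal(nrow(detect_coloc(far$ts, far$lab)), 0L)

  # coincident but in different diffusion states: nothing
  mis <- coincident_pair(state2 = 2L)
  expect_equal(nrow(detect_coloc(mis$ts, mis$lab)), 0L)
  # ... unless the state criterion is disabled
  expect_equal(nrow(detect_coloc(mis$ts, mis$lab,
                                 require_same_state = FALSE)), 1L)
})

test_that("a single-frame gap splits an event", {
  x2 <- c(0, 0, 5, 0, 0)
  ts <- make_track_set(track_rows("a", rep(0, 5), rep(0, 5), channel = 1),
                       track_rows("b", x2, rep(0, 5), channel = 2),
                       dt = 0.0305)
  ev <- detect_coloc(ts, labels_for(ts))
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$start_frame, c(0L, 3L))
})

test_that("event detection is symmetric under channel swap", {
  set.seed(8)
  n <- 20
  rows <- rbind(
    track_rows("a1", cumsum(rnorm(n, 0, 0.03)), cumsum(rnorm(n, 0, 0.03)),
               channel = 1),
    track_rows("a2", 0.05 + cumsum(rnorm(n, 0, 0.03)),
               cumsum(rnorm(n, 0, 0.03)), channel = 1),
    track_rows("b1", cumsum(rnorm(n, 0, 0.03)), cumsum(rnorm(n, 0, 0.03)),
               channel = 2))
  ts <- track_set(rows, dt = 0.0305)
  lab <- labels_for(ts)
  ev <- detect_coloc(ts, lab)
  swapped <- ts
  swapped$tracks$channel <- 3L - swapped$tracks$channel
  lab2 <- lab; lab2$channel <- 3L - lab2$channel
  ev2 <- detect_coloc(track_set(swapped$tracks, dt = 0.0305), lab2)
  expect_equal(nrow(ev), nrow(ev2))
  expect_equal(ev[c("start_frame", "end_frame")],
               ev2[c("start_frame", "end_frame")])
  expect_equal(ev$track_ch1, ev2$track_ch2)
})

test_that("censoring-aware MLE reduces to the closed form when uncensored", {
  set.seed(5)
  dt <- 0.0305
  dur <- dt * ceiling(stats::rexp(400, 1 / 0.3) / dt)
  mle <- censored_exp_mle(dur, censored = FALSE, truncation = dt)
  expect_equal(mle$rate, 1 / (mean(dur) - dt), tolerance = 1e-12)
  # censored events add exposure but no counts
  mle2 <- censored_exp_mle(c(dur, 1), censored = c(rep(FALSE, 400), TRUE),
                           truncation = dt)
  expect_equal(mle2$rate,
               400 / (sum(dur - dt) + 1 - dt), tolerance = 1e-12)
  und <- censored_exp_mle(c(1, 2), censored = TRUE, truncation = dt)
  expect_true(is.na(und$rate))
})

test_that("no events yields a zero on-rate and an undefined k_off", {
  p <- coincident_pair(sep = 0.2)
  ks <- coloc_kinetics(detect_coloc(p$ts, p$lab), p$ts)
  expect_equal(ks$on_rate, 0)
  expect_false(ks$k_off_defined)
})

binding_cfg <- function(k_on, seed, n_tracks = 200, tau = 0.3,
                        field = 100) {
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2)
  spt_config(K = 2, D = c(0.05, 0.3), A = A, pi = c(0.5, 0.5),
             sigma_loc = 0.01, dt = 0.0305, n_frames = 300,
             n_tracks = n_tracks, field = field,
             binding = list(k_on = k_on, tau = tau, offset_sd = 0.01),
             bleach_rate = 1, seed = seed)
}

test_that("scripted binding lifetime is recovered within 15%", {
  cfg <- binding_cfg(k_on = 0.5, seed = 71)
  sim <- simulate_tracks(cfg)
  tb <- sim$truth$binding
  expect_gt(nrow(tb), 500)
  # dissociation-rate estimator on the realized bound intervals
  dur <- (tb$end_frame - tb$start_frame + 1L) * cfg$dt
  mle <- censored_exp_mle(dur, tb$censored, truncation = cfg$dt)
  expect_lt(abs(mle$mean_lifetime - 0.3) / 0.3, 0.15)

  # the detector finds at least the scripted events; the extra short
  # events are post-dissociation re-encounters (the pair starts the
  # frame after unbinding still within the radius), so the
  # proximity-based lifetime underestimates the bond lifetime
  ev <- detect_coloc(sim$tracks, truth_labels(sim))
  ks <- coloc_kinetics(ev, sim$tracks)
  expect_gt(ks$n_events, nrow(tb))
  expect_lt(ks$mean_lifetime, mle$mean_lifetime)
})

test_that("doubling the scripted on-rate doubles the measured on-rate", {
  # low duty cycle (k_on * tau << 1): the free-particle pool is
  # essentially undepleted and the event count is linear in k_on
  s1 <- simulate_tracks(binding_cfg(k_on = 0.15, seed = 81,
                                    n_tracks = 150, tau = 0.2))
  s2 <- simulate_tracks(binding_cfg(k_on = 0.3, seed = 82,
                                    n_tracks = 150, tau = 0.2))
  k1 <- clustered_on_rate(detect_coloc(s1$tracks, truth_labels(s1)), s1)
  k2 <- clustered_on_rate(detect_coloc(s2$tracks, truth_labels(s2)), s2)
  ratio <- k2$rate / k1$rate
  se <- ratio * sqrt((k1$se / k1$rate)^2 + (k2$se / k2$rate)^2)
  expect_lt(abs(ratio - 2), 3 * se)
})

test_that("the shuffled baseline calibrates chance colocalization", {
  # independent channels: observed rate is within the chance spread
  cfg <- binding_cfg(k_on = 0, seed = 91, n_tracks = 120, field = 25)
  cfg$binding <- NULL
  sim <- simulate_tracks(cfg)
  lab <- truth_labels(sim)
  obs <- coloc_kinetics(detect_coloc(sim$tracks, lab), sim$tracks)$on_rate
  base <- chance_coloc_baseline(sim$tracks, lab, field = 25,
                                n_shuffles = 8, seed = 2)
  expect_lt(abs(obs - base$mean), 3 * base$sd)

  # scripted binding pushes the observed rate above chance
  simb <- simulate_tracks(binding_cfg(k_on = 0.5, seed = 92,
                                      n_tracks = 120, field = 25))
  labb <- truth_labels(simb)
  obsb <- coloc_kinetics(detect_coloc(simb$tracks, labb), simb$tracks)$on_rate
  baseb <- chance_coloc_baseline(simb$tracks, labb, field = 25,
                                 n_shuffles = 8, seed = 3)
  expect_gt(obsb, baseb$mean + 3 * baseb$sd)

  # no channel-2 particles at all: baseline is exactly zero
  ch1_only <- track_set(sim$tracks$tracks[sim$tracks$tracks$channel == 1, ],
                        dt = cfg$dt)
  base0 <- chance_coloc_baseline(ch1_only, lab, field = 25,
                                 n_shuffles = 3, seed = 4)
  expect_equal(base0$mean, 0)
})
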