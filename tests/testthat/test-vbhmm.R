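test_that("K=1 fit recovers the displacement variance of free diffusion", {
  cfg <- spt_config(K = 1, D = 0.1, A = matrix(1, 1, 1), pi = 1,
                    sigma_loc = 0, dt = 1, n_frames = 100,
                    n_tracks = 120, field = 500, bleach_rate = 1,
                    seed = 11)
  sim <- simulate_tracks(cfg)
  fit <- vb_fit(sim$tracks, K = 1, n_restarts = 1)
  r2 <- unlist(sptkit:::displacement_list(sim$tracks)$r2)
  n <- 2 * length(r2)                      # per-axis samples
  se <- 0.2 * sqrt(2 / n)                  # chi^2 sampling error of the variance
  expect_lt(abs(fit$model$sigma2 - 2 * 0.1 * 1), 3 * se)
  expect_lt(abs(fit$model$D - 0.1), 0.1 * 0.1)
})

test_that("two-state fit recovers D and the transition matrix", {
  A <- matrix(c(0.95, 0.05, 0.05, 0.95), 2, 2, byrow = TRUE)
  cfg <- spt_config(K = 2, D = c(0.01, 0.3), A = A, pi = c(0.5, 0.5),
                    sigma_loc = 0, dt = 0.03, n_frames = 200,
                    n_tracks = 120, field = 100, bleach_rate = 1,
                    seed = 5)
  sim <- simulate_tracks(cfg)
  fit <- vb_fit(sim$tracks, K = 2, channel = 1, n_restarts = 3)
  expect_lt(abs(fit$model$D[1] - 0.01) / 0.01, 0.10)
  expect_lt(abs(fit$model$D[2] - 0.3) / 0.3, 0.10)
  expect_lt(max(abs(diag(fit$model$A) - diag(A))), 0.05)
})

test_that("the lower bound is non-decreasing over iterations", {
  sim <- simulate_tracks(default_config(n_tracks = 40, seed = 3))
  for (K in c(2, 4)) {
    fit <- vb_fit(sim$tracks, K, channel = 1, n_restarts = 1)
    tr <- fit$model$elbo_trace
    expect_true(all(diff(tr) >= -1e-8 * abs(tr[-length(tr)])))
  }
})

test_that("E-step marginals match brute-force enumeration", {
  set.seed(42)
  for (K in 1:2) {
    r2 <- list(stats::rexp(6, 50), stats::rexp(4, 10), stats::rexp(2, 30))
    ln_pi <- log(seq_len(K) / sum(seq_len(K)))
    A <- matrix(stats::runif(K * K) + 0.2, K, K); A <- A / rowSums(A)
    ln_A <- log(A) - 0.05                  # deliberately subnormalized
    ln_lam <- log(c(20, 200))[seq_len(K)]
    E_lam <- exp(ln_lam) * 1.1
    es <- sptkit:::fb_estep(r2, ln_pi, ln_A, ln_lam, E_lam)
    br <- brute_hmm_marginals(r2, ln_pi, ln_A, ln_lam, E_lam)
    for (i in seq_along(r2)) {
      g <- es$gamma[(es$offsets[i] + 1L):es$offsets[i + 1L], , drop = FALSE]
      expect_lt(max(abs(g - br$gamma[[i]])), 1e-10)
    }
    expect_lt(abs(es$logZ - br$logZ), 1e-8 * abs(br$logZ))
  }
})

test_that("restart perturbations converge to the same canonical model", {
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  cfg <- spt_config(K = 2, D = c(0.02, 0.4), A = A, pi = c(0.5, 0.5),
                    sigma_loc = 0, dt = 0.03, n_frames = 100,
                    n_tracks = 60, field = 100, bleach_rate = 1,
                    seed = 8)
  sim <- simulate_tracks(cfg)
  f1 <- vb_fit(sim$tracks, 2, n_restarts = 1, seed = 1)
  f2 <- vb_fit(sim$tracks, 2, n_restarts = 4, seed = 77)
  expect_equal(f1$model$sigma2, f2$model$sigma2, tolerance = 1e-4)
  expect_equal(f1$model$A, f2$model$A, tolerance = 1e-3)
  expect_true(all(diff(f1$model$sigma2) > 0))
})

test_that("model selection finds the true K on well-separated data", {
  # single diffusive state: extra states are unsupported
  cfg1 <- spt_config(K = 1, D = 0.1, A = matrix(1, 1, 1), pi = 1,
                     sigma_loc = 0, dt = 0.03, n_frames = 150,
                     n_tracks = 80, field = 100, bleach_rate = 1,
                     seed = 19)
  sel1 <- select_model(simulate_tracks(cfg1)$tracks, K_range = 1:3,
                       n_restarts = 2, seed = 2)
  expect_equal(sel1$K, 1L)

  # two states with identical D collapse to one
  A <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  cfg2 <- spt_config(K = 2, D = c(0.1, 0.1), A = A, pi = c(0.5, 0.5),
                     sigma_loc = 0, dt = 0.03, n_frames = 150,
                     n_tracks = 80, field = 100, bleach_rate = 1,
                     seed = 23)
  sel2 <- select_model(simulate_tracks(cfg2)$tracks, K_range = 1:3,
                       n_restarts = 2, seed = 3)
  expect_equal(sel2$K, 1L)
})

test_that("state fractions are per-cell proportions that sum to one", {
  sim <- simulate_tracks(default_config(n_tracks = 40, seed = 6))
  fit <- vb_fit(sim$tracks, 4, channel = 1, sigma_loc = 0.02,
                n_restarts = 1)
  fr <- state_fractions(fit)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)

  # degenerate case: every displacement in one state
  asg <- data.frame(cell_id = "c", channel = 1, track_id = "t",
                    frame = 0:9, state = 2L)
  fr1 <- state_fractions(asg, K = 3)
  expect_equal(fr1$fraction, c(0, 1, 0))
  expect_error(state_fractions(asg[0, ], K = 3), "empty")
})

test_that("recovered state fractions match simulated occupancy", {
  A <- matrix(0.02, 4, 4); diag(A) <- 0.94
  cfg <- spt_config(K = 4, D = c(0.002, 0.05, 0.5, 4), A = A,
                    pi = rep(0.25, 4), sigma_loc = 0, dt = 0.03,
                    n_frames = 150, n_tracks = 150, field = 200,
                    bleach_rate = 1, seed = 42)
  sim <- simulate_tracks(cfg)
  fit <- vb_fit(sim$tracks, 4, channel = 1, n_restarts = 2)
  fr <- state_fractions(fit)
  st <- sim$truth$states[sim$truth$states$channel == 1, ]
  # occupancy of displacements = state of the frame the step leaves
  key <- paste(st$track_id)
  leave <- unlist(lapply(split(st$state, key), function(s) s[-length(s)]))
  truth_frac <- tabulate(leave, 4) / length(leave)
  per_track <- do.call(rbind, lapply(split(st$state, key), function(s)
    tabulate(s[-length(s)], 4) / max(1, length(s) - 1)))
  se <- apply(per_track, 2, stats::sd) / sqrt(nrow(per_track))
  expect_true(all(abs(fr$fraction - truth_frac) < 3 * se))
})

test_that("degenerate inputs raise informative errors", {
  ts <- make_track_set(track_rows("t1", 0.1, 0.2))   # single-frame track
  expect_error(vb_fit(ts, K = 1), "2 frames")
  sim <- simulate_tracks(default_config(n_tracks = 5, seed = 1))
  expect_error(vb_fit(sim$tracks, K = 0), "K")
  expect_error(select_model(sim$tracks, K_range = integer()), "empty")
})
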