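# Independent brute-force oracles used to validate the fast
# implementations on tiny instances.

# HMM smoothing marginals by full enumeration of all K^T label
# sequences, using the same tilde parameterization as the E-step.
brute_hmm_marginals <- function(r2_list, ln_pi, ln_A, ln_lam, E_lam) {
  K <- length(ln_pi)
  logZ <- 0
  gammas <- lapply(r2_list, function(r2) {
    Tn <- length(r2)
    seqs <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
    lw <- apply(seqs, 1, function(s) {
      w <- ln_pi[s[1]] +
        sum(ln_lam[s] - log(2 * pi) - E_lam[s] * r2 / 2)
      if (Tn >= 2) for (t in 2:Tn) w <- w + ln_A[s[t - 1], s[t]]
      w
    })
    m <- max(lw)
    logZ <<- logZ + m + log(sum(exp(lw - m)))
    w <- exp(lw - m); w <- w / sum(w)
    g <- matrix(0, Tn, K)
    for (t in seq_len(Tn)) for (k in seq_len(K))
      g[t, k] <- sum(w[seqs[, t] == k])
    g
  })
  list(gamma = gammas, logZ = logZ)
}

# Posterior component probabilities of the constrained intensity
# mixture by direct Bayes computation, one point at a time.
brute_mixture_resp <- function(x, mu1, sigma1, w) {
  n_max <- length(w)
  t(vapply(x, function(xi) {
    joint <- vapply(seq_len(n_max), function(n)
      w[n] * exp(-(xi - n * mu1)^2 / (2 * n * sigma1^2)) /
        sqrt(2 * pi * n * sigma1^2), numeric(1))
    joint / sum(joint)
  }, numeric(n_max)))
}

# Pooled-pair MSD: mean over every displacement pair at each lag,
# enumerated explicitly.
brute_pooled_msd <- function(blocks, max_lag) {
  vapply(seq_len(max_lag), function(lag) {
    d2 <- unlist(lapply(blocks, function(b) {
      L <- nrow(b)
      if (L <= lag) return(numeric(0))
      out <- numeric(L - lag)
      for (i in seq_len(L - lag))
        out[i] <- (b$x_um[i + lag] - b$x_um[i])^2 +
          (b$y_um[i + lag] - b$y_um[i])^2
      out
    }))
    mean(d2)
  }, numeric(1))
}

# Hand-buildable track set: one row per (track, frame).
make_track_set <- function(..., dt = 0.0305) {
  track_set(do.call(rbind, list(...)), dt = dt)
}

track_rows <- function(track_id, x, y, channel = 1, cell_id = "c1",
                       intensity = 100, frame0 = 0L) {
  data.frame(cell_id = cell_id, channel = channel, track_id = track_id,
             frame = frame0 + seq_along(x) - 1L, x_um = x, y_um = y,
             intensity = rep_len(intensity, length(x)),
             stringsAsFactors = FALSE)
}

labels_for <- function(ts, state = 1L) {
  tr <- ts$tracks
  data.frame(cell_id = tr$cell_id, channel = tr$channel,
             track_id = tr$track_id, frame = tr$frame,
             state = rep_len(state, nrow(tr)), stringsAsFactors = FALSE)
}

# Labels straight from simulation ground truth (bypasses the HMM).
truth_labels <- function(sim) {
  st <- sim$truth$states
  data.frame(cell_id = st$cell_id, channel = st$channel,
             track_id = st$track_id, frame = st$frame,
             state = st$state, stringsAsFactors = FALSE)
}

# On-event rate with a cluster-robust SE: events initiated by the same
# channel-2 particle are correlated (re-encounter bursts), so the SE
# is computed across per-particle event counts, not from a Poisson
# total.
clustered_on_rate <- function(events, sim) {
  ids <- sprintf("c2_t%04d", seq_len(sim$config$n_tracks))
  counts <- as.numeric(table(factor(events$track_ch2, levels = ids)))
  total_time <- sum(sim$tracks$tracks$channel == 1) * sim$config$dt
  list(rate = sum(counts) / total_time,
       se = sqrt(length(counts) * stats::var(counts)) / total_time,
       n = sum(counts))
}
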