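# Synthetic two-channel track generator with known ground truth.
#
# Motion model per frame: a particle in state k takes an isotropic
# Gaussian step of per-axis variance 2*D_k*dt; confined states move in
# an L x L reflecting square anchored at the position where the state
# was entered. Observed positions add Gaussian localization noise.
# Scripted binding tethers a channel-2 particle to a channel-1 particle
# for an exponential lifetime; while bound the pair shares the true
# position (plus a small offset) and the diffusion state.

reflect_coord <- function(v, lo, hi) {
  rng <- hi - lo
  y <- (v - lo) %% (2 * rng)
  if (y > rng) y <- 2 * rng - y
  lo + y
}

sample_state <- function(cum_row, u) {
  # first index whose cumulative probability exceeds u
  sum(u > cum_row) + 1L
}

track_length <- function(n_frames, bleach_rate) {
  if (bleach_rate >= 1) return(n_frames)
  min(n_frames, stats::rgeom(1L, 1 - bleach_rate) + 1L)
}

# Simulate one free-running track; returns true positions and states.
sim_single_track <- function(cfg, L) {
  K <- cfg$K
  cumA <- t(apply(cfg$A, 1L, cumsum))
  dim(cumA) <- c(K, K)
  sd_step <- sqrt(2 * cfg$D * cfg$dt)
  x <- y <- numeric(L)
  s <- integer(L)
  x[1] <- stats::runif(1, 0, cfg$field)
  y[1] <- stats::runif(1, 0, cfg$field)
  s[1] <- sample_state(cumsum(cfg$pi), stats::runif(1))
  cx <- x[1]; cy <- y[1]             # domain anchor (state entry)
  if (L >= 2L) {
    us <- stats::runif(L - 1L)
    ex <- stats::rnorm(L - 1L)
    ey <- stats::rnorm(L - 1L)
    for (t in 2:L) {
      k <- sample_state(cumA[s[t - 1L], ], us[t - 1L])
      if (k != s[t - 1L]) { cx <- x[t - 1L]; cy <- y[t - 1L] }
      s[t] <- k
      px <- x[t - 1L] + sd_step[k] * ex[t - 1L]
      py <- y[t - 1L] + sd_step[k] * ey[t - 1L]
      Lk <- cfg$confinement[k]
      if (!is.na(Lk)) {
        px <- reflect_coord(px, cx - Lk / 2, cx + Lk / 2)
        py <- reflect_coord(py, cy - Lk / 2, cy + Lk / 2)
      } else {
        px <- reflect_coord(px, 0, cfg$field)
        py <- reflect_coord(py, 0, cfg$field)
      }
      x[t] <- px; y[t] <- py
    }
  }
  list(x = x, y = y, s = s)
}

draw_order <- function(cfg, state) {
  w <- cfg$intensity$oligomer_weights
  if (is.null(w)) return(1L)
  sample.int(ncol(w), 1L, prob = w[state, ])
}

spot_intensity <- function(cfg, order, n) {
  mu1 <- cfg$intensity$mu1
  stats::rnorm(n, order * mu1, sqrt(order) * cfg$intensity$cv1 * mu1)
}

#' Simulate a two-channel single-molecule track set
#'
#' Generates channel-1 and channel-2 tracks under the switching-
#' diffusion model of the configuration, with optional scripted binding
#' of channel-2 particles to channel-1 particles, and returns the
#' observed tracks together with full ground truth (per-frame true
#' states, binding intervals, per-track oligomer orders). Identical
#' seeds give identical output.
#'
#' @param cfg an [spt_config()].
#' @param cell_id identifier stored in the track table.
#' @return list of class `spt_sim` with elements `tracks` (a
#'   [track_set()] holding both channels), `truth` (list with
#'   data.frames `states`, `binding`, `orders`) and `config`.
#' @export
simulate_tracks <- function(cfg, cell_id = "cell01") {
  cfg <- validate_spt_config(cfg)
  set.seed(cfg$seed)
  nfr <- cfg$n_frames

  ## ---- channel 1: independent tracks
  ch1 <- vector("list", cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    L <- track_length(nfr, cfg$bleach_rate)
    ch1[[i]] <- sim_single_track(cfg, L)
  }
  # frame-indexed lookup used by the binding script
  pos1x <- matrix(NA_real_, nfr, cfg$n_tracks)
  pos1y <- matrix(NA_real_, nfr, cfg$n_tracks)
  st1 <- matrix(NA_integer_, nfr, cfg$n_tracks)
  for (i in seq_len(cfg$n_tracks)) {
    L <- length(ch1[[i]]$x)
    pos1x[seq_len(L), i] <- ch1[[i]]$x
    pos1y[seq_len(L), i] <- ch1[[i]]$y
    st1[seq_len(L), i] <- ch1[[i]]$s
  }

  ## ---- channel 2: free diffusion interrupted by scripted binding
  bnd <- cfg$binding
  p_bind <- if (is.null(bnd)) 0 else 1 - exp(-bnd$k_on * cfg$dt)
  ch2 <- vector("list", cfg$n_tracks)
  events <- list()
  cumA <- t(apply(cfg$A, 1L, cumsum)); dim(cumA) <- c(cfg$K, cfg$K)
  sd_step <- sqrt(2 * cfg$D * cfg$dt)
  for (i in seq_len(cfg$n_tracks)) {
    L <- track_length(nfr, cfg$bleach_rate)
    x <- y <- numeric(L); s <- integer(L)
    x[1] <- stats::runif(1, 0, cfg$field)
    y[1] <- stats::runif(1, 0, cfg$field)
    s[1] <- sample_state(cumsum(cfg$pi), stats::runif(1))
    cx <- x[1]; cy <- y[1]
    bound_until <- -1L; bound_end_raw <- -1L; partner <- NA_integer_
    t <- 1L
    while (t <= L) {
      if (t > 1L && t > bound_until) {
        # free diffusion step from previous position
        k <- sample_state(cumA[s[t - 1L], ], stats::runif(1))
        if (k != s[t - 1L]) { cx <- x[t - 1L]; cy <- y[t - 1L] }
        s[t] <- k
        px <- x[t - 1L] + sd_step[k] * stats::rnorm(1)
        py <- y[t - 1L] + sd_step[k] * stats::rnorm(1)
        Lk <- cfg$confinement[k]
        if (!is.na(Lk)) {
          px <- reflect_coord(px, cx - Lk / 2, cx + Lk / 2)
          py <- reflect_coord(py, cy - Lk / 2, cy + Lk / 2)
        } else {
          px <- reflect_coord(px, 0, cfg$field)
          py <- reflect_coord(py, 0, cfg$field)
        }
        x[t] <- px; y[t] <- py
      }
      if (t <= bound_until) {
        # tethered to the partner: shared position and state
        if (is.na(pos1x[t, partner])) {          # partner bleached
          ev <- events[[length(events)]]
          ev$end_frame <- t - 2L                 # last tethered frame, 0-based
          ev$censored <- TRUE
          events[[length(events)]] <- ev
          bound_until <- -1L
          s[t] <- s[t - 1L]; x[t] <- x[t - 1L]; y[t] <- y[t - 1L]
          cx <- x[t]; cy <- y[t]
        } else {
          x[t] <- pos1x[t, partner] + stats::rnorm(1, 0, bnd$offset_sd)
          y[t] <- pos1y[t, partner] + stats::rnorm(1, 0, bnd$offset_sd)
          s[t] <- st1[t, partner]
          if (t == bound_until) {
            ev <- events[[length(events)]]
            ev$end_frame <- t - 1L
            ev$censored <- (bound_end_raw > L)   # cut short by track end
            events[[length(events)]] <- ev
            bound_until <- -1L
            cx <- x[t]; cy <- y[t]
          }
        }
      } else if (p_bind > 0 && stats::runif(1) < p_bind) {
        alive <- which(!is.na(pos1x[t, ]))
        if (length(alive)) {
          partner <- alive[sample.int(length(alive), 1L)]
          life <- stats::rexp(1, 1 / bnd$tau)
          dur <- max(1L, as.integer(ceiling(life / cfg$dt)))
          bound_end_raw <- t - 1L + dur
          bound_until <- min(L, bound_end_raw)
          events[[length(events) + 1L]] <-
            list(track_ch1 = partner, track_ch2 = i,
                 start_frame = t - 1L, end_frame = NA_integer_,
                 lifetime_s = life, censored = FALSE)
          x[t] <- pos1x[t, partner] + stats::rnorm(1, 0, bnd$offset_sd)
          y[t] <- pos1y[t, partner] + stats::rnorm(1, 0, bnd$offset_sd)
          s[t] <- st1[t, partner]
          if (t == bound_until) {
            ev <- events[[length(events)]]
            ev$end_frame <- t - 1L
            ev$censored <- (bound_end_raw > L)
            events[[length(events)]] <- ev
            bound_until <- -1L
            cx <- x[t]; cy <- y[t]
          }
        }
      }
      t <- t + 1L
    }
    ch2[[i]] <- list(x = x, y = y, s = s)
  }

  ## ---- assemble observed table and ground truth
  rows <- list(); states <- list(); orders <- list()
  for (ch in 1:2) {
    trks <- if (ch == 1L) ch1 else ch2
    for (i in seq_along(trks)) {
      tk <- trks[[i]]
      L <- length(tk$x)
      ord <- draw_order(cfg, tk$s[1])
      tid <- sprintf("c%d_t%04d", ch, i)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell_id, channel = ch, track_id = tid,
        frame = 0:(L - 1L),
        x_um = tk$x + stats::rnorm(L, 0, cfg$sigma_loc),
        y_um = tk$y + stats::rnorm(L, 0, cfg$sigma_loc),
        intensity = spot_intensity(cfg, ord, L),
        stringsAsFactors = FALSE)
      states[[length(states) + 1L]] <- data.frame(
        cell_id = cell_id, channel = ch, track_id = tid,
        frame = 0:(L - 1L), state = tk$s, stringsAsFactors = FALSE)
      orders[[length(orders) + 1L]] <- data.frame(
        cell_id = cell_id, channel = ch, track_id = tid,
        order = ord, stringsAsFactors = FALSE)
    }
  }
  binding <- if (length(events)) {
    ev <- do.call(rbind, lapply(events, as.data.frame))
    ev <- ev[ev$end_frame >= ev$start_frame, , drop = FALSE]
    ev$cell_id <- cell_id
    ev$track_ch1 <- sprintf("c1_t%04d", ev$track_ch1)
    ev$track_ch2 <- sprintf("c2_t%04d", ev$track_ch2)
    ev[c("cell_id", "track_ch1", "track_ch2", "start_frame",
         "end_frame", "lifetime_s", "censored")]
  } else {
    data.frame(cell_id = character(), track_ch1 = character(),
               track_ch2 = character(), start_frame = integer(),
               end_frame = integer(), lifetime_s = numeric(),
               censored = logical())
  }
  ts <- track_set(do.call(rbind, rows), dt = cfg$dt,
                  n_frames = cfg$n_frames)
  structure(list(tracks = ts,
                 truth = list(states = do.call(rbind, states),
                              binding = binding,
                              orders = do.call(rbind, orders)),
                 config = cfg),
            class = "spt_sim")
}

#' Simulate a luminescence kinetics series
#'
#' Mono-exponential response on a constant baseline with multiplicative
#' log-normal noise: `count(t) = baseline * (1 + amplitude * (1 -
#' exp(-rate * t))) * exp(noise)`. Negative `amplitude` gives a decay
#' (e.g. receptor internalization).
#'
#' @param baseline pre-ligand luminescence count (> 0).
#' @param amplitude fractional response amplitude.
#' @param rate response rate constant (1/s).
#' @param times read times (s), strictly increasing.
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed RNG seed.
#' @return data.frame `time_s, count` with attribute `baseline`.
#' @export
simulate_assay_series <- function(baseline, amplitude, rate,
                                  times = seq(0, 900, by = 20),
                                  noise_cv = 0, seed = 1L) {
  if (baseline <= 0) stop("baseline must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)
  mu <- baseline * (1 + amplitude * (1 - exp(-rate * times)))
  noise <- if (noise_cv > 0) exp(stats::rnorm(length(times), 0, noise_cv)) else 1
  out <- data.frame(time_s = times, count = mu * noise)
  attr(out, "baseline") <- baseline
  out
}
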