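# Mean-square displacement analysis of state-segmented trajectories.

# Pooled time-averaged MSD over a list of contiguous position blocks.
# Weighting by pair counts makes the ensemble curve identical to the
# mean over all displacement pairs at each lag.
msd_from_blocks <- function(blocks, max_lag, dt, state = "all") {
  lens <- vapply(blocks, nrow, integer(1))
  if (!length(blocks) || max(lens) < 2L)
    stop("no segment long enough for lag 1")
  ss <- numeric(max_lag)
  np <- numeric(max_lag)
  for (b in blocks) {
    L <- nrow(b)
    if (L < 2L) next
    for (lag in seq_len(min(max_lag, L - 1L))) {
      i <- seq_len(L - lag)
      d2 <- (b$x_um[i + lag] - b$x_um[i])^2 + (b$y_um[i + lag] - b$y_um[i])^2
      ss[lag] <- ss[lag] + sum(d2)
      np[lag] <- np[lag] + length(i)
    }
  }
  keep <- np >= 1
  data.frame(state = state, lag_s = seq_len(max_lag)[keep] * dt,
             msd_um2 = ss[keep] / np[keep], n_pairs = np[keep],
             stringsAsFactors = FALSE)
}

#' Ensemble mean-square displacement
#'
#' Time-averaged MSD per trajectory, ensemble-averaged with pair-count
#' weights (equivalently, the pooled mean over all displacement pairs
#' at each lag).
#'
#' @param ts a [track_set()].
#' @param max_lag largest lag in frames.
#' @param channel optional channel filter.
#' @return data.frame `state, lag_s, msd_um2, n_pairs` (state = "all").
#' @export
compute_msd <- function(ts, max_lag = 10L, channel = NULL) {
  blocks <- split_tracks(ts, channel = channel, min_frames = 2L)
  msd_from_blocks(blocks, max_lag, ts$metadata$dt)
}

#' Maximal constant-state segments of labelled tracks
#'
#' Cuts each track at every change of the per-frame hard state label;
#' segments shorter than `min_len` frames are dropped (and counted in
#' attribute `n_dropped`).
#'
#' @param ts a [track_set()].
#' @param labels per-frame labels from [frame_labels()].
#' @param min_len minimum segment length in frames.
#' @return list of data.frames with a `state` column.
#' @export
state_segments <- function(ts, labels, min_len = 4L) {
  tr <- merge(ts$tracks, labels,
              by = c("cell_id", "channel", "track_id", "frame"))
  tr <- tr[order(tr$cell_id, tr$channel, tr$track_id, tr$frame), ]
  key <- paste(tr$cell_id, tr$channel, tr$track_id, sep = "|")
  newtrack <- c(TRUE, key[-1] != key[-length(key)])
  newstate <- c(TRUE, tr$state[-1] != tr$state[-length(key)])
  seg_id <- cumsum(newtrack | newstate)
  segs <- split(tr, seg_id)
  lens <- vapply(segs, nrow, integer(1))
  out <- segs[lens >= min_len]
  attr(out, "n_dropped") <- sum(lens < min_len)
  out
}

#' State-wise MSD curves
#'
#' @inheritParams state_segments
#' @param max_lag largest lag in frames.
#' @param min_len minimum segment length (frames) entering the curve.
#' @return data.frame of MSD curves stacked over states.
#' @export
state_msd <- function(ts, labels, max_lag = 10L, min_len = 4L) {
  segs <- state_segments(ts, labels, min_len = min_len)
  states <- sort(unique(vapply(segs, function(s) s$state[1], integer(1))))
  do.call(rbind, lapply(states, function(k) {
    msd_from_blocks(segs[vapply(segs, function(s) s$state[1], integer(1)) == k],
                    max_lag, ts$metadata$dt, state = as.character(k))
  }))
}

#' Fit a diffusion model to an MSD curve
#'
#' Free model: `msd = 4*D*t + c`. Confined model (square domain of
#' edge L, leading-order): `msd = (L^2/3) * (1 - exp(-12*D*t/L^2)) + c`.
#' Fits are weighted least squares with pair-count weights over the
#' first `fit_lags` lags. A confined fit whose plateau `L^2/3` exceeds
#' the largest observed MSD more than tenfold is flagged `unconfined`.
#'
#' @param curve one MSD curve (`lag_s, msd_um2, n_pairs`).
#' @param model "free" or "confined".
#' @param fit_lags number of leading lags used.
#' @return list of class `msd_fit`: model, D (um^2/s), L (um, confined
#'   only), c (um^2), rss, fitted values, `unconfined` flag.
#' @export
fit_msd <- function(curve, model = c("free", "confined"), fit_lags = 10L) {
  model <- match.arg(model)
  cv <- curve[seq_len(min(fit_lags, nrow(curve))), , drop = FALSE]
  need <- if (model == "free") 3L else 4L
  if (nrow(cv) < need)
    stop("need at least ", need, " lags for the ", model, " model")
  w <- cv$n_pairs
  if (model == "free") {
    fit <- stats::lm(msd_um2 ~ lag_s, data = cv, weights = w)
    co <- stats::coef(fit)
    out <- list(model = "free", D = max(0, unname(co[2]) / 4),
                L = NA_real_, c = unname(co[1]),
                rss = sum(w * stats::resid(fit)^2),
                fitted = stats::fitted(fit), unconfined = TRUE)
  } else {
    plateau <- max(cv$msd_um2)
    slope0 <- max((cv$msd_um2[2] - cv$msd_um2[1]) /
                    (4 * (cv$lag_s[2] - cv$lag_s[1])), 1e-6)
    starts <- expand.grid(L = sqrt(3 * plateau) * c(0.5, 1, 2, 5),
                          D = slope0 * c(0.3, 1, 3))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- tryCatch(minpack.lm::nlsLM(
        msd_um2 ~ (L^2 / 3) * (1 - exp(-12 * D * lag_s / L^2)) + c0,
        data = cv, weights = w,
        start = list(L = starts$L[i], D = starts$D[i],
                     c0 = min(cv$msd_um2) / 2),
        lower = c(L = 1e-4, D = 0, c0 = 0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rss <- sum(w * stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 0)
        best <- list(fit = fit, rss = rss)
    }
    if (is.null(best))
      stop("confined MSD fit did not converge from any start")
    co <- stats::coef(best$fit)
    out <- list(model = "confined", D = unname(co["D"]),
                L = unname(co["L"]), c = unname(co["c0"]),
                rss = best$rss, fitted = stats::fitted(best$fit),
                unconfined = unname(co["L"])^2 / 3 >
                  10 * cv$msd_um2[nrow(cv)])
  }
  class(out) <- "msd_fit"
  out
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("msd_fit (%s): D = %.4g um^2/s%s, offset = %.4g um^2\n",
              x$model, x$D,
              if (x$model == "confined")
                sprintf(", L = %.4g um (%.0f nm)", x$L, 1000 * x$L) else "",
              x$c))
  invisible(x)
}

#' Localization precision from photon statistics
#'
#' Precision of a maximum-likelihood Gaussian localization with an
#' EMCCD excess-noise factor:
#' `sigma_a^2 = sigma_psf^2 + a^2/12`, and
#' `sigma_loc^2 = F_em * (sigma_a^2/N) * (16/9 + 8*pi*sigma_a^2*b^2 /
#' (N*a^2))`.
#'
#' @param N detected photons per spot.
#' @param a pixel size (um).
#' @param sigma_psf Gaussian PSF SD (um).
#' @param b background noise SD (photons per pixel).
#' @param F_em excess-noise factor (2 for EMCCD, 1 for an ideal
#'   detector).
#' @return localization precision per axis (um).
#' @export
mortensen_precision <- function(N, a, sigma_psf, b = 0, F_em = 1) {
  if (any(N <= 0) || a <= 0 || sigma_psf <= 0 || any(b < 0) || F_em < 1)
    stop("invalid precision parameters")
  sa2 <- sigma_psf^2 + a^2 / 12
  sqrt(F_em * (sa2 / N) * (16 / 9 + 8 * pi * sa2 * b^2 / (N * a^2)))
}
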