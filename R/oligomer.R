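# Constrained Gaussian-mixture decomposition of spot intensities into
# oligomer orders. Component n (n-mer) has mean n*mu1 and SD
# sqrt(n)*sigma1 (independent emitters), so only the monomer scale and
# the mixing weights are free.

mixture_responsibilities <- function(x, mu1, sigma1, w) {
  n_max <- length(w)
  dens <- vapply(seq_len(n_max), function(n)
    w[n] * stats::dnorm(x, n * mu1, sqrt(n) * sigma1), numeric(length(x)))
  dens <- matrix(dens, length(x), n_max)
  tot <- rowSums(dens)
  tot[tot == 0] <- .Machine$double.xmin
  list(r = dens / tot, ll = sum(log(tot)))
}

#' Fit an integer-multiple intensity mixture
#'
#' EM fit of the spot-intensity histogram to a mixture of Gaussians
#' whose component means are integer multiples of the monomer mean and
#' whose SDs scale with the square root of the order. The monomer
#' scale can be anchored (e.g. estimated from the fast, monomeric
#' state) or fitted freely.
#'
#' @param x spot intensities (a.u.), at least 50 samples.
#' @param n_max maximum oligomer order (components 1..n_max; brighter
#'   spots fold into the top component).
#' @param monomer optional anchor `c(mu1, sigma1)`; when supplied only
#'   the weights are fitted.
#' @param n_restarts random-weight restarts (first start is
#'   quantile-based and deterministic).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @param seed RNG seed for the restarts.
#' @return list of class `intensity_mixture`: `mu1`, `sigma1`,
#'   `weights`, `mean_order`, `loglik`, `n`, `anchored`.
#' @export
fit_intensity_mixture <- function(x, n_max = 4L, monomer = NULL,
                                  n_restarts = 3L, max_iter = 500L,
                                  tol = 1e-8, seed = 1L) {
  if (n_max < 1L) stop("n_max must be >= 1")
  x <- x[is.finite(x)]
  if (length(x) < 50L) stop("need at least 50 intensity samples")
  anchored <- !is.null(monomer)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (anchored) {
      mu1 <- monomer[1]; sigma1 <- monomer[2]
    } else {
      # start the monomer scale near the lower mode
      q <- stats::quantile(x, 0.25, names = FALSE)
      mu1 <- q * stats::runif(1, if (r == 1L) 1 else 0.7,
                              if (r == 1L) 1 else 1.3)
      sigma1 <- stats::sd(x) / 2
    }
    w <- if (r == 1L) rep(1 / n_max, n_max) else {
      g <- stats::rexp(n_max); g / sum(g)
    }
    ll_prev <- -Inf; ll <- NA_real_; ll_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      er <- mixture_responsibilities(x, mu1, sigma1, w)
      ll <- er$ll
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) && abs(ll - ll_prev) <= tol * abs(ll_prev))
        break
      ll_prev <- ll
      rk <- er$r
      w <- colMeans(rk)
      if (!anchored) {
        ns <- seq_len(n_max)
        mu1 <- sum(x) / sum(rk %*% ns)       # rows of rk sum to 1
        sq <- sweep(outer(x, ns * mu1, "-")^2, 2, ns, "/")
        sigma1 <- sqrt(sum(rk * sq) / length(x))
        if (!is.finite(sigma1) || sigma1 < 1e-12 * mu1)
          stop("degenerate mixture fit: sigma1 collapsed")
      }
    }
    if (sigma1 <= 0 || !is.finite(ll))
      stop("degenerate mixture fit")
    if (is.null(best) || ll > best$loglik + 1e-12)
      best <- list(mu1 = mu1, sigma1 = sigma1, weights = w,
                   loglik = ll, ll_trace = ll_trace)
  }
  out <- list(mu1 = best$mu1, sigma1 = best$sigma1,
              weights = best$weights,
              mean_order = sum(seq_len(n_max) * best$weights),
              loglik = best$loglik, ll_trace = best$ll_trace,
              n = length(x), n_max = n_max, anchored = anchored)
  class(out) <- "intensity_mixture"
  out
}

#' @export
print.intensity_mixture <- function(x, ...) {
  cat(sprintf("intensity_mixture: mu1 = %.4g, sigma1 = %.4g%s\n",
              x$mu1, x$sigma1, if (x$anchored) " (anchored)" else ""))
  cat("  weights:", paste(sprintf("%d-mer %.3f", seq_len(x$n_max),
                                  x$weights), collapse = ", "), "\n")
  cat(sprintf("  mean order: %.3f (n = %d)\n", x$mean_order, x$n))
  invisible(x)
}

#' Early-track spot intensities per diffusion state
#'
#' Collects, for each state, the intensities of the first `head_frames`
#' frames of every track whose per-frame label is that state (limiting
#' photobleaching bias).
#'
#' @param ts a [track_set()].
#' @param labels per-frame labels ([frame_labels()]).
#' @param channel channel filter.
#' @param head_frames frames taken from the start of each track.
#' @return named list of intensity vectors, one per state.
#' @export
state_intensities <- function(ts, labels, channel = NULL,
                              head_frames = 10L) {
  tr <- merge(ts$tracks, labels,
              by = c("cell_id", "channel", "track_id", "frame"))
  if (!is.null(channel)) tr <- tr[tr$channel %in% channel, ]
  tr <- tr[order(tr$cell_id, tr$channel, tr$track_id, tr$frame), ]
  key <- paste(tr$cell_id, tr$channel, tr$track_id, sep = "|")
  pos <- stats::ave(seq_along(key), key, FUN = seq_along)
  tr <- tr[pos <= head_frames, ]
  split(tr$intensity, tr$state)
}

#' Compare mean oligomer orders with a bootstrap CI
#'
#' Nonparametric bootstrap over spots: both samples are resampled,
#' refitted, and the difference in mean order (B minus A) is returned
#' with a percentile confidence interval.
#'
#' @param xA,xB intensity samples for the two conditions.
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed RNG seed.
#' @param ... passed to [fit_intensity_mixture()].
#' @return list `diff`, `ci`, `boot` (replicate differences).
#' @export
compare_orders <- function(xA, xB, n_boot = 1000L, level = 0.95,
                           seed = 1L, ...) {
  fitA <- fit_intensity_mixture(xA, seed = seed, ...)
  fitB <- fit_intensity_mixture(xB, seed = seed, ...)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    fa <- fit_intensity_mixture(sample(xA, replace = TRUE),
                                seed = seed + b, ...)
    fb <- fit_intensity_mixture(sample(xB, replace = TRUE),
                                seed = seed + b, ...)
    fb$mean_order - fa$mean_order
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(diff = fitB$mean_order - fitA$mean_order,
       ci = stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE),
       boot = boot, fitA = fitA, fitB = fitB)
}
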