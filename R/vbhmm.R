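# Variational-Bayes HMM over per-frame displacements.
#
# Emission: the displacement vector between consecutive frames is
# zero-mean isotropic Gaussian with per-state per-axis variance
# sigma2_k, so the squared 2D step r2 has density
# (lambda_k / (2*pi)) * exp(-lambda_k * r2 / 2) with precision
# lambda_k = 1/sigma2_k. Conjugate priors: Dirichlet on pi and on each
# row of A, Gamma on each lambda_k. Every track is an independent
# chain sharing the global parameters. The E-step uses the standard
# geometric-mean ("tilde") parameterization exp(E[log theta]); the
# lower bound is the scaled-likelihood term minus the KL divergences
# of the posterior hyperparameters from the priors, and is
# non-decreasing over iterations.

default_priors <- function(K) {
  list(alpha_pi = rep(1, K), alpha_A = matrix(1, K, K),
       gamma_shape = 1e-3, gamma_rate = 1e-3)
}

kl_dirichlet <- function(alpha, alpha0) {
  lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(alpha0)) + sum(lgamma(alpha0)) +
    sum((alpha - alpha0) * (digamma(alpha) - digamma(sum(alpha))))
}

kl_gamma <- function(a, b, a0, b0) {
  (a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
    a0 * (log(b) - log(b0)) + a * (b0 - b) / b
}

# Squared displacements per track (list of numeric vectors) for the
# chosen channel(s); tracks with < 2 frames are excluded and counted.
displacement_list <- function(ts, channel = NULL) {
  parts <- split_tracks(ts, channel = channel, min_frames = 2L)
  r2 <- lapply(parts, function(p) {
    dx <- diff(p$x_um); dy <- diff(p$y_um)
    dx^2 + dy^2
  })
  meta <- lapply(parts, function(p)
    list(cell_id = p$cell_id[1], channel = p$channel[1],
         track_id = p$track_id[1], frames = p$frame[-nrow(p)]))
  list(r2 = r2, meta = meta, n_dropped = attr(parts, "n_dropped"))
}

# Forward-backward E-step on all chains (compiled core). `r2` is a
# list of squared-displacement vectors, one per track; arguments are
# the tilde log-parameters. Returns per-displacement marginals (rows
# of `gamma` follow the concatenated track order), the summed
# transition statistics, and the scaled-likelihood term.
fb_estep <- function(r2, ln_pi, ln_A, ln_lam, E_lam,
                     want_gamma = TRUE) {
  lens <- vapply(r2, length, integer(1))
  res <- fb_estep_cpp(unlist(r2, use.names = FALSE), lens,
                      as.numeric(ln_pi),
                      matrix(ln_A, length(ln_pi), length(ln_pi)),
                      as.numeric(ln_lam), as.numeric(E_lam), want_gamma)
  res$lens <- lens
  res$offsets <- c(0L, cumsum(lens))
  res
}

vb_init <- function(r2_all, K, priors, jitter_sd, tracks_r2) {
  lx <- log(pmax(r2_all, 1e-300))
  if (jitter_sd > 0) lx <- lx + stats::rnorm(length(lx), 0, jitter_sd * stats::sd(lx))
  qs <- stats::quantile(lx, probs = seq(0, 1, length.out = K + 1L),
                        names = FALSE)
  h <- findInterval(lx, qs[-c(1, K + 1L)]) + 1L
  a <- priors$gamma_shape + tabulate(h, K)
  b <- priors$gamma_rate +
    vapply(seq_len(K), function(k) sum(r2_all[h == k]) / 2, numeric(1))
  # transition counts of the hard split, chained per track
  lens <- vapply(tracks_r2, length, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  from <- h[-ends]; to <- h[-starts]
  trans <- table(factor(from, seq_len(K)), factor(to, seq_len(K)))
  list(alpha_pi = priors$alpha_pi + K * tabulate(h, K) / length(h),
       alpha_A = priors$alpha_A + unclass(trans), a = a, b = b)
}

vb_run <- function(tracks_r2, K, priors, hyper, max_iter, tol) {
  elbo <- rep(NA_real_, max_iter)
  prev <- -Inf
  es <- NULL
  for (it in seq_len(max_iter)) {
    ln_pi <- digamma(hyper$alpha_pi) - digamma(sum(hyper$alpha_pi))
    ln_A <- digamma(hyper$alpha_A) - digamma(rowSums(hyper$alpha_A))
    ln_lam <- digamma(hyper$a) - log(hyper$b)
    E_lam <- hyper$a / hyper$b
    es <- fb_estep(tracks_r2, ln_pi, ln_A, ln_lam, E_lam,
                   want_gamma = FALSE)
    kl <- kl_dirichlet(hyper$alpha_pi, priors$alpha_pi) +
      sum(vapply(seq_len(K), function(i)
        kl_dirichlet(hyper$alpha_A[i, ], priors$alpha_A[i, ]), numeric(1))) +
      sum(kl_gamma(hyper$a, hyper$b, priors$gamma_shape, priors$gamma_rate))
    elbo[it] <- es$logZ - kl
    if (!is.finite(elbo[it]))
      stop("non-finite lower bound at iteration ", it)
    if (it > 1L && abs(elbo[it] - prev) <= tol * abs(prev)) {
      elbo <- elbo[seq_len(it)]
      break
    }
    prev <- elbo[it]
    hyper <- list(alpha_pi = priors$alpha_pi + es$N1,
                  alpha_A = priors$alpha_A + es$xi_sum,
                  a = priors$gamma_shape + es$Nk,
                  b = priors$gamma_rate + es$Sk / 2)
  }
  list(hyper = hyper, estep = es, elbo = elbo[!is.na(elbo)],
       converged = length(elbo) < max_iter)
}

#' Fit a K-state displacement VB-HMM
#'
#' Segments all trajectories of a track set (each an independent chain
#' sharing global parameters) into K diffusion states. States are
#' canonically ordered by increasing displacement variance, so state 1
#' is the slowest ("immobile") and state K the fastest. The reported
#' diffusion coefficient subtracts the static localization-noise
#' contribution: `D_k = (sigma2_k - 2*sigma_loc^2) / (2*dt)`, floored
#' at zero.
#'
#' @param ts a [track_set()].
#' @param K number of states (>= 1).
#' @param channel optional channel filter (default: all tracks).
#' @param sigma_loc localization precision per axis (um) used when
#'   converting displacement variances to diffusion coefficients.
#' @param priors prior hyperparameters, see `default_priors`.
#' @param n_restarts perturbed restarts; the best converged lower
#'   bound wins, ties broken by first index.
#' @param max_iter,tol VB iteration cap and relative lower-bound
#'   convergence tolerance.
#' @param seed RNG seed controlling restart perturbations.
#' @return list of class `vbhmm` with elements `model` (K, sigma2, D,
#'   A, pi, lower_bound, elbo_trace, hyperparameters) and `assignment`
#'   (per-displacement posterior responsibilities and hard labels).
#' @export
vb_fit <- function(ts, K, channel = NULL, sigma_loc = 0,
                   priors = NULL, n_restarts = 5L,
                   max_iter = 1000L, tol = 1e-8, seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  dl <- displacement_list(ts, channel = channel)
  if (!length(dl$r2))
    stop("no track with >= 2 frames")
  if (is.null(priors)) priors <- default_priors(K)
  r2_all <- unlist(dl$r2, use.names = FALSE)
  if (length(r2_all) < K)
    stop("fewer displacements than states")
  set.seed(seed)
  # restarts are screened with a short run; the best screened lower
  # bound is then polished to full convergence
  screen_iter <- min(max_iter, 150L)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    hyper0 <- vb_init(r2_all, K, priors,
                      jitter_sd = if (r == 1L) 0 else 0.5, dl$r2)
    fit <- tryCatch(
      vb_run(dl$r2, K, priors, hyper0, screen_iter, tol),
      error = function(e) NULL)
    if (is.null(fit)) next
    lb <- fit$elbo[length(fit$elbo)]
    if (is.null(best) || lb > best$lb + 1e-12) {
      best <- list(fit = fit, lb = lb)
    }
  }
  if (is.null(best)) stop("all VB restarts failed")
  fit <- best$fit
  if (!fit$converged && max_iter > screen_iter) {
    fit2 <- tryCatch(
      vb_run(dl$r2, K, priors, fit$hyper, max_iter - screen_iter, tol),
      error = function(e) NULL)
    if (!is.null(fit2)) {
      fit2$elbo <- c(fit$elbo, fit2$elbo)
      fit <- fit2
      best$lb <- fit$elbo[length(fit$elbo)]
    }
  }

  # canonical order: ascending posterior-mean displacement variance
  sigma2 <- fit$hyper$b / fit$hyper$a
  ord <- order(sigma2)
  hyper <- list(alpha_pi = fit$hyper$alpha_pi[ord],
                alpha_A = fit$hyper$alpha_A[ord, ord, drop = FALSE],
                a = fit$hyper$a[ord], b = fit$hyper$b[ord])
  sigma2 <- sigma2[ord]
  A <- hyper$alpha_A / rowSums(hyper$alpha_A)
  pi_hat <- hyper$alpha_pi / sum(hyper$alpha_pi)
  D <- pmax(0, (sigma2 - 2 * sigma_loc^2) / (2 * ts$metadata$dt))

  # final E-step under the converged posterior, in canonical order
  ln_pi <- digamma(hyper$alpha_pi) - digamma(sum(hyper$alpha_pi))
  ln_A <- digamma(hyper$alpha_A) - digamma(rowSums(hyper$alpha_A))
  ln_lam <- digamma(hyper$a) - log(hyper$b)
  es <- fb_estep(dl$r2, ln_pi, ln_A, ln_lam, hyper$a / hyper$b)

  resp <- do.call(rbind, lapply(seq_along(dl$r2), function(i) {
    g <- es$gamma[(es$offsets[i] + 1L):es$offsets[i + 1L], , drop = FALSE]
    md <- dl$meta[[i]]
    out <- data.frame(cell_id = md$cell_id, channel = md$channel,
                      track_id = md$track_id, frame = md$frames,
                      state = max.col(g), stringsAsFactors = FALSE)
    colnames(g) <- paste0("resp_", seq_len(K))
    cbind(out, g)
  }))
  model <- list(K = K, sigma2 = sigma2, D = D, A = A, pi = pi_hat,
                lower_bound = best$lb, elbo_trace = fit$elbo,
                hyperparameters = hyper, sigma_loc = sigma_loc,
                dt = ts$metadata$dt, converged = fit$converged,
                n_tracks = length(dl$r2), n_dropped = dl$n_dropped)
  structure(list(model = model, assignment = resp), class = "vbhmm")
}

#' @export
print.vbhmm <- function(x, ...) {
  m <- x$model
  cat(sprintf("vbhmm: K = %d, lower bound = %.2f (%s)\n", m$K,
              m$lower_bound, if (m$converged) "converged" else "iteration cap"))
  cat("  sigma2 (um^2):", signif(m$sigma2, 4), "\n")
  cat("  D (um^2/s):   ", signif(m$D, 4), "\n")
  invisible(x)
}

#' Select the number of diffusion states by the variational lower bound
#'
#' Fits the displacement VB-HMM for each candidate K and returns the
#' fit with the highest converged lower bound, together with the full
#' (K, lower bound) table.
#'
#' @inheritParams vb_fit
#' @param K_range candidate state counts.
#' @return list with `best` (a `vbhmm`), `K` (selected count) and
#'   `table` (data.frame of K vs lower bound).
#' @export
select_model <- function(ts, K_range = 1:8, channel = NULL,
                         sigma_loc = 0, n_restarts = 5L,
                         max_iter = 1000L, tol = 1e-8, seed = 1L) {
  if (!length(K_range)) stop("K_range is empty")
  fits <- vector("list", length(K_range))
  lb <- rep(NA_real_, length(K_range))
  for (i in seq_along(K_range)) {
    fits[[i]] <- tryCatch(
      vb_fit(ts, K_range[i], channel = channel, sigma_loc = sigma_loc,
             n_restarts = n_restarts, max_iter = max_iter, tol = tol,
             seed = seed + i),
      error = function(e) NULL)
    if (!is.null(fits[[i]])) lb[i] <- fits[[i]]$model$lower_bound
  }
  if (all(is.na(lb))) stop("every candidate K failed to fit")
  best <- which.max(lb)
  list(best = fits[[best]], K = K_range[best],
       table = data.frame(K = K_range, lower_bound = lb))
}

#' Per-frame diffusion-state labels
#'
#' A frame inherits the hard label of the displacement leaving it; the
#' last frame of a track inherits the previous label. This makes the
#' state defined at every frame, as required by the colocalization
#' criterion.
#'
#' @param fit a `vbhmm` (or its `assignment` data.frame).
#' @return data.frame `cell_id, channel, track_id, frame, state`.
#' @export
frame_labels <- function(fit) {
  asg <- if (inherits(fit, "vbhmm")) fit$assignment else fit
  lab <- asg[c("cell_id", "channel", "track_id", "frame", "state")]
  key <- paste(lab$cell_id, lab$channel, lab$track_id, sep = "|")
  last <- !duplicated(key, fromLast = TRUE)
  extra <- lab[last, , drop = FALSE]
  extra$frame <- extra$frame + 1L          # track's final frame
  out <- rbind(lab, extra)
  out[order(out$cell_id, out$channel, out$track_id, out$frame), ,
      drop = FALSE]
}

#' Diffusion-state fractions per cell
#'
#' Fraction of displacements assigned to each state, per cell (and
#' channel), the per-cell metric summarized across cells in the
#' figure-style tables.
#'
#' @param fit a `vbhmm` or its assignment data.frame.
#' @param K number of states (inferred from a `vbhmm`).
#' @return data.frame `cell_id, channel, state, fraction, n`.
#' @export
state_fractions <- function(fit, K = NULL) {
  asg <- if (inherits(fit, "vbhmm")) fit$assignment else fit
  if (is.null(K))
    K <- if (inherits(fit, "vbhmm")) fit$model$K else max(asg$state)
  if (!nrow(asg)) stop("empty state assignment")
  out <- do.call(rbind, lapply(
    split(asg, list(asg$cell_id, asg$channel), drop = TRUE),
    function(d) data.frame(
      cell_id = d$cell_id[1], channel = d$channel[1],
      state = seq_len(K),
      fraction = tabulate(d$state, K) / nrow(d),
      n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
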