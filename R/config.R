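#' Build and validate a simulation configuration
#'
#' A `spt_config` describes a two-channel single-molecule tracking
#' acquisition with K-state switching diffusion: per-state diffusion
#' coefficients, a per-frame transition matrix, optional square-domain
#' confinement per state, localization noise, scripted binding between
#' the channels, and oligomer-dependent spot intensities.
#'
#' @param K number of diffusion states.
#' @param D numeric length-K, diffusion coefficient per state (um^2/s).
#' @param A K x K row-stochastic per-frame transition matrix.
#' @param pi initial state distribution (length K, sums to 1).
#' @param confinement numeric length-K; edge length L (um) of the square
#'   reflecting domain for confined states, `NA` for free states.
#' @param sigma_loc localization noise SD per axis (um).
#' @param dt frame interval (s).
#' @param n_frames movie length in frames.
#' @param n_tracks tracks per channel.
#' @param field edge length of the (square) simulated field of view (um).
#' @param binding `NULL`, or a list with `k_on` (scripted binding events
#'   per free channel-2 particle per second), `tau` (mean bound lifetime,
#'   s) and `offset_sd` (per-axis SD of the bound-pair offset, um).
#' @param intensity list with `mu1` (monomer mean intensity, a.u.),
#'   `cv1` (monomer coefficient of variation) and `oligomer_weights`
#'   (K x n_max matrix; row k is the distribution over oligomer orders
#'   1..n_max for tracks starting in state k).
#' @param bleach_rate per-frame survival probability of a fluorophore.
#' @param seed integer RNG seed.
#'
#' @return a validated list of class `spt_config`.
#' @export
spt_config <- function(K, D, A, pi, confinement = rep(NA_real_, K),
                       sigma_loc = 0.02, dt = 0.0305, n_frames = 300,
                       n_tracks = 100, field = 25,
                       binding = NULL,
                       intensity = list(mu1 = 100, cv1 = 0.25,
                                        oligomer_weights = NULL),
                       bleach_rate = 1, seed = 1L) {
  A <- as.matrix(A)
  cfg <- list(K = as.integer(K), D = as.numeric(D), A = A,
              pi = as.numeric(pi), confinement = as.numeric(confinement),
              sigma_loc = sigma_loc, dt = dt,
              n_frames = as.integer(n_frames),
              n_tracks = as.integer(n_tracks), field = field,
              binding = binding, intensity = intensity,
              bleach_rate = bleach_rate, seed = as.integer(seed))
  class(cfg) <- "spt_config"
  validate_spt_config(cfg)
}

#' @rdname spt_config
#' @param cfg an `spt_config` candidate.
#' @export
validate_spt_config <- function(cfg) {
  stopifnot(is.list(cfg))
  K <- cfg$K
  if (is.null(K) || K < 1L) stop("K must be >= 1")
  if (length(cfg$D) != K || any(cfg$D < 0) || any(!is.finite(cfg$D)))
    stop("D must be length K and non-negative")
  if (!all(dim(cfg$A) == c(K, K)))
    stop("A must be a K x K matrix")
  if (any(cfg$A < 0) || any(abs(rowSums(cfg$A) - 1) > 1e-12))
    stop("rows of A must be non-negative and sum to 1")
  if (length(cfg$pi) != K || any(cfg$pi < 0) ||
      abs(sum(cfg$pi) - 1) > 1e-12)
    stop("pi must be a length-K distribution")
  if (length(cfg$confinement) != K)
    stop("confinement must be length K (NA = free)")
  conf <- cfg$confinement[!is.na(cfg$confinement)]
  if (any(conf <= 0)) stop("confinement lengths must be > 0")
  if (cfg$dt <= 0) stop("dt must be > 0")
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2")
  if (cfg$sigma_loc < 0) stop("sigma_loc must be >= 0")
  if (cfg$bleach_rate <= 0 || cfg$bleach_rate > 1)
    stop("bleach_rate is a per-frame survival probability in (0, 1]")
  if (!is.null(cfg$binding)) {
    b <- cfg$binding
    if (b$k_on < 0 || b$tau <= 0 || b$offset_sd < 0)
      stop("binding rates must be non-negative and tau > 0")
  }
  it <- cfg$intensity
  if (!is.null(it)) {
    if (it$mu1 <= 0 || it$cv1 < 0) stop("intensity mu1 > 0, cv1 >= 0 required")
    w <- it$oligomer_weights
    if (!is.null(w)) {
      w <- as.matrix(w)
      if (nrow(w) != K) stop("oligomer_weights needs one row per state")
      if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-8))
        stop("oligomer_weights rows must be distributions over orders")
      cfg$intensity$oligomer_weights <- w
    }
  }
  cfg
}

#' Default four-state simulation configuration
#'
#' Ships the package's reference synthetic acquisition: four diffusive
#' states (immobile, slow, medium, fast) switching at the frame rate,
#' the two slowest confined in reflecting square domains, imaged at a
#' 30.5 ms frame interval for 300 frames with 20 nm localization noise
#' at a particle density of ~0.3 per um^2. Diffusion coefficients and
#' switching rates are synthetic choices typical of membrane receptors;
#' they are not measured values.
#'
#' @param n_tracks tracks per channel (default 200).
#' @param seed RNG seed.
#' @param binding include scripted channel-1/channel-2 binding events.
#' @return an `spt_config`.
#' @export
default_config <- function(n_tracks = 200, seed = 1L, binding = TRUE) {
  K <- 4L
  A <- matrix(0.02, K, K)
  diag(A) <- 0.94
  w <- rbind(c(0.10, 0.50, 0.30, 0.10),   # immobile: dimers/oligomers
             c(0.40, 0.50, 0.08, 0.02),   # slow: monomer/dimer mix
             c(0.55, 0.35, 0.08, 0.02),   # medium
             c(1.00, 0.00, 0.00, 0.00))   # fast: monomeric
  spt_config(
    K = K,
    D = c(0.005, 0.03, 0.12, 0.45),
    A = A,
    pi = rep(0.25, K),
    confinement = c(0.12, 0.20, NA, NA),
    sigma_loc = 0.02, dt = 0.0305, n_frames = 300,
    n_tracks = n_tracks, field = 25,
    binding = if (binding) list(k_on = 0.3, tau = 0.3, offset_sd = 0.015),
    intensity = list(mu1 = 100, cv1 = 0.25, oligomer_weights = w),
    bleach_rate = 0.995, seed = seed)
}

#' Read / write a simulation configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns a validated `spt_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$A <- do.call(rbind, y$A)
  if (!is.null(y$intensity$oligomer_weights))
    y$intensity$oligomer_weights <- do.call(rbind, y$intensity$oligomer_weights)
  if (!is.null(y$confinement))
    y$confinement <- vapply(y$confinement,
                            function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                            numeric(1))
  do.call(spt_config, y)
}

#' @rdname read_config
#' @param cfg an `spt_config`.
#' @export
write_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$A <- lapply(seq_len(nrow(cfg$A)), function(i) as.numeric(cfg$A[i, ]))
  if (!is.null(y$intensity$oligomer_weights)) {
    w <- y$intensity$oligomer_weights
    y$intensity$oligomer_weights <-
      lapply(seq_len(nrow(w)), function(i) as.numeric(w[i, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
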