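#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-recording generator. Defaults
#' reproduce the standard study conditions: 2-D Gaussian footprints of
#' width 20-25 pixels, Bernoulli spiking at probability 0.01 per timebin
#' convolved with the double-exponential kernel
#' `g(t) = exp(-t / tau_d) - exp(-t / tau_r)` (fall time 6 timebins, rise
#' time 1), and 23 background sources (local Gaussians and blood-vessel
#' curves with random-walk temporal weights).
#'
#' Footprint "width" is the diameter of the support at 1% of peak
#' intensity; the Gaussian sigma is set accordingly
#' (`width = 2 * sigma * sqrt(2 * log(100))`) and pixels below 1% of peak
#' are truncated to zero so supports are finite.
#'
#' @param fov_shape `c(H, W)` pixels.
#' @param n_neurons neurons per session.
#' @param n_sessions number of sessions.
#' @param frames_per_session frames per session.
#' @param footprint_width range (pixels) the per-neuron width is drawn from.
#' @param spike_prob Bernoulli spiking probability per timebin.
#' @param tau_d,tau_r fall / rise time of the calcium kernel, timebins.
#' @param n_background background sources per session.
#' @param noise `"none"`, `"gaussian"` or `"salt_pepper"`; applied to
#'   rendered movies and (for gaussian) to derived traces.
#' @param noise_level s.d. of gaussian noise / flip fraction of salt-pepper,
#'   relative to peak neuron brightness.
#' @param transform footprint motion between sessions: `"none"`,
#'   `"nonrigid"`, `"ring_nonrigid"`, `"individual_shift"`.
#' @param shift_range translation magnitude range (pixels) for
#'   `"individual_shift"`.
#' @param min_spacing minimal footprint center spacing at placement, pixels.
#' @param link_frames frames per side for link extractions; `NULL` means
#'   `min(1000, floor(frames_per_session / 2))`.
#' @param seed RNG seed (integer); the whole dataset is a deterministic
#'   function of the config.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(fov_shape = c(100, 100), n_neurons = 50,
                              n_sessions = 2, frames_per_session = 3000,
                              footprint_width = c(20, 25), spike_prob = 0.01,
                              tau_d = 6, tau_r = 1, n_background = 23,
                              noise = c("none", "gaussian", "salt_pepper"),
                              noise_level = 0.05,
                              transform = c("none", "nonrigid",
                                            "ring_nonrigid",
                                            "individual_shift"),
                              shift_range = c(5, 7), min_spacing = 8,
                              link_frames = NULL, seed = 1) {
  noise <- match.arg(noise)
  transform <- match.arg(transform)
  stopifnot(n_neurons > 0, n_sessions > 0, frames_per_session > 0,
            spike_prob > 0, spike_prob < 1, tau_d > tau_r, tau_r > 0,
            n_background >= 0)
  if (is.null(link_frames))
    link_frames <- min(1000L, floor(frames_per_session / 2))
  structure(list(fov_shape = as.integer(fov_shape),
                 n_neurons = as.integer(n_neurons),
                 n_sessions = as.integer(n_sessions),
                 frames_per_session = as.integer(frames_per_session),
                 footprint_width = footprint_width, spike_prob = spike_prob,
                 tau_d = tau_d, tau_r = tau_r,
                 n_background = as.integer(n_background),
                 noise = noise, noise_level = noise_level,
                 transform = transform, shift_range = shift_range,
                 min_spacing = min_spacing,
                 link_frames = as.integer(link_frames),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

gaussian_footprint <- function(center, sigma, fov_shape, trunc_frac = 0.01) {
  rr <- matrix(seq_len(fov_shape[1]), fov_shape[1], fov_shape[2])
  cc <- matrix(seq_len(fov_shape[2]), fov_shape[1], fov_shape[2], byrow = TRUE)
  img <- exp(-((rr - center[1])^2 / (2 * sigma[1]^2) +
                 (cc - center[2])^2 / (2 * sigma[2]^2)))
  img[img < trunc_frac * max(img)] <- 0
  as.numeric(img)
}

#' Simulate neuron spatial footprints
#'
#' Places `n_neurons` 2-D Gaussian footprints (diagonal covariance, per-axis
#' sigma drawn from the configured width range) at centers sampled uniformly
#' inside the FOV margin, rejecting centers closer than `min_spacing` pixels
#' to an existing one.
#'
#' @param config a `simulation_config`. RNG state is taken as-is; callers
#'   seed it (as [make_dataset()] does).
#' @return list with `footprints` (d x K matrix), `centers` (2 x K),
#'   `sigmas` (2 x K).
#' @export
simulate_footprints <- function(config) {
  fov <- config$fov_shape
  k <- config$n_neurons
  wr <- config$footprint_width
  # width = diameter of the 1%-of-peak support
  sig_range <- wr / (2 * sqrt(2 * log(100)))
  margin <- ceiling(max(wr) / 2)
  if (fov[1] <= 2 * margin || fov[2] <= 2 * margin)
    stop("FOV too small for the configured footprint width")
  centers <- matrix(NA_real_, 2, k)
  placed <- 0L
  tries <- 0L
  while (placed < k) {
    tries <- tries + 1L
    if (tries > 200L * k)
      stop("could not place ", k, " neurons with spacing ",
           config$min_spacing, " in this FOV")
    cand <- c(stats::runif(1, margin, fov[1] - margin),
              stats::runif(1, margin, fov[2] - margin))
    if (placed > 0L) {
      d <- sqrt(colSums((centers[, seq_len(placed), drop = FALSE] - cand)^2))
      if (min(d) < config$min_spacing) next
    }
    placed <- placed + 1L
    centers[, placed] <- cand
  }
  sigmas <- matrix(stats::runif(2 * k, sig_range[1], sig_range[2]), 2, k)
  footprints <- vapply(seq_len(k), function(i)
    gaussian_footprint(centers[, i], sigmas[, i], fov), numeric(prod(fov)))
  list(footprints = footprints, centers = centers, sigmas = sigmas)
}

#' Calcium transient kernel
#'
#' `g(t) = exp(-t / tau_d) - exp(-t / tau_r)` evaluated at
#' `t = 0, 1, ..., len - 1`.
#'
#' @param tau_d,tau_r fall / rise times in timebins.
#' @param len kernel length; default covers the decay to ~1e-4.
#' @return numeric vector.
#' @export
calcium_kernel <- function(tau_d = 6, tau_r = 1, len = ceiling(10 * tau_d)) {
  t <- seq(0, len - 1)
  exp(-t / tau_d) - exp(-t / tau_r)
}

#' Simulate spike trains and fluorescence traces
#'
#' Spikes are Bernoulli(`spike_prob`) per timebin; traces are the spikes
#' convolved with the calcium kernel.
#'
#' @param config a `simulation_config`.
#' @param n_frames frames to simulate (default the configured session
#'   length).
#' @return list with `spikes` and `traces`, both `n_neurons x n_frames`.
#' @export
simulate_traces <- function(config, n_frames = config$frames_per_session) {
  k <- config$n_neurons
  spikes <- matrix(stats::rbinom(k * n_frames, 1, config$spike_prob),
                   k, n_frames)
  kern <- calcium_kernel(config$tau_d, config$tau_r)
  traces <- t(apply(spikes, 1, function(s) {
    convolve_causal(s, kern)
  }))
  list(spikes = spikes, traces = traces)
}

convolve_causal <- function(x, kern) {
  n <- length(x)
  p <- length(kern)
  padded <- c(numeric(p - 1L), x)
  out <- stats::filter(padded, kern, method = "convolution", sides = 1)
  as.numeric(out)[p:(p - 1L + n)]
}

#' Simulate background sources
#'
#' Background components emulate out-of-focus neuropil and vasculature:
#' roughly two thirds are local Gaussian blobs with substantially wider
#' covariance than neuron footprints, the rest are blood-vessel curves
#' (cubic polynomial paths rasterized and blurred with a width-3 Gaussian).
#' Temporal weights follow a positive random walk.
#'
#' @param config a `simulation_config`.
#' @param n_frames frames for the temporal components.
#' @param sigma_mult local-background sigma as a multiple of the neuron
#'   sigma scale.
#' @return list with `footprints` (d x n_background) and `weights`
#'   (n_background x n_frames); both empty-dimensioned when
#'   `n_background = 0`.
#' @export
simulate_background <- function(config, n_frames = config$frames_per_session,
                                sigma_mult = 3) {
  fov <- config$fov_shape
  nb <- config$n_background
  d <- prod(fov)
  if (nb == 0L)
    return(list(footprints = matrix(0, d, 0), weights = matrix(0, 0, n_frames)))
  sig_base <- mean(config$footprint_width) / (2 * sqrt(2 * log(100)))
  n_vessel <- floor(nb / 3)
  n_local <- nb - n_vessel
  fps <- matrix(0, d, nb)
  for (i in seq_len(n_local)) {
    ctr <- c(stats::runif(1, 1, fov[1]), stats::runif(1, 1, fov[2]))
    sig <- stats::runif(2, sigma_mult * 0.8, sigma_mult * 1.2) * sig_base
    fps[, i] <- gaussian_footprint(ctr, sig, fov)
  }
  for (i in seq_len(n_vessel)) {
    fps[, n_local + i] <- vessel_footprint(fov)
  }
  # positive random walk per source
  w <- matrix(0, nb, n_frames)
  w[, 1] <- stats::runif(nb, 0.3, 0.7)
  if (n_frames > 1) {
    steps <- matrix(stats::rnorm(nb * (n_frames - 1), 0, 0.02), nb)
    w[, -1] <- w[, 1] + t(apply(steps, 1, cumsum))
  }
  w[w < 0] <- 0
  list(footprints = fps, weights = w)
}

vessel_footprint <- function(fov, blur_sigma = 3) {
  # cubic path across the FOV, rasterized then Gaussian-blurred
  cf <- stats::rnorm(4, 0, c(1, 0.5, 0.02, 0.0005))
  xs <- seq_len(fov[2])
  mid <- fov[1] / 2
  ys <- mid + cf[1] + cf[2] * (xs - fov[2] / 2) +
    cf[3] * (xs - fov[2] / 2)^2 + cf[4] * (xs - fov[2] / 2)^3
  img <- matrix(0, fov[1], fov[2])
  ok <- ys >= 1 & ys <= fov[1]
  img[cbind(round(ys[ok]), xs[ok])] <- 1
  blurred <- gaussian_blur(img, blur_sigma)
  if (max(blurred) > 0) blurred <- blurred / max(blurred)
  as.numeric(blurred)
}

gaussian_blur <- function(img, sigma) {
  half <- ceiling(3 * sigma)
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    n <- length(v)
    padded <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + n)]
  }
  tmp <- apply(img, 2, pad_conv)
  t(apply(tmp, 1, pad_conv))
}

#' Warp footprints with per-neuron non-rigid deformations
#'
#' Each footprint is resampled through a smooth random displacement field
#' (low-order polynomial in the pixel coordinates), producing an in-place
#' deformation with small translational effect: the centroid moves by less
#' than `max_centroid_shift` pixels (fields are rescaled to enforce this)
#' and mass is approximately conserved.
#'
#' @param footprints d x K matrix.
#' @param fov_shape `c(H, W)`.
#' @param amplitude typical displacement amplitude in pixels.
#' @param max_centroid_shift hard bound on the induced centroid motion.
#' @return warped d x K matrix.
#' @export
apply_nonrigid_warp <- function(footprints, fov_shape, amplitude = 1.5,
                                max_centroid_shift = 2) {
  if (amplitude == 0) return(footprints)
  k <- ncol(footprints)
  out <- footprints
  rr <- matrix(seq_len(fov_shape[1]), fov_shape[1], fov_shape[2])
  cc <- matrix(seq_len(fov_shape[2]), fov_shape[1], fov_shape[2], byrow = TRUE)
  for (i in seq_len(k)) {
    img <- matrix(footprints[, i], fov_shape[1])
    ctr <- centroid(img)
    # smooth per-neuron field: affine + quadratic terms in centered coords
    repeat {
      a <- stats::rnorm(6, 0, amplitude / 10)
      b <- stats::rnorm(6, 0, amplitude / 10)
      u <- ctr[1] - rr; v <- ctr[2] - cc
      dr <- a[1] + a[2] * u / 10 + a[3] * v / 10 +
        a[4] * u * v / 100 + a[5] * u^2 / 100 + a[6] * v^2 / 100
      dc <- b[1] + b[2] * u / 10 + b[3] * v / 10 +
        b[4] * u * v / 100 + b[5] * u^2 / 100 + b[6] * v^2 / 100
      warped <- bilinear_sample(img, rr + dr, cc + dc)
      if (sum(warped) <= 0) next
      shift <- sqrt(sum((centroid(warped) - ctr)^2))
      if (shift < max_centroid_shift) break
    }
    out[, i] <- as.numeric(warped)
  }
  out
}

bilinear_sample <- function(img, rq, cq) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(rq); c0 <- floor(cq)
  fr <- rq - r0; fc <- cq - c0
  get <- function(r, c) {
    r <- pmin(pmax(r, 1), h); c <- pmin(pmax(c, 1), w)
    img[cbind(as.numeric(r), as.numeric(c))]
  }
  out <- (1 - fr) * (1 - fc) * get(r0, c0) +
    (1 - fr) * fc * get(r0, c0 + 1) +
    fr * (1 - fc) * get(r0 + 1, c0) +
    fr * fc * get(r0 + 1, c0 + 1)
  matrix(out, h, w)
}

#' Ring transform of a footprint
#'
#' Converts a filled footprint into the characteristic donut shape of
#' 2-photon somata: intensities are rescaled to `[0, 1]` and every pixel
#' with scaled value above 0.5 is replaced by one minus that value, so the
#' center becomes a local minimum (a peak pixel maps to 0).
#'
#' @param footprint nonnegative vector or matrix with positive peak.
#' @return transformed footprint, same shape.
#' @export
apply_ring_transform <- function(footprint) {
  peak <- max(footprint)
  if (peak <= 0) stop("degenerate footprint: zero peak")
  v <- footprint / peak
  hi <- v > 0.5
  v[hi] <- 1 - v[hi]
  v
}

#' Shift footprints independently
#'
#' Each footprint is translated by an independent displacement with
#' magnitude drawn uniformly from `shift_range` and uniform random
#' direction. Displacements that would push the footprint support outside
#' the FOV are re-drawn (bounded retries).
#'
#' @param footprints d x K matrix.
#' @param fov_shape `c(H, W)`.
#' @param shift_range `c(min, max)` magnitude in pixels.
#' @return list with `footprints` (shifted) and `shifts` (2 x K applied
#'   displacements, row/col).
#' @export
apply_individual_shift <- function(footprints, fov_shape,
                                   shift_range = c(5, 7)) {
  k <- ncol(footprints)
  out <- footprints
  shifts <- matrix(0, 2, k)
  rr <- matrix(seq_len(fov_shape[1]), fov_shape[1], fov_shape[2])
  cc <- matrix(seq_len(fov_shape[2]), fov_shape[1], fov_shape[2], byrow = TRUE)
  for (i in seq_len(k)) {
    img <- matrix(footprints[, i], fov_shape[1])
    mass0 <- sum(img)
    for (try in seq_len(50)) {
      mag <- stats::runif(1, shift_range[1], shift_range[2])
      ang <- stats::runif(1, 0, 2 * pi)
      dr <- mag * cos(ang); dc <- mag * sin(ang)
      shifted <- bilinear_sample(img, rr - dr, cc - dc)
      if (sum(shifted) >= 0.95 * mass0 || all(shift_range == 0)) {
        out[, i] <- as.numeric(shifted)
        shifts[, i] <- c(dr, dc)
        break
      }
      if (try == 50) warning("footprint ", i,
                             ": shift clipped at the FOV boundary")
    }
  }
  list(footprints = out, shifts = shifts)
}

#' Generate a complete synthetic multi-session dataset
#'
#' Emits one `session_extraction` per session (ground-truth footprints and
#' traces, re-simulated spiking per session for the same cells), a
#' `link_extraction` for every consecutive session pair (built from the
#' ground-truth traces over the boundary frames), the ground-truth cell
#' register, and optionally rendered movies.
#'
#' Styles mirror the four standard benchmark conditions:
#' \describe{
#'   \item{gaussian}{static Gaussian footprints, Gaussian noise, 256x256
#'     FOV default.}
#'   \item{nonrigid_1p}{per-session per-neuron non-rigid warps (<2 px
#'     centroid motion), Gaussian noise.}
#'   \item{nonrigid_2p}{as nonrigid_1p with ring-shaped footprints and
#'     salt-and-pepper movie noise.}
#'   \item{individual_shift}{two sessions, 100x100 FOV, footprints
#'     independently translated 5-7 px in the second session, no
#'     background.}
#' }
#'
#' @param style dataset style.
#' @param config a `simulation_config`; styles override the transform and
#'   (for `individual_shift`) drop background sources.
#' @param render_movies if `TRUE`, include per-session movies
#'   (`A C + background + noise`) as H*W x T matrices; memory-heavy, off by
#'   default.
#' @return list of class `simulated_dataset`: `sessions`, `links`, `truth`
#'   (with `register`, per-session `footprints`, `traces`, `spikes`,
#'   `centers`, applied `shifts`), `config`, optional `movies`.
#' @export
make_dataset <- function(style = c("gaussian", "nonrigid_1p", "nonrigid_2p",
                                   "individual_shift"),
                         config = NULL, render_movies = FALSE) {
  style <- match.arg(style)
  if (is.null(config)) {
    config <- switch(style,
      gaussian = simulation_config(fov_shape = c(256, 256), n_neurons = 50,
                                   n_sessions = 2, frames_per_session = 2000,
                                   noise = "gaussian"),
      nonrigid_1p = simulation_config(fov_shape = c(256, 256), n_neurons = 50,
                                      n_sessions = 4,
                                      frames_per_session = 2000,
                                      noise = "gaussian"),
      nonrigid_2p = simulation_config(fov_shape = c(256, 256), n_neurons = 50,
                                      n_sessions = 4,
                                      frames_per_session = 2000,
                                      noise = "salt_pepper"),
      individual_shift = simulation_config(fov_shape = c(100, 100),
                                           n_neurons = 50, n_sessions = 2,
                                           frames_per_session = 3000,
                                           n_background = 0, noise = "none"))
  }
  config$transform <- switch(style, gaussian = "none",
                             nonrigid_1p = "nonrigid",
                             nonrigid_2p = "ring_nonrigid",
                             individual_shift = "individual_shift")
  if (style == "individual_shift") config$n_background <- 0L
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)

  base <- simulate_footprints(config)
  ns <- config$n_sessions
  t_s <- config$frames_per_session
  fov <- config$fov_shape
  k <- config$n_neurons

  session_fp <- vector("list", ns)
  session_tr <- vector("list", ns)
  session_sp <- vector("list", ns)
  shifts <- vector("list", ns)
  for (s in seq_len(ns)) {
    fp <- base$footprints
    sh <- matrix(0, 2, k)
    if (s > 1L || config$transform %in% c("nonrigid", "ring_nonrigid")) {
      if (config$transform %in% c("nonrigid", "ring_nonrigid")) {
        fp <- apply_nonrigid_warp(fp, fov)
      } else if (config$transform == "individual_shift" && s > 1L) {
        res <- apply_individual_shift(fp, fov, config$shift_range)
        fp <- res$footprints
        sh <- res$shifts
      }
    }
    if (config$transform == "ring_nonrigid")
      fp <- apply(fp, 2, apply_ring_transform)
    st <- simulate_traces(config, t_s)
    session_fp[[s]] <- fp
    session_tr[[s]] <- st$traces
    session_sp[[s]] <- st$spikes
    shifts[[s]] <- sh
  }

  sessions <- lapply(seq_len(ns), function(s) {
    tr <- session_tr[[s]]
    if (config$noise == "gaussian" && config$noise_level > 0)
      tr <- tr + matrix(stats::rnorm(length(tr), 0,
                                     config$noise_level), nrow(tr))
    session_extraction(session_fp[[s]], tr, fov,
                       session_id = paste0("session_", s),
                       spikes = session_sp[[s]])
  })

  # links: ground-truth traces over the boundary frames; footprints from the
  # left session (the boundary field of view)
  n_link <- min(config$link_frames, floor(t_s / 2))
  links <- vector("list", max(ns - 1L, 0L))
  if (ns >= 2L) {
    for (s in seq_len(ns - 1L)) {
      link_tr <- cbind(session_tr[[s]][, (t_s - n_link + 1L):t_s, drop = FALSE],
                       session_tr[[s + 1L]][, 1L:n_link, drop = FALSE])
      links[[s]] <- link_extraction(
        session_extraction(session_fp[[s]], link_tr, fov,
                           session_id = paste0("link_", s, "_", s + 1L)),
        n_link,
        left_session_id = paste0("session_", s),
        right_session_id = paste0("session_", s + 1L))
    }
  }

  register <- cell_register(matrix(rep(seq_len(k), ns), k, ns),
                            rep(1, k))

  movies <- NULL
  if (render_movies) {
    movies <- lapply(seq_len(ns), function(s) {
      m <- session_fp[[s]] %*% session_tr[[s]]
      if (config$n_background > 0L) {
        bg <- simulate_background(config, t_s)
        m <- m + bg$footprints %*% bg$weights
      }
      peak <- max(m)
      if (config$noise == "gaussian" && config$noise_level > 0) {
        m <- m + matrix(stats::rnorm(length(m), 0, config$noise_level * peak),
                        nrow(m))
      } else if (config$noise == "salt_pepper" && config$noise_level > 0) {
        idx <- which(stats::runif(length(m)) < config$noise_level)
        m[idx] <- ifelse(stats::runif(length(idx)) < 0.5, 0, peak)
      }
      m
    })
  }

  structure(list(sessions = sessions, links = links,
                 truth = list(register = register, footprints = session_fp,
                              traces = session_tr, spikes = session_sp,
                              centers = base$centers, shifts = shifts),
                 config = config, style = style, movies = movies),
            class = "simulated_dataset")
}

#' Derive imperfect extractions from ground truth
#'
#' Emulates the error modes of a real source-extraction run without
#' re-running one: true neurons are dropped at `dropout_rate`, spurious
#' footprints (with their own traces) are injected at
#' `false_discovery_rate` (relative to the true count), traces receive
#' additive Gaussian noise `trace_noise`, and footprint centroids are
#' jittered by `footprint_jitter` pixels. The returned register maps
#' surviving true neurons to their per-session indices; injected false
#' neurons are absent from it.
#'
#' @param dataset a `simulated_dataset`.
#' @param dropout_rate,false_discovery_rate rates in `[0, 1)`.
#' @param trace_noise additive trace noise s.d.
#' @param footprint_jitter centroid jitter s.d. in pixels.
#' @param seed RNG seed for the corruption draws.
#' @return list with `sessions` (corrupted extractions) and `register`
#'   (truth rows over surviving neurons; `NA` where dropped).
#' @export
derive_extractions <- function(dataset, dropout_rate = 0,
                               false_discovery_rate = 0, trace_noise = 0,
                               footprint_jitter = 0, seed = 1) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  rates <- c(dropout_rate, false_discovery_rate)
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ns <- length(dataset$sessions)
  k <- nrow(dataset$truth$register$table)
  fov <- dataset$config$fov_shape
  reg <- matrix(NA_integer_, k, ns)
  sessions <- vector("list", ns)
  rr <- matrix(seq_len(fov[1]), fov[1], fov[2])
  cc <- matrix(seq_len(fov[2]), fov[1], fov[2], byrow = TRUE)
  for (s in seq_len(ns)) {
    keep <- which(stats::runif(k) >= dropout_rate)
    fp <- dataset$truth$footprints[[s]][, keep, drop = FALSE]
    tr <- dataset$truth$traces[[s]][keep, , drop = FALSE]
    if (footprint_jitter > 0 && length(keep) > 0L) {
      for (ii in seq_along(keep)) {
        d <- stats::rnorm(2, 0, footprint_jitter)
        img <- matrix(fp[, ii], fov[1])
        fp[, ii] <- as.numeric(bilinear_sample(img, rr - d[1], cc - d[2]))
      }
    }
    n_false <- stats::rbinom(1, k, false_discovery_rate)
    if (n_false > 0L) {
      fcfg <- dataset$config
      fcfg$n_neurons <- n_false
      fk <- simulate_footprints(fcfg)
      ftr <- simulate_traces(fcfg, ncol(tr))
      fp <- cbind(fp, fk$footprints)
      tr <- rbind(tr, ftr$traces)
    }
    if (trace_noise > 0 && nrow(tr) > 0L)
      tr <- tr + matrix(stats::rnorm(length(tr), 0, trace_noise), nrow(tr))
    # shuffle order so extracted indices do not trivially equal truth ids
    perm <- sample.int(ncol(fp))
    fp <- fp[, perm, drop = FALSE]
    tr <- tr[perm, , drop = FALSE]
    reg[keep, s] <- match(seq_along(keep), perm)
    sessions[[s]] <- session_extraction(fp, tr, fov,
                                        session_id = paste0("session_", s))
  }
  surv <- rowSums(!is.na(reg)) > 0L
  list(sessions = sessions,
       register = cell_register(reg[surv, , drop = FALSE],
                                rep(1, sum(surv))))
}
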