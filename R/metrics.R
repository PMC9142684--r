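#' Intensity-weighted centroid of a spatial footprint
#'
#' The footprint is normalized to unit mass before weighting so the result
#' is a genuine pixel coordinate, independent of overall brightness.
#'
#' @param footprint numeric vector of length `H*W` (or `H x W` matrix),
#'   nonnegative with positive total mass.
#' @param fov_shape `c(H, W)`; ignored when `footprint` is already a matrix.
#' @return numeric `c(row, col)`, 1-based pixel coordinates.
#' @export
centroid <- function(footprint, fov_shape = NULL) {
  if (is.matrix(footprint)) {
    img <- footprint
  } else {
    if (is.null(fov_shape)) stop("fov_shape required for a flattened footprint")
    img <- matrix(footprint, nrow = fov_shape[1])
  }
  mass <- sum(img)
  if (!is.finite(mass) || mass <= 0)
    stop("degenerate footprint: no positive mass")
  w <- img / mass
  r <- sum(rowSums(w) * seq_len(nrow(img)))
  cc <- sum(colSums(w) * seq_len(ncol(img)))
  c(r, cc)
}

#' Euclidean distance between two footprint centroids
#' @param fp_a,fp_b footprints (vectors or matrices on the same FOV).
#' @inheritParams centroid
#' @return nonnegative distance in pixels.
#' @export
centroid_distance <- function(fp_a, fp_b, fov_shape = NULL) {
  sqrt(sum((centroid(fp_a, fov_shape) - centroid(fp_b, fov_shape))^2))
}

#' Cosine overlap of binarized footprint supports
#'
#' Footprints are binarized (positive intensity -> 1) and the cosine of the
#' resulting support vectors is returned: 1 for identical supports, 0 for
#' disjoint ones.
#'
#' @param fp_a,fp_b footprints on the same pixel grid.
#' @return value in `[0, 1]`.
#' @export
spatial_overlap <- function(fp_a, fp_b) {
  a <- as.numeric(fp_a) > 0
  b <- as.numeric(fp_b) > 0
  na <- sum(a); nb <- sum(b)
  if (na == 0L || nb == 0L) stop("degenerate footprint: empty support")
  sum(a & b) / sqrt(na * nb)
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' `JS(P, Q) = 0.5 KL(P || M) + 0.5 KL(Q || M)` with `M = (P + Q) / 2` and
#' the convention `0 log 0 = 0`. With base-2 logarithms the value lies in
#' `[0, 1]` bits.
#'
#' @param p,q nonnegative vectors of equal length with positive mass
#'   (normalized internally).
#' @param base logarithm base (default 2, i.e. bits).
#' @return nonnegative divergence; 0 iff the normalized distributions agree.
#' @export
js_divergence <- function(p, q, base = 2) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("p and q must have equal length")
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) stop("degenerate input: zero total mass")
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i] / b[i]) / log(base)))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Jensen-Shannon divergence between two footprints
#'
#' Footprints are normalized to probability distributions over the pixel
#' grid and compared with [js_divergence()].
#'
#' @inheritParams spatial_overlap
#' @return divergence in bits, in `[0, 1]`.
#' @export
js_divergence_footprints <- function(fp_a, fp_b) {
  js_divergence(as.numeric(fp_a), as.numeric(fp_b), base = 2)
}

#' Signal-to-noise ratio of a fluorescence trace
#'
#' SNR = Var(signal) / Var(noise). The signal estimate is a running-median
#' detrend (window `window` frames); the noise is the residual. The ratio
#' is capped at `cap` so that (near-)noiseless synthetic traces yield a
#' finite value.
#'
#' @param trace numeric vector, length >= `window`.
#' @param window odd median-filter window in frames.
#' @param cap upper bound for the ratio.
#' @return positive SNR, or `NA` with a `"degenerate"` attribute for a
#'   constant trace.
#' @export
snr_of_trace <- function(trace, window = 15, cap = 1e6) {
  trace <- as.numeric(trace)
  if (length(trace) < window) stop("trace shorter than the filter window")
  if (stats::sd(trace) == 0) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  signal <- stats::runmed(trace, k = window, endrule = "median")
  noise <- trace - signal
  vs <- stats::var(signal)
  vn <- stats::var(noise)
  if (vn <= vs / cap) return(cap)
  min(vs / vn, cap)
}

#' SNR similarity (log-ratio distance)
#'
#' `|log(snr1) - log(snr2)|` (natural log); the log centralizes the heavy
#' right tail of SNR values.
#'
#' @param snr1,snr2 positive SNR values.
#' @return nonnegative distance.
#' @export
snr_similarity <- function(snr1, snr2) {
  if (is.na(snr1) || is.na(snr2) || snr1 <= 0 || snr2 <= 0)
    stop("SNR values must be positive")
  abs(log(snr1) - log(snr2))
}

#' Detect transient peaks in a trace
#'
#' Local maxima above `thresh_mult` times the robust noise level (median
#' absolute deviation of the first difference, scaled), separated by at
#' least `min_separation` frames (greedy, tallest first).
#'
#' @param trace numeric vector.
#' @param thresh_mult multiple of the robust noise level.
#' @param min_separation minimal spacing between kept peaks, frames.
#' @return integer vector of peak frame indices (possibly empty).
#' @export
find_peaks <- function(trace, thresh_mult = 3, min_separation = 10) {
  trace <- as.numeric(trace)
  t_len <- length(trace)
  if (t_len < 3L) return(integer(0))
  noise <- stats::mad(diff(trace)) / sqrt(2)
  thresh <- max(thresh_mult * noise, 1e-12)
  cand <- which(trace[-c(1L, t_len)] > trace[-c(t_len - 1L, t_len)] &
                  trace[-c(1L, t_len)] >= trace[-c(1L, 2L)]) + 1L
  cand <- cand[trace[cand] > thresh]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(trace[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (p in cand) {
    if (all(abs(kept - p) >= min_separation)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Estimate the fluorescence decay constant of a trace
#'
#' Detects transient peaks, normalizes each transient to unit peak height,
#' averages the aligned transients, and fits `exp(-t / tau_d)` to the
#' average over `fit_frames` frames after the peak by least squares on the
#' log scale. Mirrors the post-extraction decay estimators shipped with
#' source-extraction pipelines, so it works with traces from any pipeline.
#'
#' @param trace numeric vector.
#' @param fit_frames frames after the peak used in the fit.
#' @param min_peaks fewer detected peaks than this returns `NA` (failure).
#' @param ... passed to [find_peaks()].
#' @return decay constant tau_d in frames, or `NA_real_` on failure.
#' @export
estimate_decay_rate <- function(trace, fit_frames = 30, min_peaks = 3, ...) {
  trace <- as.numeric(trace)
  peaks <- find_peaks(trace, ...)
  if (length(peaks) < min_peaks) return(NA_real_)
  t_len <- length(trace)
  segs <- lapply(peaks, function(p) {
    end <- min(p + fit_frames, t_len)
    seg <- trace[p:end]
    if (seg[1] <= 0) return(NULL)
    out <- rep(NA_real_, fit_frames + 1L)
    out[seq_along(seg)] <- seg / seg[1]
    out
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) < min_peaks) return(NA_real_)
  avg <- colMeans(do.call(rbind, segs), na.rm = TRUE)
  tt <- seq_along(avg) - 1L
  # skip the peak frame itself; keep strictly positive samples for the log fit
  use <- tt >= 1 & avg > 1e-6 & is.finite(avg)
  if (sum(use) < 3L) return(NA_real_)
  fit <- stats::lm(log(avg[use]) ~ tt[use])
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) return(NA_real_)
  -1 / slope
}

#' Decay-rate similarity
#'
#' `|dec1 - dec2|` in frames; `NA` if either estimate failed, in which case
#' the tracker treats the metric as uninformative for the pair.
#'
#' @param dec1,dec2 decay constants (frames), possibly `NA`.
#' @return nonnegative distance or `NA`.
#' @export
decay_similarity <- function(dec1, dec2) {
  if (is.na(dec1) || is.na(dec2)) return(NA_real_)
  abs(dec1 - dec2)
}

#' Link-session correlation between two neurons
#'
#' Scores the identity of neuron `i` in session A and neuron `j` in session
#' B through a connecting ("link") recording that spans the boundary. Every
#' link neuron whose centroid lies within `neighbor_radius` of both
#' candidates, and which is active in both halves of the link, is tried as
#' the connecting neuron; its score is the mean of (a) the correlation of
#' neuron i's last `n` frames with the link neuron's first half, and (b)
#' the correlation of the link neuron's second half with neuron j's first
#' `n` frames. The best connecting neuron's score is returned.
#'
#' @param i,j neuron indices in `session_a` / `session_b`.
#' @param session_a,session_b `session_extraction`s flanking the link.
#' @param link a `link_extraction` spanning the boundary.
#' @param neighbor_radius pixels; candidate link neurons must be within this
#'   distance of both neurons' centroids.
#' @param activity_thresh_mult peak threshold (multiple of robust noise) for
#'   the activity test; link neurons active in exactly one half are
#'   discarded, since they cannot bridge the sessions.
#' @return correlation in `[-1, 1]`, or `NA_real_` when no eligible link
#'   neuron exists.
#' @export
link_correlation <- function(i, j, session_a, session_b, link,
                             neighbor_radius, activity_thresh_mult = 3) {
  n <- link$n_frames_each_side
  ta <- n_frames(session_a); tb <- n_frames(session_b)
  if (ta < n || tb < n)
    stop("link half-length exceeds a flanking session's frame count")
  tail_a <- session_a$traces[i, (ta - n + 1L):ta]
  head_b <- session_b$traces[j, 1L:n]
  ci <- centroid(session_a$footprints[, i], session_a$fov_shape)
  cj <- centroid(session_b$footprints[, j], session_b$fov_shape)
  lx <- link$extraction
  best <- NA_real_
  for (c_idx in seq_len(n_neurons(lx))) {
    cc <- centroid(lx$footprints[, c_idx], lx$fov_shape)
    if (sqrt(sum((cc - ci)^2)) > neighbor_radius) next
    if (sqrt(sum((cc - cj)^2)) > neighbor_radius) next
    tr <- lx$traces[c_idx, ]
    h1 <- tr[1L:n]; h2 <- tr[(n + 1L):(2L * n)]
    a1 <- length(find_peaks(h1, thresh_mult = activity_thresh_mult)) > 0L
    a2 <- length(find_peaks(h2, thresh_mult = activity_thresh_mult)) > 0L
    if (xor(a1, a2)) next
    r1 <- safe_cor(tail_a, h1)
    r2 <- safe_cor(h2, head_b)
    if (is.na(r1) || is.na(r2)) next
    score <- (r1 + r2) / 2
    if (is.na(best) || score > best) best <- score
  }
  best
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Candidate neuron pairs between two sessions
#'
#' A pair (i in A, j in B) is a candidate for identification when the two
#' footprints have non-zero binarized overlap and their centroids are at
#' most `max_dist` pixels apart. Only candidate pairs receive similarity
#' metrics and identification probabilities.
#'
#' @param session_a,session_b `session_extraction`s on the same FOV.
#' @param max_dist maximal centroid distance in pixels.
#' @return data.frame with columns `i`, `j`, `dist`, `overlap`; attribute
#'   `max_dist`.
#' @export
candidate_pairs <- function(session_a, session_b, max_dist) {
  ka <- n_neurons(session_a); kb <- n_neurons(session_b)
  cent_a <- vapply(seq_len(ka), function(k)
    centroid(session_a$footprints[, k], session_a$fov_shape), numeric(2))
  cent_b <- vapply(seq_len(kb), function(k)
    centroid(session_b$footprints[, k], session_b$fov_shape), numeric(2))
  sup_a <- session_a$footprints > 0
  sup_b <- session_b$footprints > 0
  out_i <- integer(0); out_j <- integer(0)
  out_d <- numeric(0); out_o <- numeric(0)
  for (i in seq_len(ka)) {
    d <- sqrt(colSums((cent_b - cent_a[, i])^2))
    near <- which(d <= max_dist)
    if (length(near) == 0L) next
    cross <- crossprod(sup_a[, i, drop = FALSE], sup_b[, near, drop = FALSE])
    ov <- as.numeric(cross) / sqrt(sum(sup_a[, i]) * colSums(sup_b[, near, drop = FALSE]))
    keep <- ov > 0
    out_i <- c(out_i, rep.int(i, sum(keep)))
    out_j <- c(out_j, near[keep])
    out_d <- c(out_d, d[near][keep])
    out_o <- c(out_o, ov[keep])
  }
  res <- data.frame(i = out_i, j = out_j, dist = out_d, overlap = out_o)
  attr(res, "max_dist") <- max_dist
  res
}
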