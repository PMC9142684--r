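#' Construct a linear-track run
#'
#' Behavioral and neural data for one session on a linear track: the
#' animal's position per frame, its speed (computed from position if not
#' supplied), and per-neuron event trains (deconvolved peak intensities per
#' frame, zero between events).
#'
#' @param position numeric vector, track coordinate per frame (meters, in
#'   `[0, track_length]`).
#' @param events numeric matrix, neurons x frames, nonnegative event
#'   intensities.
#' @param track_length track length in meters.
#' @param frame_rate frames per second.
#' @param speed optional per-frame speed (m/s); derived from `position` by
#'   central differences when `NULL`.
#' @param n_bins spatial bins over the middle 80% of the track.
#' @return list of class `track_run`.
#' @export
track_run <- function(position, events, track_length = 1,
                      frame_rate = 30, speed = NULL, n_bins = 20) {
  position <- as.numeric(position)
  events <- as.matrix(events)
  if (ncol(events) != length(position))
    stop("events must have one column per frame")
  if (any(position < 0 | position > track_length))
    stop("positions must lie in [0, track_length]")
  if (any(events < 0)) stop("event intensities must be nonnegative")
  if (is.null(speed)) {
    d <- diff(position)
    speed <- abs(c(d[1], (c(d, 0) + c(0, d))[2:length(position)] / 2)) *
      frame_rate
    speed[length(speed)] <- abs(d[length(d)]) * frame_rate
  }
  structure(list(position = position, events = events, speed = speed,
                 track_length = track_length, frame_rate = frame_rate,
                 n_bins = as.integer(n_bins)),
            class = "track_run")
}

#' Clean a peak event train
#'
#' Deconvolved event trains from source extraction carry outlying peak
#' intensities. Low outliers (below half the median peak intensity) are
#' removed; high outliers are capped at the median plus three scaled
#' median absolute deviations; the train is then smoothed with a Gaussian
#' kernel of width (sigma) `smooth_sd` frames.
#'
#' @param events numeric vector per frame (zeros between events).
#' @param smooth_sd Gaussian smoothing sigma in frames; 0 disables.
#' @return cleaned event vector, same length; all-zero (with attribute
#'   `"empty"`) when no event survives filtering.
#' @export
preprocess_peaks <- function(events, smooth_sd = 0.5) {
  events <- as.numeric(events)
  idx <- which(events > 0)
  if (length(idx) == 0L) {
    out <- events
    attr(out, "empty") <- TRUE
    return(out)
  }
  peaks <- events[idx]
  med <- stats::median(peaks)
  keep <- peaks >= 0.5 * med
  cap <- med + 3 * stats::mad(peaks)
  cleaned <- numeric(length(events))
  cleaned[idx[keep]] <- pmin(peaks[keep], cap)
  if (all(cleaned == 0)) {
    attr(cleaned, "empty") <- TRUE
    return(cleaned)
  }
  if (smooth_sd > 0) {
    half <- max(1L, ceiling(3 * smooth_sd))
    kern <- stats::dnorm(seq(-half, half), sd = smooth_sd)
    kern <- kern / sum(kern)
    n <- length(cleaned)
    padded <- c(numeric(half), cleaned, numeric(half))
    cleaned <- as.numeric(stats::filter(padded, kern,
                                        sides = 2))[(half + 1):(half + n)]
  }
  cleaned
}

#' Compute a linear-track place field
#'
#' Frames where the animal was within 10% of the track length of either
#' end, or moving slower than `speed_thresh`, are excluded. The interior
#' (middle 80% of the track) is divided into `n_bins` bins and the field
#' is the ratio of summed neural activity to occupancy time per bin,
#' optionally smoothed with a Gaussian of sigma `smooth_sd` bins. Bins the
#' animal never occupied are `NA`.
#'
#' @param run a `track_run`.
#' @param neuron neuron index into `run$events`.
#' @param speed_thresh movement threshold in m/s.
#' @param end_frac excluded fraction of the track at each end.
#' @param smooth_sd field smoothing sigma in bins (0 disables).
#' @param preprocess apply [preprocess_peaks()] to the event train first.
#' @return list of class `place_field`: `field` (activity per occupancy,
#'   length `n_bins`), `occupancy` (probability per bin), `n_frames_used`.
#' @export
compute_place_field <- function(run, neuron, speed_thresh = 0.02,
                                end_frac = 0.1, smooth_sd = 0.5,
                                preprocess = TRUE) {
  stopifnot(inherits(run, "track_run"))
  ev <- run$events[neuron, ]
  if (preprocess) ev <- preprocess_peaks(ev, smooth_sd = 0.5)
  lo <- end_frac * run$track_length
  hi <- (1 - end_frac) * run$track_length
  use <- run$position > lo & run$position < hi & run$speed >= speed_thresh
  pos <- run$position[use]
  ev <- ev[use]
  bins <- pmin(pmax(ceiling((pos - lo) / (hi - lo) * run$n_bins), 1L),
               run$n_bins)
  occ_frames <- tabulate(bins, nbins = run$n_bins)
  act <- vapply(seq_len(run$n_bins), function(b) sum(ev[bins == b]),
                numeric(1))
  occ_time <- occ_frames / run$frame_rate
  field <- ifelse(occ_frames > 0, act / occ_time, NA_real_)
  if (smooth_sd > 0) {
    ok <- !is.na(field)
    if (sum(ok) >= 2L) {
      half <- max(1L, ceiling(3 * smooth_sd))
      kern <- stats::dnorm(seq(-half, half), sd = smooth_sd)
      sm <- field
      f0 <- field
      f0[!ok] <- 0
      wts <- as.numeric(ok)
      csm <- function(v) {
        n <- length(v)
        padded <- c(numeric(half), v, numeric(half))
        as.numeric(stats::filter(padded, kern, sides = 2))[(half + 1):(half + n)]
      }
      num <- csm(f0)
      den <- csm(wts)
      sm[ok] <- num[ok] / den[ok]
      field <- sm
    }
  }
  occupancy <- occ_frames / sum(occ_frames)
  structure(list(field = field, occupancy = occupancy,
                 n_frames_used = sum(use), n_bins = run$n_bins),
            class = "place_field")
}

#' Spatial information score
#'
#' `sum_i p_i * lambda_i * log2(lambda_i)` where `p_i` is the occupancy
#' probability of bin i and `lambda_i` the ratio of the bin's firing rate
#' to the occupancy-weighted mean rate; the convention `0 log 0 = 0`
#' applies. Bins with undefined occupancy are excluded and the remaining
#' probabilities renormalized.
#'
#' @param field per-bin activity rate (a `place_field$field` vector).
#' @param occupancy per-bin occupancy probabilities.
#' @return information in bits (>= 0), or `NA` when total firing is zero.
#' @export
information_score <- function(field, occupancy) {
  if (inherits(field, "place_field")) {
    occupancy <- field$occupancy
    field <- field$field
  }
  ok <- !is.na(field) & occupancy > 0
  if (!any(ok)) return(NA_real_)
  p <- occupancy[ok] / sum(occupancy[ok])
  r <- field[ok]
  mean_rate <- sum(p * r)
  if (mean_rate <= 0) return(NA_real_)
  lam <- r / mean_rate
  pos <- lam > 0
  sum(p[pos] * lam[pos] * log2(lam[pos]))
}

#' Shuffle percentile of the information score
#'
#' Builds the null distribution of the information score by circularly
#' shifting the position (and speed) vector by at least `min_shift_s`
#' seconds, `n_shuffles` times, recomputing the score each time. The
#' returned percentile is the rank of the unshifted score in that null
#' distribution (ties counted half).
#'
#' @inheritParams compute_place_field
#' @param n_shuffles number of random shifts (default 500).
#' @param min_shift_s minimal shift in seconds (default 3).
#' @param seed RNG seed.
#' @param ... passed to [compute_place_field()].
#' @return list with `percentile` in `[0, 1]`, `score`, `null_scores`.
#' @export
information_percentile <- function(run, neuron, n_shuffles = 500,
                                   min_shift_s = 3, seed = 1, ...) {
  stopifnot(inherits(run, "track_run"))
  t_len <- length(run$position)
  min_shift <- ceiling(min_shift_s * run$frame_rate)
  if (t_len <= 2L * min_shift)
    stop("run too short for the requested minimal shift")
  pf <- compute_place_field(run, neuron, ...)
  obs <- information_score(pf)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  shifts <- sample(seq(min_shift, t_len - min_shift), n_shuffles,
                   replace = TRUE)
  null_scores <- vapply(shifts, function(sh) {
    idx <- c((sh + 1L):t_len, 1L:sh)
    shifted <- run
    shifted$position <- run$position[idx]
    shifted$speed <- run$speed[idx]
    information_score(compute_place_field(shifted, neuron, ...))
  }, numeric(1))
  ok <- !is.na(null_scores)
  if (is.na(obs) || !any(ok))
    return(list(percentile = NA_real_, score = obs,
                null_scores = null_scores))
  pct <- (sum(null_scores[ok] < obs) + sum(null_scores[ok] == obs) / 2) /
    sum(ok)
  list(percentile = pct, score = obs, null_scores = null_scores)
}

#' Place-field stability across tracked sessions
#'
#' For every register row tracked through at least `min_sessions` sessions,
#' every pair of sessions the cell spans contributes one identified cell
#' pair (a cell tracked through four sessions produces six pairs). For
#' each pair the Jensen-Shannon divergence between the two normalized
#' place fields is computed; summary fractions report how many pairs fall
#' below a field-similarity acceptance threshold and how many agree in
#' place-cell classification at a percentile (or information-score)
#' threshold.
#'
#' @param register a `cell_register`.
#' @param fields list (per session) of lists (per neuron) of `place_field`s.
#' @param percentiles optional list (per session) of numeric vectors of
#'   information percentiles per neuron; enables the classification
#'   consistency fraction.
#' @param scores optional list (per session) of information scores per
#'   neuron (used when `percentiles` is `NULL`).
#' @param js_thresh acceptance threshold on pairwise JS divergence.
#' @param class_thresh place-cell threshold on the percentile (or score).
#' @param min_sessions minimum sessions a row must span (default 3: rows
#'   identified in only two sessions are removed as noise-prone).
#' @return list with `pairs` (data.frame: row, session_a, session_b,
#'   js), `mean_js`, `frac_below_js_thresh`, `frac_class_consistent`
#'   (`NA` without percentiles/scores).
#' @export
placefield_stability <- function(register, fields, percentiles = NULL,
                                 scores = NULL, js_thresh = 0.1,
                                 class_thresh = 0.95, min_sessions = 3) {
  stopifnot(inherits(register, "cell_register"))
  tab <- register$table
  rows <- which(rowSums(!is.na(tab)) >= min_sessions)
  out <- list()
  for (r in rows) {
    ses <- which(!is.na(tab[r, ]))
    if (length(ses) < 2L) next
    combs <- utils::combn(ses, 2)
    for (ci in seq_len(ncol(combs))) {
      sa <- combs[1, ci]; sb <- combs[2, ci]
      fa <- fields[[sa]][[tab[r, sa]]]$field
      fb <- fields[[sb]][[tab[r, sb]]]$field
      ok <- !is.na(fa) & !is.na(fb)
      js <- if (sum(fa[ok]) > 0 && sum(fb[ok]) > 0)
        js_divergence(fa[ok], fb[ok], base = 2) else NA_real_
      cls <- NA
      vals <- if (!is.null(percentiles)) percentiles else scores
      if (!is.null(vals)) {
        va <- vals[[sa]][tab[r, sa]]
        vb <- vals[[sb]][tab[r, sb]]
        cls <- (va >= class_thresh) == (vb >= class_thresh)
      }
      out[[length(out) + 1L]] <- data.frame(
        row = r, session_a = sa, session_b = sb, js = js,
        class_consistent = cls)
    }
  }
  if (length(out) == 0L)
    return(list(pairs = data.frame(), mean_js = NA_real_,
                frac_below_js_thresh = NA_real_,
                frac_class_consistent = NA_real_))
  pairs <- do.call(rbind, out)
  list(pairs = pairs,
       mean_js = mean(pairs$js, na.rm = TRUE),
       frac_below_js_thresh = mean(pairs$js < js_thresh, na.rm = TRUE),
       frac_class_consistent = if (all(is.na(pairs$class_consistent)))
         NA_real_ else mean(pairs$class_consistent, na.rm = TRUE))
}

#' Simulate a linear-track run with tuned and untuned cells
#'
#' Generates a constant-speed back-and-forth traversal of a linear track
#' and Poisson-like event trains: place cells fire preferentially inside a
#' Gaussian tuning field at their preferred position; untuned cells fire
#' uniformly. Used in tests and examples where behavior with known ground
#' truth is needed.
#'
#' @param n_frames frames to simulate.
#' @param n_place,n_untuned numbers of tuned / untuned cells.
#' @param track_length meters.
#' @param frame_rate Hz.
#' @param field_sd tuning width in meters.
#' @param base_rate,peak_rate event probabilities per frame outside /
#'   inside the field.
#' @param seed RNG seed.
#' @return a `track_run`; attribute `"preferred"` holds the place cells'
#'   preferred positions (`NA` for untuned cells).
#' @export
simulate_track_run <- function(n_frames = 6000, n_place = 5, n_untuned = 5,
                               track_length = 1, frame_rate = 30,
                               field_sd = 0.05, base_rate = 0.002,
                               peak_rate = 0.08, seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  period <- 10 * frame_rate  # one end-to-end traversal every ~10 s
  # jittered phase advance keeps the trajectory aperiodic, as real running
  # is; a strictly periodic path would alias with circular-shift nulls
  dphase <- abs(stats::rnorm(n_frames, 2 * pi / (2 * period),
                             0.5 * 2 * pi / (2 * period)))
  phase <- cumsum(dphase)
  position <- track_length * (1 + sin(phase)) / 2
  n_cells <- n_place + n_untuned
  preferred <- c(stats::runif(n_place, 0.2, 0.8) * track_length,
                 rep(NA_real_, n_untuned))
  events <- matrix(0, n_cells, n_frames)
  for (i in seq_len(n_cells)) {
    rate <- if (is.na(preferred[i])) rep(base_rate + peak_rate / 20, n_frames)
    else base_rate + peak_rate *
      exp(-(position - preferred[i])^2 / (2 * field_sd^2))
    fires <- stats::runif(n_frames) < rate
    events[i, fires] <- stats::rlnorm(sum(fires), 0, 0.3)
  }
  run <- track_run(position, events, track_length, frame_rate)
  attr(run, "preferred") <- preferred
  run
}
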