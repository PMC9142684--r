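#' Percentile identification probability
#'
#' The simplest probability model: a candidate pair's probability for a
#' metric is the fraction of the candidate-pair population whose value is
#' strictly worse, with ties contributing half. "Worse" is larger for a
#' distance metric and smaller for a similarity metric, so good values map
#' near 1 in either case.
#'
#' @param values numeric population of metric values over candidate pairs.
#' @param x query value(s).
#' @param direction `"distance"` (smaller is better) or `"similarity"`.
#' @return probability in `[0, 1]` per query.
#' @export
percentile_probability <- function(values, x,
                                   direction = c("distance", "similarity")) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty metric population")
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(0.5)
    if (direction == "distance") {
      worse <- sum(values > xi)
    } else {
      worse <- sum(values < xi)
    }
    (worse + sum(values == xi) / 2) / length(values)
  }, numeric(1))
}

#' Boundary-reflected kernel density estimate
#'
#' Standard Gaussian KDE (Silverman bandwidth) with the sample reflected at
#' any finite theoretical bound, which removes the boundary bias that a
#' plain KDE shows for metrics confined to an interval (correlations in
#' `[-1, 1]`, overlaps in `[0, 1]`, distances in `[0, max_dist]`).
#'
#' @param values numeric sample (>= 10 values, not all identical).
#' @param bounds length-2 vector; use `-Inf`/`Inf` for an unbounded side.
#' @param n_grid evaluation grid size.
#' @return list with `x`, `y` (grid and density, integrating to 1 over the
#'   bounds) and a `fun` linear interpolator (0 outside the bounds).
#' @export
estimate_density <- function(values, bounds = c(-Inf, Inf), n_grid = 256) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) stop("need at least 2 values for a density")
  if (stats::sd(values) == 0) {
    out <- list(degenerate = TRUE, at = values[1])
    class(out) <- "reflected_density"
    return(out)
  }
  lo <- bounds[1]; hi <- bounds[2]
  bw <- stats::bw.nrd0(values)
  aug <- values
  if (is.finite(lo)) aug <- c(aug, 2 * lo - values)
  if (is.finite(hi)) aug <- c(aug, 2 * hi - values)
  from <- if (is.finite(lo)) lo else min(values) - 3 * bw
  to <- if (is.finite(hi)) hi else max(values) + 3 * bw
  d <- stats::density(aug, bw = bw, from = from, to = to, n = n_grid)
  # reflection folds mass back inside the bounds: rescale by the number of
  # copies, then renormalize numerically on the grid
  y <- d$y * length(aug) / length(values)
  step <- d$x[2] - d$x[1]
  y <- y / (sum(y) * step)
  fn <- stats::approxfun(d$x, y, yleft = 0, yright = 0)
  out <- list(x = d$x, y = y, fun = fn, bounds = c(from, to),
              degenerate = FALSE)
  class(out) <- "reflected_density"
  out
}

#' Fit a two-component Gaussian mixture to a metric population
#'
#' Assumes the candidate-pair metric values come from a mixture of an
#' "identified" population (true same-cell pairs) and a "non-identified"
#' population. A reflected KDE of the values is computed and the parametric
#' model `w f(x) + (1 - w) g(x)` (both components Gaussian) is fitted to it
#' on a fixed grid by bounded nonlinear least squares. For a distance
#' metric the lower-mean component is labeled "identified"; for a
#' similarity metric the higher-mean one.
#'
#' @param values metric population (>= 10 values recommended; below that
#'   the caller should fall back to [percentile_probability()]).
#' @param direction metric direction, as in [percentile_probability()].
#' @param bounds theoretical metric bounds for the KDE reflection.
#' @param family mixture family; only `"gaussian"`.
#' @return An `identification_model` with `method = "mixture"`, or on fit
#'   failure the soft k-means model (with a warning).
#' @export
fit_two_component_mixture <- function(values,
                                      direction = c("distance", "similarity"),
                                      bounds = c(-Inf, Inf),
                                      family = "gaussian") {
  direction <- match.arg(direction)
  family <- match.arg(family, "gaussian")
  values <- values[is.finite(values)]
  dens <- tryCatch(estimate_density(values, bounds), error = function(e) NULL)
  if (is.null(dens) || isTRUE(dens$degenerate)) {
    return(degenerate_model(values, direction))
  }
  bw <- stats::bw.nrd0(values)
  km <- stats::kmeans(values, centers = sort(range(values)), iter.max = 50)
  ord <- order(km$centers)
  mu0 <- as.numeric(km$centers[ord])
  sd0 <- vapply(ord, function(cl) {
    v <- values[km$cluster == cl]
    s <- stats::sd(v)
    if (!is.finite(s) || s <= 0) s <- stats::sd(values) / 4
    max(s, bw)
  }, numeric(1))
  w0 <- mean(km$cluster == ord[1])
  # a second start places the identified component as a narrow mode at the
  # best-value end of the population; guards against local optima when the
  # identified pairs form a sharp spike against a broad background
  best_end <- if (direction == "distance") min(values) else max(values)
  w_spike <- mean(abs(values - best_end) <= 2 * bw)
  w_spike <- min(max(w_spike, 0.02), 0.98)
  starts <- list(
    list(w = min(max(w0, 0.05), 0.95),
         mu1 = mu0[1], s1 = sd0[1], mu2 = mu0[2], s2 = sd0[2]),
    if (direction == "distance")
      list(w = w_spike, mu1 = best_end, s1 = bw,
           mu2 = mean(values[abs(values - best_end) > 2 * bw]),
           s2 = max(stats::sd(values), bw))
    else
      list(w = 1 - w_spike,
           mu1 = mean(values[abs(values - best_end) > 2 * bw]),
           s1 = max(stats::sd(values), bw), mu2 = best_end, s2 = bw))
  starts[[2]] <- lapply(starts[[2]], function(z) if (is.finite(z)) z else
    mean(values))
  df <- data.frame(x = dens$x, y = dens$y)
  fits <- lapply(starts, function(st) tryCatch(
    minpack.lm::nlsLM(
      y ~ w * stats::dnorm(x, mu1, s1) + (1 - w) * stats::dnorm(x, mu2, s2),
      data = df, start = st,
      # component widths are floored at the KDE bandwidth: the fit target
      # cannot resolve anything narrower
      lower = c(0, -Inf, bw / 2, -Inf, bw / 2),
      upper = c(1, Inf, Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL))
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (length(fits) == 0L) {
    warning("mixture fit failed to converge; falling back to soft k-means")
    return(fit_soft_kmeans(values, direction))
  }
  sse <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  fit <- fits[[which.min(sse)]]
  p <- as.list(stats::coef(fit))
  # which component is the identified one
  low_first <- p$mu1 <= p$mu2
  ident_is_1 <- if (direction == "distance") low_first else !low_first
  structure(list(
    method = "mixture", direction = direction,
    w = if (ident_is_1) p$w else 1 - p$w,
    mu_ident = if (ident_is_1) p$mu1 else p$mu2,
    sd_ident = if (ident_is_1) p$s1 else p$s2,
    mu_other = if (ident_is_1) p$mu2 else p$mu1,
    sd_other = if (ident_is_1) p$s2 else p$s1,
    n = length(values)), class = "identification_model")
}

# Model selection guard: the identified/non-identified decomposition is only
# meaningful when the population actually splits into two components. Compare
# BIC of a single Gaussian against a hard-assigned two-component mixture.
population_is_bimodal <- function(values) {
  n <- length(values)
  if (n < 4L || stats::sd(values) == 0) return(FALSE)
  floor_sd <- max(stats::sd(values) * 1e-3, 1e-12)
  ll_norm <- function(v, mu, s) sum(stats::dnorm(v, mu, s, log = TRUE))
  bic1 <- -2 * ll_norm(values, mean(values),
                       max(stats::sd(values) * sqrt((n - 1) / n), floor_sd)) +
    2 * log(n)
  km <- stats::kmeans(values, centers = sort(range(values)), iter.max = 50)
  w <- mean(km$cluster == 1)
  if (w == 0 || w == 1) return(FALSE)
  mus <- as.numeric(km$centers)
  sds <- vapply(1:2, function(cl) {
    v <- values[km$cluster == cl]
    if (length(v) < 2L) return(floor_sd)
    max(stats::sd(v) * sqrt((length(v) - 1) / length(v)), floor_sd)
  }, numeric(1))
  mix_d <- w * stats::dnorm(values, mus[1], sds[1]) +
    (1 - w) * stats::dnorm(values, mus[2], sds[2])
  bic2 <- -2 * sum(log(pmax(mix_d, 1e-300))) + 5 * log(n)
  bic2 < bic1
}

degenerate_model <- function(values, direction) {
  structure(list(method = "degenerate", direction = direction,
                 at = if (length(values)) values[1] else NA_real_,
                 n = length(values)),
            class = "identification_model")
}

#' Fit the soft k-means (fuzzy c-means) identification model
#'
#' Two cluster centers are fitted to the 1-D metric population (k-means,
#' deterministic extreme-value initialization); a query's probability is
#' its fuzzy membership in the "identified" cluster (low center for
#' distance metrics, high center for similarity metrics) under fuzzifier
#' `m`.
#'
#' @inheritParams fit_two_component_mixture
#' @param m fuzzifier, > 1; larger values give softer memberships.
#' @return An `identification_model` with `method = "soft_kmeans"`.
#' @export
fit_soft_kmeans <- function(values, direction = c("distance", "similarity"),
                            m = 2) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) < 2L || stats::sd(values) == 0)
    return(degenerate_model(values, direction))
  km <- stats::kmeans(values, centers = sort(range(values)), iter.max = 50)
  centers <- sort(as.numeric(km$centers))
  ident <- if (direction == "distance") centers[1] else centers[2]
  other <- if (direction == "distance") centers[2] else centers[1]
  structure(list(method = "soft_kmeans", direction = direction,
                 center_ident = ident, center_other = other, m = m,
                 n = length(values)),
            class = "identification_model")
}

#' Soft k-means membership probability
#'
#' Convenience wrapper: fit the two-center fuzzy model on `values` and
#' return the identified-cluster membership of `x`.
#'
#' @inheritParams fit_soft_kmeans
#' @param x query value(s).
#' @return membership in `[0, 1]` per query.
#' @export
soft_kmeans_probability <- function(values, x,
                                    direction = c("distance", "similarity"),
                                    m = 2) {
  model <- fit_soft_kmeans(values, direction, m)
  posterior_probability(model, x)
}

#' Identification probability of a metric value under a fitted model
#'
#' For the mixture model this is the Bayes posterior
#' `w f(x) / (w f(x) + (1 - w) g(x))`; where both densities underflow the
#' query is assigned to the nearer component mode (continuity in the
#' tails). For the soft k-means model it is the fuzzy membership
#' `1 / sum_c (d_ident / d_c)^(2 / (m - 1))`. A degenerate model (all
#' population values identical) is uninformative and returns 0.5.
#'
#' @param model an `identification_model`.
#' @param x query value(s).
#' @return probability in `[0, 1]` per query; non-finite queries get 0.5.
#' @export
posterior_probability <- function(model, x) {
  stopifnot(inherits(model, "identification_model"))
  vapply(x, function(xi) {
    if (!is.finite(xi)) return(0.5)
    switch(model$method,
      degenerate = 0.5,
      mixture = {
        # log space: the posterior must stay well-defined deep in the tails
        lf <- log(model$w) +
          stats::dnorm(xi, model$mu_ident, model$sd_ident, log = TRUE)
        lg <- log(1 - model$w) +
          stats::dnorm(xi, model$mu_other, model$sd_other, log = TRUE)
        if (!is.finite(lf) && !is.finite(lg)) {
          # both weights/densities degenerate: nearest component mode wins
          as.numeric(abs(xi - model$mu_ident) <= abs(xi - model$mu_other))
        } else if (!is.finite(lf)) 0
        else if (!is.finite(lg)) 1
        else 1 / (1 + exp(lg - lf))
      },
      soft_kmeans = {
        d1 <- abs(xi - model$center_ident)
        d2 <- abs(xi - model$center_other)
        if (d1 == 0) return(1)
        if (d2 == 0) return(0)
        e <- 2 / (model$m - 1)
        1 / ((d1 / d1)^e + (d1 / d2)^e)
      },
      stop("unknown model method: ", model$method))
  }, numeric(1))
}

#' Discriminatory power of a fitted mixture model
#'
#' One minus the overlap coefficient between the identified and
#' non-identified component densities: 0 when the components coincide
#' (metric useless), approaching 1 when they are fully separated.
#'
#' @param model an `identification_model` of method `"mixture"`.
#' @param n_grid integration grid size.
#' @return value in `[0, 1]`, `NA` for non-mixture models.
#' @export
discriminatory_power <- function(model, n_grid = 1024) {
  stopifnot(inherits(model, "identification_model"))
  if (model$method != "mixture") return(NA_real_)
  lo <- min(model$mu_ident - 6 * model$sd_ident,
            model$mu_other - 6 * model$sd_other)
  hi <- max(model$mu_ident + 6 * model$sd_ident,
            model$mu_other + 6 * model$sd_other)
  xs <- seq(lo, hi, length.out = n_grid)
  f <- stats::dnorm(xs, model$mu_ident, model$sd_ident)
  g <- stats::dnorm(xs, model$mu_other, model$sd_other)
  ovl <- sum(pmin(f, g)) * (xs[2] - xs[1])
  1 - min(max(ovl, 0), 1)
}

#' Fit an identification model for one metric population
#'
#' Dispatcher used by the tracker: `"percentile"` keeps the raw population,
#' `"mixture"` and `"soft_kmeans"` fit parametric models. Populations with
#' fewer than `min_fit` values fall back to the percentile model, which is
#' stable at any size.
#'
#' @param values metric population.
#' @param method one of `"soft_kmeans"`, `"mixture"`, `"percentile"`.
#' @inheritParams fit_two_component_mixture
#' @param m fuzzifier for the soft k-means model.
#' @param min_fit minimum population size for the parametric models.
#' @return An `identification_model`.
#' @export
fit_identification_model <- function(values,
                                     method = c("soft_kmeans", "mixture",
                                                "percentile"),
                                     direction = c("distance", "similarity"),
                                     bounds = c(-Inf, Inf), m = 2,
                                     min_fit = 10) {
  method <- match.arg(method)
  direction <- match.arg(direction)
  finite <- values[is.finite(values)]
  if (length(finite) == 0L)
    return(degenerate_model(finite, direction))
  if (length(finite) > 0L && stats::sd(finite) == 0)
    return(degenerate_model(finite, direction))
  if (method != "percentile" && length(finite) < min_fit)
    method <- "percentile"
  if (method != "percentile" && !population_is_bimodal(finite))
    return(degenerate_model(finite, direction))
  if (method == "percentile") {
    return(structure(list(method = "percentile", direction = direction,
                          values = finite, n = length(finite)),
                     class = "identification_model"))
  }
  if (method == "mixture")
    fit_two_component_mixture(finite, direction, bounds)
  else
    fit_soft_kmeans(finite, direction, m)
}

#' @export
print.identification_model <- function(x, ...) {
  cat(sprintf("<identification_model: %s (%s metric, n = %d)>\n",
              x$method, x$direction, x$n))
  invisible(x)
}

# probability for the percentile model has to see the stored population
model_probability <- function(model, x) {
  if (model$method == "percentile")
    percentile_probability(model$values, x, model$direction)
  else
    posterior_probability(model, x)
}
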