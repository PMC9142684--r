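test_that("calcium kernel matches its closed form", {
  k <- calcium_kernel(6, 1, 40)
  t <- 0:39
  expect_equal(k, exp(-t / 6) - exp(-t / 1))
  expect_equal(k[1], 0)
  # peak location: argmax of g, a bit after the spike
  expect_equal(which.max(k) - 1L, 2L)
})

test_that("footprint widths land in the configured range", {
  cfg <- simulation_config(n_neurons = 12, seed = 41)
  set.seed(41)
  f <- simulate_footprints(cfg)
  for (i in 1:12) {
    img <- matrix(f$footprints[, i] > 0, cfg$fov_shape[1])
    width <- max(sum(rowSums(img) > 0), sum(colSums(img) > 0))
    expect_gte(width, 19)  # grid discretization tolerance
    expect_lte(width, 26)
    # positive mass, single connected bump with one argmax
    expect_gt(sum(f$footprints[, i]), 0)
    expect_equal(sum(f$footprints[, i] == max(f$footprints[, i])), 1L)
  }
  # determinism under seed
  set.seed(41)
  f2 <- simulate_footprints(cfg)
  expect_identical(f$footprints, f2$footprints)
  # pairwise center spacing respects the placement rule
  d <- as.matrix(stats::dist(t(f$centers)))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_spacing)
})

test_that("traces are kernel-convolved Bernoulli spikes", {
  cfg <- simulation_config(n_neurons = 40, frames_per_session = 2000,
                           seed = 42)
  set.seed(42)
  st <- simulate_traces(cfg, 2000)
  # mean spike count within 3 binomial s.d. of p*T
  expected <- 0.01 * 2000
  sd3 <- 3 * sqrt(2000 * 0.01 * 0.99) / sqrt(40)
  expect_lt(abs(mean(rowSums(st$spikes)) - expected), sd3)
  expect_true(all(st$traces >= 0))
  # single spike reproduces the kernel exactly
  one <- matrix(0, 1, 100)
  one[1, 20] <- 1
  kern <- calcium_kernel(6, 1)
  tr <- scoutr:::convolve_causal(one[1, ], kern)
  expect_equal(tr[20:79], kern[1:60])
  expect_true(all(tr[1:19] == 0))
})

test_that("background sources honor the configured count and dynamics", {
  cfg <- simulation_config(n_neurons = 5, seed = 43)
  set.seed(43)
  bg <- simulate_background(cfg, n_frames = 400)
  expect_equal(ncol(bg$footprints), 23L)
  expect_equal(nrow(bg$weights), 23L)
  # zero sources -> empty background
  cfg0 <- simulation_config(n_neurons = 5, n_background = 0, seed = 43)
  bg0 <- simulate_background(cfg0, 50)
  expect_equal(ncol(bg0$footprints), 0L)
  # random-walk temporal weights: variance of increments is stationary,
  # variance of the level grows roughly linearly
  incs <- t(apply(bg$weights, 1, diff))
  v_early <- stats::var(as.numeric(bg$weights[, 50] - bg$weights[, 1]))
  v_late <- stats::var(as.numeric(bg$weights[, 350] - bg$weights[, 1]))
  expect_gt(v_late, 3 * v_early)
  expect_equal(mean(abs(incs)), 0.016, tolerance = 0.3)
})

test_that("non-rigid warp moves centroids by less than two pixels", {
  cfg <- simulation_config(n_neurons = 6, fov_shape = c(80, 80), seed = 44)
  set.seed(44)
  f <- simulate_footprints(cfg)
  set.seed(1)
  warped <- apply_nonrigid_warp(f$footprints, cfg$fov_shape)
  for (i in 1:6) {
    c0 <- centroid(f$footprints[, i], cfg$fov_shape)
    c1 <- centroid(warped[, i], cfg$fov_shape)
    expect_lt(sqrt(sum((c1 - c0)^2)), 2)
    # mass approximately conserved
    expect_equal(sum(warped[, i]), sum(f$footprints[, i]), tolerance = 0.05)
  }
  # zero amplitude is the identity
  expect_identical(apply_nonrigid_warp(f$footprints, cfg$fov_shape,
                                       amplitude = 0), f$footprints)
  # determinism
  set.seed(1)
  expect_equal(apply_nonrigid_warp(f$footprints, cfg$fov_shape), warped)
})

test_that("ring transform folds intensities above half maximum", {
  fp <- c(0, 0.2, 0.4, 0.8, 1.0, 0.6, 0.1)
  out <- apply_ring_transform(fp)
  expect_equal(out, c(0, 0.2, 0.4, 0.2, 0.0, 0.4, 0.1))
  # sub-threshold pixels pass through untouched; folded ones land in [0, 0.5]
  expect_equal(out[fp / max(fp) <= 0.5], fp[fp / max(fp) <= 0.5])
  expect_true(all(out <= 0.5))
  expect_error(apply_ring_transform(numeric(5)), "degenerate")
})

test_that("individual shifts displace centroids by the configured range", {
  cfg <- simulation_config(n_neurons = 8, seed = 45)
  set.seed(45)
  f <- simulate_footprints(cfg)
  set.seed(2)
  res <- apply_individual_shift(f$footprints, cfg$fov_shape, c(5, 7))
  for (i in 1:8) {
    c0 <- centroid(f$footprints[, i], cfg$fov_shape)
    c1 <- centroid(res$footprints[, i], cfg$fov_shape)
    d <- sqrt(sum((c1 - c0)^2))
    expect_gte(d, 4.5)
    expect_lte(d, 7.5)
  }
  # zero range is the identity
  id <- apply_individual_shift(f$footprints, cfg$fov_shape, c(0, 0))
  expect_equal(id$footprints, f$footprints)
  # determinism
  set.seed(2)
  res2 <- apply_individual_shift(f$footprints, cfg$fov_shape, c(5, 7))
  expect_identical(res$footprints, res2$footprints)
})

test_that("dataset styles wire the right conditions", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 6,
                                       frames_per_session = 300, seed = 46))
  expect_length(ds$sessions, 2L)
  expect_equal(ds$config$n_background, 0L)
  expect_equal(ds$sessions[[1]]$fov_shape, c(100L, 100L))
  # link traces equal the boundary ground-truth trace concatenation
  n <- ds$links[[1]]$n_frames_each_side
  t_s <- 300
  expect_equal(ds$links[[1]]$extraction$traces[, 1:n],
               ds$truth$traces[[1]][, (t_s - n + 1):t_s])
  expect_equal(ds$links[[1]]$extraction$traces[, (n + 1):(2 * n)],
               ds$truth$traces[[2]][, 1:n])
  # ground-truth register is the identity over sessions
  expect_equal(ds$truth$register$table,
               matrix(rep(1:6, 2), 6, 2))
  # determinism of the whole dataset
  ds2 <- make_dataset("individual_shift",
                      simulation_config(n_neurons = 6,
                                        frames_per_session = 300, seed = 46))
  expect_identical(ds$sessions[[1]]$footprints, ds2$sessions[[1]]$footprints)
  expect_identical(ds$sessions[[2]]$traces, ds2$sessions[[2]]$traces)
})

test_that("rendered movies equal footprints times traces when noise is off", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 4, fov_shape = c(60, 60),
                                       frames_per_session = 80, seed = 47),
                     render_movies = TRUE)
  m <- ds$movies[[1]]
  expect_equal(m, ds$truth$footprints[[1]] %*% ds$truth$traces[[1]])
})

test_that("derived extractions implement the corruption contract", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 30,
                                       frames_per_session = 300, seed = 48))
  # all rates zero -> extraction equals truth up to the index permutation
  clean <- derive_extractions(ds, seed = 1)
  expect_equal(nrow(clean$register$table), 30L)
  for (s in 1:2) {
    perm <- clean$register$table[, s]
    expect_false(any(is.na(perm)))
    expect_equal(clean$sessions[[s]]$traces[perm, ],
                 ds$truth$traces[[s]])
  }
  # dropout removes about the requested fraction
  drop <- derive_extractions(ds, dropout_rate = 0.3, seed = 2)
  kept1 <- sum(!is.na(drop$register$table[, 1]))
  sd3 <- 3 * sqrt(30 * 0.3 * 0.7)
  expect_lt(abs(kept1 - 21), sd3)
  # false discoveries are injected but absent from the register
  fd <- derive_extractions(ds, false_discovery_rate = 0.2, seed = 3)
  expect_gte(n_neurons(fd$sessions[[1]]), 30L)
  expect_true(all(stats::na.omit(fd$register$table[, 1]) <=
                    n_neurons(fd$sessions[[1]])))
  expect_error(derive_extractions(ds, dropout_rate = 1.2), "rates")
})
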