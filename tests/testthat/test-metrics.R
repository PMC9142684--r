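fov <- c(10, 10)

test_that("centroid is the mass-normalized intensity-weighted coordinate", {
  # point mass
  fp <- make_footprint(fov, cbind(3, 4))
  expect_equal(centroid(fp, fov), c(3, 4))
  # symmetry of two equal pixels
  fp2 <- make_footprint(fov, cbind(c(1, 3), c(1, 1)))
  expect_equal(centroid(fp2, fov), c(2, 1))
  # brute-force oracle on a random 5x5 footprint
  set.seed(1)
  img <- matrix(stats::runif(25), 5, 5)
  expected <- c(
    sum(row(img) * img / sum(img)),
    sum(col(img) * img / sum(img)))
  expect_equal(centroid(img), expected)
  expect_error(centroid(matrix(0, 5, 5)), "degenerate")
})

test_that("centroid distance is Euclidean, symmetric, zero at identity", {
  a <- make_footprint(fov, cbind(1, 1))
  b <- make_footprint(fov, cbind(4, 5))
  expect_equal(centroid_distance(a, b, fov), 5)
  expect_equal(centroid_distance(a, a, fov), 0)
  set.seed(2)
  for (i in 1:5) {
    x <- make_footprint(fov, cbind(sample(10, 3), sample(10, 3)),
                        stats::runif(3))
    y <- make_footprint(fov, cbind(sample(10, 3), sample(10, 3)),
                        stats::runif(3))
    expect_equal(centroid_distance(x, y, fov), centroid_distance(y, x, fov))
  }
})

test_that("spatial overlap is the cosine of binarized supports", {
  a <- make_footprint(fov, cbind(c(1, 2), c(1, 1)), c(0.3, 0.9))
  expect_equal(spatial_overlap(a, a), 1)
  b <- make_footprint(fov, cbind(c(5, 6), c(5, 5)))
  expect_equal(spatial_overlap(a, b), 0)
  # supports {p1,p2} and {p2,p3} -> 1/2
  p12 <- make_footprint(fov, cbind(c(1, 2), c(1, 1)))
  p23 <- make_footprint(fov, cbind(c(2, 3), c(1, 1)))
  expect_equal(spatial_overlap(p12, p23), 0.5)
  expect_error(spatial_overlap(a, numeric(100)), "degenerate")
})

test_that("JS divergence matches direct summation and is bounded", {
  expect_equal(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  # direct-sum oracle for P=[1,0], Q=[.5,.5]:
  # M=[.75,.25]; JS = .5*(1*log2(1/.75)) + .5*(.5*log2(.5/.75)+.5*log2(.5/.25))
  expected <- 0.5 * log2(1 / 0.75) +
    0.5 * (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25))
  expect_equal(js_divergence(c(1, 0), c(0.5, 0.5)), expected,
               tolerance = 1e-12)
  expect_equal(round(expected, 4), 0.3113)
  set.seed(3)
  for (i in 1:10) {
    p <- stats::runif(8); q <- stats::runif(8)
    expect_equal(js_divergence(p, q), js_divergence(q, p))
    expect_lte(js_divergence(p, q), 1)
    expect_gte(js_divergence(p, q), 0)
  }
  expect_error(js_divergence(numeric(4), c(1, 1, 1, 1)), "degenerate")
})

test_that("SNR recovers the variance ratio of a sinusoid in white noise", {
  set.seed(4)
  t <- seq_len(5000)
  a <- 2; sigma <- 0.5
  trace <- a * sin(2 * pi * t / 200) + stats::rnorm(5000, 0, sigma)
  expect_equal(snr_of_trace(trace), (a^2 / 2) / sigma^2, tolerance = 0.2)
  # noiseless trace hits the cap
  expect_equal(snr_of_trace(sin(2 * pi * t / 500)), 1e6)
  # constant trace is degenerate
  expect_true(is.na(snr_of_trace(rep(1, 100))))
})

test_that("SNR similarity is the absolute log ratio", {
  expect_equal(snr_similarity(3, 3), 0)
  expect_equal(snr_similarity(exp(1), 1), 1)
  expect_equal(snr_similarity(2, 8), snr_similarity(8, 2))
  expect_error(snr_similarity(-1, 2), "positive")
})

test_that("decay estimation recovers the kernel fall time", {
  kern <- calcium_kernel(6, 1, 60)
  spikes <- numeric(4000)
  spikes[seq(100, 3900, by = 100)] <- 1
  trace <- stats::filter(c(numeric(59), spikes), kern, method = "convolution",
                         sides = 1)
  trace <- as.numeric(trace)[60:(59 + 4000)]
  est <- estimate_decay_rate(trace)
  expect_equal(est, 6, tolerance = 0.05)
  # amplitude scaling leaves the estimate unchanged (per-peak normalization)
  expect_equal(estimate_decay_rate(3.7 * trace), est, tolerance = 1e-6)
  # fewer than three peaks fails
  two <- numeric(400); two[c(100, 250)] <- 1
  tr2 <- as.numeric(stats::filter(c(numeric(59), two), kern,
                                  sides = 1))[60:459]
  expect_true(is.na(estimate_decay_rate(tr2)))
})

test_that("decay similarity is the absolute difference with NA passthrough", {
  expect_equal(decay_similarity(6, 6), 0)
  expect_equal(decay_similarity(6, 4), 2)
  expect_equal(decay_similarity(4, 6), decay_similarity(6, 4))
  expect_true(is.na(decay_similarity(NA, 6)))
})

test_that("link correlation finds the bridging neuron", {
  set.seed(5)
  n <- 30
  kern <- calcium_kernel(6, 1, 30)
  mk_trace <- function() {
    s <- as.numeric(stats::runif(2 * n) < 0.1)
    as.numeric(stats::filter(c(numeric(29), s), kern,
                             sides = 1))[30:(29 + 2 * n)]
  }
  tr_a <- mk_trace(); tr_b <- mk_trace()
  centers <- cbind(c(8, 12), c(8, 12))
  sa <- make_session(centers, fov = c(20, 20),
                     traces = rbind(tr_a, mk_trace()))
  sb <- make_session(centers, fov = c(20, 20),
                     traces = rbind(tr_b, mk_trace()))
  # link neuron 1 carries exactly [tail of a1, head of b1]
  link_tr <- rbind(c(tr_a[(n + 1):(2 * n)], tr_b[1:n]), mk_trace())
  link <- link_extraction(make_session(centers, fov = c(20, 20),
                                       traces = link_tr), n)
  expect_equal(link_correlation(1, 1, sa, sb, link, neighbor_radius = 10), 1)
  # no link neuron within radius of both candidates -> unavailable
  far_link <- link_extraction(make_session(centers + 6, fov = c(20, 20),
                                           traces = link_tr), n)
  expect_true(is.na(link_correlation(1, 1, sa, sb, far_link,
                                     neighbor_radius = 2)))
})

test_that("link correlation equals brute-force maximum on a random instance", {
  set.seed(6)
  n <- 40
  centers <- cbind(sample(5:15, 4), sample(5:15, 4))
  sa <- make_session(centers, fov = c(20, 20), n_frames = 2 * n)
  sb <- make_session(centers, fov = c(20, 20), n_frames = 2 * n)
  link_traces <- matrix(stats::rexp(4 * 2 * n), 4)
  link <- link_extraction(make_session(centers, fov = c(20, 20),
                                       traces = link_traces), n)
  got <- link_correlation(1, 2, sa, sb, link, neighbor_radius = 50,
                          activity_thresh_mult = 0)
  tail_a <- sa$traces[1, (2 * n - n + 1):(2 * n)]
  head_b <- sb$traces[2, 1:n]
  brute <- max(vapply(1:4, function(c_idx) {
    (stats::cor(tail_a, link_traces[c_idx, 1:n]) +
       stats::cor(link_traces[c_idx, (n + 1):(2 * n)], head_b)) / 2
  }, numeric(1)))
  expect_equal(got, brute)
})

test_that("candidate pairs respect both distance and overlap filters", {
  centers <- cbind(c(5, 5, 15), c(5, 7, 15))
  ses <- make_session(centers, fov = c(20, 20))
  cp_self <- candidate_pairs(ses, ses, max_dist = 5)
  expect_true(all(paste(1:3, 1:3) %in% paste(cp_self$i, cp_self$j)))
  # centroids 10+ px apart excluded by max_dist
  expect_false(any(cp_self$i == 1 & cp_self$j == 3))
  # overlapping footprints 2 px apart share a pixel column -> included
  expect_true(any(cp_self$i == 1 & cp_self$j == 2))
  far <- make_session(cbind(c(5, 9), c(5, 5)), fov = c(20, 20))
  cp2 <- candidate_pairs(far, far, max_dist = 5)
  # 4 px apart, 3x3 supports touch at no pixel -> excluded
  expect_false(any(cp2$i == 1 & cp2$j == 2))
})
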