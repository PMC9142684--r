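test_that("similarity matrix aggregates, thresholds, and sentinels", {
  session <- c(1, 1, 2)
  pp <- data.frame(gi = c(1L, 2L), gj = c(3L, 3L),
                   a = c(0.8, 0.5), b = c(0.8, 0.6))
  w <- c(a = 0.5, b = 0.5)
  s <- build_similarity_matrix(pp, w, min_prob = 0.6, session = session)
  # convexity: all metric probs equal -> the common value
  expect_equal(s[1, 3], 0.8)
  # below min_prob -> zero
  expect_equal(s[2, 3], 0)
  # same-session entries carry the sentinel
  expect_equal(s[1, 2], -10000)
  expect_true(isSymmetric(s))
  expect_error(build_similarity_matrix(pp, c(zz = 1), 0.5, session),
               "absent")
})

test_that("connected components match a breadth-first-search oracle", {
  # block diagonal
  session <- rep(1:2, 3)
  s <- matrix(0, 6, 6)
  s[1, 2] <- s[2, 1] <- 0.9
  s[3, 4] <- s[4, 3] <- 0.9
  comps <- connected_components(s)
  expect_equal(sort(vapply(comps, paste, collapse = ",", character(1))),
               sort(c("1,2", "3,4", "5", "6")))
  # all-zero -> all singletons
  expect_length(connected_components(matrix(0, 4, 4)), 4L)
  # random sparse matrices vs BFS
  set.seed(20)
  for (i in 1:10) {
    n <- sample(4:10, 1)
    rc <- random_component_matrix(n, 3, zero_prob = 0.7)
    comps <- connected_components(rc$s_mat)
    oracle <- bfs_components(rc$s_mat > 0 & !diag(TRUE, n))
    key <- function(x) sort(vapply(x, function(c)
      paste(sort(c), collapse = ","), character(1)))
    expect_equal(key(comps), key(oracle))
  }
})

test_that("cluster initialization respects chain_prob and session validity", {
  session <- c(1, 2)
  s <- matrix(c(-10000, 0.9, 0.9, -10000), 2, 2)
  cl <- initialize_clusters(s, 1:2, session, chain_prob = 0.75)
  expect_length(cl, 1L)
  s2 <- matrix(c(-10000, 0.5, 0.5, -10000), 2, 2)
  cl2 <- initialize_clusters(s2, 1:2, session, chain_prob = 0.75)
  expect_length(cl2, 2L)
  # larger components always yield session-valid partitions
  set.seed(21)
  for (i in 1:20) {
    rc <- random_component_matrix(6, 3)
    cl <- initialize_clusters(rc$s_mat, 1:6, rc$sessions, 0.5)
    expect_setequal(unlist(cl), 1:6)
    for (c in cl) expect_false(anyDuplicated(rc$sessions[c]) > 0)
  }
})

test_that("switch/swap attains the brute-force optimum on small components", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(3:6, 1)
    rc <- random_component_matrix(n, 3)
    best <- max(vapply(enumerate_valid_partitions(rc$sessions),
                       function(p) partition_objective_oracle(rc$s_mat, p),
                       numeric(1)))
    cl0 <- initialize_clusters(rc$s_mat, seq_len(n), rc$sessions, 0)
    cl <- switch_swap_optimize(cl0, rc$s_mat, rc$sessions, bias = 0,
                               chain_prob = 0, max_iters = 200,
                               per_neuron_move_limit = 10)
    expect_equal(partition_objective_oracle(rc$s_mat, cl), best,
                 tolerance = 1e-9)
  }
})

test_that("an already-optimal two-cluster instance is a fixed point", {
  session <- c(1, 2, 1, 2)
  s <- matrix(0, 4, 4)
  s[1, 2] <- s[2, 1] <- 0.95
  s[3, 4] <- s[4, 3] <- 0.9
  s[cbind(c(1, 3), c(3, 1))] <- -10000
  s[cbind(c(2, 4), c(4, 2))] <- -10000
  cl <- switch_swap_optimize(list(c(1L, 2L), c(3L, 4L)), s, session,
                             bias = 0, chain_prob = 0)
  key <- sort(vapply(cl, function(c) paste(sort(c), collapse = ","),
                     character(1)))
  expect_equal(key, c("1,2", "3,4"))
})

test_that("bias breaks ties toward growing the larger cluster", {
  # moving neuron 4 from {1,4} into {2,3} has zero raw gain: it is accepted
  # only because growing the larger affected cluster earns +bias; with
  # bias = 0 the move is a pure tie and is not taken
  session <- c(1, 2, 1, 3)
  s <- matrix(0, 4, 4)
  s[2, 3] <- s[3, 2] <- 0.6
  s[2, 4] <- s[4, 2] <- 0.6
  s[3, 4] <- s[4, 3] <- 0.6
  same <- outer(session, session, `==`)
  s[same] <- -10000
  diag(s) <- 0
  start <- list(c(1L, 4L), c(2L, 3L))
  with_bias <- switch_swap_optimize(start, s, session, bias = 0.05,
                                    chain_prob = 0, max_iters = 20,
                                    per_neuron_move_limit = 2)
  expect_true(any(vapply(with_bias, function(c) setequal(c, c(2, 3, 4)),
                         logical(1))))
  without_bias <- switch_swap_optimize(start, s, session, bias = 0,
                                       chain_prob = 0, max_iters = 20,
                                       per_neuron_move_limit = 2)
  expect_true(any(vapply(without_bias, function(c) setequal(c, c(1, 4)),
                         logical(1))))
})

test_that("objective is monotone over accepted moves (bias excluded)", {
  set.seed(23)
  for (i in 1:10) {
    rc <- random_component_matrix(6, 3)
    cl0 <- initialize_clusters(rc$s_mat, 1:6, rc$sessions, 0.6)
    o0 <- partition_objective_oracle(rc$s_mat, cl0)
    cl <- switch_swap_optimize(cl0, rc$s_mat, rc$sessions, bias = 0.02,
                               chain_prob = 0)
    expect_gte(partition_objective_oracle(rc$s_mat, cl), o0 - 1e-9)
  }
})

test_that("raising chain_prob never enlarges the biggest cluster", {
  set.seed(24)
  for (i in 1:10) {
    rc <- random_component_matrix(6, 3, zero_prob = 0.2)
    sizes <- vapply(c(0.3, 0.6, 0.9), function(cp) {
      cl0 <- initialize_clusters(rc$s_mat, 1:6, rc$sessions, cp)
      cl <- switch_swap_optimize(cl0, rc$s_mat, rc$sessions, bias = 0.02,
                                 chain_prob = cp)
      max(lengths(cl))
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("weight perturbation keeps the base vector and the simplex", {
  w <- c(a = 0.25, b = 0.25, c = 0.25, d = 0.25)
  out <- perturb_weights(w, n_samples = 30, sd = 0.12, seed = 9)
  expect_length(out, 30L)
  expect_equal(out[[1]], w)
  for (v in out) {
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-9)
  }
  # sd = 0 reproduces the base everywhere
  same <- perturb_weights(w, 5, sd = 0, seed = 1)
  for (v in same) expect_equal(v, w)
  # reproducible under seed
  expect_equal(perturb_weights(w, 10, 0.12, 4), perturb_weights(w, 10, 0.12, 4))
})

test_that("consensus matrix counts co-clustering fractions", {
  m1 <- c(1, 1, 2, 2)
  m2 <- c(1, 2, 2, 2)
  cons <- build_consensus_matrix(list(m1, m2))
  expect_equal(diag(cons), rep(1, 4))
  expect_equal(cons[1, 2], 0.5)
  expect_equal(cons[3, 4], 1)
  expect_equal(cons[1, 3], 0)
  expect_true(isSymmetric(cons))
  ident <- build_consensus_matrix(list(m1, m1))
  expect_true(all(ident %in% c(0, 1)))
  expect_error(build_consensus_matrix(list()), "no clusterings")
})

test_that("tracking a noiseless unmoved dataset recovers ground truth", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 15,
                                       frames_per_session = 1500,
                                       shift_range = c(0, 0), seed = 31))
  cfg <- tracker_config(
    weights = stats::setNames(rep(1 / 5, 5),
                              c("link_corr", "centroid_dist", "overlap",
                                "js_div", "decay")),
    method = "mixture", min_prob = 0.65, chain_prob = 0.65, seed = 1)
  reg <- track(ds$sessions, ds$links, cfg)
  sc <- score_register(reg, ds$truth$register)
  expect_equal(sc$PDR, 1)
  expect_equal(sc$FDR, 0)
  expect_equal(sc$F1, 1)
  # register invariants: no duplicated neuron within a session column
  for (j in 1:2) {
    col <- reg$table[, j]
    expect_false(anyDuplicated(col[!is.na(col)]) > 0)
  }
  expect_true(all(rowSums(!is.na(reg$table)) <= 2))
})

test_that("tracking is deterministic under a fixed seed", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 10,
                                       frames_per_session = 800, seed = 32))
  cfg <- tracker_config(seed = 5)
  r1 <- track(ds$sessions, ds$links, cfg)
  r2 <- track(ds$sessions, ds$links, cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$score, r2$score)
})

test_that("a deleted neuron leaves a missing entry in its register row", {
  ds <- make_dataset("individual_shift",
                     simulation_config(n_neurons = 12,
                                       frames_per_session = 1200,
                                       shift_range = c(0, 0), seed = 33))
  sessions <- ds$sessions
  # delete neuron 1 from session 2
  s2 <- sessions[[2]]
  keep <- 2:n_neurons(s2)
  sessions[[2]] <- session_extraction(s2$footprints[, keep, drop = FALSE],
                                      s2$traces[keep, , drop = FALSE],
                                      s2$fov_shape)
  link <- ds$links[[1]]
  cfg <- tracker_config(
    weights = stats::setNames(rep(1 / 5, 5),
                              c("link_corr", "centroid_dist", "overlap",
                                "js_div", "decay")),
    method = "mixture", min_prob = 0.65, chain_prob = 0.65, seed = 1)
  reg <- track(sessions, list(link), cfg)
  row1 <- which(reg$table[, 1] == 1L)
  expect_length(row1, 1L)
  expect_true(is.na(reg$table[row1, 2]))
})

test_that("tracking without candidate pairs warns and returns empty", {
  s1 <- make_session(cbind(3, 3), fov = c(40, 40), n_frames = 50)
  s2 <- make_session(cbind(35, 35), fov = c(40, 40), n_frames = 50)
  expect_warning(reg <- track(list(s1, s2), NULL, tracker_config(seed = 1)),
                 "no candidate pairs")
  expect_equal(nrow(reg$table), 0L)
})
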