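#' Tracker configuration
#'
#' Parameters for multi-session tracking. Defaults follow the standard
#' operating point: `min_prob = chain_prob = 0.75`, `max_dist = 20` px,
#' equal metric weights, 30 weight vectors (base + 29 perturbations drawn
#' with s.d. 0.12, clipped at zero and renormalized).
#'
#' @param max_dist maximal centroid distance (px) for candidate pairs.
#' @param min_prob aggregated identification probabilities below this are
#'   zeroed in the similarity matrix.
#' @param chain_prob minimal mean pairwise within-cluster similarity for a
#'   cluster to be accepted without splitting.
#' @param weights named numeric vector over metrics (any subset of
#'   `link_corr`, `centroid_dist`, `overlap`, `js_div`, `snr`, `decay`),
#'   nonnegative; normalized to sum to 1. `NULL` means equal weights over
#'   all metrics available for the input.
#' @param n_weight_samples number of weight vectors used for consensus
#'   (including the unperturbed base vector).
#' @param perturbation_sd s.d. of the additive Gaussian weight perturbation.
#' @param bias constant bias (probability scale) favoring moves that grow
#'   larger clusters during switch/swap optimization.
#' @param max_iters cap on accepted switch/swap moves per clustering run (a
#'   safety valve; the per-neuron move limit already bounds the search).
#' @param per_neuron_move_limit times any single neuron may be moved.
#' @param method identification model: `"soft_kmeans"`, `"mixture"`, or
#'   `"percentile"`.
#' @param fuzzifier soft k-means fuzzifier (> 1).
#' @param use_spikes unused placeholder for pipelines carrying deconvolved
#'   traces; metrics always use the provided traces.
#' @param seed integer seed controlling the weight perturbations.
#' @return list of class `tracker_config`.
#' @export
tracker_config <- function(max_dist = 20, min_prob = 0.75, chain_prob = 0.75,
                           weights = NULL, n_weight_samples = 30,
                           perturbation_sd = 0.12, bias = 0.02,
                           max_iters = 1000, per_neuron_move_limit = 5,
                           method = c("soft_kmeans", "mixture", "percentile"),
                           fuzzifier = 2, use_spikes = FALSE, seed = 1) {
  method <- match.arg(method)
  stopifnot(min_prob >= 0, min_prob <= 1, chain_prob >= 0, chain_prob <= 1,
            n_weight_samples >= 1, bias >= 0, perturbation_sd >= 0)
  if (!is.null(weights)) {
    if (is.null(names(weights)) ||
        !all(names(weights) %in% c("link_corr", "centroid_dist", "overlap",
                                   "js_div", "snr", "decay")))
      stop("weights must be named with known metric names")
    if (any(weights < 0)) stop("weights must be nonnegative")
    if (sum(weights) <= 0) stop("weights must not all be zero")
    weights <- weights / sum(weights)
  }
  structure(list(max_dist = max_dist, min_prob = min_prob,
                 chain_prob = chain_prob, weights = weights,
                 n_weight_samples = as.integer(n_weight_samples),
                 perturbation_sd = perturbation_sd, bias = bias,
                 max_iters = as.integer(max_iters),
                 per_neuron_move_limit = as.integer(per_neuron_move_limit),
                 method = method, fuzzifier = fuzzifier,
                 use_spikes = use_spikes, seed = as.integer(seed)),
            class = "tracker_config")
}

metric_direction <- function(metric) {
  switch(metric,
         link_corr = "similarity", centroid_dist = "distance",
         overlap = "similarity", js_div = "distance",
         snr = "distance", decay = "distance",
         stop("unknown metric: ", metric))
}

metric_bounds <- function(metric, max_dist) {
  switch(metric,
         link_corr = c(-1, 1), centroid_dist = c(0, max_dist),
         overlap = c(0, 1), js_div = c(0, 1),
         snr = c(0, Inf), decay = c(0, Inf))
}

SAME_SESSION_SENTINEL <- -10000

#' Aggregate per-metric probabilities into a similarity matrix
#'
#' Cross-session entries are the weighted sum of the per-metric
#' identification probabilities for candidate pairs; entries below
#' `min_prob` are zeroed; non-candidate pairs are 0; pairs of neurons from
#' the same session get the sentinel value -10000, which keeps them out of
#' any common cluster.
#'
#' @param pair_probs data.frame with global indices `gi`, `gj` and one
#'   probability column per metric.
#' @param weights named weight vector over those metric columns (sums
#'   to 1).
#' @param min_prob threshold below which aggregates are zeroed.
#' @param session vector of session ids, one per global neuron index.
#' @return symmetric `n_cells x n_cells` matrix.
#' @export
build_similarity_matrix <- function(pair_probs, weights, min_prob, session) {
  n <- length(session)
  metrics <- names(weights)
  if (!all(metrics %in% names(pair_probs)))
    stop("weights name metrics absent from pair_probs")
  s_mat <- matrix(0, n, n)
  same <- outer(session, session, `==`)
  s_mat[same] <- SAME_SESSION_SENTINEL
  if (nrow(pair_probs) > 0L) {
    agg <- as.matrix(pair_probs[, metrics, drop = FALSE]) %*% weights
    agg <- as.numeric(agg)
    agg[agg < min_prob] <- 0
    idx <- cbind(pair_probs$gi, pair_probs$gj)
    s_mat[idx] <- agg
    s_mat[idx[, 2:1, drop = FALSE]] <- agg
  }
  s_mat
}

#' Connected components of a similarity matrix
#'
#' Components of the graph whose edges are the strictly positive
#' cross-session similarities. Each component is clustered separately.
#'
#' @param s_mat similarity matrix from [build_similarity_matrix()].
#' @return list of integer vectors (node indices), in order of first node.
#' @export
connected_components <- function(s_mat) {
  n <- nrow(s_mat)
  adj <- s_mat > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  unname(split(seq_len(n), comp$membership))
}

cluster_mean <- function(s_mat, members) {
  k <- length(members)
  if (k < 2L) return(NA_real_)
  sub <- s_mat[members, members]
  sum(sub[upper.tri(sub)]) / (k * (k - 1) / 2)
}

# objective contribution: singletons contribute 0
cluster_objective <- function(s_mat, members) {
  m <- cluster_mean(s_mat, members)
  if (is.na(m)) 0 else m
}

partition_objective <- function(s_mat, clusters) {
  sum(vapply(clusters, function(cl) cluster_objective(s_mat, cl), numeric(1)))
}

# chain_prob convention: a singleton cannot violate the threshold
cluster_chain_value <- function(s_mat, members) {
  m <- cluster_mean(s_mat, members)
  if (is.na(m)) 1 else m
}

#' Initialize clusters within a component
#'
#' Seeds two clusters with the least-similar pair of neurons, then adds the
#' remaining neurons one at a time to the cluster whose average pairwise
#' similarity decreases the least (a yet-unpaired cluster counts as average
#' 1). If no session-valid placement keeps the resulting average at or
#' above `chain_prob`, a new cluster is opened.
#'
#' @param s_mat full similarity matrix.
#' @param nodes node indices of the component.
#' @param session session id per node (full-length vector).
#' @param chain_prob acceptance threshold.
#' @return list of integer vectors partitioning `nodes`.
#' @export
initialize_clusters <- function(s_mat, nodes, session, chain_prob) {
  n <- length(nodes)
  if (n == 1L) return(list(nodes))
  sub <- s_mat[nodes, nodes]
  pairs <- which(upper.tri(sub), arr.ind = TRUE)
  worst <- pairs[which.min(sub[pairs]), ]
  if (sub[worst[1], worst[2]] >= chain_prob &&
      session[nodes[worst[1]]] != session[nodes[worst[2]]]) {
    # even the least similar pair belongs together: seed a single cluster
    clusters <- list(nodes[worst])
  } else {
    clusters <- list(nodes[worst[1]], nodes[worst[2]])
  }
  remaining <- setdiff(seq_len(n), worst)
  for (li in remaining) {
    u <- nodes[li]
    best_c <- 0L; best_dec <- Inf; best_avg <- -Inf
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (session[u] %in% session[cl]) next
      old_avg <- cluster_chain_value(s_mat, cl)
      new_avg <- cluster_mean(s_mat, c(cl, u))
      if (new_avg < chain_prob) next
      dec <- old_avg - new_avg
      if (dec < best_dec - 1e-12) {
        best_dec <- dec; best_c <- ci; best_avg <- new_avg
      }
    }
    if (best_c > 0L) {
      clusters[[best_c]] <- c(clusters[[best_c]], u)
    } else {
      clusters[[length(clusters) + 1L]] <- u
    }
  }
  clusters
}

#' Refine a partition by switch and swap moves
#'
#' Greedy local search on the clustering objective (sum over clusters of
#' mean pairwise similarity; singletons contribute zero). At each step all
#' session-valid switches (move one neuron to another or a new cluster) and
#' swaps (exchange two neurons between clusters) are scored by their
#' objective gain plus a bias: switches that raise the maximal size of the
#' affected clusters earn `+bias` (and `-bias` for the reverse); swaps earn
#' `+bias` when the larger affected cluster's mean similarity rises and
#' `-bias` when it falls. The best-scoring admissible move is applied;
#' moves are admissible only when their raw gain is non-negative (so the
#' objective never decreases) and, unless strictly improving, must not
#' shrink a multi-member cluster whose mean similarity already exceeds
#' `chain_prob`. Each neuron may move at most `per_neuron_move_limit`
#' times. When no move remains, any multi-member cluster below `chain_prob`
#' is split by exiling the least-similar member of the lowest-scoring
#' cluster, and the search resumes, until all clusters pass.
#'
#' @param clusters starting partition (list of node-index vectors).
#' @inheritParams initialize_clusters
#' @param bias bias magnitude (probability scale).
#' @param max_iters cap on accepted moves.
#' @param per_neuron_move_limit per-neuron move cap.
#' @return refined partition.
#' @export
switch_swap_optimize <- function(clusters, s_mat, session, bias = 0,
                                 chain_prob = 0, max_iters = 1000,
                                 per_neuron_move_limit = 5) {
  tol <- 1e-9
  best <- switch_swap_phase(clusters, s_mat, session, bias, chain_prob,
                            max_iters, per_neuron_move_limit)
  # refinement: single switches and swaps can strand the search in
  # configurations only escapable by two coordinated reassignments (e.g.
  # one neuron vacating a slot another must take). When the component is
  # small enough for the quadratic enumeration to be cheap, search the
  # joint two-switch neighborhood and resume the single-move phase after
  # any improvement.
  rounds <- 0L
  repeat {
    n_nodes <- length(unlist(best))
    if (n_nodes > 8L || rounds >= 20L) break
    trial <- best_joint_switch(best, s_mat, session, tol, k = 2L)
    if (is.null(trial) && n_nodes <= 6L)
      trial <- best_joint_switch(best, s_mat, session, tol, k = 3L)
    if (is.null(trial)) break
    best <- switch_swap_phase(trial, s_mat, session, bias, chain_prob,
                              max_iters, per_neuron_move_limit)
    rounds <- rounds + 1L
  }
  best
}

# one improving joint reassignment of k neurons, or NULL
best_joint_switch <- function(clusters, s_mat, session, tol, k = 2L) {
  base_obj <- partition_objective(s_mat, clusters)
  nc <- length(clusters)
  node_cl <- integer(0)
  for (ci in seq_len(nc)) node_cl[as.character(clusters[[ci]])] <- ci
  nodes <- as.integer(names(node_cl))
  if (length(nodes) < k) return(NULL)
  best_obj <- base_obj + tol
  best_cfg <- NULL
  tuples <- utils::combn(nodes, k)
  targets <- as.matrix(expand.grid(rep(list(0:nc), k)))
  for (ti in seq_len(ncol(tuples))) {
    tup <- tuples[, ti]
    homes <- node_cl[as.character(tup)]
    for (ri in seq_len(nrow(targets))) {
      tgt <- targets[ri, ]
      if (all(tgt == 0L)) next  # all exiled: reachable by single switches
      if (any(tgt == homes)) next
      cl2 <- clusters
      for (z in seq_len(k))
        cl2[[homes[z]]] <- setdiff(cl2[[homes[z]]], tup[z])
      for (z in seq_len(k)) {
        if (tgt[z] > 0L) cl2[[tgt[z]]] <- c(cl2[[tgt[z]]], tup[z])
        else cl2[[length(cl2) + 1L]] <- tup[z]
      }
      cl2 <- prune_empty(cl2)
      if (any(vapply(cl2, function(cl)
        anyDuplicated(session[cl]) > 0L, logical(1)))) next
      o <- partition_objective(s_mat, cl2)
      if (o > best_obj + tol) {
        best_obj <- o
        best_cfg <- cl2
      }
    }
  }
  best_cfg
}

switch_swap_phase <- function(clusters, s_mat, session, bias, chain_prob,
                              max_iters, per_neuron_move_limit) {
  tol <- 1e-9
  move_count <- integer(nrow(s_mat))
  iters <- 0L
  repeat {
    repeat {
      if (iters >= max_iters) {
        warning("switch/swap did not converge within max_iters; ",
                "returning best partition so far")
        return(prune_empty(clusters))
      }
      mv <- best_move(clusters, s_mat, session, bias, chain_prob,
                      move_count, per_neuron_move_limit, tol)
      if (is.null(mv)) break
      clusters <- apply_move(clusters, mv)
      move_count[mv$moved] <- move_count[mv$moved] + 1L
      iters <- iters + 1L
    }
    clusters <- prune_empty(clusters)
    # split phase: break up the lowest-scoring failing cluster
    means <- vapply(clusters, function(cl) cluster_chain_value(s_mat, cl),
                    numeric(1))
    failing <- which(means < chain_prob - tol &
                       lengths(clusters) >= 2L)
    if (length(failing) == 0L) break
    worst_ci <- failing[which.min(means[failing])]
    cl <- clusters[[worst_ci]]
    avg_to_rest <- vapply(seq_along(cl), function(ii)
      mean(s_mat[cl[ii], cl[-ii]]), numeric(1))
    exile <- which.min(avg_to_rest)
    clusters[[worst_ci]] <- cl[-exile]
    clusters[[length(clusters) + 1L]] <- cl[exile]
    if (iters >= max_iters) break
  }
  prune_empty(clusters)
}

prune_empty <- function(clusters) clusters[lengths(clusters) > 0L]

# Best admissible move, computed with incremental pair-sum algebra so each
# call costs a few matrix operations rather than per-move recomputation.
best_move <- function(clusters, s_mat, session, bias, chain_prob,
                      move_count, move_limit, tol) {
  nc <- length(clusters)
  loc <- unlist(clusters)
  m <- length(loc)
  if (m < 2L) return(NULL)
  cl_of <- rep.int(seq_len(nc), lengths(clusters))
  s_loc <- s_mat[loc, loc, drop = FALSE]
  ses <- session[loc]
  movable <- move_count[loc] < move_limit
  a_ind <- matrix(0, m, nc)
  a_ind[cbind(seq_len(m), cl_of)] <- 1
  rs <- s_loc %*% a_ind                      # rs[i, c] = sum of S[i, c]
  pairsum <- colSums(rs * a_ind) / 2
  size <- lengths(clusters)
  npairs <- size * (size - 1) / 2
  mean_c <- ifelse(npairs > 0, pairsum / npairs, 0)
  # session presence per cluster
  pres <- matrix(FALSE, nc, max(session))
  pres[cbind(cl_of, ses)] <- TRUE
  protected <- size >= 2L & mean_c > chain_prob + tol

  # source-removal objective change per node
  k_a <- size[cl_of]
  rem_pairsum <- pairsum[cl_of] - rs[cbind(seq_len(m), cl_of)]
  rem_npairs <- (k_a - 1) * (k_a - 2) / 2
  rem_mean <- ifelse(rem_npairs > 0, rem_pairsum / rem_npairs, 0)
  d_source <- rem_mean - mean_c[cl_of]

  ## switches to existing clusters: gain[i, c]
  k_b <- matrix(size, m, nc, byrow = TRUE)
  add_mean <- sweep(rs, 2, pairsum, "+") / ((k_b + 1) * k_b / 2)
  add_mean[k_b < 2L] <- 0  # joining a singleton: pair mean is S[i, member]
  one_mem <- which(size == 1L)
  for (c in one_mem) add_mean[, c] <- rs[, c]
  d_target <- sweep(add_mean, 2, mean_c, "-")
  gain_sw <- d_source + d_target
  # invalid: own cluster, session conflict, frozen node
  conflict <- t(pres)[ses, , drop = FALSE]  # conflict[i, c]
  gain_sw[conflict] <- -Inf
  gain_sw[cbind(seq_len(m), cl_of)] <- -Inf
  gain_sw[!movable, ] <- -Inf
  # protected sources allow only strictly improving departures
  prot_src <- protected[cl_of]
  if (any(prot_src)) {
    sub <- gain_sw[prot_src, , drop = FALSE]
    sub[sub <= tol] <- -Inf
    gain_sw[prot_src, ] <- sub
  }
  size_before <- pmax(k_a, k_b)
  size_after <- pmax(k_a - 1, k_b + 1)
  adj_sw <- bias * sign(size_after - size_before)
  score_sw <- gain_sw + adj_sw
  score_sw[gain_sw < -tol] <- -Inf

  # switch to a brand-new cluster (only meaningful from multi-member ones)
  gain_new <- ifelse(k_a >= 2L & movable, d_source, -Inf)
  gain_new[prot_src & gain_new <= tol] <- -Inf
  adj_new <- bias * sign(pmax(k_a - 1, 1) - k_a)
  score_new <- gain_new + adj_new
  score_new[gain_new < -tol] <- -Inf

  best <- NULL
  best_score <- tol
  if (any(is.finite(score_sw))) {
    idx <- which.max(score_sw)
    if (score_sw[idx] > best_score) {
      i <- (idx - 1L) %% m + 1L
      c <- (idx - 1L) %/% m + 1L
      best <- list(type = "switch", from = cl_of[i], to = c,
                   node = loc[i], moved = loc[i])
      best_score <- score_sw[idx]
    }
  }
  if (any(is.finite(score_new))) {
    i <- which.max(score_new)
    if (score_new[i] > best_score + 1e-15) {
      best <- list(type = "switch", from = cl_of[i], to = 0L,
                   node = loc[i], moved = loc[i])
      best_score <- score_new[i]
    }
  }

  ## swaps: gain[i, j] for nodes in different clusters
  if (nc >= 2L) {
    same_cl <- outer(cl_of, cl_of, `==`)
    rs_a_j <- rs[, cl_of, drop = FALSE]  # rs[j -> cluster of column node]
    # new pair sums when j replaces i in i's cluster
    new_ps_a <- matrix(pairsum[cl_of], m, m) -
      matrix(rs[cbind(seq_len(m), cl_of)], m, m) +
      t(rs_a_j) - t(s_loc)
    # ^ entry (i, j): pairsum[a_i] - rs[i, a_i] + rs[j, a_i] - S[j, i]
    np_a <- matrix(npairs[cl_of], m, m)
    new_mean_a <- ifelse(np_a > 0, new_ps_a / np_a, 0)
    d_a <- new_mean_a - matrix(mean_c[cl_of], m, m)
    gain_swap <- d_a + t(d_a)
    # session validity: i joins cluster(j) \ {j}, j joins cluster(i) \ {i}
    ses_eq <- outer(ses, ses, `==`)
    conf_i_in_b <- matrix(pres[cbind(rep(cl_of, each = m),
                                     rep(ses, times = m))], m, m)
    # conf_i_in_b[i, j]: session of i already present in cluster of j
    invalid <- (conf_i_in_b & !ses_eq) | t(conf_i_in_b & !ses_eq)
    gain_swap[invalid | same_cl] <- -Inf
    gain_swap[!movable, ] <- -Inf
    gain_swap[, !movable] <- -Inf
    # bias: sign of the larger cluster's mean-change
    sz_i <- matrix(size[cl_of], m, m)
    i_larger <- sz_i >= t(sz_i)
    d_larger <- ifelse(i_larger, d_a, t(d_a))
    adj_swap <- bias * ifelse(d_larger > tol, 1,
                              ifelse(d_larger < -tol, -1, 0))
    score_swap <- gain_swap + adj_swap
    score_swap[gain_swap < -tol] <- -Inf
    if (any(is.finite(score_swap))) {
      idx <- which.max(score_swap)
      if (score_swap[idx] > best_score + 1e-15) {
        i <- (idx - 1L) %% m + 1L
        j <- (idx - 1L) %/% m + 1L
        best <- list(type = "swap", a = cl_of[i], b = cl_of[j],
                     u = loc[i], v = loc[j], moved = c(loc[i], loc[j]))
        best_score <- score_swap[idx]
      }
    }
  }
  best
}

apply_move <- function(clusters, mv) {
  if (mv$type == "switch") {
    clusters[[mv$from]] <- setdiff(clusters[[mv$from]], mv$node)
    if (mv$to == 0L) {
      clusters[[length(clusters) + 1L]] <- mv$node
    } else {
      clusters[[mv$to]] <- c(clusters[[mv$to]], mv$node)
    }
  } else {
    clusters[[mv$a]] <- c(setdiff(clusters[[mv$a]], mv$u), mv$v)
    clusters[[mv$b]] <- c(setdiff(clusters[[mv$b]], mv$v), mv$u)
  }
  prune_empty(clusters)
}

#' Perturb a metric weight vector
#'
#' Returns `n_samples` weight vectors: the base vector followed by
#' `n_samples - 1` perturbations, each obtained by adding independent
#' `N(0, sd)` noise per entry, clipping negatives to zero and
#' renormalizing (resampling in the rare all-zero case).
#'
#' @param weights named base weight vector (sums to 1).
#' @param n_samples total number of vectors, including the base.
#' @param sd perturbation standard deviation.
#' @param seed integer seed.
#' @return list of weight vectors; element 1 is `weights` unchanged.
#' @export
perturb_weights <- function(weights, n_samples = 30, sd = 0.12, seed = 1) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  out <- vector("list", n_samples)
  out[[1]] <- weights
  for (i in seq_len(n_samples - 1L)) {
    for (try in seq_len(100)) {
      w <- weights + stats::rnorm(length(weights), 0, sd)
      w[w < 0] <- 0
      if (sum(w) > 0) break
      if (try == 100) stop("weight perturbation degenerated to all zeros")
    }
    out[[i + 1L]] <- w / sum(w)
  }
  out
}

#' Consensus matrix over clusterings
#'
#' Entry (i, j) is the fraction of clusterings in which nodes i and j share
#' a cluster; the diagonal is 1.
#'
#' @param memberships list of integer membership vectors over the same
#'   nodes.
#' @return symmetric matrix with unit diagonal.
#' @export
build_consensus_matrix <- function(memberships) {
  if (length(memberships) == 0L) stop("no clusterings supplied")
  n <- length(memberships[[1]])
  acc <- matrix(0, n, n)
  for (mem in memberships) {
    if (length(mem) != n) stop("clusterings cover different node sets")
    acc <- acc + outer(mem, mem, `==`)
  }
  acc / length(memberships)
}

clusters_to_membership <- function(clusters, nodes) {
  mem <- integer(length(nodes))
  names(mem) <- as.character(nodes)
  for (ci in seq_along(clusters))
    mem[as.character(clusters[[ci]])] <- ci
  unname(mem)
}

#' Track neurons across sessions
#'
#' Runs the full pipeline: candidate-pair selection and similarity metrics
#' for every session pair; per-metric identification models over each
#' pair population; aggregation into similarity matrices under the base
#' and perturbed weight vectors; per-component switch/swap clustering of
#' every matrix (components fixed by the base weights); consensus over the
#' clusterings; a final clustering of each consensus matrix; and assembly
#' of the cell register.
#'
#' @param sessions list of >= 2 `session_extraction`s on a common FOV.
#' @param links optional list of `link_extraction`s, one per consecutive
#'   session pair (element `s` spans sessions `s` and `s + 1`). When
#'   `NULL` the link-correlation metric is dropped and the remaining
#'   weights renormalized.
#' @param config a `tracker_config`.
#' @return a `cell_register`; attribute `"report"` carries fitted-model
#'   summaries and per-component diagnostics.
#' @export
track <- function(sessions, links = NULL, config = tracker_config()) {
  stopifnot(length(sessions) >= 2L)
  lapply(sessions, function(s) stopifnot(inherits(s, "session_extraction")))
  if (!is.null(links) && length(links) != length(sessions) - 1L)
    stop("links must cover every consecutive session pair")
  ns <- length(sessions)
  k_s <- vapply(sessions, n_neurons, integer(1))
  offsets <- cumsum(c(0L, k_s[-ns]))
  n_cells <- sum(k_s)
  session_of <- rep(seq_len(ns), k_s)

  metrics <- c("link_corr", "centroid_dist", "overlap", "js_div", "snr",
               "decay")
  if (is.null(links)) metrics <- setdiff(metrics, "link_corr")
  weights <- config$weights
  if (is.null(weights)) {
    weights <- stats::setNames(rep(1 / length(metrics), length(metrics)),
                               metrics)
  } else {
    weights <- weights[names(weights) %in% metrics]
    if (sum(weights) <= 0) stop("no usable metric has positive weight")
    weights <- weights / sum(weights)
  }
  metrics <- names(weights)

  # per-neuron temporal features, cached per session
  need_snr <- "snr" %in% metrics
  need_decay <- "decay" %in% metrics
  snr_log <- decay <- vector("list", ns)
  for (s in seq_len(ns)) {
    if (need_snr)
      snr_log[[s]] <- vapply(seq_len(k_s[s]), function(i) {
        v <- snr_of_trace(sessions[[s]]$traces[i, ])
        if (is.na(v)) NA_real_ else log(v)
      }, numeric(1))
    if (need_decay)
      decay[[s]] <- vapply(seq_len(k_s[s]), function(i)
        estimate_decay_rate(sessions[[s]]$traces[i, ]), numeric(1))
  }

  # metric values and per-session-pair model fits
  pair_tabs <- list()
  model_report <- list()
  for (s in seq_len(ns - 1L)) {
    for (t in (s + 1L):ns) {
      cp <- candidate_pairs(sessions[[s]], sessions[[t]], config$max_dist)
      if (nrow(cp) == 0L) next
      vals <- data.frame(gi = offsets[s] + cp$i, gj = offsets[t] + cp$j)
      raw <- list(centroid_dist = cp$dist, overlap = cp$overlap)
      if ("js_div" %in% metrics)
        raw$js_div <- vapply(seq_len(nrow(cp)), function(r)
          js_divergence_footprints(sessions[[s]]$footprints[, cp$i[r]],
                                   sessions[[t]]$footprints[, cp$j[r]]),
          numeric(1))
      if (need_snr)
        raw$snr <- abs(snr_log[[s]][cp$i] - snr_log[[t]][cp$j])
      if (need_decay)
        raw$decay <- vapply(seq_len(nrow(cp)), function(r)
          decay_similarity(decay[[s]][cp$i[r]], decay[[t]][cp$j[r]]),
          numeric(1))
      if ("link_corr" %in% metrics) {
        raw$link_corr <- if (t == s + 1L && !is.null(links[[s]])) {
          vapply(seq_len(nrow(cp)), function(r)
            link_correlation(cp$i[r], cp$j[r], sessions[[s]], sessions[[t]],
                             links[[s]], neighbor_radius = config$max_dist),
            numeric(1))
        } else rep(NA_real_, nrow(cp))
      }
      for (m in metrics) {
        v <- raw[[m]]
        if (is.null(v)) v <- rep(NA_real_, nrow(cp))
        model <- fit_identification_model(
          v, method = config$method, direction = metric_direction(m),
          bounds = metric_bounds(m, config$max_dist), m = config$fuzzifier)
        p <- rep(0.5, nrow(cp))
        ok <- is.finite(v)
        if (any(ok)) p[ok] <- model_probability(model, v[ok])
        vals[[m]] <- p
        model_report[[paste0("s", s, "_s", t, "_", m)]] <-
          list(method = model$method,
               discriminatory_power = discriminatory_power(model))
      }
      pair_tabs[[length(pair_tabs) + 1L]] <- vals
    }
  }

  empty_report <- list(weights = weights, models = model_report,
                       n_components = 0L)
  if (length(pair_tabs) == 0L) {
    warning("no candidate pairs found; returning an empty register")
    reg <- cell_register(matrix(integer(0), 0, ns), numeric(0))
    attr(reg, "report") <- empty_report
    return(reg)
  }
  pair_probs <- do.call(rbind, pair_tabs)

  base_mat <- build_similarity_matrix(pair_probs, weights, config$min_prob,
                                      session_of)
  comps <- connected_components(base_mat)
  weight_list <- perturb_weights(weights, config$n_weight_samples,
                                 config$perturbation_sd, config$seed)
  sim_mats <- lapply(weight_list, function(w)
    build_similarity_matrix(pair_probs, w, config$min_prob, session_of))

  final_clusters <- list()
  comp_report <- list()
  for (comp in comps) {
    if (length(comp) == 1L) {
      final_clusters[[length(final_clusters) + 1L]] <- comp
      next
    }
    memberships <- lapply(sim_mats, function(sm) {
      cl0 <- initialize_clusters(sm, comp, session_of, config$chain_prob)
      cl <- switch_swap_optimize(cl0, sm, session_of, config$bias,
                                 config$chain_prob, config$max_iters,
                                 config$per_neuron_move_limit)
      clusters_to_membership(cl, comp)
    })
    cons <- build_consensus_matrix(memberships)
    # embed the component consensus into full-matrix coordinates so the
    # same clustering machinery applies
    cm <- matrix(0, nrow(base_mat), nrow(base_mat))
    cm[comp, comp] <- cons
    same <- outer(session_of, session_of, `==`)
    cm[same] <- SAME_SESSION_SENTINEL
    cl0 <- initialize_clusters(cm, comp, session_of, config$chain_prob)
    cl <- switch_swap_optimize(cl0, cm, session_of, config$bias,
                               config$chain_prob, config$max_iters,
                               config$per_neuron_move_limit)
    final_clusters <- c(final_clusters, cl)
    comp_report[[length(comp_report) + 1L]] <-
      list(size = length(comp), n_clusters = length(cl))
  }

  # assemble register
  n_rows <- length(final_clusters)
  tab <- matrix(NA_integer_, n_rows, ns)
  score <- numeric(n_rows)
  for (r in seq_len(n_rows)) {
    cl <- final_clusters[[r]]
    for (u in cl) {
      s <- session_of[u]
      tab[r, s] <- u - offsets[s]
    }
    m <- cluster_mean(base_mat, cl)
    score[r] <- if (is.na(m)) 1 else min(max(m, 0), 1)
  }
  ord <- order(apply(tab, 1, function(row) {
    first <- which(!is.na(row))[1]
    first * (n_cells + 1L) + row[first]
  }))
  reg <- cell_register(tab[ord, , drop = FALSE], score[ord])
  attr(reg, "report") <- list(weights = weights, models = model_report,
                              n_components = length(comps),
                              components = comp_report)
  reg
}
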