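# Small deterministic fixtures used across the suite.

# footprint with given positive pixels on an H x W grid, flattened
make_footprint <- function(fov, coords, values = 1) {
  img <- matrix(0, fov[1], fov[2])
  img[coords] <- values
  as.numeric(img)
}

# tiny session: footprints at given centers (3x3 blobs), random-ish traces
make_session <- function(centers, fov = c(20, 20), n_frames = 60,
                         traces = NULL, session_id = NULL) {
  k <- nrow(centers)
  fps <- vapply(seq_len(k), function(i) {
    img <- matrix(0, fov[1], fov[2])
    r <- centers[i, 1]; c <- centers[i, 2]
    rr <- max(1, r - 1):min(fov[1], r + 1)
    cc <- max(1, c - 1):min(fov[2], c + 1)
    img[rr, cc] <- 0.5
    img[r, c] <- 1
    as.numeric(img)
  }, numeric(prod(fov)))
  if (is.null(traces))
    traces <- matrix(stats::rexp(k * n_frames), k, n_frames)
  session_extraction(fps, traces, fov, session_id = session_id)
}

# exhaustive enumeration of session-valid partitions (independent oracle)
enumerate_valid_partitions <- function(sessions) {
  n <- length(sessions)
  parts <- list(list())
  for (u in seq_len(n)) {
    new_parts <- list()
    for (p in parts) {
      for (ci in seq_along(p)) {
        if (sessions[u] %in% sessions[p[[ci]]]) next
        q <- p
        q[[ci]] <- c(q[[ci]], u)
        new_parts[[length(new_parts) + 1L]] <- q
      }
      q <- p
      q[[length(q) + 1L]] <- u
      new_parts[[length(new_parts) + 1L]] <- q
    }
    parts <- new_parts
  }
  parts
}

# objective used by the clustering: sum over clusters of mean pairwise
# similarity, singletons contributing zero (recomputed independently here)
partition_objective_oracle <- function(s_mat, partition) {
  sum(vapply(partition, function(cl) {
    if (length(cl) < 2L) return(0)
    sub <- s_mat[cl, cl]
    mean(sub[upper.tri(sub)])
  }, numeric(1)))
}

# random session-constrained similarity matrix shaped like the tracker's
random_component_matrix <- function(n, n_sessions = 3, zero_prob = 0.3,
                                    min_sim = 0) {
  ses <- sample(seq_len(n_sessions), n, replace = TRUE)
  s_mat <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (ses[i] == ses[j]) -10000
      else if (stats::runif(1) < zero_prob) 0
      else stats::runif(1, min_sim, 1)
      s_mat[i, j] <- s_mat[j, i] <- v
    }
  }
  list(s_mat = s_mat, sessions = ses)
}

# breadth-first-search connected components (independent oracle)
bfs_components <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  comps <- list()
  for (start in seq_len(n)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0L) {
      u <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, u)
      nb <- which(adj[u, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
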