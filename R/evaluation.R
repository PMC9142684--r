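register_rows_as_sets <- function(register) {
  tab <- register$table
  lapply(seq_len(nrow(tab)), function(r) {
    s <- which(!is.na(tab[r, ]))
    paste(s, tab[r, s], sep = ":")
  })
}

#' Discovery and false-discovery rates of a proposed register
#'
#' Scores a proposed cell register against a reference one. PDR (percent
#' discovery rate) is the fraction of available reference cells the method
#' tracked; FDR is the fraction of proposed rows containing at least one
#' false identification. Under scope `"all_sessions_only"` only rows
#' complete in every session are considered: the reference rows complete
#' everywhere are "available", a complete proposed row is a discovery when
#' it exactly matches one of them, and any other complete proposed row
#' counts as an error. An erroneous row never counts as a discovery. Under
#' scope `"all_clusters"` every reference row is available, a proposed row
#' is correct when its entries form a subset of a single reference row's
#' entries, and a discovery requires an exact match.
#'
#' @param proposed,truth `cell_register`s over the same sessions.
#' @param scope `"all_sessions_only"` (default) or `"all_clusters"`.
#' @return named numeric `c(PDR, FDR)`, both 0 for an empty proposal.
#' @export
pdr_fdr <- function(proposed, truth,
                    scope = c("all_sessions_only", "all_clusters")) {
  scope <- match.arg(scope)
  if (ncol(proposed$table) != ncol(truth$table))
    stop("registers cover different session counts")
  truth_sets <- register_rows_as_sets(truth)
  prop_sets <- register_rows_as_sets(proposed)
  ns <- ncol(truth$table)
  if (scope == "all_sessions_only") {
    truth_sets <- truth_sets[lengths(truth_sets) == ns]
    prop_sets <- prop_sets[lengths(prop_sets) == ns]
  }
  available <- length(truth_sets)
  n_prop <- length(prop_sets)
  if (n_prop == 0L) return(c(PDR = 0, FDR = 0))
  truth_keys <- vapply(truth_sets, function(s) paste(sort(s), collapse = ","),
                       character(1))
  correct <- logical(n_prop)
  discovered <- character(0)
  for (r in seq_len(n_prop)) {
    key <- paste(sort(prop_sets[[r]]), collapse = ",")
    if (scope == "all_sessions_only") {
      correct[r] <- key %in% truth_keys
      if (correct[r]) discovered <- c(discovered, key)
    } else {
      subset_ok <- any(vapply(truth_sets, function(ts)
        all(prop_sets[[r]] %in% ts), logical(1)))
      correct[r] <- subset_ok
      if (key %in% truth_keys) discovered <- c(discovered, key)
    }
  }
  pdr <- if (available == 0L) 0 else
    length(unique(discovered)) / available
  fdr <- sum(!correct) / n_prop
  c(PDR = pdr, FDR = fdr)
}

#' F1 cell-tracking quality score
#'
#' `F1 = 2 * PDR * (1 - FDR) / ((1 - FDR) + PDR)`: the harmonic-style
#' combination of the discovery rate and the complement of the
#' false-discovery rate. Returns 0 when the denominator vanishes.
#'
#' @param pdr,fdr rates in `[0, 1]` (fractions, not percentages).
#' @return score in `[0, 1]`.
#' @export
f1_score <- function(pdr, fdr) {
  stopifnot(all(pdr >= 0 & pdr <= 1), all(fdr >= 0 & fdr <= 1))
  denom <- (1 - fdr) + pdr
  out <- ifelse(denom > 0, 2 * pdr * (1 - fdr) / denom, 0)
  unname(out)
}

#' Average Jaccard similarity between matched register clusters
#'
#' Each proposed row (cluster of per-session identifications) is matched to
#' the reference cluster sharing the most entries (greedy by overlap, ties
#' to the larger reference cluster); the Jaccard index
#' `|A intersect B| / |A union B|` of the entry sets is then averaged over
#' all proposed clusters, counting unmatched clusters as 0.
#'
#' @inheritParams pdr_fdr
#' @return mean Jaccard in `[0, 1]`.
#' @export
jaccard_register <- function(proposed, truth) {
  prop_sets <- register_rows_as_sets(proposed)
  truth_sets <- register_rows_as_sets(truth)
  if (length(prop_sets) == 0L) return(0)
  overlap <- matrix(0L, length(prop_sets), length(truth_sets))
  for (i in seq_along(prop_sets))
    for (j in seq_along(truth_sets))
      overlap[i, j] <- length(intersect(prop_sets[[i]], truth_sets[[j]]))
  assigned_truth <- logical(length(truth_sets))
  jac <- numeric(length(prop_sets))
  # greedy: largest overlaps first; ties to the larger reference cluster
  ord <- order(-as.vector(overlap),
               -rep(lengths(truth_sets), each = length(prop_sets)))
  used_prop <- logical(length(prop_sets))
  for (o in ord) {
    ov <- as.vector(overlap)[o]
    if (ov == 0L) break
    i <- (o - 1L) %% length(prop_sets) + 1L
    j <- (o - 1L) %/% length(prop_sets) + 1L
    if (used_prop[i] || assigned_truth[j]) next
    used_prop[i] <- TRUE
    assigned_truth[j] <- TRUE
    jac[i] <- ov / length(union(prop_sets[[i]], truth_sets[[j]]))
  }
  mean(jac)
}

#' Jensen-Shannon divergence between cluster-size distributions
#'
#' Compares the normalized histograms of register row sizes (number of
#' sessions each tracked cell spans) between a proposed and a reference
#' register; 0 iff the size distributions coincide.
#'
#' @inheritParams pdr_fdr
#' @return divergence in bits.
#' @export
cluster_size_js <- function(proposed, truth) {
  sp <- rowSums(!is.na(proposed$table))
  st <- rowSums(!is.na(truth$table))
  if (length(sp) == 0L || length(st) == 0L)
    stop("both registers must be nonempty")
  sizes <- seq_len(max(sp, st))
  p <- tabulate(sp, nbins = length(sizes))
  q <- tabulate(st, nbins = length(sizes))
  js_divergence(p, q, base = 2)
}

#' Build a ground-truth register by matching extractions to truth
#'
#' An extracted neuron is identified with a ground-truth neuron of the same
#' session when their vectorized footprints correlate above
#' `spatial_thresh` (Pearson) and their traces correlate above
#' `temporal_thresh` over the session's frames. Unmatched extracted neurons
#' are excluded. The result is the register of ground-truth cells over
#' their per-session extracted indices.
#'
#' @param extractions list of `session_extraction`s derived from the
#'   simulated sessions.
#' @param truth the `truth` element of a `simulated_dataset`.
#' @param spatial_thresh,temporal_thresh correlation thresholds (defaults
#'   0.65 and 0.8).
#' @return a `cell_register` (rows = ground-truth cells matched in at least
#'   one session).
#' @export
ground_truth_register <- function(extractions, truth,
                                  spatial_thresh = 0.65,
                                  temporal_thresh = 0.8) {
  ns <- length(extractions)
  stopifnot(length(truth$footprints) == ns)
  k_true <- ncol(truth$footprints[[1]])
  reg <- matrix(NA_integer_, k_true, ns)
  for (s in seq_len(ns)) {
    fp_t <- truth$footprints[[s]]
    tr_t <- truth$traces[[s]]
    ext <- extractions[[s]]
    for (g in seq_len(k_true)) {
      best <- NA_integer_
      best_sc <- -Inf
      for (e in seq_len(n_neurons(ext))) {
        sc_sp <- safe_cor(fp_t[, g], ext$footprints[, e])
        if (is.na(sc_sp) || sc_sp <= spatial_thresh) next
        sc_tm <- safe_cor(tr_t[g, ], ext$traces[e, ])
        if (is.na(sc_tm) || sc_tm <= temporal_thresh) next
        if (sc_sp + sc_tm > best_sc) {
          best <- e
          best_sc <- sc_sp + sc_tm
        }
      }
      reg[g, s] <- best
    }
    # a single extracted neuron may not stand for two ground-truth cells
    dup <- duplicated(reg[, s], incomparables = NA)
    reg[dup, s] <- NA_integer_
  }
  keep <- rowSums(!is.na(reg)) > 0L
  cell_register(reg[keep, , drop = FALSE], rep(1, sum(keep)))
}

#' Score a register against a reference
#'
#' Convenience wrapper computing PDR, FDR, F1, mean Jaccard, and the
#' cluster-size Jensen-Shannon divergence in one call.
#'
#' @inheritParams pdr_fdr
#' @return named list of class `register_score`.
#' @export
score_register <- function(proposed, truth,
                           scope = c("all_sessions_only", "all_clusters")) {
  scope <- match.arg(scope)
  rates <- pdr_fdr(proposed, truth, scope)
  structure(list(PDR = unname(rates["PDR"]), FDR = unname(rates["FDR"]),
                 F1 = f1_score(rates["PDR"], rates["FDR"]),
                 jaccard = jaccard_register(proposed, truth),
                 size_js_divergence = cluster_size_js(proposed, truth)),
            class = "register_score")
}

#' @export
print.register_score <- function(x, ...) {
  cat(sprintf(
    "<register_score: PDR %.3f, FDR %.3f, F1 %.3f, Jaccard %.3f, size-JS %.3f>\n",
    x$PDR, x$FDR, x$F1, x$jaccard, x$size_js_divergence))
  invisible(x)
}
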