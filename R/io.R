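#' Construct a session extraction
#'
#' A session extraction is the standard output of a calcium-imaging source
#' extraction pipeline (e.g. CNMF-E) for one recording session: a matrix
#' `A` of spatial footprints (one column per neuron, `d = H*W` pixels,
#' nonnegative intensity) and a matrix `C` of fluorescence traces (one row
#' per neuron, one column per frame, dF/F in arbitrary units).
#'
#' Pixels are indexed the R way: 1-based, column-major, so footprint column
#' `k` reshapes to an `H x W` image via `matrix(A[, k], nrow = H)`.
#'
#' @param footprints numeric matrix, `d x K`, nonnegative; each column must
#'   contain at least one positive pixel.
#' @param traces numeric matrix, `K x T`.
#' @param fov_shape integer vector `c(H, W)` with `H * W == nrow(footprints)`.
#' @param frame_rate optional acquisition rate in Hz.
#' @param session_id optional label.
#' @param spikes optional `K x T` matrix of deconvolved events, carried as a
#'   pass-through attribute (not used by the tracker itself).
#' @return An object of class `session_extraction`.
#' @export
session_extraction <- function(footprints, traces, fov_shape,
                               frame_rate = NULL, session_id = NULL,
                               spikes = NULL) {
  footprints <- as.matrix(footprints)
  traces <- as.matrix(traces)
  fov_shape <- as.integer(fov_shape)
  if (length(fov_shape) != 2L || any(fov_shape <= 0L))
    stop("fov_shape must be two positive integers (H, W)")
  if (nrow(footprints) != prod(fov_shape))
    stop("footprint pixel count does not match fov_shape")
  if (any(footprints < 0))
    stop("footprints must be nonnegative")
  if (ncol(footprints) != nrow(traces))
    stop("trace row count (", nrow(traces),
         ") must equal footprint column count (", ncol(footprints), ")")
  if (ncol(footprints) > 0L) {
    mass <- colSums(footprints)
    if (any(mass <= 0))
      stop("every footprint must have at least one positive pixel")
  }
  if (!is.null(spikes)) {
    spikes <- as.matrix(spikes)
    if (!all(dim(spikes) == dim(traces)))
      stop("spikes must have the same dimensions as traces")
  }
  structure(
    list(footprints = footprints, traces = traces, fov_shape = fov_shape,
         frame_rate = frame_rate, session_id = session_id, spikes = spikes),
    class = "session_extraction"
  )
}

#' @export
print.session_extraction <- function(x, ...) {
  cat(sprintf("<session_extraction%s: %d neurons, %d frames, FOV %dx%d>\n",
              if (is.null(x$session_id)) "" else paste0(" ", x$session_id),
              n_neurons(x), n_frames(x), x$fov_shape[1], x$fov_shape[2]))
  invisible(x)
}

#' Number of neurons / frames in a session extraction
#' @param x a `session_extraction`.
#' @return integer count.
#' @export
n_neurons <- function(x) ncol(x$footprints)

#' @rdname n_neurons
#' @export
n_frames <- function(x) ncol(x$traces)

#' Construct a link extraction
#'
#' A link ("connecting") extraction spans a session boundary: its frames are
#' the last `n_frames_each_side` frames of the left session followed by the
#' first `n_frames_each_side` frames of the right session. It is used by the
#' link-correlation temporal metric to verify identities across the boundary.
#'
#' @param extraction a `session_extraction` with `2 * n_frames_each_side`
#'   frames.
#' @param n_frames_each_side frames taken from each side of the boundary.
#' @param left_session_id,right_session_id labels of the flanking sessions.
#' @return An object of class `link_extraction`.
#' @export
link_extraction <- function(extraction, n_frames_each_side,
                            left_session_id = NULL, right_session_id = NULL) {
  stopifnot(inherits(extraction, "session_extraction"))
  n_frames_each_side <- as.integer(n_frames_each_side)
  if (n_frames(extraction) != 2L * n_frames_each_side)
    stop("link extraction must have exactly 2 * n_frames_each_side frames")
  structure(
    list(extraction = extraction, n_frames_each_side = n_frames_each_side,
         left_session_id = left_session_id, right_session_id = right_session_id),
    class = "link_extraction"
  )
}

#' Construct a cell register
#'
#' The register is the tracker's final product: one row per tracked cell,
#' one column per session; each entry is the neuron index (1-based, within
#' that session's extraction) or `NA` when the cell was not identified in
#' that session. `score` holds each row's aggregate similarity: the mean
#' pairwise identification probability among the row's members (1 for a
#' cell seen in a single session, which cannot violate any chain threshold).
#'
#' @param table integer matrix (cells x sessions), entries neuron indices or
#'   `NA`.
#' @param score numeric vector in `[0, 1]`, one value per row.
#' @return An object of class `cell_register`.
#' @export
cell_register <- function(table, score = rep(1, nrow(table))) {
  table <- as.matrix(table)
  storage.mode(table) <- "integer"
  if (nrow(table) > 0L) {
    if (any(rowSums(!is.na(table)) == 0L))
      stop("every register row must have at least one non-missing entry")
    for (j in seq_len(ncol(table))) {
      idx <- table[, j][!is.na(table[, j])]
      if (anyDuplicated(idx))
        stop("duplicate neuron index in session column ", j)
    }
  }
  if (length(score) != nrow(table))
    stop("score length must equal row count")
  score <- as.numeric(score)
  if (any(score < -1e-9 | score > 1 + 1e-9, na.rm = TRUE))
    stop("scores must lie in [0, 1]")
  structure(list(table = table, score = pmin(pmax(score, 0), 1)),
            class = "cell_register")
}

#' @export
print.cell_register <- function(x, ...) {
  cat(sprintf("<cell_register: %d cells x %d sessions>\n",
              nrow(x$table), ncol(x$table)))
  invisible(x)
}

#' Write / read a session extraction as a plain-text directory
#'
#' The on-disk format is a directory holding `footprints.csv` (d x K, no
#' header), `traces.csv` (K x T, no header), optionally `spikes.csv`, and
#' `meta.json` with the FOV shape, frame rate and session id. Everything is
#' plain text so extractions diff and version cleanly.
#'
#' @param x a `session_extraction`.
#' @param path directory to create/overwrite.
#' @return `write_extraction` returns `path` invisibly; `read_extraction`
#'   returns a validated `session_extraction`.
#' @export
write_extraction <- function(x, path) {
  stopifnot(inherits(x, "session_extraction"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(x$footprints),
                     file.path(path, "footprints.csv"), col.names = FALSE)
  data.table::fwrite(data.table::as.data.table(x$traces),
                     file.path(path, "traces.csv"), col.names = FALSE)
  if (!is.null(x$spikes))
    data.table::fwrite(data.table::as.data.table(x$spikes),
                       file.path(path, "spikes.csv"), col.names = FALSE)
  meta <- list(fov_shape = x$fov_shape, frame_rate = x$frame_rate,
               session_id = x$session_id)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_extraction
#' @export
read_extraction <- function(path) {
  fp_file <- file.path(path, "footprints.csv")
  tr_file <- file.path(path, "traces.csv")
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(fp_file) || !file.exists(tr_file) || !file.exists(meta_file))
    stop("not an extraction directory (missing footprints/traces/meta): ", path)
  A <- as.matrix(data.table::fread(fp_file, header = FALSE))
  C <- as.matrix(data.table::fread(tr_file, header = FALSE))
  dimnames(A) <- NULL
  dimnames(C) <- NULL
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  spikes <- NULL
  sp_file <- file.path(path, "spikes.csv")
  if (file.exists(sp_file)) {
    spikes <- as.matrix(data.table::fread(sp_file, header = FALSE))
    dimnames(spikes) <- NULL
  }
  session_extraction(A, C, meta$fov_shape, frame_rate = meta$frame_rate,
                     session_id = meta$session_id, spikes = spikes)
}

#' Write / read a cell register as CSV
#'
#' One row per tracked cell; session columns hold 1-based neuron indices
#' with 0 marking a missing entry (the common MATLAB-style register
#' convention); a final `score` column carries the row's aggregate
#' similarity.
#'
#' @param register a `cell_register`.
#' @param path CSV file path.
#' @return `write_register` returns `path` invisibly; `read_register` a
#'   `cell_register`.
#' @export
write_register <- function(register, path) {
  stopifnot(inherits(register, "cell_register"))
  tab <- register$table
  tab[is.na(tab)] <- 0L
  df <- as.data.frame(tab)
  names(df) <- paste0("session_", seq_len(ncol(tab)))
  df$score <- register$score
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname write_register
#' @export
read_register <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- data.table::fread(path, header = TRUE)
  df <- as.data.frame(df)
  if (nrow(df) == 0L) {
    ses_cols <- grep("^session_", names(df))
    return(cell_register(matrix(integer(0), 0, length(ses_cols)), numeric(0)))
  }
  ses_cols <- grep("^session_", names(df))
  tab <- as.matrix(df[, ses_cols, drop = FALSE])
  storage.mode(tab) <- "integer"
  tab[tab == 0L] <- NA_integer_
  dimnames(tab) <- NULL
  score <- if ("score" %in% names(df)) df$score else rep(1, nrow(tab))
  cell_register(tab, score)
}

#' Concatenate per-cell traces across sessions
#'
#' Builds, for each register row, the full-experiment neural signal by
#' concatenating the cell's trace from every session in order. Frames of
#' sessions where the cell was not identified are filled with `NA` and
#' flagged in a logical mask, so downstream analyses can distinguish "cell
#' silent" from "cell absent".
#'
#' @param register a `cell_register` with one column per session.
#' @param sessions list of `session_extraction`, same order as the register
#'   columns.
#' @return list with `signals` (cells x total-frames numeric matrix, `NA`
#'   in gaps) and `missing` (same shape, logical, `TRUE` where the cell was
#'   absent).
#' @export
concatenate_traces <- function(register, sessions) {
  stopifnot(inherits(register, "cell_register"))
  if (ncol(register$table) != length(sessions))
    stop("register has ", ncol(register$table), " session columns but ",
         length(sessions), " sessions were supplied")
  t_s <- vapply(sessions, n_frames, integer(1))
  total <- sum(t_s)
  offsets <- cumsum(c(0L, t_s[-length(t_s)]))
  n_cells <- nrow(register$table)
  signals <- matrix(NA_real_, n_cells, total)
  missing <- matrix(TRUE, n_cells, total)
  for (s in seq_along(sessions)) {
    cols <- offsets[s] + seq_len(t_s[s])
    idx <- register$table[, s]
    for (i in seq_len(n_cells)) {
      k <- idx[i]
      if (is.na(k)) next
      if (k < 1L || k > n_neurons(sessions[[s]]))
        stop("register row ", i, " references neuron ", k,
             " outside session ", s)
      signals[i, cols] <- sessions[[s]]$traces[k, ]
      missing[i, cols] <- FALSE
    }
  }
  list(signals = signals, missing = missing)
}
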