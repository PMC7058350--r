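#' Spike-train reports
#'
#' A spike report is the paired event list `(node_id, timestamp)` that is
#' both the default output of a simulation and, for virtual nodes, the way
#' pre-generated input activity is fed in. Timestamps are in milliseconds.
#' The storage order is free; the `sorting` tag records whether events are
#' sorted by time, by node id, or not at all.
#'
#' @param population name of the node population the ids refer to.
#' @param node_ids integer vector of spiking node ids.
#' @param timestamps numeric vector of spike times (ms), parallel to
#'   `node_ids`, all non-negative.
#' @param sorting one of `"none"`, `"by_time"`, `"by_id"`. With
#'   `"by_time"` the timestamps must be non-decreasing (and symmetrically
#'   for `"by_id"`).
#' @return An object of class `sonata_spike_report`.
#' @export
spike_report <- function(population, node_ids, timestamps,
                         sorting = c("none", "by_time", "by_id")) {
  sorting <- match.arg(sorting)
  node_ids <- as.integer(node_ids)
  timestamps <- as.numeric(timestamps)
  if (length(node_ids) != length(timestamps)) {
    abort("length_mismatch", "node_ids and timestamps differ in length")
  }
  if (any(timestamps < 0)) abort("negative_timestamp", "spike timestamps must be >= 0")
  if (sorting == "by_time" && is.unsorted(timestamps)) {
    abort("unsorted", "sorting='by_time' but timestamps are not non-decreasing")
  }
  if (sorting == "by_id" && is.unsorted(node_ids)) {
    abort("unsorted", "sorting='by_id' but node_ids are not non-decreasing")
  }
  structure(list(population = population, node_ids = node_ids,
                 timestamps = timestamps, sorting = sorting),
            class = "sonata_spike_report")
}

#' @export
print.sonata_spike_report <- function(x, ...) {
  cat(sprintf("SONATA spike report '%s': %d event(s), sorting=%s\n",
              x$population, length(x$node_ids), x$sorting))
  invisible(x)
}

#' Write spikes to HDF5
#'
#' Layout: `/spikes/<population>/{timestamps, node_ids}` with a `sorting`
#' attribute on the population group.
#'
#' @param report a [spike_report()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(report, path) {
  stopifnot(inherits(report, "sonata_spike_report"))
  write_atomically(path, function(tmp) {
    rhdf5::h5createFile(tmp)
    rhdf5::h5createGroup(tmp, "spikes")
    base <- sprintf("spikes/%s", report$population)
    rhdf5::h5createGroup(tmp, base)
    h5_write_column(tmp, paste0(base, "/timestamps"), report$timestamps)
    h5_write_column(tmp, paste0(base, "/node_ids"), report$node_ids)
    h5_set_attr(tmp, base, "sorting", report$sorting)
  })
}

#' Read spikes from HDF5, optionally filtered
#'
#' @param path spikes file written by [write_spikes()].
#' @param population population to read; defaults to the single population
#'   in the file.
#' @param node_filter optional integer vector: keep only events of these
#'   nodes.
#' @param window optional numeric `c(t0, t1)`: keep events with
#'   `t0 <= t < t1` (half-open, ms).
#' @return A [spike_report()]. Filtering preserves storage order; the
#'   `sorting` tag is carried over (a filtered subsequence of a sorted
#'   sequence is still sorted).
#' @export
read_spikes <- function(path, population = NULL, node_filter = NULL, window = NULL) {
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  ls_df <- rhdf5::h5ls(path)
  pops <- h5_children(ls_df, "/spikes", "H5I_GROUP")
  if (!length(pops)) abort("missing_dataset", "%s has no populations under /spikes", path)
  if (is.null(population)) {
    if (length(pops) > 1L) {
      abort("ambiguous", "%s holds several spike populations (%s); pick one",
            path, paste(pops, collapse = ", "))
    }
    population <- pops[[1]]
  }
  if (!population %in% pops) abort("unknown_population", "no spike population '%s' in %s", population, path)
  base <- sprintf("/spikes/%s", population)
  ts <- as.numeric(h5_read_vec(path, paste0(base, "/timestamps")))
  ids <- as.integer(h5_read_vec(path, paste0(base, "/node_ids")))
  if (length(ts) != length(ids)) {
    abort("length_mismatch", "%s: timestamps and node_ids differ in length", path)
  }
  sorting <- h5_get_attr(path, base, "sorting") %||% "none"
  keep <- rep(TRUE, length(ts))
  if (!is.null(node_filter)) keep <- keep & ids %in% as.integer(node_filter)
  if (!is.null(window)) keep <- keep & ts >= window[1] & ts < window[2]
  spike_report(population, ids[keep], ts[keep], sorting)
}

#' Export / import spikes as plain CSV
#'
#' Two space-separated columns, `node_id time`, one event per line, with a
#' header. Used by the command-line `spikes` subcommand.
#'
#' @param report a [spike_report()].
#' @param path CSV file.
#' @return `path` / a [spike_report()].
#' @export
spikes_to_csv <- function(report, path) {
  write_atomically(path, function(tmp) {
    lines <- c("node_id time",
               sprintf("%d %s", report$node_ids,
                       vapply(report$timestamps, format_value, character(1))))
    writeLines(lines, tmp)
  })
}

#' @rdname spikes_to_csv
#' @param population population name for the imported report.
#' @param sorting sorting tag for the imported report.
#' @export
spikes_from_csv <- function(path, population = "spikes", sorting = "none") {
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !identical(tokenize_line(lines[[1]]), c("node_id", "time"))) {
    abort("bad_table", "%s is not a spikes CSV (expected header 'node_id time')", path)
  }
  ids <- integer(0); ts <- numeric(0)
  if (length(lines) > 1L) {
    toks <- lapply(lines[-1], tokenize_line)
    if (any(vapply(toks, length, integer(1)) != 2L)) {
      abort("ragged_row", "%s: every spike line must have two fields", path)
    }
    ids <- as.integer(vapply(toks, `[[`, character(1), 1L))
    ts <- as.numeric(vapply(toks, `[[`, character(1), 2L))
  }
  spike_report(population, ids, ts, sorting)
}

# --- element (frame/trace) reports -------------------------------------------

#' Element-report column mapping
#'
#' An element report stores all recorded values as one N x M matrix: rows
#' are frames (all values at one timestamp), columns are traces (the time
#' series of one element, e.g. an electrical compartment). The mapping
#' locates each node's columns: all elements of a node are contiguous
#' within a frame, but nodes need not appear sorted by id. `offsets` (the
#' index pointer) holds the position of each node's first column plus a
#' terminal M.
#'
#' @param elements ordered list; each entry is a list with `node_id`
#'   (scalar), `element_id` (integer vector, one per element, ids unique to
#'   the node) and optional `element_pos` (numeric in `[0, 1]`, parallel to
#'   `element_id`, e.g. the relative position of a compartment within its
#'   morphological section). Either all nodes supply `element_pos` or none;
#'   when absent, elements are taken to be stored in morphological order and
#'   the reader preserves that order exactly.
#' @return An object of class `sonata_element_mapping` with fields
#'   `node_ids`, `offsets` (length `n+1`, 0-based), `element_ids`,
#'   `element_pos` (or `NULL`) and `n_elements`.
#' @export
build_mapping <- function(elements) {
  if (!length(elements)) abort("bad_mapping", "mapping needs at least one node")
  node_ids <- vapply(elements, function(e) as.integer(e$node_id), integer(1))
  if (anyDuplicated(node_ids)) abort("duplicate_node", "duplicate node id in mapping")
  counts <- vapply(elements, function(e) length(e$element_id), integer(1))
  if (any(counts == 0L)) abort("bad_mapping", "every node needs at least one element")
  has_pos <- vapply(elements, function(e) !is.null(e$element_pos), logical(1))
  if (any(has_pos) && !all(has_pos)) {
    abort("bad_mapping", "element_pos must be given for all nodes or none")
  }
  element_ids <- as.integer(unlist(lapply(elements, `[[`, "element_id"), use.names = FALSE))
  element_pos <- NULL
  if (all(has_pos)) {
    element_pos <- as.numeric(unlist(lapply(elements, `[[`, "element_pos"), use.names = FALSE))
    if (length(element_pos) != length(element_ids)) {
      abort("bad_mapping", "element_pos must align 1:1 with element_id")
    }
    if (any(element_pos < 0 | element_pos > 1)) {
      abort("bad_mapping", "element_pos values must lie in [0, 1]")
    }
  }
  offsets <- c(0L, cumsum(counts))
  structure(list(node_ids = node_ids, offsets = as.integer(offsets),
                 element_ids = element_ids, element_pos = element_pos,
                 n_elements = sum(counts)),
            class = "sonata_element_mapping")
}

#' @export
print.sonata_element_mapping <- function(x, ...) {
  cat(sprintf("SONATA element mapping: %d node(s), %d element column(s)%s\n",
              length(x$node_ids), x$n_elements,
              if (is.null(x$element_pos)) "" else " (with element_pos)"))
  invisible(x)
}

#' Column span of one node in an element report
#'
#' @param mapping a [build_mapping()].
#' @param node_id integer node id.
#' @return Integer `c(start, end)`: the 0-based half-open column interval
#'   `[offsets[k], offsets[k+1])` of the node's elements.
#' @export
columns_for_node <- function(mapping, node_id) {
  k <- match(as.integer(node_id), mapping$node_ids)
  if (is.na(k)) abort("unknown_node", "node %d not present in mapping", node_id)
  c(mapping$offsets[k], mapping$offsets[k + 1L])
}

report_frame_count <- function(tstart, tstop, dt) {
  if (!is.numeric(dt) || dt <= 0) abort("bad_report", "dt must be > 0")
  if (tstop <= tstart) abort("bad_report", "tstop must exceed tstart")
  exact <- (tstop - tstart) / dt
  # round() with a 1e-9 relative tolerance absorbs floating drift in tstop;
  # genuinely fractional durations fall back to the completed frame count
  n <- round(exact)
  if (abs(n - exact) > 1e-9 * max(1, abs(exact))) n <- floor(exact)
  max(as.integer(n), 1L)
}

#' Create a writable element report
#'
#' Allocates the chunked N x M `data` matrix (N frames between `tstart` and
#' `tstop` at step `dt`, M element columns from the mapping) plus the
#' mapping datasets under `/report/<population>/mapping/` (`node_ids`,
#' `index_pointer`, `element_ids`, optional `element_pos`, and
#' `time = [tstart, tstop, dt]`). Chunking is essential for efficient
#' partial access but the format does not prescribe shapes; the default is
#' `(min(N, 1024), min(M, 512))`.
#'
#' @param path destination file (created/overwritten immediately — frames
#'   are appended in place, so creation is not atomic).
#' @param mapping a [build_mapping()].
#' @param tstart,tstop,dt time block in ms; `N = round((tstop - tstart)/dt)`.
#' @param chunk_shape integer `c(frames, traces)` HDF5 chunk dimensions.
#' @param population report name under `/report/`.
#' @param variable,units free-text metadata recorded on the data matrix.
#' @return A report handle for [append_frames()].
#' @export
create_element_report <- function(path, mapping, tstart, tstop, dt,
                                  chunk_shape = NULL, population = "report",
                                  variable = "v", units = "") {
  stopifnot(inherits(mapping, "sonata_element_mapping"))
  n_frames <- report_frame_count(tstart, tstop, dt)
  m <- mapping$n_elements
  if (is.null(chunk_shape)) chunk_shape <- c(min(n_frames, 1024L), min(m, 512L))
  chunk_shape <- as.integer(chunk_shape)
  if (length(chunk_shape) != 2L || any(chunk_shape < 1L)) {
    abort("bad_chunk", "chunk_shape must be two positive integers")
  }
  chunk_shape <- pmin(chunk_shape, c(n_frames, m))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "report")
  base <- sprintf("report/%s", population)
  rhdf5::h5createGroup(path, base)
  rhdf5::h5createDataset(path, paste0(base, "/data"), dims = c(n_frames, m),
                         storage.mode = "double", chunk = chunk_shape, level = 1)
  h5_set_attr(path, paste0(base, "/data"), "variable", variable)
  h5_set_attr(path, paste0(base, "/data"), "units", units)
  mbase <- paste0(base, "/mapping")
  rhdf5::h5createGroup(path, mbase)
  h5_write_column(path, paste0(mbase, "/node_ids"), mapping$node_ids)
  h5_write_column(path, paste0(mbase, "/index_pointer"), mapping$offsets)
  h5_write_column(path, paste0(mbase, "/element_ids"), mapping$element_ids)
  if (!is.null(mapping$element_pos)) {
    h5_write_column(path, paste0(mbase, "/element_pos"), mapping$element_pos)
  }
  h5_write_column(path, paste0(mbase, "/time"), as.numeric(c(tstart, tstop, dt)))
  handle <- new.env(parent = emptyenv())
  handle$path <- path
  handle$base <- base
  handle$n_frames <- n_frames
  handle$m <- m
  handle$cursor <- 0L
  class(handle) <- "sonata_report_handle"
  handle
}

#' Append frames to an element report
#'
#' Frames (rows) land at consecutive indices after the previously written
#' ones — the frame-sequential pattern in which simulators emit data. A
#' partial final block is fine; writing past N is an error.
#'
#' @param handle a [create_element_report()] handle.
#' @param rows_block numeric matrix with M columns (a vector is taken as a
#'   single frame). A zero-row block is a no-op.
#' @return The handle, invisibly (its cursor advanced).
#' @export
append_frames <- function(handle, rows_block) {
  stopifnot(inherits(handle, "sonata_report_handle"))
  if (is.null(dim(rows_block))) rows_block <- matrix(rows_block, nrow = 1L)
  if (nrow(rows_block) == 0L) return(invisible(handle))
  if (ncol(rows_block) != handle$m) {
    abort("width_mismatch", "block has %d columns, report has %d traces",
          ncol(rows_block), handle$m)
  }
  if (handle$cursor + nrow(rows_block) > handle$n_frames) {
    abort("overflow", "writing %d frame(s) at cursor %d exceeds N=%d",
          nrow(rows_block), handle$cursor, handle$n_frames)
  }
  rows <- handle$cursor + seq_len(nrow(rows_block))
  rhdf5::h5write(rows_block, handle$path, paste0(handle$base, "/data"),
                 index = list(rows, seq_len(handle$m)))
  handle$cursor <- handle$cursor + nrow(rows_block)
  invisible(handle)
}

read_mapping_h5 <- function(path, base) {
  mbase <- paste0(sub("^/", "", base), "/mapping")
  node_ids <- as.integer(h5_read_vec(path, paste0(mbase, "/node_ids")))
  offsets <- as.integer(h5_read_vec(path, paste0(mbase, "/index_pointer")))
  element_ids <- as.integer(h5_read_vec(path, paste0(mbase, "/element_ids")))
  has_pos <- tryCatch({
    ls_df <- rhdf5::h5ls(path)
    "element_pos" %in% h5_children(ls_df, paste0("/", mbase), "H5I_DATASET")
  }, error = function(e) FALSE)
  element_pos <- if (has_pos) as.numeric(h5_read_vec(path, paste0(mbase, "/element_pos"))) else NULL
  time <- as.numeric(h5_read_vec(path, paste0(mbase, "/time")))
  mapping <- structure(list(node_ids = node_ids, offsets = offsets,
                            element_ids = element_ids, element_pos = element_pos,
                            n_elements = length(element_ids)),
                       class = "sonata_element_mapping")
  list(mapping = mapping, tstart = time[1], tstop = time[2], dt = time[3])
}

report_base <- function(path, population = NULL) {
  ls_df <- rhdf5::h5ls(path)
  pops <- h5_children(ls_df, "/report", "H5I_GROUP")
  if (!length(pops)) abort("missing_dataset", "%s has no populations under /report", path)
  if (is.null(population)) {
    if (length(pops) > 1L) abort("ambiguous", "%s holds several reports; pick one", path)
    population <- pops[[1]]
  }
  if (!population %in% pops) abort("unknown_population", "no report '%s' in %s", population, path)
  sprintf("/report/%s", population)
}

#' Read an entire element report
#'
#' @param path report file.
#' @param population report name; defaults to the single one present.
#' @return A `sonata_element_report`: list with `mapping`, `tstart`,
#'   `tstop`, `dt`, `data` (N x M matrix), `variable`, `units`.
#' @export
read_element_report <- function(path, population = NULL) {
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  base <- report_base(path, population)
  meta <- read_mapping_h5(path, base)
  data <- rhdf5::h5read(path, paste0(base, "/data"))
  structure(c(meta,
              list(data = matrix(as.numeric(data), nrow = nrow(data)),
                   variable = h5_get_attr(path, paste0(base, "/data"), "variable") %||% "",
                   units = h5_get_attr(path, paste0(base, "/data"), "units") %||% "")),
            class = "sonata_element_report")
}

#' @export
print.sonata_element_report <- function(x, ...) {
  cat(sprintf("SONATA element report: %d frame(s) x %d trace(s), t=[%g, %g) ms, dt=%g ms\n",
              nrow(x$data), ncol(x$data), x$tstart, x$tstop, x$dt))
  invisible(x)
}

# resolve a Selection to 0-based column indices, honouring mapping order
select_columns <- function(mapping, node_ids = NULL, element_ids = NULL,
                           pos_range = NULL) {
  nodes <- if (is.null(node_ids)) mapping$node_ids else as.integer(node_ids)
  cols <- integer(0)
  for (nid in nodes) {
    span <- columns_for_node(mapping, nid)
    idx <- seq.int(span[1] + 1L, span[2])      # 1-based columns of this node
    if (!is.null(element_ids)) {
      idx <- idx[mapping$element_ids[idx] %in% as.integer(element_ids)]
    }
    if (!is.null(pos_range)) {
      if (is.null(mapping$element_pos)) {
        abort("no_element_pos", "mapping has no element_pos; cannot filter by position")
      }
      p <- mapping$element_pos[idx]
      idx <- idx[p >= pos_range[1] & p < pos_range[2]]
    }
    cols <- c(cols, idx)
  }
  cols
}

report_frame_rows <- function(tstart, dt, n_frames, window = NULL) {
  if (is.null(window)) return(seq_len(n_frames))
  t <- tstart + (seq_len(n_frames) - 1L) * dt
  which(t >= window[1] & t < window[2])
}

#' Read frames (rows) of an element report
#'
#' Hyperslab read of the stored matrix: rows restricted to the time window,
#' columns to the selected nodes/elements. Equivalent to slicing the dense
#' matrix, for any chunk shape.
#'
#' @param path report file.
#' @param window optional `c(t0, t1)` ms, half-open.
#' @param node_ids optional nodes to keep (mapping order preserved).
#' @param element_ids,pos_range optional per-node element filters (by id
#'   set, or by `element_pos` in half-open `[lo, hi)`).
#' @param population report name.
#' @return Numeric matrix (possibly 0-row/0-column).
#' @export
read_frames <- function(path, window = NULL, node_ids = NULL,
                        element_ids = NULL, pos_range = NULL, population = NULL) {
  base <- report_base(path, population)
  meta <- read_mapping_h5(path, base)
  n_frames <- report_frame_count(meta$tstart, meta$tstop, meta$dt)
  rows <- report_frame_rows(meta$tstart, meta$dt, n_frames, window)
  cols <- select_columns(meta$mapping, node_ids, element_ids, pos_range)
  if (!length(rows) || !length(cols)) {
    return(matrix(numeric(0), nrow = length(rows), ncol = length(cols)))
  }
  out <- rhdf5::h5read(path, paste0(base, "/data"), index = list(rows, cols))
  matrix(as.numeric(out), nrow = length(rows))
}

#' Read traces (columns) of one node
#'
#' @param path report file.
#' @param node_id the node whose element columns to read.
#' @param element_ids,pos_range optional element filters as in
#'   [read_frames()].
#' @param population report name.
#' @return Numeric matrix, N frames x selected elements, with the node's
#'   `element_id` values as column names.
#' @export
read_trace <- function(path, node_id, element_ids = NULL, pos_range = NULL,
                       population = NULL) {
  base <- report_base(path, population)
  meta <- read_mapping_h5(path, base)
  n_frames <- report_frame_count(meta$tstart, meta$tstop, meta$dt)
  cols <- select_columns(meta$mapping, node_id, element_ids, pos_range)
  if (!length(cols)) return(matrix(numeric(0), nrow = n_frames, ncol = 0L))
  out <- rhdf5::h5read(path, paste0(base, "/data"),
                       index = list(seq_len(n_frames), cols))
  out <- matrix(as.numeric(out), nrow = n_frames)
  colnames(out) <- meta$mapping$element_ids[cols]
  out
}
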