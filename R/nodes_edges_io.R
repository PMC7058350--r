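#' @importFrom rhdf5 h5createFile h5createGroup h5createDataset h5write h5read
#'   h5ls h5readAttributes H5Fopen H5Fclose H5Oopen H5Oclose h5writeAttribute
NULL

# default HDF5 chunk length for 1-D instance-table columns; the format does
# not prescribe chunking, so this is freely overridable
DEFAULT_CHUNK_ELEMS <- 65536L

h5_set_attr <- function(path, obj, name, value) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(value, oid, name, asScalar = is.character(value) && length(value) == 1L)
  invisible(NULL)
}

h5_get_attr <- function(path, obj, name) {
  at <- tryCatch(rhdf5::h5readAttributes(path, obj), error = function(e) list())
  v <- at[[name]]
  if (is.null(v)) NULL else as.vector(v)
}

# write one 1-D column; empty columns become 0-length datasets
h5_write_column <- function(path, dset, v, chunk = DEFAULT_CHUNK_ELEMS) {
  n <- length(v)
  if (is.character(v)) {
    if (n == 0L) {
      rhdf5::h5createDataset(path, dset, dims = 0L, storage.mode = "character",
                             size = 1L, chunk = NULL, level = 0)
    } else {
      rhdf5::h5write(v, path, dset)
    }
    return(invisible(NULL))
  }
  storage <- if (is.integer(v)) "integer" else "double"
  if (n == 0L) {
    rhdf5::h5createDataset(path, dset, dims = 0L, storage.mode = storage,
                           chunk = NULL, level = 0)
  } else {
    rhdf5::h5createDataset(path, dset, dims = n, storage.mode = storage,
                           chunk = min(n, chunk), level = 1)
    rhdf5::h5write(v, path, dset)
  }
  invisible(NULL)
}

h5_read_vec <- function(path, dset) {
  v <- rhdf5::h5read(path, dset)
  as.vector(v)
}

h5_children <- function(ls_df, parent, type = NULL) {
  sel <- ls_df$group == parent
  if (!is.null(type)) sel <- sel & ls_df$otype == type
  ls_df$name[sel]
}

write_groups_h5 <- function(path, base, groups) {
  for (g in groups) {
    gpath <- sprintf("%s/%d", base, g$group_id)
    rhdf5::h5createGroup(path, gpath)
    h5_set_attr(path, gpath, "size", as.integer(g$size))
    for (an in names(g$attributes)) {
      h5_write_column(path, sprintf("%s/%s", gpath, an), g$attributes[[an]])
    }
  }
}

read_groups_h5 <- function(path, ls_df, base) {
  gnames <- h5_children(ls_df, base, "H5I_GROUP")
  gnames <- gnames[grepl("^[0-9]+$", gnames)]
  lapply(sort(as.integer(gnames)), function(gid) {
    gpath <- sprintf("%s/%d", base, gid)
    anames <- h5_children(ls_df, gpath, "H5I_DATASET")
    attrs <- lapply(anames, function(an) h5_read_vec(path, sprintf("%s/%s", gpath, an)))
    names(attrs) <- anames
    size <- h5_get_attr(path, gpath, "size")
    if (is.null(size)) {
      size <- if (length(attrs)) length(attrs[[1]]) else 0L
    }
    node_group(gid, as.integer(size), attrs)
  })
}

#' Write node populations to an HDF5 file
#'
#' Layout: `/nodes/<population>/` holds the four instance columns
#' (`node_id`, `node_type_id`, `node_group_id`, `node_group_index`) and one
#' HDF5 sub-group per node group, named by its `group_id`, holding that
#' group's per-instance attribute columns. Integer and floating columns
#' round-trip exactly. The file is replaced atomically.
#'
#' @param populations a [node_population()] or list of them.
#' @param path destination `.h5` file.
#' @return `path`, invisibly.
#' @export
write_nodes <- function(populations, path) {
  if (inherits(populations, "sonata_node_population")) populations <- list(populations)
  write_atomically(path, function(tmp) {
    rhdf5::h5createFile(tmp)
    rhdf5::h5createGroup(tmp, "nodes")
    for (pop in populations) {
      stopifnot(inherits(pop, "sonata_node_population"))
      base <- sprintf("nodes/%s", pop$name)
      rhdf5::h5createGroup(tmp, base)
      h5_write_column(tmp, paste0(base, "/node_id"), pop$node_id)
      h5_write_column(tmp, paste0(base, "/node_type_id"), pop$node_type_id)
      h5_write_column(tmp, paste0(base, "/node_group_id"), pop$group_id)
      h5_write_column(tmp, paste0(base, "/node_group_index"), pop$group_index)
      write_groups_h5(tmp, base, pop$groups)
    }
  })
}

#' Read node populations from an HDF5 file
#'
#' @param path an HDF5 nodes file produced by [write_nodes()] (or following
#'   the same layout).
#' @return Named list of [node_population()]s.
#' @export
read_nodes <- function(path) {
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  ls_df <- rhdf5::h5ls(path)
  pops <- h5_children(ls_df, "/nodes", "H5I_GROUP")
  if (!length(pops)) abort("missing_dataset", "%s has no populations under /nodes", path)
  out <- lapply(pops, function(pn) {
    base <- sprintf("/nodes/%s", pn)
    dsets <- h5_children(ls_df, base, "H5I_DATASET")
    if (!"node_type_id" %in% dsets) {
      abort("missing_dataset", "%s: %s lacks mandatory dataset node_type_id", path, base)
    }
    ntid <- as.integer(h5_read_vec(path, paste0(base, "/node_type_id")))
    n <- length(ntid)
    nid <- if ("node_id" %in% dsets) {
      as.integer(h5_read_vec(path, paste0(base, "/node_id")))
    } else seq_len(n) - 1L
    gid <- if ("node_group_id" %in% dsets) {
      as.integer(h5_read_vec(path, paste0(base, "/node_group_id")))
    } else rep(0L, n)
    gidx <- if ("node_group_index" %in% dsets) {
      as.integer(h5_read_vec(path, paste0(base, "/node_group_index")))
    } else seq_len(n) - 1L
    if (length(unique(c(length(nid), n, length(gid), length(gidx)))) != 1L) {
      abort("length_mismatch", "%s: %s has node columns of unequal length", path, base)
    }
    groups <- read_groups_h5(path, ls_df, base)
    if (!length(groups) && n == 0L) groups <- list(node_group(0L, 0L))
    node_population(pn, ntid, groups, group_id = gid, group_index = gidx,
                    node_id = nid)
  })
  names(out) <- pops
  out
}

#' Write edge populations to an HDF5 file
#'
#' Layout: `/edges/<population>/` holds `source_node_id`, `target_node_id`,
#' `edge_type_id`, `edge_group_id` and `edge_group_index`, plus one HDF5
#' sub-group per edge group. The names of the source and target node
#' populations are stored as a `node_population` attribute on the respective
#' endpoint id datasets. Any range indices attached to a population (see
#' [build_edge_index()]) are written under `/edges/<population>/indices/`
#' and restored on read.
#'
#' @param populations an [edge_population()] or list of them.
#' @param path destination `.h5` file.
#' @return `path`, invisibly.
#' @export
write_edges <- function(populations, path) {
  if (inherits(populations, "sonata_edge_population")) populations <- list(populations)
  write_atomically(path, function(tmp) {
    rhdf5::h5createFile(tmp)
    rhdf5::h5createGroup(tmp, "edges")
    for (pop in populations) {
      stopifnot(inherits(pop, "sonata_edge_population"))
      base <- sprintf("edges/%s", pop$name)
      rhdf5::h5createGroup(tmp, base)
      h5_write_column(tmp, paste0(base, "/source_node_id"), pop$source_node_id)
      h5_write_column(tmp, paste0(base, "/target_node_id"), pop$target_node_id)
      h5_write_column(tmp, paste0(base, "/edge_type_id"), pop$edge_type_id)
      h5_write_column(tmp, paste0(base, "/edge_group_id"), pop$group_id)
      h5_write_column(tmp, paste0(base, "/edge_group_index"), pop$group_index)
      h5_set_attr(tmp, paste0(base, "/source_node_id"), "node_population",
                  pop$source_population)
      h5_set_attr(tmp, paste0(base, "/target_node_id"), "node_population",
                  pop$target_population)
      write_groups_h5(tmp, base, pop$groups)
      if (!is.null(pop$indices) && length(pop$indices)) {
        rhdf5::h5createGroup(tmp, paste0(base, "/indices"))
        for (idx in pop$indices) {
          dirname <- if (idx$direction == "by_target") "target_to_source" else "source_to_target"
          ibase <- sprintf("%s/indices/%s", base, dirname)
          rhdf5::h5createGroup(tmp, ibase)
          ser <- serialize_range_index(idx)
          rhdf5::h5write(ser$node_id_to_ranges, tmp, paste0(ibase, "/node_id_to_ranges"))
          rhdf5::h5write(ser$range_to_edge_id, tmp, paste0(ibase, "/range_to_edge_id"))
        }
      }
    }
  })
}

#' Read edge populations from an HDF5 file
#'
#' @param path an HDF5 edges file produced by [write_edges()].
#' @return Named list of [edge_population()]s (range indices restored when
#'   present).
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) abort("io", "no such file: %s", path)
  ls_df <- rhdf5::h5ls(path)
  pops <- h5_children(ls_df, "/edges", "H5I_GROUP")
  if (!length(pops)) abort("missing_dataset", "%s has no populations under /edges", path)
  out <- lapply(pops, function(pn) {
    base <- sprintf("/edges/%s", pn)
    dsets <- h5_children(ls_df, base, "H5I_DATASET")
    need <- c("source_node_id", "target_node_id", "edge_type_id")
    miss <- setdiff(need, dsets)
    if (length(miss)) {
      abort("missing_dataset", "%s: %s lacks mandatory dataset(s) %s",
            path, base, paste(miss, collapse = ", "))
    }
    src <- as.integer(h5_read_vec(path, paste0(base, "/source_node_id")))
    tgt <- as.integer(h5_read_vec(path, paste0(base, "/target_node_id")))
    etid <- as.integer(h5_read_vec(path, paste0(base, "/edge_type_id")))
    n <- length(etid)
    gid <- if ("edge_group_id" %in% dsets) {
      as.integer(h5_read_vec(path, paste0(base, "/edge_group_id")))
    } else rep(0L, n)
    gidx <- if ("edge_group_index" %in% dsets) {
      as.integer(h5_read_vec(path, paste0(base, "/edge_group_index")))
    } else seq_len(n) - 1L
    if (length(unique(c(length(src), length(tgt), n, length(gid), length(gidx)))) != 1L) {
      abort("length_mismatch", "%s: %s has edge columns of unequal length", path, base)
    }
    spop <- h5_get_attr(path, paste0(base, "/source_node_id"), "node_population") %||% NA_character_
    tpop <- h5_get_attr(path, paste0(base, "/target_node_id"), "node_population") %||% NA_character_
    groups <- read_groups_h5(path, ls_df, base)
    if (!length(groups) && n == 0L) groups <- list(edge_group(0L, 0L))
    indices <- NULL
    idx_base <- paste0(base, "/indices")
    idx_groups <- h5_children(ls_df, idx_base, "H5I_GROUP")
    if (length(idx_groups)) {
      indices <- list()
      for (ig in idx_groups) {
        direction <- if (ig == "target_to_source") "by_target" else "by_source"
        n2r <- rhdf5::h5read(path, sprintf("%s/%s/node_id_to_ranges", idx_base, ig))
        r2e <- rhdf5::h5read(path, sprintf("%s/%s/range_to_edge_id", idx_base, ig))
        indices[[direction]] <- deserialize_range_index(direction, n2r, r2e)
      }
    }
    edge_population(pn, spop, tpop, src, tgt, etid, groups,
                    group_id = gid, group_index = gidx, indices = indices)
  })
  names(out) <- pops
  out
}

#' Edge orderings
#'
#' Edge arrays may be stored in any order; three canonical orderings trade
#' off by-target against by-source access speed. `target_major` sorts by
#' target node id (ascending, ties by source id then original position) and
#' makes all edges of one target contiguous; `source_major` is its mirror.
#' `hybrid` divides the source x target connectivity matrix into
#' `block_size` x `block_size` blocks, traverses blocks row-major by
#' (target block, source block), and alternates the within-block order by
#' block parity (even parity target-major, odd source-major), balancing the
#' two access patterns.
#'
#' @param kind `"target_major"`, `"source_major"` or `"hybrid"`.
#' @param block_size positive integer block edge length (hybrid only).
#' @return An object of class `sonata_ordering`.
#' @export
edge_ordering <- function(kind = c("target_major", "source_major", "hybrid"),
                          block_size = NULL) {
  kind <- match.arg(kind)
  if (kind == "hybrid") {
    if (is.null(block_size) || !is_count(block_size) || block_size < 1) {
      abort("bad_ordering", "hybrid ordering requires block_size >= 1")
    }
    block_size <- as.integer(block_size)
  } else if (!is.null(block_size)) {
    abort("bad_ordering", "block_size only applies to hybrid ordering")
  }
  structure(list(kind = kind, block_size = block_size), class = "sonata_ordering")
}

ordering_permutation <- function(src, tgt, ordering) {
  orig <- seq_along(src)
  switch(ordering$kind,
    target_major = order(tgt, src, orig),
    source_major = order(src, tgt, orig),
    hybrid = {
      B <- ordering$block_size
      bi <- tgt %/% B   # block row: target blocks
      bj <- src %/% B   # block column: source blocks
      even <- (bi + bj) %% 2L == 0L
      w1 <- ifelse(even, tgt, src)
      w2 <- ifelse(even, src, tgt)
      order(bi, bj, w1, w2, orig)
    })
}

#' Sort an edge population
#'
#' Permutes all edge columns (including group membership columns) into the
#' requested [edge_ordering()]. The multiset of edges — endpoints, type and
#' per-instance attributes — is preserved; only the storage order changes.
#' Attached range indices are dropped because the permutation invalidates
#' them; rebuild with [build_edge_index()].
#'
#' @param population an [edge_population()].
#' @param ordering an [edge_ordering()] (or a kind string).
#' @param block_size convenience shortcut when `ordering` is given as the
#'   string `"hybrid"`.
#' @return A new, reordered [edge_population()].
#' @export
sort_edges <- function(population, ordering, block_size = NULL) {
  stopifnot(inherits(population, "sonata_edge_population"))
  if (is.character(ordering)) ordering <- edge_ordering(ordering, block_size)
  stopifnot(inherits(ordering, "sonata_ordering"))
  perm <- ordering_permutation(population$source_node_id,
                               population$target_node_id, ordering)
  edge_population(population$name,
                  population$source_population, population$target_population,
                  population$source_node_id[perm],
                  population$target_node_id[perm],
                  population$edge_type_id[perm],
                  population$groups,
                  group_id = population$group_id[perm],
                  group_index = population$group_index[perm],
                  indices = NULL)
}

# --- range indices -----------------------------------------------------------

#' Build a per-node range index over an edge population
#'
#' A range index maps each node id to the ordered list of half-open,
#' 0-based intervals `[start, end)` into the edge arrays at which that node
#' appears as target (`by_target`) or source (`by_source`). Over all nodes
#' the intervals tile `[0, edge_count)` exactly once. After a matching sort
#' ([sort_edges()] target-major for a `by_target` index) every node has at
#' most one interval, which is what makes indexed access fast; the index is
#' valid, if fragmented, for any edge order.
#'
#' @param population an [edge_population()].
#' @param direction `"by_target"` or `"by_source"`.
#' @return An object of class `sonata_range_index`.
#' @export
build_edge_index <- function(population, direction = c("by_target", "by_source")) {
  stopifnot(inherits(population, "sonata_edge_population"))
  direction <- match.arg(direction)
  ids <- if (direction == "by_target") population$target_node_id else population$source_node_id
  ranges <- list()
  if (length(ids)) {
    r <- rle(ids)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths           # 0-based half-open [starts, ends)
    for (k in seq_along(r$values)) {
      key <- as.character(r$values[k])
      ranges[[key]] <- rbind(ranges[[key]], c(starts[k], ends[k]))
    }
  }
  structure(list(direction = direction, ranges = ranges),
            class = "sonata_range_index")
}

#' Attach freshly built range indices to a population
#'
#' @param population an [edge_population()].
#' @param directions which indices to (re)build.
#' @return The population with `$indices` set.
#' @export
index_edges <- function(population, directions = c("by_target", "by_source")) {
  idx <- lapply(directions, function(d) build_edge_index(population, d))
  names(idx) <- directions
  population$indices <- idx
  population
}

#' Query edge indices incident to a node
#'
#' Returns the ascending, 0-based positions in the edge arrays of every edge
#' whose target (or source) is `node_id` — identical to a linear scan of the
#' relevant id column, but served from a [build_edge_index()] when one is
#' available. Unknown nodes yield an empty result.
#'
#' @param population an [edge_population()].
#' @param node_id integer node id.
#' @param direction `"by_target"` or `"by_source"`.
#' @param index optional pre-built [build_edge_index()]; defaults to the
#'   index attached to the population, falling back to building one.
#' @return Integer vector of 0-based edge indices, ascending.
#' @export
query_edges <- function(population, node_id,
                        direction = c("by_target", "by_source"), index = NULL) {
  direction <- match.arg(direction)
  if (is.null(index)) index <- population$indices[[direction]]
  if (is.null(index)) index <- build_edge_index(population, direction)
  if (index$direction != direction) {
    abort("index_direction", "index direction %s does not match request %s",
          index$direction, direction)
  }
  rr <- index$ranges[[as.character(as.integer(node_id))]]
  if (is.null(rr)) return(integer(0))
  out <- unlist(lapply(seq_len(nrow(rr)), function(k) {
    if (rr[k, 2] > rr[k, 1]) seq.int(rr[k, 1], rr[k, 2] - 1L) else integer(0)
  }), use.names = FALSE)
  as.integer(out)
}

# index <-> HDF5 serialization: node_id_to_ranges is (max_id+1) x 2 rows of
# [rstart, rend) into range_to_edge_id, itself R x 2 rows of [start, end)
serialize_range_index <- function(index) {
  keys <- as.integer(names(index$ranges))
  max_id <- if (length(keys)) max(keys) else -1L
  n2r <- matrix(0L, nrow = max_id + 1L, ncol = 2L)
  all_ranges <- matrix(0L, nrow = 0L, ncol = 2L)
  cursor <- 0L
  for (id in 0:max_id) {
    if (max_id < 0L) break
    rr <- index$ranges[[as.character(id)]]
    k <- if (is.null(rr)) 0L else nrow(rr)
    n2r[id + 1L, ] <- c(cursor, cursor + k)
    if (k > 0L) all_ranges <- rbind(all_ranges, rr)
    cursor <- cursor + k
  }
  storage.mode(n2r) <- "integer"
  storage.mode(all_ranges) <- "integer"
  list(node_id_to_ranges = n2r, range_to_edge_id = all_ranges)
}

deserialize_range_index <- function(direction, n2r, r2e) {
  n2r <- matrix(as.integer(n2r), ncol = 2L)
  r2e <- matrix(as.integer(r2e), ncol = 2L)
  ranges <- list()
  for (id in seq_len(nrow(n2r)) - 1L) {
    a <- n2r[id + 1L, 1L]; b <- n2r[id + 1L, 2L]
    if (b > a) {
      ranges[[as.character(id)]] <- r2e[(a + 1L):b, , drop = FALSE]
    }
  }
  structure(list(direction = direction, ranges = ranges),
            class = "sonata_range_index")
}
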