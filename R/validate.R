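#' Structural validation findings
#'
#' Validators never throw on bad data; they return a deterministic,
#' machine-readable table of findings ordered by file then location. An
#' empty table means every check passed. Severity `"error"` marks a
#' violation of the format's structural rules; `"warning"` marks accepted
#' but suspicious content (e.g. spikes tagged sorted-by-time that are not).
#'
#' @name sonata_findings
NULL

finding <- function(severity, code, file, location, message) {
  data.frame(severity = severity, code = code, file = file,
             location = location, message = message, stringsAsFactors = FALSE)
}

no_findings <- function() {
  finding(character(0), character(0), character(0), character(0), character(0))
}

order_findings <- function(f) {
  f[order(f$file, f$location, f$code), , drop = FALSE]
}

RESERVED_MODEL_TYPES <- c("biophysical", "point_neuron", "single compartment", "virtual")

check_type_table <- function(tt, file, out) {
  if (tt$role == "node") {
    if (!"model_type" %in% tt$columns) {
      out <- rbind(out, finding("error", "missing_model_type", file, "node_types",
                                "node type table lacks reserved column model_type"))
    } else {
      for (i in seq_along(tt$ids)) {
        mt <- tt$rows[[i]]$model_type
        if (is.null(mt) || !mt %in% RESERVED_MODEL_TYPES) {
          out <- rbind(out, finding("error", "bad_model_type", file,
                                    sprintf("node_types/%d", tt$ids[i]),
                                    sprintf("model_type %s is not a reserved value",
                                            if (is.null(mt)) "NONE" else dQuote(mt, FALSE))))
        }
      }
    }
  }
  out
}

check_groups <- function(groups, file, where, out) {
  for (g in groups) {
    lens <- vapply(g$attributes, length, integer(1))
    bad <- names(g$attributes)[lens != g$size]
    if (length(bad)) {
      out <- rbind(out, finding("error", "ragged_group", file,
                                sprintf("%s/%d", where, g$group_id),
                                sprintf("attribute column(s) %s have length != group size %d",
                                        paste(bad, collapse = ", "), g$size)))
    }
  }
  out
}

check_membership_findings <- function(group_id, group_index, groups, file, where, out) {
  gids <- vapply(groups, function(g) g$group_id, integer(1))
  sizes <- vapply(groups, function(g) g$size, integer(1))
  k <- match(group_id, gids)
  if (anyNA(k)) {
    out <- rbind(out, finding("error", "unknown_group_id", file, where,
                              sprintf("group_id value(s) %s reference no group",
                                      paste(unique(group_id[is.na(k)]), collapse = ", "))))
  }
  ok <- !is.na(k)
  bad <- ok & (group_index < 0L | group_index >= sizes[k])
  if (any(bad)) {
    out <- rbind(out, finding("error", "group_index_range", file, where,
                              sprintf("group_index out of range for %d instance(s)", sum(bad))))
  }
  out
}

check_range_index <- function(idx, n_edges, ids_column, file, where, out) {
  total <- 0L
  covered <- logical(n_edges)
  ok <- TRUE
  for (key in names(idx$ranges)) {
    rr <- idx$ranges[[key]]
    prev_end <- -1L
    for (r in seq_len(nrow(rr))) {
      a <- rr[r, 1]; b <- rr[r, 2]
      if (b <= a || a < 0L || b > n_edges || a < prev_end) { ok <- FALSE; break }
      span <- (a + 1L):b
      if (any(covered[span])) { ok <- FALSE; break }
      if (any(ids_column[span] != as.integer(key))) { ok <- FALSE; break }
      covered[span] <- TRUE
      total <- total + (b - a)
      prev_end <- b
    }
    if (!ok) break
  }
  if (!ok || total != n_edges) {
    out <- rbind(out, finding("error", "index_incomplete", file,
                              sprintf("%s/indices/%s", where, idx$direction),
                              "range index does not tile [0, edge_count) with matching ids"))
  }
  out
}

#' Validate a circuit's structure
#'
#' Checks, across files: (a) every `node_type_id` / `edge_type_id` resolves
#' to a type-table row; (b) group membership columns are in range; (c)
#' groups are homogeneous (all attribute columns of a group have the
#' group's size); (d) edge endpoints name existing nodes of the declared
#' source/target populations; (e) the node type table carries `model_type`
#' restricted to the reserved values; (f) attached range indices tile
#' `[0, edge_count)` exactly with matching ids.
#'
#' @param x a [circuit()], or a `sonata_config` bundle, or a path to a
#'   config file — non-circuit inputs are loaded first, and unreadable
#'   files become error findings rather than exceptions.
#' @param file label used in the findings' `file` column for in-memory
#'   circuits.
#' @return A findings data frame (see [sonata_findings]); empty when the
#'   circuit is structurally sound.
#' @export
validate_circuit <- function(x, file = "<memory>") {
  if (is.character(x)) {
    x <- tryCatch(load_config(x), error = function(e) e)
    if (inherits(x, "error")) {
      return(finding("error", "unreadable", file, "",
                     conditionMessage(x)))
    }
  }
  if (inherits(x, "sonata_config")) {
    prov <- x$provenance[1] %||% file
    x <- tryCatch(load_circuit(x), error = function(e) e)
    if (inherits(x, "error")) {
      return(finding("error", "unreadable", prov, "", conditionMessage(x)))
    }
    file <- prov
  }
  stopifnot(inherits(x, "sonata_circuit"))
  out <- no_findings()
  out <- check_type_table(x$node_types, file, out)
  for (pop in x$nodes) {
    where <- sprintf("nodes/%s", pop$name)
    dangling <- sort(unique(setdiff(pop$node_type_id, x$node_types$ids)))
    for (d in dangling) {
      out <- rbind(out, finding("error", "dangling_node_type_id", file, where,
                                sprintf("node_type_id %d has no row in the node type table", d)))
    }
    out <- check_membership_findings(pop$group_id, pop$group_index, pop$groups,
                                     file, where, out)
    out <- check_groups(pop$groups, file, where, out)
  }
  for (pop in x$edges) {
    where <- sprintf("edges/%s", pop$name)
    dangling <- sort(unique(setdiff(pop$edge_type_id, x$edge_types$ids)))
    for (d in dangling) {
      out <- rbind(out, finding("error", "dangling_edge_type_id", file, where,
                                sprintf("edge_type_id %d has no row in the edge type table", d)))
    }
    out <- check_membership_findings(pop$group_id, pop$group_index, pop$groups,
                                     file, where, out)
    out <- check_groups(pop$groups, file, where, out)
    for (side in c("source", "target")) {
      pname <- pop[[paste0(side, "_population")]]
      npop <- if (is.na(pname)) NULL else x$nodes[[pname]]
      if (is.null(npop)) {
        out <- rbind(out, finding("error", "unknown_population", file, where,
                                  sprintf("%s population '%s' is not a node population of the circuit",
                                          side, pname)))
      } else {
        ids <- pop[[paste0(side, "_node_id")]]
        bad <- sort(unique(ids[!ids %in% npop$node_id]))
        if (length(bad)) {
          out <- rbind(out, finding("error", "dangling_endpoint", file, where,
                                    sprintf("%s_node_id value(s) %s not present in population '%s'",
                                            side, paste(utils::head(bad, 5), collapse = ", "), pname)))
        }
      }
    }
    for (idx in pop$indices %||% list()) {
      ids_col <- if (idx$direction == "by_target") pop$target_node_id else pop$source_node_id
      out <- check_range_index(idx, length(pop$edge_type_id), ids_col, file, where, out)
    }
  }
  order_findings(out)
}

#' Validate an activity file against a circuit
#'
#' For spike files: node ids must exist in the matching circuit population,
#' timestamps must be non-negative, the two datasets equally long, and a
#' `by_time` sorting tag truthful (violation is a warning). For element
#' reports: the index pointer must be well-formed (strictly increasing from
#' 0 to M), recorded node ids must exist, and the matrix shape must agree
#' with the time block and the mapping.
#'
#' @param path an HDF5 activity file (spikes and/or element report).
#' @param circuit the [circuit()] the activity refers to.
#' @return A findings data frame.
#' @export
validate_activity <- function(path, circuit) {
  stopifnot(inherits(circuit, "sonata_circuit"))
  out <- no_findings()
  ls_df <- tryCatch(rhdf5::h5ls(path), error = function(e) e)
  if (inherits(ls_df, "error")) {
    return(finding("error", "unreadable", path, "", conditionMessage(ls_df)))
  }
  all_node_ids <- function(pname) {
    pop <- circuit$nodes[[pname]]
    if (is.null(pop)) NULL else pop$node_id
  }
  for (pn in h5_children(ls_df, "/spikes", "H5I_GROUP")) {
    base <- sprintf("/spikes/%s", pn)
    ts <- as.numeric(h5_read_vec(path, paste0(base, "/timestamps")))
    ids <- as.integer(h5_read_vec(path, paste0(base, "/node_ids")))
    if (length(ts) != length(ids)) {
      out <- rbind(out, finding("error", "length_mismatch", path, base,
                                "timestamps and node_ids differ in length"))
      next
    }
    if (any(ts < 0)) {
      out <- rbind(out, finding("error", "negative_timestamp", path, base,
                                sprintf("%d spike(s) with negative timestamp", sum(ts < 0))))
    }
    known <- all_node_ids(pn)
    if (is.null(known)) {
      out <- rbind(out, finding("error", "unknown_population", path, base,
                                sprintf("circuit has no node population '%s'", pn)))
    } else {
      bad <- sort(unique(ids[!ids %in% known]))
      if (length(bad)) {
        out <- rbind(out, finding("error", "unknown_node", path, base,
                                  sprintf("spike node_id(s) %s not in population '%s'",
                                          paste(utils::head(bad, 5), collapse = ", "), pn)))
      }
    }
    sorting <- h5_get_attr(path, base, "sorting") %||% "none"
    if (sorting == "by_time" && is.unsorted(ts)) {
      out <- rbind(out, finding("warning", "unsorted_spikes", path, base,
                                "sorting attribute says by_time but timestamps are unsorted"))
    }
  }
  for (pn in h5_children(ls_df, "/report", "H5I_GROUP")) {
    base <- sprintf("/report/%s", pn)
    meta <- tryCatch(read_mapping_h5(path, sub("^/", "", base)), error = function(e) e)
    if (inherits(meta, "error")) {
      out <- rbind(out, finding("error", "mapping_corrupt", path, base,
                                conditionMessage(meta)))
      next
    }
    off <- meta$mapping$offsets
    m <- meta$mapping$n_elements
    if (length(off) != length(meta$mapping$node_ids) + 1L ||
        off[1] != 0L || off[length(off)] != m || any(diff(off) <= 0L)) {
      out <- rbind(out, finding("error", "mapping_corrupt", path, base,
                                "index_pointer is not strictly increasing from 0 to M"))
    }
    dims <- ls_df[ls_df$group == base & ls_df$name == "data", "dim"]
    if (length(dims) == 1L) {
      d <- as.integer(strsplit(dims, " x ")[[1]])
      n_expect <- tryCatch(report_frame_count(meta$tstart, meta$tstop, meta$dt),
                           error = function(e) NA_integer_)
      if (length(d) != 2L || is.na(n_expect) || d[1] != n_expect || d[2] != m) {
        out <- rbind(out, finding("error", "shape_mismatch", path, base,
                                  sprintf("data matrix is %s; expected %s x %d from time block and mapping",
                                          dims, n_expect, m)))
      }
    }
    # report node ids must exist in some circuit population; reports are not
    # keyed by population name, so membership in any population counts
    every_id <- unique(unlist(lapply(circuit$nodes, function(p) p$node_id), use.names = FALSE))
    bad <- sort(unique(meta$mapping$node_ids[!meta$mapping$node_ids %in% every_id]))
    if (length(bad)) {
      out <- rbind(out, finding("error", "unknown_node", path, base,
                                sprintf("report node_id(s) %s not present in the circuit",
                                        paste(utils::head(bad, 5), collapse = ", "))))
    }
  }
  order_findings(out)
}

#' Render findings for humans or machines
#'
#' @param findings a findings data frame.
#' @param json if `TRUE`, one JSON object per line; otherwise aligned text.
#' @return Character vector of lines.
#' @export
format_findings <- function(findings, json = FALSE) {
  if (!nrow(findings)) return(character(0))
  if (json) {
    vapply(seq_len(nrow(findings)), function(i) {
      jsonlite::toJSON(as.list(findings[i, ]), auto_unbox = TRUE)
    }, character(1))
  } else {
    sprintf("%s [%s] %s %s: %s", toupper(findings$severity), findings$code,
            findings$file, findings$location, findings$message)
  }
}
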