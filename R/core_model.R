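#' Node groups
#'
#' A node group is a homogeneous collection of per-instance attributes: every
#' attribute column in the group has the same length, the group's size. A
#' population partitions its nodes across one or more groups, which is what
#' lets hybrid models keep the rich attribute set of compartmental neurons in
#' one group and the lean attribute set of point neurons in another.
#'
#' @param group_id non-negative integer id, unique within the population.
#' @param size number of member instances.
#' @param attributes named list of atomic vectors (integer, double or
#'   character), each of length `size`. May be empty: a group with no
#'   per-instance attributes is legal and common for virtual nodes.
#' @return An object of class `sonata_group`.
#' @export
node_group <- function(group_id, size, attributes = list()) {
  if (!is_count(group_id)) abort("bad_group", "group_id must be a non-negative integer")
  if (!is_count(size)) abort("bad_group", "size must be a non-negative integer")
  if (length(attributes)) {
    if (is.null(names(attributes)) || any(!nzchar(names(attributes)))) {
      abort("bad_group", "attributes must be a named list")
    }
    lens <- vapply(attributes, length, integer(1))
    if (any(lens != size)) {
      abort("ragged_group", "attribute column(s) %s have length != group size %d",
            paste(names(attributes)[lens != size], collapse = ", "), size)
    }
  }
  structure(list(group_id = as.integer(group_id), size = as.integer(size),
                 attributes = attributes),
            class = "sonata_group")
}

#' @rdname node_group
#' @details [edge_group()] is the same structure used for edges.
#' @export
edge_group <- node_group

check_membership <- function(group_id, group_index, groups, what) {
  gids <- vapply(groups, function(g) g$group_id, integer(1))
  if (anyDuplicated(gids)) abort("bad_population", "duplicate group ids in %s", what)
  k <- match(group_id, gids)
  if (anyNA(k)) {
    abort("unknown_group", "%s references group id(s) %s not present", what,
          paste(unique(group_id[is.na(k)]), collapse = ", "))
  }
  sizes <- vapply(groups, function(g) g$size, integer(1))
  bad <- group_index < 0L | group_index >= sizes[k]
  if (any(bad)) {
    abort("group_index_range", "%s: group_index out of range for %d instance(s)",
          what, sum(bad))
  }
  invisible(TRUE)
}

#' Node populations
#'
#' A population is a named, flat collection of nodes stored together; it is
#' the unit modellers mix and match between simulations. Each node carries a
#' `node_type_id` pointing into the node [type_table()], and a
#' (`group_id`, `group_index`) pair locating its per-instance attributes
#' inside one of the population's [node_group()]s.
#'
#' @param name population name (non-empty string).
#' @param node_type_id integer vector, one entry per node.
#' @param groups list of [node_group()] objects.
#' @param group_id,group_index integer vectors parallel to `node_type_id`.
#'   Default: all nodes in the single group, in storage order (requires
#'   exactly one group whose size equals the node count).
#' @param node_id integer vector of unique node ids; defaults to
#'   `0:(n-1)`. Ids are 0-based and need not be contiguous.
#' @return An object of class `sonata_node_population`.
#' @export
node_population <- function(name, node_type_id, groups,
                            group_id = NULL, group_index = NULL,
                            node_id = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("bad_population", "population name must be a non-empty string")
  }
  n <- length(node_type_id)
  node_type_id <- as.integer(node_type_id)
  if (is.null(group_id)) {
    if (length(groups) != 1L || groups[[1]]$size != n) {
      abort("bad_population",
            "group_id may only be omitted for a single group of matching size")
    }
    group_id <- rep(groups[[1]]$group_id, n)
    group_index <- seq_len(n) - 1L
  }
  group_id <- as.integer(group_id)
  group_index <- as.integer(group_index)
  node_id <- if (is.null(node_id)) seq_len(n) - 1L else as.integer(node_id)
  lens <- c(length(node_id), length(node_type_id), length(group_id), length(group_index))
  if (length(unique(lens)) != 1L) {
    abort("bad_population", "node columns of %s have unequal lengths", name)
  }
  if (anyDuplicated(node_id)) abort("bad_population", "duplicate node_id in %s", name)
  groups <- lapply(groups, function(g) {
    if (!inherits(g, "sonata_group")) abort("bad_population", "groups must be sonata_group objects")
    g
  })
  check_membership(group_id, group_index, groups, paste0("population ", name))
  structure(list(name = name, node_id = node_id, node_type_id = node_type_id,
                 group_id = group_id, group_index = group_index, groups = groups),
            class = "sonata_node_population")
}

#' @export
print.sonata_node_population <- function(x, ...) {
  cat(sprintf("SONATA node population '%s': %d node(s), %d group(s), %d type(s)\n",
              x$name, length(x$node_id), length(x$groups),
              length(unique(x$node_type_id))))
  invisible(x)
}

#' Edge populations
#'
#' An edge population holds directed connections (typically synapses) from
#' nodes of one population to nodes of another (possibly the same). Multiple
#' edges between one source/target pair are permitted, and populations are
#' flat — never nested. Like nodes, edges are partitioned into homogeneous
#' attribute groups, so connections onto compartmental targets (synapse
#' location, per-edge weight, ...) and onto point-neuron targets
#' (weight only) can share one population.
#'
#' @param name population name.
#' @param source_population,target_population names of the node populations
#'   the endpoint ids refer to.
#' @param source_node_id,target_node_id,edge_type_id integer vectors, one
#'   entry per edge.
#' @param groups list of [edge_group()]s.
#' @param group_id,group_index integer vectors parallel to the edge columns;
#'   same default rule as [node_population()].
#' @param indices optional named list of range indices (see
#'   [build_edge_index()]) keyed `"by_target"` / `"by_source"`.
#' @return An object of class `sonata_edge_population`.
#' @export
edge_population <- function(name, source_population, target_population,
                            source_node_id, target_node_id, edge_type_id,
                            groups, group_id = NULL, group_index = NULL,
                            indices = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("bad_population", "population name must be a non-empty string")
  }
  n <- length(edge_type_id)
  source_node_id <- as.integer(source_node_id)
  target_node_id <- as.integer(target_node_id)
  edge_type_id <- as.integer(edge_type_id)
  if (is.null(group_id)) {
    if (length(groups) != 1L || groups[[1]]$size != n) {
      abort("bad_population",
            "group_id may only be omitted for a single group of matching size")
    }
    group_id <- rep(groups[[1]]$group_id, n)
    group_index <- seq_len(n) - 1L
  }
  group_id <- as.integer(group_id)
  group_index <- as.integer(group_index)
  lens <- c(length(source_node_id), length(target_node_id), n,
            length(group_id), length(group_index))
  if (length(unique(lens)) != 1L) {
    abort("bad_population", "edge columns of %s have unequal lengths", name)
  }
  check_membership(group_id, group_index, groups, paste0("edge population ", name))
  structure(list(name = name,
                 source_population = source_population,
                 target_population = target_population,
                 source_node_id = source_node_id,
                 target_node_id = target_node_id,
                 edge_type_id = edge_type_id,
                 group_id = group_id, group_index = group_index,
                 groups = groups, indices = indices),
            class = "sonata_edge_population")
}

#' @export
print.sonata_edge_population <- function(x, ...) {
  cat(sprintf("SONATA edge population '%s' (%s -> %s): %d edge(s), %d group(s)\n",
              x$name, x$source_population, x$target_population,
              length(x$edge_type_id), length(x$groups)))
  invisible(x)
}

#' Circuits
#'
#' The circuit object ties together node populations, edge populations and
#' their type tables — everything needed to resolve any node or edge to its
#' full attribute map.
#'
#' @param nodes list of [node_population()]s.
#' @param edges list of [edge_population()]s.
#' @param node_types node [type_table()].
#' @param edge_types edge [type_table()].
#' @return An object of class `sonata_circuit`.
#' @export
circuit <- function(nodes = list(), edges = list(),
                    node_types = type_table("node"),
                    edge_types = type_table("edge")) {
  nodes <- as.list(nodes)
  edges <- as.list(edges)
  names(nodes) <- vapply(nodes, function(p) p$name, character(1))
  if (length(edges)) names(edges) <- vapply(edges, function(p) p$name, character(1))
  if (anyDuplicated(names(nodes))) abort("bad_circuit", "duplicate node population names")
  if (length(edges) && anyDuplicated(names(edges))) abort("bad_circuit", "duplicate edge population names")
  structure(list(nodes = nodes, edges = edges,
                 node_types = node_types, edge_types = edge_types),
            class = "sonata_circuit")
}

#' @export
print.sonata_circuit <- function(x, ...) {
  cat(sprintf("SONATA circuit: %d node population(s), %d edge population(s)\n",
              length(x$nodes), length(x$edges)))
  for (p in x$nodes) {
    cat(sprintf("  nodes/%s: %d node(s)\n", p$name, length(p$node_id)))
  }
  for (p in x$edges) {
    cat(sprintf("  edges/%s: %d edge(s) (%s -> %s)\n", p$name,
                length(p$edge_type_id), p$source_population, p$target_population))
  }
  invisible(x)
}

group_by_id <- function(pop, gid) {
  gids <- vapply(pop$groups, function(g) g$group_id, integer(1))
  pop$groups[[match(gid, gids)]]
}

# overlay: start from the type row, let instance-level values shadow
# same-named type-level values; provenance records where each value came from
overlay_attributes <- function(type_row, group, index0) {
  attrs <- type_row
  prov <- rep("type", length(attrs))
  names(prov) <- names(attrs)
  for (an in names(group$attributes)) {
    attrs[[an]] <- group$attributes[[an]][[index0 + 1L]]
    prov[[an]] <- "instance"
  }
  list(attributes = attrs, provenance = prov)
}

#' Resolve a node to its full attribute map
#'
#' Combines the node's type-table row with its group's per-instance
#' attributes. Instance-level values shadow type-level values of the same
#' name; `NONE`-valued type entries are absent from the result. The
#' `provenance` field records, per attribute, whether the value came from
#' the type table (`"type"`) or the node group (`"instance"`).
#'
#' @param circuit a [circuit()].
#' @param population name of the node population.
#' @param node_id integer node id (0-based).
#' @return A `sonata_resolved_node`: list with `population`, `node_id`,
#'   `node_type_id`, `attributes` (named list) and `provenance`.
#' @examples
#' tt <- type_table("node", 0L, list(list(model_type = "point_neuron")))
#' pop <- node_population("P", 0L, list(node_group(0L, 1L)))
#' resolve_node(circuit(list(pop), node_types = tt), "P", 0L)$attributes
#' @export
resolve_node <- function(circuit, population, node_id) {
  stopifnot(inherits(circuit, "sonata_circuit"))
  pop <- circuit$nodes[[population]]
  if (is.null(pop)) abort("unknown_population", "no node population named '%s'", population)
  k <- match(as.integer(node_id), pop$node_id)
  if (is.na(k)) abort("unknown_node", "node_id %d not in population '%s'", node_id, population)
  trow <- type_row(circuit$node_types, pop$node_type_id[k])
  ov <- overlay_attributes(trow, group_by_id(pop, pop$group_id[k]), pop$group_index[k])
  structure(list(population = population,
                 node_id = pop$node_id[k],
                 node_type_id = pop$node_type_id[k],
                 attributes = ov$attributes,
                 provenance = ov$provenance),
            class = "sonata_resolved_node")
}

#' Resolve an edge to its full attribute map
#'
#' Same overlay semantics as [resolve_node()], applied to the edge type
#' table and edge groups, plus the source/target endpoint ids and their node
#' population names.
#'
#' @param circuit a [circuit()].
#' @param population name of the edge population.
#' @param edge_index 0-based position in the edge arrays (edges have no ids
#'   of their own; they are addressed by storage index, which is also what
#'   [query_edges()] returns).
#' @return A `sonata_resolved_edge`.
#' @export
resolve_edge <- function(circuit, population, edge_index) {
  stopifnot(inherits(circuit, "sonata_circuit"))
  pop <- circuit$edges[[population]]
  if (is.null(pop)) abort("unknown_population", "no edge population named '%s'", population)
  n <- length(pop$edge_type_id)
  edge_index <- as.integer(edge_index)
  if (length(edge_index) != 1L || is.na(edge_index) || edge_index < 0L || edge_index >= n) {
    abort("index_range", "edge_index %s out of range [0, %d)", edge_index, n)
  }
  k <- edge_index + 1L
  trow <- type_row(circuit$edge_types, pop$edge_type_id[k])
  ov <- overlay_attributes(trow, group_by_id(pop, pop$group_id[k]), pop$group_index[k])
  structure(list(population = population,
                 edge_index = edge_index,
                 source_population = pop$source_population,
                 target_population = pop$target_population,
                 source_node_id = pop$source_node_id[k],
                 target_node_id = pop$target_node_id[k],
                 edge_type_id = pop$edge_type_id[k],
                 attributes = ov$attributes,
                 provenance = ov$provenance),
            class = "sonata_resolved_edge")
}

#' Evaluate a node-set expression
#'
#' Node sets name the subsets of nodes that act as simulation targets or
#' report/stimulus scopes. An expression is a named list of predicates over
#' resolved attributes: each key must match (conjunction across keys), and a
#' vector value is a set of allowed alternatives (disjunction within a key).
#' The reserved keys `population` and `node_id` filter on those identities
#' rather than on attributes. The empty expression selects every node.
#'
#' @param circuit a [circuit()].
#' @param expression named list (possibly empty). Values are atomic scalars
#'   or vectors.
#' @return `data.frame(population, node_id)` sorted by population name then
#'   node id.
#' @examples
#' # all biophysical nodes:  evaluate_node_set(cir, list(model_type = "biophysical"))
#' @export
evaluate_node_set <- function(circuit, expression) {
  stopifnot(inherits(circuit, "sonata_circuit"))
  if (!is.list(expression)) abort("bad_node_set", "expression must be a named list")
  if (length(expression) && (is.null(names(expression)) || any(!nzchar(names(expression))))) {
    abort("bad_node_set", "every predicate key must be named")
  }
  keys <- names(expression)
  pops <- names(circuit$nodes)
  if ("population" %in% keys) {
    want <- as.character(expression$population)
    unknown <- setdiff(want, pops)
    if (length(unknown)) {
      abort("unknown_population", "node set names unknown population(s): %s",
            paste(unknown, collapse = ", "))
    }
    pops <- intersect(pops, want)
  }
  attr_keys <- setdiff(keys, c("population", "node_id"))
  out_pop <- character(0); out_id <- integer(0)
  for (pn in sort(pops)) {
    pop <- circuit$nodes[[pn]]
    keep <- rep(TRUE, length(pop$node_id))
    if ("node_id" %in% keys) keep <- keep & pop$node_id %in% as.integer(expression$node_id)
    if (length(attr_keys)) {
      for (i in which(keep)) {
        res <- resolve_node(circuit, pn, pop$node_id[i])
        for (ak in attr_keys) {
          v <- res$attributes[[ak]]
          allowed <- expression[[ak]]
          if (is.null(v) || !any(vapply(allowed, function(a) isTRUE(a == v), logical(1)))) {
            keep[i] <- FALSE
            break
          }
        }
      }
    }
    ids <- sort(pop$node_id[keep])
    out_pop <- c(out_pop, rep(pn, length(ids)))
    out_id <- c(out_id, ids)
  }
  data.frame(population = out_pop, node_id = out_id, stringsAsFactors = FALSE)
}
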