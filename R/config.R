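#' Configuration hierarchy
#'
#' Three JSON files tie a model together: the *primary* config points at a
#' *circuit* config (where the node/edge files live) and a *simulation*
#' config (run parameters, node sets, inputs, outputs, reports). Each file
#' may open with a `manifest` block defining path variables (`$VAR` or
#' `${VAR}`) substituted throughout that file; relative paths are resolved
#' against the file's own directory, so a config tree can be moved wholesale.
#' Splitting circuit from simulation is what allows one circuit to be reused
#' under many simulation setups and vice versa.
#'
#' @name sonata_config
NULL

VAR_RE <- "\\$(\\{[A-Za-z_][A-Za-z0-9_]*\\}|[A-Za-z_][A-Za-z0-9_]*)"

substitute_vars <- function(s, vars) {
  m <- gregexpr(VAR_RE, s)
  regmatches(s, m) <- lapply(regmatches(s, m), function(hits) {
    vapply(hits, function(h) {
      name <- sub("^\\$\\{?([A-Za-z_][A-Za-z0-9_]*)\\}?$", "\\1", h)
      v <- vars[[name]]
      if (is.null(v)) abort("undefined_variable", "undefined manifest variable: %s", name)
      v
    }, character(1))
  })
  s
}

# resolve manifest entries against each other (DFS with cycle detection)
resolve_manifest_vars <- function(manifest) {
  resolved <- list()
  state <- new.env(parent = emptyenv())
  visit <- function(name, stack) {
    if (name %in% stack) {
      abort("manifest_cycle", "manifest substitution cycle: %s",
            paste(c(stack, name), collapse = " -> "))
    }
    if (!is.null(resolved[[name]])) return(resolved[[name]])
    raw <- manifest[[name]]
    if (is.null(raw)) abort("undefined_variable", "undefined manifest variable: %s", name)
    hits <- regmatches(raw, gregexpr(VAR_RE, raw))[[1]]
    for (h in hits) {
      dep <- sub("^\\$\\{?([A-Za-z_][A-Za-z0-9_]*)\\}?$", "\\1", h)
      resolved[[dep]] <<- visit(dep, c(stack, name))
    }
    val <- substitute_vars(raw, resolved)
    resolved[[name]] <<- val
    val
  }
  for (name in names(manifest)) resolved[[name]] <- visit(name, character(0))
  resolved
}

absolutize <- function(path, base_dir) {
  if (grepl("^(/|[A-Za-z]:[\\\\/])", path)) path
  else normalizePath(file.path(base_dir, path), mustWork = FALSE)
}

#' Resolve manifest variables in path values
#'
#' Substitutes every `$NAME` / `${NAME}` occurrence (recursively, manifest
#' entries may reference each other) and joins relative results to
#' `base_dir`. Undefined variables and substitution cycles are errors.
#'
#' @param manifest named list of variable definitions.
#' @param values character vector of raw path values.
#' @param base_dir directory against which relative results are resolved.
#' @return Character vector of absolute paths.
#' @examples
#' resolve_manifest(list(BASE = "/data"), "$BASE/nodes.h5", ".")
#' @export
resolve_manifest <- function(manifest, values, base_dir = ".") {
  vars <- resolve_manifest_vars(as.list(manifest))
  vapply(values, function(v) absolutize(substitute_vars(v, vars), base_dir),
         character(1), USE.NAMES = FALSE)
}

is_path_key <- function(key) {
  grepl("_(file|dir)$", key) || key %in% c("network", "simulation", "output_dir")
}

# walk a parsed JSON tree: substitute vars everywhere, absolutize values of
# path-like keys; unknown keys ride along untouched (forward compatibility)
resolve_tree <- function(x, vars, base_dir, key = "") {
  if (is.character(x) && length(x) == 1L) {
    s <- substitute_vars(x, vars)
    if (is_path_key(key)) s <- absolutize(s, base_dir)
    return(s)
  }
  if (is.list(x)) {
    nm <- names(x)
    for (i in seq_along(x)) {
      child_key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else key
      # every value inside "components" or "manifest" is a path
      if (identical(key, "components")) child_key <- "components_dir"
      x[[i]] <- resolve_tree(x[[i]], vars, base_dir, child_key)
    }
  }
  x
}

config_kind <- function(raw) {
  is_str <- function(v) is.character(v) && length(v) == 1L
  if (!is.null(raw$network) && is_str(raw$network) &&
      !is.null(raw$simulation) && is_str(raw$simulation)) return("primary")
  if (!is.null(raw$networks) || !is.null(raw$components)) return("circuit")
  if (!is.null(raw$run)) return("simulation")
  abort("unknown_config", "cannot auto-detect config kind from keys: %s",
        paste(names(raw), collapse = ", "))
}

resolve_config_file <- function(path) {
  if (!file.exists(path)) abort("io", "no such config file: %s", path)
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) abort("bad_json", "cannot parse %s: %s",
                                            path, conditionMessage(e)))
  base_dir <- dirname(normalizePath(path, mustWork = TRUE))
  vars <- resolve_manifest_vars(as.list(raw$manifest %||% list()))
  resolved <- resolve_tree(raw, vars, base_dir)
  resolved$manifest <- NULL
  list(raw = raw, resolved = resolved, path = normalizePath(path), kind = config_kind(raw))
}

normalize_run <- function(run) {
  if (is.null(run)) abort("missing_key", "simulation config lacks 'run'")
  # accept either 'tstop' or 'duration' for the total time; store as tstop
  if (is.null(run$tstop) && !is.null(run$duration)) {
    run$tstop <- run$duration
    run$duration <- NULL
  }
  if (is.null(run$tstop) || is.null(run$dt)) {
    abort("missing_key", "run must define tstop (or duration) and dt")
  }
  run$tstop <- as.numeric(run$tstop)
  run$dt <- as.numeric(run$dt)
  if (run$tstop <= 0) abort("bad_run", "tstop must be > 0")
  if (run$dt <= 0) abort("bad_run", "dt must be > 0")
  run
}

validate_simulation_config <- function(sim) {
  sim$run <- normalize_run(sim$run)
  set_names <- names(sim$node_sets %||% list())
  for (rn in names(sim$reports %||% list())) {
    cells <- sim$reports[[rn]]$cells
    if (is.character(cells) && length(cells) == 1L && !cells %in% set_names) {
      abort("dangling_node_set", "report '%s' references undefined node set '%s'",
            rn, cells)
    }
  }
  for (inm in names(sim$inputs %||% list())) {
    ns <- sim$inputs[[inm]]$node_set
    if (is.character(ns) && length(ns) == 1L && length(set_names) && !ns %in% set_names) {
      abort("dangling_node_set", "input '%s' references undefined node set '%s'", inm, ns)
    }
  }
  sim
}

#' Load a configuration bundle
#'
#' `path` may be a primary config (keys `network` and `simulation` naming
#' the two child files) or a circuit/simulation config on its own; the kind
#' is auto-detected from the keys. Each file's own manifest is applied to
#' that file's values, paths are made absolute relative to each file's
#' directory, and the simulation invariants (`tstop > 0`, `dt > 0`, node-set
#' references defined) are checked. Alternatively supply `circuit` and
#' `simulation` paths directly.
#'
#' @param path a config file (primary, circuit, or simulation).
#' @param circuit,simulation explicit paths, as an alternative to a primary
#'   config.
#' @return An object of class `sonata_config`: list with `circuit`,
#'   `simulation` (resolved key/value trees, or `NULL` for a half not
#'   given), `raw` (unresolved file contents, reused by [write_config()])
#'   and `provenance` (source file paths).
#' @export
load_config <- function(path = NULL, circuit = NULL, simulation = NULL) {
  prov <- character(0)
  raw <- list(circuit = NULL, simulation = NULL)
  halves <- list(circuit = NULL, simulation = NULL)
  take <- function(file) {
    cf <- resolve_config_file(file)
    prov <<- c(prov, cf$path)
    if (cf$kind == "primary") {
      take(cf$resolved$network)
      take(cf$resolved$simulation)
    } else if (cf$kind == "circuit") {
      halves$circuit <<- cf$resolved
      raw$circuit <<- cf$raw
    } else {
      halves$simulation <<- cf$resolved
      raw$simulation <<- cf$raw
    }
  }
  if (!is.null(path)) take(path)
  if (!is.null(circuit)) take(circuit)
  if (!is.null(simulation)) take(simulation)
  if (is.null(halves$circuit) && is.null(halves$simulation)) {
    abort("missing_key", "no circuit or simulation config given")
  }
  if (!is.null(halves$simulation)) {
    halves$simulation <- validate_simulation_config(halves$simulation)
  }
  structure(list(circuit = halves$circuit, simulation = halves$simulation,
                 raw = raw, provenance = prov),
            class = "sonata_config")
}

#' @export
print.sonata_config <- function(x, ...) {
  cat("SONATA config bundle\n")
  if (!is.null(x$simulation)) {
    cat(sprintf("  run: tstop=%g ms, dt=%g ms (%d timesteps)\n",
                x$simulation$run$tstop, x$simulation$run$dt, n_timesteps(x)))
  }
  for (p in x$provenance) cat(sprintf("  from: %s\n", p))
  invisible(x)
}

#' Number of timesteps of a simulation config
#'
#' @param bundle a [load_config()] bundle.
#' @return `round(tstop / dt)` as an integer.
#' @export
n_timesteps <- function(bundle) {
  stopifnot(inherits(bundle, "sonata_config"))
  run <- bundle$simulation$run
  if (is.null(run)) abort("missing_key", "bundle has no simulation half")
  as.integer(round(run$tstop / run$dt))
}

#' Write a configuration bundle as three JSON files
#'
#' Writes `circuit_config.json`, `simulation_config.json` and a primary
#' `config.json` pointing at them. The unresolved file contents (including
#' manifest blocks) are reused when the bundle was loaded from disk, so
#' variables survive a round trip; bundles built programmatically are
#' serialized from their resolved trees.
#'
#' @param bundle a `sonata_config`.
#' @param directory destination directory (created if needed).
#' @return Path of the primary config, invisibly.
#' @export
write_config <- function(bundle, directory) {
  stopifnot(inherits(bundle, "sonata_config"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  dump_json <- function(x, file) {
    write_atomically(file, function(tmp) {
      jsonlite::write_json(x, tmp, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
    })
  }
  cpath <- file.path(directory, "circuit_config.json")
  spath <- file.path(directory, "simulation_config.json")
  dump_json(bundle$raw$circuit %||% bundle$circuit %||% list(networks = list()), cpath)
  dump_json(bundle$raw$simulation %||% bundle$simulation %||%
              list(run = list(tstop = 0, dt = 0)), spath)
  ppath <- file.path(directory, "config.json")
  dump_json(list(network = "circuit_config.json",
                 simulation = "simulation_config.json"), ppath)
  invisible(ppath)
}

#' Load the circuit named by a config bundle
#'
#' Reads every nodes/edges entry of the bundle's circuit half, together
#' with the referenced type tables, into one [circuit()].
#'
#' @param bundle a `sonata_config` with a circuit half.
#' @return A [circuit()].
#' @export
load_circuit <- function(bundle) {
  stopifnot(inherits(bundle, "sonata_config"))
  cc <- bundle$circuit
  if (is.null(cc)) abort("missing_key", "bundle has no circuit half")
  nodes <- list(); edges <- list()
  node_types <- type_table("node"); edge_types <- type_table("edge")
  for (entry in cc$networks$nodes %||% list()) {
    nodes <- c(nodes, read_nodes(entry$nodes_file))
    if (!is.null(entry$node_types_file)) {
      node_types <- read_type_table(entry$node_types_file, "node")
    }
  }
  for (entry in cc$networks$edges %||% list()) {
    edges <- c(edges, read_edges(entry$edges_file))
    if (!is.null(entry$edge_types_file)) {
      edge_types <- read_type_table(entry$edge_types_file, "edge")
    }
  }
  circuit(nodes, edges, node_types, edge_types)
}
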