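#' Synthetic circuit specifications
#'
#' A declarative recipe for a random circuit: node populations built from
#' type-table rows with counts, and probabilistic connection rules between
#' (filtered) populations. One seed fixes every random draw, so a spec is a
#' reproducible fixture: everything the generator emits round-trips through
#' the I/O layer and validates cleanly.
#'
#' @param populations list of population recipes, each a list with `name`
#'   and `members` — a list of `(node_type_id, count)` pairs (as
#'   `list(type = , count = )`). Per-population node groups are laid out
#'   automatically: one group per distinct attribute profile.
#' @param connections list of connection rules, each a list with `source`,
#'   `target` (population names), `p` (connection probability per ordered
#'   node pair), `nsyn_range` (integer `c(lo, hi)`, synapses drawn uniformly
#'   per connected pair), `edge_type_id`, and `rich` (logical: `TRUE` stores
#'   per-edge weight plus afferent section id/position — the attribute set
#'   of connections onto compartmental targets; `FALSE` stores weight only).
#' @param node_types,edge_types the [type_table()]s the ids refer to.
#' @param seed integer seed fixing all randomness.
#' @return An object of class `sonata_circuit_spec`.
#' @export
circuit_spec <- function(populations, connections, node_types, edge_types, seed = 1L) {
  for (p in populations) {
    stopifnot(is.character(p$name), length(p$members) >= 1L)
    for (m in p$members) {
      if (!is_count(m$count)) abort("bad_spec", "population counts must be >= 0")
    }
  }
  for (cn in connections) {
    if (!is.numeric(cn$p) || cn$p < 0 || cn$p > 1) {
      abort("bad_spec", "connection probability must lie in [0, 1]")
    }
  }
  structure(list(populations = populations, connections = connections,
                 node_types = node_types, edge_types = edge_types,
                 seed = as.integer(seed)),
            class = "sonata_circuit_spec")
}

# positions are generic spatial coordinates in micrometres; a placeholder
# for real soma positions, which come from actual model data
random_positions <- function(n, radius = 400) {
  list(x = stats::runif(n, -radius, radius),
       y = stats::runif(n, -radius, radius),
       z = stats::runif(n, -radius, radius))
}

#' Generate a circuit from a spec
#'
#' Node counts are honoured exactly. For each connection rule, every
#' ordered (source, target) node pair is connected independently with
#' probability `p`; a connected pair receives `nsyn` edges, `nsyn` uniform
#' on `nsyn_range`. Rich edges draw `syn_weight` from a log-normal
#' (median ~1e-4 conductance units), `afferent_section_id` uniform on
#' 0..9 and `afferent_section_pos` uniform on `[0, 1)`; lean edges draw
#' `syn_weight` only. All draws come from one RNG stream seeded by the
#' spec, so generation is deterministic.
#'
#' @param spec a [circuit_spec()].
#' @return A [circuit()] whose nodes carry x/y/z positions (simulated
#'   populations) and whose edges are partitioned into a rich and a lean
#'   group as the rules dictate.
#' @export
generate_circuit <- function(spec) {
  stopifnot(inherits(spec, "sonata_circuit_spec"))
  with_rng(spec$seed, {
    node_pops <- lapply(spec$populations, function(prec) {
      counts <- vapply(prec$members, function(m) as.integer(m$count), integer(1))
      types <- vapply(prec$members, function(m) as.integer(m$type), integer(1))
      n <- sum(counts)
      ntid <- rep(types, counts)
      virtual <- isTRUE(prec$virtual)
      if (virtual || n == 0L) {
        groups <- list(node_group(0L, n))
      } else {
        groups <- list(node_group(0L, n, random_positions(n)))
      }
      node_population(prec$name, ntid, groups,
                      group_id = rep(0L, n), group_index = seq_len(n) - 1L)
    })
    names(node_pops) <- vapply(node_pops, function(p) p$name, character(1))

    edge_pops <- list()
    conns_by_pop <- split(spec$connections,
                          vapply(spec$connections, function(cn)
                            paste0(cn$source, "_to_", cn$target), character(1)))
    for (pop_name in names(conns_by_pop)) {
      rules <- conns_by_pop[[pop_name]]
      src_pop <- node_pops[[rules[[1]]$source]]
      tgt_pop <- node_pops[[rules[[1]]$target]]
      if (is.null(src_pop) || is.null(tgt_pop)) {
        abort("bad_spec", "connection rule references unknown population")
      }
      src <- integer(0); tgt <- integer(0); etid <- integer(0); rich <- logical(0)
      for (rule in rules) {
        n_s <- length(src_pop$node_id); n_t <- length(tgt_pop$node_id)
        if (n_s == 0L || n_t == 0L || rule$p == 0) next
        # vectorized Bernoulli over the n_s x n_t ordered pairs
        hits <- which(stats::runif(n_s * n_t) < rule$p) - 1L
        if (!length(hits)) next
        s_idx <- hits %% n_s + 1L
        t_idx <- hits %/% n_s + 1L
        nr <- rule$nsyn_range %||% c(1L, 1L)
        nsyn <- if (nr[1] == nr[2]) rep(nr[1], length(hits)) else
          sample(seq.int(nr[1], nr[2]), length(hits), replace = TRUE)
        src <- c(src, rep(src_pop$node_id[s_idx], nsyn))
        tgt <- c(tgt, rep(tgt_pop$node_id[t_idx], nsyn))
        etid <- c(etid, rep(as.integer(rule$edge_type_id), sum(nsyn)))
        rich <- c(rich, rep(isTRUE(rule$rich), sum(nsyn)))
      }
      n_e <- length(src)
      n_rich <- sum(rich); n_lean <- n_e - n_rich
      groups <- list()
      if (n_rich > 0L || n_lean == 0L) {
        groups <- c(groups, list(edge_group(0L, n_rich, if (n_rich) list(
          syn_weight = stats::rlnorm(n_rich, meanlog = log(1e-4), sdlog = 0.5),
          afferent_section_id = as.integer(sample(0:9, n_rich, replace = TRUE)),
          afferent_section_pos = stats::runif(n_rich)) else list())))
      }
      if (n_lean > 0L) {
        groups <- c(groups, list(edge_group(1L, n_lean, list(
          syn_weight = stats::rlnorm(n_lean, meanlog = log(1e-4), sdlog = 0.5)))))
      }
      gid <- ifelse(rich, 0L, 1L)
      gidx <- integer(n_e)
      gidx[rich] <- seq_len(n_rich) - 1L
      gidx[!rich] <- seq_len(n_lean) - 1L
      edge_pops[[pop_name]] <- edge_population(
        pop_name, rules[[1]]$source, rules[[1]]$target,
        src, tgt, etid, groups, group_id = gid, group_index = gidx)
    }
    circuit(node_pops, edge_pops, spec$node_types, spec$edge_types)
  })
}

#' Default hybrid type tables
#'
#' The stock type tables used by [l4_like_spec()]: three biophysical node
#' types, two point-neuron types and one virtual input type; four edge
#' types (excitatory/inhibitory onto compartmental and point targets, all
#' with a 2.0 ms delay).
#'
#' @return A list with `node_types` and `edge_types` [type_table()]s.
#' @export
default_type_tables <- function() {
  node_types <- type_table("node",
    ids = 0:5,
    rows = list(
      list(model_type = "biophysical", model_template = "ctdb:Biophys1.hoc",
           morphology = "scnn1a_m.swc", dynamics_params = "472363762_fit.json"),
      list(model_type = "biophysical", model_template = "ctdb:Biophys1.hoc",
           morphology = "rorb_m.swc", dynamics_params = "473863510_fit.json"),
      list(model_type = "biophysical", model_template = "nml:PV1.nml.xml",
           morphology = "pv1_m.swc"),
      list(model_type = "point_neuron", model_template = "nrn:IntFire1",
           dynamics_params = "if1_exc.json"),
      list(model_type = "point_neuron", model_template = "nrn:IntFire1",
           dynamics_params = "if1_inh.json"),
      list(model_type = "virtual")),
    columns = c("model_type", "model_template", "morphology", "dynamics_params"))
  edge_types <- type_table("edge",
    ids = 0:3,
    rows = list(
      list(model_template = "exp2syn", dynamics_params = "biophys_exc.json", delay = 2.0),
      list(model_template = "exp2syn", dynamics_params = "biophys_inh.json", delay = 2.0),
      list(dynamics_params = "Instantaneous_exc.json", delay = 2.0),
      list(dynamics_params = "Instantaneous_inh.json", delay = 2.0)),
    columns = c("model_template", "dynamics_params", "delay"))
  list(node_types = node_types, edge_types = edge_types)
}

#' Spec for a scaled hybrid cortical-layer circuit
#'
#' Emulates the structure of a published hybrid layer-4 model: a core of
#' 10,000 biophysically detailed neurons, an annulus of 35,000 point
#' neurons guarding against boundary artifacts, and ~10,000 virtual nodes
#' supplying input spikes — scaled by `scale` with ceiling rounding.
#' Connection probabilities (0.02 recurrent, 0.018 feedforward) reproduce
#' the model's edge counts in expectation at full scale (~40M recurrent,
#' ~8M feedforward); connections onto biophysical targets use the rich edge
#' group, onto point targets the weight-only group.
#'
#' @param scale fraction of the full model size, in `(0, 1]`.
#' @param seed seed stored in the spec.
#' @return A [circuit_spec()].
#' @export
l4_like_spec <- function(scale = 1, seed = 1L) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0 || scale > 1) {
    abort("bad_spec", "scale must lie in (0, 1]")
  }
  n_bio <- as.integer(ceiling(scale * 10000))
  n_point <- as.integer(ceiling(scale * 35000))
  n_virt <- as.integer(ceiling(scale * 10000))
  tts <- default_type_tables()
  populations <- list(
    list(name = "core_biophysical",
         members = list(list(type = 0L, count = ceiling(n_bio * 0.4)),
                        list(type = 1L, count = ceiling(n_bio * 0.35)),
                        list(type = 2L, count = n_bio - ceiling(n_bio * 0.4) - ceiling(n_bio * 0.35)))),
    list(name = "annulus_point",
         members = list(list(type = 3L, count = ceiling(n_point * 0.8)),
                        list(type = 4L, count = n_point - ceiling(n_point * 0.8)))),
    list(name = "inputs", virtual = TRUE,
         members = list(list(type = 5L, count = n_virt))))
  connections <- list(
    list(source = "core_biophysical", target = "core_biophysical",
         p = 0.02, nsyn_range = c(1L, 3L), edge_type_id = 0L, rich = TRUE),
    list(source = "annulus_point", target = "core_biophysical",
         p = 0.02, nsyn_range = c(1L, 1L), edge_type_id = 1L, rich = TRUE),
    list(source = "core_biophysical", target = "annulus_point",
         p = 0.02, nsyn_range = c(1L, 1L), edge_type_id = 2L, rich = FALSE),
    list(source = "inputs", target = "core_biophysical",
         p = 0.018, nsyn_range = c(1L, 1L), edge_type_id = 0L, rich = TRUE),
    list(source = "inputs", target = "annulus_point",
         p = 0.018, nsyn_range = c(1L, 1L), edge_type_id = 2L, rich = FALSE))
  circuit_spec(populations, connections, tts$node_types, tts$edge_types, seed)
}

#' Generate independent homogeneous Poisson spike trains
#'
#' Each node fires as an independent Poisson process at `rate_hz` over
#' `[0, duration_ms)`; event counts are Poisson with mean
#' `rate_hz * duration_ms / 1000` and times uniform on the window. The
#' report is returned sorted by time (the natural order of merged trains).
#'
#' @param node_ids integer ids of the firing (typically virtual) nodes.
#' @param rate_hz firing rate in spikes/s, `>= 0`.
#' @param duration_ms window length in ms, `>= 0`.
#' @param seed RNG seed.
#' @param population population name stored in the report.
#' @return A [spike_report()] with `sorting = "by_time"`.
#' @export
generate_poisson_spikes <- function(node_ids, rate_hz, duration_ms, seed = 1L,
                                    population = "inputs") {
  if (!is.numeric(rate_hz) || rate_hz < 0) abort("bad_spec", "rate_hz must be >= 0")
  if (!is.numeric(duration_ms) || duration_ms < 0) abort("bad_spec", "duration_ms must be >= 0")
  with_rng(seed, {
    node_ids <- as.integer(node_ids)
    counts <- stats::rpois(length(node_ids), rate_hz * duration_ms / 1000)
    ids <- rep(node_ids, counts)
    ts <- stats::runif(sum(counts), 0, duration_ms)
    o <- order(ts, ids)
    spike_report(population, ids[o], ts[o], sorting = "by_time")
  })
}

#' Trace models for synthetic element reports
#'
#' @param value constant level (e.g. -65 mV resting potential).
#' @return A model descriptor for [generate_report_traces()].
#' @export
trace_constant <- function(value) {
  structure(list(kind = "constant", value = as.numeric(value)), class = "sonata_trace_model")
}

#' @rdname trace_constant
#' @param amplitude,freq_hz amplitude and frequency shared by all traces;
#'   each trace gets an independent uniform phase.
#' @export
trace_sinusoid <- function(amplitude = 10, freq_hz = 10) {
  structure(list(kind = "sinusoid", amplitude = as.numeric(amplitude),
                 freq_hz = as.numeric(freq_hz)), class = "sonata_trace_model")
}

#' @rdname trace_constant
#' @param rho,sigma AR(1) coefficient and innovation standard deviation.
#' @export
trace_ar1 <- function(rho = 0.95, sigma = 1) {
  structure(list(kind = "ar1", rho = as.numeric(rho), sigma = as.numeric(sigma)),
            class = "sonata_trace_model")
}

#' Generate a synthetic element report
#'
#' Fills the full N x M matrix from a [trace_constant()],
#' [trace_sinusoid()] or [trace_ar1()] model, deterministically for a given
#' seed, and returns it as an in-memory report (write it with
#' [create_element_report()] + [append_frames()], or use
#' [write_element_report()] to do both).
#'
#' @param mapping a [build_mapping()].
#' @param tstart,tstop,dt time block (ms).
#' @param model a trace model descriptor.
#' @param seed RNG seed.
#' @param variable,units metadata.
#' @return A `sonata_element_report` (see [read_element_report()]).
#' @export
generate_report_traces <- function(mapping, tstart, tstop, dt,
                                   model = trace_constant(-65), seed = 1L,
                                   variable = "v", units = "mV") {
  stopifnot(inherits(mapping, "sonata_element_mapping"),
            inherits(model, "sonata_trace_model"))
  n <- report_frame_count(tstart, tstop, dt)
  m <- mapping$n_elements
  data <- with_rng(seed, switch(model$kind,
    constant = matrix(model$value, nrow = n, ncol = m),
    sinusoid = {
      t_s <- (tstart + (seq_len(n) - 1L) * dt) / 1000
      phase <- stats::runif(m, 0, 2 * pi)
      vapply(seq_len(m), function(j)
        model$amplitude * sin(2 * pi * model$freq_hz * t_s + phase[j]),
        numeric(n))
    },
    ar1 = {
      out <- matrix(0, nrow = n, ncol = m)
      eps <- matrix(stats::rnorm(n * m, sd = model$sigma), nrow = n)
      out[1, ] <- eps[1, ]
      if (n > 1) for (r in 2:n) out[r, ] <- model$rho * out[r - 1, ] + eps[r, ]
      out
    }))
  data <- matrix(data, nrow = n, ncol = m)
  structure(list(mapping = mapping, tstart = tstart, tstop = tstop, dt = dt,
                 data = data, variable = variable, units = units),
            class = "sonata_element_report")
}

#' Write an in-memory element report to HDF5
#'
#' Convenience wrapper: creates the file and appends all frames in blocks.
#'
#' @param report a `sonata_element_report`.
#' @param path destination file.
#' @param chunk_shape,population passed to [create_element_report()].
#' @param block_rows frames per append.
#' @return `path`, invisibly.
#' @export
write_element_report <- function(report, path, chunk_shape = NULL,
                                 population = "report", block_rows = 256L) {
  h <- create_element_report(path, report$mapping, report$tstart, report$tstop,
                             report$dt, chunk_shape = chunk_shape,
                             population = population,
                             variable = report$variable, units = report$units)
  n <- nrow(report$data)
  r <- 0L
  while (r < n) {
    k <- min(block_rows, n - r)
    append_frames(h, report$data[r + seq_len(k), , drop = FALSE])
    r <- r + k
  }
  invisible(path)
}

#' Write a complete synthetic bundle to a directory
#'
#' Generates a circuit from `spec`, writes nodes/edges/type tables, the
#' three config files, Poisson input spikes for the virtual population and
#' a constant-model element report over the first biophysical nodes — a
#' self-contained fixture exercising every file kind.
#'
#' @param spec a [circuit_spec()].
#' @param directory destination directory.
#' @param rate_hz,duration_ms,dt input spike rate and simulated window.
#' @param n_report_nodes how many nodes to include in the element report.
#' @return The generated [circuit()], invisibly; files land in `directory`.
#' @export
write_synth_bundle <- function(spec, directory, rate_hz = 10, duration_ms = 1000,
                               dt = 0.1, n_report_nodes = 10L) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cir <- generate_circuit(spec)
  write_nodes(cir$nodes, file.path(directory, "nodes.h5"))
  write_type_table(cir$node_types, file.path(directory, "node_types.csv"))
  if (length(cir$edges)) write_edges(cir$edges, file.path(directory, "edges.h5"))
  write_type_table(cir$edge_types, file.path(directory, "edge_types.csv"))

  virt <- evaluate_node_set(cir, list(model_type = "virtual"))
  if (nrow(virt)) {
    spikes <- generate_poisson_spikes(virt$node_id, rate_hz, duration_ms,
                                      seed = spec$seed + 1L,
                                      population = virt$population[1])
    write_spikes(spikes, file.path(directory, "input_spikes.h5"))
  }

  bio <- evaluate_node_set(cir, list(model_type = "biophysical"))
  if (nrow(bio)) {
    take <- utils::head(bio$node_id[bio$population == bio$population[1]], n_report_nodes)
    mapping <- build_mapping(lapply(take, function(nid)
      list(node_id = nid, element_id = 0L, element_pos = 0.5)))
    rep_obj <- generate_report_traces(mapping, 0, duration_ms, dt,
                                      trace_constant(-65), seed = spec$seed + 2L)
    write_element_report(rep_obj, file.path(directory, "voltage_report.h5"))
  }

  networks <- list(nodes = list(list(nodes_file = "nodes.h5",
                                     node_types_file = "node_types.csv")),
                   edges = if (length(cir$edges))
                     list(list(edges_file = "edges.h5",
                               edge_types_file = "edge_types.csv")) else list())
  circuit_raw <- list(manifest = list(BASE = "."),
                      components = list(morphologies_dir = "$BASE/components/morphologies"),
                      networks = networks)
  simulation_raw <- list(
    run = list(tstop = duration_ms, dt = dt, seed = spec$seed),
    conditions = list(celsius = 34.0),
    node_sets = list(biophysical = list(model_type = "biophysical"),
                     virtual = list(model_type = "virtual")),
    inputs = list(external_spikes = list(input_type = "spikes",
                                         node_set = "virtual",
                                         input_file = "input_spikes.h5")),
    output = list(output_dir = "output", overwrite = TRUE),
    reports = list(membrane_potential = list(variable = "v",
                                             cells = "biophysical",
                                             start = 0, end = duration_ms)))
  bundle <- structure(list(circuit = NULL, simulation = NULL,
                           raw = list(circuit = circuit_raw,
                                      simulation = simulation_raw),
                           provenance = character(0)),
                      class = "sonata_config")
  write_config(bundle, directory)
  invisible(cir)
}
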