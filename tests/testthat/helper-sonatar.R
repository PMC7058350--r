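# shared fixtures and independent oracles; everything is built in code

# the canonical five-node-type / four-edge-type example tables, as CSV text
table1_node_types_lines <- function() {
  c("node_type_id model_type model_template morphology dynamics_params",
    "0 biophysical ctdb:Biophys1.hoc scnn1a_m.swc 472363762_fit.json",
    "1 biophysical ctdb:Biophys1.hoc rorb_m.swc 473863510_fit.json",
    "2 biophysical nml:PV1.nml.xml pv1_m.swc NONE",
    "3 point_neuron nrn:IntFire1 NONE if1_exc.json",
    "4 point_neuron nrn:IntFire1 NONE if1_inh.json")
}

table1_edge_types_lines <- function() {
  c("edge_type_id model_template dynamics_params delay",
    "0 exp2syn biophys_exc.json 2.0",
    "1 exp2syn biophys_inh.json 2.0",
    "2 NONE Instantaneous_exc.json 2.0",
    "3 NONE Instantaneous_inh.json 2.0")
}

write_table1_fixtures <- function(dir) {
  np <- file.path(dir, "node_types.csv")
  ep <- file.path(dir, "edge_types.csv")
  writeLines(table1_node_types_lines(), np)
  writeLines(table1_edge_types_lines(), ep)
  list(node_types = np, edge_types = ep)
}

# a five-node circuit holding one node per example type, empty groups
five_node_circuit <- function(dir = withr::local_tempdir()) {
  paths <- write_table1_fixtures(dir)
  ntt <- read_type_table(paths$node_types, "node")
  ett <- read_type_table(paths$edge_types, "edge")
  pop <- node_population("P", 0:4, list(node_group(0L, 5L)))
  epop <- edge_population("P_to_P", "P", "P",
                          source_node_id = c(0L, 1L, 3L),
                          target_node_id = c(1L, 2L, 4L),
                          edge_type_id = c(0L, 1L, 2L),
                          groups = list(edge_group(0L, 3L)))
  circuit(list(pop), list(epop), ntt, ett)
}

# random attribute column of a random type
rand_column <- function(n) {
  switch(sample(3, 1),
         as.integer(sample.int(1000, n, replace = TRUE)),
         stats::runif(n),
         paste0("val_", sample.int(99, n, replace = TRUE)))
}

rand_node_population <- function(name, n_nodes, n_groups) {
  n_groups <- min(n_groups, max(n_nodes, 1))
  gids <- seq_len(n_groups) - 1L
  assign_g <- if (n_nodes > 0) {
    sort(sample(gids, n_nodes, replace = TRUE))
  } else integer(0)
  sizes <- vapply(gids, function(g) sum(assign_g == g), integer(1))
  groups <- lapply(gids, function(g) {
    n_attr <- sample(0:3, 1)
    attrs <- setNames(lapply(seq_len(n_attr), function(i) rand_column(sizes[g + 1L])),
                      if (n_attr) paste0("attr_", seq_len(n_attr)) else character(0))
    node_group(g, sizes[g + 1L], attrs)
  })
  gidx <- integer(n_nodes)
  for (g in gids) gidx[assign_g == g] <- seq_len(sizes[g + 1L]) - 1L
  node_population(name, sample(0:5, n_nodes, replace = TRUE), groups,
                  group_id = assign_g, group_index = gidx)
}

rand_edge_population <- function(name, n_nodes, n_edges, n_groups,
                                 src_pop = "P", tgt_pop = "P") {
  n_groups <- min(n_groups, max(n_edges, 1))
  gids <- seq_len(n_groups) - 1L
  assign_g <- if (n_edges > 0) sort(sample(gids, n_edges, replace = TRUE)) else integer(0)
  sizes <- vapply(gids, function(g) sum(assign_g == g), integer(1))
  groups <- lapply(gids, function(g) {
    n_attr <- sample(0:2, 1)
    attrs <- setNames(lapply(seq_len(n_attr), function(i) rand_column(sizes[g + 1L])),
                      if (n_attr) paste0("eattr_", seq_len(n_attr)) else character(0))
    edge_group(g, sizes[g + 1L], attrs)
  })
  gidx <- integer(n_edges)
  for (g in gids) gidx[assign_g == g] <- seq_len(sizes[g + 1L]) - 1L
  edge_population(name, src_pop, tgt_pop,
                  source_node_id = sample(0:max(n_nodes - 1L, 0L), n_edges, replace = TRUE),
                  target_node_id = sample(0:max(n_nodes - 1L, 0L), n_edges, replace = TRUE),
                  edge_type_id = sample(0:3, n_edges, replace = TRUE),
                  groups = groups, group_id = assign_g, group_index = gidx)
}

rand_circuit <- function(n_nodes, n_edges, n_groups = 2L) {
  tts <- default_type_tables()
  pop <- rand_node_population("P", n_nodes, n_groups)
  epop <- rand_edge_population("E", n_nodes, n_edges, n_groups)
  circuit(list(pop), list(epop), tts$node_types, tts$edge_types)
}

# normalize attribute list order so structural comparison ignores HDF5's
# alphabetical dataset listing
norm_group <- function(g) {
  g$attributes <- if (length(g$attributes)) {
    g$attributes[sort(names(g$attributes))]
  } else list()
  g
}

expect_same_population <- function(a, b) {
  expect_identical(a$name, b$name)
  for (f in intersect(names(a), c("node_id", "node_type_id", "source_node_id",
                                  "target_node_id", "edge_type_id",
                                  "group_id", "group_index"))) {
    expect_identical(a[[f]], b[[f]])
  }
  expect_identical(lapply(a$groups, norm_group), lapply(b$groups, norm_group))
}

# brute-force two-dictionary merge oracle for attribute overlay
merge_oracle <- function(type_row, instance_row) {
  out <- type_row
  for (nm in names(instance_row)) out[[nm]] <- instance_row[[nm]]
  out
}

# linear-scan oracle for edge queries (returns 0-based indices, ascending)
scan_oracle <- function(pop, node_id, direction) {
  col <- if (direction == "by_target") pop$target_node_id else pop$source_node_id
  which(col == node_id) - 1L
}

resolved_edge_key <- function(circ, pop_name, i0) {
  re <- resolve_edge(circ, pop_name, i0)
  attrs <- re$attributes[sort(names(re$attributes))]
  paste(re$source_node_id, re$target_node_id, re$edge_type_id,
        paste(names(attrs), vapply(attrs, format_value, character(1)),
              sep = "=", collapse = ";"),
        sep = "|")
}
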