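test_that("resolve_node reproduces the example type rows", {
  cir <- five_node_circuit()

  # a point neuron with no group attributes: map equals its type row, and
  # the NONE-valued morphology must be absent
  rn <- resolve_node(cir, "P", 3L)
  expect_identical(rn$attributes,
                   list(model_type = "point_neuron",
                        model_template = "nrn:IntFire1",
                        dynamics_params = "if1_exc.json"))
  expect_false("morphology" %in% names(rn$attributes))
  expect_true(all(rn$provenance == "type"))

  # the NeuroML type has dynamics_params NONE -> absent
  expect_false("dynamics_params" %in% names(resolve_node(cir, "P", 2L)$attributes))
})

test_that("instance attributes extend and shadow the type row", {
  dir <- withr::local_tempdir()
  paths <- write_table1_fixtures(dir)
  ntt <- read_type_table(paths$node_types, "node")
  grp <- node_group(0L, 2L, list(x = c(1.0, 4.0), y = c(2.0, 5.0), z = c(3.0, 6.0),
                                 morphology = c("cellA.swc", "cellB.swc")))
  pop <- node_population("P", c(0L, 0L), list(grp))
  cir <- circuit(list(pop), node_types = ntt)

  rn <- resolve_node(cir, "P", 0L)
  # union of type columns and group columns
  expect_setequal(names(rn$attributes),
                  c("model_type", "model_template", "morphology",
                    "dynamics_params", "x", "y", "z"))
  expect_identical(rn$attributes[c("x", "y", "z")], list(x = 1.0, y = 2.0, z = 3.0))
  # instance morphology wins over the type-level scnn1a_m.swc
  expect_identical(rn$attributes$morphology, "cellA.swc")
  expect_identical(rn$provenance[["morphology"]], "instance")

  # brute-force two-dictionary merge oracle agrees on the whole map
  oracle <- merge_oracle(type_row(ntt, 0L),
                         list(x = 1.0, y = 2.0, z = 3.0, morphology = "cellA.swc"))
  expect_identical(rn$attributes[sort(names(rn$attributes))],
                   oracle[sort(names(oracle))])

  # provenance flags partition the attribute names
  expect_setequal(names(rn$provenance), names(rn$attributes))
  expect_true(all(rn$provenance %in% c("type", "instance")))
})

test_that("resolution is idempotent and total over the population", {
  cir <- five_node_circuit()
  for (nid in cir$nodes$P$node_id) {
    r1 <- resolve_node(cir, "P", nid)
    r2 <- resolve_node(cir, "P", nid)
    expect_identical(r1, r2)
  }
})

test_that("resolve_node failure modes are distinct", {
  cir <- five_node_circuit()
  expect_error(resolve_node(cir, "nope", 0L), class = "sonatar_unknown_population")
  expect_error(resolve_node(cir, "P", 99L), class = "sonatar_unknown_node")
  cir$nodes$P$node_type_id[1] <- 77L
  expect_error(resolve_node(cir, "P", 0L), class = "sonatar_dangling_type_id")
})

test_that("resolve_edge overlays type and instance attributes", {
  cir <- five_node_circuit()
  # empty group: resolved map equals the type row exactly
  re <- resolve_edge(cir, "P_to_P", 0L)
  expect_identical(re$attributes,
                   list(model_template = "exp2syn",
                        dynamics_params = "biophys_exc.json",
                        delay = 2.0))
  expect_identical(re$source_population, "P")
  expect_identical(re$source_node_id, 0L)
  expect_identical(re$target_node_id, 1L)

  # instance-level syn_weight shadows a type-level one
  ett <- type_table("edge", 0L, list(list(model_template = "exp2syn", syn_weight = 1.0)))
  ep <- edge_population("E", "P", "P", 0L, 1L, 0L,
                        list(edge_group(0L, 1L, list(syn_weight = 0.5))))
  cir2 <- circuit(cir$nodes, list(ep), cir$node_types, ett)
  re2 <- resolve_edge(cir2, "E", 0L)
  expect_identical(re2$attributes$syn_weight, 0.5)
  expect_identical(re2$provenance[["syn_weight"]], "instance")
  expect_identical(re2$attributes,
                   merge_oracle(type_row(ett, 0L), list(syn_weight = 0.5)))
})

test_that("resolve_edge rejects bad indices and dangling types", {
  cir <- five_node_circuit()
  expect_error(resolve_edge(cir, "P_to_P", -1L), class = "sonatar_index_range")
  expect_error(resolve_edge(cir, "P_to_P", 3L), class = "sonatar_index_range")
  cir$edges$P_to_P$edge_type_id[1] <- 42L
  expect_error(resolve_edge(cir, "P_to_P", 0L), class = "sonatar_dangling_type_id")
})

test_that("node sets select by attribute, identity, and conjunction", {
  cir <- five_node_circuit()

  # the three biophysically detailed types out of five
  sel <- evaluate_node_set(cir, list(model_type = "biophysical"))
  expect_identical(sel$node_id, c(0L, 1L, 2L))

  # empty predicate selects everything
  all_sel <- evaluate_node_set(cir, list())
  expect_identical(nrow(all_sel), 5L)

  # explicit (population, node_id) list
  sel2 <- evaluate_node_set(cir, list(node_id = c(1L, 3L), population = "P"))
  expect_identical(sel2$node_id, c(1L, 3L))

  # a list value is disjunctive within its key
  sel3 <- evaluate_node_set(cir, list(model_type = c("biophysical", "point_neuron")))
  expect_identical(nrow(sel3), 5L)

  # keys combine conjunctively
  sel4 <- evaluate_node_set(cir, list(model_type = "biophysical",
                                      model_template = "nml:PV1.nml.xml"))
  expect_identical(sel4$node_id, 2L)

  expect_error(evaluate_node_set(cir, list(population = "missing")),
               class = "sonatar_unknown_population")
})

test_that("node sets are monotone under predicate relaxation", {
  cir <- five_node_circuit()
  pred <- list(model_type = "biophysical", model_template = "ctdb:Biophys1.hoc")
  full <- evaluate_node_set(cir, pred)
  for (drop in names(pred)) {
    relaxed <- evaluate_node_set(cir, pred[setdiff(names(pred), drop)])
    expect_true(all(full$node_id %in% relaxed$node_id))
  }
  # selection cardinality of {} equals the sum of population sizes
  cir2 <- circuit(list(cir$nodes$P,
                       node_population("Q", rep(3L, 4), list(node_group(0L, 4L)))),
                  node_types = cir$node_types)
  expect_identical(nrow(evaluate_node_set(cir2, list())), 9L)
})
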