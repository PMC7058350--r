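test_that("node files round-trip exactly, including the one-per-type example", {
  dir <- withr::local_tempdir()
  pop <- node_population("P", 0:4, list(node_group(0L, 5L)))
  p <- file.path(dir, "nodes.h5")
  write_nodes(pop, p)
  back <- read_nodes(p)
  expect_named(back, "P")
  expect_identical(back$P$node_type_id, 0:4)
  expect_same_population(pop, back$P)
})

test_that("empty and multi-group node populations round-trip", {
  dir <- withr::local_tempdir()
  empty <- node_population("void", integer(0), list(node_group(0L, 0L)),
                           group_id = integer(0), group_index = integer(0))
  p <- file.path(dir, "nodes.h5")
  write_nodes(empty, p)
  back <- read_nodes(p)
  expect_identical(length(back$void$node_id), 0L)
  expect_same_population(empty, back$void)

  withr::local_seed(11)
  big <- rand_node_population("big", 1000L, 2L)
  write_nodes(list(big, empty), p)
  back2 <- read_nodes(p)
  expect_setequal(names(back2), c("big", "void"))
  expect_same_population(big, back2$big)
})

test_that("edge files round-trip with groups, metadata and indices", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "edges.h5")

  # minimal three-edge population
  ep <- edge_population("E", "SRC", "TGT", c(0L, 1L, 2L), c(1L, 2L, 0L),
                        c(0L, 1L, 0L), list(edge_group(0L, 3L)))
  write_edges(ep, p)
  back <- read_edges(p)$E
  expect_identical(back$source_population, "SRC")
  expect_identical(back$target_population, "TGT")
  expect_same_population(ep, back)

  # rich vs weight-only two-group partition survives the round trip
  withr::local_seed(13)
  ep2 <- rand_edge_population("E2", 50L, 400L, 2L, "V1", "V2")
  write_edges(ep2, p)
  back2 <- read_edges(p)$E2
  expect_same_population(ep2, back2)
  expect_identical(length(back2$groups), 2L)

  # a stored range index is restored and answers queries like the original
  ep3 <- index_edges(ep2, "by_target")
  write_edges(ep3, p)
  back3 <- read_edges(p)$E2
  expect_named(back3$indices, "by_target")
  for (nid in sample(unique(ep2$target_node_id), 10)) {
    expect_identical(query_edges(back3, nid, "by_target"),
                     query_edges(ep3, nid, "by_target"))
  }
})

test_that("sort_edges matches independent key-arithmetic oracles", {
  # worked example: (source,target) pairs sorted target-major
  ep <- edge_population("E", "P", "P", c(0L, 2L, 1L), c(1L, 0L, 0L),
                        rep(0L, 3), list(edge_group(0L, 3L)))
  s <- sort_edges(ep, "target_major")
  expect_identical(cbind(s$source_node_id, s$target_node_id),
                   cbind(c(1L, 2L, 0L), c(0L, 0L, 1L)))

  # idempotence on already-sorted input
  s2 <- sort_edges(s, "target_major")
  expect_identical(s2$source_node_id, s$source_node_id)
  expect_identical(s2$target_node_id, s$target_node_id)

  withr::local_seed(17)
  pop <- rand_edge_population("R", 40L, 300L, 2L)
  big <- 1000L  # > any node id, so key arithmetic is an independent total order
  st <- sort_edges(pop, "target_major")
  expect_identical(order(st$target_node_id * big + st$source_node_id),
                   seq_along(st$source_node_id))
  ss <- sort_edges(pop, "source_major")
  expect_identical(order(ss$source_node_id * big + ss$target_node_id),
                   seq_along(ss$source_node_id))

  # hybrid degeneracy: one even-parity block is exactly target-major
  sh <- sort_edges(pop, "hybrid", block_size = 64L)
  expect_identical(sh$source_node_id, st$source_node_id)
  expect_identical(sh$target_node_id, st$target_node_id)

  # hybrid with small blocks: explicit per-edge key oracle (double keys,
  # integer arithmetic would overflow)
  B <- 7L
  shb <- sort_edges(pop, "hybrid", block_size = B)
  bi <- as.numeric(shb$target_node_id %/% B); bj <- as.numeric(shb$source_node_id %/% B)
  even <- (bi + bj) %% 2 == 0
  w1 <- ifelse(even, shb$target_node_id, shb$source_node_id)
  w2 <- ifelse(even, shb$source_node_id, shb$target_node_id)
  key <- ((bi * 1000 + bj) * 1000 + w1) * 1000 + w2
  expect_true(!is.unsorted(key))

  expect_error(edge_ordering("hybrid"), class = "sonatar_bad_ordering")
  expect_error(edge_ordering("hybrid", 0), class = "sonatar_bad_ordering")
})

test_that("sorting permutes the multiset of resolved edges, never the content", {
  withr::local_seed(19)
  cir <- rand_circuit(30L, 200L, 2L)
  keys0 <- sort(vapply(seq_along(cir$edges$E$edge_type_id) - 1L,
                       function(i) resolved_edge_key(cir, "E", i), character(1)))
  for (ord in list(edge_ordering("target_major"), edge_ordering("source_major"),
                   edge_ordering("hybrid", 7L))) {
    cir2 <- cir
    cir2$edges$E <- sort_edges(cir$edges$E, ord)
    keys <- sort(vapply(seq_along(cir2$edges$E$edge_type_id) - 1L,
                        function(i) resolved_edge_key(cir2, "E", i), character(1)))
    expect_identical(keys, keys0)
  }
})

test_that("range indices agree with a linear scan and tile the edge array", {
  withr::local_seed(23)
  pop <- rand_edge_population("R", 60L, 500L, 1L)
  for (direction in c("by_target", "by_source")) {
    idx <- build_edge_index(pop, direction)
    for (nid in sample(0:70, 50)) {
      expect_identical(query_edges(pop, nid, direction, index = idx),
                       scan_oracle(pop, nid, direction))
    }
    # completeness: querying every node partitions [0, edge_count)
    all_hits <- unlist(lapply(0:70, function(nid) query_edges(pop, nid, direction, index = idx)))
    expect_identical(sort(all_hits), seq_len(500L) - 1L)
  }

  # after a target-major sort every node has at most one by-target range
  st <- sort_edges(pop, "target_major")
  idx <- build_edge_index(st, "by_target")
  expect_true(all(vapply(idx$ranges, nrow, integer(1)) <= 1L))

  # node with no incident edges -> empty result
  expect_identical(query_edges(pop, 9999L, "by_target"), integer(0))

  # query on an empty population -> empty
  ep0 <- edge_population("Z", "P", "P", integer(0), integer(0), integer(0),
                         list(edge_group(0L, 0L)),
                         group_id = integer(0), group_index = integer(0))
  expect_identical(query_edges(ep0, 0L, "by_source"), integer(0))

  # complete bipartite 2x3: by_source of node 0 has 3 edges
  src <- rep(0:1, each = 3); tgt <- rep(2:4, times = 2)
  kb <- edge_population("K", "A", "B", src, tgt, rep(0L, 6),
                        list(edge_group(0L, 6L)))
  expect_identical(length(query_edges(kb, 0L, "by_source")), 3L)
})

test_that("query results are invariant under any ordering", {
  withr::local_seed(29)
  cir <- rand_circuit(25L, 150L, 2L)
  ref <- lapply(0:30, function(nid) {
    sort(vapply(query_edges(cir$edges$E, nid, "by_target"),
                function(i) resolved_edge_key(cir, "E", i), character(1)))
  })
  for (ord in list(edge_ordering("source_major"), edge_ordering("hybrid", 1L),
                   edge_ordering("hybrid", 64L))) {
    cir2 <- cir
    cir2$edges$E <- sort_edges(cir$edges$E, ord)
    for (nid in 0:30) {
      got <- sort(vapply(query_edges(cir2$edges$E, nid, "by_target"),
                         function(i) resolved_edge_key(cir2, "E", i), character(1)))
      expect_identical(got, ref[[nid + 1L]])
    }
  }
})
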