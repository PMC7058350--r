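# each corruption of a clean synthetic circuit must fire exactly its own
# check: one finding, matching code, nothing else

clean_cir <- function(seed = 101L) {
  withr::local_seed(seed, .local_envir = parent.frame())
  cir <- rand_circuit(40L, 200L, 2L)
  cir$edges$E <- index_edges(cir$edges$E)
  cir
}

expect_single_finding <- function(findings, code) {
  expect_identical(nrow(findings), 1L)
  expect_identical(findings$code, code)
  expect_identical(findings$severity, "error")
}

test_that("clean circuits and activity validate with zero findings", {
  cir <- clean_cir()
  expect_identical(nrow(validate_circuit(cir)), 0L)

  dir <- withr::local_tempdir()
  spikes <- generate_poisson_spikes(cir$nodes$P$node_id, 5, 500, seed = 3L,
                                    population = "P")
  sp <- file.path(dir, "spikes.h5")
  write_spikes(spikes, sp)
  expect_identical(nrow(validate_activity(sp, cir)), 0L)

  m <- build_mapping(list(list(node_id = cir$nodes$P$node_id[1], element_id = 0:1)))
  rp <- file.path(dir, "rep.h5")
  write_element_report(generate_report_traces(m, 0, 10, 0.5, trace_ar1(), seed = 4L), rp)
  expect_identical(nrow(validate_activity(rp, cir)), 0L)
})

test_that("each circuit fault fires exactly one finding", {
  base <- clean_cir()

  cir <- base
  cir$nodes$P$node_type_id[3] <- 99L
  expect_single_finding(validate_circuit(cir), "dangling_node_type_id")

  cir <- base
  cir$edges$E$edge_type_id[1] <- 88L
  expect_single_finding(validate_circuit(cir), "dangling_edge_type_id")

  cir <- base
  cir$edges$E$target_node_id[5] <- 40L  # beyond the 40-node population
  cir$edges$E$indices <- NULL           # keep the endpoint fault isolated
  expect_single_finding(validate_circuit(cir), "dangling_endpoint")

  cir <- base
  cir$nodes$P$group_id[2] <- 77L
  expect_single_finding(validate_circuit(cir), "unknown_group_id")

  cir <- base
  cir$nodes$P$group_index[2] <- 100000L
  expect_single_finding(validate_circuit(cir), "group_index_range")

  cir <- base
  gi <- which(vapply(cir$nodes$P$groups, function(g) g$size, integer(1)) > 0L)[1]
  g1 <- cir$nodes$P$groups[[gi]]
  if (!length(g1$attributes)) g1$attributes <- list(x = numeric(g1$size))
  g1$attributes[[1]] <- g1$attributes[[1]][-1]
  cir$nodes$P$groups[[gi]] <- g1
  expect_single_finding(validate_circuit(cir), "ragged_group")

  cir <- base
  cir$node_types$rows[[1]]$model_type <- "spooky"
  expect_single_finding(validate_circuit(cir), "bad_model_type")

  cir <- base
  cir$node_types$columns <- setdiff(cir$node_types$columns, "model_type")
  cir$node_types$rows <- lapply(cir$node_types$rows, function(r) {
    r$model_type <- NULL; r
  })
  expect_single_finding(validate_circuit(cir), "missing_model_type")

  cir <- base
  cir$edges$E$source_population <- "ghost"
  expect_single_finding(validate_circuit(cir), "unknown_population")

  cir <- base
  idx <- cir$edges$E$indices$by_target
  first <- names(idx$ranges)[1]
  idx$ranges[[first]] <- idx$ranges[[first]][-1, , drop = FALSE]
  if (!nrow(idx$ranges[[first]])) idx$ranges[[first]] <- NULL
  cir$edges$E$indices$by_target <- idx
  expect_single_finding(validate_circuit(cir), "index_incomplete")
})

test_that("each activity fault fires exactly one finding", {
  cir <- clean_cir()
  dir <- withr::local_tempdir()

  sp <- file.path(dir, "spikes.h5")
  write_spikes(generate_poisson_spikes(cir$nodes$P$node_id, 5, 200, seed = 5L,
                                       population = "P"), sp)

  # spike referencing a node the circuit does not contain
  rhdf5::h5write(9999L, sp, "/spikes/P/node_ids", index = list(1))
  f <- validate_activity(sp, cir)
  expect_single_finding(f, "unknown_node")

  # negative timestamp (re-write a clean file first)
  write_spikes(generate_poisson_spikes(cir$nodes$P$node_id, 5, 200, seed = 5L,
                                       population = "P"), sp)
  rhdf5::h5write(-4.0, sp, "/spikes/P/timestamps", index = list(1))
  f <- validate_activity(sp, cir)
  # breaking one timestamp also falsifies the by_time tag: the error is the
  # negative time; the stale sorting tag is only a warning
  expect_identical(f$code[f$severity == "error"], "negative_timestamp")
  expect_true(all(f$code[f$severity == "warning"] %in% "unsorted_spikes"))

  # spikes for a population the circuit lacks
  write_spikes(spike_report("mystery", 0L, 1.0), sp)
  expect_single_finding(validate_activity(sp, cir), "unknown_population")

  # element report with a corrupted (non-monotone) index pointer
  rp <- file.path(dir, "rep.h5")
  m <- build_mapping(list(list(node_id = cir$nodes$P$node_id[1], element_id = 0:1),
                          list(node_id = cir$nodes$P$node_id[2], element_id = 0:2)))
  write_element_report(generate_report_traces(m, 0, 10, 0.5, trace_constant(-65)), rp)
  rhdf5::h5write(c(0L, 4L, 3L), rp, "/report/report/mapping/index_pointer")
  expect_single_finding(validate_activity(rp, cir), "mapping_corrupt")

  # unsorted spikes marked by_time: a warning, not an error
  write_spikes(spike_report("P", cir$nodes$P$node_id[1:2], c(5, 1)), sp)
  h5_set_attr(sp, "spikes/P", "sorting", "by_time")
  f <- validate_activity(sp, cir)
  expect_identical(f$severity, "warning")
  expect_identical(f$code, "unsorted_spikes")

  # unreadable file is a finding, not an exception
  bad <- file.path(dir, "not_hdf5.h5")
  writeLines("plain text", bad)
  f <- validate_activity(bad, cir)
  expect_identical(f$code, "unreadable")
})

test_that("findings render as text and JSON lines", {
  cir <- clean_cir()
  cir$nodes$P$node_type_id[1] <- 99L
  f <- validate_circuit(cir)
  txt <- format_findings(f)
  expect_match(txt, "ERROR \\[dangling_node_type_id\\]")
  js <- format_findings(f, json = TRUE)
  parsed <- jsonlite::fromJSON(js[1])
  expect_identical(parsed$code, "dangling_node_type_id")
})
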