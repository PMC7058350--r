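test_that("spike reports round-trip for every sorting mode", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spikes.h5")
  for (sorting in c("none", "by_time", "by_id")) {
    ts <- c(3.5, 1.25, 7.0)
    ids <- c(4L, 0L, 2L)
    if (sorting == "by_time") { o <- order(ts); ts <- ts[o]; ids <- ids[o] }
    if (sorting == "by_id") { o <- order(ids); ts <- ts[o]; ids <- ids[o] }
    rep0 <- spike_report("pop", ids, ts, sorting)
    write_spikes(rep0, p)
    back <- read_spikes(p)
    expect_identical(back, rep0)
  }

  # empty report: two zero-length datasets
  write_spikes(spike_report("pop", integer(0), numeric(0)), p)
  back <- read_spikes(p)
  expect_identical(length(back$node_ids), 0L)
  expect_identical(length(back$timestamps), 0L)
})

test_that("spike filters equal a brute-force scan", {
  withr::local_seed(31)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "spikes.h5")
  n <- 10000L
  ids <- sample(0:99, n, replace = TRUE)
  ts <- stats::runif(n, 0, 1000)
  write_spikes(spike_report("pop", ids, ts), p)

  got <- read_spikes(p, window = c(100, 200))
  expect_identical(length(got$node_ids), sum(ts >= 100 & ts < 200))

  keep_nodes <- c(3L, 17L, 55L)
  got2 <- read_spikes(p, node_filter = keep_nodes, window = c(250, 300))
  oracle <- which(ids %in% keep_nodes & ts >= 250 & ts < 300)
  expect_identical(got2$node_ids, ids[oracle])
  expect_identical(got2$timestamps, ts[oracle])

  expect_error(spike_report("pop", 1L, -0.5), class = "sonatar_negative_timestamp")
  expect_error(spike_report("pop", 1:2, 1.0), class = "sonatar_length_mismatch")
})

test_that("spike CSV export/import preserves the event multiset", {
  dir <- withr::local_tempdir()
  rep0 <- spike_report("pop", c(5L, 1L, 5L), c(0.5, 2.25, 0.5))
  p <- file.path(dir, "spikes.csv")
  spikes_to_csv(rep0, p)
  back <- spikes_from_csv(p, population = "pop")
  expect_identical(back$node_ids, rep0$node_ids)
  expect_identical(back$timestamps, rep0$timestamps)
})

test_that("mappings follow the cumulative-sum oracle and keep node order", {
  m1 <- build_mapping(list(list(node_id = 0L, element_id = 0L)))
  expect_identical(m1$offsets, c(0L, 1L))
  expect_identical(m1$n_elements, 1L)

  # nodes listed as [5, 2]: order of appearance preserved, not sorted
  m <- build_mapping(list(list(node_id = 5L, element_id = 0:1),
                          list(node_id = 2L, element_id = 0:2)))
  expect_identical(m$node_ids, c(5L, 2L))
  expect_identical(m$offsets, c(0L, 2L, 5L))
  expect_identical(columns_for_node(m, 5L), c(0L, 2L))
  expect_identical(columns_for_node(m, 2L), c(2L, 5L))
  # spans partition the M columns
  spans <- vapply(m$node_ids, function(nid) diff(columns_for_node(m, nid)), integer(1))
  expect_identical(sum(spans), m$n_elements)

  # a node recording three variables gets a column span of length 3
  m3 <- build_mapping(list(list(node_id = 0L, element_id = 0:2)))
  expect_identical(diff(columns_for_node(m3, 0L)), 3L)

  expect_error(build_mapping(list(list(node_id = 0L, element_id = 0L),
                                  list(node_id = 0L, element_id = 0L))),
               class = "sonatar_duplicate_node")
  expect_error(build_mapping(list(list(node_id = 0L, element_id = integer(0)))),
               class = "sonatar_bad_mapping")
  expect_error(columns_for_node(m, 99L), class = "sonatar_unknown_node")
})

test_that("element reports enforce the frame-count and append contracts", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "rep.h5")
  m <- build_mapping(list(list(node_id = 0L, element_id = 0:3)))

  h <- create_element_report(p, m, tstart = 0, tstop = 1.0, dt = 0.1)
  expect_identical(h$n_frames, 10L)
  expect_error(create_element_report(p, m, 5, 5, 0.1), class = "sonatar_bad_report")
  expect_error(create_element_report(p, m, 0, 1, 0.1, chunk_shape = c(0, 1)),
               class = "sonatar_bad_chunk")

  X <- matrix(stats::rnorm(40), nrow = 10)
  append_frames(h, X[1:4, ])
  append_frames(h, X[5:8, ])
  expect_error(append_frames(h, X[, 1:3]), class = "sonatar_width_mismatch")
  append_frames(h, matrix(numeric(0), ncol = 4))   # zero-row no-op
  append_frames(h, X[9:10, ])                      # partial final block
  expect_error(append_frames(h, X[1, , drop = FALSE]), class = "sonatar_overflow")

  back <- read_element_report(p)
  expect_identical(back$data, X)
  expect_identical(back$dt, 0.1)
})

test_that("every read path equals the dense-matrix slice, for any chunks", {
  withr::local_seed(37)
  dir <- withr::local_tempdir()
  n <- 20L
  elems <- list(list(node_id = 7L, element_id = 0:2, element_pos = c(0.1, 0.5, 0.9)),
                list(node_id = 3L, element_id = 0:1, element_pos = c(0.7, 0.2)),
                list(node_id = 12L, element_id = 0:1, element_pos = c(0.0, 1.0)))
  m <- build_mapping(elems)
  X <- matrix(stats::rnorm(n * m$n_elements), nrow = n)
  tstart <- 0; dt <- 0.5; tstop <- n * dt

  reads <- lapply(list(c(1L, 1L), c(4L, 7L), c(20L, 2L)), function(chunk) {
    p <- file.path(dir, sprintf("rep_%d_%d.h5", chunk[1], chunk[2]))
    h <- create_element_report(p, m, tstart, tstop, dt, chunk_shape = chunk)
    append_frames(h, X)
    list(
      full = read_frames(p),
      window = read_frames(p, window = c(2.0, 6.0)),
      frame3_node7 = read_frames(p, window = c(1.0, 1.5), node_ids = 7L),
      trace3 = read_trace(p, 3L),
      trace7_filtered = read_trace(p, 7L, element_ids = c(0L, 2L)),
      pos_filter = read_trace(p, 3L, pos_range = c(0, 0.5)))
  })

  # dense in-memory oracle slices
  expect_identical(reads[[1]]$full, X)
  expect_identical(reads[[1]]$window, X[5:12, , drop = FALSE])   # t in [2, 6)
  expect_identical(reads[[1]]$frame3_node7, X[3, 1:3, drop = FALSE])
  expect_identical(unname(reads[[1]]$trace3), X[, 4:5])
  expect_identical(unname(reads[[1]]$trace7_filtered), X[, c(1, 3)])
  # node 3 has positions {0.7, 0.2}; [0, 0.5) keeps exactly one trace
  expect_identical(ncol(reads[[1]]$pos_filter), 1L)
  expect_identical(unname(reads[[1]]$pos_filter), X[, 5, drop = FALSE])

  # chunk shape never changes a single bit
  for (r in reads[-1]) expect_identical(r, reads[[1]])

  # empty window is legal
  expect_identical(nrow(read_frames(file.path(dir, "rep_1_1.h5"),
                                    window = c(50, 60))), 0L)
})

test_that("element order is preserved exactly when element_pos is absent", {
  dir <- withr::local_tempdir()
  m <- build_mapping(list(list(node_id = 1L, element_id = c(4L, 0L, 2L))))
  expect_null(m$element_pos)
  p <- file.path(dir, "nopos.h5")
  h <- create_element_report(p, m, 0, 1, 0.5)
  append_frames(h, matrix(1:6, nrow = 2))
  back <- read_element_report(p)
  expect_identical(back$mapping$element_ids, c(4L, 0L, 2L))
  expect_identical(colnames(read_trace(p, 1L)), c("4", "0", "2"))
  expect_error(read_trace(p, 1L, pos_range = c(0, 1)),
               class = "sonatar_no_element_pos")
})
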