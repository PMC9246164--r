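# Network phenotype: genome handling, pruning, lesion masks, recurrent
# evaluation semantics.

test_that("pruning removes exactly the disabled connection genes", {
  g <- wide_genome(n_total = 58, n_disabled = 7)
  p <- prune_disabled(g)
  expect_equal(nrow(g$connections), 58)
  expect_equal(nrow(p$connections), 51)
  expect_true(all(p$connections$enabled))
  expect_equal(p$nodes, g$nodes)
  expect_equal(nrow(g$connections), 58) # input untouched

  all_on <- wide_genome(n_total = 20, n_disabled = 0)
  expect_equal(prune_disabled(all_on)$connections, all_on$connections)

  g2 <- tiny_genome()
  g2$connections$enabled <- FALSE
  expect_equal(nrow(prune_disabled(g2)$connections), 0)
  expect_equal(nrow(prune_disabled(g2)$nodes), 3)
})

test_that("genome validation rejects broken genomes", {
  expect_error(lesion_genome(
    nodes = data.frame(id = c(0L, 0L), role = c("input", "output"),
                       activation = "sigmoid", aggregation = "sum",
                       bias = 0, response = 1),
    connections = data.frame(source = integer(), target = integer(),
                             weight = numeric(), enabled = logical())
  ), "unique")
  g <- tiny_genome()
  bad <- g
  bad$connections <- rbind(bad$connections,
                           data.frame(source = -9L, target = 0L, weight = 1,
                                      enabled = TRUE))
  expect_error(validate_genome(bad), "existing node")
  bad2 <- g
  bad2$nodes$activation[3] <- "no_such_fn"
  expect_error(validate_genome(bad2), "unregistered")
  bad3 <- g
  bad3$connections <- rbind(bad3$connections, bad3$connections[1, ])
  expect_error(validate_genome(bad3), "unique")
})

test_that("node lesion masks cover incoming and outgoing connections once", {
  g <- lesion_genome(
    nodes = data.frame(
      id = c(-1L, -2L, 0L, 1L, 2L, 3L),
      role = c("input", "input", rep("output", 4)),
      activation = "sigmoid", aggregation = "sum", bias = 0, response = 1
    ),
    connections = data.frame(
      source = c(-1L, -2L, 0L, 0L, 0L, 1L),
      target = c(0L, 0L, 1L, 2L, 3L, 2L),
      weight = 1, enabled = TRUE
    )
  )
  m <- node_lesion_mask(g, 0L) # 2 incoming + 3 outgoing
  expect_length(m$disabled_connections, 5)
  expect_equal(m$disabled_nodes, 0L)

  expect_length(node_lesion_mask(g, 3L, scope = "outgoing")$disabled_connections, 0)
  expect_length(node_lesion_mask(g, 0L, scope = "incoming")$disabled_connections, 2)

  iso <- lesion_genome(
    nodes = data.frame(id = c(-1L, 0L, 1L),
                       role = c("input", "output", "output"),
                       activation = "sigmoid", aggregation = "sum",
                       bias = 0, response = 1),
    connections = data.frame(source = -1L, target = 0L, weight = 1,
                             enabled = TRUE)
  )
  m_iso <- node_lesion_mask(iso, 1L)
  expect_length(m_iso$disabled_connections, 0)
  expect_equal(m_iso$disabled_nodes, 1L)

  self <- tiny_genome(self_loop = -1)
  self$connections <- self$connections[-1, ] # keep (-2->0) and (0->0)
  self <- lesion_genome(self$nodes, self$connections)
  m_self <- node_lesion_mask(self, 0L)
  expect_length(m_self$disabled_connections, 2) # self-loop counted once
  expect_error(node_lesion_mask(self, 99L), "unknown node")
})

test_that("the synchronous step follows act(bias + response * agg(w x))", {
  # fully input-lesioned sigmoid/max node emits the logistic of its bias
  g <- tiny_genome(activation = "sigmoid", aggregation = "max", bias = -0.9)
  s <- network_state(g)
  out <- step_network(g, s, c(`-1` = 1, `-2` = 1),
                      node_lesion_mask(g, 0L, scope = "incoming"))
  expect_equal(unname(out["0"]), 1 / (1 + exp(0.9)), tolerance = 1e-12)

  g2 <- tiny_genome(activation = "identity", aggregation = "sum", bias = 0,
                    weights = c(1, 1))
  out2 <- step_network(g2, network_state(g2), c(`-1` = 0.2, `-2` = 0.3))
  expect_equal(unname(out2["0"]), 0.5)
  out3 <- step_network(g2, network_state(g2), c(`-1` = 0.2, `-2` = 0.3),
                       lesion_mask("-2->0", genome = g2))
  expect_equal(unname(out3["0"]), 0.2)

  expect_error(step_network(g2, network_state(g2), c(`-1` = NaN, `-2` = 0)),
               "non-finite")
  expect_error(step_network(g2, network_state(g2), c(`-1` = 0)), "cover")
})

test_that("self-loops read the previous state (one-step delay)", {
  g <- tiny_genome(activation = "identity", aggregation = "sum", bias = 1,
                   weights = c(0, 0), self_loop = 0.5)
  s <- network_state(g)
  ins <- c(`-1` = 0, `-2` = 0)
  s1 <- step_network(g, s, ins)
  s2 <- step_network(g, s1, ins)
  expect_equal(unname(s1["0"]), 1)    # bias + 0.5 * 0
  expect_equal(unname(s2["0"]), 1.5)  # bias + 0.5 * 1
})

test_that("run_network records traces and applies winner-take-all with lowest-id ties", {
  g <- lesion_genome(
    nodes = data.frame(id = c(-1L, 0L, 1L, 2L),
                       role = c("input", rep("output", 3)),
                       activation = "sigmoid", aggregation = "sum",
                       bias = 0, response = 1),
    connections = data.frame(source = -1L, target = 0L, weight = 0,
                             enabled = TRUE)
  )
  xs <- input_series(matrix(0, nrow = 1, ncol = 1, dimnames = list(NULL, "-1")))
  res <- run_network(g, xs)
  expect_equal(unname(res$trace[1, ]), rep(0.5, 3))
  expect_equal(res$actions, 0L) # all tied, lowest output id wins
  expect_error(run_network(g, xs[0, , drop = FALSE]), "at least one timestep")
})

test_that("mask application is idempotent and equals pruning for empty masks", {
  g <- make_motif_genome()
  xs <- generate_inputs(task_spec(T = 40, seed = 5), 4)
  m <- lesion_mask(c("0->0", "-1->4"), genome = g)
  r1 <- run_network(g, xs, m)
  r2 <- run_network(g, xs, combine_masks(m, m))
  expect_identical(r1$trace, r2$trace)

  r_empty <- run_network(g, xs)
  r_pruned <- run_network(prune_disabled(g), xs)
  expect_identical(r_empty$trace, r_pruned$trace)

  # determinism: identical inputs give bit-identical traces
  expect_identical(run_network(g, xs)$trace, run_network(g, xs)$trace)
})

test_that("masking is local: disconnected components are unaffected", {
  g <- two_component_genome()
  xs <- generate_inputs(task_spec(T = 30, seed = 2), 2)
  full <- run_network(g, xs)
  cut <- run_network(g, xs, lesion_mask("-1->0", genome = g))
  # component {2, 3} has no path from the lesioned connection's target
  expect_identical(full$trace[, c("2", "3")], cut$trace[, c("2", "3")])
  expect_false(identical(full$trace[, "0"], cut$trace[, "0"]))
})

test_that("a fully node-lesioned unit emits a constant act(bias) trace", {
  g <- make_motif_genome()
  xs <- generate_inputs(task_spec(T = 30, seed = 9), 4)
  r <- run_network(g, xs, node_lesion_mask(g, 0L))
  expect_equal(unname(unique(r$trace[, "0"])), 1 / (1 + exp(0.9)),
               tolerance = 1e-12)
})

test_that("genome JSON round-trips losslessly", {
  g <- make_motif_genome()
  path <- withr::local_tempfile(fileext = ".json")
  write_genome(g, path)
  g2 <- read_genome(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$connections, g$connections)
  expect_equal(g2$metadata, g$metadata)
  expect_error(read_genome(file.path(tempdir(), "nope.json")), "not found")
})

test_that("activity traces export with a chosen_action column", {
  g <- make_motif_genome()
  xs <- generate_inputs(task_spec(T = 10, seed = 1), 4)
  r <- run_network(g, xs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(r$trace, path)
  df <- utils::read.delim(path, check.names = FALSE)
  expect_equal(nrow(df), 10)
  expect_true("chosen_action" %in% names(df))
  expect_equal(df$chosen_action, r$actions)
})
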