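# Threshold imposition, sink pruning, reachability, and the full pipeline.

test_that("thresholding is strict and drops stranded nodes", {
  fn <- chain_net(c(0.3, 0.7))       # floods are 0.3 and then 0.3
  st <- flood_network(fn)
  expect_equal(st$edges$flood, c(0.3, 0.3))
  fn2 <- flood_net(data.frame(from = c("s", "s"), to = c("a", "b"),
                              capacity = c(0.3, 0.7)), sources = "s")
  st2 <- flood_network(fn2)
  kept <- apply_threshold(st2, fn2, 0.5)
  expect_equal(nrow(kept$edges), 1)
  expect_equal(kept$edges$capacity, 0.7)
  expect_false("a" %in% kept$ids)     # stranded node dropped
  # t = 0 keeps exactly the active (non-zero flood) edges
  neg <- flood_net(data.frame(from = c("s", "u"), to = c("u", "t"),
                              capacity = c(-1, 2)), sources = "s")
  stn <- flood_network(neg)
  expect_equal(nrow(apply_threshold(stn, neg, 0)$edges), 1)
  # t at or above the maximum flood empties the network
  expect_equal(nrow(apply_threshold(st2, fn2, 0.7)$edges), 0)
  expect_error(apply_threshold(st2, fn2, -1), "threshold")
})

test_that("sink pruning keeps exactly the edges on source-to-sink paths", {
  fn <- flood_net(data.frame(from = c("s", "s", "a", "b"),
                             to = c("a", "b", "t", "dead"),
                             capacity = c(1, 1, 1, 1)),
                  sources = "s", sinks = "t")
  pruned <- prune_to_sinks(fn)
  expect_setequal(paste(pruned$edges$from, pruned$edges$to),
                  c("s a", "a t"))
  # sinks = every node: nothing more is removed
  all_sinks <- prune_to_sinks(fn, fn$ids)
  expect_equal(nrow(all_sinks$edges), nrow(fn$edges))
  # unreachable sink: empty network plus a warning, not an error
  expect_warning(empty <- prune_to_sinks(fn, "nowhere"), "no sink")
  expect_equal(nrow(empty$edges), 0)
  expect_error(prune_to_sinks(fn, character()), "non-empty")
})

test_that("the reachable sub-network is forward reachability from the inputs", {
  g <- suppressWarnings(grn(
    data.frame(source = c("a", "b", "x"), target = c("b", "c", "y"),
               weight = c(1, -2, 1)),
    signals = list(signal_spec("s1", c(a = 1)))))
  r <- reachable_subnetwork(g, scenario_config())
  expect_setequal(r$genes$id, c("a", "b", "c"))   # x, y not reachable
  expect_equal(nrow(r$edges), 2)
  # fully connected from the source: identity
  g2 <- grn(data.frame(source = "a", target = "b", weight = 1),
            signals = list(signal_spec("s1", c(a = 1))))
  r2 <- reachable_subnetwork(g2, scenario_config())
  expect_equal(r2$genes$id, g2$genes$id)
  expect_equal(r2$edges, g2$edges)
})

test_that("the worked example minimizes as its construction promises", {
  ex <- example_grn()
  mg0 <- minimize_grn(ex$grn, ex$scenario)
  # genes 2 and 5 disconnect from the sink at every threshold
  expect_false(any(c("g2", "g5") %in% mg0$genes$id))
  expect_false("g2->g6" %in% paste0(mg0$edges$source, "->", mg0$edges$target))
  # the weak positive 4->6 flood survives only below its value
  for (t in c(0.5, 1.5)) {
    sc <- ex$scenario
    sc$threshold <- t
    mg <- minimize_grn(ex$grn, sc)
    has4 <- "g4->g6" %in% paste0(mg$edges$source, "->", mg$edges$target)
    expect_equal(has4, t < 1)
    expect_equal("g4" %in% mg$genes$id, t < 1)
  }
})

test_that("the pipeline needs at least one source of information", {
  g <- grn(data.frame(source = "a", target = "b", weight = 1))
  expect_error(minimize_grn(g, scenario_config()), "no active source")
})

test_that("retained-edge count shrinks monotonically with the threshold", {
  for (i in 1:8) {
    g <- random_test_grn(i)
    fn <- transform_grn(g, scenario_config())
    st <- flood_network(fn)
    grid <- seq(0, max(abs(st$edges$flood)), length.out = 12)
    counts <- vapply(grid, function(t) nrow(apply_threshold(st, fn, t)$edges), 0L)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("the minimized network is contained in the reachable sub-network", {
  for (i in 1:8) {
    g <- random_test_grn(i)
    sc <- scenario_config(threshold = c(0, 0.5)[i %% 2 + 1])
    mg <- suppressWarnings(minimize_grn(g, sc))
    reach <- reachable_subnetwork(g, sc)
    expect_true(all(mg$genes$id %in% reach$genes$id))
    expect_true(all(paste(mg$edges$source, mg$edges$target) %in%
                      paste(reach$edges$source, reach$edges$target)))
  }
})

test_that("re-minimizing an inhibition-free minimization changes nothing", {
  spec <- generator_spec(6, edge_density = 0.3, negative_fraction = 0,
                         cycle_bias = 0.3, n_signals = 1, seed = 77L)
  g <- suppressWarnings(generate_random_grn(spec))
  sc <- scenario_config(threshold = 0.2)
  mg <- suppressWarnings(minimize_grn(g, sc))
  g2 <- suppressWarnings(grn(mg$edges[, c("source", "target", "weight")],
                             genes = g$genes[g$genes$id %in% mg$genes$id, ],
                             signals = g$signals))
  mg2 <- suppressWarnings(minimize_grn(g2, sc))
  expect_equal(paste(mg2$edges$source, mg2$edges$target),
               paste(mg$edges$source, mg$edges$target))
  expect_equal(mg2$edges$flood, mg$edges$flood)
})

test_that("minimized output serializes canonically", {
  ex <- example_grn()
  mg <- minimize_grn(ex$grn, ex$scenario)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_minimized_grn(mg, p)
  lines <- readLines(p)
  expect_equal(lines[1], "# source\ttarget\tweight\tflood")
  expect_true("g4\tg6\t5\t1" %in% lines)
})
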