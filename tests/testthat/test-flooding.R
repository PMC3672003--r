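# The essential-walk calculus and the two flood implementations.

loop_net <- function() {
  # s -> a, a -> b, b -> a: the smallest network with a revisitable cycle
  flood_net(data.frame(from = c("s", "a", "b"), to = c("a", "b", "a"),
                       capacity = c(1, 1, 1)),
            sources = "s")
}

test_that("essentialness allows revisits only when the gap brings a new node", {
  fn <- loop_net()
  expect_true(is_essential_walk(c("s", "a", "b", "a"), fn))
  expect_false(is_essential_walk(c("s", "a", "b", "a", "b"), fn))
  expect_true(is_essential_walk(c("s", "a"), fn))          # simple walk
  expect_error(is_essential_walk(c("s", "b"), fn), "not an edge")
})

test_that("saturation means no essential one-step expansion remains", {
  fn <- loop_net()
  expect_false(is_saturated_walk(c("s", "a"), fn))
  expect_true(is_saturated_walk(c("s", "a", "b", "a"), fn))
  sink_fn <- chain_net(c(2, 3))
  expect_true(is_saturated_walk(c("s", "v01", "v02"), sink_fn))  # out-degree 0
})

test_that("the essential traversal of simple topologies is exact", {
  expect_equal(enumerate_essential_traversal(chain_net(c(1, 1))),
               structure(list(c("s", "v01", "v02")), class = "traversal_set",
                         walks_total = 2L))
  diamond <- flood_net(data.frame(from = c("s", "s", "a", "b"),
                                  to = c("a", "b", "t", "t"),
                                  capacity = c(1, 1, 1, 1)),
                       sources = "s")
  tr <- enumerate_essential_traversal(diamond)
  expect_equal(unclass(tr)[1:2], list(c("s", "a", "t"), c("s", "b", "t")),
               ignore_attr = TRUE)
})

test_that("a three-cycle is unwound until every gap node is already known", {
  fn <- flood_net(data.frame(from = c("s", "a", "b", "c"),
                             to = c("a", "b", "c", "a"),
                             capacity = c(1, 1, 1, 1)),
                  sources = "s")
  tr <- enumerate_essential_traversal(fn)
  expect_equal(length(tr), 1)
  # (s,a,b,c,a) is essential (b is new in the gap) and extends once more to
  # (s,a,b,c,a,b) (c is new in that gap); the next step would close a gap
  # containing only known nodes
  expect_equal(tr[[1]], c("s", "a", "b", "c", "a", "b"))
  expect_true(is_essential_walk(c("s", "a", "b", "c", "a"), fn))
})

test_that("every essential walk is a prefix of a saturated walk, within the length bound", {
  for (i in 1:6) {
    g <- random_test_grn(i, n_max = 4)
    fn <- transform_grn(g, scenario_config())
    tr <- enumerate_essential_traversal(fn, max_walks = 2e5)
    n <- length(fn$ids)
    lens <- lengths(tr)
    expect_true(all(lens <= n^2))
    # prefix-closure: drop the last node of each saturated walk and the
    # result must still be essential and extendable to a member
    for (w in tr) {
      if (length(w) > 2) expect_true(is_essential_walk(w[-length(w)], fn))
    }
  }
})

test_that("the worklist algorithm reproduces the definitional oracle", {
  for (i in 1:40) {
    g <- random_test_grn(i)
    fn <- transform_grn(g, scenario_config())
    a <- flood_network(fn)
    b <- flood_by_definition(fn)
    expect_same_floods(a, b)
    expect_equal(a$walks_expanded, b$walks_expanded)
  }
})

test_that("positive chains carry the running minimum of prefix capacities, exactly", {
  set.seed(11)
  for (r in 1:10) {
    caps <- round(stats::runif(sample(3:10, 1), 0.2, 5), 3)
    st <- flood_network(chain_net(caps))
    expect_identical(st$edges$flood, cummin(caps))
  }
})

test_that("a regulator node polarizes its incoming flood by each edge sign", {
  # positive incoming total 3; outgoing capacities of both signs and both
  # magnitudes relative to the inflow
  fn <- flood_net(data.frame(from = c("s", "u", "u", "u", "u"),
                             to = c("u", "t1", "t2", "t3", "t4"),
                             capacity = c(3, 5, 2, -1, -7)),
                  sources = "s")
  st <- flood_network(fn)
  fl <- function(a, b) st$edges$flood[st$edges$from == a & st$edges$to == b]
  expect_equal(fl("u", "t1"), 3)    # capacity exceeds inflow
  expect_equal(fl("u", "t2"), 2)    # capacity binds
  expect_equal(fl("u", "t3"), -1)   # inhibitory, capacity binds
  expect_equal(fl("u", "t4"), -3)   # inhibitory, inflow binds
})

test_that("a node with negative incoming total propagates nothing", {
  fn <- flood_net(data.frame(from = c("s", "u"), to = c("u", "t"),
                             capacity = c(-3, 5)),
                  sources = "s")
  st <- flood_network(fn)
  expect_equal(st$edges$flood[st$edges$to == "t"], 0)
  st2 <- flood_by_definition(fn)
  expect_equal(st2$edges$flood[st2$edges$to == "t"], 0)
})

test_that("flood is replicated, not conserved, across a fan-out", {
  st <- flood_network(fan_net(2, c(5, 7, 3)))
  outs <- st$edges$flood[st$edges$from == "hub"]
  expect_identical(outs, c(2, 2, 2))
})

test_that("excess records exactly the inflow clipped away by capacity", {
  st <- flood_network(chain_net(c(5, 2, 9)))
  expect_equal(st$edges$excess, c(0, 3, 0))
  # ample capacities everywhere: no excess at all
  st2 <- flood_network(chain_net(c(1, 5, 9)))
  expect_equal(st2$edges$excess, c(0, 0, 0))
})

test_that("flooding is deterministic and independent of edge-list order", {
  g <- random_test_grn(5)
  sc <- scenario_config()
  ref <- flood_network(transform_grn(g, sc))
  set.seed(99)
  for (r in 1:5) {
    perm <- g
    perm$edges <- perm$edges[sample(nrow(perm$edges)), , drop = FALSE]
    g2 <- grn(perm$edges, perm$genes, signals = perm$signals)
    st <- flood_network(transform_grn(g2, sc))
    expect_identical(st$edges, ref$edges)
  }
})

test_that("the walk guard raises a resource error naming the bound", {
  g <- random_test_grn(3)
  fn <- transform_grn(g, scenario_config())
  expect_error(flood_network(fn, max_walks = 2), class = "floodnet_resource_error")
  expect_error(flood_by_definition(fn, max_walks = 2), "max_walks")
})

test_that("networks whose sources have no outgoing edges carry no flood", {
  fn <- flood_net(data.frame(from = "a", to = "b", capacity = 1),
                  sources = "z", nodes = data.frame(id = "z"))
  st <- flood_network(fn)
  expect_true(all(st$edges$flood == 0))
})

test_that("node flood reads the gadget, falling back to direct signal input", {
  g <- suppressWarnings(
    grn(data.frame(source = "a", target = "b", weight = 2),
        genes = data.frame(id = c("a", "b", "c"), basal = 0, saturation = 10),
        signals = list(signal_spec("s1", c(a = 2)))))
  fn <- transform_grn(g, scenario_config())
  st <- flood_network(fn)
  expect_equal(node_flood(st, fn, "c"), 0)        # unregulated gene
  expect_equal(node_flood(st, fn, "a"), 2)        # signal-only, fallback
  expect_equal(node_flood(st, fn, "b"), 2)        # via gadget
  expect_error(node_flood(st, fn, "zzz"), "unknown gene")
  # inhibition exceeding activation silences the gene
  g2 <- grn(data.frame(source = "a", target = "b", weight = -3),
            signals = list(signal_spec("s1", c(a = 5))))
  fn2 <- transform_grn(g2, scenario_config())
  st2 <- flood_network(fn2)
  expect_equal(node_flood(st2, fn2, "b"), 0)
})

test_that("capacity and polarity constraints hold on every computed state", {
  for (i in 1:15) {
    g <- random_test_grn(i)
    st <- flood_network(transform_grn(g, scenario_config()))
    expect_true(validate_flood_state(st))
    e <- st$edges
    expect_true(all(abs(e$flood) <= abs(e$capacity) + 1e-12))
    expect_true(all(e$flood * e$capacity >= 0))
    expect_true(all(e$excess >= 0))
  }
})

test_that("flood reports round numbers through TSV and JSON", {
  ex <- example_grn()
  fn <- transform_grn(ex$grn, ex$scenario)
  st <- flood_network(fn)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_flood_report(st, fn, p, "tsv")
  lines <- readLines(p)
  expect_true(any(grepl("^g2::out\tg6::in\t2\t0\t0$", lines)))
  j <- withr::local_tempfile(fileext = ".json")
  write_flood_report(st, fn, j, "json")
  rep <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(rep$genes$node_flood[rep$genes$gene == "g4"], 1)
})
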