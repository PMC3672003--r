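test_that("TSV edge lists are transcribed directly, with signed weights", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment", "a\tb\t2.0", "b\tc\t-1.5"), p)
  g <- read_grn(p)
  expect_equal(nrow(g$genes), 3)
  expect_equal(g$edges$weight[g$edges$source == "a"], 2)
  expect_equal(g$edges$weight[g$edges$source == "b"], -1.5)
})

test_that("an empty file yields an empty network", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), p)
  g <- read_grn(p)
  expect_equal(nrow(g$genes), 0)
  expect_equal(nrow(g$edges), 0)
})

test_that("parse and validation errors are specific", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t1", "a\tb\t0"), p)
  expect_error(read_grn(p), "zero")
  writeLines(c("a\tb\t1", "b\tc"), p)
  expect_error(read_grn(p), ":2:")     # parse error names the line
  writeLines(c("a\tb\t1", "a\tb\t2"), p)
  expect_error(read_grn(p), "duplicate")
  s <- withr::local_tempfile(fileext = ".sif")
  writeLines("a + b -2", s)
  expect_error(read_grn(s), "disagrees")
  writeLines("a * b", s)
  expect_error(read_grn(s), "relation")
  g <- grn(data.frame(source = "a", target = "b", weight = 1))
  g$genes <- g$genes[g$genes$id != "b", , drop = FALSE]  # dangling endpoint
  expect_error(validate_grn(g), "not a declared gene")
})

test_that("SIF rows carry sign, with optional explicit weight", {
  p <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a + b", "b - c 3... ", "x - y -0.5"), p)
  # second line is malformed on purpose
  expect_error(read_grn(p))
  writeLines(c("a + b", "x - y -0.5"), p)
  g <- read_grn(p)
  expect_equal(g$edges$weight[g$edges$source == "a"], 1)
  expect_equal(g$edges$weight[g$edges$source == "x"], -0.5)
})

test_that("read/write round-trips hold for all three formats on random GRNs", {
  for (i in 1:34) {
    g <- random_test_grn(i)
    for (fmt in c("tsv", "sif", "graphml")) {
      p <- withr::local_tempfile(fileext = paste0(".", fmt))
      write_grn(g, p, fmt)
      g2 <- read_grn(p, fmt)
      expect_equal(g2$edges, g$edges)
      expect_equal(g2$genes$id, g$genes$id)
      if (fmt == "graphml") {
        expect_equal(g2$genes$basal, g$genes$basal)
      }
    }
  }
})

test_that("signals and sinks survive a round-trip through the sidecar", {
  g <- grn(data.frame(source = "a", target = "b", weight = 2),
           genes = data.frame(id = c("a", "b"), basal = c(0, 0.3),
                              saturation = c(5, NA)),
           signals = list(signal_spec("heat", c(a = 1.5))),
           sinks = "b")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_grn(g, p)
  expect_true(file.exists(paste0(p, ".scenario.yaml")))
  g2 <- read_grn(p)
  expect_equal(length(g2$signals), 1)
  expect_equal(g2$signals[[1]]$name, "heat")
  expect_equal(g2$signals[[1]]$targets, g$signals[[1]]$targets)
  expect_equal(g2$sinks, "b")
})

test_that("GraphML preserves basal and saturation node attributes", {
  g <- grn(data.frame(source = "a", target = "b", weight = -1),
           genes = data.frame(id = c("a", "b"), basal = c(0.2, 0),
                              saturation = c(4, 7)))
  p <- withr::local_tempfile(fileext = ".graphml")
  write_grn(g, p)
  g2 <- read_grn(p)
  expect_equal(g2$genes$basal, c(0.2, 0))
  expect_equal(g2$genes$saturation, c(4, 7))
})

test_that("scenario files fill documented defaults and reject unknown genes", {
  g <- grn(data.frame(source = "a", target = "b", weight = 1))
  p <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("signals:",
               "  s1: {targets: [{gene: a, weight: 2}], active: yes}",
               "  s2: {targets: [{gene: b, weight: 1}], active: yes}",
               "  s3: {targets: [{gene: b, weight: 1}], active: no}",
               "active_signals: [s1, s2]"), p)
  sc <- load_scenario(p, g)
  expect_equal(sc$active_signals, c("s1", "s2"))
  expect_equal(sc$threshold, 0)       # missing key -> documented default
  expect_equal(sc$noise_sd, 0)
  expect_equal(sc$seed, 0L)
  writeLines(c("sinks: [zzz]"), p)
  expect_error(load_scenario(p, g), "zzz")
})

test_that("unit-weight policy replaces weights by their sign", {
  g <- grn(data.frame(source = c("a", "b"), target = c("b", "c"),
                      weight = c(2, -3)))
  sc <- scenario_config(unit_weights = TRUE, noise_sd = 0)
  g2 <- apply_weight_policy(g, sc)
  expect_equal(sort(g2$edges$weight), c(-1, 1))
  # identity when nothing requested
  g3 <- apply_weight_policy(g, scenario_config())
  expect_equal(g3$edges, g$edges)
})

test_that("weight noise is seed-deterministic and never flips a sign", {
  for (i in 1:20) {
    g <- random_test_grn(i)
    sc <- scenario_config(unit_weights = TRUE, noise_sd = 0.05, seed = 7L)
    a <- apply_weight_policy(g, sc)
    b <- apply_weight_policy(g, sc)
    expect_identical(a$edges, b$edges)
    expect_true(all(sign(a$edges$weight) ==
                      sign(g$edges$weight[match(
                        paste(a$edges$source, a$edges$target),
                        paste(g$edges$source, g$edges$target))])))
    expect_true(all(a$edges$weight != 0))
  }
})
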