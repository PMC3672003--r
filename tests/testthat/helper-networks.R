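# Shared builders for test networks and independent enumeration oracles.

# Raw flood network: a source-rooted path s -> v1 -> ... -> vk with the
# given signed capacities.
chain_net <- function(caps, source = "s") {
  k <- length(caps)
  nodes <- c(source, sprintf("v%02d", seq_len(k)))
  flood_net(data.frame(from = nodes[-(k + 1)], to = nodes[-1],
                       capacity = caps),
            sources = source)
}

# Fan-out: s -> hub, hub -> leaf_i with the given capacities.
fan_net <- function(in_cap, out_caps, source = "s") {
  leaves <- sprintf("t%02d", seq_along(out_caps))
  flood_net(data.frame(from = c(source, rep("hub", length(out_caps))),
                       to = c("hub", leaves),
                       capacity = c(in_cap, out_caps)),
            sources = source)
}

# Random small GRN used across equivalence/property tests.
random_test_grn <- function(i, n_max = 8, density = 0.25, cycle_bias = 0.4) {
  nf <- c(0, 0.3, 0.6)[i %% 3 + 1]
  spec <- generator_spec(n_genes = 2 + i %% (n_max - 1), edge_density = density,
                         negative_fraction = nf, cycle_bias = cycle_bias,
                         n_signals = 1 + i %% 2, seed = 90000 + i)
  suppressWarnings(generate_random_grn(spec))
}

# Exhaustive hypergeometric upper tail P(X >= k) by enumerating every
# possible retained set of size n from a population with K successes.
enum_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  pop <- c(rep(1, K), rep(0, N - K))
  combs <- utils::combn(N, n)
  hits <- colSums(matrix(pop[combs], nrow = n))
  mean(hits >= k)
}

expect_same_floods <- function(a, b, tol = 1e-9) {
  expect_equal(a$edges$from, b$edges$from)
  expect_equal(a$edges$to, b$edges$to)
  expect_lt(max(0, abs(a$edges$flood - b$edges$flood)), tol)
}
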