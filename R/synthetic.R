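# Random signed GRN generation, the worked-example fixture, and the
# perturbation operations used by the sensitivity analyses. Everything here
# is deterministic under a seed, so every other module is testable without
# any external dataset.

#' Specification for the random GRN generator
#'
#' @param n_genes Number of genes (>= 1).
#' @param edge_density Target edge count as a fraction of `n_genes^2`
#'   (self-loops excluded), in (0, 1]. A warning is issued when
#'   `edge_density * n_genes^2 < n_genes - 1`, i.e. when the density cannot
#'   even accommodate a spanning arborescence; the generator then keeps the
#'   arborescence and the network exceeds the requested density.
#' @param negative_fraction Probability that a regulatory edge is inhibitory.
#' @param weight_range Length-2 positive range from which weight magnitudes
#'   are drawn uniformly.
#' @param cycle_bias Extra feedback (back-)edges per gene, >= 0: each one
#'   runs from a gene to one of its arborescence ancestors, guaranteeing a
#'   directed cycle.
#' @param n_signals Number of environmental signals (>= 1), each targeting
#'   one receptor gene with a positive weight.
#' @param seed Integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_genes, edge_density = 0.15,
                           negative_fraction = 0.2, weight_range = c(0.5, 3),
                           cycle_bias = 0, n_signals = 1L, seed = 1L) {
  stopifnot(is.numeric(n_genes), n_genes >= 1,
            is.numeric(edge_density), edge_density > 0, edge_density <= 1,
            is.numeric(negative_fraction), negative_fraction >= 0,
            negative_fraction <= 1,
            length(weight_range) == 2L, all(weight_range > 0),
            weight_range[1] <= weight_range[2],
            is.numeric(cycle_bias), cycle_bias >= 0,
            is.numeric(n_signals), n_signals >= 1)
  if (edge_density * n_genes^2 < n_genes - 1) {
    warning("edge_density * n_genes^2 < n_genes - 1: requested density below ",
            "spanning-arborescence feasibility; the generated network will ",
            "be denser than requested", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes),
                 edge_density = edge_density,
                 negative_fraction = negative_fraction,
                 weight_range = as.numeric(weight_range),
                 cycle_bias = cycle_bias,
                 n_signals = as.integer(min(n_signals, n_genes)),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a random signed GRN
#'
#' Every gene is guaranteed reachable from at least one signal: the
#' generator first draws a spanning arborescence rooted at the signals'
#' receptor genes, then adds random extra edges up to the requested density
#' and `cycle_bias` feedback edges from genes to their arborescence
#' ancestors. Weight magnitudes are uniform on `weight_range`, negative with
#' probability `negative_fraction` (signal weights are always positive:
#' an active stimulus feeds its receptors). Deterministic under the spec's
#' seed.
#'
#' @param spec A [generator_spec()].
#' @return A validated `grn` with `spec$n_signals` active signals.
#' @export
generate_random_grn <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_genes
  ids <- sprintf("g%0*d", nchar(n), seq_len(n))
  lo <- spec$weight_range[1]; hi <- spec$weight_range[2]
  withr::with_seed(spec$seed, {
    rw <- function(k) {
      stats::runif(k, lo, hi) *
        ifelse(stats::runif(k) < spec$negative_fraction, -1, 1)
    }
    receptors <- sample(ids, spec$n_signals)
    signals <- lapply(seq_along(receptors), function(i) {
      signal_spec(sprintf("sig%d", i),
                  stats::setNames(stats::runif(1, lo, hi), receptors[i]))
    })
    # spanning arborescence rooted at the receptor genes
    connected <- receptors
    pending <- sample(setdiff(ids, receptors))
    parent <- character(0); child <- character(0)
    depth <- stats::setNames(rep(0L, length(receptors)), receptors)
    anc <- stats::setNames(vector("list", n), ids)
    for (gid in pending) {
      p <- if (length(connected) == 1L) connected else sample(connected, 1L)
      parent <- c(parent, p); child <- c(child, gid)
      depth[gid] <- depth[p] + 1L
      anc[[gid]] <- c(p, anc[[p]])
      connected <- c(connected, gid)
    }
    edges <- data.frame(source = parent, target = child,
                        weight = rw(length(parent)), stringsAsFactors = FALSE)
    key <- function(a, b) paste0(a, "\r", b)
    used <- key(edges$source, edges$target)
    # extra random edges up to the requested density
    m_target <- floor(spec$edge_density * n^2)
    extra_needed <- max(0L, m_target - nrow(edges))
    if (extra_needed > 0 && n > 1) {
      all_from <- rep(ids, each = n); all_to <- rep(ids, times = n)
      ok <- all_from != all_to & !key(all_from, all_to) %in% used
      pool <- which(ok)
      take <- pool[sample(length(pool), min(extra_needed, length(pool)))]
      if (length(take)) {
        edges <- rbind(edges, data.frame(source = all_from[take],
                                         target = all_to[take],
                                         weight = rw(length(take)),
                                         stringsAsFactors = FALSE))
        used <- key(edges$source, edges$target)
      }
    }
    # feedback edges from genes to their arborescence ancestors
    n_back <- floor(spec$cycle_bias * n)
    if (n_back > 0) {
      cand_from <- character(0); cand_to <- character(0)
      for (gid in ids) for (a in anc[[gid]]) {
        if (!key(gid, a) %in% used) {
          cand_from <- c(cand_from, gid); cand_to <- c(cand_to, a)
        }
      }
      if (length(cand_from)) {
        take <- sample(length(cand_from), min(n_back, length(cand_from)))
        edges <- rbind(edges, data.frame(source = cand_from[take],
                                         target = cand_to[take],
                                         weight = rw(length(take)),
                                         stringsAsFactors = FALSE))
      }
    }
    grn(edges, ids, signals = signals)
  })
}

#' Worked-example network
#'
#' A six-gene network with one input (signal-fed) gene and one sink
#' (reporter) gene, built so that each qualitative behaviour of the flooding
#' method appears in miniature: replication of one gene's flood onto two
#' high-capacity branches; an inhibitory edge whose flood is bounded by its
#' small upstream inflow rather than its own large capacity; a gene whose
#' activation and inhibition nearly cancel, leaving a weak positive flood
#' that survives only a low threshold; and a feedback branch whose strong
#' inhibition silences a gene completely, disconnecting it (and its
#' regulator) from the sink at every threshold. Capacities are locked by
#' tests so the worked example cannot drift.
#'
#' @return A list with elements `grn` (the network, sink `g6`, signal
#'   `input` on `g1` with weight 5) and `scenario` (threshold 0, saturations
#'   10, seed 0).
#' @examples
#' ex <- example_grn()
#' mg <- minimize_grn(ex$grn, ex$scenario)
#' mg$edges
#' @export
example_grn <- function() {
  edges <- data.frame(
    source = c("g1", "g1", "g3", "g3", "g4", "g6", "g5", "g2"),
    target = c("g3", "g4", "g4", "g6", "g6", "g5", "g2", "g6"),
    weight = c(2, 3, -2.5, 5, 5, 1.5, -4, 2),
    stringsAsFactors = FALSE)
  genes <- data.frame(id = sprintf("g%d", 1:6), basal = 0, saturation = 10,
                      stringsAsFactors = FALSE)
  net <- grn(edges, genes,
             signals = list(signal_spec("input", c(g1 = 5))),
             sinks = "g6")
  list(grn = net,
       scenario = scenario_config(active_signals = "input", threshold = 0,
                                  default_saturation = 10, seed = 0L))
}

#' Remove a random fraction of regulatory edges
#'
#' Uniformly removes `floor(fraction * |E|)` edges; genes are kept even if
#' they become unreachable (validation then warns), as required by
#' missing-data sensitivity analyses.
#'
#' @param grn A `grn`.
#' @param fraction Fraction of edges to remove, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `grn` with the surviving edges.
#' @export
remove_random_links <- function(grn, fraction, seed = 0L) {
  stopifnot(inherits(grn, "grn"), is.numeric(fraction),
            fraction >= 0, fraction < 1)
  k <- floor(fraction * nrow(grn$edges))
  if (k == 0) return(grn)
  drop <- withr::with_seed(seed, sample(nrow(grn$edges), k))
  suppressWarnings(grn(grn$edges[-drop, , drop = FALSE], grn$genes,
                       signals = grn$signals, sinks = grn$sinks))
}

#' Multiplicatively perturb regulatory weights
#'
#' Each weight `w` becomes `w * (1 + u)` with `u` uniform on
#' `[-rel_magnitude, +rel_magnitude]`; the multiplicative form preserves
#' every sign by construction. Noise is drawn in canonical edge order, so
#' the result is independent of the input edge ordering.
#'
#' @param grn A `grn`.
#' @param rel_magnitude Maximum relative perturbation, >= 0 (and < 1 so
#'   weights cannot vanish).
#' @param seed Integer seed.
#' @return A `grn` with perturbed weights.
#' @export
perturb_weights <- function(grn, rel_magnitude, seed = 0L) {
  stopifnot(inherits(grn, "grn"), is.numeric(rel_magnitude),
            rel_magnitude >= 0, rel_magnitude < 1)
  if (rel_magnitude == 0 || !nrow(grn$edges)) return(grn)
  e <- grn$edges   # canonical order
  u <- withr::with_seed(seed, stats::runif(nrow(e), -rel_magnitude, rel_magnitude))
  e$weight <- e$weight * (1 + u)
  suppressWarnings(grn(e, grn$genes, signals = grn$signals, sinks = grn$sinks))
}
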