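# Quantitative assessment of minimization: reporter-gene enrichment,
# size/flood statistics, and the missing-data robustness experiment.

#' Reporter-gene enrichment of a minimized network
#'
#' Tests whether reporter genes are over-represented among the genes
#' retained by minimization, against the hypergeometric null of drawing the
#' retained set uniformly from the population (normally the reachable
#' sub-network). The p-value is the upper tail `P(X >= k)` with `X ~
#' Hypergeom(N, K, n)`: `N` genes in the population, `K` of them reporters,
#' `n` retained, `k` reporters retained. Bonferroni correction multiplies by
#' the number of hypotheses tested in the run, capped at 1.
#'
#' @param population Character vector: genes in the population.
#' @param reporters Character vector: reporter genes (subset of population).
#' @param retained Character vector: genes retained by minimization (subset
#'   of population).
#' @param n_tests Bonferroni family size, >= 1 (e.g. number of scenarios
#'   evaluated together).
#' @return An object of class `enrichment_result` with fields `population`
#'   (N), `successes` (K), `sample` (n), `observed` (k), `p_raw`,
#'   `p_bonferroni`, `n_tests`.
#' @export
hypergeometric_enrichment <- function(population, reporters, retained,
                                      n_tests = 1L) {
  population <- unique(as.character(population))
  reporters <- unique(as.character(reporters))
  retained <- unique(as.character(retained))
  if (!length(population)) stop("empty population", call. = FALSE)
  if (length(setdiff(reporters, population))) {
    stop("reporters must be a subset of the population", call. = FALSE)
  }
  if (length(setdiff(retained, population))) {
    stop("retained genes must be a subset of the population", call. = FALSE)
  }
  stopifnot(is.numeric(n_tests), n_tests >= 1)
  N <- length(population); K <- length(reporters); n <- length(retained)
  k <- length(intersect(reporters, retained))
  p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(population = N, successes = K, sample = n, observed = k,
                 p_raw = p_raw,
                 p_bonferroni = min(1, p_raw * n_tests),
                 n_tests = as.integer(n_tests)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> %d/%d reporters retained (sample %d of %d); p = %.3g (Bonferroni x%d: %.3g)\n",
    x$observed, x$successes, x$sample, x$population, x$p_raw, x$n_tests,
    x$p_bonferroni))
  invisible(x)
}

#' Size and flood statistics of a minimization
#'
#' Summarizes a minimization run: node and link counts before and after,
#' counts for the reachable sub-network, the percentage of links removed
#' relative to the reachable network
#' (`100 * (1 - links_after / links_reachable)`), and the total flood
#' (sum of absolute floods over retained gene-gene edges; this convention
#' is the package's own and is labelled as such in outputs).
#'
#' @param before The original `grn`.
#' @param after The `minimized_grn` derived from it.
#' @param reachable The reachable sub-network `grn` (see
#'   [reachable_subnetwork()]).
#' @return A list with fields `nodes_before`, `nodes_after`, `links_before`,
#'   `links_after`, `reachable_nodes`, `reachable_links`,
#'   `pct_links_removed`, `total_flood_abs`, and `gene_floods` (per-gene
#'   node floods of the minimized network).
#' @export
network_stats <- function(before, after, reachable) {
  stopifnot(inherits(before, "grn"), inherits(after, "minimized_grn"),
            inherits(reachable, "grn"))
  if (length(setdiff(after$genes$id, before$genes$id))) {
    stop("minimized network contains genes absent from the original network",
         call. = FALSE)
  }
  lr <- nrow(reachable$edges)
  list(nodes_before = nrow(before$genes),
       nodes_after = nrow(after$genes),
       links_before = nrow(before$edges),
       links_after = nrow(after$edges),
       reachable_nodes = nrow(reachable$genes),
       reachable_links = lr,
       pct_links_removed = if (lr > 0) 100 * (1 - nrow(after$edges) / lr) else NA_real_,
       total_flood_abs = sum(abs(after$edges$flood)),
       gene_floods = after$genes[, c("id", "node_flood")])
}

mg_edge_keys <- function(mg) {
  if (!nrow(mg$edges)) character(0)
  else paste0(mg$edges$source, "->", mg$edges$target)
}

#' Missing-data sensitivity experiment
#'
#' Emulates minimization under network incompleteness: for each removal
#' fraction and replicate, a random set of links is removed before
#' minimization, and the result is compared with the minimization of the
#' full network. Sensitivity is the fraction of the full-data minimized
#' links ("true positive links", the only ground truth available) still
#' present in the depleted minimization.
#'
#' @param grn A `grn`.
#' @param config A `flood_scenario`.
#' @param fractions Numeric vector of removal fractions in `[0, 1)`.
#' @param n_rep Replicates per fraction (>= 1).
#' @param seed Integer seed governing all removals.
#' @return A data frame with one row per fraction: mean and sd of retained
#'   link counts and of sensitivity across replicates. The per-replicate
#'   table is attached as attribute `"replicates"`.
#' @export
sensitivity_experiment <- function(grn, config = scenario_config(),
                                   fractions = c(0, 0.25, 0.5), n_rep = 5L,
                                   seed = 0L) {
  stopifnot(all(fractions >= 0), all(fractions < 1), n_rep >= 1)
  baseline <- suppressWarnings(minimize_grn(grn, config))
  base_keys <- mg_edge_keys(baseline)
  subseeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, length(fractions) * n_rep),
           nrow = length(fractions)))
  rows <- list()
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    for (r in seq_len(n_rep)) {
      dep <- if (f == 0) grn else remove_random_links(grn, f, subseeds[i, r])
      mg <- suppressWarnings(minimize_grn(dep, config))
      keys <- mg_edge_keys(mg)
      sens <- if (length(base_keys)) mean(base_keys %in% keys) else 1
      rows[[length(rows) + 1L]] <- data.frame(
        fraction = f, rep = r, links_retained = length(keys),
        sensitivity = sens)
    }
  }
  detail <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(detail, detail$fraction), function(d) {
    data.frame(fraction = d$fraction[1], n_rep = nrow(d),
               mean_links = mean(d$links_retained),
               sd_links = stats::sd(d$links_retained),
               mean_sensitivity = mean(d$sensitivity),
               sd_sensitivity = stats::sd(d$sensitivity))
  }))
  agg <- agg[order(agg$fraction), , drop = FALSE]
  rownames(agg) <- NULL
  attr(agg, "replicates") <- detail
  agg
}
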