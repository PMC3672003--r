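# Phase three: threshold imposition, sink-connectivity pruning,
# reachable-sub-network extraction, and the end-to-end minimization
# pipeline.

subset_flood_net <- function(fn, keep_rows) {
  e <- fn$edges[keep_rows, c("from", "to", "capacity"), drop = FALSE]
  present <- unique(c(e$from, e$to))
  flood_net(e,
            sources = intersect(fn$sources, present),
            sinks = intersect(fn$sinks, present),
            nodes = fn$nodes[fn$nodes$id %in% present, , drop = FALSE])
}

#' Impose a flood threshold on a flooded network
#'
#' Retains exactly the edges whose flood magnitude strictly exceeds `t`
#' (`|f(u,v)| > t`); with `t = 0` this keeps exactly the "active" (non-zero
#' flood) edges. Nodes left without any incident retained edge are dropped.
#'
#' @param state A `flood_state` computed on `fn`.
#' @param fn The `flood_net` the state was computed on.
#' @param t Threshold, a single number >= 0.
#' @return A `flood_net` containing the surviving edges and nodes.
#' @export
apply_threshold <- function(state, fn, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("threshold must be a single number >= 0", call. = FALSE)
  }
  have <- edge_keys(state$edges)
  want <- edge_keys(fn$edges)
  if (!all(want %in% have)) {
    stop("flood state does not cover this network's edges", call. = FALSE)
  }
  fl <- state$edges$flood[match(want, have)]
  subset_flood_net(fn, abs(fl) > t)
}

#' Prune a flood network to source-to-sink paths
#'
#' Retains exactly the edges lying on some directed path from a source to a
#' sink within the current edge set, computed as (forward-reachable from the
#' sources) intersected with (backward-reachable from the sinks). Applied
#' after thresholding, this discards the parts of the network that became
#' disconnected from the outputs.
#'
#' @param fn A `flood_net`.
#' @param sinks Sink node ids; defaults to `fn$sinks`. Must be non-empty.
#' @return A `flood_net`; empty (with a warning) when no sink is reachable.
#' @export
prune_to_sinks <- function(fn, sinks = fn$sinks) {
  sinks <- as.character(sinks)
  if (!length(sinks)) {
    stop("prune_to_sinks requires a non-empty sink set", call. = FALSE)
  }
  sinks <- intersect(sinks, fn$ids)
  empty <- function() {
    warning("no sink is reachable from the sources; returning an empty network",
            call. = FALSE)
    subset_flood_net(fn, rep(FALSE, nrow(fn$edges)))
  }
  if (!length(sinks) || !nrow(fn$edges) || !length(fn$sources)) return(empty())
  g <- igraph::graph_from_data_frame(fn$edges[, c("from", "to")],
                                     directed = TRUE,
                                     vertices = data.frame(name = fn$ids))
  fwd <- unique(unlist(lapply(intersect(fn$sources, fn$ids), function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
  bwd <- unique(unlist(lapply(sinks, function(s) {
    names(igraph::subcomponent(g, s, mode = "in"))
  })))
  keep <- fn$edges$from %in% fwd & fn$edges$to %in% bwd
  if (!any(keep)) return(empty())
  subset_flood_net(fn, keep)
}

#' Reachable sub-network of a GRN
#'
#' The sub-network of genes forward-reachable (by directionality alone,
#' ignoring weights and floods) from the active signals' receptor genes and
#' from basally expressed genes. This is the denominator against which
#' minimization reduction percentages are reported.
#'
#' @param grn A `grn`.
#' @param config A `flood_scenario` naming the active signals.
#' @return A `grn` restricted to the reachable genes and the edges leaving
#'   them, carrying the active signals and any sinks that survive.
#' @export
reachable_subnetwork <- function(grn, config = scenario_config()) {
  specs <- active_signal_specs(grn, config)
  start <- unique(c(unlist(lapply(specs, function(s) s$targets$gene)),
                    grn$genes$id[grn$genes$basal > 0]))
  reach <- reachable_gene_ids(grn, start)
  e <- grn$edges[grn$edges$source %in% reach, , drop = FALSE]
  sinks <- intersect(effective_sinks(grn, config) %||% character(), reach)
  suppressWarnings(grn(e, grn$genes[grn$genes$id %in% reach, , drop = FALSE],
                       signals = specs,
                       sinks = if (length(sinks)) sinks else NULL))
}

#' Minimize a GRN by flood analysis
#'
#' The end-to-end three-phase pipeline: apply the scenario's weight policy,
#' transform the GRN into a flood network ([transform_grn()]), compute the
#' floods ([flood_network()]), impose the flood threshold
#' ([apply_threshold()]), prune to source-to-sink paths when sinks are given
#' ([prune_to_sinks()]), and map the surviving network back to gene space
#' ([reverse_transform()]). Deterministic for a fixed scenario seed and
#' independent of the input edge ordering.
#'
#' @param grn A validated `grn`.
#' @param config A `flood_scenario`.
#' @return A `minimized_grn`; its `provenance` records the active signals,
#'   threshold, seed, and node/edge counts after each stage.
#' @export
minimize_grn <- function(grn, config = scenario_config()) {
  stopifnot(inherits(grn, "grn"), inherits(config, "flood_scenario"))
  g2 <- if (config$unit_weights || config$noise_sd > 0) {
    apply_weight_policy(grn, config)
  } else grn
  fn <- transform_grn(g2, config)
  st <- flood_network(fn, max_walks = config$max_walks,
                      zero_tol = config$zero_tol)
  stages <- list(transformed = c(nodes = length(fn$ids), links = nrow(fn$edges)))
  fn_t <- apply_threshold(st, fn, config$threshold)
  stages$thresholded <- c(nodes = length(fn_t$ids), links = nrow(fn_t$edges))
  sinks <- effective_sinks(g2, config)
  if (length(sinks)) {
    fn_t <- prune_to_sinks(fn_t, gate_out_id(sinks))
    stages$sink_pruned <- c(nodes = length(fn_t$ids), links = nrow(fn_t$edges))
  }
  specs <- active_signal_specs(g2, config)
  mg <- reverse_transform(fn_t, st, threshold = config$threshold,
                          provenance = list(
                            active_signals = vapply(specs, `[[`, "", "name"),
                            threshold = config$threshold,
                            seed = config$seed,
                            sinks = sinks,
                            stages = stages))
  mg
}

#' Write a minimized network to a TSV file
#'
#' Emits `# source target weight flood` edge rows followed by a
#' `# gene node_flood signal_flood basal_flood` section. Output is in
#' canonical (source, target) order with a fixed number format, so two
#' equivalent minimizations serialize to byte-identical files.
#'
#' @param mg A `minimized_grn`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_minimized_grn <- function(mg, path) {
  stopifnot(inherits(mg, "minimized_grn"))
  e <- mg$edges
  g <- mg$genes
  lines <- c("# source\ttarget\tweight\tflood",
             if (nrow(e)) paste(e$source, e$target, fmt_num(e$weight),
                                fmt_num(e$flood), sep = "\t"),
             "# gene\tnode_flood\tsignal_flood\tbasal_flood",
             if (nrow(g)) paste(g$id, fmt_num(g$node_flood),
                                fmt_num(g$signal_flood),
                                fmt_num(g$basal_flood), sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
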