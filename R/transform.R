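# Phase one and its inverse: convert a GRN plus its active signals into a
# flood network, and map flood results back to gene space.
#
# Every gene v becomes a saturation gadget — a node pair (v::in, v::out)
# joined by an edge whose positive capacity caps the total flood through the
# gene. Gene-gene regulatory edges attach as (u::out, v::in), the only wiring
# under which the gadget edge limits the flood a gene can pass downstream.
# Active environmental signals become source nodes "@s:<name>", and a single
# always-active basal source "@b" feeds each gene's basal expression. Signal
# and basal links attach to the target's gate *output* — external input
# bypasses the gene's saturation gadget — with a scenario switch
# (`signals_to_gate_in`) for the alternative convention.

gate_in_id <- function(gene) paste0(gene, "::in")
gate_out_id <- function(gene) paste0(gene, "::out")
signal_node_id <- function(name) paste0("@s:", name)
BASAL_NODE <- "@b"

#' Transform a GRN into a flood network
#'
#' Builds the flood network on which floods are computed: one source node
#' per active signal, one always-active basal source node (present even when
#' no gene has basal expression, so node-count arithmetic is stable), one
#' saturation gadget per gene with capacity equal to the gene's saturation
#' (or the scenario default), signal/basal links into the receptor genes,
#' and one capacity-`w` link per regulatory edge. Inactive signals
#' contribute nothing.
#'
#' @param grn A validated `grn`.
#' @param config A `flood_scenario`; supplies the active signal set, the
#'   default saturation, and the gate convention for external inputs.
#' @return A `flood_net` whose sources are the active signal nodes plus the
#'   basal node, and whose sinks are the gate-output nodes of the GRN's (or
#'   scenario's) sink genes.
#' @export
transform_grn <- function(grn, config = scenario_config()) {
  stopifnot(inherits(grn, "grn"), inherits(config, "flood_scenario"))
  g <- grn$genes
  bad <- grepl("::", g$id, fixed = TRUE) | startsWith(g$id, "@")
  if (any(bad)) {
    stop("gene id collides with internal node naming ('::' or leading '@'): ",
         paste(g$id[bad], collapse = ", "), call. = FALSE)
  }
  specs <- active_signal_specs(grn, config)
  basal_genes <- g$id[g$basal > 0]
  if (!length(specs) && !length(basal_genes)) {
    stop("no active sources: no active signal and no gene with basal > 0",
         call. = FALSE)
  }
  sat <- ifelse(is.na(g$saturation), config$default_saturation, g$saturation)
  ext_gate <- if (config$signals_to_gate_in) gate_in_id else gate_out_id

  sig_ids <- vapply(specs, function(s) signal_node_id(s$name), "")
  nodes <- rbind(
    data.frame(id = sig_ids, role = rep("signal", length(sig_ids)),
               gene = rep(NA_character_, length(sig_ids)),
               stringsAsFactors = FALSE),
    data.frame(id = BASAL_NODE, role = "basal", gene = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = gate_in_id(g$id), role = rep("gate_in", nrow(g)),
               gene = g$id, stringsAsFactors = FALSE),
    data.frame(id = gate_out_id(g$id), role = rep("gate_out", nrow(g)),
               gene = g$id, stringsAsFactors = FALSE))

  gadget <- data.frame(from = gate_in_id(g$id), to = gate_out_id(g$id),
                       capacity = sat, stringsAsFactors = FALSE)
  sig <- if (length(specs)) do.call(rbind, lapply(specs, function(s) {
    data.frame(from = signal_node_id(s$name), to = ext_gate(s$targets$gene),
               capacity = s$targets$weight, stringsAsFactors = FALSE)
  }))
  bas <- if (length(basal_genes)) {
    data.frame(from = BASAL_NODE, to = ext_gate(basal_genes),
               capacity = g$basal[g$basal > 0], stringsAsFactors = FALSE)
  }
  ee <- grn$edges
  reg <- if (nrow(ee)) {
    data.frame(from = gate_out_id(ee$source), to = gate_in_id(ee$target),
               capacity = ee$weight, stringsAsFactors = FALSE)
  }
  edges <- rbind(gadget, sig, bas, reg)

  sinks <- effective_sinks(grn, config)
  flood_net(edges,
            sources = c(vapply(specs, function(s) signal_node_id(s$name), ""),
                        BASAL_NODE),
            sinks = if (length(sinks)) gate_out_id(sinks) else character(),
            nodes = nodes)
}

# Node activity restricted to the edges actually present in `fn` (which may
# be a thresholded/pruned sub-network), with floods looked up in `state`.
node_activity <- function(fn, state, gene) {
  in_id <- gate_in_id(gene); out_id <- gate_out_id(gene)
  in_i <- match(in_id, fn$ids); out_i <- match(out_id, fn$ids)
  gadget <- 0
  if (!is.na(in_i) && !is.na(out_i) && fn$C[in_i, out_i] != 0) {
    gadget <- flood_of(state, in_id, out_id)
  }
  if (gadget > state$zero_tol) return(gadget)
  e <- fn$edges
  roles <- fn$nodes$role[match(e$from, fn$nodes$id)]
  direct_rows <- which(roles %in% c("signal", "basal") &
                         e$to %in% c(in_id, out_id))
  direct <- vapply(direct_rows, function(i) flood_of(state, e$from[i], e$to[i]), 0)
  max(0, gadget, direct)
}

#' Map a flooded (possibly thresholded) flood network back to gene space
#'
#' Reverses the phase-one transformation: each saturation gadget collapses
#' back to its gene, gene-gene edges inherit the flood of their
#' `(u::out, v::in)` counterpart, the gadget-edge flood becomes the gene's
#' node flood, and direct signal/basal inflows are reported as per-gene
#' annotations rather than edges. Genes with no incident retained edge and
#' zero node activity are dropped.
#'
#' @param fn A `flood_net` produced by [transform_grn()], possibly already
#'   passed through [apply_threshold()] and [prune_to_sinks()].
#' @param state The `flood_state` computed on the *untresholded* network;
#'   it must cover every edge of `fn` (a consistency error otherwise).
#' @param threshold Threshold recorded in the result (`NA` when none was
#'   applied).
#' @param provenance Free-form list recorded in the result (scenario, seed,
#'   stage sizes).
#' @return An object of class `minimized_grn` with elements `genes`
#'   (id, node_flood, signal_flood, basal_flood), `edges`
#'   (source, target, weight, flood), `threshold`, `provenance`.
#' @export
reverse_transform <- function(fn, state, threshold = NA_real_,
                              provenance = list()) {
  stopifnot(inherits(fn, "flood_net"), inherits(state, "flood_state"))
  have <- edge_keys(state$edges)
  want <- edge_keys(fn$edges)
  if (!all(want %in% have)) {
    stop("flood state does not cover this network's edges; ",
         "it was computed on a different network", call. = FALSE)
  }
  fl <- state$edges$flood[match(want, have)]
  nd <- fn$nodes
  e <- fn$edges
  from_role <- nd$role[match(e$from, nd$id)]
  to_role <- nd$role[match(e$to, nd$id)]
  is_reg <- from_role == "gate_out" & to_role == "gate_in"
  edges <- data.frame(source = nd$gene[match(e$from[is_reg], nd$id)],
                      target = nd$gene[match(e$to[is_reg], nd$id)],
                      weight = e$capacity[is_reg],
                      flood = fl[is_reg],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL

  genes <- sort(unique(stats::na.omit(nd$gene)), method = "radix")
  nf <- vapply(genes, function(g) node_activity(fn, state, g), 0)
  ext_sum <- function(role) {
    vapply(genes, function(g) {
      rows <- from_role == role & e$to %in% c(gate_in_id(g), gate_out_id(g))
      if (!any(rows)) 0 else sum(fl[rows])
    }, 0)
  }
  gtab <- data.frame(id = genes, node_flood = nf,
                     signal_flood = ext_sum("signal"),
                     basal_flood = ext_sum("basal"),
                     stringsAsFactors = FALSE)
  keep <- gtab$id %in% c(edges$source, edges$target) |
    abs(gtab$node_flood) > state$zero_tol
  gtab <- gtab[keep, , drop = FALSE]
  rownames(gtab) <- NULL
  structure(list(genes = gtab, edges = edges,
                 threshold = threshold, provenance = provenance),
            class = "minimized_grn")
}

#' @export
print.minimized_grn <- function(x, ...) {
  cat(sprintf("<minimized_grn> %d genes, %d edges%s\n",
              nrow(x$genes), nrow(x$edges),
              if (is.na(x$threshold)) "" else sprintf(" (threshold %g)", x$threshold)))
  invisible(x)
}

#' Export a transformed flood network
#'
#' TSV: a `# transformed` header followed by `from to capacity` rows.
#' GraphML: node attribute `role`, edge attribute `capacity`.
#'
#' @param fn A `flood_net`.
#' @param path Output file.
#' @param format `"tsv"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_flood_network <- function(fn, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    e <- fn$edges
    lines <- c("# transformed", "# from\tto\tcapacity",
               if (nrow(e)) paste(e$from, e$to, fmt_num(e$capacity), sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    ed <- fn$edges
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed$from, to = ed$to, capacity = ed$capacity),
      directed = TRUE,
      vertices = data.frame(name = fn$nodes$id, role = fn$nodes$role))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
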