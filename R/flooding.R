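# The network-flooding calculus: flood networks, essential-walk predicates,
# a brute-force definitional oracle, and the scalable worklist algorithm.
#
# A flood network is a directed graph with signed, non-zero edge capacities
# and a set of source nodes. Flood propagates from the sources along
# "essential" walks: walks that may revisit nodes, but every revisit must be
# separated from the previous visit by at least one node that is new to the
# walk's prefix. This bounds traversal through cycles while still letting
# feedback loops of arbitrary size carry information once.
#
# Both implementations process walk expansions in the same canonical order —
# breadth-first by walk length, ties broken byte-lexicographically on the
# node-id sequence — so their floating-point arithmetic is performed in the
# same sequence and results agree to rounding error. Node ids are mapped to
# their radix-sort ranks, hence integer comparisons realize the
# lexicographic tie-break.

#' Construct a flood network
#'
#' Low-level constructor for the substrate of flood computation. Most users
#' obtain flood networks from [transform_grn()]; this constructor exists so
#' the calculus can be exercised on arbitrary signed directed graphs.
#'
#' @param edges Data frame with columns `from`, `to` (node ids) and
#'   `capacity` (signed, finite, non-zero).
#' @param sources Character vector of source node ids (may be empty only for
#'   networks that will never be flooded).
#' @param sinks Optional character vector of sink node ids.
#' @param nodes Optional data frame with columns `id`, `role` (one of
#'   `"signal"`, `"basal"`, `"gate_in"`, `"gate_out"`, `"plain"`) and `gene`
#'   (originating gene id or `NA`); isolated nodes may be declared here.
#' @return An object of class `flood_net`.
#' @export
flood_net <- function(edges, sources = character(), sinks = character(),
                      nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "capacity") %in% names(edges))) {
    stop("edges must have columns from, to, capacity", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$capacity <- as.numeric(edges$capacity)
  if (any(!is.finite(edges$capacity)) || any(edges$capacity == 0)) {
    stop("edge capacities must be finite and non-zero", call. = FALSE)
  }
  if (anyDuplicated(paste0(edges$from, "\r", edges$to))) {
    stop("duplicate edge in flood network", call. = FALSE)
  }
  ids <- sort(unique(c(edges$from, edges$to, sources, sinks,
                       if (!is.null(nodes)) as.character(nodes$id))),
              method = "radix")
  n <- length(ids)
  ntab <- data.frame(id = ids, role = rep("plain", n),
                     gene = rep(NA_character_, n), stringsAsFactors = FALSE)
  if (!is.null(nodes)) {
    nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
    m <- match(as.character(nodes$id), ids)
    if ("role" %in% names(nodes)) ntab$role[m] <- as.character(nodes$role)
    if ("gene" %in% names(nodes)) ntab$gene[m] <- as.character(nodes$gene)
  }
  from_i <- match(edges$from, ids)
  to_i <- match(edges$to, ids)
  ord <- order(from_i, to_i)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  from_i <- from_i[ord]; to_i <- to_i[ord]
  C <- matrix(0, n, n)
  C[cbind(from_i, to_i)] <- edges$capacity
  out <- rep(list(integer()), n)
  if (nrow(edges)) {
    sp <- split(to_i, from_i)
    for (f in names(sp)) out[[as.integer(f)]] <- sort(sp[[f]])
  }
  src_i <- match(unique(sources), ids)
  snk_i <- match(unique(sinks), ids)
  if (anyNA(src_i)) stop("source id not a node of the network", call. = FALSE)
  if (anyNA(snk_i)) stop("sink id not a node of the network", call. = FALSE)
  is_source <- rep(FALSE, n); is_source[src_i] <- TRUE
  structure(list(ids = ids, nodes = ntab,
                 edges = cbind(edges,
                               data.frame(from_i = from_i, to_i = to_i)),
                 C = C, out = out,
                 sources = ids[sort(src_i)], sinks = ids[sort(snk_i)],
                 sources_i = sort(src_i), sinks_i = sort(snk_i),
                 is_source = is_source),
            class = "flood_net")
}

#' @export
print.flood_net <- function(x, ...) {
  cat(sprintf("<flood_net> %d nodes, %d edges, %d source(s), %d sink(s)\n",
              length(x$ids), nrow(x$edges), length(x$sources), length(x$sinks)))
  invisible(x)
}

# paste0() recycles zero-length inputs to "", so key building must be
# guarded for empty edge tables
edge_keys <- function(df, a = "from", b = "to") {
  if (!nrow(df)) character(0) else paste0(df[[a]], "\r", df[[b]])
}

walk_to_int <- function(fn, walk) {
  w <- match(as.character(walk), fn$ids)
  if (anyNA(w)) stop("walk contains unknown node id: ",
                     paste(walk[is.na(w)], collapse = ", "), call. = FALSE)
  w
}

check_walk_edges <- function(fn, seq) {
  if (length(seq) < 2L) return(invisible(TRUE))
  caps <- fn$C[cbind(seq[-length(seq)], seq[-1L])]
  if (any(caps == 0)) {
    k <- which(caps == 0)[1L]
    stop(sprintf("walk step %s -> %s is not an edge of the network",
                 fn$ids[seq[k]], fn$ids[seq[k + 1L]]), call. = FALSE)
  }
  invisible(TRUE)
}

# Definitional essentialness check on an integer node sequence: for every
# pair of successive appearances (i, j) of a node, some node strictly
# between positions i and j must be absent from the prefix (x1..xi).
is_essential_int <- function(seq) {
  if (!anyDuplicated(seq)) return(TRUE)
  for (v in unique(seq[duplicated(seq)])) {
    pos <- which(seq == v)
    for (p in seq_len(length(pos) - 1L)) {
      i <- pos[p]; j <- pos[p + 1L]
      if (j == i + 1L) return(FALSE)
      if (all(seq[(i + 1L):(j - 1L)] %in% seq[1:i])) return(FALSE)
    }
  }
  TRUE
}

#' Essential-walk predicate
#'
#' A walk may revisit nodes, but between any two successive appearances of
#' the same node at positions `i < j` there must be at least one node that
#' does not appear in the walk prefix up to position `i`. Every simple walk
#' is essential; an immediate repeat (a self-loop step) never is.
#'
#' @param walk Character vector of node ids; consecutive pairs must be edges
#'   of `fn` (a structural error otherwise).
#' @param fn A `flood_net`.
#' @return `TRUE` or `FALSE`.
#' @export
is_essential_walk <- function(walk, fn) {
  seq <- walk_to_int(fn, walk)
  check_walk_edges(fn, seq)
  is_essential_int(seq)
}

#' Saturated-walk predicate
#'
#' An essential walk is saturated when no single-step expansion along an
#' outgoing edge of its last node is still essential; walks ending at a node
#' with no outgoing edges are saturated.
#'
#' @inheritParams is_essential_walk
#' @return `TRUE` or `FALSE`.
#' @export
is_saturated_walk <- function(walk, fn) {
  seq <- walk_to_int(fn, walk)
  check_walk_edges(fn, seq)
  if (!is_essential_int(seq)) stop("walk is not essential", call. = FALSE)
  for (w in fn$out[[seq[length(seq)]]]) {
    if (is_essential_int(c(seq, w))) return(FALSE)
  }
  TRUE
}

resource_error <- function(max_walks) {
  stop(structure(class = c("floodnet_resource_error", "error", "condition"),
                 list(message = sprintf(
                        "essential traversal exceeded max_walks = %g; raise max_walks or reduce the network",
                        max_walks),
                      call = NULL)))
}

# Breadth-first enumeration of every essential walk from the sources, in
# canonical order; definitional (re-checks the full predicate on every
# candidate and sorts each level explicitly). Returns the walks plus a flag
# marking the saturated ones.
enumerate_walks_definitional <- function(fn, max_walks = 1e6) {
  if (!length(fn$sources_i)) {
    stop("flood network has no source nodes", call. = FALSE)
  }
  sort_level <- function(walks) {
    if (length(walks) < 2L) return(walks)
    m <- as.data.frame(do.call(rbind, walks))
    walks[do.call(order, m)]
  }
  frontier <- list()
  for (s in fn$sources_i) for (v in fn$out[[s]]) {
    frontier[[length(frontier) + 1L]] <- c(s, v)
  }
  frontier <- sort_level(frontier)
  all_walks <- list()
  saturated <- logical()
  while (length(frontier)) {
    nxt <- list()
    for (seq in frontier) {
      all_walks[[length(all_walks) + 1L]] <- seq
      if (length(all_walks) > max_walks) resource_error(max_walks)
      kids <- 0L
      for (w in fn$out[[seq[length(seq)]]]) {
        cand <- c(seq, w)
        if (is_essential_int(cand)) {
          kids <- kids + 1L
          nxt[[length(nxt) + 1L]] <- cand
        }
      }
      saturated[[length(saturated) + 1L]] <- (kids == 0L)
    }
    frontier <- sort_level(nxt)
  }
  list(walks = all_walks, saturated = saturated)
}

#' Enumerate the essential traversal
#'
#' Returns the set of all saturated essential walks from the sources, in
#' breadth-first order with byte-lexicographic tie-breaks — the index set
#' over which network floods are accumulated. Every essential walk of the
#' network is a prefix of some member.
#'
#' @param fn A `flood_net` with at least one source.
#' @param max_walks Resource guard on the number of essential walks.
#' @return A list of walks (character vectors of node ids) of class
#'   `traversal_set`, with attribute `walks_total` (number of essential
#'   walks expanded, saturated or not).
#' @export
enumerate_essential_traversal <- function(fn, max_walks = 1e6) {
  enum <- enumerate_walks_definitional(fn, max_walks)
  sat <- enum$walks[enum$saturated]
  structure(lapply(sat, function(s) fn$ids[s]),
            class = "traversal_set",
            walks_total = length(enum$walks))
}

# Assemble a flood_state from final matrices/vectors.
build_flood_state <- function(fn, F, ntv, ntrep, walks, zero_tol) {
  e <- fn$edges
  fl <- F[cbind(e$from_i, e$to_i)]
  tail_nt <- ntv[e$from_i]
  excess <- pmax(0, tail_nt - abs(fl))
  excess[fn$is_source[e$from_i]] <- 0
  cap <- e$capacity
  stopifnot(all(abs(fl) <= abs(cap) * (1 + 1e-12) + 1e-12),
            all(fl * cap >= -1e-12))
  structure(list(edges = data.frame(from = e$from, to = e$to, capacity = cap,
                                    flood = fl, excess = excess,
                                    stringsAsFactors = FALSE),
                 node_in = stats::setNames(ntrep, fn$ids),
                 walks_expanded = walks,
                 zero_tol = zero_tol),
            class = "flood_state")
}

#' @export
print.flood_state <- function(x, ...) {
  cat(sprintf("<flood_state> %d edges, %d active (non-zero flood), %d walks expanded\n",
              nrow(x$edges), sum(x$edges$flood != 0), x$walks_expanded))
  invisible(x)
}

#' Compute network floods directly from the definition (oracle)
#'
#' Brute-force reference implementation of the flood semantics (see
#' [flood_network()] for the semantics themselves): walks are expanded
#' breadth-first from the sources in canonical order, each expansion through
#' an edge `(u, v)` rewriting the edge's cumulative flood to
#' `sign(c) * max(0, min(|c(u,v)|, total incoming at u))` and carrying the
#' signed change forward; outgoing edges of a source always carry their full
#' capacity, and expansions that change no flood (or are not essential) are
#' not pursued. Everything here is done the slow, definitional way: the
#' essentialness predicate is re-checked in full on every candidate walk,
#' each breadth-first level is sorted explicitly, and all state lives in
#' plainly scanned tables keyed by node id — no incremental bookkeeping is
#' shared with the scalable implementation. Intended as the reference
#' against which [flood_network()] is verified; do not use it beyond toy
#' sizes.
#'
#' @param fn A `flood_net` with at least one source.
#' @param max_walks Resource guard on the number of walk expansions.
#' @param zero_tol Flood changes of at most this magnitude are treated as
#'   zero.
#' @return A `flood_state`: per-edge floods and excess (inflow clipped away
#'   by capacity/saturation), per-node incoming totals, and the number of
#'   walk expansions performed.
#' @export
flood_by_definition <- function(fn, max_walks = 1e6, zero_tol = 1e-12) {
  if (!length(fn$sources)) {
    stop("flood network has no source nodes", call. = FALSE)
  }
  edges <- fn$edges[, c("from", "to", "capacity")]
  cap_of <- function(u, v) {
    i <- which(edges$from == u & edges$to == v)
    if (!length(i)) 0 else edges$capacity[i]
  }
  succ_of <- function(u) sort(edges$to[edges$from == u], method = "radix")
  flood <- stats::setNames(rep(0, nrow(edges)),
                           paste0(edges$from, "\r", edges$to))
  total_in <- stats::setNames(rep(0, length(fn$ids)), fn$ids)
  total_rep <- total_in
  total_in[fn$sources] <- Inf
  sort_level <- function(walks) {
    if (length(walks) < 2L) return(walks)
    walks[order(vapply(walks, paste, "", collapse = "\r"), method = "radix")]
  }
  walks <- 0L
  level <- sort_level(unlist(lapply(sort(fn$sources, method = "radix"),
                                    function(s) {
                                      lapply(succ_of(s), function(v) c(s, v))
                                    }), recursive = FALSE))
  # base case: source out-edges carry their full capacity
  for (w in level) {
    cap <- cap_of(w[1L], w[2L])
    flood[paste0(w[1L], "\r", w[2L])] <- cap
    if (!w[2L] %in% fn$sources) total_in[w[2L]] <- total_in[w[2L]] + cap
    total_rep[w[2L]] <- total_rep[w[2L]] + cap
    walks <- walks + 1L
  }
  if (walks > max_walks) resource_error(max_walks)
  while (length(level)) {
    nxt <- list()
    for (w in level) {
      u <- w[length(w)]
      for (v in succ_of(u)) {
        cand <- c(w, v)
        if (!is_essential_int(match(cand, fn$ids))) next
        cap <- cap_of(u, v)
        desired <- sign(cap) * max(0, min(abs(cap), total_in[u]))
        key <- paste0(u, "\r", v)
        delta <- unname(desired - flood[key])
        if (abs(delta) <= zero_tol) next
        flood[key] <- desired
        if (!v %in% fn$sources) total_in[v] <- total_in[v] + delta
        total_rep[v] <- total_rep[v] + delta
        walks <- walks + 1L
        if (walks > max_walks) resource_error(max_walks)
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    level <- sort_level(nxt)
  }
  n <- length(fn$ids)
  F <- matrix(0, n, n)
  e <- fn$edges
  F[cbind(e$from_i, e$to_i)] <- unname(flood[paste0(e$from, "\r", e$to)])
  build_flood_state(fn, F, unname(total_in[fn$ids]), unname(total_rep[fn$ids]),
                    walks, zero_tol)
}

#' Compute network floods (scalable worklist algorithm)
#'
#' Computes the network flood of every edge by expanding essential walks
#' breadth-first from the sources. Expanding a walk ending at `u` through an
#' edge `(u, v)` rewrites the edge's cumulative flood to
#' `sign(c) * max(0, min(|c(u,v)|, total incoming flood at u))` — the
#' capacity and polarity constraints applied to the algebraic sum of
#' everything the traversal has so far delivered into `u` — and the walk
#' carries the signed flood *change* forward into `v`. Outgoing edges of a
#' source always carry their full capacity. An expansion that changes no
#' flood (magnitude of the change at most `zero_tol`) has nothing to
#' propagate and is not pursued, so saturated and suppressed regions of the
#' network stop generating work; together with the essential-walk bound on
#' cycle traversal this is what keeps the traversal practical on networks
#' whose complete walk set is astronomically large.
#'
#' Expansions are processed in a canonical order — breadth-first by walk
#' length, ties broken by the byte order of the node-id sequence — so the
#' result is deterministic and independent of the input edge ordering. The
#' same order, and the same flood semantics, are implemented definitionally
#' (and far more slowly) by [flood_by_definition()]; the two agree to within
#' rounding on every input, a property the test suite asserts on hundreds of
#' random cyclic signed networks. One documented consequence of walk-carried
#' propagation is that floods record the traversal history: in cyclic
#' networks a downward correction that can only return to an edge through a
#' walk the essentialness predicate forbids leaves the edge's earlier,
#' larger flood in place (see the methods vignette).
#'
#' This implementation keeps incremental state (capacity/flood matrices,
#' per-node totals, one-step essentialness checks that exploit the parent
#' walk being essential); the oracle shares none of that machinery.
#'
#' @inheritParams flood_by_definition
#' @return A `flood_state`; see [flood_by_definition()].
#' @export
flood_network <- function(fn, max_walks = 1e6, zero_tol = 1e-12) {
  if (!length(fn$sources_i)) {
    stop("flood network has no source nodes", call. = FALSE)
  }
  n <- length(fn$ids)
  C <- fn$C
  absC <- abs(C); sgnC <- sign(C)
  F <- matrix(0, n, n)
  ntv <- numeric(n); ntv[fn$sources_i] <- Inf
  ntrep <- numeric(n)
  is_source <- fn$is_source
  out <- fn$out
  walks <- 0L
  frontier <- vector("list", sum(lengths(out[fn$sources_i])))
  fi <- 0L
  for (s in fn$sources_i) for (v in out[[s]]) {
    cap <- C[s, v]
    F[s, v] <- cap
    if (!is_source[v]) ntv[v] <- ntv[v] + cap
    ntrep[v] <- ntrep[v] + cap
    walks <- walks + 1L
    fi <- fi + 1L
    frontier[[fi]] <- c(s, v)
  }
  if (walks > max_walks) resource_error(max_walks)
  while (fi > 0L) {
    nxt <- vector("list", 2L * fi)
    ni <- 0L
    for (k in seq_len(fi)) {
      seq <- frontier[[k]]
      v <- seq[length(seq)]
      for (w in out[[v]]) {
        # incremental essentialness: only the (previous appearance of w,
        # new appearance) pair can violate the predicate
        idx <- which(seq == w)
        if (length(idx)) {
          i <- idx[length(idx)]
          if (i == length(seq)) next
          if (all(seq[(i + 1L):length(seq)] %in% seq[1:i])) next
        }
        desired <- sgnC[v, w] * max(0, min(absC[v, w], ntv[v]))
        delta <- desired - F[v, w]
        if (abs(delta) <= zero_tol) next
        F[v, w] <- desired
        if (!is_source[w]) ntv[w] <- ntv[w] + delta
        ntrep[w] <- ntrep[w] + delta
        walks <- walks + 1L
        if (walks > max_walks) resource_error(max_walks)
        ni <- ni + 1L
        if (ni > length(nxt)) nxt <- c(nxt, vector("list", length(nxt)))
        nxt[[ni]] <- c(seq, w)
      }
    }
    frontier <- nxt
    fi <- ni
  }
  build_flood_state(fn, F, ntv, ntrep, walks, zero_tol)
}

#' Check the flood constraints on a computed state
#'
#' Asserts, for every edge, the capacity constraint `|f(u,v)| <= |c(u,v)|`
#' and the polarity constraint `f(u,v) * c(u,v) >= 0`, and that excess is
#' non-negative.
#'
#' @param state A `flood_state`.
#' @param tol Numerical slack.
#' @return `TRUE` invisibly, or an error describing the violated constraint.
#' @export
validate_flood_state <- function(state, tol = 1e-9) {
  stopifnot(inherits(state, "flood_state"))
  e <- state$edges
  bad <- abs(e$flood) > abs(e$capacity) + tol
  if (any(bad)) stop("capacity constraint violated on edge ",
                     paste0(e$from[bad], "->", e$to[bad], collapse = ", "),
                     call. = FALSE)
  bad <- e$flood * e$capacity < -tol
  if (any(bad)) stop("polarity constraint violated on edge ",
                     paste0(e$from[bad], "->", e$to[bad], collapse = ", "),
                     call. = FALSE)
  if (any(e$excess < 0)) stop("negative excess", call. = FALSE)
  invisible(TRUE)
}

flood_of <- function(state, from, to) {
  i <- which(state$edges$from == from & state$edges$to == to)
  if (!length(i)) 0 else state$edges$flood[i]
}

#' Flood through a gene (node activity)
#'
#' The flood through a gene is read from its saturation-gadget edge
#' `(v_in, v_out)`, which aggregates all regulatory input to the gene. Under
#' the convention that signal and basal links attach directly to the gate
#' output, purely signal-driven genes carry no gadget flood; for those the
#' activity falls back to the largest direct signal/basal inflow at the gate
#' output (see the methods vignette). Always non-negative.
#'
#' @param state A `flood_state` computed on `fn`.
#' @param fn The transformed `flood_net` (must carry gene gadget roles).
#' @param gene Gene id.
#' @return Non-negative flood through the gene.
#' @export
node_flood <- function(state, fn, gene) {
  nd <- fn$nodes
  in_id <- nd$id[nd$role == "gate_in" & !is.na(nd$gene) & nd$gene == gene]
  out_id <- nd$id[nd$role == "gate_out" & !is.na(nd$gene) & nd$gene == gene]
  if (length(in_id) != 1L || length(out_id) != 1L) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  gadget <- flood_of(state, in_id, out_id)
  if (gadget > state$zero_tol) return(gadget)
  e <- state$edges
  src_roles <- nd$role[match(e$from, nd$id)]
  direct <- e$flood[e$to == out_id & src_roles %in% c("signal", "basal")]
  max(0, gadget, direct)
}

#' Tabulate a flood state
#'
#' @param state A `flood_state`.
#' @param fn Optional transformed `flood_net`; when supplied, a per-gene
#'   node-flood table is attached.
#' @return A list with `edges` (source, target, capacity, flood, excess) and,
#'   when `fn` is given, `genes` (gene, node_flood).
#' @export
flood_report <- function(state, fn = NULL) {
  out <- list(edges = state$edges)
  if (!is.null(fn)) {
    genes <- sort(unique(stats::na.omit(fn$nodes$gene)), method = "radix")
    out$genes <- data.frame(
      gene = genes,
      node_flood = vapply(genes, function(g) node_flood(state, fn, g), 0),
      stringsAsFactors = FALSE)
    rownames(out$genes) <- NULL
  }
  out
}

#' Write a flood report to disk
#'
#' TSV variant: edge table `source target capacity flood excess`, followed
#' (when gene information is available) by a `# gene node_flood` section.
#' JSON variant mirrors the same fields.
#'
#' @param state A `flood_state`.
#' @param fn Optional transformed `flood_net` for per-gene floods.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_flood_report <- function(state, fn = NULL, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  rep <- flood_report(state, fn)
  if (format == "tsv") {
    e <- rep$edges
    lines <- c("# source\ttarget\tcapacity\tflood\texcess",
               if (nrow(e)) paste(e$from, e$to, fmt_num(e$capacity),
                                  fmt_num(e$flood), fmt_num(e$excess),
                                  sep = "\t"))
    if (!is.null(rep$genes)) {
      lines <- c(lines, "# gene\tnode_flood",
                 paste(rep$genes$gene, fmt_num(rep$genes$node_flood), sep = "\t"))
    }
    writeLines(lines, path, useBytes = TRUE)
  } else {
    jsonlite::write_json(rep, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
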