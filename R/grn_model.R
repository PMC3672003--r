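# Domain types for user-facing gene regulatory networks (GRNs), scenario
# configuration, and readers/writers for the edge-list formats the tool
# touches (TSV, SIF dialect, GraphML).

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Declare an environmental signal
#'
#' A signal is an external stimulus (heat, a nutrient, a sigma-factor level,
#' ...) sensed by one or more receptor genes. When active it becomes a source
#' node of the flood network, feeding each receptor with a signed regulation
#' weight.
#'
#' @param name Signal name (non-empty string).
#' @param targets Data frame with columns `gene` (receptor gene id) and
#'   `weight` (non-zero signed regulation weight), or a named numeric vector
#'   `c(geneA = 2, geneB = -1)`.
#' @param active Logical; whether the signal is active by default. A scenario
#'   can override this via its `active_signals` field.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(name, targets, active = TRUE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("signal name must be a non-empty string", call. = FALSE)
  }
  if (is.numeric(targets) && !is.null(names(targets))) {
    targets <- data.frame(gene = names(targets), weight = as.numeric(targets),
                          stringsAsFactors = FALSE)
  }
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  if (!all(c("gene", "weight") %in% names(targets)) || nrow(targets) < 1L) {
    stop("signal '", name, "' needs at least one (gene, weight) target",
         call. = FALSE)
  }
  targets$gene <- as.character(targets$gene)
  targets$weight <- as.numeric(targets$weight)
  if (any(!is.finite(targets$weight)) || any(targets$weight == 0)) {
    stop("signal '", name, "' has a zero or non-finite target weight",
         call. = FALSE)
  }
  structure(list(name = name,
                 targets = targets[, c("gene", "weight")],
                 active = isTRUE(active)),
            class = "signal_spec")
}

#' Construct a gene regulatory network
#'
#' A GRN is a set of genes joined by signed, weighted, directed regulatory
#' edges, together with optional environmental signal declarations and an
#' optional set of sink (reporter/output) genes. Edge weights are
#' regulation strengths: positive for activation, negative for inhibition;
#' a zero weight is indistinguishable from an absent edge and is rejected.
#'
#' @param edges Data frame with character columns `source`, `target` and a
#'   numeric column `weight`. May have zero rows.
#' @param genes Optional gene table: a character vector of ids, or a data
#'   frame with columns `id` and optionally `basal` (basal expression, >= 0,
#'   default 0) and `saturation` (maximum flood through the gene, > 0; `NA`
#'   means "use the scenario default"). Genes appearing only in `edges` are
#'   added automatically.
#' @param signals List of [signal_spec()] objects.
#' @param sinks Optional character vector of sink gene ids.
#' @return A validated object of class `grn`.
#' @seealso [read_grn()], [transform_grn()], [minimize_grn()]
#' @export
grn <- function(edges = NULL, genes = NULL, signals = list(), sinks = NULL) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("source", "target", "weight") %in% names(edges))) {
    stop("edges must have columns source, target, weight", call. = FALSE)
  }
  edges <- edges[, c("source", "target", "weight")]
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)

  if (is.null(genes)) genes <- character()
  if (is.character(genes)) {
    genes <- data.frame(id = genes, stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(genes) > 0 && !"id" %in% names(genes)) {
    stop("genes table must have an 'id' column", call. = FALSE)
  }
  ids <- union(if (nrow(genes)) genes$id else character(),
               union(edges$source, edges$target))
  ids <- sort(ids, method = "radix")
  tab <- data.frame(id = ids, basal = rep(0, length(ids)),
                    saturation = rep(NA_real_, length(ids)),
                    stringsAsFactors = FALSE)
  if (nrow(genes)) {
    m <- match(genes$id, tab$id)
    if ("basal" %in% names(genes)) {
      b <- as.numeric(genes$basal)
      tab$basal[m] <- ifelse(is.na(b), 0, b)
    }
    if ("saturation" %in% names(genes)) tab$saturation[m] <- as.numeric(genes$saturation)
  }
  if (inherits(signals, "signal_spec")) signals <- list(signals)
  out <- structure(list(genes = tab,
                        edges = edges[order(edges$source, edges$target, method = "radix"), ,
                                      drop = FALSE],
                        signals = signals,
                        sinks = if (is.null(sinks)) NULL else as.character(sinks)),
                   class = "grn")
  rownames(out$edges) <- NULL
  validate_grn(out)
}

#' Validate a GRN
#'
#' Rejects exactly: empty gene ids, non-positive saturations, non-finite
#' basal levels, zero or non-finite edge weights, duplicate (source, target)
#' pairs, edge endpoints or signal targets or sinks that are not declared
#' genes. Emits a warning (not an error) when some gene is unreachable from
#' every active signal target and every basally expressed gene: flooding is
#' still well defined, the gene simply receives no information.
#'
#' @param x A `grn` object.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_grn <- function(x) {
  stopifnot(inherits(x, "grn"))
  g <- x$genes
  if (any(!nzchar(g$id)) || anyNA(g$id)) stop("empty gene id", call. = FALSE)
  if (anyDuplicated(g$id)) stop("duplicate gene id", call. = FALSE)
  if (any(!is.finite(g$basal)) || any(g$basal < 0)) {
    stop("basal expression must be finite and >= 0", call. = FALSE)
  }
  sat <- g$saturation
  if (any(!is.na(sat) & (sat <= 0 | !is.finite(sat)))) {
    stop("saturation must be strictly positive", call. = FALSE)
  }
  e <- x$edges
  if (nrow(e)) {
    if (any(!is.finite(e$weight))) stop("non-finite edge weight", call. = FALSE)
    if (any(e$weight == 0)) {
      stop("zero-weight edge (zero capacity means no edge): ",
           paste0(e$source[e$weight == 0], "->", e$target[e$weight == 0],
                  collapse = ", "),
           call. = FALSE)
    }
    key <- paste0(e$source, "\r", e$target)
    if (anyDuplicated(key)) {
      stop("duplicate regulatory edge: ",
           paste(unique(paste0(e$source[duplicated(key)], "->",
                               e$target[duplicated(key)])), collapse = ", "),
           call. = FALSE)
    }
    bad <- setdiff(union(e$source, e$target), g$id)
    if (length(bad)) stop("edge endpoint not a declared gene: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  for (s in x$signals) {
    if (!inherits(s, "signal_spec")) stop("signals must be signal_spec objects", call. = FALSE)
    bad <- setdiff(s$targets$gene, g$id)
    if (length(bad)) stop("signal '", s$name, "' targets unknown gene: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(x$signals) && anyDuplicated(vapply(x$signals, `[[`, "", "name"))) {
    stop("duplicate signal name", call. = FALSE)
  }
  if (!is.null(x$sinks)) {
    bad <- setdiff(x$sinks, g$id)
    if (length(bad)) stop("sink not a declared gene: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  starts <- unique(c(unlist(lapply(x$signals[vapply(x$signals, `[[`, TRUE, "active")],
                                   function(s) s$targets$gene)),
                     g$id[g$basal > 0]))
  if (length(starts) && nrow(g)) {
    reach <- reachable_gene_ids(x, starts)
    orphan <- setdiff(g$id, reach)
    if (length(orphan)) {
      warning("gene(s) unreachable from every active signal and basal input: ",
              paste(utils::head(orphan, 5), collapse = ", "),
              if (length(orphan) > 5) " ..." else "",
              call. = FALSE)
    }
  }
  invisible(x)
}

# Forward reachability in gene space (ignores weights/signs).
reachable_gene_ids <- function(grn, start) {
  start <- intersect(unique(start), grn$genes$id)
  if (!length(start)) return(character())
  if (!nrow(grn$edges)) return(start)
  g <- igraph::graph_from_data_frame(grn$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = data.frame(name = grn$genes$id))
  hit <- rep(FALSE, nrow(grn$genes))
  names(hit) <- grn$genes$id
  for (s in start) {
    hit[names(igraph::subcomponent(g, s, mode = "out"))] <- TRUE
  }
  names(hit)[hit]
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> %d genes, %d edges, %d signal(s)%s\n",
              nrow(x$genes), nrow(x$edges), length(x$signals),
              if (length(x$sinks)) sprintf(", %d sink(s)", length(x$sinks)) else ""))
  invisible(x)
}

#' Scenario configuration
#'
#' Bundles everything that turns a static GRN into a concrete flooding
#' problem: which signals are active, the flood threshold `t` used by
#' minimization, the default per-gene saturation, the weight policy (unit
#' weights, Gaussian weight noise), the random seed, and numerical
#' safeguards.
#'
#' @param active_signals Character vector of signal names to activate, or
#'   `NULL` to use each signal's own `active` flag.
#' @param threshold Flood threshold `t` >= 0; minimization retains edges with
#'   `|flood| > t` (strict).
#' @param default_saturation Positive saturation applied to genes whose own
#'   saturation is `NA`. Default 10: large relative to unit-scale regulatory
#'   weights, so saturation only binds when set deliberately.
#' @param unit_weights If `TRUE`, every regulatory weight is replaced by its
#'   sign (+1/-1) before noise is added.
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to each
#'   regulatory weight (0 disables noise).
#' @param seed Integer seed for every stochastic step run under this scenario.
#' @param max_walks Resource guard: maximum number of essential-walk
#'   expansions before flooding aborts with an error.
#' @param zero_tol Magnitude below which a flood delta is treated as zero.
#' @param signals_to_gate_in If `TRUE`, signal and basal inputs attach to the
#'   gene's saturation-gadget input node instead of its output node, so that
#'   external input is also capped by the gene's saturation (see the methods
#'   vignette for why the default follows the gadget convention verbatim).
#' @param sinks Optional character vector of sink gene ids (overrides the
#'   GRN's own sink set).
#' @param signals Optional list of [signal_spec()] (overrides the GRN's).
#' @return An object of class `flood_scenario`.
#' @export
scenario_config <- function(active_signals = NULL, threshold = 0,
                            default_saturation = 10, unit_weights = FALSE,
                            noise_sd = 0, seed = 0L, max_walks = 1e6,
                            zero_tol = 1e-12, signals_to_gate_in = FALSE,
                            sinks = NULL, signals = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L, threshold >= 0,
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0,
            is.numeric(default_saturation), default_saturation > 0,
            is.numeric(max_walks), max_walks >= 1,
            is.numeric(zero_tol), zero_tol >= 0)
  structure(list(active_signals = if (is.null(active_signals)) NULL else as.character(active_signals),
                 threshold = as.numeric(threshold),
                 default_saturation = as.numeric(default_saturation),
                 unit_weights = isTRUE(unit_weights),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed),
                 max_walks = as.numeric(max_walks),
                 zero_tol = as.numeric(zero_tol),
                 signals_to_gate_in = isTRUE(signals_to_gate_in),
                 sinks = if (is.null(sinks)) NULL else as.character(sinks),
                 signals = signals),
            class = "flood_scenario")
}

# Signals in force under a scenario: the scenario's own signal list if it has
# one, else the GRN's; filtered to the active set.
active_signal_specs <- function(grn, config) {
  specs <- config$signals %||% grn$signals
  if (!length(specs)) return(list())
  nm <- vapply(specs, `[[`, "", "name")
  keep <- if (is.null(config$active_signals)) {
    vapply(specs, `[[`, TRUE, "active")
  } else {
    unknown <- setdiff(config$active_signals, nm)
    if (length(unknown)) stop("active signal not declared: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    nm %in% config$active_signals
  }
  specs[keep]
}

effective_sinks <- function(grn, config) config$sinks %||% grn$sinks

#' Read a GRN from a file
#'
#' Three dialects are supported. `tsv`: three tab-separated columns
#' `source`, `target`, `weight`; `#` starts a comment line. `sif`:
#' whitespace-separated `source (+|-) target [weight]`; when both the
#' relation sign and a weight are given they must agree. `graphml`: a
#' directed graph with edge attribute `weight` and optional node attributes
#' `basal` and `saturation`. For `tsv` and `sif`, a sidecar scenario file
#' `<path>.scenario.yaml` written by [write_grn()] is picked up
#' automatically and restores signals and sinks.
#'
#' @param path File to read.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`; default guesses from
#'   the file extension (falling back to `tsv`).
#' @return A validated `grn`.
#' @export
read_grn <- function(path, format = c("auto", "tsv", "sif", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sif = "sif", graphml = "graphml", "tsv")
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  out <- switch(format,
                tsv = read_grn_tsv(path),
                sif = read_grn_sif(path),
                graphml = read_grn_graphml(path))
  sidecar <- paste0(path, ".scenario.yaml")
  if (format != "graphml" && file.exists(sidecar)) {
    sc <- load_scenario(sidecar, out)
    out <- grn(out$edges, out$genes, signals = sc$signals %||% list(),
               sinks = sc$sinks)
  }
  out
}

parse_weight <- function(txt, path, lineno) {
  w <- suppressWarnings(as.numeric(txt))
  if (is.na(w)) stop(sprintf("%s:%d: cannot parse weight '%s'", path, lineno, txt),
                     call. = FALSE)
  w
}

grn_from_rows <- function(rows) {
  if (!length(rows)) return(grn())
  grn(data.frame(source = vapply(rows, `[[`, "", 1L),
                 target = vapply(rows, `[[`, "", 2L),
                 weight = vapply(rows, function(r) r[[3L]], 0),
                 stringsAsFactors = FALSE))
}

read_grn_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln)) || startsWith(trimws(ln), "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 3L) stop(sprintf("%s:%d: expected 3 tab-separated fields, got %d",
                                      path, i, length(f)), call. = FALSE)
    rows[[length(rows) + 1L]] <- list(trimws(f[1L]), trimws(f[2L]),
                                      parse_weight(trimws(f[3L]), path, i))
  }
  grn_from_rows(rows)
}

read_grn_sif <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "[[:space:]]+")[[1L]]
    if (!length(f) %in% c(3L, 4L)) {
      stop(sprintf("%s:%d: expected 'source (+|-) target [weight]'", path, i),
           call. = FALSE)
    }
    if (!f[2L] %in% c("+", "-")) {
      stop(sprintf("%s:%d: relation must be '+' or '-', got '%s'", path, i, f[2L]),
           call. = FALSE)
    }
    rel <- if (f[2L] == "+") 1 else -1
    w <- if (length(f) == 4L) parse_weight(f[4L], path, i) else rel
    if (length(f) == 4L && w != 0 && sign(w) != rel) {
      stop(sprintf("%s:%d: relation sign '%s' disagrees with weight %g",
                   path, i, f[2L], w), call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- list(f[1L], f[3L], w)
  }
  grn_from_rows(rows)
}

read_grn_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  genes <- data.frame(id = vd$name, stringsAsFactors = FALSE)
  if ("basal" %in% names(vd)) genes$basal <- as.numeric(vd$basal)
  if ("saturation" %in% names(vd)) {
    sat <- as.numeric(vd$saturation)
    genes$saturation <- ifelse(sat <= 0, NA_real_, sat)  # -1 encodes unset
  }
  edges <- data.frame(source = ed$from, target = ed$to,
                      weight = if (nrow(ed)) as.numeric(ed$weight) else numeric(),
                      stringsAsFactors = FALSE)
  grn(edges, genes)
}

# 17 significant digits: lossless double -> text -> double round-trip
fmt_num <- function(x) sprintf("%.17g", x)

#' Write a GRN to a file
#'
#' Inverse of [read_grn()]: `read_grn(write_grn(g, path))` reproduces `g` up
#' to edge ordering. For `tsv` and `sif`, signals and sinks (which those
#' formats cannot express) are preserved in a sidecar
#' `<path>.scenario.yaml`; GraphML carries `basal`/`saturation` node
#' attributes but also uses the sidecar for signals and sinks.
#'
#' @param grn A `grn` object.
#' @param path Output file.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_grn <- function(grn, path, format = c("auto", "tsv", "sif", "graphml")) {
  stopifnot(inherits(grn, "grn"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     sif = "sif", graphml = "graphml", "tsv")
  }
  e <- grn$edges
  con <- NULL
  if (format == "tsv") {
    lines <- c("# source\ttarget\tweight",
               if (nrow(e)) paste(e$source, e$target, fmt_num(e$weight), sep = "\t"))
    writeLines(lines, path, useBytes = TRUE)
  } else if (format == "sif") {
    lines <- c("# source relation target weight",
               if (nrow(e)) paste(e$source, ifelse(e$weight > 0, "+", "-"),
                                  e$target, fmt_num(e$weight)))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    sat <- grn$genes$saturation
    vtab <- data.frame(name = grn$genes$id, basal = grn$genes$basal,
                       saturation = ifelse(is.na(sat), -1, sat),
                       stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(
      if (nrow(e)) data.frame(from = e$source, to = e$target, weight = e$weight)
      else data.frame(from = character(), to = character(), weight = numeric()),
      directed = TRUE, vertices = vtab)
    igraph::write_graph(g, path, format = "graphml")
  }
  if (length(grn$signals) || length(grn$sinks)) {
    write_scenario(scenario_config(signals = grn$signals, sinks = grn$sinks),
                   paste0(path, ".scenario.yaml"))
  }
  invisible(path)
}

#' Load a scenario configuration
#'
#' Reads a YAML (or JSON) scenario file and resolves it against a GRN.
#' Recognized keys: `signals` (name -> `{targets: [{gene, weight}], active}`),
#' `active_signals`, `sinks`, `threshold`, `default_saturation`,
#' `unit_weights`, `noise_sd`, `seed`, `max_walks`, `zero_tol`,
#' `signals_to_gate_in`. Missing keys take the [scenario_config()] defaults
#' (threshold 0, noise 0, seed 0). Gene ids named in signal targets or sinks
#' must exist in `grn`.
#'
#' @param path YAML/JSON file.
#' @param grn `grn` used to resolve gene ids.
#' @return A `flood_scenario`.
#' @export
load_scenario <- function(path, grn) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)   # [[ ]] below: no partial key matching
  signals <- NULL
  if (!is.null(raw[["signals"]])) {
    signals <- lapply(names(raw[["signals"]]), function(nm) {
      s <- raw[["signals"]][[nm]]
      tg <- do.call(rbind, lapply(s[["targets"]], function(t) {
        data.frame(gene = as.character(t[["gene"]]),
                   weight = as.numeric(t[["weight"]]),
                   stringsAsFactors = FALSE)
      }))
      signal_spec(nm, tg, active = s[["active"]] %||% TRUE)
    })
  }
  sc <- scenario_config(
    active_signals = raw[["active_signals"]],
    threshold = raw[["threshold"]] %||% 0,
    default_saturation = raw[["default_saturation"]] %||% 10,
    unit_weights = raw[["unit_weights"]] %||% FALSE,
    noise_sd = raw[["noise_sd"]] %||% 0,
    seed = raw[["seed"]] %||% 0L,
    max_walks = raw[["max_walks"]] %||% 1e6,
    zero_tol = raw[["zero_tol"]] %||% 1e-12,
    signals_to_gate_in = raw[["signals_to_gate_in"]] %||% FALSE,
    sinks = raw[["sinks"]],
    signals = signals)
  if (!missing(grn)) {
    for (s in sc$signals %||% list()) {
      bad <- setdiff(s$targets$gene, grn$genes$id)
      if (length(bad)) stop("scenario signal '", s$name,
                            "' targets unknown gene: ",
                            paste(bad, collapse = ", "), call. = FALSE)
    }
    bad <- setdiff(sc$sinks %||% character(), grn$genes$id)
    if (length(bad)) stop("scenario sink not in GRN: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!is.null(sc$active_signals)) {
      nm <- vapply(sc$signals %||% grn$signals, `[[`, "", "name")
      bad <- setdiff(sc$active_signals, nm)
      if (length(bad)) stop("scenario activates undeclared signal: ",
                            paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  sc
}

#' Write a scenario configuration as YAML
#'
#' @param config A `flood_scenario`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(config, path) {
  stopifnot(inherits(config, "flood_scenario"))
  out <- list()
  if (length(config$signals)) {
    out$signals <- stats::setNames(lapply(config$signals, function(s) {
      list(targets = lapply(seq_len(nrow(s$targets)), function(i) {
        list(gene = s$targets$gene[i], weight = s$targets$weight[i])
      }), active = s$active)
    }), vapply(config$signals, `[[`, "", "name"))
  }
  if (!is.null(config$active_signals)) out$active_signals <- as.list(config$active_signals)
  if (!is.null(config$sinks)) out$sinks <- as.list(config$sinks)
  out$threshold <- config$threshold
  out$default_saturation <- config$default_saturation
  out$unit_weights <- config$unit_weights
  out$noise_sd <- config$noise_sd
  out$seed <- config$seed
  out$max_walks <- config$max_walks
  out$zero_tol <- config$zero_tol
  out$signals_to_gate_in <- config$signals_to_gate_in
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Apply the scenario's weight policy to a GRN
#'
#' Optionally replaces every regulatory weight by its sign (unit weights,
#' the convention for networks whose reconstruction provides no quantitative
#' weights) and then adds i.i.d. Gaussian noise of standard deviation
#' `config$noise_sd` to each weight. A perturbed weight that would cross or
#' hit zero is clamped to `sign(w) * zero_tol`: flood and capacity must share
#' sign, so noise is never allowed to silently turn an activator into a
#' repressor. Deterministic for a fixed `config$seed`, and independent of the
#' input edge ordering (noise is drawn in canonical source/target order).
#'
#' @param grn A `grn`.
#' @param config A `flood_scenario`.
#' @return A `grn` with the policy applied to its gene-gene edge weights.
#' @export
apply_weight_policy <- function(grn, config) {
  stopifnot(inherits(grn, "grn"), inherits(config, "flood_scenario"))
  e <- grn$edges   # already in canonical (source, target) order
  if (!nrow(e)) return(grn)
  w <- e$weight
  if (config$unit_weights) w <- sign(w)
  if (config$noise_sd > 0) {
    eps <- withr::with_seed(config$seed, stats::rnorm(length(w), 0, config$noise_sd))
    w2 <- w + eps
    flip <- sign(w2) != sign(w)
    w2[flip] <- sign(w[flip]) * max(config$zero_tol, 1e-12)
    w <- w2
  }
  e$weight <- w
  out <- grn
  out$edges <- e
  validate_grn(out)
  out
}
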