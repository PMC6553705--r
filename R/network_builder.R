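# Weekly undirected, unweighted communication networks (whole and
# participant variants) and the five per-node structural features.

canonical_edge_keys <- function(a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste(lo, hi, sep = "\r")
}

split_edge_keys <- function(keys) {
  if (length(keys) == 0) return(data.table::data.table(a = character(), b = character()))
  parts <- data.table::tstrsplit(keys, "\r", fixed = TRUE)
  data.table::data.table(a = parts[[1]], b = parts[[2]])
}

#' Filter spurious communication edges
#'
#' An undirected pair is retained iff its total event count (calls plus
#' texts, both directions, over the entire study window) reaches
#' `min_events`; rarer pairs are treated as spurious contacts (e.g. spam)
#' and removed before any weekly graph is built.
#'
#' @param events event table from [read_comm_events()] or
#'   [generate_comm_log()].
#' @param min_events minimum total events (default 3).
#' @return character vector of canonical edge keys (see
#'   [edge_key_table()] to decompose).
#' @export
filter_spurious_edges <- function(events, min_events = 3L) {
  assert_scalar_number(min_events, "min_events", lower = 0)
  if (nrow(events) == 0) return(character(0))
  key <- canonical_edge_keys(events$source, events$target)
  counts <- table(key)
  names(counts)[counts >= min_events]
}

#' Decompose canonical edge keys into an endpoint table
#' @param keys character vector from [filter_spurious_edges()].
#' @return `data.table` with columns `a`, `b` (a < b lexicographically).
#' @export
edge_key_table <- function(keys) {
  if (length(keys) == 0) return(data.table::data.table(a = character(), b = character()))
  split_edge_keys(keys)
}

#' Build weekly undirected, unweighted graphs
#'
#' An edge is present in week `w` iff the pair survived the spurious-edge
#' filter and has at least one event assigned to week `w`. The
#' `participant` variant restricts nodes to the roster (edges with any
#' non-roster endpoint are dropped); the `whole` variant keeps the roster
#' plus every external contact active on a retained edge. Roster members
#' with no edges in a week remain as degree-0 nodes, so every
#' participant-week has a defined feature vector.
#'
#' @param events event table (with `week` column).
#' @param retained canonical edge keys from [filter_spurious_edges()].
#' @param variant `"whole"` or `"participant"`.
#' @param config a [study_config()].
#' @return named list (week index as character) of `igraph` graphs; each
#'   graph carries `week` and `variant` attributes.
#' @export
build_weekly_graphs <- function(events, retained, variant = c("whole", "participant"),
                                config) {
  variant <- match.arg(variant)
  roster <- config$roster
  ev <- data.table::as.data.table(events)
  if (nrow(ev) > 0) {
    ev <- ev[canonical_edge_keys(source, target) %in% retained]
    out_of <- ev$week >= config$n_weeks | ev$week < 0
    if (any(out_of)) {
      warning(sprintf("build_weekly_graphs: %d event(s) outside the %d-week window ignored",
                      sum(out_of), config$n_weeks), call. = FALSE)
      ev <- ev[!out_of]
    }
  }
  # note: build by setDT -- "key" is a reserved data.table() argument
  edge_weeks <- if (nrow(ev) > 0) {
    unique(data.table::setDT(list(key = canonical_edge_keys(ev$source, ev$target),
                                  week = ev$week)))
  } else {
    data.table::setDT(list(key = character(), week = integer()))
  }

  graphs <- vector("list", config$n_weeks)
  names(graphs) <- as.character(seq_len(config$n_weeks) - 1L)
  for (w in seq_len(config$n_weeks) - 1L) {
    ek <- split_edge_keys(edge_weeks[week == w, key])
    if (variant == "participant") {
      ek <- ek[a %in% roster & b %in% roster]
      nodes <- roster
    } else {
      nodes <- union(roster, unique(c(ek$a, ek$b)))
    }
    g <- igraph::graph_from_data_frame(ek, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    g$week <- w
    g$variant <- variant
    graphs[[as.character(w)]] <- g
  }
  graphs
}

#' Structural features of one node in a weekly graph
#'
#' Returns the five per-node features: degree; number of triangles through
#' the node; local clustering coefficient `2*triangles/(degree*(degree-1))`
#' (0 when degree < 2); shortest-path betweenness centrality normalized by
#' `(n-1)(n-2)/2`; and component-scaled (Wasserman-Faust) closeness
#' `((r-1)/(n-1)) * ((r-1)/sum(d))` where `r` counts reachable nodes
#' including the node itself and `sum(d)` the distances to them (0 for
#' isolated nodes). The scaled variants keep both centralities in `[0, 1]`
#' on the disconnected graphs weekly communication typically produces.
#'
#' @param graph an `igraph` graph from [build_weekly_graphs()].
#' @param node node name (single id).
#' @return named list: degree, triangles, clustering, betweenness, closeness.
#' @export
node_structural_features <- function(graph, node) {
  if (!node %in% igraph::V(graph)$name) {
    stop(sprintf("node '%s' not in graph", node), call. = FALSE)
  }
  feats <- graph_structural_features(graph)
  as.list(feats[feats$participant == node,
                c("degree", "triangles", "clustering", "betweenness", "closeness")])
}

# All five features for every node of one graph.
graph_structural_features <- function(graph) {
  n <- igraph::vcount(graph)
  deg <- igraph::degree(graph)
  tri <- igraph::count_triangles(graph)
  clust <- ifelse(deg < 2, 0, 2 * tri / (deg * (deg - 1)))
  btw_norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  btw <- igraph::betweenness(graph, directed = FALSE) / btw_norm
  d <- igraph::distances(graph)
  finite <- is.finite(d)
  r <- rowSums(finite)                     # reachable incl. self
  dsum <- rowSums(ifelse(finite, d, 0))
  clo <- ifelse(r <= 1, 0, ((r - 1) / max(n - 1, 1)) * ((r - 1) / dsum))
  data.table::data.table(
    participant = igraph::V(graph)$name, degree = as.numeric(deg),
    triangles = as.numeric(tri), clustering = as.numeric(clust),
    betweenness = as.numeric(btw), closeness = as.numeric(clo)
  )
}

#' Weekly structural feature table for the roster
#'
#' Runs the spurious-edge filter, builds both weekly network variants, and
#' computes the five structural features for every roster member and week.
#'
#' @param events event table.
#' @param config a [study_config()].
#' @return `data.table` (participant, week, variant, degree, triangles,
#'   clustering, betweenness, closeness), one row per roster member x week
#'   x variant.
#' @export
structural_feature_table <- function(events, config) {
  retained <- filter_spurious_edges(events, config$edge_min_events)
  out <- list()
  for (variant in c("whole", "participant")) {
    graphs <- build_weekly_graphs(events, retained, variant, config)
    per_week <- lapply(graphs, function(g) {
      feats <- graph_structural_features(g)
      feats <- feats[participant %in% config$roster]
      feats[, `:=`(week = g$week, variant = g$variant)]
      feats
    })
    out[[variant]] <- data.table::rbindlist(per_week)
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("participant", "week", "variant"))
  data.table::setorder(res, variant, week, participant)
  res[]
}

#' Export weekly graphs
#'
#' Writes all weekly graphs of one variant as a single edge-list TSV
#' (columns week, a, b) and, optionally, one GraphML file per week.
#'
#' @param graphs list from [build_weekly_graphs()].
#' @param tsv_path output TSV path.
#' @param graphml_dir optional directory for per-week GraphML files.
#' @return `tsv_path`, invisibly.
#' @export
export_weekly_graphs <- function(graphs, tsv_path, graphml_dir = NULL) {
  rows <- lapply(graphs, function(g) {
    el <- igraph::as_edgelist(g)
    if (nrow(el) == 0) {
      data.table::data.table(week = integer(), a = character(), b = character())
    } else {
      data.table::data.table(week = g$week, a = pmin(el[, 1], el[, 2]),
                             b = pmax(el[, 1], el[, 2]))
    }
  })
  data.table::fwrite(data.table::rbindlist(rows), tsv_path, sep = "\t")
  if (!is.null(graphml_dir)) {
    dir.create(graphml_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in graphs) {
      igraph::write_graph(g, file.path(graphml_dir, sprintf("week_%02d.graphml", g$week)),
                          format = "graphml")
    }
  }
  invisible(tsv_path)
}
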