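#' Parse a molecular-interaction table
#'
#' Reads either a PSI-MITAB 2.5-style tab-delimited file (the IntAct
#' exchange format; interactor IDs from columns 1-2, detection method
#' from column 7, interaction type from column 12, confidence from
#' column 15) or a simplified 5-column TSV with header
#' `interactor_a, interactor_b, detection_method, interaction_type,
#' confidence`. MITAB field syntax like `uniprotkb:P12345`,
#' `psi-mi:"MI:0006"(anti bait coip)` and `intact-miscore:0.56` is
#' unwrapped to the bare identifier, term name and numeric score.
#'
#' Records are returned as parsed: self-loops and duplicates survive
#' this stage and are removed by [clean_graph()].
#'
#' @param path File path, or a data frame already holding the five
#'   simplified columns.
#' @param aliases Optional alias map (data frame `alias, canonical`
#'   or named character vector) normalizing node identifiers;
#'   unmapped identifiers are kept verbatim.
#' @return Data frame of interaction records: `interactor_a,
#'   interactor_b, detection_method, interaction_type, confidence`.
#' @export
parse_interactions <- function(path, aliases = NULL) {
  if (is.data.frame(path)) {
    records <- path
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) stop("format error: empty interaction file")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    n1 <- length(fields[[1]])
    if (n1 >= 15) {
      records <- parse_mitab(fields)
    } else {
      header <- tolower(trimws(fields[[1]]))
      need <- c("interactor_a", "interactor_b", "detection_method",
                "interaction_type", "confidence")
      miss <- setdiff(need, header)
      if (length(miss)) {
        stop("format error (row 1): missing column(s) ",
             paste(miss, collapse = ", "))
      }
      body <- fields[-1]
      bad <- which(lengths(body) != length(header))
      if (length(bad)) {
        stop("format error (row ", bad[1] + 1L, "): expected ",
             length(header), " fields")
      }
      mat <- do.call(rbind, body)
      colnames(mat) <- header
      records <- data.frame(mat[, need, drop = FALSE],
                            stringsAsFactors = FALSE)
      records$confidence <- as.numeric(records$confidence)
    }
  }
  need <- c("interactor_a", "interactor_b", "detection_method",
            "interaction_type", "confidence")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (any(!nzchar(records$interactor_a) | !nzchar(records$interactor_b))) {
    stop("format error: empty interactor identifier")
  }
  if (any(!is.finite(records$confidence) | records$confidence < 0 |
            records$confidence > 1)) {
    stop("format error: confidence scores must lie in [0, 1]")
  }
  if (!is.null(aliases)) {
    if (is.data.frame(aliases)) {
      map <- stats::setNames(aliases$canonical, aliases$alias)
    } else map <- aliases
    swap <- function(x) ifelse(x %in% names(map), unname(map[x]), x)
    records$interactor_a <- swap(records$interactor_a)
    records$interactor_b <- swap(records$interactor_b)
  }
  rownames(records) <- NULL
  records[, need]
}

parse_mitab <- function(fields) {
  bad <- which(lengths(fields) < 15)
  if (length(bad)) {
    stop("format error (row ", bad[1], "): MITAB rows need >= 15 fields")
  }
  strip_id <- function(x) sub("^[^:]+:", "", sub("\\|.*$", "", x))
  term_name <- function(x) {
    m <- regmatches(x, regexpr("\\(([^)]*)\\)", x))
    ifelse(lengths(m) > 0 & nzchar(m), gsub("[()\"]", "", m),
           gsub("\"", "", sub("^psi-mi:", "", x)))
  }
  score <- function(x) {
    v <- suppressWarnings(as.numeric(sub("^.*:", "", sub("\\|.*$", "", x))))
    ifelse(is.na(v), 0, v)
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  data.frame(
    interactor_a = strip_id(col(1)),
    interactor_b = strip_id(col(2)),
    detection_method = term_name(col(7)),
    interaction_type = term_name(col(12)),
    confidence = score(col(15)),
    stringsAsFactors = FALSE
  )
}

#' High-confidence physical-interaction filter configuration
#'
#' Controlled-vocabulary whitelists of interaction-detection methods
#' (biochemical and cell-biology assays) and interaction types
#' (physical, not genetic), plus a minimum confidence score. The
#' defaults cover the common biochemical assay terms; edit the lists
#' for other vocabularies.
#'
#' @param methods Detection-method whitelist (non-empty).
#' @param types Interaction-type whitelist (non-empty).
#' @param min_confidence Minimum confidence in [0, 1].
#' @return A `filter_config` list.
#' @export
filter_config <- function(methods = default_method_whitelist(),
                          types = c("physical association",
                                    "direct interaction", "association"),
                          min_confidence = 0.5) {
  if (length(methods) == 0 || length(types) == 0) {
    stop("whitelists must be non-empty")
  }
  if (min_confidence < 0 || min_confidence > 1) {
    stop("min_confidence must lie in [0, 1]")
  }
  structure(list(methods = methods, types = types,
                 min_confidence = min_confidence),
            class = "filter_config")
}

#' @rdname filter_config
#' @export
default_method_whitelist <- function() {
  c("affinity chromatography technology",
    "anti bait coimmunoprecipitation",
    "anti tag coimmunoprecipitation",
    "pull down", "tandem affinity purification",
    "x-ray crystallography", "surface plasmon resonance",
    "fluorescence microscopy", "fluorescent resonance energy transfer",
    "two hybrid")
}

#' Filter interaction records to high-confidence physical interactions
#'
#' Keeps a record iff its detection method and interaction type are
#' both whitelisted and its confidence reaches the minimum. Genetic
#' interactions are dropped regardless of score.
#'
#' @param records Parsed records (see [parse_interactions()]).
#' @param config A [filter_config()].
#' @return The surviving records.
#' @export
filter_high_confidence <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  keep <- records$detection_method %in% config$methods &
    records$interaction_type %in% config$types &
    records$confidence >= config$min_confidence
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a clean interaction graph from records
#'
#' Removes self-loops, collapses redundant pairs (A-B and B-A merge
#' into one undirected edge whose `provenance` attribute lists the
#' source record rows and whose `n_records` counts them) and, being
#' edge-defined, contains no orphaned (degree-0) nodes. Cleaning is
#' idempotent: passing an already-clean graph returns it unchanged.
#'
#' @param records Interaction records, or an igraph to re-clean.
#' @return An undirected simple `igraph` graph.
#' @export
clean_graph <- function(records) {
  if (igraph::is_igraph(records)) {
    g <- igraph::simplify(records, remove.multiple = TRUE,
                          remove.loops = TRUE,
                          edge.attr.comb = list(provenance = function(x)
                            paste(x, collapse = ";"), n_records = "sum",
                            confidence = "max", "first"))
    return(igraph::delete_vertices(g, igraph::degree(g) == 0))
  }
  if (nrow(records) == 0) stop("no interaction records to build from")
  df <- data.frame(from = records$interactor_a, to = records$interactor_b,
                   provenance = as.character(seq_len(nrow(records))),
                   n_records = 1L, confidence = records$confidence,
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(provenance = function(x)
                          paste(x, collapse = ";"), n_records = "sum",
                          confidence = "max", "first"))
  igraph::delete_vertices(g, igraph::degree(g) == 0)
}

#' Attach cellular-localization annotations to graph nodes
#'
#' @param graph An igraph.
#' @param localizations Data frame `node_id, localization`, one row
#'   per annotation (a node may have several).
#' @return The graph with a `localization` vertex attribute holding
#'   `;`-separated localization sets (`NA` where unannotated).
#' @export
set_localizations <- function(graph, localizations) {
  stopifnot(all(c("node_id", "localization") %in% names(localizations)))
  sets <- tapply(localizations$localization, localizations$node_id,
                 function(x) paste(sort(unique(x)), collapse = ";"))
  v <- igraph::V(graph)$name
  igraph::set_vertex_attr(graph, "localization",
                          value = unname(sets[v]))
}

loc_set <- function(x) {
  if (is.na(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' First-degree interaction neighbourhood
#'
#' Induced subgraph on the seed nodes and their direct interaction
#' partners. Seeds absent from the graph are reported in the
#' `missing_seeds` graph attribute; isolated nodes (none arise from a
#' cleaned graph) are dropped and reported in `dropped_singletons`.
#'
#' @param graph A cleaned igraph.
#' @param seeds Character vector of seed node ids.
#' @return Induced `igraph` subgraph, with a logical `is_seed` vertex
#'   attribute.
#' @export
first_degree <- function(graph, seeds) {
  present <- intersect(seeds, igraph::V(graph)$name)
  missing <- setdiff(seeds, present)
  if (length(present) == 0) stop("none of the seeds are in the graph")
  nb <- unique(unlist(lapply(present, function(s)
    igraph::V(graph)$name[as.integer(
      igraph::neighbors(graph, s))])))
  nodes <- sort(union(present, nb))
  sg <- igraph::induced_subgraph(graph, nodes)
  iso <- igraph::V(sg)$name[igraph::degree(sg) == 0]
  sg <- igraph::delete_vertices(sg, iso)
  sg <- igraph::set_vertex_attr(sg, "is_seed",
                                value = igraph::V(sg)$name %in% present)
  sg <- igraph::set_graph_attr(sg, "missing_seeds", missing)
  igraph::set_graph_attr(sg, "dropped_singletons", iso)
}

#' Second-degree neighbourhood with localization filtering
#'
#' Extends the first-degree neighbourhood by neighbours-of-neighbours
#' whose annotated cellular localization intersects
#' `localization_filter` (by default Golgi or vesicle, the
#' compartments relevant to Golgi-derived vesicle trafficking).
#' First-degree nodes are exempt from the filter; unannotated
#' second-ring nodes are excluded.
#'
#' @param graph A cleaned igraph with a `localization` vertex
#'   attribute (see [set_localizations()]).
#' @param seeds Seed node ids.
#' @param localization_filter Character vector of admitted
#'   localizations.
#' @return Induced `igraph` subgraph.
#' @export
second_degree <- function(graph, seeds,
                          localization_filter = c("Golgi", "vesicle")) {
  if (is.null(igraph::vertex_attr(graph, "localization"))) {
    stop("graph has no localization annotations; see set_localizations()")
  }
  fd <- first_degree(graph, seeds)
  fd_nodes <- igraph::V(fd)$name
  ring <- setdiff(unique(unlist(lapply(fd_nodes, function(s)
    igraph::V(graph)$name[as.integer(igraph::neighbors(graph, s))]))),
    fd_nodes)
  loc <- igraph::vertex_attr(graph, "localization",
                             index = match(ring, igraph::V(graph)$name))
  keep <- vapply(loc, function(x) length(intersect(loc_set(x),
                                                   localization_filter)) > 0,
                 logical(1))
  nodes <- sort(union(fd_nodes, ring[keep]))
  sg <- igraph::induced_subgraph(graph, nodes)
  igraph::set_vertex_attr(sg, "is_seed",
                          value = igraph::V(sg)$name %in%
                            intersect(seeds, nodes))
}

#' Betweenness centrality report
#'
#' Unnormalized shortest-path betweenness on the undirected,
#' unweighted graph (each unordered node pair counted once), ranked
#' in decreasing order with ties broken lexicographically by node id
#' so reports are deterministic.
#'
#' @param graph A cleaned igraph.
#' @param top_k Optionally restrict the report to the top k nodes.
#' @return Data frame `node, betweenness, rank`.
#' @export
betweenness_report <- function(graph, top_k = Inf) {
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                           normalized = FALSE)
  nodes <- igraph::V(graph)$name
  ord <- order(-b, nodes)
  out <- data.frame(node = nodes[ord], betweenness = unname(b[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  if (is.finite(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  rownames(out) <- NULL
  out
}

#' Shortest path distance from a seed to tether complexes
#'
#' For each tethering complex (a named set of subunit nodes), the
#' minimum unweighted shortest-path length (in edges) from the seed
#' to any subunit present in the graph — the "number of edges
#' required to connect" a Rab with the complex. Unreachable
#' complexes get `Inf` and are flagged.
#'
#' @param graph A cleaned igraph.
#' @param seed One seed node id.
#' @param tether_sets Named list of character vectors of subunit ids.
#' @return Data frame `complex, distance, reachable`, ordered as
#'   given.
#' @export
seed_to_tether_distance <- function(graph, seed, tether_sets) {
  if (!seed %in% igraph::V(graph)$name) stop("seed not in graph: ", seed)
  res <- vapply(tether_sets, function(subunits) {
    present <- intersect(subunits, igraph::V(graph)$name)
    if (length(present) == 0) return(Inf)
    min(igraph::distances(graph, v = seed, to = present, weights = NA))
  }, numeric(1))
  data.frame(complex = names(tether_sets), distance = unname(res),
             reachable = is.finite(unname(res)), stringsAsFactors = FALSE)
}

#' Export an interaction graph
#'
#' @param graph An igraph.
#' @param path Output file.
#' @param format `"graphml"` or `"edgelist"` (tab-separated
#'   `from  to` pairs plus attributes).
#' @return Invisibly, `path`.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(graph, what = "edges")
    utils::write.table(el, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
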