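#' Generate a messy interaction table with planted structure
#'
#' Builds a ground-truth clean interaction network — optionally
#' containing planted tether-complex cliques (all pairwise subunit
#' interactions at confidence 1) and planted seed-to-complex paths of
#' a prescribed edge length — then appends the configured mess:
#' self-loops, redundant reversed duplicates, low-confidence or
#' genetic-interaction rows (the only rows referencing orphan nodes),
#' all shuffled into a table for filter/cleaning tests. Because mess
#' rows either duplicate clean edges or fail the default
#' high-confidence filter, filtering + cleaning recovers exactly the
#' planted truth.
#'
#' @param n_nodes Number of nodes in the clean network.
#' @param n_edges Number of clean edges (must be feasible:
#'   planted edges <= n_edges <= n_nodes(n_nodes-1)/2).
#' @param planted List with optional elements `cliques` (named list
#'   of subunit id vectors) and `paths` (list of
#'   `list(from =, to_complex =, length =)` specs; each path runs
#'   from a seed node to the first subunit of the named clique
#'   through fresh intermediate nodes).
#' @param mess List of rates/counts: `self_loop_rate`,
#'   `duplicate_rate`, `low_confidence_rate` (fractions of
#'   `n_edges`), `orphan_nodes` (count).
#' @param min_confidence Confidence floor of clean edges (mess rows
#'   fall below it).
#' @param seed Integer seed.
#' @return List: `records` (the messy table), `truth` (clean `nodes`,
#'   `edges`, `n_nodes`, `n_edges`), `localizations` (node
#'   annotation table: complex subunits are Golgi, path seeds
#'   Golgi+vesicle, others drawn from common compartments).
#' @export
generate_interaction_table <- function(n_nodes = 60, n_edges = 120,
                                       planted = list(),
                                       mess = list(self_loop_rate = 0.05,
                                                   duplicate_rate = 0.1,
                                                   low_confidence_rate = 0.1,
                                                   orphan_nodes = 2),
                                       min_confidence = 0.5, seed = 1) {
  cliques <- planted$cliques %||% list()
  paths <- planted$paths %||% list()
  named <- unique(unlist(cliques))
  seeds <- vapply(paths, function(p) p$from, character(1))
  path_mid <- sum(vapply(paths, function(p) max(p$length - 1, 0),
                         numeric(1)))
  base_named <- unique(c(named, seeds))
  if (length(base_named) + path_mid > n_nodes) {
    stop("infeasible: planted structure needs more than n_nodes nodes")
  }

  with_seed(seed, {
    filler <- sprintf("N%03d", seq_len(n_nodes))
    filler <- setdiff(filler, base_named)
    nodes <- c(base_named, filler)[seq_len(n_nodes)]
    methods <- default_method_whitelist()

    key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "~")
    edges <- data.frame(a = character(), b = character(),
                        stringsAsFactors = FALSE)
    add_edge <- function(a, b) {
      if (a == b || key(a, b) %in% key(edges$a, edges$b)) return(invisible())
      edges[nrow(edges) + 1L, ] <<- c(a, b)
    }
    for (cl in cliques) {
      pr <- utils::combn(cl, 2)
      for (i in seq_len(ncol(pr))) add_edge(pr[1, i], pr[2, i])
    }
    n_clique_edges <- nrow(edges)
    mid_pool <- setdiff(nodes, base_named)
    chain_mids <- character(0)
    for (p in paths) {
      target <- cliques[[p$to_complex]][1]
      chain <- p$from
      if (p$length > 1) {
        mids <- mid_pool[seq_len(p$length - 1)]
        mid_pool <- setdiff(mid_pool, mids)
        chain_mids <- c(chain_mids, mids)
        chain <- c(chain, mids)
      }
      chain <- c(chain, target)
      for (i in seq_len(length(chain) - 1)) add_edge(chain[i], chain[i + 1])
    }
    if (n_edges < nrow(edges) || n_edges > n_nodes * (n_nodes - 1) / 2) {
      stop("infeasible edge count: need between ", nrow(edges), " and ",
           n_nodes * (n_nodes - 1) / 2)
    }
    # random filler edges up to n_edges; edges touching planted path or
    # clique nodes are excluded so planted seed-to-complex shortest-path
    # lengths stay exact
    guard <- if (length(paths)) unique(c(seeds, chain_mids, named))
      else character(0)
    tries <- 0
    while (nrow(edges) < n_edges && tries < 50 * n_edges) {
      tries <- tries + 1
      ab <- sample(nodes, 2)
      if (any(ab %in% guard)) next  # keep planted path lengths exact
      add_edge(ab[1], ab[2])
    }
    if (nrow(edges) < n_edges) stop("infeasible: could not place edges")

    n_clean <- nrow(edges)
    clique_conf <- rep(1, n_clique_edges)
    other_conf <- stats::runif(n_clean - n_clique_edges,
                               max(min_confidence, 0.6), 1)
    records <- data.frame(
      interactor_a = edges$a, interactor_b = edges$b,
      detection_method = sample(methods, n_clean, replace = TRUE),
      interaction_type = sample(c("physical association",
                                  "direct interaction"), n_clean,
                                replace = TRUE),
      confidence = c(clique_conf, other_conf),
      stringsAsFactors = FALSE
    )

    n_loop <- round((mess$self_loop_rate %||% 0) * n_edges)
    n_dup <- round((mess$duplicate_rate %||% 0) * n_edges)
    n_low <- round((mess$low_confidence_rate %||% 0) * n_edges)
    n_orph <- mess$orphan_nodes %||% 0
    messy <- list()
    if (n_loop > 0) {
      who <- sample(nodes, n_loop, replace = TRUE)
      messy$loops <- data.frame(
        interactor_a = who, interactor_b = who,
        detection_method = sample(methods, n_loop, replace = TRUE),
        interaction_type = "physical association",
        confidence = stats::runif(n_loop, 0.6, 1),
        stringsAsFactors = FALSE)
    }
    if (n_dup > 0) {
      pick <- sample(n_clean, n_dup, replace = n_dup > n_clean)
      messy$dups <- data.frame(
        interactor_a = records$interactor_b[pick],
        interactor_b = records$interactor_a[pick],
        detection_method = records$detection_method[pick],
        interaction_type = records$interaction_type[pick],
        confidence = records$confidence[pick],
        stringsAsFactors = FALSE)
    }
    orphans <- if (n_orph > 0) sprintf("ORPH%02d", seq_len(n_orph))
      else character(0)
    if (n_low > 0 || n_orph > 0) {
      n_low <- max(n_low, n_orph)
      a <- sample(nodes, n_low, replace = TRUE)
      b <- sample(nodes, n_low, replace = TRUE)
      if (n_orph > 0) b[seq_len(n_orph)] <- orphans
      bad_type <- stats::runif(n_low) < 0.5
      messy$low <- data.frame(
        interactor_a = a, interactor_b = b,
        detection_method = sample(methods, n_low, replace = TRUE),
        interaction_type = ifelse(bad_type, "genetic interaction",
                                  "physical association"),
        confidence = ifelse(bad_type, stats::runif(n_low, 0.6, 1),
                            stats::runif(n_low, 0, min_confidence - 0.01)),
        stringsAsFactors = FALSE)
      # a low-confidence row duplicating a clean pair would still be
      # harmless, but keep self-pairs out so parse-stage checks stay clean
      messy$low <- messy$low[messy$low$interactor_a !=
                               messy$low$interactor_b, , drop = FALSE]
    }
    records <- rbind(records, do.call(rbind, unname(messy)))
    records <- records[sample(nrow(records)), ]
    rownames(records) <- NULL

    loc_pool <- c("Golgi", "vesicle", "nucleus", "cytosol",
                  "endoplasmic reticulum", "plasma membrane")
    loc <- rbind(
      if (length(named)) data.frame(node_id = named,
                                    localization = "Golgi"),
      if (length(seeds)) data.frame(node_id = rep(seeds, each = 2),
                                    localization = rep(c("Golgi",
                                                         "vesicle"),
                                                       length(seeds))),
      data.frame(node_id = setdiff(nodes, c(named, seeds)),
                 localization = sample(loc_pool,
                                       length(setdiff(nodes,
                                                      c(named, seeds))),
                                       replace = TRUE))
    )
    truth_edges <- data.frame(a = pmin(edges$a, edges$b),
                              b = pmax(edges$a, edges$b),
                              stringsAsFactors = FALSE)
    truth_edges <- truth_edges[order(truth_edges$a, truth_edges$b), ]
    rownames(truth_edges) <- NULL
    list(records = records,
         truth = list(nodes = sort(unique(c(edges$a, edges$b))),
                      edges = truth_edges,
                      n_nodes = length(unique(c(edges$a, edges$b))),
                      n_edges = n_clean),
         localizations = loc)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the simplified 5-column interaction TSV
#'
#' @param records Interaction record data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_interactions <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
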