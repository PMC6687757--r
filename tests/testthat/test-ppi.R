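simple_records <- function() {
  data.frame(
    interactor_a = c("A", "A", "B", "C"),
    interactor_b = c("A", "B", "A", "D"),
    detection_method = "pull down",
    interaction_type = "physical association",
    confidence = c(0.9, 0.8, 0.7, 0.95),
    stringsAsFactors = FALSE)
}

test_that("the 5-column TSV and MITAB formats both parse", {
  p <- tempfile(fileext = ".tsv")
  write_interactions(simple_records(), p)
  rec <- parse_interactions(p)
  expect_equal(nrow(rec), 4)
  expect_equal(rec$confidence[4], 0.95)

  # MITAB 2.5-style: 15 tab-separated fields, wrapped identifiers
  mitab_row <- function(a, b, meth, type, score) {
    paste(c(paste0("uniprotkb:", a), paste0("uniprotkb:", b),
            "-", "-", "-", "-",
            sprintf('psi-mi:"MI:0096"(%s)', meth),
            "-", "-", "-", "-",
            sprintf('psi-mi:"MI:0915"(%s)', type),
            "-", "-", paste0("intact-miscore:", score)),
          collapse = "\t")
  }
  pm <- tempfile(fileext = ".txt")
  writeLines(c(mitab_row("P1", "P2", "pull down",
                         "physical association", 0.8),
               mitab_row("P2", "P3", "two hybrid",
                         "direct interaction", 0.6)), pm)
  rm_ <- parse_interactions(pm)
  expect_equal(rm_$interactor_a, c("P1", "P2"))
  expect_equal(rm_$detection_method[1], "pull down")
  expect_equal(rm_$confidence, c(0.8, 0.6))

  # self-loop rows survive parsing (removed later, at cleaning)
  expect_true(any(rec$interactor_a == rec$interactor_b))

  # malformed input: missing column reported with its location
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("interactor_a\tinteractor_b\tconfidence", "A\tB\t0.5"), bad)
  expect_error(parse_interactions(bad), "format error")
  ragged <- tempfile(fileext = ".tsv")
  writeLines(c(paste(c("interactor_a", "interactor_b",
                       "detection_method", "interaction_type",
                       "confidence"), collapse = "\t"),
               "A\tB\tpull down\tphysical association\t0.5",
               "A\tB\tpull down"), ragged)
  expect_error(parse_interactions(ragged), "row 3")

  # alias normalization
  rec_al <- parse_interactions(simple_records(),
                               aliases = c(A = "P100", Zz = "P999"))
  expect_true(all(rec_al$interactor_a != "A"))
  expect_equal(rec_al$interactor_b[4], "D")  # unmapped kept verbatim
})

test_that("high-confidence filtering enforces all three conditions", {
  rec <- data.frame(
    interactor_a = c("A", "A", "A", "A"),
    interactor_b = c("B", "C", "D", "E"),
    detection_method = c("pull down", "pull down", "witchcraft",
                         "pull down"),
    interaction_type = c("physical association", "genetic interaction",
                         "physical association", "physical association"),
    confidence = c(0.9, 0.99, 0.99, 0.2),
    stringsAsFactors = FALSE)
  kept <- filter_high_confidence(rec, filter_config(min_confidence = 0.5))
  expect_equal(kept$interactor_b, "B")  # genetic / unknown method / low
  expect_error(filter_config(methods = character(0)), "non-empty")
})

test_that("cleaning removes loops and redundant pairs, idempotently", {
  g <- clean_graph(simple_records())
  # {A-A, A-B, B-A, C-D} -> edges {A-B, C-D}
  expect_equal(igraph::ecount(g), 2)
  expect_equal(sort(igraph::V(g)$name), c("A", "B", "C", "D"))
  ab <- igraph::E(g)[igraph::V(g)["A"] %--% igraph::V(g)["B"]]
  expect_equal(igraph::edge_attr(g, "n_records", ab), 2)  # merged A-B/B-A

  g2 <- clean_graph(g)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  expect_equal(sort(igraph::V(g2)$name), sort(igraph::V(g)$name))

  # cleaning commutes with confidence filtering
  fx <- generate_interaction_table(n_nodes = 25, n_edges = 40, seed = 6)
  rec <- parse_interactions(fx$records)
  a <- clean_graph(filter_high_confidence(rec))
  expect_equal(igraph::ecount(a), fx$truth$n_edges)
  expect_equal(sort(igraph::V(a)$name), fx$truth$nodes)
})

test_that("neighbourhood extraction matches adjacency scans", {
  fx <- random_graph_fixture(18, 0.15, seed = 21)
  g <- clean_graph(fx$records)
  seeds <- igraph::V(g)$name[1:2]
  fd <- first_degree(g, seeds)
  # brute-force membership from the adjacency matrix
  idx <- match(igraph::V(g)$name, fx$ids)
  want <- unique(c(seeds, unlist(lapply(seeds, function(s) {
    fx$ids[which(fx$adj[match(s, fx$ids), ] > 0)]
  }))))
  want <- intersect(want, igraph::V(g)$name)
  expect_setequal(igraph::V(fd)$name, want)

  # star graph seeded at the hub returns the whole star
  star <- data.frame(interactor_a = "HUB",
                     interactor_b = paste0("L", 1:5),
                     detection_method = "pull down",
                     interaction_type = "physical association",
                     confidence = 1, stringsAsFactors = FALSE)
  sg <- clean_graph(star)
  expect_equal(igraph::vcount(first_degree(sg, "HUB")), 6)
  expect_error(first_degree(sg, "GHOST"), "seeds")
  fd_m <- first_degree(sg, c("HUB", "GHOST"))
  expect_equal(igraph::graph_attr(fd_m, "missing_seeds"), "GHOST")
})

test_that("second-degree localization filter admits Golgi and vesicle", {
  # chain: SEED - M - {G, N}; G annotated Golgi, N nucleus
  rec <- data.frame(
    interactor_a = c("SEED", "M", "M"),
    interactor_b = c("M", "G", "N"),
    detection_method = "pull down",
    interaction_type = "physical association",
    confidence = 1, stringsAsFactors = FALSE)
  g <- clean_graph(rec)
  loc <- data.frame(node_id = c("SEED", "M", "G", "N"),
                    localization = c("Golgi", "cytosol", "Golgi",
                                     "nucleus"))
  g <- set_localizations(g, loc)
  expect_error(second_degree(clean_graph(rec), "SEED"), "localization")
  sd_ <- second_degree(g, "SEED")
  expect_true("G" %in% igraph::V(sd_)$name)
  expect_false("N" %in% igraph::V(sd_)$name)
  expect_true("M" %in% igraph::V(sd_)$name)  # first degree exempt
  # containment chain: seeds in first degree in second degree
  fd <- first_degree(g, "SEED")
  expect_true(all(igraph::V(fd)$name %in% igraph::V(sd_)$name))
})

test_that("betweenness has its closed forms and deterministic ties", {
  path3 <- clean_graph(data.frame(
    interactor_a = c("A", "B"), interactor_b = c("B", "C"),
    detection_method = "pull down",
    interaction_type = "physical association",
    confidence = 1, stringsAsFactors = FALSE))
  r <- betweenness_report(path3)
  expect_equal(r$betweenness[r$node == "B"], 1)
  expect_equal(r$betweenness[r$node != "B"], c(0, 0))

  k5 <- utils::combn(LETTERS[1:5], 2)
  complete <- clean_graph(data.frame(
    interactor_a = k5[1, ], interactor_b = k5[2, ],
    detection_method = "pull down",
    interaction_type = "physical association",
    confidence = 1, stringsAsFactors = FALSE))
  rk <- betweenness_report(complete)
  expect_true(all(rk$betweenness == 0))
  expect_equal(rk$node, LETTERS[1:5])  # lexicographic tie order
  expect_equal(betweenness_report(complete, top_k = 2)$rank, 1:2)
})

test_that("seed-to-tether distances report minima and unreachability", {
  rec <- data.frame(
    interactor_a = c("RAB", "M1", "Z1", "RAB", "ISLANDER"),
    interactor_b = c("M1", "Z1", "Z2", "C1", "CASTAWAY"),
    detection_method = "pull down",
    interaction_type = "physical association",
    confidence = 1, stringsAsFactors = FALSE)
  g <- clean_graph(rec)
  d <- seed_to_tether_distance(g, "RAB",
                               list(NRZ = c("Z1", "Z2"),
                                    COG = "C1",
                                    GHOSTS = c("X1", "X2"),
                                    FAR = "CASTAWAY"))
  expect_equal(d$distance, c(2, 1, Inf, Inf))
  expect_equal(d$reachable, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(seed_to_tether_distance(g, "NOPE", list(a = "Z1")),
               "seed")
})

test_that("graph export writes GraphML and edge lists", {
  g <- clean_graph(simple_records())
  gp <- tempfile(fileext = ".graphml")
  export_graph(g, gp, "graphml")
  back <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  ep <- tempfile(fileext = ".tsv")
  export_graph(g, ep, "edgelist")
  el <- read.delim(ep)
  expect_equal(nrow(el), igraph::ecount(g))
})
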