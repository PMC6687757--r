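#' Default pipeline configuration
#'
#' Returns the full configuration list [run_pipeline()] understands;
#' override any block (or supply a YAML file with the same
#' structure). All randomness flows from the single `seed`, from
#' which each stage derives its own sub-seed, so a full run is a
#' pure function of the configuration.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "golgiscreen-run",
    stages = c("simulate", "quantify", "score", "network", "em"),
    images = list(n_fields = 2L, n_cells = 6L, rows = 256L, cols = 256L,
                  phenotypes = c("control", "tether_kd")),
    screen = list(design = "synthetic", n_targets = 20L, n_both = 4L,
                  n_zw10_only = 3L, n_cog3_only = 1L, n_basal = 2L,
                  n_cells = 30L),
    segmentation = list(mad_k = 6, min_fragment_area_px = 4L,
                        connectivity = 8L),
    scoring = list(s_lo = 0.3, s_hi = 0.7, fold_threshold = 2,
                   replication = "all"),
    network = list(n_nodes = 60L, n_edges = 120L),
    em = list()
  )
}

#' Run the simulation and analysis pipeline end to end
#'
#' Executes the selected stages in order
#' simulate -> quantify -> score -> network -> em, writing every
#' intermediate table under `outdir` and finishing with a
#' `manifest.json` that records the package version, the seeds used,
#' and an MD5 content hash of every output file. Identical
#' configurations produce byte-identical CSV outputs.
#'
#' @param config A configuration list (see [default_run_config()]),
#'   a YAML file path, or `NULL` for the defaults. Partial lists are
#'   merged over the defaults; unknown keys are rejected.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- default_run_config()
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    for (k in names(config)) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(config[[k]])) {
        utils::modifyList(cfg[[k]], config[[k]])
      } else config[[k]]
    }
  }
  bad <- setdiff(cfg$stages, c("simulate", "quantify", "score",
                               "network", "em"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  seeds <- list(master = cfg$seed)
  emit <- function(path) outputs[[length(outputs) + 1L]] <<- path
  log_stage <- function(s) message("[golgiscreen] stage: ", s)
  run_stage <- function(name, fun) {
    log_stage(name)
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  if ("simulate" %in% cfg$stages) run_stage("simulate", function() {
    seeds$images <<- derive_seed(cfg$seed, "images")
    presets <- phenotype_presets()
    for (i in seq_len(cfg$images$n_fields)) {
      ph <- cfg$images$phenotypes[(i - 1) %% length(cfg$images$phenotypes) + 1]
      fld <- generate_field(
        field_spec(rows = cfg$images$rows, cols = cfg$images$cols,
                   n_cells = cfg$images$n_cells,
                   seed = seeds$images + i),
        presets[[ph]])
      img <- file.path(cfg$outdir, sprintf("field_%02d_%s.tif", i, ph))
      tru <- file.path(cfg$outdir, sprintf("field_%02d_%s_truth.csv", i, ph))
      write_field(fld, img, tru)
      emit(img); emit(tru)
    }
    seeds$screen <<- derive_seed(cfg$seed, "screen")
    des <- if (identical(cfg$screen$design, "default_rab")) {
      default_rab_design(seed = seeds$screen)
    } else {
      synthetic_screen_design(n_targets = cfg$screen$n_targets,
                              n_both = cfg$screen$n_both,
                              n_zw10_only = cfg$screen$n_zw10_only,
                              n_cog3_only = cfg$screen$n_cog3_only,
                              n_basal = cfg$screen$n_basal,
                              seed = seeds$screen)
    }
    scr <- generate_screen(des, n_cells = cfg$screen$n_cells,
                           seed = seeds$screen)
    p <- file.path(cfg$outdir, "screen_measurements.csv")
    utils::write.csv(scr$measurements, p, row.names = FALSE); emit(p)
    p <- file.path(cfg$outdir, "screen_truth.csv")
    utils::write.csv(scr$truth, p, row.names = FALSE); emit(p)
    seeds$network <<- derive_seed(cfg$seed, "network")
    net <- generate_interaction_table(
      n_nodes = cfg$network$n_nodes, n_edges = cfg$network$n_edges,
      planted = list(cliques = list(NRZ = c("ZW10", "RINT1", "NBAS"),
                                    COG = paste0("COG", 1:8)),
                     paths = list(list(from = "RAB6A", to_complex = "NRZ",
                                       length = 2),
                                  list(from = "RAB6A", to_complex = "COG",
                                       length = 4))),
      seed = seeds$network)
    p <- file.path(cfg$outdir, "interactions.tsv")
    write_interactions(net$records, p); emit(p)
    p <- file.path(cfg$outdir, "localizations.tsv")
    utils::write.table(net$localizations, p, sep = "\t",
                       row.names = FALSE, quote = FALSE); emit(p)
    seeds$em <<- derive_seed(cfg$seed, "em")
    em <- generate_em_table(seed = seeds$em)
    p <- file.path(cfg$outdir, "em_records.csv")
    utils::write.csv(em[names(em) != "vesicle_diameters_nm"], p,
                     row.names = FALSE); emit(p)
  })

  if ("quantify" %in% cfg$stages) run_stage("quantify", function() {
    imgs <- sort(list.files(cfg$outdir, "^field_.*\\.tif$",
                            full.names = TRUE))
    if (length(imgs) == 0) stop("no simulated fields found to quantify")
    seg <- seg_params(mad_k = cfg$segmentation$mad_k,
                      min_fragment_area_px =
                        cfg$segmentation$min_fragment_area_px,
                      connectivity = cfg$segmentation$connectivity)
    all_cells <- list()
    for (img in imgs) {
      truth <- utils::read.csv(sub("\\.tif$", "_truth.csv", img))
      q <- quantify_field(read_stack(img), truth, seg = seg,
                          psf_sigma_px = 1.2, pixel_size_um = 0.1)
      cells <- q$cells
      cells$field <- basename(img)
      cells$phenotype <- sub("^field_[0-9]+_(.*)\\.tif$", "\\1",
                             basename(img))
      all_cells[[img]] <- cells
    }
    cells <- do.call(rbind, all_cells)
    rownames(cells) <- NULL
    p <- file.path(cfg$outdir, "cell_quant.csv")
    utils::write.csv(cells, p, row.names = FALSE); emit(p)
    ctrl_cells <- cells[cells$phenotype == "control", , drop = FALSE]
    ctrl <- if (nrow(ctrl_cells)) {
      summarize_condition(ctrl_cells, "control")
    } else NULL
    sums <- lapply(split(cells, cells$phenotype), function(cc)
      summarize_condition(cc, cc$phenotype[1], control = ctrl))
    p <- file.path(cfg$outdir, "condition_summaries.csv")
    utils::write.csv(do.call(rbind, sums), p, row.names = FALSE); emit(p)
  })

  if ("score" %in% cfg$stages) run_stage("score", function() {
    p_in <- file.path(cfg$outdir, "screen_measurements.csv")
    if (!file.exists(p_in)) stop("no screen measurement table found")
    meas <- utils::read.csv(p_in, stringsAsFactors = FALSE)
    truth <- utils::read.csv(file.path(cfg$outdir, "screen_truth.csv"),
                             stringsAsFactors = FALSE)
    res <- score_screen(meas, classes = truth[c("target", "class")],
                        flags = truth[c("target", "flag")],
                        s_lo = cfg$scoring$s_lo, s_hi = cfg$scoring$s_hi,
                        fold_threshold = cfg$scoring$fold_threshold,
                        replication = cfg$scoring$replication)
    p <- file.path(cfg$outdir, "sirna_calls.csv")
    utils::write.csv(res$sirna_calls, p, row.names = FALSE); emit(p)
    p <- file.path(cfg$outdir, "target_calls.csv")
    utils::write.csv(res$target_calls, p, row.names = FALSE); emit(p)
    p <- file.path(cfg$outdir, "screen_summary.csv")
    utils::write.csv(res$summary$counts, p, row.names = FALSE); emit(p)
    p <- file.path(cfg$outdir, "screen_summary.json")
    jsonlite::write_json(list(counts = res$summary$counts,
                              membership = res$summary$membership,
                              excluded = res$summary$excluded),
                         p, auto_unbox = TRUE, pretty = TRUE); emit(p)
  })

  if ("network" %in% cfg$stages) run_stage("network", function() {
    p_in <- file.path(cfg$outdir, "interactions.tsv")
    if (!file.exists(p_in)) stop("no interaction table found")
    rec <- parse_interactions(p_in)
    g <- clean_graph(filter_high_confidence(rec, filter_config()))
    loc <- utils::read.delim(file.path(cfg$outdir, "localizations.tsv"),
                             stringsAsFactors = FALSE)
    g <- set_localizations(g, loc)
    p <- file.path(cfg$outdir, "network.graphml")
    export_graph(g, p, "graphml"); emit(p)
    p <- file.path(cfg$outdir, "network_edges.tsv")
    export_graph(g, p, "edgelist"); emit(p)
    cb <- betweenness_report(g)
    p <- file.path(cfg$outdir, "betweenness.csv")
    utils::write.csv(cb, p, row.names = FALSE); emit(p)
    if ("RAB6A" %in% igraph::V(g)$name) {
      d <- seed_to_tether_distance(g, "RAB6A",
                                   list(NRZ = c("ZW10", "RINT1", "NBAS"),
                                        COG = paste0("COG", 1:8)))
      p <- file.path(cfg$outdir, "tether_distances.csv")
      utils::write.csv(d, p, row.names = FALSE); emit(p)
    }
  })

  if ("em" %in% cfg$stages) run_stage("em", function() {
    p_in <- file.path(cfg$outdir, "em_records.csv")
    if (!file.exists(p_in)) stop("no EM record table found")
    rec <- utils::read.csv(p_in, stringsAsFactors = FALSE)
    s <- summarize_em(rec)
    p <- file.path(cfg$outdir, "em_summaries.csv")
    utils::write.csv(s, p, row.names = FALSE); emit(p)
    pick <- function(cond) s[s$condition == cond, , drop = FALSE]
    cmp <- list()
    if (all(c("Control", "ZW10") %in% s$condition)) {
      cmp$zw10_vs_control <- compare_conditions(pick("Control"),
                                                pick("ZW10"),
                                                "vesicles_within_1um")
    }
    if (all(c("Rab33B", "ZW10+Rab33B") %in% s$condition)) {
      cmp$double_vs_rab33b <- compare_conditions(pick("Rab33B"),
                                                 pick("ZW10+Rab33B"),
                                                 "vesicles_within_1um")
    }
    if (length(cmp)) {
      p <- file.path(cfg$outdir, "em_comparisons.csv")
      utils::write.csv(do.call(rbind, cmp), p, row.names = FALSE); emit(p)
    }
  })

  manifest <- list(
    package = "golgiscreen",
    version = as.character(utils::packageVersion("golgiscreen")),
    seeds = seeds, stages = cfg$stages,
    outputs = lapply(outputs, function(p)
      list(file = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
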