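test_that("field generation is deterministic and handles the empty field", {
  sp <- field_spec(n_cells = 0, seed = 7)
  f <- generate_field(sp, phenotype_presets()$control)
  expect_equal(nrow(f$truth), 0)
  expect_equal(dim(f$stack), c(256, 256, 3))
  # background-only: nothing but noise around the background level
  expect_lt(abs(mean(f$stack) - sp$background_level), 2)

  sp2 <- field_spec(n_cells = 4, seed = 11)
  f1 <- generate_field(sp2, phenotype_presets()$tether_kd)
  f2 <- generate_field(sp2, phenotype_presets()$tether_kd)
  expect_identical(f1$stack, f2$stack)
  expect_identical(f1$truth, f2$truth)

  expect_error(field_spec(rows = 8), "invalid")
  expect_error(generate_field(list(), phenotype_presets()$control),
               "invalid-spec")
})

test_that("ground-truth areas match pixel enumeration of the clean render", {
  sp <- field_spec(n_cells = 3, psf_sigma_px = 0, read_noise_sd = 0,
                   shot_noise = FALSE, seed = 5)
  f <- generate_field(sp, phenotype_presets()$control)
  # noiseless, PSF-free: Golgi pixels are exactly those above the
  # flat background + cellular context, enumerable directly
  proj <- max_project(f$stack)
  ctx_max <- sp$background_level + 30 + 10  # cytoplasm + nucleus levels
  mask <- proj > ctx_max
  expect_equal(sum(f$truth$true_area_px), sum(mask))
  expect_equal(sum(f$truth$true_area_px),
               sum(f$components$area_px))  # conservation across cells
  expect_true(all(f$truth$true_fragments >= 1))
})

test_that("field TIFF/CSV round trip preserves the stack and truth", {
  f <- generate_field(field_spec(n_cells = 2, seed = 3),
                      phenotype_presets()$control)
  img <- tempfile(fileext = ".tif"); tru <- tempfile(fileext = ".csv")
  write_field(f, img, tru)
  expect_equal(read_stack(img), f$stack)
  back <- read.csv(tru)
  expect_equal(back$true_fragments, f$truth$true_fragments)
})

test_that("expected fragment count responds monotonically to the mean", {
  means <- c(2, 4.5, 10, 22.5)
  measured <- vapply(means, function(mu) {
    ph <- phenotype_params(fragments_mean = mu, scatter_radius_px = 20)
    f <- generate_field(field_spec(n_cells = 6, psf_sigma_px = 0,
                                   read_noise_sd = 0, shot_noise = FALSE,
                                   seed = 99), ph)
    mean(f$truth$true_fragments)
  }, numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("screen generator honours planted truth and the null screen", {
  # all targets non-suppressive: every double knockdown sits at the
  # tether-alone phenotype
  des <- synthetic_screen_design(n_targets = 6, n_both = 0,
                                 n_zw10_only = 0, n_cog3_only = 0,
                                 n_basal = 0, seed = 2)
  scr <- generate_screen(des, n_cells = 200, seed = 8)
  m <- scr$measurements
  kd_mean <- mean(m$fragments[m$target == "scrambled" &
                                m$background == "ZW10"])
  dbl <- tapply(m$fragments[m$target != "scrambled" &
                              m$background == "ZW10"],
                m$target[m$target != "scrambled" & m$background == "ZW10"],
                mean)
  expect_true(all(abs(dbl - kd_mean) < 3 * sqrt(45 / 200)))

  # complete rescue: efficacy 1 dual suppressor lands on the control
  # preset mean, by the interpolation mu = KD - e*s*(KD - control)
  tg <- data.frame(target = "HIT", class = "rab", n_sirnas = 1,
                   basal_class = "no_effect", suppression_class = "both")
  eff <- data.frame(target = "HIT", sirna_id = "pool", efficacy = 1)
  des1 <- screen_design(tg, efficacies = eff)
  scr1 <- generate_screen(des1, n_cells = 2000, seed = 4)
  m1 <- scr1$measurements
  hit_mean <- mean(m1$fragments[m1$target == "HIT" &
                                  m1$background == "COG3"])
  expect_equal(hit_mean, phenotype_presets()$control$fragments_mean,
               tolerance = 0.05)

  # every measurement row joins to exactly one truth row
  expect_true(all(m$target %in% c("scrambled", scr$truth$target)))
  expect_equal(anyDuplicated(scr$truth$target), 0)

  # determinism
  expect_identical(generate_screen(des, n_cells = 31, seed = 5),
                   generate_screen(des, n_cells = 31, seed = 5))
})

test_that("default Rab design mirrors the published screen structure", {
  d <- default_rab_design()
  expect_equal(nrow(d$targets), 19)
  expect_equal(sum(d$targets$n_sirnas == 4), 8)
  expect_equal(d$n_replicates, 2)
  expect_setequal(d$backgrounds, c("ZW10", "COG3"))
  # reserved control name and empty backgrounds are rejected
  expect_error(screen_design(data.frame(
    target = "scrambled", class = "rab", n_sirnas = 1,
    basal_class = "no_effect", suppression_class = "none")),
    "invalid-design")
  expect_error(screen_design(d$targets, backgrounds = character(0)),
               "invalid-design")
})

test_that("interaction-table mess is exactly configurable", {
  # zero mess: the table is already clean, so cleaning is a no-op
  g0 <- generate_interaction_table(
    n_nodes = 20, n_edges = 30,
    mess = list(self_loop_rate = 0, duplicate_rate = 0,
                low_confidence_rate = 0, orphan_nodes = 0), seed = 3)
  expect_equal(nrow(g0$records), g0$truth$n_edges)
  gr <- clean_graph(filter_high_confidence(parse_interactions(g0$records)))
  expect_equal(igraph::ecount(gr), g0$truth$n_edges)
  expect_equal(sort(igraph::V(gr)$name), g0$truth$nodes)

  # planted clique at confidence 1 survives default filtering intact
  g1 <- generate_interaction_table(
    n_nodes = 30, n_edges = 60,
    planted = list(cliques = list(TETHER = sprintf("S%d", 1:8))), seed = 4)
  hc <- filter_high_confidence(parse_interactions(g1$records))
  gr1 <- clean_graph(hc)
  sub <- igraph::induced_subgraph(gr1, sprintf("S%d", 1:8))
  expect_equal(igraph::ecount(sub), choose(8, 2))

  # determinism and infeasibility
  expect_identical(generate_interaction_table(n_nodes = 20, n_edges = 30,
                                              seed = 9),
                   generate_interaction_table(n_nodes = 20, n_edges = 30,
                                              seed = 9))
  expect_error(generate_interaction_table(n_nodes = 5, n_edges = 100),
               "infeasible")
})

test_that("EM table draws respect configured moments", {
  cond <- data.frame(condition = "fix", n = 5,
                     mean_max_cisterna_length_nm = 900,
                     sd_max_cisterna_length_nm = 0,
                     mean_cisternae_count = 4, sd_cisternae_count = 0,
                     mean_vesicles_within_1um = 6.7,
                     sd_vesicles_within_1um = 0)
  em <- generate_em_table(cond, seed = 1)
  expect_true(all(em$vesicles_within_1um == 6.7))
  expect_true(all(em$max_cisterna_length_nm == 900))

  cond$n <- 10000; cond$sd_vesicles_within_1um <- 2
  em2 <- generate_em_table(cond, seed = 2)
  expect_equal(mean(em2$vesicles_within_1um), 6.7, tolerance = 0.02)
  expect_true(all(em2$vesicles_within_1um >= 0))

  # default configuration ships one condition per reference table row
  ref <- reference_em_table()
  em3 <- generate_em_table(seed = 3)
  expect_setequal(unique(em3$condition), ref$condition)
  expect_equal(as.vector(table(em3$condition)[ref$condition]),
               ref$n_stacks)
  expect_error(generate_em_table(within(cond, n <- 0)), "n >= 1")
})
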