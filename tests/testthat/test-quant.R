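test_that("Richardson-Lucy deconvolution keeps its contract", {
  img <- matrix(10, 32, 32)
  img[16, 10] <- 500; img[16, 22] <- 500

  # delta-kernel / zero-iteration fixed points
  expect_identical(deconvolve(img, 0, 50), img)
  expect_identical(deconvolve(img, 2, 0), img)
  expect_error(deconvolve(img - 20, 2), "negative")

  # sharpening: RMSE to the unblurred truth improves on the blurred input
  sigma <- 1.5
  k <- EBImage::makeBrush(2 * ceiling(3 * sigma) + 1, "Gaussian",
                          sigma = sigma)
  blurred <- as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
  rest <- deconvolve(blurred, sigma, 50)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(rest, img), rmse(blurred, img))
  expect_true(all(rest >= 0))

  # stacks are deconvolved plane by plane
  st <- array(blurred, dim = c(32, 32, 2))
  out <- deconvolve(st, sigma, 5)
  expect_equal(out[, , 1], out[, , 2])
})

test_that("maximum projection equals the elementwise maximum", {
  set.seed(42)
  st <- array(runif(20 * 15 * 3), dim = c(20, 15, 3))
  proj <- max_project(st)
  # brute-force elementwise loop
  oracle <- matrix(0, 20, 15)
  for (i in 1:20) for (j in 1:15) oracle[i, j] <- max(st[i, j, ])
  expect_equal(proj, oracle)
  for (p in 1:3) expect_true(all(proj >= st[, , p]))
  one <- matrix(runif(12), 4, 3)
  expect_identical(max_project(one), one)
  expect_error(max_project(array(1, c(2, 2, 0))), "plane")
})

test_that("segmentation recovers disks and respects connectivity", {
  img <- matrix(10, 64, 64)
  disk_px <- function(img, r0, c0, rad, val) {
    for (i in 1:64) for (j in 1:64) {
      if ((i - r0)^2 + (j - c0)^2 <= rad^2) img[i, j] <- val
    }
    img
  }
  img <- disk_px(img, 12, 12, 3, 100)
  img <- disk_px(img, 12, 40, 4, 100)
  img <- disk_px(img, 45, 25, 5, 100)
  labs <- segment_golgi(img, seg_params())
  expect_equal(max(labs), 3)
  # areas equal direct pixel enumeration per disk
  oracle <- brute_label(img > 50, 8)
  expect_equal(tabulate(labs[labs > 0]), tabulate(oracle[oracle > 0]))

  # constant image: no signal under median_mad, empty under otsu
  flat <- matrix(7, 32, 32)
  expect_equal(max(segment_golgi(flat, seg_params())), 0)
  expect_equal(max(segment_golgi(flat, seg_params("otsu"))), 0)

  # 1-px diagonal bridge joins two disks under 8- but not 4-connectivity
  br <- matrix(0, 32, 32)
  br[10:14, 8:12] <- 100
  br[16:20, 14:18] <- 100
  br[15, 13] <- 100  # diagonal corner touch
  l8 <- segment_golgi(br, seg_params(connectivity = 8,
                                     min_fragment_area_px = 1))
  l4 <- segment_golgi(br, seg_params(connectivity = 4,
                                     min_fragment_area_px = 1))
  expect_equal(max(l8), 1)
  expect_gt(max(l4), 1)
})

test_that("component labeling matches flood fill on random masks", {
  for (s in 1:20) {
    set.seed(s)
    mask <- matrix(runif(30 * 30) < 0.35, 30, 30)
    for (conn in c(4, 8)) {
      got <- label_components(mask, conn)
      want <- brute_label(mask, conn)
      expect_equal(max(got), max(want))
      # identical partitions: cross-tabulation is a permutation matrix
      if (max(got) > 0) {
        tab <- table(got[mask], want[mask])
        expect_true(all(rowSums(tab > 0) == 1) &&
                      all(colSums(tab > 0) == 1))
      }
    }
  }
})

test_that("fragments are assigned to the nearest nucleus with tie rules", {
  labs <- matrix(0L, 40, 60)
  labs[19:21, 9:11] <- 1L    # centroid (20, 10)
  labs[19:21, 49:51] <- 2L   # centroid (20, 50)
  labs[19:21, 29:31] <- 3L   # centroid (20, 30): equidistant
  seeds <- data.frame(cell_id = c(1, 2),
                      nucleus_row = c(20, 20), nucleus_col = c(10, 50))
  cells <- assign_to_cells(labs, seeds)
  expect_equal(cells$fragments[cells$cell_id == 1], 2)  # tie -> lower id
  expect_equal(cells$fragments[cells$cell_id == 2], 1)

  # border nuclei are dropped together with their fragments
  seeds_b <- rbind(seeds, data.frame(cell_id = 3, nucleus_row = 3,
                                     nucleus_col = 30))
  cells_b <- assign_to_cells(labs, seeds_b)
  expect_false(3 %in% cells_b$cell_id)

  # zero-fragment cells are reported with zero area (area = 0 iff n = 0)
  far <- data.frame(cell_id = 9, nucleus_row = 20, nucleus_col = 30)
  empty <- assign_to_cells(matrix(0L, 40, 60), far)
  expect_equal(empty$fragments, 0)
  expect_equal(empty$area_px, 0)
  expect_error(assign_to_cells(labs, seeds[0, ]), "seed")
})

test_that("condition summaries compute SEM and normalization correctly", {
  cells <- data.frame(fragments = c(3, 4, 5), area_px = c(30, 40, 50))
  s <- summarize_condition(cells, "demo")
  expect_equal(s$mean_fragments, 4)
  expect_equal(s$sem_fragments, 1 / sqrt(3))  # sample SD 1
  expect_equal(s$norm_fragments, 1)           # self-normalized
  expect_true(s$low_n)

  ctrl <- summarize_condition(data.frame(fragments = rep(2, 30),
                                         area_px = rep(20, 30)), "ctrl")
  expect_false(ctrl$low_n)
  s2 <- summarize_condition(cells, "demo", control = ctrl)
  expect_equal(s2$norm_fragments, 2)
  # normalization commutes with a change of area units
  cells_um <- transform(cells, area_px = area_px * 0.01)
  ctrl_um <- summarize_condition(transform(
    data.frame(fragments = rep(2, 30), area_px = rep(20, 30)),
    area_px = area_px * 0.01), "ctrl")
  expect_equal(summarize_condition(cells_um, "demo", ctrl_um)$norm_area,
               s2$norm_area)

  expect_error(summarize_condition(cells[0, ]), "empty")
  zero <- data.frame(fragments = 0, area_px = 0)
  expect_error(summarize_condition(cells, control =
                                     summarize_condition(zero)),
               "normalization|zero")
})

test_that("noiseless pipeline recovery is exact and areas are bounded", {
  for (s in 1:3) {
    ph <- if (s == 1) phenotype_presets()$control else
      phenotype_presets()$tether_kd
    f <- generate_field(field_spec(n_cells = 6, psf_sigma_px = 0,
                                   read_noise_sd = 0, shot_noise = FALSE,
                                   seed = 40 + s), ph)
    q <- quantify_field(f$stack, f$truth, psf_sigma_px = 0)
    m <- merge(f$truth, q$cells, by = "cell_id")
    expect_equal(m$fragments, m$true_fragments)
    expect_equal(m$area_px, m$true_area_px)
    expect_lt(sum(q$cells$area_px), prod(dim(f$stack)[1:2]))
  }
})

test_that("measured condition means track increasing true fragment load", {
  mus <- c(3, 6, 12)
  measured <- vapply(seq_along(mus), function(i) {
    ph <- phenotype_params(fragments_mean = mus[i], scatter_radius_px = 18)
    f <- generate_field(field_spec(n_cells = 6, psf_sigma_px = 0,
                                   read_noise_sd = 0, shot_noise = FALSE,
                                   seed = 77), ph)
    q <- quantify_field(f$stack, f$truth, psf_sigma_px = 0)
    mean(q$cells$fragments)
  }, numeric(1))
  expect_true(all(diff(measured) >= 0))
})
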