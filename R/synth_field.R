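#' Generate a synthetic fluorescence field with per-cell ground truth
#'
#' Renders a multi-plane widefield-style image of cells expressing a
#' fluorescent Golgi marker. Each cell is a dim nucleus disk, a diffuse
#' cytoplasmic halo, and a set of bright Golgi fragments: compact-
#' support Gaussian-profile blobs scattered isotropically around a
#' juxtanuclear anchor. Each fragment is placed in one z-plane. The
#' expected image is convolved with a Gaussian PSF, then Poisson shot
#' noise and additive Gaussian read noise are applied (see
#' [field_spec()]).
#'
#' Ground truth is defined on the pre-PSF, pre-noise Golgi-only
#' render: connected components of its supra-zero mask are the true
#' fragments, and each component is assigned to the nearest nucleus —
#' the same assignment rule [assign_to_cells()] uses — so truth and
#' measurement share one observable definition even when blobs planted
#' by one cell overlap or drift towards a neighbour.
#'
#' @param spec A [field_spec()].
#' @param phenotype A [phenotype_params()] or the name of a preset in
#'   [phenotype_presets()].
#' @return A `synthetic_field` list: `stack` (rows x cols x planes
#'   integer array, 16-bit range), `truth` (per-cell data frame:
#'   `cell_id, nucleus_row, nucleus_col, true_fragments,
#'   true_area_px`), `components` (per-fragment data frame: `cell_id,
#'   row, col, area_px`), plus `spec` and `phenotype`. Coordinates are
#'   1-based (row, col), origin top-left.
#' @examples
#' f <- generate_field(field_spec(n_cells = 2, seed = 3),
#'                     phenotype_presets()$control)
#' f$truth
#' @export
generate_field <- function(spec, phenotype) {
  if (!inherits(spec, "field_spec")) {
    stop("invalid-spec: `spec` must be a field_spec()")
  }
  if (is.character(phenotype)) {
    phenotype <- phenotype_presets()[[match.arg(phenotype,
                                                names(phenotype_presets()))]]
  }
  if (!inherits(phenotype, "phenotype_params")) {
    stop("`phenotype` must be phenotype_params() or a preset name")
  }
  with_seed(spec$seed, render_field(spec, phenotype))
}

# geometry constants of the cell cartoon (pixels)
.NUCLEUS_RADIUS <- 9
.CYTO_RADIUS <- 26
.CYTO_LEVEL <- 30
.NUCLEUS_LEVEL <- 10

render_field <- function(spec, phenotype) {
  rows <- spec$rows; cols <- spec$cols; planes <- spec$n_planes
  golgi <- array(0, dim = c(rows, cols, planes))
  context <- matrix(0, rows, cols)

  nuclei <- place_nuclei(spec)
  comp_df <- data.frame(cell_id = integer(), row = numeric(),
                        col = numeric(), area_px = integer())
  truth <- data.frame(cell_id = integer(), nucleus_row = numeric(),
                      nucleus_col = numeric(), true_fragments = integer(),
                      true_area_px = integer())

  if (spec$n_cells > 0) {
    for (i in seq_len(spec$n_cells)) {
      context <- add_disk(context, nuclei$nucleus_row[i],
                          nuclei$nucleus_col[i], .CYTO_RADIUS, .CYTO_LEVEL)
      context <- add_disk(context, nuclei$nucleus_row[i],
                          nuclei$nucleus_col[i], .NUCLEUS_RADIUS,
                          .NUCLEUS_LEVEL)
    }
    for (i in seq_len(spec$n_cells)) {
      k <- draw_fragment_count(1, phenotype)
      ang <- stats::runif(1, 0, 2 * pi)
      anchor <- c(nuclei$nucleus_row[i], nuclei$nucleus_col[i]) +
        (.NUCLEUS_RADIUS + 4) * c(sin(ang), cos(ang))
      placed <- matrix(numeric(0), ncol = 3)  # row, col, radius
      for (j in seq_len(k)) {
        r <- max(1.3, stats::rnorm(1,
          mean = phenotype$fragment_radius_px * sqrt(phenotype$area_scale),
          sd = 0.3))
        # rejection placement: keep a gap between a cell's fragments so
        # every planted fragment stays individually detectable, matching
        # the phenotype's calibration in *detectable* fragments per cell
        for (try in 1:40) {
          ctr <- anchor + stats::rnorm(2, sd = phenotype$scatter_radius_px)
          ctr[1] <- min(max(ctr[1], r + 2), rows - r - 1)
          ctr[2] <- min(max(ctr[2], r + 2), cols - r - 1)
          if (nrow(placed) == 0) break
          gap <- sqrt((placed[, 1] - ctr[1])^2 + (placed[, 2] - ctr[2])^2) -
            (placed[, 3] + r)
          if (min(gap) >= 3) break
        }
        placed <- rbind(placed, c(ctr, r))
        amp <- max(stats::rnorm(1, phenotype$fragment_intensity,
                                0.1 * phenotype$fragment_intensity),
                   0.4 * phenotype$fragment_intensity)
        p <- sample.int(planes, 1)
        golgi[, , p] <- add_blob(golgi[, , p], ctr[1], ctr[2], r, amp)
      }
    }
    # ground truth from the pre-PSF, pre-noise Golgi render
    mask <- apply(golgi, c(1, 2), max) > 0
    labs <- label_components(mask, connectivity = 8)
    comp_df <- component_table(labs)
    truth <- data.frame(cell_id = nuclei$cell_id,
                        nucleus_row = nuclei$nucleus_row,
                        nucleus_col = nuclei$nucleus_col,
                        true_fragments = 0L, true_area_px = 0L)
    if (nrow(comp_df) > 0) {
      owner <- nearest_seed(comp_df$row, comp_df$col,
                            nuclei$nucleus_row, nuclei$nucleus_col,
                            nuclei$cell_id)
      comp_df <- data.frame(cell_id = owner, row = comp_df$row,
                            col = comp_df$col, area_px = comp_df$area_px)
      agg_n <- tapply(comp_df$area_px, comp_df$cell_id, length)
      agg_a <- tapply(comp_df$area_px, comp_df$cell_id, sum)
      idx <- match(as.integer(names(agg_n)), truth$cell_id)
      truth$true_fragments[idx] <- as.integer(agg_n)
      truth$true_area_px[idx] <- as.integer(agg_a)
    }
  }

  for (p in seq_len(planes)) {
    expected <- spec$background_level + context + golgi[, , p]
    if (spec$psf_sigma_px > 0) {
      expected <- gaussian_blur(expected, spec$psf_sigma_px)
    }
    img <- if (spec$shot_noise) {
      matrix(stats::rpois(length(expected), pmax(expected, 0)),
             nrow(expected), ncol(expected))
    } else expected
    if (spec$read_noise_sd > 0) {
      img <- img + stats::rnorm(length(img), sd = spec$read_noise_sd)
    }
    golgi[, , p] <- round(pmin(pmax(img, 0), 65535))
  }

  structure(list(stack = golgi, truth = truth, components = comp_df,
                 spec = spec, phenotype = phenotype),
            class = "synthetic_field")
}

draw_fragment_count <- function(n, phenotype) {
  mu <- phenotype$fragments_mean - 1
  if (mu <= 0) return(rep(1L, n))
  1L + stats::rnbinom(n, mu = mu, size = phenotype$fragments_dispersion)
}

# jittered-grid nucleus placement, keeping every nucleus clear of the
# image border so no cell is dropped by the border rule
place_nuclei <- function(spec) {
  n <- spec$n_cells
  if (n == 0) {
    return(data.frame(cell_id = integer(), nucleus_row = numeric(),
                      nucleus_col = numeric()))
  }
  margin <- .NUCLEUS_RADIUS + 20
  gc_ <- ceiling(sqrt(n * spec$cols / spec$rows))
  gr_ <- ceiling(n / gc_)
  slot_h <- (spec$rows - 2 * margin) / gr_
  slot_w <- (spec$cols - 2 * margin) / gc_
  if (slot_h < 2 * .NUCLEUS_RADIUS || slot_w < 2 * .NUCLEUS_RADIUS) {
    stop("invalid-spec: too many cells for the field dimensions")
  }
  slots <- expand.grid(r = seq_len(gr_), c = seq_len(gc_))[seq_len(n), ]
  jit <- min(6, slot_h / 6, slot_w / 6)
  data.frame(
    cell_id = seq_len(n),
    nucleus_row = margin + (slots$r - 0.5) * slot_h +
      stats::runif(n, -jit, jit),
    nucleus_col = margin + (slots$c - 0.5) * slot_w +
      stats::runif(n, -jit, jit)
  )
}

add_disk <- function(img, r0, c0, radius, level) {
  rr <- max(1, floor(r0 - radius)):min(nrow(img), ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  img[rr, cc] <- img[rr, cc] + level * (d2 <= radius^2)
  img
}

# Gaussian-profile blob with hard support of radius `radius`
add_blob <- function(img, r0, c0, radius, amp) {
  rr <- max(1, floor(r0 - radius)):min(nrow(img), ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(ncol(img), ceiling(c0 + radius))
  d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
  sig2 <- (radius / 1.4)^2
  img[rr, cc] <- img[rr, cc] + amp * exp(-d2 / (2 * sig2)) * (d2 <= radius^2)
  img
}

gaussian_blur <- function(img, sigma) {
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(img, k, boundary = "replicate"))
}

# centroid and area of each label; rows ordered by label id
component_table <- function(labels) {
  n <- max(labels)
  if (n == 0) {
    return(data.frame(row = numeric(), col = numeric(), area_px = integer()))
  }
  idx <- which(labels > 0)
  lab <- labels[idx]
  r <- (idx - 1) %% nrow(labels) + 1
  c <- (idx - 1) %/% nrow(labels) + 1
  data.frame(
    row = as.numeric(tapply(r, lab, mean)),
    col = as.numeric(tapply(c, lab, mean)),
    area_px = as.integer(tapply(lab, lab, length))
  )
}

# nearest seed by Euclidean distance; ties go to the lowest cell id
nearest_seed <- function(row, col, seed_row, seed_col, seed_id) {
  ord <- order(seed_id)
  seed_row <- seed_row[ord]; seed_col <- seed_col[ord]
  seed_id <- seed_id[ord]
  vapply(seq_along(row), function(i) {
    d <- (seed_row - row[i])^2 + (seed_col - col[i])^2
    seed_id[which.min(d)]  # which.min takes the first = lowest id on ties
  }, seed_id[1])
}

#' Write a synthetic field to disk
#'
#' The image stack goes to a 16-bit multi-page TIFF (one page per
#' z-plane); the ground truth to a CSV with columns
#' `cell_id,nucleus_row,nucleus_col,true_fragments,true_area_px`.
#'
#' @param field A `synthetic_field` from [generate_field()].
#' @param image_path Output TIFF path.
#' @param truth_path Output CSV path (optional).
#' @return Invisibly, `image_path`.
#' @export
write_field <- function(field, image_path, truth_path = NULL) {
  stopifnot(inherits(field, "synthetic_field"))
  pages <- lapply(seq_len(dim(field$stack)[3]),
                  function(p) field$stack[, , p] / 65535)
  tiff::writeTIFF(pages, image_path, bits.per.sample = 16L)
  if (!is.null(truth_path)) {
    utils::write.csv(field$truth, truth_path, row.names = FALSE)
  }
  invisible(image_path)
}

#' Read a multi-page 16-bit TIFF as an image stack
#'
#' @param path TIFF path.
#' @return rows x cols x planes numeric array in camera counts.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (p in seq_along(pages)) arr[, , p] <- round(pages[[p]] * 65535)
  arr
}
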