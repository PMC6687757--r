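#' Richardson-Lucy deconvolution with a Gaussian PSF
#'
#' Sharpens the distinction between Golgi signal and diffuse
#' cytoplasmic fluorescence before projection and segmentation. The
#' multiplicative Richardson-Lucy update preserves non-negativity;
#' `n_iterations = 0` or `psf_sigma_px = 0` (a delta kernel) returns
#' the input unchanged.
#'
#' @param stack Matrix or rows x cols x planes array of non-negative
#'   intensities.
#' @param psf_sigma_px Gaussian PSF width in pixels (>= 0).
#' @param n_iterations Number of update iterations (>= 0).
#' @return Deconvolved stack, same shape, everywhere >= 0.
#' @export
deconvolve <- function(stack, psf_sigma_px, n_iterations = 20) {
  if (any(stack < 0)) stop("negative intensities in input stack")
  if (n_iterations < 0) stop("n_iterations must be >= 0")
  if (n_iterations == 0 || psf_sigma_px <= 0) return(stack)
  size <- 2L * as.integer(ceiling(3 * psf_sigma_px)) + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = psf_sigma_px)
  rl_plane <- function(obs) {
    eps <- 1e-8
    est <- pmax(obs, eps)
    for (i in seq_len(n_iterations)) {
      blurred <- as.matrix(EBImage::filter2(est, k, boundary = "replicate"))
      ratio <- obs / pmax(blurred, eps)
      est <- est * as.matrix(EBImage::filter2(ratio, k,
                                              boundary = "replicate"))
    }
    pmax(est, 0)
  }
  if (is.matrix(stack)) return(rl_plane(stack))
  out <- stack
  for (p in seq_len(dim(stack)[3])) out[, , p] <- rl_plane(stack[, , p])
  out
}

#' Maximum-intensity projection
#'
#' Compresses a z-stack into a single plane by the pixelwise maximum
#' over planes.
#'
#' @param stack Matrix (returned as is) or rows x cols x planes array.
#' @return A single matrix.
#' @export
max_project <- function(stack) {
  if (is.matrix(stack)) return(stack)
  if (length(dim(stack)) != 3 || dim(stack)[3] < 1) {
    stop("stack must have at least one plane")
  }
  Reduce(pmax, lapply(seq_len(dim(stack)[3]), function(p) stack[, , p]))
}

#' Segment Golgi fragments from a projected image
#'
#' Thresholds the image (robust `median + k * MAD` background rule by
#' default, or Otsu) and labels supra-threshold connected components,
#' discarding components smaller than `min_fragment_area_px`. A
#' constant image under the Otsu rule yields an empty labeling.
#'
#' @param image 2D numeric matrix.
#' @param params A [seg_params()].
#' @return Integer label matrix (0 = background, labels 1..n in raster
#'   order), with the threshold in `attr(, "threshold")`.
#' @export
segment_golgi <- function(image, params = seg_params()) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  if (!inherits(params, "seg_params")) stop("params must be seg_params()")
  rng <- range(image)
  if (params$threshold_rule == "median_mad") {
    med <- stats::median(image)
    madv <- stats::mad(image)
    floorv <- params$mad_floor_frac * (rng[2] - med)
    thr <- med + params$mad_k * max(madv, floorv)
  } else {
    if (rng[1] == rng[2]) {
      out <- matrix(0L, nrow(image), ncol(image))
      attr(out, "threshold") <- NA_real_
      return(out)
    }
    scaled <- (image - rng[1]) / (rng[2] - rng[1])
    thr <- rng[1] + EBImage::otsu(scaled, range = c(0, 1)) *
      (rng[2] - rng[1])
  }
  labs <- label_components(image > thr, params$connectivity)
  if (max(labs) > 0 && params$min_fragment_area_px > 1) {
    sizes <- tabulate(labs[labs > 0])
    keep <- which(sizes >= params$min_fragment_area_px)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- labs > 0
    labs[pos] <- remap[labs[pos]]
  }
  attr(labs, "threshold") <- thr
  labs
}

#' Label connected components of a binary mask
#'
#' Components are computed under 4- or 8-connectivity and numbered
#' 1..n by the raster (column-major) position of their first pixel,
#' so labeling is deterministic.
#'
#' @param mask Logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0) return(labels)
  id_of <- integer(nr * nc)
  id_of[idx] <- seq_along(idx)
  r <- (idx - 1L) %% nr + 1L
  c <- (idx - 1L) %/% nr + 1L
  shifts <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8) {
    shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))  # diagonals
  }
  edges <- integer(0)
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- c + s[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    has <- id_of[nb] > 0L
    if (any(has)) {
      edges <- c(edges, rbind(id_of[idx[ok][has]], id_of[nb[has]]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first (raster-order) pixel
  first <- tapply(seq_along(idx), comp, min)
  renum <- integer(max(comp))
  renum[as.integer(names(sort(first)))] <- seq_along(first)
  labels[idx] <- renum[comp]
  labels
}

#' Assign labeled fragments to cells by nearest nucleus
#'
#' Each fragment (label) is assigned to the nucleus seed nearest its
#' centroid; ties go to the lowest cell id. Cells whose nucleus disk
#' touches the image border are dropped, together with the fragments
#' nearest to them.
#'
#' @param labels Integer label matrix from [segment_golgi()].
#' @param seeds Data frame with columns `cell_id, nucleus_row,
#'   nucleus_col` (1-based pixel coordinates).
#' @param image Optional intensity image for per-cell mean fragment
#'   intensity.
#' @param pixel_size_um Optional pixel size; adds `area_um2`.
#' @param nucleus_radius_px Radius used for the border test.
#' @return Per-cell data frame: `cell_id, fragments, area_px`
#'   (+ `area_um2`, `mean_intensity` when computable). Cells with no
#'   fragment are kept with zeros.
#' @export
assign_to_cells <- function(labels, seeds, image = NULL,
                            pixel_size_um = NULL, nucleus_radius_px = 9) {
  need <- c("cell_id", "nucleus_row", "nucleus_col")
  if (!all(need %in% names(seeds))) {
    stop("seeds must have columns cell_id, nucleus_row, nucleus_col")
  }
  n_lab <- max(labels)
  if (n_lab > 0 && nrow(seeds) == 0) {
    stop("at least one nucleus seed is required when fragments are present")
  }
  r <- nucleus_radius_px
  keep <- seeds$nucleus_row - r >= 1 & seeds$nucleus_row + r <= nrow(labels) &
    seeds$nucleus_col - r >= 1 & seeds$nucleus_col + r <= ncol(labels)
  kept <- seeds[keep, , drop = FALSE]
  out <- data.frame(cell_id = kept$cell_id, fragments = 0L, area_px = 0L)
  if (!is.null(image)) out$mean_intensity <- NA_real_
  if (n_lab > 0 && nrow(seeds) > 0) {
    comp <- component_table(labels)
    # nearest over *all* seeds: a fragment closest to a dropped border
    # cell leaves with that cell rather than inflating a kept neighbour
    owner <- nearest_seed(comp$row, comp$col, seeds$nucleus_row,
                          seeds$nucleus_col, seeds$cell_id)
    idx <- match(owner, out$cell_id)  # NA for dropped cells
    for (i in which(!is.na(idx))) {
      out$fragments[idx[i]] <- out$fragments[idx[i]] + 1L
      out$area_px[idx[i]] <- out$area_px[idx[i]] + comp$area_px[i]
    }
    if (!is.null(image)) {
      pix <- labels > 0
      cell_of_pix <- owner[labels[pix]]
      mi <- tapply(image[pix], cell_of_pix, mean)
      hit <- match(as.numeric(names(mi)), out$cell_id)
      ok <- !is.na(hit)
      out$mean_intensity[hit[ok]] <- as.numeric(mi)[ok]
    }
  }
  if (!is.null(pixel_size_um)) {
    out$area_um2 <- out$area_px * pixel_size_um^2
  }
  out
}

#' Quantify one field end to end
#'
#' Deconvolve, project, segment and assign fragments to cells — the
#' per-field quantification pipeline.
#'
#' @param stack Image stack (array) or matrix.
#' @param seeds Nucleus seed data frame (see [assign_to_cells()]); a
#'   `synthetic_field$truth` table works directly.
#' @param seg A [seg_params()].
#' @param psf_sigma_px PSF width used for deconvolution (0 skips it).
#' @param rl_iterations Richardson-Lucy iterations.
#' @param pixel_size_um Optional pixel size for areas in um^2.
#' @return List: `cells` (per-cell quantification), `labels`,
#'   `projected`.
#' @export
quantify_field <- function(stack, seeds, seg = seg_params(),
                           psf_sigma_px = 0, rl_iterations = 20,
                           pixel_size_um = NULL) {
  dec <- deconvolve(stack, psf_sigma_px, rl_iterations)
  proj <- max_project(dec)
  labs <- segment_golgi(proj, seg)
  cells <- assign_to_cells(labs, seeds, image = proj,
                           pixel_size_um = pixel_size_um)
  list(cells = cells, labels = labs, projected = proj)
}

#' Summarize a condition's per-cell quantifications
#'
#' Mean and SEM (sample SD over sqrt(n)) of per-cell fragment count
#' and Golgi area, plus control-normalized values. Screen-grade data
#' points need at least 30 cells; smaller conditions are flagged, not
#' rejected.
#'
#' @param cells Per-cell data frame with `fragments` and `area_px`
#'   columns (from [assign_to_cells()] or a screen table).
#' @param condition Condition label.
#' @param control Either `NULL` (normalize against this condition
#'   itself), another `condition_summary`, or a list with
#'   `mean_fragments` and `mean_area_px`.
#' @return One-row `condition_summary` data frame: `condition,
#'   n_cells, mean_fragments, sem_fragments, mean_area_px,
#'   sem_area_px, norm_fragments, norm_area, low_n`.
#' @export
summarize_condition <- function(cells, condition = "condition",
                                control = NULL) {
  if (is.null(cells) || nrow(cells) == 0) {
    stop("cannot summarize an empty cell list")
  }
  n <- nrow(cells)
  sem <- function(x) if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
  out <- data.frame(
    condition = condition, n_cells = n,
    mean_fragments = mean(cells$fragments),
    sem_fragments = sem(cells$fragments),
    mean_area_px = mean(cells$area_px),
    sem_area_px = sem(cells$area_px),
    stringsAsFactors = FALSE
  )
  ref <- if (is.null(control)) {
    list(mean_fragments = out$mean_fragments, mean_area_px = out$mean_area_px)
  } else if (is.data.frame(control)) {
    list(mean_fragments = control$mean_fragments[1],
         mean_area_px = control$mean_area_px[1])
  } else control
  if (!is.finite(ref$mean_fragments) || ref$mean_fragments == 0) {
    stop("normalization error: control mean fragment count is zero")
  }
  out$norm_fragments <- out$mean_fragments / ref$mean_fragments
  out$norm_area <- if (is.finite(ref$mean_area_px) && ref$mean_area_px > 0) {
    out$mean_area_px / ref$mean_area_px
  } else NA_real_
  out$low_n <- n < 30
  class(out) <- c("condition_summary", class(out))
  out
}
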