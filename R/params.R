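#' Phenotype parameters for the synthetic Golgi renderer
#'
#' A phenotype is the per-cell generative model of Golgi organization:
#' how many fluorescent fragments a cell carries, how large and bright
#' they are, and how far they scatter from the juxtanuclear anchor.
#' Compact control cells have few fragments tightly clustered next to
#' the nucleus; tether-depleted cells have many fragments dispersed
#' over a wide radius.
#'
#' Per-cell fragment counts are drawn as
#' `1 + NegBin(mu = fragments_mean - 1, size = fragments_dispersion)`,
#' which guarantees at least one fragment, a mean of exactly
#' `fragments_mean`, and a monotone response of the expected count to
#' `fragments_mean`. Larger `fragments_dispersion` means *less*
#' cell-to-cell overdispersion (it is the negative-binomial size).
#'
#' @param fragments_mean Expected true fragments per cell (>= 1).
#' @param fragments_dispersion Negative-binomial size parameter of the
#'   per-cell fragment count (> 0; variance = mu + mu^2/size).
#' @param fragment_radius_px Mean fragment radius in pixels (> 0).
#' @param fragment_intensity Mean peak signal per fragment, in camera
#'   counts above background (> 0).
#' @param scatter_radius_px Standard deviation, in pixels, of the
#'   isotropic Gaussian scatter of fragment centroids around the
#'   juxtanuclear anchor (> 0).
#' @param area_scale Multiplier on fragment radii, scaling total Golgi
#'   area (> 0).
#' @return An object of class `phenotype_params`.
#' @seealso [phenotype_presets()] for the calibrated presets.
#' @export
phenotype_params <- function(fragments_mean,
                             fragments_dispersion = 20,
                             fragment_radius_px = 2.2,
                             fragment_intensity = 900,
                             scatter_radius_px = 6,
                             area_scale = 1) {
  p <- list(
    fragments_mean = fragments_mean,
    fragments_dispersion = fragments_dispersion,
    fragment_radius_px = fragment_radius_px,
    fragment_intensity = fragment_intensity,
    scatter_radius_px = scatter_radius_px,
    area_scale = area_scale
  )
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("phenotype parameters must be finite numeric scalars")
  }
  if (any(unlist(p) <= 0)) {
    stop("phenotype parameters must be strictly positive")
  }
  if (fragments_mean < 1) {
    stop("fragments_mean must be >= 1")
  }
  structure(p, class = "phenotype_params")
}

#' Calibrated phenotype presets
#'
#' Presets pin the generator to the fluorescence phenotypes the
#' pipeline is designed around: control cells with a compact
#' juxtanuclear Golgi of 4.5 detectable fragments on average, and
#' tether-knockdown (ZW10 or COG3 depleted) cells whose fragments are
#' five-fold more numerous and widely scattered. `basal_fragmenting`
#' models targets that fragment the Golgi on their own when depleted
#' (an intermediate, four-fold phenotype).
#'
#' @return Named list of [phenotype_params()]: `control`, `tether_kd`,
#'   `basal_fragmenting`.
#' @export
phenotype_presets <- function() {
  list(
    control = phenotype_params(
      fragments_mean = 4.5, scatter_radius_px = 6
    ),
    tether_kd = phenotype_params(
      fragments_mean = 22.5, scatter_radius_px = 30
    ),
    basal_fragmenting = phenotype_params(
      fragments_mean = 18, scatter_radius_px = 26
    )
  )
}

#' Specification of a synthetic imaging field
#'
#' Geometry and camera model of one simulated multi-plane fluorescence
#' field. The camera model is Poisson shot noise on the expected photon
#' count followed by additive Gaussian read noise; set
#' `shot_noise = FALSE` and `read_noise_sd = 0` for noiseless renders.
#'
#' @param rows,cols Image dimensions in pixels (>= 32).
#' @param n_planes Number of z-planes (>= 1).
#' @param n_cells Number of cells to place (>= 0).
#' @param pixel_size_um Physical pixel size in micrometres.
#' @param psf_sigma_px Gaussian point-spread-function width in pixels
#'   (>= 0; 0 disables blurring).
#' @param background_level Mean background counts per pixel.
#' @param read_noise_sd Standard deviation of additive read noise.
#' @param shot_noise Apply Poisson shot noise?
#' @param seed Integer seed; identical spec + seed gives bit-identical
#'   output.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(rows = 256, cols = 256, n_planes = 3, n_cells = 6,
                       pixel_size_um = 0.1, psf_sigma_px = 1.2,
                       background_level = 100, read_noise_sd = 2,
                       shot_noise = TRUE, seed = 1) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 32 || cols < 32) {
    stop("invalid field spec: image dimensions must be >= 32 pixels")
  }
  if (n_planes < 1) stop("invalid field spec: n_planes must be >= 1")
  if (n_cells < 0) stop("invalid field spec: n_cells must be >= 0")
  if (psf_sigma_px < 0) stop("invalid field spec: psf_sigma_px must be >= 0")
  if (pixel_size_um <= 0) stop("invalid field spec: pixel_size_um must be > 0")
  if (background_level < 0 || read_noise_sd < 0) {
    stop("invalid field spec: camera parameters must be non-negative")
  }
  structure(list(
    rows = as.integer(rows), cols = as.integer(cols),
    n_planes = as.integer(n_planes), n_cells = as.integer(n_cells),
    pixel_size_um = pixel_size_um, psf_sigma_px = psf_sigma_px,
    background_level = background_level, read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise), seed = as.integer(seed)
  ), class = "field_spec")
}

#' Segmentation parameters
#'
#' Controls the intensity segmentation that separates Golgi signal
#' from cytoplasm. The default rule thresholds at
#' `median + mad_k * MAD` of the projected image; the MAD is floored
#' at `mad_floor_frac` of the image dynamic range so that noiseless
#' images (MAD = 0) do not degenerate to threshold = median.
#'
#' @param threshold_rule `"median_mad"` (robust background) or
#'   `"otsu"`.
#' @param mad_k MAD multiplier (> 0).
#' @param min_fragment_area_px Minimum connected-component area kept,
#'   in pixels (>= 1).
#' @param connectivity Pixel connectivity for component labeling,
#'   4 or 8.
#' @param mad_floor_frac Lower bound on the MAD, as a fraction of
#'   `max - median` of the image (median_mad rule only).
#' @return An object of class `seg_params`.
#' @export
seg_params <- function(threshold_rule = c("median_mad", "otsu"),
                       mad_k = 6, min_fragment_area_px = 4,
                       connectivity = 8, mad_floor_frac = 0.01) {
  threshold_rule <- match.arg(threshold_rule)
  if (mad_k <= 0) stop("mad_k must be > 0")
  if (min_fragment_area_px < 1) stop("min_fragment_area_px must be >= 1")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  structure(list(
    threshold_rule = threshold_rule, mad_k = mad_k,
    min_fragment_area_px = as.integer(min_fragment_area_px),
    connectivity = as.integer(connectivity),
    mad_floor_frac = mad_floor_frac
  ), class = "seg_params")
}

# Run code under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators are pure in (args, seed).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a master seed and a stage label,
# keeping results below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483629L)
}
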