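#' Summarize per-stack EM morphometry by condition
#'
#' Collapses per-stack electron-microscopy measurements into the
#' standard condition table: number of stacks scored and mean ± SEM
#' of maximum cisterna length (nm), cisternae per stack, and
#' Golgi-associated vesicles within 1 µm of the stack. SEM is the
#' sample SD over sqrt(n); with a single stack it is reported as NA.
#'
#' @param records Data frame with columns `condition, stack_id,
#'   max_cisterna_length_nm, cisternae_count, vesicles_within_1um`.
#' @return Data frame, one row per condition: `condition, n_stacks`,
#'   and `mean_*` / `sem_*` for the three metrics. Condition order
#'   follows first appearance.
#' @export
summarize_em <- function(records) {
  need <- c("condition", "max_cisterna_length_nm", "cisternae_count",
            "vesicles_within_1um")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("no EM records to summarize")
  conds <- unique(records$condition)
  metrics <- c("max_cisterna_length_nm", "cisternae_count",
               "vesicles_within_1um")
  rows <- lapply(conds, function(cd) {
    r <- records[records$condition == cd, , drop = FALSE]
    n <- nrow(r)
    out <- data.frame(condition = cd, n_stacks = n,
                      stringsAsFactors = FALSE)
    for (mt in metrics) {
      out[[paste0("mean_", mt)]] <- mean(r[[mt]])
      out[[paste0("sem_", mt)]] <-
        if (n > 1) stats::sd(r[[mt]]) / sqrt(n) else NA_real_
    }
    out
  })
  do.call(rbind, rows)
}

#' Fold and percent change between two condition summaries
#'
#' Compares a metric's means between a reference condition `a` and a
#' condition `b`: `fold = mean_b / mean_a` and
#' `percent_change = 100 * (mean_a - mean_b) / mean_a` (positive =
#' decrease relative to the reference, reported with an explicit
#' `direction` so "30% fewer" is unambiguous about its anchor).
#'
#' @param summary_a,summary_b One-row summaries (or rows selected by
#'   condition name from a [summarize_em()] table).
#' @param metric One of `"max_cisterna_length_nm"`,
#'   `"cisternae_count"`, `"vesicles_within_1um"`.
#' @return One-row data frame: `metric, mean_a, mean_b, fold,
#'   percent_change, direction`.
#' @export
compare_conditions <- function(summary_a, summary_b, metric) {
  col <- paste0("mean_", metric)
  if (!col %in% names(summary_a) || !col %in% names(summary_b)) {
    stop("metric not present in both summaries: ", metric)
  }
  ma <- summary_a[[col]][1]; mb <- summary_b[[col]][1]
  if (!is.finite(ma) || ma == 0) stop("reference mean must be non-zero")
  pc <- 100 * (ma - mb) / ma
  data.frame(metric = metric, mean_a = ma, mean_b = mb,
             fold = mb / ma, percent_change = pc,
             direction = if (pc > 0) "decrease" else if (pc < 0)
               "increase" else "unchanged",
             stringsAsFactors = FALSE)
}

#' Vesicle diameter distributions per condition
#'
#' Bins per-stack vesicle diameter measurements into a histogram per
#' condition and reports summary quantiles — used to compare vesicle
#' size classes (e.g. the ~70 nm Golgi-proximal class) between
#' conditions.
#'
#' @param records EM records with a `vesicle_diameters_nm` list
#'   column (each element a numeric vector, possibly empty).
#' @param bin_width_nm Histogram bin width in nm.
#' @return List per condition: `breaks`, `counts`, `quantiles`
#'   (25/50/75%), `n`. Conditions with no diameters yield an empty
#'   histogram with a warning.
#' @export
diameter_distribution <- function(records, bin_width_nm = 10) {
  if (!"vesicle_diameters_nm" %in% names(records)) {
    stop("records lack a vesicle_diameters_nm column")
  }
  conds <- unique(records$condition)
  out <- list()
  for (cd in conds) {
    d <- unlist(records$vesicle_diameters_nm[records$condition == cd])
    if (length(d) == 0) {
      warning("no vesicle diameters recorded for condition ", cd)
      out[[cd]] <- list(breaks = numeric(0), counts = integer(0),
                        quantiles = NULL, n = 0L)
      next
    }
    lo <- bin_width_nm * floor(min(d) / bin_width_nm)
    hi <- bin_width_nm * ceiling(max(d) / bin_width_nm)
    if (hi == lo) hi <- lo + bin_width_nm
    breaks <- seq(lo, hi, by = bin_width_nm)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE)
    out[[cd]] <- list(breaks = h$breaks, counts = h$counts,
                      quantiles = stats::quantile(d, c(0.25, 0.5, 0.75)),
                      n = length(d))
  }
  out
}
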