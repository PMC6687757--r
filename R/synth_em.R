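#' Generate per-stack EM morphometry records
#'
#' Draws per-stack measurements from zero-truncated normal
#' distributions (lengths and counts cannot be negative) around
#' configured per-condition means and SDs — the raw-measurement
#' fixture behind condition-level EM summary tables, which real
#' studies print only in aggregated form.
#'
#' @param conditions Data frame with one row per condition:
#'   `condition, n`, and `mean_` / `sd_` pairs for
#'   `max_cisterna_length_nm`, `cisternae_count`,
#'   `vesicles_within_1um` (SD 0 reproduces the mean exactly).
#' @param vesicle_diameter_mean_nm,vesicle_diameter_sd_nm Optional
#'   per-stack vesicle diameter model; each stack records
#'   `round(vesicles_within_1um)` diameters.
#' @param seed Integer seed.
#' @return Data frame of EM records: `condition, stack_id,
#'   max_cisterna_length_nm, cisternae_count, vesicles_within_1um`,
#'   plus a `vesicle_diameters_nm` list column.
#' @export
generate_em_table <- function(conditions = default_em_conditions(),
                              vesicle_diameter_mean_nm = 60,
                              vesicle_diameter_sd_nm = 8, seed = 1) {
  need <- c("condition", "n", "mean_max_cisterna_length_nm",
            "sd_max_cisterna_length_nm", "mean_cisternae_count",
            "sd_cisternae_count", "mean_vesicles_within_1um",
            "sd_vesicles_within_1um")
  miss <- setdiff(need, names(conditions))
  if (length(miss)) stop("conditions lack column(s): ",
                         paste(miss, collapse = ", "))
  if (any(conditions$n < 1)) stop("each condition needs n >= 1")
  sds <- unlist(conditions[grep("^sd_", names(conditions))])
  if (any(sds < 0)) stop("SDs must be >= 0")

  rtruncnorm0 <- function(n, mean, sd) {
    if (sd == 0) return(rep(mean, n))
    out <- stats::rnorm(n, mean, sd)
    while (any(out < 0)) {
      bad <- out < 0
      out[bad] <- stats::rnorm(sum(bad), mean, sd)
    }
    out
  }

  with_seed(seed, {
    rows <- lapply(seq_len(nrow(conditions)), function(i) {
      cd <- conditions[i, ]
      n <- cd$n
      ves <- rtruncnorm0(n, cd$mean_vesicles_within_1um,
                         cd$sd_vesicles_within_1um)
      df <- data.frame(
        condition = cd$condition,
        stack_id = sprintf("%s_s%03d", gsub("[^A-Za-z0-9]+", "_",
                                            cd$condition), seq_len(n)),
        max_cisterna_length_nm = rtruncnorm0(
          n, cd$mean_max_cisterna_length_nm, cd$sd_max_cisterna_length_nm),
        cisternae_count = pmax(rtruncnorm0(n, cd$mean_cisternae_count,
                                           cd$sd_cisternae_count), 1),
        vesicles_within_1um = ves,
        stringsAsFactors = FALSE
      )
      df$vesicle_diameters_nm <- lapply(round(ves), function(k) {
        if (k < 1) numeric(0) else
          rtruncnorm0(k, vesicle_diameter_mean_nm, vesicle_diameter_sd_nm)
      })
      df
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Default EM condition configuration
#'
#' One condition per row of the bundled reference EM morphometry
#' table (control, single tether and Rab/Kif knockdowns, and the
#' tether + suppressor double knockdowns), with stack counts and
#' means taken from that table and SDs back-computed from the
#' printed SEMs (SD = SEM * sqrt(n)).
#'
#' @return Condition data frame suitable for [generate_em_table()].
#' @export
default_em_conditions <- function() {
  ref <- reference_em_table()
  data.frame(
    condition = ref$condition, n = ref$n_stacks,
    mean_max_cisterna_length_nm = ref$mean_max_cisterna_length_nm,
    sd_max_cisterna_length_nm = ref$sem_max_cisterna_length_nm *
      sqrt(ref$n_stacks),
    mean_cisternae_count = ref$mean_cisternae_count,
    sd_cisternae_count = ref$sem_cisternae_count * sqrt(ref$n_stacks),
    mean_vesicles_within_1um = ref$mean_vesicles_within_1um,
    sd_vesicles_within_1um = ref$sem_vesicles_within_1um *
      sqrt(ref$n_stacks),
    stringsAsFactors = FALSE
  )
}
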