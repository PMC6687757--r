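#' Define an epistatic screen design with planted truth
#'
#' A design names the targets, how many siRNAs each gets (1 encodes a
#' SMARTPool or single validated siRNA), the tether backgrounds,
#' replicates, and the planted ground truth: each target's basal
#' class, its suppression class, and per-siRNA knockdown efficacies.
#' When efficacies are not supplied they are drawn once (seeded): for
#' multi-siRNA targets two siRNAs are effective (efficacy 0.8-0.95)
#' and the rest poor (0.05-0.4), emulating the real heterogeneity in
#' which some of four siRNAs fail to deplete; single/pooled siRNAs of
#' suppressive targets are effective.
#'
#' @param targets Data frame with columns `target`, `class`
#'   (`"rab"`/`"kif"`), `n_sirnas`, `basal_class`
#'   (`"fragments_alone"`/`"no_effect"`), `suppression_class`
#'   (`"both"`, `"ZW10_only"`, `"COG3_only"`, `"none"`), and
#'   optionally `flag` (`"none"`/`"toxic"`/`"stretched"`).
#' @param backgrounds Tether backgrounds screened (subset of
#'   `c("ZW10", "COG3")`, non-empty).
#' @param n_replicates Number of independent replicates.
#' @param efficacies Optional data frame `target, sirna_id, efficacy`
#'   overriding the seeded draw.
#' @param seed Seed for the efficacy draw.
#' @return A `screen_design` list.
#' @export
screen_design <- function(targets, backgrounds = c("ZW10", "COG3"),
                          n_replicates = 2, efficacies = NULL, seed = 1) {
  need <- c("target", "class", "n_sirnas", "basal_class",
            "suppression_class")
  if (!all(need %in% names(targets))) {
    stop("targets must have columns ", paste(need, collapse = ", "))
  }
  if (length(backgrounds) < 1 ||
      !all(backgrounds %in% c("ZW10", "COG3"))) {
    stop("invalid-design: backgrounds must be a non-empty subset of ",
         "{ZW10, COG3}")
  }
  if (any(targets$target == "scrambled")) {
    stop("invalid-design: 'scrambled' is reserved for the control")
  }
  if (anyDuplicated(targets$target)) stop("duplicate target names")
  stopifnot(all(targets$class %in% c("rab", "kif")),
            all(targets$n_sirnas >= 1),
            all(targets$basal_class %in% c("fragments_alone", "no_effect")),
            all(targets$suppression_class %in%
                  c("both", "ZW10_only", "COG3_only", "none")),
            n_replicates >= 1)
  if (is.null(targets$flag)) targets$flag <- "none"
  if (is.null(efficacies)) {
    efficacies <- with_seed(derive_seed(seed, "efficacy"), {
      rows <- lapply(seq_len(nrow(targets)), function(i) {
        n <- targets$n_sirnas[i]
        eff <- if (n >= 2) {
          n_hi <- min(2L, n)
          sample(c(stats::runif(n_hi, 0.8, 0.95),
                   stats::runif(n - n_hi, 0.05, 0.4)))
        } else if (targets$suppression_class[i] != "none" ||
                   targets$basal_class[i] == "fragments_alone") {
          stats::runif(1, 0.8, 0.95)
        } else {
          stats::runif(1, 0.3, 0.9)
        }
        data.frame(target = targets$target[i],
                   sirna_id = if (n == 1) "pool" else sprintf("si%02d",
                                                              seq_len(n)),
                   efficacy = eff, stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    })
  }
  if (any(efficacies$efficacy < 0 | efficacies$efficacy > 1)) {
    stop("efficacies must lie in [0, 1]")
  }
  structure(list(targets = targets, backgrounds = backgrounds,
                 n_replicates = as.integer(n_replicates),
                 efficacies = efficacies),
            class = "screen_design")
}

#' Default Rab screen design
#'
#' Mirrors the structure of the published Rab arm of the screen: 19
#' Golgi-associated Rab targets, eight of them covered by four
#' individual siRNAs, Rab4A by two, the rest by one validated siRNA,
#' two tether backgrounds and two replicates. Planted truth follows
#' the published outcome (dual suppressors, ZW10-only suppressors,
#' basal fragmenters).
#'
#' @param seed Seed for the efficacy draw.
#' @return A [screen_design()].
#' @export
default_rab_design <- function(seed = 1) {
  four <- c("Rab6", "Rab8A", "Rab11A", "Rab22A", "Rab27A", "Rab29",
            "Rab33B", "Rab39A")
  single <- c("Rab1A", "Rab1B", "Rab2A", "Rab6A", "Rab6A'", "Rab10",
              "Rab14", "Rab30", "Rab34", "Rab43")
  tg <- data.frame(
    target = c(four, "Rab4A", single),
    class = "rab",
    n_sirnas = c(rep(4L, length(four)), 2L, rep(1L, length(single))),
    stringsAsFactors = FALSE
  )
  both <- c("Rab6", "Rab22A", "Rab27A", "Rab39A", "Rab6A", "Rab6A'")
  zw10 <- c("Rab29", "Rab11A", "Rab33B")
  tg$suppression_class <- ifelse(tg$target %in% both, "both",
                          ifelse(tg$target %in% zw10, "ZW10_only", "none"))
  tg$basal_class <- ifelse(tg$target %in% c("Rab1A", "Rab2A"),
                           "fragments_alone", "no_effect")
  screen_design(tg, seed = seed)
}

#' Synthetic benchmark screen design
#'
#' A fully multi-siRNA design for recovery benchmarking: `n_targets`
#' targets with `sirnas_per_target` siRNAs each, a configurable
#' number of planted dual, ZW10-only and COG3-only suppressors and
#' basal fragmenters, the rest non-suppressive.
#'
#' @param n_targets Total targets.
#' @param n_both,n_zw10_only,n_cog3_only Planted suppressor counts.
#' @param n_basal How many of the non-suppressive targets fragment
#'   the Golgi on their own.
#' @param sirnas_per_target siRNAs per target.
#' @param n_replicates Replicates.
#' @param seed Seed for the efficacy draw.
#' @return A [screen_design()].
#' @export
synthetic_screen_design <- function(n_targets = 20, n_both = 4,
                                    n_zw10_only = 3, n_cog3_only = 1,
                                    n_basal = 2, sirnas_per_target = 4,
                                    n_replicates = 2, seed = 1) {
  n_sup <- n_both + n_zw10_only + n_cog3_only
  stopifnot(n_sup + n_basal <= n_targets)
  cls <- c(rep("both", n_both), rep("ZW10_only", n_zw10_only),
           rep("COG3_only", n_cog3_only),
           rep("none", n_targets - n_sup))
  basal <- c(rep("no_effect", n_sup),
             rep("fragments_alone", n_basal),
             rep("no_effect", n_targets - n_sup - n_basal))
  tg <- data.frame(
    target = sprintf("T%02d", seq_len(n_targets)),
    class = "rab", n_sirnas = as.integer(sirnas_per_target),
    basal_class = basal, suppression_class = cls,
    stringsAsFactors = FALSE
  )
  screen_design(tg, n_replicates = n_replicates, seed = seed)
}

#' Generate a synthetic screen measurement table
#'
#' Draws per-cell fragment counts for every (target, siRNA,
#' background, replicate) condition of a design, plus the scrambled
#' control and tether-alone conditions each replicate requires. The
#' effective phenotype of a double knockdown interpolates linearly
#' from the tether-knockdown level towards control in proportion to
#' the siRNA's efficacy:
#' \deqn{\mu = \mu_{KD} - e \cdot s \cdot (\mu_{KD} - \mu_{control})}
#' where `e` is the efficacy and `s` is 1 when the target's planted
#' suppression class covers the background, else 0. Basal
#' fragmenters' single knockdowns interpolate from control towards
#' the `basal_fragmenting` preset the same way. Toxic targets yield
#' no measurement rows.
#'
#' @param design A [screen_design()].
#' @param phenotypes Preset list (see [phenotype_presets()]); the
#'   `control` and `tether_kd` fragment means anchor the
#'   interpolation.
#' @param n_cells Cells measured per condition (>= 30 for
#'   screen-grade data points).
#' @param seed Integer seed; the generator is a pure function of
#'   (design, phenotypes, n_cells, seed).
#' @return A `synthetic_screen` list: `measurements` (`target,
#'   sirna_id, background, replicate, cell_id, fragments, area_px`),
#'   `truth` (per-target planted classes, flags, and per-background
#'   suppressive booleans), `design`.
#' @export
generate_screen <- function(design, phenotypes = phenotype_presets(),
                            n_cells = 30, seed = 1) {
  if (!inherits(design, "screen_design")) {
    stop("invalid-design: `design` must be a screen_design()")
  }
  if (n_cells < 1) stop("n_cells must be >= 1")
  ctrl_mu <- phenotypes$control$fragments_mean
  kd_mu <- phenotypes$tether_kd$fragments_mean
  basal_mu <- phenotypes$basal_fragmenting$fragments_mean
  disp <- phenotypes$control$fragments_dispersion
  frag_area <- pi * phenotypes$control$fragment_radius_px^2

  covers <- function(supp, bg) {
    supp == "both" || (supp == "ZW10_only" && bg == "ZW10") ||
      (supp == "COG3_only" && bg == "COG3")
  }
  draw <- function(mu, n) {
    k <- if (mu <= 1) rep(1L, n) else
      1L + stats::rnbinom(n, mu = mu - 1, size = disp)
    area <- as.integer(round(k * pmax(stats::rnorm(n, frag_area, 3), 4)))
    data.frame(cell_id = seq_len(n), fragments = k, area_px = area)
  }
  tg <- design$targets
  eff_of <- function(target, sirna) {
    e <- design$efficacies
    e$efficacy[e$target == target & e$sirna_id == sirna]
  }

  with_seed(seed, {
    rows <- list()
    add <- function(target, sirna, bg, rep_, mu) {
      d <- draw(mu, n_cells)
      rows[[length(rows) + 1L]] <<- data.frame(
        target = target, sirna_id = sirna, background = bg,
        replicate = rep_, d, stringsAsFactors = FALSE)
    }
    for (rep_ in seq_len(design$n_replicates)) {
      add("scrambled", "scrambled", "none", rep_, ctrl_mu)
      for (bg in design$backgrounds) {
        add("scrambled", "scrambled", bg, rep_, kd_mu)
      }
      for (i in seq_len(nrow(tg))) {
        if (tg$flag[i] == "toxic") next
        sirnas <- design$efficacies$sirna_id[
          design$efficacies$target == tg$target[i]]
        for (si in sirnas) {
          e <- eff_of(tg$target[i], si)
          mu_none <- if (tg$basal_class[i] == "fragments_alone") {
            ctrl_mu + e * (basal_mu - ctrl_mu)
          } else ctrl_mu
          add(tg$target[i], si, "none", rep_, mu_none)
          for (bg in design$backgrounds) {
            s <- as.numeric(covers(tg$suppression_class[i], bg))
            mu <- kd_mu - e * s * (kd_mu - ctrl_mu)
            add(tg$target[i], si, bg, rep_, mu)
          }
        }
      }
    }
    truth <- tg
    truth$suppressive_zw10 <- vapply(tg$suppression_class, covers,
                                     logical(1), bg = "ZW10")
    truth$suppressive_cog3 <- vapply(tg$suppression_class, covers,
                                     logical(1), bg = "COG3")
    structure(list(measurements = do.call(rbind, rows), truth = truth,
                   design = design),
              class = "synthetic_screen")
  })
}
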