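#' Score one siRNA's rescue of tether-induced fragmentation
#'
#' In the epistatic assay, depleting a tether (ZW10 or COG3) raises
#' the normalized per-cell fragment count from `f_control` to `f_kd`;
#' co-depleting a candidate brings it to `f_double`. The fractional
#' suppression
#' \deqn{S = (F_{KD} - F_{double}) / (F_{KD} - F_{control})}
#' is 0 for no rescue and 1 for complete rescue back to control.
#' Strength is `"strong"` for `S >= s_hi`, `"weak"` for
#' `s_lo <= S < s_hi`, else `"none"`.
#'
#' @param f_control,f_kd,f_double Normalized fragment counts for the
#'   control, tether-knockdown and double-knockdown conditions.
#' @param s_lo,s_hi Weak and strong thresholds on S.
#' @return A one-row data frame: `S`, `strength`.
#' @export
call_sirna_rescue <- function(f_control, f_kd, f_double,
                              s_lo = 0.3, s_hi = 0.7) {
  if (!is.finite(f_kd) || !is.finite(f_control) || f_kd <= f_control) {
    stop("no-fragmentation: F_KD <= F_control, condition unscorable")
  }
  if (s_lo >= s_hi) stop("s_lo must be below s_hi")
  S <- (f_kd - f_double) / (f_kd - f_control)
  strength <- if (S >= s_hi) "strong" else if (S >= s_lo) "weak" else "none"
  data.frame(S = S, strength = strength, stringsAsFactors = FALSE)
}

#' Call a target a suppressor from its per-siRNA rescue strengths
#'
#' A target is a suppressor when a strong rescue is achieved by at
#' least half of its siRNAs, or a weak-or-better rescue by at least
#' three-quarters of them (both counts rounded up). For the screen's
#' standard four siRNAs per target this is exactly: strong with 2 of
#' 4, or weak with 3 of 4. A pooled siRNA (n = 1) passes with a
#' weak-or-better call.
#'
#' @param strengths Character vector of `"none"/"weak"/"strong"`
#'   per-siRNA calls.
#' @param n_sirnas Number of siRNAs tested (defaults to
#'   `length(strengths)`).
#' @return Logical: suppressor or not.
#' @export
call_target <- function(strengths, n_sirnas = length(strengths)) {
  if (length(strengths) < 1) stop("at least one rescue call is required")
  if (!all(strengths %in% c("none", "weak", "strong"))) {
    stop("strengths must be in {none, weak, strong}")
  }
  n_strong <- sum(strengths == "strong")
  n_weak_plus <- sum(strengths %in% c("weak", "strong"))
  (n_strong >= ceiling(n_sirnas / 2)) ||
    (n_weak_plus >= ceiling(0.75 * n_sirnas))
}

#' Combine per-replicate suppressor calls
#'
#' The screen was run in two independent replicates; a hit must
#' suppress in every replicate (strict AND — a target suppressing in
#' only one of two replicates is not called). A majority rule is
#' available as an alternative.
#'
#' @param calls Logical vector of per-replicate suppressor calls.
#' @param rule `"all"` (default) or `"majority"`.
#' @return Logical.
#' @export
require_replication <- function(calls, rule = c("all", "majority")) {
  rule <- match.arg(rule)
  if (length(calls) < 1) stop("at least one replicate is required")
  if (rule == "all") all(calls) else mean(calls) > 0.5
}

#' Classify a target's basal (single-knockdown) Golgi phenotype
#'
#' With no tether co-depletion, a target whose knockdown raises the
#' control-normalized fragment count at least `fold_threshold`-fold
#' fragments the Golgi on its own. Toxic treatments and the
#' cytokinesis-defective "stretched strands" phenotype cannot be read
#' from the fragment count and are passed in as explicit flags.
#'
#' @param f_none Control-normalized fragment count of the single
#'   knockdown.
#' @param fold_threshold Fold increase calling a basal fragmenter.
#' @param flag `"none"`, `"toxic"` or `"stretched"`.
#' @return One of `"fragments_alone"`, `"no_effect"`, `"toxic"`,
#'   `"stretched"`.
#' @export
classify_basal <- function(f_none, fold_threshold = 2, flag = "none") {
  flag <- match.arg(flag, c("none", "toxic", "stretched"))
  if (flag != "none") return(flag)
  if (!is.finite(f_none)) stop("control-normalized value required")
  if (f_none >= fold_threshold) "fragments_alone" else "no_effect"
}

#' Partition scored targets into suppression categories
#'
#' Produces the four-way summary of an epistatic screen: suppressors
#' of both tether knockdowns, of ZW10 only, of COG3 only, and
#' non-suppressive targets, per target class (Rab or Kif). Targets
#' with an NA call in any background (not scored, e.g. toxic) are
#' excluded and reported.
#'
#' @param calls Data frame with columns `target`, `class`,
#'   `suppress_zw10`, `suppress_cog3` (logical, NA = not scored).
#' @return A `screen_summary` list: `categories` (per-target data
#'   frame with a `category` column), `counts` (class x category
#'   counts), `membership` (named list of member vectors),
#'   `excluded` (unscored targets).
#' @export
partition_targets <- function(calls) {
  need <- c("target", "class", "suppress_zw10", "suppress_cog3")
  if (!all(need %in% names(calls))) {
    stop("calls must have columns target, class, suppress_zw10, suppress_cog3")
  }
  scored <- !is.na(calls$suppress_zw10) & !is.na(calls$suppress_cog3)
  cat_of <- function(z, c_) {
    if (z && c_) "both" else if (z) "ZW10_only" else if (c_) "COG3_only"
    else "non_suppressive"
  }
  levels_ <- c("both", "ZW10_only", "COG3_only", "non_suppressive")
  categories <- calls[scored, , drop = FALSE]
  categories$category <- factor(
    mapply(cat_of, categories$suppress_zw10, categories$suppress_cog3),
    levels = levels_
  )
  counts <- as.data.frame(table(class = categories$class,
                                category = categories$category),
                          responseName = "n")
  membership <- split(categories$target,
                      interaction(categories$class, categories$category,
                                  sep = ":"))
  stopifnot(sum(counts$n) == nrow(categories))
  structure(list(categories = categories, counts = counts,
                 membership = membership,
                 excluded = calls$target[!scored]),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Epistatic screen summary:", nrow(x$categories), "scored targets\n")
  tab <- stats::xtabs(n ~ class + category, data = x$counts)
  print(tab)
  if (length(x$excluded)) {
    cat("not scored:", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Score a full screen measurement table
#'
#' Runs the complete hit-calling chain on a per-cell screen table
#' (from [generate_screen()] or assembled from image quantification):
#' per-replicate condition means normalized to the scrambled control,
#' per-siRNA fractional suppression and strength in each tether
#' background, the per-target majority rule, strict replication, the
#' basal classification of each single knockdown, and the final
#' category partition.
#'
#' Conditions where the tether knockdown failed to fragment
#' (`F_KD <= F_control`) are reported in `unscorable` and yield NA
#' calls rather than being silently dropped.
#'
#' @param measurements Data frame with columns `target, sirna_id,
#'   background, replicate, cell_id, fragments` (a
#'   `synthetic_screen$measurements` table works directly). The
#'   scrambled control rows (`target == "scrambled"`) with
#'   `background` `"none"`, and one per tether background, must be
#'   present.
#' @param classes Optional data frame `target, class`; targets
#'   default to class `"rab"`.
#' @param flags Optional data frame `target, flag` with `"toxic"` /
#'   `"stretched"` flags; flagged targets get NA suppression calls.
#' @param s_lo,s_hi Rescue strength thresholds (see
#'   [call_sirna_rescue()]).
#' @param fold_threshold Basal fragmentation threshold (see
#'   [classify_basal()]).
#' @param replication Replication rule (see [require_replication()]).
#' @return List: `sirna_calls`, `target_calls`, `basal`, `summary`
#'   (a `screen_summary`), `unscorable`.
#' @export
score_screen <- function(measurements, classes = NULL, flags = NULL,
                         s_lo = 0.3, s_hi = 0.7, fold_threshold = 2,
                         replication = "all") {
  if (inherits(measurements, "synthetic_screen")) {
    if (is.null(classes)) classes <- measurements$truth[c("target", "class")]
    if (is.null(flags)) flags <- measurements$truth[c("target", "flag")]
    measurements <- measurements$measurements
  }
  need <- c("target", "sirna_id", "background", "replicate", "fragments")
  if (!all(need %in% names(measurements))) {
    stop("measurements lack required columns: ",
         paste(setdiff(need, names(measurements)), collapse = ", "))
  }
  m <- measurements
  backgrounds <- setdiff(unique(m$background), "none")
  if (!any(m$target == "scrambled" & m$background == "none")) {
    stop("invalid-design: scrambled control condition is missing")
  }
  for (b in backgrounds) {
    if (!any(m$target == "scrambled" & m$background == b)) {
      stop("invalid-design: tether-alone condition missing for ", b)
    }
  }
  reps <- sort(unique(m$replicate))
  cond_mean <- function(tg, si, bg, rp) {
    sel <- m$target == tg & m$background == bg & m$replicate == rp
    if (!is.null(si)) sel <- sel & m$sirna_id == si
    v <- m$fragments[sel]
    if (length(v) == 0) NA_real_ else mean(v)
  }
  ctrl <- vapply(reps, function(rp)
    mean(m$fragments[m$target == "scrambled" & m$background == "none" &
                       m$replicate == rp]), numeric(1))
  targets <- setdiff(unique(m$target), "scrambled")
  if (!is.null(classes)) {
    # targets with no measurement rows (e.g. toxic treatments) still
    # appear in the report, with NA calls
    targets <- union(targets, classes$target)
  }
  flag_of <- function(tg) {
    if (is.null(flags)) return("none")
    f <- flags$flag[match(tg, flags$target)]
    if (is.na(f) || !nzchar(f)) "none" else f
  }
  class_of <- function(tg) {
    if (is.null(classes)) return("rab")
    cl <- classes$class[match(tg, classes$target)]
    if (is.na(cl)) "rab" else cl
  }

  sirna_calls <- list(); unscorable <- list()
  for (rp_i in seq_along(reps)) {
    rp <- reps[rp_i]
    for (bg in backgrounds) {
      f_kd <- cond_mean("scrambled", NULL, bg, rp) / ctrl[rp_i]
      for (tg in targets) {
        if (flag_of(tg) != "none") next
        sis <- unique(m$sirna_id[m$target == tg & m$background == bg &
                                   m$replicate == rp])
        for (si in sis) {
          f_double <- cond_mean(tg, si, bg, rp) / ctrl[rp_i]
          row <- data.frame(target = tg, sirna_id = si, background = bg,
                            replicate = rp, f_kd = f_kd,
                            f_double = f_double, stringsAsFactors = FALSE)
          if (f_kd <= 1) {
            unscorable[[length(unscorable) + 1L]] <- row
          } else {
            call <- call_sirna_rescue(1, f_kd, f_double, s_lo, s_hi)
            row$S <- call$S; row$strength <- call$strength
            sirna_calls[[length(sirna_calls) + 1L]] <- row
          }
        }
      }
    }
  }
  sirna_calls <- do.call(rbind, sirna_calls)
  unscorable <- if (length(unscorable)) do.call(rbind, unscorable) else NULL

  target_calls <- data.frame(target = targets,
                             class = vapply(targets, class_of, character(1)),
                             suppress_zw10 = NA, suppress_cog3 = NA,
                             stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    tg <- targets[i]
    if (flag_of(tg) != "none") next
    for (bg in backgrounds) {
      per_rep <- vapply(reps, function(rp) {
        s <- sirna_calls$strength[sirna_calls$target == tg &
                                    sirna_calls$background == bg &
                                    sirna_calls$replicate == rp]
        if (length(s) == 0) return(NA)
        call_target(s)
      }, logical(1))
      if (any(is.na(per_rep))) next
      col <- if (bg == "ZW10") "suppress_zw10" else "suppress_cog3"
      target_calls[i, col] <- require_replication(per_rep, replication)
    }
  }

  basal <- data.frame(target = targets,
                      class = vapply(targets, class_of, character(1)),
                      f_none = NA_real_, basal_class = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(targets)) {
    tg <- targets[i]
    fl <- flag_of(tg)
    f_none <- mean(vapply(seq_along(reps), function(rp_i) {
      cond_mean(tg, NULL, "none", reps[rp_i]) / ctrl[rp_i]
    }, numeric(1)), na.rm = TRUE)
    basal$f_none[i] <- f_none
    basal$basal_class[i] <- if (fl != "none") {
      classify_basal(NA, fold_threshold, flag = fl)
    } else if (is.finite(f_none)) {
      classify_basal(f_none, fold_threshold)
    } else NA_character_
  }

  list(sirna_calls = sirna_calls, target_calls = target_calls,
       basal = basal, summary = partition_targets(target_calls),
       unscorable = unscorable)
}
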