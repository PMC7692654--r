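# Sequential gastric -> intestinal in vitro digestion analysis:
# phase-relative retention, dilution bookkeeping at the phase switch,
# and the anthocyanin-loss vs antioxidant-loss correlation.

#' A two-assay digestion time course for one phase
#'
#' Holds the total monomeric anthocyanin (TAC) and DPPH antioxidant
#' readings of one digestion phase, sampled on a common grid (30-min
#' intervals over 2 h in the standard protocol).
#'
#' @param pretreatment Label for the heat pretreatment (e.g.
#'   `"untreated"`, `"80C_40min"`, `"180C_7min"`).
#' @param phase `"gastric"` or `"intestinal"`.
#' @param times Sampling times in minutes, starting at 0, increasing.
#' @param tac_values TAC readings (mg C3G equivalents), non-negative.
#' @param dpph_values Antioxidant activity readings (Trolox
#'   equivalents), non-negative, same grid.
#' @param dilution_applied Whether the intestinal-phase dilution factor
#'   has already been applied to these values.
#' @return An object of class `digestion_course`.
#' @export
digestion_course <- function(pretreatment, phase, times, tac_values,
                             dpph_values, dilution_applied = FALSE) {
  phase <- match.arg(phase, c("gastric", "intestinal"))
  if (length(times) != length(tac_values) ||
      length(times) != length(dpph_values)) {
    stop("validation error: times and assay values must share one grid",
         call. = FALSE)
  }
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("validation error: times must start at 0 and increase",
         call. = FALSE)
  }
  if (any(tac_values < 0) || any(dpph_values < 0)) {
    stop("validation error: assay values must be non-negative",
         call. = FALSE)
  }
  structure(list(pretreatment = pretreatment, phase = phase,
                 times = times, tac_values = tac_values,
                 dpph_values = dpph_values,
                 dilution_applied = dilution_applied),
            class = "digestion_course")
}

#' Phase-relative retention and decrease
#'
#' Rebases each assay to its own value at the start of the phase:
#' retention at time t is `100 * value(t) / value(0)` and the decrease
#' is its complement. Rebasing per phase matches how sequential
#' digestion results are conventionally reported (each phase relative
#' to the material entering it).
#'
#' @param course A [digestion_course()].
#' @return Data frame with columns `time_min`, `assay` (`"tac"` or
#'   `"dpph"`), `retention_pct`, `decrease_pct`.
#' @export
phase_retention <- function(course) {
  stopifnot(inherits(course, "digestion_course"))
  one <- function(vals, label) {
    if (vals[1] <= 0) {
      stop("undefined retention: phase-initial ", label, " value is zero",
           call. = FALSE)
    }
    data.frame(time_min = course$times, assay = label,
               retention_pct = 100 * vals / vals[1],
               decrease_pct = 100 - 100 * vals / vals[1])
  }
  out <- rbind(one(course$tac_values, "tac"),
               one(course$dpph_values, "dpph"))
  rownames(out) <- NULL
  out
}

#' Dilution at the gastric -> intestinal transition
#'
#' When an aliquot of gastric digesta is mixed into simulated
#' intestinal juice, concentrations scale by
#' `digesta_volume / (digesta_volume + added_juice_volume)` (default
#' 5 mL into 10 mL, factor 1/3). The inverse,
#' [correct_intestinal_dilution()], restores the gastric-end scale so
#' raw and dilution-corrected series can both be reported.
#'
#' @param value Concentration(s) at the end of the gastric phase.
#' @param digesta_volume Volume of digesta carried forward, mL.
#' @param added_juice_volume Volume of intestinal juice added, mL.
#' @return The intestinal-phase initial concentration(s).
#' @export
apply_intestinal_dilution <- function(value, digesta_volume = 5,
                                      added_juice_volume = 10) {
  if (digesta_volume <= 0 || added_juice_volume <= 0) {
    stop("parameter error: volumes must be > 0", call. = FALSE)
  }
  value * digesta_volume / (digesta_volume + added_juice_volume)
}

#' @rdname apply_intestinal_dilution
#' @export
correct_intestinal_dilution <- function(value, digesta_volume = 5,
                                        added_juice_volume = 10) {
  if (digesta_volume <= 0 || added_juice_volume <= 0) {
    stop("parameter error: volumes must be > 0", call. = FALSE)
  }
  value * (digesta_volume + added_juice_volume) / digesta_volume
}

#' Correlation between anthocyanin loss and antioxidant-activity loss
#'
#' Pools the phase-relative percent-loss pairs (TAC loss, DPPH loss)
#' across all supplied courses and time points after 0, and reports the
#' Pearson correlation with its p-value.
#'
#' @param courses A [digestion_course()] or list of them.
#' @return List with `r`, `p_value`, `n` (number of paired points), and
#'   the pooled `pairs` data frame.
#' @export
loss_correlation <- function(courses) {
  if (inherits(courses, "digestion_course")) courses <- list(courses)
  stopifnot(all(vapply(courses, inherits, logical(1), "digestion_course")))
  pairs <- do.call(rbind, lapply(courses, function(cc) {
    ret <- phase_retention(cc)
    tac <- ret[ret$assay == "tac" & ret$time_min > 0, ]
    dpph <- ret[ret$assay == "dpph" & ret$time_min > 0, ]
    data.frame(pretreatment = cc$pretreatment, phase = cc$phase,
               time_min = tac$time_min,
               tac_loss_pct = tac$decrease_pct,
               dpph_loss_pct = dpph$decrease_pct)
  }))
  if (nrow(pairs) < 3L) {
    stop("insufficient data: need at least 3 paired loss points",
         call. = FALSE)
  }
  if (stats::sd(pairs$tac_loss_pct) == 0 ||
      stats::sd(pairs$dpph_loss_pct) == 0) {
    stop("undefined correlation: zero variance in a loss series",
         call. = FALSE)
  }
  ct <- stats::cor.test(pairs$tac_loss_pct, pairs$dpph_loss_pct,
                        method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs),
       pairs = pairs)
}
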