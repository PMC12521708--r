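#' Opioid rotation with incomplete cross-tolerance
#'
#' Switching opioids at the full equianalgesic dose risks overdose because
#' tolerance transfers incompletely between agents. The rotation module
#' therefore starts the new opioid at a configurable fraction of the
#' equianalgesic dose; the shipped schemes are 30%, 50% and 100%, and a plan
#' can be switched between schemes mid-course according to the patient's
#' response.
#'
#' @name rotation
NULL

#' A cross-tolerance reduction scheme
#'
#' @param cross_tolerance_fraction Fraction of the equianalgesic dose used
#'   as the starting dose of the new opioid, in (0, 1]. Presets: 0.30, 0.50,
#'   1.00.
#' @param label Display label; defaults to the percentage.
#' @return A `rotation_scheme` object.
#' @export
rotation_scheme <- function(cross_tolerance_fraction, label = NULL) {
  check_number(cross_tolerance_fraction, "cross_tolerance_fraction",
               min = 0, max = 1, strict_min = TRUE)
  if (is.null(label)) {
    label <- sprintf("%g%%", 100 * cross_tolerance_fraction)
  }
  structure(
    list(cross_tolerance_fraction = as.numeric(cross_tolerance_fraction),
         label = as.character(label)),
    class = "rotation_scheme"
  )
}

#' The three shipped rotation schemes
#'
#' @return Named list of [rotation_scheme] objects at 30%, 50% and 100% of
#'   the equianalgesic dose.
#' @export
rotation_presets <- function() {
  list(
    scheme30 = rotation_scheme(0.30),
    scheme50 = rotation_scheme(0.50),
    scheme100 = rotation_scheme(1.00)
  )
}

#' Starting dose of a new opioid under a rotation scheme
#'
#' Converts the current dose to OME, then to the equianalgesic dose of the
#' target drug, then multiplies by the scheme's cross-tolerance fraction.
#' Exact arithmetic; rounding to tablet strengths happens only in the
#' formulation mapper.
#'
#' @param from_drug,to_drug Drug names present in the formulary.
#' @param from_dose_mg Positive current dose, mg of `from_drug` per 24 h.
#' @param scheme A [rotation_scheme].
#' @param formulary A [formulary].
#' @return Positive numeric: mg of `to_drug` per 24 h.
#' @examples
#' f <- default_formulary()
#' rotate_dose("morphine", 60, "oxycodone", rotation_scheme(0.5), f)
#' @export
rotate_dose <- function(from_drug, from_dose_mg, to_drug, scheme, formulary) {
  if (!inherits(scheme, "rotation_scheme")) {
    stop_validation("'scheme' must be a rotation_scheme")
  }
  check_number(from_dose_mg, "from_dose_mg", min = 0, strict_min = TRUE)
  equi <- from_ome(to_drug, to_ome(from_drug, from_dose_mg, formulary),
                   formulary)
  equi * scheme$cross_tolerance_fraction
}

#' Taper plans for all three rotation schemes
#'
#' For each preset cross-tolerance fraction, rotates the current dose to the
#' target drug and generates a full linear taper (via [generate_taper()])
#' whose baseline is the rotated dose expressed in OME. The three plans are
#' labelled by scheme so the clinician can pick — or later switch — the one
#' matching the patient's response.
#'
#' @inheritParams rotate_dose
#' @param policy A [taper_policy] applied to each rotated baseline.
#' @param schemes List of [rotation_scheme]s (default the three presets).
#' @return Named list of `taper_plan` objects; each carries
#'   `rotation = list(to_drug, dose_mg, scheme)`.
#' @export
build_rotation_plans <- function(from_drug, from_dose_mg, to_drug, policy,
                                 formulary, schemes = rotation_presets()) {
  plans <- lapply(schemes, function(sc) {
    dose_mg <- rotate_dose(from_drug, from_dose_mg, to_drug, sc, formulary)
    baseline_ome <- to_ome(to_drug, dose_mg, formulary)
    plan <- generate_taper(baseline_ome, policy)
    plan$rotation <- list(to_drug = tolower(to_drug), dose_mg = dose_mg,
                          scheme = sc)
    plan
  })
  names(plans) <- vapply(schemes, `[[`, character(1L), "label")
  plans
}

#' Switch rotation scheme mid-course
#'
#' Re-anchors the remainder of a plan at the dose in effect on `at_day`:
#' steps up to and including `at_day` are kept, and a fresh linear taper
#' from that dose (under `policy`, with its target) is appended starting the
#' next day. The joined trajectory is continuous at the switch day.
#'
#' @param plan A `taper_plan` in progress.
#' @param at_day Day on which the switch happens (within the plan span,
#'   before the target is reached).
#' @param policy [taper_policy] governing the re-anchored remainder.
#' @return A new `taper_plan` (`plan_id` `"custom"`).
#' @export
reanchor_plan <- function(plan, at_day, policy) {
  if (!inherits(plan, "taper_plan")) {
    stop_validation("'plan' must be a taper_plan")
  }
  at_day <- check_count(at_day, "at_day", min = 0L)
  s <- plan$steps
  if (at_day > max(s$day)) {
    stop_validation(sprintf("at_day (%d) is outside the plan span", at_day))
  }
  current <- s$fixed_ome[s$day == at_day]
  if (current <= policy$target_ome) {
    stop_validation("plan already at or below the new target on at_day")
  }
  tail_plan <- generate_taper(current, policy)
  kept <- s[s$day <= at_day, , drop = FALSE]
  shifted <- tail_plan$steps[-1L, , drop = FALSE]
  shifted$day <- shifted$day + at_day
  steps <- rbind(kept, shifted)
  rownames(steps) <- NULL
  out <- new_taper_plan(steps, plan$baseline_ome, policy, "custom")
  out$reanchored_at <- at_day
  out
}
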