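#' Linear opioid taper schedules
#'
#' The taper engine turns a 24-hour opioid baseline (in mg OME) into a
#' day-indexed, strictly linear reduction schedule: every reduction removes a
#' fixed amount `reduction_fraction * baseline` (a fraction of the
#' post-stabilization baseline, never of the current dose), so a 25% acute
#' taper from any baseline reaches zero in exactly 4 steps and a 10% chronic
#' taper in exactly 10. Day 0 is baseline establishment; the first reduction
#' falls on day 1 by default.
#'
#' @name taper_engine
NULL

#' Describe one consumed opioid dose
#'
#' @param drug Drug name (must exist in the formulary used downstream).
#' @param dose_mg Total mg of the drug consumed over the 24 h window.
#' @param kind `"fixed"` (scheduled) or `"backup"` (as-needed rescue dose).
#' @return A `consumption_entry` object.
#' @export
consumption_entry <- function(drug, dose_mg, kind = c("fixed", "backup")) {
  kind <- match.arg(kind)
  if (!is.character(drug) || length(drug) != 1L || !nzchar(drug)) {
    stop_validation("'drug' must be a non-empty string")
  }
  check_number(dose_mg, "dose_mg", min = 0)
  structure(list(drug = tolower(drug), dose_mg = as.numeric(dose_mg),
                 kind = kind),
            class = "consumption_entry")
}

#' Assemble a patient case record
#'
#' Captures everything the calculator needs: opioid status (naive patients
#' taper to cessation, chronic users to their prehospital dose), pain type
#' (selects the acute or chronic preset), the last-24-hour consumption used
#' to set the starting dose, and the planned discharge day (which triggers a
#' grace period).
#'
#' @param opioid_status `"naive"` or `"chronic_user"`.
#' @param pain_type `"acute"` or `"chronic"`.
#' @param last24h List of [consumption_entry] objects.
#' @param prehospital_ome Baseline OME before hospitalization (mg/24 h); must
#'   be 0 for naive patients.
#' @param discharge_day Optional non-negative day index of hospital
#'   discharge (`NULL` if unknown).
#' @param pain_stable_hours Hours of stable pain so far (used by
#'   [is_stabilized()]).
#' @param cognitive_impairment Logical; selects a single-strength regimen in
#'   the formulation mapper.
#' @return A `patient_case` object.
#' @export
patient_case <- function(opioid_status = c("naive", "chronic_user"),
                         pain_type = c("acute", "chronic"),
                         last24h = list(),
                         prehospital_ome = 0,
                         discharge_day = NULL,
                         pain_stable_hours = 0,
                         cognitive_impairment = FALSE) {
  opioid_status <- match.arg(opioid_status)
  pain_type <- match.arg(pain_type)
  check_number(prehospital_ome, "prehospital_ome", min = 0)
  if (opioid_status == "naive" && prehospital_ome != 0) {
    stop_validation("naive patients must have prehospital_ome = 0")
  }
  if (!is.null(discharge_day)) {
    discharge_day <- check_count(discharge_day, "discharge_day", min = 0L)
  }
  check_number(pain_stable_hours, "pain_stable_hours", min = 0)
  check_flag(cognitive_impairment, "cognitive_impairment")
  if (!is.list(last24h) ||
      !all(vapply(last24h, inherits, logical(1L), "consumption_entry"))) {
    stop_validation("'last24h' must be a list of consumption_entry objects")
  }
  structure(
    list(
      opioid_status = opioid_status, pain_type = pain_type,
      last24h = last24h, prehospital_ome = as.numeric(prehospital_ome),
      discharge_day = discharge_day,
      pain_stable_hours = as.numeric(pain_stable_hours),
      cognitive_impairment = cognitive_impairment
    ),
    class = "patient_case"
  )
}

#' Read a patient case from JSON
#'
#' Schema: `{"opioid_status", "pain_type", "prehospital_ome",
#' "last24h": [{"drug", "dose_mg", "kind"}], "discharge_day",
#' "pain_stable_hours", "cognitive_impairment"}`.
#'
#' @param path Path to a patient-case JSON file.
#' @return A [patient_case] object.
#' @export
load_patient_case <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_validation(sprintf("patient case file not found: '%s'", path))
  }
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE),
    error = function(e) stop_validation(sprintf(
      "cannot parse patient case '%s': %s", path, conditionMessage(e)
    ))
  )
  entries <- lapply(raw$last24h %||% list(), function(e) {
    consumption_entry(e$drug, e$dose_mg, e$kind %||% "fixed")
  })
  patient_case(
    opioid_status = raw$opioid_status %||% "naive",
    pain_type = raw$pain_type %||% "acute",
    last24h = entries,
    prehospital_ome = raw$prehospital_ome %||% 0,
    discharge_day = raw$discharge_day,
    pain_stable_hours = raw$pain_stable_hours %||% 0,
    cognitive_impairment = isTRUE(raw$cognitive_impairment)
  )
}

#' Taper policy: the knobs of a linear reduction schedule
#'
#' @param reduction_fraction Fraction of the baseline removed per reduction
#'   step, in (0, 1]. The shipped presets use 0.25 (acute pain) and 0.10
#'   (chronic pain); the consensus range for individualized rates is
#'   0.05–0.25.
#' @param step_interval_days Days between successive reductions (2 for the
#'   acute preset, 3 for the chronic preset).
#' @param grace_days Extra hold days applied around discharge (0 = none,
#'   2 when a discharge day is known).
#' @param first_reduction_day Day index of the first reduction (default 1;
#'   day 0 is baseline establishment).
#' @param target_ome Dose at which the taper ends (0 for cessation, the
#'   prehospital dose for chronic users), mg OME/24 h.
#' @param backup_fraction Back-up (rescue) allowance as a fraction of the
#'   initial dose; must lie in \[1/10, 1/6\]. Default 1/8.
#' @return A `taper_policy` object.
#' @export
taper_policy <- function(reduction_fraction, step_interval_days,
                         grace_days = 0L, first_reduction_day = 1L,
                         target_ome = 0, backup_fraction = 1 / 8) {
  check_number(reduction_fraction, "reduction_fraction",
               min = 0, max = 1, strict_min = TRUE)
  step_interval_days <- check_count(step_interval_days, "step_interval_days",
                                    min = 1L)
  grace_days <- check_count(grace_days, "grace_days", min = 0L)
  first_reduction_day <- check_count(first_reduction_day,
                                     "first_reduction_day", min = 1L)
  check_number(target_ome, "target_ome", min = 0)
  check_number(backup_fraction, "backup_fraction", min = 1 / 10, max = 1 / 6)
  structure(
    list(
      reduction_fraction = as.numeric(reduction_fraction),
      step_interval_days = step_interval_days,
      grace_days = grace_days,
      first_reduction_day = first_reduction_day,
      target_ome = as.numeric(target_ome),
      backup_fraction = as.numeric(backup_fraction)
    ),
    class = "taper_policy"
  )
}

#' @export
print.taper_policy <- function(x, ...) {
  cat(sprintf(
    "<taper_policy> -%d%% of baseline every %d day(s), first on day %d; target %g OME; grace %d d; backup %.3f x baseline\n",
    round(100 * x$reduction_fraction), x$step_interval_days,
    x$first_reduction_day, x$target_ome, x$grace_days, x$backup_fraction
  ))
  invisible(x)
}

#' Starting dose from last-24-hour consumption
#'
#' The taper baseline is the patient's total opioid intake over the last
#' 24 h — scheduled (fixed) and back-up doses alike — converted to mg OME.
#'
#' @param case A [patient_case].
#' @param formulary A [formulary].
#' @return Positive numeric, mg OME per 24 h.
#' @export
baseline_from_24h <- function(case, formulary) {
  if (!inherits(case, "patient_case")) {
    stop_validation("'case' must be a patient_case")
  }
  if (!length(case$last24h)) {
    stop_validation("no last-24h consumption entries: baseline not derivable")
  }
  sum(vapply(case$last24h, function(e) to_ome(e$drug, e$dose_mg, formulary),
             numeric(1L)))
}

#' Is the patient stable enough to start reducing?
#'
#' Reduction starts once the patient is stable on the regimen: stable pain
#' for at least `window_hours` and only minimal back-up use (at most
#' `max_backup_count` rescue doses totalling at most `backup_ome_limit`
#' of the fixed dose over 24 h).
#'
#' @param case A [patient_case] (supplies `pain_stable_hours`).
#' @param backup_count_24h Number of back-up doses taken in the last 24 h.
#' @param backup_ome_24h Total back-up consumption, mg OME/24 h.
#' @param fixed_ome_24h Fixed (scheduled) consumption, mg OME/24 h; > 0.
#' @param window_hours Required hours of stable pain (default 48; the
#'   consensus window is 24–48 h, so values below 24 are rejected).
#' @param backup_ome_limit Maximal back-up consumption as a fraction of the
#'   fixed dose (default 0.10).
#' @param max_backup_count Maximal number of back-up doses (default 2).
#' @return Logical scalar.
#' @export
is_stabilized <- function(case, backup_count_24h, backup_ome_24h,
                          fixed_ome_24h, window_hours = 48,
                          backup_ome_limit = 0.10, max_backup_count = 2L) {
  if (!inherits(case, "patient_case")) {
    stop_validation("'case' must be a patient_case")
  }
  backup_count_24h <- check_count(backup_count_24h, "backup_count_24h", 0L)
  check_number(backup_ome_24h, "backup_ome_24h", min = 0)
  check_number(fixed_ome_24h, "fixed_ome_24h", min = 0, strict_min = TRUE)
  check_number(window_hours, "window_hours", min = 24)
  case$pain_stable_hours >= window_hours &&
    backup_ome_24h <= backup_ome_limit * fixed_ome_24h &&
    backup_count_24h <= max_backup_count
}

#' Choose the taper policy for a patient
#'
#' Acute pain selects the rapid preset (25% of baseline every other day);
#' chronic pain the gradual preset (10% every third day). The target is the
#' prehospital dose (0 for opioid-naive patients, i.e. complete cessation).
#' A two-day grace period is armed whenever a discharge day is known.
#'
#' @param case A [patient_case].
#' @param baseline_ome Positive post-stabilization baseline, mg OME/24 h.
#' @return A [taper_policy].
#' @export
select_policy <- function(case, baseline_ome) {
  if (!inherits(case, "patient_case")) {
    stop_validation("'case' must be a patient_case")
  }
  check_number(baseline_ome, "baseline_ome", min = 0, strict_min = TRUE)
  acute <- case$pain_type == "acute"
  taper_policy(
    reduction_fraction = if (acute) 0.25 else 0.10,
    step_interval_days = if (acute) 2L else 3L,
    grace_days = if (!is.null(case$discharge_day)) 2L else 0L,
    first_reduction_day = 1L,
    target_ome = case$prehospital_ome,
    backup_fraction = 1 / 8
  )
}

#' Back-up (rescue) dose for a taper
#'
#' Held at a fraction of the initial (baseline) dose throughout the
#' reduction; the consensus bracket is 1/10 to 1/6, and fractions outside it
#' are rejected rather than clamped.
#'
#' @param baseline_ome Positive baseline, mg OME/24 h.
#' @param fraction Fraction of the baseline, within \[1/10, 1/6\].
#' @return Numeric, mg OME/24 h.
#' @examples
#' backup_dose(50, 1 / 10) # 5
#' @export
backup_dose <- function(baseline_ome, fraction) {
  check_number(baseline_ome, "baseline_ome", min = 0, strict_min = TRUE)
  check_number(fraction, "fraction", min = 1 / 10, max = 1 / 6)
  fraction * baseline_ome
}

# Dense day-indexed plan from the days on which reductions happen.
# reduction_days must be strictly increasing; doses the levels after each.
build_plan_steps <- function(baseline, reduction_days, doses, backup_ome,
                             target) {
  last_day <- if (length(reduction_days)) max(reduction_days) else 0L
  days <- 0:last_day
  fixed <- numeric(length(days))
  level <- baseline
  for (i in seq_along(days)) {
    hit <- match(days[i], reduction_days)
    if (!is.na(hit)) level <- doses[hit]
    fixed[i] <- level
  }
  data.frame(
    day = days,
    fixed_ome = fixed,
    backup_ome = ifelse(fixed > target, backup_ome, 0)
  )
}

new_taper_plan <- function(steps, baseline_ome, policy, plan_id) {
  structure(
    list(steps = steps, baseline_ome = baseline_ome, policy = policy,
         plan_id = plan_id),
    class = "taper_plan"
  )
}

#' Generate a linear taper plan
#'
#' The step size is `reduction_fraction * baseline_ome`, constant across the
#' whole schedule (linear reduction — a fixed slice of the baseline, not of
#' the current dose). Reductions land on `first_reduction_day` and then
#' every `step_interval_days`; the final step is clamped so the plan ends
#' exactly on the target, never below it. The back-up allowance
#' (`backup_fraction * baseline`) is carried on every day until the fixed
#' dose reaches the target, then dropped.
#'
#' @param baseline_ome Positive baseline, mg OME/24 h; must exceed the
#'   policy target.
#' @param policy A [taper_policy].
#' @param plan_id Label for the plan (`"plan1"`..`"plan4"` or `"custom"`).
#' @return A `taper_plan`: day-indexed steps (`day`, `fixed_ome`,
#'   `backup_ome`, one row per day from day 0 to completion), the baseline,
#'   and the policy.
#' @examples
#' # rapid preset from 50 mg OME: 50, 37.5, 25, 12.5, 0 on days 0,1,3,5,7
#' plan <- generate_taper(50, taper_policy(0.25, 2))
#' plan
#' @export
generate_taper <- function(baseline_ome, policy, plan_id = "custom") {
  if (!inherits(policy, "taper_policy")) {
    stop_validation("'policy' must be a taper_policy")
  }
  check_number(baseline_ome, "baseline_ome", min = 0, strict_min = TRUE)
  check_choice(plan_id, "plan_id",
               c("plan1", "plan2", "plan3", "plan4", "custom"))
  target <- policy$target_ome
  if (baseline_ome <= target) {
    stop_validation(sprintf(
      "nothing to reduce: baseline (%g) must exceed target (%g)",
      baseline_ome, target
    ))
  }
  delta <- policy$reduction_fraction * baseline_ome
  n_red <- ceiling((baseline_ome - target) / delta)
  red_days <- policy$first_reduction_day +
    policy$step_interval_days * (seq_len(n_red) - 1L)
  doses <- pmax(baseline_ome - seq_len(n_red) * delta, target)
  backup <- policy$backup_fraction * baseline_ome
  steps <- build_plan_steps(baseline_ome, red_days, doses, backup, target)
  new_taper_plan(steps, baseline_ome, policy, plan_id)
}

#' Delay post-discharge reductions by a grace period
#'
#' Every reduction scheduled strictly after the discharge day is pushed back
#' by `grace_days`: the dose in effect at discharge is held that much
#' longer, and the rest of the schedule shifts accordingly. The set of dose
#' levels and their order are unchanged — only the timing moves.
#'
#' @param plan A `taper_plan`.
#' @param discharge_day Day of hospital discharge, within the plan span.
#' @param grace_days Positive number of hold days (the consensus value is 2).
#' @return A new `taper_plan`.
#' @examples
#' p <- generate_taper(50, taper_policy(0.25, 2))
#' apply_grace_period(p, discharge_day = 1, grace_days = 2)
#' @export
apply_grace_period <- function(plan, discharge_day, grace_days = 2L) {
  if (!inherits(plan, "taper_plan")) {
    stop_validation("'plan' must be a taper_plan")
  }
  discharge_day <- check_count(discharge_day, "discharge_day", min = 0L)
  grace_days <- check_count(grace_days, "grace_days", min = 1L)
  span <- max(plan$steps$day)
  if (discharge_day > span) {
    stop_validation(sprintf(
      "discharge_day (%d) is outside the plan span (0..%d)",
      discharge_day, span
    ))
  }
  red <- plan_reductions(plan)
  if (!nrow(red) || all(red$day <= discharge_day)) {
    return(plan) # nothing scheduled after discharge
  }
  new_days <- ifelse(red$day > discharge_day, red$day + grace_days, red$day)
  steps <- build_plan_steps(plan$baseline_ome, new_days, red$dose,
                            plan$policy$backup_fraction * plan$baseline_ome,
                            plan$policy$target_ome)
  new_taper_plan(steps, plan$baseline_ome, plan$policy, plan$plan_id)
}

# days on which the fixed dose drops, and the level reached
plan_reductions <- function(plan) {
  s <- plan$steps
  drop <- which(diff(s$fixed_ome) < 0) + 1L
  data.frame(day = s$day[drop], dose = s$fixed_ome[drop])
}

#' Two-phase (tiered) taper for chronic users with an acute pain episode
#'
#' Doses above the patient's maintenance dose are removed first under the
#' rapid (acute) policy — the step size being a fraction of the *excess* —
#' then, once the maintenance dose is re-established, an optional second
#' phase continues toward the chronic policy's target under the gradual
#' policy. The concatenated plan is non-increasing and continuous at the
#' phase boundary.
#'
#' @param maintenance_ome The patient's established maintenance dose,
#'   mg OME/24 h.
#' @param current_ome Current (elevated) dose; must exceed the maintenance
#'   dose.
#' @param acute_policy [taper_policy] for phase 1 (its `target_ome` is
#'   ignored; phase 1 always ends at the maintenance dose).
#' @param chronic_policy Optional [taper_policy] for phase 2; `NULL` to stop
#'   at the maintenance dose. Its `target_ome` must not exceed the
#'   maintenance dose.
#' @return A `taper_plan`.
#' @examples
#' tiered_taper(20, 60, taper_policy(0.25, 2))
#' @export
tiered_taper <- function(maintenance_ome, current_ome, acute_policy,
                         chronic_policy = NULL) {
  check_number(maintenance_ome, "maintenance_ome", min = 0, strict_min = TRUE)
  check_number(current_ome, "current_ome", min = 0, strict_min = TRUE)
  if (current_ome <= maintenance_ome) {
    stop_validation(sprintf(
      "current dose (%g) must exceed the maintenance dose (%g)",
      current_ome, maintenance_ome
    ))
  }
  if (!inherits(acute_policy, "taper_policy")) {
    stop_validation("'acute_policy' must be a taper_policy")
  }
  excess <- current_ome - maintenance_ome
  delta1 <- acute_policy$reduction_fraction * excess
  n1 <- ceiling(excess / delta1)
  days1 <- acute_policy$first_reduction_day +
    acute_policy$step_interval_days * (seq_len(n1) - 1L)
  doses1 <- pmax(current_ome - seq_len(n1) * delta1, maintenance_ome)

  red_days <- days1
  red_doses <- doses1
  target <- maintenance_ome
  if (!is.null(chronic_policy)) {
    if (!inherits(chronic_policy, "taper_policy")) {
      stop_validation("'chronic_policy' must be a taper_policy")
    }
    if (chronic_policy$target_ome > maintenance_ome) {
      stop_validation("phase-2 target must not exceed the maintenance dose")
    }
    target <- chronic_policy$target_ome
    if (maintenance_ome > target) {
      sub <- generate_taper(maintenance_ome, chronic_policy)
      red2 <- plan_reductions(sub)
      # phase 2 starts counting from the day phase 1 reaches maintenance
      red_days <- c(days1, max(days1) + red2$day)
      red_doses <- c(doses1, red2$dose)
    }
  }
  backup <- acute_policy$backup_fraction * current_ome
  steps <- build_plan_steps(current_ome, red_days, red_doses, backup, target)
  plan <- new_taper_plan(steps, current_ome, acute_policy, "custom")
  plan$phase_boundary_day <- max(days1)
  plan$maintenance_ome <- maintenance_ome
  plan
}

#' Plan a taper for a patient case end-to-end
#'
#' Convenience wrapper: derives the baseline from the last-24-hour
#' consumption, selects the preset policy (unless one is supplied), labels
#' the plan with the matching Fig.-3-style preset id, and applies the
#' discharge grace period when a discharge day is known.
#'
#' @param case A [patient_case].
#' @param formulary A [formulary].
#' @param policy Optional explicit [taper_policy] overriding the preset.
#' @return A `taper_plan`.
#' @export
plan_for_case <- function(case, formulary, policy = NULL) {
  baseline <- baseline_from_24h(case, formulary)
  if (is.null(policy)) policy <- select_policy(case, baseline)
  acute <- policy$step_interval_days == 2L
  graced <- policy$grace_days > 0L && !is.null(case$discharge_day)
  plan_id <- if (acute) {
    if (graced) "plan4" else "plan3"
  } else {
    if (graced) "plan2" else "plan1"
  }
  plan <- generate_taper(baseline, policy, plan_id = plan_id)
  if (graced && case$discharge_day <= max(plan$steps$day)) {
    plan <- apply_grace_period(plan, case$discharge_day, policy$grace_days)
  }
  plan
}

#' @export
print.taper_plan <- function(x, ...) {
  red <- plan_reductions(x)
  cat(sprintf(
    "<taper_plan> %s: %g -> %g mg OME/24h in %d reduction(s) over %d day(s)\n",
    x$plan_id, x$baseline_ome, x$policy$target_ome, nrow(red),
    max(x$steps$day)
  ))
  lv <- x$steps[c(1L, which(diff(x$steps$fixed_ome) < 0) + 1L), ]
  cat("  day  fixed_ome  backup_ome\n")
  for (i in seq_len(nrow(lv))) {
    cat(sprintf("  %3d  %9.4g  %10.4g\n",
                lv$day[i], lv$fixed_ome[i], lv$backup_ome[i]))
  }
  invisible(x)
}

#' @export
summary.taper_plan <- function(object, ...) {
  red <- plan_reductions(object)
  out <- list(
    plan_id = object$plan_id,
    baseline_ome = object$baseline_ome,
    target_ome = object$policy$target_ome,
    n_reductions = nrow(red),
    reduction_days = red$day,
    duration_days = max(object$steps$day),
    step_size_ome = object$policy$reduction_fraction * object$baseline_ome,
    backup_ome = object$policy$backup_fraction * object$baseline_ome
  )
  class(out) <- "summary.taper_plan"
  out
}

#' @export
print.summary.taper_plan <- function(x, ...) {
  cat(sprintf("Taper plan %s\n", x$plan_id))
  cat(sprintf("  baseline:   %g mg OME/24h\n", x$baseline_ome))
  cat(sprintf("  target:     %g mg OME/24h\n", x$target_ome))
  cat(sprintf("  step size:  %g mg OME (linear, fixed)\n", x$step_size_ome))
  cat(sprintf("  reductions: %d on day(s) %s\n", x$n_reductions,
              paste(x$reduction_days, collapse = ", ")))
  cat(sprintf("  back-up:    %g mg OME/24h until target reached\n",
              x$backup_ome))
  cat(sprintf("  duration:   %d day(s)\n", x$duration_days))
  invisible(x)
}

#' @export
as.data.frame.taper_plan <- function(x, ...) x$steps

#' Plot a taper trajectory
#'
#' Step plot of the fixed daily dose over time with the back-up allowance as
#' a dashed line; mirrors the four-trajectory figure style.
#'
#' @param x A `taper_plan`.
#' @param y Unused.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.taper_plan <- function(x, y, ...) {
  s <- x$steps
  graphics::plot(s$day, s$fixed_ome, type = "s",
                 xlab = "day", ylab = "mg OME / 24 h",
                 main = sprintf("Taper %s (baseline %g)", x$plan_id,
                                x$baseline_ome),
                 ylim = c(0, max(s$fixed_ome)), ...)
  graphics::lines(s$day, s$backup_ome, type = "s", lty = 2)
  graphics::legend("topright", legend = c("fixed", "back-up"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Serialize a taper plan
#'
#' JSON carries the full object (`plan_id`, `baseline_ome`, `policy`,
#' `steps`); CSV carries the day-indexed steps (`day`, `fixed_ome`,
#' `backup_ome`).
#'
#' @param plan A `taper_plan`.
#' @param path Output path; format chosen by extension (`.json`/`.csv`).
#' @return `path`, invisibly.
#' @export
write_taper_plan <- function(plan, path) {
  if (!inherits(plan, "taper_plan")) {
    stop_validation("'plan' must be a taper_plan")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(
        plan_id = plan$plan_id,
        baseline_ome = plan$baseline_ome,
        policy = unclass(plan$policy),
        steps = plan$steps
      ),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else if (ext == "csv") {
    utils::write.csv(plan$steps, path, row.names = FALSE)
  } else {
    stop_validation(sprintf("unsupported plan format '.%s' (json or csv)", ext))
  }
  invisible(path)
}
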