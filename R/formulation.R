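#' Mapping exact doses onto commercially available tablet strengths
#'
#' Computed daily doses are exact reals; patients swallow tablets. The
#' mapper finds, among all unit combinations within a deviation tolerance of
#' the prescribed daily dose, the one with the fewest units (lowest pill
#' burden), then distributes the units over fixed clock-time administration
#' slots. When no combination comes close enough it fails loudly, listing
#' the nearest achievable doses — deviation is surfaced, never hidden.
#'
#' @name formulation_mapper
NULL

#' Default administration slots at fixed clock times
#'
#' Fixed clock times (08:00, 20:00, ...) rather than intervals such as
#' "every 8 hours", per patient feedback on the reduction-plan handout.
#'
#' @param n_slots Number of daily administration slots, 1–4.
#' @return Data frame with columns `slot`, `time` (HH:MM), `label`.
#' @export
default_slots <- function(n_slots) {
  n_slots <- check_count(n_slots, "n_slots", min = 1L)
  if (n_slots > 4L) stop_validation("'n_slots' must be between 1 and 4")
  times <- switch(n_slots,
    "08:00",
    c("08:00", "20:00"),
    c("08:00", "14:00", "20:00"),
    c("08:00", "12:00", "16:00", "20:00")
  )
  labels <- switch(n_slots,
    "morning",
    c("morning", "evening"),
    c("morning", "afternoon", "evening"),
    c("morning", "midday", "afternoon", "evening")
  )
  data.frame(slot = seq_len(n_slots), time = times, label = labels,
             stringsAsFactors = FALSE)
}

slot_gap_hours <- function(times) {
  mins <- vapply(strsplit(times, ":"), function(p) {
    as.integer(p[1L]) * 60L + as.integer(p[2L])
  }, integer(1L))
  if (length(mins) < 2L) return(24)
  min(diff(sort(mins))) / 60
}

# all count vectors over `strengths` with total units exactly k
compositions <- function(k, n_strengths) {
  if (n_strengths == 1L) return(matrix(k, ncol = 1L))
  out <- list()
  for (c1 in 0:k) {
    sub <- compositions(k - c1, n_strengths - 1L)
    out[[length(out) + 1L]] <- cbind(c1, sub)
  }
  do.call(rbind, out)
}

# deterministic greedy distribution of units over slots, balancing slot mg
distribute_units <- function(strengths, counts, n_slots) {
  units <- rep(strengths, counts)
  units <- sort(units, decreasing = TRUE)
  slot_mg <- numeric(n_slots)
  assign_slot <- integer(length(units))
  for (i in seq_along(units)) {
    j <- which.min(slot_mg)
    assign_slot[i] <- j
    slot_mg[j] <- slot_mg[j] + units[i]
  }
  list(unit_mg = units, slot = assign_slot, slot_mg = slot_mg)
}

#' Map a daily dose to a tablet regimen
#'
#' Searches unit combinations in order of increasing pill count and returns
#' the first feasible one, i.e. the assignment minimizing total units
#' subject to `|achieved - dose_mg| <= tolerance * dose_mg`. Ties are broken
#' by (a) preferring an achieved dose at or below the prescription (a
#' deprescribing context never rounds up when it can round down), then (b)
#' fewer distinct strengths, then (c) a more even mg split across slots.
#'
#' @param dose_mg Non-negative prescribed daily dose, mg of the drug. A dose
#'   of 0 returns an empty regimen.
#' @param drug An [opioid_spec] with at least one formulation.
#' @param n_slots Number of administration slots (1–4); default 2.
#' @param tolerance Allowed relative deviation of the achieved from the
#'   prescribed dose (default 0.15).
#' @param single_strength If `TRUE`, all units must share one tablet
#'   strength (simplified regimen for cognitively impaired patients).
#' @param max_units Pill-burden cap per day (default 8).
#' @param slots Optional custom slot table as from [default_slots()].
#' @param with_food Optional logical shown on the handout (`TRUE` = take
#'   with food).
#' @return A `regimen`: data frame with one row per (slot, strength) pair —
#'   columns `slot`, `time`, `label`, `strength_mg`, `count` — and
#'   attributes `dose_mg`, `achieved_mg`, `deviation`, `drug`.
#' @examples
#' sp <- opioid_spec("morphine", 1, data.frame(
#'   strength_mg = c(10, 30), release = "immediate", units_per_pack = 20L))
#' map_daily_dose(37.5, sp, n_slots = 2)
#' @export
map_daily_dose <- function(dose_mg, drug, n_slots = 2L, tolerance = 0.15,
                           single_strength = FALSE, max_units = 8L,
                           slots = NULL, with_food = NULL) {
  if (!inherits(drug, "opioid_spec")) {
    stop_validation("'drug' must be an opioid_spec")
  }
  check_number(dose_mg, "dose_mg", min = 0)
  check_number(tolerance, "tolerance", min = 0)
  check_flag(single_strength, "single_strength")
  max_units <- check_count(max_units, "max_units", min = 1L)
  if (is.null(slots)) slots <- default_slots(n_slots) else n_slots <- nrow(slots)
  if (!nrow(drug$formulations)) {
    stop_validation(sprintf("'%s' has no formulations to map onto", drug$name))
  }
  er_only <- all(drug$formulations$release == "extended")
  if (er_only && slot_gap_hours(slots$time) < 8) {
    stop_validation(sprintf(
      paste("'%s' is available only as extended-release; slots less than 8 h",
            "apart are unsafe — request <= 2 slots"), drug$name
    ))
  }

  empty <- data.frame(slot = integer(), time = character(),
                      label = character(), strength_mg = numeric(),
                      count = integer(), stringsAsFactors = FALSE)
  if (dose_mg == 0) {
    return(new_regimen(empty, dose_mg, 0, drug, n_slots, tolerance,
                       single_strength, with_food))
  }

  strengths <- sort(unique(drug$formulations$strength_mg))
  band <- tolerance * dose_mg
  best <- NULL
  achievable <- numeric()
  for (k in seq_len(max_units)) {
    cc <- compositions(k, length(strengths))
    if (single_strength) {
      cc <- cc[rowSums(cc > 0) <= 1L, , drop = FALSE]
    }
    totals <- as.numeric(cc %*% strengths)
    achievable <- c(achievable, totals)
    feas <- which(abs(totals - dose_mg) <= band)
    if (length(feas)) {
      cand <- cc[feas, , drop = FALSE]
      ctot <- totals[feas]
      # (a) prefer not exceeding the prescribed dose
      under <- ctot <= dose_mg
      if (any(under)) {
        cand <- cand[under, , drop = FALSE]
        ctot <- ctot[under]
      }
      # (b) fewer distinct strengths
      ndist <- rowSums(cand > 0)
      keep <- ndist == min(ndist)
      cand <- cand[keep, , drop = FALSE]
      ctot <- ctot[keep]
      # (c) more even split across slots, then closest achieved, then lex
      evenness <- vapply(seq_len(nrow(cand)), function(i) {
        sm <- distribute_units(strengths, cand[i, ], n_slots)$slot_mg
        max(sm) - min(sm)
      }, numeric(1L))
      ord <- order(evenness, abs(ctot - dose_mg),
                   apply(cand, 1L, paste, collapse = ","))
      best <- list(counts = cand[ord[1L], ], total = ctot[ord[1L]])
      break
    }
  }
  if (is.null(best)) {
    near <- sort(unique(achievable))
    near <- near[order(abs(near - dose_mg))][seq_len(min(3L, length(near)))]
    stop_validation(sprintf(
      paste("no regimen within %.0f%% of %g mg using strengths {%s}",
            "(<= %d units%s); nearest achievable daily doses: %s"),
      100 * tolerance, dose_mg, paste(strengths, collapse = ", "),
      max_units, if (single_strength) ", single strength" else "",
      paste(sort(near), collapse = ", ")
    ))
  }

  dist <- distribute_units(strengths, best$counts, n_slots)
  rows <- empty
  for (j in seq_len(n_slots)) {
    in_slot <- dist$unit_mg[dist$slot == j]
    if (!length(in_slot)) next
    tab <- table(in_slot)
    rows <- rbind(rows, data.frame(
      slot = j, time = slots$time[j], label = slots$label[j],
      strength_mg = as.numeric(names(tab)), count = as.integer(tab),
      stringsAsFactors = FALSE
    ))
  }
  rows <- rows[order(rows$slot, -rows$strength_mg), , drop = FALSE]
  rownames(rows) <- NULL
  new_regimen(rows, dose_mg, best$total, drug, n_slots, tolerance,
              single_strength, with_food)
}

new_regimen <- function(rows, dose_mg, achieved, drug, n_slots, tolerance,
                        single_strength, with_food) {
  structure(
    rows,
    dose_mg = dose_mg,
    achieved_mg = achieved,
    deviation = if (dose_mg > 0) (achieved - dose_mg) / dose_mg else 0,
    drug = drug, n_slots = n_slots, tolerance = tolerance,
    single_strength = single_strength, with_food = with_food,
    class = c("regimen", "data.frame")
  )
}

#' @export
print.regimen <- function(x, ...) {
  drug <- attr(x, "drug")
  cat(sprintf(
    "<regimen> %s: %g mg/day prescribed, %g mg/day achieved (%+.1f%%), %d unit(s)\n",
    drug$name, attr(x, "dose_mg"), attr(x, "achieved_mg"),
    100 * attr(x, "deviation"), sum(x$count)
  ))
  if (nrow(x)) {
    for (i in seq_len(nrow(x))) {
      cat(sprintf("  %s (%s): %d x %g mg\n",
                  x$time[i], x$label[i], x$count[i], x$strength_mg[i]))
    }
  } else {
    cat("  (no units: dose 0)\n")
  }
  invisible(x)
}

#' Re-solve a regimen with a single tablet strength
#'
#' For cognitively impaired patients a regimen should use exactly one
#' dosage strength to minimize intake errors. Returns the input unchanged
#' if it is already single-strength; otherwise re-solves at the same
#' tolerance with the single-strength constraint.
#'
#' @param regimen A `regimen` from [map_daily_dose()].
#' @return A `regimen` using exactly one distinct strength.
#' @export
simplify_regimen <- function(regimen) {
  if (!inherits(regimen, "regimen")) {
    stop_validation("'regimen' must come from map_daily_dose()")
  }
  if (!nrow(regimen) || length(unique(regimen$strength_mg)) <= 1L) {
    return(regimen)
  }
  tryCatch(
    map_daily_dose(
      attr(regimen, "dose_mg"), attr(regimen, "drug"),
      n_slots = attr(regimen, "n_slots"),
      tolerance = attr(regimen, "tolerance"),
      single_strength = TRUE, with_food = attr(regimen, "with_food")
    ),
    opitaper_validation_error = function(e) {
      stop_validation(paste0(
        conditionMessage(e),
        "; consider relaxing the tolerance for a single-strength regimen"
      ))
    }
  )
}

#' Render a regimen as a Markdown table
#'
#' @param regimen A `regimen`.
#' @return Character vector of Markdown lines.
#' @export
regimen_markdown <- function(regimen) {
  if (!inherits(regimen, "regimen")) {
    stop_validation("'regimen' must come from map_daily_dose()")
  }
  drug <- attr(regimen, "drug")
  header <- c(
    sprintf("| time | intake (%s) |", drug$name),
    "|------|--------------|"
  )
  if (!nrow(regimen)) return(c(header, "| -- | none |"))
  body <- vapply(split(seq_len(nrow(regimen)), regimen$slot), function(idx) {
    sprintf("| %s | %s |", regimen$time[idx[1L]],
            paste(sprintf("%d x %g mg", regimen$count[idx],
                          regimen$strength_mg[idx]), collapse = " + "))
  }, character(1L))
  c(header, unname(body))
}

#' Write a regimen as CSV
#'
#' Columns: `slot`, `time`, `strength_mg`, `count`, `achieved_mg` (per-slot
#' achieved mg).
#'
#' @param regimen A `regimen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regimen <- function(regimen, path) {
  df <- as.data.frame(regimen)
  if (nrow(df)) {
    slot_mg <- tapply(df$strength_mg * df$count, df$slot, sum)
    df$achieved_mg <- as.numeric(slot_mg[as.character(df$slot)])
  } else {
    df$achieved_mg <- numeric()
  }
  utils::write.csv(df[c("slot", "time", "strength_mg", "count", "achieved_mg")],
                   path, row.names = FALSE)
  invisible(path)
}
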