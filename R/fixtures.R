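#' Seeded synthetic fixtures for the whole toolkit
#'
#' Deterministic generators for every input the toolkit consumes — patient
#' cases and Delphi rating panels — so the full pipeline is testable
#' without any external data. All randomness flows from the single seed in
#' the [fixture_spec()]; the global RNG state of the caller is saved and
#' restored.
#'
#' @name synth_fixtures
NULL

#' Specification for the fixture generators
#'
#' @param seed Integer seed; identical seeds give identical fixtures.
#' @param n_patients Number of patient cases.
#' @param n_respondents,n_items Delphi panel dimensions.
#' @param planted_consensus_items Item indices (subset of `1:n_items`) that
#'   should reach consensus by construction.
#' @param consensus_strength Probability that a respondent rates a planted
#'   item at or above the agreement cut (default 0.95).
#' @param other_strength Same probability for non-planted items
#'   (default 0.3).
#' @param perturb_prob Probability that an unchanged item's round-2 rating
#'   moves by one point (symmetric, clamped to 1..7; default 0.1). Zero
#'   makes round 2 a copy of round 1.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed = 1L, n_patients = 10L, n_respondents = 10L,
                         n_items = 49L,
                         planted_consensus_items = seq_len(ceiling(n_items / 2)),
                         consensus_strength = 0.95, other_strength = 0.3,
                         perturb_prob = 0.1) {
  seed <- check_count(seed, "seed")
  n_patients <- check_count(n_patients, "n_patients", min = 1L)
  n_respondents <- check_count(n_respondents, "n_respondents", min = 1L)
  n_items <- check_count(n_items, "n_items", min = 1L)
  check_number(consensus_strength, "consensus_strength", min = 0, max = 1)
  check_number(other_strength, "other_strength", min = 0, max = 1)
  check_number(perturb_prob, "perturb_prob", min = 0, max = 1)
  planted_consensus_items <- as.integer(planted_consensus_items)
  if (length(planted_consensus_items) &&
      !all(planted_consensus_items %in% seq_len(n_items))) {
    stop_validation("planted_consensus_items must be a subset of 1:n_items")
  }
  structure(
    list(seed = seed, n_patients = n_patients,
         n_respondents = n_respondents, n_items = n_items,
         planted_consensus_items = planted_consensus_items,
         consensus_strength = consensus_strength,
         other_strength = other_strength, perturb_prob = perturb_prob),
    class = "fixture_spec"
  )
}

#' Generate synthetic patient cases
#'
#' A mix of acute/chronic pain and naive/chronic-user statuses with
#' 24-hour baselines between 20 and 120 mg OME, split into a fixed dose and
#' a back-up dose consistent with the baseline. Chronic users get a
#' prehospital dose below their baseline; about half the cases carry a
#' discharge day.
#'
#' @param spec A [fixture_spec].
#' @param formulary A [formulary]; consumption entries use its drugs.
#' @return List of [patient_case] objects of length `spec$n_patients`.
#' @export
make_patient_cases <- function(spec, formulary) {
  if (!inherits(spec, "fixture_spec")) {
    stop_validation("'spec' must be a fixture_spec")
  }
  drugs <- names(formulary$opioids)
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_patients), function(i) {
      status <- sample(c("naive", "chronic_user"), 1L)
      pain <- sample(c("acute", "chronic"), 1L)
      baseline_ome <- stats::runif(1L, 20, 120)
      backup_share <- stats::runif(1L, 0.05, 0.15)
      drug <- sample(drugs, 1L)
      fixed_ome <- baseline_ome * (1 - backup_share)
      backup_ome <- baseline_ome * backup_share
      entries <- list(
        consumption_entry(drug, from_ome(drug, fixed_ome, formulary),
                          "fixed"),
        consumption_entry(drug, from_ome(drug, backup_ome, formulary),
                          "backup")
      )
      prehosp <- if (status == "chronic_user") {
        stats::runif(1L, 0.1, 0.6) * baseline_ome
      } else 0
      patient_case(
        opioid_status = status, pain_type = pain, last24h = entries,
        prehospital_ome = prehosp,
        discharge_day = if (stats::runif(1L) < 0.5) {
          sample(0:5, 1L)
        } else NULL,
        pain_stable_hours = sample(c(12, 24, 48, 72), 1L),
        cognitive_impairment = stats::runif(1L) < 0.1
      )
    })
  })
}

#' Generate a synthetic Delphi rating panel
#'
#' Planted items draw ratings from \{5, 6, 7\} with probability
#' `consensus_strength` (else from \{1..4\}); non-planted items the same
#' with `other_strength`. Round 2 equals round 1 on unchanged items apart
#' from a small symmetric one-point perturbation; planted items are marked
#' unchanged, non-planted items changed (reworded) and re-drawn in round 2.
#'
#' @param spec A [fixture_spec].
#' @return A [delphi_dataset].
#' @export
make_delphi_panel <- function(spec) {
  if (!inherits(spec, "fixture_spec")) {
    stop_validation("'spec' must be a fixture_spec")
  }
  planted <- seq_len(spec$n_items) %in% spec$planted_consensus_items
  with_local_seed(spec$seed, {
    draw <- function(p_agree) {
      if (stats::runif(1L) < p_agree) sample(5:7, 1L) else sample(1:4, 1L)
    }
    grid <- expand.grid(respondent_id = seq_len(spec$n_respondents),
                        item_id = seq_len(spec$n_items))
    r1 <- vapply(grid$item_id, function(it) {
      draw(if (planted[it]) spec$consensus_strength else spec$other_strength)
    }, integer(1L))
    r2 <- vapply(seq_len(nrow(grid)), function(i) {
      it <- grid$item_id[i]
      if (planted[it]) {
        # unchanged item: round 1 value plus rare one-point jitter
        v <- r1[i]
        if (stats::runif(1L) < spec$perturb_prob) {
          v <- v + sample(c(-1L, 1L), 1L)
        }
        min(max(v, 1L), 7L)
      } else {
        draw(spec$other_strength)
      }
    }, integer(1L))
    ratings <- rbind(
      data.frame(grid, round = 1L, rating = r1,
                 item_changed = !planted[grid$item_id]),
      data.frame(grid, round = 2L, rating = r2,
                 item_changed = !planted[grid$item_id])
    )
    delphi_dataset(ratings)
  })
}

#' Write all fixture files to a directory
#'
#' Emits a patient case JSON per generated case and the Delphi panel CSV,
#' ready for the command-line subcommands.
#'
#' @param spec A [fixture_spec].
#' @param formulary A [formulary].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_fixtures <- function(spec, formulary, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cases <- make_patient_cases(spec, formulary)
  paths <- character()
  for (i in seq_along(cases)) {
    p <- file.path(dir, sprintf("patient_%02d.json", i))
    cs <- cases[[i]]
    jsonlite::write_json(
      list(
        opioid_status = cs$opioid_status, pain_type = cs$pain_type,
        prehospital_ome = cs$prehospital_ome,
        last24h = lapply(cs$last24h, unclass),
        discharge_day = cs$discharge_day,
        pain_stable_hours = cs$pain_stable_hours,
        cognitive_impairment = cs$cognitive_impairment
      ),
      p, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
    )
    paths <- c(paths, p)
  }
  panel <- make_delphi_panel(spec)
  pp <- file.path(dir, "delphi_ratings.csv")
  utils::write.csv(panel$ratings, pp, row.names = FALSE)
  invisible(c(paths, pp))
}
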