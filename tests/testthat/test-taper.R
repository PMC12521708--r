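test_that("baseline sums fixed and back-up consumption in OME", {
  f <- test_formulary()
  case <- patient_case("naive", "acute", list(
    consumption_entry("morphine", 40, "fixed"),
    consumption_entry("morphine", 10, "backup")
  ))
  expect_equal(baseline_from_24h(case, f), 50)

  mixed <- patient_case("naive", "acute", list(
    consumption_entry("drug_x", 10, "fixed"),
    consumption_entry("morphine", 5, "backup")
  ))
  expect_equal(baseline_from_24h(mixed, f), 25)

  empty <- patient_case("naive", "acute", list())
  expect_error(baseline_from_24h(empty, f), "no last-24h",
               class = "opitaper_validation_error")
})

test_that("stabilization requires the pain window and minimal back-up use", {
  stable <- patient_case("naive", "acute",
                         list(consumption_entry("morphine", 50)),
                         pain_stable_hours = 48)
  unstable <- patient_case("naive", "acute",
                           list(consumption_entry("morphine", 50)),
                           pain_stable_hours = 12)
  expect_true(is_stabilized(stable, 1L, 4, 50))
  expect_false(is_stabilized(unstable, 0L, 0, 50))
  expect_false(is_stabilized(stable, 5L, 20, 50)) # both thresholds exceeded
  expect_false(is_stabilized(stable, 1L, 6, 50))  # > 10% of fixed dose
  expect_false(is_stabilized(stable, 3L, 4, 50))  # too many rescue doses
  expect_error(is_stabilized(stable, 1L, 4, 50, window_hours = 12),
               class = "opitaper_validation_error")
})

test_that("policy selection maps pain type and status to the presets", {
  acute_naive <- patient_case("naive", "acute",
                              list(consumption_entry("morphine", 50)))
  pol <- select_policy(acute_naive, 50)
  expect_equal(pol$reduction_fraction, 0.25)
  expect_equal(pol$step_interval_days, 2L)
  expect_equal(pol$grace_days, 0L)
  expect_equal(pol$target_ome, 0)

  chronic_user <- patient_case("chronic_user", "chronic",
                               list(consumption_entry("morphine", 50)),
                               prehospital_ome = 20, discharge_day = 1L)
  pol2 <- select_policy(chronic_user, 50)
  expect_equal(pol2$reduction_fraction, 0.10)
  expect_equal(pol2$step_interval_days, 3L)
  expect_equal(pol2$grace_days, 2L)
  expect_equal(pol2$target_ome, 20)

  acute_user <- patient_case("chronic_user", "acute",
                             list(consumption_entry("morphine", 60)),
                             prehospital_ome = 30)
  expect_equal(select_policy(acute_user, 60)$target_ome, 30)
  # default back-up fraction sits inside the consensus bracket
  expect_gte(pol$backup_fraction, 1 / 10)
  expect_lte(pol$backup_fraction, 1 / 6)
})

test_that("the rapid preset from 50 OME gives the canonical trajectory", {
  plan <- generate_taper(50, acute_policy())
  s <- plan$steps
  expect_equal(s$day, 0:7)
  expect_equal(s$fixed_ome[s$day %in% c(0, 1, 3, 5, 7)],
               c(50, 37.5, 25, 12.5, 0))
  expect_equal(s$fixed_ome[s$day == 2], 37.5) # held between reductions
  expect_equal(nrow(plan_reductions(plan)), 4L)
})

test_that("the gradual preset makes 10 reductions, the last on day 28", {
  plan <- generate_taper(50, chronic_policy())
  red <- plan_reductions(plan)
  expect_equal(nrow(red), 10L)
  expect_equal(red$day, 1 + 3 * (0:9))
  expect_equal(max(plan$steps$day), 28)
  expect_equal(red$dose[10], 0)
})

test_that("partial final step clamps exactly onto a nonzero target", {
  plan <- generate_taper(60, acute_policy(target = 15))
  red <- plan_reductions(plan)
  expect_equal(red$day, c(1, 3, 5))
  expect_equal(red$dose, c(45, 30, 15))
  expect_equal(nrow(red), ceiling((60 - 15) / (0.25 * 60)))
  expect_error(generate_taper(10, acute_policy(target = 15)),
               "nothing to reduce")
})

test_that("plans are linear in the baseline, not compounding", {
  set.seed(7)
  for (i in 1:20) {
    b <- runif(1, 20, 120)
    f <- sample(c(0.25, 0.10, 0.05, 0.2), 1)
    plan <- generate_taper(b, taper_policy(f, 2L))
    red <- plan_reductions(plan)
    if (nrow(red) >= 2) {
      expect_equal(red$dose[2], b * (1 - 2 * f))
      expect_false(isTRUE(all.equal(red$dose[2], b * (1 - f)^2)))
    }
  }
})

test_that("plan invariants hold over random baselines, fractions, targets", {
  set.seed(21)
  for (i in 1:60) {
    b <- runif(1, 10, 200)
    fr <- runif(1, 0.05, 0.25)
    tg <- if (runif(1) < 0.5) 0 else runif(1, 0, 0.8 * b)
    plan <- generate_taper(b, taper_policy(fr, sample(2:3, 1),
                                           target_ome = tg))
    s <- plan$steps
    expect_equal(s$fixed_ome[1], b)
    expect_equal(s$fixed_ome[nrow(s)], tg)
    expect_true(all(diff(s$fixed_ome) <= 0))
    expect_true(all(s$fixed_ome >= tg))
    expect_equal(nrow(plan_reductions(plan)), ceiling((b - tg) / (fr * b)))
    # back-up allowance constant until the target is reached, then dropped
    expect_true(all(s$backup_ome[s$fixed_ome > tg] ==
                      plan$policy$backup_fraction * b))
    expect_true(all(s$backup_ome[s$fixed_ome == tg] == 0))
  }
})

test_that("grace period shifts post-discharge reductions, preserving levels", {
  plan <- generate_taper(50, acute_policy())
  g <- apply_grace_period(plan, discharge_day = 1L, grace_days = 2L)
  s <- g$steps
  expect_equal(s$fixed_ome[s$day %in% 1:4], rep(37.5, 4)) # held through d4
  expect_equal(s$fixed_ome[s$day == 5], 25)
  expect_equal(s$fixed_ome[s$day == 7], 12.5)
  expect_equal(s$fixed_ome[s$day == 9], 0)
  # dose-level multiset and order unchanged
  expect_equal(plan_reductions(g)$dose, plan_reductions(plan)$dose)
  # discharge after the last reduction leaves the plan untouched
  expect_equal(apply_grace_period(plan, 7L, 2L), plan)
  expect_error(apply_grace_period(plan, 1L, 0L),
               class = "opitaper_validation_error")
  expect_error(apply_grace_period(plan, 99L, 2L), "outside the plan span")
})

test_that("grace shift preserves levels for random plans", {
  set.seed(33)
  for (i in 1:30) {
    b <- runif(1, 20, 150)
    plan <- generate_taper(b, taper_policy(runif(1, 0.05, 0.25),
                                           sample(2:3, 1)))
    dd <- sample(0:max(plan$steps$day), 1)
    g <- apply_grace_period(plan, dd, 2L)
    expect_equal(plan_reductions(g)$dose, plan_reductions(plan)$dose)
    before <- plan_reductions(plan)$day
    after <- plan_reductions(g)$day
    expect_equal(after, ifelse(before > dd, before + 2L, before))
  }
})

test_that("tiered taper removes the excess first, then continues if asked", {
  plan <- tiered_taper(20, 60, acute_policy())
  red <- plan_reductions(plan)
  expect_equal(red$day, c(1, 3, 5, 7))
  expect_equal(red$dose, c(50, 40, 30, 20))
  expect_equal(plan$steps$fixed_ome[plan$steps$day == 0], 60)
  expect_equal(min(plan$steps$fixed_ome), 20) # phase boundary = maintenance

  # degenerate phase 2: chronic target equals the maintenance dose
  plan2 <- tiered_taper(20, 60, acute_policy(), chronic_policy(target = 20))
  expect_equal(plan2$steps$fixed_ome, plan$steps$fixed_ome)

  # real phase 2 continues from the maintenance dose and stays continuous
  plan3 <- tiered_taper(20, 60, acute_policy(), chronic_policy(target = 0))
  s <- plan3$steps
  expect_true(all(diff(s$fixed_ome) <= 0))
  expect_equal(s$fixed_ome[s$day == plan3$phase_boundary_day], 20)
  expect_equal(s$fixed_ome[nrow(s)], 0)
  # phase-2 step size is 10% of the maintenance dose, not of the peak
  d2 <- plan_reductions(plan3)$dose
  expect_equal(d2[5], 20 - 0.10 * 20)

  expect_error(tiered_taper(60, 20, acute_policy()), "must exceed")
})

test_that("back-up sizing enforces the 1/10 to 1/6 bracket", {
  expect_equal(backup_dose(50, 1 / 10), 5)
  expect_equal(backup_dose(50, 1 / 6), 50 / 6)
  expect_error(backup_dose(50, 1 / 4), class = "opitaper_validation_error")
  expect_error(backup_dose(50, 1 / 20), class = "opitaper_validation_error")
})

test_that("plan_for_case labels the four trajectory presets", {
  f <- test_formulary()
  mk <- function(pain, discharge) {
    patient_case("naive", pain, list(consumption_entry("morphine", 50)),
                 discharge_day = discharge)
  }
  expect_equal(plan_for_case(mk("chronic", NULL), f)$plan_id, "plan1")
  expect_equal(plan_for_case(mk("chronic", 1L), f)$plan_id, "plan2")
  expect_equal(plan_for_case(mk("acute", NULL), f)$plan_id, "plan3")
  p4 <- plan_for_case(mk("acute", 1L), f)
  expect_equal(p4$plan_id, "plan4")
  expect_equal(max(p4$steps$day), 9) # grace-extended rapid plan
})

test_that("plans serialize to JSON and CSV", {
  plan <- generate_taper(50, acute_policy())
  pj <- withr::local_tempfile(fileext = ".json")
  pc <- withr::local_tempfile(fileext = ".csv")
  write_taper_plan(plan, pj)
  write_taper_plan(plan, pc)
  j <- jsonlite::fromJSON(pj)
  expect_equal(j$baseline_ome, 50)
  expect_equal(j$steps$fixed_ome, plan$steps$fixed_ome)
  csv <- read.csv(pc)
  expect_equal(csv$day, plan$steps$day)
  expect_equal(names(csv), c("day", "fixed_ome", "backup_ome"))
})
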