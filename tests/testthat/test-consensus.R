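test_that("the per-item consensus rule combines agreement share and mean", {
  all7 <- item_consensus(rep(7, 10))
  expect_true(all7$consensus)
  expect_equal(all7$prop_agree, 1)
  expect_equal(all7$mean, 7)

  all1 <- item_consensus(rep(1, 10))
  expect_false(all1$consensus)
  expect_equal(all1$prop_agree, 0)

  edge <- item_consensus(c(7, 7, 7, 7, 4))
  expect_true(edge$consensus)
  expect_equal(edge$prop_agree, 0.8)
  expect_equal(edge$mean, 6.4)

  # 80% agree but strong dissent drags the mean below the 4.5 bar
  low_mean <- item_consensus(c(rep(5, 8), 1, 1))
  expect_equal(low_mean$prop_agree, 0.8)
  expect_equal(low_mean$mean, 4.2)
  expect_false(low_mean$consensus)

  # missing ratings drop out of the denominator
  with_na <- item_consensus(c(7, 7, NA, 7, NA))
  expect_equal(with_na$prop_agree, 1)
  expect_error(item_consensus(c(NA, NA)), "all ratings missing")
})

test_that("item consensus is invariant to respondent permutation", {
  set.seed(3)
  for (i in 1:10) {
    r <- sample(1:7, 12, replace = TRUE)
    expect_identical(item_consensus(r), item_consensus(sample(r)))
  }
})

test_that("round consensus rate counts items and rounds to one decimal", {
  # 43 of 49 planted at full strength reproduces the 87.8% round rate
  spec <- fixture_spec(seed = 4L, n_respondents = 10L, n_items = 49L,
                       planted_consensus_items = 1:43,
                       consensus_strength = 1, other_strength = 0)
  panel <- make_delphi_panel(spec)
  res <- round_consensus_rate(panel, 1L)
  expect_equal(res$k_consensus, 43L)
  expect_equal(res$n_items, 49L)
  expect_equal(res$percent, 87.8)
  expect_equal(sort(res$per_item$item_id[res$per_item$consensus]), 1:43)

  none <- make_delphi_panel(fixture_spec(seed = 5L, n_items = 8L,
                                         planted_consensus_items = integer(),
                                         other_strength = 0))
  expect_equal(round_consensus_rate(none, 1L)$percent, 0)
})

test_that("stability is 1 when round 2 duplicates round 1", {
  set.seed(8)
  r1 <- matrix(sample(1:7, 60, TRUE), nrow = 6) # 6 items x 10 respondents
  panel <- make_panel(r1)
  for (m in c("pearson", "icc_a1")) {
    st <- test_retest_stability(panel, method = m)
    expect_equal(st$coefficient, 1.0)
    expect_true(st$stable)
  }
})

test_that("stability uses unchanged items only and needs at least three", {
  set.seed(9)
  r1 <- matrix(sample(1:7, 50, TRUE), nrow = 5)
  r2 <- r1
  r2[4:5, ] <- matrix(sample(1:7, 20, TRUE), nrow = 2) # reworded items
  panel <- make_panel(r1, r2, changed = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  st <- test_retest_stability(panel, method = "pearson")
  expect_equal(st$n_items, 3L)
  expect_equal(st$coefficient, 1.0) # unchanged items are identical

  few <- make_panel(r1, r2, changed = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_error(test_retest_stability(few), ">= 3 unchanged",
               class = "opitaper_validation_error")

  flat <- make_panel(matrix(4L, nrow = 4, ncol = 6))
  expect_error(test_retest_stability(flat, method = "pearson"),
               "zero variance in round 1")
})

test_that("pearson stability is symmetric in round order", {
  set.seed(10)
  r1 <- matrix(sample(1:7, 80, TRUE), nrow = 8)
  r2 <- pmin(pmax(r1 + matrix(sample(-1:1, 80, TRUE), nrow = 8), 1), 7)
  a <- test_retest_stability(make_panel(r1, r2), method = "pearson")
  b <- test_retest_stability(make_panel(r2, r1), method = "pearson")
  expect_equal(a$coefficient, b$coefficient)
  expect_identical(a$stable, a$coefficient >= 0.70)
})

test_that("ICC(A,1) matches an independent reference on a 10x8 table", {
  set.seed(42)
  subj <- rnorm(10, 5, 1.5); rater <- rnorm(8, 0, 0.3)
  mat <- round(outer(subj, rater, "+") + matrix(rnorm(80, 0, 0.5), 10, 8), 3)
  res <- icc_a1(mat)
  # frozen from pingouin.intraclass_corr (type ICC(A,1)) on this exact table
  expect_equal(res$coefficient, 0.742945856713, tolerance = 1e-9)
  expect_equal(round(res$ci_low, 2), 0.52)
  expect_equal(round(res$ci_high, 2), 0.91)
  expect_error(icc_a1(mat[1:2, ]), class = "opitaper_validation_error")
})

test_that("percent agreement is the share of identical codes", {
  expect_equal(percent_agreement(letters[1:5], letters[1:5]), 1)
  expect_equal(percent_agreement(letters[1:4], letters[5:8]), 0)
  expect_equal(percent_agreement(c("a", "a", "b", "c"),
                                 c("a", "b", "b", "c")), 0.75)
  expect_error(percent_agreement(1:3, 1:4), "equal length")
})

test_that("Brennan-Prediger corrects agreement for uniform chance", {
  expect_equal(brennan_prediger(rep("a", 6), rep("a", 6), q = 4), 1)
  # P_o at chance level 1/q gives 0
  codes1 <- c("a", "a", "b", "b")
  codes2 <- c("a", "b", "b", "a") # P_o = 0.5 = 1/q for q = 2
  expect_equal(brennan_prediger(codes1, codes2, q = 2), 0)
  # P_o = 0.9, q = 10 -> (0.9 - 0.1)/0.9
  c1 <- rep("a", 10); c2 <- c(rep("a", 9), "b")
  expect_equal(brennan_prediger(c1, c2, q = 10), 0.8 / 0.9)
  expect_error(brennan_prediger(c1, c2, q = 1),
               class = "opitaper_validation_error")
  expect_error(brennan_prediger(letters[1:5], letters[1:5], q = 3),
               "must cover")
})

test_that("kappa_BP approaches raw agreement as q grows", {
  c1 <- sample(letters[1:4], 60, TRUE)
  c2 <- c1; c2[1:6] <- "z"
  po <- percent_agreement(c1, c2)
  expect_equal(brennan_prediger(c1, c2, q = 1000), po, tolerance = 2e-3)
})

test_that("long-format CSV round-trips into a delphi_dataset", {
  spec <- fixture_spec(seed = 2L, n_items = 6L, n_respondents = 5L)
  panel <- make_delphi_panel(spec)
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(panel$ratings, p, row.names = FALSE)
  back <- read_delphi_csv(p)
  expect_equal(back$n_items, panel$n_items)
  expect_equal(back$ratings$rating, panel$ratings$rating)
  bad <- panel$ratings
  bad$rating[1] <- 9L
  expect_error(delphi_dataset(bad), "1..7")
})
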