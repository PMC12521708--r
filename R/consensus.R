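#' Delphi consensus, stability and intercoder agreement statistics
#'
#' Implements the quantitative companion of the deprescribing toolkit: the
#' consensus rule applied to 7-point Likert panels (an item reaches
#' consensus when at least 80% of respondents rate it at or above the
#' agreement cut AND its mean rating is at least 4.5), round-to-round
#' test-retest stability on unchanged items (Pearson on item means, or the
#' two-way single-measure absolute-agreement intraclass correlation
#' ICC(A,1) with its F-based confidence interval; the closing rule requires
#' a coefficient of at least 0.70), simple intercoder percent agreement,
#' and the Brennan-Prediger chance-corrected agreement coefficient.
#'
#' @name consensus_stats
NULL

#' Construct a Delphi dataset from long-format ratings
#'
#' @param ratings Data frame with columns `respondent_id`, `item_id`,
#'   `round` (1 or 2), `rating` (integer 1–7 or `NA`), and `item_changed`
#'   (logical: was the item reworded between rounds?).
#' @return A `delphi_dataset` (validated long data frame plus counts).
#' @export
delphi_dataset <- function(ratings) {
  needed <- c("respondent_id", "item_id", "round", "rating", "item_changed")
  if (!is.data.frame(ratings) || !all(needed %in% names(ratings))) {
    stop_validation(sprintf(
      "ratings must be a data frame with columns: %s",
      paste(needed, collapse = ", ")
    ))
  }
  r <- ratings$rating
  if (any(!is.na(r) & (r < 1 | r > 7 | r != round(r)))) {
    stop_validation("ratings must be integers in 1..7 (or NA)")
  }
  if (!all(ratings$round %in% c(1L, 2L))) {
    stop_validation("round must be 1 or 2")
  }
  changed <- tapply(ratings$item_changed, ratings$item_id,
                    function(x) unique(as.logical(x)))
  if (any(lengths(changed) != 1L)) {
    stop_validation("item_changed must be constant within an item")
  }
  structure(
    list(
      ratings = ratings,
      n_items = length(unique(ratings$item_id)),
      n_respondents = length(unique(ratings$respondent_id)),
      item_changed = vapply(changed, identity, logical(1L))
    ),
    class = "delphi_dataset"
  )
}

#' Read a long-format Delphi ratings CSV
#'
#' Columns: `respondent_id`, `item_id`, `round`, `rating`, `item_changed`.
#'
#' @param path Path to the CSV file.
#' @return A [delphi_dataset].
#' @export
read_delphi_csv <- function(path) {
  if (!file.exists(path)) {
    stop_validation(sprintf("Delphi ratings file not found: '%s'", path))
  }
  delphi_dataset(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Consensus rule for one item
#'
#' An item reaches consensus when the share of non-missing ratings at or
#' above `agree_cut` is at least `prop_threshold` AND the mean rating is at
#' least `mean_threshold`. Missing ratings are excluded from both numerator
#' and denominator (pairwise deletion, never imputation).
#'
#' @param ratings Vector of Likert ratings (1–7, `NA` allowed, at least one
#'   non-missing).
#' @param agree_cut Lowest rating counted as agreement (default 5, the
#'   first clearly-agree point of a 7-point scale).
#' @param prop_threshold Required share of agreeing respondents
#'   (default 0.80).
#' @param mean_threshold Required mean rating (default 4.5, "partially
#'   agree").
#' @return List: `consensus` (logical), `prop_agree`, `mean`.
#' @examples
#' item_consensus(c(7, 7, 7, 7, 4)) # prop 0.8, mean 6.4 -> consensus
#' @export
item_consensus <- function(ratings, agree_cut = 5L, prop_threshold = 0.80,
                           mean_threshold = 4.5) {
  r <- ratings[!is.na(ratings)]
  if (!length(r)) stop_validation("all ratings missing for this item")
  if (any(r < 1 | r > 7)) stop_validation("ratings must lie in 1..7")
  prop <- mean(r >= agree_cut)
  m <- mean(r)
  list(consensus = prop >= prop_threshold && m >= mean_threshold,
       prop_agree = prop, mean = m)
}

#' Consensus rate of a Delphi round
#'
#' Applies [item_consensus()] to every item rated in the given round and
#' reports how many reached consensus.
#'
#' @param dataset A [delphi_dataset].
#' @param round Round number (1 or 2).
#' @param ... Passed to [item_consensus()] (thresholds).
#' @return List: `k_consensus`, `n_items`, `percent` (0–100, one decimal),
#'   `per_item` data frame (`item_id`, `consensus`, `prop_agree`, `mean`).
#' @export
round_consensus_rate <- function(dataset, round, ...) {
  if (!inherits(dataset, "delphi_dataset")) {
    stop_validation("'dataset' must be a delphi_dataset")
  }
  round <- check_count(round, "round", min = 1L)
  df <- dataset$ratings[dataset$ratings$round == round, , drop = FALSE]
  if (!nrow(df)) stop_validation(sprintf("no ratings for round %d", round))
  items <- sort(unique(df$item_id))
  per <- lapply(items, function(it) {
    res <- item_consensus(df$rating[df$item_id == it], ...)
    data.frame(item_id = it, consensus = res$consensus,
               prop_agree = res$prop_agree, mean = res$mean)
  })
  per <- do.call(rbind, per)
  k <- sum(per$consensus)
  list(
    k_consensus = k, n_items = length(items),
    percent = round(100 * k / length(items), 1L),
    per_item = per
  )
}

#' Round-to-round stability of a Delphi panel
#'
#' Computed on unchanged items only (items reworded between rounds carry no
#' test-retest information). Item mean ratings are paired across the two
#' rounds; `"pearson"` correlates them (CI from [stats::cor.test()]),
#' `"icc_a1"` computes the two-way, single-measure, absolute-agreement
#' intraclass correlation from the item x round table of means, with the
#' standard F-distribution confidence interval. The conventional closing
#' rule deems responses stable when the coefficient is at least
#' `stable_threshold`.
#'
#' @param dataset A [delphi_dataset].
#' @param method `"pearson"` or `"icc_a1"`.
#' @param conf_level Confidence level for the interval (default 0.95).
#' @param stable_threshold Stability cut-off (default 0.70).
#' @return List: `coefficient`, `ci_low`, `ci_high`, `method`, `n_items`,
#'   `stable` (logical).
#' @export
test_retest_stability <- function(dataset, method = c("pearson", "icc_a1"),
                                  conf_level = 0.95,
                                  stable_threshold = 0.70) {
  method <- match.arg(method)
  if (!inherits(dataset, "delphi_dataset")) {
    stop_validation("'dataset' must be a delphi_dataset")
  }
  unchanged <- names(dataset$item_changed)[!dataset$item_changed]
  df <- dataset$ratings[dataset$ratings$item_id %in% unchanged, , drop = FALSE]
  m1 <- tapply(df$rating[df$round == 1L], df$item_id[df$round == 1L],
               mean, na.rm = TRUE)
  m2 <- tapply(df$rating[df$round == 2L], df$item_id[df$round == 2L],
               mean, na.rm = TRUE)
  common <- intersect(names(m1), names(m2))
  common <- common[is.finite(m1[common]) & is.finite(m2[common])]
  if (length(common) < 3L) {
    stop_validation("need >= 3 unchanged items rated in both rounds")
  }
  x <- as.numeric(m1[common]); y <- as.numeric(m2[common])
  if (method == "pearson") {
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      side <- if (stats::var(x) == 0) "round 1" else "round 2"
      stop_validation(sprintf("zero variance in %s item means", side))
    }
    r <- stats::cor(x, y)
    if (abs(r) >= 1 - 1e-12) {
      # Fisher z interval degenerates at |r| = 1
      return(list(coefficient = r, ci_low = r, ci_high = r,
                  method = method, n_items = length(common),
                  stable = r >= stable_threshold))
    }
    ct <- stats::cor.test(x, y, conf.level = conf_level)
    list(coefficient = unname(ct$estimate), ci_low = ct$conf.int[1L],
         ci_high = ct$conf.int[2L], method = method,
         n_items = length(common),
         stable = unname(ct$estimate) >= stable_threshold)
  } else {
    res <- icc_a1(cbind(x, y), conf_level = conf_level)
    c(res, list(method = method, n_items = length(common),
                stable = res$coefficient >= stable_threshold))
  }
}

#' Two-way single-measure absolute-agreement ICC, ICC(A,1)
#'
#' Mean-squares form of the two-way model with subjects (rows) and
#' measurements (columns) both crossed: `(MSR - MSE) / (MSR + (k-1) MSE +
#' (k/n)(MSC - MSE))`, with the F-based confidence interval using the
#' Satterthwaite degrees of freedom of the denominator.
#'
#' @param mat Numeric matrix, subjects x measurements (no missing values).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `coefficient`, `ci_low`, `ci_high`.
#' @export
icc_a1 <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop_validation("ICC input must be complete")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3L || k < 2L) {
    stop_validation("ICC needs >= 3 subjects and >= 2 measurements")
  }
  grand <- mean(mat)
  rm_ <- rowMeans(mat); cm <- colMeans(mat)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0) {
    stop_validation("zero variance on both sides: ICC undefined")
  }
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  icc <- (msr - mse) / denom
  if (mse == 0 && msc == 0) {
    # perfect reproduction across measurements
    return(list(coefficient = 1.0, ci_low = 1.0, ci_high = 1.0))
  }
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(coefficient = icc, ci_low = lower, ci_high = upper)
}

#' Intercoder percent agreement
#'
#' @param coder1,coder2 Equal-length categorical vectors: one code per
#'   coding unit and coder.
#' @return Fraction of units with identical codes, in \[0, 1\].
#' @export
percent_agreement <- function(coder1, coder2) {
  if (length(coder1) != length(coder2)) {
    stop_validation("coding vectors must have equal length")
  }
  if (!length(coder1)) stop_validation("need >= 1 coding unit")
  mean(as.character(coder1) == as.character(coder2))
}

#' Brennan-Prediger chance-corrected agreement
#'
#' `kappa_BP = (P_o - 1/q) / (1 - 1/q)` with observed agreement `P_o` and
#' `q` equally likely categories under chance. Ranges from `-1/(q-1)` to 1;
#' approaches `P_o` as `q` grows.
#'
#' @param coder1,coder2 Equal-length categorical coding vectors.
#' @param q Number of available categories (>= 2; at least the number of
#'   observed categories).
#' @return Numeric coefficient.
#' @examples
#' brennan_prediger(rep("a", 9), c(rep("a", 8), "b"), q = 10)
#' @export
brennan_prediger <- function(coder1, coder2, q) {
  q <- check_count(q, "q", min = 2L)
  n_obs <- length(unique(c(as.character(coder1), as.character(coder2))))
  if (n_obs > q) {
    stop_validation(sprintf(
      "observed %d categories but q = %d; q must cover all codes", n_obs, q
    ))
  }
  po <- percent_agreement(coder1, coder2)
  (po - 1 / q) / (1 - 1 / q)
}
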