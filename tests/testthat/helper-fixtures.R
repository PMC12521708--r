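# Shared fixtures: explicit conversion factors so no test depends on the
# shipped formulary's values.

test_formulary <- function() {
  formulary(
    opioid_spec("morphine", 1, data.frame(
      strength_mg = c(10, 30), release = "immediate", units_per_pack = 20L
    )),
    opioid_spec("drug_x", 2.0, data.frame(
      strength_mg = c(5, 10, 20), release = "immediate", units_per_pack = 20L
    )),
    opioid_spec("drug_er", 0.5, data.frame(
      strength_mg = c(10, 25), release = "extended", units_per_pack = 30L
    )),
    version = "test-1"
  )
}

acute_policy <- function(target = 0) taper_policy(0.25, 2L, target_ome = target)
chronic_policy <- function(target = 0) taper_policy(0.10, 3L, target_ome = target)

# Independent brute-force oracle for the formulation mapper: exhaustive
# enumeration of every count vector with <= max_units units via expand.grid.
brute_force_pack <- function(dose_mg, strengths, tolerance,
                             single_strength = FALSE, max_units = 8L) {
  grid <- do.call(expand.grid, rep(list(0:max_units), length(strengths)))
  grid <- grid[rowSums(grid) >= 1 & rowSums(grid) <= max_units, , drop = FALSE]
  if (single_strength) {
    grid <- grid[rowSums(grid > 0) <= 1L, , drop = FALSE]
  }
  totals <- as.numeric(as.matrix(grid) %*% strengths)
  feasible <- abs(totals - dose_mg) <= tolerance * dose_mg
  if (!any(feasible)) return(NULL)
  units <- rowSums(grid)[feasible]
  totals <- totals[feasible]
  min_units <- min(units)
  list(
    min_units = min_units,
    totals_at_min = totals[units == min_units],
    any_under_at_min = any(totals[units == min_units] <= dose_mg)
  )
}

# quick long-format Delphi table builder: ratings[[round]] is an
# items x respondents matrix
make_panel <- function(r1, r2 = r1, changed = rep(FALSE, nrow(r1))) {
  stopifnot(nrow(r1) == nrow(r2))
  long <- function(m, rd) {
    data.frame(
      respondent_id = rep(seq_len(ncol(m)), each = nrow(m)),
      item_id = rep(seq_len(nrow(m)), ncol(m)),
      round = rd,
      rating = as.vector(m),
      item_changed = rep(changed, ncol(m))
    )
  }
  delphi_dataset(rbind(long(r1, 1L), long(r2, 2L)))
}
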