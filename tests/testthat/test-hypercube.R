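# independent check of Latin stratification: the truncated-normal CDF maps
# a proper LHS draw to exactly one sample per equal-probability stratum
stratum_index <- function(x, a, b, n, sd_frac = 0.25) {
  mu <- (a + b) / 2; sd <- sd_frac * (b - a)
  u <- (pnorm(x, mu, sd) - pnorm(a, mu, sd)) /
    (pnorm(b, mu, sd) - pnorm(a, mu, sd))
  ceiling(u * n)
}

test_that("every sample lies inside its parameter range", {
  d <- hypercube_design(n_samples = 50, seed = 3, stage = "full")
  s <- sample_hypercube(d)
  expect_equal(nrow(s), 50L)
  rg <- default_ranges()
  for (nm in names(rg)) {
    expect_true(all(s[[nm]] >= rg[[nm]][1]), info = nm)
    expect_true(all(s[[nm]] <= rg[[nm]][2]), info = nm)
  }
  s1 <- sample_hypercube(hypercube_design(1, seed = 9))
  expect_true(s1$psi_MP >= 0.1 && s1$psi_MP <= 0.3)
})

test_that("the Latin layout places exactly one sample per stratum", {
  n <- 100
  s <- sample_hypercube(hypercube_design(n, seed = 11, stage = "full"))
  for (nm in c("F_T", "F_R", "psi_MP", "R_F_MP", "F_A", "F_B")) {
    r <- default_ranges()[[nm]]
    idx <- stratum_index(s[[nm]], r[1], r[2], n)
    expect_equal(sort(idx), 1:n, info = nm)
  }
  # k_P is stratified across its three sub-ranges, one third each
  strata <- list(c(0, 1), c(1, 100), c(100, 1000))
  counts <- vapply(strata, function(r)
    sum(s$k_P >= r[1] & s$k_P <= r[2]), integer(1))
  expect_equal(sum(counts), n)
  expect_true(all(abs(counts - n / 3) <= 1))
})

test_that("sampling is deterministic given the seed", {
  d <- hypercube_design(40, seed = 123)
  expect_identical(sample_hypercube(d), sample_hypercube(d))
  d2 <- hypercube_design(40, seed = 124)
  expect_false(identical(sample_hypercube(d), sample_hypercube(d2)))
})

test_that("model stages activate the documented parameter subsets", {
  expect_length(configure_stage("no_bio"), 2L)
  expect_length(configure_stage("snow_only"), 5L)
  expect_length(configure_stage("full"), 7L)
  s <- sample_hypercube(hypercube_design(10, seed = 2, stage = "no_bio"))
  expect_true(all(s$F_A == 0) && all(s$psi_MP == 0))
  s2 <- sample_hypercube(hypercube_design(10, seed = 2, stage = "snow_only"))
  expect_true(all(s2$psi_MP == 0))
  expect_true(any(s2$F_A > 0))
})

test_that("the plausibility filter fails unstable runs outright", {
  v <- plausibility_filter(list(stable = FALSE))
  expect_true(all(!v))
  ok <- list(stable = TRUE, F_T = 0.2, total_inventory = 100,
             cum_emission = 500, agg_formation_surface = 10,
             has_minimum = TRUE, has_subsurface_maximum = TRUE)
  v2 <- plausibility_filter(ok, ocean_area_m2 = 3.61e14)
  expect_true(v2[["plausible"]])
  # an ocean-entry fraction far above the ~4 % estimate fails criterion 3
  bad <- ok; bad$F_T <- 0.8
  expect_false(plausibility_filter(bad)[["pollution_rate"]])
  expect_false(plausibility_filter(bad)[["plausible"]])
})

test_that("tightening a threshold never increases the plausible count", {
  members <- lapply(seq(0.01, 0.9, length.out = 20), function(ft)
    list(stable = TRUE, F_T = ft, total_inventory = 100, cum_emission = 500,
         agg_formation_surface = 10, has_minimum = TRUE,
         has_subsurface_maximum = TRUE))
  count <- function(th) sum(vapply(members, function(m)
    plausibility_filter(m, th)[["plausible"]], logical(1)))
  loose <- default_filter_thresholds(F_T_band = c(0, 1))
  mid <- default_filter_thresholds()                       # 0.004-0.4
  tight <- default_filter_thresholds(F_T_band = c(0.02, 0.1))
  expect_gte(count(loose), count(mid))
  expect_gte(count(mid), count(tight))
})

test_that("a tiny ensemble runs, is seed-reproducible, and respects stages", {
  d <- hypercube_design(3, seed = 5, stage = "no_bio")
  base <- small_config(years = c(1950, 1952), spinup_years = 1)
  tab <- run_ensemble(d, base)
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$stable))
  tab2 <- run_ensemble(d, base)
  expect_identical(tab$total_inventory, tab2$total_inventory)
  # without the biological pathway no plastic leaves the free pool except
  # by rising, so uptake diagnostics are exactly zero
  expect_true(all(tab$agg_formation_surface > 0))  # snow still forms
  expect_true(all(is.na(tab$uptake_export_ratio)))  # nothing bound exports
})
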