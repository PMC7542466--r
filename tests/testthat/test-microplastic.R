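test_that("mass-particle conversion matches the bulk calibration", {
  expect_equal(mass_to_particles(236e3), 51.2e12)
  expect_equal(mass_to_particles(0), 0)
  # single-particle mass: 236e9 g / 51.2e12 particles = 4.609375e-3 g
  expect_equal(particles_to_mass(1) * 1e6, 4.609375e-3)
  # round trip is the identity
  m <- c(0, 1, 236e3, 5.5e8)
  expect_equal(particles_to_mass(mass_to_particles(m)), m)
  expect_error(mass_to_particles(-1), "non-negative")
})

test_that("aggregate formation converts Redfield nitrogen to aggregate counts", {
  # 1 mmol N -> 6.625 mmol C -> 6.625 * 12011 ug C / 8.8 ug per aggregate
  expect_equal(aggregate_count(1), 6.625 * 12011 / 8.8)
  expect_equal(aggregate_count(0), 0)
  x <- c(0.2, 1.7)
  expect_equal(aggregate_count(2 * x), 2 * aggregate_count(x))
  expect_error(aggregate_count(-1), ">= 0")
})

test_that("aggregation uptake saturates like a Monod function", {
  p <- mp_parameters(F_A = 0.003, k_P = 0.424)
  # at MP = k_P the uptake sits at half its saturated value
  expect_equal(aggregation_uptake(p$k_P, 1, p),
               0.5 * aggregate_count(1) * p$F_A)
  expect_equal(aggregation_uptake(0, 1, p), 0)
  # published low-uptake sample: MP=1, k_P=0.424, F_A=0.003, 1 mmol N
  expect_equal(aggregation_uptake(1, 1, p),
               (1 / 1.424) * aggregate_count(1) * 0.003, tolerance = 1e-12)
  expect_equal(round(aggregation_uptake(1, 1, p), 2), 19.05)
  # k_P = 0 with no plastic returns 0 (limit convention), 0/0 avoided
  p0 <- mp_parameters(F_A = 0.5, k_P = 0)
  expect_equal(aggregation_uptake(0, 1, p0), 0)
  # nondecreasing in MP and bounded by the saturated rate
  mp_seq <- seq(0, 50, by = 0.5)
  up <- aggregation_uptake(mp_seq, 1, p)
  expect_true(all(diff(up) >= 0))
  expect_true(all(up <= aggregate_count(1) * p$F_A))
})

test_that("release from aggregates and pellets is linear at the remin rate", {
  expect_equal(aggregate_release(0, 0.3), 0)
  expect_equal(aggregate_release(50, 0.1), 5)
  expect_equal(pellet_release(0, 0.3), 0)
  expect_equal(pellet_release(10, 0.2), 2)
  # identical rate constant for both bound pools at equal temperature
  mu <- remin_rate(17)
  expect_equal(aggregate_release(7, mu), pellet_release(7, mu))
  # warmer water releases more from the same bound stock
  expect_gt(aggregate_release(5, remin_rate(28)),
            aggregate_release(5, remin_rate(5)))
})

test_that("plastic grazing vanishes without preference or grazers", {
  g <- small_grid()
  st <- busy_state(g)
  p <- fixture_parameters("test_med")
  gz0 <- mp_grazing(st$MP, st, renormalise_preferences(0), 25, p)
  expect_equal(gz0$P_upt, rep(0, g$n_layers))
  st_noz <- tracer_state(g, N = 5, PH = 0.4, CO = 0.3, DZ = 0.05, Z = 0,
                         DET_A = 0.2, DET_Z = 0.1, MP = 10)
  gzz <- mp_grazing(st_noz$MP, st_noz, renormalise_preferences(0.2), 25, p)
  expect_equal(gzz$P_upt, rep(0, g$n_layers))
})

test_that("plastic grazing at half saturation matches the Holling algebra", {
  g <- column_grid(100)
  p <- fixture_parameters("test_med")
  eco <- eco_parameters()
  mp_half <- nitrogen_to_mp(eco$k_Z, p)  # plastic worth k_Z in N currency
  st <- tracer_state(g, N = 1, PH = 0, CO = 0, DZ = 0, Z = 0.4,
                     DET_A = 0, DET_Z = 0, MP = mp_half)
  prefs <- list(psi_CO = 0, psi_PH = 0, psi_DZ = 0, psi_Detr = 0,
                psi_Z = 0, psi_MP = 1)
  gz <- mp_grazing(st$MP, st, prefs, 18, p, eco)
  expect_equal(gz$G_MP_N, max_growth(18, eco) * 0.4 / 2, tolerance = 1e-12)
  expect_equal(gz$P_upt, nitrogen_to_mp(gz$G_MP_N, p), tolerance = 1e-12)
})

test_that("compartment tendencies sum to the emission (local conservation)", {
  g <- small_grid()
  st <- busy_state(g)
  eco <- eco_parameters()
  p <- fixture_parameters("test_med")
  mu <- remin_rate(rep(24, 6), eco)
  fl <- list(A_upt = aggregation_uptake(st$MP, rep(0.05, 6), p),
             A_rel = aggregate_release(st$MP_A, mu),
             P_upt = mp_grazing(st$MP, st, renormalise_preferences(0.193),
                                24, p, eco)$P_upt,
             P_rel = pellet_release(st$MP_Z, mu))
  emis <- c(3, rep(0, 5))
  td <- mp_tendencies(fl, emis)
  expect_equal(td$dMP + td$dMP_A + td$dMP_Z, emis, tolerance = 1e-12)
  # no biology, no emission: nothing moves
  fl0 <- lapply(fl, function(x) x * 0)
  td0 <- mp_tendencies(fl0, 0)
  expect_equal(td0$dMP, rep(0, 6))
  expect_equal(td0$dMP_A, rep(0, 6))
  # F_A = 0 and psi_MP = 0: pure passive tracer, tendency = emission only
  p_off <- mp_parameters(F_T = 0.3, F_A = 0, psi_MP = 0)
  fl_off <- list(A_upt = aggregation_uptake(st$MP, rep(0.05, 6), p_off),
                 A_rel = aggregate_release(rep(0, 6), mu),
                 P_upt = mp_grazing(st$MP, st, renormalise_preferences(0),
                                    24, p_off, eco)$P_upt,
                 P_rel = pellet_release(rep(0, 6), mu))
  td_off <- mp_tendencies(fl_off, emis)
  expect_equal(td_off$dMP, emis)
  expect_error(mp_tendencies(fl, emis[1:3]), "layer count")
})
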