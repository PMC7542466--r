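test_that("upwind sinking fluxes follow concentration times speed", {
  g <- small_grid()
  expect_equal(sinking_flux(rep(0, 6), rep(10, 6), g), rep(0, 6))
  expect_equal(sinking_flux(rep(2, 6), rep(10, 6), g), rep(20, 6))
  w <- 7 + 0.04 * g$mid_depth
  conc <- c(5, 4, 3, 2, 1, 0.5)
  expect_equal(sinking_flux(conc, w, g), w * conc)
  expect_error(sinking_flux(conc, -w, g), ">= 0")
})

test_that("the CFL guard names the offending layer", {
  g <- small_grid()
  tc <- transport_config(w_D0 = 7, m_w = 0.04)
  w <- mpsink:::sinking_speed(g, tc)
  expect_silent(mpsink:::check_cfl(w, g, 0.5))
  err <- tryCatch(mpsink:::check_cfl(w, g, 40), error = conditionMessage)
  expect_match(err, "CFL violation in layer")
})

test_that("rise transport moves only the buoyant fraction, never off the top", {
  g <- small_grid()
  mp <- c(1, 5, 3, 2, 1, 0.5)
  expect_equal(rise_flux(mp, 0, 1641.6, g), rep(0, 6))
  up <- rise_flux(mp, 0.074, 1641.6, g)
  expect_equal(up[1], 0)                      # no flux through the surface
  expect_equal(up[2], 0.074 * 1641.6 * mp[2]) # interface below the surface
  # sub-cycled update conserves particles and never drains the surface layer
  st <- mp
  p <- fixture_parameters("test_hi")
  for (i in 1:50) {
    st_new <- mpsink:::apply_rise(st, p$F_R, p$w_p_ms * 86400, g, 0.5)
    expect_gte(st_new[1], st[1])
    expect_equal(column_integral(st_new, g), column_integral(mp, g),
                 tolerance = 1e-9)
    expect_true(all(st_new >= -1e-12))
    st <- st_new
  }
})

test_that("seafloor exchange splits the bottom flux by F_B", {
  ex <- seafloor_exchange(60, 40, 0.888)
  expect_equal(ex$returned, 88.8)
  expect_equal(ex$lost, 11.2)
  expect_equal(seafloor_exchange(10, 5, 1)$lost, 0)
  expect_equal(seafloor_exchange(10, 5, 0)$returned, 0)
  expect_error(seafloor_exchange(-1, 0, 0.5), ">= 0")
  expect_error(seafloor_exchange(1, 0, 1.5), "0, 1")
})

test_that("a no-pathway configuration keeps plastic in the surface layer", {
  # F_A = 0, psi_MP = 0, F_R = 0 and no mixing: no vertical pathway exists
  g <- small_grid()
  p <- mp_parameters(F_T = 0.26, F_R = 0, F_A = 0, psi_MP = 0)
  st <- tracer_state(g, N = 5, PH = 0.3, CO = 0.2, DZ = 0.05, Z = 0.2)
  tc <- transport_config(kappa_bg_m2s = 0, kappa_ml_m2s = 0)
  for (i in 1:100)
    st <- step_column(st, g, rep(25, 6), 0.5, p, tcfg = tc,
                      emission = 2)$state
  expect_true(all(st$MP[-1] == 0))
  expect_equal(st$MP_A, rep(0, 6))
  expect_equal(st$MP_Z, rep(0, 6))
  expect_equal(st$MP[1], 2 * 0.5 * 100)
})

test_that("a closed column conserves particles over many steps", {
  # no emission, F_B = 1: the total particle stock is invariant
  g <- small_grid()
  p <- mp_parameters(F_T = 0.2, F_R = 0.05, F_A = 0.1, k_P = 10,
                     F_B = 1, psi_MP = 0.2, R_F_MP = 1)
  st <- busy_state(g)
  tot0 <- column_integral(st$MP + st$MP_A + st$MP_Z, g)
  n0 <- column_integral(st$N + st$PH + st$CO + st$DZ + st$Z +
                          st$DET_A + st$DET_Z, g)
  for (i in 1:2000)
    st <- step_column(st, g, rep(24, 6), 0.5, p, emission = 0)$state
  expect_equal(column_integral(st$MP + st$MP_A + st$MP_Z, g), tot0,
               tolerance = 1e-9)
  expect_equal(column_integral(st$N + st$PH + st$CO + st$DZ + st$Z +
                                 st$DET_A + st$DET_Z, g), n0,
               tolerance = 1e-9)
  expect_true(all(unlist(st) >= 0))
})

test_that("upwind transport creates no new extrema without sources", {
  g <- small_grid()
  tc <- transport_config()
  w <- mpsink:::sinking_speed(g, tc)
  conc <- c(0, 10, 0, 5, 0, 1)
  for (i in 1:200) {
    out <- mpsink:::apply_sinking(conc, w, g, 0.5)
    expect_lte(max(out$conc), max(conc) + 1e-12)
    expect_gte(min(out$conc), 0 - 1e-12)
    conc <- out$conc
  }
})
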