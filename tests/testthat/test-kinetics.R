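final_state <- function(traj) traj$states[nrow(traj$states), ]

test_that("production-rate calibration follows the steady-state balance", {
  expect_equal(calibrate_production_rate(1e-6, 24 * 3600),
               1e-6 * log(2) / 86400)
  expect_equal(calibrate_production_rate(1e-6, 24 * 3600), 8.0225e-12,
               tolerance = 1e-4)
  expect_equal(calibrate_production_rate(0, 24 * 3600), 0)
  # rate is inversely proportional to the half-life
  expect_equal(calibrate_production_rate(1e-6, 48 * 3600),
               calibrate_production_rate(1e-6, 24 * 3600) / 2)
  expect_error(calibrate_production_rate(1e-6, 0), "positive")
  expect_error(calibrate_production_rate(1e-6, -5), "positive")
})

test_that("derivatives match an independent transcription of the rate laws", {
  p <- kinetic_params(t_half = 17 * 3600, M_A0 = 1e-9)
  st <- c(M_A = 1e-9, M_B = 1e-9, P = 1e-6, MP = 0)
  d <- trap_derivatives(st, p)
  o <- oracle_derivatives(1e-9, 1e-9, 1e-6, 0,
                          k_diff = 1e3, k_bind = 8.7e5, k_unbind = 1e-6,
                          t_half = 17 * 3600, r_prod = p$r_prod)
  expect_equal(unname(d[c("M_A", "M_B", "P", "MP")]),
               unname(o[c("dM_A", "dM_B", "dP", "dMP")]))
  # the extracellular reservoir never changes
  for (mb in c(0, 1e-10, 1e-8)) {
    st2 <- c(M_A = 3e-10, M_B = mb, P = 5e-7, MP = 2e-8)
    expect_identical(trap_derivatives(st2, p)[["M_A"]], 0)
  }
  # all-zero state with no production is a fixed point
  p0 <- kinetic_params(t_half = 3600, M_A0 = 0, P0 = 0, r_prod = 0)
  expect_equal(unname(trap_derivatives(
    c(M_A = 0, M_B = 0, P = 0, MP = 0), p0)), rep(0, 4))
})

test_that("simulation limits behave: no compound, and no binding", {
  # no compound: protein relaxes to production/degradation balance
  p <- kinetic_params(t_half = 17 * 3600, M_A0 = 0)
  fin <- final_state(simulate_trapping(p))
  expect_equal(fin$M_B, 0, tolerance = 1e-12)
  expect_equal(fin$MP, 0, tolerance = 1e-12)
  expect_equal(fin$P, p$r_prod * p$t_half / log(2), tolerance = 1e-6)
  # half-life at the reference: protein returns to the reference level
  pref <- kinetic_params(t_half = 24 * 3600, M_A0 = 0)
  expect_equal(final_state(simulate_trapping(pref))$P, 1e-6,
               tolerance = 1e-6)
  # no binding: diffusion equilibrium only, fold ~ 1
  pnb <- kinetic_params(t_half = 17 * 3600, M_A0 = 1e-9, k_bind = 0)
  traj <- simulate_trapping(pnb)
  fin <- final_state(traj)
  expect_equal(fin$M_B, 1e-9, tolerance = 1e-6)
  expect_equal(fin$MP, 0, tolerance = 1e-12)
  expect_equal(accumulation_fold(traj), 1, tolerance = 1e-6)
})

test_that("trajectory container honors its contract", {
  p <- kinetic_params(t_half = 3600, M_A0 = 1e-10)
  traj <- simulate_trapping(p, n_out = 50)
  expect_length(traj$times, 50L)
  expect_true(all(diff(traj$times) > 0))
  expect_equal(unname(unlist(traj$states[1L, ])),
               c(1e-10, 0, 1e-6, 0)) # initial state first
  expect_true(all(traj$states$M_A == 1e-10)) # reservoir constant
  expect_true(all(as.matrix(traj$states) >= 0)) # non-negativity
})

test_that("closed-form steady state solves the algebraic system", {
  p <- kinetic_params(t_half = 17 * 3600, M_A0 = 1e-10)
  ss <- steady_state_closed_form(p)
  lambda <- log(2) / p$t_half
  # residual derivatives vanish
  expect_lt(max(abs(trap_derivatives(ss, p))), 1e-9 * p$r_prod)
  # total protein pool balances production against degradation
  expect_equal(ss[["P"]] + ss[["MP"]], p$r_prod / lambda, tolerance = 1e-12)
  # degenerate limits
  p0 <- kinetic_params(t_half = 17 * 3600, M_A0 = 0)
  expect_equal(unname(steady_state_closed_form(p0)),
               c(0, 0, p0$r_prod * p0$t_half / log(2), 0))
  pnb <- kinetic_params(t_half = 17 * 3600, M_A0 = 2e-9, k_bind = 0)
  ssnb <- steady_state_closed_form(pnb)
  expect_equal(ssnb[["M_B"]], 2e-9)
  expect_equal(ssnb[["MP"]], 0)
  # infinite half-life demands zero production
  expect_error(kinetic_params(t_half = Inf, M_A0 = 1e-10), "r_prod")
  pinf <- kinetic_params(t_half = Inf, M_A0 = 1e-10, r_prod = 0, P0 = 1e-6)
  ssinf <- steady_state_closed_form(pinf)
  expect_equal(ssinf[["P"]] + ssinf[["MP"]], 1e-6, tolerance = 1e-12)
  expect_lt(max(abs(trap_derivatives(ssinf, pinf))), 1e-22)
})

test_that("numeric endpoint agrees with the closed form across parameters", {
  # both routes to the steady state must coincide per component
  for (th in c(16 * 60, 3600, 17 * 3600)) {
    for (dose in c(1e-10, 1e-8)) {
      p <- kinetic_params(t_half = th, M_A0 = dose)
      fin <- final_state(simulate_trapping(p))
      ss <- steady_state_closed_form(p)
      for (comp in c("M_B", "P", "MP")) {
        expect_lt(abs(fin[[comp]] - ss[[comp]]) / ss[[comp]], 1e-3)
      }
    }
  }
})

test_that("accumulation fold is trapping-driven and guards its domain", {
  p_long <- kinetic_params(t_half = 17 * 3600, M_A0 = 1e-10)
  p_short <- kinetic_params(t_half = 16 * 60, M_A0 = 1e-10)
  f_long <- accumulation_fold(simulate_trapping(p_long))
  f_short <- accumulation_fold(simulate_trapping(p_short))
  expect_gt(f_long, f_short) # longer half-life traps more
  ss <- steady_state_closed_form(p_long)
  expect_equal(f_long, (ss[["M_B"]] + ss[["MP"]]) / ss[["M_A"]],
               tolerance = 1e-3)
  p0 <- kinetic_params(t_half = 3600, M_A0 = 0)
  expect_error(accumulation_fold(simulate_trapping(p0)), "undefined")
})

test_that("half-life by dose sweep is monotone and matches single runs", {
  p <- kinetic_params()
  half_lives <- c(16 * 60, 3600, 17 * 3600)
  doses <- c(1e-11, 1e-9, 1e-7)
  sw <- sweep_halflife_dose(p, half_lives, doses, n_out = 60)
  expect_equal(dim(sw$intracellular_final), c(3L, 3L))
  expect_true(all(sw$intracellular_final >= 0))
  # non-decreasing in t_half at fixed dose, and in dose at fixed t_half
  expect_true(all(apply(sw$intracellular_final, 2L, diff) >= 0))
  expect_true(all(apply(sw$intracellular_final, 1L, diff) >= 0))
  # a 1x1 sweep equals the plain simulation
  p1 <- kinetic_params(t_half = 3600, M_A0 = 1e-9)
  fin <- final_state(simulate_trapping(p1, n_out = 60))
  sw1 <- sweep_halflife_dose(p, 3600, 1e-9, n_out = 60)
  expect_equal(sw1$intracellular_final[1L, 1L], fin$M_B + fin$MP)
  # long format mirrors the matrices
  df <- as.data.frame(sw)
  expect_equal(nrow(df), 9L)
  expect_equal(df$intracellular, as.vector(sw$intracellular_final))
})
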