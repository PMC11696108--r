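test_that("elongation rate saturates in the translation precursor", {
  cp <- hf_params()
  expect_equal(elongation_rate(0, cp), 0)
  expect_equal(elongation_rate(1e12, cp), cp$gamma_max, tolerance = 1e-6)
  # half-saturation point of the Michaelis-Menten form
  expect_equal(elongation_rate(cp$K_gamma, cp), cp$gamma_max / 2)
  # monotone non-decreasing
  e <- seq(0, 100, length.out = 50)
  expect_true(all(diff(elongation_rate(e, cp)) >= 0))
  expect_error(elongation_rate(-1, cp), "e must be")
})

test_that("growth rate is global translation over cell mass", {
  cp <- hf_params()
  st <- cell_state()
  expect_equal(growth_rate(st, cp), 0)   # no translating ribosomes
  st <- cell_state(c(e = 1e9, c_T = 100, c_R = 400))
  # saturated elongation: lambda = gamma_max * sum(c) / M0
  expect_equal(growth_rate(st, cp), cp$gamma_max * 500 / cp$M0,
               tolerance = 1e-6)
  # hand-evaluated at e = K_gamma: gamma = 630 aa/min, sum c = 250
  st <- cell_state(c(e = 7, c_E = 250))
  expect_equal(growth_rate(st, cp), 630 * 250 / 1e8)
})

test_that("product export is the sum of two saturating transporter routes", {
  cp <- hf_params()
  st <- cell_state(c(p_Tp = 50, p_X = 1000))
  expect_equal(unname(product_export_rate(st, cp)["r_Tp"]), 0)  # p_i = 0
  st <- cell_state(c(p_i = 500, p_X = 1000))                    # Tp = 0
  r <- product_export_rate(st, cp)
  expect_equal(unname(r["v_Tp"]), 0)
  expect_equal(unname(r["r_Tp"]), unname(r["v_export"]))
  # hand-evaluated sum of the two MM terms
  st <- cell_state(c(p_i = 1000, p_Tp = 10, p_X = 100))
  v_Tp <- 726 * 10 * 1000 / (1000 + 1000)
  v_X <- 0.01 * 100 * 1000 / (1000 + 1000)
  r <- product_export_rate(st, cp)
  expect_equal(unname(r["r_Tp"]), v_Tp + v_X)
})

test_that("cell ODEs close at the zero state and are linear in transcription", {
  cp <- hf_params()
  d <- hf_design()
  dy0 <- cell_odes(0, cell_state(), cp, d, S_ext = 0)
  expect_true(all(dy0 == 0))   # nothing moves from nothing
  # doubling sTX_Ep doubles only the Ep transcription term
  st <- cell_state(c(e = 50, s_i = 200, p_R = 500, m_Ep = 3, p_E = 1000,
                     p_T = 1000))
  d1 <- hf_design(Ep = 0.4)
  d2 <- hf_design(Ep = 0.8)
  dy1 <- cell_odes(0, st, cp, d1, S_ext = 1e12)
  dy2 <- cell_odes(0, st, cp, d2, S_ext = 1e12)
  tx1 <- 0.4 * cp$w[["Ep"]] * 50 / (cp$theta[["Ep"]] + 50)
  expect_equal(dy2[["m_Ep"]] - dy1[["m_Ep"]], tx1, tolerance = 1e-10)
  same <- setdiff(names(dy1), "m_Ep")
  expect_equal(dy1[same], dy2[same])
})

test_that("proteome mass production balances dilution at the growth law", {
  # d(mass)/dt contributed by translation is gamma * sum(c); dilution removes
  # lambda * mass; at mass = M0 these cancel by construction of lambda
  cp <- hf_params()
  st <- cell_state(c(e = 30, c_T = 100, c_E = 100, c_R = 50,
                     p_T = 1e4, p_E = 1e4, p_R = 500))
  gam <- elongation_rate(30, cp)
  lam <- growth_rate(st, cp)
  expect_equal(lam, gam * 250 / cp$M0)
  expect_equal(gam * 250 - lam * cp$M0, 0)
})

test_that("compiled and reference right-hand sides integrate identically", {
  cp <- hf_params()
  d <- hf_dual_design(tau = 0)
  y0 <- cell_state(c(stats::setNames(rep(1e3, 7), paste0("p_", c("T", "E",
    "Ep", "Tp", "TF", "X", "R"))), s_i = 1e3, e = 1e3, i_i = 50))
  times <- seq(0, 60, by = 10)
  ref_rhs <- function(t, y, parms) {
    names(y) <- names(y0)
    list(as.numeric(cell_odes(t, pmax(y, 0), cp, d,
                              S_ext = 1e12, I_ext = 1e9)))
  }
  sol_r <- deSolve::lsoda(y0, times, ref_rhs, parms = NULL,
                          rtol = 1e-9, atol = 1e-8)
  parms <- hostfactory:::.pack_parms(cp, d, mode = "cell",
                                     S_clamp = 1e12, I_clamp = 1e9)
  sol_c <- deSolve::lsoda(y0, times, func = "derivs_cellbatch",
                          parms = parms, dllname = "hostfactory",
                          initfunc = "init_cellbatch",
                          rtol = 1e-9, atol = 1e-8)
  for (nm in names(y0))
    expect_equal(sol_c[, nm], unname(sol_r[, nm]), tolerance = 1e-5,
                 label = paste("state", nm))
})

test_that("half-life conversion is the log(2) identity", {
  expect_equal(half_life_to_decay_rate(log(2)), 1)
  expect_equal(half_life_to_decay_rate(200) * 200, log(2))
  expect_error(half_life_to_decay_rate(0))
  expect_error(half_life_to_decay_rate(-5))
})
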