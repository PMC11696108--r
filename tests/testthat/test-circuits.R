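test_that("topology enumeration matches the product of allowed sets", {
  expect_equal(nrow(enumerate_topologies(topology_constraint("5.1"))), 8)
  expect_equal(nrow(enumerate_topologies(topology_constraint("precursor24"))),
               24)
  expect_equal(nrow(enumerate_topologies(topology_constraint("5.2"))), 24)
  expect_equal(nrow(enumerate_topologies(topology_constraint("5.3"))), 24)
  # singletons collapse to one topology
  single <- list(T = 0, E = 1, Ep = -1, Tp = 0, TF = 0)
  expect_equal(nrow(enumerate_topologies(single)), 1)
  # brute-force product oracle, with duplicates in the allowed sets
  allowed <- list(T = c(0, 0), E = c(-1, 0, 1), Ep = c(-1, 1),
                  Tp = 0, TF = c(0, 1))
  tb <- enumerate_topologies(allowed)
  expect_equal(nrow(tb), 1 * 3 * 2 * 1 * 2)
  expect_equal(nrow(unique(tb[paste0("g_", c("T", "E", "Ep", "Tp", "TF"))])),
               nrow(tb))
  expect_error(enumerate_topologies(list(T = numeric(0), E = 0, Ep = 0,
                                         Tp = 0, TF = 0)), "empty")
})

test_that("TF is active when inducer-free and deactivated by inducer", {
  cp <- hf_params()
  expect_equal(tf_activity(1000, 0, cp), 1000)
  expect_lt(tf_activity(1000, 1e9, cp), 1e-3)
  expect_equal(tf_activity(1000, cp$K_ind_tf, cp), 500)
  expect_error(tf_activity(-1, 0, cp))
})

test_that("regulated transcription follows the topology sign", {
  cp <- hf_params()
  base <- function(gene, d) d$sTX[[gene]] * cp$w[[gene]]
  d0 <- hf_dual_design()
  # uncontrolled gene: flat in TF
  expect_equal(regulated_transcription("T", d0, 0, cp),
               regulated_transcription("T", d0, 1e6, cp))
  # activation: increasing in active TF, midpoint at TF = 1/K
  d <- hf_dual_design(K_E = 0.01)
  tf <- c(0, 10, 100, 1e3, 1e5)
  act <- vapply(tf, function(x) regulated_transcription("E", d, x, cp),
                numeric(1))
  expect_true(all(diff(act) > 0))
  mid <- regulated_transcription("E", d, 1 / 0.01, cp)
  lk <- cp$leak
  expect_equal(mid, base("E", d) * (lk + (1 - lk) * 0.5))
  # repression: decreasing, floor at the basal leak
  rep_ <- vapply(tf, function(x) regulated_transcription("Ep", d, x, cp),
                 numeric(1))
  expect_true(all(diff(rep_) < 0))
  expect_equal(regulated_transcription("Ep", d, 1e12, cp),
               base("Ep", d) * lk, tolerance = 1e-6)
})

test_that("the conditional control-strength constraint is structural", {
  # K must be zero exactly where g is zero
  expect_error(circuit_design(circuit_topology(),   # all g = 0
                              K = c(T = 0, E = 0.5, Ep = 0, Tp = 0, TF = 0)),
               "K must be 0")
  expect_error(circuit_design(circuit_topology(g_E = 1),
                              K = c(T = 0, E = 2, Ep = 0, Tp = 0, TF = 0)),
               "K must lie in")
  expect_error(circuit_design(circuit_topology(g_E = 1),
                              K = c(T = 0, E = 1e-9, Ep = 0, Tp = 0, TF = 0)),
               "K must lie in")
  d <- circuit_design(circuit_topology(g_E = 1),
                      K = c(T = 0, E = 0.5, Ep = 0, Tp = 0, TF = 0))
  expect_s3_class(validate_circuit_design(d), "circuit_design")
  expect_error(circuit_design(tau = -1), "tau")
  expect_error(circuit_design(tau = 24 * 60 + 1), "tau")
})

test_that("induction schedule is a bolus step at tau", {
  opts <- batch_options()
  d <- hf_dual_design(tau = 300)
  sched <- induction_schedule(d, opts)
  expect_equal(sched(299), 0)
  expect_equal(sched(300), opts$inducer_dose)
  expect_equal(sched(1000), opts$inducer_dose)
  bad <- hf_dual_design(tau = 1400)
  expect_error(induction_schedule(bad, batch_options(t_max = 600)), "tau")
})

test_that("a saturating dose fully deactivates the TF soon after induction", {
  cp <- hf_params()
  d <- hf_dual_design(tau = 150)
  b <- simulate_batch(cp, d, batch_options())
  tr <- b$trajectory
  pre <- tr[tr$time < 150, ]
  post <- tr[tr$time > 200, ]
  expect_true(all(pre$tf_active > 0.9 * pre$p_TF))
  expect_true(all(post$tf_active < 0.02 * post$p_TF))
})
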