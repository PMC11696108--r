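test_that("metrics are the defining ratios and satisfy their identity", {
  # arithmetic of the definitions on a synthetic result
  fake <- structure(list(titre = 12, t_end = 600, exhausted = TRUE,
                         options = batch_options(S0 = 100)),
                    class = "batch_result")
  m <- production_metrics(fake)
  expect_equal(m$vP, 0.02)
  expect_equal(m$pY, 0.12)
  expect_equal(m$vP * m$t_end, m$pY * 100)
})

test_that("batch simulation conserves bookkeeping and stays non-negative", {
  cp <- hf_params()
  b <- simulate_batch(cp, hf_design(0.2, 1, 1), batch_options())
  tr <- b$trajectory
  state_cols <- setdiff(names(tr), "time")
  expect_true(all(as.matrix(tr[state_cols]) > -1e-6))
  expect_true(all(diff(tr$S_x) <= 1e-6))            # substrate never rises
  expect_true(all(diff(tr$P_x) >= -1e-6))           # product never falls
  expect_true(all(diff(tr$B) >= -1e-8))             # no decay, no shrinkage
  # metrics identity to machine precision
  expect_equal(b$vP * b$t_end, b$pY * b$options$S0, tolerance = 1e-12)
  # event accuracy at exhaustion
  expect_true(b$exhausted)
  expect_equal(tr$S_x[nrow(tr)], b$options$eps_S, tolerance = 1e-4)
  # substrate consumed bounds exported product (1 substrate >= 1 product)
  consumed <- b$options$S0 - tr$S_x
  expect_true(all(consumed + 1e-3 * b$options$S0 * 1e-6 >= tr$P_x * 0.999))
})

test_that("without substrate uptake nothing happens", {
  cp <- hf_params()
  cp$kcat[["T"]] <- 1e-9
  b <- suppressMessages(
    simulate_batch(cp, hf_design(1, 0.5, 0.5), batch_options(t_max = 400)))
  expect_false(b$exhausted)
  expect_equal(b$trajectory$S_x[1], b$trajectory$S_x[nrow(b$trajectory)],
               tolerance = 1e-6)
  expect_lt(b$vP, 1)
})

test_that("early-phase biomass growth matches the clamped steady state", {
  cp <- hf_params()
  d <- hf_design(1, 0.2, 0.5)
  st <- exponential_steady_state(cp, d, S_ext = 1e12)
  lam <- attr(st, "rates")[["lambda"]]
  b <- simulate_batch(cp, d, batch_options())
  tr <- b$trajectory
  early <- tr[tr$time <= 100, ]
  expect_equal(early$B, 1 * exp(lam * early$time), tolerance = 1e-3)
})

test_that("titre equals the integral of export flux times biomass", {
  cp <- hf_params()
  b <- simulate_batch(cp, hf_design(0.3, 0.8, 0.8),
                      batch_options(n_out = 401))
  tr <- b$trajectory
  flux <- (tr$v_Tp + tr$v_export) * tr$B
  # trapezoidal quadrature over the returned trajectory
  quad <- sum(diff(tr$time) * (utils::head(flux, -1) + utils::tail(flux, -1)) / 2)
  expect_equal(quad, b$titre, tolerance = 5e-3)
})

test_that("one-stage productivity is single-peaked along the host-enzyme dial", {
  cp <- hf_params()
  grid <- c(0.02, 0.05, 0.15, 0.4, 1)
  vP <- vapply(grid, function(sE) {
    suppressMessages(simulate_batch(cp, hf_design(sE, 1, 1),
                                    batch_options(n_out = 2)))$vP
  }, numeric(1))
  peak <- which.max(vP)
  expect_gt(peak, 1)            # an interior optimum: too little E starves
  expect_lt(peak, length(grid)) # too much E overgrows
  expect_true(all(diff(vP[seq_len(peak)]) >= 0))
  expect_true(all(diff(vP[peak:length(vP)]) <= 0))
})

test_that("tidy/glance/autoplot work on batch results", {
  cp <- hf_params()
  b <- simulate_batch(cp, hf_design(0.2, 1, 1), batch_options(n_out = 41))
  td <- tidy(b)
  expect_true(all(c("time", "variable", "value") %in% names(td)))
  g <- glance(b)
  expect_equal(nrow(g), 1)
  expect_true(g$exhausted)
  p <- autoplot(b)
  expect_s3_class(p, "ggplot")
})
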