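test_that("pareto filter equals the pairwise-comparison oracle", {
  expect_equal(nrow(pareto_filter(tibble::tibble(a = numeric(0),
                                                 b = numeric(0)))), 0)
  pts <- tibble::tibble(a = 1, b = 1)
  expect_equal(pareto_filter(pts), pts)
  pts <- tibble::tibble(a = c(1, 0.5), b = c(1, 0.5))
  expect_equal(pareto_filter(pts), pts[1, ])

  set.seed(42)
  for (rep in 1:3) {
    n <- 200
    f1 <- round(stats::runif(n), 2)   # rounding forces plenty of ties
    f2 <- round(stats::runif(n), 2)
    pts <- tibble::tibble(f1 = f1, f2 = f2)
    got <- pareto_filter(pts)
    want <- pts[oracle_nondominated(f1, f2), ]
    expect_equal(dplyr::arrange(got, f1, f2), dplyr::arrange(want, f1, f2))
  }
  # duplicates of a nondominated point are all kept
  pts <- tibble::tibble(f1 = c(1, 1, 0.2), f2 = c(2, 2, 0.1))
  expect_equal(nrow(pareto_filter(pts)), 2)
})

test_that("hypervolume matches a rectangle-decomposition oracle", {
  pts <- tibble::tibble(f1 = c(1, 0.5), f2 = c(0.5, 1))
  # union of two rectangles: 1*0.5 + 0.5*0.5
  expect_equal(hypervolume(pts), 0.75)
  expect_equal(hypervolume(pts[0, ]), 0)
  # dominated points do not change the dominated area
  pts2 <- dplyr::bind_rows(pts, tibble::tibble(f1 = 0.4, f2 = 0.4))
  expect_equal(hypervolume(pts2), 0.75)
  # reference point shifts: (0.75 x 0.25) plus the extra (0.25 x 0.5) strip
  expect_equal(hypervolume(pts, ref = c(0.25, 0.25)), 0.3125)
  # at ref = (0.5, 0.5) the dominated rectangles have zero measure
  expect_equal(hypervolume(pts, ref = c(0.5, 0.5)), 0)
  # Monte-Carlo oracle on a random front
  set.seed(7)
  pts3 <- tibble::tibble(f1 = stats::runif(40), f2 = stats::runif(40))
  mc <- matrix(stats::runif(2e5), ncol = 2)
  inside <- vapply(seq_len(nrow(mc)), function(i)
    any(pts3$f1 >= mc[i, 1] & pts3$f2 >= mc[i, 2]), logical(1))
  expect_equal(hypervolume(pts3), mean(inside), tolerance = 0.01)
})

test_that("knee point maximises distance from the chord between extremes", {
  # right-angle front: the corner is the knee
  fr <- tibble::tibble(f1 = c(0, 1, 1), f2 = c(1, 1, 0))
  expect_equal(as.numeric(knee_point(fr)), c(1, 1))
  # two-point front: documented tie-break returns the first member
  fr2 <- tibble::tibble(f1 = c(0.2, 0.9), f2 = c(0.9, 0.2))
  expect_equal(as.numeric(knee_point(fr2)), c(0.2, 0.9))
  # quarter circle: knee at 45 degrees
  th <- seq(0, pi / 2, length.out = 201)
  fr3 <- tibble::tibble(f1 = cos(th), f2 = sin(th))
  kp <- knee_point(fr3)
  expect_equal(as.numeric(kp), c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 0.02)
  expect_error(knee_point(fr3[0, ]), "empty")
})

test_that("every optimiser front is internally nondominated", {
  cp <- hf_params()
  fr <- optimize_genotype(cp, optimizer_budget(pop_size = 12,
                                               generations = 4, seed = 11))
  tb <- fr$front
  expect_equal(nrow(pareto_filter(tb, c("r_Tp", "lambda"))), nrow(tb))
  expect_gt(nrow(tb), 0)
})
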