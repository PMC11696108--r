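test_that("experiment configs validate and round-trip through YAML", {
  cfg <- experiment_config("genotype_front", seed = 3, pop_size = 10,
                           generations = 2, half_lives = c(600, 180))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg, f)
  cfg2 <- read_experiment_config(f)
  expect_equal(cfg2$experiment, "genotype_front")
  expect_equal(cfg2$seed, 3L)
  expect_equal(cfg2$extra$half_lives, c(600, 180))
  # parse -> serialise -> parse is identity
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_experiment_config(cfg2, f2)
  expect_equal(read_experiment_config(f2), cfg2)
  expect_error(experiment_config("not_an_experiment"), "unknown experiment")
  expect_true("robustness" %in% list_experiments())
})

test_that("cell parameters round-trip through their YAML config", {
  cp <- cell_params(d_p = 0.001, drain_point = "precursor")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_cell_params(cp, f)
  cp2 <- read_cell_params(f)
  expect_equal(cp2$d_p, 0.001)
  expect_equal(cp2$drain_point, "precursor")
  expect_equal(cp2$w, cp$w)
  expect_equal(cp2$kcat, cp$kcat)
  # the bundled default parameter file matches the in-code defaults
  bundled <- read_cell_params(system.file("extdata", "default_params.yaml",
                                          package = "hostfactory"))
  expect_equal(unclass(bundled), unclass(cell_params()))
})

test_that("running an experiment writes a complete reproducible bundle", {
  dir1 <- withr::local_tempdir()
  cfg <- experiment_config("genotype_front", seed = 5, pop_size = 8,
                           generations = 2, out_dir = dir1)
  run_experiment(cfg)
  front_file <- file.path(dir1, "genotype_front.csv")
  expect_true(file.exists(front_file))
  expect_true(file.exists(file.path(dir1, "manifest.yaml")))
  tab <- utils::read.csv(front_file, comment.char = "#")
  # schema contract: all design dials plus the two objectives
  expect_true(all(c("sTX_E", "sTX_Ep", "sTX_Tp", "r_Tp", "lambda") %in%
                    names(tab)))
  # same seed reproduces byte-identical tables
  dir2 <- withr::local_tempdir()
  cfg2 <- experiment_config("genotype_front", seed = 5, pop_size = 8,
                            generations = 2, out_dir = dir2)
  run_experiment(cfg2)
  expect_identical(readLines(front_file),
                   readLines(file.path(dir2, "genotype_front.csv")))
  man <- yaml::read_yaml(file.path(dir1, "manifest.yaml"))
  expect_equal(man$config$seed, 5)
  expect_true(nzchar(man$manifest_hash))
})

test_that("degradation sweep includes the stable control and round-trips rates", {
  cp <- hf_params()
  res <- degradation_sweep(cp, optimizer_budget(8, 2, seed = 2),
                           half_lives = c(10, 3) * 60)
  expect_equal(nrow(res), 3)
  expect_equal(res$d_p[1], 0)
  # half-life column round-trips through the conversion exactly
  expect_equal(res$d_p[-1], half_life_to_decay_rate(res$half_life[-1]))
  # the stable-proteome control dominates the sweep
  expect_equal(which.max(res$hypervolume), 1L)
})

test_that("the CLI script dispatches its subcommands", {
  cli <- system.file("cli", "hostfactory.R", package = "hostfactory")
  expect_true(nzchar(cli))
  out <- system2("Rscript", c(cli, "list-experiments"), stdout = TRUE)
  expect_true("genotype_front" %in% out)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("experiment: genotype_front\nseed: 1", f)
  ok <- system2("Rscript", c(cli, "validate-config", f), stdout = TRUE)
  expect_match(ok, "config ok", all = FALSE)
})
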