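# End-to-end experiment driver: named computational experiments dispatched
# from a structured (YAML) config, with every setting echoed to a manifest
# so any run can be reproduced bit-for-bit from its output directory.

.experiments <- c("genotype_front", "one_stage_front", "two_stage_front",
                  "topology_comparison", "robustness", "degradation_sweep",
                  "burden_sweep", "transporter_retuning",
                  "precursor_variant")

#' Build or validate an experiment configuration
#'
#' @param experiment one of `r paste(.experiments, collapse = ", ")`.
#' @param constraint constraint id: `"5.1"`, `"5.2"`, `"5.3"`,
#'   `"precursor24"`.
#' @param params_file optional YAML cell-parameter file (default: the
#'   package defaults).
#' @param pop_size,generations,seed optimiser budget.
#' @param out_dir output directory (created).
#' @param ... experiment-specific settings (e.g. `half_lives`,
#'   `n_perturb`, `fraction`, `S0`, `t_max`).
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(experiment, constraint = "5.1",
                              params_file = NULL, pop_size = 24,
                              generations = 15, seed = 1,
                              out_dir = "results", ...) {
  if (!experiment %in% .experiments)
    stop("unknown experiment '", experiment, "'; see list_experiments()",
         call. = FALSE)
  structure(list(experiment = experiment, constraint = constraint,
                 params_file = params_file, pop_size = pop_size,
                 generations = generations, seed = as.integer(seed),
                 out_dir = out_dir, extra = list(...)),
            class = "experiment_config")
}

#' List the available experiments
#'
#' @return character vector of experiment names.
#' @export
list_experiments <- function() .experiments

#' Read an experiment config from YAML
#'
#' @param path YAML file.
#' @return an `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("experiment", "constraint", "params_file", "pop_size",
             "generations", "seed", "out_dir")
  args <- raw[intersect(names(raw), known)]
  extra <- raw[setdiff(names(raw), known)]
  do.call(experiment_config, c(args, extra))
}

#' @rdname read_experiment_config
#' @param config an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  flat <- c(config[setdiff(names(config), "extra")], config$extra)
  yaml::write_yaml(flat, path)
  invisible(path)
}

.write_table <- function(df, path, units = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(units))
    writeLines(paste0("# units: ", units), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.manifest <- function(config, files) {
  flat <- c(config[setdiff(names(config), "extra")], config$extra)
  list(config = flat,
       package_version = as.character(utils::packageVersion("hostfactory")),
       files = files,
       manifest_hash = rlang::hash(flat))
}

.cfg_params <- function(config) {
  p <- if (is.null(config$params_file)) cell_params() else
    read_cell_params(config$params_file)
  ex <- config$extra
  if (!is.null(ex$d_p)) p$d_p <- ex$d_p
  if (!is.null(ex$drain_point)) p$drain_point <- ex$drain_point
  validate_cell_params(p)
}

.cfg_options <- function(config) {
  ex <- config$extra
  do.call(batch_options,
          ex[intersect(names(ex),
                       c("S0", "B0", "inducer_dose", "t_max", "eps_S"))])
}

.cfg_budget <- function(config)
  optimizer_budget(config$pop_size, config$generations, config$seed)

#' Run a named experiment and write its results bundle
#'
#' Dispatches to the matching pipeline, writes tidy CSV tables plus a YAML
#' manifest (all settings, seed, package version) into `config$out_dir`,
#' and returns the in-memory result invisibly. Re-running the same config
#' reproduces the tables exactly (all stochastic steps are seeded).
#'
#' @param config an [experiment_config()] or path to a YAML config.
#' @return the experiment's result object, invisibly.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- .cfg_params(config)
  budget <- .cfg_budget(config)
  options <- .cfg_options(config)
  files <- character(0)
  out <- switch(config$experiment,
    genotype_front = {
      fr <- optimize_genotype(params, budget)
      f <- file.path(config$out_dir, "genotype_front.csv")
      .write_table(fr$front, f,
                   "sTX dimensionless; r_Tp molecules/min; lambda 1/min")
      files <- f
      fr
    },
    one_stage_front = {
      fr <- optimize_one_stage(params, budget, options)
      f <- file.path(config$out_dir, "one_stage_front.csv")
      .write_table(fr$front, f,
                   "sTX dimensionless; vP molecules/min; pY dimensionless")
      files <- f
      fr
    },
    two_stage_front = ,
    precursor_variant = ,
    topology_comparison = {
      if (config$experiment == "precursor_variant") {
        params$drain_point <- "precursor"
        config$constraint <- "precursor24"
      }
      cmp <- compare_topologies(params, topology_constraint(config$constraint),
                                budget, options)
      res <- attr(cmp, "result")
      files <- character(0)
      for (fr in res$fronts) {
        fn <- file.path(config$out_dir,
                        paste0("front_", gsub(",", "", fr$front$topology_id[1]),
                               ".csv"))
        .write_table(fr$front, fn,
                     "vP molecules/min; pY dimensionless; tau min")
        files <- c(files, fn)
      }
      f2 <- file.path(config$out_dir, "combined_front.csv")
      .write_table(res$combined$front, f2,
                   "vP molecules/min; pY dimensionless; tau min")
      f3 <- file.path(config$out_dir, "topology_ranking.csv")
      .write_table(tibble::as_tibble(cmp), f3, "hypervolume dimensionless")
      files <- c(files, f2, f3)
      cmp
    },
    robustness = {
      res <- .robustness_experiment(params, config, budget, options)
      f <- file.path(config$out_dir, "robustness.csv")
      .write_table(res$summary, f, "area in (vP, pY) units")
      files <- f
      res
    },
    degradation_sweep = {
      hl <- config$extra$half_lives %||% (c(24, 15, 10, 7, 3) * 60)
      res <- degradation_sweep(params, budget, options, half_lives = hl)
      f <- file.path(config$out_dir, "degradation_sweep.csv")
      .write_table(res, f,
                   "half_life min; d_p 1/min; hypervolume (vP,pY) units")
      files <- f
      res
    },
    burden_sweep = {
      res <- burden_sweep(params, budget, options,
                          kcat_factors = config$extra$kcat_factors %||%
                            c(1, 0.1),
                          length_factors = config$extra$length_factors %||%
                            c(1, 5))
      f <- file.path(config$out_dir, "burden_sweep.csv")
      .write_table(res, f, "factors dimensionless; gap relative hypervolume")
      files <- f
      res
    },
    transporter_retuning = {
      res <- transporter_retuning(params, budget, options)
      f <- file.path(config$out_dir, "transporter_retuning.csv")
      .write_table(res$combined$front, f,
                   "sTX dimensionless; vP molecules/min; pY dimensionless")
      files <- f
      res
    })
  yaml::write_yaml(.manifest(config, files),
                   file.path(config$out_dir, "manifest.yaml"))
  invisible(out)
}

.robustness_experiment <- function(params, config, budget, options) {
  constraint <- topology_constraint(config$constraint)
  res <- optimize_two_stage(params, constraint, budget, options)
  n <- config$extra$n_perturb %||% 200
  fraction <- config$extra$fraction %||% 0.2
  rows <- purrr::map_dfr(res$fronts, function(fr) {
    if (nrow(fr$front) == 0) return(NULL)
    kp <- knee_point(fr)
    design <- attr(kp, "design")
    rb <- robustness_area(params, design, n = n, fraction = fraction,
                          seed = config$seed, options = options)
    tibble::tibble(topology_id = fr$front$topology_id[1],
                   area = rb$area, n = rb$n, n_failed = rb$n_failed)
  })
  rows <- dplyr::arrange(rows, .data$area)
  list(summary = rows, result = res)
}

#' Sweep uniform protein degradation and re-optimise
#'
#' Re-runs the one-stage front with a uniform protein decay rate
#' `d_p = log(2) / half_life` for each half-life (a stable-proteome control
#' with `d_p = 0` is always included) and reports the front hypervolume
#' against decay rate.
#'
#' @param params a [cell_params()].
#' @param budget an [optimizer_budget()].
#' @param options a [batch_options()].
#' @param half_lives protein half-lives, minutes.
#' @return tibble: `half_life`, `d_p`, `hypervolume`, `max_vP`, `max_pY`.
#' @export
degradation_sweep <- function(params = cell_params(),
                              budget = optimizer_budget(24, 15),
                              options = batch_options(),
                              half_lives = c(24, 15, 10, 7, 3) * 60) {
  purrr::map_dfr(c(Inf, sort(half_lives, decreasing = TRUE)), function(hl) {
    p <- params
    p$d_p <- if (is.infinite(hl)) 0 else half_life_to_decay_rate(hl)
    fr <- optimize_one_stage(p, budget, options)
    tibble::tibble(half_life = hl, d_p = p$d_p,
                   hypervolume = hypervolume(fr$front,
                                             objectives = c("vP", "pY")),
                   max_vP = max(fr$front$vP), max_pY = max(fr$front$pY))
  })
}

.constraint_custom <- function(allowed, tunable, name) {
  structure(list(problem = name, allowed = allowed, tunable = tunable),
            class = "topology_constraint")
}

#' Dual-control vs one-sided switch under increasing pathway burden
#'
#' For each grid point (synthesis-enzyme turnover scaled by `kcat_factors`,
#' gene length by `length_factors`), optimises the dual-control circuit
#' (growth-phase activation of `E`, repression of `Ep` and `Tp`) and the
#' one-sided switch (control on `E` only) and reports the relative
#' hypervolume gap between them.
#'
#' @param params a [cell_params()].
#' @param budget an [optimizer_budget()] per topology.
#' @param options a [batch_options()].
#' @param kcat_factors multiplies `kcat` of `Ep`/`Tp`.
#' @param length_factors multiplies gene length of `Ep`/`Tp`.
#' @return tibble: grid point, both hypervolumes, `gap` (1 - one-sided /
#'   dual, floored at 0).
#' @export
burden_sweep <- function(params = cell_params(),
                         budget = optimizer_budget(24, 15),
                         options = batch_options(),
                         kcat_factors = c(1, 0.1),
                         length_factors = c(1, 5)) {
  dual <- circuit_topology(g_E = 1, g_Ep = -1, g_Tp = -1)
  onesided <- circuit_topology(g_E = 1)
  grid <- tidyr::expand_grid(kcat_factor = kcat_factors,
                             length_factor = length_factors)
  purrr::pmap_dfr(grid, function(kcat_factor, length_factor) {
    p <- params
    p$kcat[c("Ep", "Tp")] <- p$kcat[c("Ep", "Tp")] * kcat_factor
    p$n[c("Ep", "Tp")] <- p$n[c("Ep", "Tp")] * length_factor
    cs <- .constraint_custom(
      list(T = 0, E = 1, Ep = c(-1, 0), Tp = c(-1, 0), TF = 0),
      c("E", "Ep", "Tp", "TF"), "burden")
    norm <- normalization_constants(p, cs, optimizer_budget(
      budget$pop_size, max(5, budget$generations %/% 2), budget$seed),
      options)
    hv <- vapply(list(dual, onesided), function(tp) {
      cs1 <- .constraint_custom(as.list(as.numeric(tp)) |>
                                  stats::setNames(.circuit_genes),
                                c("E", "Ep", "Tp", "TF"), "burden1")
      r <- optimize_two_stage(p, cs1, budget, options, norm = norm)
      hypervolume(r$combined$front, objectives = c("vP_norm", "pY_norm"))
    }, numeric(1))
    tibble::tibble(kcat_factor = kcat_factor,
                   length_factor = length_factor,
                   hv_dual = hv[1], hv_onesided = hv[2],
                   gap = max(0, 1 - hv[2] / hv[1]))
  })
}

#' Re-tune or control the nutrient transporter on the best circuit
#'
#' Extends the highest-performing dual-control topology (growth-phase
#' activation of `E`, repression of `Ep`, `Tp`) with the transporter `T`
#' either constitutively re-tunable (`g_T = 0`, `sTX_T` free) or TF
#' controlled (`g_T = +/-1`), and optimises all three variants.
#'
#' @param params a [cell_params()].
#' @param budget an [optimizer_budget()] per topology.
#' @param options a [batch_options()].
#' @return a `two_stage_result` over the three `g_T` variants with `sTX_T`
#'   tunable in `[1e-3, 2]`.
#' @export
transporter_retuning <- function(params = cell_params(),
                                 budget = optimizer_budget(24, 15),
                                 options = batch_options(),
                                 norm = c(vP_max = 1, pY_max = 1)) {
  cs <- .constraint_custom(
    list(T = c(-1, 0, 1), E = 1, Ep = -1, Tp = -1, TF = 0),
    c("T", "E", "Ep", "Tp", "TF"), "transporter_retuning")
  optimize_two_stage(params, cs, budget, options, norm = norm)
}
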