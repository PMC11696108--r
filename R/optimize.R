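# The three design problems: (i) genotype objectives (synthesis vs growth),
# (ii) one-stage culture objectives (productivity vs yield) over constitutive
# transcription scalings, (iii) two-stage culture objectives over inducible
# circuit designs (topology enumerated exhaustively, continuous dials
# optimised by NSGA-II inside each topology). Continuous dials are searched
# in log10 space because the boxes span 3-6 decades.

# codec: map [0,1]^n decision vectors to circuit designs -------------------
.log_decode <- function(u, lo, hi) 10^(log10(lo) + u * (log10(hi) - log10(lo)))

.codec_constitutive <- function() {
  # sTX_E, sTX_Ep, sTX_Tp in [1e-3, 1] (log scale); no circuit, no TF gene
  bounds <- rbind(lo = c(T = 1, E = 1e-3, Ep = 1e-3, Tp = 1e-3, TF = 0),
                  hi = c(T = 1, E = 1, Ep = 1, Tp = 1, TF = 0))
  list(
    n_var = 3L,
    var_names = c("sTX_E", "sTX_Ep", "sTX_Tp"),
    decode = function(u) {
      s <- .log_decode(u, 1e-3, 1)
      circuit_design(sTX = c(T = 1, E = s[1], Ep = s[2], Tp = s[3], TF = 0),
                     tau = 0, sTX_bounds = bounds)
    })
}

.codec_two_stage <- function(topology, tunable) {
  g <- as.numeric(topology)
  names(g) <- .circuit_genes
  ctrl <- .circuit_genes[g != 0]
  fixed <- setdiff(.circuit_genes, tunable)
  bounds <- rbind(lo = c(T = 1, E = 1e-3, Ep = 1e-3, Tp = 1e-3, TF = 1e-3),
                  hi = c(T = 1, E = 2, Ep = 2, Tp = 2, TF = 2))
  bounds["lo", fixed] <- 1; bounds["hi", fixed] <- 1
  bounds["lo", tunable] <- 1e-3; bounds["hi", tunable] <- 2
  nv <- length(tunable) + length(ctrl) + 1L
  list(
    n_var = nv,
    var_names = c(paste0("sTX_", tunable),
                  paste0("K_", ctrl, recycle0 = TRUE), "tau"),
    decode = function(u) {
      sTX <- stats::setNames(rep(1, 5), .circuit_genes)
      sTX[tunable] <- .log_decode(u[seq_along(tunable)], 1e-3, 2)
      K <- stats::setNames(rep(0, 5), .circuit_genes)
      if (length(ctrl))
        K[ctrl] <- .log_decode(
          u[length(tunable) + seq_along(ctrl)], 1e-6, 1)
      tau <- u[nv] * 24 * 60
      circuit_design(topology = circuit_topology(g[1], g[2], g[3], g[4],
                                                 g[5]),
                     sTX = sTX, K = K, tau = tau, sTX_bounds = bounds)
    })
}

# warm-start rows for the unit-cube search: the box midpoint and the
# baseline strain (every scaling at its unscaled value 1, mid-strength
# control, induction at a quarter of the horizon); keeps early generations
# anchored at viable cells when most random corners are non-growing
.codec_seeds <- function(codec) {
  mid <- rep(0.5, codec$n_var)
  base <- vapply(codec$var_names, function(v) {
    if (startsWith(v, "sTX_")) {
      hi <- if (identical(codec$n_var, 3L)) 1 else 2
      (log10(1) - log10(1e-3)) / (log10(hi) - log10(1e-3))
    } else if (startsWith(v, "K_")) {
      (log10(1e-2) - log10(1e-6)) / (0 - log10(1e-6))
    } else 0.25
  }, numeric(1))
  rbind(mid, base, deparse.level = 0)
}

.design_row <- function(design) {
  tibble::tibble(
    !!!stats::setNames(as.list(as.numeric(design$topology)),
                       paste0("g_", .circuit_genes)),
    !!!stats::setNames(as.list(unname(design$sTX)),
                       paste0("sTX_", .circuit_genes)),
    !!!stats::setNames(as.list(unname(design$K)),
                       paste0("K_", .circuit_genes)),
    tau = design$tau)
}

.front_table <- function(res, codec, obj_names) {
  designs <- apply(res$X, 1, codec$decode)
  rows <- dplyr::bind_rows(lapply(designs, .design_row))
  rows[[obj_names[1]]] <- res$F[, 1]
  rows[[obj_names[2]]] <- res$F[, 2]
  ord <- order(rows[[obj_names[1]]], decreasing = TRUE)
  attr(rows, "objectives") <- obj_names
  list(front = rows[ord, ], designs = designs[ord])
}

#' Optimise the production genotype (synthesis vs growth)
#'
#' Maximises the cell-level objectives `(r_Tp, lambda)` over the
#' constitutive transcription scalings `sTX_E, sTX_Ep, sTX_Tp` in
#' `[1e-3, 1]` at the mid-exponential steady state.
#'
#' @param params a [cell_params()].
#' @param budget an [optimizer_budget()].
#' @param S_ext clamped substrate for the steady state.
#' @return a `pareto_front` with objectives `r_Tp`, `lambda`.
#' @export
optimize_genotype <- function(params = cell_params(),
                              budget = optimizer_budget(),
                              S_ext = 1e12) {
  codec <- .codec_constitutive()
  fn <- function(u) {
    d <- codec$decode(u)
    o <- genotype_objectives(params, d, S_ext)
    c(o$r_Tp, o$lambda)
  }
  res <- nsga2(fn, codec$n_var, budget, seed_designs = .codec_seeds(codec))
  ft <- .front_table(res, codec, c("r_Tp", "lambda"))
  new_pareto_front(ft$front, ft$designs, "genotype (synthesis vs growth)",
                   budget, budget$seed,
                   list(n_eval = res$n_eval, n_failed = res$n_failed))
}

# culture objective evaluator shared by the one- and two-stage problems;
# non-exhausting or failed batches score (0, 0)
.culture_objectives <- function(params, design, options) {
  res <- simulate_batch(params, design, options)
  if (!res$exhausted) return(c(0, 0))
  c(res$vP, res$pY)
}

#' Optimise one-stage culture production (productivity vs yield)
#'
#' Maximises `(vP, pY)` from batch simulations over the constitutive
#' scalings `sTX_E, sTX_Ep, sTX_Tp`; no circuit, no induction.
#'
#' @param params a [cell_params()].
#' @param budget an [optimizer_budget()].
#' @param options a [batch_options()]; the trajectory resolution is reduced
#'   internally during the search.
#' @return a `pareto_front` with objectives `vP`, `pY`.
#' @export
optimize_one_stage <- function(params = cell_params(),
                               budget = optimizer_budget(),
                               options = batch_options()) {
  fast <- options; fast$n_out <- 2
  codec <- .codec_constitutive()
  fn <- function(u) .culture_objectives(params, codec$decode(u), fast)
  res <- nsga2(fn, codec$n_var, budget, seed_designs = .codec_seeds(codec))
  ft <- .front_table(res, codec, c("vP", "pY"))
  new_pareto_front(ft$front, ft$designs, "one-stage (vP vs pY)",
                   budget, budget$seed,
                   list(n_eval = res$n_eval, n_failed = res$n_failed,
                        options = options))
}

#' Normalisation constants for the two-stage objectives
#'
#' `vP_max` and `pY_max` from separate single-objective maximisations over
#' the constraint's design space, each run once on the constraint's
#' fully-controlled topology and once without any circuit, keeping the
#' larger value. The two-stage objectives are reported both raw and divided
#' by these constants.
#'
#' @param params a [cell_params()].
#' @param constraint a [topology_constraint()].
#' @param budget an [optimizer_budget()] for each single-objective run.
#' @param options a [batch_options()].
#' @return named vector `c(vP_max, pY_max)`.
#' @export
normalization_constants <- function(params = cell_params(),
                                    constraint = topology_constraint("5.1"),
                                    budget = optimizer_budget(pop_size = 30,
                                                              generations = 20),
                                    options = batch_options()) {
  fast <- options; fast$n_out <- 2
  full <- vapply(constraint$allowed, function(s) {
    if (any(s > 0)) 1 else if (any(s < 0)) -1 else 0
  }, numeric(1))
  topos <- list(
    do.call(circuit_topology, as.list(unname(full))),
    circuit_topology())
  best <- c(vP_max = 0, pY_max = 0)
  for (k in 1:2) {
    for (tp in topos) {
      codec <- if (all(tp == 0)) .codec_constitutive() else
        .codec_two_stage(tp, constraint$tunable)
      fn <- function(u) .culture_objectives(params, codec$decode(u), fast)[k]
      r <- ga_maximize(fn, codec$n_var, budget,
                       seed_designs = .codec_seeds(codec))
      if (r$f > best[k]) best[k] <- r$f
    }
  }
  if (any(best <= 0))
    stop("normalisation constants must be positive; optimiser found none",
         call. = FALSE)
  best
}

#' Optimise two-stage (inducible circuit) culture production
#'
#' For each topology admitted by the constraint, maximises the normalised
#' culture objectives `(vP/vP_max, pY/pY_max)` over the continuous dials
#' (transcription scalings in `[1e-3, 2]`, control strengths in
#' `[1e-6, 1]` where the gene is controlled, induction time in
#' `[0, 1440]` min) with NSGA-II; topologies are enumerated exhaustively in
#' an outer loop.
#'
#' @param params a [cell_params()].
#' @param constraint a [topology_constraint()].
#' @param budget an [optimizer_budget()] applied per topology.
#' @param options a [batch_options()].
#' @param norm optional pre-computed `c(vP_max, pY_max)`; computed via
#'   [normalization_constants()] when missing.
#' @param norm_budget budget for the normalisation runs.
#' @return a `two_stage_result`: list of per-topology `pareto_front`s
#'   (`$fronts`), the combined nondominated front (`$combined`, a
#'   `pareto_front`), and `$norm`.
#' @export
optimize_two_stage <- function(params = cell_params(),
                               constraint = topology_constraint("5.1"),
                               budget = optimizer_budget(),
                               options = batch_options(),
                               norm = NULL,
                               norm_budget = optimizer_budget(
                                 pop_size = 30, generations = 20,
                                 seed = budget$seed)) {
  if (is.null(norm))
    norm <- normalization_constants(params, constraint, norm_budget, options)
  fast <- options; fast$n_out <- 2
  topos <- enumerate_topologies(constraint)
  fronts <- vector("list", nrow(topos))
  for (i in seq_len(nrow(topos))) {
    tp <- topos$topology[[i]]
    codec <- .codec_two_stage(tp, constraint$tunable)
    fn <- function(u) {
      .culture_objectives(params, codec$decode(u), fast) /
        c(norm[1], norm[2])
    }
    res <- nsga2(fn, codec$n_var, budget, seed_designs = .codec_seeds(codec))
    ft <- .front_table(res, codec, c("vP_norm", "pY_norm"))
    ft$front$vP <- ft$front$vP_norm * norm[[1]]
    ft$front$pY <- ft$front$pY_norm * norm[[2]]
    ft$front$topology_id <- paste(as.numeric(tp), collapse = ",")
    attr(ft$front, "objectives") <- c("vP_norm", "pY_norm")
    fronts[[i]] <- new_pareto_front(
      ft$front, ft$designs,
      paste0("two-stage ", constraint$problem, " [",
             paste(as.numeric(tp), collapse = ","), "]"),
      budget, budget$seed,
      list(n_eval = res$n_eval, n_failed = res$n_failed))
  }
  all_front <- dplyr::bind_rows(lapply(fronts, function(f) f$front))
  all_designs <- do.call(c, lapply(fronts, function(f) f$designs))
  all_front$.idx <- seq_len(nrow(all_front))
  nd <- pareto_filter(all_front, c("vP_norm", "pY_norm"))
  keep <- nd$.idx
  nd$.idx <- NULL
  all_front$.idx <- NULL
  attr(nd, "objectives") <- c("vP_norm", "pY_norm")
  combined <- new_pareto_front(
    nd, all_designs[keep],
    paste0("two-stage ", constraint$problem, " combined"),
    budget, budget$seed)
  structure(list(fronts = fronts, combined = combined, norm = norm,
                 constraint = constraint, budget = budget),
            class = "two_stage_result")
}

#' @export
print.two_stage_result <- function(x, ...) {
  cat(sprintf("<two_stage_result> %s: %d topologies\n",
              x$constraint$problem, length(x$fronts)))
  cat(sprintf("  vP_max = %.4g, pY_max = %.4g\n", x$norm[1], x$norm[2]))
  print(x$combined)
  invisible(x)
}

#' Rank circuit topologies by optimised front quality
#'
#' Runs [optimize_two_stage()] (or reuses a supplied result) and ranks every
#' topology by the hypervolume of its normalised front; a topology is in the
#' top-performance group when its hypervolume is within `tol` of the best.
#'
#' @param params a [cell_params()].
#' @param constraint a [topology_constraint()].
#' @param budget an [optimizer_budget()] per topology.
#' @param options a [batch_options()].
#' @param tol relative hypervolume tolerance for top-group membership
#'   (default 2\%).
#' @param result optional pre-computed `two_stage_result`.
#' @param norm forwarded to [optimize_two_stage()]; rankings and group
#'   membership are invariant to this rescaling.
#' @return a `topology_ranking`: tibble with `topology_id`, per-gene `g`
#'   columns, `hypervolume`, `rank`, `top_group`; the underlying
#'   `two_stage_result` in attribute `"result"`.
#' @export
compare_topologies <- function(params = cell_params(),
                               constraint = topology_constraint("5.1"),
                               budget = optimizer_budget(),
                               options = batch_options(),
                               tol = 0.02,
                               result = NULL,
                               norm = c(vP_max = 1, pY_max = 1)) {
  if (is.null(result))
    result <- optimize_two_stage(params, constraint, budget, options,
                                 norm = norm)
  hv <- vapply(result$fronts, function(f)
    hypervolume(f$front, objectives = c("vP_norm", "pY_norm")), numeric(1))
  ids <- vapply(result$fronts, function(f)
    f$front$topology_id[1] %||% NA_character_, character(1))
  g <- do.call(rbind, lapply(result$fronts, function(f)
    as.numeric(strsplit(f$front$topology_id[1], ",")[[1]])))
  colnames(g) <- paste0("g_", .circuit_genes)
  tb <- tibble::as_tibble(g)
  tb$topology_id <- ids
  tb$hypervolume <- hv
  tb$rank <- rank(-hv, ties.method = "min")
  tb$top_group <- hv >= (1 - tol) * max(hv)
  tb <- dplyr::arrange(tb, .data$rank)
  structure(tb, class = c("topology_ranking", class(tb)),
            result = result, tol = tol)
}
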