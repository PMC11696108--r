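# Batch-culture simulation: population biomass, external substrate, product
# and inducer, with the single-cell model embedded in the same state vector.

#' Batch culture options
#'
#' @param S0 initial substrate, molecules per culture (> 0).
#' @param B0 initial biomass, cells (> 0).
#' @param inducer_dose bolus of external inducer added at the induction time.
#' @param t_max horizon, min.
#' @param eps_S substrate-exhaustion threshold (event-detected); defaults to
#'   `1e-3 * S0` because the depletion ODE approaches zero asymptotically.
#' @param n_out number of output time points in the returned trajectory.
#' @return a `batch_options` list.
#' @export
batch_options <- function(S0 = 1e12, B0 = 1, inducer_dose = 1e10,
                          t_max = 24 * 60, eps_S = 1e-3 * S0,
                          n_out = 201) {
  stopifnot(S0 > 0, B0 > 0, t_max > 0, eps_S >= 0, inducer_dose >= 0)
  structure(list(S0 = S0, B0 = B0, inducer_dose = inducer_dose,
                 t_max = t_max, eps_S = eps_S, n_out = n_out),
            class = "batch_options")
}

.batch_segment <- function(y0, t0, t1, parms, n_out) {
  times <- unique(c(t0, seq(t0, t1, length.out = max(2, n_out))))
  atol <- pmax(abs(y0), 1) * 1e-10
  deSolve::lsodar(y = y0, times = times, func = "derivs_cellbatch",
                  parms = parms, dllname = "hostfactory",
                  initfunc = "init_cellbatch",
                  rootfunc = "root_cellbatch", nroot = 1,
                  nout = 8, outnames = .out_names,
                  rtol = 1e-8, atol = atol, maxsteps = 50000)
}

#' Simulate a batch culture
#'
#' Integrates the coupled cell + culture ODEs: `dB/dt = lambda B`,
#' `dS_x/dt = -r_T B`, `dP_x/dt = r_Tp B`, `dI_x/dt = -r_uInd B`, with all
#' specific rates computed from the embedded cell model. Cells start at the
#' pre-induction mid-exponential steady state for substrate `S0`; at the
#' design's induction time `tau` an inducer bolus is added. Integration
#' stops at substrate exhaustion (`S_x <= eps_S`, root-detected) or at
#' `t_max`.
#'
#' @param params a [cell_params()].
#' @param design a [circuit_design()]; `tau >= t_max` or a zero dose means
#'   the culture is never induced.
#' @param options a [batch_options()].
#' @param y0_cell optional pre-computed initial cell state (skips the
#'   steady-state solve; used by optimisers that cache it).
#' @return a `batch_result`: list with `trajectory` (tibble: time, culture
#'   states, cell states, instantaneous rates), `t_end`, `titre`, `vP`,
#'   `pY`, `exhausted`, plus the inputs.
#' @export
simulate_batch <- function(params = cell_params(),
                           design = circuit_design(),
                           options = batch_options(),
                           y0_cell = NULL) {
  validate_circuit_design(design)
  if (is.null(y0_cell))
    y0_cell <- exponential_steady_state(params, design, S_ext = options$S0)
  y0 <- cell_state(y0_cell)
  y0[["B"]] <- options$B0
  y0[["S_x"]] <- options$S0
  y0[["P_x"]] <- 0
  y0[["I_x"]] <- 0

  parms <- .pack_parms(params, design, mode = "batch",
                       eps_S = options$eps_S)
  tau <- design$tau
  induce <- options$inducer_dose > 0 && tau < options$t_max &&
    any(design$topology != 0)

  if (induce && tau > 0) {
    seg1 <- .batch_segment(y0, 0, tau, parms,
                           ceiling(options$n_out * tau / options$t_max))
    rooted <- !is.null(attr(seg1, "troot")) && length(attr(seg1, "troot"))
    if (rooted) {
      sols <- list(seg1)
      troot <- attr(seg1, "troot")
    } else {
      y1 <- seg1[nrow(seg1), .state_names]
      y1[["I_x"]] <- y1[["I_x"]] + options$inducer_dose
      seg2 <- .batch_segment(y1, tau, options$t_max, parms, options$n_out)
      troot <- attr(seg2, "troot")
      sols <- list(seg1, seg2[-1, , drop = FALSE])
    }
  } else {
    if (induce) y0[["I_x"]] <- options$inducer_dose
    seg <- .batch_segment(y0, 0, options$t_max, parms, options$n_out)
    troot <- attr(seg, "troot")
    sols <- list(seg)
  }
  sol <- do.call(rbind, sols)
  exhausted <- !is.null(troot) && length(troot) > 0
  t_end <- if (exhausted) troot[1] else options$t_max
  if (!exhausted)
    rlang::inform(
      "substrate not exhausted within t_max; metrics computed at horizon",
      class = "hostfactory_no_exhaustion", .frequency = "once",
      .frequency_id = "hostfactory_no_exhaustion")

  traj <- tibble::as_tibble(as.data.frame(sol))
  names(traj)[1] <- "time"
  titre <- traj$P_x[nrow(traj)]

  res <- structure(
    list(trajectory = traj, t_end = t_end, titre = titre,
         vP = titre / t_end, pY = titre / options$S0,
         exhausted = exhausted, params = params, design = design,
         options = options),
    class = "batch_result")
  res
}

#' Culture production metrics
#'
#' Volumetric productivity `vP = P(t_end) / t_end` and product yield
#' `pY = P(t_end) / S0` of a finished batch.
#'
#' @param result a `batch_result` from [simulate_batch()].
#' @return tibble with one row: `vP`, `pY`, `titre`, `t_end`, `exhausted`.
#' @export
production_metrics <- function(result) {
  stopifnot(inherits(result, "batch_result"))
  if (result$t_end <= 0) stop("t_end must be positive", call. = FALSE)
  tibble::tibble(vP = result$titre / result$t_end,
                 pY = result$titre / result$options$S0,
                 titre = result$titre, t_end = result$t_end,
                 exhausted = result$exhausted)
}

#' @export
print.batch_result <- function(x, ...) {
  cat("<batch_result>\n")
  cat(sprintf("  t_end = %.1f min (%s)\n", x$t_end,
              if (x$exhausted) "substrate exhausted" else "horizon reached"))
  cat(sprintf("  titre = %.4g molecules; vP = %.4g /min; pY = %.4g\n",
              x$titre, x$vP, x$pY))
  invisible(x)
}

#' Tidy a batch result into its trajectory table
#'
#' @param x a `batch_result`.
#' @param ... unused.
#' @return long tibble: `time`, `variable`, `value`.
#' @export
tidy.batch_result <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"time",
                      names_to = "variable", values_to = "value")
}

#' One-row summary of a batch result
#'
#' @param x a `batch_result`.
#' @param ... unused.
#' @return tibble: `vP`, `pY`, `titre`, `t_end`, `exhausted`.
#' @export
glance.batch_result <- function(x, ...) production_metrics(x)

#' Plot batch-culture trajectories
#'
#' Biomass, substrate, external product and growth rate against time.
#'
#' @param object a `batch_result`.
#' @param vars trajectory columns to show.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.batch_result <- function(object,
                                  vars = c("B", "S_x", "P_x", "lambda"),
                                  ...) {
  df <- tidy(object)
  df <- df[df$variable %in% vars, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL) +
    ggplot2::theme_minimal()
}
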