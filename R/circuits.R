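# Genetic circuit designs: topology vector, transcription scalings, control
# strengths and induction time, with the box constraints of the three design
# problems.

#' Circuit topology vector
#'
#' Five integers `g = (g_T, g_E, g_Ep, g_Tp, g_TF)` stating the effect of the
#' *active* transcription factor on each gene: -1 repression, 0 no control,
#' +1 activation. The TF is active in the growth phase (no inducer) and is
#' deactivated by inducer binding, so `g_E = +1` is the
#' "inducer-deactivation of the host enzyme" motif: E is activated while
#' growing and collapses to the basal leak after induction.
#'
#' @param g_T,g_E,g_Ep,g_Tp,g_TF integers in `{-1, 0, 1}`.
#' @return named integer vector of class `circuit_topology`.
#' @export
circuit_topology <- function(g_T = 0, g_E = 0, g_Ep = 0, g_Tp = 0, g_TF = 0) {
  g <- c(T = g_T, E = g_E, Ep = g_Ep, Tp = g_Tp, TF = g_TF)
  if (length(g) != 5 || !all(g %in% c(-1, 0, 1)))
    stop("topology elements must be -1, 0 or +1", call. = FALSE)
  structure(g, class = "circuit_topology")
}

#' Circuit design: topology, scalings, strengths, induction time
#'
#' @param topology a [circuit_topology()].
#' @param sTX named transcription scalings for `T, E, Ep, Tp, TF`.
#' @param K named control strengths (per-molecule affinity of active TF for
#'   the gene's operator); must be 0 exactly where `g = 0` and in
#'   `[1e-6, 1]` where `g != 0`.
#' @param tau induction time, min, in `[0, 1440]`.
#' @param sTX_bounds 2 x 5 matrix (rows lo/hi) of box bounds for `sTX`.
#' @return object of class `circuit_design`.
#' @export
circuit_design <- function(topology = circuit_topology(),
                           sTX = c(T = 1, E = 1, Ep = 1, Tp = 1, TF = 1),
                           K = NULL,
                           tau = 0,
                           sTX_bounds = NULL) {
  if (!inherits(topology, "circuit_topology"))
    topology <- do.call(circuit_topology, as.list(stats::setNames(
      topology, c("g_T", "g_E", "g_Ep", "g_Tp", "g_TF"))))
  if (is.null(K))
    K <- ifelse(topology != 0, 1e-3, 0)
  names(K) <- .circuit_genes
  sTX <- sTX[.circuit_genes]
  if (is.null(sTX_bounds))
    sTX_bounds <- rbind(lo = rep(1e-3, 5), hi = rep(2, 5))
  colnames(sTX_bounds) <- .circuit_genes
  obj <- structure(
    list(topology = topology, sTX = sTX, K = K, tau = tau,
         sTX_bounds = sTX_bounds),
    class = "circuit_design")
  validate_circuit_design(obj)
}

#' Validate a circuit design against its structural constraints
#'
#' Enforces the conditional strength constraint (`K = 0` iff `g = 0`,
#' otherwise `1e-6 <= K <= 1`), the scaling box, and the induction-time
#' bound `0 <= tau <= 1440` min.
#'
#' @param design a `circuit_design`.
#' @return the design, invisibly, or an error.
#' @export
validate_circuit_design <- function(design) {
  stopifnot(inherits(design, "circuit_design"))
  g <- design$topology; K <- design$K; sTX <- design$sTX
  if (anyNA(sTX) || anyNA(K))
    stop("design has missing values", call. = FALSE)
  off <- g == 0
  if (any(K[off] != 0))
    stop("K must be 0 for uncontrolled genes (g = 0)", call. = FALSE)
  if (any(K[!off] < 1e-6 | K[!off] > 1))
    stop("K must lie in [1e-6, 1] for controlled genes", call. = FALSE)
  if (any(sTX < design$sTX_bounds["lo", ] - 1e-12) ||
      any(sTX > design$sTX_bounds["hi", ] + 1e-12))
    stop("sTX outside its box bounds", call. = FALSE)
  if (design$tau < 0 || design$tau > 24 * 60)
    stop("induction time tau must lie in [0, 1440] min", call. = FALSE)
  design
}

#' @export
print.circuit_design <- function(x, ...) {
  cat("<circuit_design>\n")
  cat("  g   :", sprintf("%+d", x$topology), "\n")
  cat("  sTX :", signif(x$sTX, 3), "\n")
  cat("  K   :", signif(x$K, 3), "\n")
  cat("  tau :", round(x$tau, 1), "min\n")
  invisible(x)
}

#' Topology constraints of the optimisation problems
#'
#' Returns the per-gene allowed sets of `g` values and the set of tunable
#' `sTX` dials for the named problem:
#' \describe{
#'   \item{"5.1"}{TF control on `E` (activation or none) and `Ep`, `Tp`
#'     (repression or none); `sTX_T` fixed at 1. 8 topologies.}
#'   \item{"5.2"}{as 5.1 plus TF autoregulation `g_TF` in `{-1,0,1}`.}
#'   \item{"5.3"}{as 5.1 plus TF control and constitutive tuning of the
#'     nutrient transporter `T`.}
#'   \item{"precursor24"}{product drains the translation precursor: `E`,
#'     `Ep`, `Tp` constitutive or repressed pre-induction, TF free to
#'     autoregulate. 24 topologies.}
#' }
#'
#' @param problem one of `"5.1"`, `"5.2"`, `"5.3"`, `"precursor24"`.
#' @return a `topology_constraint`: list of allowed-`g` sets, tunable dials.
#' @export
topology_constraint <- function(problem = c("5.1", "5.2", "5.3",
                                            "precursor24")) {
  problem <- match.arg(problem)
  allowed <- switch(problem,
    "5.1" = list(T = 0, E = c(0, 1), Ep = c(-1, 0), Tp = c(-1, 0), TF = 0),
    "5.2" = list(T = 0, E = c(0, 1), Ep = c(-1, 0), Tp = c(-1, 0),
                 TF = c(-1, 0, 1)),
    "5.3" = list(T = c(-1, 0, 1), E = c(0, 1), Ep = c(-1, 0),
                 Tp = c(-1, 0), TF = 0),
    "precursor24" = list(T = 0, E = c(-1, 0), Ep = c(-1, 0), Tp = c(-1, 0),
                         TF = c(-1, 0, 1)))
  tunable <- switch(problem,
    "5.1" = c("E", "Ep", "Tp", "TF"),
    "5.2" = c("E", "Ep", "Tp", "TF"),
    "5.3" = c("T", "E", "Ep", "Tp", "TF"),
    "precursor24" = c("E", "Ep", "Tp", "TF"))
  structure(list(problem = problem, allowed = allowed, tunable = tunable),
            class = "topology_constraint")
}

#' Enumerate all circuit topologies admitted by a constraint
#'
#' Cartesian product of the per-gene allowed sets, deduplicated, in a
#' deterministic (odometer) order.
#'
#' @param constraint a [topology_constraint()] or a bare list of allowed sets.
#' @return tibble with one row per topology, columns `g_T..g_TF` and a
#'   list-column `topology` of [circuit_topology()] objects.
#' @export
#' @examples
#' nrow(enumerate_topologies(topology_constraint("5.1")))   # 8
enumerate_topologies <- function(constraint) {
  allowed <- if (inherits(constraint, "topology_constraint"))
    constraint$allowed else constraint
  if (any(lengths(allowed) == 0))
    stop("empty allowed set for some gene", call. = FALSE)
  grid <- expand.grid(rev(lapply(allowed, unique)),
                      KEEP.OUT.ATTRS = FALSE)[, 5:1]
  names(grid) <- paste0("g_", .circuit_genes)
  grid <- unique(grid)
  tb <- tibble::as_tibble(grid)
  tb$topology <- purrr::pmap(grid, circuit_topology)
  tb
}

#' Active transcription-factor concentration
#'
#' The TF is active in its inducer-free form; internal inducer binds and
#' deactivates it, so induction releases repressed genes and withdraws
#' activation. Hill-1 binding with deactivation constant `K_ind_tf`.
#'
#' @param tf_total total TF protein, molecules/cell.
#' @param inducer internal inducer `i_i`, molecules/cell.
#' @param params a [cell_params()].
#' @return active TF, molecules/cell: `tf_total * K / (K + inducer)`.
#' @export
tf_activity <- function(tf_total, inducer, params = cell_params()) {
  if (any(tf_total < 0) || any(inducer < 0))
    stop("tf_total and inducer must be >= 0", call. = FALSE)
  tf_total * params$K_ind_tf / (params$K_ind_tf + inducer)
}

#' Circuit-regulated transcription rate of one gene
#'
#' Base rate `sTX_gene * w_gene * e / (theta_gene + e)` scaled by a Hill-1
#' term in the active TF with strength `K_gene`; a shared basal leak keeps
#' both fully-repressed and unactivated genes expressible at a small
#' fraction of the full rate.
#'
#' @param gene one of `"T" "E" "Ep" "Tp" "TF"`.
#' @param design a [circuit_design()].
#' @param tf_active active TF, molecules/cell.
#' @param params a [cell_params()].
#' @param e translation precursor (molecules/cell); transcription saturates
#'   in `e`.
#' @return transcription rate, transcripts/min.
#' @export
regulated_transcription <- function(gene, design, tf_active,
                                    params = cell_params(), e = Inf) {
  stopifnot(gene %in% .circuit_genes, tf_active >= 0)
  validate_circuit_design(design)
  g <- design$topology[[gene]]
  base <- design$sTX[[gene]] * params$w[[gene]] *
    (if (is.infinite(e)) 1 else e / (params$theta[[gene]] + e))
  if (g == 0) return(base)
  K <- design$K[[gene]]
  occ <- K * tf_active / (1 + K * tf_active)
  lk <- params$leak
  if (g > 0) base * (lk + (1 - lk) * occ)
  else       base * (lk + (1 - lk) * (1 - occ))
}

#' External inducer input schedule
#'
#' Zero before the induction time `tau`; a bolus of `dose` molecules is added
#' to the culture at `t = tau` and thereafter depletes only through cellular
#' uptake (handled by the batch ODEs).
#'
#' @param design a [circuit_design()].
#' @param options a [batch_options()].
#' @return function `I(t)` giving the bolus contribution at time `t` (step
#'   function used by the simulator to split integration at `tau`).
#' @export
induction_schedule <- function(design, options = batch_options()) {
  tau <- design$tau
  if (tau < 0 || tau > options$t_max)
    stop("tau must lie in [0, t_max]", call. = FALSE)
  dose <- options$inducer_dose
  function(t) ifelse(t >= tau, dose, 0)
}
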