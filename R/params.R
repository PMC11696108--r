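#' @importFrom rlang .data
NULL

# gene order used everywhere: index into per-gene vectors
.genes <- c("T", "E", "Ep", "Tp", "TF", "X", "R")
.circuit_genes <- c("T", "E", "Ep", "Tp", "TF")

#' Host cell parameters
#'
#' Constructs the parameter set of the host-aware single-cell model: an
#' E. coli-like host expressing a two-enzyme heterologous synthesis pathway
#' (`Ep` makes the product, `Tp` exports it) alongside its native nutrient
#' transporter `T`, metabolic enzyme `E`, a non-specific transporter `X`
#' (which also carries the housekeeping proteome mass, under negative
#' autoregulation), ribosomes `R`, and the circuit transcription factor `TF`.
#'
#' Units are minutes for time and molecules per cell for intracellular
#' species; external pools are molecules per culture. Growth emerges from the
#' global translation rate: `lambda = gamma(e) * sum(c_x) / M0`, so any
#' heterologous expression or metabolite drain feeds back on growth through
#' competition for ribosomes and for the translation precursor `e`.
#'
#' @param M0 total cell protein mass, amino-acid equivalents.
#' @param gamma_max maximal peptide elongation rate, aa/min/ribosome.
#' @param K_gamma half-saturation of elongation in precursor `e`.
#' @param ns precursor units gained per catabolised internal metabolite.
#' @param d_m mRNA decay rate, 1/min.
#' @param d_p protein decay rate, 1/min (0 = stable proteome).
#' @param kb,ku mRNA-ribosome binding/unbinding rates.
#' @param w named vector of maximal transcription rates, transcripts/min,
#'   for genes `r paste(.genes, collapse = ", ")`.
#' @param theta named vector of transcription half-saturation constants in `e`.
#' @param n named vector of gene lengths (codons).
#' @param kcat,Km named turnover/Michaelis constants for `T`, `E`, `Ep`,
#'   `Tp`, `X`. `Km["T"]` acts on the external substrate pool (culture
#'   units); the rest are molecules/cell.
#' @param v_ind,Km_ind inducer uptake Vmax (molecules/min/cell) and external
#'   half-saturation.
#' @param K_ind_tf internal inducer level that deactivates half the TF pool.
#' @param Kq_X,hq_X autoregulation threshold and Hill coefficient of `X`.
#' @param leak basal fraction of full transcription under TF control.
#' @param drain_point `"metabolite"`: the pathway consumes the internal
#'   metabolite `s_i`; `"precursor"`: it directly drains the translation
#'   precursor `e`.
#'
#' @return An object of class `cell_params` (a validated named list).
#' @export
#' @examples
#' cp <- cell_params()
#' cp$gamma_max
cell_params <- function(M0 = 1e8,
                        gamma_max = 1260,
                        K_gamma = 7,
                        ns = 0.5,
                        d_m = 0.1,
                        d_p = 0,
                        kb = 1,
                        ku = 1,
                        w = c(T = 4.14, E = 4.14, Ep = 4.14, Tp = 4.14,
                              TF = 4.14, X = 948.93, R = 930),
                        theta = c(T = 4.38, E = 4.38, Ep = 4.38, Tp = 4.38,
                                  TF = 4.38, X = 4.38, R = 426.87),
                        n = c(T = 300, E = 300, Ep = 300, Tp = 300,
                              TF = 300, X = 300, R = 7549),
                        kcat = c(T = 726, E = 5800, Ep = 5800, Tp = 726,
                                 X = 0.01),
                        Km = c(T = 1e9, E = 1e3, Ep = 1e3, Tp = 1e3,
                               X = 1e3),
                        v_ind = 1000,
                        Km_ind = 1e6,
                        K_ind_tf = 10,
                        Kq_X = 1.522e5,
                        hq_X = 4,
                        leak = 1e-3,
                        drain_point = c("metabolite", "precursor")) {
  drain_point <- match.arg(drain_point)
  obj <- structure(
    list(M0 = M0, gamma_max = gamma_max, K_gamma = K_gamma, ns = ns,
         d_m = d_m, d_p = d_p, kb = kb, ku = ku,
         w = w[.genes], theta = theta[.genes], n = n[.genes],
         kcat = kcat[c("T", "E", "Ep", "Tp", "X")],
         Km = Km[c("T", "E", "Ep", "Tp", "X")],
         v_ind = v_ind, Km_ind = Km_ind, K_ind_tf = K_ind_tf,
         Kq_X = Kq_X, hq_X = hq_X, leak = leak,
         drain_point = drain_point),
    class = "cell_params")
  validate_cell_params(obj)
}

validate_cell_params <- function(x) {
  stopifnot(inherits(x, "cell_params"))
  num <- unlist(x[setdiff(names(x), "drain_point")])
  if (anyNA(num) || any(!is.finite(num)))
    stop("cell_params contains missing or non-finite values", call. = FALSE)
  if (any(num < 0))
    stop("all kinetic constants must be >= 0", call. = FALSE)
  if (x$M0 <= 0) stop("M0 must be positive", call. = FALSE)
  if (any(x$n < 1)) stop("gene lengths must be >= 1 codon", call. = FALSE)
  if (!x$drain_point %in% c("metabolite", "precursor"))
    stop("drain_point must be 'metabolite' or 'precursor'", call. = FALSE)
  x
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params> host-aware cell model parameters\n")
  cat("  M0 =", format(x$M0, big.mark = ","),
      "aa; gamma_max =", x$gamma_max, "aa/min; d_p =", x$d_p, "1/min\n")
  cat("  drain point:", x$drain_point, "\n")
  cat("  genes:", paste(.genes, collapse = " "), "\n")
  invisible(x)
}

#' Convert a protein half-life to a first-order decay rate
#'
#' @param half_life protein half-life in minutes (> 0).
#' @return decay rate `log(2) / half_life` in 1/min.
#' @export
#' @examples
#' half_life_to_decay_rate(7 * 60)   # ~0.0017 1/min
#' half_life_to_decay_rate(10 * 60)  # ~0.0012 1/min
half_life_to_decay_rate <- function(half_life) {
  if (any(!is.finite(half_life)) || any(half_life <= 0))
    stop("half_life must be positive and finite", call. = FALSE)
  log(2) / half_life
}

#' Read / write cell parameters as a YAML config
#'
#' Flat key-value serialisation; vectors keep their gene names. Round-trips
#' exactly (`read_cell_params(write_cell_params(x, f))` equals `x`).
#'
#' @param path file path.
#' @param params a `cell_params` object.
#' @return `read_cell_params` returns a `cell_params`;
#'   `write_cell_params` returns `path` invisibly.
#' @export
read_cell_params <- function(path) {
  raw <- yaml::read_yaml(path)
  vecs <- c("w", "theta", "n", "kcat", "Km")
  for (v in vecs) raw[[v]] <- unlist(raw[[v]])
  do.call(cell_params, raw)
}

#' @rdname read_cell_params
#' @export
write_cell_params <- function(params, path) {
  validate_cell_params(params)
  out <- unclass(params)
  vecs <- c("w", "theta", "n", "kcat", "Km")
  for (v in vecs) out[[v]] <- as.list(out[[v]])
  yaml::write_yaml(out, path)
  invisible(path)
}

# Pack parameters + design + mode into the flat vector the compiled RHS
# expects; layout must match src/cell_odes.c.
.pack_parms <- function(params, design = NULL, mode = c("cell", "batch"),
                        S_clamp = 0, I_clamp = 0, eps_S = 0) {
  mode <- match.arg(mode)
  if (is.null(design)) design <- circuit_design()
  g <- design$topology
  sTX <- design$sTX[.circuit_genes]
  K <- design$K[.circuit_genes]
  c(mode = as.numeric(mode == "batch"),
    drain = as.numeric(params$drain_point == "precursor"),
    M0 = params$M0, gamma_max = params$gamma_max, K_gamma = params$K_gamma,
    ns = params$ns, d_m = params$d_m, d_p = params$d_p,
    kb = params$kb, ku = params$ku,
    params$w, params$theta, params$n,
    kcat_T = params$kcat[["T"]], Km_T = params$Km[["T"]],
    kcat_E = params$kcat[["E"]], Km_E = params$Km[["E"]],
    kcat_Ep = params$kcat[["Ep"]], Km_Ep = params$Km[["Ep"]],
    kcat_Tp = params$kcat[["Tp"]], Km_Tp = params$Km[["Tp"]],
    kcat_X = params$kcat[["X"]], Km_X = params$Km[["X"]],
    v_ind = params$v_ind, Km_ind = params$Km_ind,
    K_ind_tf = params$K_ind_tf,
    Kq_X = params$Kq_X, hq_X = params$hq_X,
    g, sTX, K,
    leak = params$leak, S_clamp = S_clamp, I_clamp = I_clamp,
    eps_S = eps_S, res65 = 0)
}

# state template and helpers ------------------------------------------------

.state_names <- c("B", "S_x", "P_x", "I_x", "s_i", "e", "p_i", "i_i",
                  paste0("m_", .genes), paste0("c_", .genes),
                  paste0("p_", .genes))

#' Construct a cell/culture state vector
#'
#' @param values named numeric values overriding the (zero) template; free
#'   ribosomes are `p_R`.
#' @return named numeric vector of length 29 in canonical order.
#' @export
cell_state <- function(values = NULL) {
  y <- stats::setNames(numeric(length(.state_names)), .state_names)
  if (!is.null(values)) {
    bad <- setdiff(names(values), .state_names)
    if (length(bad))
      stop("unknown state names: ", paste(bad, collapse = ", "),
           call. = FALSE)
    y[names(values)] <- values
  }
  if (any(!is.finite(y)) || any(y < 0))
    stop("state must be finite and non-negative", call. = FALSE)
  y
}

.out_names <- c("lambda", "r_T", "v_E", "v_Ep", "v_Tp", "v_export",
                "r_uInd", "tf_active")
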