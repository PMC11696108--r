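# Robustness of a design's culture performance to parameter perturbation:
# perturb every continuous dial by independent multiplicative U(1-f, 1+f),
# re-evaluate (vP, pY), and measure the area of the convex hull containing
# the perturbed performance cloud. Larger area = performance moves more
# under the same perturbation = less robust.

#' Perturb a circuit design
#'
#' Every continuous parameter (the tunable `sTX`, the active `K`, and `tau`)
#' is multiplied by an independent uniform factor in
#' `[1 - fraction, 1 + fraction]`; the topology is untouched and results are
#' clipped back into the design's box (clips counted in attribute
#' `"n_clipped"`).
#'
#' @param design a [circuit_design()].
#' @param fraction perturbation half-width (0.2 = +/-20\%).
#' @return a perturbed, valid `circuit_design`.
#' @export
perturb_design <- function(design, fraction = 0.2) {
  validate_circuit_design(design)
  stopifnot(fraction >= 0)
  n_clip <- 0L
  jitter <- function(x, lo, hi) {
    x2 <- x * stats::runif(length(x), 1 - fraction, 1 + fraction)
    cl <- pmin(pmax(x2, lo), hi)
    n_clip <<- n_clip + sum(cl != x2)
    cl
  }
  sTX <- design$sTX
  tune <- design$sTX_bounds["hi", ] > design$sTX_bounds["lo", ]
  sTX[tune] <- jitter(sTX[tune], design$sTX_bounds["lo", tune],
                      design$sTX_bounds["hi", tune])
  K <- design$K
  on <- design$topology != 0
  K[on] <- jitter(K[on], 1e-6, 1)
  tau <- jitter(design$tau, 0, 24 * 60)
  out <- circuit_design(design$topology, sTX = sTX, K = K, tau = tau,
                        sTX_bounds = design$sTX_bounds)
  attr(out, "n_clipped") <- n_clip
  out
}

# shoelace area of a polygon given vertex coordinates in order
.polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Convex hull area of a point cloud
#'
#' @param x,y point coordinates.
#' @return area of the convex hull (0 for degenerate/collinear clouds, with
#'   a warning).
#' @export
hull_area <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    warning("fewer than 3 points: hull area 0", call. = FALSE)
    return(0)
  }
  h <- grDevices::chull(x, y)
  a <- .polygon_area(x[h], y[h])
  if (a == 0) warning("degenerate (collinear) cloud: hull area 0",
                      call. = FALSE)
  a
}

#' Robustness of culture performance to design-parameter variation
#'
#' Evaluates `(vP, pY)` for `n` independently perturbed copies of a design
#' and reports the convex-hull area of the performance cloud.
#'
#' @param params a [cell_params()].
#' @param design the reference [circuit_design()] (typically a front's knee
#'   point).
#' @param n number of perturbations.
#' @param fraction perturbation half-width.
#' @param seed integer seed.
#' @param options a [batch_options()].
#' @param normalise divide the cloud by the reference `(vP, pY)` before
#'   taking the area (area then in relative units).
#' @return a `robustness_result`: list with `cloud` (tibble `vP`, `pY`),
#'   `area`, `reference` (tibble), `n_failed`, `seed`, `fraction`.
#' @export
robustness_area <- function(params = cell_params(), design,
                            n = 1000, fraction = 0.2, seed = 1,
                            options = batch_options(),
                            normalise = FALSE) {
  set.seed(seed)
  fast <- options; fast$n_out <- 2
  ref <- .culture_objectives(params, design, fast)
  evals <- purrr::map(seq_len(n), function(i) {
    d <- perturb_design(design, fraction)
    tryCatch(.culture_objectives(params, d, fast),
             error = function(e) c(NA_real_, NA_real_))
  })
  cloud <- tibble::tibble(vP = vapply(evals, `[`, numeric(1), 1),
                          pY = vapply(evals, `[`, numeric(1), 2))
  n_failed <- sum(!stats::complete.cases(cloud))
  if (n_failed == n) stop("all perturbed evaluations failed", call. = FALSE)
  sc <- if (normalise) ref else c(1, 1)
  area <- if (fraction == 0) 0 else
    hull_area(cloud$vP / sc[1], cloud$pY / sc[2])
  structure(list(cloud = cloud, area = area,
                 reference = tibble::tibble(vP = ref[1], pY = ref[2]),
                 n = n, n_failed = n_failed, fraction = fraction,
                 seed = seed, normalise = normalise),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf(
    "<robustness_result> n = %d, fraction = %.2f, area = %.4g%s\n",
    x$n, x$fraction, x$area, if (x$normalise) " (normalised)" else ""))
  invisible(x)
}

#' @export
tidy.robustness_result <- function(x, ...) x$cloud

#' @export
glance.robustness_result <- function(x, ...) {
  tibble::tibble(area = x$area, n = x$n, n_failed = x$n_failed,
                 fraction = x$fraction,
                 vP_ref = x$reference$vP, pY_ref = x$reference$pY)
}

#' Plot a robustness cloud with its convex hull
#'
#' @param object a `robustness_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.robustness_result <- function(object, ...) {
  cl <- object$cloud[stats::complete.cases(object$cloud), ]
  h <- grDevices::chull(cl$vP, cl$pY)
  hull <- cl[c(h, h[1]), ]
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$vP, y = .data$pY)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_path(data = hull, colour = "firebrick") +
    ggplot2::geom_point(data = object$reference, colour = "black",
                        shape = 4, size = 3) +
    ggplot2::labs(x = "volumetric productivity vP",
                  y = "product yield pY") +
    ggplot2::theme_minimal()
}
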