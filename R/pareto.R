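# Pareto utilities for two maximised objectives: nondominated filtering,
# hypervolume, knee-point selection.

#' Nondominated subset of a set of objective pairs
#'
#' Both objectives are maximised. A point is dominated if another point is
#' >= in both coordinates and > in at least one. Implemented as a sweep over
#' points sorted by the first objective (descending) keeping the running
#' best second objective; ties handled so duplicates of a nondominated
#' point are all kept. Input order is preserved in the output.
#'
#' @param points data frame / tibble whose first two numeric columns (or
#'   columns named by `objectives`) hold the objective values.
#' @param objectives length-2 character vector of objective column names.
#' @return the nondominated rows of `points`, original order (a tibble).
#' @export
pareto_filter <- function(points, objectives = NULL) {
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) return(points)
  if (is.null(objectives))
    objectives <- names(points)[vapply(points, is.numeric, TRUE)][1:2]
  f1 <- points[[objectives[1]]]; f2 <- points[[objectives[2]]]
  if (any(!is.finite(f1)) || any(!is.finite(f2)))
    stop("objective values must be finite", call. = FALSE)
  ord <- order(f1, f2, decreasing = TRUE)
  keep <- logical(nrow(points))
  best2 <- -Inf
  # process groups of equal f1 together: within a group only the max-f2
  # points survive (duplicates are mutually nondominated and all kept),
  # and the group survives iff it strictly improves the running best f2
  i <- 1
  while (i <= length(ord)) {
    j <- i
    while (j < length(ord) && f1[ord[j + 1]] == f1[ord[i]]) j <- j + 1
    grp <- ord[i:j]
    g2max <- max(f2[grp])
    if (g2max > best2) {
      keep[grp[f2[grp] == g2max]] <- TRUE
      best2 <- g2max
    }
    i <- j + 1
  }
  points[keep, , drop = FALSE]
}

# logical domination helper (maximise-maximise)
.dominates <- function(a, b) all(a >= b) && any(a > b)

#' Hypervolume (dominated area) of a 2-D maximisation front
#'
#' Area jointly dominated by the points relative to a reference point
#' (default the origin). Standard front-comparison scalar: larger is better,
#' non-decreasing in optimiser budget.
#'
#' @param points data frame with two numeric objective columns.
#' @param ref reference point, length 2 (must be dominated by all points
#'   counted; points below `ref` contribute nothing).
#' @param objectives objective column names (default first two numeric).
#' @return scalar area.
#' @export
hypervolume <- function(points, ref = c(0, 0), objectives = NULL) {
  points <- tibble::as_tibble(points)
  if (nrow(points) == 0) return(0)
  if (is.null(objectives))
    objectives <- names(points)[vapply(points, is.numeric, TRUE)][1:2]
  nd <- pareto_filter(points, objectives)
  f1 <- nd[[objectives[1]]] - ref[1]
  f2 <- nd[[objectives[2]]] - ref[2]
  ok <- f1 > 0 & f2 > 0
  if (!any(ok)) return(0)
  f1 <- f1[ok]; f2 <- f2[ok]
  ord <- order(f1, decreasing = TRUE)
  f1 <- f1[ord]; f2 <- f2[ord]
  area <- 0; prev2 <- 0
  for (i in seq_along(f1)) {
    if (f2[i] > prev2) {
      area <- area + f1[i] * (f2[i] - prev2)
      prev2 <- f2[i]
    }
  }
  area
}

#' Knee point of a Pareto front
#'
#' The front member maximising perpendicular distance from the chord joining
#' the two extremes of the front, computed in objective space normalised to
#' the unit square (so the choice is invariant to rescaling either
#' objective). Singleton fronts return their only member; exact ties return
#' the first member in front order.
#'
#' @param front a `pareto_front` (see [optimize_genotype()]) or a data frame
#'   of objective pairs.
#' @param objectives objective column names.
#' @return the selected row (tibble, one row); for a `pareto_front`, the
#'   corresponding design is attached as attribute `"design"`.
#' @export
knee_point <- function(front, objectives = NULL) {
  tb <- if (inherits(front, "pareto_front")) front$front else
    tibble::as_tibble(front)
  if (nrow(tb) == 0) stop("empty front", call. = FALSE)
  if (is.null(objectives))
    objectives <- names(tb)[vapply(tb, is.numeric, TRUE)][1:2]
  x <- tb[[objectives[1]]]; y <- tb[[objectives[2]]]
  rx <- range(x); ry <- range(y)
  sx <- if (diff(rx) > 0) (x - rx[1]) / diff(rx) else rep(0.5, length(x))
  sy <- if (diff(ry) > 0) (y - ry[1]) / diff(ry) else rep(0.5, length(y))
  if (nrow(tb) <= 2) {
    idx <- 1L
  } else {
    a <- which.max(sx - sy)   # max-f1 extreme
    b <- which.max(sy - sx)   # max-f2 extreme
    vx <- sx[b] - sx[a]; vy <- sy[b] - sy[a]
    nrm <- sqrt(vx^2 + vy^2)
    if (nrm == 0) {
      idx <- 1L
    } else {
      d <- abs(vx * (sy - sy[a]) - vy * (sx - sx[a])) / nrm
      idx <- which.max(d)   # first maximiser wins ties
    }
  }
  out <- tb[idx, , drop = FALSE]
  if (inherits(front, "pareto_front"))
    attr(out, "design") <- front$designs[[idx]]
  out
}

# pareto_front container ----------------------------------------------------

new_pareto_front <- function(front, designs, problem, budget, seed,
                             extra = list()) {
  structure(c(list(front = front, designs = designs, problem = problem,
                   budget = budget, seed = seed), extra),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %s: %d nondominated designs\n",
              x$problem, nrow(x$front)))
  cat(sprintf("  budget: pop %d x %d generations, seed %d\n",
              x$budget$pop_size, x$budget$generations, x$seed))
  print(utils::head(x$front, 5))
  invisible(x)
}

#' Tidy a Pareto front
#'
#' @param x a `pareto_front`.
#' @param ... unused.
#' @return tibble: one row per front member with decision variables and
#'   objectives.
#' @export
tidy.pareto_front <- function(x, ...) x$front

#' One-row summary of a Pareto front
#'
#' @param x a `pareto_front`.
#' @param ... unused.
#' @return tibble: front size, hypervolume, objective ranges.
#' @export
glance.pareto_front <- function(x, ...) {
  obj <- attr(x$front, "objectives") %||% names(x$front)[
    vapply(x$front, is.numeric, TRUE)][1:2]
  tibble::tibble(n = nrow(x$front),
                 hypervolume = hypervolume(x$front, objectives = obj),
                 !!paste0("max_", obj[1]) := max(x$front[[obj[1]]]),
                 !!paste0("max_", obj[2]) := max(x$front[[obj[2]]]))
}

#' Plot a Pareto front
#'
#' @param object a `pareto_front`.
#' @param ... unused.
#' @return a ggplot of the two objectives.
#' @export
autoplot.pareto_front <- function(object, ...) {
  obj <- attr(object$front, "objectives") %||% names(object$front)[
    vapply(object$front, is.numeric, TRUE)][1:2]
  ggplot2::ggplot(object$front,
                  ggplot2::aes(x = .data[[obj[1]]], y = .data[[obj[2]]])) +
    ggplot2::geom_step(direction = "vh", colour = "grey60") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(title = object$problem) +
    ggplot2::theme_minimal()
}
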