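# Elitist multiobjective genetic algorithm (NSGA-II): fast nondominated
# sorting, crowding distance, binary tournament selection, simulated binary
# crossover and polynomial mutation, all on decision vectors scaled to
# [0, 1]. Written here because no multiobjective GA is available in the
# installed stack; the algorithmic components follow the standard NSGA-II
# formulation.

#' Optimiser budget and GA settings
#'
#' @param pop_size population size (>= 4, rounded up to even).
#' @param generations number of generations (>= 1).
#' @param seed integer random seed; every run with the same seed and budget
#'   is bitwise-reproducible.
#' @param p_cross crossover probability (per pair).
#' @param eta_cross SBX distribution index.
#' @param eta_mut polynomial-mutation distribution index.
#' @param p_mut per-variable mutation probability (default `1/n_var`).
#' @return an `optimizer_budget` list.
#' @export
optimizer_budget <- function(pop_size = 60, generations = 60, seed = 1,
                             p_cross = 0.9, eta_cross = 15, eta_mut = 20,
                             p_mut = NULL) {
  stopifnot(pop_size >= 4, generations >= 1)
  pop_size <- pop_size + pop_size %% 2
  structure(list(pop_size = pop_size, generations = generations,
                 seed = as.integer(seed), p_cross = p_cross,
                 eta_cross = eta_cross, eta_mut = eta_mut, p_mut = p_mut),
            class = "optimizer_budget")
}

# fast nondominated sort; F: n x 2 matrix, maximisation. Returns integer
# front rank per row (1 = nondominated).
.nds_rank <- function(F) {
  n <- nrow(F)
  rank <- integer(n)
  dominated_count <- integer(n)
  dominates_list <- vector("list", n)
  for (i in seq_len(n)) {
    di <- which(F[, 1] >= F[i, 1] & F[, 2] >= F[i, 2] &
                  (F[, 1] > F[i, 1] | F[, 2] > F[i, 2]))
    dominated_count[i] <- length(di)
    dj <- which(F[i, 1] >= F[, 1] & F[i, 2] >= F[, 2] &
                  (F[i, 1] > F[, 1] | F[i, 2] > F[, 2]))
    dominates_list[[i]] <- dj
  }
  current <- which(dominated_count == 0)
  r <- 1L
  while (length(current)) {
    rank[current] <- r
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates_list[[i]]) {
        dominated_count[j] <- dominated_count[j] - 1L
        if (dominated_count[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- unique(nxt)
    r <- r + 1L
  }
  rank
}

.crowding <- function(F) {
  n <- nrow(F)
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in 1:2) {
    o <- order(F[, k])
    rng <- F[o[n], k] - F[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (F[o[3:n], k] - F[o[1:(n - 2)], k]) / rng
  }
  d
}

.sbx <- function(p1, p2, eta, p_cross) {
  n <- length(p1)
  c1 <- p1; c2 <- p2
  if (stats::runif(1) < p_cross) {
    do <- stats::runif(n) < 0.5
    u <- stats::runif(n)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    c1[do] <- 0.5 * ((1 + beta[do]) * p1[do] + (1 - beta[do]) * p2[do])
    c2[do] <- 0.5 * ((1 - beta[do]) * p1[do] + (1 + beta[do]) * p2[do])
  }
  list(pmin(pmax(c1, 0), 1), pmin(pmax(c2, 0), 1))
}

.polymut <- function(x, eta, p_mut) {
  n <- length(x)
  do <- stats::runif(n) < p_mut
  if (any(do)) {
    u <- stats::runif(sum(do))
    xi <- x[do]
    delta <- ifelse(
      u < 0.5,
      (2 * u + (1 - 2 * u) * (1 - xi)^(eta + 1))^(1 / (eta + 1)) - 1,
      1 - (2 * (1 - u) + (2 * u - 1) * xi^(eta + 1))^(1 / (eta + 1)))
    x[do] <- pmin(pmax(xi + delta, 0), 1)
  }
  x
}

# binary tournament on (rank, -crowding)
.tournament <- function(rank, crowd) {
  n <- length(rank)
  a <- sample.int(n, n, replace = TRUE)
  b <- sample.int(n, n, replace = TRUE)
  better <- rank[a] < rank[b] |
    (rank[a] == rank[b] & crowd[a] > crowd[b])
  ifelse(better, a, b)
}

#' NSGA-II over the unit hypercube
#'
#' Maximises two objectives returned by `fn(x)` for decision vectors `x` in
#' `[0,1]^n_var`. Evaluation failures (errors or non-finite objectives) are
#' recorded and scored `(0, 0)` so the search continues.
#'
#' @param fn function of a numeric vector, returning two finite objective
#'   values (larger is better).
#' @param n_var number of decision variables.
#' @param budget an [optimizer_budget()].
#' @param seed_designs optional matrix of rows in `[0,1]^n_var` injected
#'   into the initial population.
#' @return list: `X` (decision rows of the archive of all nondominated
#'   solutions encountered), `F` (their objectives), `n_eval`, `n_failed`.
#' @export
nsga2 <- function(fn, n_var, budget = optimizer_budget(),
                  seed_designs = NULL) {
  set.seed(budget$seed)
  np <- budget$pop_size
  p_mut <- budget$p_mut %||% (1 / n_var)
  n_failed <- 0L

  evaluate <- function(X) {
    t(apply(X, 1, function(x) {
      f <- tryCatch(suppressWarnings(fn(x)),
                    error = function(e) c(NA_real_, NA_real_))
      if (length(f) != 2 || any(!is.finite(f))) {
        n_failed <<- n_failed + 1L
        c(0, 0)
      } else as.numeric(f)
    }))
  }

  # external archive of every nondominated solution seen: the returned
  # front, so a longer run (same seed = same search prefix) can only add
  # dominated area, making front quality monotone in budget
  arch_X <- matrix(numeric(0), 0, n_var)
  arch_F <- matrix(numeric(0), 0, 2)
  update_archive <- function(X, F) {
    AX <- rbind(arch_X, X); AF <- rbind(arch_F, F)
    keep <- .nds_rank(AF) == 1L
    AX <- AX[keep, , drop = FALSE]; AF <- AF[keep, , drop = FALSE]
    dup <- duplicated(round(AX, 12))
    arch_X <<- AX[!dup, , drop = FALSE]
    arch_F <<- AF[!dup, , drop = FALSE]
  }

  X <- matrix(stats::runif(np * n_var), np, n_var)
  if (!is.null(seed_designs)) {
    k <- min(nrow(seed_designs), np)
    X[seq_len(k), ] <- seed_designs[seq_len(k), , drop = FALSE]
  }
  F <- evaluate(X)
  n_eval <- np
  update_archive(X, F)

  for (gen in seq_len(budget$generations)) {
    rank <- .nds_rank(F)
    crowd <- numeric(np)
    for (r in unique(rank)) {
      idx <- rank == r
      crowd[idx] <- .crowding(F[idx, , drop = FALSE])
    }
    parents <- .tournament(rank, crowd)
    child <- matrix(0, np, n_var)
    for (i in seq(1, np, by = 2)) {
      cc <- .sbx(X[parents[i], ], X[parents[i + 1], ],
                 budget$eta_cross, budget$p_cross)
      child[i, ] <- .polymut(cc[[1]], budget$eta_mut, p_mut)
      child[i + 1, ] <- .polymut(cc[[2]], budget$eta_mut, p_mut)
    }
    Fc <- evaluate(child)
    n_eval <- n_eval + np
    update_archive(child, Fc)
    XX <- rbind(X, child); FF <- rbind(F, Fc)
    rk <- .nds_rank(FF)
    sel <- integer(0)
    for (r in sort(unique(rk))) {
      idx <- which(rk == r)
      if (length(sel) + length(idx) <= np) {
        sel <- c(sel, idx)
      } else {
        cd <- .crowding(FF[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)][
          seq_len(np - length(sel))])
        break
      }
    }
    X <- XX[sel, , drop = FALSE]
    F <- FF[sel, , drop = FALSE]
  }

  list(X = arch_X, F = arch_F, n_eval = n_eval, n_failed = n_failed)
}

#' Single-objective elitist GA over the unit hypercube
#'
#' Same variation operators as [nsga2()] but with scalar tournament
#' selection and mu+lambda elitism; used for the normalisation constants
#' (separate maximisation of each culture metric).
#'
#' @param fn function of a numeric vector returning one finite value to
#'   maximise.
#' @inheritParams nsga2
#' @return list: `x` (best decision vector), `f` (best value), `n_eval`.
#' @export
ga_maximize <- function(fn, n_var, budget = optimizer_budget(),
                        seed_designs = NULL) {
  set.seed(budget$seed)
  np <- budget$pop_size
  p_mut <- budget$p_mut %||% (1 / n_var)
  evaluate <- function(X) {
    apply(X, 1, function(x) {
      f <- tryCatch(suppressWarnings(fn(x)), error = function(e) NA_real_)
      if (!is.finite(f)) 0 else f
    })
  }
  X <- matrix(stats::runif(np * n_var), np, n_var)
  if (!is.null(seed_designs)) {
    k <- min(nrow(seed_designs), np)
    X[seq_len(k), ] <- seed_designs[seq_len(k), , drop = FALSE]
  }
  f <- evaluate(X)
  n_eval <- np
  for (gen in seq_len(budget$generations)) {
    a <- sample.int(np, np, replace = TRUE)
    b <- sample.int(np, np, replace = TRUE)
    parents <- ifelse(f[a] >= f[b], a, b)
    child <- matrix(0, np, n_var)
    for (i in seq(1, np, by = 2)) {
      cc <- .sbx(X[parents[i], ], X[parents[i + 1], ],
                 budget$eta_cross, budget$p_cross)
      child[i, ] <- .polymut(cc[[1]], budget$eta_mut, p_mut)
      child[i + 1, ] <- .polymut(cc[[2]], budget$eta_mut, p_mut)
    }
    fc <- evaluate(child)
    n_eval <- n_eval + np
    XX <- rbind(X, child); ff <- c(f, fc)
    sel <- order(ff, decreasing = TRUE)[seq_len(np)]
    X <- XX[sel, , drop = FALSE]; f <- ff[sel]
  }
  list(x = X[1, ], f = f[1], n_eval = n_eval)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
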