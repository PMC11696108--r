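# Shared fixtures for the test suite. Everything is built in code; the small
# budgets here keep a full test run to a few minutes while still exercising
# every pipeline end to end.

hf_params <- function(...) cell_params(...)

# box allowing the constitutive (no TF) strain with free sTX_E/Ep/Tp
hf_bounds <- rbind(lo = c(T = 1, E = 1e-3, Ep = 0, Tp = 0, TF = 0),
                   hi = c(T = 1, E = 1, Ep = 1, Tp = 1, TF = 0))

# constitutive strain design (no circuit)
hf_design <- function(E = 1, Ep = 1e-3, Tp = 1e-3) {
  circuit_design(sTX = c(T = 1, E = E, Ep = Ep, Tp = Tp, TF = 0),
                 sTX_bounds = hf_bounds)
}

# dual-control two-stage circuit with sensible mid-range dials
hf_dual_design <- function(tau = 160, K_E = 0.01, K_Ep = 1, K_Tp = 1) {
  circuit_design(circuit_topology(g_E = 1, g_Ep = -1, g_Tp = -1),
                 sTX = c(T = 1, E = 1, Ep = 2, Tp = 2, TF = 0.5),
                 K = c(T = 0, E = K_E, Ep = K_Ep, Tp = K_Tp, TF = 0),
                 tau = tau)
}

# brute-force O(n^2) nondominated oracle (maximise both)
oracle_nondominated <- function(f1, f2) {
  n <- length(f1)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && f1[j] >= f1[i] && f2[j] >= f2[i] &&
          (f1[j] > f1[i] || f2[j] > f2[i])) {
        dominated <- TRUE
        break
      }
    }
    keep[i] <- !dominated
  }
  keep
}

# independent gift-wrapping convex hull + shoelace area oracle
oracle_hull_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3) return(0)
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (k in seq_len(nrow(pts))) {
      if (k == cur) next
      cross <- (pts[cand, 1] - pts[cur, 1]) * (pts[k, 2] - pts[cur, 2]) -
        (pts[cand, 2] - pts[cur, 2]) * (pts[k, 1] - pts[cur, 1])
      if (cand == cur || cross < 0 ||
          (cross == 0 && sum((pts[k, ] - pts[cur, ])^2) >
             sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- k
    }
    cur <- cand
    if (cur == start) break
    if (length(hull) > nrow(pts)) break
  }
  hx <- pts[hull, 1]; hy <- pts[hull, 2]
  m <- length(hx)
  abs(sum(hx * hy[c(2:m, 1)] - hx[c(2:m, 1)] * hy)) / 2
}
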