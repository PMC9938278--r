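#' Drift of the reduced spiking subsystem
#'
#' The fast (V, N) subsystem used for bifurcation analysis: the TREK1,
#' ACh and GABA conductances are zeroed (noise off) so only the leak,
#' calcium and delayed-rectifier potassium currents remain, plus an
#' optional quasi-steady sodium current (`M = m_inf(V)^3`,
#' `H = h_inf(V)`).
#'
#' @param V,N state of the reduced system.
#' @param p `sac_params` parameter set.
#' @param Iapp applied current (pA).
#' @param include_na include quasi-steady sodium? Default `FALSE`.
#' @return `c(dV, dN)` in mV/ms and 1/ms.
#' @export
reduced_drift <- function(V, N, p, Iapp = p$Iapp, include_na = FALSE) {
  I <- -p$gLeak * (V - p$ELeak) -
    p$gCa * gate_inf(V, p$V1, p$V2) * (V - p$ECa) -
    p$gK * N * (V - p$EK)
  if (include_na) {
    r <- sodium_rates(V, p)
    minf <- r$alpha_m / (r$alpha_m + r$beta_m)
    hinf <- r$alpha_h / (r$alpha_h + r$beta_h)
    I <- I - p$gNa * minf^3 * hinf * (V - p$ENa)
  }
  c(dV = (I + Iapp) / p$Cm,
    dN = rate_lambda(V, p$V3, p$V4) * (gate_inf(V, p$V3, p$V4) - N) / p$tauN)
}

# net membrane current of the reduced system with N at steady state;
# equilibria of (V, N) are exactly the roots of iv_curve(V) + Iapp
iv_curve <- function(V, p, include_na = FALSE) {
  vapply(V, function(v)
    reduced_drift(v, gate_inf(v, p$V3, p$V4), p, Iapp = 0,
                  include_na = include_na)[["dV"]] * p$Cm,
    numeric(1))
}

#' Equilibria of the reduced (V, N) system
#'
#' Finds all fixed points of the reduced spiking subsystem at a given
#' applied current. Because `dN = 0` forces `N = N_inf(V)`, roots are
#' located on the one-dimensional steady-state I-V curve by scanning a
#' dense grid of voltages (multi-start) and polishing each sign change
#' with a bracketing root finder; duplicates are merged at 1e-3 mV. Each
#' equilibrium is classified from the eigenvalues of the 2x2 Jacobian.
#'
#' @param p `sac_params` parameter set (gTREK/gACh/gGABA are forced to 0
#'   for the reduced analysis).
#' @param Iapp applied current (pA).
#' @param v_range voltage search window (mV).
#' @param n_starts number of grid starts across `v_range`.
#' @param include_na include quasi-steady sodium (default `FALSE`: the
#'   sodium current shifts depolarisation speed, not the fold).
#' @return data.frame with columns `V_star`, `N_star`, `classification`
#'   (one of `stable-node`, `unstable-node`, `saddle`, `focus-stable`,
#'   `focus-unstable`), `eig1_re`, `eig1_im`, `eig2_re`, `eig2_im`.
#'   Zero rows if no root converges.
#' @examples
#' eq <- find_equilibria(sac_parameters(), Iapp = 0)
#' eq$classification
#' @export
find_equilibria <- function(p, Iapp = 0, v_range = c(-90, 0), n_starts = 64,
                            include_na = FALSE) {
  p <- sac_params_override(p, gTREK = 0, gACh = 0, gGABA = 0, sigma = 0)
  f <- function(v) iv_curve(v, p, include_na) + Iapp
  grid <- seq(v_range[1], v_range[2], length.out = max(n_starts, 2))
  fg <- f(grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1)) {
    if (!is.finite(fg[i]) || !is.finite(fg[i + 1])) next
    if (fg[i] == 0) roots <- c(roots, grid[i])
    if (fg[i] * fg[i + 1] < 0) {
      r <- tryCatch(stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-12),
                    error = function(e) NULL)
      if (!is.null(r)) roots <- c(roots, r$root)
    }
  }
  if (fg[length(grid)] == 0) roots <- c(roots, grid[length(grid)])
  roots <- sort(roots)
  if (length(roots) > 1)
    roots <- roots[c(TRUE, diff(roots) > 1e-3)]
  if (!length(roots))
    return(data.frame(V_star = numeric(0), N_star = numeric(0),
                      classification = character(0),
                      eig1_re = numeric(0), eig1_im = numeric(0),
                      eig2_re = numeric(0), eig2_im = numeric(0)))
  out <- lapply(roots, function(v) {
    n <- gate_inf(v, p$V3, p$V4)
    J <- reduced_jacobian(v, n, p, Iapp, include_na)
    ev <- eigen(J, only.values = TRUE)$values
    data.frame(V_star = v, N_star = n,
               classification = classify_eigenvalues(ev),
               eig1_re = Re(ev[1]), eig1_im = Im(ev[1]),
               eig2_re = Re(ev[2]), eig2_im = Im(ev[2]))
  })
  do.call(rbind, out)
}

reduced_jacobian <- function(V, N, p, Iapp, include_na = FALSE, h = 1e-6) {
  f <- function(v, n) reduced_drift(v, n, p, Iapp, include_na)
  dv <- (f(V + h, N) - f(V - h, N)) / (2 * h)
  dn <- (f(V, N + h) - f(V, N - h)) / (2 * h)
  matrix(c(dv[1], dn[1], dv[2], dn[2]), 2, 2)
}

classify_eigenvalues <- function(ev, tol = 1e-12) {
  if (any(abs(Im(ev)) > tol)) {
    if (max(Re(ev)) < 0) "focus-stable" else "focus-unstable"
  } else {
    re <- Re(ev)
    if (all(re < 0)) "stable-node"
    else if (all(re > 0)) "unstable-node"
    else "saddle"
  }
}

# does the below-threshold resting configuration (stable node + saddle) exist?
has_rest_pair <- function(eq) {
  all(c("stable-node", "saddle") %in% eq$classification)
}

#' Saddle-node bifurcation current of the reduced system
#'
#' Locates, by bisection on the presence of the stable-node/saddle
#' equilibrium pair, the applied current at which the two coalesce. That
#' fold sets the spiking threshold: above it only the focus remains and
#' the cell oscillates.
#'
#' @param p `sac_params` parameter set.
#' @param I_lo,I_hi bracketing currents (pA); the rest pair must exist at
#'   `I_lo` and be gone at `I_hi`.
#' @param tol bisection tolerance (pA).
#' @param include_na passed to [find_equilibria()].
#' @param n_starts root-scan grid density; finer than the
#'   [find_equilibria()] default so the nearly-coalesced node/saddle pair
#'   is still resolved close to the fold.
#' @return List with `I_sn` (pA) and `V_sn` (mV, coalescence voltage).
#' @examples
#' saddle_node_current(sac_parameters())
#' @export
saddle_node_current <- function(p, I_lo = 0, I_hi = 10, tol = 1e-4,
                                include_na = FALSE, n_starts = 1024) {
  lo_eq <- find_equilibria(p, I_lo, n_starts = n_starts,
                           include_na = include_na)
  hi_eq <- find_equilibria(p, I_hi, n_starts = n_starts,
                           include_na = include_na)
  if (!has_rest_pair(lo_eq))
    stop("no stable-node/saddle pair at I_lo = ", I_lo, " pA; cannot bracket the fold")
  if (has_rest_pair(hi_eq))
    stop("stable-node/saddle pair still present at I_hi = ", I_hi,
         " pA; cannot bracket the fold")
  lo <- I_lo; hi <- I_hi; eq_lo <- lo_eq
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    eq <- find_equilibria(p, mid, n_starts = n_starts,
                          include_na = include_na)
    if (has_rest_pair(eq)) { lo <- mid; eq_lo <- eq } else hi <- mid
  }
  vs <- eq_lo$V_star[eq_lo$classification %in% c("stable-node", "saddle")]
  list(I_sn = (lo + hi) / 2, V_sn = mean(vs))
}

#' Codimension-1 bifurcation scan in applied current
#'
#' Tabulates all equilibria of the reduced system over a grid of applied
#' currents and locates the saddle-node fold. Below the fold three
#' equilibria coexist (stable node, saddle, focus); above it only the
#' focus survives and spiking is possible.
#'
#' @param p `sac_params` parameter set.
#' @param I_values applied-current grid (pA).
#' @param include_na passed to [find_equilibria()].
#' @return List of class `sac_bifurcation`: `branches` (data.frame with
#'   `I`, `V_star`, `N_star`, `classification`), `I_sn`, `V_sn`.
#' @export
bifurcation_scan <- function(p, I_values = seq(0, 10, by = 0.1),
                             include_na = FALSE) {
  rows <- lapply(I_values, function(I) {
    eq <- find_equilibria(p, I, include_na = include_na)
    if (!nrow(eq)) return(NULL)
    cbind(I = I, eq[c("V_star", "N_star", "classification")])
  })
  branches <- do.call(rbind, rows)
  sn <- tryCatch(
    saddle_node_current(p, min(I_values), max(I_values), include_na = include_na),
    error = function(e) list(I_sn = NA_real_, V_sn = NA_real_))
  structure(list(branches = branches, I_sn = sn$I_sn, V_sn = sn$V_sn),
            class = "sac_bifurcation")
}

#' @export
print.sac_bifurcation <- function(x, ...) {
  cat("Codimension-1 scan:", nrow(x$branches), "equilibria on",
      length(unique(x$branches$I)), "current values\n")
  cat(sprintf("Saddle-node fold: I_sn = %.4f pA at V_sn = %.2f mV\n",
              x$I_sn, x$V_sn))
  invisible(x)
}

# apply overrides to an existing sac_params object
sac_params_override <- function(p, ...) {
  q <- merge_named(unclass(p), list(...), what = "parameter")
  class(q) <- class(p)
  q
}
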