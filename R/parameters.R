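#' Biophysical model parameters for a starburst amacrine cell
#'
#' Returns the full parameter set of the SAC wave model as a named list of
#' class `sac_params`. Defaults are the published reference values for every
#' biophysical constant; any field can be overridden by name.
#'
#' Working units are consistent throughout the package: time in ms, voltage
#' in mV, current in pA, conductance in nS, capacitance in pF and
#' concentration in mM. Dimensionless gains (`lambda`, `alpha`, `beta`,
#' `rho_e`, `rho_i`, `delta`, `De`, `Di`, bias weights) act in these working
#' units.
#'
#' Fields:
#' \describe{
#'   \item{V1, V2}{Calcium gating half-activation (mV) and slope (mV).}
#'   \item{V3, V4}{Potassium gating half-activation (mV) and slope (mV).}
#'   \item{V0e, Vse, V0i, Vsi}{Release midpoints (mV) and steepness
#'     (1/mV) of the ACh and GABA release sigmoids.}
#'   \item{V7..V18}{Sodium alpha/beta rate constants (Hodgkin-Huxley form,
#'     shifted so half points sit at V8 = -40, V11 = V14 = -65, V17 = -35).}
#'   \item{Cm}{Membrane capacitance (pF).}
#'   \item{gLeak, gCa, gK, gNa, gTREK, gACh, gGABA}{Maximal conductances (nS).}
#'   \item{ELeak, ECa, EK, ENa, EACh, ECl}{Reversal potentials (mV).}
#'   \item{sigma}{Stationary amplitude of the noise current (pA). The OU
#'     state W has stationary SD `sqrt(tauW / 2)`, so the instantaneous
#'     noise current is `sigma * W / sqrt(tauW / 2)`.}
#'   \item{tauN, tauA, tauB, tauC, tauACh, tauGABA, tauW}{Time constants (ms).}
#'   \item{C0}{Basal calcium production (mM).}
#'   \item{lambda}{Calcium clearance gain.}
#'   \item{delta}{Calcium-current to concentration conversion (mM/pA).}
#'   \item{alpha, beta}{cAMP-decay and TREK1 activation gains.}
#'   \item{rho_e, rho_i}{ACh / GABA release gains (mM at full release).}
#'   \item{Kd}{Squared half-activation constant of the receptor Hill
#'     function (mM^2); activation is T^2/(T^2 + Kd).}
#'   \item{De, Di}{Diffusion rate scales (1/ms) of the ACh and GABA fields
#'     on the cell lattice.}
#'   \item{dXe, dYe, dXi, dYi}{Directional bias weight pairs
#'     (`c(L =, R =)` / `c(U =, D =)`) of the diffusion stencils.}
#'   \item{Iapp}{Applied (injected) current (pA).}
#' }
#'
#' @param ... named overrides of individual fields, e.g. `gACh = 0`.
#'   Unknown names are an error (with a nearest-match hint).
#' @return A named list of class `sac_params`.
#' @examples
#' p <- sac_parameters(gTREK = 0, Iapp = 10)
#' p$Cm
#' @export
sac_parameters <- function(...) {
  p <- list(
    # gating constants (mV)
    V1 = -20, V2 = 20, V3 = -25, V4 = 7,
    # release sigmoids
    V0e = -40, Vse = 0.2, V0i = -40, Vsi = 0.2,
    # sodium rate constants
    V7 = 10, V8 = -40, V9 = 10, V10 = 4, V11 = -65, V12 = 18,
    V13 = 0.07, V14 = -65, V15 = 20, V16 = 1, V17 = -35, V18 = 10,
    # membrane
    Cm = 17,
    gLeak = 2, gCa = 8.5, gK = 4, gNa = 2, gTREK = 2,
    gACh = 0.215, gGABA = 0.9,
    ELeak = -70, ECa = 50, EK = -90, ENa = 55, EACh = 0, ECl = -65,
    # noise: stationary amplitude (pA) of the OU noise current
    sigma = 5, tauW = 1000,
    # kinetics
    tauN = 5, tauA = 8300, tauB = 8300, tauC = 2000,
    tauACh = 540, tauGABA = 1000,
    # calcium / second messengers
    C0 = 0.088, lambda = 2.702, delta = 0.010503,
    alpha = 625, beta = 34,
    # release and receptors
    rho_e = 6, rho_i = 5, Kd = 0.1,
    # diffusion
    De = 0.005, Di = 0.005,
    dXe = c(L = 1, R = 1), dYe = c(U = 1, D = 1),
    dXi = c(L = 1, R = 1), dYi = c(U = 1.9, D = 0.1),
    # applied current
    Iapp = 0
  )
  p <- merge_named(p, list(...), what = "parameter")
  class(p) <- c("sac_params", "list")
  validate_params(p)
  p
}

#' Initial state of a single model cell
#'
#' The ten dynamical quantities of one cell at t = 0, at their published
#' reference values: membrane voltage `V` (mV), potassium gate `N`, sodium
#' activation `M` and inactivation `H`, calcium `C` (mM), cAMP-decay `A`,
#' active TREK1 fraction `B`, extracellular ACh `E` and GABA `I` (mM), and
#' the OU noise state `W`.
#'
#' @param ... named overrides of individual state variables.
#' @return Named numeric vector of length 10.
#' @examples
#' sac_initial_state(V = -70)
#' @export
sac_initial_state <- function(...) {
  s <- c(V = -63.6, N = 0, M = 0.062, H = 0.550, C = 0.085,
         A = 0.026, B = 0, E = 0.066, I = 0.053, W = 0)
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(s))
    if (length(bad)) stop("unknown state variable(s): ", paste(bad, collapse = ", "))
    s[names(ov)] <- unlist(ov)
  }
  s
}

#' Max-interval burst-sorting parameters
#'
#' Thresholds of the three-phase max-interval burst sorter: `ISI_start` /
#' `ISI_end` open and extend a burst (ms), bursts closer than `IBI_min` (ms)
#' are merged, and bursts shorter than `Duration_min` (ms) or with fewer
#' than `SPB_min` spikes are discarded.
#'
#' @param ISI_start,ISI_end,IBI_min,Duration_min ms thresholds.
#' @param SPB_min minimum spikes per burst.
#' @return Named list of class `sac_maxint`.
#' @export
max_interval_params <- function(ISI_start = 500, ISI_end = 500, IBI_min = 1000,
                                Duration_min = 100, SPB_min = 4) {
  q <- list(ISI_start = ISI_start, ISI_end = ISI_end, IBI_min = IBI_min,
            Duration_min = Duration_min, SPB_min = SPB_min)
  if (any(unlist(q) <= 0)) stop("all max-interval parameters must be positive")
  class(q) <- c("sac_maxint", "list")
  q
}

# merge named overrides over defaults; error on unknown keys with a hint
merge_named <- function(defaults, overrides, what = "key") {
  if (!length(overrides)) return(defaults)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("all ", what, " overrides must be named")
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) {
    hints <- vapply(bad, function(k) nearest_key_hint(k, names(defaults)),
                    character(1))
    stop("unknown ", what, "(s): ",
         paste0("'", bad, "'", hints, collapse = ", "))
  }
  for (k in names(overrides)) {
    v <- overrides[[k]]
    d <- defaults[[k]]
    if (length(d) > 1L) { # bias pair
      v <- unlist(v)
      if (length(v) != length(d)) stop("'", k, "' must have length ", length(d))
      names(v) <- names(d)
    }
    defaults[[k]] <- as.numeric(v)
    names(defaults[[k]]) <- names(d)
  }
  defaults
}

# closest valid key by edit distance (case-insensitive), for error hints
nearest_key_hint <- function(k, valid) {
  d <- utils::adist(k, valid, ignore.case = TRUE)[1, ]
  if (min(d) <= max(2, nchar(k) %/% 2))
    paste0(" (did you mean '", valid[which.min(d)], "'?)")
  else ""
}

validate_params <- function(p) {
  stopifnot(p$Cm > 0)
  taus <- c(p$tauN, p$tauA, p$tauB, p$tauC, p$tauACh, p$tauGABA, p$tauW)
  if (any(taus <= 0)) stop("all time constants must be positive")
  gs <- c(p$gLeak, p$gCa, p$gK, p$gNa, p$gTREK, p$gACh, p$gGABA)
  if (any(gs < 0)) stop("conductances must be nonnegative")
  if (any(c(p$dXe, p$dYe, p$dXi, p$dYi) < 0))
    stop("diffusion bias weights must be nonnegative")
  if (p$Kd <= 0) stop("Kd must be positive")
  invisible(p)
}

#' @export
print.sac_params <- function(x, ...) {
  cat("SAC model parameters (", length(x), " fields)\n", sep = "")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 8), " = ", format(flat)),
      sep = "\n")
  invisible(x)
}

# flatten params into the numeric vector layout the C++ core expects
params_to_vector <- function(p) {
  c(V1 = p$V1, V2 = p$V2, V3 = p$V3, V4 = p$V4,
    V0e = p$V0e, Vse = p$Vse, V0i = p$V0i, Vsi = p$Vsi,
    V7 = p$V7, V8 = p$V8, V9 = p$V9, V10 = p$V10, V11 = p$V11, V12 = p$V12,
    V13 = p$V13, V14 = p$V14, V15 = p$V15, V16 = p$V16, V17 = p$V17, V18 = p$V18,
    Cm = p$Cm, gLeak = p$gLeak, gCa = p$gCa, gK = p$gK, gNa = p$gNa,
    gTREK = p$gTREK, gACh = p$gACh, gGABA = p$gGABA,
    ELeak = p$ELeak, ECa = p$ECa, EK = p$EK, ENa = p$ENa, EACh = p$EACh,
    ECl = p$ECl, sigma = p$sigma, tauW = p$tauW,
    tauN = p$tauN, tauA = p$tauA, tauB = p$tauB, tauC = p$tauC,
    tauACh = p$tauACh, tauGABA = p$tauGABA,
    C0 = p$C0, lambda = p$lambda, delta = p$delta,
    alpha = p$alpha, beta = p$beta, rho_e = p$rho_e, rho_i = p$rho_i,
    Kd = p$Kd, De = p$De, Di = p$Di,
    dXeL = unname(p$dXe[1]), dXeR = unname(p$dXe[2]),
    dYeU = unname(p$dYe[1]), dYeD = unname(p$dYe[2]),
    dXiL = unname(p$dXi[1]), dXiR = unname(p$dXi[2]),
    dYiU = unname(p$dYi[1]), dYiD = unname(p$dYi[2]),
    Iapp = p$Iapp)
}
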