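#' Steady-state gating sigmoid
#'
#' Fraction of open voltage-gated channels at voltage `V`, the standard
#' Morris-Lecar form `0.5 * (1 + tanh((V - Vhalf) / Vslope))`. With the
#' default parameters this is `M_inf(V)` for calcium channels
#' (`Vhalf = V1`, `Vslope = V2`) and `N_inf(V)` for potassium channels
#' (`Vhalf = V3`, `Vslope = V4`).
#'
#' @param V membrane voltage (mV); vectorised.
#' @param Vhalf half-activation voltage (mV).
#' @param Vslope slope factor (mV), nonzero.
#' @return Open fraction in \[0, 1\].
#' @examples
#' gate_inf(-20, -20, 20) # 0.5 at the half-activation point
#' @export
gate_inf <- function(V, Vhalf, Vslope) {
  stopifnot(Vslope != 0)
  0.5 * (1 + tanh((V - Vhalf) / Vslope))
}

#' Potassium relaxation rate multiplier
#'
#' Voltage-dependent rate constant `cosh((V - V3) / (2 * V4))` that scales
#' the approach of the potassium gate N towards `N_inf(V)`. Equals 1 at
#' `V = V3` and is symmetric about it.
#'
#' @param V membrane voltage (mV); vectorised.
#' @param V3 half-activation voltage of the K gate (mV).
#' @param V4 slope factor (mV), nonzero.
#' @return Rate multiplier (>= 1).
#' @export
rate_lambda <- function(V, V3, V4) {
  stopifnot(V4 != 0)
  cosh((V - V3) / (2 * V4))
}

#' Neurotransmitter release sigmoid
#'
#' Voltage-dependent release fraction
#' `Phi(V) = 1 / (1 + exp(-Vs * (V - V0)))`: the proportion of maximal
#' ACh/GABA release at voltage `V`, with midpoint `V0` and steepness `Vs`.
#'
#' @param V membrane voltage (mV); vectorised.
#' @param Vs steepness (1/mV).
#' @param V0 release midpoint (mV).
#' @return Release fraction in \[0, 1\].
#' @export
release_phi <- function(V, Vs, V0) {
  1 / (1 + exp(-Vs * (V - V0)))
}

#' Fractional receptor activation by a neurotransmitter
#'
#' Second-order Hill activation `T^2 / (T^2 + Kd)` of ACh or GABA
#' receptors by transmitter concentration `T` (mM). `Kd` is the squared
#' half-activation constant (mM^2): activation is 0.5 when `T^2 = Kd`.
#'
#' @param T transmitter concentration (mM), nonnegative; vectorised.
#' @param Kd squared half-activation constant (mM^2), positive.
#' @return Activation fraction in \[0, 1\].
#' @export
receptor_activation <- function(T, Kd) {
  if (any(T < 0)) stop("negative transmitter concentration is an invalid state")
  stopifnot(Kd > 0)
  T^2 / (T^2 + Kd)
}

#' Sodium channel opening and closing rates
#'
#' Hodgkin-Huxley alpha/beta rates (1/ms) for the sodium activation gate M
#' and inactivation gate H. `alpha_m` has its removable singularity at
#' `V = V8` filled by the limit `V9 / V7`. With default parameters these
#' reduce to the classic squid-axon rates shifted to half points at
#' -40 / -65 / -35 mV.
#'
#' @param V membrane voltage (mV); vectorised.
#' @param p `sac_params` parameter set.
#' @return List with components `alpha_m`, `beta_m`, `alpha_h`, `beta_h`.
#' @examples
#' sodium_rates(-40, sac_parameters())$alpha_m # 1.0 at the singular point
#' @export
sodium_rates <- function(V, p) {
  x <- V - p$V8
  den <- p$V7 * (exp(-x / p$V9) - 1)
  am <- ifelse(abs(x) < 1e-7, p$V9 / p$V7, -x / den)
  list(
    alpha_m = am,
    beta_m  = p$V10 * exp(-(V - p$V11) / p$V12),
    alpha_h = p$V13 * exp(-(V - p$V14) / p$V15),
    beta_h  = 1 / (p$V16 * exp(-(V - p$V17) / p$V18) + 1)
  )
}

#' Ionic current breakdown for one cell state
#'
#' Evaluates every ionic current (pA) at a given state, in the convention
#' `I_n = -g_n * R * (V - E_n)` so that a positive value depolarises. The
#' sum of all components plus the applied current equals `Cm * dV/dt`.
#' The noise current is `sigma * W / sqrt(tauW / 2)`: `sigma` is the
#' stationary amplitude of the noise current (pA) and `sqrt(tauW / 2)` is
#' the stationary SD of the unit-diffusion OU state W.
#'
#' @param s named state vector as from [sac_initial_state()].
#' @param p `sac_params` parameter set.
#' @return Named numeric vector with components `Ileak`, `ICa`, `IK`,
#'   `ITREK`, `INa`, `IACh`, `IGABA`, `Inoise`.
#' @examples
#' s <- sac_initial_state()
#' sum(ionic_currents(s, sac_parameters()))
#' @export
ionic_currents <- function(s, p) {
  V <- s[["V"]]
  c(Ileak = -p$gLeak * (V - p$ELeak),
    ICa   = -p$gCa * gate_inf(V, p$V1, p$V2) * (V - p$ECa),
    IK    = -p$gK * s[["N"]] * (V - p$EK),
    ITREK = -p$gTREK * s[["B"]] * (V - p$EK),
    INa   = -p$gNa * s[["M"]]^3 * s[["H"]] * (V - p$ENa),
    IACh  = -p$gACh * receptor_activation(s[["E"]], p$Kd) * (V - p$EACh),
    IGABA = -p$gGABA * receptor_activation(s[["I"]], p$Kd) * (V - p$ECl),
    Inoise = p$sigma * s[["W"]] / sqrt(p$tauW / 2))
}

#' Deterministic drift of the full single-cell system
#'
#' Right-hand side of the ten-variable model: membrane voltage, potassium
#' gate, sodium gates, calcium, cAMP decay, TREK1 activation, the two
#' extracellular transmitter pools and the OU noise state. The stochastic
#' (Wiener) part of W is handled by the integrator; here `dW = -W / tauW`.
#'
#' For a cell embedded in a lattice, `lap_e` and `lap_i` are the discrete
#' diffusion operator values (stencil-weighted neighbour exchange) of the
#' ACh and GABA fields at this cell; for an isolated cell they are 0.
#' Diffusion enters as `De * lap_e` directly in dE/dt (a rate in 1/ms),
#' while release and decay are scaled by the pool time constants.
#'
#' @param s named state vector (see [sac_initial_state()]).
#' @param p `sac_params` parameter set.
#' @param lap_e,lap_i discrete Laplacian of the ACh / GABA field (mM).
#' @return Named numeric vector of time derivatives (per ms).
#' @export
sac_rhs <- function(s, p, lap_e = 0, lap_i = 0) {
  cur <- ionic_currents(s, p)
  V <- s[["V"]]
  rates <- sodium_rates(V, p)
  dV <- (sum(cur) + p$Iapp) / p$Cm
  dN <- rate_lambda(V, p$V3, p$V4) * (gate_inf(V, p$V3, p$V4) - s[["N"]]) / p$tauN
  dM <- rates$alpha_m * (1 - s[["M"]]) - rates$beta_m * s[["M"]]
  dH <- rates$alpha_h * (1 - s[["H"]]) - rates$beta_h * s[["H"]]
  dC <- (p$C0 + p$delta * cur[["ICa"]] - p$lambda * s[["C"]]) / p$tauC
  dA <- (p$alpha * s[["C"]]^4 * (1 - s[["A"]]) - s[["A"]]) / p$tauA
  dB <- (p$beta * s[["A"]]^4 * (1 - s[["B"]]) - s[["B"]]) / p$tauB
  dE <- p$De * lap_e + (p$rho_e * release_phi(V, p$Vse, p$V0e) - s[["E"]]) / p$tauACh
  dI <- p$Di * lap_i + (p$rho_i * release_phi(V, p$Vsi, p$V0i) - s[["I"]]) / p$tauGABA
  dW <- -s[["W"]] / p$tauW
  c(V = dV, N = dN, M = dM, H = dH, C = dC, A = dA, B = dB, E = dE, I = dI, W = dW)
}

#' One exact Ornstein-Uhlenbeck update
#'
#' Advances the noise state by `dt` using the exact discretisation of the
#' unit-diffusion OU process `dW = -(W / tauW) dt + dB`:
#' `W' = W * exp(-dt/tauW) + sqrt(tauW/2 * (1 - exp(-2 dt/tauW))) * z`
#' with `z` standard normal. The stationary distribution has mean 0 and
#' variance `tauW / 2`; the noise current injected into the membrane is
#' `sigma * W / sqrt(tauW / 2)`, with stationary SD `sigma` (pA).
#'
#' @param W current noise state (vectorised over independent cells).
#' @param dt time step (ms), positive.
#' @param tauW noise correlation time (ms).
#' @param z optional standard-normal draw(s); defaults to `rnorm`.
#' @return Updated noise state, same length as `W`.
#' @export
ou_step <- function(W, dt, tauW, z = stats::rnorm(length(W))) {
  stopifnot(dt > 0, tauW > 0)
  a <- exp(-dt / tauW)
  W * a + sqrt(tauW / 2 * (1 - a * a)) * z
}
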