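#' Simulate one isolated model cell
#'
#' Integrates the ten-variable stochastic single-cell model (no lattice
#' coupling; the diffusion terms are zero) with fixed-step Euler-Maruyama
#' for the ODE states and an exact-discretisation substep for the OU noise
#' state. The same seed always yields a bit-identical trace.
#'
#' @param params `sac_params` parameter set.
#' @param t_end simulated time (ms); default 300 s.
#' @param dt integration step (ms).
#' @param seed integer master seed for the cell's noise stream.
#' @param save_every saving interval (ms), a multiple of `dt`.
#' @param init initial state vector (see [sac_initial_state()]).
#' @return A data.frame of class `sac_trace` with columns `t`, the ten
#'   state variables and the TREK1 current `ITREK` (pA), sampled at
#'   `save_every`. Attributes: `params`, `dt`, `seed`.
#' @examples
#' tr <- simulate_cell(t_end = 1000, seed = 1)
#' range(tr$V)
#' @export
simulate_cell <- function(params = sac_parameters(), t_end = 300000,
                          dt = 0.05, seed = 1, save_every = 1,
                          init = sac_initial_state()) {
  validate_params(params)
  res <- cpp_simulate(params_to_vector(params),
                      matrix(init, nrow = 1), 1L, 1L,
                      t_end, dt, save_every, as.numeric(seed),
                      coupled = FALSE, save_fields = FALSE, full_trace = TRUE)
  tr <- as.data.frame(res$trace)
  names(tr) <- c("V", "N", "M", "H", "C", "A", "B", "E", "I", "W")
  tr <- cbind(t = res$t, tr)
  tr$ITREK <- -params$gTREK * tr$B * (tr$V - params$EK)
  structure(tr, params = params, dt = dt, seed = seed,
            class = c("sac_trace", "data.frame"))
}

#' Simulation presets for the network comparison conditions
#'
#' Returns the parameter set of one of the four lattice conditions:
#' `no_nt` (all transmitter conductances zero, cells isolated),
#' `ach_only` (GABA off), `depol_gaba` (chloride reversal -55 mV, GABA
#' depolarising) and `hyper_gaba` (chloride reversal -65 mV, GABA
#' hyperpolarising).
#'
#' @param params base `sac_params`.
#' @param preset one of `"no_nt"`, `"ach_only"`, `"depol_gaba"`,
#'   `"hyper_gaba"`, or `"none"` (use `params` unchanged).
#' @return Modified `sac_params`.
#' @export
preset_params <- function(params = sac_parameters(),
                          preset = c("none", "no_nt", "ach_only",
                                     "depol_gaba", "hyper_gaba")) {
  preset <- match.arg(preset)
  switch(preset,
         none = params,
         no_nt = sac_params_override(params, gACh = 0, gGABA = 0),
         ach_only = sac_params_override(params, gGABA = 0),
         depol_gaba = sac_params_override(params, ECl = -55),
         hyper_gaba = sac_params_override(params, ECl = -65))
}

#' Simulate a 2D lattice of coupled cells
#'
#' Integrates `nx * ny` cells, each with an independent OU noise stream
#' derived from `(seed, cell index)`, sharing the extracellular ACh and
#' GABA fields through biased Crank-Nicolson diffusion with no-flux
#' boundaries. Cell `(ix, iy)` sits at lattice site x = ix, y = iy with y
#' increasing "upward" (the direction favoured by the first entry of the
#' `dY` weight pairs).
#'
#' @param nx,ny lattice extent in cells.
#' @param params base `sac_params` (modified by `preset`).
#' @param preset condition label, see [preset_params()].
#' @param t_end simulated time (ms).
#' @param dt integration step (ms).
#' @param seed integer master seed.
#' @param save_every saving interval (ms).
#' @param save_fields keep the E and I fields (memory-heavy for long
#'   runs); the voltage field is always kept.
#' @param init per-cell initial state; a single state vector recycled to
#'   all cells, or an `ncell x 10` matrix.
#' @return List of class `sac_lattice`: `t` (ms), `V` (and optionally
#'   `E`, `I`) as `nx x ny x nt` arrays, plus `nx`, `ny`, `preset`,
#'   `seed`, `params`, `dt`.
#' @examples
#' lat <- simulate_lattice(3, 3, t_end = 200, seed = 1)
#' dim(lat$V)
#' @export
simulate_lattice <- function(nx = 64, ny = 64, params = sac_parameters(),
                             preset = "none", t_end = 300000, dt = 0.05,
                             seed = 1, save_every = 1, save_fields = TRUE,
                             init = sac_initial_state()) {
  params <- preset_params(params, preset)
  validate_params(params)
  ncell <- as.integer(nx) * as.integer(ny)
  if (is.matrix(init)) {
    stopifnot(nrow(init) == ncell, ncol(init) == 10)
    init_m <- init
  } else {
    init_m <- matrix(rep(init, each = ncell), nrow = ncell)
  }
  res <- cpp_simulate(params_to_vector(params), init_m,
                      as.integer(nx), as.integer(ny),
                      t_end, dt, save_every, as.numeric(seed),
                      coupled = TRUE, save_fields = save_fields,
                      full_trace = FALSE)
  nt <- length(res$t)
  out <- list(t = res$t,
              V = array(res$V, dim = c(nx, ny, nt)),
              nx = as.integer(nx), ny = as.integer(ny),
              preset = preset, seed = seed, params = params, dt = dt)
  if (save_fields) {
    out$E <- array(res$E, dim = c(nx, ny, nt))
    out$I <- array(res$I, dim = c(nx, ny, nt))
  }
  class(out) <- c("sac_lattice", "list")
  out
}

#' @export
print.sac_lattice <- function(x, ...) {
  cat(sprintf("SAC lattice solution: %d x %d cells, %.1f s at %g ms sampling (preset '%s', seed %s)\n",
              x$nx, x$ny, max(x$t) / 1000, diff(x$t[1:2]), x$preset,
              format(x$seed)))
  invisible(x)
}

#' @export
print.sac_trace <- function(x, ...) {
  cat(sprintf("SAC single-cell trace: %.1f s at %g ms sampling (seed %s)\n",
              max(x$t) / 1000, diff(x$t[1:2]), format(attr(x, "seed"))))
  print(utils::head(as.data.frame(x), 4))
  cat("... (", nrow(x), " samples)\n", sep = "")
  invisible(x)
}

# voltage trace of one lattice cell as a sac_trace-compatible data.frame
lattice_cell_trace <- function(lat, ix, iy) {
  data.frame(t = lat$t, V = lat$V[ix, iy, ])
}
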