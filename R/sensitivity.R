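# per-trial event metrics of one simulated cell
trial_metrics <- function(trace, q) {
  sp <- detect_spikes(trace)
  b <- max_interval_bursts(sp, q)
  c(spike = if (nrow(sp$spikes)) mean(sp$spikes$end - sp$spikes$start) else NA_real_,
    burst = if (nrow(b)) mean(b$end - b$start) else NA_real_,
    ibi = if (nrow(b) > 1) mean(interburst_intervals(b)) / 1000 else NA_real_)
}

# ensemble mean of trial metrics over a seed list for one parameter set
ensemble_metrics <- function(p, seeds, t_end, dt, q) {
  m <- vapply(seeds, function(s)
    trial_metrics(simulate_cell(p, t_end = t_end, dt = dt, seed = s), q),
    numeric(3))
  rowMeans(m, na.rm = TRUE)
}

#' Percent-change gradient of one model parameter
#'
#' Perturbs a single scalar parameter by a relative fraction (default
#' +10 percent, applied multiplicatively so negative-valued parameters
#' grow in magnitude), re-simulates an ensemble of isolated noisy cells
#' with the same seeds as the baseline (common random numbers), and
#' reports the percent change of the three summary metrics: mean spike
#' duration (ms), mean burst duration (ms) and mean interburst interval
#' (s). Metrics undefined at baseline (no events) give `NA` gradients.
#'
#' @param p baseline `sac_params`.
#' @param name parameter field to perturb (scalar fields only).
#' @param n_trials trials per condition (ignored when `seeds` is given).
#' @param perturbation relative change (0.1 = +10 percent).
#' @param seeds integer seed vector shared by baseline and perturbed runs.
#' @param t_end,dt simulation length and step (ms).
#' @param q `sac_maxint` burst thresholds.
#' @param baseline optional precomputed baseline metric vector (as
#'   returned in `$baseline_mean`), reused across a sweep.
#' @return List of class `sac_gradient`: `parameter`, `baseline_mean`,
#'   `perturbed_mean`, `gradient_pct` (each a named vector over the
#'   metrics spike/burst/ibi).
#' @export
parameter_gradient <- function(p, name, n_trials = 40, perturbation = 0.1,
                               seeds = seq_len(n_trials), t_end = 300000,
                               dt = 0.05, q = max_interval_params(),
                               baseline = NULL) {
  if (!name %in% names(p)) stop("unknown parameter: ", name)
  if (length(p[[name]]) != 1) stop("'", name, "' is not a scalar parameter")
  if (length(seeds) < 1) stop("need at least one trial")
  if (is.null(baseline)) baseline <- ensemble_metrics(p, seeds, t_end, dt, q)
  p2 <- p
  p2[[name]] <- p[[name]] * (1 + perturbation)
  perturbed <- ensemble_metrics(p2, seeds, t_end, dt, q)
  structure(list(parameter = name,
                 baseline_mean = baseline,
                 perturbed_mean = perturbed,
                 gradient_pct = (perturbed / baseline - 1) * 100),
            class = "sac_gradient")
}

#' @export
print.sac_gradient <- function(x, ...) {
  cat(sprintf("%s +%.0f%%: spike %+.2f%%, burst %+.2f%%, IBI %+.2f%%\n",
              x$parameter, 10, x$gradient_pct[["spike"]],
              x$gradient_pct[["burst"]], x$gradient_pct[["ibi"]]))
  invisible(x)
}

#' Default parameter list for the gradient sweep
#'
#' The 46 scalar biophysical parameters screened in the sensitivity
#' analysis: gating constants, sodium rate constants, capacitance,
#' conductances, reversal potentials, time constants and the
#' calcium/second-messenger gains. Excludes the bias vectors, diffusion
#' and receptor constants and the noise gain.
#'
#' @return Character vector of parameter names.
#' @export
gradient_parameters <- function() {
  c("V1", "V2", "V3", "V4", "V0e", "V0i", "Vse", "Vsi",
    "V7", "V8", "V9", "V10", "V11", "V12", "V13", "V14", "V15", "V16",
    "V17", "V18", "Cm", "gLeak", "gCa", "gK", "gNa", "gTREK", "gACh",
    "gGABA", "ELeak", "ECa", "EK", "ENa", "EACh", "ECl",
    "tauN", "tauA", "tauB", "tauC", "tauACh", "tauGABA", "tauW",
    "C0", "lambda", "delta", "alpha", "beta")
}

#' Gradient sweep over many parameters
#'
#' Runs [parameter_gradient()] for each named parameter with a shared
#' baseline ensemble and shared seeds (common random numbers across
#' parameters and between baseline/perturbed runs, to reduce Monte-Carlo
#' variance). Failures for individual parameters are recorded and the
#' sweep continues.
#'
#' @inheritParams parameter_gradient
#' @param names parameters to sweep; defaults to [gradient_parameters()].
#' @return data.frame with one row per parameter: `parameter`,
#'   `spike_pct`, `burst_pct`, `ibi_pct`, `error` (NA unless that
#'   parameter failed).
#' @export
gradient_sweep <- function(p = sac_parameters(), names = gradient_parameters(),
                           n_trials = 40, perturbation = 0.1,
                           seeds = seq_len(n_trials), t_end = 300000,
                           dt = 0.05, q = max_interval_params()) {
  baseline <- ensemble_metrics(p, seeds, t_end, dt, q)
  rows <- lapply(names, function(nm) {
    g <- tryCatch(parameter_gradient(p, nm, perturbation = perturbation,
                                     seeds = seeds, t_end = t_end, dt = dt,
                                     q = q, baseline = baseline),
                  error = function(e) e)
    if (inherits(g, "error"))
      return(data.frame(parameter = nm, spike_pct = NA_real_,
                        burst_pct = NA_real_, ibi_pct = NA_real_,
                        error = conditionMessage(g)))
    data.frame(parameter = nm,
               spike_pct = g$gradient_pct[["spike"]],
               burst_pct = g$gradient_pct[["burst"]],
               ibi_pct = g$gradient_pct[["ibi"]],
               error = NA_character_)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_mean") <- baseline
  out
}
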