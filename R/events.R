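#' Detect spikes by mean + 4 SD thresholding
#'
#' The detection threshold is the whole-trace mean voltage plus four times
#' its standard deviation. Samples strictly above threshold form a boolean
#' vector; maximal runs of consecutive supra-threshold samples become
#' spikes. A spike's start is the time of its first supra-threshold sample
#' and its end is the time just after its last one, so a single-sample
#' spike has duration equal to the sampling interval. A constant trace has
#' SD 0 and yields no spikes.
#'
#' @param trace a `sac_trace`, any data.frame with `t` and `V` columns
#'   (ms, mV, uniform sampling), or a numeric voltage vector (then
#'   `dt` gives the sampling interval and time starts at 0).
#' @param dt sampling interval (ms) when `trace` is a bare vector.
#' @return List of class `sac_spikes`: `spikes` (data.frame with `start`,
#'   `end` in ms), `threshold` (mV), `dt` (ms).
#' @examples
#' v <- rep(-60, 1000); v[300:304] <- 0
#' detect_spikes(v, dt = 1)$spikes
#' @export
detect_spikes <- function(trace, dt = NULL) {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(dt)) stop("dt is required for a bare voltage vector")
    tv <- seq(0, by = dt, length.out = length(trace))
    v <- as.numeric(trace)
  } else {
    stopifnot(all(c("t", "V") %in% names(trace)))
    tv <- trace$t
    v <- trace$V
    dt <- if (length(tv) > 1) tv[2] - tv[1] else 1
  }
  if (length(v) < 2)
    return(structure(list(spikes = empty_spikes(), threshold = NA_real_,
                          dt = dt), class = "sac_spikes"))
  thr <- mean(v) + 4 * stats::sd(v)
  above <- v > thr
  if (!any(above))
    return(structure(list(spikes = empty_spikes(), threshold = thr, dt = dt),
                     class = "sac_spikes"))
  r <- rle(above)
  ends_idx <- cumsum(r$lengths)
  starts_idx <- ends_idx - r$lengths + 1
  keep <- r$values
  spikes <- data.frame(start = tv[starts_idx[keep]],
                       end = tv[ends_idx[keep]] + dt)
  structure(list(spikes = spikes, threshold = thr, dt = dt),
            class = "sac_spikes")
}

empty_spikes <- function() data.frame(start = numeric(0), end = numeric(0))

#' @export
print.sac_spikes <- function(x, ...) {
  cat(sprintf("%d spikes (threshold %.2f mV)\n", nrow(x$spikes), x$threshold))
  invisible(x)
}

#' Max-interval burst sorting
#'
#' Groups a sorted spike train into bursts with the three-phase
#' max-interval algorithm. Phase 1: a burst opens at a spike whose
#' following inter-spike interval (onset to onset) is below `ISI_start`
#' and extends while successive ISIs stay below `ISI_end`. Phase 2:
#' bursts whose gap (end of one to start of the next) is below `IBI_min`
#' are merged. Phase 3: bursts shorter than `Duration_min` or with fewer
#' than `SPB_min` spikes are discarded.
#'
#' @param spikes a `sac_spikes` object or a data.frame with `start` and
#'   `end` columns (ms), sorted by start.
#' @param q `sac_maxint` thresholds, see [max_interval_params()].
#' @return data.frame with columns `start`, `end` (ms) and `n_spikes`;
#'   zero rows if no group survives.
#' @examples
#' s <- data.frame(start = seq(0, 900, 100), end = seq(0, 900, 100))
#' max_interval_bursts(s)
#' @export
max_interval_bursts <- function(spikes, q = max_interval_params()) {
  s <- if (inherits(spikes, "sac_spikes")) spikes$spikes else spikes
  n <- nrow(s)
  if (n == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  if (is.unsorted(s$start)) stop("spike train must be sorted by start time")
  # phase 1: open/extend by ISI thresholds (ISIs between spike onsets)
  isi <- diff(s$start)
  first <- integer(0); last <- integer(0)
  i <- 1L
  while (i <= n) {
    if (i < n && isi[i] < q$ISI_start) {
      j <- i + 1L
      while (j < n && isi[j] < q$ISI_end) j <- j + 1L
      first <- c(first, i); last <- c(last, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(first))
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0)))
  b <- data.frame(start = s$start[first], end = s$end[last],
                  n_spikes = last - first + 1L)
  # phase 2: merge bursts separated by less than IBI_min
  if (nrow(b) > 1) {
    gaps <- b$start[-1] - b$end[-nrow(b)]
    grp <- cumsum(c(1L, as.integer(gaps >= q$IBI_min)))
    b <- data.frame(
      start = tapply(b$start, grp, min),
      end = tapply(b$end, grp, max),
      n_spikes = as.integer(tapply(b$n_spikes, grp, sum)))
  }
  # phase 3: duration and spike-count filters
  b <- b[(b$end - b$start) >= q$Duration_min & b$n_spikes >= q$SPB_min, ,
         drop = FALSE]
  rownames(b) <- NULL
  b
}

#' Interburst intervals
#'
#' Time from the end of each burst to the start of the next (ms).
#'
#' @param bursts data.frame from [max_interval_bursts()], sorted.
#' @return Numeric vector of length `nrow(bursts) - 1` (empty for fewer
#'   than two bursts).
#' @export
interburst_intervals <- function(bursts) {
  if (nrow(bursts) < 2) return(numeric(0))
  bursts$start[-1] - bursts$end[-nrow(bursts)]
}

#' Amplitude statistics of a voltage trace
#'
#' Minimum and maximum voltage, plus the baseline estimated as the mode
#' of a 1 mV histogram (the midpoint of the most populated bin; ties take
#' the most hyperpolarised bin). The mode is preferred over the mean
#' because depolarised bursts skew the mean upward.
#'
#' @param trace `sac_trace`, data.frame with `V`, or numeric vector.
#' @param bin_mv histogram bin width (mV).
#' @return Named vector `c(baseline, min_amp, max_amp)` in mV.
#' @export
trace_stats <- function(trace, bin_mv = 1) {
  v <- if (is.numeric(trace) && is.null(dim(trace))) trace else trace$V
  if (!length(v)) stop("empty trace")
  if (max(v) == min(v))
    return(c(baseline = v[1], min_amp = v[1], max_amp = v[1]))
  breaks <- seq(floor(min(v) / bin_mv) * bin_mv - bin_mv / 2,
                ceiling(max(v) / bin_mv) * bin_mv + bin_mv / 2, by = bin_mv)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  c(baseline = h$mids[which.max(h$counts)], min_amp = min(v), max_amp = max(v))
}
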