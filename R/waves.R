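#' Segment spatiotemporal wave events from a 3D burst mask
#'
#' Labels 6-connected (face-adjacent) components of a boolean
#' `(x, y, t)` array in which `TRUE` marks a cell bursting at a time
#' sample. Components confined to a single `(x, y)` site are isolated
#' bursts, not waves, and are excluded. Uses union-find over adjacent
#' voxel pairs.
#'
#' @param mask 3D logical array `(x, y, t)`.
#' @param sample_ms temporal sampling of the mask (ms).
#' @return List of class `sac_waves`: `events`, a list where each element
#'   has `voxels` (matrix of x, y, t indices) and the bounding-box metrics
#'   of [wave_metrics()]; and `n_excluded`, the number of single-site
#'   components dropped.
#' @examples
#' m <- array(FALSE, c(3, 3, 4)); m[1:2, 1, 1:2] <- TRUE
#' length(wave_segmentation(m)$events)
#' @export
wave_segmentation <- function(mask, sample_ms = 1) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  d <- dim(mask)
  idx <- which(mask)
  if (!length(idx))
    return(structure(list(events = list(), n_excluded = 0L),
                     class = "sac_waves"))
  pos <- arrayInd(idx, d)
  # map linear voxel index -> rank among TRUE voxels
  rank <- integer(prod(d))
  rank[idx] <- seq_along(idx)
  edges_from <- integer(0); edges_to <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (axis in 1:3) {
    ok <- pos[, axis] < d[axis]
    nb <- idx[ok] + strides[axis]
    hit <- mask[nb]
    edges_from <- c(edges_from, rank[idx[ok][hit]])
    edges_to <- c(edges_to, rank[nb[hit]])
  }
  comp <- union_find(length(idx), edges_from, edges_to)
  events <- list(); n_excl <- 0L
  for (cid in unique(comp)) {
    vox <- pos[comp == cid, , drop = FALSE]
    sites <- unique(vox[, 1:2, drop = FALSE])
    if (nrow(sites) < 2) { n_excl <- n_excl + 1L; next }
    colnames(vox) <- c("x", "y", "t")
    ev <- list(voxels = vox)
    ev <- c(ev, wave_metrics_bbox(range(vox[, 1]), range(vox[, 2]),
                                  range(vox[, 3]), sample_ms))
    events[[length(events) + 1L]] <- ev
  }
  structure(list(events = events, n_excluded = n_excl), class = "sac_waves")
}

# weighted quick-union with path compression; returns component id per node
union_find <- function(n, from, to) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_along(from)) {
    a <- find(from[k]); b <- find(to[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

wave_metrics_bbox <- function(xr, yr, tr, sample_ms) {
  duration_ms <- (tr[2] - tr[1]) * sample_ms
  area <- (xr[2] - xr[1] + 1) * (yr[2] - yr[1] + 1)
  list(duration = duration_ms / 1000,
       area = area,
       velocity = if (duration_ms > 0) area / (duration_ms / 1000) else NA_real_)
}

#' Bounding-box metrics of one wave event
#'
#' Duration is the elapsed time between the first and last time sample of
#' the event; area is the inclusive x-extent times the inclusive y-extent
#' (so a wave one cell wide still has area equal to its length); velocity
#' is area covered per unit time (`NA` for zero-duration events).
#'
#' @param w one element of `wave_segmentation()$events` (needs `voxels`).
#' @param sample_ms temporal sampling (ms).
#' @return List with `duration` (s), `area` (cells), `velocity` (cells/s).
#' @export
wave_metrics <- function(w, sample_ms = 1) {
  vox <- w$voxels
  wave_metrics_bbox(range(vox[, 1]), range(vox[, 2]), range(vox[, 3]),
                    sample_ms)
}

# Segment waves directly from per-cell burst interval tables; equivalent to
# voxel labeling of the burst mask but avoids materialising nx*ny*nt voxels.
# Nodes are bursts; two bursts connect when their cells are 4-neighbours (or
# identical) and their sample-index spans intersect (same-cell bursts only
# touch if they share or abut samples, which phase-2 merging precludes).
wave_segmentation_bursts <- function(bursts_by_cell, nx, ny, sample_ms = 1) {
  nodes <- list()
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    b <- bursts_by_cell[[(iy - 1) * nx + ix]]
    if (is.null(b) || !nrow(b)) next
    for (k in seq_len(nrow(b))) {
      s0 <- ceiling(b$start[k] / sample_ms)
      s1 <- floor(b$end[k] / sample_ms)
      if (s1 < s0) next # burst falls between samples
      nodes[[length(nodes) + 1L]] <-
        c(ix = ix, iy = iy, s0 = s0, s1 = s1)
    }
  }
  if (!length(nodes))
    return(structure(list(events = list(), n_excluded = 0L),
                     class = "sac_waves"))
  nd <- do.call(rbind, nodes)
  n <- nrow(nd)
  cellkey <- (nd[, "iy"] - 1) * nx + nd[, "ix"]
  by_cell <- split(seq_len(n), cellkey)
  from <- integer(0); to <- integer(0)
  for (a in seq_len(n)) {
    # neighbours to the right and above only (each pair considered once)
    for (d in list(c(1, 0), c(0, 1))) {
      jx <- nd[a, "ix"] + d[1]; jy <- nd[a, "iy"] + d[2]
      if (jx > nx || jy > ny) next
      cand <- by_cell[[as.character((jy - 1) * nx + jx)]]
      if (is.null(cand)) next
      hit <- cand[nd[cand, "s0"] <= nd[a, "s1"] & nd[cand, "s1"] >= nd[a, "s0"]]
      from <- c(from, rep(a, length(hit))); to <- c(to, hit)
    }
    # temporal adjacency within the same cell (abutting sample spans)
    cand <- by_cell[[as.character(cellkey[a])]]
    hit <- cand[cand != a & nd[cand, "s0"] <= nd[a, "s1"] + 1 &
                  nd[cand, "s1"] >= nd[a, "s0"] - 1]
    from <- c(from, rep(a, length(hit))); to <- c(to, hit)
  }
  comp <- union_find(n, from, to)
  events <- list(); n_excl <- 0L
  for (cid in unique(comp)) {
    mem <- which(comp == cid)
    sites <- unique(nd[mem, c("ix", "iy"), drop = FALSE])
    if (nrow(sites) < 2) { n_excl <- n_excl + 1L; next }
    ev <- list(members = nd[mem, , drop = FALSE])
    ev <- c(ev, wave_metrics_bbox(range(nd[mem, "ix"]), range(nd[mem, "iy"]),
                                  range(c(nd[mem, "s0"], nd[mem, "s1"])),
                                  sample_ms))
    events[[length(events) + 1L]] <- ev
  }
  structure(list(events = events, n_excluded = n_excl), class = "sac_waves")
}

#' @export
print.sac_waves <- function(x, ...) {
  cat(length(x$events), "wave events (", x$n_excluded,
      "single-site components excluded )\n")
  invisible(x)
}

#' Summary metrics for one simulation condition
#'
#' Runs the full quantification pipeline on a lattice solution or a list
#' of single-cell traces: per-cell amplitude statistics, spike detection,
#' max-interval burst sorting and interburst intervals, and (for a
#' lattice) 3D wave segmentation with the wave/burst ratio and wave
#' duration/area/velocity. Each metric is reported as mean and SD over
#' all cells/events; metrics with no events have `n = 0` and `NA`
#' mean/SD.
#'
#' @param x a `sac_lattice`, or a list of `sac_trace` / data.frames with
#'   `t` and `V`.
#' @param q `sac_maxint` burst-sorting thresholds.
#' @return data.frame with columns `metric`, `mean`, `sd`, `n` and rows
#'   baseline, min_amplitude, max_amplitude (mV), spike_duration (ms),
#'   burst_duration (ms), ibi (s), plus for lattices wave_burst_ratio,
#'   wave_duration (s), wave_area (cells), wave_velocity (cells/s).
#' @export
summarize_condition <- function(x, q = max_interval_params()) {
  is_lattice <- inherits(x, "sac_lattice")
  traces <- if (is_lattice) {
    unlist(lapply(seq_len(x$ny), function(iy)
      lapply(seq_len(x$nx), function(ix) lattice_cell_trace(x, ix, iy))),
      recursive = FALSE)
  } else x
  spike_dur <- c(); burst_dur <- c(); ibis <- c()
  base <- c(); vmin <- c(); vmax <- c()
  bursts_by_cell <- vector("list", length(traces))
  n_bursts <- 0L
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    st <- trace_stats(tr)
    base <- c(base, st[["baseline"]])
    vmin <- c(vmin, st[["min_amp"]])
    vmax <- c(vmax, st[["max_amp"]])
    sp <- detect_spikes(tr)
    if (nrow(sp$spikes)) spike_dur <- c(spike_dur, sp$spikes$end - sp$spikes$start)
    b <- max_interval_bursts(sp, q)
    bursts_by_cell[[i]] <- b
    n_bursts <- n_bursts + nrow(b)
    if (nrow(b)) burst_dur <- c(burst_dur, b$end - b$start)
    ibis <- c(ibis, interburst_intervals(b))
  }
  row <- function(metric, vals) data.frame(
    metric = metric,
    mean = if (length(vals)) mean(vals) else NA_real_,
    sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
    n = length(vals))
  out <- rbind(row("baseline", base), row("min_amplitude", vmin),
               row("max_amplitude", vmax), row("spike_duration", spike_dur),
               row("burst_duration", burst_dur), row("ibi", ibis / 1000))
  if (is_lattice) {
    sample_ms <- if (length(x$t) > 1) x$t[2] - x$t[1] else 1
    w <- wave_segmentation_bursts(bursts_by_cell, x$nx, x$ny, sample_ms)
    ratio <- if (n_bursts > 0) length(w$events) / n_bursts else NA_real_
    out <- rbind(out,
                 data.frame(metric = "wave_burst_ratio", mean = ratio,
                            sd = NA_real_, n = n_bursts),
                 row("wave_duration", vapply(w$events, `[[`, 0, "duration")),
                 row("wave_area", vapply(w$events, `[[`, 0, "area")),
                 row("wave_velocity",
                     stats::na.omit(vapply(w$events, `[[`, 0, "velocity"))))
  }
  rownames(out) <- NULL
  out
}
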