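# Independent reference implementations used as oracles. These are written
# in a different style from the package code on purpose: chain partition +
# repeated-pass merging for the burst sorter, queue flood fill for the 3D
# labeling, and a vectorised whole-lattice stepper for the integrator.

# --- max-interval burst sorter, chain formulation (requires ISI_start <= ISI_end)
oracle_max_interval <- function(spikes, q) {
  s <- if (inherits(spikes, "sac_spikes")) spikes$spikes else spikes
  n <- nrow(s)
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  if (n == 0) return(empty)
  stopifnot(q$ISI_start <= q$ISI_end)
  # chains: maximal runs with consecutive onset gaps < ISI_end
  gap <- diff(s$start)
  chain_id <- cumsum(c(1, as.integer(gap >= q$ISI_end)))
  bursts <- list()
  for (cid in unique(chain_id)) {
    idx <- which(chain_id == cid)
    if (length(idx) < 2) next
    g <- diff(s$start[idx])
    open_at <- which(g < q$ISI_start)
    if (!length(open_at)) next
    mem <- idx[open_at[1]:length(idx)]
    bursts[[length(bursts) + 1]] <-
      c(start = s$start[mem[1]], end = s$end[mem[length(mem)]],
        n_spikes = length(mem))
  }
  if (!length(bursts)) return(empty)
  b <- as.data.frame(do.call(rbind, bursts))
  # merge by repeated passes until stable
  repeat {
    if (nrow(b) < 2) break
    gaps <- b$start[-1] - b$end[-nrow(b)]
    k <- which(gaps < q$IBI_min)
    if (!length(k)) break
    k <- k[1]
    b$end[k] <- b$end[k + 1]
    b$n_spikes[k] <- b$n_spikes[k] + b$n_spikes[k + 1]
    b <- b[-(k + 1), , drop = FALSE]
  }
  b <- b[(b$end - b$start) >= q$Duration_min & b$n_spikes >= q$SPB_min, ,
         drop = FALSE]
  rownames(b) <- NULL
  b$n_spikes <- as.integer(b$n_spikes)
  b
}

# --- 3D 6-connected labeling by queue-based flood fill
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  cur <- 0L
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  for (lin in which(mask)) {
    if (labels[lin] != 0L) next
    cur <- cur + 1L
    queue <- matrix(arrayInd(lin, d), ncol = 3)
    labels[lin] <- cur
    while (nrow(queue)) {
      v <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (si in seq_len(nrow(shifts))) {
        w <- v + shifts[si, ]
        if (any(w < 1) || any(w > d)) next
        if (mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- cur
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

# component summary (site count, bbox) from a flood-fill label array,
# dropping single-(x,y)-site components, for comparison with wave_segmentation
oracle_wave_summary <- function(mask) {
  labels <- oracle_flood_fill(mask)
  out <- list()
  for (cid in setdiff(unique(as.integer(labels)), 0L)) {
    vox <- arrayInd(which(labels == cid), dim(mask))
    if (nrow(unique(vox[, 1:2, drop = FALSE])) < 2) next
    out[[length(out) + 1]] <- list(
      n_vox = nrow(vox),
      xr = range(vox[, 1]), yr = range(vox[, 2]), tr = range(vox[, 3]))
  }
  out
}

# --- pure-R reference integrator for a small lattice (deterministic part
# only; W is frozen at 0, so compare with sigma = 0 runs)
oracle_lattice_step <- function(states, p, nx, ny, dt) {
  ncell <- nx * ny
  new <- states
  for (i in seq_len(ncell)) {
    s <- states[i, ]
    d <- sac_rhs(s, p, 0, 0)
    v <- s + dt * d
    v[c("N", "M", "H", "A", "B")] <- pmin(pmax(v[c("N", "M", "H", "A", "B")], 0), 1)
    v[c("C", "E", "I")] <- pmax(v[c("C", "E", "I")], 0)
    v["W"] <- 0
    new[i, ] <- v
  }
  stE <- build_stencil(p$De, p$dXe, p$dYe)
  stI <- build_stencil(p$Di, p$dXi, p$dYi)
  new[, "E"] <- as.vector(diffusion_step(matrix(new[, "E"], nx, ny), stE, dt))
  new[, "I"] <- as.vector(diffusion_step(matrix(new[, "I"], nx, ny), stI, dt))
  new
}

# random spike train with a mix of short and long ISIs
random_train <- function(n, seed) {
  set.seed(seed)
  isis <- sample(c(stats::rexp(n, 1 / 80), stats::rexp(n, 1 / 1500)), n)
  starts <- cumsum(c(stats::runif(1, 0, 100), isis))[1:n]
  widths <- pmin(stats::runif(n, 0, 30), c(diff(starts), Inf) * 0.9)
  data.frame(start = starts, end = starts + widths)
}

# random sparse 3D mask
random_mask <- function(d, p_true, seed) {
  set.seed(seed)
  array(stats::runif(prod(d)) < p_true, d)
}
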