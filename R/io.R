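#' Load a run configuration
#'
#' Reads a YAML configuration and merges it over the package defaults.
#' Recognised top-level keys: `parameters` (overrides of
#' [sac_parameters()] fields), `preset`, `lattice` (`nx`, `ny`),
#' `integration` (`dt`, `t_end`, `save_every`), `burst` (overrides of
#' [max_interval_params()] fields), `seed` and `output`. Unknown keys at
#' any level are an error naming the key and its nearest valid match.
#' An empty file yields the pure defaults.
#'
#' @param path YAML file; `NULL` for pure defaults.
#' @return List of class `sac_config` with fully resolved `parameters`
#'   (`sac_params`), `burst` (`sac_maxint`), `preset`, `lattice`,
#'   `integration`, `seed`, `output`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  template <- list(parameters = NULL, preset = "none", lattice = NULL,
                   integration = NULL, burst = NULL, seed = 1, output = NULL)
  bad <- setdiff(names(raw), names(template))
  if (length(bad)) {
    hints <- vapply(bad, function(k) nearest_key_hint(k, names(template)),
                    character(1))
    stop("unknown config key(s): ", paste0("'", bad, "'", hints, collapse = ", "))
  }
  pars <- do.call(sac_parameters, as.list(raw$parameters))
  burst <- do.call(max_interval_params,
                   merge_named(unclass(max_interval_params()),
                               as.list(raw$burst), what = "burst parameter"))
  lattice <- merge_named(list(nx = 64, ny = 64), as.list(raw$lattice),
                         what = "lattice key")
  integration <- merge_named(list(dt = 0.05, t_end = 300000, save_every = 1),
                             as.list(raw$integration), what = "integration key")
  preset <- if (is.null(raw$preset)) "none" else raw$preset
  preset <- match.arg(preset, c("none", "no_nt", "ach_only", "depol_gaba",
                                "hyper_gaba"))
  structure(list(parameters = pars, burst = burst, preset = preset,
                 lattice = lattice, integration = integration,
                 seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
                 output = raw$output),
            class = "sac_config")
}

#' Write / read a single-cell trace as delimited text
#'
#' Tab-separated text with a full-precision representation (17 significant
#' digits), so a write/read round trip reproduces the numeric values
#' bit-exactly.
#'
#' @param trace `sac_trace` or data.frame.
#' @param path output file.
#' @return `write_trace` the path invisibly; `read_trace` a data.frame.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  fmt <- vapply(df, function(col) sprintf("%.17g", col), character(nrow(df)))
  lines <- c(paste(names(df), collapse = "\t"),
             apply(matrix(fmt, nrow = nrow(df)), 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

#' Write / read a lattice solution
#'
#' Stores the (x, y, t) arrays in a serialised data file next to a JSON
#' manifest (`manifest.json`) carrying the lattice shape, preset, seed,
#' step sizes, resolved parameters and package version, so a run can be
#' reproduced from the manifest alone. Re-reading restores the arrays
#' bit-exactly. Partial writes are cleaned up on failure.
#'
#' @param lat `sac_lattice`.
#' @param dir output directory (created if needed).
#' @return `write_lattice` the directory invisibly; `read_lattice` a
#'   `sac_lattice`.
#' @export
write_lattice <- function(lat, dir) {
  stopifnot(inherits(lat, "sac_lattice"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "fields.rds")
  man_path <- file.path(dir, "manifest.json")
  ok <- FALSE
  on.exit(if (!ok) unlink(c(data_path, man_path)), add = TRUE)
  saveRDS(lat[intersect(c("t", "V", "E", "I"), names(lat))], data_path)
  manifest <- list(nx = lat$nx, ny = lat$ny, preset = lat$preset,
                   seed = lat$seed, dt = lat$dt,
                   save_every = if (length(lat$t) > 1) lat$t[2] - lat$t[1] else NA,
                   t_end = max(lat$t),
                   parameters = lapply(unclass(lat$params), as.numeric),
                   package_version = as.character(utils::packageVersion("sacwaves")))
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(dir)
}

#' @rdname write_lattice
#' @export
read_lattice <- function(dir) {
  fields <- readRDS(file.path(dir, "fields.rds"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  pars <- man$parameters
  pars[c("dXe", "dYe", "dXi", "dYi")] <-
    lapply(pars[c("dXe", "dYe", "dXi", "dYi")], function(v)
      stats::setNames(v, if (length(v) == 2) c("L", "R") else NULL))
  names(pars$dYe) <- names(pars$dYi) <- c("U", "D")
  out <- c(fields, list(nx = man$nx, ny = man$ny, preset = man$preset,
                        seed = man$seed, dt = man$dt,
                        params = do.call(sac_parameters, pars)))
  class(out) <- c("sac_lattice", "list")
  out
}

#' Write burst or wave event tables as CSV
#'
#' @param events data.frame (bursts) or `sac_waves` object.
#' @param path output CSV.
#' @return The path, invisibly.
#' @export
write_events_csv <- function(events, path) {
  df <- if (inherits(events, "sac_waves")) {
    if (length(events$events)) do.call(rbind, lapply(events$events, function(e)
      data.frame(duration = e$duration, area = e$area, velocity = e$velocity)))
    else data.frame(duration = numeric(0), area = numeric(0),
                    velocity = numeric(0))
  } else as.data.frame(events)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Deterministic test fixtures with attached ground truth
#'
#' Generates small synthetic inputs for the analysis pipeline, pure given
#' `(kind, arguments, seed)`:
#' \describe{
#'   \item{`spike_train`}{`groups` groups of `spikes_per_group` spikes
#'     with within-group interval `isi` and between-group gap `gap` (ms).
#'     Ground truth: the burst count implied by the max-interval rules.}
#'   \item{`voltage_trace`}{a flat baseline with rectangular spike pulses
#'     arranged in the same group structure; ground truth: spike count,
#'     spike duration and expected burst count.}
#'   \item{`burst_mask`}{a 3D logical array with `n_blobs` rectangular
#'     multi-site blobs at random disjoint locations plus
#'     `n_single_site` single-site (non-wave) components; ground truth:
#'     the wave count `n_blobs`.}
#' }
#'
#' @param kind fixture type.
#' @param groups,spikes_per_group,isi,gap spike-train structure.
#' @param baseline_mv,pulse_mv,pulse_ms,dt_ms voltage-trace shape.
#' @param dim_xyt,n_blobs,n_single_site burst-mask shape.
#' @param seed integer seed.
#' @param q `sac_maxint` thresholds used to derive ground truth.
#' @return The fixture object, with a `ground_truth` attribute.
#' @export
make_fixture <- function(kind = c("spike_train", "voltage_trace", "burst_mask"),
                         groups = 2, spikes_per_group = 5, isi = 100,
                         gap = 600, baseline_mv = -60, pulse_mv = 0,
                         pulse_ms = 5, dt_ms = 1,
                         dim_xyt = c(8, 8, 50), n_blobs = 2,
                         n_single_site = 1, seed = 1,
                         q = max_interval_params()) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "spike_train") {
    starts <- unlist(lapply(seq_len(groups) - 1, function(g)
      g * ((spikes_per_group - 1) * isi + gap) + (seq_len(spikes_per_group) - 1) * isi))
    s <- data.frame(start = starts, end = starts)
    truth <- grouped_train_truth(groups, spikes_per_group, isi, gap, q)
    return(structure(s, ground_truth = list(n_bursts = truth)))
  }
  if (kind == "voltage_trace") {
    spike_starts <- unlist(lapply(seq_len(groups) - 1, function(g)
      500 + g * ((spikes_per_group - 1) * isi + gap) + (seq_len(spikes_per_group) - 1) * isi))
    t_end <- max(spike_starts) + 1000
    tv <- seq(0, t_end, by = dt_ms)
    v <- rep(baseline_mv, length(tv))
    for (s0 in spike_starts)
      v[tv >= s0 & tv < s0 + pulse_ms] <- pulse_mv
    tr <- data.frame(t = tv, V = v)
    truth <- list(n_spikes = length(spike_starts), spike_duration = pulse_ms,
                  n_bursts = grouped_train_truth(groups, spikes_per_group,
                                                 isi, gap, q))
    return(structure(tr, ground_truth = truth))
  }
  # burst_mask: place disjoint rectangular blobs on a coarse grid
  d <- dim_xyt
  mask <- array(FALSE, d)
  placed <- 0; guard <- 0
  occupied <- array(FALSE, d)
  while (placed < n_blobs && guard < 1000) {
    guard <- guard + 1
    sx <- sample(2:max(2, d[1] %/% 2), 1); sy <- sample(2:max(2, d[2] %/% 2), 1)
    st <- sample(2:max(2, d[3] %/% 3), 1)
    x0 <- sample(seq_len(d[1] - sx + 1), 1); y0 <- sample(seq_len(d[2] - sy + 1), 1)
    t0 <- sample(seq_len(d[3] - st + 1), 1)
    xr <- x0:(x0 + sx - 1); yr <- y0:(y0 + sy - 1); tr_ <- t0:(t0 + st - 1)
    # pad by one voxel to keep blobs disconnected
    px <- max(1, x0 - 1):min(d[1], x0 + sx); py <- max(1, y0 - 1):min(d[2], y0 + sy)
    pt <- max(1, t0 - 1):min(d[3], t0 + st)
    if (any(occupied[px, py, pt])) next
    mask[xr, yr, tr_] <- TRUE
    occupied[px, py, pt] <- TRUE
    placed <- placed + 1
  }
  singles <- 0; guard <- 0
  while (singles < n_single_site && guard < 1000) {
    guard <- guard + 1
    x0 <- sample(d[1], 1); y0 <- sample(d[2], 1); t0 <- sample(d[3] - 1, 1)
    px <- max(1, x0 - 1):min(d[1], x0 + 1); py <- max(1, y0 - 1):min(d[2], y0 + 1)
    pt <- max(1, t0 - 1):min(d[3], t0 + 2)
    if (any(occupied[px, py, pt])) next
    mask[x0, y0, t0 + 0:1] <- TRUE
    occupied[px, py, pt] <- TRUE
    singles <- singles + 1
  }
  if (placed < n_blobs || singles < n_single_site)
    stop("could not place all fixture components; enlarge dim_xyt")
  structure(mask, ground_truth = list(n_waves = placed,
                                      n_single_site = singles))
}

# closed-form burst count for the regular grouped trains built by
# make_fixture (groups of equal-ISI spikes separated by a fixed gap);
# independent of the max_interval_bursts implementation
grouped_train_truth <- function(groups, spikes_per_group, isi, gap, q) {
  if (isi >= q$ISI_start || spikes_per_group < 2) return(0L)
  merged <- gap < q$IBI_min
  group_dur <- (spikes_per_group - 1) * isi
  if (merged) {
    dur <- (groups - 1) * (group_dur + gap) + group_dur
    n_sp <- groups * spikes_per_group
    if (dur >= q$Duration_min && n_sp >= q$SPB_min) 1L else 0L
  } else {
    if (group_dur >= q$Duration_min && spikes_per_group >= q$SPB_min)
      as.integer(groups) else 0L
  }
}

#' Write a run manifest
#'
#' JSON record of a completed simulation: resolved parameters, preset,
#' seed, integration settings and package version.
#'
#' @param x `sac_trace` or `sac_lattice`.
#' @param path output JSON file.
#' @return The path, invisibly.
#' @export
write_manifest <- function(x, path) {
  p <- if (inherits(x, "sac_lattice")) x$params else attr(x, "params")
  manifest <- list(
    type = class(x)[1],
    seed = if (inherits(x, "sac_lattice")) x$seed else attr(x, "seed"),
    dt = if (inherits(x, "sac_lattice")) x$dt else attr(x, "dt"),
    preset = if (inherits(x, "sac_lattice")) x$preset else "none",
    parameters = lapply(unclass(p), as.numeric),
    package_version = as.character(utils::packageVersion("sacwaves")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
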