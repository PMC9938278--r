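test_that("wave segmentation matches its hand-built examples", {
  # one cell bursting alone is excluded by the single-site rule
  m <- array(FALSE, c(4, 4, 20)); m[2, 2, 3:12] <- TRUE
  w <- wave_segmentation(m)
  expect_equal(length(w$events), 0)
  expect_equal(w$n_excluded, 1L)
  # a 3x3 block bursting over overlapping windows is one wave
  m2 <- array(FALSE, c(5, 5, 30)); m2[2:4, 2:4, 5:25] <- TRUE
  w2 <- wave_segmentation(m2)
  expect_equal(length(w2$events), 1)
  expect_equal(w2$events[[1]]$area, 9)
  # two blocks separated in time by more than one sample are two waves
  m3 <- array(FALSE, c(5, 5, 40))
  m3[1:2, 1:2, 3:8] <- TRUE
  m3[4:5, 4:5, 20:26] <- TRUE
  expect_equal(length(wave_segmentation(m3)$events), 2)
  # empty mask
  expect_equal(length(wave_segmentation(array(FALSE, c(3, 3, 3)))$events), 0)
})

test_that("segmentation equals queue flood fill on random masks", {
  for (i in 1:40) {
    m <- random_mask(c(8, 8, 50), p_true = runif(1, 0.01, 0.1), seed = 900 + i)
    got <- wave_segmentation(m)
    want <- oracle_wave_summary(m)
    expect_equal(length(got$events), length(want))
    if (!length(want)) next
    key <- function(e) paste(e[[1]], collapse = ",")
    got_k <- sort(vapply(got$events, function(e)
      paste(nrow(e$voxels), range(e$voxels[, 1])[1], range(e$voxels[, 1])[2],
            range(e$voxels[, 2])[1], range(e$voxels[, 2])[2],
            range(e$voxels[, 3])[1], range(e$voxels[, 3])[2]), ""))
    want_k <- sort(vapply(want, function(e)
      paste(e$n_vox, e$xr[1], e$xr[2], e$yr[1], e$yr[2], e$tr[1], e$tr[2]), ""))
    expect_identical(got_k, want_k)
  }
})

test_that("wave metrics follow the bounding-box definitions", {
  # a component spanning x 2..4, one y site, t samples 1..1000 at 1 ms
  vox <- cbind(x = rep(2:4, each = 1000), y = 5, t = rep(1:1000, 3))
  m <- wave_metrics(list(voxels = vox), sample_ms = 1)
  expect_equal(m$duration, 0.999)
  expect_equal(m$area, 3)
  expect_equal(m$velocity, 3 / 0.999)
  # metrics are a function of the voxel set, not its ordering
  m2 <- wave_metrics(list(voxels = vox[sample(nrow(vox)), ]), sample_ms = 1)
  expect_equal(m, m2)
})

test_that("interval-based lattice segmentation equals voxel labeling", {
  q <- max_interval_params()
  set.seed(77)
  for (rep in 1:15) {
    nx <- 4; ny <- 3; nt <- 120
    bursts <- vector("list", nx * ny)
    mask <- array(FALSE, c(nx, ny, nt))
    for (cell in seq_len(nx * ny)) {
      nb <- sample(0:2, 1)
      if (!nb) { bursts[[cell]] <- data.frame(start = numeric(0), end = numeric(0)); next }
      st <- sort(sample(seq(1, nt - 30, by = 1), nb))
      en <- pmin(st + sample(3:25, nb, replace = TRUE), nt - 1)
      keep <- c(TRUE, if (nb > 1) st[-1] > en[-nb] + 2 else NULL)
      st <- st[keep]; en <- en[keep]
      bursts[[cell]] <- data.frame(start = st, end = en)
      ix <- ((cell - 1) %% nx) + 1; iy <- ((cell - 1) %/% nx) + 1
      for (k in seq_along(st)) mask[ix, iy, (st[k]:en[k]) + 1] <- TRUE
    }
    got <- sacwaves:::wave_segmentation_bursts(bursts, nx, ny, sample_ms = 1)
    want <- wave_segmentation(mask, sample_ms = 1)
    expect_equal(length(got$events), length(want$events))
    expect_equal(got$n_excluded, want$n_excluded)
    expect_equal(sort(vapply(got$events, `[[`, 0, "area")),
                 sort(vapply(want$events, `[[`, 0, "area")))
    expect_equal(sort(vapply(got$events, `[[`, 0, "duration")),
                 sort(vapply(want$events, `[[`, 0, "duration")))
  }
})

test_that("condition summaries report the full metric block and handle empties", {
  # two flat traces with planted pulse groups
  fx <- make_fixture("voltage_trace", groups = 2, spikes_per_group = 5,
                     isi = 100, gap = 600)
  s <- summarize_condition(list(fx, fx))
  expect_setequal(s$metric, c("baseline", "min_amplitude", "max_amplitude",
                              "spike_duration", "burst_duration", "ibi"))
  expect_equal(s$mean[s$metric == "baseline"], -60)
  expect_equal(s$mean[s$metric == "spike_duration"], 5)
  expect_equal(s$n[s$metric == "burst_duration"], 2) # one merged burst per trace
  expect_equal(s$n[s$metric == "ibi"], 0)
  expect_true(is.na(s$mean[s$metric == "ibi"]))
  # flat traces: every event metric is absent, not zero
  flat <- data.frame(t = 0:999, V = rep(-60, 1000))
  s0 <- summarize_condition(list(flat))
  expect_true(is.na(s0$mean[s0$metric == "spike_duration"]))
  expect_equal(s0$n[s0$metric == "burst_duration"], 0)
})

test_that("voxel mask time indexing matches burst intervals on the sample grid", {
  # one burst [10, 14] ms at 1 ms sampling covers exactly samples 10..14
  bursts <- list(data.frame(start = 10, end = 14),
                 data.frame(start = 12, end = 13))
  w <- sacwaves:::wave_segmentation_bursts(bursts, nx = 2, ny = 1,
                                           sample_ms = 1)
  expect_equal(length(w$events), 1)
  expect_equal(w$events[[1]]$duration, (14 - 10) / 1000)
})
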