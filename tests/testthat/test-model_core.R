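test_that("gating, rate and release functions match their closed forms", {
  p <- sac_parameters()
  # half-activation points and saturation
  expect_equal(gate_inf(-20, p$V1, p$V2), 0.5)
  expect_equal(gate_inf(-25, p$V3, p$V4), 0.5)
  expect_equal(gate_inf(1e6, p$V1, p$V2), 1)
  expect_equal(gate_inf(-1e6, p$V1, p$V2), 0)
  # rate multiplier: 1 at V3, cosh(1) one slope-width out, symmetric
  expect_equal(rate_lambda(-25, -25, 7), 1)
  expect_equal(rate_lambda(-11, -25, 7), cosh(1))
  expect_equal(rate_lambda(-39, -25, 7), rate_lambda(-11, -25, 7))
  # release sigmoid
  expect_equal(release_phi(-40, 0.2, -40), 0.5)
  expect_equal(release_phi(-30, 0.2, -40), 1 / (1 + exp(-2)))
  expect_equal(release_phi(-1e5, 0.2, -40), 0, tolerance = 1e-12)
  # receptor Hill activation
  expect_equal(receptor_activation(0, 0.1), 0)
  expect_equal(receptor_activation(sqrt(0.1), 0.1), 0.5)
  expect_equal(receptor_activation(1, 0.1), 1 / 1.1)
  expect_error(receptor_activation(-0.1, 0.1), "invalid state")
})

test_that("gating outputs stay in [0, 1] across the physiological range", {
  p <- sac_parameters()
  v <- seq(-120, 60, by = 0.25)
  for (f in list(gate_inf(v, p$V1, p$V2), gate_inf(v, p$V3, p$V4),
                 release_phi(v, p$Vse, p$V0e), release_phi(v, p$Vsi, p$V0i))) {
    expect_true(all(f >= 0 & f <= 1))
  }
  r <- sodium_rates(v, p)
  expect_true(all(unlist(r) >= 0))
  expect_true(all(rate_lambda(v, p$V3, p$V4) >= 1))
})

test_that("sodium rates reduce to the classic form with the singularity filled", {
  p <- sac_parameters()
  r <- sodium_rates(-40, p)
  expect_equal(r$alpha_m, 1)          # L'Hopital limit at V = V8
  expect_equal(sodium_rates(-65, p)$beta_m, 4)
  expect_equal(sodium_rates(-35, p)$beta_h, 0.5)
  # continuity across the singular point
  eps <- sodium_rates(-40 + 1e-9, p)$alpha_m
  expect_equal(eps, 1, tolerance = 1e-6)
})

test_that("worked synaptic currents at -40 mV with full receptor activation", {
  p <- sac_parameters()
  s <- sac_initial_state(V = -40, E = 1e12, I = 1e12) # activation == 1
  cur <- ionic_currents(s, p)
  expect_equal(cur[["IACh"]], 8.6, tolerance = 1e-14)
  expect_equal(cur[["IGABA"]], -22.5, tolerance = 1e-14)
  # leak current vanishes at its reversal potential
  expect_equal(ionic_currents(sac_initial_state(V = p$ELeak), p)[["Ileak"]], 0)
})

test_that("current-sum conservation holds to machine precision", {
  p <- sac_parameters(Iapp = 3.7)
  set.seed(42)
  worst <- 0
  for (i in 1:10000) {
    s <- c(V = runif(1, -100, 20), N = runif(1), M = runif(1), H = runif(1),
           C = runif(1, 0, 2), A = runif(1), B = runif(1),
           E = runif(1, 0, 8), I = runif(1, 0, 8), W = rnorm(1, 0, 25))
    resid <- p$Cm * sac_rhs(s, p)[["V"]] - p$Iapp - sum(ionic_currents(s, p))
    worst <- max(worst, abs(resid))
  }
  expect_lt(worst, 1e-10)
})

test_that("drift vanishes at the appropriate steady states", {
  # rest at the leak reversal when only leak is present
  p <- sac_parameters(gCa = 0, gK = 0, gNa = 0, gTREK = 0, gACh = 0,
                      gGABA = 0, sigma = 0, Iapp = 0)
  s <- sac_initial_state(V = p$ELeak, W = 0)
  expect_equal(sac_rhs(s, p)[["V"]], 0)
  # calcium steady state with the calcium current silenced
  p2 <- sac_parameters(gCa = 0)
  s2 <- sac_initial_state(V = -120, C = p2$C0 / p2$lambda)
  expect_equal(sac_rhs(s2, p2)[["C"]], 0, tolerance = 1e-12)
  # reduced-system drift vanishes at every reported equilibrium
  eq <- find_equilibria(sac_parameters(), Iapp = 0)
  for (k in seq_len(nrow(eq))) {
    d <- reduced_drift(eq$V_star[k], eq$N_star[k], sac_parameters(), Iapp = 0)
    expect_lt(max(abs(d)), 1e-8)
  }
})

test_that("R and C++ right-hand sides agree at random states", {
  p <- sac_parameters(Iapp = 1.2)
  pv <- sacwaves:::params_to_vector(p)
  set.seed(7)
  for (i in 1:50) {
    s <- c(V = runif(1, -90, 10), N = runif(1), M = runif(1), H = runif(1),
           C = runif(1, 0, 1), A = runif(1), B = runif(1),
           E = runif(1, 0, 6), I = runif(1, 0, 6), W = rnorm(1, 0, 20))
    lap <- rnorm(2, 0, 0.5)
    expect_equal(sacwaves:::cpp_rhs(s, pv, lap[1], lap[2]),
                 sac_rhs(s, p, lap[1], lap[2]), tolerance = 1e-12)
  }
})

test_that("OU noise has the exact stationary mean and variance", {
  tauW <- 1000
  n <- 200000
  dt <- 500 # long steps decorrelate samples; the update is exact for any dt
  set.seed(11)
  a <- exp(-dt / tauW)
  b <- sqrt(tauW / 2 * (1 - a^2))
  w <- as.numeric(stats::filter(b * rnorm(n), a, method = "recursive"))
  expect_lt(abs(mean(w)) / (sqrt(tauW / 2) / sqrt(n / 10)), 4)
  expect_equal(var(w), tauW / 2, tolerance = 0.05)
  # single-step contract
  expect_equal(ou_step(3, dt = 10, tauW = tauW, z = 0), 3 * exp(-10 / tauW))
  # sigma = 0 silences the noise current regardless of W
  p0 <- sac_parameters(sigma = 0)
  s <- sac_initial_state(W = 123)
  expect_identical(ionic_currents(s, p0)[["Inoise"]], 0)
})

test_that("parameter defaults round-trip the reference table and validate", {
  p <- sac_parameters()
  expect_identical(p$Cm, 17)
  expect_identical(p$gACh, 0.215)
  expect_identical(p$sigma, 5)
  expect_identical(p$tauW, 1000)
  expect_identical(p$tauB, 8300)
  expect_identical(unname(p$dYi), c(1.9, 0.1))
  expect_identical(sac_initial_state()[["V"]], -63.6)
  expect_error(sac_parameters(gNA = 1), "gNa")
  expect_error(sac_parameters(Cm = -1))
  expect_error(sac_parameters(tauN = 0))
})
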