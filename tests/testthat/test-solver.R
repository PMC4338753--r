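test_that("passive single compartment follows the analytic RC charging curve", {
  m <- soma_only_morph(10, 10) # area pi*10*10 um2
  p <- pc_passive(cm = c(soma = 1, dend = 1, axon = 1, myelin = 1),
                  gleak = c(soma = 1e-4, dend = 1e-4, axon = 1e-4,
                            myelin = 1e-4), eleak = -65)
  mod <- pc_model(m, empty_channels(), p)
  area <- pi * 10 * 10 * 1e-8            # cm2
  g <- 1e-4 * area * 1e6                 # uS
  C <- 1 * area * 1e3                    # nF
  amp <- 0.01
  tau <- C / g
  vinf <- -65 + amp / g
  rel_err <- function(dt) {
    tr <- pc_run(mod, 300, dt = dt, stim = pc_stim_step("soma", amp, 0, 310),
                 settle = 400, v_init = -65)
    v_theory <- vinf + (-65 - vinf) * exp(-tr$time / tau)
    list(tr = tr,
         err = max(abs(tr$v[, 1] - v_theory)) / (vinf - (-65)))
  }
  # first-order implicit step: ~0.15% of the deflection at dt = 0.025 ms,
  # converging linearly toward the analytic curve
  e1 <- rel_err(0.025)
  e2 <- rel_err(0.005)
  expect_lt(e1$err, 2.5e-3)
  expect_lt(e2$err, 5e-4)
  expect_lt(e2$err, e1$err / 3)
  # and the computed trajectory matches the implicit recurrence exactly
  # (a step starting on a sample boundary acts from the integration step
  # that ends on that boundary, so the first recorded sample is n = 2)
  a <- 1 / (1 + e1$tr$dt / tau)
  v_be <- vinf + (-65 - vinf) * a^(seq_along(e1$tr$time) + 1)
  expect_lt(max(abs(e1$tr$v[, 1] - v_be)), 1e-9)
})

test_that("with all channels off the voltage relaxes to the leak reversal", {
  mod <- pc_model(pc_morphology(40, seed = 5), empty_channels())
  for (v0 in c(-90, -30)) {
    tr <- pc_run(mod, 50, settle = 600, v_init = v0)
    expect_equal(unname(tr$v[nrow(tr$v), 1]), mod$passive$eleak,
                 tolerance = 1e-6)
  }
})

test_that("axial coupling conductances follow the cylindrical formula", {
  # two identical sections d = 1 um, L = 100 um, Ra = 122 Ohm cm
  m <- structure(data.frame(id = 1:2, parent = c(0L, 1L),
                            tag = c("soma", "terminal_dendrite"),
                            diam = 1, length = 100),
                 class = c("pc_morphology", "data.frame"))
  p <- pc_passive()
  # coarse discretisation (one compartment per section) so the coupling is
  # section-to-section
  mod <- pc_model(m, empty_channels(), p, d_lambda = 10)
  # conductance between the two sections:
  # g = 1 / (Ra*(L1/2)/(pi r^2) + Ra*(L2/2)/(pi r^2))
  l_half <- (100 / 2) * 1e-4 # cm
  r_cm <- 0.5e-4
  rhalf <- 122 * l_half / (pi * r_cm^2) / 1e6 # MOhm
  g_theory <- 1 / (2 * rhalf)
  k <- mod$first_comp[2]
  expect_equal(mod$sys$gax[k], g_theory, tolerance = 1e-12)
  # doubling Ra halves every coupling conductance (same discretisation)
  p2 <- pc_passive(ra = 244)
  mod2 <- pc_model(m, empty_channels(), p2, d_lambda = 10)
  expect_equal(mod2$sys$gax[-1], mod$sys$gax[-1] / 2, tolerance = 1e-12)
  # tree sparsity: every non-root compartment couples to exactly one parent
  expect_true(all(mod$sys$parent[-1] >= 0))
  expect_true(all(mod$sys$gax[-1] > 0))
})

test_that("finite-cable input resistance matches the sealed-end formula", {
  d <- 2; L <- 600
  m <- cable_morph(d = d, L_total = L, nsec = 12)
  gl <- 5e-5; Rm <- 1 / gl; Ra <- 122
  p <- pc_passive(ra = Ra,
                  cm = c(soma = 1, dend = 1, axon = 1, myelin = 1),
                  gleak = c(soma = gl, dend = gl, axon = gl, myelin = gl),
                  eleak = -65)
  mod <- pc_model(m, empty_channels(), p, d_lambda = 0.02)
  rin <- impedance_from_soma(mod, passive = FALSE)$rin
  lambda <- sqrt((d * 1e-4 / 4) * (Rm / Ra))     # cm
  r_inf <- (Rm * Ra)^0.5 * 2 / (pi * (d * 1e-4)^1.5) / 1e6 # MOhm
  rin_theory <- r_inf / tanh((L * 1e-4) / lambda)
  expect_lt(abs(rin - rin_theory) / rin_theory, 0.01)
})

test_that("charge balance holds for the passive model", {
  m <- soma_only_morph(20, 20)
  p <- pc_passive(cm = c(soma = 1, dend = 1, axon = 1, myelin = 1),
                  gleak = c(soma = 5e-5, dend = 5e-5, axon = 5e-5,
                            myelin = 5e-5), eleak = -65)
  mod <- pc_model(m, empty_channels(), p)
  area <- pi * 20 * 20 * 1e-8
  g <- 5e-5 * area * 1e6; C <- area * 1e3
  amp <- 0.02; dur <- 200
  tr <- pc_run(mod, dur, stim = pc_stim_step("soma", amp, 20, 120),
               settle = 500, v_init = -65, rec_every = 1)
  dt <- tr$dt
  v <- tr$v[, 1]
  # discrete charge accounting consistent with the implicit update:
  # C (v_k - v_{k-1}) = dt (-g (v_k - E) + I_k) summed over steps
  v0 <- -65 # settled exactly at the leak reversal before the step
  q_inj <- amp * dt * sum(tr$time >= 20 & tr$time < 120)
  q_cap <- C * (v[length(v)] - v0)
  q_leak <- sum(g * (v - (-65))) * dt
  expect_lt(abs(q_inj - (q_cap + q_leak)) / q_inj, 1e-6)
})

test_that("a 1 nS single compartment measures 1 GOhm input resistance", {
  m <- soma_only_morph(10, 10)
  gl <- 1e-9 / (pi * 10 * 10 * 1e-8) # S/cm2 so that g*area = 1 nS
  p <- pc_passive(cm = c(soma = 1, dend = 1, axon = 1, myelin = 1),
                  gleak = c(soma = gl, dend = gl, axon = gl, myelin = gl),
                  eleak = -65)
  mod <- pc_model(m, empty_channels(), p)
  tr <- pc_run(mod, 200, stim = pc_stim_step("soma", -0.01, 0, 200),
               settle = 100, v_init = -65, rec_every = 4)
  dv <- unname(tr$v[nrow(tr$v), 1]) - (-65)
  expect_equal(dv / -0.01, 1000, tolerance = 0.01)
})

test_that("runs are deterministic and zero-duration runs are empty", {
  mod <- pc_model(pc_morphology(40, seed = 2))
  a <- pc_run(mod, 100, settle = 100)
  b <- pc_run(mod, 100, settle = 100)
  expect_identical(a$v, b$v)
  z <- pc_run(mod, 0, settle = 0)
  expect_equal(length(z$time), 0)
})

test_that("the divergence guard aborts with a diagnostic", {
  # drive a tiny passive compartment far past the +/-200 mV guard
  m <- soma_only_morph(10, 10)
  mod <- pc_model(m, empty_channels())
  expect_error(pc_run(mod, 50, stim = pc_stim_step("soma", 100, 0, 50),
                      settle = 0), "diverged")
})

test_that("spikes initiate in the AIS before the soma", {
  tr <- canonical_spont()
  th <- -20
  up_soma <- tr$time[which(diff(tr$v[, "soma"] > th) == 1)]
  up_ais <- tr$time[which(diff(tr$v[, "AIS"] > th) == 1)]
  expect_gt(length(up_soma), 10)
  for (t_s in up_soma) {
    lead <- t_s - up_ais[which.min(abs(up_ais - t_s))]
    expect_gt(lead, 0)    # AIS crosses threshold first
    expect_lt(lead, 1)    # by well under a millisecond
  }
})

test_that("the somatic impedance of the assembled model is calibrated", {
  imp <- impedance_from_soma(canonical_model())
  expect_lt(abs(imp$rin - 14) / 14, 0.10)
  expect_lt(abs(imp$cin - 1090) / 1090, 0.10)
})
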