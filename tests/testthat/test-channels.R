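test_that("Q10 scaling follows the closed form", {
  expect_equal(q10_scale(1, 37, 37), 1)
  expect_equal(q10_scale(1, 23, 37), 3^1.4, tolerance = 1e-12)
  expect_equal(q10_scale(1, 23, 37), 4.6555, tolerance = 1e-4)
  expect_equal(q10_scale(2, 37, 23), 2 * 3^(-1.4), tolerance = 1e-12)
  expect_equal(q10_scale(2, 37, 23), 0.4296, tolerance = 1e-3)
})

test_that("the default channel table reproduces the reference densities", {
  tab <- pc_channelome()
  expect_equal(pc_gmax("Nav1.6", "AIS", tab), 0.5)
  expect_equal(pc_gmax("Nav1.6", "soma", tab), 0.214)
  expect_equal(pc_gmax("Nav1.6", "node", tab), 0.03)
  expect_equal(pc_gmax("Kv3.4", "soma", tab), 0.05)
  expect_equal(pc_gmax("Kv3.4", "collateral", tab), 0.02)
  expect_equal(pc_gmax("Kv1.1", "paraAIS", tab), 0.01)
  expect_equal(pc_gmax("KCa1.1", "terminal_dendrite", tab), 3.5e-2)
  expect_equal(pc_gmax("Cav2.1", "principal_dendrite", tab), 1e-3)
  expect_equal(pc_gmax("Cav3.1", "AIS", tab), 1e-5)
  expect_equal(pc_gmax("HCN1", "soma", tab), 4e-4)
  expect_equal(pc_gmax("Kir2.x", "soma", tab), 3e-5)
  # the paraAIS carries only Kv1.1, myelin carries nothing
  para <- tab[tab$region == "paraAIS" & tab$gmax > 0, ]
  expect_equal(para$channel, "Kv1.1")
  expect_equal(nrow(tab[tab$region == "myelin", ]), 0)
  for (ch in setdiff(pc_channel_names(), "Kv1.1"))
    expect_equal(pc_gmax(ch, "myelin", tab), 0)
})

test_that("fixed reversal potentials are as specified", {
  expect_equal(pc_erev("Nav1.6"), 60)
  expect_equal(pc_erev("Kv3.4"), -88)
  expect_equal(pc_erev("HCN1"), -34.4)
  expect_equal(pc_erev("TRP"), 0)
  expect_true(is.na(pc_erev("Cav2.1"))) # GHK-updated
})

test_that("gate steady states behave as documented", {
  # Kv1.1 alpha(v) = beta(v) at -45 mV => per-gate steady state 0.5
  expect_equal(unname(gate_steady_state("Kv1.1", -45)[1, 1]), 0.5,
               tolerance = 1e-9)
  # Cav2.1 activation: per-gate half-activation -29.5 mV, slope -8.5 mV
  expect_equal(unname(gate_steady_state("Cav2.1", -29.5)[1, 1]), 0.5,
               tolerance = 1e-9)
  m1 <- gate_steady_state("Cav2.1", -29.5 + 1e-3)[1, 1]
  m0 <- gate_steady_state("Cav2.1", -29.5 - 1e-3)[1, 1]
  slope <- unname((m1 - m0) / 2e-3) # dm/dV at half = -1/(4k) with k = -8.5
  expect_equal(slope, 1 / (4 * 8.5), tolerance = 1e-3)
  # Ca-dependent gating: KCa1.1 open fraction rises from 45 nM to 1.6 uM
  v <- -20
  lo <- gate_steady_state("KCa1.1", v, cai = 4.5e-5)
  hi <- gate_steady_state("KCa1.1", v, cai = 1.6e-3)
  open <- function(g) g[1, 1]^3 * g[1, 2]^2 * g[1, 3]
  expect_gt(open(hi), open(lo))
  # monotone in Cai at fixed V
  cais <- c(4.5e-5, 2e-4, 8e-4, 1.6e-3, 5e-3)
  opens <- vapply(cais, function(ca)
    open(gate_steady_state("KCa1.1", v, cai = ca)), 0)
  expect_true(all(diff(opens) > 0))
})

test_that("gate values stay in [0, 1] over the working voltage range", {
  v <- seq(-120, 60, by = 2.5)
  for (ch in setdiff(pc_channel_names(), c("Nav1.6", "KCa2.2", "TRP"))) {
    inf <- gate_steady_state(ch, v)
    tau <- gate_time_constant(ch, v)
    expect_true(all(inf >= 0 & inf <= 1), label = ch)
    expect_true(all(tau > 0), label = paste(ch, "tau"))
  }
})

test_that("Markov stationary occupancies match master-equation integration", {
  for (case in list(list(ch = "Nav1.6", v = -80, cai = 4.5e-5),
                    list(ch = "Nav1.6", v = -40, cai = 4.5e-5),
                    list(ch = "KCa2.2", v = -60, cai = 4.5e-5),
                    list(ch = "KCa2.2", v = -60, cai = 1.6e-3))) {
    Q <- markov_rate_matrix(case$ch, case$v, case$cai)
    ss <- markov_steady_state(case$ch, case$v, case$cai)
    p0 <- rep(0, nrow(Q)); p0[1] <- 1
    p_int <- integrate_master(Q, p0, t_end = 4000, dt = 0.02)
    expect_equal(sum(ss$p), 1, tolerance = 1e-12)
    expect_lt(max(abs(ss$p - p_int)), 1e-6)
  }
})

test_that("SK2 stationary occupancies obey detailed balance products", {
  # the 6-state scheme is a tree, so stationary occupancies are products
  # of forward/backward rate ratios along the unique paths
  cai <- 8e-4
  Q <- markov_rate_matrix("KCa2.2", -60, cai)
  p <- markov_steady_state("KCa2.2", -60, cai)$p
  r <- c(1,
         Q[1, 2] / Q[2, 1],
         Q[1, 2] / Q[2, 1] * Q[2, 3] / Q[3, 2],
         Q[1, 2] / Q[2, 1] * Q[2, 3] / Q[3, 2] * Q[3, 4] / Q[4, 3],
         Q[1, 2] / Q[2, 1] * Q[2, 3] / Q[3, 2] * Q[3, 5] / Q[5, 3],
         Q[1, 2] / Q[2, 1] * Q[2, 3] / Q[3, 2] * Q[3, 4] / Q[4, 3] *
           Q[4, 6] / Q[6, 4])
  expect_equal(p, r / sum(r), tolerance = 1e-9)
})

test_that("Nav1.6 is shut at strong hyperpolarisation", {
  ss <- markov_steady_state("Nav1.6", -80)
  # open + blocked occupancy negligible at -80 mV
  expect_lt(ss$p[6] + ss$p[7], 1e-4)
})

test_that("channel current follows the ohmic form and units", {
  expect_equal(channel_current("Kv3.4", v = -88, open = 0.7,
                               area = 1e-6, gmax = 0.01), 0)
  expect_equal(channel_current("Kv3.4", v = 0, open = 1,
                               area = 1e-6, gmax = 0), 0)
  # 0.01 S/cm2 fully open on 1e-6 cm2 at 100 mV driving force -> 1 nA
  expect_equal(channel_current("Kv3.4", v = 12, open = 1,
                               area = 1e-6, gmax = 0.01), 1,
               tolerance = 1e-12)
})

test_that("the calcium reversal policy reproduces the reference value", {
  expect_equal(ghk_ca_reversal(1e-3, 1e-3), 0)
  # default cao is back-solved so that Erev = 137.5 mV at rest
  expect_equal(ghk_ca_reversal(resting_calcium(), pc_default_cao(),
                               310.15), 137.5, tolerance = 1e-6)
  expect_equal(ghk_ca_reversal(4.5e-5, 2, 310), 143, tolerance = 1)
  # decreasing in Cai
  cais <- c(4.5e-5, 1e-4, 1e-3, 1e-2)
  es <- ghk_ca_reversal(cais, 1.33)
  expect_true(all(diff(es) < 0))
  expect_error(ghk_ca_reversal(-1, 2), "positive")
})

test_that("Q10 scaling changes tau but not the steady state", {
  v <- seq(-90, 20, by = 10)
  i37 <- gate_steady_state("Kv1.1", v, celsius = 37)
  i22 <- gate_steady_state("Kv1.1", v, celsius = 22)
  t37 <- gate_time_constant("Kv1.1", v, celsius = 37)
  t22 <- gate_time_constant("Kv1.1", v, celsius = 22)
  expect_equal(i37, i22, tolerance = 1e-12)
  expect_equal(t22 / t37, matrix(3^1.5, length(v), 1,
                                 dimnames = dimnames(t22)),
               tolerance = 1e-9)
})

test_that("gates and occupancies stay bounded under arbitrary clamps", {
  set.seed(11)
  # piecewise-random waveform within [-120, 60] mV
  lv <- runif(40, -120, 60)
  v <- rep(lv, each = 200)
  for (ch in c("Nav1.6", "KCa2.2", "Kv3.4", "KCa1.1", "Cav3.1", "HCN1")) {
    cl <- pc_clamp_channel(ch, v, dt = 0.025, v_hold = -65)
    expect_true(all(cl$states >= -1e-12 & cl$states <= 1 + 1e-12),
                label = ch)
    expect_true(all(cl$open >= 0 & cl$open <= 1), label = ch)
    if (ch %in% c("Nav1.6", "KCa2.2"))
      expect_equal(rowSums(cl$states), rep(1, length(v)), tolerance = 1e-9)
  }
})

test_that("dynamic gating converges to the steady state under long clamp", {
  v <- -47.5
  n <- 80000 # 2 s
  cl <- pc_clamp_channel("Nav1.6", rep(v, n), v_hold = -90)
  ss <- markov_steady_state("Nav1.6", v)
  expect_equal(cl$open[n], ss$open, tolerance = 1e-5)
  cl2 <- pc_clamp_channel("Kv4.3", rep(v, 40000), v_hold = -90)
  inf <- gate_steady_state("Kv4.3", v)
  expect_equal(cl2$states[40000, ], unname(inf[1, ]), tolerance = 1e-5)
})

test_that("Nav1.6 shows transient, persistent and resurgent components", {
  dt <- 0.025
  # transient: large, rapidly decaying open probability on a step to 0 mV
  w <- c(rep(-90, 40), rep(0, 800))
  cl <- pc_clamp_channel("Nav1.6", w, dt, v_hold = -90)
  expect_gt(max(cl$open), 0.3)
  expect_lt(cl$open[length(w)], 0.05 * max(cl$open))
  # persistent: small non-zero steady open probability at -40 mV
  ss <- markov_steady_state("Nav1.6", -40)
  expect_gt(ss$open, 1e-4)
  expect_lt(ss$open, 0.05)
  # resurgent: repolarisation to -30 mV after a strong step reopens the
  # channel transiently (unblocking), peaking after the repolarisation
  w <- c(rep(-90, 40), rep(30, 80), rep(-30, 600))
  cl <- pc_clamp_channel("Nav1.6", w, dt, v_hold = -90)
  seg <- cl$open[121:720]
  o_end_step <- cl$open[120]
  expect_gt(max(seg), 2 * o_end_step) # transient reopening
  expect_gt(which.max(seg) * dt, 0.2) # peaks after repolarisation
  expect_lt(seg[600], max(seg) / 2)   # decays back toward persistent level
})
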