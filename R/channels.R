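# Channel models: the Purkinje-cell channelome, gating kinetics access,
# temperature scaling, and reversal-potential policies.

#' Region tags of the Purkinje-cell model
#'
#' The model is divided into electrotonic regions; channel densities and
#' calcium-pump densities are assigned per region.
#'
#' @return Character vector of the nine region tags.
#' @export
pc_regions <- function() {
  c("soma", "trunk_dendrite", "principal_dendrite", "terminal_dendrite",
    "AIS", "paraAIS", "myelin", "node", "collateral")
}

DEND_TAGS <- c("trunk_dendrite", "principal_dendrite", "terminal_dendrite")

#' Names of the ionic channel models
#'
#' @return Character vector of the fifteen channel names (NC-IUPHAR
#'   nomenclature) plus the TRP leak used by the Z- variant.
#' @export
pc_channel_names <- function() as.character(cpp_channel_names())

pc_channel_code <- function(channel) {
  code <- match(channel, pc_channel_names()) - 1L
  if (anyNA(code)) stop("unknown channel: ", paste(channel[is.na(code)], collapse = ", "))
  code
}

#' Channel metadata (kinetic scheme, gates, reversal policy)
#'
#' @param channel Channel name, e.g. `"Nav1.6"`.
#' @return List with kinetics kind (`"hh"` or `"markov"`), gate count and
#'   exponents, Markov state count, source-data temperature and whether the
#'   channel carries calcium (GHK-updated reversal).
#' @export
pc_channel_info <- function(channel) {
  info <- cpp_channel_info(pc_channel_code(channel))
  info$erev <- pc_erev(channel)
  info
}

# fixed reversal potentials (mV); Ca channels use the GHK-updated reversal
PC_EREV <- c(
  "Nav1.6" = 60, "Kv1.1" = -88, "Kv1.5" = -88, "Kv3.3" = -88, "Kv3.4" = -88,
  "Kv4.3" = -88, "Kir2.x" = -88, "KCa1.1" = -88, "KCa2.2" = -88,
  "KCa3.1" = -88, "Cav2.1" = NA, "Cav3.1" = NA, "Cav3.2" = NA, "Cav3.3" = NA,
  "HCN1" = -34.4, "TRP" = 0
)

pc_erev <- function(channel) unname(PC_EREV[channel])

#' Default channel distribution table
#'
#' The canonical placement and maximal conductance density of the fifteen
#' channel models across the model regions.  Dendritic densities are carried
#' by all three dendritic orders except Nav1.6, which is restricted to the
#' trunk (main dendrite) as in the immunohistochemical picture the model
#' encodes.  The paraAIS carries only Kv1.1 and myelin carries no channels.
#'
#' @return A data frame with columns `channel`, `region`, `gmax` (S/cm2).
#' @export
pc_channelome <- function() {
  row <- function(channel, region, gmax) {
    if (identical(region, "dendrites")) region <- DEND_TAGS
    data.frame(channel = channel, region = region, gmax = gmax)
  }
  tab <- rbind(
    row("Nav1.6", "trunk_dendrite", 0.016),
    row("Nav1.6", "soma", 0.214),
    row("Nav1.6", "AIS", 0.5),
    row("Nav1.6", "node", 0.03),
    row("Nav1.6", "collateral", 0.03),
    row("Kv1.1", "dendrites", 0.0012),
    row("Kv1.1", "soma", 0.002),
    row("Kv1.1", "paraAIS", 0.01),
    row("Kv1.5", "dendrites", 1.3e-4),
    row("Kv3.3", "dendrites", 0.01),
    row("Kv3.4", "soma", 0.05),
    row("Kv3.4", "AIS", 0.01),
    row("Kv3.4", "node", 0.01),
    row("Kv3.4", "collateral", 0.02),
    row("Kv4.3", "dendrites", 0.001),
    row("Kir2.x", "dendrites", 1e-5),
    row("Kir2.x", "soma", 3e-5),
    row("KCa1.1", "dendrites", 3.5e-2),
    row("KCa1.1", "soma", 0.01),
    row("KCa2.2", "dendrites", 1e-3),
    row("KCa2.2", "soma", 1e-3),
    row("KCa3.1", "dendrites", 0.002),
    row("KCa3.1", "soma", 0.01),
    row("Cav2.1", "dendrites", 1e-3),
    row("Cav2.1", "soma", 2.2e-4),
    row("Cav2.1", "AIS", 2.2e-4),
    row("Cav2.1", "node", 2.2e-4),
    row("Cav2.1", "collateral", 2.2e-4),
    row("Cav3.1", "dendrites", 5e-6),
    row("Cav3.1", "soma", 7e-6),
    row("Cav3.1", "AIS", 1e-5),
    row("Cav3.1", "node", 1e-5),
    row("Cav3.1", "collateral", 1e-5),
    row("Cav3.2", "dendrites", 0.0012),
    row("Cav3.2", "soma", 0.0008),
    row("Cav3.3", "dendrites", 1e-4),
    row("Cav3.3", "soma", 1e-4),
    row("HCN1", "dendrites", 4e-6),
    row("HCN1", "soma", 4e-4)
  )
  rownames(tab) <- NULL
  tab
}

#' Query the default conductance density of a channel in a region
#'
#' @param channel Channel name.
#' @param region Region tag (see [pc_regions()]).
#' @param channels Channel table, defaults to [pc_channelome()].
#' @return Density in S/cm2 (0 when the channel is absent from the region).
#' @export
pc_gmax <- function(channel, region, channels = pc_channelome()) {
  hit <- channels$channel == channel & channels$region == region
  if (!any(hit)) 0 else sum(channels$gmax[hit])
}

#' Temperature (Q10) scaling of a kinetic rate
#'
#' Rates measured at the experimental temperature are rescaled to the
#' simulation temperature as `rate * q10^((t_sim - t_exp)/10)`.
#'
#' @param rate Rate constant (1/ms).
#' @param t_exp Temperature of the source data (degrees C).
#' @param t_sim Simulation temperature (degrees C).
#' @param q10 Scaling factor per 10 degrees (default 3).
#' @return Scaled rate.
#' @export
q10_scale <- function(rate, t_exp, t_sim, q10 = 3) {
  rate * q10^((t_sim - t_exp) / 10)
}

#' Steady-state gate values of a Hodgkin-Huxley channel
#'
#' @param channel Channel name (must use HH gating).
#' @param v Membrane potential(s), mV.
#' @param cai Intracellular free calcium (mM) seen by Ca-dependent gates.
#' @param celsius Simulation temperature.
#' @return Matrix (length(v) x n_gates) of steady-state values in \[0, 1\].
#' @export
gate_steady_state <- function(channel, v, cai = resting_calcium(),
                              celsius = 37) {
  info <- pc_channel_info(channel)
  if (info$kind == "markov")
    stop(channel, " uses a Markov scheme; see markov_steady_state()")
  if (info$n_gates == 0) {
    return(matrix(1, length(v), 1, dimnames = list(NULL, "open")))
  }
  out <- cpp_hh_inf_tau(pc_channel_code(channel), v, cai, celsius)
  colnames(out$inf) <- paste0("gate", seq_len(ncol(out$inf)))
  out$inf
}

#' Gate time constants of a Hodgkin-Huxley channel
#'
#' @inheritParams gate_steady_state
#' @return Matrix of time constants (ms), one column per gate.
#' @export
gate_time_constant <- function(channel, v, cai = resting_calcium(),
                               celsius = 37) {
  info <- pc_channel_info(channel)
  if (info$kind == "markov") stop(channel, " uses a Markov scheme")
  out <- cpp_hh_inf_tau(pc_channel_code(channel), v, cai, celsius)
  colnames(out$tau) <- paste0("gate", seq_len(ncol(out$tau)))
  out$tau
}

#' Transition-rate matrix of a Markov channel
#'
#' @param channel `"Nav1.6"` or `"KCa2.2"`.
#' @param v Membrane potential, mV.
#' @param cai Intracellular free calcium, mM.
#' @param celsius Simulation temperature.
#' @return Square matrix Q with `Q[i, j]` the transition rate (1/ms) from
#'   state i to state j and `-rowSums` on the diagonal; attribute
#'   `conducting` gives the 0-based indices of conducting states.
#' @export
markov_rate_matrix <- function(channel, v, cai = resting_calcium(),
                               celsius = 37) {
  cpp_markov_rate_matrix(pc_channel_code(channel), v, cai, celsius)
}

#' Stationary occupancy of a Markov channel
#'
#' Solves for the probability vector in the null space of the transposed
#' rate matrix (the stationary distribution of the master equation).
#'
#' @inheritParams markov_rate_matrix
#' @return Named list: `p` occupancy vector (sums to 1), `open` summed
#'   occupancy of conducting states.
#' @export
markov_steady_state <- function(channel, v, cai = resting_calcium(),
                                celsius = 37) {
  Q <- markov_rate_matrix(channel, v, cai, celsius)
  n <- nrow(Q)
  M <- rbind(t(Q), rep(1, n))
  p <- qr.solve(M, c(rep(0, n), 1))
  if (any(p < -1e-8)) warning("rate matrix may be reducible at this (v, cai)")
  p <- pmax(p, 0)
  p <- p / sum(p)
  cond <- attr(Q, "conducting") + 1L
  list(p = p, open = sum(p[cond]))
}

#' Ionic current through a channel population
#'
#' Ohmic current `I = gmax * area * open * (v - erev)`, outward positive.
#'
#' @param channel Channel name (fixes the reversal policy).
#' @param v Membrane potential, mV.
#' @param open Open fraction in \[0, 1\].
#' @param area Membrane area, cm2.
#' @param gmax Maximal conductance density, S/cm2.
#' @param cai,cao Calcium concentrations (mM), used for the GHK-updated
#'   reversal of Ca channels.
#' @param celsius Temperature.
#' @return Current in nA.
#' @export
channel_current <- function(channel, v, open, area, gmax,
                            cai = resting_calcium(), cao = pc_default_cao(),
                            celsius = 37) {
  info <- cpp_channel_info(pc_channel_code(channel))
  erev <- if (info$is_ca_ion) ghk_ca_reversal(cai, cao, celsius + 273.15)
          else pc_erev(channel)
  gmax * area * 1e6 * open * (v - erev) # uS * mV = nA
}

#' Calcium reversal potential (single-ion GHK / Nernst form)
#'
#' @param cai,cao Intra- and extracellular free calcium, mM.
#' @param temp_k Absolute temperature, K.
#' @return Reversal potential, mV.
#' @export
ghk_ca_reversal <- function(cai, cao, temp_k = 310.15) {
  if (any(cai <= 0) || any(cao <= 0)) stop("concentrations must be positive")
  1000 * 8.31446 * temp_k / (2 * 96485.332) * log(cao / cai)
}

#' Default extracellular calcium concentration
#'
#' Chosen so that the GHK-updated calcium reversal equals 137.5 mV at the
#' resting intracellular concentration of 45 nM and 37 C.
#'
#' @param celsius Temperature used for the back-calculation.
#' @return Concentration in mM.
#' @export
pc_default_cao <- function(celsius = 37) {
  coef <- 1000 * 8.31446 * (celsius + 273.15) / (2 * 96485.332)
  resting_calcium() * exp(137.5 / coef)
}

#' Single-channel voltage-clamp simulation
#'
#' Integrates one channel's gating under an arbitrary voltage waveform
#' (exponential Euler for HH gates, implicit Euler for Markov schemes),
#' starting from the steady state at a holding potential.  Used to inspect
#' kinetics (e.g. the resurgent Na current) and as a convergence oracle.
#'
#' @param channel Channel name.
#' @param v Voltage waveform, one sample per time step (mV).
#' @param dt Time step, ms.
#' @param cai Calcium waveform (mM), recycled to `length(v)`.
#' @param v_hold Holding potential for initialisation.
#' @param celsius Temperature.
#' @return List with `open` (open fraction per step) and `states`
#'   (gate values or Markov occupancies per step).
#' @export
pc_clamp_channel <- function(channel, v, dt = 0.025,
                             cai = resting_calcium(), v_hold = v[1],
                             celsius = 37) {
  cai <- rep_len(cai, length(v))
  cpp_clamp_channel(pc_channel_code(channel), v, cai, dt, celsius,
                    v_hold, cai[1])
}
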