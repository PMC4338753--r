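# Intracellular calcium: submembrane shell stacks, diffusible buffers
# (calbindin, parvalbumin) and a generic extrusion pump.

#' Resting intracellular free calcium
#'
#' @return 4.5e-5 mM (45 nM), the resting operating point of the
#'   Ca-dependent K channels.
#' @export
resting_calcium <- function() 4.5e-5

#' Diffusible calcium buffer parameters
#'
#' Calbindin and parvalbumin as passive diffusible buffers, each with a
#' single effective binding site (total concentration mM, on-rate
#' 1/(mM ms), off-rate 1/ms, diffusion coefficient um2/ms).  Calmodulin and
#' other active Ca sensors are deliberately absent.
#'
#' @return List with `btot`, `kon`, `koff`, `dif`, and the free-calcium
#'   diffusion coefficient `dca`.
#' @export
pc_buffers <- function() {
  list(
    btot = c(calbindin = 0.16, parvalbumin = 0.08),
    kon = c(calbindin = 43.5, parvalbumin = 5),
    koff = c(calbindin = 0.0358, parvalbumin = 9.5e-4),
    dif = c(calbindin = 0.028, parvalbumin = 0.043),
    dca = 0.233
  )
}

#' Calcium subsystem parameters
#'
#' @param depth Outer (submembrane) shell depth, um.
#' @param max_shells Cap on the number of shells per compartment.
#' @param pump_rate Generic pump rate constant converting the region-wise
#'   pump densities (mol/cm2) into a maximal extrusion flux.
#' @param pump_kd Pump half-saturation, mM.
#' @param buffers Buffer parameter list, see [pc_buffers()].
#' @param substeps Sub-steps of the calcium update per voltage step.
#' @param permeation Calcium-channel permeation model: `"ohmic"` (ohmic
#'   current against the GHK-updated reversal, the default) or `"ghk"`
#'   (constant-field flux with the table densities read as permeabilities
#'   in cm/s).
#' @return Parameter list consumed by [pc_model()].
#' @export
pc_calcium_params <- function(depth = 0.1, max_shells = 4, pump_rate = 1e5,
                              pump_kd = 5e-4, buffers = pc_buffers(),
                              substeps = 2, permeation = c("ohmic", "ghk")) {
  permeation <- match.arg(permeation)
  list(depth = depth, max_shells = max_shells, pump_rate = pump_rate,
       pump_kd = pump_kd, buffers = buffers, substeps = substeps,
       permeation = permeation)
}

# region-wise pump densities (mol/cm2)
PC_PUMP_DENSITY <- c(
  soma = 5e-8, trunk_dendrite = 2e-8, principal_dendrite = 2e-8,
  terminal_dendrite = 2e-8, AIS = 5e-8, node = 5e-7, collateral = 5e-8
)

#' Build a submembrane shell stack for a cylindrical compartment
#'
#' The outermost shell has thickness `depth`; the remaining radius is split
#' into equal-thickness inner shells.  The number of shells adapts to the
#' compartment diameter: `max(1, min(max_shells, floor(radius / depth)))`.
#' Shell volumes always sum to the cylinder volume.
#'
#' @param diameter Compartment diameter, um.
#' @param depth Outer shell depth, um.
#' @param length Compartment length, um.
#' @param max_shells Shell-count cap.
#' @return List: `n` shells, `vol` (um3, outermost first), `gd` (diffusion
#'   geometry factor, contact area / centre distance, um), `bounds` radii.
#' @export
make_shells <- function(diameter, depth = 0.1, length = 1, max_shells = 4) {
  r <- diameter / 2
  n <- max(1L, min(as.integer(max_shells), as.integer(floor(r / depth))))
  if (n == 1L) {
    return(list(n = 1L, vol = pi * r^2 * length, gd = numeric(0),
                bounds = c(r, 0)))
  }
  tin <- (r - depth) / (n - 1)
  bounds <- c(r, r - depth, r - depth - tin * seq_len(n - 1))
  bounds[n + 1] <- 0
  vol <- pi * (bounds[-(n + 1)]^2 - bounds[-1]^2) * length
  centres <- (bounds[-(n + 1)] + bounds[-1]) / 2
  gd <- 2 * pi * bounds[2:n] * length / (centres[1:(n - 1)] - centres[2:n])
  list(n = n, vol = vol, gd = gd, bounds = bounds)
}

#' Initialise a shell stack state at equilibrium
#'
#' @param shells Geometry from [make_shells()].
#' @param cai Free calcium, mM.
#' @param buffers Buffer parameters.
#' @return List with `free` (per shell) and `bound` (buffers x shells).
#' @export
pc_ca_init <- function(shells, cai = resting_calcium(),
                       buffers = pc_buffers()) {
  kd <- buffers$koff / buffers$kon
  free <- rep(cai, shells$n)
  bound <- outer(buffers$btot * cai / (cai + kd), rep(1, shells$n))
  list(free = free, bound = bound)
}

#' Advance a calcium shell stack by one time step
#'
#' Influx from the calcium current into the outermost shell, radial
#' diffusion of free calcium and bound buffer, buffer binding kinetics, and
#' Michaelis-Menten pump extrusion from the outermost shell (balanced by a
#' constant leak so the resting concentration is a fixed point).  This is
#' the same scheme as the compiled engine, exposed for direct use and
#' testing.
#'
#' @param state State list from [pc_ca_init()].
#' @param shells Geometry from [make_shells()].
#' @param i_ca Calcium current, nA (outward positive; inward is negative
#'   and raises the submembrane concentration).
#' @param dt Time step, ms.
#' @param pump_vmax Maximal pump flux, mM um3 / ms (0 disables the pump).
#' @param pump_kd Pump half-saturation, mM.
#' @param buffers Buffer parameters.
#' @param substeps Explicit sub-steps.
#' @param ca_rest Resting concentration used to balance the pump leak.
#' @return Updated state.
#' @export
pc_ca_step <- function(state, shells, i_ca = 0, dt = 0.025, pump_vmax = 0,
                       pump_kd = 5e-4, buffers = pc_buffers(), substeps = 2,
                       ca_rest = resting_calcium()) {
  kcaf <- 1e6 / (2 * 96485.332)
  jleak <- pump_vmax * ca_rest / (ca_rest + pump_kd)
  free <- state$free
  bound <- state$bound
  n <- shells$n
  dtc <- dt / substeps
  for (s in seq_len(substeps)) {
    influx <- -i_ca * kcaf + jleak -
      pump_vmax * free[1] / (free[1] + pump_kd)
    free[1] <- free[1] + dtc * influx / shells$vol[1]
    if (n > 1) {
      for (j in seq_len(n - 1)) {
        fl <- buffers$dca * shells$gd[j] * (free[j] - free[j + 1])
        free[j] <- free[j] - dtc * fl / shells$vol[j]
        free[j + 1] <- free[j + 1] + dtc * fl / shells$vol[j + 1]
        for (b in seq_along(buffers$btot)) {
          fb <- buffers$dif[b] * shells$gd[j] * (bound[b, j] - bound[b, j + 1])
          bound[b, j] <- bound[b, j] - dtc * fb / shells$vol[j]
          bound[b, j + 1] <- bound[b, j + 1] + dtc * fb / shells$vol[j + 1]
        }
      }
    }
    for (j in seq_len(n)) {
      for (b in seq_along(buffers$btot)) {
        r <- buffers$kon[b] * free[j] * (buffers$btot[b] - bound[b, j]) -
          buffers$koff[b] * bound[b, j]
        d <- dtc * r
        if (d > free[j]) d <- free[j]
        bound[b, j] <- bound[b, j] + d
        free[j] <- free[j] - d
      }
      if (!is.finite(free[j]) || free[j] < 0) {
        if (!is.finite(free[j]) || free[j] < -1e-6)
          stop("negative calcium concentration: time step too large")
        free[j] <- 1e-9
      }
    }
  }
  list(free = free, bound = bound)
}

#' Total calcium content of a shell stack
#'
#' Volume-weighted free plus buffer-bound calcium; conserved in a closed
#' stack (no current, pump disabled).
#'
#' @param state,shells State and geometry.
#' @return Total calcium, mM um3.
#' @export
pc_ca_total <- function(state, shells) {
  sum(state$free * shells$vol) + sum(colSums(state$bound) * shells$vol)
}
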