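# Model assembly and the simulation front end: compartmentalisation,
# axial coupling, passive parameters, stimuli, runs, impedance.

#' Passive membrane parameters
#'
#' Specific capacitance and leak are region-resolved.  The somatic specific
#' capacitance is 0.77 uF/cm2; dendritic membrane uses a higher effective
#' value (default 1.81 uF/cm2) that folds in the spine membrane not
#' represented geometrically, which is what makes a 70,000 um2 cell measure
#' about 1090 pF from the soma.  Myelin capacitance is low (wrapping).
#' The leak conductances are the values calibrated so that the assembled
#' desk-scale model measures about 14 MOhm from the soma; the leak reversal
#' is -61 mV, near the pacemaking AHP floor.
#'
#' @param ra Axial resistivity, Ohm cm.
#' @param cm Named per-region specific capacitance, uF/cm2.
#' @param gleak Named per-region leak density, S/cm2.
#' @param eleak Leak reversal, mV.
#' @return Passive-parameter list.
#' @export
pc_passive <- function(ra = 122,
                       cm = c(soma = 0.77, dend = 1.81, axon = 0.77,
                              myelin = 0.09),
                       gleak = c(soma = 4.772e-5, dend = 1.122e-4,
                                 axon = 4.772e-5, myelin = 2.39e-6),
                       eleak = -61) {
  list(ra = ra, cm = cm, gleak = gleak, eleak = eleak)
}

region_class <- function(tag) {
  ifelse(tag == "soma", "soma",
  ifelse(tag %in% DEND_TAGS, "dend",
  ifelse(tag == "myelin", "myelin", "axon")))
}

# spatial discretisation: compartments no longer than d_lambda * lambda(100 Hz)
nseg_rule <- function(diam, len, tag, ra, cm_region, d_lambda = 0.1) {
  if (tag == "myelin") return(1L)
  lam100 <- 1e5 * sqrt(diam / (4 * pi * 100 * ra * cm_region))
  max(1L, as.integer(ceiling(len / (d_lambda * lam100))))
}

#' Assemble a simulatable Purkinje-cell model
#'
#' Discretises the morphology into compartments (each at most
#' `d_lambda` x the 100 Hz length constant; myelinated internodes are
#' single compartments), computes axial coupling conductances from the
#' cylindrical half-resistances, distributes channels by region tag,
#' and attaches calcium shell stacks wherever the pump table places them.
#'
#' @param morphology A [pc_morphology()].
#' @param channels Channel table (see [pc_channelome()]).
#' @param passive Passive parameters (see [pc_passive()]).
#' @param celsius Simulation temperature.
#' @param ca Calcium parameters (see [pc_calcium_params()]).
#' @param d_lambda Spatial-accuracy fraction.
#' @param nseg_min Lower bound on compartments per section (testing aid).
#' @return An object of class `pc_model`.
#' @export
pc_model <- function(morphology = pc_morphology(), channels = pc_channelome(),
                     passive = pc_passive(), celsius = 37,
                     ca = pc_calcium_params(), d_lambda = 0.1,
                     nseg_min = 1L) {
  m <- morphology
  stopifnot(all(m$parent %in% c(0L, m$id)))
  # sections must come after their parents for the tree solve
  pos <- match(m$parent, m$id)
  if (any(!is.na(pos) & pos >= seq_len(nrow(m))))
    stop("sections must be ordered parent-before-child")

  rc <- region_class(m$tag)
  cmr <- unname(passive$cm[ifelse(rc == "dend", "dend", rc)])
  glr <- unname(passive$gleak[ifelse(rc == "dend", "dend", rc)])

  nseg <- integer(nrow(m))
  for (i in seq_len(nrow(m)))
    nseg[i] <- max(nseg_min,
                   nseg_rule(m$diam[i], m$length[i], m$tag[i], passive$ra,
                             cmr[i], d_lambda))

  ncomp <- sum(nseg)
  parent <- integer(ncomp)
  area <- cm_nF <- gleak_uS <- gax <- numeric(ncomp)
  tag <- character(ncomp)
  sec_of <- integer(ncomp)
  first_comp <- last_comp <- integer(nrow(m))
  half_r <- numeric(ncomp) # axial half-resistance of each compartment, MOhm

  k <- 0L
  for (i in seq_len(nrow(m))) {
    li <- m$length[i] / nseg[i]            # um
    ai <- pi * m$diam[i] * li * 1e-8       # cm2
    rhalf <- passive$ra * (li / 2 * 1e-4) /
      (pi * (m$diam[i] / 2 * 1e-4)^2) / 1e6 # MOhm
    for (s in seq_len(nseg[i])) {
      k <- k + 1L
      if (s == 1L) {
        parent[k] <- if (m$parent[i] == 0L) 0L else last_comp[match(m$parent[i], m$id)]
      } else parent[k] <- k - 1L
      area[k] <- ai
      cm_nF[k] <- cmr[i] * ai * 1e3
      gleak_uS[k] <- glr[i] * ai * 1e6
      tag[k] <- m$tag[i]
      sec_of[k] <- m$id[i]
      half_r[k] <- rhalf
      if (s == 1L) first_comp[i] <- k
    }
    last_comp[i] <- k
  }
  for (k in seq_len(ncomp)) {
    p <- parent[k]
    gax[k] <- if (p == 0L) 0 else 1 / (half_r[k] + half_r[p])
  }

  # channel instances aggregated per channel
  chan <- list()
  for (ch in unique(channels$channel)) {
    rows <- channels[channels$channel == ch & channels$gmax > 0, , drop = FALSE]
    if (nrow(rows) == 0) next
    comp <- integer(0); gbar <- numeric(0)
    info <- cpp_channel_info(pc_channel_code(ch))
    # conductances in uS; Ca channels carry GHK permeability-area products
    # (cm^3/s) instead, with the table value read as permeability in cm/s
    unit <- if (info$is_ca_ion && identical(ca$permeation, "ghk")) 1 else 1e6
    for (r in seq_len(nrow(rows))) {
      sel <- which(tag == rows$region[r])
      comp <- c(comp, sel)
      gbar <- c(gbar, rows$gmax[r] * area[sel] * unit)
    }
    if (length(comp) == 0) next
    erev <- pc_erev(ch)
    chan[[length(chan) + 1]] <- list(
      type = pc_channel_code(ch), channel = ch,
      erev = if (is.na(erev)) 0 else erev,
      comp = comp - 1L, gbar = gbar)
  }

  # calcium shell stacks where the pump table places them
  calist <- list()
  for (k in which(tag %in% names(PC_PUMP_DENSITY))) {
    li <- m$length[match(sec_of[k], m$id)] / nseg[match(sec_of[k], m$id)]
    sh <- make_shells(area[k] * 1e8 / (pi * li), ca$depth, li, ca$max_shells)
    calist[[length(calist) + 1]] <- list(
      comp = k - 1L, vol = sh$vol, gd = sh$gd,
      pump_vmax = PC_PUMP_DENSITY[[tag[k]]] * ca$pump_rate * (area[k] * 1e8))
  }

  sys <- list(
    parent = parent - 1L, cm = cm_nF, gleak = gleak_uS,
    eleak = rep(passive$eleak, ncomp), gax = gax, chan = chan,
    ca = calist,
    buffers = list(btot = unname(ca$buffers$btot), kon = unname(ca$buffers$kon),
                   koff = unname(ca$buffers$koff), dif = unname(ca$buffers$dif),
                   dca = ca$buffers$dca),
    ca_substeps = ca$substeps, pump_kd = ca$pump_kd,
    ca_ghk = if (identical(ca$permeation, "ghk")) 1L else 0L,
    cao = pc_default_cao(celsius), carest = resting_calcium())

  structure(list(
    morphology = m, channels = channels, passive = passive, ca = ca,
    celsius = celsius, d_lambda = d_lambda, nseg = nseg,
    comp = data.frame(tag = tag, section = sec_of, area_cm2 = area,
                      parent = parent),
    first_comp = first_comp, last_comp = last_comp, sys = sys),
    class = "pc_model")
}

#' @export
print.pc_model <- function(x, ...) {
  cat("Purkinje-cell model:", nrow(x$morphology), "sections,",
      nrow(x$comp), "compartments,",
      sprintf("area %.0f um2, %g C\n", total_area(x$morphology), x$celsius))
  invisible(x)
}

#' Scale (or knock out) a channel in selected regions
#'
#' Returns a rebuilt model whose channel table has `gmax` multiplied by
#' `scale` for the given channel/region; `scale = 0` is a knockout.
#'
#' @param model A `pc_model`.
#' @param channel Channel name.
#' @param region A region tag, `"dendrites"` (all three dendritic orders) or
#'   `"all"`.
#' @param scale Multiplicative factor.
#' @return Edited `pc_model`.
#' @export
pc_edit <- function(model, channel, region = "all", scale = 0) {
  tab <- model$channels
  regions <- if (identical(region, "all")) unique(tab$region)
             else if (identical(region, "dendrites")) DEND_TAGS
             else region
  hit <- tab$channel == channel & tab$region %in% regions
  if (!any(hit) && scale != 0 && channel != "TRP")
    warning("no ", channel, " in ", paste(regions, collapse = "/"))
  tab$gmax[hit] <- tab$gmax[hit] * scale
  pc_model(model$morphology, tab, model$passive, model$celsius, model$ca,
           model$d_lambda)
}

#' Add a TRP leak conductance to the dendrites (Z- variant)
#'
#' @param model A `pc_model`.
#' @param gmax TRP density, S/cm2.
#' @return Edited model.
#' @export
pc_add_trp <- function(model, gmax) {
  tab <- rbind(model$channels,
               data.frame(channel = "TRP", region = DEND_TAGS, gmax = gmax))
  pc_model(model$morphology, tab, model$passive, model$celsius, model$ca,
           model$d_lambda)
}

# ---------------------------------------------------------------------------
# recording sites and stimuli
# ---------------------------------------------------------------------------

#' Resolve a named recording/stimulation site to a compartment
#'
#' Site names: `"soma"`, `"AIS"` (midpoint), `"paraAIS"`, `"node1"`..
#' `"node3"` (midpoints), `"collateral"` (distal end), `"trunk"` (middle
#' trunk section), `"terminal"` (most distal terminal dendrite by path
#' length), or a list `list(section =, pos =)` with pos in \[0, 1\].
#'
#' @param model A `pc_model`.
#' @param site Site name or list.
#' @return Compartment index (1-based).
#' @export
pc_site <- function(model, site) {
  m <- model$morphology
  comp_at <- function(sec_id, pos) {
    i <- match(sec_id, m$id)
    model$first_comp[i] + min(model$nseg[i] - 1L,
                              as.integer(pos * model$nseg[i]))
  }
  if (is.list(site)) return(comp_at(site$section, site$pos))
  if (is.numeric(site)) return(as.integer(site))
  secs_of <- function(tg) m$id[m$tag == tg]
  switch(site,
    soma = comp_at(secs_of("soma")[1], 0.5),
    AIS = comp_at(secs_of("AIS")[1], 0.5),
    paraAIS = comp_at(secs_of("paraAIS")[1], 0.5),
    node1 = comp_at(secs_of("node")[1], 0.5),
    node2 = comp_at(secs_of("node")[2], 0.5),
    node3 = comp_at(secs_of("node")[3], 0.5),
    collateral = comp_at(rev(secs_of("collateral"))[1], 0.95),
    trunk = {
      ids <- secs_of("trunk_dendrite")
      comp_at(ids[ceiling(length(ids) / 2)], 0.5)
    },
    terminal = {
      ids <- secs_of("terminal_dendrite")
      if (length(ids) == 0) stop("no terminal dendrites in this morphology")
      depth <- pc_path_length(m)
      comp_at(ids[which.max(depth[match(ids, m$id)])], 0.5)
    },
    stop("unknown site: ", site)
  )
}

# path length from the soma to the distal end of every section, um
pc_path_length <- function(m) {
  depth <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- match(m$parent[i], m$id)
    depth[i] <- m$length[i] + if (is.na(p)) 0 else depth[p]
  }
  depth
}

#' Step-current stimulus
#'
#' The current is applied to every integration step whose end time lies in
#' `[onset, offset)`; a step beginning exactly on a sample boundary
#' therefore acts from the integration step ending on that boundary.
#'
#' @param site Site (see [pc_site()]).
#' @param amp Amplitude, nA.
#' @param onset,offset Start and end times, ms (protocol time).
#' @return Stimulus description.
#' @export
pc_stim_step <- function(site, amp, onset, offset) {
  list(site = site, kind = 0L, t0 = onset, t1 = offset, amp = amp)
}

#' Piecewise-linear (ramp) current stimulus
#'
#' @param site Site.
#' @param t Times, ms (protocol time), strictly increasing.
#' @param a Amplitudes at `t`, nA; zero outside the range.
#' @return Stimulus description.
#' @export
pc_stim_ramp <- function(site, t, a) {
  stopifnot(length(t) == length(a), !is.unsorted(t, strictly = TRUE))
  list(site = site, kind = 1L, t = t, a = a)
}

# ---------------------------------------------------------------------------
# running simulations
# ---------------------------------------------------------------------------

#' Run a simulation
#'
#' Integrates the model with the fixed-step implicit scheme.  The model is
#' first settled for `settle` ms without stimulation (this transient is
#' discarded); stimulus and trace times are relative to the end of the
#' settling window.
#'
#' @param model A `pc_model`.
#' @param duration Recorded duration, ms.
#' @param dt Time step, ms (default 0.025).
#' @param stim List of stimuli ([pc_stim_step()] / [pc_stim_ramp()]).
#' @param record Character vector of site names (or list of site specs).
#' @param settle Settling window, ms.
#' @param record_ca Also record submembrane free calcium at the sites.
#' @param rec_every Record every n-th step.
#' @param v_init Initial voltage, mV.
#' @param vclamp Optional voltage clamp: `list(site =, t =, a =)`.
#' @return A `pc_traces` object: `time` (ms), `v` (matrix, one column per
#'   site), optionally `ca`.
#' @export
pc_run <- function(model, duration, dt = 0.025, stim = list(),
                   record = "soma", settle = 500, record_ca = FALSE,
                   rec_every = 1L, v_init = -65, vclamp = NULL) {
  if (length(stim) > 0 && !is.null(stim$kind)) stim <- list(stim)
  sites <- if (is.character(record)) as.list(record) else record
  rec_comp <- vapply(sites, function(s) pc_site(model, s), 1L)
  site_names <- vapply(seq_along(sites), function(i)
    if (is.character(sites[[i]])) sites[[i]] else paste0("site", i), "")
  cstim <- lapply(stim, function(s) {
    s2 <- s
    s2$comp <- pc_site(model, s$site) - 1L
    if (s$kind == 0L) { s2$t0 <- s$t0 + settle; s2$t1 <- s$t1 + settle }
    else s2$t <- s$t + settle
    s2
  })
  cl <- NULL
  if (!is.null(vclamp))
    cl <- list(comp = pc_site(model, vclamp$site) - 1L,
               t = vclamp$t + settle, a = vclamp$a)
  out <- cpp_sim_run(model$sys, dt, settle + duration, cstim, rec_comp - 1L,
                     settle + dt / 2, as.integer(rec_every), record_ca,
                     v_init, model$celsius, cl)
  colnames(out$v) <- site_names
  if (record_ca && !is.null(out$ca)) colnames(out$ca) <- site_names
  structure(list(time = out$time - settle, v = out$v, ca = out$ca,
                 dt = dt * rec_every, sites = site_names, settle = settle),
            class = "pc_traces")
}

#' @export
print.pc_traces <- function(x, ...) {
  cat(sprintf("pc_traces: %.1f ms at %.3f ms resolution, sites: %s\n",
              diff(range(x$time)), x$dt, paste(x$sites, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.pc_traces <- function(x, ...) {
  d <- data.frame(time = x$time)
  for (s in seq_along(x$sites)) d[[x$sites[s]]] <- x$v[, s]
  if (!is.null(x$ca))
    for (s in seq_along(x$sites)) d[[paste0("ca_", x$sites[s])]] <- x$ca[, s]
  d
}

#' Plot recorded traces
#'
#' @param x A `pc_traces`.
#' @param sites Which sites to draw.
#' @param ... Passed to `matplot`.
#' @export
plot.pc_traces <- function(x, sites = x$sites, ...) {
  sel <- match(sites, x$sites)
  graphics::matplot(x$time, x$v[, sel, drop = FALSE], type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::legend("topright", legend = sites, col = seq_along(sel), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Passive model copy (all active conductances removed)
#'
#' @param model A `pc_model`.
#' @return Model with every channel density zero.
#' @export
pc_passive_model <- function(model) {
  tab <- model$channels
  tab$gmax <- 0
  pc_model(model$morphology, tab, model$passive, model$celsius, model$ca,
           model$d_lambda)
}

#' Somatic input resistance and capacitance
#'
#' Applies a small hyperpolarising step (-10 pA) at the soma of the passive
#' model; the input resistance is the steady voltage deflection over the
#' current, and the input capacitance is the charging-transient integral
#' divided by the resistance.
#'
#' @param model A `pc_model` (made passive internally unless
#'   `passive = FALSE`).
#' @param amp Test current, nA.
#' @param passive Strip active conductances first.
#' @return List with `rin` (MOhm) and `cin` (pF).
#' @export
impedance_from_soma <- function(model, amp = -0.01, passive = TRUE) {
  pm <- if (passive) pc_passive_model(model) else model
  dur <- 700
  tr <- pc_run(pm, dur, stim = pc_stim_step("soma", amp, 100, dur),
               record = "soma", settle = 700)
  v <- tr$v[, 1]
  pre <- v[tr$time < 100]
  v0 <- mean(pre[length(pre) - (0:100)])
  vinf <- mean(v[tr$time > dur - 100])
  rin <- (vinf - v0) / amp
  on <- tr$time >= 100 & tr$time <= dur - 100
  # charging integral: area between the asymptote and the transient
  tau <- sum((vinf - v[on]) * tr$dt) / (vinf - v0)
  list(rin = rin, cin = 1000 * tau / rin)
}

#' Calibrate the leak to a target somatic input resistance
#'
#' Scales the leak densities of all regions by a common factor until the
#' passive input resistance matches `target_rin`.
#'
#' @param model A `pc_model`.
#' @param target_rin Target, MOhm.
#' @return List with the scale factor, the resulting passive set, and the
#'   rebuilt model.
#' @export
pc_calibrate_leak <- function(model, target_rin = 14) {
  f <- function(s) {
    p <- model$passive
    p$gleak <- p$gleak * s
    mm <- pc_model(model$morphology, model$channels, p, model$celsius,
                   model$ca, model$d_lambda)
    impedance_from_soma(mm)$rin - target_rin
  }
  s <- uniroot(f, c(0.2, 5), tol = 1e-3)$root
  p <- model$passive
  p$gleak <- p$gleak * s
  list(scale = s, passive = p,
       model = pc_model(model$morphology, model$channels, p, model$celsius,
                        model$ca, model$d_lambda))
}
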