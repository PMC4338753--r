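# The standard Purkinje-cell experiments as named, scriptable protocols:
# spontaneous firing (with its control conditions), F/I by steps and ramps,
# complex bursting, bistability under channel down-regulation,
# hyperpolarising sag, the knockout battery, firing variants, dendritic
# injection, and the conductance robustness scan.

pc_condition <- function(label, stimuli = list(), edits = list(),
                         structural = NULL, duration = 2000,
                         record = "soma", record_ca = FALSE, settle = 500) {
  list(label = label, stimuli = stimuli, edits = edits,
       structural = structural, duration = duration, record = record,
       record_ca = record_ca, settle = settle)
}

new_protocol <- function(name, conditions, analyse) {
  structure(list(name = name, conditions = conditions, analyse = analyse),
            class = "pc_protocol")
}

#' @export
print.pc_protocol <- function(x, ...) {
  cat("Protocol:", x$name, "-", length(x$conditions), "condition(s):",
      paste(vapply(x$conditions, `[[`, "", "label"), collapse = ", "), "\n")
  invisible(x)
}

apply_edits <- function(model, edits, structural = NULL, trp = NULL) {
  if (!is.null(structural) && structural == "no_dendrites")
    model <- pc_model(pc_remove_dendrites(model$morphology), model$channels,
                      model$passive, model$celsius, model$ca, model$d_lambda)
  for (e in edits) model <- pc_edit(model, e$channel, e$region, e$scale)
  if (!is.null(trp)) model <- pc_add_trp(model, trp)
  model
}

#' Run a protocol on a model
#'
#' Each condition runs on an edited copy of the model (the model object
#' itself is never modified), and the protocol's analysis turns the traces
#' into metrics and a pass/fail verdict.
#'
#' @param protocol A `pc_protocol`.
#' @param model A `pc_model`.
#' @param dt Time step, ms.
#' @return A `pc_protocol_result`: list with `traces` per condition,
#'   `metrics` and `verdict`.
#' @export
run_protocol <- function(protocol, model, dt = 0.025) {
  traces <- list()
  for (cond in protocol$conditions) {
    mod <- apply_edits(model, cond$edits, cond$structural, cond$trp)
    traces[[cond$label]] <- pc_run(mod, cond$duration, dt = dt,
                                   stim = cond$stimuli, record = cond$record,
                                   settle = cond$settle,
                                   record_ca = cond$record_ca)
  }
  out <- protocol$analyse(traces, model)
  structure(list(name = protocol$name, traces = traces,
                 metrics = out$metrics, verdict = out$verdict),
            class = "pc_protocol_result")
}

#' @export
print.pc_protocol_result <- function(x, ...) {
  cat("Protocol result:", x$name, "\n")
  utils::str(x$metrics, give.attr = FALSE)
  cat("verdict:", if (isTRUE(x$verdict$pass)) "PASS" else "FAIL", "\n")
  invisible(x)
}

rate_of <- function(tr, site = "soma", from = 0) {
  train <- detect_spikes(tr$time, tr$v[, site])
  firing_rate(train, window = c(from, max(tr$time)),
              duration = max(tr$time) - from)
}

#' Spontaneous-firing protocol
#'
#' Pacemaking in the absence of current injection, plus its three control
#' conditions: AIS Nav1.6 knockout (must silence firing), dendrites removed
#' (rate and spike amplitude must increase), and dendritic Cav2.1 knockout
#' (must silence firing).  The maximum admissible spontaneous rate is
#' 75 Hz.
#'
#' @param duration Recorded duration per condition, ms.
#' @param skip Initial window excluded from rate measurements, ms.
#' @return A `pc_protocol`.
#' @export
protocol_spontaneous <- function(duration = 2500, skip = 500) {
  conds <- list(
    pc_condition("default", duration = duration,
                 record = c("soma", "AIS", "node3")),
    pc_condition("nav16_ais_ko", duration = duration,
                 edits = list(list(channel = "Nav1.6", region = "AIS",
                                   scale = 0))),
    pc_condition("no_dendrites", duration = duration,
                 structural = "no_dendrites"),
    pc_condition("cav21_dend_ko", duration = duration,
                 edits = list(list(channel = "Cav2.1", region = "dendrites",
                                   scale = 0)))
  )
  new_protocol("spontaneous", conds, function(traces, model) {
    r0 <- rate_of(traces$default, from = skip)
    rko <- rate_of(traces$nav16_ais_ko, from = skip)
    rnd <- rate_of(traces$no_dendrites, from = skip)
    rca <- rate_of(traces$cav21_dend_ko, from = skip)
    tr0 <- detect_spikes(traces$default$time, traces$default$v[, "soma"])
    trn <- detect_spikes(traces$no_dendrites$time,
                         traces$no_dendrites$v[, "soma"])
    amp0 <- if (nrow(tr0)) mean(tr0$peak) else NA
    ampn <- if (nrow(trn)) mean(trn$peak) else NA
    metrics <- list(rate = r0, rate_nav16_ais_ko = rko,
                    rate_no_dendrites = rnd, rate_cav21_dend_ko = rca,
                    peak = amp0, peak_no_dendrites = ampn)
    verdict <- list(
      fires = r0 > 0, below_75 = r0 <= 75,
      silenced_by_ais_nav_ko = rko == 0,
      silenced_by_dend_cav_ko = rca == 0,
      faster_without_dendrites = isTRUE(rnd > r0),
      larger_spikes_without_dendrites = isTRUE(ampn > amp0))
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

#' F/I protocol (steps or double ramp)
#'
#' Step mode: somatic current steps, steady rate measured over the last
#' `measure` ms of each step.  Ramp mode: a triangular 0 -> peak -> 0 nA
#' ramp; instantaneous rates are reported together with the up/down
#' asymmetry (hysteresis).
#'
#' @param mode `"step"` or `"ramp"`.
#' @param currents Step amplitudes, nA.
#' @param step_dur Step duration, ms.
#' @param measure Measurement window at the end of each step, ms.
#' @param peak Ramp peak, nA.
#' @param ramp_dur Total ramp duration, ms.
#' @param record Sites to record.
#' @return A `pc_protocol`.
#' @export
protocol_fi <- function(mode = c("step", "ramp"),
                        currents = seq(0, 1.6, by = 0.1), step_dur = 1000,
                        measure = 500, peak = 1.6, ramp_dur = 2000,
                        record = "soma") {
  mode <- match.arg(mode)
  if (mode == "step") {
    conds <- lapply(currents, function(a)
      pc_condition(sprintf("I_%.2f", a), duration = step_dur,
                   stimuli = if (a > 0) pc_stim_step("soma", a, 0, step_dur)
                             else list(),
                   record = record))
    return(new_protocol("fi_step", conds, function(traces, model) {
      rate <- vapply(traces, function(tr)
        rate_of(tr, from = step_dur - measure), 0)
      fit <- fi_curve(currents, unname(rate))
      metrics <- list(current = currents, rate = unname(rate),
                      slope = fit$slope, linear_max_rate = fit$linear_max_rate)
      verdict <- list(monotone_overall =
                        rate[length(rate)] > rate[1])
      verdict$pass <- all(unlist(verdict))
      list(metrics = metrics, verdict = verdict)
    }))
  }
  conds <- list(pc_condition("ramp", duration = ramp_dur + 500,
    stimuli = pc_stim_ramp("soma", c(0, ramp_dur / 2, ramp_dur),
                           c(0, peak, 0)),
    record = record))
  new_protocol("fi_ramp", conds, function(traces, model) {
    tr <- traces$ramp
    train <- detect_spikes(tr$time, tr$v[, "soma"])
    ir <- instantaneous_rate(train)
    up <- ir[ir$t <= ramp_dur / 2, ]
    dn <- ir[ir$t > ramp_dur / 2 & ir$t <= ramp_dur, ]
    cur_at <- function(t) peak * (1 - abs(t - ramp_dur / 2) / (ramp_dur / 2))
    metrics <- list(
      t = ir$t, rate = ir$rate, current = cur_at(ir$t),
      onset_rate = if (nrow(up)) up$rate[1] else NA,
      max_rate = if (nrow(ir)) max(ir$rate) else NA,
      end_rate = if (nrow(dn)) dn$rate[nrow(dn)] else NA)
    # hysteresis: mean rate on the way up vs down at mid-range currents
    mid <- function(d) d[cur_at(d$t) > 0.4 * peak & cur_at(d$t) < 0.9 * peak, ]
    hyst <- if (nrow(mid(up)) && nrow(mid(dn)))
      mean(mid(up)$rate) - mean(mid(dn)$rate) else NA
    metrics$hysteresis <- hyst
    verdict <- list(asymmetric = is.na(hyst) || abs(hyst) > 1)
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

#' Complex-bursting protocol
#'
#' A long suprathreshold somatic step; the response is segmented into
#' bursts and the burst metrics reported.  The canonical model switches
#' from tonic firing to repetitive bursting above about 2 nA.
#'
#' @param amplitude Step amplitude, nA.
#' @param duration Step duration, ms.
#' @return A `pc_protocol`.
#' @export
protocol_burst <- function(amplitude = 2.2, duration = 2500) {
  stopifnot(amplitude > 0)
  conds <- list(pc_condition("step", duration = duration,
    stimuli = pc_stim_step("soma", amplitude, 0, duration),
    record = c("soma", "terminal"), record_ca = TRUE))
  new_protocol("burst", conds, function(traces, model) {
    tr <- traces$step
    # short refractory so that intra-burst spikes are resolved
    train <- detect_spikes(tr$time, tr$v[, "soma"], refractory = 0.25)
    bm <- tryCatch(burst_metrics(train, duration = duration),
                   error = function(e) NULL)
    persists <- !is.null(bm) &&
      max(train$t) > duration - 3 * (duration / max(bm$n_bursts, 1))
    metrics <- list(rate = firing_rate(train, duration = duration),
                    bursting = !is.null(bm),
                    bursts_per_s = if (!is.null(bm)) bm$bursts_per_s else NA,
                    spikes_per_burst = if (!is.null(bm)) bm$spikes_per_burst
                                       else NA,
                    intra_burst_freq = if (!is.null(bm)) bm$intra_burst_freq
                                       else NA,
                    persists = persists)
    verdict <- list(bursting = !is.null(bm), persists = persists)
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

#' Classify a trace as tonic or bursting
#'
#' @param train Spike train.
#' @return `"silent"`, `"tonic"` or `"bursting"`.
#' @export
classify_firing <- function(train) {
  if (nrow(train) < 4) return("silent")
  isi <- diff(train$t)
  if (stats::sd(isi) / mean(isi) < 0.3) return("tonic")
  bm <- tryCatch(burst_metrics(train), error = function(e) NULL)
  if (!is.null(bm) && bm$n_bursts >= 2) "bursting" else "tonic"
}

#' Bistability protocol
#'
#' Applies a brief positive (0.2 nA, 200 ms) and later a brief negative
#' (-0.1 nA, 200 ms) somatic pulse to the intact model and to a
#' down-regulated model (AIS Nav1.6 or dendritic Cav2.1 removed).  The
#' down-regulated cell should be toggled persistently between an up-state
#' (firing outlasting the positive pulse) and a down-state (silence
#' outlasting the negative pulse), while the intact model must return to
#' its baseline after each pulse.
#'
#' @param which_ko `"AIS_Nav16"` or `"dend_Cav21"`.
#' @param persist Persistence window used for the verdicts, ms.
#' @return A `pc_protocol`.
#' @export
protocol_bistability <- function(which_ko = c("AIS_Nav16", "dend_Cav21"),
                                 persist = 1000) {
  which_ko <- match.arg(which_ko)
  ko <- if (which_ko == "AIS_Nav16")
    list(list(channel = "Nav1.6", region = "AIS", scale = 0))
  else
    list(list(channel = "Cav2.1", region = "dendrites", scale = 0))
  t_pos <- 500; t_neg <- 500 + 200 + persist + 300
  dur <- t_neg + 200 + persist + 200
  stim <- list(pc_stim_step("soma", 0.2, t_pos, t_pos + 200),
               pc_stim_step("soma", -0.1, t_neg, t_neg + 200))
  conds <- list(
    pc_condition("intact", stimuli = stim, duration = dur),
    pc_condition("ko", stimuli = stim, edits = ko, duration = dur))
  new_protocol(paste0("bistability_", which_ko), conds,
               function(traces, model) {
    win_rate <- function(tr, a, b) {
      train <- detect_spikes(tr$time, tr$v[, "soma"])
      firing_rate(train, window = c(a, b), duration = b - a)
    }
    seg <- function(tr) list(
      base = win_rate(tr, 0, t_pos),
      post_pos = win_rate(tr, t_pos + 250, t_pos + 200 + persist),
      post_neg = win_rate(tr, t_neg + 250, t_neg + 200 + persist))
    si <- seg(traces$intact); sk <- seg(traces$ko)
    metrics <- list(intact = si, ko = sk)
    verdict <- list(
      intact_returns_to_baseline =
        abs(si$post_pos - si$base) < pmax(0.3 * si$base, 5) &&
        abs(si$post_neg - si$base) < pmax(0.3 * si$base, 5),
      ko_silent_at_rest = sk$base == 0,
      ko_up_state = sk$post_pos > 0,
      ko_down_state = sk$post_neg == 0)
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

#' Hyperpolarising-step protocol (sag and rebound)
#'
#' A family of negative somatic steps; reports the sag (difference between
#' the early voltage trough and the late steady hyperpolarisation, driven
#' by the H current) and the presence of rebound spikes after stimulus
#' offset.
#'
#' @param amps Step amplitudes, nA (negative).
#' @param duration Step duration, ms.
#' @return A `pc_protocol`.
#' @export
protocol_hyperpolarization <- function(amps = c(-0.5, -1, -1.5),
                                       duration = 800) {
  conds <- lapply(seq_along(amps), function(i)
    pc_condition(sprintf("I_%.2f", amps[i]), duration = duration + 600,
      stimuli = if (amps[i] != 0)
        pc_stim_step("soma", amps[i], 100, 100 + duration) else list()))
  new_protocol("hyperpolarization", conds, function(traces, model) {
    per <- lapply(seq_along(amps), function(i) {
      tr <- traces[[i]]
      v <- tr$v[, "soma"]; t <- tr$time
      early <- v[t > 100 & t < 100 + duration / 2]
      late <- v[t > 100 + duration * 0.75 & t < 100 + duration]
      vmin <- min(early); vss <- mean(late)
      reb <- detect_spikes(t[t > 100 + duration], v[t > 100 + duration])
      list(amp = amps[i], v_trough = vmin, v_steady = vss,
           sag = vss - vmin, rebound_spikes = nrow(reb))
    })
    sags <- vapply(per, `[[`, 0, "sag")
    metrics <- list(per_step = per, max_sag = max(sags))
    verdict <- list(sag_present = max(sags) > 0,
                    rebound = any(vapply(per, `[[`, 0,
                                         "rebound_spikes") > 0))
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

# expected qualitative outcomes of the knockout battery
KO_BATTERY <- list(
  list(label = "Nav1.6", edits = list(list(channel = "Nav1.6",
       region = "all", scale = 0)), expect_spont = "silent",
       expect_burst = "silent"),
  list(label = "Cav2.1", edits = list(list(channel = "Cav2.1",
       region = "all", scale = 0)), expect_spont = "silent",
       expect_burst = "no_burst"),
  list(label = "KCa1.1", edits = list(list(channel = "KCa1.1",
       region = "all", scale = 0)), expect_spont = "faster",
       expect_burst = "no_burst"),
  list(label = "KCa2.2", edits = list(list(channel = "KCa2.2",
       region = "all", scale = 0)), expect_spont = "faster",
       expect_burst = "burst"),
  list(label = "Kv1.1+Kv1.5", edits = list(
       list(channel = "Kv1.1", region = "all", scale = 0),
       list(channel = "Kv1.5", region = "all", scale = 0)),
       expect_spont = "faster_or_equal", expect_burst = "any"),
  list(label = "HCN1", edits = list(list(channel = "HCN1",
       region = "all", scale = 0)), expect_spont = "unchanged",
       expect_burst = "any")
)

#' Knockout battery
#'
#' One protocol per channel knockout; each runs a spontaneous and a 2 nA
#' step condition and compares the outcome with the expected qualitative
#' verdict (silencing, faster firing, burst abolition or preservation).
#'
#' @param battery Subset of knockouts by label; default all six.
#' @param duration Per-condition duration, ms.
#' @param burst_amp Step amplitude for the evoked condition, nA.
#' @return List of `pc_protocol` objects.
#' @export
protocol_ko <- function(battery = NULL, duration = 2500, burst_amp = 2) {
  rows <- KO_BATTERY
  if (!is.null(battery))
    rows <- Filter(function(r) r$label %in% battery, rows)
  lapply(rows, function(row) {
    conds <- list(
      pc_condition("control_spont", duration = duration),
      pc_condition("control_step", duration = duration,
        stimuli = pc_stim_step("soma", burst_amp, 0, duration)),
      pc_condition("ko_spont", duration = duration, edits = row$edits),
      pc_condition("ko_step", duration = duration, edits = row$edits,
        stimuli = pc_stim_step("soma", burst_amp, 0, duration)))
    new_protocol(paste0("ko_", row$label), conds, function(traces, model) {
      tr_of <- function(lbl) detect_spikes(traces[[lbl]]$time,
                                           traces[[lbl]]$v[, "soma"])
      r_ctrl <- firing_rate(tr_of("control_spont"), duration = duration)
      r_ko <- firing_rate(tr_of("ko_spont"), duration = duration)
      cl_ctrl <- classify_firing(tr_of("control_step"))
      cl_ko <- classify_firing(tr_of("ko_step"))
      # tr_of uses the default refractory; bursting classification needs
      # intra-burst resolution
      cl_ctrl <- classify_firing(detect_spikes(
        traces$control_step$time, traces$control_step$v[, "soma"],
        refractory = 0.25))
      cl_ko <- classify_firing(detect_spikes(
        traces$ko_step$time, traces$ko_step$v[, "soma"],
        refractory = 0.25))
      spont_ok <- switch(row$expect_spont,
        silent = r_ko == 0,
        faster = r_ko > r_ctrl,
        faster_or_equal = r_ko >= 0.95 * r_ctrl,
        unchanged = abs(r_ko - r_ctrl) < pmax(0.25 * r_ctrl, 3))
      burst_ok <- switch(row$expect_burst,
        silent = cl_ko == "silent",
        no_burst = cl_ko != "bursting",
        burst = cl_ko == "bursting" || cl_ctrl != "bursting",
        any = TRUE)
      metrics <- list(label = row$label, rate_control = r_ctrl,
                      rate_ko = r_ko, step_class_control = cl_ctrl,
                      step_class_ko = cl_ko)
      verdict <- list(spont_as_expected = spont_ok,
                      burst_as_expected = burst_ok,
                      pass = isTRUE(spont_ok) && isTRUE(burst_ok))
      list(metrics = metrics, verdict = verdict)
    })
  })
}

#' Purkinje-cell firing variants
#'
#' The Z- variant adds a dendritic TRP leak (0 mV reversal) to raise the
#' basal rate; the CF-PC variant scales Cav2.1 to 60 percent everywhere;
#' the P-PC variant combines HCN1 x0.5, Kv3.4 x1.08 and Kv4.3 x0.5.
#'
#' @param kind `"Zminus"`, `"CF_PC"` or `"P_PC"`.
#' @param duration Spontaneous duration, ms.
#' @param trp_gmax Dendritic TRP density for the Z- variant, S/cm2.
#' @return A `pc_protocol`.
#' @export
protocol_variants <- function(kind = c("Zminus", "CF_PC", "P_PC"),
                              duration = 2500, trp_gmax = 6e-5) {
  kind <- match.arg(kind)
  edits <- switch(kind,
    Zminus = list(),
    CF_PC = list(list(channel = "Cav2.1", region = "all", scale = 0.6)),
    P_PC = list(list(channel = "HCN1", region = "all", scale = 0.5),
                list(channel = "Kv3.4", region = "all", scale = 1.08),
                list(channel = "Kv4.3", region = "all", scale = 0.5)))
  conds <- list(
    pc_condition("control", duration = duration),
    pc_condition("variant", duration = duration, edits = edits))
  p <- new_protocol(paste0("variant_", kind), conds,
                    function(traces, model) {
    r0 <- rate_of(traces$control, from = 500)
    r1 <- rate_of(traces$variant, from = 500)
    metrics <- list(rate_control = r0, rate_variant = r1)
    verdict <- switch(kind,
      Zminus = list(faster = r1 > r0),
      CF_PC = list(fires = r1 >= 0),
      P_PC = list(fires = r1 >= 0))
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
  if (kind == "Zminus") p$conditions[[2]]$trp <- trp_gmax
  p
}

#' Dendritic current injection (synaptic-like burst-pause responses)
#'
#' A brief strong pulse into a tagged dendritic site: 3 nA for 10 ms in the
#' most distal terminal dendrite (parallel-fibre-like) or 3 nA for 30 ms in
#' the trunk (climbing-fibre-like).  Reports the burst and pause structure
#' around the pulse.
#'
#' @param site `"terminal"` or `"trunk"`.
#' @param amp Pulse amplitude, nA.
#' @param duration Recorded duration, ms.
#' @return A `pc_protocol`.
#' @export
protocol_dendritic_injection <- function(site = c("terminal", "trunk"),
                                         amp = 3, duration = 1500) {
  site <- match.arg(site)
  width <- if (site == "terminal") 10 else 30
  onset <- 700
  conds <- list(pc_condition("pulse", duration = duration,
    stimuli = if (amp != 0) pc_stim_step(site, amp, onset, onset + width)
              else list(),
    record = c("soma", site)))
  new_protocol(paste0("dend_inject_", site), conds,
               function(traces, model) {
    tr <- traces$pulse
    train <- detect_spikes(tr$time, tr$v[, "soma"])
    base_isi <- {
      pre <- train$t[train$t < onset]
      if (length(pre) > 2) mean(diff(pre)) else NA
    }
    burst_n <- sum(train$t >= onset & train$t <= onset + width + 30)
    post <- train$t[train$t > onset + width + 30]
    pause <- if (length(post)) post[1] - (onset + width) else NA
    metrics <- list(baseline_isi = base_isi, burst_spikes = burst_n,
                    pause = pause)
    verdict <- list(
      burst = amp == 0 || burst_n >= 2,
      pause = amp == 0 || (is.finite(pause) && is.finite(base_isi) &&
                           pause > base_isi))
    verdict$pass <- all(unlist(verdict))
    list(metrics = metrics, verdict = verdict)
  })
}

#' Robustness scan over a channel's maximal conductance
#'
#' Scales one channel's density over a multiplicative grid and checks, at
#' each scale, whether the model keeps its canonical features: spontaneous
#' rate in (0, 95) Hz, and (optionally) preserved bursting under a 2.2 nA
#' step and a step-F/I rate within 20 Hz of the canonical one.  The
#' channel is classified from the widest contiguous passing interval
#' around scale 1: critical (margin < 15 percent), subcritical (15--30),
#' non-critical (> 50).
#'
#' @param model Canonical model.
#' @param channel Channel name.
#' @param scales Multiplicative grid (must bracket 1).
#' @param features Subset of `c("spont", "burst", "fi")`.
#' @param duration Per-run duration, ms.
#' @param fi_current Current used for the F/I feature, nA.
#' @return A `pc_robustness` list: per-scale results, margins and class.
#' @export
robustness_scan <- function(model, channel,
                            scales = c(0.5, 0.7, 0.85, 0.9, 0.95, 1,
                                       1.05, 1.1, 1.15, 1.3, 1.5),
                            features = c("spont", "burst"),
                            duration = 2000, fi_current = 1) {
  stopifnot(1 %in% scales, min(scales) <= 0.5 || max(scales) >= 1.5)
  ref_rate <- NULL
  res <- lapply(scales, function(s) {
    mod <- pc_edit(model, channel, "all", s)
    out <- list(scale = s)
    tr <- pc_run(mod, duration, record = "soma", settle = 500)
    train <- detect_spikes(tr$time, tr$v[, 1])
    out$rate <- firing_rate(train, duration = duration)
    out$spont_ok <- out$rate > 0 && out$rate < 95
    if ("burst" %in% features) {
      trb <- pc_run(mod, duration,
                    stim = pc_stim_step("soma", 2.2, 0, duration),
                    record = "soma", settle = 500)
      cl <- classify_firing(detect_spikes(trb$time, trb$v[, 1],
                                          refractory = 0.25))
      out$burst_ok <- cl == "bursting"
    } else out$burst_ok <- TRUE
    if ("fi" %in% features) {
      trf <- pc_run(mod, duration,
                    stim = pc_stim_step("soma", fi_current, 0, duration),
                    record = "soma", settle = 500)
      out$fi_rate <- firing_rate(detect_spikes(trf$time, trf$v[, 1]),
                                 duration = duration)
    }
    out
  })
  if ("fi" %in% features) {
    ref_rate <- res[[which(scales == 1)]]$fi_rate
    for (i in seq_along(res))
      res[[i]]$fi_ok <- abs(res[[i]]$fi_rate - ref_rate) <= 20
  } else for (i in seq_along(res)) res[[i]]$fi_ok <- TRUE
  ok <- vapply(res, function(r) r$spont_ok && r$burst_ok && r$fi_ok, TRUE)
  i1 <- which(scales == 1)
  lo <- i1; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i1; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  lower_margin <- 1 - scales[lo]
  upper_margin <- scales[hi] - 1
  margin <- min(lower_margin, upper_margin)
  class <- if (margin < 0.15) "critical"
           else if (margin < 0.30) "subcritical"
           else if (margin > 0.50 ||
                    (lower_margin >= 0.5 && upper_margin >= 0.5))
             "non_critical"
           else "intermediate"
  structure(list(channel = channel, scales = scales, results = res,
                 ok = ok, lower_margin = lower_margin,
                 upper_margin = upper_margin, class = class),
            class = "pc_robustness")
}

#' @export
print.pc_robustness <- function(x, ...) {
  cat(sprintf("Robustness of %s: -%d%% / +%d%% -> %s\n", x$channel,
              round(100 * x$lower_margin), round(100 * x$upper_margin),
              x$class))
  invisible(x)
}

#' Z- variant model (dendritic TRP leak)
#'
#' @param model Canonical model.
#' @param trp_gmax TRP density, S/cm2 (default calibrated so the basal rate
#'   rises well above the canonical one).
#' @return Edited model.
#' @export
pc_variant_zminus <- function(model, trp_gmax = 6e-5) {
  pc_add_trp(model, trp_gmax)
}
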