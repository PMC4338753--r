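# Spike-train and burst analysis: detection, spike shape, transmission
# reliability, conduction velocity, F/I summaries.

#' Detect spikes in a voltage trace
#'
#' A spike is the local maximum following an upward threshold crossing;
#' at most one spike is kept per refractory window.
#'
#' @param time Sample times, ms (uniform).
#' @param v Voltage trace, mV.
#' @param threshold Crossing threshold, mV (default -20 for full somatic /
#'   axonal spikes).
#' @param refractory Minimum separation between spikes, ms.
#' @return A `pc_spike_train`: data frame with `t` (peak time, ms) and
#'   `peak` (peak voltage, mV).
#' @export
detect_spikes <- function(time, v, threshold = -20, refractory = 1) {
  if (inherits(time, "pc_traces")) stop("pass time and voltage vectors")
  up <- which(diff(v > threshold) == 1)
  ts <- numeric(0); pk <- numeric(0)
  n <- length(v)
  for (i in up) {
    # local maximum after the crossing (end of the supra-threshold lobe)
    j <- i
    while (j < n && v[j + 1] >= threshold) j <- j + 1
    seg <- i:j
    k <- seg[which.max(v[seg])]
    if (length(ts) > 0 && time[k] - ts[length(ts)] < refractory) {
      if (v[k] > pk[length(pk)]) { ts[length(ts)] <- time[k]; pk[length(pk)] <- v[k] }
      next
    }
    ts <- c(ts, time[k]); pk <- c(pk, v[k])
  }
  structure(data.frame(t = ts, peak = pk), class = c("pc_spike_train",
                                                     "data.frame"))
}

#' Mean firing rate of a spike train
#'
#' @param train A `pc_spike_train`.
#' @param window Optional c(start, end) in ms; defaults to the full span.
#' @param duration Recording duration used as denominator (ms); defaults to
#'   the window length.
#' @return Rate in Hz.
#' @export
firing_rate <- function(train, window = NULL, duration = NULL) {
  t <- train$t
  if (!is.null(window)) t <- t[t >= window[1] & t <= window[2]]
  if (is.null(duration)) {
    duration <- if (!is.null(window)) diff(window) else diff(range(train$t))
  }
  if (duration <= 0) return(0)
  1000 * length(t) / duration
}

#' Instantaneous firing rate (reciprocal inter-spike interval)
#'
#' @param train A `pc_spike_train`.
#' @return Data frame with `t` (time of the second spike of each interval)
#'   and `rate` (Hz).
#' @export
instantaneous_rate <- function(train) {
  if (nrow(train) < 2) return(data.frame(t = numeric(0), rate = numeric(0)))
  data.frame(t = train$t[-1], rate = 1000 / diff(train$t))
}

#' Spike shape metrics
#'
#' Per-spike afterhyperpolarisation (AHP) trough (minimum voltage in the
#' following inter-spike interval), AHP-to-peak amplitude, and half width
#' measured at half of the AHP-to-peak amplitude.
#'
#' @param time,v Trace.
#' @param train Detected spikes ([detect_spikes()]).
#' @return List with vectors `half_width` (ms), `ahp` (mV), `amplitude`
#'   (AHP-to-peak, mV), `peak` (mV) and their means (`mean_half_width`,
#'   `mean_ahp`, `mean_amplitude`).
#' @export
spike_shape <- function(time, v, train) {
  ns <- nrow(train)
  if (ns < 1) stop("no spikes in the train")
  idx <- vapply(train$t, function(tt) which.min(abs(time - tt)), 1L)
  hw <- ahp <- amp <- rep(NA_real_, ns)
  for (k in seq_len(ns)) {
    i0 <- idx[k]
    i1 <- if (k < ns) idx[k + 1] else length(v)
    if (i1 <= i0 + 2) next
    tr_min <- min(v[i0:i1])
    ahp[k] <- tr_min
    amp[k] <- v[i0] - tr_min
    half <- tr_min + amp[k] / 2
    # width of the last upward-to-downward excursion through `half`
    li <- i0
    while (li > 1 && v[li - 1] >= half) li <- li - 1
    ri <- i0
    while (ri < length(v) && v[ri + 1] >= half) ri <- ri + 1
    # sub-sample interpolation at both flanks
    tl <- if (li > 1)
      stats::approx(v[c(li - 1, li)], time[c(li - 1, li)], xout = half)$y
      else time[li]
    tr2 <- if (ri < length(v))
      stats::approx(v[c(ri + 1, ri)], time[c(ri + 1, ri)], xout = half)$y
      else time[ri]
    hw[k] <- tr2 - tl
  }
  ok <- stats::complete.cases(hw, ahp, amp)
  list(half_width = hw, ahp = ahp, amplitude = amp, peak = train$peak,
       mean_half_width = mean(hw[ok]), mean_ahp = mean(ahp[ok]),
       mean_amplitude = mean(amp[ok]))
}

#' Spike-transmission reliability between two sites
#'
#' Fraction of reference spikes matched by a spike at the second site
#' within a time window (greedy nearest-neighbour matching; each target
#' spike is used at most once).
#'
#' @param train_ref Reference train (e.g. AIS).
#' @param train_target Target train (e.g. 3rd node of Ranvier).
#' @param window Matching half-window, ms.
#' @return Fraction in \[0, 1\].
#' @export
transmission_reliability <- function(train_ref, train_target, window = 1) {
  if (nrow(train_ref) == 0) return(NA_real_)
  used <- rep(FALSE, nrow(train_target))
  hit <- 0
  for (tt in train_ref$t) {
    d <- abs(train_target$t - tt)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= window) {
      hit <- hit + 1
      used[j] <- TRUE
    }
  }
  hit / nrow(train_ref)
}

#' Conduction velocity between two recording sites
#'
#' Median per-spike peak-time delay over a known path length.
#'
#' @param train_a,train_b Trains at the proximal and distal site.
#' @param path_length Path length between the sites, um.
#' @param window Matching half-window for pairing spikes, ms.
#' @param min_spikes Minimum number of propagated spikes required.
#' @return Velocity in m/s.
#' @export
conduction_velocity <- function(train_a, train_b, path_length, window = 2,
                                min_spikes = 5) {
  delays <- c()
  used <- rep(FALSE, nrow(train_b))
  for (tt in train_a$t) {
    d <- train_b$t - tt
    d[used | d < 0] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && is.finite(d[j]) && d[j] <= window) {
      delays <- c(delays, d[j])
      used[j] <- TRUE
    }
  }
  if (length(delays) < min_spikes)
    stop("too few propagated spikes for a velocity estimate")
  md <- stats::median(delays)
  if (md <= 0) stop("non-positive conduction delay")
  (path_length / 1000) / md # um/ms = mm/s; /1000 -> m/s
}

#' Axonal path length from the AIS midpoint to the 3rd-node midpoint
#'
#' @return Path length in um (8.5 + 4 + 100 + 4 + 100 + 4 + 100 + 2).
#' @export
axon_path_length <- function() {
  17 / 2 + 4 + 100 + 4 + 100 + 4 + 100 + 4 / 2
}

#' Burst metrics from a spike train
#'
#' Bursts are segmented at inter-spike intervals exceeding `gap_factor`
#' times the intra-burst median interval (found iteratively from the
#' shortest intervals).
#'
#' @param train Spike train.
#' @param gap_factor Boundary criterion (default 3).
#' @param duration Recording span used for the bursts-per-second rate, ms.
#' @return List: `n_bursts`, `bursts_per_s`, `spikes_per_burst` (mean),
#'   `intra_burst_freq` (Hz, mean reciprocal intra-burst interval),
#'   `boundaries` (list of spike-time vectors per burst).
#' @export
burst_metrics <- function(train, gap_factor = 3, duration = NULL) {
  if (nrow(train) < 4) stop("no-burst: too few spikes")
  isi <- diff(train$t)
  intra <- stats::median(isi[isi <= stats::quantile(isi, 0.5)])
  breaks <- which(isi > gap_factor * intra)
  if (length(breaks) < 1) stop("no-burst: no interval gaps found")
  starts <- c(1, breaks + 1)
  ends <- c(breaks, nrow(train))
  keep <- ends - starts >= 1 # at least two spikes per burst
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) < 2) stop("no-burst: fewer than two bursts")
  if (is.null(duration)) duration <- diff(range(train$t)) + mean(diff(train$t))
  bursts <- Map(function(s, e) train$t[s:e], starts, ends)
  intra_isi <- unlist(lapply(bursts, function(b) diff(b)))
  list(n_bursts = length(bursts),
       bursts_per_s = 1000 * length(bursts) / duration,
       spikes_per_burst = mean(ends - starts + 1),
       intra_burst_freq = mean(1000 / intra_isi),
       boundaries = bursts)
}

#' F/I curve summary
#'
#' Least-squares line over the quasi-linear range and the rate at which the
#' curve departs from linearity.
#'
#' @param current Injected currents, nA.
#' @param rate Steady firing rates, Hz.
#' @param tol Relative residual tolerance defining the linear range.
#' @return List: `slope` (Hz/nA), `intercept`, `linear_max_rate` (top of the
#'   quasi-linear range, Hz), `fit` residuals.
#' @export
fi_curve <- function(current, rate, tol = 0.15) {
  stopifnot(length(current) == length(rate), length(current) >= 5)
  ord <- order(current)
  current <- current[ord]; rate <- rate[ord]
  # grow the linear range from the low-current end
  kmax <- length(current)
  k <- 5
  while (k <= kmax) {
    fit <- lm(rate[1:k] ~ current[1:k])
    res <- abs(stats::residuals(fit))
    span <- max(rate[1:k]) - min(rate[1:k])
    if (span > 0 && max(res) > tol * max(span, 1)) break
    k <- k + 1
  }
  k <- min(k, kmax)
  fit <- lm(rate[1:k] ~ current[1:k])
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       linear_max_rate = max(rate[1:k]),
       linear_range = current[c(1, k)],
       residuals = unname(stats::residuals(fit)))
}
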