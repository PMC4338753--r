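# Shared fixtures: tiny analytic models and a session cache for the
# expensive canonical-model runs reused across acceptance tests.

acc_cache <- new.env(parent = emptyenv())

canonical_model <- function() {
  if (is.null(acc_cache$model)) acc_cache$model <- pc_model()
  acc_cache$model
}

# 2 s spontaneous run of the canonical model, soma + AIS + node3 at full
# resolution (shared by the pacemaking, spike-shape and axon tests)
canonical_spont <- function() {
  if (is.null(acc_cache$spont))
    acc_cache$spont <- pc_run(canonical_model(), 2000,
                              record = c("soma", "AIS", "node3"),
                              settle = 500)
  acc_cache$spont
}

# single-compartment morphology (soma only)
soma_only_morph <- function(diam = 29.8, len = 29.8) {
  structure(data.frame(id = 1L, parent = 0L, tag = "soma",
                       diam = diam, length = len),
            class = c("pc_morphology", "data.frame"))
}

# unbranched passive cable hanging off a negligible root
cable_morph <- function(d = 2, L_total = 500, nsec = 10) {
  root <- data.frame(id = 1L, parent = 0L, tag = "soma",
                     diam = d, length = 1e-3)
  secs <- data.frame(id = 1L + seq_len(nsec), parent = seq_len(nsec),
                     tag = "terminal_dendrite", diam = d,
                     length = L_total / nsec)
  structure(rbind(root, secs), class = c("pc_morphology", "data.frame"))
}

# channel table with a subset of channels on the soma
soma_channels <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(channel = r[[1]], region = "soma",
               gmax = as.numeric(r[[2]]))))
}

empty_channels <- function() {
  tab <- pc_channelome()
  tab$gmax <- 0
  tab
}

# independent oracle for the stationary occupancy of a Markov scheme:
# closed-form propagation p(t) = expm(t Q^T) p0, with the matrix
# exponential computed by scaling-and-squaring of a Taylor series
integrate_master <- function(Q, p0, t_end, dt = NULL) {
  A <- t(Q) * t_end
  s <- max(0L, ceiling(log2(max(1, norm(A, "1")))))
  B <- A / 2^s
  E <- diag(nrow(A))
  term <- E
  for (k in 1:30) {
    term <- term %*% B / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  as.vector(E %*% p0)
}

# synthetic triangular spike train generator
triangle_train <- function(n = 10, period = 20, base = -60, peak = 20,
                           width = 1, dt = 0.025, total = NULL) {
  if (is.null(total)) total <- n * period + 10
  t <- seq(0, total, by = dt)
  v <- rep(base, length(t))
  for (k in seq_len(n)) {
    t0 <- k * period
    tri <- pmax(0, 1 - abs(t - t0) / (width / 2))
    v <- pmax(v, base + (peak - base) * tri)
  }
  list(time = t, v = v)
}

# consolidated criterion assertion: one expectation per criterion listing
# any failed sub-checks by name
expect_criterion <- function(checks) {
  failed <- names(checks)[!vapply(checks, isTRUE, TRUE)]
  expect_identical(failed, character(0))
}
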