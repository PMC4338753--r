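# Configuration files, trace export, and reproducibility manifests.

#' Load a model configuration file
#'
#' YAML configuration with optional blocks `morphology` (n_dendrites, seed,
#' target_area), `passive` (ra, eleak, cm, gleak), `calcium` (depth,
#' max_shells, pump_rate, pump_kd, substeps, permeation), `simulation`
#' (dt, celsius) and `channels` (list of `{channel, region, gmax}`
#' overrides; region may be `dendrites` or `all`).  An empty file yields
#' the canonical model.  Unknown keys are rejected.
#'
#' @param path Config file path (YAML); `NULL` gives the defaults.
#' @return List with `morphology`, `channels`, `passive`, `ca`,
#'   `sim` (dt, celsius) ready for [pc_model()].
#' @export
pc_load_config <- function(path = NULL) {
  cfg <- if (is.null(path) || !nzchar(path)) list()
         else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("morphology", "passive", "calcium", "simulation", "channels")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))

  mo <- cfg$morphology
  check_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) stop("unknown key(s) in ", where, ": ",
                          paste(bad, collapse = ", "))
  }
  check_keys(mo, c("n_dendrites", "seed", "target_area"), "morphology")
  morph <- pc_morphology(
    n_dendrites = mo$n_dendrites %||% 400,
    seed = mo$seed %||% 1,
    target_area = mo$target_area %||% 70000)

  pv <- cfg$passive
  check_keys(pv, c("ra", "eleak", "cm", "gleak"), "passive")
  passive <- pc_passive()
  for (k in intersect(names(pv), c("ra", "eleak"))) passive[[k]] <- pv[[k]]
  for (k in names(pv$cm)) passive$cm[[k]] <- pv$cm[[k]]
  for (k in names(pv$gleak)) passive$gleak[[k]] <- pv$gleak[[k]]

  cc <- cfg$calcium
  check_keys(cc, c("depth", "max_shells", "pump_rate", "pump_kd",
                   "substeps", "permeation"), "calcium")
  ca <- do.call(pc_calcium_params, cc %||% list())

  sm <- cfg$simulation
  check_keys(sm, c("dt", "celsius"), "simulation")
  sim <- list(dt = sm$dt %||% 0.025, celsius = sm$celsius %||% 37)

  channels <- pc_channelome()
  for (ov in cfg$channels) {
    check_keys(ov, c("channel", "region", "gmax", "scale"), "channels")
    if (is.null(ov$channel) || is.null(ov$region))
      stop("channel override needs 'channel' and 'region'")
    regions <- if (identical(ov$region, "dendrites")) DEND_TAGS
               else if (identical(ov$region, "all")) unique(channels$region)
               else ov$region
    hit <- channels$channel == ov$channel & channels$region %in% regions
    if (!is.null(ov$gmax)) {
      if (ov$gmax < 0) stop("gmax must be non-negative")
      channels$gmax[hit] <- ov$gmax
    }
    if (!is.null(ov$scale)) {
      if (ov$scale < 0) stop("scale must be non-negative")
      channels$gmax[hit] <- channels$gmax[hit] * ov$scale
    }
  }

  list(morphology = morph, channels = channels, passive = passive, ca = ca,
       sim = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a model from a configuration
#'
#' @param config Output of [pc_load_config()] (or a path to a config file).
#' @return A `pc_model`.
#' @export
pc_model_from_config <- function(config = NULL) {
  if (is.character(config) || is.null(config))
    config <- pc_load_config(config)
  pc_model(config$morphology, config$channels, config$passive,
           celsius = config$sim$celsius, ca = config$ca)
}

#' Write recorded traces to CSV
#'
#' One `time` column (ms) plus one column per recorded site (and
#' `ca_<site>` columns when calcium was recorded).
#'
#' @param traces A `pc_traces`.
#' @param path Output file.
#' @param decimate Keep every n-th sample (default 4, i.e. 0.1 ms at the
#'   default time step).
#' @export
pc_write_traces <- function(traces, path, decimate = 4L) {
  d <- as.data.frame(traces)
  d <- d[seq(1, nrow(d), by = decimate), , drop = FALSE]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest for reproducibility
#'
#' Captures the configuration, the channel table digest, the morphology
#' seed and aggregates, and versions, sufficient to re-execute a run.
#'
#' @param model A `pc_model`.
#' @param extra Named list merged into the manifest.
#' @return Manifest list (serialise with `jsonlite::write_json`).
#' @export
pc_manifest <- function(model, extra = list()) {
  tab <- model$channels
  digest <- sum(as.integer(charToRaw(paste(tab$channel, tab$region,
                                           signif(tab$gmax, 10),
                                           collapse = ";")))) +
            round(1e6 * sum(tab$gmax))
  c(list(
    package = "purkinje",
    version = as.character(utils::packageVersion("purkinje")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    morphology = list(
      n_sections = nrow(model$morphology),
      seed = attr(model$morphology, "seed"),
      target_area = attr(model$morphology, "target_area"),
      total_area = total_area(model$morphology)),
    n_compartments = nrow(model$comp),
    celsius = model$celsius,
    passive = model$passive,
    calcium = model$ca[c("depth", "max_shells", "pump_rate", "pump_kd",
                         "substeps", "permeation")],
    channel_table_checksum = digest),
    extra)
}

#' Write protocol metrics as JSON
#'
#' @param result A `pc_protocol_result` (or list of them).
#' @param path Output file.
#' @export
pc_write_metrics <- function(result, path) {
  strip <- function(r) list(name = r$name, metrics = r$metrics,
                            verdict = r$verdict)
  out <- if (inherits(result, "pc_protocol_result")) strip(result)
         else lapply(result, strip)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
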