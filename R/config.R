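# Declarative configuration: loading, validation, manifests, spike-table IO.

#' Load and validate a model configuration
#'
#' Reads the YAML configuration (the package default when \code{path} is
#' NULL), validates its structure and cross-references, and returns the
#' configuration tree.
#'
#' @param path path to a YAML configuration, or NULL for the shipped default.
#' @return validated configuration list (class \code{bla_config}).
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_config.yaml", package = "blanet")
  if (!file.exists(path)) stopf("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  class(cfg) <- c("bla_config", "list")
  cfg
}

#' Default model configuration
#' @export
default_config <- function() load_config(NULL)

#' Validate a configuration tree
#'
#' Checks required sections, population counts, connection-rule consistency
#' (uni + bi == overall within table rounding) and cell/channel
#' cross-references; raises a descriptive error naming the offending path.
#' @param cfg configuration list.
#' @return invisibly TRUE.
#' @export
validate_config <- function(cfg) {
  need <- c("populations", "geometry", "reversals", "calcium", "cells",
            "receptors", "stp", "connections", "weights",
            "synapse_conductance", "afferents", "background", "lfp",
            "simulation", "experiments")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stopf("config missing section(s): %s", paste(miss, collapse = ", "))
  for (p in c("PN_A", "PN_C", "PV", "CR", "SOM")) {
    if (is.null(cfg$populations[[p]]$count))
      stopf("config missing populations.%s.count", p)
  }
  known <- names(channel_registry())
  for (ct in names(cfg$cells)) {
    cell <- cfg$cells[[ct]]
    cn <- vapply(cell$compartments, function(cp) cp$name, "")
    for (cp in cell$compartments) {
      for (f in c("diam", "L", "cm", "Ra", "gL", "EL"))
        if (is.null(cp[[f]])) stopf("config missing cells.%s.compartments.%s.%s", ct, cp$name, f)
      if (cp$diam <= 0 || cp$L <= 0 || cp$cm <= 0 || cp$Ra <= 0 || cp$gL < 0)
        stopf("non-positive geometry/passive value in cells.%s.%s", ct, cp$name)
      if (!is.null(cp$parent) && !cp$parent %in% cn)
        stopf("cells.%s.%s.parent '%s' is not a compartment", ct, cp$name, cp$parent)
    }
    for (comp in names(cell$channels)) {
      if (!comp %in% cn) stopf("cells.%s.channels names unknown compartment '%s'", ct, comp)
      bad <- setdiff(names(cell$channels[[comp]]), known)
      if (length(bad)) stopf("cells.%s.channels.%s references unknown channel '%s'", ct, comp, bad[1])
    }
  }
  for (i in seq_along(cfg$connections)) {
    rule <- cfg$connections[[i]]
    if (abs((rule$uni + rule$bi) - rule$overall) > 0.05)
      stopf("connections[%d] (%s->%s): uni + bi != overall", i, rule$src, rule$dst)
    if (rule$overall < 0 || rule$overall > 100)
      stopf("connections[%d]: probability outside [0,100]", i)
    if (!is.null(rule$stp) && !rule$stp %in% names(cfg$stp))
      stopf("connections[%d] references unknown stp rule '%s'", i, rule$stp)
  }
  if (cfg$simulation$discard_ms >= cfg$simulation$duration_ms)
    stopf("simulation.discard_ms must be < duration_ms")
  if (cfg$lfp$sample_interval_ms < cfg$simulation$dt_ms)
    stopf("lfp.sample_interval_ms must be >= simulation.dt_ms")
  invisible(TRUE)
}

#' Write a configuration back to YAML (lossless round-trip)
#' @param cfg configuration list; @param path output file.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Run manifest
#'
#' A JSON-serialisable record of everything that determined a run: the full
#' parameter echo, seed, case/ablation id, scale, and package version.
#' @export
run_manifest <- function(cfg, seed, case = NULL, ablate = "none", scale = 1,
                         extra = list()) {
  c(list(
    package = "blanet",
    version = as.character(utils::packageVersion("blanet")),
    seed = seed, case = case, ablate = ablate, scale = scale,
    config = unclass(cfg)
  ), extra)
}

#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write / read a spike table (CSV: time_ms, cell_id, cell_type)
#' @export
write_spike_table <- function(spikes, path) {
  stopifnot(all(c("time_ms", "cell_id", "cell_type") %in% names(spikes)))
  write.csv(spikes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_table
#' @export
read_spike_table <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a simulation run directory
#'
#' Persists a \code{bla_sim} result as plain-text artifacts: spike table
#' (CSV), LFP trace (CSV: time_ms, value), and a JSON manifest echoing the
#' full configuration; \code{read_run} round-trips them.
#'
#' @param sim a \code{bla_sim} result; @param dir output directory.
#' @param manifest a \code{\link{run_manifest}} (optional).
#' @export
write_run <- function(sim, dir, manifest = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spike_table(sim$spikes, file.path(dir, "spikes.csv"))
  if (!is.null(sim$lfp)) {
    lfp <- data.frame(time_ms = seq_along(sim$lfp) * sim$lfp_dt_ms,
                      value = sim$lfp)
    write.csv(lfp, file.path(dir, "lfp.csv"), row.names = FALSE)
  }
  if (!is.null(manifest)) write_manifest(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_run
#' @export
read_run <- function(dir) {
  out <- list(spikes = read_spike_table(file.path(dir, "spikes.csv")))
  lf <- file.path(dir, "lfp.csv")
  if (file.exists(lf)) {
    d <- read.csv(lf)
    out$lfp <- d$value
    out$lfp_dt_ms <- if (nrow(d) > 1) d$time_ms[2] - d$time_ms[1] else NA_real_
  }
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) out$manifest <- jsonlite::read_json(mf)
  out
}
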