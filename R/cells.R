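# The five cell types as multicompartment models: geometry, passive
# constants, channel densities, soma-rooted coupling trees, and the
# electrophysiological measurement protocols used to validate them.

#' Build a cell model
#'
#' Constructs the multicompartment model of one cell type from the
#' configuration: cylindrical compartments (area = pi * diam * L, no end
#' caps), absolute capacitances and conductances, coupling conductances from
#' the standard two-half-segment series formula, and channel instances.
#'
#' @param type one of "PN_A", "PN_C", "PV", "SOM", "CR".
#' @param config a configuration from \code{\link{load_config}}.
#' @return a \code{cell_model} list with elements \code{type}, \code{comps}
#'   (data frame of per-compartment geometry and passive properties) and
#'   \code{channels} (data frame of channel instances).
#' @export
build_cell <- function(type, config = default_config()) {
  spec <- config$cells[[type]]
  if (is.null(spec)) stopf("unknown cell type '%s'", type)
  comps <- do.call(rbind, lapply(spec$compartments, function(cp) {
    cp$parent <- cp$parent %||% NA_character_
    as.data.frame(cp, stringsAsFactors = FALSE)
  }))
  comps$parent_idx <- match(comps$parent, comps$name)   # NA for the root
  if (sum(is.na(comps$parent_idx)) != 1 || !is.na(comps$parent_idx[1]))
    stopf("cell '%s': compartments must form a tree rooted at the first (soma) entry", type)
  if (any(!is.na(comps$parent_idx) & comps$parent_idx >= seq_len(nrow(comps))))
    stopf("cell '%s': parents must precede children", type)
  # areas (cm2) and absolute passive properties (nF, uS)
  comps$area_cm2 <- pi * (comps$diam * 1e-4) * (comps$L * 1e-4)
  comps$C_nF <- comps$cm * comps$area_cm2 * 1e3        # uF/cm2 * cm2 -> nF
  comps$gL_uS <- comps$gL * comps$area_cm2 * 1e6       # S/cm2 -> uS
  # coupling to parent: series of the two half-cylinder axial resistances
  gc <- rep(NA_real_, nrow(comps))
  for (i in seq_len(nrow(comps))) {
    p <- comps$parent_idx[i]
    if (is.na(p)) next
    rr <- function(j) {
      r_cm <- comps$diam[j] / 2 * 1e-4
      comps$Ra[j] * (comps$L[j] / 2 * 1e-4) / (pi * r_cm^2)   # Ohm
    }
    gc[i] <- 1 / (rr(i) + rr(p)) * 1e6                        # uS
  }
  comps$gc_uS <- gc
  # channel instances
  reg <- channel_registry(config$nat_rates, isTRUE(config$calcium$sahp_square))
  ch <- list()
  for (comp in names(spec$channels)) {
    ci <- match(comp, comps$name)
    for (nm in names(spec$channels[[comp]])) {
      gbar <- spec$channels[[comp]][[nm]]
      if (is.null(gbar) || gbar <= 0) next
      def <- reg[[nm]]
      ch[[length(ch) + 1]] <- data.frame(
        comp_idx = ci, channel = nm, gbar = gbar,
        gbar_uS = gbar * comps$area_cm2[ci] * 1e6,
        p = def$p, q = def$q, erev = def$erev,
        ca_gated = isTRUE(def$ca_gated),
        ca_gain = if (isTRUE(def$ca_source))
          config$calcium$influx_per_nA[[nm]] %||% 0 else 0)
    }
  }
  structure(list(type = type, comps = comps,
                 channels = do.call(rbind, ch),
                 targets = spec$targets, config = config),
            class = "cell_model")
}

#' Passive signature of an isolated cell
#'
#' Simulates the standard current-step protocol on the isolated cell: relax
#' to rest, then apply a small somatic step (default -10 pA for 500 ms).
#' Returns the resting potential, the input resistance
#' R_IN = dV_ss / dI, and the membrane time constant (time to 63.2% of the
#' steady-state deflection).
#'
#' @param cell a \code{\link{build_cell}} model.
#' @param step_nA step amplitude, nA (default -0.01 = -10 pA).
#' @param step_ms step duration, ms.
#' @param settle_ms pre-step relaxation, ms.
#' @param dt_ms integration step, ms.
#' @return list with \code{v_rest} (mV), \code{r_in} (MOhm), \code{tau_m} (ms).
#' @export
measure_passive <- function(cell, step_nA = -0.01, step_ms = 500,
                            settle_ms = 2000, dt_ms = 0.1) {
  res <- single_cell_sim(cell, amp_nA = step_nA,
                         t_on = settle_ms, t_off = settle_ms + step_ms,
                         duration_ms = settle_ms + step_ms, dt_ms = dt_ms,
                         record_v = TRUE)
  if (length(res$spike_times) > 0 && any(res$spike_times < settle_ms))
    stopf("cell '%s' spikes spontaneously at rest; passive measurement invalid", cell$type)
  v <- res$v[1, ]
  t <- res$t
  i_rest <- max(which(t <= settle_ms))
  v_rest <- v[i_rest]
  v_ss <- v[length(v)]
  dv <- v_ss - v_rest
  r_in <- dv / step_nA                # mV/nA = MOhm
  v63 <- v_rest + 0.632 * dv
  after <- which(t > settle_ms)
  hit <- if (dv < 0) which(v[after] <= v63) else which(v[after] >= v63)
  tau_m <- if (length(hit)) t[after[hit[1]]] - settle_ms else NA_real_
  list(v_rest = v_rest, r_in = r_in, tau_m = tau_m)
}

#' Somatic current-step response
#'
#' Injects a continuous somatic current step and returns somatic spike times
#' (upward 0 mV crossings, 2 ms detection refractory).
#'
#' @param cell a cell model.
#' @param amplitude_nA step amplitude, nA (> 0 for a depolarising step).
#' @param duration_ms step duration, ms.
#' @param settle_ms pre-step relaxation, ms.
#' @return spike times relative to step onset, ms.
#' @export
current_step_response <- function(cell, amplitude_nA, duration_ms = 1000,
                                  settle_ms = 1000, dt_ms = 0.1) {
  stopifnot(duration_ms > 0)
  res <- single_cell_sim(cell, amp_nA = amplitude_nA, t_on = settle_ms,
                         t_off = settle_ms + duration_ms,
                         duration_ms = settle_ms + duration_ms, dt_ms = dt_ms)
  st <- res$spike_times
  st[st >= settle_ms] - settle_ms
}

#' Calibrate leak parameters to a passive target
#'
#' Solves for the leak conductance density and leak reversal of a cell type
#' such that the simulated step protocol reproduces a target input
#' resistance, with the resting potential as a soft secondary target.  Used
#' once to produce the shipped interneuron leak defaults.
#'
#' @param type cell type; @param config configuration.
#' @param r_in_target MOhm; @param v_rest_target mV (soft).
#' @return list(gL, EL, achieved = list(v_rest, r_in, tau_m)).
#' @export
calibrate_passive <- function(type, config = default_config(),
                              r_in_target = NULL, v_rest_target = NULL) {
  tg <- config$cells[[type]]$targets
  r_in_target <- r_in_target %||% tg$r_in
  v_rest_target <- v_rest_target %||% tg$v_rest
  obj <- function(par) {
    cfg <- config
    for (i in seq_along(cfg$cells[[type]]$compartments)) {
      cfg$cells[[type]]$compartments[[i]]$gL <- exp(par[1])
      cfg$cells[[type]]$compartments[[i]]$EL <- par[2]
    }
    ps <- tryCatch(measure_passive(build_cell(type, cfg)),
                   error = function(e) NULL)
    if (is.null(ps) || !is.finite(ps$r_in)) return(1e6)
    ((ps$r_in - r_in_target) / r_in_target)^2 * 400 +
      ((ps$v_rest - v_rest_target) / 20)^2
  }
  start <- c(log(config$cells[[type]]$compartments[[1]]$gL),
             config$cells[[type]]$compartments[[1]]$EL)
  fit <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-6))
  cfg <- config
  for (i in seq_along(cfg$cells[[type]]$compartments)) {
    cfg$cells[[type]]$compartments[[i]]$gL <- exp(fit$par[1])
    cfg$cells[[type]]$compartments[[i]]$EL <- fit$par[2]
  }
  list(gL = exp(fit$par[1]), EL = fit$par[2],
       achieved = measure_passive(build_cell(type, cfg)))
}
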