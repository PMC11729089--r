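# Fixed-step network simulation: flattens cells, synapses and inputs into
# the arrays consumed by the C++ core, runs the integration, and wraps the
# result.

# gate-table bundle in the matrix layout the core expects
core_gate_tables <- function(config) {
  reg <- channel_registry(config$nat_rates, isTRUE(config$calcium$sahp_square))
  gt <- build_gate_tables(reg)
  ncolmax <- max(vapply(gt$tables, function(t) length(t$inf), 0L))
  pad <- function(x) c(x, rep(x[length(x)], ncolmax - length(x)))
  inf <- do.call(rbind, lapply(gt$tables, function(t) pad(t$inf)))
  tau <- do.call(rbind, lapply(gt$tables, function(t) pad(t$tau)))
  list(inf = inf, tau = tau,
       is_ca = vapply(gt$tables, function(t) as.integer(t$ca), 0L),
       v0 = gt$v0, dv = gt$dv, lc0 = gt$lc0, dlc = gt$dlc,
       ids = gt$ids, registry = reg)
}

# flatten a list of cell models (one per cell instance, or per-type templates
# replicated) into compartment/channel arrays
flatten_cells <- function(types, config, tabs) {
  tmpl <- lapply(unique(types), function(ty) build_cell(ty, config))
  names(tmpl) <- unique(types)
  rev <- config$reversals
  comp_list <- list(); chan_list <- list()
  offset <- 0L
  soma <- integer(length(types))
  for (ci in seq_along(types)) {
    m <- tmpl[[types[ci]]]
    nc <- nrow(m$comps)
    comp_list[[ci]] <- data.frame(
      cell = ci - 1L,
      C = m$comps$C_nF, gL = m$comps$gL_uS, EL = m$comps$EL,
      parent = ifelse(is.na(m$comps$parent_idx), -1L,
                      m$comps$parent_idx - 1L + offset),
      gc = ifelse(is.na(m$comps$gc_uS), 0, m$comps$gc_uS))
    ch <- m$channels
    chan_list[[ci]] <- if (is.null(ch) || nrow(ch) == 0) {
      data.frame(comp = integer(0), g = numeric(0), E = numeric(0),
                 p = integer(0), q = integer(0), mtab = integer(0),
                 htab = integer(0), cagate = integer(0), cagain = numeric(0))
    } else data.frame(
      comp = ch$comp_idx - 1L + offset,
      g = ch$gbar_uS,
      E = vapply(ch$erev, function(e) rev[[e]], 0),
      p = ch$p, q = ch$q,
      mtab = vapply(ch$channel, function(n) tabs$ids[[paste0(n, ".m")]], 0L),
      htab = vapply(ch$channel, function(n)
        tabs$ids[[paste0(n, ".h")]] %||% -1L, 0L),
      cagate = as.integer(ch$ca_gated),
      cagain = ch$ca_gain)
    soma[ci] <- offset            # 0-based soma index
    offset <- offset + nc
  }
  comp <- do.call(rbind, comp_list)
  chan <- do.call(rbind, chan_list)
  list(comp = comp, chan = chan, soma = soma, templates = tmpl)
}

empty_syn <- function() {
  data.frame(comp = integer(0), g = numeric(0), E = numeric(0),
             aT = numeric(0), beta = numeric(0), onsteps = integer(0),
             mg = integer(0), stp = integer(0), f = numeric(0),
             tauF = numeric(0), d1 = numeric(0), taud1 = numeric(0),
             d2 = numeric(0), taud2 = numeric(0), pre = integer(0),
             delay = integer(0))
}

# synapse rows for one batch of edges (vectorised); pre = -1 for afferents
syn_rows <- function(post_comp, weight, receptor, stp_name, b_ACh, pre,
                     delay_steps, config, ach) {
  rec <- config$receptors[[receptor]]
  gmax <- config$synapse_conductance[[receptor]]
  st <- if (identical(stp_name, "none") || is.null(stp_name)) NULL
        else config$stp[[stp_name]]
  kind <- if (is.null(st)) 0L else if (st$d1 < 1 || st$d2 < 1) 1L else 2L
  af <- 1 + b_ACh * (ach - 1)
  n <- length(post_comp)
  data.frame(
    comp = post_comp, g = weight * gmax * af, E = rec$E,
    aT = rec$alphaTmax, beta = rec$beta,
    onsteps = as.integer(round(rec$on_dur / config$simulation$dt_ms)),
    mg = as.integer(receptor == "NMDA"),
    stp = rep(kind, n),
    f = if (is.null(st)) 1 else st$f, tauF = if (is.null(st)) 1e9 else st$tau_F,
    d1 = if (is.null(st)) 1 else st$d1, taud1 = if (is.null(st)) 1e9 else st$tau_D1,
    d2 = if (is.null(st)) 1 else st$d2, taud2 = if (is.null(st)) 1e9 else st$tau_D2,
    pre = pre, delay = pmax(1L, delay_steps))
}

# postsynaptic compartment (0-based global index) for a connection:
# perisomatic for PV+ and VP/SI GABAergic inputs, first dendrite otherwise
target_comp_offset <- function(perisomatic, post_ncomp) {
  ifelse(perisomatic | post_ncomp < 2, 0L, 1L)
}

#' Run a network simulation
#'
#' Integrates the network with the fixed-step core: Hodgkin-Huxley
#' compartments, delayed synaptic event delivery, OU background, optional
#' LFP accumulation.  Bitwise reproducible for a fixed (network, inputs,
#' seed) triple.
#'
#' @param network a \code{\link{build_network}} object.
#' @param inputs afferent spike trains from \code{\link{make_case_inputs}}.
#' @param ach cholinergic tone level (0, 1 or 2).
#' @param duration_ms,dt_ms simulation length and step.
#' @param seed integer seed for the background-noise stream.
#' @param background_multiplier scalar on the excitatory background drive of
#'   principal neurons (the renormalisation knob).
#' @param ablate "none", "PV", "SOM" or "CR": zero the efferent synaptic
#'   weights of that interneuron group (cells remain present and driven).
#' @param record_v cell ids whose somatic voltage to record at dt.
#' @param lfp logical: accumulate the line-source LFP.
#' @param record_currents logical: also record per-compartment transmembrane
#'   currents averaged over each LFP sample interval.
#' @param ou logical: include the OU background (disable for silent-network
#'   checks).
#' @return a \code{bla_sim} result: spike table, LFP trace, voltage traces.
#' @export
run_simulation <- function(network, inputs, ach = 1, duration_ms = NULL,
                           dt_ms = NULL, seed = 1,
                           background_multiplier = 1, ablate = "none",
                           record_v = integer(0), lfp = TRUE,
                           record_currents = FALSE, ou = TRUE) {
  config <- network$config
  dt <- dt_ms %||% config$simulation$dt_ms
  duration <- duration_ms %||% config$simulation$duration_ms
  n_steps <- as.integer(round(duration / dt))
  tabs <- core_gate_tables(config)
  fc <- flatten_cells(network$cells$type, config, tabs)
  ncomp_by_cell <- as.integer(table(factor(fc$comp$cell, levels = 0:(nrow(network$cells) - 1))))

  # --- synapses (per connection class, so STP rule and ACh sensitivity are
  # class-level; excitatory edges expand to an AMPA and an NMDA synapse) ----
  syn <- list()
  ed <- network$edges
  if (!is.null(ed) && nrow(ed) > 0) {
    if (ablate != "none") {
      src_grp <- wire_group(network$cells$type[ed$pre])
      ed$weight[src_grp == ablate] <- 0
    }
    # down-scaled networks have proportionally fewer intrinsic inputs per
    # cell; compensate the per-synapse strength so the mean synaptic drive
    # per cell matches the full-size network
    ed$weight <- ed$weight / (network$scale %||% 1)
    peri <- startsWith(ed$class, "PV->")
    pc <- fc$soma[ed$post] + target_comp_offset(peri, ncomp_by_cell[ed$post])
    dsteps <- as.integer(round(ed$delay_ms / dt))
    for (k in unique(ed$class)) {
      sel <- which(ed$class == k)
      rcp <- ed$receptor[sel[1]]
      stp_name <- ed$stp[sel[1]]
      b <- ed$b_ACh[sel[1]]
      recs <- if (rcp == "exc") c("AMPA", "NMDA") else "GABA_A"
      for (r in recs)
        syn[[length(syn) + 1]] <- syn_rows(pc[sel], ed$weight[sel], r,
                                           stp_name, b, ed$pre[sel] - 1L,
                                           dsteps[sel], config, ach)
    }
  }
  # VP/SI afferent synapses (event-driven, pre = -1)
  vp <- network$afferents$vpsi
  vp_syn_index <- NULL
  if (!is.null(vp) && nrow(vp) > 0) {
    pc <- fc$soma[vp$post]              # perisomatic
    n_before <- sum(vapply(syn, nrow, 0L))
    syn[[length(syn) + 1]] <- syn_rows(pc, vp$weight, "GABA_A", NULL,
                                       0, rep(-1L, nrow(vp)),
                                       rep(1L, nrow(vp)), config, 1)
    # per-target ACh sensitivity
    i <- length(syn)
    af <- 1 + vp$b_ACh * (ach - 1)
    syn[[i]]$g <- syn[[i]]$g * af
    vp_syn_index <- n_before + seq_len(nrow(vp)) - 1L   # 0-based
  }
  # thalamic synapses
  th <- network$afferents$thalamic
  th_syn_index <- NULL
  if (!is.null(th) && nrow(th) > 0) {
    pc <- fc$soma[th$post] + target_comp_offset(FALSE, ncomp_by_cell[th$post])
    idx0 <- sum(vapply(syn, nrow, 0L))
    for (r in c("AMPA", "NMDA")) {
      syn[[length(syn) + 1]] <- syn_rows(pc, th$weight, r,
                                         NULL, config$afferents$thalamic$b_ACh,
                                         rep(-1L, nrow(th)),
                                         rep(1L, nrow(th)), config, ach)
    }
    th_syn_index <- list(ampa = idx0 + seq_len(nrow(th)) - 1L,
                         nmda = idx0 + nrow(th) + seq_len(nrow(th)) - 1L)
  }
  syn <- if (length(syn)) do.call(rbind, syn) else empty_syn()

  # --- afferent events -----------------------------------------------------
  ev_step <- integer(0); ev_syn <- integer(0)
  if (!is.null(inputs)) {
    if (!is.null(inputs$vpsi) && !is.null(vp_syn_index)) {
      for (i in seq_along(inputs$vpsi)) {
        tt <- inputs$vpsi[[i]]
        tt <- tt[tt >= 0 & tt < duration]
        if (!length(tt)) next
        rows <- which(vp$afferent == i)
        if (!length(rows)) next
        st <- as.integer(round(tt / dt))
        ev_step <- c(ev_step, rep(st, times = length(rows)))
        ev_syn <- c(ev_syn, rep(vp_syn_index[rows], each = length(st)))
      }
    }
    if (!is.null(inputs$thalamic) && !is.null(th_syn_index)) {
      for (i in seq_along(inputs$thalamic)) {
        tt <- inputs$thalamic[[i]]
        tt <- tt[tt >= 0 & tt < duration]
        if (!length(tt)) next
        st <- as.integer(round(tt / dt))
        ev_step <- c(ev_step, st, st)
        ev_syn <- c(ev_syn, rep(th_syn_index$ampa[i], length(st)),
                    rep(th_syn_index$nmda[i], length(st)))
      }
    }
    o <- order(ev_step)
    ev_step <- ev_step[o]; ev_syn <- ev_syn[o]
  }

  # --- OU background -------------------------------------------------------
  bg <- config$background
  af_bg <- 1 + bg$b_ACh * (ach - 1)
  types <- network$cells$type
  par_of <- function(field) vapply(types, function(ty) bg$by_type[[ty]][[field]], 0)
  is_pn <- types %in% c("PN_A", "PN_C")
  mult <- ifelse(is_pn, background_multiplier, 1)
  ge_mean <- par_of("ge_mean") * af_bg * mult
  ge_sd <- par_of("ge_sd") * af_bg * mult
  gi_mean <- par_of("gi_mean") * af_bg
  gi_sd <- par_of("gi_sd") * af_bg
  if (!ou) { ge_mean[] <- 0; ge_sd[] <- 0; gi_mean[] <- 0; gi_sd[] <- 0 }

  # --- LFP coefficients ----------------------------------------------------
  clfp <- rep(0, nrow(fc$comp))
  lfp_bin <- 0L
  if (lfp || record_currents) {
    clfp <- lfp_coefficients(network, fc, config)
    lfp_bin <- as.integer(round(config$lfp$sample_interval_ms / dt))
  }

  # --- initial voltages ----------------------------------------------------
  v0 <- rep(NA_real_, nrow(fc$comp))
  for (ty in unique(types)) {
    tg <- fc$templates[[ty]]$targets
    tv <- tg$v_init %||% tg$v_rest %||% -70
    sel <- fc$comp$cell %in% (which(types == ty) - 1L)
    v0[sel] <- tv
  }

  net <- list(
    comp_cell = fc$comp$cell, comp_C = fc$comp$C, comp_gL = fc$comp$gL,
    comp_EL = fc$comp$EL, comp_parent = as.integer(fc$comp$parent),
    comp_gc = fc$comp$gc, comp_v0 = v0, comp_clfp = clfp,
    cell_soma = as.integer(fc$soma),
    ch_comp = as.integer(fc$chan$comp), ch_g = fc$chan$g, ch_E = fc$chan$E,
    ch_p = as.integer(fc$chan$p), ch_q = as.integer(fc$chan$q),
    ch_mtab = as.integer(fc$chan$mtab), ch_htab = as.integer(fc$chan$htab),
    ch_cagate = as.integer(fc$chan$cagate), ch_cagain = fc$chan$cagain,
    gate_tables = tabs[c("inf", "tau", "is_ca", "v0", "dv", "lc0", "dlc")],
    ca_rest = config$calcium$ca_rest, ca_floor = config$calcium$ca_floor,
    tau_ca = config$calcium$tau_ca_ms,
    sy_comp = as.integer(syn$comp), sy_g = syn$g, sy_E = syn$E,
    sy_aT = syn$aT, sy_beta = syn$beta, sy_onsteps = as.integer(syn$onsteps),
    sy_mg = as.integer(syn$mg), sy_stp = as.integer(syn$stp),
    sy_f = syn$f, sy_tauF = syn$tauF, sy_d1 = syn$d1, sy_taud1 = syn$taud1,
    sy_d2 = syn$d2, sy_taud2 = syn$taud2,
    sy_pre = as.integer(syn$pre), sy_delay = as.integer(syn$delay),
    ev_step = as.integer(ev_step), ev_syn = as.integer(ev_syn),
    ou_ge_mean = ge_mean, ou_ge_sd = ge_sd,
    ou_gi_mean = gi_mean, ou_gi_sd = gi_sd,
    ou_taue = bg$tau_e_ms, ou_taui = bg$tau_i_ms,
    ou_Ee = bg$E_e, ou_Ei = bg$E_i,
    inj_comp = integer(0), inj_amp = numeric(0),
    inj_on = integer(0), inj_off = integer(0))

  opts <- list(dt = dt, n_steps = n_steps,
               seed = sub_seed(seed, "ou-noise"),
               record_v = as.integer(fc$soma[record_v]),
               lfp_bin_steps = lfp_bin,
               record_currents = record_currents,
               spike_threshold = config$simulation$spike_threshold_mV,
               refractory_steps = as.integer(round(
                 config$simulation$spike_refractory_ms / dt)))

  res <- sim_core(net, opts)
  spikes <- data.frame(time_ms = res$spike_time,
                       cell_id = res$spike_cell,
                       cell_type = types[res$spike_cell],
                       stringsAsFactors = FALSE)
  out <- list(spikes = spikes,
              lfp = if (lfp_bin > 0) res$lfp else NULL,
              lfp_dt_ms = if (lfp_bin > 0) lfp_bin * dt else NULL,
              v = res$v, v_cells = record_v, v_dt_ms = dt,
              i_binned = if (record_currents) res$i_binned else NULL,
              comp_cell = fc$comp$cell,
              duration_ms = duration, dt_ms = dt, seed = seed,
              ach = ach, ablate = ablate,
              background_multiplier = background_multiplier,
              n_cells = nrow(network$cells), types = types)
  class(out) <- "bla_sim"
  out
}

#' Mean firing rates by cell type
#'
#' @param result a \code{bla_sim} result (or a spike data frame).
#' @param discard_ms transient to drop from the start, ms.
#' @param duration_ms total simulated time, ms (taken from the result when
#'   available).
#' @param types full per-cell type vector (for cells that never spiked).
#' @return data frame (type, mean_hz, sd_hz, n_cells).
#' @export
firing_rates <- function(result, discard_ms = 0, duration_ms = NULL,
                         types = NULL) {
  if (inherits(result, "bla_sim")) {
    spikes <- result$spikes; duration_ms <- duration_ms %||% result$duration_ms
    types <- types %||% result$types
  } else spikes <- result
  window <- duration_ms - discard_ms
  if (is.null(window) || window <= 0) stopf("empty analysis window")
  sp <- spikes[spikes$time_ms > discard_ms, ]
  counts <- rep(0L, length(types))
  tb <- table(sp$cell_id)
  counts[as.integer(names(tb))] <- as.integer(tb)
  rate <- counts / (window / 1000)
  out <- do.call(rbind, lapply(unique(types), function(ty) {
    r <- rate[types == ty]
    data.frame(type = ty, mean_hz = mean(r), sd_hz = stats::sd(r),
               n_cells = length(r))
  }))
  out
}

# single-cell simulation through the same core (no synapses, no OU)
single_cell_sim <- function(cell, amp_nA = 0, t_on = 0, t_off = 0,
                            duration_ms = 1000, dt_ms = 0.1,
                            record_v = TRUE, v_init = NULL) {
  config <- cell$config
  tabs <- core_gate_tables(config)
  fc <- flatten_cells(cell$type, config, tabs)
  n_steps <- as.integer(round(duration_ms / dt_ms))
  v0 <- rep(v_init %||% cell$targets$v_init %||% cell$targets$v_rest %||% -70,
            nrow(fc$comp))
  syn <- empty_syn()
  net <- list(
    comp_cell = fc$comp$cell, comp_C = fc$comp$C, comp_gL = fc$comp$gL,
    comp_EL = fc$comp$EL, comp_parent = as.integer(fc$comp$parent),
    comp_gc = fc$comp$gc, comp_v0 = v0, comp_clfp = rep(0, nrow(fc$comp)),
    cell_soma = as.integer(fc$soma),
    ch_comp = as.integer(fc$chan$comp), ch_g = fc$chan$g, ch_E = fc$chan$E,
    ch_p = as.integer(fc$chan$p), ch_q = as.integer(fc$chan$q),
    ch_mtab = as.integer(fc$chan$mtab), ch_htab = as.integer(fc$chan$htab),
    ch_cagate = as.integer(fc$chan$cagate), ch_cagain = fc$chan$cagain,
    gate_tables = tabs[c("inf", "tau", "is_ca", "v0", "dv", "lc0", "dlc")],
    ca_rest = config$calcium$ca_rest, ca_floor = config$calcium$ca_floor,
    tau_ca = config$calcium$tau_ca_ms,
    sy_comp = as.integer(syn$comp), sy_g = syn$g, sy_E = syn$E,
    sy_aT = syn$aT, sy_beta = syn$beta, sy_onsteps = as.integer(syn$onsteps),
    sy_mg = as.integer(syn$mg), sy_stp = as.integer(syn$stp),
    sy_f = syn$f, sy_tauF = syn$tauF, sy_d1 = syn$d1, sy_taud1 = syn$taud1,
    sy_d2 = syn$d2, sy_taud2 = syn$taud2,
    sy_pre = as.integer(syn$pre), sy_delay = as.integer(syn$delay),
    ev_step = integer(0), ev_syn = integer(0),
    ou_ge_mean = 0, ou_ge_sd = 0, ou_gi_mean = 0, ou_gi_sd = 0,
    ou_taue = 2.7, ou_taui = 10.5, ou_Ee = 0, ou_Ei = -75,
    inj_comp = 0L, inj_amp = amp_nA,
    inj_on = as.integer(round(t_on / dt_ms)),
    inj_off = as.integer(round(t_off / dt_ms)))
  opts <- list(dt = dt_ms, n_steps = n_steps, seed = 1,
               record_v = if (record_v) 0L else integer(0),
               lfp_bin_steps = 0L, record_currents = FALSE,
               spike_threshold = config$simulation$spike_threshold_mV,
               refractory_steps = as.integer(round(
                 config$simulation$spike_refractory_ms / dt_ms)))
  res <- sim_core(net, opts)
  list(spike_times = res$spike_time, v = res$v,
       t = seq_len(n_steps) * dt_ms)
}
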