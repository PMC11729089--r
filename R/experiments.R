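# The in-silico experiment suite: six cases crossing VP/SI input rhythmicity
# with cholinergic tone, the multi-seed protocol, background-drive
# renormalisation, and the interneuron-ablation study.

#' Experimental case definition
#'
#' Cases 1-6 map rhythmicity x cholinergic tone:
#' 1 (baseline, ACh 1), 2 (theta, 1), 3 (theta, 2), 4 (theta, 0),
#' 5 (baseline, 2), 6 (baseline, 0).
#'
#' @param id case id, 1..6.
#' @return list(id, vp_si = "baseline"|"theta", ach).
#' @export
case_spec <- function(id) {
  map <- list(
    `1` = list(vp_si = "baseline", ach = 1),
    `2` = list(vp_si = "theta", ach = 1),
    `3` = list(vp_si = "theta", ach = 2),
    `4` = list(vp_si = "theta", ach = 0),
    `5` = list(vp_si = "baseline", ach = 2),
    `6` = list(vp_si = "baseline", ach = 0))
  s <- map[[as.character(id)]]
  if (is.null(s)) stopf("case id must be in 1..6")
  c(list(id = id), s)
}

#' Generate the afferent spike trains for a case
#'
#' VP/SI afferents: in the rhythmic ("theta") regime every afferent emits one
#' event per 8 Hz cycle with independent Gaussian jitter per event; in the
#' baseline regime each afferent is an independent 2 Hz Poisson train.
#' Thalamic/cortical sources are always independent Poisson trains; the
#' renormalisation multiplier scales the rate of sources targeting principal
#' neurons.
#'
#' @param network a \code{bla_network}; @param case_id case id 1..6.
#' @param duration_ms train length; @param seed master seed.
#' @param thalamic_multiplier scalar on PN-targeting thalamic rates.
#' @return list(vpsi = list of spike-time vectors, thalamic = list of
#'   spike-time vectors, regime).
#' @export
make_case_inputs <- function(network, case_id, duration_ms, seed = 1,
                             thalamic_multiplier = 1) {
  config <- network$config
  cs <- case_spec(case_id)
  av <- config$afferents$vpsi
  n_aff <- network$afferents$n_vpsi
  vpsi <- vector("list", n_aff)
  if (cs$vp_si == "theta") {
    period <- 1000 / av$theta$f
    n_ev <- ceiling(duration_ms / period) + 3
    for (i in seq_len(n_aff)) {
      tt <- jittered_rhythmic_times(period, av$jitter_sigma_ms, n_ev,
                                    seed = sub_seed(seed, paste0("vpsi-", i)))
      vpsi[[i]] <- tt[tt >= 0 & tt < duration_ms]
    }
  } else {
    for (i in seq_len(n_aff))
      vpsi[[i]] <- poisson_train(av$rate_hz, duration_ms,
                                 seed = sub_seed(seed, paste0("vpsi-", i)))
  }
  th <- network$afferents$thalamic
  is_pn <- network$cells$type[th$post] %in% c("PN_A", "PN_C")
  thal <- vector("list", nrow(th))
  for (k in seq_len(nrow(th))) {
    rate <- config$afferents$thalamic$rate_hz *
      (if (is_pn[k]) thalamic_multiplier else 1)
    thal[[k]] <- poisson_train(rate, duration_ms,
                               seed = sub_seed(seed, paste0("thal-", k)))
  }
  list(vpsi = vpsi, thalamic = thal, regime = cs$vp_si, ach = cs$ach)
}

# run one seed of one case and analyse it
run_case_seed <- function(case_id, seed, config, scale, duration_ms,
                          discard_ms, background_multiplier, ablate = "none",
                          network = NULL) {
  cs <- case_spec(case_id)
  net <- network %||% build_network(config, seed, scale)
  inputs <- make_case_inputs(net, case_id, duration_ms, seed,
                             thalamic_multiplier = background_multiplier)
  sim <- run_simulation(net, inputs, ach = cs$ach,
                        duration_ms = duration_ms, seed = seed,
                        background_multiplier = background_multiplier,
                        ablate = ablate, lfp = TRUE)
  analyze_run(sim, config, discard_ms)
}

#' Analyse a simulation: retained-window LFP spectrum and firing rates
#'
#' @param sim a \code{bla_sim}; @param config configuration.
#' @param discard_ms initial transient to drop.
#' @return list(psd, peak_theta, prominence, rates, lfp, sim meta).
#' @export
analyze_run <- function(sim, config, discard_ms = NULL) {
  discard_ms <- discard_ms %||% config$simulation$discard_ms
  fs <- 1000 / sim$lfp_dt_ms
  keep <- seq_along(sim$lfp) * sim$lfp_dt_ms > discard_ms
  x <- sim$lfp[keep]
  win <- min(2, (length(x) / fs) / 2)
  psd <- welch_psd(x, fs, window_sec = win)
  tb <- unlist(config$experiments$theta_band_hz)
  fb <- unlist(config$experiments$floor_band_hz)
  pk <- peak_power(psd, tb)
  rates <- firing_rates(sim, discard_ms = discard_ms)
  list(psd = psd, peak_theta = pk,
       prominence = theta_prominence(psd, tb, fb),
       rates = rates, discard_ms = discard_ms,
       retained_ms = sim$duration_ms - discard_ms)
}

#' Renormalise the principal-neuron background drive
#'
#' Bisection on a scalar multiplier of the PN excitatory background (OU
#' conductance and thalamic rate) until the PN_A mean rate is within
#' tolerance of its target (0.45 Hz); checks PN_C against its 0.6 Hz target.
#'
#' @param config configuration; @param scale network scale.
#' @param case_id case under which to renormalise.
#' @param seed seed used for the search runs.
#' @param ablate ablated group ("none" for the intact network).
#' @param duration_ms,discard_ms length of each search run.
#' @param tol relative tolerance; @param max_iter bisection budget.
#' @return list(multiplier, rates, iterations).
#' @export
renormalize_background <- function(config, scale = 1, case_id = 1, seed = 1,
                                   ablate = "none", duration_ms = 5000,
                                   discard_ms = 2000, tol = NULL,
                                   max_iter = NULL) {
  tol <- tol %||% config$experiments$renorm_tolerance
  max_iter <- max_iter %||% config$experiments$renorm_max_iter
  target <- config$experiments$baseline_rates_hz$PN_A
  cs <- case_spec(case_id)
  net <- build_network(config, seed, scale)
  rate_at <- function(m) {
    inputs <- make_case_inputs(net, case_id, duration_ms, seed,
                               thalamic_multiplier = m)
    sim <- run_simulation(net, inputs, ach = cs$ach,
                          duration_ms = duration_ms, seed = seed,
                          background_multiplier = m, ablate = ablate,
                          lfp = FALSE)
    r <- firing_rates(sim, discard_ms = discard_ms)
    list(pn_a = r$mean_hz[r$type == "PN_A"], rates = r)
  }
  lo <- NA; hi <- NA; m <- config$experiments$background_multiplier
  it <- 0
  r <- rate_at(m)
  while (it < max_iter) {
    it <- it + 1
    if (abs(r$pn_a - target) / target <= tol)
      return(list(multiplier = m, rates = r$rates, iterations = it))
    if (r$pn_a > target) { hi <- m; m <- if (is.na(lo)) m / 2 else (m + lo) / 2 }
    else { lo <- m; m <- if (is.na(hi)) m * 2 else (m + hi) / 2 }
    r <- rate_at(m)
  }
  stopf("background renormalisation did not converge in %d iterations (last PN_A rate %.3f Hz)",
        max_iter, r$pn_a)
}

#' Run one experimental case over seeds
#'
#' For each seed: build the network, generate the case's inputs, simulate,
#' reconstruct the LFP, and compute the spectrum; aggregate peak theta power
#' and firing rates as mean and SD over seeds.
#'
#' @param case_id case 1..6; @param config configuration.
#' @param n_seeds number of network instantiations; @param scale scale.
#' @param seeds explicit seed vector (overrides n_seeds).
#' @param duration_ms,discard_ms simulation protocol (defaults from config).
#' @param background_multiplier PN drive multiplier (renormalised baseline).
#' @param ablate ablated interneuron group.
#' @return a \code{case_summary} list.
#' @export
run_case <- function(case_id, config = default_config(), n_seeds = NULL,
                     scale = 1, seeds = NULL, duration_ms = NULL,
                     discard_ms = NULL, background_multiplier = NULL,
                     ablate = "none") {
  seeds <- seeds %||% seq_len(n_seeds %||% config$experiments$n_seeds)
  duration_ms <- duration_ms %||% config$simulation$duration_ms
  discard_ms <- discard_ms %||% config$simulation$discard_ms
  bm <- background_multiplier %||% config$experiments$background_multiplier
  per_seed <- lapply(seeds, function(s)
    run_case_seed(case_id, s, config, scale, duration_ms, discard_ms, bm,
                  ablate = ablate))
  pw <- vapply(per_seed, function(x) x$peak_theta$power, 0)
  pf <- vapply(per_seed, function(x) x$peak_theta$freq, 0)
  prom <- vapply(per_seed, function(x) x$prominence, 0)
  rates <- do.call(rbind, lapply(seq_along(per_seed), function(i) {
    r <- per_seed[[i]]$rates; r$seed <- seeds[i]; r
  }))
  structure(list(
    case = case_id, ablate = ablate, seeds = seeds, scale = scale,
    peak_theta_power = pw, peak_theta_freq = pf, prominence = prom,
    power_mean = mean(pw), power_sd = sd(pw),
    rates = rates, per_seed = per_seed,
    background_multiplier = bm), class = "case_summary")
}

#' Run an interneuron-ablation experiment (Case 3 base)
#'
#' Disconnects the efferent synapses of one interneuron group (cells remain
#' present and driven), renormalises the PN background drive back to the
#' baseline firing-rate targets, then runs the full Case-3 protocol.
#'
#' @param group "PV", "SOM", "CR" or "none" (= intact Case 3).
#' @inheritParams run_case
#' @param renorm_duration_ms,renorm_discard_ms protocol for the search runs.
#' @export
run_ablation <- function(group = c("none", "PV", "SOM", "CR"),
                         config = default_config(), n_seeds = NULL,
                         scale = 1, seeds = NULL, duration_ms = NULL,
                         discard_ms = NULL, background_multiplier = NULL,
                         renorm_duration_ms = 5000, renorm_discard_ms = 2000) {
  group <- match.arg(group)
  seeds <- seeds %||% seq_len(n_seeds %||% config$experiments$n_seeds)
  rn <- renormalize_background(config, scale = scale, case_id = 3,
                               seed = seeds[1], ablate = group,
                               duration_ms = renorm_duration_ms,
                               discard_ms = renorm_discard_ms,
                               max_iter = config$experiments$renorm_max_iter)
  out <- run_case(3, config, scale = scale, seeds = seeds,
                  duration_ms = duration_ms, discard_ms = discard_ms,
                  background_multiplier = rn$multiplier, ablate = group)
  out$renorm <- rn
  out
}

#' Compare case summaries by ANOVA
#'
#' For the six-case design: two-way fixed-effects ANOVA (rhythmicity x
#' cholinergic tone, with interaction) on per-seed peak theta power.  For
#' ablation summaries: one-way ANOVA across groups plus Bonferroni-corrected
#' pairwise t comparisons against the intact base.
#'
#' @param summaries list of \code{case_summary} objects.
#' @param design "cases" or "ablation".
#' @return list with the ANOVA table (and pairwise comparisons for the
#'   ablation design).
#' @export
compare_cases <- function(summaries, design = c("cases", "ablation")) {
  design <- match.arg(design)
  if (design == "cases") {
    df <- do.call(rbind, lapply(summaries, function(s) {
      cs <- case_spec(s$case)
      data.frame(power = s$peak_theta_power, rhythm = cs$vp_si,
                 ach = factor(cs$ach), n = length(s$peak_theta_power))
    }))
    if (length(unique(table(interaction(df$rhythm, df$ach)))) != 1)
      stopf("unbalanced design: equal seeds per cell required")
    fit <- aov(power ~ rhythm * ach, data = df)
    list(design = "cases", anova = summary(fit)[[1]], data = df)
  } else {
    df <- do.call(rbind, lapply(summaries, function(s)
      data.frame(power = s$peak_theta_power, group = s$ablate)))
    fit <- aov(power ~ group, data = df)
    base <- df$power[df$group == "none"]
    groups <- setdiff(unique(df$group), "none")
    pw <- do.call(rbind, lapply(groups, function(g) {
      tt <- stats::t.test(df$power[df$group == g], base, var.equal = TRUE)
      data.frame(group = g, t = unname(tt$statistic), p_raw = tt$p.value)
    }))
    pw$p_bonf <- pmin(1, pw$p_raw * nrow(pw))
    list(design = "ablation", anova = summary(fit)[[1]], pairwise = pw,
         data = df)
  }
}
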