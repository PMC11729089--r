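# AMPA, NMDA and GABA-A receptor models.
#
# Transmission uses the pulse-transmitter ("ON") first-order scheme: a
# presynaptic spike holds ON = 1 for `on_dur` ms, during which the open
# fraction r relaxes toward alphaTmax/(alphaTmax+beta); afterwards r decays
# with rate beta.  The synaptic current is
#     I = w * gmax * F * s(V) * r * (V - E)    [nA, with gmax in uS]
# where s(V) is the NMDA Mg2+ block and F the short-term-plasticity state.
# Cholinergic tone ACh in {0,1,2} scales the current by 1 + b_ACh*(ACh-1).

#' Synapse specification
#'
#' @param receptor "AMPA", "NMDA" or "GABA_A".
#' @param g_max maximal conductance, uS.
#' @param E reversal potential, mV (defaults: 0 for AMPA/NMDA, -75 for GABA_A).
#' @param alphaTmax opening rate while transmitter is present, 1/ms.
#' @param beta closing rate, 1/ms.
#' @param on_dur transmitter pulse duration per presynaptic spike, ms.
#' @param b_ACh cholinergic sensitivity (0 = insensitive).
#' @param stp an \code{\link{stp_rule}} or \code{NULL}.
#' @return a \code{synapse_spec} list.
#' @export
synapse_spec <- function(receptor = c("AMPA", "NMDA", "GABA_A"),
                         g_max = 0.001, E = NULL, alphaTmax = NULL,
                         beta = NULL, on_dur = NULL, b_ACh = 0, stp = NULL) {
  receptor <- match.arg(receptor)
  defaults <- list(
    AMPA   = list(E = 0,   alphaTmax = 1.1,   beta = 0.5,    on_dur = 1),
    NMDA   = list(E = 0,   alphaTmax = 0.072, beta = 0.01,   on_dur = 5),
    GABA_A = list(E = -75, alphaTmax = 5,     beta = 0.143,  on_dur = 1)
  )[[receptor]]
  spec <- list(receptor = receptor, g_max = g_max,
               E = E %||% defaults$E,
               alphaTmax = alphaTmax %||% defaults$alphaTmax,
               beta = beta %||% defaults$beta,
               on_dur = on_dur %||% defaults$on_dur,
               mg_block = receptor == "NMDA",
               b_ACh = b_ACh, stp = stp)
  stopifnot(spec$g_max >= 0, spec$beta > 0, spec$alphaTmax > 0, spec$on_dur > 0)
  if (receptor == "GABA_A" && spec$E > -60) stopf("GABA_A reversal must be <= -60 mV")
  class(spec) <- "synapse_spec"
  spec
}

#' Short-term plasticity rule
#'
#' Facilitating synapses multiply state F by \code{f} (>= 1) at each
#' presynaptic spike, with exponential recovery back to 1 (tau_F).
#' Depressing synapses multiply two states D1, D2 by \code{d1}, \code{d2}
#' (<= 1), each recovering to 1 with its own time constant; the effective
#' multiplier is F*D1*D2, never above 1 for a pure depressing rule.
#'
#' @param kind "depressing" or "facilitating".
#' @param f facilitation factor per spike (>= 1).
#' @param tau_F recovery time constant of F, ms.
#' @param d1,d2 fast/slow depression factors per spike (0 < d <= 1).
#' @param tau_D1,tau_D2 recovery time constants, ms.
#' @export
stp_rule <- function(kind = c("depressing", "facilitating"),
                     f = 1, tau_F = 20, d1 = 1, d2 = 1,
                     tau_D1 = 40, tau_D2 = 70) {
  kind <- match.arg(kind)
  if (kind == "facilitating" && f < 1) stopf("facilitating rule needs f >= 1")
  if (kind == "depressing" && (d1 <= 0 || d1 > 1 || d2 <= 0 || d2 > 1))
    stopf("depressing factors must be in (0, 1]")
  structure(list(kind = kind, f = f, tau_F = tau_F, d1 = d1, d2 = d2,
                 tau_D1 = tau_D1, tau_D2 = tau_D2), class = "stp_rule")
}

#' Fresh synapse state
#' @export
synapse_state <- function() {
  list(r = 0, F = 1, D1 = 1, D2 = 1, on_until = -Inf)
}

#' Advance receptor kinetics by one time step
#'
#' Exact within-step integration of r' = alphaTmax*ON*(1-r) - beta*r, with ON
#' determined by the transmitter pulse window.  A presynaptic spike at the
#' start of the step opens the pulse for \code{spec$on_dur} ms.
#'
#' @param state synapse state (see \code{\link{synapse_state}}).
#' @param spec a \code{\link{synapse_spec}}.
#' @param dt step, ms (> 0).
#' @param t current time, ms.
#' @param spike logical: presynaptic spike arriving at time t.
#' @return updated state.
#' @export
step_receptor <- function(state, spec, dt, t = 0, spike = FALSE) {
  stopifnot(dt > 0)
  if (spike) state$on_until <- t + spec$on_dur
  if (t < state$on_until) {
    lam <- spec$alphaTmax + spec$beta
    rinf <- spec$alphaTmax / lam
    state$r <- rinf + (state$r - rinf) * exp(-lam * dt)
  } else {
    state$r <- state$r * exp(-spec$beta * dt)
  }
  state
}

#' NMDA magnesium-block factor
#'
#' \code{s(V) = 1 / (1 + 0.33 * exp(-0.06 V))}; 1 for non-NMDA receptors.
#' @param V postsynaptic potential, mV.
#' @export
mg_block <- function(V) 1 / (1 + 0.33 * exp(-0.06 * V))

#' Cholinergic gain factor
#'
#' \code{1 + b_ACh * (ACh - 1)} for tone levels ACh in \{0, 1, 2\}
#' (low / baseline / high); baseline tone leaves the current unchanged.
#' @param b_ACh sensitivity; @param ACh tone level.
#' @export
ach_factor <- function(b_ACh, ACh) {
  if (!ACh %in% c(0, 1, 2)) stopf("ACh level must be 0, 1 or 2")
  1 + b_ACh * (ACh - 1)
}

#' Synaptic current
#'
#' @param state synapse state; @param spec synapse spec.
#' @param w dimensionless synaptic weight.
#' @param V_post postsynaptic membrane potential, mV.
#' @param ACh cholinergic tone level in \{0,1,2\}.
#' @return current, nA (positive outward).
#' @export
synaptic_current <- function(state, spec, w, V_post, ACh = 1) {
  if (!is.finite(V_post)) stopf("non-finite V_post")
  s <- if (spec$mg_block) mg_block(V_post) else 1
  Fmult <- state$F * state$D1 * state$D2
  I <- w * spec$g_max * Fmult * s * state$r * (V_post - spec$E)
  I * ach_factor(spec$b_ACh, ACh)
}

#' Apply a presynaptic spike to the short-term-plasticity state
#'
#' States first recover exponentially from the previous spike to time
#' \code{t_spike}, then the per-spike factors are applied.
#'
#' @param state synapse state carrying F, D1, D2 and \code{last_spike}.
#' @param rule an \code{\link{stp_rule}} (or NULL for a static synapse).
#' @param t_spike spike time, ms (non-decreasing across calls).
#' @export
stp_on_spike <- function(state, rule, t_spike) {
  if (is.null(rule)) return(state)
  last <- state$last_spike %||% -Inf
  if (t_spike < last) stopf("spike times must be non-decreasing")
  if (is.finite(last)) {
    dt <- t_spike - last
    state$F  <- 1 + (state$F  - 1) * exp(-dt / rule$tau_F)
    state$D1 <- 1 + (state$D1 - 1) * exp(-dt / rule$tau_D1)
    state$D2 <- 1 + (state$D2 - 1) * exp(-dt / rule$tau_D2)
  }
  state$F <- state$F * rule$f
  state$D1 <- state$D1 * rule$d1
  state$D2 <- state$D2 * rule$d2
  state$last_spike <- t_spike
  state
}

#' Short-term-plasticity multiplier at a given time
#'
#' Effective synaptic multiplier F*D1*D2 after exponential recovery from the
#' last spike; capped at 1 for depressing rules.
#' @export
stp_multiplier <- function(state, rule, t) {
  if (is.null(rule)) return(1)
  last <- state$last_spike %||% -Inf
  F <- state$F; D1 <- state$D1; D2 <- state$D2
  if (is.finite(last)) {
    dt <- t - last
    F  <- 1 + (F  - 1) * exp(-dt / rule$tau_F)
    D1 <- 1 + (D1 - 1) * exp(-dt / rule$tau_D1)
    D2 <- 1 + (D2 - 1) * exp(-dt / rule$tau_D2)
  }
  m <- F * D1 * D2
  if (rule$kind == "depressing") min(m, 1) else m
}

# Table 5 rules keyed by connection class.
stp_table <- function() {
  dep <- stp_rule("depressing", f = 1, tau_F = 20, d1 = 0.95, d2 = 0.9,
                  tau_D1 = 40, tau_D2 = 70)
  fac <- stp_rule("facilitating", f = 1.5, tau_F = 150, d1 = 1, d2 = 1,
                  tau_D1 = 40, tau_D2 = 70)
  list(
    "PN->PN" = dep, "PN->PV" = dep, "PV->PN" = dep, "PV->PV" = dep,
    "SOM->PV" = dep, "CR->PN" = dep, "SOM->PN" = dep,
    "PN->CR" = fac, "PN->SOM" = fac
  )
}
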