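# Voltage- and calcium-gated ionic currents.
#
# Every current follows the Hodgkin-Huxley form
#     I = gbar * m^p * h^q * (V - E),
# with each gating variable x relaxing as dx/dt = (x_inf - x)/tau_x.
# Rates are in 1/ms, voltages in mV, conductance densities in S/cm2,
# current densities in mA/cm2.  Removable singularities of trap-form rates
# a*(V-V0)/(exp((V-V0)/k)-1) are evaluated by their analytic limit (vtrap).

# -- per-channel gate definitions ------------------------------------------

gates_na <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) 0.4 * vtrap(-(V + 30), 7.2),
      beta  = function(V) 0.124 * vtrap(V + 30, 7.2),
      inf   = function(V) { a <- 0.4 * vtrap(-(V + 30), 7.2); b <- 0.124 * vtrap(V + 30, 7.2); a / (a + b) },
      tau   = function(V) { a <- 0.4 * vtrap(-(V + 30), 7.2); b <- 0.124 * vtrap(V + 30, 7.2); 0.6156 / (a + b) }
    ),
    h = list(
      alpha = function(V) 0.03 * vtrap(-(V + 45), 1.5),
      beta  = function(V) 0.01 * vtrap(V + 45, 1.5),
      inf   = function(V) 1 / (1 + exp((V + 50) / 4)),
      tau   = function(V) { a <- 0.03 * vtrap(-(V + 45), 1.5); b <- 0.01 * vtrap(V + 45, 1.5); 0.6156 / (a + b) }
    )
  )
}

gates_kdr <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) exp(-0.1144 * (V + 15)),
      beta  = function(V) exp(-0.0801 * (V + 15)),
      inf   = function(V) 1 / (1 + exp((-V - 15) / 11)),
      tau   = function(V) {
        a <- exp(-0.1144 * (V + 15)); b <- exp(-0.0801 * (V + 15))
        50 * b / (1 + a)
      }
    )
  )
}

gates_h <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) exp(0.0832 * (V + 75)),
      beta  = function(V) exp(0.0333 * (V + 75)),
      inf   = function(V) 1 / (1 + exp((V + 81) / 8)),
      tau   = function(V) {
        a <- exp(0.0832 * (V + 75)); b <- exp(0.0333 * (V + 75))
        b / (0.0081 * (1 + a))
      }
    )
  )
}

gates_km <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) 0.016 * exp((V + 52.7) / 23),
      beta  = function(V) 0.016 * exp(-(V + 52.7) / 18.8),
      inf   = function(V) 1 / (1 + exp((-V - 52.7) / 10.3)),
      tau   = function(V) {
        a <- 0.016 * exp((V + 52.7) / 23); b <- 0.016 * exp(-(V + 52.7) / 18.8)
        1 / (a + b)
      }
    )
  )
}

gates_ca <- function(nat = NULL) {
  list(
    m = list(
      inf = function(V) 1 / (1 + exp((-V - 30) / 11)),
      tau = function(V) 2.5 / (exp(-(V + 37.1) / 32.3) + exp((V + 37.1) / 32.3))
    ),
    h = list(
      inf = function(V) 1 / (1 + exp((V + 12.6) / 18.9)),
      tau = function(V) rep(420, length(V))
    )
  )
}

gates_nap <- function(nat = NULL) {
  list(
    m = list(
      inf = function(V) 1 / (1 + exp((-V - 48) / 5)),
      tau = function(V) 2.5 + 14 * exp(-abs(V + 40) / 10)
    )
  )
}

gates_na12 <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) 0.182 * vtrap(-(V + 30), 7),
      beta  = function(V) 0.124 * vtrap(V + 30, 7),
      inf   = function(V) { a <- 0.182 * vtrap(-(V + 30), 7); b <- 0.124 * vtrap(V + 30, 7); a / (a + b) },
      tau   = function(V) { a <- 0.182 * vtrap(-(V + 30), 7); b <- 0.124 * vtrap(V + 30, 7); 1 / (a + b) }
    ),
    h = list(
      alpha = function(V) 0.024 * vtrap(-(V + 50), 5),
      beta  = function(V) 0.0091 * vtrap(V + 75, 5),
      inf   = function(V) 1 / (1 + exp((V + 72) / 6.2)),
      tau   = function(V) { a <- 0.024 * vtrap(-(V + 50), 5); b <- 0.0091 * vtrap(V + 75, 5); 1 / (a + b) }
    )
  )
}

gates_na16 <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) 0.182 * vtrap(-(V + 43), 6),
      beta  = function(V) 0.124 * vtrap(V + 43, 6),
      inf   = function(V) { a <- 0.182 * vtrap(-(V + 43), 6); b <- 0.124 * vtrap(V + 43, 6); a / (a + b) },
      tau   = function(V) { a <- 0.182 * vtrap(-(V + 43), 6); b <- 0.124 * vtrap(V + 43, 6); 1 / (a + b) }
    ),
    h = gates_na12()$h
  )
}

gates_nat <- function(nat = list(Ra = 0.182, Rb = 0.124, Rd = 0.024, Rg = 0.0091)) {
  list(
    m = list(
      alpha = function(V) nat$Ra * vtrap(-(V + 15), 7.2),
      beta  = function(V) nat$Rb * vtrap(V + 15, 7.2),
      inf   = function(V) { a <- nat$Ra * vtrap(-(V + 15), 7.2); b <- nat$Rb * vtrap(V + 15, 7.2); a / (a + b) },
      tau   = function(V) { a <- nat$Ra * vtrap(-(V + 15), 7.2); b <- nat$Rb * vtrap(V + 15, 7.2); 1 / (a + b) }
    ),
    h = list(
      alpha = function(V) nat$Rd * vtrap(-(V + 30), 1.5),
      beta  = function(V) nat$Rg * vtrap(V + 30, 1.5),
      inf   = function(V) 1 / (1 + exp((V + 35) / 4)),
      tau   = function(V) { a <- nat$Rd * vtrap(-(V + 30), 1.5); b <- nat$Rg * vtrap(V + 30, 1.5); 1 / (a + b) }
    )
  )
}

gates_cal <- function(nat = NULL) {
  list(
    m = list(
      alpha = function(V) 15.69 * vtrap(81.5 - V, 10),
      beta  = function(V) 0.29 * exp(-V / 10.86),
      inf   = function(V) { a <- 15.69 * vtrap(81.5 - V, 10); b <- 0.29 * exp(-V / 10.86); a / (a + b) },
      tau   = function(V) { a <- 15.69 * vtrap(81.5 - V, 10); b <- 0.29 * exp(-V / 10.86); 1 / (a + b) }
    )
  )
}

# Calcium-dependent slow afterhyperpolarisation gate.  Rates depend on
# log10 of the calcium signal c = [Ca]_i^2 (default) or [Ca]_i; the time
# constant is fixed at 48 ms.
gates_sahp <- function(square = TRUE) {
  L <- function(Ca) if (square) 2 * log10(Ca) else log10(Ca)
  list(
    m = list(
      alpha = function(Ca) 0.0048 * exp(5 * L(Ca) + 17.5),
      beta  = function(Ca) 0.012 * exp(-(2 * L(Ca) + 20)),
      inf   = function(Ca) {
        a <- 0.0048 * exp(5 * L(Ca) + 17.5); b <- 0.012 * exp(-(2 * L(Ca) + 20))
        a / (a + b)
      },
      tau = function(Ca) rep(48, length(Ca))
    )
  )
}

# -- registry ---------------------------------------------------------------

#' Ionic channel registry
#'
#' Returns the definition of every ionic current in the model: gating
#' exponents \code{p} (activation) and \code{q} (inactivation, 0 if absent),
#' the reversal-potential class, and the gate rate/steady-state functions.
#'
#' @param nat_rates list with elements \code{Ra, Rb, Rd, Rg}: opening/closing
#'   rate coefficients (1/ms per mV) of the transient Na channel, whose
#'   magnitudes are free parameters of the model.
#' @param sahp_square logical; if \code{TRUE} the sAHP rates use
#'   \code{log10([Ca]^2)}, otherwise \code{log10([Ca])}.
#' @return named list of channel definitions.
#' @export
channel_registry <- function(nat_rates = list(Ra = 0.182, Rb = 0.124, Rd = 0.024, Rg = 0.0091),
                             sahp_square = TRUE) {
  list(
    na    = list(p = 3, q = 1, erev = "E_Na", gates = gates_na()),
    kdr   = list(p = 1, q = 0, erev = "E_K",  gates = gates_kdr()),
    hcn   = list(p = 1, q = 0, erev = "E_H",  gates = gates_h()),
    km    = list(p = 2, q = 0, erev = "E_K",  gates = gates_km()),
    ca    = list(p = 2, q = 1, erev = "E_Ca", gates = gates_ca(), ca_source = TRUE),
    nap   = list(p = 1, q = 0, erev = "E_Na", gates = gates_nap()),
    sahp  = list(p = 1, q = 0, erev = "E_K",  gates = gates_sahp(sahp_square), ca_gated = TRUE),
    na12  = list(p = 3, q = 1, erev = "E_Na", gates = gates_na12()),
    na16  = list(p = 3, q = 1, erev = "E_Na", gates = gates_na16()),
    nat   = list(p = 3, q = 1, erev = "E_Na", gates = gates_nat(nat_rates)),
    cal   = list(p = 2, q = 0, erev = "E_Ca", gates = gates_cal(), ca_source = TRUE)
  )
}

#' Evaluate a gating variable's steady state and time constant
#'
#' @param channel channel name (see \code{\link{channel_registry}}).
#' @param gate \code{"m"} (activation) or \code{"h"} (inactivation).
#' @param V membrane potential, mV (ignored for the calcium-gated sAHP gate).
#' @param Ca intracellular calcium, concentration units (required > 0 for the
#'   sAHP gate).
#' @param registry a channel registry.
#' @return list with \code{inf} (dimensionless, in [0,1]) and \code{tau} (ms).
#' @export
eval_gate <- function(channel, gate = "m", V = NULL, Ca = NULL,
                      registry = channel_registry()) {
  def <- registry[[channel]]
  if (is.null(def)) stopf("unknown channel '%s'", channel)
  g <- def$gates[[gate]]
  if (is.null(g)) stopf("channel '%s' has no '%s' gate", channel, gate)
  if (isTRUE(def$ca_gated)) {
    if (is.null(Ca) || any(!is.finite(Ca)) || any(Ca <= 0))
      stopf("calcium-gated channel '%s' requires Ca > 0", channel)
    list(inf = g$inf(Ca), tau = g$tau(Ca))
  } else {
    if (is.null(V) || any(!is.finite(V))) stopf("non-finite V")
    list(inf = g$inf(V), tau = g$tau(V))
  }
}

#' Instantaneous channel current density
#'
#' \code{I = gbar * m^p * h^q * (V - E)}; positive current is outward.
#'
#' @param gbar maximal conductance density, S/cm2 (>= 0).
#' @param p,q gating exponents (q = 0 when there is no inactivation gate).
#' @param m,h gating states in [0,1] (\code{h} ignored when q = 0).
#' @param V membrane potential, mV.
#' @param E reversal potential, mV.
#' @return current density, mA/cm2.
#' @export
channel_current <- function(gbar, p, m, V, E, q = 0, h = 1) {
  if (any(gbar < 0)) stopf("gbar must be >= 0")
  if (any(m < 0 | m > 1) || (q > 0 && any(h < 0 | h > 1)))
    stopf("gating state outside [0,1]")
  gbar * m^p * (if (q > 0) h^q else 1) * (V - E)
}

# Uniform lookup tables for the integration core: steady state and time
# constant of every gate on a dense voltage grid (and a log10-Ca grid for the
# sAHP gate).  The core advances gates by exact exponential relaxation using
# these tables.
build_gate_tables <- function(registry = channel_registry(),
                              v_range = c(-120, 60), dv = 0.05,
                              lca_range = c(-8, 2), dlca = 0.01) {
  V <- seq(v_range[1], v_range[2], by = dv)
  LC <- seq(lca_range[1], lca_range[2], by = dlca)
  tabs <- list(); ids <- list()
  for (nm in names(registry)) {
    def <- registry[[nm]]
    for (g in names(def$gates)) {
      key <- paste0(nm, ".", g)
      gg <- def$gates[[g]]
      if (isTRUE(def$ca_gated)) {
        ca <- 10^LC
        tabs[[key]] <- list(inf = gg$inf(ca), tau = gg$tau(ca), ca = TRUE)
      } else {
        tabs[[key]] <- list(inf = gg$inf(V), tau = gg$tau(V), ca = FALSE)
      }
      ids[[key]] <- length(tabs) - 1L
    }
  }
  list(tables = tabs, ids = ids, v0 = v_range[1], dv = dv,
       lc0 = lca_range[1], dlc = dlca, nv = length(V), nlc = length(LC))
}
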