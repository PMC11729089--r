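# Line-source reconstruction of the extracellular potential.
#
# Each compartment is a uniform line current along the cell's dendritic axis
# (oriented along +z, soma at the placed coordinate); the potential at the
# electrode is the closed-form line-source expression, summed over all
# compartments of all neurons and scaled by a global factor.

#' Line-source extracellular potential of one compartment
#'
#' \deqn{\Phi = I / (4 \pi \sigma \Delta s) \log | (\sqrt{h^2+r^2} - h) /
#' (\sqrt{l^2+r^2} - l) |}
#' with \code{l = ds + h}.  With I in nA, distances in um and sigma in S/m
#' the potential is in mV.
#'
#' @param I transmembrane current, nA.
#' @param ds compartment (line) length, um.
#' @param r radial distance from the line, um (> 0).
#' @param h longitudinal distance from the far end of the line, um (signed;
#'   negative when the electrode lies alongside the segment).
#' @param sigma extracellular conductivity, S/m.
#' @param l longitudinal distance from the start of the line (default ds + h).
#' @export
line_source_potential <- function(I, ds, r, h, sigma = 0.3, l = ds + h) {
  if (any(r <= 0)) stopf("electrode on the line source (r = 0): enforce a minimum radial distance")
  stopifnot(all(ds > 0))
  num <- sqrt(h^2 + r^2) - h
  den <- sqrt(l^2 + r^2) - l
  I / (4 * pi * sigma * ds) * log(abs(num / den))
}

# relative z-spans of each compartment of a cell type: soma [0, L_soma];
# the soma's first child extends upward from the soma top, its second child
# downward from the soma base; a dendrite's child continues its direction.
compartment_spans <- function(cell_model) {
  comps <- cell_model$comps
  n <- nrow(comps)
  z0 <- numeric(n); z1 <- numeric(n); dir <- numeric(n)
  z0[1] <- 0; z1[1] <- comps$L[1]; dir[1] <- 1
  child_count <- integer(n)
  for (i in seq_len(n)[-1]) {
    p <- comps$parent_idx[i]
    child_count[p] <- child_count[p] + 1L
    if (p == 1L) {
      if (child_count[p] == 1L) { dir[i] <- 1; z0[i] <- z1[1] }
      else { dir[i] <- -1; z0[i] <- z0[1] }
    } else {
      dir[i] <- dir[p]
      z0[i] <- if (dir[p] > 0) max(z0[p], z1[p]) else min(z0[p], z1[p])
    }
    z1[i] <- z0[i] + dir[i] * comps$L[i]
  }
  data.frame(name = comps$name, z0 = z0, z1 = z1)
}

#' Compartment line-segment geometry of a network
#'
#' @param network a \code{bla_network}.
#' @return data frame (cell, comp, x, y, z0, z1) with absolute coordinates,
#'   one row per compartment in flattened order.
#' @export
compartment_geometry <- function(network) {
  config <- network$config
  types <- network$cells$type
  tmpl <- lapply(unique(types), function(ty) build_cell(ty, config))
  names(tmpl) <- unique(types)
  spans <- lapply(tmpl, compartment_spans)
  out <- lapply(seq_along(types), function(ci) {
    sp <- spans[[types[ci]]]
    data.frame(cell = ci, comp = seq_len(nrow(sp)),
               x = network$cells$x[ci], y = network$cells$y[ci],
               z0 = network$cells$z[ci] + sp$z0,
               z1 = network$cells$z[ci] + sp$z1)
  })
  do.call(rbind, out)
}

# per-compartment LFP coefficients (potential per nA, times the global
# scale), in flattened compartment order
lfp_coefficients <- function(network, fc, config, electrode = NULL) {
  geom <- compartment_geometry(network)
  el <- electrode %||% unlist(config$geometry$electrode_um)
  lfp_coefficients_geom(geom, el, config$lfp$sigma_S_per_m,
                        config$lfp$scale,
                        config$geometry$min_electrode_radius_um)
}

lfp_coefficients_geom <- function(geom, electrode, sigma, scale, min_r) {
  r <- pmax(sqrt((electrode[1] - geom$x)^2 + (electrode[2] - geom$y)^2), min_r)
  ds <- abs(geom$z1 - geom$z0)
  dirn <- sign(geom$z1 - geom$z0)
  l <- (electrode[3] - geom$z0) * dirn
  h <- l - ds
  line_source_potential(1, ds, r, h, sigma, l) * scale
}

#' Sum compartmental currents into an LFP trace (reference summation)
#'
#' Independent double-loop summation of the line-source potentials of a set
#' of compartment current traces; used to cross-check the accumulation
#' performed inside the integration core.
#'
#' @param currents matrix (n_compartments x n_samples) of transmembrane
#'   currents, nA.
#' @param geom compartment geometry (\code{\link{compartment_geometry}}).
#' @param electrode electrode position (x, y, z), um.
#' @param sigma conductivity, S/m; @param scale global LFP scale factor.
#' @param min_r minimum radial distance clamp, um.
#' @return numeric LFP trace (length n_samples).
#' @export
sum_lfp <- function(currents, geom, electrode, sigma = 0.3, scale = 1000,
                    min_r = 1) {
  if (nrow(currents) != nrow(geom)) stopf("currents/geometry misalignment")
  out <- numeric(ncol(currents))
  for (i in seq_len(nrow(geom))) {
    r <- max(sqrt((electrode[1] - geom$x[i])^2 + (electrode[2] - geom$y[i])^2),
             min_r)
    ds <- abs(geom$z1[i] - geom$z0[i])
    dirn <- sign(geom$z1[i] - geom$z0[i])
    l <- (electrode[3] - geom$z0[i]) * dirn
    h <- l - ds
    out <- out + line_source_potential(currents[i, ], ds, r, h, sigma, l)
  }
  out * scale
}
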