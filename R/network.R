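# Network instantiation: population composition, uniform 3-D placement,
# intrinsic wiring with joint unidirectional/bidirectional pair sampling,
# afferent wiring with fixed convergence, log-normal weights with an upper
# cutoff, and distance-dependent conduction delays.

pop_order <- c("PN_A", "PN_C", "PV", "CR", "SOM")

#' Place cells in the model volume
#'
#' @param counts named vector of per-type counts.
#' @param volume_um placement box (x, y, z extents, um).
#' @param seed integer seed.
#' @return data frame (id, type, x, y, z).
#' @export
place_cells <- function(counts, volume_um = c(600, 600, 600), seed = 1) {
  if (any(volume_um <= 0)) stopf("region volume must be > 0")
  n <- sum(counts)
  if (n / prod(volume_um / 1000) > 5e4)
    stopf("cell count exceeds the density cap for the configured volume")
  set.seed(seed)
  data.frame(
    id = seq_len(n),
    type = rep(names(counts), counts),
    x = runif(n, 0, volume_um[1]),
    y = runif(n, 0, volume_um[2]),
    z = runif(n, 0, volume_um[3]),
    stringsAsFactors = FALSE)
}

#' Conduction delay between two points (distance / conduction velocity)
#' @param p1,p2 length-3 coordinates or nx3 matrices, um.
#' @param velocity_um_per_ms axonal conduction velocity.
#' @return delay, ms.
#' @export
conduction_delay <- function(p1, p2, velocity_um_per_ms = 500) {
  p1 <- rbind(p1); p2 <- rbind(p2)
  unname(sqrt(rowSums((p1 - p2)^2))) / velocity_um_per_ms
}

#' Sample log-normal synaptic weights with an upper cutoff
#'
#' Draws from a log-normal whose truncated (at \code{cutoff_factor * mean})
#' arithmetic mean equals \code{mean}; draws above the cutoff are resampled,
#' not clipped.
#'
#' @param n number of draws; @param mean target arithmetic mean (> 0).
#' @param sdlog log-scale shape parameter.
#' @param cutoff_factor cutoff as a multiple of the mean.
#' @export
sample_weight <- function(n, mean, sdlog = 0.5, cutoff_factor = 3) {
  if (mean <= 0) stopf("weight mean must be > 0")
  cut <- cutoff_factor * mean
  # solve for mu so the truncated mean hits the target
  trunc_mean <- function(mu) {
    exp(mu + sdlog^2 / 2) *
      pnorm((log(cut) - mu - sdlog^2) / sdlog) /
      pnorm((log(cut) - mu) / sdlog)
  }
  mu <- uniroot(function(m) trunc_mean(m) - mean,
                interval = log(mean) + c(-2, 1.5), extendInt = "yes")$root
  out <- numeric(0)
  while (length(out) < n) {
    w <- stats::rlnorm(2 * (n - length(out)) + 10, mu, sdlog)
    out <- c(out, w[w <= cut])
  }
  out[seq_len(n)]
}

# Joint sampling of one unordered pair block: categories
# {none, uni a->b, uni b->a, bidirectional}.
sample_pair_block <- function(ia, ib, p_uni_ab, p_uni_ba, p_bi) {
  n <- length(ia)
  u <- runif(n)
  cat <- integer(n)
  cat[u < p_bi] <- 3L
  cat[u >= p_bi & u < p_bi + p_uni_ab] <- 1L
  cat[u >= p_bi + p_uni_ab & u < p_bi + p_uni_ab + p_uni_ba] <- 2L
  list(ab = c(ia[cat == 1L | cat == 3L], NULL), ab_to = ib[cat == 1L | cat == 3L],
       ba = ib[cat == 2L | cat == 3L], ba_to = ia[cat == 2L | cat == 3L])
}

# wiring group of a cell type ("PN" merges the two principal subtypes)
wire_group <- function(type) ifelse(type %in% c("PN_A", "PN_C"), "PN", type)

#' Wire the intrinsic network
#'
#' Draws directed edges for every connection class so that unidirectional and
#' bidirectional fractions match the configured table in expectation;
#' reciprocal pairs are sampled jointly per unordered pair (one categorical
#' draw), not as two independent Bernoulli draws.
#'
#' @param cells placement data frame; @param config configuration.
#' @param seed integer seed.
#' @return data frame of directed edges (pre, post, class, receptor, stp,
#'   b_ACh, weight, delay_ms).
#' @export
wire_intrinsic <- function(cells, config, seed = 1) {
  set.seed(seed)
  rules <- config$connections
  key <- vapply(rules, function(r) paste0(r$src, "->", r$dst), "")
  names(rules) <- key
  grp <- wire_group(cells$type)
  groups <- c("PN", "PV", "SOM", "CR")
  idx <- lapply(groups, function(g) cells$id[grp == g])
  names(idx) <- groups
  pre <- integer(0); post <- integer(0); klass <- character(0)

  add_edges <- function(p, q, k) {
    pre <<- c(pre, p); post <<- c(post, q); klass <<- c(klass, rep(k, length(p)))
  }
  for (a in seq_along(groups)) for (b in a:length(groups)) {
    ga <- groups[a]; gb <- groups[b]
    rab <- rules[[paste0(ga, "->", gb)]]
    rba <- rules[[paste0(gb, "->", ga)]]
    if (is.null(rab) && is.null(rba)) next
    p_bi <- (if (!is.null(rab)) rab$bi else rba$bi) / 100
    p_uab <- if (!is.null(rab)) rab$uni / 100 else 0
    p_uba <- if (!is.null(rba)) rba$uni / 100 else 0
    if (ga == gb) {
      ids <- idx[[ga]]
      n <- length(ids)
      if (n < 2) next
      cmb <- t(utils::combn(ids, 2))
      blk <- sample_pair_block(cmb[, 1], cmb[, 2], p_uab, p_uab, p_bi)
    } else {
      ia <- rep(idx[[ga]], each = length(idx[[gb]]))
      ib <- rep(idx[[gb]], times = length(idx[[ga]]))
      blk <- sample_pair_block(ia, ib, p_uab, p_uba, p_bi)
    }
    if (!is.null(rab)) add_edges(blk$ab, blk$ab_to, paste0(ga, "->", gb))
    if (ga == gb) {
      if (!is.null(rab)) add_edges(blk$ba, blk$ba_to, paste0(ga, "->", gb))
    } else if (!is.null(rba)) add_edges(blk$ba, blk$ba_to, paste0(gb, "->", ga))
  }
  edges <- data.frame(pre = pre, post = post, class = klass,
                      stringsAsFactors = FALSE)
  # attach per-class synapse properties and per-edge weights/delays
  edges$receptor <- vapply(rules[edges$class], function(r) r$receptor, "")
  edges$stp <- vapply(rules[edges$class],
                      function(r) if (is.null(r$stp)) "none" else r$stp, "")
  edges$b_ACh <- vapply(rules[edges$class], function(r) r$b_ACh, 0)
  edges$weight <- NA_real_
  for (k in unique(edges$class)) {
    sel <- edges$class == k
    edges$weight[sel] <- sample_weight(sum(sel), rules[[k]]$w_mean,
                                       config$weights$sdlog,
                                       config$weights$cutoff_factor)
  }
  v <- config$geometry$conduction_velocity_um_per_ms
  xyz <- as.matrix(cells[, c("x", "y", "z")])
  edges$delay_ms <- conduction_delay(xyz[edges$pre, , drop = FALSE],
                                     xyz[edges$post, , drop = FALSE], v)
  edges
}

#' Wire VP/SI and thalamic/cortical afferents
#'
#' VP/SI GABAergic afferents contact every principal neuron with convergence
#' 1 and every PV+ interneuron with mean convergence 10.1; thalamic/cortical
#' glutamatergic sources contact PNs, SOM+ and CR+ cells (one independent
#' source per target), not PV+ cells.
#'
#' @param cells placement data frame; @param config configuration.
#' @param n_afferents number of VP/SI afferent cells.
#' @param seed integer seed.
#' @return list with \code{vpsi} (afferent, post, weight, b_ACh) and
#'   \code{thalamic} (source, post, weight) data frames.
#' @export
wire_afferents <- function(cells, config, n_afferents = NULL, seed = 1) {
  set.seed(seed)
  aff <- config$afferents
  n_aff <- n_afferents %||% aff$vpsi$n_afferents
  pn <- cells$id[cells$type %in% c("PN_A", "PN_C")]
  pv <- cells$id[cells$type == "PV"]
  # PNs: convergence exactly 1
  vp_pn <- data.frame(afferent = sample.int(n_aff, length(pn), replace = TRUE),
                      post = pn)
  vp_pn$w_mean <- aff$vpsi$w_mean$PN
  vp_pn$b_ACh <- aff$vpsi$b_ACh$PN
  # PVs: mean convergence 10.1 (base in-degree plus remainder spread)
  conv <- aff$vpsi$convergence$PV
  total <- round(conv * length(pv))
  base <- total %/% length(pv)
  extra <- sample(pv, total - base * length(pv))
  indeg <- stats::setNames(rep(base, length(pv)), pv)
  indeg[as.character(extra)] <- indeg[as.character(extra)] + 1L
  vp_pv <- do.call(rbind, lapply(pv, function(p) {
    k <- indeg[[as.character(p)]]
    data.frame(afferent = sample.int(n_aff, k, replace = n_aff < k), post = p)
  }))
  vp_pv$w_mean <- aff$vpsi$w_mean$PV
  vp_pv$b_ACh <- aff$vpsi$b_ACh$PV
  vpsi <- rbind(vp_pn, vp_pv)
  vpsi$weight <- NA_real_
  for (wm in unique(vpsi$w_mean)) {
    sel <- vpsi$w_mean == wm
    vpsi$weight[sel] <- sample_weight(sum(sel), wm, config$weights$sdlog,
                                      config$weights$cutoff_factor)
  }
  # thalamic/cortical: one independent source per target cell
  tg <- cells$id[cells$type %in% aff$thalamic$targets]
  thal <- data.frame(source = seq_along(tg), post = tg)
  thal$weight <- sample_weight(nrow(thal), aff$thalamic$w_mean,
                               config$weights$sdlog,
                               config$weights$cutoff_factor)
  list(vpsi = vpsi, thalamic = thal, n_vpsi = n_aff)
}

#' Build the full network
#'
#' Places the populations, wires intrinsic and afferent connectivity, and
#' returns a network object.  \code{scale} proportionally reduces all
#' population and afferent counts (preserving fractions and convergence
#' ratios) for desk-scale runs.
#'
#' @param config configuration; @param seed master seed; @param scale factor.
#' @return a \code{bla_network} list.
#' @export
build_network <- function(config = default_config(), seed = 1, scale = 1) {
  counts <- vapply(pop_order, function(p) config$populations[[p]]$count, 0)
  if (scale != 1)
    counts <- stats::setNames(pmax(1L, as.integer(round(counts * scale))),
                              names(counts))
  cells <- place_cells(counts, unlist(config$geometry$volume_um),
                       seed = sub_seed(seed, "place"))
  edges <- wire_intrinsic(cells, config, seed = sub_seed(seed, "wire"))
  n_aff <- if (scale == 1) config$afferents$vpsi$n_afferents else
    max(1L, as.integer(round(config$afferents$vpsi$n_afferents * scale)))
  aff <- wire_afferents(cells, config, n_afferents = n_aff,
                        seed = sub_seed(seed, "afferents"))
  structure(list(cells = cells, edges = edges, afferents = aff,
                 config = config, seed = seed, scale = scale),
            class = "bla_network")
}

#' @export
print.bla_network <- function(x, ...) {
  cat("BLA network:", nrow(x$cells), "cells,", nrow(x$edges),
      "intrinsic edges,", nrow(x$afferents$vpsi), "VP/SI synapses (",
      x$afferents$n_vpsi, "afferent cells ),", nrow(x$afferents$thalamic),
      "thalamic sources\n")
  print(table(x$cells$type))
  invisible(x)
}
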