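# Population composition, placement, wiring statistics, weights, delays.

test_that("default composition is exact and conserved", {
  net <- build_network(bla_cfg, seed = 1, scale = 1)
  tb <- table(net$cells$type)
  expect_equal(unname(tb[c("PN_A", "PN_C", "PV", "CR", "SOM")]),
               c(569, 231, 93, 56, 51), ignore_attr = TRUE)
  expect_equal(sum(tb), 1000)
  expect_equal(net$afferents$n_vpsi, 893)
  expect_equal(sum(net$cells$type %in% c("PN_A", "PN_C")), 800)
})

test_that("placement is uniform in the volume and reproducible per seed", {
  a <- place_cells(c(PN_A = 200), c(600, 600, 600), seed = 5)
  b <- place_cells(c(PN_A = 200), c(600, 600, 600), seed = 5)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 600))
  expect_error(place_cells(c(PN_A = 10), c(0, 600, 600)), "volume")
})

test_that("conduction delays follow distance / velocity and are a metric", {
  expect_equal(conduction_delay(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(conduction_delay(c(0, 0, 0), c(250, 0, 0)), 0.5)
  p1 <- c(10, 20, 30); p2 <- c(300, 200, 100)
  expect_equal(conduction_delay(p1, p2), conduction_delay(p2, p1))
  expect_equal(conduction_delay(p1, 2 * p2 - p1), 2 * conduction_delay(p1, p2))
})

test_that("log-normal weights respect the cutoff and the configured mean", {
  set.seed(1)
  w <- sample_weight(1e5, mean = 2, sdlog = 0.5, cutoff_factor = 3)
  expect_lte(max(w), 6)
  expect_gt(min(w), 0)
  expect_equal(mean(w), 2, tolerance = 0.02)
  expect_error(sample_weight(10, 0), "> 0")
})

test_that("realized connection probabilities match the configured table", {
  # full population size, averaged over seeds; binomial tolerance
  probs <- sapply(1:2, function(s) {
    net <- build_network(bla_cfg, seed = s, scale = 1)
    n_pn <- 800; n_pv <- 93; n_som <- 51
    c(pv_pn = sum(net$edges$class == "PV->PN") / (n_pv * n_pn),
      pn_som = sum(net$edges$class == "PN->SOM") / (n_pn * n_som),
      pn_pn = sum(net$edges$class == "PN->PN") / (n_pn * (n_pn - 1)))
  })
  p <- rowMeans(probs)
  se <- function(p0, n) 3 * sqrt(p0 * (1 - p0) / n / 2)
  expect_lt(abs(p["pv_pn"] - 0.52), se(0.52, 93 * 800))
  expect_lt(abs(p["pn_som"] - 0.3119), se(0.3119, 800 * 51))
  expect_lt(abs(p["pn_pn"] - 0.02), se(0.02, 800 * 799))
})

test_that("reciprocal pairs are sampled jointly: bidirectional fraction matches", {
  net <- build_network(bla_cfg, seed = 3, scale = 1)
  ed <- net$edges[net$edges$class %in% c("PN->PV", "PV->PN"), ]
  key_fwd <- paste(ed$pre[ed$class == "PN->PV"], ed$post[ed$class == "PN->PV"])
  key_rev <- paste(ed$post[ed$class == "PV->PN"], ed$pre[ed$class == "PV->PN"])
  bi <- length(intersect(key_fwd, key_rev)) / (800 * 93)
  expect_equal(bi, 0.1558, tolerance = 3 * sqrt(0.1558 * 0.8442 / (800 * 93)) / 0.1558)
})

test_that("unlisted pairs get no edges and there are no self-edges", {
  net <- build_network(bla_cfg, seed = 2, scale = 0.25)
  grp_pre <- ifelse(net$cells$type[net$edges$pre] %in% c("PN_A", "PN_C"), "PN",
                    net$cells$type[net$edges$pre])
  grp_post <- ifelse(net$cells$type[net$edges$post] %in% c("PN_A", "PN_C"), "PN",
                     net$cells$type[net$edges$post])
  expect_equal(sum(grp_pre == "SOM" & grp_post == "CR"), 0)
  expect_equal(sum(grp_pre == "PV" & grp_post == "CR"), 0)
  expect_equal(sum(net$edges$pre == net$edges$post), 0)
  expect_true(all(net$edges$delay_ms >= 0))
  expect_true(all(net$edges$weight > 0))
})

test_that("VP/SI afferents have the stated convergence; PV gets no thalamic input", {
  net <- build_network(bla_cfg, seed = 4, scale = 1)
  vp <- net$afferents$vpsi
  ty <- net$cells$type[vp$post]
  pn_deg <- table(factor(vp$post[ty %in% c("PN_A", "PN_C")],
                         levels = net$cells$id[net$cells$type %in% c("PN_A", "PN_C")]))
  expect_equal(mean(pn_deg), 1)        # exactly one afferent per PN
  pv_ids <- net$cells$id[net$cells$type == "PV"]
  pv_deg <- table(factor(vp$post[ty == "PV"], levels = pv_ids))
  expect_equal(mean(pv_deg), 10.1, tolerance = 0.005)
  th_ty <- net$cells$type[net$afferents$thalamic$post]
  expect_equal(sum(th_ty == "PV"), 0)
  expect_true(all(c("PN_A", "PN_C", "SOM", "CR") %in% th_ty))
})

test_that("network build is reproducible per seed and scale preserves fractions", {
  a <- build_network(bla_cfg, seed = 9, scale = 0.25)
  b <- build_network(bla_cfg, seed = 9, scale = 0.25)
  expect_identical(a$cells, b$cells)
  expect_identical(a$edges, b$edges)
  tb <- table(a$cells$type) / nrow(a$cells)
  expect_equal(unname(tb["PN_A"]), 0.569, tolerance = 0.01, ignore_attr = TRUE)
  # VP/SI convergence onto PV preserved under scaling
  pv_ids <- a$cells$id[a$cells$type == "PV"]
  deg <- table(factor(a$afferents$vpsi$post, levels = pv_ids))
  expect_equal(mean(deg[as.character(pv_ids)]), 10.1, tolerance = 0.01)
})
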