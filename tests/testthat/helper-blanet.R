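# Shared fixtures: configuration is loaded once; tiny networks are built in
# code at test time.

bla_cfg <- default_config()

tiny_network <- function(seed = 1, scale = 0.1) {
  build_network(bla_cfg, seed = seed, scale = scale)
}

# manual two-population toy network (one PN_A, one PV) with a single edge,
# used for causality/PSP-level checks
toy_network <- function(w = 2, delay_ms = 5, config = bla_cfg) {
  cells <- data.frame(id = 1:2, type = c("PN_A", "PV"),
                      x = c(100, 300), y = c(300, 300), z = c(300, 300))
  edges <- data.frame(pre = 1L, post = 2L, class = "PN->PV",
                      receptor = "exc", stp = "none", b_ACh = 0,
                      weight = w, delay_ms = delay_ms,
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, edges = edges,
                 afferents = list(vpsi = NULL, thalamic = NULL, n_vpsi = 0),
                 config = config, seed = 1, scale = 1),
            class = "bla_network")
}
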