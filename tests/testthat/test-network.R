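test_that("location gradients evaluate exactly and reject out-of-range positions", {
  lp <- location_params(2.5)
  expect_equal(lp$tau_q, 30)
  expect_equal(lp$w_FS, 7)    # w_FS = 10 - 1.2 u
  expect_equal(lp$S, 0.75)
  lp0 <- location_params(0)
  expect_equal(unlist(lp0), c(tau_q = 60, w_FS = 10, S = 1))
  expect_equal(location_params(5)$S, 0)
  expect_error(location_params(5.1), "within")
  expect_error(location_params(-0.2), "within")
})

test_that("the lateral kernel has the printed central excitation and long-range inhibition", {
  eps <- 1e-9
  w <- lateral_weight(2.5, 2.5 + eps)
  expect_equal(w$w_exc, 0.75 * 0.16, tolerance = 1e-6)
  expect_equal(w$w_inh, 0.75 * (1 - 1.15), tolerance = 1e-6)
  expect_equal(w$w_exc - w$w_inh, 0.2325, tolerance = 1e-6)  # net central excitation
  # far targets: pure inhibition of magnitude S at the source
  far <- lateral_weight(0.5, 4.9)
  expect_lt(far$w_exc, 1e-12)
  expect_equal(far$w_inh, location_params(0.5)$S, tolerance = 1e-6)
  # rostral-most source: S = 1, short-range disinhibition of -0.15 nS
  w0 <- lateral_weight(0, eps)
  expect_equal(w0$w_inh, 1 - 1.15, tolerance = 1e-6)
  expect_error(lateral_weight(1, 1), "self-connection")
})

test_that("signed weights route onto non-negative conductances and preserve the net drive", {
  r <- route_signed_weights(0.12, -0.1125)
  expect_equal(r$exc, 0.2325)
  expect_equal(r$inh, 0)
  expect_equal(route_signed_weights(0, 0.75), list(exc = 0, inh = 0.75))
  expect_equal(route_signed_weights(0, 0), list(exc = 0, inh = 0))
  we <- runif(50, 0, 0.2); wi <- runif(50, -0.2, 1)
  r <- route_signed_weights(we, wi)
  expect_true(all(r$exc >= 0) && all(r$inh >= 0))
  expect_equal(r$exc - r$inh, we - wi)
})

test_that("the net lateral kernel is symmetric, locally excitatory and globally inhibitory", {
  d <- seq(0.01, 2.5, by = 0.01)
  u0 <- 2.5
  right <- lateral_weight(u0, u0 + d[d <= 2.49])
  left <- lateral_weight(u0, u0 - d[d <= 2.49])
  expect_equal(right$w_exc - right$w_inh, left$w_exc - left$w_inh)
  net <- right$w_exc - right$w_inh
  expect_true(all(net[d <= 0.3] > 0))
  expect_true(all(net[d >= 0.5 & d <= 2.49] < 0))
  expect_equal(sum(diff(sign(net)) != 0), 1)  # a single zero crossing
})

test_that("the network assembles one-to-one feedforward and all-to-all routed lateral weights", {
  net <- build_network()
  g <- net$grid
  expect_equal(net$w_FS, 10 - 1.2 * g$positions)
  expect_true(all(diff(net$w_FS) < 0))         # strong rostral, weak caudal
  expect_equal(dim(net$W_exc_routed), c(200, 200))
  expect_true(all(diag(net$W_exc_routed) == 0) && all(diag(net$W_inh_routed) == 0))
  off_diag <- !diag(TRUE, 200)
  expect_true(all((net$W_exc_routed + net$W_inh_routed)[off_diag] > 0))
  expect_true(all(net$W_exc_routed >= 0) && all(net$W_inh_routed >= 0))
  # matrix construction agrees with the pairwise kernel + routing route
  set.seed(7)
  for (case in 1:25) {
    i <- sample(200, 1); j <- sample(setdiff(1:200, i), 1)
    w <- lateral_weight(g$positions[i], g$positions[j], net$cfg)
    r <- route_signed_weights(w$w_exc, w$w_inh)
    expect_equal(net$W_exc_routed[i, j], r$exc)
    expect_equal(net$W_inh_routed[i, j], r$inh)
  }
  # lateral output scales with S: net central weight decreases rostral -> caudal
  u <- seq(0.2, 4.8, by = 0.2)
  net_central <- vapply(u, function(x) {
    w <- lateral_weight(x, x + 1e-9); w$w_exc - w$w_inh
  }, 0)
  expect_true(all(diff(net_central) < 0))
})

test_that("invalid configurations are rejected", {
  expect_error(network_config(sigma_exc = 0.8, sigma_inh = 0.7), "sigma_exc")
  cfg_bad <- network_config()
  cfg_bad$wFS_slope <- -3   # w_FS < 0 at the caudal end
  expect_error(build_network(cfg_bad), "w_FS")
})

test_that("simulation is silent without input and deterministic with it", {
  net <- build_network()
  rec0 <- simulate_network(net, stimulus_spec(I0 = 0))
  expect_equal(nrow(rec0$input$spikes), 0)
  expect_equal(nrow(rec0$sc$spikes), 0)
  rec1 <- get_default_run()
  m <- get_model()
  rec2 <- simulate_network(m$network, stimulus_spec(), dt = m$dt)
  expect_identical(rec1$input$spikes, rec2$input$spikes)
  expect_identical(rec1$sc$spikes, rec2$sc$spikes)
  # refractory guarantee inside the network
  isi_min <- min(unlist(lapply(split(rec1$sc$spikes$t_ms, rec1$sc$spikes$neuron), function(x)
    if (length(x) > 1) min(diff(sort(x))) else Inf)))
  expect_gte(isi_min, m$network$sc_params$t_ref - 1e-9)
})

test_that("spike records respect their invariants and survive a text round trip", {
  rec <- get_default_run()$sc
  expect_true(all(rec$spikes$t_ms >= 0 & rec$spikes$t_ms <= rec$t_end))
  expect_equal(rec$spikes$u_mm, rec$positions[rec$spikes$neuron])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spike_record(rec, path)
  back <- read_spike_record(path, t_end = rec$t_end)
  expect_equal(back$spikes$neuron, rec$spikes$neuron)
  expect_equal(back$spikes$t_ms, rec$spikes$t_ms)
  expect_equal(back$layer, "sc")
})
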