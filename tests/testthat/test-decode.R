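make_record <- function(neuron, t_ms, t_end = 400, grid = map_grid()) {
  spike_record("sc", neuron, t_ms, grid, dt = 0.05, t_end = t_end)
}

test_that("a single spike decodes to a step of exactly one spike vector", {
  rec <- make_record(101L, 80)
  traj <- decode_trajectory(rec, zeta = 1.2)
  m <- spike_vector(2.5, zeta = 1.2)
  expect_equal(traj$S_deg[traj$t_ms < 80], rep(0, sum(traj$t_ms < 80)))
  expect_equal(traj$S_deg[traj$t_ms >= 80], rep(m, sum(traj$t_ms >= 80)))
  expect_equal(traj$S_deg[1], 0)
})

test_that("decoding is linear: the trajectory of a merged record is the sum of the parts", {
  a <- make_record(c(50L, 120L), c(30, 90))
  b <- make_record(c(80L, 80L, 150L), c(45, 100, 200))
  ab <- make_record(c(50L, 120L, 80L, 80L, 150L), c(30, 90, 45, 100, 200))
  expect_equal(decode_trajectory(ab)$S_deg,
               decode_trajectory(a)$S_deg + decode_trajectory(b)$S_deg)
})

test_that("the final amplitude conserves the weighted spike count regardless of timing", {
  rec <- get_default_run()$sc
  m <- get_model()
  traj <- decode_trajectory(rec, zeta = m$zeta, N_ref = m$N_ref)
  counts <- spike_counts(rec)
  expected <- sum(spike_vector(rec$positions, zeta = m$zeta, N_ref = m$N_ref) * counts)
  expect_equal(traj$S_deg[nrow(traj)], expected, tolerance = 1e-9)
  # shuffling all spike times leaves the final amplitude untouched
  shuffled <- rec
  shuffled$spikes$t_ms <- rev(400 - shuffled$spikes$t_ms)
  traj2 <- decode_trajectory(shuffled, zeta = m$zeta, N_ref = m$N_ref)
  expect_equal(traj2$S_deg[nrow(traj2)], expected, tolerance = 1e-9)
})

test_that("an empty record decodes to the zero trajectory and the input layer is rejected", {
  empty <- make_record(integer(0), numeric(0))
  traj <- decode_trajectory(empty)
  expect_true(all(traj$S_deg == 0))
  inp <- get_default_run()$input
  expect_error(decode_trajectory(inp), "SC layer")
})

test_that("Savitzky-Golay velocity reproduces polynomial trajectories exactly", {
  t_end <- 300
  rec <- make_record(integer(0), numeric(0), t_end = t_end)
  traj <- decode_trajectory(rec)
  expect_true(all(abs(eye_velocity(traj)$V_degs) < 1e-9))
  ramp <- traj
  ramp$S_deg <- 0.013 * ramp$t_ms   # deg per ms
  v <- eye_velocity(ramp)$V_degs
  expect_equal(v, rep(13, length(v)), tolerance = 1e-9)
  expect_error(eye_velocity(traj, window = 10), "window")
  short <- traj[1:5, ]; attr(short, "dt") <- 1
  class(short) <- class(traj)
  expect_error(eye_velocity(short), "shorter")
})

gauss_traj <- function(R = 12, mu = 120, sd = 15, t_end = 300) {
  t <- seq(0, t_end)
  traj <- structure(data.frame(t_ms = t, S_deg = R * pnorm(t, mu, sd)),
                    class = c("saccade_trajectory", "data.frame"),
                    dt = 1, zeta = 1, N_ref = 500)
  traj
}

test_that("metrics recover the displacement of a Gaussian velocity pulse within 2%", {
  met <- saccade_metrics(eye_velocity(gauss_traj(R = 12)))
  expect_false(met$flagged)
  expect_equal(met$R_deg, 12, tolerance = 0.02)
  expect_equal(met$V_peak_degs, 12 * dnorm(0) / 15 * 1000, tolerance = 0.01)
  expect_equal(met$D_ms, met$offset_ms - met$onset_ms)
})

test_that("a zero trajectory is flagged instead of yielding metrics", {
  met <- saccade_metrics(eye_velocity(decode_trajectory(make_record(integer(0), numeric(0)))))
  expect_true(met$flagged)
  expect_equal(met$R_deg, 0)
  expect_true(is.na(met$D_ms))
})

test_that("a triangular velocity profile yields the closed-form V_peak * D / R of the 5% criterion", {
  # triangle of duration T and peak v: the 5% onset/offset crossings give
  # D = 0.95 T and R_measured = 0.995 R, so V*D/R = 2 * 0.95 / 0.995 = 1.9095
  t <- seq(0, 400)
  T_dur <- 100; v_pk <- 0.3   # deg/ms
  v <- pmax(0, v_pk * (1 - abs(t - 150) / (T_dur / 2)))
  traj <- structure(data.frame(t_ms = t, S_deg = cumsum(v) - v[1]),
                    class = c("saccade_trajectory", "data.frame"),
                    dt = 1, zeta = 1, N_ref = 500)
  met <- saccade_metrics(eye_velocity(traj))
  expect_equal(met$V_peak_degs * met$D_ms / 1000 / met$R_deg,
               2 * 0.95 / 0.995, tolerance = 0.05)
})

test_that("time rescaling leaves the amplitude unchanged and divides the peak velocity", {
  rec <- get_default_run()$sc
  m <- get_model()
  met1 <- saccade_metrics(eye_velocity(decode_trajectory(rec, zeta = m$zeta)))
  stretched <- rec
  stretched$spikes$t_ms <- stretched$spikes$t_ms * 2
  stretched$t_end <- rec$t_end * 2
  met2 <- saccade_metrics(eye_velocity(decode_trajectory(stretched, zeta = m$zeta)))
  expect_equal(met2$R_deg, met1$R_deg, tolerance = 0.02)
  expect_equal(met2$V_peak_degs, met1$V_peak_degs / 2, tolerance = 0.10)
})

test_that("spike densities integrate back to the spike count", {
  expect_true(all(spike_density(numeric(0), 400)$rate_sps == 0))
  one <- spike_density(3, 400, dt = 1, sigma_ms = 4)   # kernel truncated at t = 0
  expect_equal(sum(one$rate_sps) / 1000, 1, tolerance = 1e-3)
  set.seed(42)
  train <- sort(runif(73, 0, 380))
  sd_tr <- spike_density(train, 400)
  expect_equal(sum(sd_tr$rate_sps) / 1000, 73, tolerance = 1e-3)
  # periodic train: plateau at the firing rate for kernels >> ISI
  per <- seq(50, 350, by = 5)   # 200 spk/s
  sd_per <- spike_density(per, 400, sigma_ms = 25)
  mid <- sd_per$rate_sps[sd_per$t_ms > 150 & sd_per$t_ms < 250]
  expect_equal(mean(mid), 200, tolerance = 0.02)
})

test_that("the central cell is the maximal-count neuron with ties broken toward the centre", {
  rec <- make_record(c(90L, 90L, 110L, 110L, 140L), c(10, 20, 30, 40, 50))
  expect_equal(central_cell(rec, u_T = 2.6), 110L)  # tie 90 vs 110, 110 closer to 2.6 mm
  expect_equal(central_cell(rec, u_T = 2.0), 90L)
})

test_that("the saturating main-sequence fit recovers its own parameters", {
  R <- c(2, 5, 8, 11, 15, 19, 24, 30, 37, 45)
  V <- 1637 * (1 - exp(-0.031 * R))
  fit <- fit_main_sequence(R, V)
  expect_equal(fit$V0, 1637, tolerance = 1e-4)
  expect_equal(fit$alpha, 0.031, tolerance = 1e-4)
  # 5% multiplicative noise: parameters within 10%
  set.seed(11)
  Vn <- V * (1 + 0.05 * rnorm(length(V)))
  fitn <- fit_main_sequence(R, Vn)
  expect_equal(fitn$V0, 1637, tolerance = 0.10)
  expect_equal(fitn$alpha, 0.031, tolerance = 0.10)
  # far from saturation the initial slope V0 * alpha equals the data slope
  Rs <- seq(0.1, 1, by = 0.1)
  fit_lin <- fit_main_sequence(Rs, 40 * Rs)
  expect_equal(fit_lin$V0 * fit_lin$alpha, 40, tolerance = 0.02)
  expect_error(fit_main_sequence(c(1, 2), c(10, 20)))
})

test_that("the kinematic slope is the zero-intercept least-squares solution", {
  expect_equal(fit_kinematic_slope(c(3, 7, 21), 2 * c(3, 7, 21))$k, 2)
  set.seed(3)
  R <- runif(12, 2, 40); VD <- 2 * R
  expect_equal(fit_kinematic_slope(R, VD)$k, 2, tolerance = 1e-12)
  expect_error(fit_kinematic_slope(c(0, 0), c(1, 2)), "zero")
})
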