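test_that("canonical HRF has the double-gamma shape", {
  expect_equal(canonical_hrf(0), 0)
  expect_error(canonical_hrf(-1), "t >= 0")
  tt <- seq(0, 32, by = 0.01)
  h <- canonical_hrf(tt)
  # peak close to 5 s (numerical maximization of the default kernel)
  expect_lt(abs(tt[which.max(h)] - 5), 0.2)
  # positive main lobe dominates the undershoot
  expect_gt(sum(h) * 0.01, 0)
  # zero beyond the kernel support
  expect_equal(canonical_hrf(c(33, 40)), c(0, 0))
})

test_that("condition regressors match a direct convolution oracle", {
  set.seed(51)
  tl <- build_run_timeline(block_protocol(), counterbalanced_orders(4))
  reg <- condition_regressor(tl, "c33")
  expect_length(reg, 171)

  # independent oracle: Riemann-sum convolution evaluated at volume times
  onsets <- condition_onsets(tl, "c33")
  dt <- 0.01
  oracle <- vapply(2 * (0:170), function(t) {
    s <- seq(0, 32, by = dt)
    box_at <- function(u) {
      as.numeric(colSums(outer(onsets, u, function(o, uu) uu >= o & uu < o + 16)) > 0)
    }
    sum(canonical_hrf(s) * box_at(t - s) * (t - s >= 0)) * dt
  }, numeric(1))
  expect_lt(max(abs(reg - oracle)), 0.02)

  # linearity: regressor of a condition equals the sum of single-block
  # responses
  p1 <- block_protocol(n_conditions = 2, sequences_per_run = 1, pre_blank = 0,
                       blank_appended = FALSE)
  tl1 <- build_run_timeline(p1, list(c(1L, 2L)))
  # peaks lag block onsets by roughly the HRF peak and decay afterwards
  r1 <- condition_regressor(tl1, "c1")
  t_peak <- 2 * (which.max(r1) - 1)
  expect_gt(t_peak, 4)
  expect_lt(t_peak, 22)
  expect_lt(r1[length(r1)], max(r1) / 4)
  # superposition: a two-block condition regressor is the sum of the
  # single-block responses placed at each onset
  tl2 <- build_run_timeline(tiny_protocol(), list(c(1L, 2L), c(1L, 2L)))
  r2 <- condition_regressor(tl2, "c1", tr = 2)
  single <- function(onset) {
    s <- seq(0, tl2$total_duration - 2, by = 2)
    vapply(s, function(t) {
      u <- seq(0, 32, by = 0.001)
      sum(canonical_hrf(u) * (t - u >= onset & t - u < onset + 8)) * 0.001
    }, numeric(1))
  }
  on <- condition_onsets(tl2, "c1")
  expect_lt(max(abs(r2 - (single(on[1]) + single(on[2])))), 0.02)
})

test_that("simulated nodes follow the forward model", {
  set.seed(52)
  tl <- build_run_timeline(block_protocol(), counterbalanced_orders(4))
  # zero everything: constant at baseline
  quiet <- noise_params(innovation_sd = 0, drift_sd = rep(0, 4))
  y0 <- simulate_node(tl, rep(0, 4), quiet, baseline = 500)
  expect_equal(as.numeric(y0), rep(500, 171))
  # determinism
  set.seed(53); y1 <- simulate_node(tl, c(1, 1.1, 1.2, 1.3))
  set.seed(53); y2 <- simulate_node(tl, c(1, 1.1, 1.2, 1.3))
  expect_identical(y1, y2)
  expect_equal(attr(y1, "truth"), c(1, 1.1, 1.2, 1.3))
})

test_that("ARMA(1,1) noise matches its theoretical lag-1 autocorrelation", {
  a <- 0.3; b <- -0.1
  rho1 <- (1 + a * b) * (a + b) / (1 + 2 * a * b + b^2)
  set.seed(54)
  x <- glasscoh:::arma11_noise(1e4, a, b, 1)
  r1 <- acf(x, plot = FALSE, lag.max = 1)$acf[2]
  expect_lt(abs(r1 - rho1), 0.03)
  # lag-2 decays by the AR coefficient
  r2 <- acf(x, plot = FALSE, lag.max = 2)$acf[3]
  expect_lt(abs(r2 - a * rho1), 0.03)
})

test_that("simulated cohorts have the configured structure", {
  set.seed(55)
  coh <- simulate_cohort(protocol = block_protocol(n_runs = 2),
                         profiles = list(area_profile("V1"),
                                         area_profile("V3")),
                         n_participants = 3, nodes_per_hemi = 2,
                         null_nodes_per_hemi = 1)
  expect_s3_class(coh, "glass_cohort")
  expect_length(coh$participants, 3)
  expect_equal(coh$areas, c("V1", "V3"))
  p1 <- coh$participants[[1]]
  expect_length(p1$timelines, 2)
  expect_equal(dim(p1$areas$V3$Y), c(2 * 171, 6))
  expect_equal(sum(p1$areas$V3$responsive), 4)
  expect_true(all(p1$areas$V3$truth[!p1$areas$V3$responsive, ] == 0))
  expect_true(all(p1$areas$V3$meridian_distance >= 0 &
                    p1$areas$V3$meridian_distance <= 90))
  # V1 profile is flat: all four condition amplitudes equal
  expect_true(all(area_profile("V1")$condition_amplitudes == 1))
  # per-participant truth (profile + jitter) is shared across the area's
  # responsive nodes
  tv1 <- p1$areas$V1$truth[p1$areas$V1$responsive, ]
  expect_true(all(abs(sweep(tv1, 2, tv1[1, ])) < 1e-12))
  # V3 default truth is linear with the 0.153 full-vs-zero difference
  expect_equal(unname(area_profile("V3")$condition_amplitudes),
               1 + 0.153 * (0:3) / 3)
  # built-in full-vs-zero differences per area
  d <- vapply(c("V1", "V2", "V3", "hMT+", "DRA", "VRA"), function(a) {
    amps <- area_profile(a)$condition_amplitudes
    unname(amps[4] - amps[1])
  }, numeric(1))
  expect_equal(unname(d), c(0, 0, 0.153, 0.101, 0.185, 0.246))
})

test_that("behavioral simulation produces consistent event trains", {
  set.seed(56)
  tl <- build_run_timeline(block_protocol(), counterbalanced_orders(4))
  # perfect observer with a fixed lag: every target answered 5 bins later
  tr <- simulate_behavior_run(tl, lag = 0.5, hit_rate = 1,
                              false_alarm_rate = 0)
  expect_length(tr$target_bins, 3420)
  expect_length(tr$condition_bins, 3420)
  targets <- which(tr$target_bins == 1)
  targets <- targets[targets + 5 <= 3420]
  expect_true(all(tr$response_bins[targets + 5] == 1))
  # no responses without hits or false alarms
  tr0 <- simulate_behavior_run(tl, hit_rate = 0, false_alarm_rate = 0)
  expect_equal(sum(tr0$response_bins), 0)
  # expected target count per run is duration x rate x target probability
  set.seed(57)
  counts <- replicate(40, sum(simulate_behavior_run(tl)$target_bins))
  expect_lt(abs(mean(counts) - 342 * 3 / 20), 3 * sd(counts) / sqrt(40))
})
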