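test_that("Legendre drift regressors are the standard polynomials", {
  P <- legendre_regressors(3, 1)
  expect_equal(unname(P[, 1]), c(1, 1, 1))
  expect_equal(unname(P[, 2]), c(-1, 0, 1))
  P4 <- legendre_regressors(171, 3)
  # endpoints of P2 and P3
  expect_equal(unname(P4[c(1, 171), 3]), c(1, 1))
  expect_equal(unname(P4[c(1, 171), 4]), c(-1, 1))
  # discrete orthogonality approaches the continuous one as n grows
  Pn <- legendre_regressors(1000, 3)
  G <- crossprod(Pn) / 1000
  offdiag <- G[row(G) != col(G)]
  expect_true(all(abs(offdiag) < 0.01))
  expect_error(legendre_regressors(3, 3), "at least")
})

test_that("design matrix has the protocol's shape and bookkeeping", {
  proto <- block_protocol()
  set.seed(61)
  tls <- lapply(1:12, function(r) {
    build_run_timeline(proto, counterbalanced_orders(4))
  })
  mot <- lapply(1:12, function(r) matrix(rnorm(171 * 6), 171, 6))
  d <- build_design_matrix(tls, mot, proto)
  expect_equal(dim(d$X), c(2016, 58))
  expect_true(all(lengths(d$run_rows) == 168))
  expect_equal(length(d$condition_cols), 4)
  expect_equal(length(d$drift_cols), 48)
  expect_equal(length(d$motion_cols), 6)
  # Legendre columns vanish outside their own run
  for (r in c(1, 7)) {
    cols <- d$drift_cols[(r - 1) * 4 + 1:4]
    other <- setdiff(seq_len(2016), d$run_rows[[r]])
    expect_true(all(d$X[other, cols] == 0))
  }
  expect_false(any(colSums(abs(d$X)) == 0))

  # single run: 168 x 14; censor 0 keeps all volumes
  d1 <- build_design_matrix(tls[1], mot[1], proto)
  expect_equal(dim(d1$X), c(168, 14))
  proto0 <- block_protocol(censor_volumes_per_run = 0)
  d0 <- build_design_matrix(tls, mot, proto0)
  expect_equal(nrow(d0$X), 12 * 171)

  expect_error(
    build_design_matrix(tls[1], list(matrix(0, 10, 6)), proto),
    "n_volumes x 6")
})

test_that("ARMA(1,1) estimation recovers known generators", {
  set.seed(62)
  # white noise: both coefficients near zero
  est0 <- estimate_arma11(rnorm(1e4))
  expect_lt(abs(est0["a"]), 0.05)
  expect_lt(abs(est0["b"]), 0.05)
  # AR(1)
  y <- as.numeric(arima.sim(list(ar = 0.3), 1e4))
  est1 <- estimate_arma11(y)
  expect_lt(abs(est1["a"] - 0.3), 0.05)
  # full ARMA(1,1), cross-checked against stats::arima on the same series
  z <- as.numeric(arima.sim(list(ar = 0.5, ma = 0.3), 5e3))
  est2 <- estimate_arma11(z)
  ref <- coef(arima(z, order = c(1, 0, 1), include.mean = FALSE))
  expect_lt(abs(est2["a"] - ref["ar1"]), 0.05)
  expect_lt(abs(est2["b"] - ref["ma1"]), 0.05)
  # run boundaries are respected (estimates pooled across segments)
  est3 <- estimate_arma11(y, run_rows = split(1:1e4, rep(1:10, each = 1e3)))
  expect_lt(abs(est3["a"] - 0.3), 0.05)
  # degenerate input falls back with a warning
  expect_warning(est4 <- estimate_arma11(rep(1, 100)), "constant")
  expect_equal(unname(est4), c(0, 0))
  expect_error(estimate_arma11(rnorm(10)), "at least 50")
})

test_that("noiseless GLM fits are exact and psc conversion is scale free", {
  proto <- block_protocol(n_runs = 2)
  set.seed(63)
  tls <- lapply(1:2, function(r) {
    build_run_timeline(proto, counterbalanced_orders(4))
  })
  mot <- lapply(1:2, function(r) matrix(rnorm(171 * 6), 171, 6))
  d <- build_design_matrix(tls, mot, proto)
  amps <- c(c0 = 1, c33 = 1.051, c66 = 1.102, c100 = 1.153)
  quiet <- noise_params(innovation_sd = 0, drift_sd = rep(0, 4))
  y <- unlist(lapply(tls, function(tl) {
    simulate_node(tl, amps, quiet, baseline = 1000)
  }))
  fit <- fit_node_glm(y, d, whiten = FALSE)
  # noiseless identifiability: psc equals the generating amplitudes
  expect_equal(betas_to_psc(fit), amps, tolerance = 1e-10)
  expect_equal(fit$baseline_mean, 1000, tolerance = 1e-10)

  # rescaling the signal rescales betas and baseline, leaving psc fixed
  fit_k <- fit_node_glm(3 * y, d, whiten = FALSE)
  expect_equal(coef(fit_k), 3 * coef(fit), tolerance = 1e-9)
  expect_equal(betas_to_psc(fit_k), betas_to_psc(fit), tolerance = 1e-9)

  # adding a constant moves only the drift intercepts
  fit_c <- fit_node_glm(y + 50, d, whiten = FALSE)
  expect_equal(coef(fit_c)[d$condition_cols], coef(fit)[d$condition_cols],
               tolerance = 1e-9)
  expect_equal(fit_c$baseline_mean, 1050, tolerance = 1e-9)

  # whitening with (a, b) = (0, 0) is exactly ordinary least squares
  W <- glasscoh:::whiten_series(cbind(y), 0, 0,
                                list(seq_along(y)))
  expect_identical(as.numeric(W), as.numeric(y))
})

test_that("whitened fits agree with OLS up to noise efficiency", {
  proto <- block_protocol(n_runs = 2)
  set.seed(64)
  tls <- lapply(1:2, function(r) {
    build_run_timeline(proto, counterbalanced_orders(4))
  })
  d <- build_design_matrix(tls, NULL, proto)
  amps <- c(1, 1.2, 1.4, 1.6)
  y <- unlist(lapply(tls, function(tl) {
    simulate_node(tl, amps, noise_params(), baseline = 1000)
  }))
  f_w <- fit_node_glm(y, d, whiten = TRUE)
  f_o <- fit_node_glm(y, d, whiten = FALSE)
  expect_lt(max(abs(betas_to_psc(f_w) - betas_to_psc(f_o))), 0.2)
  expect_true(all(abs(f_w$arma) < 0.95))
  res <- node_responsiveness(f_w)
  expect_gt(res$t, 2)
  expect_lt(res$p, 0.05)
})

test_that("FDR node selection follows Benjamini-Hochberg within hemisphere", {
  # hand-executed BH at q = 0.001 on {1e-4, 2e-4, 0.5}:
  # 1e-4 <= (1/3) q and 2e-4 <= (2/3) q pass, 0.5 fails
  sel <- select_responsive_nodes(c(1e-4, 2e-4, 0.5), rep("lh", 3), q = 0.001)
  expect_equal(sel, c(TRUE, TRUE, FALSE))
  expect_equal(select_responsive_nodes(rep(1, 5), rep("lh", 5)),
               rep(FALSE, 5))
  # correction is independent across hemispheres
  p <- c(1e-5, 0.9, 0.9, 1e-5)
  sel2 <- select_responsive_nodes(p, c("lh", "lh", "rh", "rh"))
  expect_equal(sel2, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("under the null the selected fraction respects the FDR level", {
  set.seed(65)
  # one-sided p-values of pure-null nodes are uniform
  n_rep <- 200
  false_sel <- replicate(n_rep, {
    p <- runif(50)
    mean(select_responsive_nodes(p, rep("lh", 50), q = 0.05))
  })
  expect_lte(mean(false_sel), 0.05 + 2 * sd(false_sel) / sqrt(n_rep))
})

test_that("area response matrices average nodes then center participants", {
  one <- matrix(c(1, 2, 3, 4), 1)
  m <- area_coherence_response(list(one, one + 1), area = "V3")
  expect_equal(unclass(m),
               matrix(rep(c(-1.5, -0.5, 0.5, 1.5), each = 2), 2),
               ignore_attr = TRUE)
  expect_equal(rowSums(m), c(0, 0))
  # averaging identical nodes is the identity
  two <- rbind(one, one)
  m2 <- area_coherence_response(list(two, two))
  expect_equal(unclass(m2)[1, ], c(-1.5, -0.5, 0.5, 1.5),
               ignore_attr = TRUE)
  expect_error(area_coherence_response(list(one, one[0, , drop = FALSE])),
               "no selected nodes")
})
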