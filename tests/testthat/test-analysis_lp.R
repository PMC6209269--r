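test_that("projection estimator: rod limit and freely jointed limit", {
  # rigid rod: lp equals the contour length exactly
  ch <- make_chain(100, straight = TRUE)
  expect_equal(chain_lp(list(ch$frame), ch$topo, 1), 99)
  expect_error(chain_lp(list(), ch$topo, 1), "frame")
  expect_error(chain_lp(list(ch$frame), make_topology(2), 1), "2 bonds")
  # freely jointed: lp -> b
  s <- sample_wlc_ensemble(k_bend = 0, T = 1, n_bonds = 50, n_chains = 4000,
                           seed = 21)
  lp <- chain_lp(s$frames, s$topo, 1)
  terms <- polybundle:::chain_lp_terms(s$frames, s$topo, 1)
  se <- sd(terms$proj / mean(terms$b1)) / sqrt(length(s$frames))
  expect_lt(abs(lp - 1), 3 * se)
})

test_that("projection estimator matches the independent-angle closed form", {
  s <- sample_wlc_ensemble(k_bend = 5, T = 1, n_bonds = 50, n_chains = 4000,
                           seed = 22)
  lp <- chain_lp(s$frames, s$topo, 1)
  lp_th <- wlc_lp_theory(s$cos_gamma, 50)
  terms <- polybundle:::chain_lp_terms(s$frames, s$topo, 1)
  se <- sd(terms$proj / mean(terms$b1)) / sqrt(length(s$frames))
  expect_lt(abs(lp - lp_th), 3 * se)
  # lp never exceeds the contour length
  expect_lte(lp, 50)
})

test_that("unwrapping removes periodic images before the projection", {
  ch <- make_chain(20, straight = TRUE)
  pos <- ch$frame$positions
  box <- 6
  wrapped <- pos - box * floor(pos / box)       # rod crosses the box
  fr <- make_frame(wrapped, box = box, periodic = TRUE)
  expect_equal(chain_lp(list(fr), ch$topo, 1), 19, tolerance = 1e-9)
})

test_that("bundle_lp is the mean of embedded per-chain values", {
  b <- make_bundle(bundle_spec(4, 30))
  pr <- bundle_lp(list(b$frame), b$topo)
  expect_equal(pr$lp_bundle, mean(pr$lp_chain))
  expect_equal(pr$lp_chain, rep(29, 4))  # bundle of identical rigid rods
  expect_true(is.na(pr$lpr))
  pr2 <- bundle_lp(list(b$frame), b$topo, lp_ref = 29)
  expect_equal(pr2$lpr, 1)               # N-fold rod bundle vs rod reference
})

test_that("crossover fit recovers the plateau and is exact at N = 1", {
  # algebraic identity at N = 1 for any plateau
  expect_equal(crossover_lpr(1, 5), 1)
  expect_equal(crossover_lpr(1, 123.4), 1)
  s <- make_synthetic_curves("crossover-eq4", params = list(lpr_inf = 5))
  f <- fit_crossover(s$N, s$lpr)
  expect_true(f$converged)
  expect_equal(f$lpr_inf, 5, tolerance = 1e-8)
  expect_equal(crossover_lpr(1, f$lpr_inf), 1)
  # noisy recovery: within 10% of truth in >= 90% of 20 seeds
  ok <- 0
  for (sd_ in 1:20) {
    sn <- make_synthetic_curves("crossover-eq4", params = list(lpr_inf = 5),
                                noise_sd = 0.25, seed = sd_)
    fn <- fit_crossover(sn$N, sn$lpr)
    if (fn$converged && abs(fn$lpr_inf - 5) / 5 < 0.1) ok <- ok + 1
  }
  expect_gte(ok, 18)
  # degenerate data flagged, not silently fitted
  expect_false(fit_crossover(c(1, 2, 4), c(2, 2, 2))$converged)
  expect_error(fit_crossover(c(1, 1, 1), c(1, 2, 3)), "distinct")
})

test_that("low-T linear fit recovers intercept and slope", {
  d <- data.frame(T = seq(0.02, 0.18, by = 0.02))
  d$lp <- 40 - 12 * d$T
  f <- fit_lowT(d, t_max = 0.2)
  expect_equal(f$lp0, 40, tolerance = 1e-10)
  expect_equal(f$A, 12, tolerance = 1e-10)
  expect_error(fit_lowT(d[1, , drop = FALSE]), "fewer than 3")
  # full quasi-harmonic data restricted to T <= 0.1 TD: intercept within 1%
  dq <- data.frame(T = seq(0.01, 0.1, by = 0.01))
  dq$lp <- quasiharmonic_lp(dq$T, 40, 12, TD = 1)
  fq <- fit_lowT(dq, t_max = 0.1)
  expect_lt(abs(fq$lp0 - 40) / 40, 0.01)
})

test_that("quasi-harmonic fit: self-consistency, recovery, masking", {
  s <- make_synthetic_curves("lowT-linear",
                             params = list(lp0 = 40, A = 12, TD = 0.5))
  f <- fit_quasiharmonic(s)
  expect_true(f$converged)
  expect_equal(f$lp0, 40, tolerance = 1e-6)
  expect_equal(f$A, 12, tolerance = 1e-6)
  expect_equal(f$TD, 0.5, tolerance = 1e-6)
  # masking contract: points at/above tm are excluded and reported
  fm <- fit_quasiharmonic(s, tm = 1.0)
  expect_identical(fm$excluded, which(s$T >= 1.0))
  expect_true(fm$converged)
  # 5%-of-lp0 noise, 20 seeds: lp0 within 5% always here; A within 25% in >= 80%
  okl <- oka <- 0
  for (sd_ in 1:20) {
    sn <- make_synthetic_curves("lowT-linear",
                                params = list(lp0 = 40, A = 12, TD = 0.5),
                                noise_sd = 2, seed = sd_)
    fn <- fit_quasiharmonic(sn)
    if (fn$converged && abs(fn$lp0 - 40) / 40 < 0.05) okl <- okl + 1
    if (fn$converged && abs(fn$A - 12) / 12 < 0.25) oka <- oka + 1
  }
  expect_gte(okl, 16)
  expect_gte(oka, 16)
})

test_that("scaling check covers the stated exponent", {
  n <- c(1, 2, 3, 4, 5)
  r <- scaling_check(n, n^2, 2)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_true(r$pass)
  set.seed(31)
  y <- 10 * n^-2 * exp(rnorm(5, 0, 0.05))
  r2 <- scaling_check(n, y, -2)
  expect_true(r2$pass)
  # small-N limit of the crossover relation approaches slope 2
  nn <- c(1, 1.5, 2)
  lpr <- crossover_lpr(nn, 1e4)
  r3 <- scaling_check(nn, lpr, 2)
  expect_equal(r3$slope, 2, tolerance = 1e-2)
  expect_error(scaling_check(n, c(-1, 1, 1, 1, 1), 2), "positive")
})
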