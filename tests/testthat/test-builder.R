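test_that("make_chain geometry: straight rods and self-avoiding walks", {
  ch <- make_chain(5, straight = TRUE)
  re <- ch$frame$positions[5, ] - ch$frame$positions[1, ]
  expect_equal(sqrt(sum(re^2)), 4)
  big <- make_chain(100, straight = TRUE)
  expect_equal(nrow(big$topo$bonds), 99)
  expect_equal(nrow(big$topo$angles), 98)
  # random variant keeps nonbonded beads at >= 0.9 sigma over several seeds
  for (s in 1:5) {
    rw <- make_chain(25, straight = FALSE, seed = s)
    d <- as.matrix(dist(rw$frame$positions))
    nb <- abs(row(d) - col(d)) > 1
    expect_true(min(d[nb & upper.tri(d)]) >= 0.9)
    # bonds at sigma
    expect_equal(d[cbind(1:24, 2:25)], rep(1, 24), tolerance = 1e-12)
  }
})

test_that("make_bundle fills a hexagonal lattice in shells", {
  # N = 1 reduces to the straight chain
  b1 <- make_bundle(bundle_spec(1, 10))
  expect_equal(b1$frame$positions, make_chain(10)$frame$positions,
               ignore_attr = TRUE)
  # N = 7: center + full first shell at the lattice spacing
  sp <- 2^(1 / 6)
  b7 <- make_bundle(bundle_spec(7, 5))
  ax <- unique(b7$frame$positions[, 1:2])
  r <- sqrt(rowSums(ax^2))
  expect_equal(sort(r), c(0, rep(sp, 6)), tolerance = 1e-9)
  # Np = N * L
  b8 <- make_bundle(bundle_spec(8, 100))
  expect_equal(b8$topo$n_beads, 800)
})

test_that("solution spec inverts the volume-fraction definition", {
  spec <- solution_spec(50, 100, 2.61e-3)
  expect_equal(spec$box_side, (50 * 100 * (pi / 6) / 2.61e-3)^(1 / 3),
               tolerance = 1e-12)
  expect_equal(spec$box_side, 100.1, tolerance = 1e-3)
  # realized phi equals spec phi identically
  phi_real <- 50 * 100 * (pi / 6) / spec$box_side^3
  expect_equal(phi_real, 2.61e-3, tolerance = 1e-12)
  expect_error(solution_spec(phi = 0.6))
})

test_that("make_solution places non-overlapping chains, same topology across seeds", {
  spec <- solution_spec(6, 12, 5e-3)
  s1 <- make_solution(spec, seed = 1)
  s2 <- make_solution(spec, seed = 2)
  expect_identical(s1$topo$chain_id, s2$topo$chain_id)
  expect_false(identical(s1$frame$positions, s2$frame$positions))
  # no interchain overlap below one sigma (contact count at 0.999)
  cnt <- polybundle:::cpp_contact_counts(s1$frame$positions,
                                         s1$frame$box, TRUE,
                                         s1$topo$chain_id, 0.999)
  expect_equal(sum(cnt), 0)
})

test_that("WLC sampler matches its quadrature oracle", {
  # freely jointed: symmetric density
  expect_equal(wlc_cos_gamma(0), 0)
  # stiff limit 1 - T/k
  expect_equal(wlc_cos_gamma(100), 1 - 1 / 100, tolerance = 1e-6)
  # quadrature equals the closed form coth(K) - 1/K
  for (K in c(0.5, 2, 10))
    expect_equal(wlc_cos_gamma(K), 1 / tanh(K) - 1 / K, tolerance = 1e-9)
  # sampled mean bond correlation within 3 standard errors of quadrature
  s <- sample_wlc_ensemble(k_bend = 5, T = 1, n_bonds = 30, n_chains = 2000,
                           seed = 9)
  cg <- vapply(s$frames, function(fr) {
    b <- diff(fr$positions)
    mean(rowSums(b[-nrow(b), ] * b[-1, ]))
  }, numeric(1))
  se <- sd(cg) / sqrt(length(cg))
  expect_lt(abs(mean(cg) - s$cos_gamma), 3 * se)
  # unit bonds
  b <- diff(s$frames[[1]]$positions)
  expect_equal(sqrt(rowSums(b^2)), rep(1, 30), tolerance = 1e-12)
})

test_that("synthetic curves carry their ground truth", {
  c4 <- make_synthetic_curves("crossover-eq4", params = list(lpr_inf = 5))
  expect_equal(c4$lpr[c4$N == 1], 1)          # crossover is exact at N = 1
  expect_equal(attr(c4, "truth")$lpr_inf, 5)
  cm <- make_synthetic_curves("melting-sigmoid", params = list(t0 = 0.6))
  expect_equal(attr(cm, "truth")$tm, 0.6)
  cl <- make_synthetic_curves("lowT-linear", params = list(lp0 = 40, A = 12))
  expect_equal(cl$lp[1], 40 - 12 * cl$T[1])   # TD = 0: exact line
  expect_equal(quasiharmonic_lp(0, 40, 12, 0.5), 40)
  # noise is reproducible by seed
  n1 <- make_synthetic_curves("crossover-eq4", noise_sd = 0.1, seed = 3)
  n2 <- make_synthetic_curves("crossover-eq4", noise_sd = 0.1, seed = 3)
  expect_identical(n1$lpr, n2$lpr)
})

test_that("builders emit frames that pass model validation", {
  p <- model_params()
  for (sys in list(make_bundle(bundle_spec(4, 10)),
                   make_chain(12, straight = FALSE, seed = 2),
                   make_solution(solution_spec(4, 10, 5e-3), seed = 3))) {
    e <- compute_energies(sys$frame, sys$topo, p)   # no overextension error
    expect_true(is.finite(e$e_pot))
  }
})
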