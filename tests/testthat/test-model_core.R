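test_that("parameter validation enforces the model invariants", {
  expect_s3_class(model_params(), "pb_params")
  expect_error(model_params(r_cut = 1.1), "r_cut")
  expect_error(model_params(r_shift = 1.5), "r_shift")
  expect_error(model_params(epsilon = -1))
})

test_that("force-shifted pair potential matches its closed form and vanishes at the cutoff", {
  p <- model_params()
  # cutoff continuity, forced by the shift construction
  at_rc <- pair_energy_force(2.5, p)
  expect_identical(at_rc$energy, 0)
  expect_identical(at_rc$force, 0)
  # closed-form oracle at the LJ minimum: shifted value, not -epsilon
  r_min <- 2^(1 / 6)
  expect_equal(pair_energy_force(r_min, p)$energy, ref_shifted_lj(r_min),
               tolerance = 1e-12)
  expect_equal(ref_shifted_lj(r_min), -0.92996, tolerance = 1e-5)
  # energy/force grid agreement with the independent expression
  r <- seq(0.9, 3.0, by = 0.07)
  expect_equal(pair_energy_force(r, p)$energy, ref_shifted_lj(r),
               tolerance = 1e-12)
  expect_error(pair_energy_force(0, p), "invalid geometry")
  expect_error(pair_energy_force(-1, p), "invalid geometry")
})

test_that("pair force is the central finite difference of the energy", {
  p <- model_params(epsilon = 1.3, k_bend = 11)
  set.seed(4)
  r <- runif(50, 0.85, 2.49)
  f_ana <- pair_energy_force(r, p)$force
  f_num <- -vapply(r, function(ri)
    num_deriv(function(x) pair_energy_force(x, p)$energy, ri), numeric(1))
  expect_equal(f_ana, f_num, tolerance = 1e-6)
})

test_that("FENE bond matches its closed form, diverges at R0, errors beyond", {
  p <- model_params()
  at0 <- fene_energy_force(0, p)
  expect_identical(at0$energy, 0)
  expect_identical(at0$force, 0)
  # half extension: -(30 * 1.5^2 / 2) * log(1 - 0.25)
  expect_equal(fene_energy_force(0.75, p)$energy, -33.75 * log(0.75),
               tolerance = 1e-12)
  expect_equal(-33.75 * log(0.75), 9.70927, tolerance = 1e-5)
  expect_error(fene_energy_force(1.5, p), "overextension")
  # force vs finite differences inside the domain
  set.seed(5)
  r <- runif(40, 0.2, 1.4)
  f_num <- -vapply(r, function(ri)
    num_deriv(function(x) fene_energy_force(x, p)$energy, ri), numeric(1))
  expect_equal(fene_energy_force(r, p)$force, f_num, tolerance = 1e-6)
  # monotone in extension
  e <- fene_energy_force(seq(0.1, 1.4, by = 0.1), p)$energy
  expect_true(all(diff(e) > 0))
  # nonzero r_shift recovers the offset form
  ps <- model_params(r_shift = 0.2)
  expect_equal(fene_energy_force(0.2 + 0.75, ps)$energy, -33.75 * log(0.75),
               tolerance = 1e-12)
})

test_that("bending term is kbend(1 + cos theta) with exact gradients", {
  p <- model_params(k_bend = 7)
  collinear <- bend_energy_force(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2), p)
  expect_equal(collinear$energy, 0, tolerance = 1e-14)
  right <- bend_energy_force(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), p)
  expect_equal(right$energy, 7, tolerance = 1e-12)
  expect_error(bend_energy_force(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), p),
               "invalid geometry")
  # gradient check on random triples
  set.seed(6)
  for (k in 1:100) {
    tri <- matrix(rnorm(9), 3, 3)
    ana <- bend_energy_force(tri[1, ], tri[2, ], tri[3, ], p)
    f_ana <- rbind(ana$f_i, ana$f_j, ana$f_k)
    f_num <- matrix(0, 3, 3)
    for (b in 1:3) for (d in 1:3) {
      f_num[b, d] <- -num_deriv(function(x) {
        tt <- tri; tt[b, d] <- x
        bend_energy_force(tt[1, ], tt[2, ], tt[3, ], p)$energy
      }, tri[b, d])
    }
    expect_equal(f_ana, f_num, tolerance = 1e-5)
  }
})

test_that("energy decomposition splits pair terms by chain and respects the cutoff", {
  p <- model_params()
  # two isolated beads on different chains exactly at the cutoff
  topo2 <- make_topology(c(1, 1))
  fr2 <- make_frame(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  e2 <- compute_energies(fr2, topo2, p)
  expect_identical(e2$e_pair_inter, 0)
  # straight chain of 5 beads at bond length sigma has zero bending energy
  ch <- make_chain(5, straight = TRUE)
  e5 <- compute_energies(ch$frame, ch$topo, p)
  expect_equal(e5$e_bend, 0, tolerance = 1e-14)
  expect_identical(e5$e_pair_inter, 0)
  # inter + intra equals the chain-blind total
  sys <- random_two_chain_frame(L = 12, seed = 8)
  eb <- compute_energies(sys$frame, sys$topo, p)
  # recompute with all beads labeled as one chain but identical bond list
  topo_merged <- sys$topo
  topo_merged$chain_id <- rep(1L, 24)
  em <- compute_energies(sys$frame, topo_merged, p)
  expect_equal(eb$e_pair_inter + eb$e_pair_intra,
               em$e_pair_inter + em$e_pair_intra, tolerance = 1e-12)
  # overextended bond raises
  bad <- make_frame(rbind(c(0, 0, 0), c(1.6, 0, 0)))
  expect_error(compute_energies(bad, make_topology(2), p), "overextension")
})

test_that("cell-list energies are bit-identical to the all-pairs loop", {
  p <- model_params()
  for (s in 1:10) {
    sys <- random_two_chain_frame(L = 15, box = 8, seed = 100 + s)
    ea <- compute_energies(sys$frame, sys$topo, p, method = "auto")
    eb <- compute_energies(sys$frame, sys$topo, p, method = "brute")
    expect_identical(ea$e_pair_inter, eb$e_pair_inter)
    expect_identical(ea$e_pair_intra, eb$e_pair_intra)
    expect_identical(ea$e_fene, eb$e_fene)
  }
})

test_that("whole-system forces agree with finite differences of the total energy", {
  p <- model_params(k_bend = 9)
  sys <- random_two_chain_frame(L = 8, box = 10, seed = 17)
  fr <- sys$frame
  e0 <- compute_energies(fr, sys$topo, p)
  h <- 1e-5
  set.seed(18)
  for (k in 1:10) {
    b <- sample(16, 1); d <- sample(3, 1)
    ep <- em <- fr
    ep$positions[b, d] <- ep$positions[b, d] + h
    em$positions[b, d] <- em$positions[b, d] - h
    f_num <- -(compute_energies(ep, sys$topo, p)$e_pot -
                 compute_energies(em, sys$topo, p)$e_pot) / (2 * h)
    expect_equal(e0$forces[b, d], f_num, tolerance = 1e-5)
  }
})

test_that("topology construction gives linear chains with interior angles only", {
  topo <- make_topology(c(100, 5))
  expect_equal(topo$n_beads, 105)
  expect_equal(nrow(topo$bonds), 99 + 4)
  expect_equal(nrow(topo$angles), 98 + 3)
  expect_true(all(table(c(topo$bonds)) <= 2))  # each bead in <= 2 bonds
  expect_equal(topo$chain_id[101], 2L)
})
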