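test_that("quench schedule arithmetic and target track", {
  sch <- quench_schedule(2.0, 0.1, 1e-4)
  expect_equal(sch$n_steps, 19000L)
  expect_error(quench_schedule(0.1, 2.0, 1e-4))
  expect_error(quench_schedule(2.0, 0.1, 0))
  # thermostat target at the half-way step: (T_start + T_end)/2 +/- rate
  b <- make_bundle(bundle_spec(1, 5))
  sch2 <- quench_schedule(1.0, 0.5, 1e-3)
  q <- run_quench(b$frame, b$topo, model_params(), sch2, seed = 2,
                  sample_every = 50)
  half <- q$series[which.min(abs(q$series$step - sch2$n_steps / 2)), ]
  expect_equal(half$T_target, 0.75, tolerance = 2 * 1e-3 / 0.75)
  expect_equal(q$series$T_target[nrow(q$series)], 0.5, tolerance = 1e-9)
})

test_that("a single isolated bead at rest does not move", {
  topo <- make_topology(1)
  fr <- make_frame(matrix(c(1, 2, 3), 1, 3))
  out <- velocity_verlet_step(fr, topo, model_params())
  expect_identical(out$positions, fr$positions)
})

test_that("a straight stiff chain at T -> 0 stays straight", {
  p <- model_params(k_bend = 40)
  ch <- make_chain(10, straight = TRUE)
  res <- run_nvt(ch$frame, ch$topo, p, T = 1e-10, n_steps = 2000,
                 sample_every = 200, seed = 3, init_vel = FALSE)
  expect_true(all(res$series$e_bend < 1e-8))
})

test_that("run_nvt validates inputs and reproduces itself bit-for-bit", {
  b <- make_bundle(bundle_spec(2, 8))
  p <- model_params()
  expect_error(run_nvt(b$frame, b$topo, p, T = 0.5, n_steps = 0),
               "n_steps")
  r1 <- run_nvt(b$frame, b$topo, p, T = 0.3, n_steps = 1500,
                sample_every = 100, seed = 11)
  r2 <- run_nvt(b$frame, b$topo, p, T = 0.3, n_steps = 1500,
                sample_every = 100, seed = 11)
  expect_identical(r1$frame$positions, r2$frame$positions)
  expect_identical(r1$frame$velocities, r2$frame$velocities)
  r3 <- run_nvt(b$frame, b$topo, p, T = 0.3, n_steps = 1500,
                sample_every = 100, seed = 12)
  expect_false(identical(r1$frame$positions, r3$frame$positions))
})

test_that("a cold two-chain bundle stays laterally bound", {
  b <- make_bundle(bundle_spec(2, 20))
  r <- run_nvt(b$frame, b$topo, model_params(k_bend = 7), T = 0.1,
               n_steps = 20000, sample_every = 200, seed = 13)
  expect_true(mean(r$series$e_pair_inter) < 0)
})

test_that("integration failure carries the step index", {
  # two bonded beads with huge opposing velocities overextend the bond
  topo <- make_topology(2)
  fr <- make_frame(rbind(c(0, 0, 0), c(1, 0, 0)),
                   rbind(c(-200, 0, 0), c(200, 0, 0)))
  expect_error(run_nvt(fr, topo, model_params(), T = 0.1, n_steps = 100,
                       sample_every = 10, seed = 1, init_vel = FALSE),
               "integration failure at step")
})
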