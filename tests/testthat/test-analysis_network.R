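test_that("contact graph: parallel chains connect, distant chains do not", {
  L <- 20
  z <- seq_len(L) - 1
  near <- make_frame(rbind(cbind(0, 0, z), cbind(1.1, 0, z)))
  topo <- make_topology(c(L, L))
  cg <- build_contact_graph(near, topo, r_contact = 1.5, m_contact = 3)
  expect_equal(nrow(cg$edges), 1)
  expect_gte(cg$edges$weight[1], 20)
  far <- make_frame(rbind(cbind(0, 0, z), cbind(5, 0, z)))
  expect_equal(nrow(build_contact_graph(far, topo)$edges), 0)
})

test_that("contact counts equal the brute-force oracle on random frames", {
  for (s in 1:10) {
    sys <- random_two_chain_frame(L = 12, box = 7, seed = 300 + s)
    cg <- build_contact_graph(sys$frame, sys$topo, r_contact = 1.5,
                              m_contact = 1)
    w <- if (nrow(cg$edges)) sum(cg$edges$weight) else 0
    expect_equal(w, brute_contact_count(sys$frame$positions, 7,
                                        sys$topo$chain_id, 1.5))
  }
})

test_that("local cross sections see the constructed bundle", {
  b7 <- make_bundle(bundle_spec(7, 20))
  cs <- local_cross_section(b7$frame, b7$topo, bead = 10, r_loc = 10)
  expect_equal(cs$local_n, 7)
  # diameter formula vs direct max-extent on the ideal lattice: the
  # disk-radius relation overestimates a 7-site hexagon by ~21%
  direct <- 2 * 2^(1 / 6) + 1
  expect_lt(abs(cs$diameter - direct) / direct, 0.25)
  # isolated single chain: one chain, diameter = sigma
  ch <- make_chain(10, straight = TRUE)
  cs1 <- local_cross_section(ch$frame, ch$topo, bead = 5)
  expect_equal(cs1$local_n, 1)
  expect_equal(cs1$diameter, 1)
  # end beads are skipped
  expect_null(local_cross_section(ch$frame, ch$topo, bead = 1))
})

test_that("network statistics: ideal bundles and fiber-wise averaging", {
  b8 <- make_bundle(bundle_spec(8, 20))
  ns <- network_stats(b8$frame, b8$topo)
  expect_equal(ns$mean_n, 8)
  expect_equal(ns$sd_n, 0)
  expect_equal(ns$n_fibers, 1)
  # two disjoint ideal bundles of equal length: equal-weight fiber average
  b4 <- make_bundle(bundle_spec(4, 20))
  pos <- rbind(b4$frame$positions,
               sweep(b8$frame$positions, 2, c(50, 0, 0), `+`))
  topo <- make_topology(rep(20L, 12))
  ns2 <- network_stats(make_frame(pos), topo)
  expect_equal(ns2$mean_n, 6)
  expect_equal(ns2$n_fibers, 2)
  # diameter grows with N on constructed bundles
  db <- vapply(c(2, 4, 8), function(N)
    network_stats(make_bundle(bundle_spec(N, 20))$frame,
                  make_topology(rep(20L, N)))$db_mean, numeric(1))
  expect_true(all(diff(db) > 0))
})

test_that("statistics are invariant under rotation, translation and rewrapping", {
  b <- make_bundle(bundle_spec(3, 15))
  ns0 <- network_stats(b$frame, b$topo)
  # proper rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos_rt <- sweep(b$frame$positions %*% t(R), 2, c(3, -2, 11), `+`)
  ns1 <- network_stats(make_frame(pos_rt), b$topo)
  expect_equal(ns1$mean_n, ns0$mean_n)
  expect_equal(ns1$db_mean, ns0$db_mean, tolerance = 1e-9)
  # periodic rewrapping
  box <- 40
  wrapped <- b$frame$positions - box * floor(b$frame$positions / box)
  ns2 <- network_stats(make_frame(wrapped, box = box, periodic = TRUE),
                       b$topo)
  expect_equal(ns2$mean_n, ns0$mean_n)
  expect_equal(ns2$db_mean, ns0$db_mean, tolerance = 1e-9)
})
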