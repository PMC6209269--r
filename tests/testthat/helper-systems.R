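# Shared fixtures and numerical utilities for the suite.

# central finite difference of a scalar function
num_deriv <- function(f, x, h = 1e-5) (f(x + h) - f(x - h)) / (2 * h)

# independent closed-form evaluation of the force-shifted LJ energy,
# written out from first principles (the oracle for pair_energy_force)
ref_shifted_lj <- function(r, eps = 1, s = 1, rc = 2.5) {
  ulj <- function(r) 4 * eps * ((s / r)^12 - (s / r)^6)
  dulj <- function(r) 4 * eps * (-12 * s^12 / r^13 + 6 * s^6 / r^7)
  ifelse(r >= rc, 0, ulj(r) - ulj(rc) - (r - rc) * dulj(rc))
}

# two random-walk chains dropped in a periodic box (valid pb_frame + topo)
random_two_chain_frame <- function(L = 15, box = 8, seed = 1) {
  set.seed(seed)
  pos <- rbind(polybundle:::random_walk_chain(L),
               sweep(polybundle:::random_walk_chain(L), 2,
                     stats::runif(3, 0, box), `+`))
  list(topo = make_topology(c(L, L)),
       frame = make_frame(pos, box = box, periodic = TRUE))
}

# brute-force interchain contact count in plain R (minimum image)
brute_contact_count <- function(pos, box, cid, r_contact) {
  n <- nrow(pos)
  cnt <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (cid[i] == cid[j]) next
    d <- pos[i, ] - pos[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) < r_contact) cnt <- cnt + 1
  }
  cnt
}
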