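#' Bundle specification
#'
#' @param n_chains Number of chains N (the melting/rigidity studies use
#'   N in 1, 2, 3, 4, 5, 8, 10, 16, 32; any integer >= 1 is allowed).
#' @param chain_length Beads per chain L (>= 3 so at least one angle exists).
#' @param lattice_spacing Interchain axis distance in sigma; default
#'   \eqn{2^{1/6}\sigma}, the pair-potential minimum, so bundles start near
#'   mechanical equilibrium.
#' @export
bundle_spec <- function(n_chains, chain_length,
                        lattice_spacing = 2^(1 / 6)) {
  stopifnot(n_chains >= 1, chain_length >= 3, lattice_spacing > 0)
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 lattice_spacing = lattice_spacing),
            class = "pb_bundle_spec")
}

#' Dilute-solution specification
#'
#' The box side is derived from the bead volume fraction phi with the bead
#' volume taken as the sphere volume \eqn{(\pi/6)\sigma^3}:
#' \code{box = (n_chains * chain_length * (pi/6) / phi)^(1/3)}. The network
#' study uses 50 chains of L = 100 at phi = 2.61e-3 (box of about 100 sigma).
#'
#' @param n_chains,chain_length Chain count and beads per chain.
#' @param phi Bead volume fraction, in (0, 0.49).
#' @export
solution_spec <- function(n_chains = 50, chain_length = 100,
                          phi = 2.61e-3) {
  stopifnot(n_chains >= 1, chain_length >= 2, phi > 0, phi < 0.49)
  box <- (n_chains * chain_length * (pi / 6) / phi)^(1 / 3)
  structure(list(n_chains = as.integer(n_chains),
                 chain_length = as.integer(chain_length),
                 phi = phi, box_side = box),
            class = "pb_solution_spec")
}

#' Build a single chain
#'
#' Consecutive beads at bond length sigma. The straight variant is collinear
#' along z; the random variant is a self-avoiding-ish random walk in which a
#' trial bead is rejected whenever it comes within one sigma of any
#' non-bonded predecessor.
#'
#' @param L Beads (>= 2).
#' @param straight Logical.
#' @param seed Seed for the random variant.
#' @param sigma Bond length.
#' @return List with \code{topo} and \code{frame}.
#' @export
make_chain <- function(L, straight = TRUE, seed = 1, sigma = 1) {
  stopifnot(L >= 2)
  topo <- make_topology(L)
  if (straight) {
    pos <- cbind(0, 0, sigma * (seq_len(L) - 1))
  } else {
    set.seed(seed)
    pos <- random_walk_chain(L, sigma)
  }
  list(topo = topo, frame = make_frame(pos))
}

random_walk_chain <- function(L, sigma = 1, min_dist = 1.0 * sigma,
                              max_tries = 500) {
  repeat {
    pos <- matrix(0, L, 3)
    pos[2, ] <- c(0, 0, sigma)
    ok <- TRUE
    for (i in seq_len(L)[-(1:2)]) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        d <- stats::rnorm(3)
        d <- sigma * d / sqrt(sum(d^2))
        cand <- pos[i - 1, ] + d
        prev <- pos[seq_len(i - 2), , drop = FALSE]  # non-bonded predecessors
        dd <- sqrt(rowSums(sweep(prev, 2, cand)^2))
        if (all(dd >= min_dist)) { pos[i, ] <- cand; placed <- TRUE; break }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
}

# Hexagonal lattice sites filled in spiral (shell) order from the center:
# sorted by distance then polar angle, giving near-circular cross sections.
hex_sites <- function(n, spacing) {
  k <- ceiling(sqrt(n)) + 2
  ij <- expand.grid(i = -k:k, j = -k:k)
  x <- spacing * (ij$i + ij$j / 2)
  y <- spacing * (ij$j * sqrt(3) / 2)
  r <- sqrt(x^2 + y^2)
  ang <- atan2(y, x)
  ord <- order(round(r, 9), ang)
  cbind(x[ord], y[ord])[seq_len(n), , drop = FALSE]
}

#' Build an ideal N-chain bundle
#'
#' N straight parallel chains placed on a 2D hexagonal lattice filled in
#' spiral order from the center (N = 7 gives one center chain plus the full
#' first shell). Ready for equilibration at the target temperature.
#'
#' @param spec \code{\link{bundle_spec}}.
#' @return List with \code{topo} and \code{frame}.
#' @export
make_bundle <- function(spec) {
  stopifnot(inherits(spec, "pb_bundle_spec"))
  N <- spec$n_chains; L <- spec$chain_length
  sites <- hex_sites(N, spec$lattice_spacing)
  z <- seq_len(L) - 1
  pos <- do.call(rbind, lapply(seq_len(N), function(c)
    cbind(sites[c, 1], sites[c, 2], z)))
  list(topo = make_topology(rep(L, N)), frame = make_frame(pos))
}

#' Build a dispersed-solution initial configuration
#'
#' Chains are generated as random walks, randomly rotated and translated in
#' the periodic box, and rejected when any bead comes within one sigma of an
#' already placed chain. The realized bead volume fraction equals
#' \code{spec$phi} exactly by construction of the box side.
#'
#' @param spec \code{\link{solution_spec}}.
#' @param seed Integer seed.
#' @param max_retries Placement attempts per chain before a packing error.
#' @return List with \code{topo} and \code{frame} (periodic).
#' @export
make_solution <- function(spec, seed = 1, max_retries = 200) {
  stopifnot(inherits(spec, "pb_solution_spec"))
  set.seed(seed)
  N <- spec$n_chains; L <- spec$chain_length; box <- spec$box_side
  placed <- NULL
  all_pos <- vector("list", N)
  for (c in seq_len(N)) {
    done <- FALSE
    for (t in seq_len(max_retries)) {
      ch <- random_walk_chain(L)
      ch <- sweep(ch, 2, colMeans(ch))
      R <- random_rotation()
      ch <- ch %*% t(R)
      ch <- sweep(ch, 2, stats::runif(3, 0, box), `+`)
      if (is.null(placed) ||
          cpp_min_cross_dist(ch, placed, box, TRUE) >= 1.0) {
        all_pos[[c]] <- ch
        placed <- rbind(placed, ch)
        done <- TRUE
        break
      }
    }
    if (!done) stop("packing error: could not place chain ", c,
                    " after ", max_retries, " attempts")
  }
  list(topo = make_topology(rep(L, N)),
       frame = make_frame(do.call(rbind, all_pos), box = box,
                          periodic = TRUE))
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample the exact equilibrium ensemble of an isolated semi-flexible chain
#'
#' Generates chains with rigid unit bonds whose interior angles are
#' independent draws from the Boltzmann density
#' \eqn{\propto \exp(-k_{bend}(1+\cos\theta)/T)\,\sin\theta} with uniform
#' torsions -- the exact equilibrium ensemble of an isolated chain under the
#' bending potential alone. Also returns the 1D-quadrature value of the
#' bond-direction correlation \eqn{\langle\cos\theta'\rangle}, the
#' independent oracle for persistence-length estimator tests.
#'
#' @param k_bend Bending strength in epsilon (>= 0).
#' @param T Temperature in epsilon/kB (> 0).
#' @param n_bonds Bonds per chain.
#' @param n_chains Chains to sample.
#' @param seed Integer seed.
#' @return List: \code{frames} (one single-chain \code{pb_frame} per chain),
#'   \code{topo}, \code{cos_gamma} (quadrature \eqn{\langle\cos\theta'\rangle}),
#'   \code{K} (= k_bend/T).
#' @export
sample_wlc_ensemble <- function(k_bend, T, n_bonds, n_chains, seed = 1) {
  stopifnot(k_bend >= 0, T > 0, n_bonds >= 1, n_chains >= 1)
  K <- k_bend / T
  set.seed(seed)
  pos <- cpp_wlc_positions(as.integer(n_chains), as.integer(n_bonds), K)
  L <- n_bonds + 1
  frames <- lapply(seq_len(n_chains), function(c)
    make_frame(pos[(c - 1) * L + seq_len(L), , drop = FALSE]))
  list(frames = frames, topo = make_topology(L),
       cos_gamma = wlc_cos_gamma(K), K = K)
}

#' Bond-direction correlation of the discrete WLC by quadrature
#'
#' \eqn{\langle\cos\theta'\rangle = -\langle u \rangle} under the density
#' \eqn{\propto e^{-K(1+u)}} on \eqn{u = \cos\theta \in [-1, 1]}, evaluated
#' by 1D numerical quadrature (closed form: \eqn{\coth K - 1/K}).
#'
#' @param K Stiffness-to-temperature ratio k_bend/T.
#' @export
wlc_cos_gamma <- function(K) {
  if (K < 1e-12) return(0)
  w <- function(u) exp(-K * (1 + u))
  num <- stats::integrate(function(u) -u * w(u), -1, 1,
                          rel.tol = 1e-12)$value
  den <- stats::integrate(w, -1, 1, rel.tol = 1e-12)$value
  num / den
}

#' Closed-form persistence length of a chain with independent bond angles
#'
#' \eqn{l_p = b\,(1 - c^n)/(1 - c)} for n bonds of length b with
#' bond-correlation c; reduces to the contour length n*b for a rigid rod
#' (c = 1) and to b for a freely jointed chain (c = 0).
#'
#' @param c Bond-direction correlation.
#' @param n_bonds Number of bonds.
#' @param b Bond length.
#' @export
wlc_lp_theory <- function(c, n_bonds, b = 1) {
  if (abs(1 - c) < 1e-14) return(b * n_bonds)
  b * (1 - c^n_bonds) / (1 - c)
}

#' Crossover relation for the relative bundle persistence length
#'
#' \eqn{l_{pr}(N) = l_{pr}^\infty N^2 / (l_{pr}^\infty - 1 + N^2)}: equals 1
#' exactly at N = 1 for any plateau, grows as N^2 for small N, and
#' saturates at \eqn{l_{pr}^\infty}.
#'
#' @param N Chain counts.
#' @param lpr_inf Plateau value.
#' @export
crossover_lpr <- function(N, lpr_inf) {
  lpr_inf * N^2 / (lpr_inf - 1 + N^2)
}

#' Quasi-harmonic temperature dependence of the persistence length
#'
#' \eqn{l_p(T) = l_{p0} - A\,T\,e^{-T_D/T}}; at low temperature the
#' exponential is negligible and the linear form \eqn{l_{p0} - A T}
#' dominates.
#'
#' @param T Temperatures.
#' @param lp0 Zero-temperature persistence length.
#' @param A Slope parameter.
#' @param TD Activation temperature.
#' @export
quasiharmonic_lp <- function(T, lp0, A, TD) {
  lp0 - A * T * exp(-TD / pmax(T, .Machine$double.eps))
}

logistic_curve <- function(T, e_low, e_high, t0, width) {
  e_low + (e_high - e_low) / (1 + exp(-(T - t0) / width))
}

#' Synthetic analysis fixtures
#'
#' Emits noiseless or noisy observable curves from the closed forms used by
#' the analysis stages, with the ground truth recorded for recovery tests:
#' \describe{
#'   \item{melting-sigmoid}{Ebond(T): logistic step between baselines
#'     \code{e_low} and \code{e_high}, centered at \code{t0}, width
#'     \code{width}.}
#'   \item{crossover-eq4}{lpr(N) from \code{\link{crossover_lpr}}.}
#'   \item{lowT-linear}{lp(T) from \code{\link{quasiharmonic_lp}}
#'     (TD = 0 gives the exact line lp0 - A*T).}
#' }
#'
#' @param kind One of the three kinds above.
#' @param params Named list overriding the curve defaults.
#' @param noise_sd Gaussian noise standard deviation added to y.
#' @param seed Integer seed.
#' @param grid x grid (temperatures or N values); sensible default per kind.
#' @return \code{pb_series} data.frame with attributes \code{truth} and
#'   \code{kind}.
#' @export
make_synthetic_curves <- function(kind = c("melting-sigmoid",
                                           "crossover-eq4", "lowT-linear"),
                                  params = list(), noise_sd = 0, seed = 1,
                                  grid = NULL) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "melting-sigmoid") {
    p <- utils::modifyList(list(e_low = -1, e_high = 0, t0 = 0.6,
                                width = 0.05), params)
    x <- grid %||% seq(0.01, 1.5, by = 0.05)
    y <- logistic_curve(x, p$e_low, p$e_high, p$t0, p$width)
    df <- data.frame(T = x, ebond = y + stats::rnorm(length(x), 0, noise_sd))
    p$tm <- p$t0
  } else if (kind == "crossover-eq4") {
    p <- utils::modifyList(list(lpr_inf = 5), params)
    x <- grid %||% c(1, 2, 3, 4, 5, 8, 10, 16, 32)
    y <- crossover_lpr(x, p$lpr_inf)
    df <- data.frame(N = x, lpr = y + stats::rnorm(length(x), 0, noise_sd))
  } else {
    p <- utils::modifyList(list(lp0 = 40, A = 12, TD = 0), params)
    x <- grid %||% seq(0.02, 1.5, by = 0.02)
    y <- quasiharmonic_lp(x, p$lp0, p$A, p$TD)
    df <- data.frame(T = x, lp = y + stats::rnorm(length(x), 0, noise_sd))
  }
  attr(df, "truth") <- p
  attr(df, "kind") <- kind
  class(df) <- c("pb_series", "data.frame")
  df
}
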