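#' Interaction-model parameters
#'
#' Collects every constant of the bead-spring model in reduced units
#' (energy epsilon, length sigma, kB = 1): a force-shifted 12-6
#' Lennard-Jones pair potential acting between all non-bonded beads, a FENE
#' spring along the backbone, and a three-body bending term
#' \eqn{k_{bend}(1+\cos\theta)} at every interior bead.
#'
#' @param epsilon Cohesion strength (energy unit). Sweepable, typically
#'   0.8--1.8.
#' @param sigma Bead diameter (length unit).
#' @param r_cut Pair cutoff in sigma. Must exceed \eqn{2^{1/6}\sigma} so the
#'   attractive tail is present; default 2.5.
#' @param k_fene FENE spring constant in epsilon/sigma^2 (default 30).
#' @param r0_fene Maximum FENE extension in sigma (default 1.5).
#' @param r_shift FENE offset \eqn{r_s} in sigma (default 0, the standard
#'   Kremer--Grest form).
#' @param k_bend Bending strength in epsilon (model sweep range 4--80; the
#'   dilute-solution quench study uses 0.7).
#' @param mass Bead mass (default 1).
#' @param dt Integration timestep in reduced time units (default 0.005).
#' @param exclude_bonded_pairs Drop directly bonded (1-2) pairs from the
#'   nonbonded sum. Default FALSE: excluded volume acts among all beads, so
#'   the FENE log term plus the pair repulsion set the equilibrium bond
#'   length near 0.97 sigma; excluding 1-2 pairs would leave a bare FENE
#'   bond whose minimum sits at r = r_shift and collapse the backbone.
#' @return An object of class \code{pb_params}.
#' @export
model_params <- function(epsilon = 1.0, sigma = 1.0, r_cut = 2.5,
                         k_fene = 30, r0_fene = 1.5, r_shift = 0,
                         k_bend = 7.0, mass = 1, dt = 0.005,
                         exclude_bonded_pairs = FALSE) {
  stopifnot(epsilon > 0, sigma > 0, k_fene > 0, r0_fene > 0,
            k_bend >= 0, mass > 0, dt > 0, r_shift >= 0)
  if (r_cut <= 2^(1 / 6) * sigma)
    stop("r_cut must exceed 2^(1/6)*sigma (attractive tail required)")
  if (r_shift >= r0_fene)
    stop("r_shift must be smaller than r0_fene")
  structure(list(epsilon = epsilon, sigma = sigma, r_cut = r_cut,
                 k_fene = k_fene, r0_fene = r0_fene, r_shift = r_shift,
                 k_bend = k_bend, k_B = 1.0, mass = mass, dt = dt,
                 exclude_bonded_pairs = isTRUE(exclude_bonded_pairs)),
            class = "pb_params")
}

#' @export
print.pb_params <- function(x, ...) {
  cat("Bead-spring model parameters (reduced units):\n")
  cat(sprintf("  epsilon = %g, sigma = %g, r_cut = %g\n",
              x$epsilon, x$sigma, x$r_cut))
  cat(sprintf("  FENE: k = %g, R0 = %g, r_shift = %g\n",
              x$k_fene, x$r0_fene, x$r_shift))
  cat(sprintf("  k_bend = %g, mass = %g, dt = %g\n", x$k_bend, x$mass, x$dt))
  invisible(x)
}

#' Linear-chain topology
#'
#' Builds the bead -> chain map, the bond list, and the angle-triple list for
#' a set of linear chains given their bead counts. Bonds connect consecutive
#' beads; an angle triple exists exactly for every interior bead.
#'
#' @param chain_lengths Integer vector, beads per chain.
#' @return An object of class \code{pb_topology} with fields \code{n_beads},
#'   \code{chain_id}, \code{bonds} (2-column matrix), \code{angles}
#'   (3-column matrix) and \code{chain_lengths}.
#' @export
make_topology <- function(chain_lengths) {
  chain_lengths <- as.integer(chain_lengths)
  stopifnot(length(chain_lengths) >= 1, all(chain_lengths >= 1))
  n <- sum(chain_lengths)
  chain_id <- rep(seq_along(chain_lengths), chain_lengths)
  offs <- cumsum(c(0L, chain_lengths[-length(chain_lengths)]))
  bonds <- do.call(rbind, lapply(seq_along(chain_lengths), function(c) {
    L <- chain_lengths[c]
    if (L < 2) return(NULL)
    i <- offs[c] + seq_len(L - 1)
    cbind(i, i + 1L)
  }))
  angles <- do.call(rbind, lapply(seq_along(chain_lengths), function(c) {
    L <- chain_lengths[c]
    if (L < 3) return(NULL)
    i <- offs[c] + seq_len(L - 2)
    cbind(i, i + 1L, i + 2L)
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  dimnames(bonds) <- NULL; dimnames(angles) <- NULL
  structure(list(n_beads = n, chain_id = chain_id,
                 bonds = bonds, angles = angles,
                 chain_lengths = chain_lengths),
            class = "pb_topology")
}

#' @export
print.pb_topology <- function(x, ...) {
  cat(sprintf("Topology: %d beads in %d chain(s), %d bonds, %d angles\n",
              x$n_beads, length(x$chain_lengths), nrow(x$bonds),
              nrow(x$angles)))
  invisible(x)
}

#' Simulation frame
#'
#' Positions and velocities of every bead, plus the (cubic, optionally
#' periodic) box. Coordinates are kept unwrapped; the minimum-image
#' convention is applied to every pair term when \code{periodic} is TRUE.
#'
#' @param positions Np x 3 numeric matrix (sigma).
#' @param velocities Np x 3 numeric matrix (reduced units); defaults to zero.
#' @param box Cubic box side in sigma.
#' @param periodic Logical, apply periodic boundary conditions.
#' @param time Step index (metadata).
#' @return An object of class \code{pb_frame}.
#' @export
make_frame <- function(positions, velocities = NULL, box = Inf,
                       periodic = FALSE, time = 0L) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, all(is.finite(positions)))
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  stopifnot(identical(dim(velocities), dim(positions)))
  if (periodic) stopifnot(is.finite(box), box > 0)
  structure(list(positions = positions, velocities = velocities,
                 box = box, periodic = periodic, time = time),
            class = "pb_frame")
}

#' @export
print.pb_frame <- function(x, ...) {
  cat(sprintf("Frame: %d beads, box = %g (%s), time = %d\n",
              nrow(x$positions), x$box,
              if (x$periodic) "periodic" else "open", as.integer(x$time)))
  invisible(x)
}

check_frame_topo <- function(frame, topo) {
  if (nrow(frame$positions) != topo$n_beads)
    stop("frame and topology disagree on bead count")
  invisible(TRUE)
}

#' Pair energy and radial force
#'
#' Force-shifted Lennard-Jones:
#' \eqn{U(r) = U_{LJ}(r) - U_{LJ}(r_c) - (r - r_c) U'_{LJ}(r_c)} for
#' \eqn{r < r_c} and exactly zero (energy and force) beyond the cutoff, so
#' both are continuous at \eqn{r_c}. The force is the radial component
#' \eqn{-dU/dr} (positive = repulsive).
#'
#' @param r Distance(s) in sigma, must be > 0.
#' @param params \code{\link{model_params}}.
#' @return List with numeric \code{energy} and \code{force}.
#' @export
pair_energy_force <- function(r, params = model_params()) {
  if (any(!is.finite(r)) || any(r <= 0))
    stop("invalid geometry: pair distance must be > 0")
  cpp_pair_ef(as.numeric(r), params$epsilon, params$sigma, params$r_cut)
}

#' FENE bond energy and radial force
#'
#' \eqn{U(r) = -(k_F R_0^2/2)\,\ln[1 - ((r - r_s)/R_0)^2]}; diverges as the
#' extension approaches \eqn{R_0}, which in a running simulation signals
#' integrator blow-up and is raised as a bond-overextension error.
#'
#' @inheritParams pair_energy_force
#' @export
fene_energy_force <- function(r, params = model_params()) {
  cpp_fene_ef(as.numeric(r), params$k_fene, params$r0_fene, params$r_shift)
}

#' Bending energy and forces for one angle triple
#'
#' \eqn{U(\theta) = k_{bend}(1 + \cos\theta)} with \eqn{\theta} the interior
#' angle at the central bead, so a straight chain (\eqn{\theta = \pi}) costs
#' nothing. Forces are the exact negative gradient on all three beads.
#'
#' @param r_i,r_j,r_k Length-3 position vectors; j is the central bead.
#' @param params \code{\link{model_params}}.
#' @return List with \code{energy}, \code{f_i}, \code{f_j}, \code{f_k}.
#' @export
bend_energy_force <- function(r_i, r_j, r_k, params = model_params()) {
  cpp_bend_ef(as.numeric(r_i), as.numeric(r_j), as.numeric(r_k),
              params$k_bend)
}

#' Energy decomposition of a frame
#'
#' Evaluates all model terms: nonbonded pair energy split by chain identity
#' into interchain and intrachain parts (excluded volume acts among all
#' beads, bonded pairs included, unless
#' \code{exclude_bonded_pairs = TRUE} in the parameters), FENE bond energy,
#' bending energy, and kinetic energy. Periodic frames use the minimum-image convention. By default a
#' cell list accelerates the pair sum when the box admits one; its pair terms
#' are accumulated in the same (i, j) order as the all-pairs double loop, so
#' the result is bit-identical to \code{method = "brute"}.
#'
#' @param frame \code{\link{make_frame}} object.
#' @param topo \code{\link{make_topology}} object.
#' @param params \code{\link{model_params}}.
#' @param method "auto" (cell list when possible) or "brute" (O(Np^2) loop).
#' @return An object of class \code{pb_energies}: \code{e_pair_inter},
#'   \code{e_pair_intra}, \code{e_fene}, \code{e_bend}, \code{e_kin},
#'   \code{e_pot}, \code{e_total}, \code{t_kin} and the force matrix.
#' @export
compute_energies <- function(frame, topo, params = model_params(),
                             method = c("auto", "brute")) {
  method <- match.arg(method)
  check_frame_topo(frame, topo)
  box <- if (is.finite(frame$box)) frame$box else 0
  res <- cpp_energies(frame$positions, frame$velocities, box,
                      isTRUE(frame$periodic),
                      topo$bonds - 1L, topo$angles - 1L,
                      as.integer(topo$chain_id), unclass(params),
                      if (method == "brute") 1L else 0L)
  e_pot <- res$e_pair_inter + res$e_pair_intra + res$e_fene + res$e_bend
  structure(list(e_pair_inter = res$e_pair_inter,
                 e_pair_intra = res$e_pair_intra,
                 e_fene = res$e_fene, e_bend = res$e_bend,
                 e_kin = res$e_kin, e_pot = e_pot,
                 e_total = e_pot + res$e_kin,
                 t_kin = 2 * res$e_kin / (3 * topo$n_beads),
                 forces = res$forces),
            class = "pb_energies")
}

#' @export
print.pb_energies <- function(x, ...) {
  cat("Energy breakdown (epsilon units):\n")
  cat(sprintf("  pair inter %-12.6g pair intra %-12.6g\n",
              x$e_pair_inter, x$e_pair_intra))
  cat(sprintf("  FENE       %-12.6g bend       %-12.6g\n",
              x$e_fene, x$e_bend))
  cat(sprintf("  kinetic    %-12.6g total      %-12.6g (T_kin = %.4g)\n",
              x$e_kin, x$e_total, x$t_kin))
  invisible(x)
}

# Unwrap the beads of each chain by walking bonds with minimum image; the
# first bead of each chain anchors the image choice.
unwrap_chains <- function(frame, topo) {
  if (!frame$periodic) return(frame$positions)
  pos <- frame$positions
  box <- frame$box
  out <- pos
  offs <- cumsum(c(0L, topo$chain_lengths[-length(topo$chain_lengths)]))
  for (c in seq_along(topo$chain_lengths)) {
    L <- topo$chain_lengths[c]
    if (L < 2) next
    idx <- offs[c] + seq_len(L)
    d <- diff(pos[idx, , drop = FALSE])
    d <- d - box * round(d / box)
    out[idx, ] <- rbind(pos[idx[1], , drop = FALSE],
                        matrix(pos[idx[1], ], L - 1, 3, byrow = TRUE) +
                          apply(d, 2, cumsum))
  }
  out
}
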