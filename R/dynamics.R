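#' Thermostat specification
#'
#' The canonical-ensemble runs use either a single Nose-Hoover chain (the
#' replication default) or a Langevin (BAOAB) thermostat. Small systems --
#' one or two short chains -- are weakly ergodic under Nose-Hoover, so the
#' desk-scale tests use Langevin.
#'
#' @param kind "nose-hoover" or "langevin".
#' @param target_T Target temperature in epsilon/kB.
#' @param coupling Relaxation time in reduced units: the Nose-Hoover damping
#'   time (default 0.5) or the Langevin damping time 1/gamma (default 1.0).
#' @param xi Nose-Hoover auxiliary momentum (carried across restarts).
#' @return Object of class \code{pb_thermostat}.
#' @export
thermostat <- function(kind = c("langevin", "nose-hoover"), target_T,
                       coupling = NULL, xi = 0) {
  kind <- match.arg(kind)
  stopifnot(target_T > 0)
  if (is.null(coupling)) coupling <- if (kind == "nose-hoover") 0.5 else 1.0
  stopifnot(coupling > 0)
  structure(list(kind = kind, target_T = target_T, coupling = coupling,
                 xi = xi),
            class = "pb_thermostat")
}

#' Linear temperature-quench schedule
#'
#' The thermostat target drops by \code{rate} (epsilon/kB per time step)
#' every step, from \code{T_start} down to \code{T_end}; the run length is
#' \code{ceiling((T_start - T_end)/rate)} steps. The network-formation
#' protocol uses cooling rates 1e-7, 1e-5 and 1e-4 per step between T = 2
#' and T = 0.1.
#'
#' @param T_start,T_end Temperatures in epsilon/kB, \code{T_start > T_end > 0}.
#' @param rate Temperature decrement per step.
#' @return Object of class \code{pb_quench} with derived \code{n_steps}.
#' @export
quench_schedule <- function(T_start = 2.0, T_end = 0.1, rate = 1e-4) {
  stopifnot(T_start > T_end, T_end > 0, rate > 0)
  structure(list(T_start = T_start, T_end = T_end, rate = rate,
                 n_steps = as.integer(ceiling((T_start - T_end) / rate))),
            class = "pb_quench")
}

therm_code <- function(th) {
  if (is.null(th)) return(0L)
  if (th$kind == "nose-hoover") 1L else 2L
}

samples_to_series <- function(samp, meta = list()) {
  df <- as.data.frame(samp)
  attr(df, "meta") <- meta
  class(df) <- c("pb_series", "data.frame")
  df
}

#' Maxwell-Boltzmann velocity initialization
#'
#' Draws velocities at temperature \code{T} and removes the center-of-mass
#' drift.
#'
#' @param n_beads Number of beads.
#' @param T Temperature in epsilon/kB.
#' @param mass Bead mass.
#' @return n x 3 velocity matrix.
#' @export
init_velocities <- function(n_beads, T, mass = 1) {
  v <- matrix(stats::rnorm(3 * n_beads, sd = sqrt(T / mass)), n_beads, 3)
  sweep(v, 2, colMeans(v))
}

#' Single velocity-Verlet step
#'
#' Advances one timestep; with \code{thermostat = NULL} this is a
#' microcanonical (NVE) update.
#'
#' @param frame,topo,params Frame, topology and model parameters.
#' @param therm \code{\link{thermostat}} or NULL for NVE.
#' @return Updated \code{pb_frame} (with the Nose-Hoover momentum carried in
#'   attribute \code{xi}).
#' @export
velocity_verlet_step <- function(frame, topo, params = model_params(),
                                 therm = NULL) {
  check_frame_topo(frame, topo)
  box <- if (is.finite(frame$box)) frame$box else 0
  tc <- therm_code(therm)
  res <- cpp_run_md(frame$positions, frame$velocities, box,
                    isTRUE(frame$periodic),
                    topo$bonds - 1L, topo$angles - 1L,
                    as.integer(topo$chain_id), unclass(params), tc,
                    if (tc == 0L) 1.0 else therm$target_T, 0, 0,
                    if (tc == 0L) 1.0 else therm$coupling,
                    1L, 0L, 0L, if (tc == 1L) therm$xi else 0)
  out <- make_frame(res$positions, res$velocities, frame$box,
                    frame$periodic, frame$time + 1L)
  attr(out, "xi") <- res$xi
  out
}

#' Canonical (NVT) run
#'
#' Thermostatted velocity-Verlet dynamics at fixed target temperature.
#' Returns the final frame together with an observable time series (energy
#' decomposition and instantaneous kinetic temperature) sampled every
#' \code{sample_every} steps, and optionally stored trajectory frames.
#'
#' @param frame,topo,params Frame, topology, model parameters.
#' @param T Target temperature in epsilon/kB.
#' @param n_steps Number of steps (>= 1).
#' @param sample_every Sampling stride for observables.
#' @param seed Integer seed (mandatory: drives Langevin noise and any
#'   velocity initialization).
#' @param therm_kind "langevin" or "nose-hoover".
#' @param coupling Thermostat relaxation time (see \code{\link{thermostat}}).
#' @param traj_every Stride for storing frames (0 = none).
#' @param init_vel Draw Maxwell-Boltzmann velocities at \code{T} first
#'   (default: only when the frame's velocities are all zero).
#' @return List with \code{frame}, \code{series} (class \code{pb_series}),
#'   \code{frames} (list of stored \code{pb_frame}s) and \code{xi}.
#' @export
run_nvt <- function(frame, topo, params = model_params(), T, n_steps,
                    sample_every = 100, seed = 1,
                    therm_kind = c("langevin", "nose-hoover"),
                    coupling = NULL, traj_every = 0, init_vel = NULL) {
  therm_kind <- match.arg(therm_kind)
  if (n_steps < 1) stop("n_steps must be >= 1")
  check_frame_topo(frame, topo)
  th <- thermostat(therm_kind, target_T = T, coupling = coupling,
                   xi = attr(frame, "xi") %||% 0)
  set.seed(seed)
  if (is.null(init_vel)) init_vel <- all(frame$velocities == 0)
  vel <- if (init_vel)
    init_velocities(topo$n_beads, T, params$mass) else frame$velocities
  box <- if (is.finite(frame$box)) frame$box else 0
  res <- cpp_run_md(frame$positions, vel, box, isTRUE(frame$periodic),
                    topo$bonds - 1L, topo$angles - 1L,
                    as.integer(topo$chain_id), unclass(params),
                    therm_code(th), T, 0, 0, th$coupling,
                    as.integer(n_steps), as.integer(max(1, sample_every)),
                    as.integer(traj_every), th$xi)
  fin <- make_frame(res$positions, res$velocities, frame$box, frame$periodic,
                    frame$time + as.integer(n_steps))
  attr(fin, "xi") <- res$xi
  frames <- lapply(res$trajectory, make_frame, box = frame$box,
                   periodic = frame$periodic)
  list(frame = fin,
       series = samples_to_series(res$samples,
                                  list(T = T, thermostat = therm_kind,
                                       seed = seed, n_steps = n_steps)),
       frames = frames, xi = res$xi)
}

#' Temperature-quench run
#'
#' Lowers the thermostat target linearly by \code{schedule$rate} per step
#' from \code{T_start} to \code{T_end}, emulating the non-equilibrium
#' network-formation protocol.
#'
#' @param frame,topo,params Frame, topology, model parameters.
#' @param schedule \code{\link{quench_schedule}}.
#' @param seed Integer seed.
#' @param therm_kind,coupling Thermostat selection, as in \code{\link{run_nvt}}.
#' @param sample_every,traj_every Observable and trajectory strides.
#' @return List with \code{frame}, \code{series}, \code{frames}.
#' @export
run_quench <- function(frame, topo, params = model_params(), schedule,
                       seed = 1, therm_kind = c("langevin", "nose-hoover"),
                       coupling = NULL, sample_every = 1000,
                       traj_every = 0) {
  therm_kind <- match.arg(therm_kind)
  stopifnot(inherits(schedule, "pb_quench"))
  check_frame_topo(frame, topo)
  th <- thermostat(therm_kind, target_T = schedule$T_start,
                   coupling = coupling)
  set.seed(seed)
  vel <- if (all(frame$velocities == 0))
    init_velocities(topo$n_beads, schedule$T_start, params$mass)
  else frame$velocities
  box <- if (is.finite(frame$box)) frame$box else 0
  res <- cpp_run_md(frame$positions, vel, box, isTRUE(frame$periodic),
                    topo$bonds - 1L, topo$angles - 1L,
                    as.integer(topo$chain_id), unclass(params),
                    therm_code(th), schedule$T_start, schedule$rate,
                    schedule$T_end, th$coupling, schedule$n_steps,
                    as.integer(max(1, sample_every)),
                    as.integer(traj_every), 0)
  fin <- make_frame(res$positions, res$velocities, frame$box, frame$periodic,
                    frame$time + schedule$n_steps)
  frames <- lapply(res$trajectory, make_frame, box = frame$box,
                   periodic = frame$periodic)
  list(frame = fin,
       series = samples_to_series(res$samples,
                                  list(schedule = unclass(schedule),
                                       thermostat = therm_kind, seed = seed)),
       frames = frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
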