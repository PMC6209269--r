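#' Persistence length of one chain from a trajectory
#'
#' Projection estimator: \eqn{l_p = \langle R_e \cdot l_1 \rangle /
#' \langle |l_1| \rangle}, with \eqn{R_e} the chain end-to-end vector and
#' \eqn{l_1} its first bond vector, averaged over frames. Chains are
#' unwrapped (bond-walk minimum image) before the projection, so periodic
#' wrapping never enters. For a rigid rod the estimator returns the contour
#' length exactly.
#'
#' @param frames List of \code{pb_frame}s (>= 1).
#' @param topo \code{pb_topology}.
#' @param chain_index Which chain.
#' @return Scalar persistence length in sigma.
#' @export
chain_lp <- function(frames, topo, chain_index = 1) {
  if (length(frames) < 1) stop("need at least one frame")
  L <- topo$chain_lengths[chain_index]
  if (is.na(L) || L < 3) stop("chain must have at least 2 bonds")
  s <- chain_lp_terms(frames, topo, chain_index)
  mean(s$proj) / mean(s$b1)
}

# Per-frame numerator (Re . l1) and denominator (|l1|) terms for one chain.
chain_lp_terms <- function(frames, topo, chain_index) {
  offs <- cumsum(c(0L, topo$chain_lengths[-length(topo$chain_lengths)]))
  idx <- offs[chain_index] + seq_len(topo$chain_lengths[chain_index])
  proj <- numeric(length(frames))
  b1 <- numeric(length(frames))
  for (f in seq_along(frames)) {
    pos <- unwrap_chains(frames[[f]], topo)[idx, , drop = FALSE]
    l1 <- pos[2, ] - pos[1, ]
    re <- pos[nrow(pos), ] - pos[1, ]
    proj[f] <- sum(re * l1)
    b1[f] <- sqrt(sum(l1^2))
  }
  list(proj = proj, b1 = b1)
}

#' Bundle persistence length
#'
#' Per-chain persistence lengths are computed for every chain while it is
#' embedded in the bundle (each chain's own end-to-end and first-bond
#' vectors), and the bundle value is their arithmetic mean. The relative
#' persistence length lpr is the ratio against an isolated-chain reference
#' at matching stiffness and temperature.
#'
#' @param frames List of \code{pb_frame}s.
#' @param topo \code{pb_topology} (all chains the same length).
#' @param lp_ref Isolated-chain reference \eqn{l_{pc}} (scalar), or NULL to
#'   skip the ratio.
#' @return Object of class \code{pb_persistence}: \code{lp_chain},
#'   \code{lp_bundle}, \code{lp_ref}, \code{lpr}, \code{n_frames},
#'   \code{se} (standard error of the bundle mean).
#' @export
bundle_lp <- function(frames, topo, lp_ref = NULL) {
  if (length(unique(topo$chain_lengths)) != 1)
    stop("all chains must have the same length")
  N <- length(topo$chain_lengths)
  lp_i <- vapply(seq_len(N), function(c) chain_lp(frames, topo, c),
                 numeric(1))
  lp_b <- mean(lp_i)
  # error bar: chain-to-chain spread when N > 1, else frame-block error
  se <- if (N > 1) {
    stats::sd(lp_i) / sqrt(N)
  } else {
    block_se_ratio(chain_lp_terms(frames, topo, 1))
  }
  lpr <- if (is.null(lp_ref)) NA_real_ else lp_b / lp_ref
  structure(list(lp_chain = lp_i, lp_bundle = lp_b,
                 lp_ref = lp_ref %||% NA_real_, lpr = lpr,
                 n_frames = length(frames), se = se),
            class = "pb_persistence")
}

# Block-averaged standard error of a ratio-of-means estimator.
block_se_ratio <- function(terms, n_blocks = 5) {
  n <- length(terms$proj)
  if (n < n_blocks * 2) return(NA_real_)
  bl <- cut(seq_len(n), n_blocks, labels = FALSE)
  vals <- vapply(seq_len(n_blocks), function(b)
    mean(terms$proj[bl == b]) / mean(terms$b1[bl == b]), numeric(1))
  stats::sd(vals) / sqrt(n_blocks)
}

#' @export
print.pb_persistence <- function(x, ...) {
  cat(sprintf("Bundle persistence length: lp = %.4g sigma (se %.3g, %d chains, %d frames)\n",
              x$lp_bundle, x$se, length(x$lp_chain), x$n_frames))
  if (!is.na(x$lpr))
    cat(sprintf("  reference lpc = %.4g, lpr = %.4g\n", x$lp_ref, x$lpr))
  invisible(x)
}

#' Fit the crossover relation for lpr(N)
#'
#' Weighted least squares of \code{\link{crossover_lpr}} over its single
#' parameter, the plateau \eqn{l_{pr}^\infty}. The relation returns exactly
#' 1 at N = 1 for any plateau, so the fit is structurally anchored there.
#' The initial guess is the largest observed lpr.
#'
#' @param n_values Chain counts (>= 3 distinct values, including small N).
#' @param lpr_values Observed relative persistence lengths.
#' @param weights Optional weights (e.g. inverse variances).
#' @return Object of class \code{pb_fit}: \code{lpr_inf}, \code{se},
#'   \code{residual_norm}, \code{converged}.
#' @export
fit_crossover <- function(n_values, lpr_values, weights = NULL) {
  stopifnot(length(n_values) == length(lpr_values))
  if (length(unique(n_values)) < 3)
    stop("need at least 3 distinct N values")
  w <- weights %||% rep(1, length(n_values))
  rss <- function(p) sum(w * (lpr_values - crossover_lpr(n_values, p))^2)
  start <- max(max(lpr_values), 1.05)
  # single-parameter weighted least squares: golden-section refinement on a
  # bracket around the initial guess (largest observed lpr)
  opt <- stats::optimize(rss, interval = c(1, max(4 * start, 10)),
                         tol = .Machine$double.eps^0.5)
  p_hat <- opt$minimum
  if (stats::sd(lpr_values) < 1e-12 || p_hat >= max(4 * start, 10) * 0.999) {
    return(structure(list(lpr_inf = NA_real_, se = NA_real_,
                          residual_norm = NA_real_, converged = FALSE),
                     class = c("pb_crossover_fit", "pb_fit")))
  }
  # Gauss-Newton standard error from the analytic gradient of the model
  grad <- n_values^2 * (n_values^2 - 1) / (p_hat - 1 + n_values^2)^2
  dof <- max(length(n_values) - 1, 1)
  s2 <- opt$objective / dof
  se <- if (sum(w * grad^2) > 0) sqrt(s2 / sum(w * grad^2)) else NA_real_
  structure(list(lpr_inf = p_hat, se = se,
                 residual_norm = sqrt(opt$objective), converged = TRUE),
            class = c("pb_crossover_fit", "pb_fit"))
}

#' Low-temperature linear fit of lp(T)
#'
#' Ordinary least squares of lp against T restricted to \code{T <= t_max}
#' (default window 0.2 epsilon/kB, where the linear form lp0 - A*T
#' dominates). Returns the intercept lp0 and slope magnitude A.
#'
#' @param lp_vs_T Data frame / \code{pb_series} with columns \code{T} and
#'   \code{lp}.
#' @param t_max Upper window bound.
#' @return Object of class \code{pb_fit}: \code{lp0}, \code{A}, their
#'   standard errors, and the window used.
#' @export
fit_lowT <- function(lp_vs_T, t_max = 0.2) {
  d <- lp_vs_T[lp_vs_T$T <= t_max, , drop = FALSE]
  if (nrow(d) < 3) stop("low-T window holds fewer than 3 temperatures")
  fit <- stats::lm(lp ~ T, data = d)
  co <- suppressWarnings(summary(fit)$coefficients)
  structure(list(lp0 = unname(co[1, 1]), A = -unname(co[2, 1]),
                 lp0_se = unname(co[1, 2]), A_se = unname(co[2, 2]),
                 window = c(min(d$T), t_max), n = nrow(d)),
            class = c("pb_lowT_fit", "pb_fit"))
}

#' Quasi-harmonic fit of lp(T)
#'
#' Nonlinear least squares of \code{\link{quasiharmonic_lp}} for
#' (lp0, A, TD), initialized from \code{\link{fit_lowT}} and a small grid of
#' TD starting values. Data at or above a supplied melting temperature are
#' excluded and reported.
#'
#' @param lp_vs_T Data frame with columns \code{T} and \code{lp}.
#' @param tm Optional melting temperature; points with \code{T >= tm} are
#'   masked out.
#' @param t_max_lin Window for the linear initialization.
#' @return Object of class \code{pb_fit}: \code{lp0}, \code{A}, \code{TD},
#'   standard errors, \code{excluded} (row indices masked), \code{converged}.
#' @export
fit_quasiharmonic <- function(lp_vs_T, tm = NULL, t_max_lin = 0.2) {
  excl <- integer(0)
  d <- as.data.frame(lp_vs_T)
  if (!is.null(tm) && is.finite(tm)) {
    excl <- which(d$T >= tm)
    if (length(excl)) d <- d[-excl, , drop = FALSE]
  }
  if (nrow(d) < 4) stop("need at least 4 temperatures below the mask")
  lin <- tryCatch(fit_lowT(d, t_max = t_max_lin), error = function(e) NULL)
  lp0_0 <- if (!is.null(lin)) lin$lp0 else max(d$lp)
  A_0 <- if (!is.null(lin) && lin$A > 0) lin$A else
    max((max(d$lp) - min(d$lp)) / diff(range(d$T)), 1e-3)
  best <- NULL
  for (td0 in c(0.05, 0.2, 0.5, 1, 2)) {
    fit <- tryCatch(
      stats::nls(lp ~ quasiharmonic_lp(T, lp0, A, TD), data = d,
                 start = list(lp0 = lp0_0, A = A_0, TD = td0),
                 algorithm = "port",
                 lower = c(lp0 = 0, A = 0, TD = 0),
                 control = stats::nls.control(maxiter = 500, tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    return(structure(list(lp0 = NA_real_, A = NA_real_, TD = NA_real_,
                          converged = FALSE, excluded = excl,
                          diagnostics = "all quasi-harmonic starts failed"),
                     class = c("pb_qh_fit", "pb_fit")))
  }
  co <- stats::coef(best$fit)
  ses <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                  error = function(e) rep(NA_real_, 3))
  structure(list(lp0 = unname(co["lp0"]), A = unname(co["A"]),
                 TD = unname(co["TD"]),
                 lp0_se = unname(ses[1]), A_se = unname(ses[2]),
                 TD_se = unname(ses[3]),
                 residual_norm = sqrt(best$rss),
                 excluded = excl, converged = TRUE),
            class = c("pb_qh_fit", "pb_fit"))
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Fit result:\n")
  flds <- setdiff(names(x), c("excluded", "converged", "diagnostics"))
  for (f in flds)
    if (is.numeric(x[[f]]) && length(x[[f]]) <= 2)
      cat(sprintf("  %s = %s\n", f, paste(signif(x[[f]], 6), collapse = ", ")))
  if (!is.null(x$converged)) cat("  converged:", x$converged, "\n")
  invisible(x)
}

#' Power-law scaling check
#'
#' Log-log slope of y against N with a confidence interval; passes when the
#' interval covers the stated exponent (used for the small-N lp0 ~ N^2 and
#' A ~ N^-2 trends).
#'
#' @param n_values Chain counts (>= 3).
#' @param y_values Positive response values.
#' @param exponent Exponent under test.
#' @param level Confidence level.
#' @return List: \code{slope}, \code{ci}, \code{pass}.
#' @export
scaling_check <- function(n_values, y_values, exponent, level = 0.95) {
  if (any(y_values <= 0)) stop("y values must be positive")
  if (length(n_values) < 3) stop("need at least 3 points")
  fit <- stats::lm(log(y_values) ~ log(n_values))
  ci <- suppressWarnings(stats::confint(fit, level = level))[2, ]
  list(slope = unname(stats::coef(fit)[2]), ci = unname(ci),
       pass = exponent >= ci[1] && exponent <= ci[2])
}
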