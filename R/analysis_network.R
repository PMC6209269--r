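#' Chain contact graph
#'
#' Two chains are connected when at least \code{m_contact} interchain bead
#' pairs lie within \code{r_contact} (minimum-image distances in periodic
#' boxes); edge weights are the contact counts. The defaults
#' (r_contact = 1.5 sigma, m_contact = 3) are package conventions, exposed
#' because the measurement protocol is not fixed by the model itself.
#'
#' @param frame,topo Frame and topology.
#' @param r_contact Contact distance in sigma (>= sigma).
#' @param m_contact Minimum bead-pair contacts per edge.
#' @return Object of class \code{pb_contact_graph}: \code{edges} data frame
#'   (i, j, weight), \code{n_chains}, \code{graph} (igraph object),
#'   \code{membership} (connected-component id per chain).
#' @export
build_contact_graph <- function(frame, topo, r_contact = 1.5,
                                m_contact = 3) {
  check_frame_topo(frame, topo)
  stopifnot(r_contact >= 1)
  box <- if (is.finite(frame$box)) frame$box else 0
  cnt <- cpp_contact_counts(frame$positions, box, isTRUE(frame$periodic),
                            as.integer(topo$chain_id), r_contact)
  nc <- length(topo$chain_lengths)
  idx <- which(upper.tri(cnt) & cnt >= m_contact, arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1], j = idx[, 2],
                      weight = cnt[idx])
  g <- igraph::graph_from_data_frame(
    edges[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nc)))
  if (nrow(edges)) igraph::E(g)$weight <- edges$weight
  memb <- igraph::components(g)$membership
  structure(list(edges = edges, n_chains = nc, graph = g,
                 membership = as.integer(memb),
                 r_contact = r_contact, m_contact = m_contact),
            class = "pb_contact_graph")
}

#' @export
print.pb_contact_graph <- function(x, ...) {
  cat(sprintf("Contact graph: %d chains, %d edges, %d component(s)\n",
              x$n_chains, nrow(x$edges), max(x$membership)))
  invisible(x)
}

# Local tangent at a bead: averaged bond direction over a window of up to
# 5 beads centered on it (clipped at chain ends).
local_tangent <- function(pos, idx_in_chain, chain_pos) {
  L <- nrow(chain_pos)
  lo <- max(1, idx_in_chain - 2)
  hi <- min(L, idx_in_chain + 2)
  t <- chain_pos[hi, ] - chain_pos[lo, ]
  n <- sqrt(sum(t^2))
  if (n == 0) return(NULL)
  t / n
}

#' Local fiber cross section at a bead
#'
#' The local fiber axis is the averaged bond direction over a 5-bead window
#' around the bead. All beads within an axial slab of thickness sigma and
#' radial distance \code{r_loc} of the axis are collected; \code{local_n}
#' is the number of distinct chains among them and the local diameter is
#' \eqn{2\sqrt{2} R_{g\perp} + \sigma}, where \eqn{R_{g\perp}} is the planar
#' radius of gyration of the collected beads about the axis (the uniform-disk
#' radius relation, plus one bead diameter).
#'
#' @param frame,topo Frame and topology.
#' @param bead Bead index (must not be a chain end).
#' @param r_loc Radial search distance in sigma.
#' @return List: \code{local_n}, \code{diameter}, \code{n_collected};
#'   or \code{NULL} (skipped) for end beads.
#' @export
local_cross_section <- function(frame, topo, bead, r_loc = 10) {
  check_frame_topo(frame, topo)
  cid <- topo$chain_id[bead]
  offs <- cumsum(c(0L, topo$chain_lengths[-length(topo$chain_lengths)]))
  iloc <- bead - offs[cid]
  L <- topo$chain_lengths[cid]
  if (iloc == 1L || iloc == L) return(NULL)  # end bead: skipped
  pos <- unwrap_chains(frame, topo)
  chain_rows <- offs[cid] + seq_len(L)
  tang <- local_tangent(pos, iloc, pos[chain_rows, , drop = FALSE])
  if (is.null(tang)) stop("invalid geometry: degenerate local tangent")
  d <- sweep(frame$positions, 2, frame$positions[bead, ])
  if (frame$periodic) d <- d - frame$box * round(d / frame$box)
  ax <- as.vector(d %*% tang)
  rad2 <- rowSums(d^2) - ax^2
  sel <- abs(ax) <= 0.5 & rad2 <= r_loc^2
  chains <- unique(topo$chain_id[sel])
  rg2 <- mean(pmax(rad2[sel], 0))
  list(local_n = length(chains),
       diameter = 2 * sqrt(2) * sqrt(rg2) + 1,
       n_collected = sum(sel))
}

#' Network fiber statistics
#'
#' Aggregates \code{\link{local_cross_section}} over all interior beads of a
#' (typically quenched) configuration. Beads whose local chain count jumps
#' by more than 2 against both neighbors are flagged as junction/defect
#' regions -- tie-chain branch points -- and excluded from the means.
#' Chains are grouped into fibers via the contact graph; \code{mean_n} and
#' \code{db_mean} are unweighted means over the per-fiber averages, so two
#' disjoint ideal bundles of 4 and 8 chains give mean_n = 6.
#'
#' @param frame,topo Frame and topology.
#' @param r_contact,m_contact Contact-graph thresholds.
#' @param r_loc Cross-section radial distance.
#' @param junction_rule Apply the junction-exclusion rule (default TRUE).
#' @return Object of class \code{pb_fiber_stats}: \code{per_bead} data frame
#'   (bead, chain, fiber, local_n, local_db, junction), \code{mean_n},
#'   \code{sd_n}, \code{db_mean}, \code{db_sd}, \code{n_fibers},
#'   \code{per_fiber}.
#' @export
network_stats <- function(frame, topo, r_contact = 1.5, m_contact = 3,
                          r_loc = 10, junction_rule = TRUE) {
  cg <- build_contact_graph(frame, topo, r_contact, m_contact)
  rows <- vector("list", topo$n_beads)
  for (b in seq_len(topo$n_beads)) {
    cs <- local_cross_section(frame, topo, b, r_loc)
    if (is.null(cs)) next
    rows[[b]] <- data.frame(bead = b, chain = topo$chain_id[b],
                            fiber = cg$membership[topo$chain_id[b]],
                            local_n = cs$local_n, local_db = cs$diameter)
  }
  pb <- do.call(rbind, rows)
  pb$junction <- FALSE
  if (junction_rule && nrow(pb) > 2) {
    for (ch in unique(pb$chain)) {
      r <- which(pb$chain == ch)
      v <- pb$local_n[r]
      if (length(v) < 3) next
      mid <- 2:(length(v) - 1)
      jump <- abs(v[mid] - v[mid - 1]) > 2 & abs(v[mid] - v[mid + 1]) > 2
      pb$junction[r[mid][jump]] <- TRUE
    }
  }
  keep <- pb[!pb$junction, , drop = FALSE]
  per_fiber <- do.call(rbind, lapply(split(keep, keep$fiber), function(g)
    data.frame(fiber = g$fiber[1], n_chains = length(unique(g$chain)),
               mean_n = mean(g$local_n), mean_db = mean(g$local_db),
               n_beads = nrow(g))))
  structure(list(per_bead = pb,
                 per_fiber = per_fiber,
                 mean_n = mean(per_fiber$mean_n),
                 sd_n = stats::sd(keep$local_n),
                 db_mean = mean(per_fiber$mean_db),
                 db_sd = stats::sd(keep$local_db),
                 n_fibers = nrow(per_fiber),
                 thresholds = list(r_contact = r_contact,
                                   m_contact = m_contact, r_loc = r_loc)),
            class = "pb_fiber_stats")
}

#' @export
print.pb_fiber_stats <- function(x, ...) {
  cat(sprintf("Fiber network: %d fiber(s); chains per fiber %.3g +/- %.3g; Db = %.3g +/- %.3g sigma\n",
              x$n_fibers, x$mean_n, x$sd_n, x$db_mean, x$db_sd))
  invisible(x)
}
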