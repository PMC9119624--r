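# Order parameters: inter-chain contact counts, chain clustering, radii of
# gyration of the specific patch, radial shell profiles, dwell and
# maturation kinetics.
#
# Contact definition: two beads from different chains within 2.5 sigma
# (minimum image) are in contact.  A contact between two specific beads is a
# specific contact; any contact involving a non-specifically attractive bead
# (either non-specific flavor) is a non-specific contact.  "Per bead"
# normalization: specific contacts are divided by the number of specific
# beads in the system, non-specific contacts by the total bead count.

min_image_disp <- function(d, box) d - box * round(d / box)

topology_of <- function(x) {
  if (inherits(x, "pp_system_state")) {
    list(roles = x$roles, chain_id = x$chain_id, box_edge = x$box_edge)
  } else if (inherits(x, "pp_trajectory")) {
    x$topology
  } else stop("need a pp_system_state or pp_trajectory")
}

#' Inter-chain contact counts of a single frame
#'
#' @param state A `pp_system_state` (or a position matrix if `roles`,
#'   `chain_id` and `box_edge` are given).
#' @param cutoff Contact cutoff in Angstrom; default `2.5 sigma` of the
#'   default engine parameters.
#' @param roles,chain_id,box_edge Topology, when `state` is a bare matrix.
#' @return List with raw inter-chain pair counts `n_sp_pairs`,
#'   `n_ns_pairs`, `n_any_pairs`, and the per-bead order parameters `n_sp`
#'   (specific pairs per specific bead) and `n_ns` (non-specific pairs per
#'   bead).
#' @export
contact_counts <- function(state, cutoff = 2.5 * 4.5, roles = NULL,
                           chain_id = NULL, box_edge = NULL) {
  if (inherits(state, "pp_system_state")) {
    pos <- state$positions; roles <- state$roles
    chain_id <- state$chain_id; box_edge <- state$box_edge
  } else pos <- state
  res <- cpp_contacts(pos, role_codes(roles), chain_id - 1L, box_edge, cutoff)
  n_specific <- sum(roles == "specific")
  list(n_sp_pairs = res$n_sp_pairs, n_ns_pairs = res$n_ns_pairs,
       n_any_pairs = res$n_any_pairs,
       n_sp = if (n_specific > 0) res$n_sp_pairs / n_specific else 0,
       n_ns = res$n_ns_pairs / length(roles),
       adjacency = res$adjacency)
}

#' Cluster chains of a frame into connected components
#'
#' Two chains are connected iff any inter-chain bead pair is within the
#' cutoff; clusters are the connected components of that graph.
#'
#' @inheritParams contact_counts
#' @return List with integer `labels` (one per chain) and `n_lc`, the
#'   number of chains in the largest cluster.
#' @export
cluster_chains <- function(state, cutoff = 2.5 * 4.5, roles = NULL,
                           chain_id = NULL, box_edge = NULL) {
  cc <- contact_counts(state, cutoff, roles, chain_id, box_edge)
  g <- igraph::graph_from_adjacency_matrix(cc$adjacency != 0,
                                           mode = "undirected")
  comp <- igraph::components(g)
  list(labels = as.integer(comp$membership), n_lc = max(comp$csize))
}

# Unwrap a frame across periodic boundaries: each chain is first made
# contiguous by walking its bonds with minimum-image steps; then, within
# each cluster, chains are attached to already-unwrapped neighbors by
# minimum-image displacement of their centroids (breadth-first over the
# chain contact graph).
unwrap_frame <- function(pos, chain_id, box, labels, adjacency) {
  n_chain <- max(chain_id)
  out <- pos
  for (c in seq_len(n_chain)) {
    idx <- which(chain_id == c)
    if (length(idx) > 1) {
      steps <- min_image_disp(diff(pos[idx, , drop = FALSE]), box)
      walked <- apply(steps, 2, cumsum)
      if (is.null(dim(walked))) walked <- matrix(walked, nrow = 1)
      out[idx, ] <- rbind(pos[idx[1], ],
                          sweep(walked, 2, pos[idx[1], ], "+"))
    }
  }
  cent <- t(vapply(seq_len(n_chain),
                   function(c) colMeans(out[chain_id == c, , drop = FALSE]),
                   numeric(3)))
  for (cl in unique(labels)) {
    members <- which(labels == cl)
    if (length(members) < 2) next
    done <- members[1]
    todo <- setdiff(members, done)
    while (length(todo) > 0) {
      attached <- FALSE
      for (j in todo) {
        nbrs <- done[adjacency[j, done] != 0]
        if (length(nbrs) == 0) next
        p <- nbrs[1]
        shift <- (cent[p, ] + min_image_disp(cent[j, ] - cent[p, ], box)) -
          cent[j, ]
        idx <- which(chain_id == j)
        out[idx, ] <- sweep(out[idx, , drop = FALSE], 2, shift, "+")
        cent[j, ] <- cent[j, ] + shift
        done <- c(done, j)
        todo <- setdiff(todo, j)
        attached <- TRUE
        break
      }
      if (!attached) break  # defensive; components guarantee attachment
    }
  }
  out
}

#' Radius of gyration of the specific beads
#'
#' `Rg_red` is the root-mean-square distance of all specific beads from
#' their centroid, computed on cluster-unwrapped coordinates; `Rg_norm`
#' divides by the frame's largest-cluster size `N_lc` (the printed
#' normalization of the model, units Angstrom per chain count).
#'
#' @inheritParams contact_counts
#' @return List with `rg_red` (A), `rg_norm` (A, `rg_red / n_lc`) and
#'   `n_lc`.
#' @export
rg_specific <- function(state, cutoff = 2.5 * 4.5, roles = NULL,
                        chain_id = NULL, box_edge = NULL) {
  if (inherits(state, "pp_system_state")) {
    pos <- state$positions; roles <- state$roles
    chain_id <- state$chain_id; box_edge <- state$box_edge
  } else pos <- state
  if (sum(roles == "specific") < 1) stop("no specific beads in system")
  cc <- contact_counts(pos, cutoff, roles, chain_id, box_edge)
  cl <- cluster_chains(pos, cutoff, roles, chain_id, box_edge)
  up <- unwrap_frame(pos, chain_id, box_edge, cl$labels, cc$adjacency)
  red <- up[roles == "specific", , drop = FALSE]
  cen <- colMeans(red)
  rg <- sqrt(mean(rowSums(sweep(red, 2, cen)^2)))
  list(rg_red = rg, rg_norm = rg / cl$n_lc, n_lc = cl$n_lc)
}

#' Radial shell profile of the specific beads
#'
#' Concentric spherical shells of fixed width are drawn about the center of
#' the largest cluster when a multimer exists (`N_lc >= 2`), else about the
#' box center (freely diffusing state). Per shell the fraction of specific
#' beads (denominator: specific beads of the largest cluster when a
#' multimer exists, else all specific beads in the system) and their number
#' density `phi_red = N_red_in_shell / ((4/3) pi (R2^3 - R1^3))` are
#' reported.
#'
#' @inheritParams contact_counts
#' @param shell_width Shell thickness, Angstrom (default 3).
#' @param r_max Outer radius of the last shell; default half the box edge.
#' @return `data.frame` with columns `r_inner`, `r_outer`, `count`,
#'   `fraction`, `phi_red`, plus attributes `center` and `multimer`.
#' @export
shell_profile <- function(state, cutoff = 2.5 * 4.5, shell_width = 3,
                          r_max = NULL, roles = NULL, chain_id = NULL,
                          box_edge = NULL) {
  if (inherits(state, "pp_system_state")) {
    pos <- state$positions; roles <- state$roles
    chain_id <- state$chain_id; box_edge <- state$box_edge
  } else pos <- state
  if (is.null(r_max)) r_max <- box_edge / 2
  cc <- contact_counts(pos, cutoff, roles, chain_id, box_edge)
  cl <- cluster_chains(pos, cutoff, roles, chain_id, box_edge)
  multimer <- cl$n_lc >= 2
  if (multimer) {
    up <- unwrap_frame(pos, chain_id, box_edge, cl$labels, cc$adjacency)
    big <- which.max(tabulate(cl$labels))
    in_big <- cl$labels[chain_id] == big
    center <- colMeans(up[in_big, , drop = FALSE])
    red_idx <- which(roles == "specific" & in_big)
    d <- sqrt(rowSums(sweep(up[red_idx, , drop = FALSE], 2, center)^2))
    denom <- length(red_idx)
  } else {
    center <- rep(box_edge / 2, 3)
    red_idx <- which(roles == "specific")
    disp <- min_image_disp(sweep(pos[red_idx, , drop = FALSE], 2, center),
                           box_edge)
    d <- sqrt(rowSums(disp^2))
    denom <- length(red_idx)
  }
  edges <- seq(0, r_max + shell_width, by = shell_width)
  counts <- vapply(seq_len(length(edges) - 1), function(k) {
    sum(d >= edges[k] & d < edges[k + 1])
  }, 1L)
  vol <- (4 / 3) * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  out <- data.frame(r_inner = edges[-length(edges)], r_outer = edges[-1],
                    count = counts,
                    fraction = if (denom > 0) counts / denom else 0,
                    phi_red = counts / vol)
  attr(out, "center") <- center
  attr(out, "multimer") <- multimer
  out
}

#' Per-frame contact series of a trajectory
#'
#' @param traj A `pp_trajectory`.
#' @param cutoff Contact cutoff, Angstrom; defaults to `2.5 sigma` of the
#'   trajectory's engine parameters.
#' @param include_rg Also compute `rg_red`/`rg_norm` per frame (slower).
#' @return `data.frame` with one row per frame: `time` (fs), raw pair
#'   counts, per-bead `n_sp` and `n_ns`, `n_lc`, and optionally `rg_red`,
#'   `rg_norm`.
#' @export
contact_series <- function(traj, cutoff = NULL, include_rg = FALSE) {
  stopifnot(inherits(traj, "pp_trajectory"))
  top <- traj$topology
  if (is.null(cutoff)) {
    p <- traj$metadata$params
    cutoff <- if (!is.null(p)) 2.5 * p$sigma else 2.5 * 4.5
  }
  m <- cpp_contact_series(traj$frames, role_codes(top$roles),
                          top$chain_id - 1L, top$box_edge, cutoff)
  n_specific <- sum(top$roles == "specific")
  out <- data.frame(time = traj$times, n_sp_pairs = m[, "n_sp_pairs"],
                    n_ns_pairs = m[, "n_ns_pairs"],
                    n_any_pairs = m[, "n_any_pairs"], n_lc = m[, "n_lc"])
  out$n_sp <- if (n_specific > 0) out$n_sp_pairs / n_specific else 0
  out$n_ns <- out$n_ns_pairs / length(top$roles)
  if (include_rg) {
    rg <- vapply(seq_len(n_frames(traj)), function(k) {
      r <- rg_specific(frame_positions(traj, k), cutoff, roles = top$roles,
                       chain_id = top$chain_id, box_edge = top$box_edge)
      c(r$rg_red, r$rg_norm)
    }, numeric(2))
    out$rg_red <- rg[1, ]
    out$rg_norm <- rg[2, ]
  }
  out
}

#' Dwell-time analysis of a two-chain trajectory
#'
#' The chains are "in contact" in a frame when any inter-chain bead pair is
#' within the cutoff. Dwell intervals are maximal runs of consecutive
#' in-contact frames (length = run length x frame interval); an interval
#' still open at the trajectory end is flagged censored and enters the mean
#' at its censored length (the simulation timescale is the upper limit).
#'
#' @inheritParams contact_series
#' @return Object of class `pp_kinetics` with `dwell_intervals` (fs),
#'   `dwell_censored` (logical flags) and `t_dwell` (mean, fs; `NA` if the
#'   chains never touch).
#' @export
dwell_times <- function(traj, cutoff = NULL) {
  cs <- contact_series(traj, cutoff)
  if (length(unique(traj$topology$chain_id)) != 2) {
    stop("dwell-time analysis requires a two-chain trajectory")
  }
  frame_dt <- if (length(traj$times) > 1) diff(traj$times)[1] else 0
  r <- rle(cs$n_any_pairs > 0)
  lens <- r$lengths[r$values]
  if (length(lens) == 0) {
    res <- list(dwell_intervals = numeric(0), dwell_censored = logical(0),
                t_dwell = NA_real_)
  } else {
    censored <- logical(length(lens))
    if (r$values[length(r$values)]) censored[length(censored)] <- TRUE
    intervals <- lens * frame_dt
    res <- list(dwell_intervals = intervals, dwell_censored = censored,
                t_dwell = mean(intervals))
  }
  structure(res, class = "pp_kinetics")
}

#' Maturation-time analysis of a two-chain trajectory
#'
#' The clock starts at the first in-contact frame where the raw inter-chain
#' specific-contact count is below `n_sp_threshold` (the non-specific
#' dimer). Maturation is reached at the first later frame where the count
#' is at least the threshold and stays there for every frame spanning the
#' next `stability_ns` nanoseconds. Trajectories that never mature (or
#' never form the non-specific dimer, or whose stability window cannot be
#' verified before the trajectory ends) report the trajectory length,
#' flagged censored. A first contact made directly at or above the
#' threshold (and sustained) gives a maturation time of zero.
#'
#' @inheritParams contact_series
#' @param n_sp_threshold Raw specific-contact count defining maturity
#'   (default 10).
#' @param stability_ns Required persistence of the mature state, ns
#'   (default 20).
#' @param smooth_ns Width (ns) of the centered moving-average window
#'   applied to the specific-contact count before thresholding (default 1).
#'   The contact count is a fluctuating order parameter; single-frame
#'   recrossings of the threshold at fine sampling are noise, not departures
#'   from the mature configuration, and under a strictly per-frame rule no
#'   finite maturation time would ever be observed. `smooth_ns = 0` gives
#'   the literal per-frame rule.
#' @return Object of class `pp_kinetics` with `t_mature` (fs) and
#'   `mature_censored`.
#' @export
maturation_times <- function(traj, cutoff = NULL, n_sp_threshold = 10,
                             stability_ns = 20, smooth_ns = 1) {
  cs <- contact_series(traj, cutoff)
  if (length(unique(traj$topology$chain_id)) != 2) {
    stop("maturation analysis requires a two-chain trajectory")
  }
  span <- traj$times[nrow(cs)] - traj$times[1]
  censored <- list(t_mature = span, mature_censored = TRUE)
  in_contact <- cs$n_any_pairs > 0
  first <- which(in_contact)[1]
  if (is.na(first)) {
    return(structure(censored, class = "pp_kinetics"))
  }
  n_sp_state <- cs$n_sp_pairs
  if (smooth_ns > 0 && nrow(cs) > 2) {
    frame_dt <- diff(cs$time)[1]
    half <- min(floor(smooth_ns * 1e6 / frame_dt / 2),
                floor((nrow(cs) - 1) / 2))
    if (half >= 1) {
      k <- 2 * half + 1
      sm <- stats::filter(cs$n_sp_pairs, rep(1 / k, k), sides = 2)
      # edges keep the raw counts (no partial-window extrapolation)
      n_sp_state <- ifelse(is.na(sm), cs$n_sp_pairs, as.numeric(sm))
    }
  }
  hot <- n_sp_state >= n_sp_threshold
  stab_fs <- stability_ns * 1e6
  nfr <- nrow(cs)
  stable_at <- function(k) {
    # all frames spanning [t_k, t_k + window] must be at/above threshold,
    # and the window must fit inside the trajectory
    t_end <- cs$time[k] + stab_fs
    if (cs$time[nfr] < t_end) return(FALSE)
    upto <- which(cs$time >= t_end)[1]
    all(hot[k:upto])
  }
  # already mature (and sustained) at first touch: zero maturation time
  if (hot[first] && stable_at(first)) {
    return(structure(list(t_mature = 0, mature_censored = FALSE),
                     class = "pp_kinetics"))
  }
  clock <- which(in_contact & !hot)[1]  # first non-specific dimer frame
  if (is.na(clock)) {
    return(structure(censored, class = "pp_kinetics"))
  }
  for (k in clock:nfr) {
    if (hot[k] && stable_at(k)) {
      return(structure(list(t_mature = cs$time[k] - cs$time[clock],
                            mature_censored = FALSE),
                       class = "pp_kinetics"))
    }
  }
  structure(censored, class = "pp_kinetics")
}

#' @export
print.pp_kinetics <- function(x, ...) {
  if (!is.null(x$dwell_intervals)) {
    cat(sprintf("Dwell: %d interval(s), mean T_dwell = %g fs (%d censored)\n",
                length(x$dwell_intervals),
                if (length(x$dwell_intervals)) mean(x$dwell_intervals) else NA,
                sum(x$dwell_censored)))
  }
  if (!is.null(x$t_mature)) {
    cat(sprintf("Maturation: T_mature = %g fs%s\n", x$t_mature,
                if (isTRUE(x$mature_censored)) " (censored)" else ""))
  }
  invisible(x)
}
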