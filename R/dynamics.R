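# R-level dynamics interface over the compiled engine: force field
# resolution, energy/force evaluation, Langevin stepping and trajectories.

role_codes <- function(roles) {
  m <- match(roles, BEAD_ROLES)
  if (anyNA(m)) stop("unknown bead role")
  m - 1L
}

#' Resolve a force field from an interaction table
#'
#' Converts the k_B T interaction strengths to kcal/mol at the table's
#' reference temperature (done once: the potential is temperature
#' independent across a replica ladder) and resolves per-role-pair LJ depths
#' and cutoffs: attractive pairs are truncated (unshifted) at `2.5 sigma`;
#' repulsive-only pairs use a 1 k_B T depth truncated at `2^(1/6) sigma` so
#' only the repulsive branch acts. Directly bonded (1-2) pairs are excluded
#' from non-bonded interactions.
#'
#' @param table An [interaction_table()].
#' @param params Engine parameters.
#' @return Object of class `pp_force_field` with 4x4 matrices `eps_kcal`
#'   and `r_cut` indexed by role.
#' @export
force_field <- function(table, params = engine_params()) {
  stopifnot(inherits(table, "pp_interaction_table"),
            inherits(params, "pp_engine_params"))
  eps_kcal <- kBT_to_kcal(table$eps, table$T_ref)
  r_cut <- matrix(params$r_cut_attr, 4, 4,
                  dimnames = dimnames(table$eps))
  rep_pairs <- table$mode == "repulsive_only"
  # inert/cross-flavor pairs: WCA-style purely repulsive truncation
  eps_kcal[rep_pairs] <- kBT_to_kcal(1, table$T_ref)
  r_cut[rep_pairs] <- 2^(1 / 6) * params$sigma
  # a cross-flavor "repulsive" pair between two attractive flavors keeps
  # excluded volume; fully inactive pairs would be eps == 0 attractive only
  zero_attr <- table$eps == 0 & table$mode == "attractive"
  eps_kcal[zero_attr] <- 0
  structure(list(eps_kcal = eps_kcal, r_cut = r_cut, table = table,
                 params = params),
            class = "pp_force_field")
}

#' Potential energy terms and forces of a configuration
#'
#' Evaluates the three energy terms -- harmonic stretching
#' `k_s (r - r0)^2`, bending `kappa (1 - cos theta)` and truncated
#' Lennard-Jones -- together with their analytic forces, using
#' minimum-image distances in the periodic cubic box.
#'
#' @param state A `pp_system_state`.
#' @param ff A [force_field()].
#' @return List with energies `e_stretch`, `e_bend`, `e_pair` (kcal/mol),
#'   the matching N x 3 force matrices `f_stretch`, `f_bend`, `f_pair`
#'   (kcal/mol/A), and their totals `e_total`, `f_total`.
#' @export
energy_forces <- function(state, ff) {
  stopifnot(inherits(ff, "pp_force_field"))
  p <- ff$params
  out <- cpp_energy_forces(state$positions, role_codes(state$roles),
                           state$chain_id - 1L, state$box_edge,
                           list(ks = p$ks, r0 = p$r0, kappa = p$kappa,
                                sigma = p$sigma),
                           ff$eps_kcal, ff$r_cut)
  out$e_total <- out$e_stretch + out$e_bend + out$e_pair
  out$f_total <- out$f_stretch + out$f_bend + out$f_pair
  out
}

#' @rdname energy_forces
#' @export
stretch_energy <- function(state, ff) energy_forces(state, ff)$e_stretch

#' @rdname energy_forces
#' @export
bend_energy <- function(state, ff) energy_forces(state, ff)$e_bend

#' @rdname energy_forces
#' @export
pair_energy <- function(state, ff) energy_forces(state, ff)$e_pair

new_trajectory <- function(topology, times, frames, metadata = list(),
                           pe = NULL, ke_temp = NULL, bond_len = NULL,
                           final_vel = NULL) {
  structure(list(topology = topology, times = times, frames = frames,
                 metadata = metadata, pe = pe, ke_temp = ke_temp,
                 bond_len = bond_len, final_vel = final_vel),
            class = "pp_trajectory")
}

#' @export
print.pp_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d beads, %d chains, %d frames, t = %g..%g fs\n",
              dim(x$frames)[1], length(unique(x$topology$chain_id)),
              dim(x$frames)[3], x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pp_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$frames)[3]

#' Extract one frame of a trajectory as a position matrix
#' @param traj A `pp_trajectory`.
#' @param k Frame index (1-based).
#' @return N x 3 matrix of positions.
#' @export
frame_positions <- function(traj, k) {
  matrix(traj$frames[, , k], ncol = 3)
}

#' Run Langevin dynamics
#'
#' Advances the system with the BAOAB splitting of Langevin dynamics
#' (friction `1/damping_time` per bead, exact Ornstein-Uhlenbeck noise
#' step), whose stationary distribution is the NVT ensemble at the engine
#' temperature. Positions are wrapped into the periodic box every step. A
#' Verlet neighbor list with `0.5 sigma` skin, rebuilt whenever any bead has
#' moved more than half the skin, accelerates the non-bonded sum without
#' changing it.
#'
#' @param state Initial `pp_system_state`.
#' @param ff Force field from [force_field()].
#' @param n_steps Number of timesteps (>= 1).
#' @param report_every Frames are stored every this many steps; the initial
#'   state is always frame 1.
#' @param seed Integer seed for the thermostat noise stream (ignored when
#'   `rng_state` is given).
#' @param rng_state Optional saved generator state (4 hex strings) for exact
#'   restarts.
#' @param use_nlist Use the neighbor list (`FALSE` forces naive all-pair
#'   evaluation; results are identical).
#' @return A `pp_trajectory`; `metadata$final_state` holds the end state and
#'   `metadata$rng_state` the generator state for restarts. Per-interval
#'   means of the instantaneous kinetic temperature (`ke_temp`, K) and of
#'   the mean bond length (`bond_len`, A) are accumulated every step.
#' @export
run_ld <- function(state, ff, n_steps, report_every = 1000, seed = 1,
                   rng_state = NULL, use_nlist = TRUE) {
  stopifnot(inherits(state, "pp_system_state"), inherits(ff, "pp_force_field"))
  if (n_steps < 1) stop("n_steps must be >= 1")
  p <- ff$params
  if (is.null(rng_state)) rng_state <- cpp_seed_rng(as.integer(seed))
  res <- cpp_run(state$positions, state$velocities, role_codes(state$roles),
                 state$chain_id - 1L, state$box_edge, state$time,
                 list(ks = p$ks, r0 = p$r0, kappa = p$kappa, sigma = p$sigma,
                      dt = p$dt, T = p$T, damping_fs = p$damping_time * 1000,
                      mass = p$mass),
                 ff$eps_kcal, ff$r_cut, as.integer(n_steps),
                 as.integer(report_every), rng_state, use_nlist)
  final_state <- structure(
    list(positions = res$final_pos, velocities = res$final_vel,
         roles = state$roles, chain_id = state$chain_id,
         box_edge = state$box_edge,
         time = state$time + n_steps * p$dt),
    class = "pp_system_state")
  new_trajectory(
    topology = list(roles = state$roles, chain_id = state$chain_id,
                    box_edge = state$box_edge),
    times = res$times, frames = res$frames,
    metadata = list(params = p, table = ff$table, seed = seed,
                    rng_state = res$rng_state, final_state = final_state,
                    n_rebuilds = res$n_rebuilds, final_pe = res$final_pe),
    pe = res$pe, ke_temp = res$ke_temp, bond_len = res$bond_len,
    final_vel = res$final_vel)
}

#' Advance the system by a single Langevin step
#'
#' One BAOAB update; identical generator state gives identical output.
#'
#' @inheritParams run_ld
#' @return List with the new `state` and the advanced `rng_state`.
#' @export
langevin_step <- function(state, ff, seed = 1, rng_state = NULL) {
  traj <- run_ld(state, ff, n_steps = 1, report_every = 1, seed = seed,
                 rng_state = rng_state, use_nlist = FALSE)
  list(state = traj$metadata$final_state, rng_state = traj$metadata$rng_state)
}
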