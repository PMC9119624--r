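# Bead roles, interaction table, engine parameters, units.
#
# The model distinguishes four bead roles:
#   specific        -- the short "functional patch" beads (strong, exclusive
#                      attraction of strength eps_sp; drawn red in the field)
#   nonspecific     -- promiscuously attractive non-core beads (eps_ns; blue)
#   inert           -- excluded-volume-only beads (black)
#   alt_nonspecific -- a second non-specific flavor that attracts itself and
#                      specific beads but is repulsive toward the first
#                      non-specific flavor (green); used in heterogeneous
#                      two-component mixtures
#
# Interaction strengths are stored in units of k_B T at a reference
# temperature and converted to kcal/mol once at engine setup; the potential
# itself is temperature independent (only the thermostat temperature varies
# across replicas).

BEAD_ROLES <- c("specific", "nonspecific", "inert", "alt_nonspecific")

#' Bead role labels
#'
#' The four bead roles of the coarse-grained model, in their canonical
#' (fixed) order. Integer role codes used internally are `0:3` in this order.
#'
#' @return Character vector of the four role labels.
#' @export
bead_roles <- function() BEAD_ROLES

#' Convert an energy from k_B T to kcal/mol
#'
#' @param eps Energy in units of k_B T (non-negative).
#' @param T_ref Reference temperature in Kelvin.
#' @return Energy in kcal/mol, `eps * k_B * T_ref` with
#'   `k_B = 0.0019872041` kcal/mol/K.
#' @examples
#' kBT_to_kcal(1.2, 310)
#' @export
kBT_to_kcal <- function(eps, T_ref) {
  if (any(!is.finite(eps)) || any(eps < 0)) {
    stop("eps must be a non-negative energy in k_B T units")
  }
  if (!is.finite(T_ref) || T_ref <= 0) stop("T_ref must be a positive temperature")
  eps * KB_KCAL * T_ref
}

#' Convert an energy from kcal/mol to k_B T
#'
#' Inverse of [kBT_to_kcal()].
#'
#' @param e Energy in kcal/mol.
#' @param T_ref Reference temperature in Kelvin.
#' @return Energy in k_B T units.
#' @export
kcal_to_kBT <- function(e, T_ref) {
  if (!is.finite(T_ref) || T_ref <= 0) stop("T_ref must be a positive temperature")
  e / (KB_KCAL * T_ref)
}

#' Pairwise interaction table
#'
#' Builds the symmetric role-pair interaction table. Specific-specific pairs
#' attract with strength `eps_sp`; pairs involving a non-specific flavor
#' attract with `eps_ns`, except that the two non-specific flavors
#' (`nonspecific` vs `alt_nonspecific`) are mutually repulsive. Pairs
#' involving inert beads are repulsive-only. Repulsive-only pairs use a
#' purely repulsive truncation of the Lennard-Jones potential (cut at
#' `2^(1/6) sigma`, WCA-style) with a depth of 1 k_B T at `T_ref`.
#'
#' @param eps_sp Specific-specific attraction, k_B T units. Must exceed
#'   `eps_ns` (the model requires specific interactions to be the stronger).
#' @param eps_ns Non-specific attraction, k_B T units (>= 0).
#' @param system_kind One of `"default"`, `"system1"`, `"system2"` (the
#'   homogeneous system and the two heterogeneous mixtures). The table is
#'   canonical across kinds; the kind is recorded for provenance and used by
#'   the system builder to decide which chain types are present.
#' @param T_ref Reference temperature (K) at which k_B T energies are
#'   anchored.
#' @return An object of class `pp_interaction_table` with elements `eps`
#'   (4x4 matrix, k_B T), `mode` (4x4 character, `"attractive"` or
#'   `"repulsive_only"`), `eps_sp`, `eps_ns`, `T_ref`, `system_kind`.
#' @examples
#' tab <- interaction_table(1.2, 0.5)
#' tab$eps["specific", "specific"]
#' @export
interaction_table <- function(eps_sp, eps_ns, system_kind = "default",
                              T_ref = 310) {
  system_kind <- match.arg(system_kind, c("default", "system1", "system2"))
  if (!is.finite(eps_ns) || eps_ns < 0) stop("eps_ns must be >= 0")
  if (!is.finite(eps_sp) || eps_sp <= eps_ns) {
    stop("eps_sp must exceed eps_ns: the model requires specific ",
         "interactions to be stronger than non-specific ones (eps_sp > eps_ns)")
  }
  r <- BEAD_ROLES
  eps <- matrix(0, 4, 4, dimnames = list(r, r))
  mode <- matrix("repulsive_only", 4, 4, dimnames = list(r, r))
  set <- function(a, b, e, m) {
    eps[a, b] <<- e; eps[b, a] <<- e
    mode[a, b] <<- m; mode[b, a] <<- m
  }
  set("specific", "specific", eps_sp, "attractive")
  set("nonspecific", "nonspecific", eps_ns, "attractive")
  set("nonspecific", "specific", eps_ns, "attractive")
  set("alt_nonspecific", "alt_nonspecific", eps_ns, "attractive")
  set("alt_nonspecific", "specific", eps_ns, "attractive")
  set("alt_nonspecific", "nonspecific", 0, "repulsive_only")
  # inert rows stay repulsive_only with eps 0
  structure(list(eps = eps, mode = mode, eps_sp = eps_sp, eps_ns = eps_ns,
                 T_ref = T_ref, system_kind = system_kind),
            class = "pp_interaction_table")
}

#' Look up the interaction between two roles
#'
#' Symmetric in role order.
#'
#' @param table An interaction table from [interaction_table()].
#' @param a,b Role labels.
#' @return List with `eps` (k_B T) and `mode`.
#' @export
interaction_lookup <- function(table, a, b) {
  stopifnot(inherits(table, "pp_interaction_table"))
  a <- match.arg(a, BEAD_ROLES)
  b <- match.arg(b, BEAD_ROLES)
  list(eps = table$eps[a, b], mode = table$mode[a, b])
}

#' @export
print.pp_interaction_table <- function(x, ...) {
  cat(sprintf("Interaction table (%s): eps_sp = %g, eps_ns = %g k_B T at %g K\n",
              x$system_kind, x$eps_sp, x$eps_ns, x$T_ref))
  print(x$eps)
  invisible(x)
}

#' Engine parameters
#'
#' Defaults are the standard coarse-grained parameter set: each bead maps
#' onto 2-3 amino acids (mass 110 Da, the mean amino-acid mass), bead size
#' and equilibrium bond length sigma = r0 = 4.5 Angstrom, harmonic bond
#' stiffness k_s = 10 kcal/mol/A^2 (the stretching energy is
#' `k_s (r - r0)^2`, written without the conventional 1/2, so the effective
#' stiffness is `2 k_s`), bending stiffness kappa = 2 kcal/mol, timestep
#' 30 fs, thermostat temperature 310 K and damping time 1.2 ps. The
#' attractive Lennard-Jones cutoff is `2.5 sigma`.
#'
#' @param ks Spring constant, kcal/mol/A^2.
#' @param r0 Equilibrium bond length, Angstrom.
#' @param kappa Bending stiffness, kcal/mol.
#' @param sigma Lennard-Jones size parameter, Angstrom.
#' @param dt Integration timestep, fs.
#' @param T Thermostat temperature, Kelvin.
#' @param damping_time Langevin damping time, ps.
#' @param mass Bead mass, Da.
#' @return Object of class `pp_engine_params`; includes the derived
#'   attractive cutoff `r_cut_attr = 2.5 * sigma`.
#' @export
engine_params <- function(ks = 10, r0 = 4.5, kappa = 2, sigma = 4.5,
                          dt = 30, T = 310, damping_time = 1.2, mass = 110) {
  vals <- c(ks = ks, r0 = r0, kappa = kappa, sigma = sigma, dt = dt, T = T,
            damping_time = damping_time, mass = mass)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    bad <- names(vals)[!is.finite(vals) | vals <= 0][1]
    stop("engine parameter '", bad, "' must be strictly positive")
  }
  structure(list(ks = ks, r0 = r0, kappa = kappa, sigma = sigma, dt = dt,
                 T = T, damping_time = damping_time, mass = mass,
                 r_cut_attr = 2.5 * sigma),
            class = "pp_engine_params")
}

#' @export
print.pp_engine_params <- function(x, ...) {
  cat(sprintf(paste0("Engine parameters: ks=%g kcal/mol/A^2, r0=%g A, ",
                     "kappa=%g kcal/mol,\n  sigma=%g A (attractive cutoff %g A), ",
                     "dt=%g fs, T=%g K, damping=%g ps, mass=%g Da\n"),
              x$ks, x$r0, x$kappa, x$sigma, x$r_cut_attr, x$dt, x$T,
              x$damping_time, x$mass))
  invisible(x)
}

#' Chain specification
#'
#' @param roles Character vector of bead roles along the chain (values from
#'   [bead_roles()]).
#' @param n_frac Optional percentage (0-100) of non-core beads that are
#'   attractive non-specific; recorded for provenance when the chain was
#'   built by [three_bead_roles()].
#' @return Object of class `pp_chain_spec` with `length`, `roles`, `n_frac`.
#' @export
chain_spec <- function(roles, n_frac = NA_real_) {
  if (!all(roles %in% BEAD_ROLES)) {
    stop("unknown bead role: ", paste(setdiff(unique(roles), BEAD_ROLES),
                                      collapse = ", "))
  }
  structure(list(length = length(roles), roles = roles, n_frac = n_frac),
            class = "pp_chain_spec")
}

#' System specification
#'
#' A full description of a simulated system: chain types with counts, the
#' periodic cubic box (given directly or derived from a target molar
#' concentration of chains), and the build seed.
#'
#' @param chains List of `list(spec = chain_spec, count = n)` entries, or a
#'   single `pp_chain_spec` with `count`.
#' @param count Convenience: if `chains` is a single chain spec, its count.
#' @param box_edge Cubic box edge in Angstrom. Exactly one of `box_edge` and
#'   `concentration` must be given.
#' @param concentration Target chain concentration in mol/L; the box edge is
#'   derived via [box_from_concentration()].
#' @param seed Integer seed controlling placement and initial velocities.
#' @param params Engine parameters (used to validate the box against the
#'   interaction cutoff).
#' @return Object of class `pp_system_spec`.
#' @export
system_spec <- function(chains, count = NULL, box_edge = NULL,
                        concentration = NULL, seed = 1,
                        params = engine_params()) {
  if (inherits(chains, "pp_chain_spec")) {
    chains <- list(list(spec = chains, count = if (is.null(count)) 1L else count))
  }
  n_chains <- sum(vapply(chains, function(ch) as.integer(ch$count), 1L))
  if (n_chains < 1) stop("at least one chain required")
  if (is.null(box_edge) == is.null(concentration)) {
    stop("give exactly one of box_edge or concentration")
  }
  if (is.null(box_edge)) {
    box_edge <- box_from_concentration(n_chains, concentration)
  }
  if (box_edge <= 2 * params$r_cut_attr) {
    stop("box_edge must exceed twice the interaction cutoff (",
         2 * params$r_cut_attr, " A)")
  }
  structure(list(chains = chains, n_chains = n_chains, box_edge = box_edge,
                 seed = as.integer(seed), params = params),
            class = "pp_system_spec")
}
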