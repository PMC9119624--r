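# System builder: role sequences, box sizing, seeded self-avoiding
# placement of chains, and deterministic fixture trajectories with known
# contact histories (ground truth for the analysis stages).

KCAL_PER_DA_TO_A_FS2 <- 4.184e-4  # (kcal/mol/A)/Da -> A/fs^2

# run body with a private RNG stream seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Default two-bead chain role sequence
#'
#' A chain of `M` beads with a contiguous central block of `patch_len`
#' specific beads starting at 0-based index `floor((M - patch_len)/2)`;
#' all remaining beads are non-specific. With the default 80-mer and a
#' 7-bead patch the non-core beads split 36 before / 37 after the patch.
#'
#' @param M Chain length in beads.
#' @param patch_len Length of the specific patch (default 7).
#' @return Character vector of roles, length `M`.
#' @examples
#' table(default_chain_roles(80, 7))
#' @export
default_chain_roles <- function(M = 80, patch_len = 7) {
  if (patch_len > M) stop("patch_len must not exceed chain length M")
  if (patch_len < 0 || M < 1) stop("M >= 1 and patch_len >= 0 required")
  roles <- rep("nonspecific", M)
  start <- floor((M - patch_len) / 2)  # 0-based
  if (patch_len > 0) roles[(start + 1):(start + patch_len)] <- "specific"
  roles
}

#' Three-bead chain role sequence
#'
#' Central specific patch as in [default_chain_roles()]; of the `M -
#' patch_len` non-core beads, exactly `round(n_frac/100 * (M - patch_len))`
#' (round-half-away-from-zero) are attractive non-specific beads, chosen
#' uniformly at random under `seed`; the remainder are inert. `n_frac`
#' denominates the non-core beads, not the whole chain.
#'
#' @param M Chain length in beads.
#' @param patch_len Specific patch length.
#' @param n_frac Percentage (0-100) of non-core beads that are attractive.
#' @param seed Integer seed for the placement of the attractive beads.
#' @return Character vector of roles, length `M`.
#' @export
three_bead_roles <- function(M = 80, patch_len = 7, n_frac = 100, seed = 1) {
  if (n_frac < 0 || n_frac > 100) stop("n_frac must be a percentage in [0, 100]")
  roles <- default_chain_roles(M, patch_len)
  non_core <- which(roles != "specific")
  n_ns <- round_half_away(n_frac / 100 * length(non_core))
  roles[non_core] <- "inert"
  if (n_ns > 0) {
    picked <- with_seed(seed, sample(non_core, n_ns))
    roles[picked] <- "nonspecific"
  }
  roles
}

#' Box edge for a target chain concentration
#'
#' `edge = (n_chains / (N_A * conc * 1e-27))^(1/3)` Angstrom, with
#' `N_A = 6.02214076e23`.
#'
#' @param n_chains Number of chains in the box.
#' @param conc Chain concentration in mol/L.
#' @return Cubic box edge in Angstrom.
#' @examples
#' box_from_concentration(30, 200e-6)  # ~629 A
#' @export
box_from_concentration <- function(n_chains, conc) {
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (!is.finite(conc) || conc <= 0) stop("conc must be a positive concentration")
  (n_chains / (N_AVOGADRO * conc * 1e-27))^(1 / 3)
}

#' Chain concentration implied by a box
#'
#' Inverse of [box_from_concentration()].
#'
#' @param n_chains Number of chains.
#' @param box_edge Cubic box edge, Angstrom.
#' @return Concentration in mol/L.
#' @export
concentration_from_box <- function(n_chains, box_edge) {
  n_chains / (N_AVOGADRO * box_edge^3 * 1e-27)
}

# expand a system spec into per-bead role / chain-id vectors
expand_spec <- function(spec) {
  roles <- character(0)
  chain_id <- integer(0)
  cid <- 0L
  for (entry in spec$chains) {
    for (k in seq_len(entry$count)) {
      cid <- cid + 1L
      roles <- c(roles, entry$spec$roles)
      chain_id <- c(chain_id, rep(cid, entry$spec$length))
    }
  }
  list(roles = roles, chain_id = chain_id)
}

#' Build an initial system configuration
#'
#' Chains are placed as self-avoiding random walks with bond length `r0`:
#' bead directions are drawn uniformly on the sphere and a candidate bead is
#' rejected if it comes within `sigma` of any already-placed non-bonded bead
#' (minimum-image). Placement retries are bounded per bead and per chain;
#' exhausting them raises an error suggesting a larger box. Velocities are
#' drawn from the Maxwell-Boltzmann distribution at the engine temperature.
#' The whole build is a deterministic function of `spec$seed`.
#'
#' @param spec A [system_spec()].
#' @param params Engine parameters; defaults to those recorded in `spec`.
#' @return Object of class `pp_system_state` with fields `positions`
#'   (N x 3, Angstrom, wrapped into `[0, box)`), `velocities` (N x 3,
#'   A/fs), `roles`, `chain_id`, `box_edge`, `time` (fs).
#' @export
build_system <- function(spec, params = spec$params) {
  stopifnot(inherits(spec, "pp_system_spec"))
  ex <- expand_spec(spec)
  n <- length(ex$roles)
  box <- spec$box_edge
  r0 <- params$r0
  sigma <- params$sigma
  sig2 <- sigma^2

  min_image_d2 <- function(p, mat) {
    d <- sweep(mat, 2, p)
    d <- d - box * round(d / box)
    rowSums(d * d)
  }

  pos <- with_seed(spec$seed, {
    placed <- matrix(NA_real_, n, 3)
    n_placed <- 0L
    chain_lens <- rle(ex$chain_id)$lengths
    for (ci in seq_along(chain_lens)) {
      M <- chain_lens[ci]
      ok_chain <- FALSE
      for (attempt in 1:60) {
        cpos <- matrix(NA_real_, M, 3)
        cpos[1, ] <- runif(3, 0, box)
        if (n_placed > 0 &&
            min(min_image_d2(cpos[1, ], placed[1:n_placed, , drop = FALSE])) < sig2) next
        fail <- FALSE
        for (b in seq_len(M)[-1]) {
          placed_b <- FALSE
          for (try in 1:150) {
            u <- rnorm(3)
            cand <- cpos[b - 1, ] + r0 * u / sqrt(sum(u * u))
            if (b > 2 &&
                min(min_image_d2(cand, cpos[1:(b - 2), , drop = FALSE])) < sig2) next
            if (n_placed > 0 &&
                min(min_image_d2(cand, placed[1:n_placed, , drop = FALSE])) < sig2) next
            cpos[b, ] <- cand
            placed_b <- TRUE
            break
          }
          if (!placed_b) { fail <- TRUE; break }
        }
        if (!fail) { ok_chain <- TRUE; break }
      }
      if (!ok_chain) {
        stop("could not place chain ", ci, " without overlaps after bounded ",
             "retries; try a larger box (current edge ", round(box, 1), " A)")
      }
      placed[(n_placed + 1):(n_placed + M), ] <- cpos
      n_placed <- n_placed + M
    }
    placed
  })

  vel <- with_seed(spec$seed + 1000003L, {
    sd_v <- sqrt(KB_KCAL * params$T * KCAL_PER_DA_TO_A_FS2 / params$mass)
    matrix(rnorm(3 * n, sd = sd_v), n, 3)
  })

  pos <- pos - box * floor(pos / box)
  structure(list(positions = pos, velocities = vel, roles = ex$roles,
                 chain_id = ex$chain_id, box_edge = box, time = 0),
            class = "pp_system_state")
}

#' @export
print.pp_system_state <- function(x, ...) {
  cat(sprintf("System state: %d beads in %d chains, box %.1f A, t = %g fs\n",
              nrow(x$positions), length(unique(x$chain_id)), x$box_edge, x$time))
  print(table(x$roles))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fixture trajectories: rigid two-chain placements realizing a scripted
# contact history exactly.  Both chains are straight rods along x with bond
# length r0; chain B is translated whole to (dx, d, 0) relative to chain A.
# The solver searches integer + fractional bead shifts and a small grid of
# separations d for a placement whose specific-contact count matches the
# script exactly (contact segments), or places the chains far apart.
# ---------------------------------------------------------------------------

fixture_solve_placement <- function(roles, r0, cutoff, sigma, n_sp,
                                    in_contact) {
  M <- length(roles)
  sp_idx <- which(roles == "specific") - 1L   # 0-based bead indices
  if (!in_contact) {
    return(list(dx = 0, d = 4 * cutoff))
  }
  count_pairs <- function(dx, d) {
    # pair (i in A, j in B): distance^2 = (r0*(j - i) + dx)^2 + d^2
    off <- outer(0:(M - 1), 0:(M - 1), function(i, j) (r0 * (j - i) + dx)^2)
    close <- off + d^2 < cutoff^2
    sp <- sum(close[sp_idx + 1L, sp_idx + 1L])
    list(sp = sp, any = sum(close))
  }
  for (d in c(10.8, 10.0, 9.0, 8.0, 7.0)) {
    if (d >= cutoff || d < sigma) next
    for (frac in c(0, 0.5, 0.25, 0.75)) {
      for (k in 0:(M - 1)) {
        dx <- (k + frac) * r0
        cnt <- count_pairs(dx, d)
        if (cnt$sp == n_sp && cnt$any >= 1) {
          return(list(dx = dx, d = d))
        }
      }
    }
  }
  stop("unsatisfiable scripted contact count: ", n_sp,
       " specific contacts cannot be realized by rigid placement")
}

#' Deterministic fixture trajectory with a scripted contact history
#'
#' Builds a two-chain trajectory of rigid placements whose per-frame contact
#' pattern is known exactly by construction, for testing the analysis
#' operations. Each script segment holds the chains either apart (no
#' contacts at all) or in contact with an exact number of inter-chain
#' specific contacts at the `2.5 sigma` cutoff.
#'
#' @param script List of segments, each `list(frames =, contact =, n_sp =)`:
#'   number of frames, whether the chains are in contact, and (for contact
#'   segments) the exact specific-contact pair count required.
#' @param params Engine parameters (geometry only; no dynamics involved).
#' @param roles Role sequence of each chain.
#' @param frame_dt Time between frames, fs.
#' @return A `pp_trajectory` whose frames realize the script.
#' @export
make_fixture_trajectory <- function(script, params = engine_params(),
                                    roles = default_chain_roles(),
                                    frame_dt = 3000) {
  stopifnot(length(script) >= 1)
  M <- length(roles)
  r0 <- params$r0
  cutoff <- params$r_cut_attr
  box <- 2 * (M * r0 + 10 * cutoff)
  a_y <- box / 2
  x0 <- box / 4
  n_frames <- sum(vapply(script, function(s) {
    if (s$frames < 1) stop("script segment durations must be positive")
    as.integer(s$frames)
  }, 1L))

  pos_a <- cbind(x0 + (0:(M - 1)) * r0, rep(a_y, M), rep(a_y, M))
  frames <- array(NA_real_, c(2 * M, 3, n_frames))
  k <- 0L
  for (s in script) {
    n_sp <- if (is.null(s$n_sp)) 0L else as.integer(s$n_sp)
    plc <- fixture_solve_placement(roles, r0, cutoff, params$sigma, n_sp,
                                   isTRUE(s$contact))
    pos_b <- cbind(x0 + (0:(M - 1)) * r0 + plc$dx, rep(a_y + plc$d, M),
                   rep(a_y, M))
    fr <- rbind(pos_a, pos_b)
    fr <- fr - box * floor(fr / box)
    for (i in seq_len(s$frames)) {
      k <- k + 1L
      frames[, , k] <- fr
    }
  }

  new_trajectory(topology = list(roles = rep(roles, 2),
                                 chain_id = rep(1:2, each = M),
                                 box_edge = box),
                 times = (seq_len(n_frames) - 1) * frame_dt,
                 frames = frames,
                 metadata = list(params = params, fixture = TRUE))
}
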