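# Parallel-tempering (replica-exchange) layer over the Langevin engine:
# temperature ladder, Metropolis configuration swaps with velocity
# rescaling, and free-energy profiles over contact order parameters.

#' Temperature ladder for replica exchange
#'
#' Uniformly spaced temperatures `T_min, T_min + dT, ..., T_max`. The range
#' must be an exact multiple of the spacing.
#'
#' @param T_min,T_max Lowest and highest replica temperatures, K.
#' @param dT Spacing, K.
#' @param swap_interval Time between swap attempts, fs (default just under
#'   0.5 ns: the largest multiple of 30 fs not exceeding it).
#' @return Object of class `pp_replica_ladder` with `temperatures` and
#'   `swap_interval`.
#' @examples
#' length(temperature_ladder(309, 4, 401)$temperatures)  # 24
#' @export
temperature_ladder <- function(T_min, dT, T_max, swap_interval = 499980) {
  if (T_max < T_min) stop("T_max must be >= T_min")
  if (dT <= 0) stop("dT must be positive")
  k <- (T_max - T_min) / dT
  if (abs(k - round(k)) > 1e-9) {
    stop("ladder range (T_max - T_min) must be divisible by dT")
  }
  structure(list(temperatures = T_min + dT * (0:round(k)),
                 swap_interval = swap_interval),
            class = "pp_replica_ladder")
}

#' Metropolis swap probability between two replicas
#'
#' `min(1, exp[(1/(k_B T_i) - 1/(k_B T_j)) * (E_i - E_j)])`: the Boltzmann
#' acceptance rule for exchanging configurations between temperatures.
#'
#' @param E_i,E_j Potential energies of the two replicas, kcal/mol.
#' @param T_i,T_j Their temperatures, K.
#' @return Acceptance probability in `[0, 1]`.
#' @export
swap_probability <- function(E_i, E_j, T_i, T_j) {
  if (T_i <= 0 || T_j <= 0) stop("temperatures must be positive")
  d_beta <- 1 / (KB_KCAL * T_i) - 1 / (KB_KCAL * T_j)
  min(1, exp(d_beta * (E_i - E_j)))
}

#' Replica-exchange Langevin dynamics
#'
#' Runs one replica per ladder temperature from a common initial
#' configuration (velocities redrawn per replica at its own temperature).
#' Every `swap_interval` of simulated time, configuration swaps are
#' attempted between neighboring temperature pairs, alternating even and
#' odd pairs on successive attempts; accepted swaps exchange positions and
#' carry velocities rescaled by `sqrt(T_new/T_old)`. Every attempt is
#' logged. Replicas are advanced sequentially; results depend only on the
#' seed, not on scheduling.
#'
#' @param spec A [system_spec()] for the simulated system.
#' @param table Interaction table.
#' @param ladder A [temperature_ladder()].
#' @param n_steps Total timesteps per replica.
#' @param report_every Frame interval in steps.
#' @param seed Master seed; per-replica thermostat streams and the swap
#'   stream are derived from it.
#' @return List with `trajectories` (one `pp_trajectory` per temperature
#'   slot, frames concatenated across segments), `swap_log` (`data.frame`:
#'   attempt time, pair indices, energies, probability, outcome),
#'   `config_id` (matrix tracking which initial configuration occupies each
#'   temperature slot after each attempt) and the `ladder`.
#' @export
run_remd <- function(spec, table, ladder, n_steps, report_every = 1000,
                     seed = 1) {
  stopifnot(inherits(ladder, "pp_replica_ladder"))
  params <- spec$params
  if (ladder$swap_interval %% params$dt != 0) {
    stop("swap_interval must be a multiple of the timestep dt")
  }
  seg_steps <- as.integer(ladder$swap_interval / params$dt)
  temps <- ladder$temperatures
  n_rep <- length(temps)
  n_seg <- max(1L, floor(n_steps / seg_steps))

  base_state <- build_system(spec)
  ffs <- lapply(temps, function(Tk) {
    p <- params
    p$T <- Tk
    force_field(table, p)
  })
  # one state per temperature slot; per-replica Maxwell-Boltzmann velocities
  states <- lapply(seq_len(n_rep), function(k) {
    st <- base_state
    sd_v <- sqrt(KB_KCAL * temps[k] * KCAL_PER_DA_TO_A_FS2 / params$mass)
    st$velocities <- with_seed(spec$seed + 7919L * k,
                               matrix(rnorm(3 * nrow(st$positions), sd = sd_v),
                                      ncol = 3))
    st
  })
  rng_states <- lapply(seq_len(n_rep),
                       function(k) cpp_seed_rng(as.integer(seed + 104729L * k)))
  config <- seq_len(n_rep)  # which initial configuration sits in each slot

  frames_acc <- vector("list", n_rep)
  times_acc <- vector("list", n_rep)
  pe_acc <- vector("list", n_rep)
  log <- list()
  config_log <- matrix(NA_integer_, n_seg, n_rep)
  pe <- numeric(n_rep)

  for (seg in seq_len(n_seg)) {
    for (k in seq_len(n_rep)) {
      traj <- run_ld(states[[k]], ffs[[k]], seg_steps, report_every,
                     rng_state = rng_states[[k]])
      states[[k]] <- traj$metadata$final_state
      rng_states[[k]] <- traj$metadata$rng_state
      pe[k] <- traj$metadata$final_pe
      drop1 <- if (seg == 1) seq_len(n_frames(traj)) else -1L
      frames_acc[[k]] <- c(frames_acc[[k]],
                           list(traj$frames[, , drop1, drop = FALSE]))
      times_acc[[k]] <- c(times_acc[[k]], list(traj$times[drop1]))
      pe_acc[[k]] <- c(pe_acc[[k]], list(traj$pe[drop1]))
    }
    # alternate even/odd neighbor pairs
    first <- if (seg %% 2 == 1) 1L else 2L
    pairs <- if (first > n_rep - 1) integer(0) else seq(first, n_rep - 1, by = 2)
    u <- with_seed(seed + 900001L + seg, runif(length(pairs)))
    for (pi in seq_along(pairs)) {
      i <- pairs[pi]; j <- i + 1L
      p_acc <- swap_probability(pe[i], pe[j], temps[i], temps[j])
      accepted <- u[pi] < p_acc
      if (accepted) {
        si <- states[[i]]; sj <- states[[j]]
        ri <- sqrt(temps[j] / temps[i])  # config i moves to slot j
        tmp_pos <- si$positions
        si$positions <- sj$positions
        sj$positions <- tmp_pos
        tmp_vel <- si$velocities
        si$velocities <- sj$velocities / ri
        sj$velocities <- tmp_vel * ri
        states[[i]] <- si; states[[j]] <- sj
        tmp <- pe[i]; pe[i] <- pe[j]; pe[j] <- tmp
        tmp <- config[i]; config[i] <- config[j]; config[j] <- tmp
      }
      log[[length(log) + 1]] <-
        data.frame(time = states[[1]]$time, i = i, j = j, E_i = pe[i],
                   E_j = pe[j], p = p_acc, accepted = accepted)
    }
    config_log[seg, ] <- config
  }

  trajectories <- lapply(seq_len(n_rep), function(k) {
    frames <- array(unlist(frames_acc[[k]]),
                    c(nrow(base_state$positions), 3,
                      sum(vapply(frames_acc[[k]],
                                 function(f) dim(f)[3], 1L))))
    new_trajectory(topology = list(roles = base_state$roles,
                                   chain_id = base_state$chain_id,
                                   box_edge = base_state$box_edge),
                   times = unlist(times_acc[[k]]), frames = frames,
                   metadata = list(params = params, table = table,
                                   temperature = temps[k], seed = seed),
                   pe = unlist(pe_acc[[k]]))
  })
  swap_log <- if (length(log)) do.call(rbind, log) else
    data.frame(time = numeric(0), i = integer(0), j = integer(0),
               E_i = numeric(0), E_j = numeric(0), p = numeric(0),
               accepted = logical(0))
  list(trajectories = trajectories, swap_log = swap_log,
       config_id = config_log, ladder = ladder)
}

#' Free-energy profile over an order parameter
#'
#' `F(b) = -ln P(b)` in units of k_B T at the stated statistical
#' temperature, from the histogram of per-frame order-parameter values,
#' shifted so the minimum is zero. Empty bins are `NA` (no value is
#' imputed).
#'
#' @param order_values Numeric per-frame values (e.g. specific contacts per
#'   specific bead at the base temperature).
#' @param bin_width Histogram bin width in order-parameter units
#'   (default 0.1).
#' @param statistical_temperature Temperature label of the profile, K.
#' @return Object of class `pp_free_energy` with `bin_center`, `F`
#'   (k_B T), `count`, `bin_width`, `statistical_temperature`.
#' @export
free_energy_profile <- function(order_values, bin_width = 0.1,
                                statistical_temperature = 309) {
  if (length(order_values) == 0) stop("no order-parameter values given")
  lo <- floor(min(order_values) / bin_width) * bin_width
  hi <- ceiling(max(order_values) / bin_width + 1e-9) * bin_width
  edges <- seq(lo, max(hi, lo + bin_width), by = bin_width)
  idx <- pmin(findInterval(order_values, edges, rightmost.closed = TRUE),
              length(edges) - 1)
  counts <- tabulate(idx, nbins = length(edges) - 1)
  p <- counts / sum(counts)
  f <- ifelse(counts > 0, -log(p), NA_real_)
  f <- f - min(f, na.rm = TRUE)
  structure(list(bin_center = edges[-length(edges)] + bin_width / 2,
                 F = f, count = counts, bin_width = bin_width,
                 statistical_temperature = statistical_temperature),
            class = "pp_free_energy")
}

#' @export
print.pp_free_energy <- function(x, ...) {
  cat(sprintf("Free-energy profile at %g K (%d bins, width %g):\n",
              x$statistical_temperature, length(x$F), x$bin_width))
  print(data.frame(bin_center = x$bin_center, F_kBT = round(x$F, 3),
                   count = x$count))
  invisible(x)
}
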