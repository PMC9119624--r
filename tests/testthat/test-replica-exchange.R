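test_that("temperature ladders are uniform and validated", {
  l <- temperature_ladder(309, 4, 401)
  expect_length(l$temperatures, 24)
  expect_equal(l$temperatures[1], 309)
  expect_equal(l$temperatures[24], 401)
  expect_true(all(abs(diff(l$temperatures) - 4) < 1e-12))
  expect_equal(temperature_ladder(309, 4, 309)$temperatures, 309)
  expect_length(temperature_ladder(300, 10, 350)$temperatures, 6)
  expect_error(temperature_ladder(300, 7, 350), "divisible")
  expect_error(temperature_ladder(350, 4, 300), "T_max")
  expect_error(temperature_ladder(300, -1, 300), "positive")
})

test_that("swap probability degenerate cases and symmetry", {
  expect_equal(swap_probability(-50, -50, 310, 350), 1)
  expect_equal(swap_probability(-10, -80, 330, 330), 1)
  expect_equal(swap_probability(120.5, 80.2, 330, 330), 1)
  set.seed(3)
  for (k in 1:20) {
    e <- rnorm(2, sd = 40); tt <- 300 + runif(2) * 100
    expect_equal(swap_probability(e[1], e[2], tt[1], tt[2]),
                 swap_probability(e[2], e[1], tt[2], tt[1]))
  }
  expect_error(swap_probability(0, 0, -1, 300), "positive")
})

test_that("mean acceptance for two harmonic oscillators matches numeric integration", {
  # oracle: E ~ Exp(beta) for a 1-D harmonic oscillator (two quadratic dof);
  # expected acceptance = int min(1, exp(d_beta (E1 - E2))) dP1 dP2,
  # evaluated independently by quadrature on a fine grid
  kB <- 0.0019872041
  b1 <- 1 / (kB * 310); b2 <- 1 / (kB * 380)
  g <- seq(0.0005, 12, by = 0.001)  # in units of kB*310 energy
  e <- g / b1
  w1 <- b1 * exp(-b1 * e) / sum(b1 * exp(-b1 * e))
  w2 <- b2 * exp(-b2 * e) / sum(b2 * exp(-b2 * e))
  acc <- outer(e, e, function(x, y) pmin(1, exp((1 / (kB * 310) - 1 / (kB * 380)) * (x - y))))
  expected <- as.numeric(w1 %*% acc %*% w2)

  set.seed(17)
  n <- 20000
  E1 <- stats::rexp(n, rate = b1)
  E2 <- stats::rexp(n, rate = b2)
  p <- vapply(seq_len(n),
              function(i) swap_probability(E1[i], E2[i], 310, 380), 1)
  se <- sd(p) / sqrt(n)
  expect_lt(abs(mean(p) - expected), 3 * se + 0.002)
})

small_spec <- function(seed = 1) {
  system_spec(chain_spec(default_chain_roles(10, 3)), count = 2,
              box_edge = 60, seed = seed)
}

test_that("a single-replica ladder degenerates to plain dynamics", {
  ladder <- temperature_ladder(310, 1, 310, swap_interval = 300 * 30)
  res <- run_remd(small_spec(), interaction_table(1.2, 0.5), ladder,
                  n_steps = 900, report_every = 300, seed = 5)
  expect_length(res$trajectories, 1)
  expect_equal(nrow(res$swap_log), 0)
  tr <- res$trajectories[[1]]
  expect_equal(n_frames(tr), 4)  # frames every 300 steps over 900 steps
  expect_true(all(diff(tr$times) > 0))
})

test_that("equal-temperature replicas always accept swaps", {
  ladder <- structure(list(temperatures = c(310, 310),
                           swap_interval = 200 * 30),
                      class = "pp_replica_ladder")
  res <- run_remd(small_spec(), interaction_table(1.2, 0.5), ladder,
                  n_steps = 1000, report_every = 200, seed = 2)
  expect_gt(nrow(res$swap_log), 0)
  expect_true(all(res$swap_log$p == 1))
  expect_true(all(res$swap_log$accepted))
})

test_that("exchange conserves replica count and temperature occupancy", {
  ladder <- temperature_ladder(309, 30, 399, swap_interval = 150 * 30)
  res <- run_remd(small_spec(), interaction_table(1.2, 0.8), ladder,
                  n_steps = 1500, report_every = 150, seed = 9)
  expect_length(res$trajectories, 4)
  # each attempt row references a valid neighbor pair
  expect_true(all(res$swap_log$j == res$swap_log$i + 1))
  # every temperature slot holds exactly one configuration at all times
  for (seg in seq_len(nrow(res$config_id))) {
    expect_setequal(res$config_id[seg, ], 1:4)
  }
  # alternation: odd attempts start at pair 1, even at pair 2
  segs <- unique(res$swap_log$time)
  first_pair <- vapply(segs, function(s) min(res$swap_log$i[res$swap_log$time == s]), 1)
  expect_true(all(first_pair[c(TRUE, FALSE)] == 1))
  if (length(first_pair) > 1) expect_true(all(first_pair[c(FALSE, TRUE)] == 2))
})

test_that("swapping preserves the sampled distribution (two-bead toy)", {
  # base-temperature bond-length statistics with and without exchange
  spec <- system_spec(chain_spec(rep("nonspecific", 2)), count = 1,
                      box_edge = 60, seed = 3)
  tab <- interaction_table(1.2, 0.5)
  ladder <- temperature_ladder(310, 60, 370, swap_interval = 50 * 30)
  res <- run_remd(spec, tab, ladder, n_steps = 6e4, report_every = 10,
                  seed = 21)
  expect_gt(mean(res$swap_log$accepted), 0.05)  # swaps actually happen
  mi_bond <- function(traj, box) {
    vapply(seq_len(n_frames(traj)), function(k) {
      d <- frame_positions(traj, k)[1, ] - frame_positions(traj, k)[2, ]
      sqrt(sum((d - box * round(d / box))^2))
    }, 1)
  }
  r_swap <- mi_bond(res$trajectories[[1]], 60)[-(1:1000)]
  # independent plain run at the base temperature
  st <- build_system(spec)
  tr <- run_ld(st, force_field(tab, spec$params), 6e4, report_every = 10,
               seed = 22)
  r_plain <- mi_bond(tr, 60)[-(1:1000)]
  # means agree within combined stochastic error (conservative allowance)
  expect_lt(abs(mean(r_swap) - mean(r_plain)), 0.02)
  expect_lt(abs(var(r_swap) - var(r_plain)) / var(r_plain), 0.25)
})

test_that("free-energy profiles follow -ln P with min at zero", {
  vals <- c(rep(0.05, 25), rep(0.15, 25), rep(0.25, 25), rep(0.35, 25))
  prof <- free_energy_profile(vals, bin_width = 0.1)
  expect_true(all(abs(prof$F) < 1e-12))

  two <- c(rep(0.05, 80), rep(0.15, 20))
  p2 <- free_energy_profile(two, bin_width = 0.1)
  expect_equal(p2$F[1], 0)
  expect_equal(p2$F[2], log(4), tolerance = 1e-12)

  delta <- rep(0.42, 50)
  pd <- free_energy_profile(delta, bin_width = 0.1)
  expect_equal(sum(!is.na(pd$F)), 1)
  expect_equal(pd$F[!is.na(pd$F)], 0)

  expect_error(free_energy_profile(numeric(0)), "no order-parameter")
})

test_that("empty bins between occupied ones carry NA, not imputed values", {
  vals <- c(rep(0.05, 50), rep(0.45, 50))
  prof <- free_energy_profile(vals, bin_width = 0.1)
  expect_true(all(is.na(prof$F[2:4])))
  expect_equal(prof$F[c(1, 5)], c(0, 0))
})
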