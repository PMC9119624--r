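p <- engine_params()
tab <- interaction_table(1.2, 0.5)
ff <- force_field(tab, p)

test_that("force-field resolution converts units and truncations", {
  expect_equal(ff$eps_kcal["specific", "specific"], 1.2 * KB * 310)
  expect_equal(ff$r_cut["specific", "specific"], 11.25)
  expect_equal(ff$r_cut["inert", "specific"], 2^(1 / 6) * 4.5)
  expect_equal(ff$eps_kcal["inert", "inert"], KB * 310)  # 1 k_B T depth
  ff0 <- force_field(interaction_table(1.2, 0), p)
  expect_equal(ff0$eps_kcal["nonspecific", "nonspecific"], 0)
})

test_that("stretching energy follows the printed form (no 1/2 factor)", {
  st <- raw_state(cbind(50 + c(0, 4.5, 9.0), 50, 50), rep("nonspecific", 3),
                  rep(1L, 3), 200)
  expect_equal(stretch_energy(st, ff), 0)
  st$positions[3, 1] <- 50 + 4.5 + 5.5  # one bond stretched to 5.5 A
  expect_equal(stretch_energy(st, ff), 10 * 1.0^2)
})

test_that("bending energy is kappa (1 - cos theta)", {
  straight <- raw_state(cbind(50 + c(0, 4.5, 9.0), 50, 50),
                        rep("nonspecific", 3), rep(1L, 3), 200)
  expect_equal(bend_energy(straight, ff), 0)
  right <- straight
  right$positions <- rbind(c(50, 50, 50), c(54.5, 50, 50), c(54.5, 54.5, 50))
  expect_equal(bend_energy(right, ff), 2 * (1 - 0))
  folded <- straight
  folded$positions <- rbind(c(50, 50, 50), c(54.5, 50, 50), c(52.5, 50, 50))
  expect_equal(bend_energy(folded, ff), 2 * 2)  # theta = pi: 2 kappa
})

test_that("pair energy has its zero at sigma and minimum -eps at 2^(1/6) sigma", {
  two <- function(r) raw_state(rbind(c(50, 50, 50), c(50 + r, 50, 50)),
                               rep("specific", 2), 1:2, 200)
  expect_equal(pair_energy(two(4.5), ff), 0, tolerance = 1e-12)
  eps_sp_kcal <- 1.2 * KB * 310
  expect_equal(pair_energy(two(2^(1 / 6) * 4.5), ff), -eps_sp_kcal,
               tolerance = 1e-12)
  # beyond the cutoff: exactly zero energy and force
  beyond <- energy_forces(two(11.26), ff)
  expect_identical(beyond$e_pair, 0)
  expect_true(all(beyond$f_pair == 0))
  inside <- energy_forces(two(11.24), ff)
  expect_lt(inside$e_pair, 0)
})

test_that("pair energy equals the all-pairs oracle on random states", {
  set.seed(42)
  for (rep in 1:5) {
    st <- random_frame(2, 25, box = 60, spread = 14)
    got <- suppressWarnings(pair_energy(st, ff))
    want <- oracle_pair_energy(st, ff)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("analytic forces match central-difference gradients", {
  set.seed(7)
  for (rep in 1:3) {
    # two short chains, mildly perturbed from a sane geometry
    base <- build_system(system_spec(chain_spec(default_chain_roles(6, 2)),
                                     count = 2, box_edge = 60, seed = rep))
    st <- base
    st$positions <- st$positions + matrix(rnorm(nrow(st$positions) * 3,
                                                sd = 0.2), ncol = 3)
    ef <- energy_forces(st, ff)
    for (term in c("stretch", "bend", "pair")) {
      g <- numeric_gradient(st, ff, paste0("e_", term))
      expect_lt(max(abs(ef[[paste0("f_", term)]] + g)), 1e-6)
    }
  }
})

test_that("net force vanishes (translation invariance under PBC)", {
  set.seed(11)
  for (rep in 1:5) {
    st <- build_system(system_spec(chain_spec(default_chain_roles(12, 3)),
                                   count = 3, box_edge = 50, seed = rep))
    st$positions <- st$positions + matrix(rnorm(108, sd = 0.3), ncol = 3)
    ef <- energy_forces(st, ff)
    expect_lt(max(abs(colSums(ef$f_total))), 1e-9)
  }
})

test_that("zero-length bonds are rejected", {
  st <- raw_state(rbind(c(50, 50, 50), c(50, 50, 50), c(54.5, 50, 50)),
                  rep("nonspecific", 3), rep(1L, 3), 200)
  expect_error(energy_forces(st, ff), "zero-length bond")
})

test_that("close overlaps trigger a warning but still return an energy", {
  st <- raw_state(rbind(c(50, 50, 50), c(51, 50, 50)),
                  rep("nonspecific", 2), 1:2, 200)  # r = 1 < 0.3 sigma
  expect_warning(e <- energy_forces(st, ff), "0.3 sigma")
  expect_true(is.finite(e$e_pair))
})

test_that("runs are deterministic and restartable from saved rng state", {
  st <- build_system(dimer_spec(seed = 2))
  t1 <- run_ld(st, ff, 300, report_every = 100, seed = 5)
  t2 <- run_ld(st, ff, 300, report_every = 100, seed = 5)
  expect_identical(t1$frames, t2$frames)
  expect_identical(t1$metadata$rng_state, t2$metadata$rng_state)

  # run 200 steps, then 100 more from the saved state == a single 300-step run
  a <- run_ld(st, ff, 200, report_every = 100, seed = 5)
  b <- run_ld(a$metadata$final_state, ff, 100, report_every = 100,
              rng_state = a$metadata$rng_state)
  expect_equal(frame_positions(b, 2), frame_positions(t1, 4),
               tolerance = 1e-12)
})

test_that("neighbor-list and naive evaluation give identical trajectories", {
  st <- build_system(dimer_spec(seed = 3, box = 80))
  with_list <- run_ld(st, ff, 100, report_every = 10, seed = 9,
                      use_nlist = TRUE)
  naive <- run_ld(st, ff, 100, report_every = 10, seed = 9,
                  use_nlist = FALSE)
  expect_equal(with_list$frames, naive$frames, tolerance = 1e-10)
  expect_gt(with_list$metadata$n_rebuilds, 0)
})

test_that("frame bookkeeping and argument validation behave", {
  st <- build_system(dimer_spec(seed = 2))
  expect_error(run_ld(st, ff, 0), "n_steps")
  tr <- run_ld(st, ff, 2500, report_every = 1000, seed = 1)
  expect_equal(n_frames(tr), floor(2500 / 1000) + 1)
  expect_true(all(diff(tr$times) > 0))
  expect_equal(tr$times[2] - tr$times[1], 1000 * 30)
})

test_that("free single bead drifts ballistically in the frictionless limit", {
  pfree <- engine_params(damping_time = 1e12)  # effectively no thermostat
  st <- raw_state(matrix(c(10, 10, 10), 1), "nonspecific", 1L, 1000,
                  vel = matrix(c(1e-3, 2e-3, -1e-3), 1))
  ffree <- force_field(tab, pfree)
  tr <- run_ld(st, ffree, 100, report_every = 100, seed = 1)
  expect_equal(frame_positions(tr, 2)[1, ],
               c(10, 10, 10) + c(1e-3, 2e-3, -1e-3) * 100 * 30,
               tolerance = 1e-4)
})

test_that("coincident non-bonded beads blow up with a named error", {
  st <- raw_state(rbind(c(50, 50, 50), c(50, 50, 50)),
                  rep("nonspecific", 2), 1:2, 200)
  expect_error(run_ld(st, ff, 10, report_every = 10, seed = 1), "blew up")
})

test_that("single Langevin steps equal a one-step run", {
  st <- build_system(dimer_spec(seed = 6))
  s1 <- langevin_step(st, ff, seed = 3)
  tr <- run_ld(st, ff, 1, report_every = 1, seed = 3)
  expect_equal(s1$state$positions, tr$metadata$final_state$positions,
               tolerance = 1e-12)
})

test_that("equipartition on a single harmonic bond: var(r) = k_B T / (2 k_s)", {
  st <- build_system(system_spec(chain_spec(rep("nonspecific", 2)), count = 1,
                                 box_edge = 60, seed = 1))
  tr <- run_ld(st, ff, 4e5, report_every = 20, seed = 12)
  r <- vapply(seq_len(n_frames(tr)), function(k) {
    d <- frame_positions(tr, k)
    sqrt(sum((d[1, ] - d[2, ] -
                60 * round((d[1, ] - d[2, ]) / 60))^2))
  }, 1)
  r <- r[-(1:2000)]  # discard equilibration
  expect_equal(var(r), KB * 310 / (2 * 10), tolerance = 0.05)
  expect_equal(mean(r), 4.5, tolerance = 0.01)
})

test_that("kinetic temperature relaxes to the thermostat set point", {
  st <- build_system(system_spec(chain_spec(default_chain_roles(80, 7)),
                                 count = 1, box_edge = 300, seed = 2))
  tr <- run_ld(st, ff, 1.5e5, report_every = 500, seed = 4)
  t_kin <- mean(tr$ke_temp[-(1:60)])
  expect_equal(t_kin, 310, tolerance = 0.03)
})
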