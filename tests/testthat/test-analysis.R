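cutoff <- 2.5 * 4.5

test_that("contact classification applies the cutoff at the boundary", {
  two <- function(r, roles) raw_state(rbind(c(40, 40, 40), c(40 + r, 40, 40)),
                                      roles, 1:2, 150)
  blue <- rep("nonspecific", 2)
  expect_equal(contact_counts(two(11.0, blue), cutoff)$n_ns_pairs, 1)
  expect_equal(contact_counts(two(11.5, blue), cutoff)$n_ns_pairs, 0)
  red <- rep("specific", 2)
  expect_equal(contact_counts(two(11.0, red), cutoff)$n_sp_pairs, 1)
  # mixed pair counts as non-specific, not specific
  mixed <- contact_counts(two(5, c("specific", "nonspecific")), cutoff)
  expect_equal(mixed$n_sp_pairs, 0)
  expect_equal(mixed$n_ns_pairs, 1)
  # specific-inert within range is neither specific nor non-specific
  ri <- contact_counts(two(5, c("specific", "inert")), cutoff)
  expect_equal(ri$n_sp_pairs + ri$n_ns_pairs, 0)
  expect_equal(ri$n_any_pairs, 1)
})

test_that("well-separated chains report zero contacts", {
  # two straight 10-mers placed far apart in a large box
  rod <- function(origin) cbind(origin[1] + (0:9) * 4.5, origin[2], origin[3])
  st <- raw_state(rbind(rod(c(20, 20, 20)), rod(c(400, 400, 400))),
                  rep(default_chain_roles(10, 3), 2),
                  rep(1:2, each = 10), 500)
  cc <- contact_counts(st, cutoff)
  expect_equal(cc$n_any_pairs, 0)
  expect_equal(cc$n_sp, 0)
  expect_equal(cc$n_ns, 0)
})

test_that("contacts, clusters, Rg and shells match brute-force oracles", {
  set.seed(101)
  n_checked <- 0
  for (rep in 1:100) {
    st <- random_frame(n_chains = sample(2:4, 1),
                       beads_per_chain = sample(4:12, 1),
                       box = 80, spread = 18)
    cc <- contact_counts(st, cutoff)
    oc <- oracle_contacts(st, cutoff)
    expect_equal(cc$n_sp_pairs, oc$n_sp_pairs)
    expect_equal(cc$n_ns_pairs, oc$n_ns_pairs)
    expect_equal(cc$n_any_pairs, oc$n_any_pairs)
    expect_equal(unname(cc$adjacency != 0), unname(oc$adj != 0))

    cl <- cluster_chains(st, cutoff)
    ocl <- oracle_clusters(oc$adj)
    expect_equal(cl$n_lc, ocl$n_lc)
    # same partition up to label permutation
    expect_equal(outer(cl$labels, cl$labels, "=="),
                 outer(ocl$labels, ocl$labels, "=="))

    if (sum(st$roles == "specific") > 0) {
      rg <- rg_specific(st, cutoff)
      expect_equal(rg$rg_red, oracle_rg(st), tolerance = 1e-10)
      expect_equal(rg$rg_norm * rg$n_lc, rg$rg_red, tolerance = 1e-12)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 80)
})

test_that("Rg degenerate cases follow the definition", {
  # all specific beads coincident -> 0
  pos <- rbind(c(40, 40, 40), c(40, 40, 40), c(60, 60, 60))
  st <- raw_state(pos, c("specific", "specific", "nonspecific"),
                  c(1L, 2L, 3L), 150)
  expect_equal(rg_specific(st, cutoff)$rg_red, 0)
  # two specific beads 2d apart -> Rg = d
  st2 <- raw_state(rbind(c(40, 40, 40), c(40 + 16, 40, 40)),
                   rep("specific", 2), 1:2, 150)
  expect_equal(rg_specific(st2, cutoff)$rg_red, 8)
  st3 <- raw_state(rbind(c(40, 40, 40)), "nonspecific", 1L, 150)
  expect_error(rg_specific(st3, cutoff), "no specific beads")
})

test_that("Rg uses unwrapped coordinates across the periodic boundary", {
  # a bonded two-bead chain straddling the boundary: beads at 1 and 99
  # in a 100 A box are 2 A apart by minimum image, not 98 A
  st <- raw_state(rbind(c(1, 50, 50), c(99, 50, 50)),
                  rep("specific", 2), c(1L, 1L), 100)
  expect_equal(rg_specific(st, cutoff)$rg_red, 1)
})

test_that("shell profiles follow the printed density formula", {
  # single specific bead at distance 4 from the center: shell [3, 6)
  center <- c(60, 60, 60)
  st <- raw_state(rbind(center, center + c(4, 0, 0)),
                  c("nonspecific", "specific"), c(1L, 1L), 120)
  sp <- shell_profile(st, cutoff, shell_width = 3)
  row <- sp[sp$r_inner == 3, ]
  expect_equal(row$count, 1)
  expect_equal(row$fraction, 1)
  expect_equal(row$phi_red, 1 / ((4 / 3) * pi * (6^3 - 3^3)),
               tolerance = 1e-12)
  expect_equal(sum(sp$count), 1)  # the nonspecific bead is not counted
})

test_that("system-wide shell fractions sum to one for a free state", {
  set.seed(5)
  n <- 60
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  st <- raw_state(pos, rep("specific", n), seq_len(n), 100)
  # isolated single-bead chains: freely diffusing normalization
  sp <- shell_profile(st, cutoff = 0.1, shell_width = 3,
                      r_max = sqrt(3) / 2 * 100 + 3)
  expect_equal(sum(sp$fraction), 1)
  expect_false(attr(sp, "multimer"))
})

test_that("uniform beads give an approximately flat density profile", {
  set.seed(6)
  n <- 4000
  pos <- matrix(runif(3 * n, 0, 100), n, 3)
  st <- raw_state(pos, rep("specific", n), seq_len(n), 100)
  sp <- shell_profile(st, cutoff = 0.01, shell_width = 5, r_max = 45)
  rho <- n / 100^3
  # chi-square-style consistency: observed shell counts vs uniform density
  expected <- rho * (4 / 3) * pi * (sp$r_outer^3 - sp$r_inner^3)
  keep <- expected > 20
  chi2 <- sum((sp$count[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, 2 * sum(keep) + 6 * sqrt(2 * sum(keep)))
})

test_that("multimer shell profiles center on the largest cluster", {
  # two 1-bead chains in contact near a corner + one far-away free chain
  pos <- rbind(c(5, 5, 5), c(9, 5, 5), c(80, 80, 80))
  st <- raw_state(pos, c("specific", "specific", "specific"),
                  1:3, 120)
  sp <- shell_profile(st, cutoff, shell_width = 3)
  expect_true(attr(sp, "multimer"))
  # denominator: the 2 reds of the cluster; both sit within 2 A of center
  expect_equal(sp$fraction[1], 1)
  expect_equal(sum(sp$count), 2)
})

frame_dt_ns <- 1e6  # 1 ns between fixture frames

test_that("dwell intervals are read off the fixture exactly", {
  tr <- make_fixture_trajectory(list(
    list(frames = 50, contact = TRUE, n_sp = 0),
    list(frames = 50, contact = FALSE)), frame_dt = 3000)
  dw <- dwell_times(tr)
  expect_equal(length(dw$dwell_intervals), 1)
  expect_equal(dw$dwell_intervals[1], 50 * 3000)
  expect_false(dw$dwell_censored[1])
  expect_equal(dw$t_dwell, 50 * 3000)

  # multiple binding events
  tr2 <- make_fixture_trajectory(list(
    list(frames = 20, contact = TRUE, n_sp = 0),
    list(frames = 10, contact = FALSE),
    list(frames = 40, contact = TRUE, n_sp = 0),
    list(frames = 30, contact = FALSE)), frame_dt = 3000)
  dw2 <- dwell_times(tr2)
  expect_equal(dw2$dwell_intervals, c(20, 40) * 3000)
  expect_equal(dw2$t_dwell, 30 * 3000)
})

test_that("dwell censoring flags open intervals at the trajectory end", {
  always <- make_fixture_trajectory(list(
    list(frames = 80, contact = TRUE, n_sp = 0)), frame_dt = 3000)
  dw <- dwell_times(always)
  expect_true(dw$dwell_censored[1])
  expect_equal(dw$dwell_intervals[1], 80 * 3000)

  never <- make_fixture_trajectory(list(
    list(frames = 40, contact = FALSE)), frame_dt = 3000)
  dwn <- dwell_times(never)
  expect_equal(length(dwn$dwell_intervals), 0)
  expect_true(is.na(dwn$t_dwell))
})

test_that("maturation time runs from first contact to sustained threshold", {
  tr <- make_fixture_trajectory(list(
    list(frames = 10, contact = TRUE, n_sp = 0),
    list(frames = 90, contact = TRUE, n_sp = 12)), frame_dt = frame_dt_ns)
  mt <- maturation_times(tr)
  expect_false(mt$mature_censored)
  expect_equal(mt$t_mature, 10 * frame_dt_ns)
})

test_that("a transient crossing of the threshold does not count as mature", {
  tr <- make_fixture_trajectory(list(
    list(frames = 10, contact = TRUE, n_sp = 0),
    list(frames = 1, contact = TRUE, n_sp = 12),
    list(frames = 89, contact = TRUE, n_sp = 0)), frame_dt = frame_dt_ns)
  mt <- maturation_times(tr)
  expect_true(mt$mature_censored)
  expect_equal(mt$t_mature, 99 * frame_dt_ns)  # trajectory length
})

test_that("first contact already mature and sustained gives T_mature = 0", {
  tr <- make_fixture_trajectory(list(
    list(frames = 30, contact = FALSE),
    list(frames = 70, contact = TRUE, n_sp = 12)), frame_dt = frame_dt_ns)
  mt <- maturation_times(tr)
  expect_false(mt$mature_censored)
  expect_equal(mt$t_mature, 0)
})

test_that("never-maturing trajectories report the trajectory length", {
  tr <- make_fixture_trajectory(list(
    list(frames = 100, contact = FALSE)), frame_dt = frame_dt_ns)
  mt <- maturation_times(tr)
  expect_true(mt$mature_censored)
  expect_equal(mt$t_mature, 99 * frame_dt_ns)
})

test_that("kinetics functions insist on two-chain trajectories", {
  st <- build_system(system_spec(chain_spec(default_chain_roles(10, 3)),
                                 count = 3, box_edge = 100, seed = 1))
  tr <- structure(list(topology = list(roles = st$roles,
                                       chain_id = st$chain_id,
                                       box_edge = 100),
                       times = c(0, 1),
                       frames = array(st$positions, c(30, 3, 2)),
                       metadata = list()), class = "pp_trajectory")
  expect_error(dwell_times(tr), "two-chain")
  expect_error(maturation_times(tr), "two-chain")
})
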