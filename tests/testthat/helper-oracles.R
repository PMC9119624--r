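# Shared fixtures and independent brute-force oracles.  Oracles are written
# in plain R straight from the definitions, independent of the compiled
# paths they check.

KB <- 0.0019872041

# a bare system state from explicit pieces
raw_state <- function(pos, roles, chain_id, box, vel = NULL) {
  structure(list(positions = pos,
                 velocities = if (is.null(vel)) matrix(0, nrow(pos), 3) else vel,
                 roles = roles, chain_id = chain_id, box_edge = box,
                 time = 0),
            class = "pp_system_state")
}

# random multi-chain frame confined to the inner half of the box so that
# minimum-image equals plain euclidean distance (oracle stays elementary)
random_frame <- function(n_chains, beads_per_chain, box = 80, spread = 20) {
  n <- n_chains * beads_per_chain
  center <- box / 2
  pos <- matrix(runif(3 * n, center - spread, center + spread), n, 3)
  roles <- sample(c("specific", "nonspecific"), n, replace = TRUE)
  raw_state(pos, roles, rep(seq_len(n_chains), each = beads_per_chain), box)
}

oracle_min_image <- function(d, box) d - box * round(d / box)

oracle_dist <- function(pos, i, j, box) {
  sqrt(sum(oracle_min_image(pos[i, ] - pos[j, ], box)^2))
}

# all-pairs contact counting straight from the definition
oracle_contacts <- function(st, cutoff) {
  n <- nrow(st$positions)
  nsp <- 0; nns <- 0; nany <- 0
  nc <- max(st$chain_id)
  adj <- matrix(0L, nc, nc)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (st$chain_id[i] == st$chain_id[j]) next
      if (oracle_dist(st$positions, i, j, st$box_edge) >= cutoff) next
      nany <- nany + 1
      adj[st$chain_id[i], st$chain_id[j]] <- 1L
      adj[st$chain_id[j], st$chain_id[i]] <- 1L
      ri <- st$roles[i]; rj <- st$roles[j]
      if (ri == "specific" && rj == "specific") nsp <- nsp + 1
      else if (ri %in% c("nonspecific", "alt_nonspecific") ||
               rj %in% c("nonspecific", "alt_nonspecific")) nns <- nns + 1
    }
  }
  list(n_sp_pairs = nsp, n_ns_pairs = nns, n_any_pairs = nany, adj = adj)
}

# connected components by naive union-find over the oracle adjacency
oracle_clusters <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (adj[i, j]) parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(n), find, 1L)
  labels <- match(roots, unique(roots))
  list(labels = labels, n_lc = max(table(labels)))
}

# definitional Rg of the specific beads (no wrapping: frames are confined)
oracle_rg <- function(st) {
  red <- st$positions[st$roles == "specific", , drop = FALSE]
  cen <- colMeans(red)
  sqrt(mean(rowSums(sweep(red, 2, cen)^2)))
}

# all-pairs LJ energy straight from the truncated potential definition
oracle_pair_energy <- function(st, ff) {
  n <- nrow(st$positions)
  p <- ff$params
  e <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (st$chain_id[i] == st$chain_id[j] && abs(i - j) == 1) next
      eps <- ff$eps_kcal[st$roles[i], st$roles[j]]
      if (eps == 0) next
      rc <- ff$r_cut[st$roles[i], st$roles[j]]
      r <- oracle_dist(st$positions, i, j, st$box_edge)
      if (r >= rc) next
      sr6 <- (p$sigma / r)^6
      e <- e + 4 * eps * (sr6^2 - sr6)
    }
  }
  e
}

# central-difference gradient of one energy term
numeric_gradient <- function(st, ff, term, h = 1e-5) {
  n <- nrow(st$positions)
  g <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (d in 1:3) {
      sp <- st; sp$positions[i, d] <- sp$positions[i, d] + h
      sm <- st; sm$positions[i, d] <- sm$positions[i, d] - h
      g[i, d] <- (energy_forces(sp, ff)[[term]] -
                    energy_forces(sm, ff)[[term]]) / (2 * h)
    }
  }
  g
}

# short dimer spec used across engine tests
dimer_spec <- function(seed = 1, box = 120, params = engine_params()) {
  system_spec(chain_spec(default_chain_roles(80, 7)), count = 2,
              box_edge = box, seed = seed, params = params)
}
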