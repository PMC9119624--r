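# Configuration and trajectory I/O.
#
# Configs are plain key/value text (Debian-control style, read.dcf/write.dcf)
# with role sequences as run-length strings ("36B-7R-37B": B = nonspecific,
# R = specific, K = inert, G = alt_nonspecific).  Trajectories are written
# as XYZ (roles encoded as the same one-letter symbols) or a LAMMPS-dump
# style text dialect; "internal" uses RDS for lossless runtime storage.

ROLE_LETTERS <- c(specific = "R", nonspecific = "B", inert = "K",
                  alt_nonspecific = "G")

roles_to_rle <- function(roles) {
  r <- rle(unname(ROLE_LETTERS[roles]))
  paste0(r$lengths, r$values, collapse = "-")
}

rle_to_roles <- function(s) {
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)([RBKG])$", parts))
  if (any(vapply(m, length, 1L) != 3)) {
    stop("malformed role run-length string: ", s)
  }
  unlist(lapply(m, function(x) {
    rep(names(ROLE_LETTERS)[ROLE_LETTERS == x[3]], as.integer(x[2]))
  }))
}

CONFIG_KEYS <- c("kind", "n_chains", "chain_length", "patch_len", "roles",
                 "eps_sp", "eps_ns", "system", "n_frac", "temperature",
                 "dt", "box_edge", "concentration", "seed", "steps",
                 "report_every")

#' Assemble a run configuration
#'
#' @param kind `"dimer"` (2 chains) or `"multimer"`.
#' @param n_chains Chain count; defaults to 2 for a dimer, 30 for a
#'   multimer.
#' @param chain_length,patch_len Chain geometry (default 80-mer, 7-bead
#'   central patch).
#' @param roles Optional explicit role run-length string overriding the
#'   default architecture (e.g. `"36B-7R-37B"`).
#' @param eps_sp,eps_ns Interaction strengths, k_B T.
#' @param system `"default"`, `"system1"` (half the chains have inert
#'   non-core beads) or `"system2"` (half the chains use the second
#'   non-specific flavor).
#' @param n_frac Optional percentage of attractive non-core beads
#'   (three-bead model); `NA` for the plain two-bead chain.
#' @param temperature Thermostat temperature, K.
#' @param dt Timestep, fs.
#' @param box_edge Box edge, Angstrom; or give `concentration` (mol/L).
#'   The dimer default is a 120 Angstrom box (desk-scale kinetics); the
#'   multimer default is the 200 uM concentration.
#' @param concentration Chain concentration, mol/L.
#' @param seed Build/run seed.
#' @param steps,report_every Run length and frame interval in steps.
#' @return Object of class `pp_run_config`.
#' @export
run_config <- function(kind = "dimer", n_chains = NULL, chain_length = 80,
                       patch_len = 7, roles = NULL, eps_sp = 1.2,
                       eps_ns = 0.5, system = "default", n_frac = NA,
                       temperature = 310, dt = 30, box_edge = NULL,
                       concentration = NULL, seed = 1, steps = 1e5,
                       report_every = 1000) {
  kind <- match.arg(kind, c("dimer", "multimer"))
  if (is.null(n_chains)) n_chains <- if (kind == "dimer") 2L else 30L
  if (is.null(box_edge) && is.null(concentration)) {
    if (kind == "dimer") box_edge <- 120 else concentration <- 200e-6
  }
  cfg <- list(kind = kind, n_chains = as.integer(n_chains),
              chain_length = as.integer(chain_length),
              patch_len = as.integer(patch_len), roles = roles,
              eps_sp = eps_sp, eps_ns = eps_ns,
              system = match.arg(system, c("default", "system1", "system2")),
              n_frac = n_frac, temperature = temperature, dt = dt,
              box_edge = box_edge, concentration = concentration,
              seed = as.integer(seed), steps = as.integer(steps),
              report_every = as.integer(report_every))
  # validate the interaction constraint and role string eagerly
  interaction_table(cfg$eps_sp, cfg$eps_ns, cfg$system)
  if (!is.null(cfg$roles)) rle_to_roles(cfg$roles)
  structure(cfg, class = "pp_run_config")
}

#' Read a run configuration from a key/value file
#'
#' Unknown keys are rejected with the offending key named.
#'
#' @param path File path.
#' @return A `pp_run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  keys <- colnames(m)
  bad <- setdiff(keys, CONFIG_KEYS)
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  get_k <- function(k, as = identity) {
    if (k %in% keys && !is.na(m[1, k])) as(m[1, k]) else NULL
  }
  num <- function(x) as.numeric(x)
  args <- list(
    kind = get_k("kind"), n_chains = get_k("n_chains", num),
    chain_length = get_k("chain_length", num),
    patch_len = get_k("patch_len", num), roles = get_k("roles"),
    eps_sp = get_k("eps_sp", num), eps_ns = get_k("eps_ns", num),
    system = get_k("system"), n_frac = get_k("n_frac", num),
    temperature = get_k("temperature", num), dt = get_k("dt", num),
    box_edge = get_k("box_edge", num),
    concentration = get_k("concentration", num),
    seed = get_k("seed", num), steps = get_k("steps", num),
    report_every = get_k("report_every", num))
  do.call(run_config, args[!vapply(args, is.null, TRUE)])
}

#' Write a run configuration
#'
#' Inverse of [read_config()]; the write/read round trip is lossless.
#'
#' @param cfg A `pp_run_config`.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pp_run_config"))
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, function(v) is.null(v) ||
                         (length(v) == 1 && is.na(v)), TRUE)]
  write.dcf(as.data.frame(vals, stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Materialize the system described by a configuration
#'
#' @param cfg A `pp_run_config`.
#' @return List with the `spec` ([system_spec()]), interaction `table`,
#'   force field `ff` and built initial `state`.
#' @export
config_system <- function(cfg) {
  stopifnot(inherits(cfg, "pp_run_config"))
  params <- engine_params(dt = cfg$dt, T = cfg$temperature)
  table <- interaction_table(cfg$eps_sp, cfg$eps_ns, cfg$system,
                             T_ref = 310)
  base_roles <- if (!is.null(cfg$roles)) rle_to_roles(cfg$roles)
    else if (!is.na(cfg$n_frac))
      three_bead_roles(cfg$chain_length, cfg$patch_len, cfg$n_frac, cfg$seed)
    else default_chain_roles(cfg$chain_length, cfg$patch_len)
  chains <- if (cfg$system == "default") {
    list(list(spec = chain_spec(base_roles), count = cfg$n_chains))
  } else {
    # heterogeneous mixtures: half type-1 chains, half the variant type
    variant <- base_roles
    swap_to <- if (cfg$system == "system1") "inert" else "alt_nonspecific"
    variant[variant == "nonspecific"] <- swap_to
    n1 <- ceiling(cfg$n_chains / 2)
    list(list(spec = chain_spec(base_roles), count = n1),
         list(spec = chain_spec(variant), count = cfg$n_chains - n1))
  }
  spec <- system_spec(chains, box_edge = cfg$box_edge,
                      concentration = cfg$concentration, seed = cfg$seed,
                      params = params)
  list(spec = spec, table = table, ff = force_field(table, params),
       state = build_system(spec))
}

# ---------------------------------------------------------------------------
# XYZ
# ---------------------------------------------------------------------------

#' Write a trajectory in XYZ format
#'
#' Roles are encoded as one-letter element symbols (R/B/K/G); the comment
#' line carries the time, box edge and per-chain bead counts so the file
#' round-trips without side information.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @export
write_xyz <- function(traj, path) {
  top <- traj$topology
  sym <- unname(ROLE_LETTERS[top$roles])
  n <- length(sym)
  chains <- paste(rle(top$chain_id)$lengths, collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    p <- frame_positions(traj, k)
    writeLines(c(as.character(n),
                 sprintf("t=%.6g box=%.10g chains=%s", traj$times[k],
                         top$box_edge, chains)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", sym, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' @param path File path.
#' @param chains_of Bead count per chain when the comment line does not
#'   carry `chains=`; all chains are then taken equal.
#' @return A `pp_trajectory`.
#' @export
read_xyz <- function(path, chains_of = NULL) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("empty or truncated XYZ file")
  n <- suppressWarnings(as.integer(lines[1]))
  if (is.na(n)) stop("malformed XYZ header")
  per <- n + 2
  nf <- length(lines) %/% per
  if (nf < 1 || length(lines) %% per != 0) {
    stop("truncated XYZ frame ", nf + 1)
  }
  comment <- lines[2]
  box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", comment))
  chains_m <- regmatches(comment, regexec("chains=([0-9,]+)", comment))[[1]]
  chain_lens <- if (length(chains_m) == 2) {
    as.integer(strsplit(chains_m[2], ",")[[1]])
  } else if (!is.null(chains_of)) {
    rep(as.integer(chains_of), n / as.integer(chains_of))
  } else n
  frames <- array(NA_real_, c(n, 3, nf))
  times <- numeric(nf)
  roles <- NULL
  for (k in seq_len(nf)) {
    off <- (k - 1) * per
    times[k] <- as.numeric(sub(".*t=([0-9.eE+-]+).*", "\\1", lines[off + 2]))
    body <- lines[off + 2 + seq_len(n)]
    parts <- strsplit(trimws(body), "[[:space:]]+")
    if (k == 1) {
      sym <- vapply(parts, `[`, "", 1)
      roles <- names(ROLE_LETTERS)[match(sym, ROLE_LETTERS)]
      if (anyNA(roles)) stop("unknown role symbol in XYZ: ",
                             paste(unique(sym[is.na(roles)]), collapse = ","))
    }
    frames[, , k] <- t(vapply(parts, function(x) as.numeric(x[2:4]),
                              numeric(3)))
  }
  new_trajectory(topology = list(roles = roles,
                                 chain_id = rep(seq_along(chain_lens),
                                                chain_lens),
                                 box_edge = box),
                 times = times, frames = frames,
                 metadata = list(source = path, format = "xyz"))
}

# ---------------------------------------------------------------------------
# LAMMPS-dump dialect
# ---------------------------------------------------------------------------

#' Write a trajectory as LAMMPS-dump style text
#'
#' Per frame: `ITEM: TIMESTEP` (time in fs), `ITEM: NUMBER OF ATOMS`,
#' `ITEM: BOX BOUNDS pp pp pp` and `ITEM: ATOMS id mol type x y z` with
#' `mol` the chain id and `type` the 1-based role code.
#'
#' @param traj A `pp_trajectory`.
#' @param path Output path.
#' @export
write_lammps_dump <- function(traj, path) {
  top <- traj$topology
  n <- length(top$roles)
  type <- role_codes(top$roles) + 1L
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(n_frames(traj))) {
    p <- frame_positions(traj, k)
    writeLines(c("ITEM: TIMESTEP", sprintf("%.6g", traj$times[k]),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 rep(sprintf("0 %.10g", top$box_edge), 3),
                 "ITEM: ATOMS id mol type x y z"), con)
    writeLines(sprintf("%d %d %d %.6f %.6f %.6f", seq_len(n), top$chain_id,
                       type, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a LAMMPS-dump style trajectory
#'
#' @param path File path.
#' @return A `pp_trajectory`.
#' @export
read_lammps_dump <- function(path) {
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  times <- numeric(0)
  roles <- NULL
  chain_id <- NULL
  box <- NA_real_
  frame_no <- 0L
  while (i <= length(lines)) {
    frame_no <- frame_no + 1L
    need <- function(cond, what) {
      if (!cond) stop("malformed dump at frame ", frame_no, ": ", what)
    }
    need(grepl("^ITEM: TIMESTEP", lines[i]), "expected ITEM: TIMESTEP")
    t <- as.numeric(lines[i + 1])
    need(grepl("^ITEM: NUMBER OF ATOMS", lines[i + 2]),
         "expected ITEM: NUMBER OF ATOMS")
    n <- as.integer(lines[i + 3])
    need(grepl("^ITEM: BOX BOUNDS", lines[i + 4]), "expected ITEM: BOX BOUNDS")
    bounds <- as.numeric(strsplit(trimws(lines[i + 5]), "[[:space:]]+")[[1]])
    box <- bounds[2] - bounds[1]
    need(grepl("^ITEM: ATOMS", lines[i + 8]), "missing ITEM: ATOMS header")
    cols <- strsplit(sub("^ITEM: ATOMS ", "", lines[i + 8]),
                     "[[:space:]]+")[[1]]
    need(all(c("id", "x", "y", "z") %in% cols), "need id x y z columns")
    need(i + 8 + n <= length(lines), "truncated atom block")
    body <- lines[i + 8 + seq_len(n)]
    m <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                               as.numeric))
    need(ncol(m) == length(cols), "column count mismatch")
    ord <- order(m[, which(cols == "id")])
    m <- m[ord, , drop = FALSE]
    pos <- m[, match(c("x", "y", "z"), cols), drop = FALSE]
    if (is.null(roles)) {
      roles <- if ("type" %in% cols) {
        BEAD_ROLES[m[, which(cols == "type")]]
      } else rep("nonspecific", n)
      chain_id <- if ("mol" %in% cols) {
        as.integer(m[, which(cols == "mol")])
      } else rep(1L, n)
    }
    frames[[frame_no]] <- pos
    times[frame_no] <- t
    i <- i + 9L + n
  }
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  new_trajectory(topology = list(roles = roles, chain_id = chain_id,
                                 box_edge = box),
                 times = times, frames = arr,
                 metadata = list(source = path, format = "lammps_dump"))
}

#' Read or write a trajectory in a named format
#'
#' @param traj Trajectory (for writing).
#' @param path File path.
#' @param format `"xyz"`, `"lammps_dump"` or `"internal"` (RDS).
#' @return `read_trajectory()` returns a `pp_trajectory`.
#' @export
write_trajectory <- function(traj, path,
                             format = c("lammps_dump", "xyz", "internal")) {
  format <- match.arg(format)
  switch(format,
         xyz = write_xyz(traj, path),
         lammps_dump = write_lammps_dump(traj, path),
         internal = { saveRDS(traj, path); invisible(path) })
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path,
                            format = c("auto", "lammps_dump", "xyz",
                                       "internal")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1, warn = FALSE)
    format <- if (grepl("^ITEM:", first)) "lammps_dump" else "xyz"
  }
  switch(format,
         xyz = read_xyz(path),
         lammps_dump = read_lammps_dump(path),
         internal = readRDS(path))
}
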