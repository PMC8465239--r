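fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a state as extended XYZ
#'
#' One frame per file: the bead count, a comment line carrying the box and
#' step, then one line per bead with the species label, position and
#' velocity. Numbers are printed with 17 significant digits so a
#' write-read-write cycle is bit-identical.
#'
#' @param state A `dpd_state`.
#' @param path File path.
#' @return `write_xyz()` returns `path` invisibly; `read_xyz()` a
#'   `dpd_state` (without bonded topology).
#' @export
write_xyz <- function(state, path) {
  n <- nrow(state$pos)
  hdr <- c(as.character(n),
           paste("box", paste(fmt17(state$box), collapse = " "),
                 "step", state$step))
  body <- paste(dpd_species()[state$species],
                fmt17(state$pos[, 1]), fmt17(state$pos[, 2]),
                fmt17(state$pos[, 3]),
                fmt17(state$vel[, 1]), fmt17(state$vel[, 2]),
                fmt17(state$vel[, 3]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  n <- as.integer(lines[1])
  hdr <- strsplit(lines[2], "\\s+")[[1]]
  box <- as.numeric(hdr[2:4])
  step <- as.integer(hdr[6])
  parts <- strsplit(lines[2 + seq_len(n)], "\\s+")
  m <- matrix(unlist(parts), nrow = n, byrow = TRUE)
  sp <- match(m[, 1], dpd_species())
  num <- apply(m[, 2:7, drop = FALSE], 2, as.numeric)
  new_dpd_state(num[, 1:3, drop = FALSE], num[, 4:6, drop = FALSE],
                sp, rep(0L, n), box, step = step)
}

#' Write / read LAMMPS-style dump frames
#'
#' The familiar dump dialect: `ITEM: TIMESTEP`, `ITEM: NUMBER OF ATOMS`,
#' `ITEM: BOX BOUNDS pp pp pp`, then
#' `ITEM: ATOMS id mol type x y z vx vy vz`. `write_lammps_dump()` appends
#' one frame per state in `frames` (a single `dpd_state` is accepted);
#' `read_lammps_dump()` returns the reference state rebuilt from the first
#' frame (molecule ids and species preserved) and the full frame list.
#' 17-digit output makes round trips bit-exact.
#'
#' @param frames A `dpd_state` or list of frames (`step`, `pos`, `vel`).
#' @param state Reference `dpd_state` for species/mol when `frames` is a
#'   frame list.
#' @param path File path.
#' @return `write_lammps_dump()` returns `path` invisibly;
#'   `read_lammps_dump()` a list with `state` and `frames`.
#' @export
write_lammps_dump <- function(frames, path, state = NULL) {
  if (inherits(frames, "dpd_state")) {
    state <- frames
    frames <- list(list(step = state$step, pos = state$pos, vel = state$vel))
  }
  if (is.null(state)) abort("`state` is required for a bare frame list")
  n <- nrow(state$pos)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    writeLines(c("ITEM: TIMESTEP", as.character(fr$step),
                 "ITEM: NUMBER OF ATOMS", as.character(n),
                 "ITEM: BOX BOUNDS pp pp pp",
                 paste("0", fmt17(state$box[1])),
                 paste("0", fmt17(state$box[2])),
                 paste("0", fmt17(state$box[3])),
                 "ITEM: ATOMS id mol type x y z vx vy vz",
                 paste(seq_len(n), state$mol, state$species,
                       fmt17(fr$pos[, 1]), fmt17(fr$pos[, 2]),
                       fmt17(fr$pos[, 3]),
                       fmt17(fr$vel[, 1]), fmt17(fr$vel[, 2]),
                       fmt17(fr$vel[, 3]))),
               con)
  }
  invisible(path)
}

#' @rdname write_lammps_dump
#' @export
read_lammps_dump <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  frames <- list()
  state <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] != "ITEM: TIMESTEP") abort("malformed dump file")
    step <- as.integer(lines[i + 1])
    n <- as.integer(lines[i + 3])
    box <- vapply(lines[i + 5:7],
                  function(l) as.numeric(strsplit(l, "\\s+")[[1]][2]),
                  numeric(1), USE.NAMES = FALSE)
    rows <- strsplit(lines[i + 8 + seq_len(n)], "\\s+")
    m <- matrix(as.numeric(unlist(rows)), nrow = n, byrow = TRUE)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (is.null(state))
      state <- new_dpd_state(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE],
                             as.integer(m[, 3]), as.integer(m[, 2]), box,
                             step = step)
    frames[[length(frames) + 1]] <-
      list(step = step, pos = m[, 4:6, drop = FALSE],
           vel = m[, 7:9, drop = FALSE])
    i <- i + 9L + n
  }
  list(state = state, frames = frames)
}

#' Export a profile or series as CSV with a metadata sidecar
#'
#' Writes the tibble to `path` and a YAML sidecar (`<path>.yml`) recording
#' the quantity, axis, units, bin geometry and frame count, so every
#' numeric output file carries its units.
#'
#' @param x A profile/series tibble from the analysis functions.
#' @param path Output CSV path.
#' @param units Named character vector of column units (sensible defaults
#'   per quantity are filled in when omitted).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(x, path, units = NULL) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  meta <- list(
    quantity = attr(x, "quantity") %||% class(x)[1],
    axis = attr(x, "axis") %||% NA,
    n_frames = attr(x, "n_frames") %||% NA,
    columns = as.list(units %||% default_units(x)))
  if (!is.null(attr(x, "bin_edges")))
    meta$bin_edges <- as.numeric(attr(x, "bin_edges"))
  if (!is.null(attr(x, "total"))) meta$total <- attr(x, "total")
  yaml::write_yaml(meta, paste0(path, ".yml"))
  invisible(path)
}

default_units <- function(x) {
  u <- c(z = "rc", density = "beads/rc^3", p2 = "dimensionless",
         sigma = "kBT/rc^3", pxx = "kBT/rc^3", pyy = "kBT/rc^3",
         pzz = "kBT/rc^3", vx = "rc/tau", step = "steps",
         rgxx = "rc", rgyy = "rc", rgzz = "rc", delta = "dimensionless",
         pair = "kBT", bond = "kBT", angle = "kBT", kinetic = "kBT",
         potential = "kBT", total = "kBT", acc_px = "m*rc/tau")
  found <- u[intersect(names(u), names(x))]
  out <- as.list(rep("dimensionless", ncol(x)))
  names(out) <- names(x)
  out[names(found)] <- found
  out
}

#' Checkpoint a state to disk and restore it
#'
#' Self-describing binary (RDS) container holding the state, its topology
#' and the configuration used to create it.
#'
#' @param state A `dpd_state`.
#' @param config The `run_config` (stored alongside).
#' @param path Checkpoint path.
#' @return `read_checkpoint()` returns `list(state, config)`.
#' @export
write_checkpoint <- function(state, config, path) {
  saveRDS(list(state = state, config = config,
               version = as.character(utils::packageVersion("dpdlipid"))),
          path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  if (!file.exists(path)) abort(paste0("checkpoint not found: ", path))
  readRDS(path)[c("state", "config")]
}

# Rebuild bonded topology from species + molecule labels of a dump file:
# bead order within each molecule is heads first, then tail(s), as the
# builders emit them.
infer_topology <- function(species, mol) {
  mols <- sort(unique(mol[mol > 0]))
  bonds <- list(); angles <- list(); rows <- list()
  for (m in mols) {
    idx <- which(mol == m)
    sp <- dpd_species()[species[idx]]
    if (sp[1] %in% c("H1", "T1")) {
      nh <- sum(sp == "H1"); nt <- sum(sp == "T1")
      tp <- build_lipid_type1(nh, nt)
      ty <- 1L
    } else {
      nh <- sum(sp == "H2"); nt <- sum(sp == "T2") / 2
      tp <- build_lipid_type2(nh, nt)
      ty <- 2L
    }
    off <- idx[1] - 1L
    bonds[[length(bonds) + 1]] <-
      mutate(tp$bonds, i = .data$i + off, j = .data$j + off)
    angles[[length(angles) + 1]] <-
      mutate(tp$angles, i = .data$i + off, j = .data$j + off,
             k = .data$k + off)
    rows[[length(rows) + 1]] <-
      tibble(mol = m, type = ty, first = idx[1],
             n_beads = length(idx), n_head = nh)
  }
  list(bonds = bind_rows(bonds), angles = bind_rows(angles),
       molecules = bind_rows(rows))
}

#' Simulate from a config file
#'
#' Reads a TOML run configuration, builds the initial state, runs the
#' engine (with shear when `swap_interval` is finite), and writes the
#' trajectory dump, energy CSV, final-state XYZ, a checkpoint and a JSON
#' run manifest into `out_dir`.
#'
#' @param config_path Path to a TOML config (see [read_run_config()]).
#' @param overrides Named list of config keys overriding the file.
#' @param out_dir Output directory (created if needed).
#' @param start `"random"` or `"bilayer"` initial configuration.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
cli_simulate <- function(config_path, overrides = list(),
                         out_dir = ".", start = c("random", "bilayer")) {
  start <- match.arg(start)
  config <- read_run_config(config_path)
  if (length(overrides)) {
    params <- config$params
    config <- do.call(run_config,
                      modifyList(config[setdiff(names(config), "params")],
                                 overrides))
    config$params <- params
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- interaction_table(config$interaction_mode)
  st <- if (start == "random") random_initial_configuration(config)
        else preassembled_bilayer(config)
  run <- run_dpd(st, config$total_steps, table = tab, params = config$params,
                 seed = config$seed, swap_interval = config$swap_interval,
                 n_slabs = config$n_slabs,
                 traj_every = config$traj_every,
                 energy_every = config$energy_every,
                 profile_every = config$profile_every,
                 profile_bins = config$profile_bins)
  paths <- list(
    trajectory = file.path(out_dir, "trajectory.dump"),
    energy = file.path(out_dir, "energy.csv"),
    final_xyz = file.path(out_dir, "final.xyz"),
    checkpoint = file.path(out_dir, "checkpoint.rds"),
    manifest = file.path(out_dir, "manifest.json"))
  frames <- if (length(run$frames)) run$frames
            else list(list(step = run$state$step, pos = run$state$pos,
                           vel = run$state$vel))
  write_lammps_dump(frames, paths$trajectory, state = run$state)
  write_profile_csv(energy_series(run), paths$energy)
  write_xyz(run$state, paths$final_xyz)
  write_checkpoint(run$state, config, paths$checkpoint)
  manifest <- list(
    config = config[setdiff(names(config), "params")],
    params = unclass(config$params),
    seed = config$seed, start = start,
    version = as.character(utils::packageVersion("dpdlipid")),
    outputs = paths,
    shear = run$shear[c("acc_px", "n_swaps", "n_skipped")],
    status = "ok")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Analyze a trajectory file
#'
#' Reads a LAMMPS-style dump written by [cli_simulate()], reconstructs the
#' molecule topology from the molecule/species columns, restricts to the
#' last `window` fraction of frames (the steady-state window), and writes
#' one CSV per requested observable.
#'
#' @param trajectory_path Dump file path.
#' @param observables Subset of `"density"`, `"order"`, `"rg"`,
#'   `"tension"`, `"velocity"`, `"classify"`.
#' @param window Fraction of trailing frames to analyse (default 0.25).
#' @param out_dir Output directory.
#' @param n_bins Bins for the binned observables.
#' @return Named list of written file paths, invisibly.
#' @export
cli_analyze <- function(trajectory_path,
                        observables = c("density", "order", "rg"),
                        window = 0.25, out_dir = ".", n_bins = 30) {
  valid <- c("density", "order", "rg", "tension", "velocity", "classify")
  bad <- setdiff(observables, valid)
  if (length(bad))
    abort(paste0("unknown observable(s): ", paste(bad, collapse = ", "),
                 "; valid names: ", paste(valid, collapse = ", ")))
  traj <- read_lammps_dump(trajectory_path)
  if (length(traj$frames) == 0) abort("insufficient data: empty trajectory")
  state <- traj$state
  state$topology <- infer_topology(state$species, state$mol)
  keep <- max(1, ceiling(length(traj$frames) * window))
  frames <- tail(traj$frames, keep)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (obs in observables) {
    path <- file.path(out_dir, paste0(obs, ".csv"))
    res <- switch(obs,
      density = density_profile(frames, state = state, n_bins = n_bins),
      order = order_parameter(frames, state = state, n_bins = n_bins),
      rg = rg_components_series(frames, state = state),
      tension = tension_profile(
        pressure_profile(frames, state = state, n_slabs = n_bins)),
      velocity = velocity_profile(frames, box = state$box,
                                  n_bins = n_bins)$profile,
      classify = {
        lab <- classify_structure(
          new_dpd_state(frames[[length(frames)]]$pos,
                        frames[[length(frames)]]$vel,
                        state$species, state$mol, state$box))
        tibble(label = lab$label,
               cluster_size = lab$evidence$cluster_size,
               spans = length(lab$evidence$spanned_axes))
      })
    write_profile_csv(res, path)
    out[[obs]] <- path
  }
  invisible(out)
}

#' Run a phase sweep from a grid config file
#'
#' The grid file is flat TOML with keys `nt1`, `nt2` (arrays), `seeds`,
#' `box`, `n1`, `n2`, `steps`, `swap_interval`. Completed cells found in an
#' existing `diagram.csv` in `out_dir` are skipped, so an interrupted sweep
#' resumes where it stopped. Writes `diagram.csv` (per-seed rows) and
#' `diagram.json` (modal labels).
#'
#' @param grid_config Path to the grid TOML.
#' @param out_dir Output directory.
#' @return The per-seed diagram tibble, invisibly.
#' @export
cli_sweep <- function(grid_config, out_dir = ".") {
  if (!file.exists(grid_config))
    abort(paste0("grid config not found: ", grid_config))
  kv <- parse_flat_toml(grid_config)$top
  need <- c("nt1", "nt2")
  for (k in need)
    if (is.null(kv[[k]])) abort(paste0("grid config missing field: ", k))
  swap <- kv$swap_interval %||% Inf
  if (identical(swap, "off")) swap <- Inf
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out_dir, "diagram.csv")
  done <- if (file.exists(csv_path)) read.csv(csv_path) else NULL
  grid <- tidyr::expand_grid(nt1 = kv$nt1, nt2 = kv$nt2,
                             seed = kv$seeds %||% 1)
  if (!is.null(done))
    grid <- dplyr::anti_join(grid, done, by = c("nt1", "nt2", "seed"))
  res <- if (nrow(grid) > 0) {
    parts <- purrr::pmap(grid, function(nt1, nt2, seed)
      phase_sweep(nt1 = nt1, nt2 = nt2, seeds = seed,
                  box = kv$box %||% 15, n1 = kv$n1 %||% 150,
                  n2 = kv$n2 %||% 150, steps = kv$steps %||% 50000,
                  swap_interval = swap))
    bind_rows(parts)
  } else NULL
  all <- bind_rows(done, res)
  write.csv(as.data.frame(all), csv_path, row.names = FALSE)
  jsonlite::write_json(modal_phase(structure(all, class = c("phase_diagram",
                                                            class(all)))),
                       file.path(out_dir, "diagram.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(all)
}
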