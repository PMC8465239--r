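#' Bead species of the two-lipid model
#'
#' Five coarse-grained species: water (`W`), head and tail beads of the
#' single-tail lipid (`H1`, `T1`) and of the double-tail lipid (`H2`, `T2`).
#' Species are stored as integer codes `1:5` in this order throughout the
#' package.
#'
#' @return Character vector of the five species labels, in code order.
#' @export
dpd_species <- function() c("W", "H1", "T1", "H2", "T2")

#' DPD force-field parameters
#'
#' Bundles the thermostat and integrator constants of the standard DPD
#' scheme in reduced units (lengths in `rc`, energies in `kBT`, mass `m = 1`,
#' time in `tau`). The noise amplitude is tied to the friction by the
#' fluctuation-dissipation relation `sigma^2 = 2 * gamma * kBT`; by default
#' `sigma` is derived from `gamma` and `kBT`, and supplying an inconsistent
#' `sigma` is an error.
#'
#' @param gamma Friction coefficient of the dissipative force (default 4.5).
#' @param kBT Thermostat target energy (default 1, the reduced-unit choice).
#' @param sigma Noise amplitude; default `sqrt(2 * gamma * kBT)`.
#' @param dt Integration timestep in units of `tau` (default 0.01).
#' @param lambda Mixing parameter of the modified velocity-Verlet scheme
#'   (default 0.5, which reduces to standard velocity-Verlet).
#' @param rc Cutoff length; the simulation length unit (default 1).
#' @param m Bead mass (default 1).
#' @return A list of class `dpd_params`.
#' @examples
#' p <- dpd_params()
#' p$sigma  # 3.0 at gamma = 4.5, kBT = 1
#' @export
dpd_params <- function(gamma = 4.5, kBT = 1, sigma = NULL, dt = 0.01,
                       lambda = 0.5, rc = 1, m = 1) {
  if (dt <= 0) abort("`dt` must be > 0")
  if (lambda <= 0 || lambda > 1) abort("`lambda` must be in (0, 1]")
  if (rc <= 0) abort("`rc` must be > 0")
  fd <- sqrt(2 * gamma * kBT)
  if (is.null(sigma)) {
    sigma <- fd
  } else if (abs(sigma^2 - 2 * gamma * kBT) > 1e-10) {
    abort("`sigma` violates fluctuation-dissipation: sigma^2 must equal 2*gamma*kBT")
  }
  structure(list(gamma = gamma, kBT = kBT, sigma = sigma, dt = dt,
                 lambda = lambda, rc = rc, m = m),
            class = "dpd_params")
}

#' Conservative repulsion table over the five species
#'
#' Builds the symmetric 5x5 matrix of maximum repulsion amplitudes
#' `a[s, t]` (units `kBT / rc`). Two conventions are provided:
#'
#' * `"amphiphilic"` (default): species are grouped into a hydrophilic class
#'   (water and both head species) and a hydrophobic class (both tail
#'   species); `a = a_like` within a class and `a = a_unlike` across classes.
#'   This is the standard lipid-DPD convention and makes heads effectively
#'   water-miscible while tails demix from water, which is what drives
#'   bilayer self-assembly.
#' * `"literal"`: `a = a_like` on the species diagonal only and `a_unlike`
#'   between any two distinct species, so head beads also repel water.
#'   Retained for audit; it does not self-assemble bilayers.
#'
#' @param mode `"amphiphilic"` or `"literal"`.
#' @param a_like Repulsion within a class / species (default 25).
#' @param a_unlike Repulsion across classes / species (default 100).
#' @return A 5x5 symmetric numeric matrix with species dimnames.
#' @examples
#' interaction_table()["H1", "W"]          # 25: heads mix with water
#' interaction_table("literal")["H1", "W"] # 100
#' @export
interaction_table <- function(mode = c("amphiphilic", "literal"),
                              a_like = 25, a_unlike = 100) {
  mode <- match.arg(mode)
  sp <- dpd_species()
  a <- matrix(a_unlike, 5, 5, dimnames = list(sp, sp))
  if (mode == "literal") {
    diag(a) <- a_like
  } else {
    philic <- c("W", "H1", "H2")
    phobic <- c("T1", "T2")
    a[philic, philic] <- a_like
    a[phobic, phobic] <- a_like
  }
  a
}

species_code <- function(label) match(label, dpd_species())

new_lipid_topology <- function(species, bonds, angles, n_head, n_tail_per_tail,
                               n_tails, type) {
  structure(list(species = species, bonds = bonds, angles = angles,
                 n_head = n_head, n_tail_per_tail = n_tail_per_tail,
                 n_tails = n_tails, type = type),
            class = "lipid_topology")
}

#' Single-tail lipid topology (type 1)
#'
#' A linear chain of `nh` head beads followed by `nt` tail beads. All
#' consecutive pairs are bonded harmonically (`ks`, `rs`); every consecutive
#' triple of the backbone carries a bending term with `ktheta = 6`,
#' `theta0 = pi` (head triples, tail triples, and -- so that the whole
#' backbone is straight at equilibrium, matching the rod-like initial shape
#' factor of 1 -- the head-tail junction triples as well; set
#' `junction_angles = FALSE` to restrict bending to pure head/tail triples).
#'
#' @param nh Number of head beads (>= 2).
#' @param nt Number of tail beads (>= 1).
#' @param ks,rs Bond spring constant and equilibrium length (defaults 120,
#'   0.7 `rc`).
#' @param ktheta,theta0 Backbone bending constant and equilibrium angle
#'   (defaults 6, `pi`).
#' @param junction_angles Apply the backbone bending term across the
#'   head-tail junction (default `TRUE`).
#' @return A `lipid_topology` with `nh + nt` beads and tibbles of bond and
#'   angle terms (bead indices are 1-based within the molecule).
#' @examples
#' top <- build_lipid_type1(3, 10)
#' nrow(top$bonds)   # 12
#' nrow(top$angles)  # 11
#' @export
build_lipid_type1 <- function(nh = 3, nt = 10, ks = 120, rs = 0.7,
                              ktheta = 6, theta0 = pi,
                              junction_angles = TRUE) {
  if (nh < 2 || nt < 1) abort("invalid architecture: need nh >= 2 and nt >= 1")
  n <- nh + nt
  species <- c(rep(species_code("H1"), nh), rep(species_code("T1"), nt))
  bonds <- tibble(i = seq_len(n - 1), j = seq_len(n - 1) + 1, ks = ks, rs = rs)
  trip <- seq_len(n - 2)
  if (!junction_angles) {
    # keep triples entirely within the head block or within the tail block
    trip <- trip[trip + 2 <= nh | trip > nh]
  }
  angles <- tibble(i = trip, j = trip + 1, k = trip + 2,
                   ktheta = ktheta, theta0 = theta0)
  new_lipid_topology(species, bonds, angles, nh, nt, 1L, 1L)
}

#' Double-tail lipid topology (type 2)
#'
#' `nh` head beads in a chain, with two tails of `nt_per_tail` beads each
#' bonded to the last head bead. Triples entirely within the head block or
#' within one tail are straight (`ktheta = 6`, `theta0 = pi`). Each tail
#' adds two junction bending terms at `theta0 = 2*pi/3`: one on the last two
#' head beads plus the first tail bead (`ktheta = 3`) and one on the last
#' head bead plus the first two tail beads (`ktheta = 4.5`), giving the
#' molecule its splayed, roughly cylindrical shape. Each tail couples to the
#' head independently; the two first-tail beads are not coupled to each
#' other.
#'
#' @param nh Number of head beads (>= 2).
#' @param nt_per_tail Beads per tail (>= 1); total beads `nh + 2 * nt_per_tail`.
#' @param ks,rs Bond parameters (defaults 120, 0.7 `rc`).
#' @param ktheta,theta0 Straight-backbone bending parameters (defaults 6, `pi`).
#' @param kj1,kj2 Junction bending constants (defaults 3 and 4.5).
#' @param thetaj Junction equilibrium angle (default `2*pi/3`).
#' @return A `lipid_topology`.
#' @examples
#' top <- build_lipid_type2(3, 10)
#' length(top$species)  # 23
#' nrow(top$bonds)      # 22
#' @export
build_lipid_type2 <- function(nh = 3, nt_per_tail = 10, ks = 120, rs = 0.7,
                              ktheta = 6, theta0 = pi,
                              kj1 = 3, kj2 = 4.5, thetaj = 2 * pi / 3) {
  if (nh < 2 || nt_per_tail < 1)
    abort("invalid architecture: need nh >= 2 and nt_per_tail >= 1")
  nt <- nt_per_tail
  species <- c(rep(species_code("H2"), nh), rep(species_code("T2"), 2 * nt))
  tail1 <- nh + seq_len(nt)
  tail2 <- nh + nt + seq_len(nt)
  bonds <- bind_rows(
    tibble(i = seq_len(nh - 1), j = seq_len(nh - 1) + 1),
    tibble(i = nh, j = tail1[1]),
    tibble(i = nh, j = tail2[1]),
    if (nt > 1) tibble(i = tail1[-nt], j = tail1[-1]),
    if (nt > 1) tibble(i = tail2[-nt], j = tail2[-1])
  )
  bonds$ks <- ks
  bonds$rs <- rs
  straight <- function(idx) {
    if (length(idx) < 3) return(NULL)
    s <- seq_len(length(idx) - 2)
    tibble(i = idx[s], j = idx[s + 1], k = idx[s + 2],
           ktheta = ktheta, theta0 = theta0)
  }
  angles <- bind_rows(
    straight(seq_len(nh)),
    straight(tail1),
    straight(tail2),
    # (head[nh-1], head[nh], first tail bead), per tail
    tibble(i = nh - 1, j = nh, k = c(tail1[1], tail2[1]),
           ktheta = kj1, theta0 = thetaj),
    # (head[nh], first tail bead, second tail bead), per tail
    if (nt > 1) tibble(i = nh, j = c(tail1[1], tail2[1]),
                       k = c(tail1[2], tail2[2]),
                       ktheta = kj2, theta0 = thetaj)
  )
  new_lipid_topology(species, bonds, angles, nh, nt, 2L, 2L)
}

#' Physical unit mapping of the reduced-unit system
#'
#' The length unit is the cutoff `rc = (rho * Vp)^(1/3)` for bead volume
#' `Vp` at number density `rho`; the time unit `tau = rc * sqrt(m / kBT)`
#' maps to `tau_ns` nanoseconds.
#'
#' @param rho Bead number density in beads per `rc^3` (default 3).
#' @param Vp_nm3 Physical volume of one bead in nm^3 (default 0.03).
#' @param tau_ns Physical duration of one `tau` in ns (default 1.88).
#' @return A list of class `unit_system` with `rc_nm`, `rho`, `Vp_nm3`, `tau_ns`.
#' @export
unit_system <- function(rho = 3, Vp_nm3 = 0.03, tau_ns = 1.88) {
  structure(list(rc_nm = (rho * Vp_nm3)^(1 / 3), rho = rho,
                 Vp_nm3 = Vp_nm3, tau_ns = tau_ns),
            class = "unit_system")
}

#' Physical duration of a number of timesteps
#'
#' @param n_steps Number of DPD timesteps (>= 0).
#' @param units A [unit_system()].
#' @param params A [dpd_params()] (supplies `dt` in units of `tau`).
#' @return Duration in nanoseconds.
#' @examples
#' physical_time(1)    # 0.0188 ns
#' physical_time(100)  # 1.88 ns
#' @export
physical_time <- function(n_steps, units = unit_system(), params = dpd_params()) {
  if (any(n_steps < 0)) abort("`n_steps` must be >= 0")
  n_steps * params$dt * units$tau_ns
}

#' Full run configuration
#'
#' Collects every knob of a simulation: box, lipid counts and architectures,
#' density, shear protocol, run length and output cadences. Defaults are the
#' production conditions of the asymmetric-membrane study: a cubic box of
#' side 30 `rc`, 600 + 600 lipids with 3 head beads and 10-bead tails,
#' density 3, 200,000 steps. `swap_interval = Inf` means no shear; 6 and 1
#' are the weak and strong shear settings.
#'
#' @param box Box lengths `(Lx, Ly, Lz)` in `rc` (scalar is recycled).
#' @param n1,n2 Number of type-1 / type-2 lipid chains.
#' @param nh1,nh2 Head beads per lipid (defaults 3).
#' @param nt1 Tail beads of the type-1 lipid.
#' @param nt2 Beads per tail of the type-2 lipid (two tails).
#' @param rho Total bead number density (default 3); water fills the box to
#'   `round(rho * V)` beads.
#' @param total_steps Number of integration steps.
#' @param swap_interval `W`: one momentum-swap event every `W` steps;
#'   `Inf` (or 0) disables shear.
#' @param n_slabs Number of z-slabs for the swap protocol (default 20).
#' @param profile_bins Bins of the accumulated velocity profile (default 50).
#' @param seed Integer seed controlling both construction and the pair noise.
#' @param traj_every,energy_every,profile_every Output cadences in steps
#'   (0 disables).
#' @param interaction_mode Passed to [interaction_table()].
#' @param params A [dpd_params()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(box = 30, n1 = 600, n2 = 600, nh1 = 3, nh2 = 3,
                       nt1 = 10, nt2 = 10, rho = 3,
                       total_steps = 200000, swap_interval = Inf,
                       n_slabs = 20, profile_bins = 50, seed = 1,
                       traj_every = 0, energy_every = 100,
                       profile_every = 10,
                       interaction_mode = "amphiphilic",
                       params = dpd_params()) {
  box <- rep(as.numeric(box), length.out = 3)
  if (any(box <= 2 * params$rc)) abort("box lengths must exceed 2*rc")
  structure(list(box = box, n1 = n1, n2 = n2, nh1 = nh1, nh2 = nh2,
                 nt1 = nt1, nt2 = nt2, rho = rho,
                 total_steps = total_steps, swap_interval = swap_interval,
                 n_slabs = n_slabs, profile_bins = profile_bins, seed = seed,
                 traj_every = traj_every, energy_every = energy_every,
                 profile_every = profile_every,
                 interaction_mode = interaction_mode, params = params),
            class = "run_config")
}

#' Read / write a run configuration as TOML
#'
#' The config file is the flat `key = value` TOML dialect with optional
#' `[params]` section for the force-field constants; every key of
#' [run_config()] and [dpd_params()] is recognised and defaults to the
#' production value when absent.
#'
#' @param path File path.
#' @param config A `run_config` (for writing).
#' @return `read_run_config()` returns a `run_config`;
#'   `write_run_config()` returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  kv <- parse_flat_toml(path)
  pkeys <- kv$params %||% list()
  top <- kv$top
  known <- c("box", "n1", "n2", "nh1", "nh2", "nt1", "nt2", "rho",
             "total_steps", "swap_interval", "n_slabs", "profile_bins",
             "seed", "traj_every", "energy_every", "profile_every",
             "interaction_mode")
  bad <- setdiff(names(top), known)
  if (length(bad))
    abort(paste0("unknown config key: ", paste(bad, collapse = ", ")))
  pknown <- c("gamma", "kBT", "sigma", "dt", "lambda", "rc", "m")
  badp <- setdiff(names(pkeys), pknown)
  if (length(badp))
    abort(paste0("unknown [params] key: ", paste(badp, collapse = ", ")))
  if (!is.null(top$swap_interval) && identical(top$swap_interval, "off"))
    top$swap_interval <- Inf
  params <- do.call(dpd_params, pkeys)
  do.call(run_config, c(top, list(params = params)))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  fmt <- function(v) {
    if (is.character(v)) paste0('"', v, '"')
    else if (is.infinite(v)) '"off"'
    else paste(format(v, digits = 17), collapse = ", ")
  }
  top <- config[setdiff(names(config), "params")]
  lines <- c(
    vapply(names(top), function(k) {
      v <- top[[k]]
      if (k == "box") paste0("box = [", paste(v, collapse = ", "), "]")
      else paste0(k, " = ", fmt(v))
    }, character(1)),
    "", "[params]",
    vapply(names(unclass(config$params)), function(k)
      paste0(k, " = ", fmt(config$params[[k]])), character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

# minimal flat TOML reader: comments, [section], key = value where value is
# a number, bool, quoted string, or [num, num, ...]
parse_flat_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(top = list())
  section <- "top"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3) abort(paste0("malformed config line: ", ln))
    key <- m[2]; val <- trimws(m[3])
    parsed <- if (grepl('^".*"$', val)) {
      gsub('^"|"$', "", val)
    } else if (val %in% c("true", "false")) {
      val == "true"
    } else if (grepl("^\\[.*\\]$", val)) {
      as.numeric(trimws(strsplit(gsub("^\\[|\\]$", "", val), ",")[[1]]))
    } else {
      x <- suppressWarnings(as.numeric(val))
      if (is.na(x)) abort(paste0("unparseable value for key ", key, ": ", val))
      x
    }
    out[[section]][[key]] <- parsed
  }
  out
}
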