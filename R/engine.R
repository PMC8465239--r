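#' DPD weight function
#'
#' Linear soft-core weight `w(r) = 1 - r/rc` for `r < rc`, zero beyond the
#' cutoff. The conservative force uses `w`, the dissipative force `w^2` and
#' the random force `w`, which together satisfy fluctuation-dissipation.
#'
#' @param r Distance(s), >= 0.
#' @param rc Cutoff (default 1).
#' @return Numeric vector of weights.
#' @export
dpd_weight <- function(r, rc = 1) {
  if (any(r < 0)) abort("`r` must be >= 0")
  ifelse(r < rc, 1 - r / rc, 0)
}

# topology pieces in the 0-based form the C++ kernels expect
topology_arrays <- function(state) {
  tp <- state$topology
  if (is.null(tp) || is.null(tp$bonds) || nrow(tp$bonds) == 0) {
    bonds <- matrix(0L, 0, 2); bks <- numeric(0); brs <- numeric(0)
  } else {
    bonds <- cbind(tp$bonds$i, tp$bonds$j) - 1L
    bks <- tp$bonds$ks; brs <- tp$bonds$rs
  }
  if (is.null(tp) || is.null(tp$angles) || nrow(tp$angles) == 0) {
    angles <- matrix(0L, 0, 3); akt <- numeric(0); at0 <- numeric(0)
  } else {
    angles <- cbind(tp$angles$i, tp$angles$j, tp$angles$k) - 1L
    akt <- tp$angles$ktheta; at0 <- tp$angles$theta0
  }
  list(bonds = bonds, bks = bks, brs = brs,
       angles = angles, akt = akt, at0 = at0)
}

#' Forces on every bead
#'
#' Evaluates the full force field -- conservative, dissipative and random
#' pair forces within the cutoff (minimum image, cell-list search), harmonic
#' bonds and angle bending -- for one state. The random term for pair (i, j)
#' at a given step is a counter-based function of `(seed, step, i, j)`, so
#' `zeta_ij = zeta_ji` holds exactly and results do not depend on iteration
#' order. Set `sigma = gamma = 0` in `params` via [dpd_params()] arguments
#' for a purely conservative evaluation.
#'
#' @param state A `dpd_state`.
#' @param table Interaction table from [interaction_table()].
#' @param params A [dpd_params()].
#' @param seed,step Keys of the random stream.
#' @param gaussian Draw Gaussian rather than uniform unit-variance noise.
#' @return List with `forces` (N x 3) and potential-energy parts
#'   `e_pair`, `e_bond`, `e_angle`.
#' @export
pair_forces <- function(state, table = interaction_table(),
                        params = dpd_params(), seed = 1, step = 0,
                        gaussian = FALSE) {
  if (params$rc <= 0) abort("rc must be > 0")
  ta <- topology_arrays(state)
  cpp_forces(state$pos, state$vel, state$species, state$box, table,
             params$rc, params$gamma, params$sigma, params$dt,
             seed, step, gaussian,
             ta$bonds, ta$bks, ta$brs, ta$angles, ta$akt, ta$at0)
}

#' @rdname pair_forces
#' @details `bond_forces()` and `angle_forces()` evaluate only the bonded
#'   terms (conservative pair forces and the thermostat switched off),
#'   returning the same structure.
#' @export
bond_forces <- function(state, params = dpd_params()) {
  ta <- topology_arrays(state)
  cpp_forces(state$pos, state$vel, state$species, state$box,
             matrix(0, 5, 5), params$rc, 0, 0, params$dt, 0, 0, FALSE,
             ta$bonds, ta$bks, ta$brs, matrix(0L, 0, 3), numeric(0), numeric(0))
}

#' @rdname pair_forces
#' @export
angle_forces <- function(state, params = dpd_params()) {
  ta <- topology_arrays(state)
  cpp_forces(state$pos, state$vel, state$species, state$box,
             matrix(0, 5, 5), params$rc, 0, 0, params$dt, 0, 0, FALSE,
             matrix(0L, 0, 2), numeric(0), numeric(0), ta$angles, ta$akt, ta$at0)
}

#' Potential and kinetic energy of a state
#'
#' Potential energy is the sum of the conservative-force antiderivatives:
#' soft pair term `(a rc / 2) (1 - r/rc)^2`, bond term
#' `(ks / (2 rs)) (r - rs)^2` and bending term `ktheta (theta - theta0)^2`.
#'
#' @inheritParams pair_forces
#' @return List with `potential` (and its parts) and `kinetic`.
#' @export
total_energy <- function(state, table = interaction_table(),
                         params = dpd_params()) {
  fr <- pair_forces(state, table,
                    dpd_params(gamma = 0, kBT = params$kBT, dt = params$dt,
                               lambda = params$lambda, rc = params$rc,
                               m = params$m))
  kin <- 0.5 * params$m * sum(state$vel^2)
  list(potential = fr$e_pair + fr$e_bond + fr$e_angle,
       e_pair = fr$e_pair, e_bond = fr$e_bond, e_angle = fr$e_angle,
       kinetic = kin)
}

#' Advance a state by one modified velocity-Verlet step
#'
#' Position update with the half-squared-timestep force term, a predicted
#' velocity using the mixing parameter `lambda`, force recomputation at the
#' new positions with the predicted velocity (this is where the dissipative
#' force sees the updated velocity), then the trapezoidal velocity
#' correction. Positions are rewrapped into the box.
#'
#' @inheritParams pair_forces
#' @param table Interaction table.
#' @return The advanced `dpd_state`.
#' @export
velocity_verlet_step <- function(state, table = interaction_table(),
                                 params = dpd_params(), seed = 1,
                                 gaussian = FALSE) {
  run_dpd(state, n_steps = 1, table = table, params = params, seed = seed,
          gaussian = gaussian)$state
}

#' Run the simulator
#'
#' Advances a state by `n_steps`, optionally interleaving one momentum-swap
#' event every `swap_interval` steps (reverse non-equilibrium shear between
#' slab 0 and the mid slab), and records trajectory frames, an energy
#' series, the accumulated transferred x-momentum and a binned vx profile
#' at the requested cadences. Fully deterministic for a fixed seed.
#'
#' @param state A `dpd_state`.
#' @param n_steps Number of steps (>= 0).
#' @param table Interaction table.
#' @param params A [dpd_params()].
#' @param seed Seed of the pair-noise stream.
#' @param swap_interval `W`; `Inf` or 0 disables shear.
#' @param n_slabs Slabs of the swap partition (default 20).
#' @param traj_every,energy_every,profile_every Output cadences in steps
#'   (0 disables). `profile_bins` sets the vx-profile resolution.
#' @param profile_bins Number of z-bins of the accumulated velocity profile.
#' @param gaussian Use Gaussian pair noise instead of uniform.
#' @return An object of class `dpd_run`: list with the final `state`,
#'   `frames` (each with step, pos, vel), `energy` tibble (per-part
#'   potential, kinetic, accumulated swapped momentum), `shear` bookkeeping
#'   and the vx-profile accumulators.
#' @export
run_dpd <- function(state, n_steps, table = interaction_table(),
                    params = dpd_params(), seed = 1,
                    swap_interval = Inf, n_slabs = 20,
                    traj_every = 0, energy_every = 0, profile_every = 0,
                    profile_bins = 50, gaussian = FALSE) {
  stopifnot(inherits(state, "dpd_state"))
  if (n_steps < 0) abort("`n_steps` must be >= 0")
  swap <- if (is.finite(swap_interval) && swap_interval >= 1)
    as.integer(swap_interval) else 0L
  ta <- topology_arrays(state)
  if (n_steps == 0) {
    res <- list(state = state, frames = list(),
                energy = tibble(step = integer(), pair = numeric(),
                                bond = numeric(), angle = numeric(),
                                kinetic = numeric(), acc_px = numeric()),
                shear = list(acc_px = 0, n_swaps = 0L, n_skipped = 0L,
                             swap_interval = swap_interval,
                             n_slabs = n_slabs, window_steps = 0L),
                vx_profile = tibble(z = numeric(), vx = numeric(),
                                    n = numeric()),
                params = params, table = table)
    class(res) <- "dpd_run"
    return(res)
  }
  out <- cpp_run(state$pos, state$vel, state$species, state$box, table,
                 params$rc, params$gamma, params$sigma, params$dt,
                 params$lambda,
                 ta$bonds, ta$bks, ta$brs, ta$angles, ta$akt, ta$at0,
                 as.integer(n_steps), seed, state$step,
                 swap, as.integer(n_slabs),
                 as.integer(traj_every), as.integer(energy_every),
                 as.integer(profile_bins), as.integer(profile_every),
                 gaussian)
  new_state <- new_dpd_state(out$pos, out$vel, state$species, state$mol,
                             state$box, state$topology, out$step)
  cnt <- out$vx_count
  prof <- tibble(
    z = (seq_len(profile_bins) - 0.5) * state$box[3] / profile_bins,
    vx = ifelse(cnt > 0, out$vx_sum / pmax(cnt, 1), NA_real_),
    n = cnt)
  res <- list(
    state = new_state,
    frames = out$frames,
    energy = as_tibble(out$energy),
    shear = list(acc_px = out$acc_px, n_swaps = out$n_swaps,
                 n_skipped = out$n_skipped, swap_interval = swap_interval,
                 n_slabs = n_slabs, window_steps = as.integer(n_steps)),
    vx_profile = prof,
    params = params, table = table)
  class(res) <- "dpd_run"
  res
}

#' @export
print.dpd_run <- function(x, ...) {
  cat("<dpd_run> advanced to step ", x$state$step, ", ",
      length(x$frames), " frames, ", nrow(x$energy), " energy samples\n",
      sep = "")
  if (x$shear$n_swaps > 0)
    cat("  shear: ", x$shear$n_swaps, " swaps, accumulated px = ",
        signif(x$shear$acc_px, 6), "\n", sep = "")
  invisible(x)
}

#' Neighbour pairs within a cutoff
#'
#' Enumerates every unordered bead pair with minimum-image distance below
#' `cutoff`, via the same cell-list search the force kernels use (falling
#' back to all-pairs for boxes under three cells per axis). Used by the
#' structure classifier and exposed for testing against brute-force
#' enumeration.
#'
#' @param state A `dpd_state` (or an N x 3 position matrix with `box`).
#' @param cutoff Pair cutoff in rc.
#' @param box Box lengths, required when `state` is a bare matrix.
#' @return Tibble with 1-based `i`, `j`, distance `r`, and the
#'   minimum-image displacement components `dx`, `dy`, `dz` (r_i - r_j).
#' @export
neighbor_pairs <- function(state, cutoff = 1, box = NULL) {
  if (inherits(state, "dpd_state")) {
    pos <- state$pos; box <- state$box
  } else {
    pos <- state
    if (is.null(box)) abort("`box` is required for a bare position matrix")
  }
  as_tibble(cpp_neighbor_pairs(pos, box, cutoff))
}

#' Energy trace of a run
#'
#' Tidies the energy series of a [run_dpd()] result into long form, with
#' the total potential and total energy derived columns.
#'
#' @param run A `dpd_run`.
#' @return Tibble with columns `step`, `pair`, `bond`, `angle`, `kinetic`,
#'   `potential`, `total`, `acc_px`.
#' @export
energy_series <- function(run) {
  stopifnot(inherits(run, "dpd_run"))
  mutate(run$energy,
         potential = .data$pair + .data$bond + .data$angle,
         total = .data$potential + .data$kinetic)
}
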