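
# normalize analysis input to a list of frames (pos/vel matrices) plus the
# reference state carrying species/mol/box/topology
analysis_frames <- function(x, state = NULL) {
  if (inherits(x, "dpd_state"))
    return(list(state = x, frames = list(list(step = x$step, pos = x$pos,
                                              vel = x$vel))))
  if (inherits(x, "dpd_run")) {
    frames <- if (length(x$frames) > 0) x$frames
              else list(list(step = x$state$step, pos = x$state$pos,
                             vel = x$state$vel))
    return(list(state = x$state, frames = frames))
  }
  if (is.list(x) && length(x) > 0 && !is.null(state))
    return(list(state = state, frames = x))
  abort("expected a dpd_state, a dpd_run, or a frame list with `state`")
}

#' Unwrap lipid molecules across periodic boundaries
#'
#' Walks each molecule's bond graph from its first bead, replacing every
#' bonded neighbour's coordinates by the minimum-image position relative to
#' its already-placed partner. Water beads are untouched. Required before
#' any gyration analysis, since wrapped chains straddle box faces.
#'
#' @param pos N x 3 position matrix (wrapped).
#' @param state The `dpd_state` supplying box and topology.
#' @return Position matrix with bonded molecules made whole.
#' @export
unwrap_molecules <- function(pos, state) {
  tp <- state$topology
  if (is.null(tp) || nrow(tp$bonds) == 0) return(pos)
  box <- state$box
  b <- arrange(tp$bonds, .data$j)
  for (r in seq_len(nrow(b))) {
    i <- b$i[r]; j <- b$j[r]
    d <- pos[j, ] - pos[i, ]
    d <- d - box * round(d / box)
    pos[j, ] <- pos[i, ] + d
  }
  pos
}

#' Species density profile
#'
#' Frame-averaged number density (beads per rc^3) of each requested species
#' in equal bins along one box axis.
#'
#' @param x A `dpd_state`, a `dpd_run` (frames are averaged; the final
#'   state is used when no frames were recorded), or a list of frames with
#'   `state` supplied.
#' @param species Character vector of species labels (see [dpd_species()]);
#'   default all five.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param n_bins Number of bins (>= 2).
#' @param state Reference state when `x` is a bare frame list.
#' @return A tibble of class `dpd_profile` with columns `z` (bin centre on
#'   the chosen axis), `species`, `density`; attributes carry the axis, bin
#'   edges, bin volume and frame count.
#' @export
density_profile <- function(x, species = dpd_species(), axis = "z",
                            n_bins = 30, state = NULL) {
  if (n_bins < 2) abort("`n_bins` must be >= 2")
  species <- match.arg(species, dpd_species(), several.ok = TRUE)
  af <- analysis_frames(x, state)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- af$state$box[ax]
  bin_vol <- prod(af$state$box) / n_bins
  codes <- match(species, dpd_species())
  sel <- af$state$species %in% codes
  if (!any(sel)) abort("empty species selection")
  sp_sel <- af$state$species[sel]
  counts <- matrix(0, n_bins, length(codes))
  for (fr in af$frames) {
    b <- pmin(floor(fr$pos[sel, ax] / L * n_bins) + 1, n_bins)
    for (s in seq_along(codes))
      counts[, s] <- counts[, s] + tabulate(b[sp_sel == codes[s]], n_bins)
  }
  counts <- counts / (length(af$frames) * bin_vol)
  edges <- seq(0, L, length.out = n_bins + 1)
  out <- tibble(z = rep((edges[-1] + edges[-(n_bins + 1)]) / 2,
                        times = length(species)),
                species = rep(species, each = n_bins),
                density = as.vector(counts))
  structure(out, class = c("dpd_profile", class(out)),
            axis = axis, bin_edges = edges, bin_volume = bin_vol,
            n_frames = length(af$frames), quantity = "density")
}

#' P2 orientational order parameter of lipid head groups
#'
#' For each chain the direction is the unit vector from the first to the
#' last head bead; `P2 = (3 cos^2(theta) - 1) / 2` against the reference
#' axis is averaged over chains (and frames) per bin of the head-block
#' centroid along that axis. P2 is 1 for chains parallel to the axis, -0.5
#' for perpendicular chains, and 0 for isotropic orientations; it is even
#' in the chain direction, so head ordering does not depend on which end
#' counts as first.
#'
#' @inheritParams density_profile
#' @param lipid_type Restrict to lipid type 1 or 2; `NULL` (default) uses
#'   both.
#' @param n_bins Number of centroid bins.
#' @return A `dpd_profile` tibble with columns `z`, `p2`, `n_chains`;
#'   attribute `overall` holds the unbinned ensemble average.
#' @export
order_parameter <- function(x, axis = "z", n_bins = 30, lipid_type = NULL,
                            state = NULL) {
  af <- analysis_frames(x, state)
  tp <- af$state$topology
  if (is.null(tp)) abort("state has no molecule topology")
  mols <- tp$molecules
  if (!is.null(lipid_type)) mols <- filter(mols, .data$type %in% lipid_type)
  if (any(mols$n_head < 2)) abort("head block needs >= 2 beads")
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- af$state$box[ax]
  box <- af$state$box
  first <- mols$first
  last_head <- mols$first + mols$n_head - 1L
  p2_all <- numeric(0)
  cent_all <- numeric(0)
  n_dropped <- 0L
  for (fr in af$frames) {
    d <- fr$pos[last_head, , drop = FALSE] - fr$pos[first, , drop = FALSE]
    d <- d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
    len <- sqrt(rowSums(d^2))
    ok <- len > 1e-12
    n_dropped <- n_dropped + sum(!ok)
    cosq <- (d[ok, ax] / len[ok])^2
    p2_all <- c(p2_all, (3 * cosq - 1) / 2)
    # head-block centroid along the axis: midpoint of the first-to-last
    # head vector (exact for evenly spaced head beads)
    cent <- fr$pos[first[ok], ax] + d[ok, ax] / 2
    cent_all <- c(cent_all, cent %% L)
  }
  if (n_dropped > 0)
    warn(paste0(n_dropped, " zero-length chain vectors excluded"))
  b <- pmin(floor(cent_all / L * n_bins) + 1, n_bins)
  edges <- seq(0, L, length.out = n_bins + 1)
  out <- tibble(z = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                p2 = as.numeric(tapply(p2_all, factor(b, levels = seq_len(n_bins)),
                                       mean)),
                n_chains = tabulate(b, n_bins))
  structure(out, class = c("dpd_profile", class(out)),
            axis = axis, bin_edges = edges,
            n_frames = length(af$frames),
            overall = mean(p2_all), quantity = "order_parameter")
}

#' Gyration tensor of one chain
#'
#' Second moment of the bead positions about the chain's centre of mass:
#' `G[a, b] = mean((r_a - com_a) * (r_b - com_b))`. Pass unwrapped
#' coordinates (see [unwrap_molecules()]).
#'
#' @param chain_positions N x 3 matrix of one chain's bead coordinates.
#' @return An object of class `gyration_result`: the 3x3 tensor, its
#'   eigenvalues sorted descending (`lambda`, the squared semi-axis
#'   measures), and `components` = sqrt of the diagonal entries
#'   (Rgxx, Rgyy, Rgzz, in length units).
#' @examples
#' g <- gyration_tensor(cbind(c(-1, 1), 0, 0))
#' g$tensor[1, 1]  # 1
#' @export
gyration_tensor <- function(chain_positions) {
  p <- as.matrix(chain_positions)
  if (nrow(p) < 2) abort("undefined shape: a chain needs >= 2 beads")
  cp <- sweep(p, 2, colMeans(p))
  g <- crossprod(cp) / nrow(p)
  ev <- sort(eigen(g, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0 & ev > -1e-12] <- 0
  structure(list(tensor = g, lambda = ev, components = sqrt(pmax(diag(g), 0))),
            class = "gyration_result")
}

#' Shape factor from gyration eigenvalues
#'
#' `delta = 1 - 3 (L1 L2 + L2 L3 + L1 L3) / (L1 + L2 + L3)^2` where the
#' `L` are the gyration-tensor eigenvalues (squared lengths). Ranges from 0
#' for spherically symmetric objects to 1 for perfectly collinear
#' ("cigar") ones; invariant under rigid rotation and uniform scaling.
#'
#' @param gyration A `gyration_result` or a numeric vector of the three
#'   eigenvalues.
#' @return The shape factor in [0, 1].
#' @examples
#' shape_factor(c(1, 0, 0))      # 1: rod
#' shape_factor(c(1, 1, 1))      # 0: sphere
#' shape_factor(c(1, 1, 0))      # 0.25: flat disc
#' @export
shape_factor <- function(gyration) {
  ev <- if (inherits(gyration, "gyration_result")) gyration$lambda
        else as.numeric(gyration)
  if (length(ev) != 3) abort("need three eigenvalues")
  s <- sum(ev)
  if (s <= 0) abort("undefined shape factor: all eigenvalues are zero")
  1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[1] * ev[3]) / s^2
}

#' Per-frame gyration components and shape factor of a lipid type
#'
#' For every trajectory frame, unwraps each chain of the given lipid type,
#' computes its gyration tensor, and averages the component lengths
#' `Rgxx = sqrt(G[x, x])` (and y, z alike) and the shape factor over
#' chains.
#'
#' @inheritParams density_profile
#' @param lipid_type 1, 2, or `c(1, 2)` (reported separately).
#' @return A tibble of class `rg_series`: columns `step`, `type`, `rgxx`,
#'   `rgyy`, `rgzz`, `delta`, `n_chains`.
#' @export
rg_components_series <- function(x, lipid_type = c(1, 2), state = NULL) {
  af <- analysis_frames(x, state)
  tp <- af$state$topology
  if (is.null(tp)) abort("state has no molecule topology")
  rows <- list()
  for (fr in af$frames) {
    up <- unwrap_molecules(fr$pos, af$state)
    for (ty in lipid_type) {
      mols <- filter(tp$molecules, .data$type == ty)
      if (nrow(mols) == 0) next
      comp <- matrix(0, nrow(mols), 3)
      dl <- numeric(nrow(mols))
      for (m in seq_len(nrow(mols))) {
        idx <- mols$first[m] + seq_len(mols$n_beads[m]) - 1L
        g <- gyration_tensor(up[idx, , drop = FALSE])
        comp[m, ] <- g$components
        dl[m] <- shape_factor(g)
      }
      rows[[length(rows) + 1]] <-
        tibble(step = fr$step, type = ty,
               rgxx = mean(comp[, 1]), rgyy = mean(comp[, 2]),
               rgzz = mean(comp[, 3]), delta = mean(dl),
               n_chains = nrow(mols))
    }
  }
  out <- bind_rows(rows)
  structure(out, class = c("rg_series", class(out)))
}

#' Irving-Kirkwood slab pressure profile
#'
#' Diagonal pressure-tensor components per z-slab: the kinetic term
#' `m v_a^2` is assigned to each bead's slab; the configurational (virial)
#' term `F_a d_a` of every pair interaction is distributed over the slabs
#' crossed by the minimum-image segment between the two beads, proportional
#' to the length inside each slab (Irving-Kirkwood contour). Virial content
#' is the conservative pair, bond and angle forces; the thermostat's
#' dissipative and random forces are excluded (their ensemble average is
#' the ideal part already counted kinetically, and their instantaneous
#' values only add noise). The slab-volume-weighted mean of the profile
#' equals the global virial pressure exactly.
#'
#' @inheritParams density_profile
#' @param n_slabs Number of z-slabs (>= 2).
#' @param table Interaction table.
#' @param params Force-field parameters (for `rc`).
#' @return A tibble of class `pressure_profile`: `slab`, `z`, `pxx`,
#'   `pyy`, `pzz` (frame-averaged); attribute `global` holds the
#'   volume-weighted global components, `slab_height` the slab thickness.
#' @export
pressure_profile <- function(x, n_slabs = 30, table = interaction_table(),
                             params = dpd_params(), state = NULL) {
  if (n_slabs < 2) abort("`n_slabs` must be >= 2")
  af <- analysis_frames(x, state)
  ta <- topology_arrays(af$state)
  acc <- matrix(0, n_slabs, 3)
  for (fr in af$frames) {
    pp <- cpp_pressure_profile(fr$pos, fr$vel, af$state$species,
                               af$state$box, table, params$rc,
                               ta$bonds, ta$bks, ta$brs,
                               ta$angles, ta$akt, ta$at0, as.integer(n_slabs))
    acc <- acc + pp$pressure
  }
  acc <- acc / length(af$frames)
  Lz <- af$state$box[3]
  out <- tibble(slab = seq_len(n_slabs),
                z = (seq_len(n_slabs) - 0.5) * Lz / n_slabs,
                pxx = acc[, 1], pyy = acc[, 2], pzz = acc[, 3])
  structure(out, class = c("pressure_profile", class(out)),
            global = colMeans(acc), slab_height = Lz / n_slabs,
            n_frames = length(af$frames))
}

#' Interfacial tension profile
#'
#' Normal-tangential pressure contrast per slab,
#' `sigma_z = pzz - (pxx + pyy) / 2`, from a [pressure_profile()]. The
#' attribute `total` is the z-integral (the total interfacial tension of
#' the configuration, in kBT / rc^2).
#'
#' @param pressure A `pressure_profile`.
#' @return A `dpd_profile` tibble with columns `z`, `sigma`.
#' @export
tension_profile <- function(pressure) {
  stopifnot(inherits(pressure, "pressure_profile"))
  out <- tibble(z = pressure$z,
                sigma = pressure$pzz - 0.5 * (pressure$pxx + pressure$pyy))
  structure(out, class = c("dpd_profile", class(out)),
            axis = "z", quantity = "tension",
            total = sum(out$sigma) * attr(pressure, "slab_height"))
}
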