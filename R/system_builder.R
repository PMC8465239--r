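#' Particle system state
#'
#' The simulator's central object: wrapped bead coordinates and velocities,
#' species and molecule labels, the periodic box, and the assembled bonded
#' topology. Construct states with [random_initial_configuration()],
#' [preassembled_bilayer()] or [synthetic_geometry()].
#'
#' @param pos,vel N x 3 numeric matrices (rc and rc/tau units).
#' @param species Integer species codes (1..5, see [dpd_species()]).
#' @param mol Integer molecule ids; 0 marks water.
#' @param box Box lengths `(Lx, Ly, Lz)` in rc.
#' @param topology System-level bonded topology (bonds/angles/molecules), or
#'   `NULL` for unbonded fixtures.
#' @param step Step index carried by the state.
#' @return An object of class `dpd_state`.
#' @keywords internal
new_dpd_state <- function(pos, vel, species, mol, box, topology = NULL,
                          step = 0L) {
  structure(list(pos = pos, vel = vel, species = as.integer(species),
                 mol = as.integer(mol), box = as.numeric(box),
                 topology = topology, step = as.integer(step)),
            class = "dpd_state")
}

#' @export
print.dpd_state <- function(x, ...) {
  cat("<dpd_state> ", nrow(x$pos), " beads in box ",
      paste(signif(x$box, 4), collapse = " x "), " rc, step ", x$step, "\n",
      sep = "")
  tab <- table(factor(dpd_species()[x$species], levels = dpd_species()))
  cat("  species:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
as_tibble.dpd_state <- function(x, ...) {
  tibble(bead = seq_len(nrow(x$pos)),
         species = dpd_species()[x$species],
         mol = x$mol,
         x = x$pos[, 1], y = x$pos[, 2], z = x$pos[, 3],
         vx = x$vel[, 1], vy = x$vel[, 2], vz = x$vel[, 3])
}

# Assemble the system-level bonded topology for n1 + n2 lipids placed
# consecutively (type 1 first), beads numbered from 1.
assemble_topology <- function(config) {
  t1 <- build_lipid_type1(config$nh1, config$nt1)
  t2 <- build_lipid_type2(config$nh2, config$nt2)
  n_mol <- config$n1 + config$n2
  sizes <- c(rep(length(t1$species), config$n1),
             rep(length(t2$species), config$n2))
  first <- cumsum(c(1, sizes))[seq_len(n_mol)]
  types <- c(rep(1L, config$n1), rep(2L, config$n2))
  tops <- list(t1, t2)
  bonds <- vector("list", n_mol)
  angles <- vector("list", n_mol)
  species <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    tp <- tops[[types[m]]]
    off <- first[m] - 1L
    bonds[[m]] <- mutate(tp$bonds, i = .data$i + off, j = .data$j + off)
    angles[[m]] <- mutate(tp$angles, i = .data$i + off, j = .data$j + off,
                          k = .data$k + off)
    species[[m]] <- tp$species
  }
  list(
    species = unlist(species),
    mol = rep(seq_len(n_mol), times = sizes),
    bonds = bind_rows(bonds),
    angles = bind_rows(angles),
    molecules = tibble(mol = seq_len(n_mol), type = types, first = first,
                       n_beads = sizes,
                       n_head = ifelse(types == 1L, config$nh1, config$nh2)),
    templates = tops
  )
}

# random orthonormal frame (u, w) from the R RNG
random_frame <- function() {
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  w <- rnorm(3); w <- w - sum(w * u) * u
  nw <- sqrt(sum(w^2))
  while (nw < 1e-8) {
    w <- rnorm(3); w <- w - sum(w * u) * u; nw <- sqrt(sum(w^2))
  }
  list(u = u, w = w / nw)
}

# idealized internal geometry of one lipid, relative to its first bead:
# every bond at rs, every bending term at its equilibrium angle
lipid_template_coords <- function(top, u, w, rs = 0.7) {
  n <- length(top$species)
  xyz <- matrix(0, n, 3)
  nh <- top$n_head
  for (b in seq_len(nh)) xyz[b, ] <- (b - 1) * rs * u
  if (top$type == 1L) {
    for (b in (nh + 1):n) xyz[b, ] <- (b - 1) * rs * u
  } else {
    nt <- top$n_tail_per_tail
    anchor <- xyz[nh, ]
    for (s in c(1, -1)) {
      d1 <- cos(pi / 3) * u + s * sin(pi / 3) * w
      d2 <- cos(2 * pi / 3) * u + s * sin(2 * pi / 3) * w
      idx <- nh + (if (s == 1) seq_len(nt) else nt + seq_len(nt))
      xyz[idx[1], ] <- anchor + rs * d1
      if (nt > 1)
        for (m in 2:nt) xyz[idx[m], ] <- xyz[idx[1], ] + (m - 1) * rs * d2
    }
  }
  xyz
}

wrap_positions <- function(pos, box) {
  for (k in 1:3) pos[, k] <- pos[, k] - box[k] * floor(pos[, k] / box[k])
  pos
}

maxwell_velocities <- function(n, kBT = 1, m = 1) {
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT / m)), n, 3)
  sweep(v, 2, colMeans(v))  # exact zero net momentum
}

#' Random initial configuration
#'
#' Builds each lipid at its idealized internal geometry (all bonds at `rs`,
#' all bending terms at their equilibrium angle), drops it at a uniformly
#' random position and orientation, and fills the box with water to total
#' density `rho`. Overlaps are not rejected: DPD potentials are soft and
#' relax them within a few steps. Velocities are Maxwell-Boltzmann at `kBT`
#' shifted to exactly zero net momentum. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `dpd_state` with `round(rho * V)` beads.
#' @examples
#' cfg <- run_config(box = 10, n1 = 25, n2 = 25, nt1 = 10, nt2 = 10)
#' st <- random_initial_configuration(cfg)
#' nrow(st$pos)  # 3000
#' @export
random_initial_configuration <- function(config, seed = config$seed) {
  topo <- assemble_topology(config)
  n_lipid <- length(topo$species)
  n_total <- round(config$rho * prod(config$box))
  n_water <- n_total - n_lipid
  if (n_water < 0)
    abort("infeasible density: lipid beads alone exceed rho * V")
  rs <- topo$templates[[1]]$bonds$rs[1]
  withr_seed(seed, {
    pos <- matrix(0, n_total, 3)
    for (m in seq_len(nrow(topo$molecules))) {
      row <- topo$molecules[m, ]
      fr <- random_frame()
      xyz <- lipid_template_coords(topo$templates[[row$type]], fr$u, fr$w, rs)
      com <- runif(3) * config$box
      idx <- row$first + seq_len(row$n_beads) - 1L
      pos[idx, ] <- sweep(xyz, 2, colMeans(xyz)) + rep(com, each = row$n_beads)
    }
    if (n_water > 0)
      pos[n_lipid + seq_len(n_water), ] <-
        matrix(runif(3 * n_water), ncol = 3) %*% diag(config$box)
    vel <- maxwell_velocities(n_total, config$params$kBT, config$params$m)
    new_dpd_state(wrap_positions(pos, config$box), vel,
                  c(topo$species, rep(species_code("W"), n_water)),
                  c(topo$mol, rep(0L, n_water)),
                  config$box, topology = topo[c("bonds", "angles", "molecules")])
  })
}

withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

#' Pre-assembled asymmetric bilayer
#'
#' Places the two lipid species as two apposed leaflets normal to z around
#' the box mid-plane -- type 2 in the upper leaflet, type 1 in the lower,
#' chains straight along z with tails meeting at the mid-plane -- and fills
#' the water outside the membrane slab. A fast-equilibration fixture: it
#' skips the random self-assembly stage.
#'
#' @inheritParams random_initial_configuration
#' @param gap Distance in rc between each leaflet's tail end and the
#'   mid-plane (default 0.3).
#' @return A `dpd_state`.
#' @export
preassembled_bilayer <- function(config, seed = config$seed, gap = 0.3) {
  topo <- assemble_topology(config)
  n_lipid <- length(topo$species)
  n_total <- round(config$rho * prod(config$box))
  n_water <- n_total - n_lipid
  if (n_water < 0)
    abort("infeasible density: lipid beads alone exceed rho * V")
  rs <- topo$templates[[1]]$bonds$rs[1]
  Lz <- config$box[3]
  z0 <- Lz / 2
  len1 <- if (config$n1 > 0) (config$nh1 + config$nt1 - 1) * rs else 0
  len2 <- if (config$n2 > 0) (config$nh2 + config$nt2 - 1) * rs else 0
  z_bottom <- z0 - gap - len1
  z_top <- z0 + gap + len2
  if (z_bottom < 0.5 || z_top > Lz - 0.5)
    abort("box too thin along z for the requested leaflet thickness")
  grid_xy <- function(n) {
    g <- ceiling(sqrt(n))
    i <- (seq_len(n) - 1) %% g
    j <- (seq_len(n) - 1) %/% g
    cbind((i + 0.5) * config$box[1] / g, (j + 0.5) * config$box[2] / g)
  }
  withr_seed(seed, {
    pos <- matrix(0, n_total, 3)
    xy1 <- grid_xy(config$n1)
    xy2 <- grid_xy(config$n2)
    for (m in seq_len(nrow(topo$molecules))) {
      row <- topo$molecules[m, ]
      nb <- row$n_beads
      idx <- row$first + seq_len(nb) - 1L
      if (row$type == 1L) {
        # lower leaflet: head start at the bottom, chain straight up
        xy <- xy1[m, ]
        zs <- z_bottom + (seq_len(nb) - 1) * rs
        pos[idx, ] <- cbind(rep(xy[1], nb), rep(xy[2], nb), zs)
      } else {
        # upper leaflet: head start at the top, both tails straight down
        xy <- xy2[m - config$n1, ]
        nh <- config$nh2; nt <- config$nt2
        zh <- z_top - (seq_len(nh) - 1) * rs
        zt <- z_top - (nh - 1) * rs - seq_len(nt) * rs
        # offset the two tails slightly in x to avoid exact overlap
        pos[idx, ] <- cbind(
          c(rep(xy[1], nh), rep(xy[1] - 0.15, nt), rep(xy[1] + 0.15, nt)),
          rep(xy[2], nb),
          c(zh, zt, zt))
      }
    }
    if (n_water > 0) {
      lo <- z_bottom - 0.3
      hi <- z_top + 0.3
      below <- lo
      above <- Lz - hi
      zw <- runif(n_water) * (below + above)
      zw <- ifelse(zw < below, zw, hi + (zw - below))
      pos[n_lipid + seq_len(n_water), ] <-
        cbind(runif(n_water) * config$box[1], runif(n_water) * config$box[2], zw)
    }
    vel <- maxwell_velocities(n_total, config$params$kBT, config$params$m)
    new_dpd_state(wrap_positions(pos, config$box), vel,
                  c(topo$species, rep(species_code("W"), n_water)),
                  c(topo$mol, rep(0L, n_water)),
                  config$box, topology = topo[c("bonds", "angles", "molecules")])
  })
}

#' Synthetic morphology fixtures
#'
#' Builds idealized bead arrangements of the three self-assembled
#' morphologies -- a flat slab spanning x and y, a cylinder spanning one
#' axis, and a closed spherical shell -- as classifier test fixtures. Tail
#' beads form the body on a lattice fine enough to be single-cluster at the
#' interaction range; head beads coat the surfaces; water fills the rest.
#' These are geometric constructions, not simulation outputs.
#'
#' @param shape `"slab"`, `"cylinder"` or `"sphere"`.
#' @param box Box lengths in rc (scalar recycled).
#' @param radius Cylinder / sphere radius in rc (default a quarter of the
#'   smallest box edge).
#' @param thickness Tail-slab (or shell) thickness in rc (default 2).
#' @param spacing Lattice spacing of the tail body (default 0.5, safely
#'   below the clustering cutoff of 1 rc).
#' @param axis For `"slab"` the normal axis, for `"cylinder"` the axis it
#'   spans: `"x"`, `"y"` or `"z"`.
#' @param rho Total bead density used to size the water fill (default 3).
#' @param seed Seed for the water placement and velocities.
#' @return A `dpd_state` (no bonded topology).
#' @export
synthetic_geometry <- function(shape = c("slab", "cylinder", "sphere"),
                               box = 12, radius = NULL, thickness = 2,
                               spacing = 0.5, axis = c("z", "x", "y"),
                               rho = 3, seed = 1) {
  shape <- match.arg(shape)
  axis <- match.arg(axis)
  box <- rep(as.numeric(box), length.out = 3)
  ax <- match(axis, c("x", "y", "z"))
  if (is.null(radius)) radius <- min(box) / 4
  ctr <- box / 2
  gvec <- function(L) {
    n <- max(2, floor(L / spacing))
    (seq_len(n) - 0.5) * (L / n)
  }
  g <- expand.grid(x = gvec(box[1]), y = gvec(box[2]), z = gvec(box[3]))
  p <- as.matrix(g)
  d_ax <- p[, ax] - ctr[ax]
  perp <- sqrt(rowSums((p[, -ax, drop = FALSE] -
                          rep(ctr[-ax], each = nrow(p)))^2))
  r_ctr <- sqrt(rowSums(sweep(p, 2, ctr)^2))
  half <- thickness / 2
  sel_tail <- switch(shape,
    slab = abs(d_ax) <= half,
    cylinder = perp <= radius,
    sphere = abs(r_ctr - radius) <= half)
  sel_head <- switch(shape,
    slab = abs(d_ax) > half & abs(d_ax) <= half + 0.7,
    cylinder = perp > radius & perp <= radius + 0.7,
    sphere = abs(r_ctr - radius) > half & abs(r_ctr - radius) <= half + 0.7)
  tails <- p[sel_tail, , drop = FALSE]
  heads <- p[sel_head, , drop = FALSE]
  n_struct <- nrow(tails) + nrow(heads)
  n_water <- max(0, round(rho * prod(box)) - n_struct)
  withr_seed(seed, {
    water <- matrix(runif(3 * n_water), ncol = 3) %*% diag(box)
    pos <- rbind(tails, heads, water)
    vel <- maxwell_velocities(nrow(pos))
    new_dpd_state(wrap_positions(pos, box), vel,
                  c(rep(species_code("T1"), nrow(tails)),
                    rep(species_code("H1"), nrow(heads)),
                    rep(species_code("W"), n_water)),
                  rep(0L, nrow(pos)), box)
  })
}
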