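no_thermo <- dpd_params(gamma = 0)

test_that("weight function is linear inside the cutoff and zero beyond", {
  expect_identical(dpd_weight(0), 1)
  expect_identical(dpd_weight(0.5), 0.5)
  expect_identical(dpd_weight(1.2), 0)
  expect_equal(dpd_weight(c(0.25, 2)), c(0.75, 0))
  expect_error(dpd_weight(-0.1), ">= 0")
})

test_that("conservative pair force matches the soft-repulsion form", {
  st <- two_bead_state(0.5)
  f <- pair_forces(st, params = no_thermo)
  expect_equal(f$forces[1, ], c(-12.5, 0, 0))      # a w = 25 * 0.5, repulsive
  expect_equal(f$forces[2, ], c(12.5, 0, 0))
  expect_equal(f$e_pair, 0.5 * 25 * 0.5^2)
  # beyond the cutoff: nothing
  far <- pair_forces(two_bead_state(1.2), params = no_thermo)
  expect_equal(far$forces, matrix(0, 2, 3))
  expect_identical(far$e_pair, 0)
  # dissipative term vanishes for beads at rest even with the thermostat on,
  # and the random term is exactly antisymmetric: net force stays zero
  g <- pair_forces(two_bead_state(0.5), params = dpd_params(), seed = 3,
                   step = 17)
  expect_equal(colSums(g$forces), c(0, 0, 0), tolerance = 1e-12)
})

test_that("bond force is zero at rs, repulsive below, restoring above", {
  top <- list(species = c(2L, 2L),
              bonds = tibble::tibble(i = 1L, j = 2L, ks = 120, rs = 0.7),
              angles = tibble::tibble(i = integer(), j = integer(),
                                      k = integer(), ktheta = numeric(),
                                      theta0 = numeric()),
              n_head = 2L, n_tail_per_tail = 0L, n_tails = 0L, type = 1L)
  at <- function(r) {
    st <- molecule_state(structure(top, class = "lipid_topology"),
                         rbind(c(5, 5, 5), c(5 + r, 5, 5)))
    bond_forces(st)$forces[2, 1]
  }
  expect_equal(at(0.7), 0)
  expect_equal(at(0.35), 60)      # ks (1 - 0.5), pushing j away from i
  expect_equal(at(1.4), -120)     # stretched to 2 rs: pulled back
})

test_that("angle forces vanish at theta0 and match the bending energy", {
  # straight triple with theta0 = 2*pi/3, ktheta = 3
  top <- build_lipid_type2(3, 1)
  bent <- top
  bent$angles <- tibble::tibble(i = 1L, j = 2L, k = 3L, ktheta = 3,
                                theta0 = 2 * pi / 3)
  bent$bonds <- bent$bonds[0, ]
  st <- molecule_state(structure(bent, class = "lipid_topology"),
                       rbind(c(4, 5, 5), c(5, 5, 5), c(6, 5, 5),
                             c(5, 6, 5), c(5, 4, 5)))
  f <- angle_forces(st)
  expect_equal(f$e_angle, 3 * (pi / 3)^2, tolerance = 1e-10)
  # triple at its equilibrium angle: no force
  eq <- bent
  eq$angles$theta0 <- pi
  st_eq <- molecule_state(structure(eq, class = "lipid_topology"), st$pos)
  expect_equal(max(abs(angle_forces(st_eq)$forces)), 0, tolerance = 1e-12)
})

test_that("bonded-force gradients match central finite differences", {
  set.seed(21)
  top <- build_lipid_type2(3, 3)
  n <- length(top$species)
  st <- molecule_state(top, matrix(runif(3 * n, 2, 6), n, 3))
  f <- pair_forces(st, matrix(0, 5, 5), no_thermo)
  h <- 1e-6
  for (i in sample(n, 4)) for (d in 1:3) {
    num <- 0
    for (s in c(1, -1)) {
      st2 <- st
      st2$pos[i, d] <- st2$pos[i, d] + s * h
      e <- pair_forces(st2, matrix(0, 5, 5), no_thermo)
      num <- num - s * (e$e_bond + e$e_angle) / (2 * h)
    }
    expect_equal(f$forces[i, d], num, tolerance = 1e-5)
  }
  # every angle triple exerts zero net force
  fa <- angle_forces(st)
  expect_lt(max(abs(colSums(fa$forces))), 1e-10)
})

test_that("conservative force is the exact gradient of the potential", {
  cfg <- run_config(box = 4, n1 = 2, n2 = 2, nt1 = 2, nt2 = 2,
                    total_steps = 0)
  st <- random_initial_configuration(cfg, seed = 2)
  # perturb so bonded terms are loaded
  set.seed(3)
  st$pos <- st$pos + matrix(rnorm(length(st$pos), sd = 0.05),
                            nrow(st$pos), 3)
  st$pos <- dpdlipid:::wrap_positions(st$pos, st$box)
  tab <- interaction_table()
  f <- pair_forces(st, tab, no_thermo)
  h <- 1e-6
  for (i in c(1, 10, 30)) for (d in 1:3) {
    num <- 0
    for (s in c(1, -1)) {
      st2 <- st
      st2$pos[i, d] <- st2$pos[i, d] + s * h
      e <- pair_forces(st2, tab, no_thermo)
      num <- num - s * (e$e_pair + e$e_bond + e$e_angle) / (2 * h)
    }
    expect_equal(f$forces[i, d], num, tolerance = 1e-4)
  }
})

test_that("free flight and zero-step runs behave trivially", {
  st <- two_bead_state(5)           # out of range: no forces
  st$vel[1, ] <- c(1, 0, 0)
  out <- velocity_verlet_step(st, params = no_thermo)
  expect_equal(out$pos[1, 1] - st$pos[1, 1], 0.01)
  expect_equal(out$vel, st$vel)
  same <- run_dpd(st, 0)
  expect_identical(same$state, st)
})

test_that("the conservative integrator conserves energy on a bonded molecule", {
  top <- build_lipid_type1(3, 5)
  n <- length(top$species)
  pos <- cbind(3 + seq(0, by = 0.75, length.out = n), 3 + 0.1 * seq_len(n), 4)
  st <- molecule_state(top, pos)
  e0 <- total_energy(st, interaction_table(), no_thermo)
  run <- run_dpd(st, 5000, params = no_thermo, energy_every = 100)
  es <- energy_series(run)
  drift <- max(abs(es$total - (e0$potential + e0$kinetic)))
  expect_lt(drift / n, 1e-3)
})

test_that("energy components agree with direct evaluation", {
  st <- two_bead_state(1.5)
  e <- total_energy(st)
  expect_identical(e$potential, 0)
  # ideal-gas kinetic energy
  set.seed(8)
  st$vel <- matrix(rnorm(6), 2, 3)
  expect_equal(total_energy(st)$kinetic, 0.5 * sum(st$vel^2))
})

test_that("thermostat holds momentum exactly and temperature near kBT", {
  st <- random_initial_configuration(water_config(6), seed = 9)
  run <- run_dpd(st, 1500, seed = 4, energy_every = 25)
  expect_lt(max(abs(colSums(run$state$vel))), 1e-8)
  es <- dplyr::filter(energy_series(run), step > 500)
  Tavg <- mean(2 * es$kinetic / (3 * nrow(st$pos)))
  expect_equal(Tavg, 1, tolerance = 0.05)
  # bitwise reproducibility
  run2 <- run_dpd(st, 1500, seed = 4, energy_every = 25)
  expect_identical(run$state, run2$state)
  run3 <- run_dpd(st, 1500, seed = 5)
  expect_false(identical(run$state$pos, run3$state$pos))
})

test_that("cell-list pair enumeration equals brute force on random boxes", {
  set.seed(31)
  for (trial in 1:100) {
    L <- runif(3, 2.2, 6)
    n <- sample(20:60, 1)
    pos <- matrix(runif(3 * n), n, 3) %*% diag(L)
    got <- neighbor_pairs(pos, cutoff = 1, box = L)
    want <- brute_pairs(pos, L, 1)
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    expect_setequal(key(got$i, got$j),
                    if (nrow(want)) key(want[, 1], want[, 2]) else character())
    if (nrow(want)) {
      ord_g <- order(key(got$i, got$j))
      ord_w <- order(key(want[, 1], want[, 2]))
      expect_equal(got$r[ord_g], want[ord_w, 3], tolerance = 1e-12)
    }
  }
})

test_that("integration blow-up is reported with the step index", {
  st <- two_bead_state(5)
  st$vel[1, ] <- c(1, 0, 0)
  # an absurd timestep overflows the position update immediately
  expect_error(run_dpd(st, 5, params = dpd_params(gamma = 0, dt = 1e200)),
               "step")
})
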