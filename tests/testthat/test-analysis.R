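test_that("density profile is flat for bulk water and integrates to counts", {
  st <- random_initial_configuration(water_config(10), seed = 21)
  dp <- density_profile(st, species = "W", n_bins = 10)
  expect_true(all(abs(dp$density - 3) < 0.5))
  bin_vol <- attr(dp, "bin_volume")
  expect_equal(sum(dp$density) * bin_vol, 3000, tolerance = 0.5 / 3000)
  # a single bead lands in exactly one bin at 1/bin-volume
  one <- dpdlipid:::new_dpd_state(matrix(c(1, 1, 4.3), 1), matrix(0, 1, 3),
                                  1L, 0L, c(6, 6, 6))
  d1 <- density_profile(one, species = "W", n_bins = 6)
  expect_equal(sum(d1$density > 0), 1L)
  expect_equal(max(d1$density), 1 / attr(d1, "bin_volume"))
  expect_equal(d1$z[which.max(d1$density)], 4.5)
  expect_error(density_profile(st, species = "T1"), "empty species")
})

test_that("bilayer density profiles stack heads outside interdigitated tails", {
  cfg <- run_config(box = c(8, 8, 12), n1 = 40, n2 = 40, nt1 = 4, nt2 = 4,
                    total_steps = 0)
  st <- preassembled_bilayer(cfg, seed = 2)
  run <- run_dpd(st, 800, seed = 3, traj_every = 200)
  dp <- density_profile(run, n_bins = 24)
  peak <- function(s) {
    d <- dplyr::filter(dp, species == s)
    d$z[which.max(d$density)]
  }
  expect_gt(peak("H2"), peak("H1"))
  expect_true(peak("T1") > peak("H1") && peak("T1") < peak("H2"))
  expect_true(peak("T2") > peak("H1") && peak("T2") < peak("H2"))
})

test_that("order parameter hits the analytic anchors", {
  n <- 400
  along_z <- aligned_chain_state(matrix(rep(c(0, 0, 1), n), n, 3,
                                        byrow = TRUE))
  expect_equal(attr(order_parameter(along_z), "overall"), 1,
               tolerance = 1e-12)
  # chains in the xy-plane: P2 = -1/2
  set.seed(5)
  phi <- runif(n, 0, 2 * pi)
  in_plane <- aligned_chain_state(cbind(cos(phi), sin(phi), 0))
  expect_equal(attr(order_parameter(in_plane), "overall"), -0.5,
               tolerance = 1e-12)
  # isotropic orientations average to zero
  set.seed(6)
  m <- 1e5
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  iso <- aligned_chain_state(u, n_head = 2, box = c(60, 60, 60))
  expect_equal(attr(order_parameter(iso), "overall"), 0, tolerance = 0.01)
  # reversal invariance: P2 is even in the chain direction
  rev_state <- aligned_chain_state(-u[1:500, , drop = FALSE], n_head = 2)
  fwd_state <- aligned_chain_state(u[1:500, , drop = FALSE], n_head = 2)
  expect_equal(attr(order_parameter(rev_state), "overall"),
               attr(order_parameter(fwd_state), "overall"),
               tolerance = 1e-12)
})

test_that("gyration tensor matches point-mass arithmetic", {
  g <- gyration_tensor(rbind(c(-1.5, 0, 0), c(1.5, 0, 0)))
  expect_equal(g$tensor[1, 1], 9 / 4)
  expect_equal(sum(abs(g$tensor)) - g$tensor[1, 1], 0)
  octa <- gyration_tensor(rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
  expect_equal(octa$tensor, diag(3) / 3)
  set.seed(9)
  for (i in 1:20) {
    ch <- matrix(rnorm(39), 13, 3)
    gg <- gyration_tensor(ch)
    expect_equal(sum(gg$lambda), sum(diag(gg$tensor)), tolerance = 1e-10)
  }
  expect_error(gyration_tensor(matrix(1, 1, 3)), "undefined shape")
})

test_that("shape factor spans rods, spheres and discs and is invariant", {
  expect_equal(shape_factor(c(1, 0, 0)), 1)
  expect_equal(shape_factor(c(2, 2, 2)), 0)
  expect_equal(shape_factor(c(1, 1, 0)), 0.25)
  expect_error(shape_factor(c(0, 0, 0)), "undefined")
  # rotation and scale invariance of the full pipeline
  set.seed(10)
  ch <- matrix(rnorm(30), 10, 3)
  d0 <- shape_factor(gyration_tensor(ch))
  for (i in 1:100) {
    q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    s <- runif(1, 0.1, 10)
    expect_equal(shape_factor(gyration_tensor(s * ch %*% q)), d0,
                 tolerance = 1e-9)
  }
})

test_that("rg series sees upright chains in the as-built bilayer", {
  cfg <- run_config(box = c(6, 6, 10), n1 = 12, n2 = 12, nt1 = 3, nt2 = 3,
                    total_steps = 0)
  st <- preassembled_bilayer(cfg, seed = 4)
  rg <- rg_components_series(st)
  expect_identical(nrow(rg), 2L)
  expect_true(all(rg$rgzz > rg$rgxx))
  expect_true(all(rg$rgzz > rg$rgyy))
  expect_identical(rg_components_series(st), rg)   # deterministic
  # unwrapping survives chains split by the periodic boundary
  st2 <- st
  st2$pos[, 3] <- (st2$pos[, 3] + 5) %% st2$box[3]
  rg2 <- rg_components_series(st2)
  expect_equal(rg2$rgzz, rg$rgzz, tolerance = 1e-10)
})

test_that("pressure profile reduces to the ideal gas and matches the virial", {
  st <- random_initial_configuration(water_config(7), seed = 31)
  ideal <- pressure_profile(st, n_slabs = 7, table = matrix(0, 5, 5))
  expect_equal(unname(attr(ideal, "global")),
               unname(colSums(st$vel^2) / prod(st$box)))
  expect_equal(mean(attr(ideal, "global")), 3, tolerance = 0.05)
  expect_true(all(abs(c(ideal$pxx, ideal$pyy, ideal$pzz) - 3) < 1.2))
  # interacting, bonded, with bent angles: slab mean == independent virial
  cfg <- run_config(box = 5, n1 = 4, n2 = 4, nt1 = 4, nt2 = 3,
                    total_steps = 0)
  stl <- random_initial_configuration(cfg, seed = 32)
  set.seed(33)
  stl$pos <- dpdlipid:::wrap_positions(
    stl$pos + matrix(rnorm(length(stl$pos), sd = 0.08), nrow(stl$pos), 3),
    stl$box)
  pr <- pressure_profile(stl, n_slabs = 11)
  glob <- attr(pr, "global")
  expect_equal(unname(c(mean(pr$pxx), mean(pr$pyy), mean(pr$pzz))),
               unname(glob), tolerance = 1e-10)
  brute <- brute_global_virial(stl, interaction_table())
  expect_equal(unname(glob), unname(brute), tolerance = 1e-6)
  # slab slicing is invariant under a periodic shift of all coordinates
  st_shift <- stl
  st_shift$pos[, 3] <- (st_shift$pos[, 3] + 1.7) %% st_shift$box[3]
  expect_equal(unname(attr(pressure_profile(st_shift, n_slabs = 11),
                           "global")),
               unname(glob), tolerance = 1e-9)
  expect_error(pressure_profile(stl, n_slabs = 1), "n_slabs")
})

test_that("tension is exactly zero for isotropic pressure and small in bulk", {
  iso <- structure(tibble::tibble(slab = 1:5, z = 1:5 - 0.5,
                                  pxx = 3, pyy = 3, pzz = 3),
                   class = c("pressure_profile", "tbl_df", "tbl", "data.frame"),
                   slab_height = 1, global = c(3, 3, 3))
  tn <- tension_profile(iso)
  expect_identical(unique(tn$sigma), 0)
  expect_identical(attr(tn, "total"), 0)
  # equilibrated bulk water: every slab isotropic within noise
  st <- random_initial_configuration(water_config(7), seed = 41)
  run <- run_dpd(st, 600, seed = 42, traj_every = 100)
  pw <- pressure_profile(run, n_slabs = 7)
  tw <- tension_profile(pw)
  expect_lt(max(abs(tw$sigma)), 1.0)
  expect_lt(abs(mean(tw$sigma)), 0.3)
})
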