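test_that("a swap exchanges the extreme x-momenta and conserves everything", {
  # four free beads: two in the bottom slab (z ~ 0), two in the mid slab
  box <- c(10, 10, 10)
  pos <- rbind(c(1, 1, 0.2), c(2, 2, 0.3),      # slab 0
               c(1, 1, 5.2), c(2, 2, 5.3))      # slab 10 of 20
  vel <- cbind(c(-2, 1, 3, 0), 0, 0)
  st <- dpdlipid:::new_dpd_state(pos, vel, rep(1L, 4), rep(0L, 4), box)
  p0 <- colSums(st$vel)
  ke0 <- sum(st$vel^2) / 2
  run <- run_dpd(st, 1, table = matrix(0, 5, 5),
                 params = dpd_params(gamma = 0, dt = 1e-9),
                 swap_interval = 1, n_slabs = 20)
  expect_identical(run$shear$n_swaps, 1L)
  expect_equal(run$shear$acc_px, 5)                   # 3 - (-2)
  expect_equal(sort(run$state$vel[1:2, 1]), c(1, 3))  # -2 became 3
  expect_equal(sort(run$state$vel[3:4, 1]), c(-2, 0))
  expect_equal(colSums(run$state$vel), p0, tolerance = 1e-14)
  expect_equal(sum(run$state$vel^2) / 2, ke0, tolerance = 1e-14)
  # all-zero momenta: the swap is a no-op
  st$vel[] <- 0
  run0 <- run_dpd(st, 1, table = matrix(0, 5, 5),
                  params = dpd_params(gamma = 0, dt = 1e-9),
                  swap_interval = 1, n_slabs = 20)
  expect_equal(run0$shear$acc_px, 0)
})

test_that("momentum flux follows px / (2 t Lx Ly)", {
  expect_equal(momentum_flux(9, 1, 3, 3), 0.5)
  expect_identical(momentum_flux(0, 2, 3, 3), 0)
  expect_equal(momentum_flux(9, 2, 3, 3), 0.25)   # doubling t halves it
  expect_error(momentum_flux(1, 0, 3, 3), "undefined flux")
})

test_that("the profile fit recovers an imposed linear field and flat noise", {
  box <- c(6, 6, 10)
  set.seed(12)
  n <- 4000
  mk <- function(vxfun) {
    pos <- matrix(runif(3 * n), n, 3) %*% diag(box)
    list(step = 0L, pos = pos,
         vel = cbind(vxfun(pos[, 3]), rnorm(n, sd = 0.01),
                     rnorm(n, sd = 0.01)))
  }
  vp <- velocity_profile(list(mk(function(z) 0.1 * z)), box = box,
                         n_bins = 40, n_slabs = 20)
  expect_equal(vp$shear_rate, 0.1, tolerance = 0.01)
  expect_true(all(abs(tidy(vp)$slope - 0.1) < 0.005))
  expect_true(is.na(glance(vp)$flux))
  # equilibrium noise: slope indistinguishable from zero
  vp0 <- velocity_profile(list(mk(function(z) rnorm(n, sd = 0.3))),
                          box = box, n_bins = 40, n_slabs = 20)
  td <- tidy(vp0)
  expect_true(all(abs(td$slope) < 3 * td$std.error))
  expect_error(velocity_profile(list(), box = box), "insufficient")
})

test_that("shorter swap intervals drive larger fluxes and shear rates", {
  st <- random_initial_configuration(water_config(8), seed = 14)
  fits <- lapply(c(12, 6, 3, 1), function(W) {
    run <- run_dpd(st, 2500, seed = 6, swap_interval = W, n_slabs = 20,
                   profile_every = 5, profile_bins = 40)
    velocity_profile(run)
  })
  flux <- vapply(fits, function(f) f$flux, numeric(1))
  rate <- vapply(fits, function(f) f$shear_rate, numeric(1))
  eta <- vapply(fits, function(f) f$viscosity, numeric(1))
  expect_true(all(diff(flux) > 0))
  expect_true(all(diff(rate) > 0))
  # Newtonian consistency: the two strongest drives agree on the viscosity
  expect_equal(eta[4], eta[3], tolerance = 0.2)
  # window shorter than one swap interval
  expect_error(velocity_profile(
    run_dpd(st, 3, seed = 6, swap_interval = 10, profile_every = 1)),
    "swap interval")
})
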