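test_that("random configurations hit the exact bead budget", {
  cfg <- run_config(box = 10, n1 = 25, n2 = 25, seed = 5, total_steps = 0)
  st <- random_initial_configuration(cfg)
  expect_identical(nrow(st$pos), 3000L)            # rho * L^3
  expect_identical(sum(st$mol > 0), 25L * 13L + 25L * 23L)
  expect_identical(sum(st$species == 1), 3000L - 900L)
  expect_true(all(st$pos >= 0 & st$pos < rep(st$box, each = 3000)))
  expect_error(
    random_initial_configuration(
      run_config(box = 3, n1 = 50, n2 = 50, total_steps = 0)),
    "infeasible density")
})

test_that("construction is seed-deterministic with zero net momentum", {
  cfg <- run_config(box = 6, n1 = 5, n2 = 5, nt1 = 4, nt2 = 4,
                    total_steps = 0)
  a <- random_initial_configuration(cfg, seed = 7)
  b <- random_initial_configuration(cfg, seed = 7)
  expect_identical(a, b)
  c2 <- random_initial_configuration(cfg, seed = 8)
  expect_false(identical(a$pos, c2$pos))
  cfgb <- run_config(box = c(6, 6, 12), n1 = 5, n2 = 5, nt1 = 4, nt2 = 4,
                     total_steps = 0)
  for (st in list(a, preassembled_bilayer(cfgb, seed = 7))) {
    expect_lt(max(abs(colSums(st$vel))), 1e-10)
  }
})

test_that("as-built molecules sit at their equilibrium internal geometry", {
  cfg <- run_config(box = 12, n1 = 6, n2 = 6, nt1 = 5, nt2 = 4,
                    total_steps = 0)
  st <- random_initial_configuration(cfg, seed = 11)
  box <- st$box
  b <- st$topology$bonds
  for (k in seq_len(nrow(b))) {
    d <- st$pos[b$i[k], ] - st$pos[b$j[k], ]
    d <- d - box * round(d / box)
    expect_equal(sqrt(sum(d^2)), b$rs[k], tolerance = 1e-8)
  }
  a <- st$topology$angles
  for (k in seq_len(nrow(a))) {
    u <- st$pos[a$i[k], ] - st$pos[a$j[k], ]
    v <- st$pos[a$k[k], ] - st$pos[a$j[k], ]
    u <- u - box * round(u / box); v <- v - box * round(v / box)
    th <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
    expect_equal(th, a$theta0[k], tolerance = 1e-6)
  }
})

test_that("preassembled bilayer has tails at the mid-plane and upright heads", {
  cfg <- run_config(box = 10, n1 = 40, n2 = 40, nt1 = 3, nt2 = 2,
                    total_steps = 0)
  st <- preassembled_bilayer(cfg, seed = 3)
  z0 <- st$box[3] / 2
  mid <- abs(st$pos[, 3] - z0) < 1
  tail_codes <- match(c("T1", "T2"), dpd_species())
  expect_gt(mean(st$species[mid] %in% tail_codes), 0.9)
  op <- order_parameter(st)
  expect_equal(attr(op, "overall"), 1, tolerance = 1e-10)
  # type-2 heads above, type-1 heads below the mid-plane
  expect_true(all(st$pos[st$species == 4, 3] > z0))
  expect_true(all(st$pos[st$species == 2, 3] < z0))
  expect_error(
    preassembled_bilayer(run_config(box = 5, n1 = 4, n2 = 4,
                                    total_steps = 0)),
    "too thin")
})
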