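test_that("fluctuation-dissipation fixes sigma from gamma and kBT", {
  expect_identical(dpd_params(gamma = 4.5, kBT = 1)$sigma, 3)
  expect_equal(dpd_params(gamma = 2, kBT = 0.5)$sigma, sqrt(2))
  expect_error(dpd_params(sigma = 2.9), "fluctuation-dissipation")
  expect_error(dpd_params(dt = 0), "dt")
  expect_error(dpd_params(lambda = 0), "lambda")
})

test_that("lipid topologies obey chain/tree combinatorics for all tail lengths", {
  for (nt in 1:10) {
    t1 <- build_lipid_type1(3, nt)
    n <- 3 + nt
    expect_length(t1$species, n)
    expect_equal(nrow(t1$bonds), n - 1)
    expect_equal(nrow(t1$angles), n - 2)
    # bond graph connected and acyclic: n-1 edges touching all beads
    expect_setequal(unique(c(t1$bonds$i, t1$bonds$j)), seq_len(n))
    expect_true(all(t1$bonds$rs == 0.7))
    expect_true(all(t1$bonds$ks == 120))

    t2 <- build_lipid_type2(3, nt)
    n2 <- 3 + 2 * nt
    expect_length(t2$species, n2)
    expect_equal(nrow(t2$bonds), n2 - 1)
    # angle count by the stated rules: head triples + within-tail triples +
    # one junction of each kind per tail
    n_head_triples <- 1
    n_tail_triples <- 2 * max(0, nt - 2)
    n_j1 <- 2
    n_j2 <- if (nt >= 2) 2 else 0
    expect_equal(nrow(t2$angles),
                 n_head_triples + n_tail_triples + n_j1 + n_j2)
    expect_equal(sum(t2$angles$ktheta == 3), 2)
    expect_equal(sum(t2$angles$ktheta == 4.5), n_j2)
    expect_true(all(t2$angles$theta0[t2$angles$ktheta %in% c(3, 4.5)] ==
                      2 * pi / 3))
  }
  expect_identical(nrow(build_lipid_type2(3, 2)$angles), 5L)
  expect_error(build_lipid_type1(1, 5), "invalid architecture")
  expect_error(build_lipid_type2(3, 0), "invalid architecture")
})

test_that("junction bending of the single-tail lipid is optional", {
  with_j <- build_lipid_type1(3, 5)
  without <- build_lipid_type1(3, 5, junction_angles = FALSE)
  # triples fully inside the head (1) or tail (3) blocks remain
  expect_identical(nrow(without$angles), 4L)
  expect_lt(nrow(without$angles), nrow(with_j$angles))
})

test_that("interaction table is symmetric and encodes both conventions", {
  for (mode in c("amphiphilic", "literal")) {
    a <- interaction_table(mode)
    expect_identical(a, t(a))
    expect_true(all(a > 0))
    expect_identical(a["T1", "T1"], 25)
    expect_identical(a["T1", "W"], 100)
  }
  expect_identical(interaction_table("literal")["H1", "W"], 100)
  expect_identical(interaction_table("amphiphilic")["H1", "W"], 25)
  expect_identical(interaction_table("amphiphilic")["H1", "H2"], 25)
  expect_identical(interaction_table("amphiphilic")["T1", "T2"], 25)
})

test_that("physical time maps steps to nanoseconds", {
  expect_equal(physical_time(1), 0.0188)
  expect_identical(physical_time(0), 0)
  expect_equal(physical_time(100), 1.88)
  expect_error(physical_time(-1), ">= 0")
  u <- unit_system(rho = 3, Vp_nm3 = 0.03)
  expect_equal(u$rc_nm, (3 * 0.03)^(1 / 3))
})

test_that("run config round-trips through TOML and rejects unknown keys", {
  cfg <- run_config(box = c(10, 10, 12), n1 = 20, n2 = 10, nt1 = 4, nt2 = 3,
                    total_steps = 500, swap_interval = 6, seed = 42)
  path <- withr::local_tempfile(fileext = ".toml")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_equal(back[setdiff(names(back), "params")],
               cfg[setdiff(names(cfg), "params")])
  expect_equal(unclass(back$params), unclass(cfg$params))
  # "off" spelling for no shear
  writeLines(c('swap_interval = "off"', "n1 = 2", "n2 = 2"), path)
  expect_identical(read_run_config(path)$swap_interval, Inf)
  writeLines("bogus_key = 3", path)
  expect_error(read_run_config(path), "bogus_key")
  expect_error(read_run_config("/nonexistent/x.toml"), "x.toml")
  expect_error(run_config(box = 1.5), "exceed 2")
})
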