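test_that("Lorentz-Berthelot combination reproduces like-pair and cross-pair values", {
  o_tip <- nb_params(-0.834, 0.1521, 1.7682)
  o_m07 <- nb_params(-1.0, 0.12, 1.70)
  like <- lorentz_berthelot(o_tip, o_tip)
  expect_equal(like$epsilon, 0.1521)
  expect_equal(like$rmin, 3.5364)
  cross <- lorentz_berthelot(o_tip, o_m07)
  expect_equal(cross$epsilon, sqrt(0.1521 * 0.12), tolerance = 1e-12)
  expect_equal(cross$rmin, 3.4682)
  # commutative, exactly
  ba <- lorentz_berthelot(o_m07, o_tip)
  expect_identical(cross$epsilon, ba$epsilon)
  expect_identical(cross$rmin, ba$rmin)
  # a dummy site carries no LJ pair
  dum <- nb_params(0, 0, 0, has_lj = FALSE)
  expect_error(lorentz_berthelot(o_tip, dum), class = "ohmd_no_lj_pair")
})

test_that("12-6 kernel has its minimum at rmin, zero at sigma, and matches a scalar oracle", {
  pair <- lorentz_berthelot(nb_params(0, 0.1521, 1.7682),
                            nb_params(0, 0.1521, 1.7682))
  expect_equal(lj_pair_energy(pair, pair$rmin), -pair$epsilon)
  expect_equal(lj_pair_energy(pair, pair$rmin / 2^(1 / 6)), 0,
               tolerance = 1e-12)
  set.seed(7)
  for (k in 1:1000) {
    eps <- runif(1, 0.01, 0.3); rmh <- runif(1, 0.2, 2.5)
    r <- runif(1, 0.5, 12)
    p <- lorentz_berthelot(nb_params(0, eps, rmh), nb_params(0, eps, rmh))
    oracle <- eps * ((2 * rmh / r)^12 - 2 * (2 * rmh / r)^6)
    expect_equal(lj_pair_energy(p, r), oracle, tolerance = 1e-12)
  }
  expect_error(lj_pair_energy(pair, 0), class = "ohmd_invalid_geometry")
})

test_that("Coulomb kernel uses the declared constant and is symmetric", {
  expect_equal(coulomb_pair_energy(1, 1, 1), 332.0636)
  expect_equal(coulomb_pair_energy(0, 1, 2.5), 0)
  expect_equal(coulomb_pair_energy(-0.7, 0.3, 1.9),
               coulomb_pair_energy(0.3, -0.7, 1.9))
  expect_error(coulomb_pair_energy(1, 1, -1), class = "ohmd_invalid_geometry")
})

test_that("catalogued models carry the published parameters and net charges", {
  net <- c(TIP3P = 0, OH_full = -1.0, M07 = -0.7, M09 = -0.9,
           OH_2p_opt = -1.0, OH_3AP = -0.9, OH_5AP = -0.9)
  for (nm in names(net)) {
    tpl <- build_model(nm)
    expect_equal(tpl$net_charge, unname(net[nm]), tolerance = 1e-9,
                 label = nm)
    expect_equal(sum(tpl$sites$q), unname(net[nm]), tolerance = 1e-9)
  }
  tip <- build_model("TIP3P")
  expect_equal(tip$sites$q, c(-0.834, 0.417, 0.417))
  expect_equal(tip$sites$eps[1], 0.1521)
  expect_equal(tip$sites$rmin_half[1], 1.7682)

  m07 <- build_model("M07")
  expect_equal(nrow(m07$sites), 2L)
  expect_equal(m07$sites$q, c(-1.0, 0.3))
  expect_equal(m07$sites$eps, c(0.12, 0.046))

  ap <- build_model("OH_3AP")
  expect_equal(nrow(ap$sites), 5L)
  expect_equal(ap$sites$q[1], 0.4)
  expect_equal(ap$sites$q[3:5], rep(-0.458, 3))
  expect_equal(ap$sites$mass[3:5], rep(1, 3))   # APs weigh 1 amu
  # O-AP bond length 0.70 A in the internal geometry
  d_oap <- sqrt(rowSums(ap$local[3:5, , drop = FALSE]^2))
  expect_equal(d_oap, rep(0.70, 3), tolerance = 1e-12)

  expect_error(build_model("nonesuch"), class = "ohmd_unknown_model")
})

test_that("protonated titratable variant is TIP3P-identical with silent APs", {
  ap <- build_model("OH_3AP", titratable = TRUE)
  tip <- build_model("TIP3P")
  prot <- ap$protonated
  expect_equal(prot$q[1:3], tip$sites$q)
  expect_equal(prot$eps[1:3], tip$sites$eps)
  expect_equal(prot$rmin_half[1:3], tip$sites$rmin_half)
  expect_equal(prot$q[4:6], rep(0, 3))
  expect_false(any(prot$has_lj[4:6]))
  # deprotonated state: the dummy hydrogen is inert
  expect_equal(ap$sites$q[3], 0)
  expect_false(ap$sites$has_lj[3])
  # titratable geometry is TIP3P's, so the water state is exactly TIP3P
  expect_equal(sqrt(sum((ap$local[2, ] - ap$local[1, ])^2)), 0.9572,
               tolerance = 1e-10)
})

test_that("geometry overrides propagate to the built template", {
  ap <- build_model("OH_3AP", geometry = list(r_oap = 0.8))
  d_oap <- sqrt(rowSums(ap$local[3:5, , drop = FALSE]^2))
  expect_equal(d_oap, rep(0.8, 3), tolerance = 1e-12)
  oh <- build_model("M07", geometry = list(r_oh = 1.0))
  expect_equal(sqrt(sum((oh$local[2, ] - oh$local[1, ])^2)), 1.0,
               tolerance = 1e-12)
})

test_that("model PDB writer emits a parseable single-molecule file", {
  f <- tempfile(fileext = ".pdb")
  write_model_pdb(build_model("OH_3AP"), f)
  lines <- readLines(f)
  expect_true(sum(grepl("^ATOM", lines)) == 5)
  unlink(f)
})
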