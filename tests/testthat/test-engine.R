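test_that("production nonbonded energy equals the naive double-loop oracle", {
  sys <- random_water_system(8, box = 14, seed = 11)
  for (scheme in c("force_shift", "plain")) {
    cfg <- engine_config(cutoff = 7, scheme = scheme)
    got <- nonbonded_energy(sys, cfg)
    ora <- naive_nonbonded(sys, 7, scheme)
    expect_equal(got$coulomb, ora$coulomb, tolerance = 1e-10)
    expect_equal(got$lj, ora$lj, tolerance = 1e-10)
    expect_equal(got$total, ora$total, tolerance = 1e-10)
  }
})

test_that("pairs beyond the cutoff contribute nothing", {
  tpl <- build_model("TIP3P")
  sys <- assemble_system(list(
    list(template = tpl, origin = c(10, 10, 5), axis = c(0, 0, 1)),
    list(template = tpl, origin = c(10, 10, 25), axis = c(0, 0, 1))),
    box = 60, periodic = TRUE)
  e <- nonbonded_energy(sys, engine_config(cutoff = 12))
  expect_equal(e$total, 0)
})

test_that("two unit point charges at 1 A give the bare Coulomb energy", {
  sys <- point_system(rbind(c(5, 5, 5), c(5, 5, 6)), qs = c(1, 1))
  e <- nonbonded_energy(sys, engine_config(cutoff = 20, scheme = "plain"))
  expect_equal(e$coulomb, 332.0636, tolerance = 1e-10)
})

test_that("overlapping interacting sites raise a singular-geometry error", {
  sys <- point_system(rbind(c(5, 5, 5), c(5, 5, 5 + 1e-9)), qs = c(1, 1))
  expect_error(nonbonded_energy(sys, engine_config(cutoff = 20)),
               "singular geometry")
})

test_that("forces are the analytic gradient of the energy", {
  sys <- random_water_system(5, box = 13, seed = 3)
  cfg <- engine_config(cutoff = 6)
  f <- compute_forces(sys, cfg)
  h <- 1e-5
  idx <- cbind(c(1, 4, 8, 13), c(1, 2, 3, 1))
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; ax <- idx[k, 2]
    sp <- sys; sp$pos[i, ax] <- sp$pos[i, ax] + h
    sm <- sys; sm$pos[i, ax] <- sm$pos[i, ax] - h
    num <- -(nonbonded_energy(sp, cfg)$total -
             nonbonded_energy(sm, cfg)$total) / (2 * h)
    expect_equal(f[i, ax], num, tolerance = 1e-6)
  }
  # Newton's third law: no net force without a field
  expect_lt(max(abs(colSums(f))), 1e-10)
})

test_that("a free particle moves in a straight line", {
  sys <- point_system(rbind(c(10, 10, 10)), qs = 0)
  sys$vel[1, ] <- c(1, -2, 0.5)
  cfg <- engine_config(timestep_fs = 2, cutoff = 5)
  out <- run_md(sys, cfg, 100, thermostat = FALSE)
  expect_equal(out$state$pos[1, ], c(10, 10, 10) + 0.2 * c(1, -2, 0.5),
               tolerance = 1e-12)
})

test_that("NVE dimer conserves energy and momentum", {
  set.seed(5)
  tpl <- build_model("TIP3P")
  sys <- assemble_system(list(
    list(template = tpl, origin = c(15, 15, 14), axis = c(0, 0, 1)),
    list(template = tpl, origin = c(15, 15, 17), axis = c(1, 0, 0.2))),
    box = 30, periodic = TRUE)
  sys <- maxwell_boltzmann(sys, 298, zero_momentum = TRUE)
  cfg <- engine_config(timestep_fs = 2, cutoff = 12)
  out <- run_md(sys, cfg, 5000, thermostat = FALSE)   # 10 ps
  etot <- out$epot + out$ekin
  drift <- abs(unname(coef(lm(etot ~ seq_along(etot)))[2])) * length(etot)
  expect_lt(drift / mean(out$ekin), 0.005)
  p <- colSums(out$state$vel * sys$mass)
  expect_lt(max(abs(p)), 1e-8 * 5000)
})

test_that("rigid constraints are restored after perturbation and hold in dynamics", {
  tpl <- build_model("TIP3P")
  sys <- assemble_system(list(list(template = tpl, origin = c(10, 10, 10),
                                   axis = c(0, 0, 1))),
                         box = 20, periodic = FALSE)
  sys$pos[2, 3] <- sys$pos[2, 3] + 0.05
  sys <- apply_rigid_constraints(sys)
  expect_equal(sqrt(sum((sys$pos[2, ] - sys$pos[1, ])^2)), 0.9572,
               tolerance = 1e-8)
  # already satisfied: identity
  before <- sys$pos
  sys2 <- apply_rigid_constraints(sys)
  expect_equal(sys2$pos, before, tolerance = 1e-10)
  # constraint violation along a 100-step run stays tiny
  set.seed(8)
  sys <- maxwell_boltzmann(sys, 298)
  out <- run_md(sys, engine_config(cutoff = 5), 100, thermostat = FALSE)
  d <- sqrt(sum((out$state$pos[2, ] - out$state$pos[1, ])^2))
  expect_equal(d, 0.9572, tolerance = 1e-6)
})

test_that("velocity-rescale thermostat scales exactly and respects its tolerance", {
  set.seed(9)
  sys <- random_water_system(5, box = 14, seed = 9)
  sys <- maxwell_boltzmann(sys, 320)
  expect_equal(instantaneous_temperature(sys), 320, tolerance = 1e-6)
  sys2 <- velocity_rescale_thermostat(sys, 298, tolerance = 5)
  expect_equal(instantaneous_temperature(sys2), 298, tolerance = 1e-6)
  # inside the tolerance band nothing happens
  sys3 <- maxwell_boltzmann(sys, 300)
  sys4 <- velocity_rescale_thermostat(sys3, 298, tolerance = 5)
  expect_identical(sys3$vel, sys4$vel)
  # zero kinetic energy reinitializes from Maxwell-Boltzmann
  sys$vel[] <- 0
  sys5 <- velocity_rescale_thermostat(sys, 298, tolerance = 5)
  expect_gt(kinetic_energy(sys5), 0)
})

test_that("long NVT run holds the target temperature", {
  set.seed(10)
  sys <- build_water_box(64, temperature = 298)
  cfg <- engine_config(cutoff = 6)
  sys <- minimize_steepest_descent(sys, 80, config = cfg)$state
  out <- run_md(sys, cfg, 5000)   # 10 ps
  expect_lt(abs(mean(tail(out$temperature, 2500)) - 298), 3)
})

test_that("steepest descent is monotone and stalls at a minimum", {
  tpl <- build_model("TIP3P")
  sys <- assemble_system(list(
    list(template = tpl, origin = c(10, 10, 10), axis = c(0, 0, 1)),
    list(template = tpl, origin = c(10, 10, 12.0), axis = c(0, 0, -1))),
    box = 20, periodic = FALSE)
  cfg <- engine_config(cutoff = 9)
  e0 <- nonbonded_energy(sys, cfg)$total
  r <- minimize_steepest_descent(sys, 150, config = cfg)
  expect_lt(r$energy, e0)
  expect_true(all(diff(r$trace) <= 1e-12))
  # restarting from the minimum changes little
  r2 <- minimize_steepest_descent(r$state, 10, step_size = 1e-4, config = cfg)
  expect_lt(r$energy - r2$energy, 1e-4)
})

test_that("uniform field exerts the converted force and drives drift by sign", {
  expect_equal(external_field_force(1, 1 / 31), 23.0609 / 31, tolerance = 1e-12)
  expect_equal(external_field_force(0, 5), 0)
  # a negative charge drifts against the field
  neg <- point_system(rbind(c(10, 10, 10)), qs = -1)
  cfg <- engine_config(cutoff = 5, field_z = 0.1)
  out <- run_md(neg, cfg, 200, thermostat = FALSE)
  expect_lt(out$state$pos[1, 3], 10)
  pos <- point_system(rbind(c(10, 10, 10)), qs = 1)
  out2 <- run_md(pos, cfg, 200, thermostat = FALSE)
  expect_gt(out2$state$pos[1, 3], 10)
})

test_that("the Ewald sum reproduces the rock-salt Madelung constant", {
  a <- 2.0
  ns <- 6
  grid <- as.matrix(expand.grid(0:(ns - 1), 0:(ns - 1), 0:(ns - 1)))
  sys <- point_system(grid * a, qs = (-1)^rowSums(grid), box = ns * a,
                      periodic = TRUE)
  e <- nonbonded_energy(sys, engine_config(cutoff = 5.9, scheme = "ewald"))
  madelung <- -e$coulomb * a / (332.0636 * nrow(grid) / 2)
  expect_equal(madelung, 1.74756, tolerance = 2e-3)
})

test_that("Ewald forces agree with finite differences of the Ewald energy", {
  sys <- random_water_system(5, box = 16, seed = 13)
  cfg <- engine_config(cutoff = 7, scheme = "ewald")
  f <- compute_forces(sys, cfg)
  h <- 1e-5
  for (i in c(1, 8)) for (ax in 1:3) {
    sp <- sys; sp$pos[i, ax] <- sp$pos[i, ax] + h
    sm <- sys; sm$pos[i, ax] <- sm$pos[i, ax] - h
    num <- -(nonbonded_energy(sp, cfg)$total -
             nonbonded_energy(sm, cfg)$total) / (2 * h)
    expect_equal(f[i, ax], num, tolerance = 1e-5)
  }
})

test_that("periodic boxes smaller than twice the cutoff are refused", {
  sys <- random_water_system(3, box = 10, seed = 2)
  expect_error(nonbonded_energy(sys, engine_config(cutoff = 9)),
               class = "ohmd_invalid_config")
})
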