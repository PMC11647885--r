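make_donor_acceptor <- function(d_oo = 2.8, angle_deg = 180, model = "M07") {
  ## water O at origin donating H1 along +z; hydroxide O on a ray at the
  ## requested D-H...A angle from the donor H
  tpl <- build_model(model, titratable = TRUE)
  w <- tpl$local
  hpos <- w[2, ]                      # (0, 0, 0.9572)
  th <- (180 - angle_deg) * pi / 180  # deviation from linear
  target <- hpos + (d_oo - 0.9572) * c(sin(th), 0, cos(th))
  ## actual O..O distance for non-linear geometries differs; rescale later
  assemble_system(
    list(list(template = tpl, origin = c(0, 0, 0), state = "water"),
         list(template = tpl, origin = target, axis = c(0, 1, 0),
              state = "oh")),
    box = 40, periodic = FALSE)
}

test_that("hydrogen-bond detection applies both distance and angle criteria", {
  hc <- hop_config()
  sys <- make_donor_acceptor(2.8, 180)
  p <- find_hbond_pairs(sys, hc)
  expect_equal(nrow(p), 1L)
  expect_equal(p$donor, 1L)
  expect_equal(p$acceptor, 2L)
  expect_equal(p$angle, 180, tolerance = 1e-6)
  # too far
  far <- make_donor_acceptor(4.0, 180)
  expect_equal(nrow(find_hbond_pairs(far, hc)), 0L)
  # bent below the angular cutoff
  bent <- make_donor_acceptor(2.8, 90)
  expect_equal(nrow(find_hbond_pairs(bent, hc)), 0L)
})

test_that("mirror-symmetric partners give exactly zero hop energy", {
  sys <- mirror_pair_system("M07", gap = 2.8)
  cfg <- engine_config(cutoff = 12)
  didx <- seq(sys$mols$first[1], length.out = 3)
  de <- delta_e_hop(sys, donor = 1, acceptor = 2, h_site = didx[2], cfg)
  expect_equal(de$dE, 0, tolerance = 1e-8)
})

test_that("incremental hop energy equals the difference of two full naive evaluations", {
  set.seed(31)
  sys <- build_water_box(24, hydroxide = "M07", titratable = 5)
  cfg <- engine_config(cutoff = 4.4)
  sys <- minimize_steepest_descent(sys, 60, config = cfg)$state
  sys <- run_md(sys, cfg, 200)$state
  pairs <- find_hbond_pairs(sys, hop_config(), titratable_only = TRUE)
  expect_gt(nrow(pairs), 0)
  for (k in seq_len(min(3, nrow(pairs)))) {
    p <- pairs[k, ]
    de <- delta_e_hop(sys, p$donor, p$acceptor, p$h_site, cfg)
    e_before <- naive_nonbonded(sys, cfg$cutoff)$total
    after <- sys
    after$mols$state[p$donor] <- "oh"
    after$mols$state[p$acceptor] <- "water"
    after <- ohmd:::refresh_mol_params(after, p$acceptor)
    ## transferred H on the acceptor bond sphere along the donated direction
    aidx <- seq(after$mols$first[p$acceptor], length.out = 3)
    oa <- sys$pos[aidx[1], ]
    dv <- sys$pos[p$h_site, ] - oa
    dv <- dv - sys$box * round(dv / sys$box)
    after$pos[aidx[3], ] <- oa + 0.9572 * dv / sqrt(sum(dv^2))
    ## donor: donated H becomes the dummy in place
    didx <- seq(after$mols$first[p$donor], length.out = 3)
    tpl <- ohmd:::mol_template(after, p$donor)
    prm <- ohmd:::deprot_params(tpl, match(p$h_site, didx))
    after$q[didx] <- prm$q; after$eps[didx] <- prm$eps
    after$rmin_half[didx] <- prm$rmin_half; after$has_lj[didx] <- prm$has_lj
    e_after <- naive_nonbonded(after, cfg$cutoff)$total
    expect_equal(de$dE, e_after - e_before, tolerance = 1e-10)
  }
})

test_that("incremental Ewald hop energy equals the full lattice-sum difference", {
  set.seed(55)
  sys <- build_water_box(64, hydroxide = "M07", titratable = 5)
  cfg <- engine_config(cutoff = 6, scheme = "ewald")
  sys <- minimize_steepest_descent(sys, 100, config = cfg)$state
  sys <- run_md(sys, cfg, 300)$state
  pairs <- find_hbond_pairs(sys, hop_config(), titratable_only = TRUE)
  expect_gt(nrow(pairs), 0)
  for (k in seq_len(min(2, nrow(pairs)))) {
    p <- pairs[k, ]
    de <- delta_e_hop(sys, p$donor, p$acceptor, p$h_site, cfg)
    st <- sys
    didx <- seq(st$mols$first[p$donor], length.out = 3)
    tpl <- ohmd:::mol_template(st, p$donor)
    prm <- ohmd:::deprot_params(tpl, match(p$h_site, didx))
    st$q[didx] <- prm$q; st$eps[didx] <- prm$eps
    st$rmin_half[didx] <- prm$rmin_half; st$has_lj[didx] <- prm$has_lj
    aidx <- seq(st$mols$first[p$acceptor], length.out = 3)
    prm <- ohmd:::mol_template(st, p$acceptor)$protonated
    st$q[aidx] <- prm$q; st$eps[aidx] <- prm$eps
    st$rmin_half[aidx] <- prm$rmin_half; st$has_lj[aidx] <- prm$has_lj
    oa <- sys$pos[aidx[1], ]
    dv <- sys$pos[p$h_site, ] - oa
    dv <- dv - sys$box * round(dv / sys$box)
    st$pos[aidx[3], ] <- oa + 0.9572 * dv / sqrt(sum(dv^2))
    full <- nonbonded_energy(st, cfg)$total - nonbonded_energy(sys, cfg)$total
    expect_equal(de$dE, full, tolerance = 1e-9)
  }
})

test_that("threshold-Metropolis rule accepts deterministically at and below C", {
  expect_true(accept_hop(35, 35, 298))
  expect_true(accept_hop(25, 35, 298))
  expect_true(accept_hop(-1e6, 0, 298))
})

test_that("acceptance frequency at dE = C + kT ln 2 converges to one half", {
  set.seed(32)
  kT <- 0.0019872 * 298
  dE <- 10 + kT * log(2)
  acc <- replicate(1e5, accept_hop(dE, 10, 298))
  expect_equal(mean(acc), 0.5, tolerance = 0.01)
})

test_that("executing a hop conserves charge and site count and moves the hydroxide id", {
  set.seed(33)
  sys <- build_water_box(24, hydroxide = "OH_3AP", titratable = 5)
  cfg <- engine_config(cutoff = 4.4)
  sys <- minimize_steepest_descent(sys, 60, config = cfg)$state
  sys <- run_md(sys, cfg, 200)$state
  pairs <- find_hbond_pairs(sys, hop_config(), titratable_only = TRUE)
  expect_gt(nrow(pairs), 0)
  p <- pairs[1, ]
  q0 <- total_charge(sys)
  n0 <- nrow(sys$pos)
  new <- execute_hop(sys, p$donor, p$acceptor, p$h_site)
  expect_false(attr(new, "aborted"))
  expect_equal(total_charge(new), q0, tolerance = 1e-12)
  expect_equal(nrow(new$pos), n0)
  expect_equal(new$hydroxide, p$donor)
  expect_equal(new$mols$state[p$acceptor], "water")
  ## constraints remain exactly satisfied
  cs <- new$constraints
  d <- sqrt(rowSums((new$pos[cs$i, ] - new$pos[cs$j, ])^2))
  expect_lt(max(abs(d - cs$d)), 1e-8)
  ## the reverse hop restores the identities
  didx <- seq(new$mols$first[p$donor], length.out = new$mols$nsites[p$donor])
  back_h <- didx[2]  # the hydroxide's real H donates back
  rev <- execute_hop(new, donor = p$acceptor, acceptor = p$donor,
                     h_site = seq(new$mols$first[p$acceptor],
                                  length.out = 3)[3])
  expect_equal(rev$hydroxide, p$acceptor)
  expect_equal(rev$mols$state[p$donor], "water")
  expect_equal(total_charge(rev), q0, tolerance = 1e-12)
})

test_that("post-hop minimization is an identity at zero steps and removes energy otherwise", {
  set.seed(34)
  sys <- build_water_box(24, hydroxide = "OH_3AP", titratable = 5)
  cfg <- engine_config(cutoff = 4.4)
  sys <- minimize_steepest_descent(sys, 40, config = cfg)$state
  r0 <- posthop_minimize(sys, 0, cfg)
  expect_identical(r0$state$pos, sys$pos)
  expect_equal(r0$energy_removed, 0)
  sys <- run_md(sys, cfg, 100)$state
  r4 <- posthop_minimize(sys, 4, cfg)
  expect_gte(r4$energy_removed, 0)
})

test_that("with hopping suppressed the driver reproduces plain dynamics exactly", {
  set.seed(35)
  sys <- build_water_box(24, hydroxide = "M07", titratable = 5)
  cfg <- engine_config(cutoff = 4.4)
  sys <- minimize_steepest_descent(sys, 40, config = cfg)$state
  hc <- hop_config(C = -1e6, interval = 10)
  set.seed(99)
  hop <- run_hopping_md(sys, hc, cfg, 200)
  plain <- run_md(sys, cfg, 200)
  expect_identical(hop$state$pos, plain$state$pos)
  expect_identical(hop$state$vel, plain$state$vel)
  expect_equal(sum(hop$events$accepted), 0L)
})

test_that("accepted-hop count is non-decreasing in the threshold C", {
  set.seed(36)
  sys <- build_water_box(48, hydroxide = "M07", titratable = 5)
  cfg <- engine_config(cutoff = 5.5)
  sys <- minimize_steepest_descent(sys, 80, config = cfg)$state
  sys <- run_md(sys, cfg, 500)$state
  counts <- vapply(c(-1e6, 25, 60), function(C) {
    set.seed(100)
    r <- run_hopping_md(sys, hop_config(C = C, interval = 10), cfg, 1500)
    sum(r$events$accepted)
  }, 0)
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[3], 0)
})

test_that("the titratable pool follows the hydroxide", {
  set.seed(37)
  sys <- build_water_box(48, hydroxide = "OH_3AP", titratable = 5)
  cfg <- engine_config(cutoff = 5.5)
  sys <- minimize_steepest_descent(sys, 80, config = cfg)$state
  r <- run_hopping_md(sys, hop_config(C = 45, interval = 10, min_steps = 2),
                      cfg, 1000)
  st <- r$state
  expect_equal(sum(st$mols$state == "oh"), 1L)
  expect_equal(sum(st$mols$titratable), 5L)
  ## after an explicit refresh the titratable set is exactly the
  ## hydroxide's four nearest waters
  st <- update_titratable_pool(st, 5)
  oh_o <- st$mols$first[st$hydroxide]
  waters <- which(st$mols$state == "water" & !st$mols$fixed)
  d <- vapply(waters, function(m) {
    dd <- st$pos[st$mols$first[m], ] - st$pos[oh_o, ]
    dd <- dd - st$box * round(dd / st$box)
    sqrt(sum(dd^2))
  }, 0)
  nearest4 <- waters[order(d)][1:4]
  expect_setequal(which(st$mols$titratable & st$mols$state == "water"),
                  nearest4)
  ## charge conserved through every accepted hop
  expect_equal(total_charge(st), -0.9, tolerance = 1e-9)
})
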