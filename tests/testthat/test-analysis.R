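test_that("RDF of an ideal gas is flat at one", {
  tr <- ideal_gas_traj()
  rdf <- compute_rdf(tr, seq_len(200), seq_len(200), bin_width = 0.25)
  sel <- rdf$r > 2 & rdf$r < 9
  expect_lt(max(abs(rdf$g[sel] - 1)), 0.15)
  expect_lt(abs(mean(rdf$g[sel]) - 1), 0.02)
  expect_true(all(rdf$g >= 0))
})

test_that("a two-particle frame fills exactly one RDF bin", {
  co <- array(c(1, 1, 1, 1, 1, 3.42), dim = c(2, 3, 1))
  co <- aperm(array(rbind(c(1, 1, 1), c(1, 1, 3.42)), c(2, 3, 1)), c(1, 2, 3))
  tr <- new_trajectory(co, time = 0.1, box = 12, element = c("X", "X"),
                       molid = 1:2)
  rdf <- compute_rdf(tr, 1, 2, bin_width = 0.1)
  hit <- which(rdf$counts > 0)
  expect_length(hit, 1L)
  expect_true(rdf$r[hit] > 2.32 && rdf$r[hit] < 2.52)
})

test_that("RDF matches a naive per-frame double-loop oracle bin-exactly", {
  tr <- ideal_gas_traj(n = 30, nf = 5, L = 12, seed = 42)
  bw <- 0.2; rmax <- 6
  rdf <- compute_rdf(tr, 1:10, 11:30, bin_width = bw, r_max = rmax)
  counts <- numeric(length(rdf$counts))
  for (f in 1:5) {
    for (i in 1:10) for (j in 11:30) {
      d <- tr$coords[i, , f] - tr$coords[j, , f]
      d <- d - 12 * round(d / 12)
      r <- sqrt(sum(d^2))
      if (r < rmax) {
        b <- floor(r / bw) + 1
        counts[b] <- counts[b] + 1
      }
    }
  }
  expect_identical(rdf$counts, counts)
})

test_that("first peak is located on constructed profiles and monotone input errors", {
  r <- seq(0.025, 8, by = 0.05)
  g <- 1 + 3 * exp(-(r - 2.45)^2 / (2 * 0.12^2))
  g[r < 1.8] <- 0
  rdf <- structure(list(r = r, g = g, density = 0.0334, counts = g,
                        bin_width = 0.05), class = "oh_rdf")
  pk <- first_peak(rdf)
  expect_equal(pk$r_peak, 2.45, tolerance = 0.05)
  mono <- structure(list(r = r, g = seq(0, 3, length.out = length(r)),
                         density = 0.0334, counts = g, bin_width = 0.05),
                    class = "oh_rdf")
  expect_error(first_peak(mono), class = "ohmd_analysis")
})

test_that("coordination number of uniform g equals the sphere integral", {
  bw <- 3e-5
  r <- seq(bw / 2, 3.0, by = bw)
  rdf <- structure(list(r = r, g = rep(1, length(r)), density = 0.0334,
                        counts = r, bin_width = bw), class = "oh_rdf")
  cn <- coordination_number(rdf, limit = 3.0)
  expect_equal(cn, 4 / 3 * pi * 0.0334 * 27, tolerance = 1e-10)
  rdf$density <- 0
  expect_equal(coordination_number(rdf, limit = 3.0), 0)
})

test_that("unwrapping produces continuous paths and round trips through wrap", {
  nf <- 60
  x <- seq(0.2, by = 0.4, length.out = nf)   # crosses a 10 A box twice
  co <- array(0, dim = c(1, 3, nf))
  co[1, 1, ] <- x %% 10
  tr <- new_trajectory(co, time = seq_len(nf) * 0.1, box = 10,
                       element = "X")
  un <- unwrap(tr)
  expect_true(all(diff(un$coords[1, 1, ]) > 0))
  expect_equal(un$coords[1, 1, ], x, tolerance = 1e-10)
  rewrapped <- wrap(un)
  expect_equal(rewrapped$coords[1, 1, ], co[1, 1, ], tolerance = 1e-10)
  # stationary particle: identity
  co2 <- array(rep(c(5, 5, 5), nf), dim = c(1, 3, nf))
  tr2 <- new_trajectory(aperm(array(rep(c(5, 5, 5), each = nf),
                                    c(nf, 3, 1)), c(3, 2, 1)),
                        time = seq_len(nf) * 0.1, box = 10, element = "X")
  expect_equal(unwrap(tr2)$coords, tr2$coords)
})

test_that("Einstein estimator recovers known diffusion in 1D and 3D", {
  set.seed(43)
  dt <- 0.01; n <- 1e5; D <- 0.5
  x <- apply(matrix(rnorm(3 * n, sd = sqrt(2 * D * dt)), n, 3), 2, cumsum)
  ## short-lag fit: Brownian MSD estimates at long lags are dominated by
  ## trajectory-level noise, the early lags carry the statistics
  fit <- einstein_diffusion(x, time = seq_len(n) * dt, d = 3,
                            max_lag_frac = 0.01, fit_window = c(0.002, 0.05))
  expect_equal(fit$D, D, tolerance = 0.05)
  z <- cumsum(rnorm(n, sd = sqrt(2 * 1.0 * dt)))
  f1 <- einstein_diffusion(z, time = seq_len(n) * dt, d = 1,
                           max_lag_frac = 0.01, fit_window = c(0.002, 0.05))
  expect_equal(f1$D, 1.0, tolerance = 0.05)
  f3 <- einstein_diffusion(matrix(z, ncol = 1), time = seq_len(n) * dt, d = 3,
                           max_lag_frac = 0.01, fit_window = c(0.002, 0.05))
  expect_equal(f3$D, f1$D / 3, tolerance = 1e-12)
  # stationary
  s <- einstein_diffusion(rep(0, 1000), time = seq_len(1000) * dt, d = 1)
  expect_equal(s$D, 0)
  expect_error(einstein_diffusion(z[1:10], time = (1:10) * dt,
                                  max_lag_frac = 2), class = "ohmd_domain")
})

test_that("the diffusion estimator is unbiased over seeds", {
  dt <- 0.01; n <- 2e4
  for (d in c(1, 3)) {
    est <- vapply(1:20, function(s) {
      set.seed(s)
      x <- apply(matrix(rnorm(d * n, sd = sqrt(2 * 0.8 * dt)), n, d),
                 2, cumsum)
      einstein_diffusion(x, time = seq_len(n) * dt, d = d,
                         max_lag_frac = 0.01, fit_window = c(0.002, 0.05))$D
    }, 0)
    expect_equal(mean(est), 0.8, tolerance = 0.02)
  }
})

test_that("electrophoretic mobility is slope over field, with known recovery", {
  t <- seq(0, 100, by = 0.1)
  expect_equal(electrophoretic_mobility(0.1 * t, t, 1 / 31), 3.1,
               tolerance = 1e-9)
  expect_equal(electrophoretic_mobility(rep(2, length(t)), t, 0.05), 0,
               tolerance = 1e-9)
  expect_error(electrophoretic_mobility(t, t, 0), class = "ohmd_domain")
  set.seed(44)
  mu <- 12; E <- 1 / 31; dt <- 0.1
  z <- cumsum(rnorm(5000, mean = mu * E * dt, sd = 0.3))
  expect_equal(electrophoretic_mobility(z, seq_len(5000) * dt, E), mu,
               tolerance = 0.1 * mu)
})

test_that("hydroxide identification assigns hydrogens to nearest oxygens", {
  ## three waters + one hydroxide on a line, well separated
  pos <- rbind(c(2, 2, 2), c(2.9, 2, 2), c(2, 2.9, 2),      # water 1
               c(6, 6, 6), c(6.9, 6, 6), c(6, 6.9, 6),      # water 2
               c(2, 6, 6), c(2.9, 6, 6), c(2, 6.9, 6),      # water 3
               c(6, 2, 2), c(6.9, 2, 2))                    # hydroxide
  el <- c("O", "H", "H", "O", "H", "H", "O", "H", "H", "O", "H")
  r <- identify_hydroxide(pos, el, box = c(12, 12, 12))
  expect_equal(r$o_index, 10L)
  expect_false(r$flagged)
  ## exact tie: deterministic low-index assignment, frame flagged
  tie <- rbind(c(2, 2, 2), c(4, 2, 2),                      # two oxygens
               c(3, 2, 2), c(1.1, 2, 2), c(4.9, 2, 2))      # middle H is tied
  elt <- c("O", "O", "H", "H", "H")
  rt <- identify_hydroxide(tie, elt, box = c(20, 20, 20))
  expect_true(rt$flagged)
  expect_equal(rt$assignments[1], 1L)   # tie breaks to the lower O index
  expect_equal(rt$o_index, 2L)
  ## an oxygen with three hydrogens is ambiguous
  h3 <- rbind(c(2, 2, 2), c(9, 9, 9),
              c(2.9, 2, 2), c(2, 2.9, 2), c(2, 2, 2.9))
  elh <- c("O", "O", "H", "H", "H")
  expect_error(identify_hydroxide(h3, elh, box = c(20, 20, 20)),
               class = "ohmd_ambiguous_frame")
})

test_that("hop classification separates rattles from true hops", {
  r <- classify_hops(c("A", "A", "B", "B", "A", "A", "C"))
  expect_equal(r$n_transfers, 3)
  expect_equal(r$n_rattle_pairs, 1)
  expect_equal(r$n_true_hops, 1)
  expect_equal(unlist(classify_hops(rep("A", 10))[1:3], use.names = FALSE),
               c(0, 0, 0))
  r2 <- classify_hops(c("A", "B", "C", "D"))
  expect_equal(r2$n_transfers, 3)
  expect_equal(r2$n_true_hops, 3)
  ## accounting identity on random series, both modes
  set.seed(45)
  for (k in 1:30) {
    s <- sample(LETTERS[1:4], 50, replace = TRUE)
    rp <- classify_hops(s, mode = "pair")
    expect_equal(rp$n_true_hops + 2 * rp$n_rattle_pairs, rp$n_transfers)
    rr <- classify_hops(s, mode = "reversal")
    expect_equal(rr$n_true_hops + rr$n_rattle_pairs, rr$n_transfers)
  }
})

test_that("solvation-state counting matches constructed first shells", {
  tplw <- build_model("TIP3P")
  tploh <- build_model("M07")
  ## tetrahedral 3 donors + 1 water accepting the hydroxide's H
  oh_o <- c(10, 10, 10)
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  mols <- list(list(template = tploh, origin = oh_o, axis = c(-1, -1, 1),
                    state = "oh"))
  for (k in 1:3) {
    o <- oh_o + 2.7 * dirs[k, ]
    mols[[k + 1]] <- list(template = tplw, origin = o,
                          axis = oh_o - o, state = "water")
  }
  ## acceptor water along the hydroxide's O-H axis
  hax <- c(-1, -1, 1) / sqrt(3)
  oa <- oh_o + hax * 2.7
  mols[[5]] <- list(template = tplw, origin = oa, axis = c(0, 1, 0),
                    state = "water")
  sys <- assemble_system(mols, box = 40, periodic = FALSE)
  st <- solvation_state(sys)
  expect_equal(st$n_accepted, 3)
  expect_equal(st$n_donated, 1)
  ## isolated hydroxide
  iso <- assemble_system(list(list(template = tploh, origin = c(5, 5, 5),
                                   state = "oh")), box = 40,
                         periodic = FALSE)
  expect_equal(unlist(solvation_state(iso), use.names = FALSE), c(0, 0))
  ## square-planar 4 donors, no acceptor
  mols4 <- list(list(template = tploh, origin = oh_o, axis = c(0, 0, 1),
                     state = "oh"))
  for (k in 1:4) {
    ang <- (k - 1) * pi / 2
    o <- oh_o + 2.7 * c(cos(ang), sin(ang), 0)
    mols4[[k + 1]] <- list(template = tplw, origin = o, axis = oh_o - o,
                           state = "water")
  }
  sys4 <- assemble_system(mols4, box = 40, periodic = FALSE)
  st4 <- solvation_state(sys4)
  expect_equal(st4$n_accepted, 4)
  expect_equal(st4$n_donated, 0)
})
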