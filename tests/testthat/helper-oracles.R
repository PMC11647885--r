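# Independent scalar oracles and small fixture builders used across tests.

KCOUL_T <- 332.0636
KB_T <- 0.0019872

# Naive O(N^2) nonbonded oracle, written independently of the production
# kernel: explicit loops, minimum image, force-shifted or plain Coulomb,
# 12-6 LJ under Lorentz-Berthelot rules. Returns the decomposition.
naive_nonbonded <- function(sys, cutoff, scheme = "force_shift",
                            field_z = 0, walls = NULL) {
  n <- nrow(sys$pos)
  ec <- el <- ef <- er <- 0
  for (i in seq_len(n)) {
    zi <- sys$pos[i, 3]
    if (field_z != 0) ef <- ef - sys$q[i] * field_z * 23.0609 * zi
    if (!is.null(walls) && sys$restrained[i] && !sys$fixed[i]) {
      if (zi > walls$zhi) er <- er + 0.5 * walls$k * (zi - walls$zhi)^2
      if (zi < walls$zlo) er <- er + 0.5 * walls$k * (walls$zlo - zi)^2
    }
    if (i == n) next
    for (j in (i + 1):n) {
      if (sys$molid[i] == sys$molid[j]) next
      if (sys$fixed[i] && sys$fixed[j]) next
      d <- sys$pos[i, ] - sys$pos[j, ]
      for (ax in 1:3) if (sys$periodic[ax])
        d[ax] <- d[ax] - sys$box[ax] * round(d[ax] / sys$box[ax])
      r <- sqrt(sum(d^2))
      if (r > cutoff) next
      qq <- sys$q[i] * sys$q[j]
      if (qq != 0) {
        if (scheme == "force_shift")
          ec <- ec + KCOUL_T * qq * (1 / r - 1 / cutoff + (r - cutoff) / cutoff^2)
        else ec <- ec + KCOUL_T * qq / r
      }
      if (sys$has_lj[i] && sys$has_lj[j]) {
        ep <- sqrt(sys$eps[i] * sys$eps[j])
        R <- sys$rmin_half[i] + sys$rmin_half[j]
        el <- el + ep * ((R / r)^12 - 2 * (R / r)^6)
      }
    }
  }
  list(coulomb = ec, lj = el, field = ef, restraint = er,
       total = ec + el + ef + er)
}

# A bare point-charge template (single site molecule).
point_template <- function(q = 0, eps = 0, rmin_half = 0, mass = 10) {
  sites <- data.frame(name = "X", role = "O", element = "X", mass = mass,
                      q = q, eps = eps, rmin_half = rmin_half,
                      has_lj = eps > 0, stringsAsFactors = FALSE)
  structure(list(name = "POINT", kind = "point", sites = sites,
                 local = matrix(0, 1, 3), net_charge = q, titratable = FALSE,
                 protonated = NULL,
                 constraints = data.frame(i = integer(), j = integer(),
                                          d = numeric())),
            class = "oh_template")
}

point_system <- function(positions, qs, box = 100, periodic = FALSE,
                         eps = 0, rmin_half = 0) {
  mols <- lapply(seq_len(nrow(positions)), function(i)
    list(template = point_template(qs[i], eps, rmin_half),
         origin = positions[i, ], axis = c(0, 0, 1), state = "water"))
  assemble_system(mols, box = box, periodic = periodic)
}

# Random small water configuration (nw waters in a cubic box).
random_water_system <- function(nw = 5, box = 20, seed = 42) {
  set.seed(seed)
  tpl <- build_model("TIP3P")
  centers <- matrix(runif(3 * nw, 3, box - 3), nw, 3)
  # keep O-O above 2.4 A by rejection
  for (pass in 1:200) {
    d <- as.matrix(dist(centers)); diag(d) <- Inf
    bad <- which(d < 2.6, arr.ind = TRUE)
    if (!nrow(bad)) break
    centers[bad[1, 1], ] <- runif(3, 3, box - 3)
  }
  mols <- lapply(seq_len(nw), function(i)
    list(template = tpl, origin = centers[i, ], axis = rnorm(3),
         ref = rnorm(3), state = "water"))
  assemble_system(mols, box = box, periodic = TRUE)
}

# Mirror-symmetric titratable pair: a water donating its H1 straight at a
# hydroxide across the z = 0 plane. Coordinates are exact mirror images.
mirror_pair_system <- function(model = "M07", gap = 2.8) {
  tpl <- build_model(model, titratable = TRUE)
  wl <- tpl$local                       # O origin, H1 +z, H2 in xz plane
  donor <- sweep(wl, 2, c(0, 0, -gap / 2 - 0), "+")
  donor[, 3] <- donor[, 3]              # H1 points +z toward acceptor
  mirror <- donor
  mirror[, 3] <- -mirror[, 3]           # reflect through z = 0
  # acceptor: row2 (real H) must be the mirror of donor H2, row3 the mirror
  # of donor H1 (the dummy slot faces the incoming proton)
  acc <- mirror[c(1, 3, 2), , drop = FALSE]
  if (nrow(wl) > 3) acc <- rbind(acc, mirror[4:nrow(wl), , drop = FALSE])
  assemble_system(
    list(list(template = tpl, origin = c(0, 0, 0), state = "water"),
         list(template = tpl, origin = c(0, 0, 0), state = "oh")),
    box = 50, periodic = FALSE,
    coords = list(donor, acc))
}

# Uniform random (ideal-gas) trajectory: every site its own molecule.
ideal_gas_traj <- function(n = 200, nf = 40, L = 20, seed = 41) {
  set.seed(seed)
  co <- array(runif(n * 3 * nf, 0, L), dim = c(n, 3, nf))
  new_trajectory(co, time = seq_len(nf) * 0.1, box = L,
                 element = rep("X", n), molid = seq_len(n))
}
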