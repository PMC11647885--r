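#' Build a bulk water box
#'
#' Places water molecules on a jittered cubic lattice with random rigid-body
#' orientations, optionally replacing one molecule (the one nearest the box
#' center) by a hydroxide and promoting its nearest neighbours to titratable
#' waters, then assigns Maxwell-Boltzmann velocities. Deterministic for a
#' fixed RNG seed.
#'
#' @param n Number of molecules (waters, including the one replaced by the
#'   hydroxide if requested).
#' @param edge Box edge, Å. Default sets the density to `density` g/mL.
#' @param density Target density used when `edge` is `NULL` (g/mL).
#' @param hydroxide `NULL`, or a hydroxide model name (e.g. `"M07"`,
#'   `"OH_3AP"`) replacing one water.
#' @param titratable Number of titratable (proton-hopping capable) molecules
#'   including the hydroxide itself; 0 builds the plain/standalone form.
#' @param temperature Temperature for initial velocities, K.
#' @param min_oo Minimum O-O distance enforced by the build, Å.
#' @param catalog Parameter catalogue.
#' @return An `oh_system`.
#' @export
build_water_box <- function(n, edge = NULL, density = 0.997,
                            hydroxide = NULL, titratable = 0,
                            temperature = 298, min_oo = 2.2,
                            catalog = model_catalog()) {
  mass_w <- 18.0154
  if (is.null(edge)) {
    ## density in g/mL: n * m / (NA * V)
    edge <- (n * mass_w / (0.60221408 * density))^(1 / 3)
  }
  rho <- n * mass_w / (0.60221408 * edge^3)
  if (rho < 0.5 || rho > 1.5)
    ohmd_error(sprintf("infeasible density %.3f g/mL", rho), "ohmd_build")
  k <- ceiling(n^(1 / 3))
  sp <- edge / k
  grid <- as.matrix(expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k)))
  grid <- (grid - 0.5) * sp
  grid <- grid[seq_len(n), , drop = FALSE]
  jit <- matrix(stats::runif(3 * n, -0.08, 0.08) * sp, n, 3)
  centers <- grid + jit

  water <- build_model("TIP3P", catalog)
  titr_n <- max(0L, as.integer(titratable))
  oh_m <- NULL
  idx_oh <- integer()
  idx_titr <- integer()
  if (!is.null(hydroxide)) {
    oh_m <- build_model(hydroxide, catalog, titratable = titr_n > 0)
    d2c <- rowSums(sweep(centers, 2, rep(edge / 2, 3))^2)
    idx_oh <- which.min(d2c)
    if (titr_n > 1) {
      d2oh <- rowSums(sweep(centers, 2, centers[idx_oh, ])^2)
      idx_titr <- setdiff(order(d2oh), idx_oh)[seq_len(titr_n - 1)]
    }
  }
  titr_tpl <- if (length(idx_titr)) build_model(hydroxide, catalog,
                                               titratable = TRUE)
  mols <- lapply(seq_len(n), function(i) {
    if (i %in% idx_oh)
      list(template = oh_m, origin = centers[i, ], axis = random_axis(),
           ref = random_axis(), state = "oh")
    else if (i %in% idx_titr)
      list(template = titr_tpl, origin = centers[i, ], axis = random_axis(),
           ref = random_axis(), state = "water")
    else
      list(template = water, origin = centers[i, ], axis = random_axis(),
           ref = random_axis(), state = "water")
  })
  sys <- assemble_system(mols, box = edge, periodic = TRUE)
  ## min O-O check (minimum image)
  o <- sys$pos[sys$role == "O", , drop = FALSE]
  dmin <- min_pair_distance(o, sys$box, sys$periodic)
  if (dmin < min_oo)
    ohmd_error(sprintf("build produced O-O contact at %.2f Å", dmin),
               "ohmd_build")
  maxwell_boltzmann(sys, temperature)
}

min_pair_distance <- function(x, box, periodic) {
  n <- nrow(x)
  dmin <- Inf
  for (ax in 1:3) {
    d <- outer(x[, ax], x[, ax], "-")
    if (periodic[ax]) d <- d - box[ax] * round(d / box[ax])
    if (ax == 1) acc <- d^2 else acc <- acc + d^2
  }
  diag(acc) <- Inf
  sqrt(min(acc))
}

#' Build a (n,n) armchair carbon nanotube
#'
#' Standard rolled-graphene construction with a C-C bond length of 1.42 Å;
#' the tube axis is z and the carbons are flagged fixed. Radius
#' `R = |Ch|/2pi` with `|Ch| = a sqrt(3) n`, `a = 1.42 sqrt(3)` (about
#' 4.07 Å for (6,6)).
#'
#' @param n,m Chiral indices; only armchair (`n == m`) is supported.
#' @param length Tube length, Å (rounded to whole unit cells).
#' @param a_cc C-C bond length, Å.
#' @param eps,rmin_half Carbon LJ parameters (kcal/mol, Å); carbons carry no
#'   charge.
#' @return List with `coords` (k x 3 matrix centred on z = 0), `radius`, and
#'   `length` actually built.
#' @export
build_cnt <- function(n = 6, m = 6, length = 100, a_cc = 1.42,
                      eps = 0.07, rmin_half = 1.9924) {
  if (n != m) ohmd_error("only armchair (n = m) tubes are supported",
                         "ohmd_unsupported")
  a <- a_cc * sqrt(3)
  ch_len <- a * sqrt(3 * n^2)      # |Ch| = a sqrt(n^2 + nm + m^2), n = m
  radius <- ch_len / (2 * pi)
  ncell <- max(1L, round(length / a))
  ## orthogonal graphene cell: width sqrt(3) a (along Ch), height a (axis)
  pts <- list()
  for (j in seq_len(ncell) - 1L) {
    y <- j * a
    for (i in seq_len(n) - 1L) {
      x0 <- i * sqrt(3) * a
      pts[[length(pts) + 1L]] <- rbind(
        c(x0, y), c(x0 + a_cc, y),
        c(x0 + 1.5 * a_cc, y + a / 2), c(x0 + 2.5 * a_cc, y + a / 2))
    }
  }
  sheet <- do.call(rbind, pts)
  theta <- 2 * pi * sheet[, 1] / ch_len
  z <- sheet[, 2]
  coords <- cbind(radius * cos(theta), radius * sin(theta), z - mean(range(z)))
  list(coords = coords, radius = radius, length = diff(range(z)),
       eps = eps, rmin_half = rmin_half, n = n, m = m)
}

cnt_template <- function(cnt) {
  k <- nrow(cnt$coords)
  sites <- data.frame(name = sprintf("C%d", seq_len(k)), role = "C_nanotube",
                      element = "C", mass = 12.011, q = 0, eps = cnt$eps,
                      rmin_half = cnt$rmin_half, has_lj = TRUE,
                      stringsAsFactors = FALSE)
  structure(list(name = "CNT", kind = "cnt", sites = sites,
                 local = cnt$coords, net_charge = 0, titratable = FALSE,
                 protonated = NULL,
                 constraints = data.frame(i = integer(), j = integer(),
                                          d = numeric())),
            class = "oh_template")
}

#' Fill a nanotube with a single file of water
#'
#' Places waters along the tube axis, designates a block of titratable
#' molecules around the centre with the central one deprotonated (the
#' hydroxide), registers flat-bottom z-walls at the tube ends, and assigns
#' Maxwell-Boltzmann velocities. The initial dipole order along the axis is
#' a build convention; both choices relax within picoseconds under the
#' thermostat.
#'
#' @param cnt A tube from [build_cnt()].
#' @param n_titratable Number of titratable molecules (including the
#'   hydroxide).
#' @param n_plain Number of plain TIP3P waters.
#' @param model Hydroxide model for the titratable residues.
#' @param temperature K.
#' @param wall_k Wall force constant, kcal/(mol Å^2).
#' @param margin Distance from the tube termini to the first/last water, Å.
#' @param dipoles Initial dipole order along the axis.
#' @param catalog Parameter catalogue.
#' @return An `oh_system` with the walls stored in
#'   `attr(, "walls")`.
#' @export
fill_single_file <- function(cnt, n_titratable = 5, n_plain = 40,
                             model = "OH_3AP", temperature = 298,
                             wall_k = 10, margin = 2.0,
                             dipoles = c("alternating", "uniform"),
                             catalog = model_catalog()) {
  dipoles <- match.arg(dipoles)
  nw <- n_titratable + n_plain
  zlo <- -cnt$length / 2 + margin
  zhi <- cnt$length / 2 - margin
  spacing <- (zhi - zlo) / (nw - 1)
  if (spacing < 2.0)
    ohmd_error("overfill: single-file spacing below 2 Å", "ohmd_build")
  zs <- seq(zlo, zhi, length.out = nw)
  center <- which.min(abs(zs))
  half <- (n_titratable - 1) %/% 2
  idx_titr <- seq(center - half, center + half + (n_titratable - 1) %% 2)
  idx_titr <- idx_titr[idx_titr >= 1 & idx_titr <= nw][seq_len(n_titratable)]

  water <- build_model("TIP3P", catalog)
  titr <- build_model(model, catalog, titratable = TRUE)
  mols <- vector("list", nw + 1L)
  mols[[1]] <- list(template = cnt_template(cnt), origin = c(0, 0, 0),
                    axis = c(0, 0, 1), fixed = TRUE, state = "water")
  for (i in seq_len(nw)) {
    updown <- if (dipoles == "uniform" || i %% 2 == 0) 1 else -1
    ## dipole (bisector) along +/- z: point O->H1 45 degrees off axis
    ax <- normalize(c(0.7, 0, updown * 0.72))
    st <- if (i %in% idx_titr && i == center) "oh" else "water"
    tpl <- if (i %in% idx_titr) titr else water
    mols[[i + 1L]] <- list(template = tpl, origin = c(0, 0, zs[i]),
                           axis = ax, ref = c(0, 1, 0), state = st)
  }
  sys <- assemble_system(mols, box = c(4 * cnt$radius + 2 * 12,
                                       4 * cnt$radius + 2 * 12,
                                       cnt$length + 24),
                         periodic = FALSE)
  sys$restrained <- sys$role == "O" & !sys$fixed
  attr(sys, "walls") <- list(zlo = -cnt$length / 2, zhi = cnt$length / 2,
                             k = wall_k)
  maxwell_boltzmann(sys, temperature)
}
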