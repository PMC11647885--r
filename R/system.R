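## SystemState: flat per-site arrays plus a molecule table. Sites of a
## molecule are contiguous; positions are kept unwrapped (minimum image is
## applied only when evaluating interactions), so intramolecular geometry is
## always real-space.

normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) ohmd_error("zero-length direction", "ohmd_invalid_geometry")
  v / n
}

## Orthonormal frame mapping local +z to `axis`, local +x toward `ref`.
frame_matrix <- function(axis, ref = NULL) {
  e3 <- normalize(axis)
  if (is.null(ref)) ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- ref - sum(ref * e3) * e3
  if (sqrt(sum(w^2)) < 1e-8) {
    ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    w <- ref - sum(ref * e3) * e3
  }
  e1 <- normalize(w)
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  cbind(e1, e2, e3)
}

## Rigid-body placement of a template: oxygen at `origin`, local +z along
## `axis` (the O->H1 direction), azimuth set by `ref`.
seat_template <- function(template, origin, axis = c(0, 0, 1), ref = NULL) {
  M <- frame_matrix(axis, ref)
  sweep(template$local %*% t(M), 2, origin, "+")
}

random_axis <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Assemble a simulation system from placed molecule templates
#'
#' @param mols List of entries `list(template=, origin=, axis=, ref=,
#'   state=)`; `state` is `"water"` or `"oh"` (ignored for non-titratable
#'   templates), `axis` the O->H1 direction.
#' @param box Edge lengths, Å (length 3 or scalar for a cube).
#' @param periodic Logical length 3 (or scalar), per-axis periodicity.
#' @param coords Optional list of explicit per-molecule coordinate matrices
#'   (overrides seating).
#' @return An object of class `oh_system`.
#' @export
assemble_system <- function(mols, box, periodic = TRUE, coords = NULL) {
  box <- rep(as.numeric(box), length.out = 3)
  periodic <- rep(as.logical(periodic), length.out = 3)
  nm <- length(mols)
  poslist <- vector("list", nm)
  params <- vector("list", nm)
  molrows <- vector("list", nm)
  conslist <- vector("list", nm)
  offset <- 0L
  for (m in seq_len(nm)) {
    e <- mols[[m]]
    tpl <- e$template
    ns <- nrow(tpl$sites)
    p <- if (!is.null(coords) && !is.null(coords[[m]])) coords[[m]]
         else seat_template(tpl, e$origin,
                            if (is.null(e$axis)) c(0, 0, 1) else e$axis, e$ref)
    poslist[[m]] <- p
    st <- if (is.null(e$state)) if (tpl$kind == "water") "water" else "oh"
          else e$state
    prm <- tpl$sites
    if (tpl$titratable && st == "water") prm <- tpl$protonated
    params[[m]] <- prm
    fixed <- isTRUE(e$fixed)
    molrows[[m]] <- data.frame(
      id = m, model = tpl$name, state = st, titratable = tpl$titratable,
      fixed = fixed, first = offset + 1L, nsites = ns,
      stringsAsFactors = FALSE)
    cs <- tpl$constraints
    if (nrow(cs) && !fixed)
      conslist[[m]] <- data.frame(i = cs$i + offset, j = cs$j + offset, d = cs$d)
    offset <- offset + ns
  }
  prm <- do.call(rbind, params)
  moltab <- do.call(rbind, molrows)
  cons <- do.call(rbind, conslist)
  if (is.null(cons)) cons <- data.frame(i = integer(), j = integer(), d = numeric())
  n <- offset
  sys <- structure(list(
    pos = do.call(rbind, poslist),
    vel = matrix(0, n, 3),
    mass = prm$mass,
    q = prm$q, eps = prm$eps, rmin_half = prm$rmin_half,
    has_lj = prm$has_lj,
    element = prm$element, role = prm$role, site_name = prm$name,
    molid = rep(moltab$id, moltab$nsites),
    fixed = rep(moltab$fixed, moltab$nsites),
    restrained = rep(FALSE, n),
    box = box, periodic = periodic, time = 0,
    mols = moltab,
    templates = setNames(lapply(mols, `[[`, "template"),
                         vapply(mols, function(e) e$template$name, "")),
    constraints = cons,
    hydroxide = NA_integer_
  ), class = "oh_system")
  oh <- which(moltab$state == "oh")
  if (length(oh) > 1)
    ohmd_error("more than one hydroxide in the system", "ohmd_invalid_system")
  if (length(oh) == 1) sys$hydroxide <- oh
  sys
}

#' @export
print.oh_system <- function(x, ...) {
  cat(sprintf("<oh_system> %d sites, %d molecules, box %.2f x %.2f x %.2f Å, t = %.3f ps\n",
              nrow(x$pos), nrow(x$mols), x$box[1], x$box[2], x$box[3], x$time))
  if (!is.na(x$hydroxide))
    cat(sprintf("  hydroxide: molecule %d (%s)\n", x$hydroxide,
                x$mols$model[x$hydroxide]))
  invisible(x)
}

mol_sites <- function(state, m) {
  f <- state$mols$first[m]
  seq.int(f, f + state$mols$nsites[m] - 1L)
}

## Template used by molecule m (templates list is per molecule).
mol_template <- function(state, m) state$templates[[m]]

## Re-derive per-site parameters of molecule m from its template and state.
refresh_mol_params <- function(state, m) {
  tpl <- mol_template(state, m)
  prm <- if (tpl$titratable && state$mols$state[m] == "water") tpl$protonated
         else tpl$sites
  idx <- mol_sites(state, m)
  state$q[idx] <- prm$q
  state$eps[idx] <- prm$eps
  state$rmin_half[idx] <- prm$rmin_half
  state$has_lj[idx] <- prm$has_lj
  state$role[idx] <- prm$role
  state
}

#' Draw Maxwell-Boltzmann velocities
#'
#' Assigns velocities at temperature `T` to all mobile sites from the
#' Maxwell-Boltzmann distribution and projects them onto the rigid-body
#' constraint manifold. Uses the current RNG state.
#'
#' @param state An `oh_system`.
#' @param T Temperature (K).
#' @param zero_momentum Remove the net linear momentum first.
#' @return The system with new velocities.
#' @export
maxwell_boltzmann <- function(state, T = 298, zero_momentum = TRUE) {
  n <- nrow(state$pos)
  sdv <- sqrt(KBOLTZ * T * FCONV / state$mass)
  v <- matrix(stats::rnorm(3 * n), n, 3) * sdv
  v[state$fixed, ] <- 0
  if (zero_momentum && any(!state$fixed)) {
    mob <- !state$fixed
    p <- colSums(v[mob, , drop = FALSE] * state$mass[mob])
    v[mob, ] <- sweep(v[mob, , drop = FALSE], 2,
                      p / sum(state$mass[mob]), "-")
  }
  state$vel <- v
  state <- project_velocities(state)
  ## constraint projection removes kinetic energy; rescale to the target
  Ti <- instantaneous_temperature(state)
  if (Ti > 0 && T > 0) {
    mob <- !state$fixed
    state$vel[mob, ] <- state$vel[mob, ] * sqrt(T / Ti)
  }
  state
}

project_velocities <- function(state) {
  cs <- state$constraints
  if (!nrow(cs)) return(state)
  invm <- ifelse(state$fixed, 0, 1 / state$mass)
  state$vel <- cpp_rattle(state$pos, state$vel, cs$i, cs$j, cs$d, invm,
                          1e-10, 500L)
  state
}

#' Degrees of freedom of the mobile system
#'
#' `3 N_mobile - N_constraints - 3` when the whole system is mobile (net
#' momentum is conserved/removed), without the momentum correction when fixed
#' scaffold sites (e.g. nanotube carbons) are present.
#'
#' @param state An `oh_system`.
#' @return Number of degrees of freedom.
#' @export
n_dof <- function(state) {
  nmob <- sum(!state$fixed)
  nd <- 3 * nmob - nrow(state$constraints)
  if (!any(state$fixed)) nd <- nd - 3
  max(nd, 1)
}

#' Kinetic energy and instantaneous temperature
#'
#' @param state An `oh_system`.
#' @return `kinetic_energy`: kcal/mol; `instantaneous_temperature`: K.
#' @export
kinetic_energy <- function(state) {
  mob <- !state$fixed
  sum(0.5 * state$mass[mob] * rowSums(state$vel[mob, , drop = FALSE]^2)) / FCONV
}

#' @rdname kinetic_energy
#' @export
instantaneous_temperature <- function(state) {
  2 * kinetic_energy(state) / (n_dof(state) * KBOLTZ)
}

#' Total charge of the system
#' @param state An `oh_system`.
#' @return Net charge (e).
#' @export
total_charge <- function(state) sum(state$q)
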