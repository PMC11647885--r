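#' Hop configuration
#'
#' Parameters of the stochastic proton-hopping layer: the empirical threshold
#' `C` of the modified Metropolis rule (accept with probability
#' `min(1, exp(-(dE - C)/kT))`), the attempt interval in MD steps, the number
#' of post-hop minimization steps, and the geometric hydrogen-bond criterion
#' (donor-O to acceptor-O distance and D-H...A angle).
#'
#' @param C Threshold, kcal/mol.
#' @param interval MD steps between hop attempts.
#' @param min_steps Post-hop steepest-descent steps (0 for 2p models, 4 for
#'   the 3AP model).
#' @param temperature K.
#' @param r_da Maximum donor-O to acceptor-O distance, Å.
#' @param theta_min Minimum D-H...A angle, degrees.
#' @param pool_size Titratable molecules maintained per hydroxide.
#' @return An object of class `hop_config`.
#' @export
hop_config <- function(C = 0, interval = 10, min_steps = 0,
                       temperature = 298, r_da = 3.5, theta_min = 120,
                       pool_size = 5) {
  if (interval < 1) ohmd_error("interval must be >= 1", "ohmd_invalid_config")
  if (min_steps < 0) ohmd_error("min_steps must be >= 0", "ohmd_invalid_config")
  structure(list(C = C, interval = as.integer(interval),
                 min_steps = as.integer(min_steps),
                 temperature = temperature, r_da = r_da,
                 theta_min = theta_min, pool_size = as.integer(pool_size)),
            class = "hop_config")
}

mol_o_site <- function(state, m) state$mols$first[m]

## minimum-image displacement a - b
mi_disp <- function(a, b, box, periodic) {
  d <- a - b
  for (ax in which(periodic)) d[ax] <- d[ax] - box[ax] * round(d[ax] / box[ax])
  d
}

#' Find hydrogen-bonded donor candidates for a proton hop
#'
#' Returns water molecules donating a hydrogen bond to the current hydroxide
#' oxygen under the geometric criterion: donor-O to acceptor-O distance at
#' most `r_da` and D-H...A angle at least `theta_min`.
#'
#' @param state An `oh_system` with a hydroxide.
#' @param config A [hop_config()].
#' @param titratable_only Restrict donors to titratable molecules.
#' @return Data frame with columns `donor`, `h_site` (global site index of
#'   the donated hydrogen), `acceptor`, `r_oo`, `angle`.
#' @export
find_hbond_pairs <- function(state, config = hop_config(),
                             titratable_only = FALSE) {
  acc <- state$hydroxide
  empty <- data.frame(donor = integer(), h_site = integer(),
                      acceptor = integer(), r_oo = numeric(),
                      angle = numeric())
  if (is.na(acc)) return(empty)
  oa <- state$pos[mol_o_site(state, acc), ]
  cand <- which(state$mols$state == "water" & !state$mols$fixed &
                state$mols$model != "CNT")
  if (titratable_only) cand <- cand[state$mols$titratable[cand]]
  out <- list()
  for (m in cand) {
    osite <- mol_o_site(state, m)
    od <- state$pos[osite, ]
    doo <- mi_disp(oa, od, state$box, state$periodic)
    r <- sqrt(sum(doo^2))
    if (r > config$r_da) next
    idx <- mol_sites(state, m)
    hs <- idx[state$role[idx] == "H"]
    for (h in hs) {
      hp <- state$pos[h, ]
      v1 <- mi_disp(od, hp, state$box, state$periodic)
      v2 <- mi_disp(oa, hp, state$box, state$periodic)
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= config$theta_min)
        out[[length(out) + 1L]] <- data.frame(donor = m, h_site = h,
                                              acceptor = acc, r_oo = r,
                                              angle = ang)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

## Parameter rows for a titratable molecule in the hydroxide state with the
## donated hydrogen (template row `donated_local`, 2 or 3) as the dummy.
deprot_params <- function(tpl, donated_local) {
  prm <- tpl$sites          # template convention: H1 real, H2 (row 3) dummy
  if (donated_local == 2L) { # H1 donated: swap the roles of the hydrogens
    prm[c(2, 3), ] <- prm[c(3, 2), ]
  }
  prm
}

## Energy of all pairs touching `group_mols` (plus their one-body terms).
## Under Ewald this is the real-space (screened) part only; the lattice-sum
## pieces are differenced separately by delta_e_hop.
group_energy <- function(state, config, group_mols, pos = state$pos,
                         q = state$q, eps = state$eps, rmh = state$rmin_half,
                         haslj = state$has_lj) {
  a <- kernel_args(state, config)
  ingroup <- as.integer(state$molid %in% group_mols)
  cpp_nonbonded(pos, q, eps, rmh, as.integer(haslj), a$molid, a$isfixed,
                a$restrained, a$box, a$periodic, a$cutoff, a$scheme, a$efz,
                a$walls, list(), ingroup, a$ewald, FALSE)
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

## Intramolecular exclusion term of the Ewald sum for one molecule, as it
## enters the total energy (negative erf correction).
ewald_excl_term <- function(pos, q, idx, alpha) {
  e <- 0
  for (i in seq_along(idx)) {
    if (i == 1L) next
    for (j in seq_len(i - 1)) {
      qi <- q[idx[i]]; qj <- q[idx[j]]
      if (qi == 0 || qj == 0) next
      r <- sqrt(sum((pos[idx[i], ] - pos[idx[j], ])^2))
      e <- e - KCOUL * qi * qj * erf_(alpha * r) / r
    }
  }
  e
}

#' Energy change of a proton hop
#'
#' Evaluates `dE = E_after - E_before` where the "after" state swaps the
#' nonbonded identities of the hydrogen-bonded partners: the donor takes the
#' hydroxide parameter set with its donated hydrogen becoming the
#' non-interacting dummy, and the acceptor takes the protonated (TIP3P)
#' set with its dummy materialized as a real hydrogen at the transferred
#' position — on the O-H bond sphere along the direction of the donated
#' hydrogen (the hop proceeds along the hydrogen bond; the acceptor's bond
#' constraint is applied to the placement). All other coordinates are
#' untouched, so two mirror-symmetric partners give exactly `dE = 0`. Only
#' pairs involving the two partners contribute, so the evaluation is
#' incremental under truncated electrostatics.
#'
#' @param state An `oh_system`.
#' @param donor Donor molecule id (water, titratable).
#' @param acceptor Acceptor molecule id (the hydroxide).
#' @param h_site Global site index of the donated hydrogen.
#' @param config An [engine_config()].
#' @param sf Internal: cached Ewald structure factor for the current
#'   coordinates (recomputed when absent).
#' @return List: `dE` (kcal/mol), `decomposition` (`coulomb`, `lj`),
#'   `before`, `after`.
#' @export
delta_e_hop <- function(state, donor, acceptor, h_site,
                        config = engine_config(), sf = NULL) {
  if (!state$mols$titratable[donor] || state$mols$state[donor] != "water")
    ohmd_error("donor is not a titratable water", "ohmd_bookkeeping")
  if (donor == acceptor || state$mols$state[acceptor] != "oh")
    ohmd_error("acceptor is not the hydroxide", "ohmd_bookkeeping")
  grp <- c(donor, acceptor)
  e0 <- group_energy(state, config, grp)

  q <- state$q; eps <- state$eps; rmh <- state$rmin_half; haslj <- state$has_lj
  pos <- state$pos
  ## donor -> hydroxide identity, donated H as dummy
  dtpl <- mol_template(state, donor)
  didx <- mol_sites(state, donor)
  prm <- deprot_params(dtpl, match(h_site, didx))
  q[didx] <- prm$q; eps[didx] <- prm$eps
  rmh[didx] <- prm$rmin_half; haslj[didx] <- prm$has_lj
  ## acceptor -> protonated identity; the dummy materializes on the O-H
  ## bond sphere pointing at the donated hydrogen
  atpl <- mol_template(state, acceptor)
  aidx <- mol_sites(state, acceptor)
  prm <- atpl$protonated
  q[aidx] <- prm$q; eps[aidx] <- prm$eps
  rmh[aidx] <- prm$rmin_half; haslj[aidx] <- prm$has_lj
  oa <- state$pos[aidx[1L], ]
  dvec <- mi_disp(state$pos[h_site, ], oa, state$box, state$periodic)
  r_oh_a <- atpl$constraints$d[1]   # acceptor O-H bond length
  pos[aidx[3L], ] <- oa + r_oh_a * normalize(dvec)
  e1 <- group_energy(state, config, grp, pos = pos, q = q, eps = eps,
                     rmh = rmh, haslj = haslj)
  extra <- 0
  if (config$scheme == "ewald") {
    ## lattice-sum pieces: reciprocal-space delta from the cached structure
    ## factor, self-energy delta, and intramolecular exclusion deltas (the
    ## net charge is conserved, so the background term cancels)
    ew <- ewald_params(state, config)
    if (is.null(sf))
      sf <- cpp_ewald_sf(state$pos, state$q, state$box, ew[1], ew[2])
    changed <- c(didx, aidx)
    dek <- cpp_ewald_de_kspace(sf, state$pos, state$q, as.integer(changed),
                               pos[changed, , drop = FALSE], q[changed])
    dself <- -KCOUL * ew[1] / sqrt(pi) *
      (sum(q[changed]^2) - sum(state$q[changed]^2))
    dexcl <- ewald_excl_term(pos, q, didx, ew[1]) +
      ewald_excl_term(pos, q, aidx, ew[1]) -
      ewald_excl_term(state$pos, state$q, didx, ew[1]) -
      ewald_excl_term(state$pos, state$q, aidx, ew[1])
    extra <- dek + dself + dexcl
  }
  list(dE = e1$total - e0$total + extra,
       decomposition = c(coulomb = e1$coulomb - e0$coulomb + extra,
                         lj = e1$lj - e0$lj),
       before = e0$total, after = e1$total + extra)
}

#' Threshold-Metropolis acceptance rule
#'
#' Accept with probability `min(1, exp(-(dE - C)/kT))`; deterministic accept
#' when `dE <= C`. Draws from the current RNG state.
#'
#' @param dE Hop energy, kcal/mol.
#' @param C Threshold, kcal/mol.
#' @param temperature K (> 0).
#' @return Logical.
#' @export
accept_hop <- function(dE, C, temperature = 298) {
  if (temperature <= 0) ohmd_error("temperature must be > 0", "ohmd_invalid_config")
  x <- dE - C
  if (x <= 0) return(TRUE)
  stats::runif(1) < exp(-x / (KBOLTZ * temperature))
}

mol_com_velocity <- function(state, m) {
  idx <- mol_sites(state, m)
  colSums(state$vel[idx, , drop = FALSE] * state$mass[idx]) /
    sum(state$mass[idx])
}

## Re-seat a titratable molecule rigidly: O stays, template H1 along `axis`,
## azimuth toward `ref`; whole molecule gets velocity `v`.
reseat_mol <- function(state, m, axis, ref, v = NULL) {
  idx <- mol_sites(state, m)
  tpl <- mol_template(state, m)
  o <- state$pos[idx[1L], ]
  state$pos[idx, ] <- seat_template(tpl, o, axis, ref)
  if (!is.null(v)) state$vel[idx, ] <- matrix(v, length(idx), 3, byrow = TRUE)
  state
}

#' Execute an accepted proton hop
#'
#' Swaps the protonation identities exactly as [delta_e_hop()] evaluates
#' them: the acceptor becomes a water with the transferred hydrogen
#' materialized along the hydrogen bond (its rigid geometry re-seated about
#' that new O-H axis), and the donor becomes the hydroxide with its donated
#' hydrogen demoted to the dummy. The new hydroxide is re-canonicalized as
#' a rigid body — oxygen and the remaining real hydrogen stay exactly in
#' place while the dummy and any auxiliary particles move to their template
#' positions about the new O-H axis (azimuth toward the donated side).
#' Each re-seated molecule takes its centre-of-mass velocity.
#' Auxiliary-particle charges switch per the protonation variants; total
#' charge and site count are conserved. If the donated hydrogen overlaps
#' the acceptor oxygen the hop is aborted and the state returned unchanged
#' with `attr(, "aborted") = TRUE`.
#'
#' @inheritParams delta_e_hop
#' @return The updated `oh_system`.
#' @export
execute_hop <- function(state, donor, acceptor, h_site) {
  if (!state$mols$titratable[donor] || state$mols$state[donor] != "water")
    ohmd_error("donor is not a titratable water", "ohmd_bookkeeping")
  didx <- mol_sites(state, donor)
  aidx <- mol_sites(state, acceptor)
  hpos <- state$pos[h_site, ]
  oa <- state$pos[aidx[1L], ]
  dvec <- mi_disp(hpos, oa, state$box, state$periodic)
  if (sqrt(sum(dvec^2)) < 0.4) {
    attr(state, "aborted") <- TRUE
    return(state)
  }
  vd <- mol_com_velocity(state, donor)
  va <- mol_com_velocity(state, acceptor)
  ## donor: remaining real H defines the hydroxide axis; dummy and APs are
  ## re-seated at template positions with the dummy toward the donated side
  other_h <- setdiff(didx[state$role[didx] == "H"], h_site)[1]
  od <- state$pos[didx[1L], ]
  axis_d <- state$pos[other_h, ] - od
  ref_d <- state$pos[h_site, ] - od
  ## acceptor: the materialized hydrogen points at the donated hydrogen;
  ## the old real hydrogen sets the azimuth so it moves as little as the
  ## rigid geometry allows
  ref_a <- state$pos[aidx[2L], ] - oa
  state <- reseat_mol(state, donor, axis_d, ref_d, vd)
  state <- reseat_mol(state, acceptor, dvec, ref_a, va)
  state$mols$state[donor] <- "oh"
  state$mols$state[acceptor] <- "water"
  state <- refresh_mol_params(state, donor)
  state <- refresh_mol_params(state, acceptor)
  state$hydroxide <- donor
  attr(state, "aborted") <- FALSE
  state
}

#' Post-hop energy minimization
#'
#' Runs `n_steps` of constrained steepest descent on all mobile sites and
#' reports the energy removed (nonnegative). The default step size is set
#' so that the few prescribed steps remove a substantial part of the energy
#' an accepted hop adds (the minimization is meant to approximately cancel
#' it).
#'
#' @param state An `oh_system`.
#' @param n_steps Minimization steps (0 = identity).
#' @param config An [engine_config()].
#' @param step_size Initial maximum displacement, Å.
#' @return List: `state`, `energy_removed` (kcal/mol).
#' @export
posthop_minimize <- function(state, n_steps, config = engine_config(),
                             step_size = 0.1) {
  if (n_steps <= 0) return(list(state = state, energy_removed = 0))
  r <- minimize_steepest_descent(state, n_steps, step_size = step_size,
                                 config = config)
  list(state = r$state, energy_removed = max(0, r$trace[1] - r$energy))
}

#' Maintain the titratable pool around the hydroxide
#'
#' Keeps the `pool_size - 1` waters nearest the hydroxide oxygen titratable:
#' a plain water entering that shell trades places (rigid geometry and
#' centre-of-mass velocity) with the farthest titratable molecule, which
#' reverts to plain water. The exchange is exact for the nonbonded energy
#' since a protonated titratable molecule is TIP3P-identical.
#'
#' @param state An `oh_system`.
#' @param pool_size Pool size per hydroxide.
#' @return The updated system.
#' @export
update_titratable_pool <- function(state, pool_size = 5) {
  acc <- state$hydroxide
  if (is.na(acc)) return(state)
  oa <- state$pos[mol_o_site(state, acc), ]
  waters <- which(state$mols$state == "water" & !state$mols$fixed &
                  state$mols$model != "CNT")
  if (!length(waters)) return(state)
  d <- vapply(waters, function(m) {
    sqrt(sum(mi_disp(state$pos[mol_o_site(state, m), ], oa, state$box,
                     state$periodic)^2))
  }, 0)
  want <- waters[order(d)][seq_len(min(pool_size - 1, length(waters)))]
  have <- waters[state$mols$titratable[waters]]
  for (w in setdiff(want, have)) {
    free <- setdiff(have, want)
    if (!length(free)) break
    state <- promote_molecule(state, w, free[1])
    have <- c(setdiff(have, free[1]), w)
  }
  state
}

## Make molecule `donor` titratable, trading with titratable molecule `tit`
## (water state). Templates with matching site counts are relabelled in
## place (no coordinate changes — a protonated titratable residue is
## TIP3P-identical); auxiliary-particle templates trade rigid geometries.
## Returns the updated state.
promote_molecule <- function(state, donor, tit) {
  if (state$mols$nsites[donor] == state$mols$nsites[tit]) {
    for (f in c("model", "titratable")) {
      tmp <- state$mols[[f]][donor]
      state$mols[[f]][donor] <- state$mols[[f]][tit]
      state$mols[[f]][tit] <- tmp
    }
    tpl <- state$templates[[donor]]
    state$templates[[donor]] <- state$templates[[tit]]
    state$templates[[tit]] <- tpl
    state <- refresh_mol_params(state, donor)
    state <- refresh_mol_params(state, tit)
  } else {
    state <- swap_molecule_sites(state, donor, tit)
  }
  state
}

## Titratable (water-state) partner to trade away: the farthest from the
## hydroxide.
farthest_titratable <- function(state, config) {
  acc <- state$hydroxide
  tits <- which(state$mols$state == "water" & state$mols$titratable &
                !state$mols$fixed)
  if (!length(tits)) return(NA_integer_)
  oa <- state$pos[mol_o_site(state, acc), ]
  d <- vapply(tits, function(m)
    sqrt(sum(mi_disp(state$pos[mol_o_site(state, m), ], oa, state$box,
                     state$periodic)^2)), 0)
  tits[which.max(d)]
}

## Trade the geometry of two water-state molecules (one titratable, one
## plain): each template is re-seated on the other's O position and O-H
## directions; centre-of-mass velocities follow the positions.
swap_molecule_sites <- function(state, a, b) {
  ga <- geom_of(state, a)
  gb <- geom_of(state, b)
  va <- mol_com_velocity(state, a)
  vb <- mol_com_velocity(state, b)
  state <- put_mol(state, a, gb, vb)
  state <- put_mol(state, b, ga, va)
  state
}

geom_of <- function(state, m) {
  idx <- mol_sites(state, m)
  o <- state$pos[idx[1L], ]
  list(o = o, axis = state$pos[idx[2L], ] - o,
       ref = state$pos[idx[3L], ] - o)
}

put_mol <- function(state, m, g, v) {
  idx <- mol_sites(state, m)
  tpl <- mol_template(state, m)
  state$pos[idx, ] <- seat_template(tpl, g$o, g$axis, g$ref)
  state$vel[idx, ] <- matrix(v, length(idx), 3, byrow = TRUE)
  state
}

#' Combined molecular dynamics and proton hopping
#'
#' Interleaves MD with hop attempts every `config$interval` steps. At each
#' attempt the hydrogen-bonded donor candidates are found, one is chosen
#' uniformly at random, its hop energy is evaluated by the nonbonded identity
#' swap, and the threshold-Metropolis rule decides acceptance; accepted hops
#' execute the identity swap, run the post-hop minimization and update the
#' titratable pool. With `evaluate_only = TRUE` every candidate is evaluated
#' and logged but no hop is ever accepted (used to sample the hop-energy
#' distribution).
#'
#' @param state An `oh_system` with exactly one hydroxide.
#' @param config A [hop_config()].
#' @param engine An [engine_config()].
#' @param n_steps Total MD steps.
#' @param evaluate_only Log hop energies without accepting.
#' @param save_stride Save full frames every this many steps (0 = none;
#'   must be a multiple of the attempt interval).
#' @param progress Print progress every ~10 ps.
#' @return List: `state`, `events` (one row per evaluated attempt: step,
#'   donor, acceptor, dE, coulomb, lj, accepted, energy_removed),
#'   `oh_series` (time, molecule id and oxygen position of the hydroxide at
#'   every attempt interval), `trajectory` (when `save_stride > 0`).
#' @export
run_hopping_md <- function(state, config = hop_config(),
                           engine = engine_config(), n_steps,
                           evaluate_only = FALSE, save_stride = 0,
                           progress = FALSE) {
  if (is.na(state$hydroxide))
    ohmd_error("system has no hydroxide", "ohmd_bookkeeping")
  interval <- config$interval
  nchunk <- as.integer(n_steps %/% interval)
  if (save_stride > 0 && save_stride %% interval != 0)
    ohmd_error("save_stride must be a multiple of the attempt interval",
               "ohmd_invalid_config")
  events <- list(); nev <- 0L
  add_event <- function(e) {
    nev <<- nev + 1L
    events[[nev]] <<- e
  }
  oh_series <- matrix(NA_real_, nchunk, 4)
  oh_mol <- integer(nchunk)
  frames <- list()
  frame_times <- numeric()
  state <- update_titratable_pool(state, config$pool_size)
  for (ch in seq_len(nchunk)) {
    res <- run_md(state, engine, interval, save_stride = 0)
    state <- res$state
    step <- ch * interval
    ## hop attempt over all hydrogen-bonded waters; a plain donor is
    ## switched with a titratable residue on demand before evaluation
    pairs <- find_hbond_pairs(state, config, titratable_only = FALSE)
    if (nrow(pairs)) {
      sf <- if (engine$scheme == "ewald") {
        ew <- ewald_params(state, engine)
        cpp_ewald_sf(state$pos, state$q, state$box, ew[1], ew[2])
      }
      sel <- if (evaluate_only) seq_len(nrow(pairs))
             else sample.int(nrow(pairs), 1)
      for (k in sel) {
        p <- pairs[k, ]
        donor <- p$donor
        h_site <- p$h_site
        if (!state$mols$titratable[donor]) {
          tit <- farthest_titratable(state, config)
          if (is.na(tit)) {
            warning("no titratable residue available for promotion",
                    call. = FALSE)
            next
          }
          swapped <- state$mols$nsites[donor] != state$mols$nsites[tit]
          state <- promote_molecule(state, donor, tit)
          if (swapped) {
            ## the titratable body now sits on the donor's geometry;
            ## coordinates moved, so the cached structure factor is stale
            h_local <- match(h_site, mol_sites(state, donor))
            donor <- tit
            h_site <- mol_sites(state, tit)[h_local]
            sf <- NULL
          }
        }
        de <- delta_e_hop(state, donor, p$acceptor, h_site, engine, sf = sf)
        accepted <- FALSE
        eremoved <- 0
        if (!evaluate_only &&
            accept_hop(de$dE, config$C, config$temperature)) {
          newstate <- execute_hop(state, donor, p$acceptor, h_site)
          if (!isTRUE(attr(newstate, "aborted"))) {
            accepted <- TRUE
            attr(newstate, "aborted") <- NULL
            state <- newstate
            if (config$min_steps > 0) {
              pm <- posthop_minimize(state, config$min_steps, engine)
              state <- pm$state
              eremoved <- pm$energy_removed
            }
            state <- update_titratable_pool(state, config$pool_size)
          }
        }
        add_event(data.frame(step = step, donor = donor,
                             acceptor = p$acceptor, dE = de$dE,
                             coulomb = de$decomposition[["coulomb"]],
                             lj = de$decomposition[["lj"]],
                             accepted = accepted,
                             energy_removed = eremoved))
      }
    }
    oh_mol[ch] <- state$hydroxide
    oh_series[ch, ] <- c(state$time,
                         state$pos[mol_o_site(state, state$hydroxide), ])
    if (save_stride > 0 && (ch * interval) %% save_stride == 0) {
      frames[[length(frames) + 1L]] <- state$pos
      frame_times <- c(frame_times, state$time)
    }
    if (progress && ch %% max(1, round(10 / (interval * engine$dt))) == 0)
      message(sprintf("  t = %.1f ps, %d events", state$time, nev))
  }
  events <- if (nev) do.call(rbind, events[seq_len(nev)]) else
    data.frame(step = integer(), donor = integer(), acceptor = integer(),
               dE = numeric(), coulomb = numeric(), lj = numeric(),
               accepted = logical(), energy_removed = numeric())
  out <- list(state = state, events = events,
              oh_series = data.frame(time = oh_series[, 1], mol = oh_mol,
                                     x = oh_series[, 2], y = oh_series[, 3],
                                     z = oh_series[, 4]))
  if (length(frames)) {
    coords <- array(unlist(frames),
                    dim = c(nrow(state$pos), 3, length(frames)))
    out$trajectory <- new_trajectory(
      coords, time = frame_times, box = state$box,
      periodic = state$periodic, element = state$element,
      role = state$role, molid = state$molid)
  }
  out
}
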