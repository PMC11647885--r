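#' Coupling-window schedule for free-energy perturbation
#'
#' @param n_windows Number of perturbation windows (default 10, giving
#'   uniformly spaced coupling values with endpoints 0 and 1).
#' @param equil_ps Per-window equilibration, ps.
#' @param prod_ps Per-window production, ps.
#' @param replicas Independent repeats (the replica standard deviation is
#'   the reported uncertainty).
#' @param sample_interval Steps between energy-difference samples.
#' @return An object of class `lambda_schedule`.
#' @export
lambda_schedule <- function(n_windows = 10, equil_ps = 2, prod_ps = 8,
                            replicas = 3, sample_interval = 10) {
  values <- seq(0, 1, length.out = n_windows + 1)
  structure(list(values = values, n_windows = n_windows,
                 equil_ps = equil_ps, prod_ps = prod_ps,
                 replicas = replicas,
                 sample_interval = as.integer(sample_interval)),
            class = "lambda_schedule")
}

#' Lambda-coupled pair interaction
#'
#' Dual-topology coupling of a transforming site between endpoint parameter
#' sets A and B. Charges interpolate linearly and the two Lennard-Jones
#' endpoint legs mix as `(1-c) E_A + c E_B`. For pairs that exist at both
#' endpoints the legs are plain 12-6 (an identity transform is exact at
#' every coupling value); for pairs that vanish at one endpoint a
#' Beutler-style soft core is applied to the surviving LJ leg *and* the
#' Coulomb term (`r^6` shifted by `s*c*Rmin^6` when the pair vanishes at B,
#' `s*(1-c)*Rmin^6` when it appears there), so both endpoints are recovered
#' exactly and any overlap stays finite for intermediate coupling.
#'
#' @param coupling Coupling value in `[0, 1]`.
#' @param a,b Endpoint [nb_params()] of the transforming site.
#' @param softcore Soft-core strength `s`.
#' @return List with the interpolated charge `q` and
#'   `pair_energy(partner, r)`, the interaction energy with a partner site
#'   (an `nb_params`) at distance r (plain Coulomb scheme).
#' @export
scaled_interaction <- function(coupling, a, b, softcore = 0.5) {
  if (coupling < 0 || coupling > 1)
    ohmd_error("coupling must be in [0, 1]", "ohmd_domain")
  cc <- coupling
  q <- (1 - cc) * a$q + cc * b$q
  pair_energy <- function(partner, r) {
    if (any(r <= 0)) ohmd_error("invalid geometry: r must be > 0",
                                "ohmd_invalid_geometry")
    hasA <- a$has_lj && partner$has_lj
    hasB <- b$has_lj && partner$has_lj
    alpha <- 0
    if (hasA && !hasB)
      alpha <- softcore * cc * (a$rmin_half + partner$rmin_half)^6
    if (hasB && !hasA)
      alpha <- softcore * (1 - cc) * (b$rmin_half + partner$rmin_half)^6
    e <- KCOUL * q * partner$q / (r^6 + alpha)^(1 / 6)
    leg <- function(p) {
      epsij <- sqrt(p$epsilon * partner$epsilon)
      R <- p$rmin_half + partner$rmin_half
      u <- R^6 / (r^6 + alpha)
      epsij * (u^2 - 2 * u)
    }
    if (hasA && cc < 1) e <- e + (1 - cc) * leg(a)
    if (hasB && cc > 0) e <- e + cc * leg(b)
    e
  }
  list(q = q, pair_energy = pair_energy)
}

#' Zwanzig (exponential averaging) free-energy estimator
#'
#' `dG = -kT ln < exp(-dU/kT) >`, evaluated with a log-sum-exp guard.
#'
#' @param dU Energy-difference samples, kcal/mol.
#' @param temperature K.
#' @return Window free energy, kcal/mol.
#' @export
zwanzig_dg <- function(dU, temperature = 298) {
  if (!length(dU)) ohmd_error("no samples", "ohmd_domain")
  kT <- KBOLTZ * temperature
  x <- -dU / kT
  m <- max(x)
  -kT * (m + log(mean(exp(x - m))))
}

#' Bennett acceptance ratio estimator
#'
#' Self-consistent BAR solution from forward (`dU_f`, sampled at the lower
#' window) and backward (`dU_b`, sampled at the upper window) differences.
#'
#' @param dU_f,dU_b kcal/mol.
#' @param temperature K.
#' @return Window free energy, kcal/mol.
#' @export
bar_dg <- function(dU_f, dU_b, temperature = 298) {
  kT <- KBOLTZ * temperature
  M <- kT * log(length(dU_f) / length(dU_b))
  fermi <- function(x) 1 / (1 + exp(x / kT))
  obj <- function(dg) {
    mean(fermi(dU_f - dg + M)) - mean(fermi(dU_b + dg - M))
  }
  lo <- min(c(dU_f, -dU_b)) - 50
  hi <- max(c(dU_f, -dU_b)) + 50
  stats::uniroot(obj, c(lo, hi), tol = 1e-8)$root
}

make_alch <- function(state, solute, prmB, lambda, softcore = 0.5) {
  n <- nrow(state$pos)
  qB <- state$q; epsB <- state$eps; rmhB <- state$rmin_half
  hasB <- state$has_lj
  idx <- mol_sites(state, solute)
  qB[idx] <- prmB$q
  epsB[idx] <- prmB$eps
  rmhB[idx] <- prmB$rmin_half
  hasB[idx] <- prmB$has_lj
  mask <- integer(n)
  mask[idx] <- 1L
  list(mask = mask, q = qB, eps = epsB, rmh = rmhB,
       haslj = as.integer(hasB), lambda = lambda, softcore = softcore)
}

dummy_params <- function(tpl) {
  prm <- tpl$sites
  prm$q <- 0
  prm$eps <- 0
  prm$rmin_half <- 0
  prm$has_lj <- FALSE
  prm
}

#' Alchemical solvation free energy by windowed FEP
#'
#' Two coupling schemes. `"water_to_oh"`: the solute water transforms into
#' the hydroxide (endpoint A = TIP3P, endpoint B = the hydroxide parameter
#' set with the second hydrogen as a dummy); the self-solvation free energy
#' of TIP3P (-6.10 kcal/mol) is added to the total so the result is the
#' ion's solvation free energy. `"annihilate"`: all solute sites transform
#' into dummies (endpoint B = no interactions); the solvation free energy is
#' the negative of the annihilation free energy. Within each window,
#' dynamics run under the scaled interaction and energy differences to the
#' neighbouring coupling values are collected; window free energies use the
#' exponential (Zwanzig) estimator by default, or BAR.
#'
#' @param state An `oh_system`; the solute is `state$hydroxide` for
#'   `"annihilate"` and `solute` (a water id) for `"water_to_oh"`.
#' @param scheme `"water_to_oh"` or `"annihilate"`.
#' @param schedule A [lambda_schedule()].
#' @param engine An [engine_config()].
#' @param solute Solute molecule id (defaults to the hydroxide, or the
#'   water nearest the box centre for `"water_to_oh"`).
#' @param model Hydroxide model name for `"water_to_oh"`.
#' @param estimator `"zwanzig"` or `"bar"`.
#' @param self_solvation TIP3P self-solvation free energy added in scheme
#'   (a), kcal/mol.
#' @param endpoint_params Optional data frame overriding the endpoint-B
#'   per-site parameters (columns `q`, `eps`, `rmin_half`, `has_lj`).
#' @param catalog Parameter catalogue.
#' @return An object of class `fep_result`: `dg_windows`, `dg_total`,
#'   `dg_replicas`, `uncertainty`, `scheme`.
#' @export
run_fep <- function(state, scheme = c("water_to_oh", "annihilate"),
                    schedule = lambda_schedule(), engine = engine_config(),
                    solute = NULL, model = "M09", estimator = c("zwanzig", "bar"),
                    self_solvation = -6.10, endpoint_params = NULL,
                    catalog = model_catalog()) {
  scheme <- match.arg(scheme)
  estimator <- match.arg(estimator)
  if (scheme == "water_to_oh") {
    if (is.null(solute)) {
      waters <- which(state$mols$state == "water" & !state$mols$fixed &
                      state$mols$model != "CNT")
      ctr <- state$box / 2
      d2 <- vapply(waters, function(m)
        sum((state$pos[mol_o_site(state, m), ] - ctr)^2), 0)
      solute <- waters[which.min(d2)]
    }
    tplB <- build_model(model, catalog, titratable = TRUE)
    if (nrow(tplB$sites) != state$mols$nsites[solute])
      ohmd_error("water_to_oh requires a 2p hydroxide target (site counts must match)",
                 "ohmd_domain")
    prmB <- tplB$sites
  } else {
    if (is.null(solute)) solute <- state$hydroxide
    if (is.na(solute)) ohmd_error("no solute to annihilate", "ohmd_domain")
    prmB <- dummy_params(mol_template(state, solute))
  }
  if (!is.null(endpoint_params)) prmB <- endpoint_params
  vals <- schedule$values
  nw <- length(vals) - 1
  eq_steps <- max(1L, round(schedule$equil_ps / engine$dt))
  pr_steps <- max(1L, round(schedule$prod_ps / engine$dt))
  si <- schedule$sample_interval
  reps <- numeric(schedule$replicas)
  win_store <- matrix(0, schedule$replicas, nw)
  for (rep in seq_len(schedule$replicas)) {
    st <- maxwell_boltzmann(state, engine$temperature)
    fwd <- vector("list", nw)
    bwd <- vector("list", nw)
    for (w in seq_along(vals)) {
      lam <- vals[w]
      alch <- make_alch(st, solute, prmB, lam)
      st <- run_md(st, engine, eq_steps, thermostat = TRUE,
                   alch = alch)$state
      nsamp <- pr_steps %/% si
      du_up <- if (w <= nw) numeric(nsamp) else NULL
      du_dn <- if (w > 1) numeric(nsamp) else NULL
      for (s in seq_len(nsamp)) {
        st <- run_md(st, engine, si, thermostat = TRUE, alch = alch)$state
        e0 <- fep_solute_energy(st, engine, solute, prmB, lam)
        if (!is.null(du_up))
          du_up[s] <- fep_solute_energy(st, engine, solute, prmB,
                                        vals[w + 1]) - e0
        if (!is.null(du_dn))
          du_dn[s] <- fep_solute_energy(st, engine, solute, prmB,
                                        vals[w - 1]) - e0
      }
      if (!is.null(du_up)) fwd[[w]] <- du_up
      if (w > 1) bwd[[w - 1]] <- du_dn
    }
    dgw <- vapply(seq_len(nw), function(w) {
      if (estimator == "bar") bar_dg(fwd[[w]], bwd[[w]], engine$temperature)
      else zwanzig_dg(fwd[[w]], engine$temperature)
    }, 0)
    win_store[rep, ] <- dgw
    reps[rep] <- sum(dgw)
  }
  total <- mean(reps)
  if (scheme == "water_to_oh") {
    sfe <- total + self_solvation
  } else {
    sfe <- -total
  }
  structure(list(dg_windows = colMeans(win_store),
                 dg_total = total, sfe = sfe,
                 dg_replicas = reps,
                 uncertainty = if (length(reps) > 1) stats::sd(reps) else NA,
                 scheme = scheme, lambda = vals),
            class = "fep_result")
}

## Energy of all pairs involving the solute under coupling `lam`.
fep_solute_energy <- function(state, engine, solute, prmB, lam) {
  alch <- make_alch(state, solute, prmB, lam)
  a <- kernel_args(state, engine, alch)
  ingroup <- if (engine$scheme == "ewald") integer() else
    as.integer(state$molid == solute)
  cpp_nonbonded(state$pos, a$q, a$eps, a$rmh, a$haslj, a$molid, a$isfixed,
                a$restrained, a$box, a$periodic, a$cutoff, a$scheme, a$efz,
                a$walls, a$alch, ingroup, a$ewald, FALSE)$total
}

#' @export
print.fep_result <- function(x, ...) {
  cat(sprintf("<fep_result> scheme %s: dG = %.2f kcal/mol, SFE = %.2f +/- %s kcal/mol\n",
              x$scheme, x$dg_total, x$sfe,
              if (is.na(x$uncertainty)) "NA" else sprintf("%.2f", x$uncertainty)))
  invisible(x)
}
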