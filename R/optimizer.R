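#' Optimization target specification
#'
#' Observable targets for the force-field parameterization, by default the
#' first-shell coordination number (CN = 4.5) and the first-peak height
#' (Peak = 4) of the hydroxide-oxygen/water-oxygen g(r).
#'
#' @param targets Named numeric, e.g. `c(CN = 4.5, Peak = 4)`.
#' @param weights Named numeric weights (recycled to 1).
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(targets = c(CN = 4.5, Peak = 4), weights = NULL) {
  if (!length(targets)) ohmd_error("at least one target required",
                                   "ohmd_invalid_config")
  if (is.null(weights)) weights <- setNames(rep(1, length(targets)),
                                            names(targets))
  structure(list(targets = targets, weights = weights[names(targets)]),
            class = "target_spec")
}

#' Chi-squared objective
#'
#' Weighted sum of squared deviations between observed and target
#' observables: `chi2 = sum w (A_exp - A_obs)^2`.
#'
#' @param A_obs Named numeric observables (must cover all target names).
#' @param targets A [target_spec()].
#' @return Scalar chi-squared.
#' @export
chi2 <- function(A_obs, targets) {
  nm <- names(targets$targets)
  if (!all(nm %in% names(A_obs)))
    ohmd_error(sprintf("missing observable(s): %s",
                       paste(setdiff(nm, names(A_obs)), collapse = ", ")),
               "ohmd_key")
  sum(targets$weights * (targets$targets - A_obs[nm])^2)
}

#' Finite-difference gradient of chi-squared
#'
#' Central differences of the observables per parameter (relative step
#' `delta`), combined by the chain rule
#' `dchi2/dlambda = sum -2 w (A_exp - A_obs) dA/dlambda`.
#'
#' @param lambda Named parameter vector (e.g. `eps_o`, `eps_h`,
#'   `rmin_half_o`, `rmin_half_h`), all positive.
#' @param evaluator Function mapping a parameter vector to named observables.
#' @param targets A [target_spec()].
#' @param delta Relative step size.
#' @return Named gradient vector, with attributes `A_obs` and `dA` (the
#'   observable Jacobian).
#' @export
finite_diff_gradient <- function(lambda, evaluator, targets, delta = 0.05) {
  if (delta <= 0) ohmd_error("delta must be > 0", "ohmd_invalid_config")
  A0 <- evaluator(lambda)
  nm <- names(targets$targets)
  dA <- matrix(0, length(nm), length(lambda),
               dimnames = list(nm, names(lambda)))
  for (k in seq_along(lambda)) {
    h <- delta * abs(lambda[k])
    if (h == 0) h <- delta
    lp <- lambda; lp[k] <- lambda[k] + h
    lm <- lambda; lm[k] <- lambda[k] - h
    Ap <- evaluator(lp)
    Am <- evaluator(lm)
    dA[, k] <- (Ap[nm] - Am[nm]) / (2 * h)
  }
  g <- drop(crossprod(dA, -2 * targets$weights * (targets$targets - A0[nm])))
  structure(setNames(as.numeric(g), names(lambda)), A_obs = A0, dA = dA)
}

#' Steepest-descent parameter update
#'
#' `lambda' = lambda - alpha * gradient`, clamped to the positive domain
#' (floor `1e-6`) with a warning when a clamp triggers.
#'
#' @param lambda Named parameter vector.
#' @param gradient Gradient of chi-squared.
#' @param alpha Step size (> 0).
#' @return Updated parameter vector.
#' @export
sd_update <- function(lambda, gradient, alpha) {
  if (alpha <= 0) ohmd_error("alpha must be > 0", "ohmd_invalid_config")
  out <- lambda - alpha * gradient[names(lambda)]
  if (any(out <= 0)) {
    warning("parameter clamped at positive floor", call. = FALSE)
    out[out <= 0] <- 1e-6
  }
  out
}

#' Single-parameter scan
#'
#' Evaluates the observables along a grid of one parameter, holding the
#' others fixed.
#'
#' @param lambda Base parameter vector.
#' @param name Parameter to vary.
#' @param grid Values to evaluate.
#' @param evaluator Observable evaluator.
#' @param targets A [target_spec()] for the chi-squared column.
#' @return Data frame `(value, <observables...>, chi2)` sorted by value.
#' @export
scan_parameter <- function(lambda, name, grid, evaluator,
                           targets = target_spec()) {
  if (!name %in% names(lambda))
    ohmd_error(sprintf("unknown parameter '%s'", name), "ohmd_key")
  if (!length(grid)) ohmd_error("empty grid", "ohmd_invalid_config")
  grid <- sort(grid)
  rows <- lapply(grid, function(v) {
    l <- lambda; l[name] <- v
    A <- evaluator(l)
    cbind(data.frame(value = v), as.data.frame(as.list(A)),
          data.frame(chi2 = chi2(A, targets)))
  })
  do.call(rbind, rows)
}

#' Steepest-descent chi-squared optimization
#'
#' Iterates [finite_diff_gradient()] and [sd_update()]; with
#' `backtrack = TRUE` the step size is halved whenever an update increases
#' chi-squared (the update is rejected), making the chi-squared trace
#' non-increasing for a deterministic evaluator.
#'
#' @param lambda Starting parameter vector.
#' @param evaluator Observable evaluator (deterministic given a seed).
#' @param targets A [target_spec()].
#' @param alpha Initial step size.
#' @param n_iter Iterations.
#' @param delta Finite-difference relative step.
#' @param backtrack Halve alpha on chi-squared increase.
#' @param tol Stop when chi-squared falls below this.
#' @return List: `lambda`, `chi2`, `trace` (data frame per iteration).
#' @export
optimize_parameters <- function(lambda, evaluator, targets = target_spec(),
                                alpha = 1e-3, n_iter = 50, delta = 0.05,
                                backtrack = TRUE, tol = 0) {
  A <- evaluator(lambda)
  x2 <- chi2(A, targets)
  trace <- list()
  for (it in seq_len(n_iter)) {
    g <- finite_diff_gradient(lambda, evaluator, targets, delta)
    cand <- sd_update(lambda, g, alpha)
    Ac <- evaluator(cand)
    x2c <- chi2(Ac, targets)
    accepted <- x2c <= x2 || !backtrack
    if (accepted) {
      lambda <- cand; x2 <- x2c; A <- Ac
    } else alpha <- alpha / 2
    trace[[it]] <- data.frame(iter = it, chi2 = x2, alpha = alpha,
                              accepted = accepted,
                              t(as.matrix(lambda)))
    if (x2 <= tol) break
  }
  list(lambda = lambda, chi2 = x2, A_obs = A,
       trace = do.call(rbind, trace))
}

#' Starting parameter sets for the LJ scan
#'
#' The catalogued initial sets (original CHARMM, the charged-ring-model
#' set, and the Lee-Meuwly set) as named parameter vectors.
#'
#' @param name One of `"charmm"`, `"ufimtsev"`, `"lee-meuwly"`.
#' @param catalog Parameter catalogue.
#' @return Named numeric vector with charges and LJ parameters.
#' @export
starting_set <- function(name, catalog = model_catalog()) {
  ss <- catalog$starting_sets
  if (!name %in% names(ss))
    ohmd_error(sprintf("unknown starting set '%s'", name), "ohmd_key")
  unlist(ss[[name]])
}

#' Simulation-backed CN/Peak evaluator
#'
#' Returns an evaluator that builds a bulk box with a 2p hydroxide carrying
#' the candidate LJ parameters, runs a short equilibration + production at
#' 298 K, and measures CN and Peak from the hydroxide-oxygen/water-oxygen
#' RDF. Deterministic given `seed` (common random numbers across
#' evaluations).
#'
#' @param n_waters Box size (molecules).
#' @param equil_ps,prod_ps Equilibration and production lengths, ps.
#' @param charges Named charges `c(q_o=, q_h=)` held fixed during LJ
#'   optimization.
#' @param seed RNG seed applied before every evaluation.
#' @param cutoff Nonbonded cutoff, Å.
#' @return Function mapping a parameter vector to `c(CN=, Peak=)`.
#' @export
make_cn_peak_evaluator <- function(n_waters = 216, equil_ps = 10,
                                   prod_ps = 20,
                                   charges = c(q_o = -1.074, q_h = 0.074),
                                   seed = 1, cutoff = 9.0) {
  force(charges)
  function(lambda) {
    set.seed(seed)
    cat <- model_catalog()
    cat$oh_full$o$q <- unname(charges["q_o"])
    cat$oh_full$h$q <- unname(charges["q_h"])
    cat$oh_full$net_charge <- sum(charges)
    cat$oh_full$o$eps <- unname(lambda["eps_o"])
    cat$oh_full$h$eps <- unname(lambda["eps_h"])
    cat$oh_full$o$rmin_half <- unname(lambda["rmin_half_o"])
    cat$oh_full$h$rmin_half <- unname(lambda["rmin_half_h"])
    sys <- build_water_box(n_waters, hydroxide = "OH_full", catalog = cat)
    cfg <- engine_config(cutoff = cutoff)
    sys <- minimize_steepest_descent(sys, 150)$state
    sys <- run_md(sys, cfg, round(equil_ps / cfg$dt))$state
    res <- run_md(sys, cfg, round(prod_ps / cfg$dt), save_stride = 50)
    traj <- res$trajectory
    oh_o <- mol_o_site(res$state, res$state$hydroxide)
    w_o <- which(traj$role == "O" & seq_along(traj$role) != oh_o)
    rdf <- compute_rdf(traj, oh_o, w_o)
    pk <- first_peak(rdf)
    c(CN = coordination_number(rdf), Peak = pk$g_peak)
  }
}
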