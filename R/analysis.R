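#' Radial distribution function
#'
#' Pair-histogram g(r) between two site selections, normalized per shell
#' volume and the number density of the B species, so that uncorrelated
#' species give g = 1. Requires a periodic box and `r_max <= L/2`.
#'
#' @param traj An `oh_trajectory` with box metadata.
#' @param sel_a,sel_b Site selections: integer indices, or a logical vector,
#'   or a function of the trajectory returning indices.
#' @param bin_width Å.
#' @param r_max Å.
#' @param blocks Number of trajectory blocks for the uncertainty estimate
#'   (0 = none).
#' @param exclude_same_mol Drop pairs within the same molecule.
#' @return An object of class `oh_rdf`: `r` (bin centres), `g`, `density`
#'   (B-species number density, Å^-3), `counts`, `bin_width`, optional
#'   `g_se` block standard errors.
#' @export
compute_rdf <- function(traj, sel_a, sel_b, bin_width = 0.05, r_max = NULL,
                        blocks = 0, exclude_same_mol = TRUE) {
  if (is.null(traj$box))
    ohmd_error("RDF requires a periodic box", "ohmd_domain")
  L <- min(traj$box[traj$periodic])
  if (is.null(r_max)) r_max <- L / 2
  if (r_max > L / 2 + 1e-9)
    ohmd_error("r_max must be <= L/2", "ohmd_domain")
  ia <- resolve_sel(traj, sel_a)
  ib <- resolve_sel(traj, sel_b)
  nf <- n_frames(traj)
  molid <- if (is.null(traj$molid)) rep(1L, dim(traj$coords)[1]) else
    as.integer(traj$molid)
  excl <- exclude_same_mol && !is.null(traj$molid)
  counts <- cpp_rdf_counts(traj$coords, as.integer(ia), as.integer(ib),
                           traj$box, as.integer(traj$periodic), bin_width,
                           r_max, molid, excl)
  nb <- length(counts)
  edges <- seq(0, by = bin_width, length.out = nb + 1)
  vol <- prod(traj$box)
  rho_b <- length(ib) / vol
  shell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nb + 1)]^3)
  norm <- length(ia) * nf * shell * rho_b
  g <- counts / norm
  out <- list(r = (edges[-1] + edges[-(nb + 1)]) / 2, g = g,
              density = rho_b, counts = counts, bin_width = bin_width,
              n_frames = nf, n_a = length(ia))
  if (blocks > 1 && nf >= blocks) {
    cut <- split(seq_len(nf), ceiling(seq_len(nf) / (nf / blocks)))
    gb <- vapply(cut, function(fr) {
      cc <- cpp_rdf_counts(traj$coords[, , fr, drop = FALSE],
                           as.integer(ia), as.integer(ib), traj$box,
                           as.integer(traj$periodic), bin_width, r_max,
                           molid, excl)
      cc / (length(ia) * length(fr) * shell * rho_b)
    }, numeric(nb))
    out$g_se <- apply(gb, 1, stats::sd) / sqrt(length(cut))
  }
  structure(out, class = "oh_rdf")
}

resolve_sel <- function(traj, sel) {
  if (is.function(sel)) sel <- sel(traj)
  if (is.logical(sel)) sel <- which(sel)
  if (!length(sel)) ohmd_error("empty selection", "ohmd_domain")
  as.integer(sel)
}

smooth3 <- function(x) {
  n <- length(x)
  if (n < 3) return(x)
  c(x[1], (x[-c(1, 2)] + x[-c(1, n)] + x[-c(n - 1, n)]) / 3, x[n])
}

#' First peak of a radial distribution function
#'
#' Location and height of the first local maximum after the excluded-volume
#' region (the first bin where g exceeds `rise`), on a 3-bin moving average.
#'
#' @param rdf An `oh_rdf`.
#' @param rise g threshold marking the end of the excluded-volume region.
#' @param smooth Apply the 3-bin moving average.
#' @return List: `r_peak` (Å), `g_peak` (height of the raw g at the peak
#'   bin).
#' @export
first_peak <- function(rdf, rise = 0.5, smooth = TRUE) {
  g <- if (smooth) smooth3(rdf$g) else rdf$g
  start <- which(g > rise)[1]
  if (is.na(start)) ohmd_error("no peak found: g never rises", "ohmd_analysis")
  for (i in seq(max(start, 2), length(g) - 1)) {
    if (g[i] >= g[i - 1] && g[i] > g[i + 1])
      return(list(r_peak = rdf$r[i], g_peak = rdf$g[i]))
  }
  ohmd_error("no peak found: g is monotone", "ohmd_analysis")
}

#' First minimum after the first peak
#'
#' Search window defaults to 2.8-3.8 Å (the first solvation-shell boundary
#' of hydroxide-water RDFs).
#'
#' @param rdf An `oh_rdf`.
#' @param window Search window, Å.
#' @return r at the minimum, Å.
#' @export
first_minimum <- function(rdf, window = c(2.8, 3.8)) {
  pk <- first_peak(rdf)
  g <- smooth3(rdf$g)
  idx <- which(rdf$r > max(pk$r_peak, window[1]) & rdf$r <= window[2])
  if (!length(idx)) ohmd_error("no minimum found in window", "ohmd_analysis")
  for (i in idx) {
    if (i > 1 && i < length(g) && g[i] <= g[i - 1] && g[i] < g[i + 1])
      return(rdf$r[i])
  }
  rdf$r[idx[which.min(g[idx])]]
}

#' Coordination number
#'
#' Density-weighted integral of g(r): `CN = 4 pi rho int_0^limit g r^2 dr`,
#' the mean number of B-species sites inside the integration limit.
#'
#' @param rdf An `oh_rdf`.
#' @param limit Integration limit (Å) or `"auto"` for the first minimum
#'   after the first peak.
#' @param window Search window passed to [first_minimum()] for `"auto"`.
#' @return CN (count).
#' @export
coordination_number <- function(rdf, limit = "auto", window = c(2.8, 3.8)) {
  if (identical(limit, "auto")) limit <- first_minimum(rdf, window)
  sel <- rdf$r <= limit
  sum(4 * pi * rdf$density * rdf$g[sel] * rdf$r[sel]^2 * rdf$bin_width)
}

#' Unwrap periodic-boundary jumps
#'
#' Adds box-length corrections whenever a site's frame-to-frame displacement
#' exceeds half the box on a periodic axis, producing continuous coordinates.
#' The first frame is unchanged.
#'
#' @param traj An `oh_trajectory` with box metadata.
#' @return The unwrapped trajectory.
#' @export
unwrap <- function(traj) {
  if (is.null(traj$box)) return(traj)
  co <- traj$coords
  nf <- dim(co)[3]
  if (nf < 2) return(traj)
  for (ax in which(traj$periodic)) {
    L <- traj$box[ax]
    raw <- matrix(co[, ax, ], nrow = dim(co)[1])
    d <- raw[, -1, drop = FALSE] - raw[, -nf, drop = FALSE]
    shift <- -L * round(d / L)
    cum <- if (ncol(shift) == 1) shift else t(apply(shift, 1, cumsum))
    co[, ax, -1] <- raw[, -1, drop = FALSE] + cum
  }
  traj$coords <- co
  traj
}

#' Wrap coordinates into the primary box
#' @param traj An `oh_trajectory`.
#' @return The wrapped trajectory.
#' @export
wrap <- function(traj) {
  if (is.null(traj$box)) return(traj)
  for (ax in which(traj$periodic)) {
    L <- traj$box[ax]
    traj$coords[, ax, ] <- traj$coords[, ax, ] -
      L * floor(traj$coords[, ax, ] / L)
  }
  traj
}

#' Einstein diffusion coefficient
#'
#' Mean squared displacement with all frames as time origins, evaluated on a
#' lag grid, and `D = slope/(2d)` from a least-squares fit over the window
#' of the MSD's linear portion.
#'
#' @param x Positions: a matrix (frames x dims) of unwrapped coordinates, or
#'   a numeric vector for 1D.
#' @param time Frame times, ps.
#' @param d Dimensionality of the analysis (1 or 3); defaults to
#'   `ncol(x)`.
#' @param fit_window Fraction of the maximum lag used for the fit.
#' @param max_lag_frac Maximum lag as a fraction of the trajectory length.
#' @param n_lags Number of lag points evaluated.
#' @return List: `D` (Å^2/ps), `msd` data frame (lag time, msd), `fit`.
#' @export
einstein_diffusion <- function(x, time, d = NULL,
                               fit_window = c(0.1, 0.5),
                               max_lag_frac = 0.25, n_lags = 200) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  if (is.null(d)) d <- ncol(x)
  nf <- nrow(x)
  if (length(time) != nf)
    ohmd_error("time length must match positions", "ohmd_domain")
  maxlag <- max(2L, as.integer(floor(nf * max_lag_frac)))
  if (maxlag >= nf)
    ohmd_error("fit window longer than trajectory", "ohmd_domain")
  lags <- unique(pmax(1L, round(seq(1, maxlag, length.out = min(n_lags, maxlag)))))
  dt <- mean(diff(time))
  msd <- vapply(lags, function(l) {
    dx <- x[(1 + l):nf, , drop = FALSE] - x[1:(nf - l), , drop = FALSE]
    mean(rowSums(dx^2))
  }, 0)
  tl <- lags * dt
  sel <- tl >= fit_window[1] * max(tl) & tl <= fit_window[2] * max(tl)
  if (sum(sel) < 2) sel <- seq_along(tl)
  fit <- stats::lm(msd[sel] ~ tl[sel])
  list(D = unname(coef(fit)[2]) / (2 * d),
       msd = data.frame(t = tl, msd = msd),
       fit = c(intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2])))
}

#' Electrophoretic mobility from drift under a field
#'
#' `mobility = slope(z vs t) / field`.
#'
#' @param z Unwrapped drift coordinate, Å.
#' @param time ps.
#' @param field Field magnitude, V/Å (nonzero).
#' @return Mobility, Å^2/(V ps).
#' @export
electrophoretic_mobility <- function(z, time, field) {
  if (field == 0) ohmd_error("zero field", "ohmd_domain")
  unname(coef(stats::lm(z ~ time))[2]) / field
}

#' Identify the hydroxide oxygen in a raw frame
#'
#' Assigns every hydrogen to its minimum-image-nearest oxygen; the unique
#' oxygen with exactly one assigned hydrogen is the hydroxide. Frames where
#' zero or several oxygens carry one hydrogen raise an ambiguous-frame
#' error; exact distance ties break to the lower oxygen index and flag the
#' frame.
#'
#' @param pos n x 3 coordinates.
#' @param element Element labels (`"O"`/`"H"`).
#' @param box,periodic Box metadata.
#' @return List: `o_index` (into the oxygen subset order, as a global site
#'   index), `assignments` (per-H oxygen site index), `flagged`.
#' @export
identify_hydroxide <- function(pos, element, box, periodic = TRUE) {
  periodic <- rep(as.logical(periodic), length.out = 3)
  io <- which(element == "O")
  ih <- which(element == "H")
  if (length(ih) != 2 * length(io) - 1)
    ohmd_error("counts must satisfy n_H = 2 n_O - 1", "ohmd_domain")
  flagged <- FALSE
  assign <- integer(length(ih))
  for (k in seq_along(ih)) {
    d <- sweep(pos[io, , drop = FALSE], 2, pos[ih[k], ], "-")
    for (ax in which(periodic)) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
    r <- sqrt(rowSums(d^2))
    best <- min(r)
    ties <- which(r <= best + 1e-12)
    if (length(ties) > 1) flagged <- TRUE
    assign[k] <- io[ties[1]]
  }
  cnt <- table(factor(assign, levels = io))
  if (any(cnt >= 3))
    ohmd_error("ambiguous frame: an oxygen has 3 assigned hydrogens",
               "ohmd_ambiguous_frame")
  one <- io[cnt == 1]
  if (length(one) != 1)
    ohmd_error(sprintf("ambiguous frame: %d single-hydrogen oxygens",
                       length(one)), "ohmd_ambiguous_frame")
  list(o_index = one, assignments = assign, flagged = flagged)
}

#' Classify proton transfers into rattles and true hops
#'
#' Transfers are the change points of the per-frame hydroxide index series.
#' A consecutive pair `i -> j, j -> i` is a rattling pair; in the default
#' accounting both members are excluded from the true hops, so
#' `n_true = n_transfers - 2 n_rattle_pairs`. `mode = "reversal"` excludes
#' only the returning member.
#'
#' @param series Per-frame hydroxide identity (indices or labels).
#' @param mode `"pair"` or `"reversal"`.
#' @return List: `n_transfers`, `n_rattle_pairs`, `n_true_hops`,
#'   `transfers` data frame (frame, from, to, rattle).
#' @export
classify_hops <- function(series, mode = c("pair", "reversal")) {
  mode <- match.arg(mode)
  ch <- which(series[-1] != series[-length(series)])
  if (!length(ch))
    return(list(n_transfers = 0L, n_rattle_pairs = 0, n_true_hops = 0L,
                transfers = data.frame(frame = integer(), from = series[0],
                                       to = series[0], rattle = logical())))
  tr <- data.frame(frame = ch + 1L,
                   from = series[ch], to = series[ch + 1L],
                   rattle = FALSE, stringsAsFactors = FALSE)
  nt <- nrow(tr)
  k <- 1L
  while (k < nt) {
    if (!tr$rattle[k] && tr$from[k + 1L] == tr$to[k] &&
        tr$to[k + 1L] == tr$from[k]) {
      tr$rattle[c(k, k + 1L)] <- TRUE
      k <- k + 2L
    } else k <- k + 1L
  }
  npairs <- sum(tr$rattle) / 2
  ntrue <- if (mode == "pair") nt - 2 * npairs else nt - npairs
  list(n_transfers = nt, n_rattle_pairs = npairs, n_true_hops = ntrue,
       transfers = tr)
}

#' Solvation state of the hydroxide
#'
#' Counts hydrogen bonds in the first shell under the geometric criterion:
#' waters donating a hydrogen to the hydroxide oxygen (`n_accepted`) and
#' waters accepting the hydroxide's hydrogen (`n_donated`).
#'
#' @param state An `oh_system` with a hydroxide.
#' @param config A [hop_config()] carrying the H-bond criterion.
#' @return List: `n_accepted`, `n_donated`.
#' @export
solvation_state <- function(state, config = hop_config()) {
  acc <- state$hydroxide
  if (is.na(acc)) ohmd_error("no hydroxide", "ohmd_bookkeeping")
  accepted <- nrow(find_hbond_pairs(state, config, titratable_only = FALSE))
  ## donated: hydroxide's real H pointing at a water oxygen
  aidx <- mol_sites(state, acc)
  oa <- state$pos[aidx[1L], ]
  hs <- aidx[state$role[aidx] == "H"]
  ndon <- 0L
  waters <- which(state$mols$state == "water" & !state$mols$fixed &
                  state$mols$model != "CNT")
  for (m in waters) {
    ow <- state$pos[mol_o_site(state, m), ]
    r <- sqrt(sum(mi_disp(ow, oa, state$box, state$periodic)^2))
    if (r > config$r_da) next
    for (h in hs) {
      hp <- state$pos[h, ]
      v1 <- mi_disp(oa, hp, state$box, state$periodic)
      v2 <- mi_disp(ow, hp, state$box, state$periodic)
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      if (acos(pmin(1, pmax(-1, cosang))) * 180 / pi >= config$theta_min)
        ndon <- ndon + 1L
    }
  }
  list(n_accepted = accepted, n_donated = ndon)
}
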