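#' Nonbonded site parameters
#'
#' A single site's nonbonded parameters: partial charge, Lennard-Jones well
#' depth and half-Rmin (the CHARMM `Rmin/2` convention, so a like pair has its
#' energy minimum at twice this value).
#'
#' @param q Partial charge (e).
#' @param epsilon LJ well depth (kcal/mol, nonnegative magnitude).
#' @param rmin_half Half of the like-pair minimum distance (Å).
#' @param has_lj Does the site carry LJ terms? Dummy sites have `q = 0` and
#'   `has_lj = FALSE`.
#' @return An object of class `nb_params`.
#' @export
nb_params <- function(q = 0, epsilon = 0, rmin_half = 0, has_lj = epsilon > 0) {
  if (epsilon < 0) ohmd_error("epsilon must be a nonnegative magnitude", "ohmd_invalid_params")
  if (has_lj && rmin_half <= 0) ohmd_error("rmin_half must be > 0 for LJ sites", "ohmd_invalid_params")
  structure(list(q = q, epsilon = epsilon, rmin_half = rmin_half,
                 has_lj = isTRUE(has_lj)), class = "nb_params")
}

#' Lorentz-Berthelot combination rule
#'
#' Pair LJ parameters from two site parameter sets: geometric mean for the
#' well depth, sum of the half-Rmin values for the pair minimum distance.
#'
#' @param a,b `nb_params` objects, both with `has_lj = TRUE`.
#' @return List with `epsilon` (kcal/mol) and `rmin` (Å).
#' @export
lorentz_berthelot <- function(a, b) {
  if (!a$has_lj || !b$has_lj)
    ohmd_error("no LJ pair: a site lacks LJ terms", "ohmd_no_lj_pair")
  list(epsilon = sqrt(a$epsilon * b$epsilon), rmin = a$rmin_half + b$rmin_half)
}

#' 12-6 Lennard-Jones pair energy
#'
#' `E(r) = eps * ((rmin/r)^12 - 2 (rmin/r)^6)`; the minimum value `-eps`
#' occurs at the pair minimum distance `rmin`.
#'
#' @param pair Pair parameters from [lorentz_berthelot()].
#' @param r Distance(s), Å.
#' @return Energy, kcal/mol.
#' @export
lj_pair_energy <- function(pair, r) {
  if (any(r <= 0)) ohmd_error("invalid geometry: r must be > 0", "ohmd_invalid_geometry")
  u <- (pair$rmin / r)^6
  pair$epsilon * (u^2 - 2 * u)
}

#' Coulomb pair energy
#'
#' `E = k q_a q_b / r` with `k = 332.0636` kcal Å / (mol e^2).
#'
#' @param q_a,q_b Charges (e).
#' @param r Distance(s), Å.
#' @return Energy, kcal/mol.
#' @export
coulomb_pair_energy <- function(q_a, q_b, r) {
  if (any(r <= 0)) ohmd_error("invalid geometry: r must be > 0", "ohmd_invalid_geometry")
  KCOUL * q_a * q_b / r
}

#' Model catalogue
#'
#' Reads the packaged parameter catalogue (TIP3P and the hydroxide models:
#' the full-charge 2p ion, the reduced-charge M07 and M09 models, the
#' LJ-optimized 2p model, and the 3AP / 5AP auxiliary-particle models).
#'
#' @param path Optional path to an alternative YAML catalogue.
#' @return Named list of raw catalogue entries, class `oh_catalog`.
#' @export
model_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "models.yaml", package = "ohmd")
  cat <- yaml::read_yaml(path)
  structure(cat, class = "oh_catalog")
}

deg2rad <- function(x) x * pi / 180

site_row <- function(name, role, element, mass, q = 0, eps = 0, rmh = 0) {
  data.frame(name = name, role = role, element = element, mass = mass,
             q = q, eps = eps, rmin_half = rmh, has_lj = eps > 0,
             stringsAsFactors = FALSE)
}

entry_site <- function(e, key, name, role, element) {
  p <- e[[key]]
  site_row(name, role, element,
           mass = if (is.null(p$mass)) 1.0 else p$mass,
           q = if (is.null(p$q)) 0 else p$q,
           eps = if (is.null(p$eps)) 0 else p$eps,
           rmh = if (is.null(p$rmin_half)) 0 else p$rmin_half)
}

water_local <- function(r_oh, a_hoh) {
  th <- deg2rad(a_hoh)
  rbind(c(0, 0, 0),
        c(0, 0, r_oh),
        r_oh * c(sin(th), 0, cos(th)))
}

ap_local <- function(r_oap, a_hoap, azimuths) {
  th <- deg2rad(a_hoap)
  t(vapply(deg2rad(azimuths), function(phi)
    r_oap * c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th)),
    numeric(3)))
}

all_pair_constraints <- function(local) {
  n <- nrow(local)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- sqrt(rowSums((local[idx[, 1], , drop = FALSE] -
                     local[idx[, 2], , drop = FALSE])^2))
  data.frame(i = idx[, 1], j = idx[, 2], d = d)
}

#' Build a molecule template
#'
#' Returns a fully specified rigid molecule: sites with nonbonded parameters,
#' internal geometry (local frame: oxygen at the origin, the primary hydrogen
#' along +z), the full rigid constraint set, and for titratable templates the
#' protonated (TIP3P-identical) parameter variant.
#'
#' Titratable templates carry a second hydrogen that is a non-interacting
#' dummy in the hydroxide state and a real TIP3P hydrogen in the water state;
#' they use the TIP3P internal geometry in both states so that the protonated
#' variant is exactly TIP3P. Standalone hydroxide templates use the
#' catalogue's O-H bond length (default 0.97 Å).
#'
#' @param name Model name (case-insensitive): `"TIP3P"`, `"OH_full"`,
#'   `"M07"`, `"M09"`, `"OH_2p_opt"`, `"OH_3AP"`, `"OH_5AP"`.
#' @param catalog A catalogue from [model_catalog()].
#' @param titratable Build the titratable (proton-hopping capable) variant.
#' @param geometry Named list overriding catalogue geometry entries
#'   (`r_oh`, `r_oap`, `a_hoap`, ...).
#' @return An object of class `oh_template`.
#' @export
build_model <- function(name, catalog = model_catalog(), titratable = FALSE,
                        geometry = list()) {
  key <- tolower(name)
  if (!key %in% names(catalog))
    ohmd_error(sprintf("unknown model '%s'", name), "ohmd_unknown_model")
  e <- catalog[[key]]
  g <- utils::modifyList(e$geometry, geometry)
  kind <- e$kind
  tip <- catalog[["tip3p"]]

  if (kind == "water") {
    sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                   entry_site(e, "h", "H1", "H", "H"),
                   entry_site(e, "h", "H2", "H", "H"))
    local <- water_local(g$r_oh, g$a_hoh)
    prot <- sites
    titr <- FALSE
  } else if (kind == "oh_2p") {
    if (titratable) {
      ## TIP3P geometry; H2 is the dummy in the hydroxide state.
      local <- water_local(tip$geometry$r_oh, tip$geometry$a_hoh)
      sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                     entry_site(e, "h", "H1", "H", "H"),
                     site_row("H2", "DUM", "H", catalog$tip3p$h$mass))
      prot <- rbind(entry_site(tip, "o", "O", "O", "O"),
                    entry_site(tip, "h", "H1", "H", "H"),
                    entry_site(tip, "h", "H2", "H", "H"))
      titr <- TRUE
    } else {
      local <- rbind(c(0, 0, 0), c(0, 0, g$r_oh))
      sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                     entry_site(e, "h", "H1", "H", "H"))
      prot <- NULL
      titr <- FALSE
    }
  } else if (kind == "oh_3ap") {
    apq <- e$ap
    ap <- site_row(paste0("AP", 1:3), "AP", "X", apq$mass, q = apq$q)
    if (titratable) {
      wl <- water_local(tip$geometry$r_oh, tip$geometry$a_hoh)
      ## APs about the O-H1 axis, azimuths straddling the molecular plane
      local <- rbind(wl, ap_local(g$r_oap, g$a_hoap, c(60, 180, 300)))
      sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                     entry_site(e, "h", "H1", "H", "H"),
                     site_row("H2", "DUM", "H", tip$h$mass),
                     ap)
      prot <- rbind(entry_site(tip, "o", "O", "O", "O"),
                    entry_site(tip, "h", "H1", "H", "H"),
                    entry_site(tip, "h", "H2", "H", "H"),
                    site_row(paste0("AP", 1:3), "AP", "X", apq$mass))
      titr <- TRUE
    } else {
      local <- rbind(c(0, 0, 0), c(0, 0, g$r_oh),
                     ap_local(g$r_oap, g$a_hoap, c(0, 120, 240)))
      sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                     entry_site(e, "h", "H1", "H", "H"),
                     ap)
      prot <- NULL
      titr <- FALSE
    }
  } else if (kind == "oh_5ap") {
    if (titratable)
      ohmd_error("the 5AP model is catalogued without a titratable variant",
                 "ohmd_unknown_model")
    ## Approximate (synthetic) geometry: four charged APs arranged
    ## tetrahedrally about the anti-H axis, plus the LJ-bearing AP on the O-H
    ## axis at 0.425 Å and the hydrogen charge site on the hydrogen.
    ap4 <- ap_local(g$r_oap, g$a_hoap, c(0, 90, 180, 270))
    local <- rbind(c(0, 0, 0), c(0, 0, g$r_oh), c(0, 0, 0.8 * g$r_oh),
                   ap4, c(0, 0, -g$r_oap_lj))
    q_ap <- (e$net_charge - e$o$q - e$h_chargesite$q) / 4
    sites <- rbind(entry_site(e, "o", "O", "O", "O"),
                   entry_site(e, "h", "H1", "H", "H"),
                   site_row("HCS", "H_chargesite", "X", e$h_chargesite$mass,
                            q = e$h_chargesite$q),
                   site_row(paste0("AP", 1:4), "AP", "X", e$ap$mass, q = q_ap,
                            eps = e$ap_lj$eps, rmh = e$ap_lj$rmin_half),
                   site_row("APX", "AP", "X", e$ap_lj_extra$mass,
                            eps = e$ap_lj_extra$eps,
                            rmh = e$ap_lj_extra$rmin_half))
    prot <- NULL
    titr <- FALSE
  } else {
    ohmd_error(sprintf("unknown model kind '%s'", kind), "ohmd_unknown_model")
  }

  net <- sum(sites$q)
  if (abs(net - e$net_charge) > 1e-9)
    ohmd_error(sprintf("charge-sum mismatch for %s: %.6f vs declared %.6f",
                       name, net, e$net_charge), "ohmd_integrity")
  structure(list(name = name, kind = kind, sites = sites, local = local,
                 net_charge = net, titratable = titr, protonated = prot,
                 constraints = all_pair_constraints(local)),
            class = "oh_template")
}

#' @export
print.oh_template <- function(x, ...) {
  cat(sprintf("<oh_template> %s (%d sites, net %+0.4f e%s)\n", x$name,
              nrow(x$sites), x$net_charge,
              if (x$titratable) ", titratable" else ""))
  print(x$sites, ...)
  invisible(x)
}

#' Write a single molecule template to a PDB file
#'
#' Writes the template's local-frame coordinates as a one-residue PDB entry
#' for visual inspection (uses \pkg{bio3d} when available, otherwise a
#' minimal fixed-width writer).
#'
#' @param template An `oh_template`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_pdb <- function(template, path) {
  el <- template$sites$element
  nm <- template$sites$name
  xyz <- template$local
  if (requireNamespace("bio3d", quietly = TRUE)) {
    bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                     resno = rep(1, nrow(xyz)), resid = rep("MOL", nrow(xyz)),
                     elety = nm, eleno = seq_len(nrow(xyz)))
  } else {
    lines <- sprintf(
      "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(xyz)), substr(nm, 1, 4), "MOL", 1,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, substr(el, 1, 2))
    writeLines(c(lines, "END"), path)
  }
  invisible(path)
}
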