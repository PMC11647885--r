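#' Trajectory container
#'
#' Time-ordered coordinate frames with element labels and optional box and
#' molecule metadata; the substrate of all analyses.
#'
#' @param coords n x 3 x nframes array, Å.
#' @param time Frame times, ps (strictly increasing).
#' @param box Edge lengths (Å) or `NULL` for non-periodic data.
#' @param periodic Logical length 3.
#' @param element Per-site element labels.
#' @param role,molid Optional per-site role labels and molecule map.
#' @return An object of class `oh_trajectory`.
#' @export
new_trajectory <- function(coords, time, box = NULL, periodic = !is.null(box),
                           element = NULL, role = NULL, molid = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    ohmd_error("coords must be an n x 3 x nframes array", "ohmd_invalid_trajectory")
  if (length(time) != dim(coords)[3])
    ohmd_error("time length must match frame count", "ohmd_invalid_trajectory")
  if (any(diff(time) <= 0))
    ohmd_error("times must be strictly increasing", "ohmd_invalid_trajectory")
  structure(list(coords = coords, time = time,
                 box = if (is.null(box)) NULL else rep(box, length.out = 3),
                 periodic = rep(as.logical(periodic), length.out = 3),
                 element = element, role = role, molid = molid),
            class = "oh_trajectory")
}

#' @export
print.oh_trajectory <- function(x, ...) {
  cat(sprintf("<oh_trajectory> %d sites x %d frames, t = %.3f..%.3f ps%s\n",
              dim(x$coords)[1], dim(x$coords)[3], min(x$time), max(x$time),
              if (is.null(x$box)) " (non-periodic)" else
                sprintf(", box %.2f %.2f %.2f", x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Write a trajectory to a multi-frame XYZ file
#'
#' Standard XYZ dialect: count line, comment line carrying `t=<ps>` and
#' `box=<Lx,Ly,Lz>` when known, then `element x y z` rows (`%.6f`).
#'
#' @param traj An `oh_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  n <- dim(traj$coords)[1]
  con <- file(path, "w")
  on.exit(close(con))
  el <- if (is.null(traj$element)) rep("X", n) else traj$element
  for (f in seq_len(n_frames(traj))) {
    meta <- sprintf("t=%.6f", traj$time[f])
    if (!is.null(traj$box))
      meta <- paste0(meta, sprintf(" box=%.6f,%.6f,%.6f", traj$box[1],
                                   traj$box[2], traj$box[3]))
    writeLines(c(as.character(n), meta), con)
    writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", el,
                       traj$coords[, 1, f], traj$coords[, 2, f],
                       traj$coords[, 3, f]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' Parses the `t=`/`box=` comment-line metadata written by [write_xyz()];
#' files without box metadata load as non-periodic and analyses requiring a
#' box refuse them. Malformed frames raise a parse error with the offending
#' line number.
#'
#' @param path XYZ file.
#' @return An `oh_trajectory`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  nline <- length(lines)
  pos <- 1L
  frames <- list()
  times <- numeric()
  box <- NULL
  n <- NA_integer_
  el <- NULL
  while (pos <= nline) {
    if (!grepl("^\\s*\\d+\\s*$", lines[pos]))
      ohmd_error(sprintf("XYZ parse error at line %d: expected atom count", pos),
                 "ohmd_parse")
    nf <- as.integer(lines[pos])
    if (is.na(n)) n <- nf
    if (nf != n)
      ohmd_error(sprintf("XYZ parse error at line %d: frame count mismatch", pos),
                 "ohmd_parse")
    if (pos + 1L + n > nline)
      ohmd_error(sprintf("XYZ parse error at line %d: short frame", pos),
                 "ohmd_parse")
    cm <- lines[pos + 1L]
    tm <- regmatches(cm, regexec("t=([-0-9.eE+]+)", cm))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else length(times))
    bm <- regmatches(cm, regexec("box=([-0-9.eE+]+),([-0-9.eE+]+),([-0-9.eE+]+)",
                                 cm))[[1]]
    if (length(bm) == 4 && is.null(box)) box <- as.numeric(bm[2:4])
    body <- lines[pos + 1L + seq_len(n)]
    toks <- strsplit(trimws(body), "\\s+")
    bad <- which(vapply(toks, length, 0L) < 4)
    if (length(bad))
      ohmd_error(sprintf("XYZ parse error at line %d: malformed atom row",
                         pos + 1L + bad[1]), "ohmd_parse")
    if (is.null(el)) el <- vapply(toks, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(toks, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  coords <- array(unlist(frames), dim = c(n, 3, length(frames)))
  new_trajectory(coords, times, box = box, periodic = !is.null(box),
                 element = el)
}

#' Write a system snapshot as PDB
#'
#' @param state An `oh_system`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pdb_snapshot <- function(state, path) {
  n <- nrow(state$pos)
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), substr(state$site_name, 1, 4),
    ifelse(state$role == "C_nanotube", "CNT",
           ifelse(state$mols$state[state$molid] == "oh", "OH", "HOH")),
    state$molid %% 10000,
    state$pos[, 1], state$pos[, 2], state$pos[, 3], 1, 0,
    substr(state$element, 1, 2))
  writeLines(c(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1",
                       state$box[1], state$box[2], state$box[3]),
               lines, "END"), path)
  invisible(path)
}

#' Convert a system snapshot to a single-frame trajectory
#' @param state An `oh_system`.
#' @return An `oh_trajectory` with one frame.
#' @export
as_trajectory <- function(state) {
  new_trajectory(array(state$pos, dim = c(nrow(state$pos), 3, 1)),
                 time = state$time, box = state$box,
                 periodic = state$periodic, element = state$element,
                 role = state$role, molid = state$molid)
}

#' Read a run configuration file
#'
#' YAML with sections `system`, `engine`, `hopping`, `field`, `restraints`;
#' any subset may be present, missing values fall back to package defaults.
#'
#' @param path YAML config file.
#' @return Named list of sections.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)

#' Write a hop-event log
#'
#' Tab-separated, one row per attempt: step, donor, acceptor, ΔE and its
#' decomposition, accepted flag.
#'
#' @param events Data frame of hop events.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
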