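#' Write a configuration or trajectory in XYZ format
#'
#' Bead types are written as atom labels `LAD`/`NLD`, and lamin beads (if a
#' shell is supplied) as `LAM`, so standard molecular viewers can render
#' nucleus snapshots.
#'
#' @param traj a [run_bd()] trajectory with frames, a single N x 3 matrix,
#'   or a [chromatin_chain()].
#' @param path output file.
#' @param bead_type per-bead types; taken from the trajectory/chain when
#'   available.
#' @param shell optional [build_shell()] appended to every frame.
#' @param comment header comment (seed/config provenance).
#' @return the path, invisibly.
#' @export
write_xyz <- function(traj, path, bead_type = NULL, shell = NULL,
                      comment = "ladsim") {
  frames <- if (inherits(traj, "chromatin_chain")) {
    bead_type <- bead_type %||% traj$bead_type
    list(traj$positions)
  } else traj_frames(traj)
  if (inherits(traj, "bd_trajectory") && is.null(bead_type))
    bead_type <- traj$bead_type
  lab <- if (is.null(bead_type)) rep("CHR", nrow(frames[[1]]))
    else ifelse(bead_type == "LAD", "LAD", "NLD")
  lam <- if (!is.null(shell)) shell$lamin_positions else NULL
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames) {
    all_pos <- rbind(f, lam)
    all_lab <- c(lab, rep("LAM", if (is.null(lam)) 0 else nrow(lam)))
    writeLines(c(as.character(nrow(all_pos)), comment), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", all_lab,
                       all_pos[, 1], all_pos[, 2], all_pos[, 3]), con)
  }
  invisible(path)
}

#' Write a trajectory as LAMMPS-dump-style text
#'
#' One `ITEM:`-delimited block per frame with `id type x y z` rows
#' (type 1 = non-LAD, 2 = LAD, 3 = lamin).
#'
#' @inheritParams write_xyz
#' @return the path, invisibly.
#' @export
write_dump <- function(traj, path, bead_type = NULL, shell = NULL) {
  frames <- traj_frames(traj)
  if (inherits(traj, "bd_trajectory") && is.null(bead_type))
    bead_type <- traj$bead_type
  steps <- if (inherits(traj, "bd_trajectory")) traj$frame_steps
    else seq_along(frames) - 1L
  ty <- if (is.null(bead_type)) rep(1L, nrow(frames[[1]]))
    else ifelse(bead_type == "LAD", 2L, 1L)
  lam <- if (!is.null(shell)) shell$lamin_positions else NULL
  rc <- if (!is.null(shell)) shell$confinement_radius else
    max(abs(unlist(frames)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    pos <- rbind(frames[[i]], lam)
    tt <- c(ty, rep(3L, if (is.null(lam)) 0 else nrow(lam)))
    writeLines(c("ITEM: TIMESTEP", as.character(steps[i]),
                 "ITEM: NUMBER OF ATOMS", as.character(nrow(pos)),
                 "ITEM: BOX BOUNDS ff ff ff",
                 rep(sprintf("%.6f %.6f", -rc, rc), 3),
                 "ITEM: ATOMS id type x y z"), con)
    writeLines(sprintf("%d %d %.6f %.6f %.6f", seq_len(nrow(pos)), tt,
                       pos[, 1], pos[, 2], pos[, 3]), con)
  }
  invisible(path)
}

#' Write per-frame thermodynamic log as CSV
#'
#' Columns: step, the six energy terms (+ diagnostic trap term and total),
#' radius of gyration, bond count.
#'
#' @param traj a [run_bd()] trajectory.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_thermo <- function(traj, path) {
  df <- data.frame(step = traj$frame_steps, traj$energies,
                   rg = traj$rg, bonds = traj$bond_counts,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a classification record as JSON
#'
#' One JSON object per run: mode, wetting flag, com offset, evidence and
#' thresholds, plus any metadata supplied.
#'
#' @param call an [classify_organization()] result.
#' @param path output JSON.
#' @param meta named list of extra fields (parameters, seed, ...).
#' @return the path, invisibly.
#' @export
write_classification <- function(call, path, meta = list()) {
  rec <- c(meta, list(mode = as.character(call$mode),
                      wetting = call$wetting,
                      com_offset = call$com_offset,
                      evidence = as.list(call$evidence),
                      thresholds = as.list(call$thresholds)))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
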