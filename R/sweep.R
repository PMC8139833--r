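#' Run one full simulation at a (phi, psi, epsilon) point
#'
#' Builds the system at the requested volume fraction (the confinement
#' radius follows from `phi` via [radius_for_fraction()]), runs the
#' two-stage equilibration protocol and a production run, and classifies
#' the resulting organization mode from the radial profile and the
#' centre-of-mass offset.
#'
#' @param phi global chromatin volume fraction.
#' @param psi bondable LAD fraction.
#' @param epsilon chromatin self-attraction (kT).
#' @param n_beads chain length of the scaled-down system.  The full-scale
#'   chromosome (N = 37,333) is cluster-scale; the organization modes are
#'   controlled by the intensive parameters (phi, psi, epsilon), so the
#'   default desk-scale N = 2000 reproduces them.
#' @param seed integer seed for the whole run.
#' @param dt production (and attractive-stage) timestep, in tau.
#' @param production_steps,sampling_interval production run length and
#'   frame spacing.
#' @param n_shells radial profile resolution.
#' @param output_dir when non-`NULL`, write trajectory (`dump`),
#'   thermo CSV, profile CSV and classification JSON there.
#' @param annotation optional [lad_annotation()] for the bead typing.
#' @param mean_domain_beads mean LAD domain length of the synthetic
#'   pattern.  At full chromosome scale the domains average 150 beads
#'   (90 kbp), i.e. ~0.4% of the chain; scaled-down chains keep that
#'   relative architecture (many alternating domains) by scaling the
#'   domain length with N rather than keeping its absolute size.
#' @param ... further [equilibrate_protocol()] arguments.
#' @return a list with `call` (the [classify_organization()] result),
#'   `profile`, `com_offset`, `bond_count`, `rg`, the protocol log and
#'   (invisibly large) the production `trajectory`.
#' @export
run_single <- function(phi, psi, epsilon, n_beads = 2000L, seed = 1L,
                       dt = 5e-4, production_steps = 40000L,
                       sampling_interval = 2000L, n_shells = 30L,
                       output_dir = NULL, annotation = NULL,
                       mean_domain_beads = max(5, round(0.004 * n_beads)),
                       ...) {
  params <- sim_params(n_beads = n_beads, phi = phi, psi = psi,
                       epsilon = epsilon, rng_seed = seed)
  chain <- build_chain(params, annotation = annotation,
                       mean_domain_beads = mean_domain_beads, seed = seed)
  shell <- build_shell(params$confinement_radius)
  state <- sim_state(chain, shell, params)

  set.seed(seed + 3L)
  state <- equilibrate_protocol(state, dt_attractive = dt, ...)
  plog <- attr(state, "protocol_log")
  res <- run_bd(state, production_steps, sampling_interval = sampling_interval,
                dt = dt, max_disp = 0.25, record_frames = TRUE)
  traj <- res$trajectory

  prof <- radial_profile(traj, n_shells = n_shells)
  off <- com_offset(traj)
  call <- classify_organization(prof, com_offset = off)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    tag <- sprintf("phi%.2f_psi%.2f_eps%.2f_seed%d", phi, psi, epsilon, seed)
    write_dump(traj, file.path(output_dir, paste0(tag, ".dump")),
               shell = shell)
    write_thermo(traj, file.path(output_dir, paste0(tag, "_thermo.csv")))
    write.csv(as.data.frame(prof),
              file.path(output_dir, paste0(tag, "_profile.csv")),
              row.names = FALSE)
    write_classification(call, file.path(output_dir, paste0(tag, ".json")),
                         meta = list(phi = phi, psi = psi, epsilon = epsilon,
                                     n_beads = n_beads, seed = seed,
                                     converged = all(plog$converged)))
  }

  list(call = call, profile = prof, com_offset = off,
       bond_count = mean(traj$bond_counts),
       rg = mean(traj$rg), protocol_log = plog,
       converged = all(plog$converged), trajectory = traj,
       params = params)
}

#' State-diagram sweep over (phi, psi, epsilon)
#'
#' Runs [run_single()] for every grid point x seed combination and
#' tabulates the organization calls, plus a majority-vote consensus per
#' grid point.  With an `output_dir` the sweep is resumable: completed
#' rows found in `sweep_results.csv` are skipped and the table is
#' append-only.
#'
#' @param grid data frame with columns `phi`, `psi`, `epsilon`.
#' @param seeds integer vector of replicate seeds.
#' @param n_beads scaled chain length.
#' @param output_dir optional directory for per-run artifacts and the
#'   results table.
#' @param ... passed to [run_single()].
#' @return a list with `results` (one row per run: parameters, seed, mode,
#'   com_offset, bond count, R_g, converged/error flags) and `consensus`
#'   (majority-vote mode per grid point).
#' @export
run_sweep <- function(grid, seeds = 1L, n_beads = 2000L, output_dir = NULL,
                      ...) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1,
            all(c("phi", "psi", "epsilon") %in% names(grid)))
  if (any(grid$phi <= 0 | grid$phi > 1) || any(grid$psi < 0 | grid$psi > 1) ||
      any(grid$epsilon < 0))
    stop("invalid sweep grid: need phi in (0,1], psi in [0,1], epsilon >= 0")
  table_path <- if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    file.path(output_dir, "sweep_results.csv")
  } else NULL
  done <- if (!is.null(table_path) && file.exists(table_path))
    read.table(table_path, header = TRUE, sep = ",") else NULL

  rows <- list()
  for (g in seq_len(nrow(grid))) for (s in seeds) {
    key <- c(grid$phi[g], grid$psi[g], grid$epsilon[g], s)
    if (!is.null(done) &&
        any(abs(done$phi - key[1]) < 1e-9 & abs(done$psi - key[2]) < 1e-9 &
            abs(done$epsilon - key[3]) < 1e-9 & done$seed == key[4])) next
    row <- tryCatch({
      r <- run_single(grid$phi[g], grid$psi[g], grid$epsilon[g],
                      n_beads = n_beads, seed = s,
                      output_dir = output_dir, ...)
      data.frame(phi = key[1], psi = key[2], epsilon = key[3], seed = s,
                 mode = as.character(r$call$mode), wetting = r$call$wetting,
                 com_offset = r$com_offset, bonds = r$bond_count,
                 rg = r$rg, converged = r$converged, error = "")
    }, error = function(e)
      data.frame(phi = key[1], psi = key[2], epsilon = key[3], seed = s,
                 mode = NA_character_, wetting = NA, com_offset = NA_real_,
                 bonds = NA_real_, rg = NA_real_, converged = FALSE,
                 error = conditionMessage(e)))
    rows[[length(rows) + 1]] <- row
    if (!is.null(table_path))
      write.table(row, table_path, sep = ",", row.names = FALSE,
                  col.names = !file.exists(table_path), append = TRUE)
  }
  results <- rbind(done, do.call(rbind, c(rows, list(NULL))))
  if (is.null(results) || !nrow(results)) stop("empty sweep")

  consensus <- do.call(rbind, lapply(
    split(results, interaction(results$phi, results$psi, results$epsilon,
                               drop = TRUE)),
    function(d) {
      tab <- table(d$mode[!is.na(d$mode)])
      data.frame(phi = d$phi[1], psi = d$psi[1], epsilon = d$epsilon[1],
                 mode = if (length(tab)) names(which.max(tab)) else NA,
                 n_runs = nrow(d))
    }))
  rownames(consensus) <- NULL
  list(results = results, consensus = consensus)
}
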