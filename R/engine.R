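#' Simulation state
#'
#' Bundles the chain, lamina shell, current bond set, parameter set and
#' step counter.
#'
#' @param chain a [chromatin_chain()].
#' @param shell a [build_shell()] lamina; `NULL` for unconfined systems.
#' @param params a [sim_params()].
#' @param bonds an initial [bond_set()]; empty by default.
#' @return an object of class `sim_state`.
#' @export
sim_state <- function(chain, shell = NULL, params, bonds = bond_set(chain)) {
  if (is.null(shell)) shell <- no_shell()
  structure(list(chain = chain, shell = shell, bonds = bonds,
                 params = params, step = 0L),
            class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> step %d | N = %d | %d bond(s)\n",
              x$step, x$chain$n_beads, bond_count(x$bonds)))
  invisible(x)
}

#' Brownian-dynamics trajectory
#'
#' Frames recorded by [run_bd()]: positions (optional), step numbers,
#' radius of gyration, bond counts and the energy breakdown per frame.
#' @name bd_trajectory
NULL

#' @export
print.bd_trajectory <- function(x, ...) {
  cat(sprintf("<bd_trajectory> %d frame(s), steps %d..%d, dt = %g tau\n",
              length(x$frame_steps), min(x$frame_steps), max(x$frame_steps),
              x$dt))
  invisible(x)
}

#' Advance the simulation by Brownian-dynamics steps
#'
#' Overdamped Langevin update per bead:
#' `r(t+dt) = r(t) - (dt/gamma) grad E + noise`, with thermal noise of
#' per-component variance `2 kT dt / gamma` (Gaussian by default; the
#' `"uniform"` option draws `sqrt(6 kT dt/gamma) * xi` with `xi` uniform in
#' \[-1, 1\], which has the same second moment).  Lamin beads never move.
#' After each step the LAD-lamina bond set is updated (see
#' [update_bonds()]).  Chromatin pair interactions are evaluated with a
#' cell-list neighbour search; `use_cells = FALSE` selects the all-pairs
#' reference path.
#'
#' A step that would displace a bead by more than `sigma/2` raises an
#' `unstable-timestep` error unless displacements are capped via
#' `max_disp` (the soft push-off mode used to relax overlapping initial
#' configurations).
#'
#' @param state a [sim_state()].
#' @param n_steps number of steps (>= 1).
#' @param sampling_interval record a frame every this many steps.
#' @param dt timestep in tau; defaults to the parameter set's `timestep`.
#'   Production runs of the dense confined systems use smaller steps than
#'   the nominal 0.01 tau for stability of the position-only update (see
#'   the methods vignette).
#' @param noise `"gaussian"` (default), `"uniform"`, or `"none"`.
#' @param attract use attractive chromatin-chromatin cutoff (default) or
#'   repulsive-only.
#' @param max_disp displacement cap in sigma (0 = off, hard guard active).
#' @param bond_every attempt bond updates every this many steps.
#' @param use_cells cell-list (default) vs all-pairs evaluation.
#' @param record_frames keep full position frames (default TRUE).
#' @param trap_k diagnostic external harmonic trap `k r^2` (default 0).
#' @return a list with the advanced `state` and the `trajectory`
#'   (class `bd_trajectory`).
#' @export
run_bd <- function(state, n_steps, sampling_interval = 1000L,
                   dt = NULL, noise = "gaussian", attract = TRUE,
                   max_disp = 0, bond_every = 1L, use_cells = TRUE,
                   record_frames = TRUE, trap_k = 0) {
  stopifnot(inherits(state, "sim_state"), n_steps >= 1)
  params <- state$params
  if (is.null(dt)) dt <- params$timestep
  if (dt > 0.01 * params$damping + 1e-15)
    stop("unstable-timestep: dt must not exceed 0.01 tau")
  sys <- as_engine_system(state$chain, state$shell, state$bonds)
  par <- engine_par(params, attract = attract, dt = dt, noise = noise,
                    max_disp = max_disp, bond_every = bond_every,
                    use_cells = use_cells, trap_k = trap_k,
                    confined = sys$confined)
  res <- cpp_run(sys$pos, sys$type, sys$bondable, sys$bond, sys$lam, par,
                 as.integer(n_steps), as.integer(sampling_interval),
                 record_frames)
  state$chain$positions <- res$positions
  state$bonds <- structure(
    ifelse(res$bond < 0L, NA_integer_, res$bond + 1L), class = "bond_set")
  traj <- structure(list(
    frames = if (record_frames) res$frames else NULL,
    frame_steps = res$frame_steps + state$step,
    rg = res$rg,
    bond_counts = res$bond_counts,
    energies = res$energies,
    sampling_interval = as.integer(sampling_interval),
    dt = dt,
    bead_type = state$chain$bead_type,
    confinement_radius = state$shell$confinement_radius,
    bead_diameter = params$bead_diameter,
    n_break = res$n_break, n_form = res$n_form,
    n_capped = res$n_capped),
    class = "bd_trajectory")
  state$step <- state$step + as.integer(n_steps)
  list(state = state, trajectory = traj)
}

#' Single Langevin step
#'
#' One overdamped update of every chromatin bead followed by a bond-update
#' pass; see [run_bd()] for the scheme and arguments.
#'
#' @inheritParams run_bd
#' @param ... passed to [run_bd()].
#' @return the advanced [sim_state()].
#' @export
langevin_step <- function(state, ...) {
  run_bd(state, n_steps = 1L, sampling_interval = 1L,
         record_frames = FALSE, ...)$state
}

#' Two-stage equilibration protocol
#'
#' Stage `pushoff`: short run with displacements capped at `pushoff_cap`
#' and purely repulsive chromatin interactions, removing the overlaps of
#' the random-walk initial configuration.  Stage `repulsive`: chromatin-
#' chromatin interactions restricted to the excluded-volume core while the
#' lamin LJ attraction and LAD bonding are active; run until the windowed
#' mean radius of gyration plateaus.  Stage `attractive`: the configured
#' self-attraction (cutoff 2.5 sigma) is switched on and the system
#' re-equilibrates to a second plateau.  The plateau criterion is a
#' relative change of the windowed mean R_g below `tol` over two
#' consecutive windows.
#'
#' @param state a freshly initialized [sim_state()].
#' @param dt timestep for the repulsive stage; the attractive stage runs at
#'   `dt_attractive` (contact statistics of the self-attracting dense phase
#'   need the smaller step; see the methods vignette).
#' @param dt_attractive timestep of the attractive stage.
#' @param max_disp displacement limiter applied during both plateau stages.
#' @param pushoff_steps steps of the capped push-off stage.
#' @param pushoff_cap displacement cap during push-off (sigma).
#' @param window steps per plateau window.
#' @param sample_every R_g sampling interval within windows.
#' @param tol relative plateau tolerance (default 1%).
#' @param max_windows per stage; a `non-convergence` warning is raised if
#'   no plateau is reached (the state is still returned).
#' @return the equilibrated `sim_state`, with a `protocol_log` attribute
#'   recording the stages (`pushoff`, `repulsive`, `attractive`), their
#'   step counts and final R_g.
#' @export
equilibrate_protocol <- function(state, dt = 1e-3, dt_attractive = 5e-4,
                                 max_disp = 0.25, pushoff_steps = 2000L,
                                 pushoff_cap = 0.05, window = 10000L,
                                 sample_every = 500L, tol = 0.01,
                                 max_windows = 30L) {
  log <- list()
  res <- run_bd(state, pushoff_steps, sampling_interval = pushoff_steps,
                dt = dt, attract = FALSE, max_disp = pushoff_cap,
                record_frames = FALSE)
  state <- res$state
  log[[1]] <- data.frame(stage = "pushoff", steps = pushoff_steps,
                         rg = tail(res$trajectory$rg, 1))

  run_stage <- function(state, stage, attract, dt_stage) {
    means <- numeric(0)
    converged <- FALSE
    used <- 0L
    for (w in seq_len(max_windows)) {
      res <- run_bd(state, window, sampling_interval = sample_every,
                    dt = dt_stage, attract = attract, max_disp = max_disp,
                    record_frames = FALSE)
      state <- res$state
      used <- used + as.integer(window)
      means <- c(means, mean(res$trajectory$rg[-1]))
      k <- length(means)
      if (k >= 3 &&
          abs(means[k] - means[k - 1]) / means[k - 1] < tol &&
          abs(means[k - 1] - means[k - 2]) / means[k - 2] < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged)
      warning("non-convergence: no R_g plateau in stage '", stage,
              "' within ", max_windows, " windows")
    list(state = state,
         row = data.frame(stage = stage, steps = used,
                          rg = tail(means, 1), converged = converged))
  }

  s1 <- run_stage(state, "repulsive", attract = FALSE, dt_stage = dt)
  s2 <- run_stage(s1$state, "attractive", attract = TRUE,
                  dt_stage = dt_attractive)
  log[[1]]$converged <- TRUE
  out <- s2$state
  attr(out, "protocol_log") <- rbind(log[[1]], s1$row, s2$row)
  out
}
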