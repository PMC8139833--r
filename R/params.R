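#' Simulation parameters in reduced units
#'
#' Collects every model constant of the chromatin-lamina simulation in one
#' validated container.  Internally the package works in reduced units:
#' bead diameter `sigma = 1`, thermal energy `kT = 1`, damping time
#' `tau = 1`.  The SI mapping (sigma = 10 nm, kT = 4.1e-21 J, tau = 2 us at
#' water viscosity) is applied only at input/output.
#'
#' The defaults are the standard parameter set of the model: one bead per
#' 600 bp, spring constant `k_s = 100 kT/sigma^2` with rest length `sigma`,
#' bending stiffness `k_b = 2 kT` (persistence length `2 sigma`), attractive
#' Lennard-Jones cutoff `2.5 sigma` (repulsive-only cutoff `2^(1/6) sigma`),
#' LAD-lamin bond spring `k_bond = 10 kT/sigma^2` with formation/zero-energy
#' distance `r_b = 2.5 sigma` and bond energy `U_bond = 10 kT`, lamin LJ
#' strengths `eps_lm = eps_ln = 1 kT`, and timestep `0.01 tau`.
#'
#' @param n_beads number of chromatin beads N.
#' @param phi global chromatin volume fraction; used to derive the
#'   confinement radius when `confinement_radius` is not given.
#' @param confinement_radius nucleus radius R_c in sigma units; overrides
#'   `phi`.  Use `NULL` together with `phi = NULL` for an unconfined chain.
#' @param epsilon chromatin-chromatin LJ strength in kT.  Either a scalar
#'   (the same for all bead-type pairs) or a symmetric 2x2 matrix indexed
#'   (non-LAD, LAD) for type-specific attractions.
#' @param psi fraction of LAD beads allowed to bond to the lamina, in [0,1].
#' @param bead_diameter bead diameter sigma (reduced unit 1).
#' @param bp_per_bead base pairs represented by one bead.
#' @param cutoff_attractive attractive LJ cutoff r_c.
#' @param spring_constant chain spring constant k_s.
#' @param rest_length spring rest length 2a (touching beads: sigma).
#' @param bending_stiffness bending prefactor k_b in kT.
#' @param kbond,ubond,r_bond LAD-lamin bond spring constant, bond energy
#'   controlling the break probability `exp(-ubond/kT)`, and the distance
#'   below which bonds form (also the zero of the bond energy).
#' @param eps_lad_lamin,eps_nonlad_lamin lamin LJ strength seen by LAD beads
#'   (attractive, cutoff 2.5 sigma) and by non-LAD beads (repulsive-only,
#'   cutoff 2^(1/6) sigma).
#' @param damping damping time gamma*m expressed as a time (tau).
#' @param timestep integration timestep in tau.
#' @param thermal_energy kT in reduced units.
#' @param rng_seed integer seed recorded with the parameters.
#' @return an object of class `sim_params` (a validated named list with the
#'   derived fields `cutoff_repulsive = 2^(1/6) sigma`, `epsilon_matrix`,
#'   `persistence_length = bending_stiffness * sigma / kT` and, when
#'   confined, `confinement_radius`).
#' @examples
#' p <- sim_params(n_beads = 500, phi = 0.3)
#' p$confinement_radius
#' @export
sim_params <- function(n_beads,
                       phi = NULL,
                       confinement_radius = NULL,
                       epsilon = 1,
                       psi = 1,
                       bead_diameter = 1,
                       bp_per_bead = 600,
                       cutoff_attractive = 2.5 * bead_diameter,
                       spring_constant = 100,
                       rest_length = bead_diameter,
                       bending_stiffness = 2,
                       kbond = 10,
                       ubond = 10,
                       r_bond = 2.5 * bead_diameter,
                       eps_lad_lamin = 1,
                       eps_nonlad_lamin = 1,
                       damping = 1,
                       timestep = 0.01,
                       thermal_energy = 1,
                       rng_seed = 1L) {
  stopifnot(n_beads >= 0, bp_per_bead > 0)
  if (psi < 0 || psi > 1) stop("psi must lie in [0, 1]")
  for (nm in c("bead_diameter", "cutoff_attractive", "rest_length", "r_bond",
               "damping", "timestep", "thermal_energy")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0)
      stop("invalid parameter: ", nm, " must be a positive scalar")
  }
  if (is.matrix(epsilon)) {
    if (!all(dim(epsilon) == c(2L, 2L)) ||
        !isTRUE(all.equal(epsilon, t(epsilon))) || any(epsilon < 0))
      stop("epsilon matrix must be symmetric, 2x2 and non-negative")
    eps_mat <- epsilon
  } else {
    if (length(epsilon) != 1L || epsilon < 0)
      stop("epsilon must be a non-negative scalar or a 2x2 matrix")
    eps_mat <- matrix(epsilon, 2, 2)
  }
  dimnames(eps_mat) <- list(c("nonLAD", "LAD"), c("nonLAD", "LAD"))

  if (is.null(confinement_radius) && !is.null(phi))
    confinement_radius <- radius_for_fraction(n_beads, bead_diameter, phi)
  if (!is.null(confinement_radius) && confinement_radius <= 0)
    stop("invalid parameter: confinement_radius must be positive")

  p <- list(
    n_beads = as.integer(n_beads),
    bead_diameter = bead_diameter,
    bp_per_bead = as.integer(bp_per_bead),
    epsilon_matrix = eps_mat,
    cutoff_attractive = cutoff_attractive,
    cutoff_repulsive = 2^(1 / 6) * bead_diameter,
    spring_constant = spring_constant,
    rest_length = rest_length,
    bending_stiffness = bending_stiffness,
    persistence_length = bending_stiffness * bead_diameter / thermal_energy,
    kbond = kbond,
    ubond = ubond,
    r_bond = r_bond,
    eps_lad_lamin = eps_lad_lamin,
    eps_nonlad_lamin = eps_nonlad_lamin,
    psi = psi,
    confinement_radius = confinement_radius,
    phi = if (!is.null(confinement_radius))
      global_volume_fraction(n_beads, bead_diameter, confinement_radius)
      else NA_real_,
    damping = damping,
    timestep = timestep,
    thermal_energy = thermal_energy,
    rng_seed = as.integer(rng_seed)
  )
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> N =", x$n_beads,
      if (!is.null(x$confinement_radius))
        sprintf("| R_c = %.3g sigma (phi = %.3g)", x$confinement_radius, x$phi)
      else "| unconfined",
      sprintf("| eps = %.3g kT | psi = %.3g", x$epsilon_matrix[2, 2], x$psi),
      "\n")
  invisible(x)
}

#' Global chromatin volume fraction
#'
#' The volume of the chain (N spheres of diameter sigma) divided by the
#' volume of the spherical nucleus: `phi = N (sigma/2)^3 / R_c^3`.
#'
#' @param n_beads number of beads N.
#' @param bead_diameter bead diameter sigma (any length unit).
#' @param confinement_radius nucleus radius R_c (same unit).
#' @return the volume fraction (may exceed 1 for infeasible geometries;
#'   callers may reject such values).
#' @examples
#' global_volume_fraction(37333, 10, 210)  # ~0.5
#' @export
global_volume_fraction <- function(n_beads, bead_diameter, confinement_radius) {
  if (any(bead_diameter <= 0) || any(confinement_radius <= 0))
    stop("invalid parameter: bead_diameter and confinement_radius must be > 0")
  if (any(n_beads < 0)) stop("invalid parameter: n_beads must be >= 0")
  n_beads * (bead_diameter / 2)^3 / confinement_radius^3
}

#' Confinement radius for a target volume fraction
#'
#' Inverse of [global_volume_fraction()]: the radius at which N beads of a
#' given diameter occupy the volume fraction `phi`.
#'
#' @inheritParams global_volume_fraction
#' @param phi target volume fraction, in (0, 1].
#' @return the confinement radius in the unit of `bead_diameter`.
#' @export
radius_for_fraction <- function(n_beads, bead_diameter, phi) {
  if (any(phi <= 0)) stop("invalid parameter: phi must be > 0")
  if (any(bead_diameter <= 0)) stop("invalid parameter: bead_diameter must be > 0")
  (n_beads / phi)^(1 / 3) * bead_diameter / 2
}

#' Damping time of a bead in a viscous solvent
#'
#' The Stokes-like damping time `3 pi eta sigma^3 / kT` that defines the
#' reduced time unit tau.  With water viscosity (1 mPa s), a 10 nm bead and
#' kT = 4.1e-21 J this is about 2 microseconds.
#'
#' @param viscosity solvent viscosity eta (Pa s).
#' @param bead_diameter bead diameter sigma (m).
#' @param thermal_energy kT (J).
#' @return the damping time in seconds.
#' @examples
#' damping_time(1e-3, 10e-9, 4.1e-21)  # ~2.3e-6 s
#' @export
damping_time <- function(viscosity, bead_diameter, thermal_energy) {
  if (any(viscosity < 0) || any(bead_diameter <= 0) || any(thermal_energy <= 0))
    stop("invalid parameter: arguments must be positive (viscosity >= 0)")
  3 * pi * viscosity * bead_diameter^3 / thermal_energy
}

#' Number of beads representing a base-pair length
#'
#' Truncating division: a trailing partial bead is dropped, so 22.4 Mbp at
#' 600 bp/bead maps to 37,333 beads.
#'
#' @param bp_length sequence length in bp.
#' @param bp_per_bead base pairs per bead.
#' @return integer bead count.
#' @export
beads_for_sequence <- function(bp_length, bp_per_bead) {
  if (any(bp_per_bead <= 0)) stop("invalid parameter: bp_per_bead must be > 0")
  if (any(bp_length < 0)) stop("invalid parameter: bp_length must be >= 0")
  as.integer(bp_length %/% bp_per_bead)
}

#' Read simulation parameters from a JSON config file
#'
#' Every constructor argument of [sim_params()] is a recognized key; keys
#' that are absent keep their defaults.
#'
#' @param path path to a JSON file of `key: value` pairs.
#' @return a [sim_params()] object.
#' @export
read_params <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_params, cfg)
}

# internal: flat parameter list handed to the compiled engine
engine_par <- function(params,
                       attract = TRUE,
                       dt = NULL,
                       noise = c("gaussian", "uniform", "none"),
                       max_disp = 0,
                       bond_every = 1L,
                       use_cells = TRUE,
                       trap_k = 0,
                       confined = !is.null(params$confinement_radius)) {
  noise <- match.arg(noise)
  list(
    sigma = params$bead_diameter,
    eps_matrix = params$epsilon_matrix,
    chrom_cutoff = if (attract) params$cutoff_attractive else params$cutoff_repulsive,
    ks = params$spring_constant,
    rest = params$rest_length,
    kb = params$bending_stiffness,
    Rc = if (confined) params$confinement_radius else -1,
    eps_wall = 1,
    eps_lm = params$eps_lad_lamin,
    eps_ln = params$eps_nonlad_lamin,
    cut_lm = params$cutoff_attractive,
    kbond = params$kbond,
    ubond = params$ubond,
    rbond = params$r_bond,
    dt = if (is.null(dt)) params$timestep else dt,
    gamma = params$damping,
    kT = params$thermal_energy,
    trap_k = trap_k,
    noise = match(noise, c("none", "gaussian", "uniform")) - 1L,
    max_disp = max_disp,
    bond_every = as.integer(bond_every),
    use_cells = use_cells
  )
}

# internal: run code with a temporarily-seeded RNG, restoring global state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
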