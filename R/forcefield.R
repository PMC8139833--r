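#' Truncated-and-shifted Lennard-Jones pair interaction
#'
#' Energy `4 eps [(sigma/r)^12 - (sigma/r)^6]`, shifted so it is continuous
#' (zero) at the cutoff, and the magnitude of the corresponding pair force
#' `24 eps [2 (sigma/r)^12 - (sigma/r)^6] / r` (positive = repulsive).  The
#' force is the unshifted analytic derivative; both vanish identically
#' beyond the cutoff.  With cutoff `2^(1/6) sigma` this is the purely
#' repulsive (WCA) core used for self-avoiding chains.
#'
#' @param r pair distance(s), > 0.
#' @param eps interaction strength in kT.
#' @param sigma bead diameter.
#' @param cutoff truncation distance.
#' @return a list with vectors `energy` and `force`.
#' @examples
#' lj_pair(2^(1/6), 1, 1, 2.5)$force  # 0 at the potential minimum
#' @export
lj_pair <- function(r, eps, sigma = 1, cutoff = 2.5 * sigma) {
  if (any(r <= 0)) stop("singular-overlap: r must be > 0")
  sr6 <- (sigma / r)^6
  shift <- local({
    s6 <- (sigma / cutoff)^6
    4 * eps * (s6^2 - s6)
  })
  inside <- r < cutoff
  energy <- ifelse(inside, 4 * eps * (sr6^2 - sr6) - shift, 0)
  force <- ifelse(inside, 24 * eps * (2 * sr6^2 - sr6) / r, 0)
  list(energy = energy, force = force)
}

#' Chain stretching and bending energies
#'
#' Stretching: `sum_i k_s (r_i - 2a)^2` over the N-1 springs, where `r_i`
#' is the distance between consecutive beads and `2a` the rest length.
#' Bending: `sum_i k_b (1 - cos theta_i)` over the N-2 internal angles,
#' with `theta` the angle between successive bond vectors (zero for a
#' straight chain), which gives persistence length `l_p = k_b sigma / kT`
#' in the stiff limit.
#'
#' @param positions N x 3 matrix (N >= 2).
#' @param spring_constant k_s in kT/sigma^2.
#' @param rest_length rest length 2a.
#' @param bending_stiffness k_b in kT.
#' @return a named numeric vector `c(stretch = , bend = )`.
#' @export
bonded_terms <- function(positions, spring_constant = 100, rest_length = 1,
                         bending_stiffness = 2) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n >= 2)
  b <- diff(positions)
  len <- sqrt(rowSums(b^2))
  if (any(len < 1e-12))
    stop("singular-angle: coincident consecutive beads")
  stretch <- sum(spring_constant * (len - rest_length)^2)
  bend <- 0
  if (n >= 3) {
    dot <- rowSums(b[-nrow(b), , drop = FALSE] * b[-1, , drop = FALSE])
    cosang <- pmin(1, pmax(-1, dot / (len[-length(len)] * len[-1])))
    bend <- sum(bending_stiffness * (1 - cosang))
  }
  c(stretch = stretch, bend = bend)
}

#' Total potential energy, broken down by term
#'
#' Evaluates the six contributions of the model Hamiltonian: chain
#' stretching and bending, chromatin-chromatin LJ (pair-type-dependent
#' epsilon, attractive cutoff `2.5 sigma` or repulsive-only
#' `2^(1/6) sigma`), the continuum wall repulsion on the gap to the
#' envelope, the lamin-bead LJ (attractive for LAD, repulsive for
#' non-LAD), and the LAD-lamin bond springs
#' `-k_bond (r_b - sigma)^2 + k_bond (r - sigma)^2`.
#'
#' @param chain a [chromatin_chain()].
#' @param shell a [build_shell()] lamina (or `no_shell()` when unconfined).
#' @param bonds a [bond_set()] (per-bead lamin index or `NA`).
#' @param params a [sim_params()].
#' @param attract use the attractive chromatin-chromatin cutoff (`TRUE`,
#'   default) or the repulsive-only cutoff.
#' @param use_cells evaluate pairs with the cell-list search (default) or
#'   the all-pairs path (for cross-checking).
#' @return an `energy_breakdown`: named vector with the six terms, `trap`
#'   (diagnostic external trap, normally 0) and their sum `total`.
#' @export
total_energy <- function(chain, shell, bonds = bond_set(chain), params,
                         attract = TRUE, use_cells = TRUE) {
  sys <- as_engine_system(chain, shell, bonds)
  par <- engine_par(params, attract = attract, use_cells = use_cells,
                    confined = sys$confined)
  e <- cpp_energy(sys$pos, sys$type, sys$bondable, sys$bond, sys$lam, par)
  class(e) <- c("energy_breakdown", class(e))
  e
}

#' Forces on every chromatin bead
#'
#' Minus the gradient of [total_energy()] with respect to each bead
#' position.  Lamin beads are static and receive no force.
#'
#' @inheritParams total_energy
#' @return an N x 3 matrix of force vectors (kT/sigma).
#' @export
forces <- function(chain, shell, bonds = bond_set(chain), params,
                   attract = TRUE, use_cells = TRUE) {
  sys <- as_engine_system(chain, shell, bonds)
  par <- engine_par(params, attract = attract, use_cells = use_cells,
                    confined = sys$confined)
  cpp_forces(sys$pos, sys$type, sys$bondable, sys$bond, sys$lam, par)
}

# internal: translate R containers into the compiled engine's arrays
as_engine_system <- function(chain, shell, bonds) {
  confined <- !is.na(shell$confinement_radius) &&
    nrow(shell$lamin_positions) >= 0 && !is.na(shell$confinement_radius)
  bond <- as.integer(ifelse(is.na(bonds), -1L, bonds - 1L))
  list(pos = chain$positions,
       type = as.integer(chain$bead_type == "LAD"),
       bondable = as.integer(chain$bondable),
       bond = bond,
       lam = shell$lamin_positions,
       confined = !is.na(shell$confinement_radius))
}
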