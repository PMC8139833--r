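#' LAD-lamin bond set
#'
#' The current dynamic bonds, stored as a per-bead integer vector: entry
#' `i` is the (1-based) index of the lamin bead bonded to chromatin bead
#' `i`, or `NA` when unbonded.  Each LAD bead holds at most one bond, so
#' the bond count can never exceed `round(psi * n_LAD)`.
#'
#' @param chain a [chromatin_chain()].
#' @param pairs optional two-column matrix `(bead_index, lamin_index)` of
#'   initial bonds (1-based).
#' @return an object of class `bond_set`.
#' @export
bond_set <- function(chain, pairs = NULL) {
  b <- rep(NA_integer_, chain$n_beads)
  if (!is.null(pairs) && nrow(pairs)) {
    pairs <- matrix(as.integer(pairs), ncol = 2)
    if (anyDuplicated(pairs[, 1]))
      stop("corrupted-state: more than one bond on a LAD bead")
    if (!all(chain$bondable[pairs[, 1]]))
      stop("corrupted-state: bond on a non-bondable bead")
    b[pairs[, 1]] <- pairs[, 2]
  }
  structure(b, class = "bond_set")
}

#' @export
print.bond_set <- function(x, ...) {
  cat(sprintf("<bond_set> %d bond(s) over %d beads\n",
              sum(!is.na(x)), length(x)))
  invisible(x)
}

#' Count of current LAD-lamin bonds
#' @param bonds a [bond_set()].
#' @return integer bond count.
#' @export
bond_count <- function(bonds) sum(!is.na(bonds))

#' Shifted-harmonic LAD-lamin bond energy
#'
#' `E = -k_bond (r_b - sigma)^2 + k_bond (r - sigma)^2`: zero at the
#' formation distance `r = r_b`, minimal (`-k_bond (r_b - sigma)^2`) at
#' contact `r = sigma`.
#'
#' @param r LAD-lamin distance(s).
#' @param kbond bond spring constant (kT/sigma^2).
#' @param sigma bead diameter (equilibrium bond length).
#' @param r_bond formation/zero-energy distance r_b.
#' @return bond energy in kT.
#' @examples
#' bond_energy(2.5)  # 0 at r_b
#' @export
bond_energy <- function(r, kbond = 10, sigma = 1, r_bond = 2.5 * sigma) {
  -kbond * (r_bond - sigma)^2 + kbond * (r - sigma)^2
}

#' One dynamic bond update pass
#'
#' First the breaking pass: every existing bond whose current length
#' exceeds `r_b` is deleted with the Boltzmann probability
#' `exp(-U_bond/kT)` (bonds shorter than `r_b` never break).  Then the
#' formation pass: every unbonded, bondable LAD bead with at least one
#' lamin bead within `r_b` bonds to the nearest such lamin bead (exact
#' distance ties go to the lowest lamin index).
#'
#' @param chain a [chromatin_chain()].
#' @param shell a [build_shell()] lamina.
#' @param bonds the current [bond_set()].
#' @param params a [sim_params()].
#' @return the updated `bond_set`.  Uses R's RNG stream (seed with
#'   `set.seed` for reproducibility).
#' @export
update_bonds <- function(chain, shell, bonds, params) {
  sys <- as_engine_system(chain, shell, bonds)
  par <- engine_par(params, confined = TRUE)
  nb <- cpp_update_bonds(sys$pos, sys$type, sys$bondable, sys$bond, sys$lam,
                         par)
  structure(ifelse(nb < 0L, NA_integer_, nb + 1L), class = "bond_set")
}
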