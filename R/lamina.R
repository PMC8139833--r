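#' Static lamin-bead shell on the confinement sphere
#'
#' Places `M ~ 4 pi R_c^2 / spacing^2` lamin beads on the sphere of radius
#' `R_c` by a Fibonacci (golden-angle) lattice, a deterministic
#' near-uniform covering.  Lamin beads never move and do not interact with
#' each other; they carry the LAD/non-LAD Lennard-Jones interactions and
#' the LAD bonds.  Hard-wall confinement itself is enforced by the
#' continuum wall potential (see [total_energy()]), not by these beads.
#'
#' @param confinement_radius nucleus radius R_c (sigma units).
#' @param surface_spacing target nearest-neighbour spacing; the default of
#'   one bead diameter guarantees every LAD bead near the wall has a lamin
#'   bead within bonding range.
#' @return an object of class `lamina_shell` with fields `lamin_positions`
#'   (M x 3), `confinement_radius`, `surface_spacing`.
#' @export
build_shell <- function(confinement_radius, surface_spacing = 1) {
  if (surface_spacing <= 0)
    stop("invalid parameter: surface_spacing must be > 0")
  if (confinement_radius <= surface_spacing)
    stop("invalid parameter: confinement_radius must exceed surface_spacing")
  m <- max(4L, round(4 * pi * confinement_radius^2 / surface_spacing^2))
  i <- seq_len(m) - 1
  z <- 1 - (2 * i + 1) / m
  theta <- pi * (3 - sqrt(5)) * i  # golden angle
  rxy <- sqrt(pmax(0, 1 - z^2))
  pos <- confinement_radius *
    cbind(x = rxy * cos(theta), y = rxy * sin(theta), z = z)
  structure(list(lamin_positions = pos,
                 confinement_radius = confinement_radius,
                 surface_spacing = surface_spacing),
            class = "lamina_shell")
}

#' @export
print.lamina_shell <- function(x, ...) {
  cat(sprintf("<lamina_shell> M = %d lamin beads | R_c = %.3g sigma\n",
              nrow(x$lamin_positions), x$confinement_radius))
  invisible(x)
}

#' Distance from a bead to the nuclear wall
#'
#' The gap `R_c - |r|` to the nearest point of the spherical envelope; the
#' wall repulsion acts on this gap and vanishes for gaps beyond
#' `2^(1/6) sigma`.
#'
#' @param position a 3-vector or an N x 3 matrix of positions.
#' @param confinement_radius nucleus radius R_c.
#' @return the gap(s); an error is raised for beads outside the sphere
#'   (which signals integrator blow-up).
#' @export
wall_gap <- function(position, confinement_radius) {
  pos <- if (is.matrix(position)) position else matrix(position, ncol = 3)
  gap <- confinement_radius - sqrt(rowSums(pos^2))
  if (any(gap < 0))
    stop("escaped-bead: position outside the confinement sphere")
  gap
}

# internal: an empty shell stand-in for unconfined systems
no_shell <- function() {
  structure(list(lamin_positions = matrix(numeric(0), 0, 3),
                 confinement_radius = NA_real_, surface_spacing = NA_real_),
            class = "lamina_shell")
}
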