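#' Radial chromatin volume-fraction profile
#'
#' Bins bead centres into `n_shells` concentric shells of equal thickness
#' and converts counts to a local volume fraction
#' `phi(r) = (beads in shell) * v_bead / V_shell`, averaged over frames.
#' Radii are normalized so `r = 1` is the nuclear envelope.  The
#' volume-weighted mean of `phi(r)` recovers the global volume fraction.
#'
#' @param traj a [run_bd()] trajectory with recorded frames, or a list of
#'   N x 3 position matrices.
#' @param confinement_radius nucleus radius (defaults to the trajectory's).
#' @param n_shells number of shells (>= 5).
#' @param bead_diameter bead diameter sigma.
#' @return an object of class `radial_profile`: data frame columns
#'   `shell_center` (r/R_c), `phi_local`, plus attributes `n_frames`,
#'   `global_phi`.
#' @export
radial_profile <- function(traj, confinement_radius = NULL, n_shells = 30L,
                           bead_diameter = NULL) {
  frames <- traj_frames(traj)
  if (!length(frames)) stop("invalid-input: empty trajectory")
  stopifnot(n_shells >= 5)
  if (is.null(confinement_radius))
    confinement_radius <- attr(frames, "confinement_radius")
  if (is.null(bead_diameter))
    bead_diameter <- attr(frames, "bead_diameter") %||% 1
  if (is.null(confinement_radius) || is.na(confinement_radius))
    stop("invalid-input: confinement_radius required")

  edges <- seq(0, 1, length.out = n_shells + 1)
  vol <- (4 / 3) * pi * confinement_radius^3 * diff(edges^3)
  vbead <- (4 / 3) * pi * (bead_diameter / 2)^3
  counts <- matrix(0, length(frames), n_shells)
  for (f in seq_along(frames)) {
    rr <- sqrt(rowSums(frames[[f]]^2)) / confinement_radius
    rr[rr >= 1] <- 1 - 1e-12
    counts[f, ] <- tabulate(findInterval(rr, edges, rightmost.closed = TRUE),
                            nbins = n_shells)
  }
  phi <- colMeans(counts) * vbead / vol
  n <- nrow(frames[[1]])
  out <- data.frame(shell_center = (edges[-1] + edges[-length(edges)]) / 2,
                    phi_local = phi)
  structure(out,
            n_frames = length(frames),
            n_beads = n,
            confinement_radius = confinement_radius,
            bead_diameter = bead_diameter,
            global_phi = n * vbead / ((4 / 3) * pi * confinement_radius^3),
            class = c("radial_profile", "data.frame"))
}

#' @export
plot.radial_profile <- function(x, ...) {
  plot(x$shell_center, x$phi_local, type = "b", pch = 16,
       xlab = "r / R_c", ylab = expression(phi(r)), ...)
  abline(h = attr(x, "global_phi"), lty = 2, col = "grey50")
  invisible(x)
}

#' Classify the nuclear organization mode
#'
#' Diagnoses peripheral, conventional or central organization from the
#' radial profile: peripheral when the profile peaks in the outer fifth of
#' the nucleus (`r > peak_outer`) and the inner half is depleted below
#' `inner_frac` of the peak; central when the peak sits at `r <
#' peak_inner` and the outermost shell is below `outer_frac` of the peak,
#' or when an off-centre condensate is flagged by the centre-of-mass
#' offset (`com_offset > wetting_com`, the wetting-droplet diagnostic —
#' such droplets are grouped with the central class); conventional
#' otherwise.  The call is invariant under rescaling of the profile.
#'
#' @param profile a [radial_profile()].
#' @param com_offset chain centre-of-mass distance from the nuclear
#'   centre, as a fraction of R_c.
#' @param peak_outer,peak_inner,inner_frac,outer_frac,wetting_com
#'   classification thresholds (defaults 0.8, 0.6, 0.10, 0.50, 0.15).
#' @param smooth apply a volume-weighted 3-shell moving average before
#'   applying the rules (default TRUE).  Inner shells have tiny volumes, so
#'   single-bead fluctuations produce large spurious phi spikes there; the
#'   volume weighting suppresses them without moving the envelope peak.
#' @return an `organization_call`: list with `mode` (factor: peripheral /
#'   conventional / central), `wetting` flag, `com_offset` and the
#'   profile summary statistics used as evidence.
#' @export
classify_organization <- function(profile, com_offset = 0,
                                  peak_outer = 0.8, peak_inner = 0.6,
                                  inner_frac = 0.10, outer_frac = 0.50,
                                  wetting_com = 0.15, smooth = TRUE) {
  r <- profile$shell_center
  phi <- profile$phi_local
  bd <- attr(profile, "bead_diameter")
  rc_n <- attr(profile, "confinement_radius")
  scaled <- !is.null(bd) && !is.null(rc_n) && is.finite(bd) &&
    is.finite(rc_n)
  dr <- diff(r)[1]
  vol <- diff(c(0, r + dr / 2)^3)
  if (smooth && length(phi) >= 3) {
    # volume-weighted moving average over at least one bead diameter, so
    # the solid-like radial layering of dense scaled-down systems does not
    # masquerade as structure
    h <- if (scaled) max(1, ceiling(0.5 * bd / (dr * rc_n))) else 1
    k <- length(phi)
    phi <- vapply(seq_len(k), function(i) {
      j <- max(1, i - h):min(k, i + h)
      sum(phi[j] * vol[j]) / sum(vol[j])
    }, numeric(1))
  }
  if (scaled) {
    # merge inner shells until every evaluated bin holds >= 10 bead
    # volumes: the innermost equal-thickness shells are smaller than one
    # bead and single-bead fluctuations produce arbitrarily large phi there
    vmin <- 10 * (4 / 3) * pi * (bd / 2)^3 / ((4 / 3) * pi * rc_n^3)
    bin <- integer(length(r))
    b <- 1L
    acc_v <- 0
    for (i in seq_along(r)) {
      bin[i] <- b
      acc_v <- acc_v + vol[i]
      if (acc_v >= vmin) {
        b <- b + 1L
        acc_v <- 0
      }
    }
    phi <- as.numeric(tapply(phi * vol, bin, sum) / tapply(vol, bin, sum))
    r <- as.numeric(tapply(r * vol, bin, sum) / tapply(vol, bin, sum))
    # bead centres cannot reach the outermost ~0.9 sigma (wall repulsion);
    # evaluate the rules in units of the accessible radius so "the
    # envelope" means the envelope a bead can touch
    acc <- 1 - 0.9 * bd / rc_n
    keep <- r <= acc + 1e-9
    if (sum(keep) >= 5) {
      r <- r[keep] / acc
      phi <- phi[keep]
    }
  }
  pk <- max(phi)
  r_peak <- r[which.max(phi)]
  inner_mean <- mean(phi[r < 0.5])
  outer_phi <- phi[length(phi)]

  peripheral <- r_peak > peak_outer && inner_mean < inner_frac * pk
  central <- r_peak < peak_inner && outer_phi < outer_frac * pk
  wetting <- com_offset > wetting_com
  mode <- if (peripheral) "peripheral"
    else if (central || wetting) "central"
    else "conventional"
  structure(list(
    mode = factor(mode, levels = c("peripheral", "conventional", "central")),
    wetting = !peripheral && wetting,
    com_offset = com_offset,
    evidence = c(peak_phi = pk, r_peak = r_peak, inner_mean = inner_mean,
                 outer_phi = outer_phi),
    thresholds = c(peak_outer = peak_outer, peak_inner = peak_inner,
                   inner_frac = inner_frac, outer_frac = outer_frac,
                   wetting_com = wetting_com)),
    class = "organization_call")
}

#' @export
print.organization_call <- function(x, ...) {
  cat(sprintf("<organization_call> %s%s | com offset %.3f R_c | peak at r = %.2f\n",
              as.character(x$mode), if (x$wetting) " (wetting)" else "",
              x$com_offset, x$evidence[["r_peak"]]))
  invisible(x)
}

#' Contact map and contact probability P(s)
#'
#' A contact is any non-adjacent bead pair (`|i - j| > 1`) closer than the
#' contact distance (default 2.5 sigma), averaged over frames.  The map is
#' coarse-grained into `bin_beads` x `bin_beads` blocks; the diagonal is 1
#' by convention.  `P(s)` is the mean contact frequency at contour
#' separation `s`.
#'
#' @param traj trajectory or list of position matrices.
#' @param contact_distance contact threshold.
#' @param bin_beads beads per matrix bin (>= 1).
#' @return a list with the symmetric `map`, the `p_s` data frame
#'   (`s`, `p`), `contact_distance` and `bin_beads`.
#' @export
contact_map <- function(traj, contact_distance = 2.5, bin_beads = 1L) {
  frames <- traj_frames(traj)
  if (!length(frames)) stop("invalid-input: empty trajectory")
  stopifnot(bin_beads >= 1)
  n <- nrow(frames[[1]])
  acc <- matrix(0, n, n)
  for (f in frames) {
    d <- as.matrix(stats::dist(f))
    acc <- acc + (d < contact_distance)
  }
  acc <- acc / length(frames)
  # exclude trivial neighbours, set diagonal convention
  acc[abs(row(acc) - col(acc)) <= 1] <- 0
  ps <- vapply(seq_len(n - 2) + 1, function(s)
    mean(acc[cbind(seq_len(n - s), seq_len(n - s) + s)]), numeric(1))
  diag(acc) <- 1
  nb <- ceiling(n / bin_beads)
  if (bin_beads > 1L) {
    g <- (seq_len(n) - 1L) %/% bin_beads + 1L
    acc <- rowsum(t(rowsum(acc, g)), g) / bin_beads^2
  }
  list(map = acc,
       p_s = data.frame(s = seq_len(n - 2) + 1, p = ps),
       contact_distance = contact_distance, bin_beads = as.integer(bin_beads))
}

#' Subchain scaling exponent
#'
#' Fits `<R_g^2(s)> ~ s^(2 nu)` over subchain lengths
#' `s in [s_min, s_max]` (default `[10, N/2]`) from a set of decorrelated
#' conformations, returning the Flory exponent `nu` with a bootstrap
#' confidence interval over conformations.  Expected values: ~0.5 for an
#' ideal chain, ~0.588 self-avoiding, ~1/3 for a collapsed globule.
#'
#' @param conformations list of N x 3 position matrices (>= 20).
#' @param s_min,s_max fit range in beads.
#' @param saturation_frac subchain sizes whose mean `R_g^2(s)` exceeds this
#'   fraction of the whole-chain `R_g^2` are excluded from the fit: for
#'   compact globules `R_g(s)` saturates at the globule size well below
#'   `s = N`, and including the saturated regime biases the exponent
#'   downward.
#' @param n_boot bootstrap replicates.
#' @return list with `nu`, `ci` (2.5/97.5%), and the `rg2` table.
#' @export
scaling_exponent <- function(conformations, s_min = 10, s_max = NULL,
                             saturation_frac = 0.5, n_boot = 200L) {
  conformations <- traj_frames(conformations)
  if (length(conformations) < 20)
    stop("invalid-input: need >= 20 decorrelated conformations")
  n <- nrow(conformations[[1]])
  if (is.null(s_max)) s_max <- floor(n / 2)
  s_vals <- unique(round(exp(seq(log(s_min), log(s_max), length.out = 12))))
  # per-conformation mean subchain Rg^2 via prefix sums over windows
  rg2_of <- function(pos, s) {
    cs <- apply(rbind(0, pos), 2, cumsum)
    cs2 <- cumsum(c(0, rowSums(pos^2)))
    i0 <- seq_len(n - s + 1)
    m2 <- (cs2[i0 + s] - cs2[i0]) / s
    mx <- (cs[i0 + s, ] - cs[i0, ]) / s
    mean(m2 - rowSums(mx^2))
  }
  tab <- vapply(conformations,
                function(p) vapply(s_vals, function(s) rg2_of(p, s),
                                   numeric(1)),
                numeric(length(s_vals)))
  tab <- matrix(tab, nrow = length(s_vals))
  # drop the saturated regime where subchains feel the whole-chain size
  rg2_chain <- mean(vapply(conformations, function(p) {
    c0 <- colMeans(p)
    mean(rowSums(sweep(p, 2, c0)^2))
  }, numeric(1)))
  keep <- rowMeans(tab) <= saturation_frac * rg2_chain
  if (sum(keep) >= 4) {
    s_vals <- s_vals[keep]
    tab <- tab[keep, , drop = FALSE]
  }
  fit_nu <- function(w) {
    y <- log(rowMeans(tab[, w, drop = FALSE]))
    unname(coef(lm(y ~ log(s_vals)))[2] / 2)
  }
  nu <- fit_nu(seq_len(ncol(tab)))
  boots <- vapply(seq_len(n_boot), function(b)
    fit_nu(sample.int(ncol(tab), replace = TRUE)), numeric(1))
  list(nu = nu,
       ci = quantile(boots, c(0.025, 0.975), names = FALSE),
       rg2 = data.frame(s = s_vals, rg2 = rowMeans(tab)))
}

#' Persistence length from tangent correlations
#'
#' Fits `<cos theta(s)> = exp(-s sigma / l_p)` to the mean bond-vector
#' correlation over separations `s = 1..s_max` (in bonds) and returns
#' `l_p` in length units.  For self-avoiding chains the correlation is
#' exponential only in its initial decay — beyond roughly two decay
#' lengths a slow excluded-volume tail takes over — so the fit is a
#' weighted log-linear regression through the origin (delta-method
#' weights, proportional to `c(s)^2`) restricted to separations with
#' `c(s) >= exp(-2) c(1)`.  Raises a fit-failure error when the
#' correlation does not decay (rigid rod).
#'
#' @param conformations list of N x 3 position matrices (>= 20).
#' @param bead_diameter sigma.
#' @param s_max largest separation considered in the fit.
#' @return list with `persistence_length`, the fitted decay per bond, and
#'   the correlation table.
#' @export
persistence_length <- function(conformations, bead_diameter = 1,
                               s_max = 10L) {
  conformations <- traj_frames(conformations)
  if (length(conformations) < 20)
    stop("invalid-input: need >= 20 decorrelated conformations")
  s_vals <- seq_len(s_max)
  corr <- sapply(conformations, function(pos) {
    b <- diff(pos)
    b <- b / sqrt(rowSums(b^2))
    vapply(s_vals, function(s) {
      i <- seq_len(nrow(b) - s)
      mean(rowSums(b[i, , drop = FALSE] * b[i + s, , drop = FALSE]))
    }, numeric(1))
  })
  cmean <- rowMeans(matrix(corr, nrow = length(s_vals)))
  # initial-decay region: within two decay lengths of s = 1, and positive
  usable <- cmean > max(0.01, exp(-2) * cmean[1])
  if (sum(usable) < 2 || cmean[1] <= 0)
    stop("fit-failure: tangent correlation does not decay exponentially")
  s_u <- s_vals[usable]
  y <- log(cmean[usable])
  w <- cmean[usable]^2          # Var(log c) ~ Var(c)/c^2
  rate <- -sum(w * y * s_u) / sum(w * s_u^2)
  if (rate < 1e-3)
    stop("fit-failure: non-decaying tangent correlation (rigid rod?)")
  list(persistence_length = bead_diameter / rate,
       decay_per_bond = rate,
       correlation = data.frame(s = s_vals, cos_theta = cmean))
}

#' Angular LAD/non-LAD segregation at the periphery
#'
#' Restricted to beads in the peripheral shell (`r > r_min * R_c`), the
#' index is the observed same-type fraction among each bead's `k` nearest
#' neighbours on the sphere, divided by its expectation under random type
#' shuffling (mean of `n_shuffle` permutations).  An index near 1 means
#' angularly mixed; values above 1 mean LAD and non-LAD demix in the
#' angular direction.
#'
#' @param positions N x 3 positions of one frame.
#' @param bead_type per-bead types (`LAD`/`nonLAD`).
#' @param confinement_radius nucleus radius.
#' @param r_min inner edge of the peripheral shell (fraction of R_c).
#' @param k neighbours per bead.
#' @param n_shuffle type permutations for the null.
#' @param seed optional seed for the permutations.
#' @return list with `index`, `observed`, `expected`, `n_peripheral`, and
#'   a `degenerate` flag (single-type periphery returns index 1).
#' @export
angular_segregation <- function(positions, bead_type, confinement_radius,
                                r_min = 0.8, k = 10L, n_shuffle = 100L,
                                seed = NULL) {
  rr <- sqrt(rowSums(positions^2)) / confinement_radius
  sel <- rr > r_min
  if (sum(sel) < 100)
    stop("invalid-input: need >= 100 beads in the peripheral shell")
  p <- positions[sel, , drop = FALSE]
  p <- p / sqrt(rowSums(p^2))
  ty <- as.integer(bead_type[sel] == "LAD")
  if (length(unique(ty)) == 1L)
    return(list(index = 1, observed = 1, expected = 1,
                n_peripheral = sum(sel), degenerate = TRUE))
  np <- nrow(p)
  d <- as.matrix(stats::dist(p))
  diag(d) <- Inf
  nn <- apply(d, 1, function(row) order(row)[seq_len(k)])
  same_frac <- function(tt) mean(tt[as.vector(nn)] == rep(tt, each = k))
  obs <- same_frac(ty)
  expd <- with_seed(seed, mean(vapply(seq_len(n_shuffle),
                                      function(i) same_frac(sample(ty)),
                                      numeric(1))))
  list(index = obs / expd, observed = obs, expected = expd,
       n_peripheral = np, degenerate = FALSE)
}

#' Centre-of-mass offset of the chain
#'
#' Distance of the chain's centre of mass from the nuclear centre as a
#' fraction of R_c, averaged over frames: the wetting-droplet diagnostic.
#'
#' @param traj trajectory or list of position matrices.
#' @param confinement_radius nucleus radius.
#' @return mean offset in units of R_c.
#' @export
com_offset <- function(traj, confinement_radius = NULL) {
  frames <- traj_frames(traj)
  if (is.null(confinement_radius))
    confinement_radius <- attr(frames, "confinement_radius")
  mean(vapply(frames, function(f) sqrt(sum(colMeans(f)^2)), numeric(1))) /
    confinement_radius
}

# internal: accept a bd_trajectory or a bare list of position matrices
traj_frames <- function(traj) {
  if (inherits(traj, "bd_trajectory")) {
    if (is.null(traj$frames))
      stop("invalid-input: trajectory was run with record_frames = FALSE")
    out <- traj$frames
    attr(out, "confinement_radius") <- traj$confinement_radius
    attr(out, "bead_diameter") <- traj$bead_diameter
    return(out)
  }
  if (is.matrix(traj)) return(list(traj))
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
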