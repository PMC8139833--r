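# Independent reference implementations used as oracles.  Everything here is
# plain R written directly from the model definitions, kept deliberately
# separate from the package's compiled evaluation path.

# full potential energy by naive double loops
oracle_energy <- function(chain, shell, bonds, params, attract = TRUE) {
  pos <- chain$positions
  n <- nrow(pos)
  sig <- params$bead_diameter
  wca <- 2^(1 / 6) * sig
  cut <- if (attract) params$cutoff_attractive else params$cutoff_repulsive

  lj <- function(r, eps, cutoff) {
    if (eps == 0 || r >= cutoff) return(0)
    s6 <- (sig / r)^6
    sc6 <- (sig / cutoff)^6
    4 * eps * (s6^2 - s6) - 4 * eps * (sc6^2 - sc6)
  }

  stretch <- 0
  for (i in seq_len(n - 1)) {
    r <- sqrt(sum((pos[i + 1, ] - pos[i, ])^2))
    stretch <- stretch + params$spring_constant * (r - params$rest_length)^2
  }
  bend <- 0
  if (n >= 3) for (i in 2:(n - 1)) {
    b1 <- pos[i, ] - pos[i - 1, ]
    b2 <- pos[i + 1, ] - pos[i, ]
    cosang <- sum(b1 * b2) / sqrt(sum(b1^2) * sum(b2^2))
    bend <- bend + params$bending_stiffness * (1 - cosang)
  }
  chrom <- 0
  emat <- params$epsilon_matrix
  ti <- as.integer(chain$bead_type == "LAD") + 1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
    chrom <- chrom + lj(r, emat[ti[i], ti[j]], cut)
  }
  wall <- 0
  lamin <- 0
  bond_e <- 0
  if (!is.na(shell$confinement_radius)) {
    rc_n <- shell$confinement_radius
    for (i in seq_len(n)) {
      gap <- rc_n - sqrt(sum(pos[i, ]^2))
      wall <- wall + lj(gap, 1, wca)
    }
    lam <- shell$lamin_positions
    for (i in seq_len(n)) {
      eps_i <- if (ti[i] == 2L) params$eps_lad_lamin else params$eps_nonlad_lamin
      cut_i <- if (ti[i] == 2L) params$cutoff_attractive else wca
      for (j in seq_len(nrow(lam))) {
        r <- sqrt(sum((pos[i, ] - lam[j, ])^2))
        lamin <- lamin + lj(r, eps_i, cut_i)
      }
    }
    for (i in which(!is.na(bonds))) {
      r <- sqrt(sum((pos[i, ] - lam[bonds[i], ])^2))
      bond_e <- bond_e + params$kbond * (r - params$bead_diameter)^2 -
        params$kbond * (params$r_bond - params$bead_diameter)^2
    }
  }
  c(stretch = stretch, bend = bend, chrom_lj = chrom, wall = wall,
    lamin_lj = lamin, bond = bond_e,
    total = stretch + bend + chrom + wall + lamin + bond_e)
}

# small relaxed confined test system (deterministic)
make_relaxed_system <- function(n = 50, Rc = 6, epsilon = 1, psi = 1,
                                seed = 7) {
  params <- sim_params(n_beads = n, confinement_radius = Rc,
                       epsilon = epsilon, psi = psi, rng_seed = seed)
  shell <- build_shell(Rc)
  types <- synthesize_lad_pattern(n, 0.5, 5, seed = seed)
  chain <- chromatin_chain(initial_configuration(n, Rc, 1, seed = seed),
                           types, select_bondable(types, psi, seed = seed))
  st <- sim_state(chain, shell, params)
  set.seed(seed)
  st <- run_bd(st, 3000, 3000, dt = 1e-3, max_disp = 0.05, attract = FALSE,
               record_frames = FALSE)$state
  st <- run_bd(st, 2000, 2000, dt = 5e-4, max_disp = 0.25,
               record_frames = FALSE)$state
  st
}

# ideal discrete worm-like-chain sampler: bond angles drawn directly from the
# Boltzmann weight exp(-kb (1 - cos theta)), no dynamics involved
sample_wlc <- function(n_beads, kb, n_conf = 30, seed = 1) {
  set.seed(seed)
  draw_cos <- function(m) {
    # inverse-CDF sampling of p(c) ~ exp(kb c) on [-1, 1]
    u <- runif(m)
    if (kb == 0) return(2 * u - 1)
    log(exp(-kb) + u * (exp(kb) - exp(-kb))) / kb
  }
  lapply(seq_len(n_conf), function(k) {
    u <- matrix(0, n_beads - 1, 3)
    u[1, ] <- c(0, 0, 1)
    for (i in 2:(n_beads - 1)) {
      c0 <- draw_cos(1)
      s0 <- sqrt(1 - c0^2)
      phi <- runif(1, 0, 2 * pi)
      # orthonormal frame around previous bond
      a <- u[i - 1, ]
      ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- ref - sum(ref * a) * a
      e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(a[2] * e1[3] - a[3] * e1[2],
              a[3] * e1[1] - a[1] * e1[3],
              a[1] * e1[2] - a[2] * e1[1])
      u[i, ] <- c0 * a + s0 * (cos(phi) * e1 + sin(phi) * e2)
    }
    rbind(0, apply(u, 2, cumsum))
  })
}
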