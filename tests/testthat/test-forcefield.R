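test_that("LJ pair energy and force match the closed form", {
  # at r = sigma the unshifted energy crosses zero and the force is 24 eps
  lj <- lj_pair(1, eps = 1, sigma = 1, cutoff = 2.5)
  shift <- 4 * ((1 / 2.5)^12 - (1 / 2.5)^6)
  expect_equal(lj$energy, -shift, tolerance = 1e-12)
  expect_equal(lj$force, 24)
  # at the minimum 2^(1/6) sigma the force vanishes, unshifted energy is -eps
  lj <- lj_pair(2^(1 / 6), 2, 1, 2.5)
  expect_equal(lj$force, 0, tolerance = 1e-12)
  expect_equal(lj$energy + 2 * shift, -2, tolerance = 1e-12)
  # beyond the cutoff both vanish
  lj <- lj_pair(2.6, 1, 1, 2.5)
  expect_equal(unlist(lj), c(energy = 0, force = 0))
  expect_error(lj_pair(0, 1), "singular")
})

test_that("bonded terms evaluate the spring and bending sums", {
  # straight chain at rest spacing: both zero
  pos <- cbind(0, 0, 0:4)
  expect_equal(unname(bonded_terms(pos, 100, 1, 2)), c(0, 0))
  # one spring stretched by 0.1 sigma at k_s = 100 -> 1 kT (no 1/2 factor)
  pos <- cbind(0, 0, c(0, 1.1))
  expect_equal(bonded_terms(pos, 100, 1, 2)[["stretch"]], 1, tolerance = 1e-12)
  # one right-angle kink at k_b = 2 -> 2 kT
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  bt <- bonded_terms(pos, 100, 1, 2)
  expect_equal(bt[["bend"]], 2, tolerance = 1e-12)
  expect_equal(bt[["stretch"]], 0, tolerance = 1e-12)
  expect_error(bonded_terms(rbind(c(0, 0, 0), c(0, 0, 0))), "singular-angle")
})

test_that("energy breakdown matches the naive double-loop oracle", {
  for (seed in c(7, 21, 99)) {
    st <- make_relaxed_system(n = 40, Rc = 5.5, seed = seed)
    e <- total_energy(st$chain, st$shell, st$bonds, st$params)
    o <- oracle_energy(st$chain, st$shell, st$bonds, st$params)
    for (term in names(o))
      expect_equal(e[[term]], o[[term]], tolerance = 1e-10,
                   label = paste(term, "seed", seed))
    expect_equal(e[["total"]],
                 sum(e[c("stretch", "bend", "chrom_lj", "wall",
                         "lamin_lj", "bond", "trap")]),
                 tolerance = 1e-10)
  }
})

test_that("two distant beads have zero total energy", {
  p <- sim_params(n_beads = 2, epsilon = 1, psi = 0, spring_constant = 0,
                  bending_stiffness = 0)
  ch <- chromatin_chain(rbind(c(0, 0, 0), c(3, 0, 0)), rep("nonLAD", 2))
  e <- total_energy(ch, ladsim:::no_shell(), bond_set(ch), p)
  expect_equal(e[["total"]], 0, tolerance = 1e-9)
})

test_that("analytic forces match central finite differences of the energy", {
  st <- make_relaxed_system(n = 50, Rc = 6, seed = 11)
  f <- forces(st$chain, st$shell, st$bonds, st$params)
  h <- 1e-6
  E <- function(ch) total_energy(ch, st$shell, st$bonds, st$params)[["total"]]
  set.seed(4)
  for (i in sample(50, 12)) for (k in 1:3) {
    chp <- st$chain; chp$positions[i, k] <- chp$positions[i, k] + h
    chm <- st$chain; chm$positions[i, k] <- chm$positions[i, k] - h
    fd <- -(E(chp) - E(chm)) / (2 * h)
    expect_equal(fd, f[i, k], tolerance = 1e-5,
                 label = sprintf("force[%d,%d]", i, k))
  }
})

test_that("forces vanish for an isolated straight chain at rest length", {
  p <- sim_params(n_beads = 5, epsilon = 0, psi = 0)
  ch <- chromatin_chain(cbind(0, 0, 0:4), rep("nonLAD", 5))
  f <- forces(ch, ladsim:::no_shell(), bond_set(ch), p)
  expect_true(all(abs(f) < 1e-12))
})

test_that("internal interactions conserve momentum", {
  st <- make_relaxed_system(n = 60, Rc = 7, seed = 5)
  p_free <- st$params
  ch <- st$chain
  f <- forces(ch, ladsim:::no_shell(), bond_set(ch), p_free)
  fmax <- max(abs(f))
  expect_lt(max(abs(colSums(f))), 1e-9 * max(1, fmax))
})

test_that("chain-only energy is invariant under rigid motions", {
  st <- make_relaxed_system(n = 30, Rc = 5.5, seed = 13)
  ch <- st$chain
  p <- st$params
  e0 <- total_energy(ch, ladsim:::no_shell(), bond_set(ch), p)[["total"]]
  ch_t <- ch; ch_t$positions <- ch$positions + rep(c(1.3, -0.4, 2), each = 30)
  expect_equal(total_energy(ch_t, ladsim:::no_shell(), bond_set(ch_t),
                            p)[["total"]], e0, tolerance = 1e-9)
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  ch_r <- ch; ch_r$positions <- ch$positions %*% rot
  expect_equal(total_energy(ch_r, ladsim:::no_shell(), bond_set(ch_r),
                            p)[["total"]], e0, tolerance = 1e-9)
})

test_that("cell-list evaluation equals the all-pairs reference", {
  st <- make_relaxed_system(n = 200, Rc = 8, seed = 17)
  e1 <- total_energy(st$chain, st$shell, st$bonds, st$params,
                     use_cells = TRUE)
  e2 <- total_energy(st$chain, st$shell, st$bonds, st$params,
                     use_cells = FALSE)
  expect_equal(as.numeric(e1), as.numeric(e2), tolerance = 1e-10)
  f1 <- forces(st$chain, st$shell, st$bonds, st$params, use_cells = TRUE)
  f2 <- forces(st$chain, st$shell, st$bonds, st$params, use_cells = FALSE)
  expect_lt(max(abs(f1 - f2)) / max(1, max(abs(f1))), 1e-10)
})

test_that("type-specific epsilon matrix drives pair interactions", {
  # two LAD beads attract with eps_LL, two nonLAD with eps_nn
  emat <- matrix(c(0.2, 0.5, 0.5, 1.5), 2, 2)
  p <- sim_params(n_beads = 2, epsilon = emat, psi = 0,
                  spring_constant = 0, bending_stiffness = 0)
  r <- 1.3
  for (tt in list(c("nonLAD", "nonLAD"), c("nonLAD", "LAD"),
                  c("LAD", "LAD"))) {
    ch <- chromatin_chain(rbind(c(0, 0, 0), c(r, 0, 0)), tt)
    e <- total_energy(ch, ladsim:::no_shell(), bond_set(ch), p)
    eps <- emat[1 + (tt[1] == "LAD"), 1 + (tt[2] == "LAD")]
    expect_equal(e[["chrom_lj"]], lj_pair(r, eps, 1, 2.5)$energy,
                 tolerance = 1e-12)
  }
})
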