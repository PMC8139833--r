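free_beads <- function(n, spread = 5, seed = 1) {
  p <- sim_params(n_beads = n, psi = 0, epsilon = 0, spring_constant = 0,
                  bending_stiffness = 0)
  set.seed(seed)
  ch <- chromatin_chain(matrix(rnorm(3 * n, 0, spread), n, 3),
                        rep("nonLAD", n))
  sim_state(ch, NULL, p)
}

test_that("zero force with noise disabled leaves positions unchanged", {
  st <- free_beads(20)
  pos0 <- st$chain$positions
  st2 <- run_bd(st, 100, 100, dt = 1e-3, noise = "none",
                record_frames = FALSE)$state
  expect_identical(st2$chain$positions, pos0)
  expect_equal(st2$step, 100L)
})

test_that("free beads diffuse with MSD = 6 D t", {
  st <- free_beads(800)
  pos0 <- st$chain$positions
  set.seed(5)
  nst <- 5000; dt <- 2e-3
  st2 <- run_bd(st, nst, nst, dt = dt, record_frames = FALSE)$state
  msd <- mean(rowSums((st2$chain$positions - pos0)^2))
  expect_equal(msd, 6 * dt * nst, tolerance = 0.05)
})

test_that("uniform-noise mode diffuses at the same rate", {
  st <- free_beads(800)
  pos0 <- st$chain$positions
  set.seed(6)
  st2 <- run_bd(st, 5000, 5000, dt = 2e-3, noise = "uniform",
                record_frames = FALSE)$state
  msd <- mean(rowSums((st2$chain$positions - pos0)^2))
  expect_equal(msd, 6 * 2e-3 * 5000, tolerance = 0.05)
})

test_that("a harmonic well samples the Boltzmann variance kT/(2k)", {
  n <- 500
  p <- sim_params(n_beads = n, psi = 0, epsilon = 0, spring_constant = 0,
                  bending_stiffness = 0)
  set.seed(2)
  ch <- chromatin_chain(matrix(rnorm(3 * n, 0, 0.07), n, 3),
                        rep("nonLAD", n))
  st <- sim_state(ch, NULL, p)
  st <- run_bd(st, 2000, 2000, dt = 2e-4, trap_k = 100,
               record_frames = FALSE)$state
  r <- run_bd(st, 20000, 250, dt = 2e-4, trap_k = 100, record_frames = TRUE)
  v <- mean(vapply(r$trajectory$frames[-1], function(f) mean(f^2),
                   numeric(1)))
  expect_equal(v, 1 / (2 * 100), tolerance = 0.05)
})

test_that("trajectories are deterministic for a fixed seed", {
  st <- make_relaxed_system(n = 40, Rc = 5.5, seed = 23)
  set.seed(99)
  r1 <- run_bd(st, 500, 100, dt = 5e-4, max_disp = 0.25)
  set.seed(99)
  r2 <- run_bd(st, 500, 100, dt = 5e-4, max_disp = 0.25)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
  expect_identical(r1$state$bonds, r2$state$bonds)
})

test_that("trajectory length is floor(n_steps / interval) + 1", {
  st <- free_beads(10)
  r <- run_bd(st, 1000, 300, dt = 1e-3)
  expect_equal(length(r$trajectory$frames), 1000 %/% 300 + 1)
  expect_equal(r$trajectory$frame_steps, c(0L, 300L, 600L, 900L))
})

test_that("cell-list and all-pairs runs agree", {
  st <- make_relaxed_system(n = 100, Rc = 6.5, seed = 41)
  set.seed(7)
  r1 <- run_bd(st, 200, 200, dt = 5e-4, max_disp = 0.25, use_cells = TRUE)
  set.seed(7)
  r2 <- run_bd(st, 200, 200, dt = 5e-4, max_disp = 0.25, use_cells = FALSE)
  expect_lt(max(abs(r1$state$chain$positions - r2$state$chain$positions)),
            1e-8)
})

test_that("oversized timesteps and blow-ups raise typed errors", {
  st <- free_beads(5)
  expect_error(run_bd(st, 10, 10, dt = 0.02), "unstable-timestep")
  # two deeply overlapping beads, uncapped: displacement guard fires
  p <- sim_params(n_beads = 2, epsilon = 1, psi = 0)
  ch <- chromatin_chain(rbind(c(0, 0, 0), c(0.55, 0, 0)), rep("nonLAD", 2))
  st2 <- sim_state(ch, NULL, p)
  set.seed(1)
  expect_error(run_bd(st2, 10, 10, dt = 5e-3), "unstable-timestep")
})

test_that("no bead escapes the sphere in a stable confined run", {
  st <- make_relaxed_system(n = 60, Rc = 5, seed = 3)
  set.seed(8)
  r <- run_bd(st, 3000, 300, dt = 5e-4, max_disp = 0.25)
  for (f in r$trajectory$frames)
    expect_true(all(sqrt(rowSums(f^2)) < 5))
})

test_that("two-stage equilibration runs its stages in order and bonds LADs", {
  params <- sim_params(n_beads = 150, phi = 0.1, psi = 1, epsilon = 1,
                       rng_seed = 5)
  chain <- build_chain(params, mean_domain_beads = 5, seed = 5)
  shell <- build_shell(params$confinement_radius)
  st <- sim_state(chain, shell, params)
  set.seed(10)
  st2 <- suppressWarnings(
    equilibrate_protocol(st, dt = 1e-3, pushoff_steps = 1500,
                         window = 4000, sample_every = 400,
                         max_windows = 8))
  log <- attr(st2, "protocol_log")
  expect_equal(log$stage, c("pushoff", "repulsive", "attractive"))
  expect_gt(bond_count(st2$bonds), 0)

  # self-attraction compacts a dilute chain that is not pinned to the wall
  params0 <- sim_params(n_beads = 150, phi = 0.1, psi = 0, epsilon = 1,
                        rng_seed = 6)
  chain0 <- build_chain(params0, mean_domain_beads = 5, seed = 6)
  st0 <- sim_state(chain0, build_shell(params0$confinement_radius), params0)
  set.seed(11)
  st0 <- suppressWarnings(
    equilibrate_protocol(st0, dt = 1e-3, pushoff_steps = 1500,
                         window = 4000, sample_every = 400,
                         max_windows = 8))
  log0 <- attr(st0, "protocol_log")
  expect_lt(log0$rg[3], log0$rg[2])
})
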