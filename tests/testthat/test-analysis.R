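uniform_sphere_frames <- function(n, Rc, n_frames = 5, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(i) {
    r <- Rc * runif(n)^(1 / 3)
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    u * r
  })
}

test_that("radial profiles conserve the global volume fraction", {
  frames <- uniform_sphere_frames(2000, 10, n_frames = 4)
  prof <- radial_profile(frames, confinement_radius = 10, n_shells = 25,
                         bead_diameter = 1)
  edges <- seq(0, 1, length.out = 26)
  vw_mean <- sum(prof$phi_local * diff(edges^3))
  expect_equal(vw_mean, attr(prof, "global_phi"), tolerance = 1e-10)
  expect_true(all(prof$phi_local >= 0))
})

test_that("uniformly filled nuclei give flat profiles", {
  frames <- uniform_sphere_frames(3000, 10, n_frames = 20, seed = 3)
  prof <- radial_profile(frames, confinement_radius = 10, n_shells = 10)
  phi0 <- attr(prof, "global_phi")
  counts <- phi0 * diff(seq(0, 1, length.out = 11)^3) * 10^3 * 8 * 20
  se <- phi0 / sqrt(counts / 20) / sqrt(20)
  # each shell within ~3 standard errors of the global mean
  expect_true(all(abs(prof$phi_local - phi0) < 3.5 * phi0 / sqrt(counts)))
})

test_that("mass localized in one shell appears only there", {
  set.seed(2)
  n <- 500
  r <- 10 * runif(n, 0.85, 0.95)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  prof <- radial_profile(list(u * r), confinement_radius = 10,
                         n_shells = 20)
  occupied <- prof$phi_local > 0
  expect_true(all(prof$shell_center[occupied] > 0.8 &
                  prof$shell_center[occupied] < 1))
  expect_error(radial_profile(list(), confinement_radius = 10),
               "invalid-input")
})

synthetic_profile <- function(phi) {
  structure(data.frame(shell_center = seq(1 / 60, 1 - 1 / 60,
                                          length.out = 30),
                       phi_local = phi),
            class = c("radial_profile", "data.frame"))
}

test_that("organization calls follow the profile rules", {
  r <- seq(1 / 60, 1 - 1 / 60, length.out = 30)
  # flat -> conventional
  expect_equal(as.character(classify_organization(
    synthetic_profile(rep(0.3, 30)))$mode), "conventional")
  # empty centre, sharp envelope peak -> peripheral
  peri <- ifelse(r > 0.8, 0.5 * exp(-((1 - r) / 0.1)^2), 0.001)
  expect_equal(as.character(classify_organization(
    synthetic_profile(peri))$mode), "peripheral")
  # central condensate, empty envelope -> central
  cent <- 0.6 * exp(-(r / 0.3)^2)
  expect_equal(as.character(classify_organization(
    synthetic_profile(cent))$mode), "central")
  # scale invariance of the call
  for (prof in list(peri, cent)) {
    c1 <- classify_organization(synthetic_profile(prof))
    c2 <- classify_organization(synthetic_profile(prof * 7.3))
    expect_identical(c1$mode, c2$mode)
  }
  # off-centre condensate: wetting droplets are grouped with central
  half <- ifelse(r > 0.3 & r < 0.9, 0.4, 0.01)
  call <- classify_organization(synthetic_profile(half), com_offset = 0.3)
  expect_equal(as.character(call$mode), "central")
  expect_true(call$wetting)
})

test_that("contact maps count non-adjacent pairs within reach", {
  # straight rod: no pairs beyond |i-j|>1 are in contact
  rod <- cbind(0, 0, seq(0, by = 1, length.out = 30))
  cm <- contact_map(list(rod), contact_distance = 2.5)
  off <- abs(row(cm$map) - col(cm$map)) > 1
  expect_true(all(cm$map[off][abs(row(cm$map) - col(cm$map))[off] > 2] == 0))
  expect_true(all(diag(cm$map) == 1))
  expect_true(isSymmetric(cm$map))
  # |i-j| = 2 pairs at distance 2 < 2.5 are contacts
  expect_equal(cm$p_s$p[cm$p_s$s == 2], 1)
  expect_equal(cm$p_s$p[cm$p_s$s == 3], 0)
  # binning preserves symmetry
  cm2 <- contact_map(list(rod), bin_beads = 5)
  expect_true(isSymmetric(cm2$map))
  expect_equal(dim(cm2$map), c(6, 6))
})

test_that("scaling exponent recovers the ideal-chain value on random walks", {
  set.seed(8)
  confs <- lapply(1:40, function(i) {
    steps <- matrix(rnorm(599 * 3), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2))
    rbind(0, apply(steps, 2, cumsum))
  })
  fit <- scaling_exponent(confs)
  expect_equal(fit$nu, 0.5, tolerance = 0.03)
  expect_lt(fit$ci[1], fit$nu)
  expect_gt(fit$ci[2], fit$nu)
  expect_error(scaling_exponent(confs[1:5]), "invalid-input")
})

test_that("persistence length is recovered from ideal worm-like chains", {
  # independent Boltzmann sampler of bond angles, no dynamics
  confs <- sample_wlc(400, kb = 4, n_conf = 40, seed = 2)
  fit <- persistence_length(confs)
  # kb = 4: discrete WLC decay -ln(coth(4) - 1/4) per bond
  lp_true <- -1 / log(1 / tanh(4) - 1 / 4)
  expect_equal(fit$persistence_length, lp_true, tolerance = 0.10)

  # freely-jointed limit: lp below 1.5 sigma
  confs0 <- sample_wlc(400, kb = 0.5, n_conf = 30, seed = 3)
  expect_lt(persistence_length(confs0)$persistence_length, 1.5)

  # frozen straight conformations: no decay -> fit failure
  rodl <- lapply(1:25, function(i) cbind(0, 0, 0:100))
  expect_error(persistence_length(rodl), "fit-failure")
  expect_error(persistence_length(confs[1:3]), "invalid-input")
})

test_that("angular segregation distinguishes demixed from shuffled types", {
  set.seed(11)
  n <- 600
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  pos <- u * 9.5
  # hemispheres of LAD / nonLAD: strongly demixed
  ty <- factor(ifelse(pos[, 3] > 0, "LAD", "nonLAD"),
               levels = c("nonLAD", "LAD"))
  seg <- angular_segregation(pos, ty, 10, seed = 1)
  expect_gt(seg$index, 1.5)
  # shuffled types: index ~ 1
  seg0 <- angular_segregation(pos, sample(ty), 10, seed = 1)
  expect_equal(seg0$index, 1, tolerance = 0.05)
  # degenerate single-type periphery
  seg1 <- angular_segregation(pos, factor(rep("LAD", n),
                                          levels = c("nonLAD", "LAD")),
                              10, seed = 1)
  expect_true(seg1$degenerate)
  expect_equal(seg1$index, 1)
  expect_error(angular_segregation(pos[1:50, ], ty[1:50], 10),
               "invalid-input")
})
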