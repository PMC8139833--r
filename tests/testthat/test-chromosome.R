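test_that("BED-like LAD intervals are parsed, sorted and merged", {
  a <- read_lad_intervals(c("chrX\t0\t600", "chrX\t600\t1200"))
  expect_equal(nrow(a$intervals), 1)
  expect_equal(unname(a$intervals[1, ]), c(0, 1200))

  expect_equal(nrow(read_lad_intervals(character(0))$intervals), 0)

  a <- read_lad_intervals(c("chrX\t900\t1200", "chrX\t0\t300"))
  expect_equal(unname(a$intervals), cbind(c(0, 900), c(300, 1200)),
               ignore_attr = TRUE)

  expect_error(read_lad_intervals("chrX\t500\t100"), "line 1")
  expect_error(read_lad_intervals(c("chrX\t0\t100", "chrX\tfoo\t200")),
               "line 2")
  expect_error(read_lad_intervals("chrX\t100"), "line 1")
})

test_that("bead labelling follows the majority (>= 50%) overlap rule", {
  a <- lad_annotation(cbind(0, 1200))
  expect_equal(as.character(intervals_to_bead_labels(a, 2)),
               c("LAD", "LAD"))
  # each bead exactly half covered: ties label LAD
  a <- lad_annotation(cbind(300, 900))
  expect_equal(as.character(intervals_to_bead_labels(a, 2)),
               c("LAD", "LAD"))
  # under half covered -> nonLAD
  a <- lad_annotation(cbind(0, 299))
  expect_equal(as.character(intervals_to_bead_labels(a, 1)), "nonLAD")
  # empty annotation, and beads past the annotation end
  a <- lad_annotation(matrix(numeric(0), ncol = 2), 6000)
  expect_true(all(intervals_to_bead_labels(a, 10) == "nonLAD"))
})

test_that("bead labels are invariant under interval splitting", {
  whole <- lad_annotation(cbind(0, 1200), 2400)
  split <- lad_annotation(cbind(c(0, 600), c(600, 1200)), 2400)
  expect_identical(intervals_to_bead_labels(whole, 4),
                   intervals_to_bead_labels(split, 4))
})

test_that("synthetic LAD patterns reproduce their configured statistics", {
  expect_true(all(synthesize_lad_pattern(100, 1, 10, seed = 1) == "LAD"))
  expect_true(all(synthesize_lad_pattern(100, 0, 10, seed = 1) == "nonLAD"))
  expect_error(synthesize_lad_pattern(100, 1.5, 10), "lad_fraction")

  # ensemble over seeds at full scale: fraction and mean LAD block length
  fracs <- blocks <- numeric(20)
  for (s in 1:20) {
    ty <- synthesize_lad_pattern(37333, 0.48, 150, seed = s)
    fracs[s] <- mean(ty == "LAD")
    r <- rle(as.character(ty))
    blocks[s] <- mean(r$lengths[r$values == "LAD"])
  }
  expect_lt(abs(mean(fracs) - 0.48), 0.03)
  expect_lt(abs(mean(blocks) - 150) / 150, 0.10)

  expect_identical(synthesize_lad_pattern(1000, 0.48, 150, seed = 9),
                   synthesize_lad_pattern(1000, 0.48, 150, seed = 9))
})

test_that("bondable selection flags exactly round(psi * n_LAD) LAD beads", {
  ty <- factor(rep(c("LAD", "nonLAD"), c(1000, 500)),
               levels = c("nonLAD", "LAD"))
  expect_equal(sum(select_bondable(ty, 0.5, seed = 1)), 500)
  expect_equal(sum(select_bondable(ty, 1, seed = 1)), 1000)
  expect_equal(sum(select_bondable(ty, 0, seed = 1)), 0)
  b <- select_bondable(ty, 0.731, seed = 2)
  expect_equal(sum(b), round(0.731 * 1000))
  expect_true(all(ty[b] == "LAD"))
  # count is seed-invariant
  counts <- vapply(1:10, function(s) sum(select_bondable(ty, 0.33, seed = s)),
                   numeric(1))
  expect_true(all(counts == counts[1]))
  expect_error(select_bondable(ty, 2), "psi")
})

test_that("initial configurations are confined, centred and reproducible", {
  pos <- initial_configuration(200, 8, 1, seed = 3)
  expect_true(all(sqrt(rowSums(pos^2)) <= 8 - 0.5 + 1e-9))
  expect_lt(sqrt(sum(colMeans(pos)^2)), 0.05 * 8)
  steps <- sqrt(rowSums(diff(pos)^2))
  expect_true(all(abs(steps - 1) < 1e-6))
  expect_identical(pos, initial_configuration(200, 8, 1, seed = 3))
  expect_error(initial_configuration(10000, 5, 1, seed = 1),
               "infeasible-geometry")
})

test_that("chain container enforces type/bondable consistency", {
  pos <- matrix(rnorm(30), 10, 3)
  ty <- rep(c("LAD", "nonLAD"), 5)
  expect_error(chromatin_chain(pos, ty, bondable = rep(TRUE, 10)),
               "bondable")
  ch <- chromatin_chain(pos, ty, bondable = ty == "LAD")
  expect_equal(ch$n_beads, 10)
  df <- bead_labels_table(ch)
  expect_equal(df$bead_index, 0:9)
  expect_equal(df$type[1], "LAD")
})

test_that("the packaged synthetic annotation maps onto a chain", {
  bed <- system.file("extdata", "synthetic_chrX_lads.bed", package = "ladsim")
  a <- read_lad_intervals(bed)
  expect_gt(nrow(a$intervals), 10)
  n <- beads_for_sequence(a$chromosome_length_bp, 600)
  labs <- intervals_to_bead_labels(a, n)
  expect_gt(mean(labs == "LAD"), 0.3)
  expect_lt(mean(labs == "LAD"), 0.6)
})
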