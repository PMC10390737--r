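test_that("zero-signal PI spec yields the constant baseline", {
  spec <- slice_spec(image_shape = c(50L, 50L), pi_amplitude = 0,
                     pi_baseline = 321, read_noise_sd = 0,
                     noise_gain = Inf, seed = 2)
  sim <- simulate_pi_channel(spec)
  expect_true(all(sim$image == 321))
  expect_true(all(sim$noiseless == 321))
})

test_that("generators are pure functions of (spec, seed)", {
  spec <- slice_spec(image_shape = c(80L, 80L), seed = 99)
  expect_identical(simulate_pi_channel(spec)$image,
                   simulate_pi_channel(spec)$image)
  expect_identical(simulate_neurite_channel(spec)$image,
                   simulate_neurite_channel(spec)$image)
  spec2 <- slice_spec(image_shape = c(200L, 200L), pixel_size = 1,
                      cell_count = 10L, seed = 99)
  expect_identical(simulate_cell_channel(spec2)$image,
                   simulate_cell_channel(spec2)$image)
  t1 <- simulate_ct_table("G1", 3, 3, -1, seed = 5)
  t2 <- simulate_ct_table("G1", 3, 3, -1, seed = 5)
  expect_identical(t1, t2)
  # generator leaves the session RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(simulate_pi_channel(spec))
  expect_identical(.Random.seed, before)
})

test_that("noisy PI centre matches the analytic profile within 3 SEM", {
  spec <- slice_spec(pi_sigma = 500, pi_baseline = 100, pi_amplitude = 1000,
                     seed = 12)
  sim <- simulate_pi_channel(spec)
  d <- distance_map_um(spec$image_shape, spec$lesion_center, spec$pixel_size)
  inner <- d <= 50
  f <- function(r) r * (100 + 1000 * exp(-r^2 / (2 * 500^2)))
  analytic <- 2 * integrate(f, 0, 50)$value / 50^2
  vals <- sim$image[, , 1][inner]
  sem <- sd(vals) / sqrt(sum(inner))
  expect_lt(abs(mean(vals) - analytic), 3 * sem + 1e-9)
})

test_that("noiseless PI signal is radially nonincreasing", {
  spec <- slice_spec(image_shape = c(60L, 60L), seed = 1)
  sim <- simulate_pi_channel(spec)
  d <- distance_map_um(spec$image_shape, spec$lesion_center, spec$pixel_size)
  ord <- order(d)
  expect_true(all(diff(sim$noiseless[ord]) <= 1e-12))
})

test_that("filament generator honours zero density and single filaments", {
  spec <- slice_spec(image_shape = c(100L, 100L),
                     density_factors = c(lesion = 0, perilesion = 0,
                                         periphery = 0),
                     read_noise_sd = 0, noise_gain = Inf, seed = 3)
  sim <- simulate_neurite_channel(spec)
  expect_equal(nrow(sim$ground_truth), 0)
  expect_true(all(sim$image == spec$background))
  # one seeded filament without branching: exact count and path length
  spec2 <- slice_spec(image_shape = c(200L, 200L), pixel_size = 2,
                      branching_prob = 0, filament_steps = c(50L, 50L),
                      seed = 8)
  sim2 <- simulate_neurite_channel(spec2, seeds = matrix(c(100, 100), 1))
  expect_equal(nrow(sim2$ground_truth), 1)
  expect_equal(sim2$ground_truth$n_steps, 50)
  expect_equal(sim2$ground_truth$length_um, 50 * 2)
})

test_that("ground-truth filament length is lower in the depleted core", {
  wins <- 0
  for (s in 1:20) {
    spec <- slice_spec(image_shape = c(350L, 350L), pixel_size = 8,
                       density_factors = c(lesion = 0.2, perilesion = 0.6,
                                           periphery = 1.0), seed = 600 + s)
    sim <- simulate_neurite_channel(spec)
    gt <- sim$ground_truth
    core_len <- sum(gt$length_um[gt$region == "lesion"])
    peri_len <- sum(gt$length_um[gt$region == "periphery"])
    if (core_len < peri_len) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("every filament has one ground-truth record and lengths add up", {
  spec <- slice_spec(image_shape = c(150L, 150L), pixel_size = 4, seed = 44)
  sim <- simulate_neurite_channel(spec)
  gt <- sim$ground_truth
  expect_equal(gt$filament, seq_len(nrow(gt)))
  expect_true(all(gt$length_um >= 0))
  expect_equal(sum(gt$length_um), sum(gt$n_steps) * spec$pixel_size)
  roi <- c(0, 0, 150)
  agg <- filament_truth_in_roi(gt, roi)
  expect_equal(agg$n_filaments, nrow(gt))
  expect_equal(agg$length_um, sum(gt$length_um))
})

test_that("cell generator obeys counts, interpolation and ellipse areas", {
  spec <- slice_spec(image_shape = c(120L, 120L), pixel_size = 1,
                     cell_count = 0L, read_noise_sd = 0, noise_gain = Inf,
                     seed = 5)
  sim0 <- simulate_cell_channel(spec)
  expect_equal(nrow(sim0$ground_truth), 0)
  expect_true(all(sim0$image == spec$background))
  # the recorded amoeboid probability follows the interpolation rule exactly
  spec1 <- slice_spec(image_shape = c(600L, 600L), pixel_size = 1,
                      lesion_center = c(300, 300), cell_count = 120L,
                      amoeboid_fraction_core = 1,
                      amoeboid_fraction_periphery = 0, seed = 6)
  sim1 <- simulate_cell_channel(spec1)
  gt <- sim1$ground_truth
  r_corner <- max(sqrt((c(0, 0, 599, 599) - 300)^2 +
                       (c(0, 599, 0, 599) - 300)^2))
  expect_equal(gt$p_amoeboid, 1 - pmin(gt$dist_um / r_corner, 1))
  expect_equal(nrow(gt), 120)
  # amoeboid shift concentrates toward the core
  expect_gt(mean(gt$class[gt$dist_um < median(gt$dist_um)] == "amoeboid"),
            mean(gt$class[gt$dist_um >= median(gt$dist_um)] == "amoeboid"))
  # degenerate fractions force a single class
  spec_all <- slice_spec(image_shape = c(300L, 300L), pixel_size = 1,
                         cell_count = 25L, amoeboid_fraction_core = 1,
                         amoeboid_fraction_periphery = 1, seed = 6)
  expect_true(all(simulate_cell_channel(spec_all)$ground_truth$class ==
                  "amoeboid"))
  # fixed-area ellipse: rendered pixel area tracks the analytic area
  spec2 <- slice_spec(image_shape = c(80L, 80L), pixel_size = 1,
                      cell_count = 1L, amoeboid_fraction_core = 1,
                      amoeboid_fraction_periphery = 1,
                      cell_area_range = c(pi * 5 * 10, pi * 5 * 10),
                      seed = 7)
  sim2 <- simulate_cell_channel(spec2)
  expect_equal(sim2$ground_truth$designed_area_um2, pi * 50)
  expect_lt(abs(sum(sim2$binary_truth) - pi * 50) / (pi * 50), 0.08)
})

test_that("impossible packing fails after a bounded number of attempts", {
  spec <- slice_spec(image_shape = c(60L, 60L), pixel_size = 1,
                     cell_count = 200L, seed = 9)
  expect_error(simulate_cell_channel(spec, max_attempts_per_cell = 20),
               "non-overlapping")
})

test_that("Ct tables invert exactly without noise and reject bad input", {
  tb <- simulate_ct_table(c("G1", "G2"), 4, 4,
                          c(G1 = -2, G2 = 1), ct_noise_sd = 0, seed = 11)
  fc <- delta_delta_ct(tb, ctrl_group = "CTRL")
  expect_equal(as.vector(tapply(fc$log2fc[fc$group == "TBI"],
                                fc$gene[fc$group == "TBI"], mean)),
               c(-2, 1))
  expect_true(all(abs(fc$log2fc[fc$group == "TBI" & fc$gene == "G1"] + 2)
                  < 1e-12))
  expect_error(simulate_ct_table("G1", 1, 4, 0), ">= 2")
  expect_error(simulate_ct_table("G1", 4, 4, 0, ct_noise_sd = -1), ">= 0")
  expect_error(simulate_ct_table("G1", 3, 3, c(RPL27 = 1)), "reference")
})

test_that("a planted null keeps the downstream t-test at its nominal size", {
  rejections <- 0
  for (s in 1:500) {
    tb <- simulate_ct_table("G1", 6, 6, 0, ct_noise_sd = 0.2,
                            seed = 20000 + s)
    fc <- delta_delta_ct(tb, ctrl_group = "CTRL")
    p <- t.test(log2fc ~ group, data = fc)$p.value
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gte(rejections / 500, 0.03)
  expect_lte(rejections / 500, 0.07)
})
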