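test_that("unbranched growth has no junctions and is seed-deterministic", {
  cfg <- small_network_config(rng_seed = 3L, branch_probability = 0)
  net <- generate_vessel_network(cfg)
  expect_gt(nrow(net$segments), 0L)
  expect_equal(nrow(net$junction_points), 0L)

  net2 <- generate_vessel_network(cfg)
  expect_identical(net, net2)

  len <- with(net$segments, sqrt((r1 - r0)^2 + (c1 - c0)^2))
  expect_equal(net$total_length_um, sum(len) * cfg$pixel_size_um)

  # all segments inside image bounds
  expect_true(all(net$segments$r0 >= 1 & net$segments$r1 <= cfg$image_height_px))
  expect_true(all(net$segments$c0 >= 1 & net$segments$c1 <= cfg$image_width_px))
})

test_that("higher branch probability yields more junctions on average", {
  mean_j <- function(bp) {
    mean(vapply(1:20, function(s) {
      nrow(generate_vessel_network(
        small_network_config(rng_seed = s, branch_probability = bp)
      )$junction_points)
    }, numeric(1)))
  }
  expect_gt(mean_j(0.10), mean_j(0.02))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(network_config(image_height_px = 0), class = "vesselfract_config_error")
  expect_error(network_config(pixel_size_um = 0), class = "vesselfract_config_error")
  expect_error(network_config(branch_probability = 1.2), class = "vesselfract_config_error")
  expect_error(network_config(width_range_px = c(0, 2)), class = "vesselfract_config_error")
  expect_error(lesion_spec(c(1, 1), -1), class = "vesselfract_config_error")
  expect_error(lesion_spec(c(1, 1), 5, core_ablation_fraction = 2),
               class = "vesselfract_config_error")
})

test_that("ablation identity, full ablation and flat-core removal are exact", {
  net <- generate_vessel_network(small_network_config(rng_seed = 5L))
  # radius 0, global 0: identity
  les0 <- lesion_spec(c(128, 128), radius_px = 0, global_ablation_fraction = 0)
  expect_identical(ablate_network(net, les0, 1L)$segments, net$segments)

  # global 1: empty network
  les1 <- lesion_spec(c(128, 128), radius_px = 0, global_ablation_fraction = 1)
  gone <- ablate_network(net, les1, 1L)
  expect_equal(nrow(gone$segments), 0L)
  expect_equal(gone$total_length_um, 0)
  expect_equal(nrow(gone$junction_points), 0L)

  # flat core = 1: no surviving midpoint inside the radius
  lesc <- lesion_spec(c(128, 128), radius_px = 60,
                      core_ablation_fraction = 1, falloff = "flat")
  surv <- ablate_network(net, lesc, 2L)$segments
  if (nrow(surv)) {
    d <- sqrt(((surv$r0 + surv$r1) / 2 - 128)^2 +
              ((surv$c0 + surv$c1) / 2 - 128)^2)
    expect_true(all(d > 60))
  }
})

test_that("ablation never increases junction count or total length", {
  for (s in 1:5) {
    net <- generate_vessel_network(small_network_config(rng_seed = s))
    les <- lesion_spec(c(128, 128), radius_px = 60,
                       core_ablation_fraction = 0.8,
                       global_ablation_fraction = 0.3)
    ab <- ablate_network(net, les, rng_seed = s + 100L)
    expect_lte(ab$total_length_um, net$total_length_um)
    expect_lte(nrow(ab$junction_points), nrow(net$junction_points))
  }
})

test_that("rasterization draws segments at their widths over background", {
  cfg <- small_network_config(rng_seed = 1L)
  # empty network: pure background
  empty <- generate_vessel_network(small_network_config(1L, trunks = 0L))
  img <- rasterize_network(empty, cfg)
  expect_true(all(img < 0.5))

  # one horizontal 100-px segment of width 1: 100-101 foreground pixels
  one <- empty
  one$segments <- data.frame(r0 = 100, c0 = 50, r1 = 100, c1 = 150,
                             width_px = 1L)
  img1 <- rasterize_network(one, cfg)
  expect_true(sum(img1 > 0.5) >= 99 && sum(img1 > 0.5) <= 102)
  expect_equal(pixel_size(img1), cfg$pixel_size_um)
})

test_that("rasterize-binarize-skeletonize round trip recovers total length", {
  # sparse non-overlapping network (few trunks, no branching)
  cfg <- small_network_config(rng_seed = 8L, trunks = 10L,
                              branch_probability = 0)
  net <- generate_vessel_network(cfg)
  expect_gte(nrow(net$segments), 10L)
  img <- rasterize_network(net)
  mask <- binarize(img, method = "fixed", fixed_threshold = 0.5)
  g <- extract_network_graph(skeletonize_mask(mask), cfg$pixel_size_um)
  expect_lt(abs(g$total_length_um / net$total_length_um - 1), 0.10)
})

test_that("MR phantom realizes requested fractions and exact means", {
  cfg <- mr_phantom_config(lesion_fraction_of_brain = 0.038, noise_sd = 0,
                           hemorrhage_fraction_of_brain = 0, rng_seed = 2L)
  ph <- generate_mr_phantom(cfg)
  expect_gte(ph$realized_lesion_fraction, 0.034)
  expect_lte(ph$realized_lesion_fraction, 0.042)

  # noise-free: every voxel sits exactly at its compartment mean
  expect_setequal(unique(as.numeric(ph$t2)),
                  c(cfg$background_mean, cfg$brain_mean, cfg$lesion_mean))
  expect_true(all(ph$t2[ph$masks$lesion] == cfg$lesion_mean))
  expect_true(all(ph$phase == 0))

  # zero lesion fraction: empty lesion mask, bimodal volume
  ph0 <- generate_mr_phantom(mr_phantom_config(lesion_fraction_of_brain = 0,
                                               hemorrhage_fraction_of_brain = 0,
                                               noise_sd = 0))
  expect_equal(sum(ph0$masks$lesion), 0L)
  expect_equal(sort(unique(as.numeric(ph0$t2))), c(10, 100))

  # hemorrhage carries negative phase inside the lesion
  ph2 <- generate_mr_phantom(mr_phantom_config(noise_sd = 0, rng_seed = 4L))
  expect_true(all(ph2$phase[ph2$masks$hemorrhage] < 0))
  expect_true(all(ph2$masks$lesion[ph2$masks$hemorrhage]))

  # unrealizable request errors
  expect_error(generate_mr_phantom(
    mr_phantom_config(lesion_fraction_of_brain = 0.01,
                      hemorrhage_fraction_of_brain = 0.5)),
    class = "vesselfract_config_error")

  # determinism with noise
  cfgn <- mr_phantom_config(rng_seed = 11L)
  expect_identical(generate_mr_phantom(cfgn), generate_mr_phantom(cfgn))
})
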