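test_that("binarization separates a two-valued image exactly", {
  img <- vessel_image(matrix(c(rep(10, 60), rep(200, 40)) / 255, 10), 5)
  m <- binarize(img, method = "otsu")
  expect_identical(unclass(m)[, , drop = TRUE], unclass(img) > 100 / 255,
                   ignore_attr = TRUE)
  expect_equal(sum(m), 40L)
  expect_equal(pixel_size(m), 5)

  zero <- vessel_image(matrix(0, 5, 5), 1)
  expect_equal(sum(binarize(zero, method = "fixed", fixed_threshold = 1 / 255)),
               0L)
  expect_error(binarize(vessel_image(matrix(0.4, 5, 5), 1), method = "otsu"),
               class = "vesselfract_config_error")
})

test_that("skeletonization thins rectangles, disks and empty masks correctly", {
  rect <- matrix(FALSE, 20, 110)
  rect[9:11, 6:105] <- TRUE
  sk <- skeletonize_mask(rect)
  expect_true(all(sk <= rect))                  # skeleton inside the mask
  g <- extract_network_graph(sk, 1)
  expect_equal(g$junction_count, 0L)
  expect_gt(g$total_length_um, 90)
  expect_lt(g$total_length_um, 101)

  expect_equal(sum(skeletonize_mask(matrix(FALSE, 8, 8))), 0L)

  disk <- matrix(FALSE, 50, 50)
  disk[outer((1:50 - 25)^2, (1:50 - 25)^2, `+`) <= 400] <- TRUE
  skd <- skeletonize_mask(disk)
  expect_lte(sum(skd), 5L)
  gd <- extract_network_graph(skd, 1)
  expect_lt(gd$total_length_um, 0.10 * 40 * pi)
})

test_that("graph extraction counts junctions, endpoints and step lengths", {
  g <- extract_network_graph(make_plus(), 1)
  expect_equal(g$junction_count, 1L)
  expect_equal(sum(g$nodes$kind == "endpoint"), 4L)

  gl <- extract_network_graph(make_hline(10L), 1)
  expect_equal(gl$total_length_um, 9)
  expect_equal(gl$junction_count, 0L)

  gd <- extract_network_graph(make_diag(10L), 1)
  expect_equal(gd$total_length_um, 9 * sqrt(2))

  # pixel-size linearity: doubling the pixel size doubles the length
  gl2 <- extract_network_graph(make_hline(10L), 2)
  expect_equal(gl2$total_length_um, 2 * gl$total_length_um)
})

test_that("junction count matches an exhaustive neighbour-clustering oracle", {
  set.seed(42)
  for (rep in 1:8) {
    m <- matrix(FALSE, 20, 20)
    # random thin strokes, then thin to a valid skeleton
    for (k in 1:4) {
      r <- sample(3:18, 2); c <- sample(3:18, 2)
      n <- max(abs(r[2] - r[1]), abs(c[2] - c[1])) + 1L
      rr <- round(seq(r[1], r[2], length.out = n))
      cc <- round(seq(c[1], c[2], length.out = n))
      m[cbind(rr, cc)] <- TRUE
    }
    sk <- skeletonize_mask(m)
    g <- extract_network_graph(sk, 1)
    expect_equal(g$junction_count, oracle_junction_count(unclass(sk)))
  }
})

test_that("metrics are restricted to the ROI and densities are exact", {
  mask <- vessel_mask(matrix(FALSE, 30, 30), 2)
  g <- extract_network_graph(skeletonize_mask(mask), 2)
  met <- compute_metrics(mask, g)
  expect_equal(met$junction_count, 0L)
  expect_equal(met$total_length_um, 0)
  expect_equal(met$vessel_density, 0)

  full <- vessel_mask(matrix(TRUE, 10, 10), 2)
  gf <- extract_network_graph(skeletonize_mask(full), 2)
  metf <- compute_metrics(full, gf)
  expect_equal(metf$vessel_density, 1)
  expect_equal(metf$roi_area_um2, 100 * 4)

  expect_error(compute_metrics(full, gf, matrix(FALSE, 10, 10)),
               class = "vesselfract_config_error")
  expect_error(compute_metrics(full, gf, matrix(TRUE, 5, 5)),
               class = "vesselfract_config_error")

  # ROI restriction: only steps and junctions inside the ROI count
  plus <- vessel_mask(make_plus(), 1)
  gp <- extract_network_graph(unclass(plus), 1)
  left <- matrix(FALSE, 21, 21); left[, 1:10] <- TRUE
  mp <- compute_metrics(plus, gp, left)
  expect_equal(mp$junction_count, 0L)   # cluster centre sits on the midline
  expect_lt(mp$total_length_um, gp$total_length_um / 2)
})

test_that("junctions and total length are invariant under rotations and flips", {
  for (s in 1:3) {
    cfg <- small_network_config(rng_seed = s, size = 192L, trunks = 12L)
    net <- generate_vessel_network(cfg)
    img <- rasterize_network(net, noise_sd = 0.02, rng_seed = s)
    mask <- unclass(binarize(img))
    attributes(mask) <- list(dim = dim(mask))
    vals <- vapply(d4_variants(mask), function(v) {
      g <- extract_network_graph(skeletonize_mask(v), 20)
      c(g$junction_count, g$total_length_um)
    }, numeric(2))
    expect_true(all(vals[1, ] == vals[1, 1]))
    expect_equal(max(abs(vals[2, ] - vals[2, 1])), 0, tolerance = 1e-6)
  }
})

test_that("synthetic junction counts are recovered from rasterized images", {
  ratios <- vapply(1:6, function(s) {
    cfg <- small_network_config(rng_seed = s)
    net <- generate_vessel_network(cfg)
    img <- rasterize_network(net, noise_sd = 0.02, rng_seed = s + 50L)
    g <- extract_network_graph(skeletonize_mask(binarize(img)), 20)
    g$junction_count / nrow(net$junction_points)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.10)
})
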