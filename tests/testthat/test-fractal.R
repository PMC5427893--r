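cfg_stride1 <- fractal_config(stride_px = 1L)

test_that("LFD is 1 on a line, 2 on a filled square", {
  line <- matrix(FALSE, 101, 101)
  line[51, ] <- TRUE
  mp <- local_fractal_dimension_map(line, config = cfg_stride1)
  expect_equal(mp$lfd[51, 51], 1, tolerance = 0.05)

  sq <- matrix(TRUE, 101, 101)
  mp2 <- local_fractal_dimension_map(sq, config = cfg_stride1)
  expect_equal(mp2$lfd[51, 51], 2, tolerance = 0.05)
})

test_that("mean LFD of a level-7 Sierpinski triangle matches box counting", {
  sp <- sierpinski_mask(7L)
  oracle <- box_count_dimension(sp)
  expect_equal(oracle, log(3) / log(2), tolerance = 0.05)

  mp <- local_fractal_dimension_map(sp, config = cfg_stride1)
  interior <- matrix(FALSE, 128, 128)
  interior[17:112, 17:112] <- TRUE
  sel <- mp$valid_mask & interior
  expect_gt(sum(sel), 500)
  expect_equal(mean(mp$lfd[sel]), oracle, tolerance = 0.10)
  expect_equal(mean(mp$lfd[sel]), log(3) / log(2), tolerance = 0.10)
})

test_that("LFD histograms are normalized over fixed bins", {
  mk_map <- function(values) {
    lfd <- matrix(NA_real_, 4, 4)
    lfd[seq_along(values)] <- values
    structure(list(lfd = lfd, valid_mask = !is.na(lfd),
                   n_clipped = 0L, n_invalid = 0L,
                   n_valid = length(values), config = fractal_config()),
              class = "lfd_map")
  }
  h1 <- lfd_histogram(mk_map(rep(1.5, 8)))
  expect_equal(sum(h1$relative_frequencies), 1, tolerance = 1e-9)
  expect_equal(sum(h1$relative_frequencies > 0), 1L)
  expect_equal(max(h1$relative_frequencies), 1)

  h2 <- lfd_histogram(mk_map(c(1.0, 2.0, 1.0, 2.0)))
  expect_equal(sort(h2$relative_frequencies[h2$relative_frequencies > 0]),
               c(0.5, 0.5))

  set.seed(1)
  h3 <- lfd_histogram(mk_map(runif(16, 0, 2.2)))
  expect_equal(sum(h3$relative_frequencies), 1, tolerance = 1e-9)

  empty <- mk_map(numeric(0))
  expect_error(lfd_histogram(empty))
})

test_that("moment features follow the sample distribution", {
  # symmetric triangular sample: zero skewness
  tri <- c(seq(1, 2, by = 0.01), seq(2, 1, by = -0.01))
  f <- fractal_features(tri)
  expect_equal(f$skewness, 0, tolerance = 0.02)

  # normal draws: excess kurtosis 0
  set.seed(123)
  v <- rnorm(1e5, mean = 1.1, sd = 0.15)
  fn <- fractal_features(v)
  expect_equal(fn$kurtosis, 0, tolerance = 0.05)
  expect_equal(fn$skewness, 0, tolerance = 0.05)

  # degenerate single-valued map
  fd <- fractal_features(rep(1.25, 50))
  expect_equal(fd$peak_frequency, 1)
  expect_false(fd$moments_defined)
  expect_true(is.na(fd$skewness) && is.na(fd$kurtosis))
})

test_that("the LFD value multiset is invariant under rotations and flips", {
  cfg <- small_network_config(rng_seed = 4L, size = 128L, trunks = 10L)
  mask <- unclass(binarize(rasterize_network(generate_vessel_network(cfg))))
  attributes(mask) <- list(dim = dim(mask))
  ref <- sort(local_fractal_dimension_map(mask, config = cfg_stride1)$lfd,
              na.last = NA)
  for (v in d4_variants(mask)) {
    got <- sort(local_fractal_dimension_map(v, config = cfg_stride1)$lfd,
                na.last = NA)
    expect_equal(got, ref)
  }
})

test_that("features are stable under stride subsampling", {
  cfg <- network_config(rng_seed = 6L)    # full-density plexus
  mask <- binarize(rasterize_network(generate_vessel_network(cfg),
                                     noise_sd = 0.02, rng_seed = 6L))
  f1 <- fractal_features(local_fractal_dimension_map(
    mask, config = fractal_config(stride_px = 1L)))
  f4 <- fractal_features(local_fractal_dimension_map(
    mask, config = fractal_config(stride_px = 4L)))
  expect_lte(abs(f1$peak_lfd - f4$peak_lfd), 0.02)
  expect_lte(abs(f1$skewness - f4$skewness), 0.1)
})

test_that("an ROI without foreground yields an empty flagged map", {
  mask <- matrix(FALSE, 40, 40)
  mp <- local_fractal_dimension_map(mask, config = fractal_config())
  expect_equal(mp$n_valid, 0L)
  expect_false(any(mp$valid_mask))
})

test_that("ablation shifts the LFD histogram left and flattens it", {
  # focal + global lesion vs sham-like network, a handful of replicates
  n_ok <- 0L
  nrep <- 5L
  for (i in seq_len(nrep)) {
    cfg <- network_config(image_height_px = 384L, image_width_px = 384L,
                          n_seed_trunks = 24L, max_steps = 80L,
                          rng_seed = 500L + i)
    net <- generate_vessel_network(cfg)
    les <- lesion_spec(c(192, 269), radius_px = 75,
                       core_ablation_fraction = 0.9,
                       global_ablation_fraction = 0.4)
    ab <- ablate_network(net, les, rng_seed = 600L + i)
    feats <- function(n, s) {
      img <- rasterize_network(n, noise_sd = 0.02, rng_seed = s)
      fractal_features(local_fractal_dimension_map(binarize(img),
                                                   config = fractal_config()))
    }
    a <- feats(net, 700L + i)
    b <- feats(ab, 800L + i)
    if (b$peak_lfd < a$peak_lfd && b$peak_frequency < a$peak_frequency &&
        b$skewness < a$skewness && b$kurtosis < a$kurtosis)
      n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, nrep - 1L)
})
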