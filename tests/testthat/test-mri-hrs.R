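test_that("SWI phase mask follows its closed form", {
  # zero phase leaves the magnitude untouched (homodyne included)
  ph <- generate_mr_phantom(mr_phantom_config(rng_seed = 3L))
  s0 <- swi_process(ph$magnitude, array(0, dim(ph$magnitude)))
  expect_lt(max(abs(s0$swi - ph$magnitude)), 1e-8)

  # closed-form mask values, exercised through swi_process without filtering
  s1 <- swi_process(matrix(100, 8, 8), matrix(-pi / 2, 8, 8), hanning_size = 0)
  expect_equal(unique(as.numeric(s1$swi)), 100 * 0.5^4)
  s2 <- swi_process(matrix(100, 8, 8), matrix(-pi, 8, 8), hanning_size = 0)
  expect_equal(unique(as.numeric(s2$swi)), 0)
  expect_equal(swi_phase_mask(c(-pi, -pi / 2, 0, 1)), c(0, 0.5, 1, 1))

  expect_error(swi_process(matrix(1, 4, 4), matrix(0, 4, 5)),
               class = "vesselfract_config_error")
})

test_that("HRS leaves a uniform region unsplit", {
  dm <- c(16L, 16L, 4L)
  vol <- array(50, dm)
  tree <- hrs_segment(vol, array(TRUE, dm))
  expect_length(tree$leaves, 1L)
  expect_equal(tree$leaves[[1L]]$mean, 50)
  expect_true(is.na(hrs_first_split(tree)))
  expect_error(hrs_segment(vol, array(FALSE, dm)),
               class = "vesselfract_config_error")
})

test_that("HRS splits a two-Gaussian phantom at the histogram valley", {
  tg <- two_gaussian_volume(seed = 9L)
  tree <- hrs_segment(tg$volume, tg$brain)
  expect_gte(hrs_first_split(tree), 100)
  expect_lte(hrs_first_split(tree), 140)
  mns <- vapply(tree$leaves, `[[`, numeric(1), "mean")
  expect_lt(min(abs(mns - 60)), 3)
  expect_lt(min(abs(mns - 180)), 3)
})

test_that("HRS separates three compartments to their true means", {
  dm <- c(48L, 48L, 12L)
  set.seed(21)
  vol <- array(rnorm(prod(dm), 40, 5), dm)
  mid <- array(FALSE, dm); mid[8:20, 8:40, 3:10] <- TRUE
  hot <- array(FALSE, dm); hot[30:42, 8:40, 3:10] <- TRUE
  vol[mid] <- rnorm(sum(mid), 120, 5)
  vol[hot] <- rnorm(sum(hot), 220, 5)
  tree <- hrs_segment(vol, array(TRUE, dm))
  mns <- vapply(tree$leaves, `[[`, numeric(1), "mean")
  expect_gte(length(tree$leaves), 3L)
  for (target in c(40, 120, 220)) expect_lt(min(abs(mns - target)), 5)
})

test_that("the HRS tree is a partition at every node", {
  tg <- two_gaussian_volume(seed = 10L)
  tree <- hrs_segment(tg$volume, tg$brain)
  check_node <- function(node) {
    if (is.null(node$children)) return(invisible(TRUE))
    kids <- c(node$children[[1L]]$idx, node$children[[2L]]$idx)
    expect_setequal(kids, node$idx)
    expect_equal(length(kids), length(node$idx))   # disjoint children
    check_node(node$children[[1L]])
    check_node(node$children[[2L]])
  }
  check_node(tree$root)
  # leaves partition the root
  all_leaf <- sort(unlist(lapply(tree$leaves, `[[`, "idx")))
  expect_identical(all_leaf, sort(tree$root$idx))
})

test_that("HRS is equivariant under constant intensity shifts", {
  tg <- two_gaussian_volume(seed = 12L)
  t1 <- hrs_segment(tg$volume, tg$brain)
  t2 <- hrs_segment(tg$volume + 500, tg$brain)
  m1 <- vapply(t1$leaves, `[[`, numeric(1), "mean")
  m2 <- vapply(t2$leaves, `[[`, numeric(1), "mean")
  expect_equal(sort(m2), sort(m1) + 500, tolerance = 1e-8)
  idx1 <- lapply(t1$leaves, `[[`, "idx")
  idx2 <- lapply(t2$leaves, `[[`, "idx")
  expect_setequal(vapply(idx1, paste, "", collapse = ","),
                  vapply(idx2, paste, "", collapse = ","))
})

test_that("lesion extraction by a-priori mean recovers the phantom lesion", {
  tg <- two_gaussian_volume(seed = 9L)
  tree <- hrs_segment(tg$volume, tg$brain)

  none <- extract_lesion(tree, hrs_config(), tg$brain,
                         mean_target = 500, mean_tolerance = 10)
  expect_equal(none$volume_percent, 0)

  les <- extract_lesion(tree, hrs_config(), tg$brain,
                        mean_target = 180, mean_tolerance = 10)
  expect_gte(dice_coefficient(les$lesion_mask, tg$lesion), 0.90)
  true_pct <- 100 * sum(tg$lesion) / sum(tg$brain)
  expect_lt(abs(les$volume_percent / true_pct - 1), 0.15)
})

test_that("SWI + HRS recovers the phantom hemorrhage", {
  ph <- generate_mr_phantom(mr_phantom_config(rng_seed = 3L))
  sw <- swi_process(ph$magnitude, ph$phase)
  tree <- hrs_segment(sw$swi, ph$masks$brain)
  mns <- vapply(tree$leaves, `[[`, numeric(1), "mean")
  # window of 40 below the darkest leaf: the fourth-power mask compresses
  # hemorrhage well below half the brain intensity, and partial-phase
  # boundary leaves land in between
  hem <- extract_lesion(tree, hrs_config(), ph$masks$brain,
                        mean_target = min(mns), mean_tolerance = 40)
  expect_gte(dice_coefficient(hem$lesion_mask, ph$masks$hemorrhage), 0.8)
})

test_that("the threshold fallback recovers the phantom brain mask", {
  ph <- generate_mr_phantom(mr_phantom_config(rng_seed = 5L))
  bm <- estimate_brain_mask(ph$t2)
  expect_gte(dice_coefficient(bm, ph$masks$brain), 0.95)
})

test_that("volumes round-trip through NIfTI and overlays are written", {
  ph <- generate_mr_phantom(mr_phantom_config(shape_voxels = c(24L, 24L, 8L),
                                              rng_seed = 6L))
  f <- tempfile(fileext = ".nii.gz")
  write_volume_nifti(ph$t2, f, ph$config$voxel_size_mm)
  back <- read_volume_nifti(f)
  expect_equal(dim(back), dim(ph$t2))
  expect_equal(as.numeric(back), as.numeric(ph$t2), tolerance = 1e-6)

  paths <- write_lesion_overlay_png(ph$t2, ph$masks$lesion,
                                    file.path(tempdir(), "ovl"))
  expect_length(paths, 8L)
  expect_true(all(file.exists(paths)))
})
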