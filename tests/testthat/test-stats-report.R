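test_that("percent reduction reproduces the published group effects", {
  # junctions, total length and vessel density group means
  expect_equal(round(percent_reduction(3239.60, 2124.67), 1), 34.4)
  expect_equal(round(percent_reduction(122.31, 95.96), 1), 21.5)
  expect_equal(round(percent_reduction(115.83, 85.75), 1), 26.0)

  expect_equal(percent_reduction(7, 7), 0)
  expect_equal(percent_reduction(10, 15), -50)
  expect_error(percent_reduction(0, 1), class = "vesselfract_config_error")

  # complement identity: reduction + 100 * treated/control = 100
  for (p in list(c(3239.60, 2124.67), c(5, 1), c(2, 9))) {
    expect_equal(percent_reduction(p[1], p[2]) + 100 * p[2] / p[1], 100,
                 tolerance = 1e-9)
  }
})

test_that("group comparisons handle identical, equal and degenerate groups", {
  set.seed(7)
  x <- rnorm(6)
  cmp <- group_compare(list(a = x, b = x), design = "two_group_t")
  expect_equal(cmp$comparisons$t_statistic, 0)
  expect_equal(cmp$comparisons$p_value, 1)

  g3 <- group_compare(list(a = x, b = x, c = x), design = "anova_bonferroni")
  expect_true(all(g3$comparisons$adjusted_p == 1))

  deg <- group_compare(list(a = rep(2, 4), b = rep(2, 4)))
  expect_true(deg$comparisons$degenerate)
  expect_true(is.na(deg$comparisons$t_statistic))

  expect_error(group_compare(list(a = 1:3, b = 4:6, c = 7:9),
                             design = "two_group_t"),
               class = "vesselfract_config_error")
  expect_error(group_compare(list(a = 1, b = 2:4)),
               class = "vesselfract_config_error")
})

test_that("Bonferroni adjustment grows with the number of comparisons", {
  set.seed(11)
  gs <- lapply(1:4, function(i) rnorm(6, mean = 0.3 * i))
  names(gs) <- paste0("g", 1:4)
  p2 <- group_compare(gs[1:2], design = "anova_bonferroni")$comparisons
  p4 <- group_compare(gs, design = "anova_bonferroni")$comparisons
  k <- p4$group_a == "g1" & p4$group_b == "g2"
  expect_equal(p2$p_value[1], p4$p_value[k])
  expect_gte(p4$adjusted_p[k], p2$adjusted_p[1])
  expect_true(all(p4$adjusted_p <= 1))
  expect_true(all(p4$adjusted_p >= p4$p_value))
})

test_that("correlation returns exact r-squared for exact relations", {
  x <- 1:10
  expect_equal(correlate(x, 2 * x + 1)$r_squared, 1)

  y <- rnorm(10)
  resid <- y - fitted(lm(y ~ x))     # orthogonal to x by construction
  expect_lt(correlate(x, resid)$r_squared, 1e-12)

  expect_error(correlate(x, rep(1, 10)), class = "vesselfract_config_error")
  expect_error(correlate(1:2, 1:2), class = "vesselfract_config_error")
})

test_that("reports summarize groups and flag non-computable effects", {
  set.seed(3)
  tb <- expand.grid(group = c("sham", "tbi"), subject = 1:4,
                    region = c("whole", "ring1"),
                    metric = c("junction_count", "vessel_density"),
                    stringsAsFactors = FALSE)
  tb$value <- rnorm(nrow(tb), mean = ifelse(tb$group == "sham", 10, 7))
  rep1 <- build_report(tb)
  expect_equal(nrow(rep1$effects), 4L)           # metric x region
  expect_true(all(rep1$effects$computable))
  expect_equal(nrow(rep1$summary), 8L)
  expect_true(all(c("percent_reduction", "p_value") %in% names(rep1$effects)))

  # an empty treated group is reported but marked not computable
  rep2 <- build_report(tb[tb$group == "sham", ])
  expect_true(all(!rep2$effects$computable))
  expect_true(all(is.na(rep2$effects$p_value)))

  expect_error(build_report(tb[, -5]), class = "vesselfract_config_error")

  # deterministic serialization: regenerating writes identical bytes
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  m1 <- tempfile(fileext = ".md"); m2 <- tempfile(fileext = ".md")
  write_report(rep1, f1, m1)
  write_report(build_report(tb), f2, m2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(readLines(m1), readLines(m2))
})
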