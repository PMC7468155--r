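test_that("unit vectors land on the unit circle at the expected points", {
  a <- angle_set(c(0, pi / 2, pi / 4), "direction", warn_small = FALSE)
  v <- unit_vectors(a)
  expect_equal(v[1, ], c(x = 1, y = 0))
  expect_equal(v[2, ], c(x = 0, y = 1), tolerance = 1e-12)
  expect_equal(unname(v[3, ]), c(0.70710678, 0.70710678), tolerance = 1e-8)
  expect_equal(unname(sqrt(rowSums(v^2))), rep(1, 3))
})

test_that("resultant length matches closed-form cases", {
  expect_equal(resultant_length(rep(1.234, 7)), 1)
  expect_equal(resultant_length(deg2rad(c(0, 120, 240))), 0, tolerance = 1e-12)
  expect_equal(resultant_length(deg2rad(c(0, 90))), sqrt(2) / 2,
               tolerance = 1e-12)
})

test_that("circular SD follows S = sqrt(-2 ln R) with the R = 0 sentinel", {
  expect_equal(circular_sd(rep(0.7, 12)), 0)
  expect_identical(circular_sd(deg2rad(c(0, 180))), Inf)
  expect_equal(circular_sd(deg2rad(c(0, 90))), sqrt(-2 * log(sqrt(2) / 2)),
               tolerance = 1e-12)
  expect_equal(circular_sd(deg2rad(c(0, 90))), 0.83255461, tolerance = 1e-7)
})

test_that("circular mean handles wraparound and the undefined case", {
  expect_equal(circular_mean(deg2rad(c(350, 10))), 0, tolerance = 1e-12)
  expect_equal(circular_mean(rep(2.5, 5)), 2.5)
  expect_equal(circular_mean(deg2rad(c(0, 90))), pi / 4, tolerance = 1e-12)
  expect_true(is.na(circular_mean(deg2rad(c(0, 120, 240)))))
})

test_that("R and S are invariant under rotation and period shifts", {
  set.seed(42)
  for (i in 1:20) {
    th <- stats::runif(sample(2:40, 1), 0, 2 * pi)
    rot <- stats::runif(1, -10, 10)
    expect_equal(resultant_length(th + rot), resultant_length(th),
                 tolerance = 1e-12)
    expect_equal(circular_sd(th + 2 * pi), circular_sd(th), tolerance = 1e-12)
  }
  # axis mode: adding pi to an observation changes nothing
  set.seed(7)
  th <- stats::runif(20, 0, pi)
  a1 <- angle_set(th, "axis", warn_small = FALSE)
  th2 <- th + ifelse(seq_along(th) %% 2 == 0, pi, 0)
  a2 <- angle_set(th2, "axis", warn_small = FALSE)
  expect_equal(summarize_angles(a1)$S, summarize_angles(a2)$S,
               tolerance = 1e-12)
})

test_that("axial summaries double the angles", {
  # 10 and 190 degrees are the same axis
  a <- angle_set(deg2rad(c(10, 190)), "axis", warn_small = FALSE)
  s <- axial_summary(a)
  expect_equal(s$R, 1, tolerance = 1e-12)
  expect_equal(s$S, 0, tolerance = 1e-6)
  expect_equal(s$mean_angle_rad, deg2rad(10), tolerance = 1e-9)
  # orthogonal axes are maximally spread
  b <- angle_set(deg2rad(c(0, 90)), "axis", warn_small = FALSE)
  sb <- axial_summary(b)
  expect_equal(sb$R, 0, tolerance = 1e-12)
  expect_identical(sb$S, Inf)
  # 45-degree separation behaves like 90 degrees of directional data
  d <- angle_set(deg2rad(c(0, 45)), "axis", warn_small = FALSE)
  expect_equal(axial_summary(d)$S, 0.83255461, tolerance = 1e-7)
})

test_that("summarize_angles dispatches by mode and bundles n, mean, R, S", {
  s <- summarize_angles(angle_set(rep(1.2, 20), "direction"))
  expect_equal(s[c("n", "R", "S")], list(n = 20L, R = 1, S = 0))
  expect_equal(s$mean_angle_rad, 1.2)
  expect_s3_class(s, "CircularSummary")
  ax <- summarize_angles(angle_set(rep(0.4, 20), "axis"))
  expect_equal(ax$mode, "axis")
  expect_equal(ax$S, 0)
})

test_that("large von Mises samples match the Bessel-ratio closed form", {
  set.seed(123)
  for (kappa in c(1, 400)) {
    th <- rvonmises(1e5, mu = 1, kappa = kappa)
    s <- circular_sd(th)
    expect_equal(s, vonmises_circular_sd(kappa),
                 tolerance = if (kappa == 1) 0.02 else 0.1)
  }
  # the two regimes bracket the healthy (~0.07) vs disorganized (~1.29)
  # dispersion levels seen in airway epithelia
  expect_lt(vonmises_circular_sd(400), 0.08)
  expect_gt(vonmises_circular_sd(1), 1.2)
})

test_that("expected circular SD decreases with concentration", {
  kap <- c(0.5, 1, 2, 5, 20, 100, 400)
  expect_true(all(diff(vonmises_circular_sd(kap)) < 0))
  # and the empirical S of samples follows the same ordering
  set.seed(9)
  emp <- sapply(c(1, 10, 100), function(k) circular_sd(rvonmises(2000, 0, k)))
  expect_true(all(diff(emp) < 0))
})

test_that("kappa = 0 sampling is uniform: resultant is O(1/sqrt(n))", {
  set.seed(5)
  n <- 4000
  r <- replicate(20, resultant_length(rvonmises(n, 0, 0)))
  # under uniformity E[R] ~ sqrt(pi)/(2 sqrt(n)); 10/sqrt(n) is ~20 sigma
  expect_true(all(r < 10 / sqrt(n)))
})

test_that("rose histograms conserve counts with half-open bins", {
  set.seed(31)
  th <- stats::runif(57, 0, 2 * pi)
  a <- angle_set(th, "direction")
  r <- rose_histogram(a, bin_width_deg = 15)
  expect_equal(sum(r$counts), 57)
  expect_length(r$counts, 24)
  # an angle exactly on an edge goes to the higher bin
  b <- angle_set(deg2rad(c(15, 30)), "direction", warn_small = FALSE)
  rb <- rose_histogram(b, bin_width_deg = 15)
  expect_equal(rb$counts[2], 1)  # [15, 30)
  expect_equal(rb$counts[3], 1)  # [30, 45)
  # 16 angles at 16 distinct bin centers, width 22.5 -> all counts 1
  cent <- angle_set(deg2rad(seq(11.25, 360, by = 22.5)), "direction")
  expect_equal(rose_histogram(cent, 22.5)$counts, rep(1L, 16))
  # axis mode spans [0, 180)
  ax <- rose_histogram(angle_set(stats::runif(20, 0, pi), "axis"), 15)
  expect_length(ax$counts, 12)
  expect_error(rose_histogram(a, bin_width_deg = 17), "divide")
})

test_that("rose data frame and plot export are consistent", {
  a <- angle_set(deg2rad(c(5, 5, 50, 100)), "direction", warn_small = FALSE)
  r <- rose_histogram(a, 45)
  df <- as.data.frame(r)
  expect_equal(names(df), c("bin_start_deg", "bin_end_deg", "count"))
  expect_equal(sum(df$count), 4)
  expect_equal(df$bin_end_deg - df$bin_start_deg, rep(45, 8))
  p <- plot_rose(r)
  expect_s3_class(p, "ggplot")
})

test_that("angle sets validate input and warn below the 15-cell minimum", {
  expect_warning(angle_set(deg2rad(1:14), "direction"), "15 ciliated cells")
  expect_silent(angle_set(deg2rad(1:15), "direction"))
  expect_error(angle_set(numeric(0), "direction"), "at least one")
  expect_error(angle_set(c(0, NaN), "direction"), "finite")
  # fundamental-domain storage
  a <- angle_set(deg2rad(370), "direction", warn_small = FALSE)
  expect_equal(rad2deg(a$angles_rad), 10, tolerance = 1e-9)
  b <- angle_set(deg2rad(200), "axis", warn_small = FALSE)
  expect_equal(rad2deg(b$angles_rad), 20, tolerance = 1e-9)
})
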