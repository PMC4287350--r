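test_that("DFT magnitudes behave on pure signals", {
  co <- fourier_coefficients(rep(3, 8))
  expect_equal(unname(co["coeff0"]), 24)
  expect_equal(unname(co[paste0("coeff", 1:7)]), rep(0, 7))
  expect_equal(harmonic_ratio(co), 0)
  t <- 0:7
  co1 <- fourier_coefficients(cos(2 * pi * t / 8))
  expect_equal(unname(co1["coeff1"]), 4)
  expect_equal(unname(co1["coeff7"]), 4)
  expect_equal(unname(co1[c("coeff2", "coeff3", "coeff4")]), rep(0, 3))
  expect_equal(harmonic_ratio(co1), 1)
  co2 <- fourier_coefficients(cos(4 * pi * t / 8))
  expect_equal(unname(co2["coeff2"]), 4)
  expect_equal(harmonic_ratio(co2), 0)
  expect_error(fourier_coefficients(1:7), "exactly 8")
})

test_that("conjugate symmetry and Parseval hold for arbitrary profiles", {
  set.seed(9)
  for (rep in 1:25) {
    x <- runif(8, 0, 200)
    co <- fourier_coefficients(x)
    expect_equal(unname(co[paste0("coeff", 1:3)]),
                 unname(co[paste0("coeff", 7:5)]))
    expect_equal(sum(co^2), 8 * sum(x^2), tolerance = 1e-9)
  }
})

test_that("the three-criterion classifier matches direct evaluation", {
  # cosine profile: amplitude 15 about mean 30 gives ln(45/15) = 1.0986,
  # a borderline miss of the 1.1 fold criterion; amplitude 16 clears it
  t <- seq(0, 140, by = 20)
  p15 <- 30 + 15 * cos(2 * pi * (t - 40) / 160)
  p16 <- 30 + 16 * cos(2 * pi * (t - 40) / 160)
  d15 <- is_regulated(p15, detail = TRUE)
  expect_gt(d15$ratio, 0.35)
  expect_false(d15$criteria[["fold"]])
  expect_false(d15$regulated)
  d16 <- is_regulated(p16, detail = TRUE)
  # sampled extrema: max at t=40, min at t=120 gives ln(46/14) = 1.19
  expect_equal(d16$log_fold, log(46 / 14))
  expect_true(d16$regulated)
  expect_false(is_regulated(rep(50, 8)))              # ratio 0
  # pure first harmonic with peak 15: fails only the a >= 20 floor
  low <- 7.5 * (1 + cos(2 * pi * t / 160))
  expect_equal(is_regulated(low, detail = TRUE)$a, 15)
  expect_false(is_regulated(low))
  # a zero trough passes the fold criterion when the peak is high enough
  expect_true(is_regulated(c(0, 10, 40, 80, 40, 10, 0, 0)))
})

test_that("criteria 1-2 are scale-invariant, criterion 3 is not", {
  t <- seq(0, 140, by = 20)
  prof <- 40 * exp(0.8 * cos(2 * pi * (t - 60) / 160))
  for (s in c(0.01, 0.5, 1, 20)) {
    d <- is_regulated(prof * s, detail = TRUE)
    d1 <- is_regulated(prof, detail = TRUE)
    expect_equal(d$ratio, d1$ratio, tolerance = 1e-12)
    expect_equal(d$log_fold, d1$log_fold, tolerance = 1e-12)
  }
  expect_true(is_regulated(prof))
  expect_false(is_regulated(prof * 0.01))             # fails only a >= 20
})

test_that("pure higher harmonics are never classified regulated", {
  t <- 0:7
  for (k in 2:4) {
    prof <- 100 * (1 + 0.9 * cos(2 * pi * k * t / 8))
    expect_equal(harmonic_ratio(prof), 0, tolerance = 1e-9)
    expect_false(is_regulated(prof))
  }
})

test_that("display normalization centers, bounds, and scales profiles", {
  lev <- c(2, 2, 8, 2, 2, 2, 2, 2)
  y <- normalize_profile(lev, pseudocount = 0)
  # hand oracle: log2 -> (1,1,3,1,...), mean 1.25, maxabs 1.75
  expect_equal(y, (log2(lev) - 1.25) / 1.75)
  expect_equal(max(y), 1)
  expect_equal(normalize_profile(rep(7, 8)), rep(0, 8))
  set.seed(2)
  for (rep in 1:10) {
    y <- normalize_profile(rpois(8, 40))
    expect_true(all(y >= -1 & y <= 1))
    expect_equal(mean(y), 0)
    expect_true(any(abs(y) == 1) || all(y == 0))
  }
})

test_that("peak time uses the 20-min grid with earliest-tie rule", {
  expect_equal(peak_time(c(0, 0, 0, 9, 1, 0, 0, 0)), 60)
  expect_equal(peak_time(rep(5, 8)), 0)
  x <- c(0, 0, 7, 0, 0, 7, 0, 0)                      # ties at 40 and 100
  expect_equal(peak_time(x), 40)
})

test_that("k-means recovers planted phase groups and orders by peak time", {
  set.seed(5)
  mk <- function(phase, n) t(replicate(n, normalize_profile(
    rpois(8, cosine_profile(80, 1, phase)))))
  X <- rbind(mk(20, 12), mk(120, 12))
  truth <- rep(1:2, each = 12)
  cl <- kmeans_profiles(X, k = 2, seed = 0)
  expect_equal(rand_index(cl, truth), 1.0)
  expect_equal(unique(cl[1:12]), 1L)    # earlier peak -> lower label
  expect_equal(unique(cl[13:24]), 2L)
  # duplicates share a label; k = 1 puts everything together
  X2 <- X[c(1, 1, 15), ]
  cl2 <- kmeans_profiles(X2, k = 2, seed = 0)
  expect_equal(cl2[1], cl2[2])
  expect_equal(kmeans_profiles(X, k = 1), rep(1L, nrow(X)))
  expect_warning(kmeans_profiles(X2[c(1, 1), ], k = 3), "reducing k")
})

test_that("hierarchical grouping recovers planted groups", {
  set.seed(6)
  mk <- function(phase, n) t(replicate(n, normalize_profile(
    rpois(8, cosine_profile(80, 1, phase)))))
  X <- rbind(mk(0, 8), mk(60, 8), mk(120, 8))
  truth <- rep(1:3, each = 8)
  g <- hierarchical_groups(X, 3)
  expect_equal(rand_index(g, truth), 1.0)
  expect_equal(length(unique(hierarchical_groups(X, nrow(X)))), nrow(X))
  # identical profiles merge first
  X3 <- rbind(X[1, ], X[1, ], X[24, ])
  g3 <- hierarchical_groups(X3, 2)
  expect_equal(g3[1], g3[2])
  expect_false(g3[3] == g3[1])
})
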