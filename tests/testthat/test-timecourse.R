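test_that("the spline basis has the advertised rank and span", {
  days <- c(3, 9, 11, 15, 20)
  b3 <- spline_basis(days, df = 3)
  expect_equal(dim(b3), c(5L, 4L))
  expect_equal(qr(b3)$rank, 4L)

  # df = 1: a natural spline with no interior knot is linear, so the basis
  # spans {1, t} exactly
  b1 <- spline_basis(days, df = 1)
  fit <- stats::lm.fit(b1, days)
  expect_lt(max(abs(fit$residuals)), 1e-10)

  expect_error(spline_basis(days, df = 4), "df")
  expect_error(spline_basis(c(3, 9), df = 1), "3 distinct")

  # any function already in the span is reproduced exactly by projection
  set.seed(7)
  for (i in 1:10) {
    y <- b3 %*% rnorm(4)
    proj <- b3 %*% qr.solve(crossprod(b3), crossprod(b3, y))
    expect_lt(max(abs(proj - y)), 1e-10)
  }
})

test_that("the strain statistic compares nested least-squares fits", {
  days <- c(3, 9, 11, 15, 20)
  basis <- spline_basis(days)

  flat <- matrix(5, 2, 5)
  s <- strain_statistic(flat, basis)
  expect_equal(s$f_stat, 0)
  expect_equal(s$rss0, 0)

  # exact linear trend: spline absorbs it, F hits rss0 / delta
  lin <- rbind(2 * days, 2 * days)
  s2 <- strain_statistic(lin, basis)
  rss0_oracle <- sum((c(lin) - mean(lin))^2)
  expect_lt(s2$rss1, 1e-16)
  expect_equal(s2$f_stat, min(rss0_oracle / 1e-8, 1e12), tolerance = 1e-6)

  # opposite trends in the two replicates: no consistent change, F ~ 0
  opp <- rbind(days - mean(days), mean(days) - days)
  s3 <- strain_statistic(opp, basis)
  x <- basis[rep(1:5, each = 2), ]
  y <- c(opp)
  rss1_oracle <- sum(stats::lm.fit(x, y)$residuals^2)
  rss0_o <- sum((y - mean(y))^2)
  expect_equal(s3$f_stat, (rss0_o - rss1_oracle) / (rss1_oracle + 1e-8))
  expect_lt(s3$f_stat, 1e-6)

  # pivotality: adding a constant leaves the statistic unchanged
  set.seed(12)
  obs <- matrix(rnorm(10), 2, 5)
  expect_equal(strain_statistic(obs + 7, basis)$f_stat,
               strain_statistic(obs, basis)$f_stat, tolerance = 1e-9)

  # nested models: rss1 <= rss0 on random inputs
  for (i in 1:20) {
    si <- strain_statistic(matrix(rnorm(10), 2, 5), basis)
    expect_lte(si$rss1, si$rss0)
  }
})

test_that("the pooled permutation null is well-formed and calibrated", {
  prof <- trend_profiles(10, slope = 0, noise_sd = 0.3, seed = 3)
  basis <- spline_basis(prof$days)
  null2 <- suppressWarnings(permutation_null(prof, basis, b = 2, seed = 1))
  expect_length(null2$stats, 20)
  null2b <- suppressWarnings(permutation_null(prof, basis, b = 2, seed = 1))
  expect_identical(null2$stats, null2b$stats)
  expect_error(permutation_null(prof, basis, b = 0), "at least 1")
  expect_warning(permutation_null(prof, basis, b = 5, seed = 1), "coarse")

  # flat truth: observed statistics are exchangeable with the null
  prof0 <- trend_profiles(40, slope = 0, noise_sd = 0.3, seed = 4)
  obs <- chronoscreen:::all_strain_statistics(prof0, basis)
  null <- suppressWarnings(permutation_null(prof0, basis, b = 50, seed = 2))
  p <- stats::wilcox.test(obs$f_stat, null$stats)$p.value
  expect_gt(p, 0.01)
})

test_that("empirical p-values follow the add-one permutation formula", {
  null <- structure(list(stats = c(0.1, 0.2, 0.5, 1, 2), b = 1,
                         n_strains = 5, seed = 1),
                    class = "null_distribution")
  expect_equal(empirical_pvalues(3, null), 1 / 6)
  expect_equal(empirical_pvalues(0, null), 1)
  expect_equal(empirical_pvalues(0.5, null), 4 / 6)  # ties count as >=
  set.seed(5)
  big <- structure(list(stats = stats::rexp(20000), b = 1, n_strains = 1,
                        seed = 1), class = "null_distribution")
  expect_equal(empirical_pvalues(stats::median(big$stats), big), 0.5,
               tolerance = 0.01)
})

test_that("pi0 estimation and q-values follow the Storey recipe", {
  expect_equal(estimate_pi0(c(runif(50, 0, 0.5), runif(50, 0.5, 1))), 1.0)
  p <- c(rep(0.01, 90), seq(0.51, 0.99, length.out = 10))
  expect_equal(estimate_pi0(p), 0.2)
  expect_error(estimate_pi0(runif(100), lambda = 1.2), "lambda")

  set.seed(6)
  expect_gte(estimate_pi0(runif(5000)), 0.9)

  # hand-worked step-up example
  expect_equal(qvalues(c(0.01, 0.02, 0.03), pi0 = 1), rep(0.03, 3))
  expect_equal(qvalues(rep(1, 10), pi0 = 0.7), rep(0.7, 10))
  # monotone non-decreasing in p on random inputs
  for (i in 1:10) {
    pv <- runif(100)
    q <- qvalues(pv, pi0 = 0.8)
    expect_true(all(diff(q[order(pv)]) >= -1e-12))
    expect_true(all(q <= 0.8 + 1e-12))
  }
})

test_that("significance thresholding and power behave as expected", {
  res <- tibble::tibble(strain_id = letters[1:4], q_value = rep(1, 4))
  expect_length(significant_strains(res), 0)
  expect_length(significant_strains(res, q_cutoff = 1), 4)

  # planted trend magnitude increases the median statistic
  basis <- spline_basis(c(3, 9, 11, 15, 20))
  med_f <- sapply(c(0.1, 0.3, 0.6), function(slope) {
    prof <- trend_profiles(30, slope = -slope, noise_sd = 0.3, seed = 8)
    stats::median(chronoscreen:::all_strain_statistics(prof, basis)$f_stat)
  })
  expect_true(all(diff(med_f) > 0))
})

test_that("the full time-course test flags planted trends, not nulls", {
  # 150 flat strains + 30 with a strong planted decline
  days <- c(3, 9, 11, 15, 20)
  set.seed(10)
  mk <- function() {
    flat <- matrix(rnorm(150 * 5, 0, 0.3), 150)
    down <- sweep(matrix(rnorm(30 * 5, 0, 0.3), 30), 2,
                  -0.6 * (seq_along(days) - 1), "+")
    m <- rbind(flat, down)
    m[, 1] <- 0
    rownames(m) <- sprintf("s%03d", 1:180)
    m
  }
  prof <- make_profiles(list(mk(), mk()), days)
  res <- timecourse_test(prof, b = 200, seed = 2)
  sig <- significant_strains(res, 0.1)
  planted <- sprintf("s%03d", 151:180)
  expect_gte(length(intersect(sig, planted)) / 30, 0.9)
  fdp <- length(setdiff(sig, planted)) / max(length(sig), 1)
  expect_lte(fdp, 0.15)
})
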