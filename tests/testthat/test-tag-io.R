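test_that("tag tables round-trip through TSV losslessly", {
  tbl <- make_tag_table(c("yal001c", "yal002w"),
                        values = function(s, tg, r, d) {
                          100 * (1 + (s == "yal002w")) + r + d / 3
                        })
  expect_equal(nrow(tbl), 2 * 2 * 2 * 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tag_intensities(tbl, path)
  back <- read_tag_intensities(path)
  expect_equal(back$intensity,
               validate_tag_intensities(tbl)$intensity, tolerance = 1e-12)
  expect_equal(back$strain_id, validate_tag_intensities(tbl)$strain_id)
})

test_that("malformed tag tables are rejected with row context", {
  tbl <- make_tag_table("a", days = c(3, 9), replicates = 1)
  expect_error(validate_tag_intensities(rbind(tbl, tbl[1, ])), "duplicate")
  expect_error(validate_tag_intensities(tbl[, -5]), "missing column")
  bad <- tbl; bad$intensity[2] <- -1
  expect_error(validate_tag_intensities(bad), "negative")
  uneven <- make_tag_table("a", days = c(3, 9), replicates = 1:2)
  uneven <- uneven[!(uneven$replicate == 2 & uneven$day == 9), ]
  expect_error(validate_tag_intensities(uneven), "same set of days")
})

test_that("pool CFU tables derive percent survival against the reference", {
  cfu <- tibble::tibble(replicate = rep(1:2, each = 3),
                        day = rep(c(3, 9, 15), 2),
                        cfu_per_ml = c(100, 50, 10, 200, 80, 40) * 1e6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pool_cfu(cfu, path)
  back <- read_pool_cfu(path, reference_day = 3)
  expect_equal(back$percent_survival[back$day == 3], c(100, 100))
  expect_equal(back$percent_survival[back$replicate == 1 & back$day == 15],
               10)
  expect_error(read_pool_cfu(path, reference_day = 4), "reference")
})

test_that("mean normalization equalizes array means and preserves ratios", {
  # arrays (1 replicate, days 3/9/11) with means 200, 20, 380: grand mean
  # 200, so [10, 30] is scaled by 10 and the first array is unchanged
  tbl <- tibble::tibble(
    strain_id = rep(c("a", "b"), 3), tag = "up", replicate = 1L,
    day = rep(c(3, 9, 11), each = 2),
    intensity = c(100, 300, 10, 30, 370, 390)
  )
  norm <- mean_normalize(tbl)
  expect_equal(norm$intensity[norm$day == 3], c(100, 300))
  expect_equal(norm$intensity[norm$day == 9], c(100, 300))

  # postcondition on an arbitrary table: every array mean equals the grand
  # mean, and within-array ratios are unchanged
  set.seed(4)
  big <- make_tag_table(sprintf("s%02d", 1:8),
                        values = function(s, tg, r, d) runif(1, 10, 1000))
  bn <- mean_normalize(big)
  means <- tapply(bn$intensity, paste(bn$replicate, bn$day), mean)
  expect_true(all(abs(means - mean(means)) < 1e-9))
  a1 <- big[big$replicate == 1 & big$day == 3 & big$tag == "up", ]
  b1 <- bn[bn$replicate == 1 & bn$day == 3 & bn$tag == "up", ]
  expect_equal(b1$intensity / b1$intensity[1], a1$intensity / a1$intensity[1])

  zero <- tbl; zero$intensity[zero$day == 9] <- 0
  expect_error(mean_normalize(zero), "all-zero")
})

test_that("tag combination uses the geometric mean with background fallback", {
  tbl <- tibble::tibble(strain_id = c("a", "a"), tag = c("up", "down"),
                        replicate = 1L, day = 3,
                        intensity = c(100, 400))
  expect_equal(combine_tags(tbl)$intensity, 200)

  flags <- tibble::tibble(strain_id = "a", tag = "down", replicate = 1L,
                          is_background = TRUE)
  comb <- combine_tags(tbl, flags)
  expect_equal(comb$intensity, 100)
  expect_equal(comb$n_tags, 1L)

  # idempotence: up = down = x returns x
  for (x in c(0.5, 7, 1234.5)) {
    t2 <- tbl; t2$intensity <- x
    expect_equal(combine_tags(t2)$intensity, x)
  }

  # a lone tag is used even if flagged; both-flagged keeps the geometric mean
  both <- tibble::tibble(strain_id = "a", tag = "up", replicate = 1L,
                         day = 3, intensity = 5)
  fb <- tibble::tibble(strain_id = "a", tag = "up", replicate = 1L,
                       is_background = TRUE)
  expect_equal(combine_tags(both, fb)$intensity, 5)
})

test_that("aging profiles are log2 ratios anchored at the reference day", {
  ints <- tibble::tibble(
    strain_id = rep("a", 4), replicate = rep(1:2, each = 2),
    day = rep(c(3, 9), 2), intensity = c(800, 200, 800, 100)
  )
  prof <- compute_profiles(ints, reference_day = 3)
  expect_equal(unname(prof$replicates[["1"]]["a", "9"]), -2)
  expect_equal(unname(prof$replicates[["2"]]["a", "9"]), -3)
  expect_equal(unname(prof$average["a", "9"]), -2.5)
  expect_equal(unname(prof$average["a", "3"]), 0)

  # zero reference intensity masks the strain with a reason code
  z <- ints; z$intensity[1] <- 0
  pz <- compute_profiles(z, 3)
  expect_true(all(is.na(pz$replicates[["1"]]["a", ])))
  expect_equal(pz$mask$reason, "zero_reference")
})

test_that("profiles shift by log2(c) when one array is rescaled", {
  set.seed(8)
  tbl <- make_tag_table(sprintf("s%02d", 1:6), replicates = 1,
                        values = function(s, tg, r, d) runif(1, 50, 500))
  p1 <- compute_profiles(combine_tags(tbl), 3)
  scaled <- tbl
  scaled$intensity[scaled$day == 15] <- scaled$intensity[scaled$day == 15] * 8
  p2 <- compute_profiles(combine_tags(scaled), 3)
  expect_equal(p2$replicates[["1"]][, "15"],
               p1$replicates[["1"]][, "15"] + 3)
  other <- setdiff(colnames(p1$average), "15")
  expect_equal(p2$replicates[["1"]][, other], p1$replicates[["1"]][, other])
})
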