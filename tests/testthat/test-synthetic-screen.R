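test_that("truth planting follows the configured fractions and rounding", {
  cfg <- screen_config(n_strains = 1000, frac_long = 0.05, frac_short = 0.1,
                       seed = 3)
  truth <- simulate_truth(cfg)
  expect_equal(sum(truth$true_class == "long"), 50)
  expect_equal(sum(truth$true_class == "short"), 100)

  cfg0 <- screen_config(n_strains = 200, frac_long = 0, frac_short = 0)
  expect_true(all(simulate_truth(cfg0)$true_class == "neutral"))

  # class multipliers act on the baseline midpoint
  expect_gt(min(truth$true_t50[truth$true_class == "long"]),
            max(truth$true_t50[truth$true_class == "short"]))
})

test_that("the generator is deterministic for a fixed seed", {
  cfg <- screen_config(n_strains = 80, seed = 11)
  s1 <- simulate_screen(cfg)
  s2 <- simulate_screen(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$viable_counts, s2$viable_counts)
  expect_identical(s1$pool_cfu, s2$pool_cfu)
  expect_identical(s1$intensities, s2$intensities)
})

test_that("invalid configurations are rejected", {
  expect_error(screen_config(frac_long = 0.6, frac_short = 0.5), "<= 1")
  expect_error(screen_config(short_t50_multiplier = 1.2), "0, 1")
  expect_error(screen_config(timepoints = c(3, 9, 9, 15)), "increasing")
  expect_error(screen_config(timepoints = c(9, 11), reference_day = 3),
               "reference_day")
})

test_that("pool dynamics follow the normalized Boltzmann sigmoid", {
  # closed-form check: survival at day 9 for t50 = 9, tau = 2 relative to
  # day 3 equals sigma(9)/sigma(3) with sigma(t) = 1/(1 + exp((t-9)/2))
  cfg <- noiseless_config(n_strains = 3, pool_t50_sd = 0)
  truth <- simulate_truth(cfg)
  truth$true_t50 <- rep(9, 3)
  dyn <- simulate_pool_dynamics(truth, cfg)
  sig <- function(t) 1 / (1 + exp((t - 9) / 2))
  cfg2 <- cfg; cfg2$slope_tau <- 2
  dyn2 <- simulate_pool_dynamics(truth, cfg2)
  expect_equal(unname(dyn2$viable_counts[1, "9"] /
                        dyn2$viable_counts[1, "3"]),
               sig(9) / sig(3), tolerance = 1e-12)

  # conservation: pool CFU before jitter equals the sum of strain counts
  expect_equal(dyn$pool_cfu$cfu_per_ml[dyn$pool_cfu$replicate == 1],
               unname(colSums(dyn$viable_counts)), tolerance = 1e-12)
})

test_that("equal lifespans give constant relative abundance", {
  cfg <- noiseless_config(n_strains = 20, pool_t50_sd = 0,
                          frac_long = 0, frac_short = 0)
  truth <- simulate_truth(cfg)
  dyn <- simulate_pool_dynamics(truth, cfg)
  shares <- sweep(dyn$viable_counts, 2, colSums(dyn$viable_counts), "/")
  expect_true(all(abs(shares - shares[, 1]) < 1e-12))
})

test_that("adaptive regrowth injects CFUs after the regrow day", {
  cfg <- noiseless_config(n_strains = 20, pool_t50_sd = 0, regrow_gain = 10,
                          frac_long = 0, frac_short = 0)
  truth <- simulate_truth(cfg)
  dyn0 <- simulate_pool_dynamics(truth, cfg)
  truth$regrows[1] <- TRUE
  truth$regrow_day[1] <- cfg$regrow_day
  dyn1 <- simulate_pool_dynamics(truth, cfg)
  day15 <- function(d) sum(d$viable_counts[, "15"])
  day9 <- function(d) sum(d$viable_counts[, "9"])
  expect_gt(day15(dyn1), day15(dyn0))
  expect_equal(day9(dyn1), day9(dyn0))  # before regrow day: unchanged
})

test_that("tag intensities are proportional to viable-cell share", {
  cfg <- noiseless_config(n_strains = 10, pool_t50_sd = 0,
                          frac_long = 0, frac_short = 0)
  truth <- simulate_truth(cfg)
  dyn <- simulate_pool_dynamics(truth, cfg)
  tags <- simulate_tag_intensities(dyn$viable_counts, truth, cfg)
  # symmetry: identical strains, zero noise -> one common intensity
  # (equal lifespans keep every share constant at 1/n across days too)
  expect_equal(length(unique(round(tags$intensity, 9))), 1L)
  # linearity: doubling one strain's counts doubles its intensity
  counts2 <- dyn$viable_counts
  counts2[1, ] <- 2 * counts2[1, ]
  tags2 <- simulate_tag_intensities(counts2, truth, cfg)
  s1 <- tags$strain_id == truth$strain_id[1]
  ratio_obs <- tags2$intensity[s1] / tags$intensity[s1]
  # share renormalization: strain 1 doubles, total grows by one strain share
  expect_true(all(abs(ratio_obs - 2 / (1 + 1 / cfg$n_strains)) < 1e-9))
  # extinct pool errors
  expect_error(simulate_tag_intensities(dyn$viable_counts * 0, truth, cfg),
               "extinct")
})

test_that("background tags are uncorrelated with strain abundance", {
  # Monte Carlo over seeds: strain 1 carries background tags; its planted
  # midpoint varies with the seed but its intensity must not track it
  abund <- numeric(60)
  inten <- numeric(60)
  for (i in 1:60) {
    cfg <- screen_config(n_strains = 30, pool_t50_sd = 2, noise_sigma = 0.1,
                         tag_affinity_sigma = 0, frac_background_tags = 0,
                         p_regrow = 0, cfu_jitter_sigma = 0, seed = i)
    truth <- simulate_truth(cfg)
    truth$uptag_background[1] <- TRUE
    truth$downtag_background[1] <- TRUE
    dyn <- simulate_pool_dynamics(truth, cfg)
    tags <- simulate_tag_intensities(dyn$viable_counts, truth, cfg)
    abund[i] <- dyn$viable_counts[1, "15"] / sum(dyn$viable_counts[, "15"])
    sel <- tags$strain_id == truth$strain_id[1] & tags$day == 15 &
      tags$replicate == 1 & tags$tag == "up"
    inten[i] <- tags$intensity[sel]
  }
  expect_gt(stats::cor.test(abund, inten)$p.value, 0.01)
})

test_that("recovery metrics follow the confusion-matrix conventions", {
  cfg <- screen_config(n_strains = 100, frac_long = 0.1, frac_short = 0.2,
                       seed = 5)
  truth <- simulate_truth(cfg)
  perfect <- tibble::tibble(strain_id = truth$strain_id,
                            class = truth$true_class)
  m <- evaluate_recovery(truth, perfect)
  expect_true(all(m$precision == 1) && all(m$recall == 1))

  none <- perfect[0, ]
  m0 <- evaluate_recovery(truth, none)
  expect_true(all(m0$recall == 0))
  expect_true(all(is.nan(m0$precision)) && all(m0$no_calls))

  # random calls on a 50/50 short/neutral truth: precision ~ 0.5
  cfg2 <- screen_config(n_strains = 2000, frac_long = 0, frac_short = 0.5,
                        seed = 6)
  truth2 <- simulate_truth(cfg2)
  set.seed(99)
  rand <- tibble::tibble(strain_id = truth2$strain_id,
                         class = sample(c("short", "neutral"), 2000,
                                        replace = TRUE))
  m2 <- evaluate_recovery(truth2, rand)
  expect_equal(m2$precision[m2$class == "short"], 0.5, tolerance = 0.06)

  expect_error(evaluate_recovery(truth, tibble::tibble(strain_id = "nope",
                                                       class = "short")),
               "absent")
})
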