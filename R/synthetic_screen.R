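#' Configuration for a synthetic pooled lifespan screen
#'
#' Bundles every parameter of the synthetic screen generator. Defaults emulate
#' the design of a pooled chronological-lifespan competition screen of the
#' non-essential haploid yeast deletion collection: ~4,800 strains aged
#' together in two replicate pools, sampled at days 3, 9, 11, 15 and 20 with
#' day 3 defining 100% survival, roughly 10% of barcode tags hybridizing at
#' background level, and a small fraction of strains undergoing adaptive
#' regrowth around day 12 which inflates pool CFU counts late in the
#' experiment.
#'
#' @param n_strains Number of deletion strains in the pool.
#' @param timepoints Sampling days, strictly increasing, must contain
#'   `reference_day`.
#' @param reference_day Day defining 100% survival (default 3).
#' @param n_replicates Number of replicate pools (default 2).
#' @param pool_t50_mean,pool_t50_sd Mean and SD (days) of the baseline
#'   survival midpoint across strains; drawn from a normal truncated below at
#'   the first timepoint.
#' @param slope_tau Slope width (days) of the Boltzmann survival sigmoid,
#'   shared across strains.
#' @param frac_long,frac_short Fractions of strains planted as long- and
#'   short-lived (`frac_long + frac_short <= 1`).
#' @param long_t50_multiplier Multiplier (> 1) applied to the baseline t50 of
#'   long-lived strains.
#' @param short_t50_multiplier Multiplier in (0, 1) applied to the baseline
#'   t50 of short-lived strains.
#' @param noise_sigma SD of the lognormal measurement noise on tag
#'   intensities (log scale). Sampling noise is folded in here rather than
#'   modeled as a separate multinomial draw.
#' @param tag_affinity_sigma SD of per-tag log hybridization affinity.
#' @param frac_background_tags Probability that a tag (uptag or downtag,
#'   independently) hybridizes at background level regardless of strain
#'   abundance.
#' @param background_level Intensity level of background tags, in the same
#'   arbitrary fluorescence units as the simulated intensities.
#' @param p_regrow Per-strain probability of adaptive regrowth.
#' @param regrow_day Day at which regrowing strains gain abundance.
#' @param regrow_gain Multiplicative viable-count gain (> 1) applied to
#'   regrowing strains from `regrow_day` on.
#' @param initial_cells_per_strain Viable cells per strain at the reference
#'   day (per mL of pool culture).
#' @param cfu_jitter_sigma SD of the lognormal jitter applied independently
#'   to each replicate pool's CFU counts (plating noise).
#' @param intensity_scale Arbitrary fluorescence scale factor mapping
#'   relative abundance to intensity units.
#' @param seed Integer seed; every stochastic stage of the generator derives
#'   its stream from it, so identical configs give bit-identical screens.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(n_strains = 4800,
                          timepoints = c(3L, 9L, 11L, 15L, 20L),
                          reference_day = 3L,
                          n_replicates = 2L,
                          pool_t50_mean = 11,
                          pool_t50_sd = 0.5,
                          slope_tau = 1.5,
                          frac_long = 0.01,
                          frac_short = 0.12,
                          long_t50_multiplier = 1.8,
                          short_t50_multiplier = 0.5,
                          noise_sigma = 0.3,
                          tag_affinity_sigma = 0.5,
                          frac_background_tags = 0.10,
                          background_level = 20,
                          p_regrow = 0.02,
                          regrow_day = 12L,
                          regrow_gain = 5,
                          initial_cells_per_strain = 2e4,
                          cfu_jitter_sigma = 0.02,
                          intensity_scale = 1e6,
                          seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains), timepoints = as.numeric(timepoints),
    reference_day = as.numeric(reference_day),
    n_replicates = as.integer(n_replicates),
    pool_t50_mean = pool_t50_mean, pool_t50_sd = pool_t50_sd,
    slope_tau = slope_tau, frac_long = frac_long, frac_short = frac_short,
    long_t50_multiplier = long_t50_multiplier,
    short_t50_multiplier = short_t50_multiplier,
    noise_sigma = noise_sigma, tag_affinity_sigma = tag_affinity_sigma,
    frac_background_tags = frac_background_tags,
    background_level = background_level, p_regrow = p_regrow,
    regrow_day = as.numeric(regrow_day), regrow_gain = regrow_gain,
    initial_cells_per_strain = initial_cells_per_strain,
    cfu_jitter_sigma = cfu_jitter_sigma, intensity_scale = intensity_scale,
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  stopifnot_scalar_number(cfg$n_strains, "n_strains", lower = 1)
  if (length(cfg$timepoints) < 2 || any(diff(cfg$timepoints) <= 0)) {
    abort("`timepoints` must be strictly increasing with at least 2 days")
  }
  if (!cfg$reference_day %in% cfg$timepoints) {
    abort("`timepoints` must include `reference_day`")
  }
  if (cfg$n_replicates < 1) abort("`n_replicates` must be >= 1")
  stopifnot_scalar_number(cfg$frac_long, "frac_long", 0, 1)
  stopifnot_scalar_number(cfg$frac_short, "frac_short", 0, 1)
  if (cfg$frac_long + cfg$frac_short > 1) {
    abort("`frac_long + frac_short` must be <= 1")
  }
  if (cfg$long_t50_multiplier <= 1) abort("`long_t50_multiplier` must be > 1")
  if (cfg$short_t50_multiplier <= 0 || cfg$short_t50_multiplier >= 1) {
    abort("`short_t50_multiplier` must lie in (0, 1)")
  }
  for (f in c("pool_t50_sd", "noise_sigma", "tag_affinity_sigma",
              "cfu_jitter_sigma")) {
    stopifnot_scalar_number(cfg[[f]], f, lower = 0)
  }
  for (f in c("pool_t50_mean", "slope_tau", "background_level",
              "initial_cells_per_strain", "intensity_scale")) {
    if (cfg[[f]] <= 0) abort(sprintf("`%s` must be positive", f))
  }
  stopifnot_scalar_number(cfg$p_regrow, "p_regrow", 0, 1)
  stopifnot_scalar_number(cfg$frac_background_tags, "frac_background_tags", 0, 1)
  if (cfg$regrow_gain <= 1) abort("`regrow_gain` must be > 1")
  invisible(cfg)
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>", x$n_strains, "strains,", x$n_replicates,
      "replicate pools, days", paste(x$timepoints, collapse = ","),
      "(reference", paste0(x$reference_day, ")"), "seed", x$seed, "\n")
  invisible(x)
}

# Normal truncated below at `floor`, by rejection (cheap at these sizes).
rtruncnorm_floor <- function(n, mean, sd, floor) {
  if (sd == 0) return(pmax(rep(mean, n), floor))
  out <- rnorm(n, mean, sd)
  bad <- which(out < floor)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < floor]
  }
  out
}

#' Plant per-strain ground truth for a synthetic screen
#'
#' Draws each strain's true survival midpoint, lifespan class, adaptive
#' regrowth status, tag hybridization affinities and background-tag flags.
#' Exactly `round(frac_long * n)` strains are long-lived and
#' `round(frac_short * n)` short-lived; their baseline t50 (truncated normal,
#' floored at the first sampling day) is multiplied by the configured class
#' multiplier.
#'
#' @param config A [screen_config()].
#' @return A tibble of class `synthetic_truth` with columns `strain_id`,
#'   `true_t50`, `true_class`, `regrows`, `regrow_day`, `uptag_affinity`,
#'   `downtag_affinity`, `uptag_background`, `downtag_background`.
#' @export
simulate_truth <- function(config) {
  validate_screen_config(config)
  n <- config$n_strains
  n_long <- round(config$frac_long * n)
  n_short <- round(config$frac_short * n)
  with_seed(config$seed, {
    base_t50 <- rtruncnorm_floor(n, config$pool_t50_mean, config$pool_t50_sd,
                                 floor = min(config$timepoints))
    cls <- rep("neutral", n)
    special <- sample.int(n, n_long + n_short)
    cls[special[seq_len(n_long)]] <- "long"
    if (n_short > 0) cls[special[n_long + seq_len(n_short)]] <- "short"
    mult <- ifelse(cls == "long", config$long_t50_multiplier,
                   ifelse(cls == "short", config$short_t50_multiplier, 1))
    regrows <- runif(n) < config$p_regrow
    truth <- tibble::tibble(
      strain_id = sprintf("strain_%05d", seq_len(n)),
      true_t50 = base_t50 * mult,
      true_class = cls,
      regrows = regrows,
      regrow_day = ifelse(regrows, config$regrow_day, NA_real_),
      uptag_affinity = exp(rnorm(n, 0, config$tag_affinity_sigma)),
      downtag_affinity = exp(rnorm(n, 0, config$tag_affinity_sigma)),
      uptag_background = runif(n) < config$frac_background_tags,
      downtag_background = runif(n) < config$frac_background_tags
    )
    class(truth) <- c("synthetic_truth", class(truth))
    truth
  })
}

#' Simulate pool survival dynamics
#'
#' Propagates each strain's viable-cell count over the sampling days using
#' the shared Boltzmann survival sigmoid normalized to 1 at the reference
#' day. Strains flagged for adaptive regrowth have their counts multiplied by
#' `regrow_gain` from `regrow_day` onwards (a step-gain simplification of
#' renewed growth, sufficient to reproduce the late CFU bump seen in pooled
#' aging cultures). Pool CFU per replicate is the column sum of viable counts
#' with independent lognormal plating jitter.
#'
#' @param truth A `synthetic_truth` tibble from [simulate_truth()].
#' @param config The matching [screen_config()].
#' @return A list with `viable_counts` (strain x day matrix, before jitter)
#'   and `pool_cfu` (tibble: replicate, day, cfu_per_ml).
#' @export
simulate_pool_dynamics <- function(truth, config) {
  validate_screen_config(config)
  if (nrow(truth) != config$n_strains) {
    abort("`truth` and `config` disagree on the number of strains")
  }
  days <- config$timepoints
  surv <- vapply(days, function(t) {
    boltzmann_survival(t, truth$true_t50, config$slope_tau,
                       config$reference_day)
  }, numeric(nrow(truth)))
  counts <- config$initial_cells_per_strain * surv
  gain <- outer(ifelse(truth$regrows, config$regrow_gain, 1) - 1,
                as.numeric(days >= config$regrow_day)) + 1
  counts <- counts * gain
  dimnames(counts) <- list(truth$strain_id, as.character(days))
  totals <- colSums(counts)
  pool_cfu <- with_seed(config$seed + 1L, {
    dplyr::bind_rows(lapply(seq_len(config$n_replicates), function(r) {
      tibble::tibble(
        replicate = r, day = days,
        cfu_per_ml = unname(totals) * exp(rnorm(length(days), 0,
                                                config$cfu_jitter_sigma))
      )
    }))
  })
  list(viable_counts = counts, pool_cfu = pool_cfu)
}

#' Simulate barcode tag intensities from viable counts
#'
#' Converts viable-cell counts to per-tag array intensities. Outgrowth of the
#' sampled aliquot before DNA extraction is assumed proportion-preserving, so
#' each tag reports its strain's relative abundance among viable cells at
#' that day, scaled by the tag's hybridization affinity, with lognormal
#' measurement noise independent per tag, day and replicate. Tags flagged as
#' background hybridize near `background_level` regardless of abundance.
#'
#' @param viable_counts Strain x day matrix from [simulate_pool_dynamics()].
#' @param truth The matching `synthetic_truth` tibble.
#' @param config The matching [screen_config()].
#' @return A tag intensity tibble (columns `strain_id`, `tag`, `replicate`,
#'   `day`, `intensity`) covering all replicates.
#' @export
simulate_tag_intensities <- function(viable_counts, truth, config) {
  validate_screen_config(config)
  totals <- colSums(viable_counts)
  if (any(totals <= 0)) {
    abort("pool extinct: zero total viable cells at a sampled day")
  }
  rel <- sweep(viable_counts, 2, totals, "/")
  n <- nrow(rel); days <- config$timepoints; tn <- length(days)
  with_seed(config$seed + 2L, {
    out <- vector("list", 2L * config$n_replicates)
    i <- 1L
    for (r in seq_len(config$n_replicates)) {
      for (tag in c("up", "down")) {
        aff <- if (tag == "up") truth$uptag_affinity else truth$downtag_affinity
        bg <- if (tag == "up") truth$uptag_background else truth$downtag_background
        noise <- matrix(exp(rnorm(n * tn, 0, config$noise_sigma)), n, tn)
        sig <- aff * rel * config$intensity_scale * noise
        sig[bg, ] <- config$background_level * noise[bg, , drop = FALSE]
        out[[i]] <- tibble::tibble(
          strain_id = rep(truth$strain_id, times = tn),
          tag = tag, replicate = r,
          day = rep(days, each = n),
          intensity = as.vector(sig)
        )
        i <- i + 1L
      }
    }
    dplyr::arrange(dplyr::bind_rows(out), .data$strain_id, .data$tag,
                   .data$replicate, .data$day)
  })
}

#' Simulate a complete synthetic screen
#'
#' Convenience wrapper chaining [simulate_truth()],
#' [simulate_pool_dynamics()] and [simulate_tag_intensities()].
#'
#' @param config A [screen_config()].
#' @return A list with `truth`, `viable_counts`, `pool_cfu`, `intensities`
#'   and the `config`.
#' @export
simulate_screen <- function(config = screen_config()) {
  truth <- simulate_truth(config)
  dyn <- simulate_pool_dynamics(truth, config)
  intens <- simulate_tag_intensities(dyn$viable_counts, truth, config)
  list(truth = truth, viable_counts = dyn$viable_counts,
       pool_cfu = dyn$pool_cfu, intensities = intens, config = config)
}

#' Score predicted lifespan classes against planted truth
#'
#' Computes per-class confusion metrics. Strains missing from `calls`
#' (e.g. removed by QC) count as non-calls: they can only cost recall, never
#' precision. Precision with zero calls for a class is reported as `NaN` with
#' `no_calls = TRUE`.
#'
#' @param truth A `synthetic_truth` tibble.
#' @param calls Tibble with columns `strain_id` and `class`
#'   (short/long/neutral); a subset of the truth's strains.
#' @return Tibble with one row per class: `class`, `n_true`, `n_called`,
#'   `tp`, `precision`, `recall`, `no_calls`.
#' @export
evaluate_recovery <- function(truth, calls) {
  if (!all(calls$strain_id %in% truth$strain_id)) {
    abort("`calls` contains strain ids absent from `truth`")
  }
  classes <- c("short", "long", "neutral")
  merged <- dplyr::left_join(
    dplyr::select(tibble::as_tibble(truth), "strain_id", "true_class"),
    calls, by = "strain_id"
  )
  dplyr::bind_rows(lapply(classes, function(cl) {
    n_true <- sum(merged$true_class == cl)
    n_called <- sum(merged$class == cl, na.rm = TRUE)
    tp <- sum(merged$true_class == cl & !is.na(merged$class) &
                merged$class == cl)
    tibble::tibble(
      class = cl, n_true = n_true, n_called = n_called, tp = tp,
      precision = if (n_called > 0) tp / n_called else NaN,
      recall = if (n_true > 0) tp / n_true else NaN,
      no_calls = n_called == 0
    )
  }))
}
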