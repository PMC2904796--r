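#' Detect strains indistinguishable from array background
#'
#' Excludes strains whose combined (strain-level) intensity stays below
#' `k_factor * background_level` at every sampled day in at least one
#' replicate. These are strains that grow extremely slowly or whose tags
#' hybridize poorly: their log2 ratios track noise, not abundance. A strain
#' that rises above background at even one day is retained.
#'
#' @param strain_intensities Tibble from [combine_tags()].
#' @param background_level Background intensity (> 0), same units as the
#'   intensities.
#' @param k_factor Background multiple defining "similar to background"
#'   (default 2).
#' @return Character vector of excluded strain ids.
#' @export
detect_background_strains <- function(strain_intensities, background_level,
                                      k_factor = 2) {
  if (background_level <= 0) abort("`background_level` must be positive")
  tbl <- tibble::as_tibble(strain_intensities)
  flags <- dplyr::summarise(
    dplyr::group_by(tbl, .data$strain_id, .data$replicate),
    all_below = all(.data$intensity < k_factor * background_level),
    .groups = "drop"
  )
  sort(unique(flags$strain_id[flags$all_below]))
}

#' Replicate concordance (RSME) per strain
#'
#' The root squared mean error between a strain's two replicate aging
#' profiles, over non-reference days (the reference column is identically
#' zero in both replicates and would only dilute the statistic):
#' `RSME_s = sqrt(mean_t (r1[s,t] - r2[s,t])^2)`. Days masked in either
#' replicate are omitted from the mean; strains without any shared
#' non-reference day get `NA`.
#'
#' @param profiles An `aging_profiles` object with exactly two replicate
#'   layers.
#' @return Named numeric vector of RSMEs (NA = uncomputable).
#' @export
replicate_rsme <- function(profiles) {
  if (length(profiles$replicates) != 2) {
    abort("RSME requires exactly two replicate layers")
  }
  nonref <- profiles$days != profiles$reference_day
  d <- (profiles$replicates[[1]] - profiles$replicates[[2]])[, nonref,
                                                             drop = FALSE]
  sqrt(rowMeans(d^2, na.rm = TRUE))
}

#' Exclude strains with high replicate RSME
#'
#' Applies the percentile rule for replicate discordance: the threshold is
#' the nearest-rank percentile of the computable RSMEs (the value at
#' position `ceiling(p/100 * n)` of the sorted values) and strains strictly
#' above it are excluded. Strict inequality means ties at the threshold are
#' retained, and the nearest-rank definition gives a reproducible integer
#' cutoff.
#'
#' @param rsme Named numeric vector from [replicate_rsme()]; `NA` entries are
#'   ignored for the threshold and never excluded by this rule.
#' @param percentile Percentile (default 90).
#' @return List with `excluded` (character vector), `threshold`, and
#'   `percentile`.
#' @export
filter_high_rsme <- function(rsme, percentile = 90) {
  vals <- rsme[!is.na(rsme)]
  if (length(vals) == 0) abort("no computable RSME values")
  sorted <- sort(vals)
  rank <- ceiling(percentile / 100 * length(sorted))
  threshold <- sorted[rank]
  excluded <- names(vals)[vals > threshold]
  list(excluded = sort(excluded), threshold = unname(threshold),
       percentile = percentile)
}

#' Run both QC filters and average the survivors
#'
#' Applies the two exclusion rules in order — background-level strains
#' first, then the high-RSME rule on the survivors — and returns the
#' averaged profiles of the retained strains along with a QC report.
#'
#' @param strain_intensities Tibble from [combine_tags()] (normalized).
#' @param profiles The matching `aging_profiles` object.
#' @param background_level,k_factor Passed to
#'   [detect_background_strains()].
#' @param rsme_percentile Passed to [filter_high_rsme()] (default 90).
#' @return List of class `qc_report`: `retained`, `excluded_background`,
#'   `excluded_rsme`, `rsme` (per-strain, survivors of the background
#'   filter), `rsme_threshold`, and `profiles` (the averaged
#'   `aging_profiles` restricted to retained strains).
#' @export
qc_screen <- function(strain_intensities, profiles, background_level,
                      k_factor = 2, rsme_percentile = 90) {
  bg <- detect_background_strains(strain_intensities, background_level,
                                  k_factor)
  after_bg <- setdiff(profiles$strains, bg)
  prof_bg <- subset_profiles(profiles, after_bg)
  rsme <- replicate_rsme(prof_bg)
  hi <- filter_high_rsme(rsme, rsme_percentile)
  retained <- setdiff(after_bg, hi$excluded)
  structure(
    list(retained = retained,
         excluded_background = bg,
         excluded_rsme = hi$excluded,
         rsme = rsme,
         rsme_threshold = hi$threshold,
         rsme_percentile = rsme_percentile,
         profiles = subset_profiles(prof_bg, retained)),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", length(x$retained), "strains retained;",
      length(x$excluded_background), "excluded at background level;",
      length(x$excluded_rsme),
      sprintf("excluded by RSME > %.4g (%gth percentile)\n",
              x$rsme_threshold, x$rsme_percentile))
  invisible(x)
}
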