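#' Read a tag intensity table
#'
#' Reads a tab-separated table of per-tag barcode array intensities with
#' columns `strain_id`, `tag` (up/down), `replicate`, `day`, `intensity`.
#' Validates keys, day coverage and non-negativity.
#'
#' @param path Path to a TSV file ('.' decimal separator, header required).
#' @return A validated tibble sorted by strain, tag, replicate, day.
#' @export
read_tag_intensities <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           strain_id = readr::col_character(),
                           tag = readr::col_character(),
                           replicate = readr::col_integer(),
                           day = readr::col_double(),
                           intensity = readr::col_double()
                         ))
  validate_tag_intensities(tbl)
}

#' Write a tag intensity table to TSV
#'
#' @param table A tag intensity tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_intensities <- function(table, path) {
  readr::write_tsv(validate_tag_intensities(table), path)
  invisible(path)
}

#' Validate a tag intensity table
#'
#' Checks required columns, tag levels, duplicate (strain, tag, replicate,
#' day) keys, negative intensities, and that all replicates share one day
#' set.
#'
#' @param table A data frame of per-tag intensities.
#' @return The table as a tibble, sorted.
#' @export
validate_tag_intensities <- function(table) {
  required <- c("strain_id", "tag", "replicate", "day", "intensity")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(table)[required]
  if (!all(tbl$tag %in% c("up", "down"))) {
    abort("`tag` must be 'up' or 'down'")
  }
  neg <- which(tbl$intensity < 0)
  if (length(neg) > 0) {
    abort(sprintf("negative intensity at row %d", neg[1]))
  }
  key <- paste(tbl$strain_id, tbl$tag, tbl$replicate, tbl$day)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort(sprintf("duplicate (strain, tag, replicate, day) key at row %d: %s",
                  dup[1], key[dup[1]]))
  }
  day_sets <- tapply(tbl$day, tbl$replicate, function(d) sort(unique(d)))
  if (length(unique(lapply(day_sets, identical, day_sets[[1]]))) > 1 ||
      !all(vapply(day_sets, identical, logical(1), day_sets[[1]]))) {
    abort("all replicates must share the same set of days")
  }
  dplyr::arrange(tbl, .data$strain_id, .data$tag, .data$replicate, .data$day)
}

#' Read a pool CFU table
#'
#' Reads per-replicate pool colony-forming-unit counts (columns `replicate`,
#' `day`, `cfu_per_ml`) and derives the percent-survival column relative to
#' `reference_day` (reference day = 100% by definition).
#'
#' @param path TSV path.
#' @param reference_day Day defining 100% survival (default 3).
#' @return Tibble with columns `replicate`, `day`, `cfu_per_ml`,
#'   `percent_survival`.
#' @export
read_pool_cfu <- function(path, reference_day = 3) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           replicate = readr::col_integer(),
                           day = readr::col_double(),
                           cfu_per_ml = readr::col_double()
                         ))
  validate_pool_cfu(tbl, reference_day)
}

#' Write a pool CFU table to TSV
#'
#' @param table A pool CFU tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pool_cfu <- function(table, path) {
  readr::write_tsv(table[c("replicate", "day", "cfu_per_ml")], path)
  invisible(path)
}

validate_pool_cfu <- function(tbl, reference_day) {
  required <- c("replicate", "day", "cfu_per_ml")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste("missing column(s):", paste(missing, collapse = ", ")))
  }
  if (any(tbl$cfu_per_ml <= 0)) abort("`cfu_per_ml` must be positive")
  tbl <- tibble::as_tibble(tbl)[required]
  refs <- tbl[tbl$day == reference_day, ]
  if (nrow(refs) == 0) abort("reference day absent from pool CFU table")
  tbl <- dplyr::group_by(tbl, .data$replicate)
  tbl <- dplyr::mutate(
    tbl,
    percent_survival = 100 * .data$cfu_per_ml /
      .data$cfu_per_ml[.data$day == reference_day]
  )
  dplyr::arrange(dplyr::ungroup(tbl), .data$replicate, .data$day)
}

#' Mean-normalize barcode arrays
#'
#' Each (replicate, day) combination is one hybridization array. Every array
#' is rescaled by (grand mean of all arrays) / (its own mean), so all array
#' means agree afterwards while relative intensities within an array are
#' untouched. Using the grand mean as target keeps output in input units;
#' any common target would give identical downstream log2 ratios.
#'
#' @param table A tag intensity tibble.
#' @return The normalized table.
#' @export
mean_normalize <- function(table) {
  tbl <- validate_tag_intensities(table)
  arr <- paste(tbl$replicate, tbl$day)
  means <- tapply(tbl$intensity, arr, mean)
  if (any(means == 0)) abort("array with all-zero intensities")
  grand <- mean(means)
  tbl$intensity <- as.numeric(tbl$intensity * (grand / means[arr]))
  tbl
}

#' Flag background-level tags
#'
#' A tag (strain x up/down x replicate) is flagged as background when its
#' intensity stays below `k_factor * background_level` at every sampled day
#' in that replicate — the signature of a tag that hybridizes poorly or of a
#' strain lost from the pool before the first sampling.
#'
#' @param table A (normalized) tag intensity tibble.
#' @param background_level Background intensity level (> 0), in the same
#'   units as the table.
#' @param k_factor Multiple of the background level below which a tag is
#'   considered indistinguishable from background (default 2).
#' @return Tibble `strain_id`, `tag`, `replicate`, `is_background`.
#' @export
flag_background_tags <- function(table, background_level, k_factor = 2) {
  if (background_level <= 0) abort("`background_level` must be positive")
  tbl <- tibble::as_tibble(table)
  out <- dplyr::summarise(
    dplyr::group_by(tbl, .data$strain_id, .data$tag, .data$replicate),
    is_background = all(.data$intensity < k_factor * background_level),
    .groups = "drop"
  )
  out
}

#' Combine uptag and downtag intensities per strain
#'
#' Collapses the two barcode tags to one strain-level intensity per
#' (strain, replicate, day) using the geometric mean — the arithmetic mean on
#' the log scale, matching the multiplicative error model of array
#' intensities. When exactly one tag is flagged background the other is used
#' alone; when both are flagged the geometric mean is kept and the strain is
#' left to the background strain filter.
#'
#' @param table A normalized tag intensity tibble.
#' @param background_flags Optional tibble from [flag_background_tags()];
#'   `NULL` means no tag is flagged.
#' @return Tibble `strain_id`, `replicate`, `day`, `intensity`, `n_tags`
#'   (number of tags used).
#' @export
combine_tags <- function(table, background_flags = NULL) {
  tbl <- tibble::as_tibble(table)
  if (is.null(background_flags)) {
    tbl$is_background <- FALSE
  } else {
    tbl <- dplyr::left_join(tbl, background_flags,
                            by = c("strain_id", "tag", "replicate"))
    tbl$is_background[is.na(tbl$is_background)] <- FALSE
  }
  wide <- tidyr::pivot_wider(tbl, id_cols = c("strain_id", "replicate", "day"),
                             names_from = "tag",
                             values_from = c("intensity", "is_background"))
  for (col in c("intensity_up", "intensity_down",
                "is_background_up", "is_background_down")) {
    if (!col %in% names(wide)) wide[[col]] <- NA
  }
  up <- wide$intensity_up
  down <- wide$intensity_down
  bg_up <- isTRUE_vec(wide$is_background_up)
  bg_down <- isTRUE_vec(wide$is_background_down)
  # a tag is skipped only when it is background and the other tag is a
  # usable non-background alternative; a lone tag is always used
  use_up <- !is.na(up) & !(bg_up & !is.na(down) & !bg_down)
  use_down <- !is.na(down) & !(bg_down & !is.na(up) & !bg_up)
  n_tags <- use_up + use_down
  lg <- ifelse(use_up, log(pmax(up, .Machine$double.xmin)), 0) +
    ifelse(use_down, log(pmax(down, .Machine$double.xmin)), 0)
  out <- tibble::tibble(
    strain_id = wide$strain_id, replicate = wide$replicate, day = wide$day,
    intensity = exp(lg / n_tags), n_tags = as.integer(n_tags)
  )
  out <- out[n_tags > 0, ]
  dplyr::arrange(out, .data$strain_id, .data$replicate, .data$day)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Build per-strain aging profiles
#'
#' Computes each strain's aging profile: the log2 ratio of its strain-level
#' intensity at every day relative to the reference day,
#' `r[s, t] = log2(I[s, t] / I[s, ref])`, per replicate, plus the averaged
#' layer (arithmetic mean of replicate log2 ratios where present). Strains
#' with zero or missing reference-day intensity in a replicate are masked in
#' that replicate with a reason code; missingness propagates as `NA`, never
#' as silent drops.
#'
#' @param strain_intensities Tibble from [combine_tags()] (columns
#'   `strain_id`, `replicate`, `day`, `intensity`).
#' @param reference_day Day whose intensity anchors the ratios (default 3).
#' @return An `aging_profiles` object: list with `strains`, `days`,
#'   `reference_day`, `replicates` (list of strain x day matrices of log2
#'   ratios), `average` (strain x day matrix), and `mask` (tibble of masked
#'   strain/replicate pairs with reasons).
#' @export
compute_profiles <- function(strain_intensities, reference_day = 3) {
  tbl <- tibble::as_tibble(strain_intensities)
  days <- sort(unique(tbl$day))
  if (!reference_day %in% days) abort("reference day absent from data")
  reps <- sort(unique(tbl$replicate))
  strains <- sort(unique(tbl$strain_id))
  mask <- list()
  layers <- lapply(reps, function(r) {
    sub <- tbl[tbl$replicate == r, ]
    m <- matrix(NA_real_, length(strains), length(days),
                dimnames = list(strains, as.character(days)))
    m[cbind(match(sub$strain_id, strains), match(sub$day, days))] <-
      sub$intensity
    ref <- m[, as.character(reference_day)]
    bad <- which(is.na(ref) | ref <= 0)
    if (length(bad) > 0) {
      mask[[length(mask) + 1L]] <<- tibble::tibble(
        strain_id = strains[bad], replicate = r,
        reason = ifelse(is.na(ref[bad]), "missing_reference",
                        "zero_reference")
      )
      m[bad, ] <- NA_real_
      ref[bad] <- NA_real_
    }
    log2(m / ref)
  })
  names(layers) <- as.character(reps)
  avg <- Reduce(`+`, lapply(layers, function(m) ifelse(is.na(m), 0, m))) /
    Reduce(`+`, lapply(layers, function(m) matrix(as.numeric(!is.na(m)),
                                                  nrow(m), ncol(m))))
  avg[!is.finite(avg)] <- NA_real_
  structure(
    list(strains = strains, days = days, reference_day = reference_day,
         replicates = layers, average = avg,
         mask = if (length(mask) > 0) dplyr::bind_rows(mask) else
           tibble::tibble(strain_id = character(), replicate = integer(),
                          reason = character())),
    class = "aging_profiles"
  )
}

#' @export
print.aging_profiles <- function(x, ...) {
  cat("<aging_profiles>", length(x$strains), "strains x",
      length(x$days), "days (reference", paste0(x$reference_day, "),"),
      length(x$replicates), "replicate layer(s);",
      nrow(x$mask), "masked strain/replicate pair(s)\n")
  invisible(x)
}

#' Restrict an aging profile set to a subset of strains
#'
#' @param profiles An `aging_profiles` object.
#' @param strains Character vector of strain ids to keep.
#' @return The restricted `aging_profiles` object.
#' @export
subset_profiles <- function(profiles, strains) {
  keep <- profiles$strains %in% strains
  profiles$strains <- profiles$strains[keep]
  profiles$replicates <- lapply(profiles$replicates,
                                function(m) m[keep, , drop = FALSE])
  profiles$average <- profiles$average[keep, , drop = FALSE]
  profiles$mask <- profiles$mask[profiles$mask$strain_id %in% strains, ]
  profiles
}
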