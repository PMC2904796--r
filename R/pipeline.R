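#' Run the full screen analysis pipeline
#'
#' Orchestrates the end-to-end analysis in the canonical order: array mean
#' normalization, background-tag flagging, up/downtag combination, aging
#' profiles, QC (background strains then high-RSME strains), K-means
#' clustering with short/long/neutral classification, time-course
#' significance testing with q-values, survival-curve reconstruction and
#' lifespan fitting, and (optionally) term enrichment of the short-lived
#' significant set.
#'
#' @param intensities Tag intensity tibble (or TSV path).
#' @param pool_cfu Pool CFU tibble (or TSV path).
#' @param reference_day Reference day defining 100% survival (default 3).
#' @param background_level Background intensity level for the QC filters.
#' @param k_factor Background multiple (default 2).
#' @param rsme_percentile RSME exclusion percentile (default 90).
#' @param k Number of K-means clusters (default 10).
#' @param theta_short,theta_long Cluster classification boundaries in log2
#'   units (default 0.5).
#' @param df Spline degrees of freedom (default `min(3, T - 2)`).
#' @param b Number of permutations (default 1000).
#' @param lambda pi0 tuning parameter (default 0.5).
#' @param q_cutoff Significance cutoff on q-values (default 0.1).
#' @param annotation Optional `annotation_map` for enrichment of the
#'   short-lived significant strains; the universe defaults to all strains
#'   retained after the background filter.
#' @param alpha Enrichment significance level (default 0.01).
#' @param seed Master seed; stage seeds are derived from it by fixed
#'   offsets.
#' @param out_dir Optional directory: when given, all stage outputs are
#'   written there as TSV/JSON.
#' @return A list of class `run_report` with elements `counts` (named
#'   integer vector reconciling every stage), `qc`, `cluster_model`,
#'   `classes`, `timecourse`, `significant`, `survival_fits`, `enrichment`
#'   (or NULL), `params`, and `artifacts` (paths written, or NULL).
#' @export
run_screen_pipeline <- function(intensities, pool_cfu,
                                reference_day = 3,
                                background_level,
                                k_factor = 2,
                                rsme_percentile = 90,
                                k = 10, theta_short = 0.5, theta_long = 0.5,
                                df = NULL, b = 1000, lambda = 0.5,
                                q_cutoff = 0.1,
                                annotation = NULL, alpha = 0.01,
                                seed = 1L, out_dir = NULL) {
  if (is.character(intensities)) intensities <- read_tag_intensities(intensities)
  if (is.character(pool_cfu)) pool_cfu <- read_pool_cfu(pool_cfu, reference_day)
  intensities <- validate_tag_intensities(intensities)
  n_input <- length(unique(intensities$strain_id))

  normalized <- mean_normalize(intensities)
  tag_flags <- flag_background_tags(normalized, background_level, k_factor)
  combined <- combine_tags(normalized, tag_flags)
  profiles <- compute_profiles(combined, reference_day)
  qc <- qc_screen(combined, profiles, background_level, k_factor,
                  rsme_percentile)

  model <- kmeans_profiles(qc$profiles, k = k, seed = seed + 10L)
  model <- classify_clusters(model, theta_short, theta_long)
  classes <- strain_classes(model)

  tc <- timecourse_test(qc$profiles, df = df, b = b, seed = seed + 20L,
                        lambda = lambda)
  sig <- significant_strains(tc, q_cutoff)

  surv <- reconstruct_survival(qc$profiles, pool_cfu)
  fits <- fit_all_strains(surv)

  enr <- NULL
  if (!is.null(annotation)) {
    short_sig <- intersect(classes$strain_id[classes$class == "short"], sig)
    if (length(short_sig) > 0) enr <- enrich(short_sig, annotation, alpha)
  }

  counts <- c(
    n_input = n_input,
    n_background = length(qc$excluded_background),
    n_rsme = length(qc$excluded_rsme),
    n_retained = length(qc$retained),
    n_clustered = length(model$assignment),
    n_short = sum(classes$class == "short"),
    n_long = sum(classes$class == "long"),
    n_neutral = sum(classes$class == "neutral"),
    n_tested = sum(tc$testable),
    n_significant = length(sig)
  )
  stopifnot(counts["n_retained"] ==
              counts["n_input"] - counts["n_background"] - counts["n_rsme"])
  stopifnot(counts["n_short"] + counts["n_long"] + counts["n_neutral"] ==
              counts["n_clustered"])

  params <- list(reference_day = reference_day,
                 background_level = background_level, k_factor = k_factor,
                 rsme_percentile = rsme_percentile, k = k,
                 theta_short = theta_short, theta_long = theta_long,
                 df = attr(tc, "df"), b = b, lambda = lambda,
                 q_cutoff = q_cutoff, alpha = alpha, seed = seed,
                 version = as.character(utils::packageVersion("chronoscreen")))

  artifacts <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    artifacts <- c(
      classes = file.path(out_dir, "strain_classes.tsv"),
      timecourse = file.path(out_dir, "timecourse_results.tsv"),
      centroids = file.path(out_dir, "cluster_centroids.tsv"),
      survival = file.path(out_dir, "strain_survival.tsv"),
      fits = file.path(out_dir, "lifespan_fits.tsv"),
      rsme = file.path(out_dir, "rsme.tsv"),
      report = file.path(out_dir, "run_report.json")
    )
    readr::write_tsv(classes, artifacts[["classes"]])
    readr::write_tsv(tibble::as_tibble(tc), artifacts[["timecourse"]])
    cent <- tibble::as_tibble(model$centroids)
    names(cent) <- as.character(model$days)
    cent <- dplyr::bind_cols(tibble::tibble(cluster = seq_len(model$k),
                                            label = model$cluster_labels),
                             cent)
    readr::write_tsv(cent, artifacts[["centroids"]])
    readr::write_tsv(tibble::as_tibble(surv), artifacts[["survival"]])
    readr::write_tsv(fits, artifacts[["fits"]])
    readr::write_tsv(tibble::tibble(strain_id = names(qc$rsme),
                                    rsme = unname(qc$rsme)),
                     artifacts[["rsme"]])
    if (!is.null(enr)) {
      artifacts[["enrichment"]] <- file.path(out_dir, "enrichment.tsv")
      readr::write_tsv(enr, artifacts[["enrichment"]])
    }
    jsonlite::write_json(
      list(counts = as.list(counts), params = params,
           rsme_threshold = qc$rsme_threshold, pi0 = attr(tc, "pi0")),
      artifacts[["report"]], auto_unbox = TRUE, digits = NA
    )
  }

  structure(
    list(counts = counts, qc = qc, cluster_model = model, classes = classes,
         timecourse = tc, significant = sig, survival_fits = fits,
         enrichment = enr, params = params, artifacts = artifacts),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  c_ <- x$counts
  cat("<run_report>\n")
  cat(sprintf("  input strains        %6d\n", c_["n_input"]))
  cat(sprintf("  background excluded  %6d\n", c_["n_background"]))
  cat(sprintf("  high-RSME excluded   %6d\n", c_["n_rsme"]))
  cat(sprintf("  retained             %6d\n", c_["n_retained"]))
  cat(sprintf("  short / long / neutral  %d / %d / %d\n",
              c_["n_short"], c_["n_long"], c_["n_neutral"]))
  cat(sprintf("  significant (q <= %g) %5d of %d tested\n",
              x$params$q_cutoff, c_["n_significant"], c_["n_tested"]))
  invisible(x)
}
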