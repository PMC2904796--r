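# Shared fixture builders. Everything is generated in code; no data files.

# A small noise-free screen configuration; individual tests override fields.
noiseless_config <- function(n_strains = 50, seed = 1L, pool_t50_sd = 0.5,
                             ...) {
  screen_config(n_strains = n_strains, noise_sigma = 0,
                tag_affinity_sigma = 0, frac_background_tags = 0,
                p_regrow = 0, cfu_jitter_sigma = 0,
                pool_t50_sd = pool_t50_sd, seed = seed, ...)
}

# Tag intensity table for a handful of strains with explicit values:
# `values` is a function(strain, tag, replicate, day) -> intensity.
make_tag_table <- function(strains, days = c(3, 9, 11, 15, 20),
                           replicates = 1:2,
                           values = function(s, tg, r, d) 100) {
  grid <- expand.grid(strain_id = strains, tag = c("up", "down"),
                      replicate = as.integer(replicates), day = days,
                      stringsAsFactors = FALSE)
  grid$intensity <- mapply(values, grid$strain_id, grid$tag,
                           grid$replicate, grid$day)
  tibble::as_tibble(grid)
}

# Build an aging_profiles object directly from replicate log2-ratio
# matrices (strain x day, reference column included and zero).
make_profiles <- function(replicates, days, reference_day = days[1]) {
  strains <- rownames(replicates[[1]])
  layers <- lapply(replicates, function(m) {
    dimnames(m) <- list(strains, as.character(days))
    m
  })
  avg <- Reduce(`+`, lapply(layers, function(m) ifelse(is.na(m), 0, m))) /
    Reduce(`+`, lapply(layers, function(m) matrix(as.numeric(!is.na(m)),
                                                  nrow(m), ncol(m))))
  avg[!is.finite(avg)] <- NA_real_
  dimnames(avg) <- list(strains, as.character(days))
  structure(list(strains = strains, days = days,
                 reference_day = reference_day,
                 replicates = layers, average = avg,
                 mask = tibble::tibble(strain_id = character(),
                                       replicate = integer(),
                                       reason = character())),
            class = "aging_profiles")
}

# Profiles for a planted linear trend: slope per day step, two replicates
# with iid normal noise.
trend_profiles <- function(n_strains, slope, noise_sd = 0.3,
                           days = c(3, 9, 11, 15, 20), seed = 1) {
  set.seed(seed)
  tt <- seq_along(days) - 1
  base <- outer(rep(slope, n_strains), tt)
  mk <- function() {
    m <- base + matrix(rnorm(n_strains * length(days), 0, noise_sd),
                       n_strains)
    m[, 1] <- 0
    rownames(m) <- sprintf("s%04d", seq_len(n_strains))
    m
  }
  make_profiles(list(mk(), mk()), days)
}
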