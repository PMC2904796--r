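#' Natural cubic spline basis over sampling days
#'
#' Design matrix for the smooth alternative in the time-course test: an
#' intercept column plus a natural cubic spline basis with `df` degrees of
#' freedom and interior knots at day quantiles. With `df = 1` the basis
#' spans exactly the linear functions of day.
#'
#' @param days Numeric vector of distinct sampling days (>= 3).
#' @param df Spline degrees of freedom (default `min(3, length(days) - 2)`);
#'   must satisfy `df <= length(days) - 2` so the fit never saturates.
#' @return A `length(days) x (df + 1)` full-column-rank matrix whose first
#'   column is the intercept, with the days as rownames.
#' @export
spline_basis <- function(days, df = NULL) {
  days <- sort(unique(days))
  if (length(days) < 3) abort("need at least 3 distinct days")
  if (is.null(df)) df <- min(3, length(days) - 2)
  if (df < 1 || df > length(days) - 2) {
    abort("`df` must lie in [1, number of days - 2]")
  }
  basis <- cbind(1, splines::ns(days, df = df))
  dimnames(basis) <- list(as.character(days),
                          c("intercept", paste0("ns", seq_len(df))))
  if (qr(basis)$rank < ncol(basis)) abort("spline basis is rank deficient")
  basis
}

#' Time-course statistic for one strain
#'
#' Tests whether a strain's representation changes over the time course
#' consistently across replicates. Both replicates' log2-ratio observations
#' are stacked and two nested least-squares fits are compared: an
#' intercept-only null and the spline alternative. The statistic is the raw
#' residual-sum-of-squares ratio
#' `F = (rss0 - rss1) / (rss1 + delta)` with a small guard `delta` so exact
#' fits do not divide by zero; permutation calibration makes any
#' degrees-of-freedom scaling irrelevant. The statistic is capped at 1e12.
#'
#' @param obs Replicate x day matrix of log2 ratios (NA = masked).
#' @param basis Basis from [spline_basis()] whose rows match the columns of
#'   `obs`.
#' @param delta Guard added to the denominator (default 1e-8).
#' @return List with `f_stat`, `rss0`, `rss1`, `n_obs`, and `testable`
#'   (FALSE when observations cannot support the fit).
#' @export
strain_statistic <- function(obs, basis, delta = 1e-8) {
  if (ncol(obs) != nrow(basis)) {
    abort("`obs` columns must match `basis` rows (days)")
  }
  x <- basis[rep(seq_len(nrow(basis)), each = nrow(obs)), , drop = FALSE]
  y <- as.vector(obs)
  keep <- !is.na(y)
  y <- y[keep]
  x <- x[keep, , drop = FALSE]
  if (length(y) < ncol(basis) + 1 || qr(x)$rank < ncol(x)) {
    return(list(f_stat = NA_real_, rss0 = NA_real_, rss1 = NA_real_,
                n_obs = length(y), testable = FALSE))
  }
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(stats::lm.fit(x, y)$residuals^2)
  rss1 <- min(rss1, rss0)  # nested models; guards rounding
  f <- min((rss0 - rss1) / (rss1 + delta), 1e12)
  list(f_stat = f, rss0 = rss0, rss1 = rss1, n_obs = length(y),
       testable = TRUE)
}

# Observed statistics for all strains at once. Complete-case strains go
# through one matrix path; strains with masked days fall back to the
# per-strain fit. Returns a tibble.
all_strain_statistics <- function(profiles, basis, delta = 1e-8) {
  layers <- profiles$replicates
  day_cols <- as.character(sort(unique(profiles$days)))
  y_mat <- do.call(cbind, lapply(layers, function(m) m[, day_cols,
                                                       drop = FALSE]))
  x <- basis[rep(seq_len(nrow(basis)), times = length(layers)), ,
             drop = FALSE]
  stats_complete <- function(ymat, xmat) {
    fit <- stats::lm.fit(xmat, t(ymat))
    res <- t(as.matrix(fit$residuals))
    rss1 <- rowSums(res^2)
    rss0 <- rowSums((ymat - rowMeans(ymat))^2)
    rss1 <- pmin(rss1, rss0)
    tibble::tibble(rss0 = rss0, rss1 = rss1,
                   f_stat = pmin((rss0 - rss1) / (rss1 + delta), 1e12))
  }
  complete <- stats::complete.cases(y_mat)
  out <- tibble::tibble(strain_id = rownames(y_mat),
                        f_stat = NA_real_, rss0 = NA_real_,
                        rss1 = NA_real_, testable = FALSE)
  if (any(complete)) {
    cc <- stats_complete(y_mat[complete, , drop = FALSE], x)
    out$f_stat[complete] <- cc$f_stat
    out$rss0[complete] <- cc$rss0
    out$rss1[complete] <- cc$rss1
    out$testable[complete] <- TRUE
  }
  for (i in which(!complete)) {
    obs <- matrix(y_mat[i, ], nrow = length(layers), byrow = TRUE)
    s <- strain_statistic(obs, basis, delta)
    out$f_stat[i] <- s$f_stat
    out$rss0[i] <- s$rss0
    out$rss1[i] <- s$rss1
    out$testable[i] <- s$testable
  }
  out
}

#' Pooled permutation null for the time-course statistic
#'
#' For each permutation round, day labels are permuted once per replicate
#' (independently across replicates, but shared across all strains within a
#' replicate) and every strain's statistic is recomputed. Sharing the
#' permutation across strains preserves the cross-strain dependence
#' structure; pooling the `B x n` null values across strains gives the
#' resolution that five time points (120 distinct day orderings) cannot give
#' per strain.
#'
#' @param profiles An `aging_profiles` object (replicate layers are used).
#' @param basis Basis from [spline_basis()].
#' @param b Number of permutation rounds (default 1000; < 100 draws a
#'   warning, < 1 is an error).
#' @param seed Integer seed.
#' @param delta Denominator guard (default 1e-8).
#' @return List of class `null_distribution`: `stats` (numeric vector of
#'   pooled null statistics), `b`, `n_strains`, `seed`.
#' @export
permutation_null <- function(profiles, basis, b = 1000, seed = 1L,
                             delta = 1e-8) {
  if (b < 1) abort("`b` must be at least 1")
  if (b < 100) warn("fewer than 100 permutations: p-values will be coarse")
  layers <- profiles$replicates
  day_cols <- as.character(sort(unique(profiles$days)))
  tn <- length(day_cols)
  y_mat <- do.call(cbind, lapply(layers, function(m) m[, day_cols,
                                                       drop = FALSE]))
  complete <- stats::complete.cases(y_mat)
  testable_n <- nrow(y_mat)
  null_stats <- with_seed(seed, {
    res <- vector("list", b)
    for (bi in seq_len(b)) {
      perms <- lapply(seq_along(layers), function(r) sample.int(tn))
      x <- do.call(rbind, lapply(perms, function(p) basis[p, , drop = FALSE]))
      vals <- rep(NA_real_, testable_n)
      if (any(complete)) {
        ymat <- y_mat[complete, , drop = FALSE]
        fit <- stats::lm.fit(x, t(ymat))
        rss1 <- rowSums(t(as.matrix(fit$residuals))^2)
        rss0 <- rowSums((ymat - rowMeans(ymat))^2)
        rss1 <- pmin(rss1, rss0)
        vals[complete] <- pmin((rss0 - rss1) / (rss1 + delta), 1e12)
      }
      for (i in which(!complete)) {
        vals[i] <- strain_statistic_permuted(y_mat[i, ], basis, perms, tn,
                                             delta)
      }
      res[[bi]] <- vals[!is.na(vals)]
    }
    unlist(res)
  })
  structure(list(stats = null_stats, b = b, n_strains = nrow(y_mat),
                 seed = seed),
            class = "null_distribution")
}

# Statistic for one strain under given per-replicate day permutations;
# handles masked (NA) days. `y` is the strain's row of the stacked matrix.
strain_statistic_permuted <- function(y, basis, perms, tn, delta = 1e-8) {
  x <- do.call(rbind, lapply(perms, function(p) basis[p, , drop = FALSE]))
  keep <- !is.na(y)
  if (sum(keep) < ncol(basis) + 1) return(NA_real_)
  xk <- x[keep, , drop = FALSE]
  if (qr(xk)$rank < ncol(xk)) return(NA_real_)
  yk <- y[keep]
  rss0 <- sum((yk - mean(yk))^2)
  rss1 <- min(sum(stats::lm.fit(xk, yk)$residuals^2), rss0)
  min((rss0 - rss1) / (rss1 + delta), 1e12)
}

#' Empirical p-values from a pooled permutation null
#'
#' `p_s = (1 + #\{null >= F_s\}) / (1 + |null|)`, the standard
#' add-one permutation p-value; its smallest attainable value is
#' `1 / (|null| + 1)`.
#'
#' @param f_stats Numeric vector of observed statistics (NA allowed).
#' @param null A `null_distribution`.
#' @return Numeric vector of p-values in (0, 1].
#' @export
empirical_pvalues <- function(f_stats, null) {
  nv <- sort(null$stats)
  m <- length(nv)
  if (m == 0) abort("empty null distribution")
  # #{null >= F} via binary search on the sorted null
  ge <- m - findInterval(f_stats - .Machine$double.eps^0.5, nv)
  p <- (1 + ge) / (1 + m)
  p[is.na(f_stats)] <- NA_real_
  p
}

#' Estimate the null proportion pi0
#'
#' Storey's fixed-lambda estimator:
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) m))`, floored at `1/m`.
#' The default `lambda = 0.5` is robust at the few-thousand-test scale of a
#' genome-wide deletion screen.
#'
#' @param pvals Numeric vector of p-values (NA dropped).
#' @param lambda Tuning parameter in (0, 1) (default 0.5).
#' @return Estimated pi0 in (0, 1].
#' @export
estimate_pi0 <- function(pvals, lambda = 0.5) {
  if (lambda <= 0 || lambda >= 1) abort("`lambda` must lie in (0, 1)")
  p <- pvals[!is.na(pvals)]
  m <- length(p)
  if (m < 20) abort("need at least 20 p-values to estimate pi0")
  max(min(1, sum(p > lambda) / ((1 - lambda) * m)), 1 / m)
}

#' Storey q-values from p-values
#'
#' Step-up transformation: with p sorted ascending,
#' `q_(i) = min_(j >= i) pi0 * m * p_(j) / j`, mapped back to the input
#' order. q is monotone non-decreasing in p and bounded by `pi0`.
#'
#' @param pvals Numeric vector of p-values (NA preserved).
#' @param pi0 Null proportion from [estimate_pi0()] (default 1, the
#'   conservative Benjamini-Hochberg limit).
#' @return Numeric vector of q-values.
#' @export
qvalues <- function(pvals, pi0 = 1) {
  q <- rep(NA_real_, length(pvals))
  idx <- which(!is.na(pvals))
  p <- pvals[idx]
  m <- length(p)
  if (m == 0) return(q)
  ord <- order(p)
  qs <- rev(cummin(rev(pi0 * m * p[ord] / seq_len(m))))
  q[idx[ord]] <- pmin(qs, 1)
  q
}

#' Run the full time-course significance analysis
#'
#' Convenience wrapper: spline basis, observed statistics, pooled
#' permutation null, empirical p-values, pi0 and q-values.
#'
#' @param profiles An `aging_profiles` object restricted to QC-retained
#'   strains.
#' @param df Spline degrees of freedom (default `min(3, T - 2)`).
#' @param b Number of permutations (default 1000).
#' @param seed Integer seed.
#' @param lambda pi0 tuning parameter (default 0.5).
#' @return A tibble of class `timecourse_result` with columns `strain_id`,
#'   `f_stat`, `rss0`, `rss1`, `p_value`, `q_value`, `testable`, plus
#'   attributes `pi0`, `b`, `df`, `seed`.
#' @export
timecourse_test <- function(profiles, df = NULL, b = 1000, seed = 1L,
                            lambda = 0.5) {
  basis <- spline_basis(profiles$days, df)
  obs <- all_strain_statistics(profiles, basis)
  null <- permutation_null(profiles, basis, b = b, seed = seed)
  obs$p_value <- empirical_pvalues(obs$f_stat, null)
  pi0 <- estimate_pi0(obs$p_value, lambda)
  obs$q_value <- qvalues(obs$p_value, pi0)
  attr(obs, "pi0") <- pi0
  attr(obs, "b") <- b
  attr(obs, "df") <- ncol(basis) - 1L
  attr(obs, "seed") <- seed
  class(obs) <- c("timecourse_result", class(obs))
  obs
}

#' Strains significant at a q-value cutoff
#'
#' @param results A `timecourse_result` tibble.
#' @param q_cutoff FDR level (default 0.1).
#' @return Character vector of significant strain ids.
#' @export
significant_strains <- function(results, q_cutoff = 0.1) {
  results$strain_id[!is.na(results$q_value) & results$q_value <= q_cutoff]
}
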