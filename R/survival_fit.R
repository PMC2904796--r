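#' Reconstruct per-strain survival curves
#'
#' Approximates each strain's survival curve by multiplying its fold-ratio
#' change (2 to the averaged log2 ratio) by the pool CFU count at each day.
#' Pool CFUs are averaged across replicates first. Percent survival is
#' anchored at the reference day (= 100%).
#'
#' @param profiles An `aging_profiles` object; the averaged layer is used.
#' @param pool_cfu Pool CFU tibble (columns `replicate`, `day`,
#'   `cfu_per_ml`) covering every profile day.
#' @return A tibble of class `strain_survival` with columns `strain_id`,
#'   `day`, `estimated_cfu`, `percent_survival`.
#' @export
reconstruct_survival <- function(profiles, pool_cfu) {
  days <- profiles$days
  cfu <- dplyr::summarise(dplyr::group_by(tibble::as_tibble(pool_cfu),
                                          .data$day),
                          cfu_per_ml = mean(.data$cfu_per_ml),
                          .groups = "drop")
  if (!all(days %in% cfu$day)) {
    abort("pool CFU table is missing one or more profile days")
  }
  cfu_vec <- cfu$cfu_per_ml[match(days, cfu$day)]
  est <- sweep(2^profiles$average[, as.character(days), drop = FALSE], 2,
               cfu_vec, "*")
  ref <- est[, as.character(profiles$reference_day)]
  out <- tibble::tibble(
    strain_id = rep(rownames(est), times = length(days)),
    day = rep(days, each = nrow(est)),
    estimated_cfu = as.vector(est),
    percent_survival = as.vector(100 * est / ref)
  )
  class(out) <- c("strain_survival", class(out))
  out
}

#' Fit a Boltzmann sigmoid to a survival curve
#'
#' Least-squares fit of `V(t) = bottom + (top - bottom)/(1 + exp((t -
#' t50)/tau))` to percent-survival points. Fitting is done in the
#' (bottom, span = top - bottom, t50, tau) parameterization with box
#' constraints (span >= 0, tau > 0, t50 within 10 days of the sampled
#' range), by Levenberg-Marquardt with a bounded quasi-Newton fallback.
#' Initial values: top = max, bottom = min, t50 = the day whose value is
#' nearest the half-range, tau = (last - first)/8.
#'
#' @param days Numeric vector of days (>= 4 points).
#' @param percent Percent survival at those days.
#' @return A list of class `boltzmann_fit`: `top`, `bottom`, `t50`, `tau`,
#'   `rss`, `converged`, `degenerate` (TRUE when the curve is flat or
#'   rising and no fit is attempted), `extrapolated` (t50 outside the
#'   sampled day range).
#' @export
fit_boltzmann <- function(days, percent) {
  ord <- order(days)
  t <- as.numeric(days[ord]); y <- as.numeric(percent[ord])
  if (length(t) < 4) abort("need at least 4 points to fit")
  rng <- max(y) - min(y)
  degenerate <- rng < 5 || all(diff(y) >= 0)
  if (isTRUE(degenerate)) {
    out <- list(top = NA_real_, bottom = NA_real_, t50 = NA_real_,
                tau = NA_real_, rss = NA_real_, converged = FALSE,
                degenerate = TRUE, extrapolated = FALSE)
    class(out) <- "boltzmann_fit"
    return(out)
  }
  half <- min(y) + rng / 2
  start <- c(bottom = min(y), span = rng,
             t50 = t[which.min(abs(y - half))], tau = (max(t) - min(t)) / 8)
  lower <- c(bottom = -Inf, span = 0, t50 = min(t) - 10, tau = 1e-6)
  upper <- c(bottom = Inf, span = Inf, t50 = max(t) + 10,
             tau = (max(t) - min(t)) * 10)
  model <- function(p, t) p[1] + p[2] / (1 + exp((t - p[3]) / p[4]))
  fit <- tryCatch({
    nls_fit <- minpack.lm::nlsLM(
      y ~ bottom + span / (1 + exp((t - t50) / tau)),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    p <- stats::coef(nls_fit)
    list(par = p, rss = sum(stats::resid(nls_fit)^2),
         converged = nls_fit$convInfo$isConv)
  }, error = function(e) NULL)
  if (is.null(fit)) {
    opt <- stats::optim(start, function(p) sum((y - model(p, t))^2),
                        method = "L-BFGS-B",
                        lower = lower,
                        upper = pmin(upper, c(1e6, 1e6, Inf, Inf)),
                        control = list(maxit = 500))
    fit <- list(par = opt$par, rss = opt$value,
                converged = opt$convergence == 0)
  }
  p <- fit$par
  out <- list(top = unname(p["bottom"] + p["span"]),
              bottom = unname(p["bottom"]), t50 = unname(p["t50"]),
              tau = unname(p["tau"]), rss = fit$rss,
              converged = isTRUE(fit$converged), degenerate = FALSE,
              extrapolated = p["t50"] < min(t) || p["t50"] > max(t))
  out$extrapolated <- unname(out$extrapolated)
  class(out) <- "boltzmann_fit"
  out
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<boltzmann_fit> degenerate curve (flat or rising); no fit\n")
  } else {
    cat(sprintf(
      "<boltzmann_fit> top %.4g, bottom %.4g, t50 %.4g d, tau %.4g d (rss %.4g%s)\n",
      x$top, x$bottom, x$t50, x$tau, x$rss,
      if (x$extrapolated) ", extrapolated" else ""))
  }
  invisible(x)
}

#' Mean lifespan from a Boltzmann fit
#'
#' The day at which the fitted curve crosses 50% absolute survival
#' (reference day = 100%): `t50 + tau * log((top - 50)/(50 - bottom))`.
#' This equals the midpoint parameter `t50` when top = 100 and bottom = 0,
#' and is undefined (NA) when the fitted curve never crosses 50%.
#'
#' @param fit A converged `boltzmann_fit`.
#' @return Mean lifespan in days, or `NA` with attribute
#'   `"undefined" = TRUE` when the curve does not cross 50%.
#' @export
mean_lifespan <- function(fit) {
  if (fit$degenerate || !fit$converged) {
    return(structure(NA_real_, undefined = TRUE))
  }
  if (fit$top <= 50 || fit$bottom >= 50) {
    return(structure(NA_real_, undefined = TRUE))
  }
  fit$t50 + fit$tau * log((fit$top - 50) / (50 - fit$bottom))
}

#' Area under a survival curve
#'
#' Trapezoidal area of percent survival over days, in percent x days. A
#' model-free lifespan summary that is monotone under pointwise dominance
#' of curves.
#'
#' @param days Numeric vector of days (>= 2).
#' @param percent Percent survival at those days.
#' @return Area in percent-days.
#' @export
survival_auc <- function(days, percent) {
  if (length(days) < 2) abort("need at least 2 points")
  ord <- order(days)
  pracma::trapz(as.numeric(days[ord]), as.numeric(percent[ord]))
}

#' Fit lifespan summaries for every strain
#'
#' Runs [fit_boltzmann()], [mean_lifespan()] and [survival_auc()] over a
#' reconstructed survival set.
#'
#' @param survival A `strain_survival` tibble from [reconstruct_survival()].
#' @return Tibble with one row per strain: fit parameters, `rss`,
#'   `converged`, `degenerate`, `extrapolated`, `mean_lifespan`, `auc`.
#' @export
fit_all_strains <- function(survival) {
  by_strain <- split(tibble::as_tibble(survival),
                     survival$strain_id)
  rows <- lapply(names(by_strain), function(s) {
    d <- by_strain[[s]]
    ok <- !is.na(d$percent_survival)
    if (sum(ok) < 4) {
      return(tibble::tibble(strain_id = s, top = NA_real_, bottom = NA_real_,
                            t50 = NA_real_, tau = NA_real_, rss = NA_real_,
                            converged = FALSE, degenerate = TRUE,
                            extrapolated = FALSE, mean_lifespan = NA_real_,
                            auc = NA_real_))
    }
    f <- fit_boltzmann(d$day[ok], d$percent_survival[ok])
    tibble::tibble(strain_id = s, top = f$top, bottom = f$bottom,
                   t50 = f$t50, tau = f$tau, rss = f$rss,
                   converged = f$converged, degenerate = f$degenerate,
                   extrapolated = f$extrapolated,
                   mean_lifespan = as.numeric(mean_lifespan(f)),
                   auc = survival_auc(d$day[ok], d$percent_survival[ok]))
  })
  dplyr::bind_rows(rows)
}
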