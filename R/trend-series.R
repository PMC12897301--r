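# Model-based age-standardised 5-year survival series, its delta-method
# confidence band, the AACS trend statistic, and its case-resampling
# bootstrap.

# Per-stratum quantities for the delta method: Breslow Lambda0_a(t), its
# base variance sum(d/S0^2), and q_a = sum(d * S1 / S0^2) (the derivative of
# the baseline w.r.t. beta, negated).
baseline_components <- function(model, t = 5) {
  lapply(model$baseline, function(bl) {
    sel <- bl$time <= t + 1e-12
    S1 <- bl$S1[sel, , drop = FALSE]
    list(lambda = sum(bl$d[sel] / bl$S0[sel]),
         v0 = sum(bl$d[sel] / bl$S0[sel]^2),
         q = colSums(bl$d[sel] * S1 / bl$S0[sel]^2))
  })
}

# Age-standardised fitted S5 values (no band): the vectorised fast path
# reused by the bootstrap; arithmetic identical to standardise() per year.
fitted_std_s5 <- function(model, weights, years) {
  lam <- vapply(weights$grouping, function(g) {
    bl <- model$baseline[[g]]
    sel <- bl$time <= 5 + 1e-12
    sum(bl$d[sel] / bl$S0[sel])
  }, numeric(1))
  X <- year_basis_eval(model$basis, years)
  m <- exp(drop(X %*% model$beta))
  drop(weights$weights %*% exp(-outer(lam, m)))
}

#' Model-based age-standardised 5-year survival series
#'
#' For each calendar year `y` and age stratum `a`, the fitted 5-year
#' survival is `S_a(5 | y) = exp(-Lambda0_a(5) * exp(x(y)' beta))` with the
#' Breslow baseline cumulative hazard at 5 years; the overall value is the
#' weighted combination over strata ([standardise()]). Years beyond the last
#' fitted diagnosis year continue the last segment's slope and are flagged
#' `extrapolated`. The 95\% band treats `(beta, Lambda0_1..Lambda0_A)` as
#' jointly asymptotically normal (delta method), with the baseline-versus-
#' coefficient covariance from the fit, and is clipped to \[0, 1\].
#'
#' @param model a fitted `coxjp` model whose strata match the weights'
#'   grouping.
#' @param weights an [age_weights()] over the model's strata.
#' @param years calendar years of the series; default runs from the
#'   reference year through one year past the last fitted diagnosis year
#'   (modelled prediction to the end of follow-up).
#' @return a `trend_series` object: data fields `years`, `s5`, `se`,
#'   `band_low`, `band_high`, `extrapolated`, plus `aacs` over the series.
#' @export
adjusted_s5_series <- function(model, weights, years = NULL) {
  stopifnot(inherits(model, "coxjp"), inherits(weights, "age_weights"))
  if (!setequal(weights$grouping, model$strata)) {
    stop("weights grouping {", paste(weights$grouping, collapse = ", "),
         "} does not match model strata {",
         paste(model$strata, collapse = ", "), "}")
  }
  if (is.null(years)) {
    years <- seq(model$basis$y0, model$year_range[2] + 1L)
  }
  comp <- baseline_components(model, 5)
  for (g in weights$grouping) {
    if (comp[[g]]$lambda <= 0) {
      stop("no baseline cumulative hazard available for stratum ", g)
    }
  }
  p <- length(model$beta)
  A <- length(weights$grouping)
  V <- model$cov
  # joint covariance of (beta, Lambda_1..Lambda_A)
  Sig <- matrix(0, p + A, p + A)
  Sig[1:p, 1:p] <- V
  for (a in seq_len(A)) {
    qa <- comp[[weights$grouping[a]]]$q
    Sig[1:p, p + a] <- -V %*% qa
    Sig[p + a, 1:p] <- Sig[1:p, p + a]
    for (b in seq_len(A)) {
      qb <- comp[[weights$grouping[b]]]$q
      Sig[p + a, p + b] <- drop(t(qa) %*% V %*% qb) +
        if (a == b) comp[[weights$grouping[a]]]$v0 else 0
    }
  }
  X <- year_basis_eval(model$basis, years)
  m <- exp(drop(X %*% model$beta))
  s5 <- numeric(length(years))
  se <- numeric(length(years))
  for (i in seq_along(years)) {
    sa <- vapply(weights$grouping,
                 function(g) exp(-comp[[g]]$lambda * m[i]), numeric(1))
    lam <- vapply(weights$grouping, function(g) comp[[g]]$lambda, numeric(1))
    s5[i] <- sum(weights$weights * sa)
    grad <- numeric(p + A)
    grad[1:p] <- -sum(weights$weights * lam * m[i] * sa) * X[i, ]
    grad[p + seq_len(A)] <- -weights$weights * m[i] * sa
    se[i] <- sqrt(drop(t(grad) %*% Sig %*% grad))
  }
  out <- structure(list(
    years = years, s5 = s5, se = se,
    band_low = pmin(pmax(s5 - qnorm(0.975) * se, 0), 1),
    band_high = pmin(pmax(s5 + qnorm(0.975) * se, 0), 1),
    extrapolated = years > model$year_range[2],
    weights = weights, model = model
  ), class = "trend_series")
  out$aacs <- aacs(out)
  out
}

#' Average absolute change in survival (AACS)
#'
#' The average yearly change of fitted 5-year survival over the series, in
#' percentage points: `(s5[last] - s5[first]) * 100 / (years - 1)`. Optional
#' `from`/`to` restrict the computation to a sub-period (e.g. one segment of
#' a joinpoint model).
#'
#' @param series a `trend_series`, or a data.frame with columns `years`
#'   and `s5` (survival proportions in \[0, 1\]).
#' @param from,to optional first/last calendar year of the period.
#' @return AACS in percentage points per year.
#' @export
aacs <- function(series, from = NULL, to = NULL) {
  years <- series$years
  s5 <- series$s5
  keep <- rep(TRUE, length(years))
  if (!is.null(from)) keep <- keep & years >= from
  if (!is.null(to)) keep <- keep & years <= to
  years <- years[keep]
  s5 <- s5[keep]
  if (length(years) < 2) stop("AACS needs at least two years")
  (s5[length(s5)] - s5[1]) * 100 / (years[length(years)] - years[1])
}

#' @export
print.trend_series <- function(x, ...) {
  cat(sprintf("Age-standardised 5-year survival series, %d-%d\n",
              min(x$years), max(x$years)))
  cat(sprintf("  start %.1f%%, end %.1f%%%s\n", 100 * x$s5[1],
              100 * x$s5[length(x$s5)],
              if (any(x$extrapolated)) sprintf(" (%d extrapolated year%s)",
                sum(x$extrapolated), if (sum(x$extrapolated) > 1) "s" else "")
              else ""))
  if (!is.null(x$aacs_ci)) {
    cat(sprintf("  AACS %.2f pp/yr [%.2f, %.2f]\n", x$aacs,
                x$aacs_ci[1], x$aacs_ci[2]))
  } else {
    cat(sprintf("  AACS %.2f pp/yr\n", x$aacs))
  }
  invisible(x)
}

#' Bootstrap confidence interval for the AACS
#'
#' Case-level resampling with replacement: each replicate refits the Cox
#' model coefficients and Breslow baselines with the joinpoint locations
#' held fixed at the selected basis (locations are not re-selected), then
#' recomputes the age-standardised series and its AACS. Replicates that
#' fail to fit (e.g. a resample leaves a stratum without events) are
#' dropped and counted; more than 10\% failures is an error. The reported
#' statistic and interval are the median and the 2.5th/97.5th percentiles
#' of the bootstrap distribution.
#'
#' @param observations data.frame from [cox_observations()].
#' @param basis the selected [year_basis()] (joinpoints fixed).
#' @param weights an [age_weights()]; held fixed across replicates (the
#'   case-pool standard is treated as a constant, not re-estimated).
#' @param B number of bootstrap replicates (default 500).
#' @param seed integer seed; the same seed reproduces the same triple.
#' @param years calendar years of the series; default as in
#'   [adjusted_s5_series()].
#' @return list with `median`, `ci` (2.5th and 97.5th percentiles), `draws`
#'   (successful replicate AACS values) and `n_failed`.
#' @export
bootstrap_aacs <- function(observations, basis, weights, B = 500, seed = 1,
                           years = NULL) {
  set.seed(seed)
  n <- nrow(observations)
  if (is.null(years)) {
    years <- seq(basis$y0, max(observations$year) + 1L)
  }
  # plain vectors: replicate resampling avoids data.frame row indexing
  time <- observations$time
  event <- observations$event
  year <- observations$year
  stratum <- observations$stratum
  draws <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    rep_obs <- list(time = time[idx], event = event[idx], year = year[idx],
                    stratum = stratum[idx])
    fit <- tryCatch(fit_cox_prepared(prepare_cox_data(rep_obs), basis),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (!setequal(fit$strata, weights$grouping)) next
    s5 <- tryCatch(fitted_std_s5(fit, weights, years),
                   error = function(e) NULL)
    if (is.null(s5)) next
    draws[b] <- aacs(list(years = years, s5 = s5))
  }
  n_failed <- sum(is.na(draws))
  if (n_failed > 0.1 * B) {
    stop(n_failed, " of ", B, " bootstrap replicates failed to fit")
  }
  draws <- draws[!is.na(draws)]
  list(median = median(draws),
       ci = unname(quantile(draws, c(0.025, 0.975))),
       draws = draws, n_failed = n_failed)
}
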