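# Age-stratified Cox proportional-hazards model with a continuous
# piecewise-linear diagnosis-year effect, joinpoint selection by BIC, and
# Breslow baseline cumulative hazards per stratum. The partial likelihood,
# gradient and observed information (Efron tie handling) are computed in a
# small C++ kernel; Newton-Raphson with step halving runs here.

#' Prepare Cox model observations from case records
#'
#' Right-truncates follow-up at `horizon` years (later deaths become
#' censorings at the horizon) and attaches diagnosis year and stratum.
#'
#' @param cases a `registry_cases` table.
#' @param horizon truncation horizon in years (default 5).
#' @param grouping age grouping used as strata (default the three-group
#'   standardisation grouping); `NULL` for an unstratified fit.
#' @return data.frame with columns `time`, `event`, `year`, `stratum`.
#' @export
cox_observations <- function(cases, horizon = 5,
                             grouping = c("0-4", "5-9", "10-14")) {
  obs <- followup_observations(cases)
  event <- ifelse(obs$time > horizon, 0L, obs$event)
  time <- pmin(obs$time, horizon)
  stratum <- if (is.null(grouping)) rep("all", nrow(obs)) else
    map_age_group(obs$age_group, grouping)
  data.frame(time = time, event = event, year = obs$diagnosis_year,
             stratum = stratum, stringsAsFactors = FALSE)
}

#' Fit a stratified Cox model with a piecewise-linear year effect
#'
#' Maximises the stratified Cox partial likelihood (Efron tie handling) by
#' Newton-Raphson with step halving, to a gradient norm of 1e-8. The
#' covariates are the year-basis functions: an offset `year - y0` plus one
#' hinge per joinpoint, so coefficients are per-segment slope increments of
#' the log hazard per calendar year. Baseline cumulative hazards per stratum
#' are Breslow estimates at covariate value 0, i.e. at the reference year.
#'
#' @param observations data.frame from [cox_observations()] (columns `time`,
#'   `event`, `year`, `stratum`).
#' @param basis a [year_basis()].
#' @param beta_init optional starting coefficients (warm start).
#' @return a `coxjp` model object with elements `beta`, `cov` (inverse
#'   observed information), `loglik`, `n_events`, `strata`, `baseline`
#'   (per-stratum step functions of the cumulative hazard and the risk-set
#'   sums needed for delta-method variances), `basis`, `bic`.
#' @export
fit_cox <- function(observations, basis, beta_init = NULL) {
  fit_cox_prepared(prepare_cox_data(observations), basis, beta_init)
}

# Sort once (by stratum, then time) and index the strata; reused across a
# joinpoint grid so the per-model cost is the Newton iterations only.
prepare_cox_data <- function(observations) {
  ord <- order(observations$stratum, observations$time)
  obs <- list(time = observations$time[ord],
              event = observations$event[ord],
              year = observations$year[ord],
              stratum = observations$stratum[ord])
  strata <- unique(obs$stratum)
  ev_by_stratum <- tapply(obs$event, obs$stratum, sum)[strata]
  if (sum(obs$event) < 1) stop("no events: cannot fit a Cox model")
  if (any(ev_by_stratum < 1)) {
    stop("stratum without events: ",
         paste(strata[ev_by_stratum < 1], collapse = ", "))
  }
  sidx <- match(obs$stratum, strata)
  first <- !duplicated(sidx)
  obs$strata <- strata
  obs$sstart <- which(first) - 1L
  obs$send <- c(which(first)[-1] - 1L, length(sidx)) - 1L
  obs
}

fit_cox_prepared <- function(obs, basis, beta_init = NULL) {
  stopifnot(inherits(basis, "year_basis"))
  strata <- obs$strata
  X <- year_basis_eval(basis, obs$year)
  p <- ncol(X)
  # centre the basis for numerical conditioning; the partial likelihood, its
  # gradient, the information and the coefficients are invariant, and the
  # baseline risk-set sums are un-centred below
  xbar <- colMeans(X)
  Xc <- sweep(X, 2, xbar)
  sstart <- obs$sstart
  send <- obs$send

  beta <- if (is.null(beta_init)) rep(0, p) else as.numeric(beta_init)
  stopifnot(length(beta) == p)
  res <- cox_ll(obs$time, obs$event, Xc, sstart, send, beta, FALSE)
  converged <- FALSE
  for (iter in seq_len(100)) {
    if (sqrt(sum(res$grad^2)) <= 1e-8) {
      converged <- TRUE
      break
    }
    delta <- tryCatch(solve(res$info, res$grad), error = function(e) {
      stop("singular information matrix (flat likelihood direction)")
    })
    step <- 1
    repeat {
      cand <- beta + step * delta
      res_new <- cox_ll(obs$time, obs$event, Xc, sstart, send, cand, FALSE)
      if (is.finite(res_new$loglik) &&
          res_new$loglik >= res$loglik - 1e-9 * (abs(res$loglik) + 1)) break
      step <- step / 2
      if (step < 1e-10) stop("step halving failed: partial likelihood not improving")
    }
    beta <- cand
    res <- res_new
  }
  if (!converged && sqrt(sum(res$grad^2)) > 1e-8) {
    stop("Newton iterations did not converge in 100 steps (|grad| = ",
         format(sqrt(sum(res$grad^2))), ")")
  }
  if (any(abs(beta) > 50)) {
    stop("monotone partial likelihood: apparent separation in the year effect")
  }
  final <- cox_ll(obs$time, obs$event, Xc, sstart, send, beta, TRUE)
  bl <- final$baseline
  shift <- exp(drop(xbar %*% beta))
  baseline <- lapply(seq_along(strata), function(s) {
    sel <- bl$stratum == s
    ord <- order(bl$time[sel])
    S1c <- bl$S1[sel, , drop = FALSE][ord, , drop = FALSE]
    S0c <- bl$S0[sel][ord]
    # un-centre: w_unc = w_cen * exp(xbar' beta), x = xc + xbar
    list(time = bl$time[sel][ord], d = bl$d[sel][ord],
         S0 = S0c * shift,
         S1 = (S1c + outer(S0c, xbar)) * shift)
  })
  names(baseline) <- strata
  d <- sum(obs$event)
  model <- structure(list(
    beta = setNames(as.numeric(beta), colnames(X)),
    cov = solve(final$info),
    loglik = final$loglik,
    n_events = d,
    n = length(obs$time),
    strata = strata,
    baseline = baseline,
    basis = basis,
    year_range = range(obs$year)
  ), class = "coxjp")
  model$bic <- bic(model)
  model
}

#' Bayesian information criterion of a fitted Cox-joinpoint model
#'
#' `-2 * log partial likelihood + p * log(d)` with `p` the number of basis
#' coefficients and `d` the number of events (the standard effective sample
#' size for Cox-model BIC). Joinpoint locations are not counted as
#' parameters by default; set `count_joinpoints = TRUE` to penalise them
#' too.
#'
#' @param model a fitted `coxjp` model.
#' @param count_joinpoints add the number of joinpoints to the parameter
#'   count.
#' @return the criterion value.
#' @export
bic <- function(model, count_joinpoints = FALSE) {
  stopifnot(inherits(model, "coxjp"))
  if (model$n_events == 0) stop("BIC undefined with zero events")
  p <- length(model$beta) + if (count_joinpoints) length(model$basis$joinpoints) else 0
  -2 * model$loglik + p * log(model$n_events)
}

#' @export
print.coxjp <- function(x, ...) {
  tau <- x$basis$joinpoints
  cat("Cox-joinpoint model (reference year ", x$basis$y0, ")\n", sep = "")
  cat("  joinpoints:", if (length(tau)) paste(tau, collapse = ", ") else "none", "\n")
  slopes <- coef_to_slopes(x$beta)
  seg_from <- c(x$basis$y0, tau)
  for (i in seq_along(slopes)) {
    cat(sprintf("  segment %d (from %d): slope %+.4f log-hazard/yr\n",
                i, seg_from[i], slopes[i]))
  }
  cat(sprintf("  strata: %s; events %d/%d; logPL %.3f; BIC %.3f\n",
              paste(x$strata, collapse = ", "), x$n_events, x$n,
              x$loglik, x$bic))
  invisible(x)
}

#' Breslow baseline cumulative hazard at a time point
#'
#' @param model a `coxjp` model.
#' @param stratum stratum label.
#' @param t time in years since diagnosis.
#' @return cumulative hazard at covariate 0 (the reference year).
#' @export
baseline_cumhaz <- function(model, stratum, t = 5) {
  bl <- model$baseline[[stratum]]
  if (is.null(bl)) stop("unknown stratum: ", stratum)
  sum(bl$d[bl$time <= t + 1e-12] / bl$S0[bl$time <= t + 1e-12])
}

#' Select joinpoints by exhaustive BIC search
#'
#' Fits models with 0 up to `max_joinpoints` joinpoints over the full grid
#' of integer-year placements that leave at least `min_segment` years in
#' every segment (including before the first and after the last joinpoint),
#' and returns the model minimising BIC. Ties are broken toward fewer
#' joinpoints, then earlier joinpoint years.
#'
#' @param observations data.frame from [cox_observations()].
#' @param max_joinpoints maximum number of joinpoints (default 2).
#' @param min_segment minimum segment length in years (default 3).
#' @return the best `coxjp` model; `$grid` holds the full BIC table
#'   (`joinpoints`, `loglik`, `bic` per admissible placement).
#' @export
select_joinpoints <- function(observations, max_joinpoints = 2,
                              min_segment = 3) {
  y0 <- min(observations$year)
  y_end <- max(observations$year)
  candidates <- list(integer(0))
  if (max_joinpoints >= 1) {
    taus <- seq(y0 + min_segment, y_end - min_segment)
    candidates <- c(candidates, lapply(taus, function(t) t))
    if (max_joinpoints >= 2) {
      for (t1 in taus) {
        t2s <- taus[taus >= t1 + min_segment]
        candidates <- c(candidates, lapply(t2s, function(t2) c(t1, t2)))
      }
    }
  }
  fits <- vector("list", length(candidates))
  grid <- data.frame(joinpoints = vapply(candidates, paste, character(1),
                                         collapse = ","),
                     n_joinpoints = vapply(candidates, length, integer(1)),
                     loglik = NA_real_, bic = NA_real_,
                     stringsAsFactors = FALSE)
  prep <- prepare_cox_data(observations)
  warm <- NULL
  for (i in seq_along(candidates)) {
    basis <- year_basis(y0, candidates[[i]], y_end = y_end,
                        min_segment = min_segment)
    init <- if (!is.null(warm)) c(warm, rep(0, length(candidates[[i]])))
    fit <- tryCatch(fit_cox_prepared(prep, basis, beta_init = init),
                    error = function(e) NULL)
    if (i == 1 && !is.null(fit)) warm <- unname(fit$beta[1])
    if (!is.null(fit)) {
      fits[[i]] <- fit
      grid$loglik[i] <- fit$loglik
      grid$bic[i] <- fit$bic
    }
  }
  if (all(is.na(grid$bic))) stop("no admissible joinpoint model could be fitted")
  # ties toward fewer joinpoints, then earlier years (candidate order is
  # already 0-jp, then tau ascending, then pairs ascending)
  best <- which(grid$bic <= min(grid$bic, na.rm = TRUE) + 1e-9)[1]
  model <- fits[[best]]
  model$grid <- grid
  model
}
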