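#' Confounder adjustment specification
#'
#' Controls the time-varying confounder adjustment of the health impact
#' function: annual harmonics for seasonality, calendar-year indicators,
#' day-of-week indicators, and linear terms for temperature and relative
#' humidity.
#'
#' @param confounders character subset of `c("temp", "rh")`.
#' @param harmonics number of annual sine/cosine pairs (0 disables).
#' @param dow include day-of-week indicators.
#' @param year_effects include calendar-year indicators.
#' @return a list of class `confounder_spec`.
#' @export
confounder_spec <- function(confounders = c("temp", "rh"), harmonics = 1L,
                            dow = TRUE, year_effects = TRUE) {
  stopifnot(all(confounders %in% c("temp", "rh")), harmonics >= 0)
  structure(list(confounders = confounders, harmonics = as.integer(harmonics),
                 dow = dow, year_effects = year_effects),
            class = "confounder_spec")
}

# zip-wise lagged copy of x; rows whose lag predates the series are NA
shift_within_zip <- function(x, zip, l) {
  if (l == 0L) return(x)
  n <- length(x)
  out <- rep(NA_real_, n)
  idx <- seq_len(n) - l
  ok <- idx >= 1L
  ok[ok] <- zip[idx[ok]] == zip[ok]
  out[ok] <- x[idx[ok]]
  out
}

#' Build the distributed-lag Poisson design for one outcome
#'
#' Produces the regression inputs of the health impact function: lagged
#' aPM2.5 regressors (one unconstrained coefficient per lag over the
#' window), the confounder basis, a log-population offset (per 100,000
#' persons), and the ZIP intercept structure. The first `max(lag_window)`
#' days of each ZIP, whose lagged exposures predate the series, are
#' dropped.
#'
#' @param panel a ZIP-day panel (see [generate_panel()] for columns).
#' @param outcome `"respiratory"` or `"cardiovascular"`.
#' @param lag_window inclusive lag range in days, e.g. `c(0, 4)`.
#' @param confounders a [confounder_spec()].
#' @param trim_lag number of leading days dropped per ZIP; defaults to
#'   `max(lag_window)`. Set it to the largest lag across several candidate
#'   windows so competing fits use the same observations (required for
#'   likelihood-based comparison such as BIC).
#' @return a list of class `hif_design` with elements `X` (model matrix
#'   without intercept), `y`, `offset`, `zip` (factor), `lag_cols`,
#'   `data` (the trimmed panel rows), `outcome`, `lag_window`.
#' @export
build_design <- function(panel, outcome = c("respiratory", "cardiovascular"),
                         lag_window = c(0L, 4L),
                         confounders = confounder_spec(),
                         trim_lag = NULL) {
  outcome <- match.arg(outcome)
  stopifnot(length(lag_window) == 2, lag_window[1] >= 0,
            lag_window[2] >= lag_window[1])
  trim_lag <- max(as.integer(trim_lag %||% lag_window[2]), lag_window[2])
  panel <- dplyr::arrange(panel, .data$zip_id, .data$date)
  days_per_zip <- min(table(panel$zip_id))
  if (days_per_zip <= trim_lag) {
    abort("lag window longer than the shortest per-ZIP series.")
  }
  lags <- seq(lag_window[1], lag_window[2])
  zip_chr <- panel$zip_id
  lag_mat <- vapply(lags, function(l) shift_within_zip(panel$apm, zip_chr, l),
                    numeric(nrow(panel)))
  colnames(lag_mat) <- paste0("apm_lag", lags)
  day_in_zip <- stats::ave(seq_along(zip_chr), zip_chr, FUN = seq_along)
  keep <- day_in_zip > trim_lag

  doy <- as.integer(format(panel$date, "%j"))
  parts <- list(lag_mat)
  if (confounders$harmonics > 0) {
    for (h in seq_len(confounders$harmonics)) {
      parts[[length(parts) + 1L]] <- cbind(
        setNames(data.frame(sin(2 * pi * h * doy / 365.25),
                            cos(2 * pi * h * doy / 365.25)),
                 paste0(c("sin", "cos"), h)))
    }
  }
  if (confounders$year_effects) {
    yr <- factor(format(panel$date, "%Y"))
    if (nlevels(yr) > 1) {
      ym <- model.matrix(~ yr)[, -1, drop = FALSE]
      colnames(ym) <- paste0("year", levels(yr)[-1])
      parts[[length(parts) + 1L]] <- ym
    }
  }
  if (confounders$dow) {
    dw <- factor(format(panel$date, "%w"))
    dm <- model.matrix(~ dw)[, -1, drop = FALSE]
    colnames(dm) <- paste0("dow", colnames(dm))
    parts[[length(parts) + 1L]] <- dm
  }
  if ("temp" %in% confounders$confounders) {
    parts[[length(parts) + 1L]] <- cbind(temp = panel$temp)
  }
  if ("rh" %in% confounders$confounders) {
    parts[[length(parts) + 1L]] <- cbind(rh = panel$rh)
  }
  X <- do.call(cbind, lapply(parts, as.matrix))[keep, , drop = FALSE]
  y_col <- if (outcome == "respiratory") "resp_count" else "cardio_count"
  structure(list(
    X = X,
    y = panel[[y_col]][keep],
    offset = log(panel$population[keep] / 1e5),
    zip = factor(zip_chr[keep]),
    lag_cols = colnames(lag_mat),
    data = panel[keep, , drop = FALSE],
    outcome = outcome,
    lag_window = as.integer(lag_window)
  ), class = "hif_design")
}

# Poisson IRLS with the per-ZIP intercept block profiled out: at each
# iteration the weighted least-squares step is solved by weighted
# within-ZIP centering of the design and working response (exact block
# elimination), so the result is the joint fixed-effects MLE without ever
# forming ZIP dummy columns. The slope covariance is the inverse of the
# centered weighted cross-product (the Schur complement of the intercept
# block), so standard errors account for intercept estimation.
fit_fe_absorb <- function(X, y, offset, zip, tol = 1e-10, max_iter = 50L) {
  zi <- as.integer(zip)
  s_y <- pmax(rowsum(y, zi)[, 1], 1e-8)
  beta <- rep(0, ncol(X))
  alpha <- log(s_y) - log(rowsum(exp(offset), zi)[, 1])
  eta <- offset + alpha[zi]
  dev_old <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    w <- mu
    z <- (eta - offset) + (y - mu) / mu
    w_z <- rowsum(w, zi)[, 1]
    mx <- rowsum(X * w, zi) / w_z
    mz <- rowsum(z * w, zi)[, 1] / w_z
    Xc <- X - mx[zi, , drop = FALSE]
    zc <- z - mz[zi]
    sw <- sqrt(w)
    A <- crossprod(Xc * sw)
    beta <- drop(chol2inv(chol(A)) %*% crossprod(Xc * sw, zc * sw))
    alpha <- mz - drop(mx %*% beta)
    eta <- pmin(offset + alpha[zi] + drop(X %*% beta), 30)  # overflow guard
    dev <- -2 * sum(dpois(y, exp(eta), log = TRUE))
    if (is.finite(dev) && abs(dev - dev_old) / (abs(dev) + 0.1) < tol) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  mu <- exp(eta)
  w_z <- rowsum(mu, zi)[, 1]
  Xc <- X - (rowsum(X * mu, zi) / w_z)[zi, , drop = FALSE]
  V <- chol2inv(chol(crossprod(Xc * sqrt(mu))))
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = setNames(beta, colnames(X)), vcov = V,
       loglik = sum(dpois(y, mu, log = TRUE)),
       k = ncol(X) + nlevels(zip), n = length(y), converged = converged,
       zip_intercepts = setNames(alpha, levels(zip)))
}

# direct joint fit with explicit ZIP dummies (small panels / cross-check)
fit_fe_direct <- function(X, y, offset, zip) {
  Z <- if (nlevels(zip) == 1L) {
    matrix(1, length(y), 1L)  # degenerate: global intercept
  } else {
    model.matrix(~ zip - 1)
  }
  colnames(Z) <- paste0("zip", levels(zip))
  Xd <- cbind(Z, X)
  fit <- suppressWarnings(glm.fit(Xd, y, family = poisson(), offset = offset,
                                  intercept = FALSE))
  p <- fit$rank
  Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  V_all <- chol2inv(Rmat)
  dimnames(V_all) <- list(colnames(Xd), colnames(Xd))
  keep <- colnames(X)
  mu <- fit$fitted.values
  list(coefficients = coef(fit)[keep], vcov = V_all[keep, keep, drop = FALSE],
       loglik = sum(dpois(y, mu, log = TRUE)),
       k = ncol(Xd), n = length(y), converged = fit$converged,
       zip_intercepts = coef(fit)[colnames(Z)])
}

fit_fe_ranef <- function(X, y, offset, zip) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    abort("method 'ranef' requires the lme4 package.")
  }
  df <- data.frame(y = y, zip = zip, off = offset, X, check.names = FALSE)
  fml <- stats::as.formula(paste(
    "y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + "),
    "+ (1 | zip) + offset(off)"))
  fit <- lme4::glmer(fml, data = df, family = poisson(),
                     control = lme4::glmerControl(calc.derivs = FALSE))
  beta <- lme4::fixef(fit)[colnames(X)]
  V <- as.matrix(stats::vcov(fit))[colnames(X), colnames(X), drop = FALSE]
  list(coefficients = beta, vcov = V, loglik = as.numeric(stats::logLik(fit)),
       k = attr(stats::logLik(fit), "df"), n = length(y),
       converged = TRUE, zip_intercepts = NULL)
}

#' Fit a distributed-lag Poisson health impact function
#'
#' Maximum-likelihood Poisson regression of daily ED counts on lagged
#' aPM2.5 with confounder adjustment, per-ZIP intercepts and a
#' log-population offset. The cumulative log relative risk per ug/m3 is
#' the sum of the lag coefficients; its standard error comes from the
#' linear-combination variance of the coefficient covariance, and the
#' percent change per 10 ug/m3 is `100 * (exp(10 * beta) - 1)` with a Wald
#' 95% interval.
#'
#' Per-ZIP intercepts are fixed effects by default. For large panels they
#' are absorbed (profiled out) rather than carried as explicit dummy
#' columns; both routes maximize the same likelihood. An exchangeable
#' random-intercept mode (`method = "ranef"`, via lme4) is provided for
#' sensitivity analysis.
#'
#' @inheritParams build_design
#' @param method `"auto"` (absorb when > 30 ZIPs, else direct),
#'   `"absorb"`, `"direct"`, or `"ranef"`.
#' @return an object of class `hif`; see [glance.hif()] and [tidy.hif()].
#' @examples
#' cfg <- generator_config(n_zips = 4, end_date = "2008-12-31")
#' fit_hif(generate_panel(cfg), "cardiovascular", lag_window = c(0, 0))
#' @export
fit_hif <- function(panel, outcome = c("respiratory", "cardiovascular"),
                    lag_window = c(0L, 4L), confounders = confounder_spec(),
                    method = c("auto", "absorb", "direct", "ranef"),
                    trim_lag = NULL) {
  outcome <- match.arg(outcome)
  method <- match.arg(method)
  des <- build_design(panel, outcome, lag_window, confounders, trim_lag)
  if (all(des$y == 0)) abort("outcome counts are all zero; cannot fit.")
  if (method == "auto") {
    method <- if (nlevels(des$zip) > 30) "absorb" else "direct"
  }
  fit <- switch(method,
    absorb = fit_fe_absorb(des$X, des$y, des$offset, des$zip),
    direct = fit_fe_direct(des$X, des$y, des$offset, des$zip),
    ranef = fit_fe_ranef(des$X, des$y, des$offset, des$zip)
  )
  if (!isTRUE(fit$converged)) warn("health impact function fit did not converge.")
  lag_cols <- des$lag_cols
  beta_l <- fit$coefficients[lag_cols]
  beta <- sum(beta_l)
  se <- sqrt(sum(fit$vcov[lag_cols, lag_cols]))
  z <- qnorm(0.975)
  structure(list(
    outcome = outcome,
    lag_window = des$lag_window,
    lag_coefficients = beta_l,
    beta_per_ug = beta,
    se_beta = se,
    pct_per10 = 100 * (exp(10 * beta) - 1),
    ci95 = 100 * (exp(10 * (beta + c(-1, 1) * z * se)) - 1),
    bic = -2 * fit$loglik + fit$k * log(fit$n),
    loglik = fit$loglik,
    n = fit$n,
    k = fit$k,
    coefficients = fit$coefficients,
    vcov = fit$vcov,
    baseline_rate = baseline_rates(panel, outcome),
    method = method,
    converged = isTRUE(fit$converged)
  ), class = "hif")
}

#' Select the distributed-lag window by BIC
#'
#' Fits the health impact function for each candidate lag window and
#' returns the window minimizing the Bayesian Information Criterion
#' (`-2 logLik + k log n`, with `n` the ZIP-day observations after lag
#' trimming). Ties break toward the shorter window. All candidates are fit
#' on a common sample -- each ZIP's first `max` lag days across candidates
#' are dropped for every fit -- so their likelihoods are comparable.
#'
#' @inheritParams fit_hif
#' @param candidates list of lag windows, e.g. `list(c(0, 0), c(0, 4))`.
#' @return the selected lag window (integer pair) with attributes `bic`
#'   (named vector over candidates) and `fits` (the fitted `hif`s).
#' @export
select_lag_window <- function(panel, outcome = c("respiratory", "cardiovascular"),
                              candidates = list(c(0L, 0L), c(0L, 4L)),
                              confounders = confounder_spec(),
                              method = c("auto", "absorb", "direct", "ranef")) {
  outcome <- match.arg(outcome)
  if (length(candidates) < 1) abort("at least one candidate window required.")
  widths <- vapply(candidates, function(w) diff(range(w)), numeric(1))
  candidates <- candidates[order(widths)]  # stable: ties resolve to shorter
  common_trim <- max(vapply(candidates, max, numeric(1)))
  fits <- vector("list", length(candidates))
  bics <- rep(NA_real_, length(candidates))
  for (j in seq_along(candidates)) {
    fits[[j]] <- tryCatch(
      fit_hif(panel, outcome, candidates[[j]], confounders, method,
              trim_lag = common_trim),
      error = function(e) {
        warn(sprintf("candidate window [%s] failed: %s",
                     paste(candidates[[j]], collapse = ","), conditionMessage(e)))
        NULL
      })
    if (!is.null(fits[[j]])) bics[j] <- fits[[j]]$bic
  }
  if (all(is.na(bics))) abort("no candidate lag window could be fitted.")
  best <- which.min(bics)
  out <- as.integer(candidates[[best]])
  names(bics) <- vapply(candidates, function(w) paste(w, collapse = "-"), "")
  attr(out, "bic") <- bics
  attr(out, "fits") <- fits
  out
}

#' Baseline ED visit rate of a panel
#'
#' Observed visits per 100,000 persons per day:
#' `sum(counts) / sum(population over ZIP-days) * 1e5`.
#'
#' @inheritParams build_design
#' @return a single rate.
#' @export
baseline_rates <- function(panel, outcome = c("respiratory", "cardiovascular")) {
  outcome <- match.arg(outcome)
  if (!nrow(panel)) abort("empty panel.")
  person_days <- sum(as.numeric(panel$population))
  if (person_days <= 0) abort("zero population.")
  y_col <- if (outcome == "respiratory") "resp_count" else "cardio_count"
  sum(panel[[y_col]]) / person_days * 1e5
}

#' Per-lag coefficients of a health impact function as a tibble
#'
#' @param x a `hif` object.
#' @param ... unused.
#' @return a tibble with one row per lag coefficient (broom convention).
#' @method tidy hif
#' @export
tidy.hif <- function(x, ...) {
  est <- x$lag_coefficients
  se <- sqrt(diag(x$vcov)[names(est)])
  tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * stats::pnorm(-abs(unname(est / se)))
  )
}

#' One-row summary of a fitted health impact function
#'
#' @param x a `hif` object.
#' @param ... unused.
#' @return a one-row tibble with the cumulative effect (percent change per
#'   10 ug/m3 with 95% CI), BIC, sample size and baseline rate.
#' @method glance hif
#' @export
glance.hif <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome,
    lag_min = x$lag_window[1], lag_max = x$lag_window[2],
    beta_per_ug = x$beta_per_ug, se_beta = x$se_beta,
    pct_per10 = x$pct_per10, ci_low = x$ci95[1], ci_high = x$ci95[2],
    bic = x$bic, logLik = x$loglik, nobs = x$n,
    baseline_rate = x$baseline_rate, method = x$method,
    converged = x$converged
  )
}

#' @export
print.hif <- function(x, ...) {
  cat(sprintf(
    "<hif> %s | lags %d-%d | %+.2f%% per 10 ug/m3 (95%% CI %.2f, %.2f) | BIC %.1f\n",
    x$outcome, x$lag_window[1], x$lag_window[2],
    x$pct_per10, x$ci95[1], x$ci95[2], x$bic))
  invisible(x)
}
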