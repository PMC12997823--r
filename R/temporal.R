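# Diel and circalunar analysis: hourly split models, raised-cosine
# regression of the hourly coefficient series, and extraction of the
# covariate-by-moon interaction.

#' Fit the selected structure to each hourly table
#'
#' One fit per hour of day. A non-convergent hour is flagged and its entry
#' left out of the coefficient series; downstream regressions use the
#' available hours.
#'
#' @param hourly_tables list of 24 `useavail` tables.
#' @param spec a [model_spec()] (default structure `Sfr` at the hourly
#'   level).
#' @return object of class `hourly_fits`: list with `fits` (length 24, `NULL`
#'   where non-convergent), `series` (see
#'   [hourly_coefficient_series()]), `aic_mean`, `aic_sd`, `failed_hours`.
#' @export
fit_hourly_models <- function(hourly_tables,
                              spec = model_spec("Sfr", "hourly")) {
  stopifnot(length(hourly_tables) == 24L)
  fits <- vector("list", 24L)
  failed <- integer(0)
  for (h in 0:23) {
    f <- tryCatch(fit_glmm(hourly_tables[[h + 1L]], spec, keep_model = FALSE),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) {
      failed <- c(failed, h)
      warning("hour ", h, " model did not converge; dropped from series")
    } else fits[[h + 1L]] <- f
  }
  aics <- vapply(fits[!vapply(fits, is.null, TRUE)], `[[`, 0, "aic")
  structure(list(fits = fits, series = hourly_coefficient_series(fits),
                 aic_mean = mean(aics), aic_sd = stats::sd(aics),
                 failed_hours = failed),
            class = "hourly_fits")
}

#' Hourly coefficient series per covariate and side
#'
#' For structures with the inside/outside factor, the inside series is the
#' covariate main effect (inside is the reference level) and the outside
#' series is main effect + interaction, with variance from the fixed-effect
#' covariance matrix. Structures without the factor yield one series per
#' covariate (`side = "all"`).
#'
#' @param fits list of 24 [fit_glmm()] results (`NULL` entries skipped).
#' @return data.frame with columns `hour`, `covariate`, `side`, `estimate`,
#'   `variance`.
#' @export
hourly_coefficient_series <- function(fits) {
  out <- list()
  for (h in 0:23) {
    fit <- fits[[h + 1L]]
    if (is.null(fit)) next
    co <- fit$coefficients
    V <- fit$vcov_fixed
    for (cv in fit$spec$covariates) {
      i_main <- which(co$term == cv)
      if (length(i_main) == 0L) next
      if ("in_out" %in% all.vars(stats::as.formula(paste("~", fit$spec$fixed)))) {
        i_int <- which(co$term %in% paste0(cv, ":in_outoutside"))
        out[[length(out) + 1L]] <- data.frame(
          hour = h, covariate = cv, side = "inside",
          estimate = co$estimate[i_main], variance = V[i_main, i_main])
        if (length(i_int) == 1L)
          out[[length(out) + 1L]] <- data.frame(
            hour = h, covariate = cv, side = "outside",
            estimate = co$estimate[i_main] + co$estimate[i_int],
            variance = V[i_main, i_main] + V[i_int, i_int] +
              2 * V[i_main, i_int])
      } else {
        out[[length(out) + 1L]] <- data.frame(
          hour = h, covariate = cv, side = "all",
          estimate = co$estimate[i_main], variance = V[i_main, i_main])
      }
    }
  }
  do.call(rbind, out)
}

#' Raised-cosine regression of an hourly coefficient series
#'
#' Ordinary least squares of the 24 hourly coefficients on a raised-cosine
#' daily template: `single` peaks at noon with its trough at midnight,
#' `r1(h) = (1 + cos(2 pi (h - 12) / 24)) / 2`; `double` peaks at 06:00 and
#' 18:00, `r2(h) = (1 + cos(2 pi (h - 6) / 12)) / 2`. The two templates are
#' orthogonal harmonics over a full day, and the F statistic is invariant to
#' affine rescaling of the template. A variance-weighted fit (weights
#' `1/variance`) is available via `weights`.
#'
#' @param values hourly coefficient estimates.
#' @param hours hours of day the values belong to (default `0:23`); at least
#'   20 must be present.
#' @param template `"single"` or `"double"`.
#' @param weights optional OLS weights (e.g. reciprocal within-model
#'   variances).
#' @return list with `F`, `p`, `df` (1, n-2), `amplitude` (slope),
#'   `intercept`, `fitted`.
#' @export
raised_cosine_regression <- function(values, hours = 0:23,
                                     template = c("single", "double"),
                                     weights = NULL) {
  template <- match.arg(template)
  ok <- is.finite(values)
  values <- values[ok]; hours <- hours[ok]
  if (!is.null(weights)) weights <- weights[ok]
  n <- length(values)
  if (n < 20L) stop("need at least 20 of 24 hourly values")
  r <- raised_cosine_template(hours, template)
  if (stats::sd(values) < 1e-12)
    return(list(F = 0, p = 1, df = c(1, n - 2), amplitude = 0,
                intercept = mean(values), fitted = rep(mean(values), n)))
  fit <- stats::lm(values ~ r, weights = weights)
  an <- suppressWarnings(stats::anova(fit))  # perfect fits trip a warning
  list(F = an$`F value`[1L], p = an$`Pr(>F)`[1L], df = c(1, n - 2),
       amplitude = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       fitted = unname(stats::fitted(fit)))
}

#' Diel-pattern tests for every covariate and side
#'
#' Regresses each hourly coefficient series on both raised-cosine templates.
#'
#' @param hourly_fits a [fit_hourly_models()] result.
#' @param weighted use variance-weighted regression.
#' @return data.frame with `covariate`, `side`, `F_single`, `p_single`,
#'   `F_double`, `p_double`, `amplitude_single`, `amplitude_double`.
#' @export
diel_tests <- function(hourly_fits, weighted = FALSE) {
  s <- hourly_fits$series
  out <- list()
  for (cv in unique(s$covariate)) for (sd_ in unique(s$side)) {
    sub <- s[s$covariate == cv & s$side == sd_, , drop = FALSE]
    if (nrow(sub) == 0L) next
    w <- if (weighted) 1 / sub$variance else NULL
    r1 <- raised_cosine_regression(sub$estimate, sub$hour, "single", w)
    r2 <- raised_cosine_regression(sub$estimate, sub$hour, "double", w)
    out[[length(out) + 1L]] <- data.frame(
      covariate = cv, side = sd_,
      F_single = r1$F, p_single = r1$p,
      F_double = r2$F, p_double = r2$p,
      amplitude_single = r1$amplitude, amplitude_double = r2$amplitude)
  }
  do.call(rbind, out)
}

#' Extract a covariate-by-moon interaction
#'
#' Pulls the `covariate:moon` interaction from a fitted temporal structure
#' (`Tf`/`Tr`/`Tfr`/`STf`/`STr`/`STfr`) and builds the predicted relative
#' selection curve over moon illumination 0-100% in steps of 10: at
#' illumination m the selection curve over the covariate (z-score range -2
#' to 2) is `exp((b + g m / 100) x)`, so the 0% curve equals the
#' main-effect-only curve.
#'
#' @param fit an [fit_glmm()] result whose structure includes moon
#'   interactions.
#' @param covariate covariate name, e.g. `"WC"`.
#' @return list with `estimate`, `se`, `z`, `p` of the interaction and
#'   `curve` (data.frame `moon_pct`, `covariate_z`, `rel_selection`).
#' @export
lunar_interaction <- function(fit, covariate) {
  co <- fit$coefficients
  term <- paste0(covariate, ":moon")
  i <- which(co$term == term)
  if (length(i) == 0L)
    stop("fit has no ", term, " interaction term")
  i_main <- which(co$term == covariate)
  b <- co$estimate[i_main]; g <- co$estimate[i]
  grid <- expand.grid(moon_pct = seq(0, 100, by = 10),
                      covariate_z = seq(-2, 2, length.out = 41))
  grid$rel_selection <- exp((b + g * grid$moon_pct / 100) * grid$covariate_z)
  list(estimate = g, se = co$se[i], z = co$z[i], p = co$p[i], curve = grid)
}
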