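# Binomial (logit) mixed models for the use-availability tables: named
# hypothesis structures, design construction with covariate standardisation,
# fitting via lme4::glmer (Laplace approximation), and the df/AIC accounting
# used by the model-selection stage (df = n fixed effects + n variance
# components).

MODEL_NAMES <- c("0", "Gf", "Gr", "Gfr", "Sf", "Sr", "Sfr",
                 "Tf", "Tr", "Tfr", "STf", "STr", "STfr")

#' Hypothesis model specification
#'
#' The thirteen named model structures of the risk-coping hypothesis set.
#' The suffix picks the covariates: `f` (forage: WC + SVD + NDVI), `r` (risk:
#' WC + ProxW + TRI), `fr` (all five); the prefix picks the interaction
#' factor: `G` none, `S` crossed with the inside/outside-protected-area
#' factor, `T` crossed with moon illumination, `ST` crossed with both. Model
#' `"0"` is the woody-cover-only null. Random intercepts are management area
#' and individual at the landscape level, plus year and season-nested-in-year
#' at the home-range (and hourly) level.
#'
#' @param name one of `"0"`, `"Gf"`, `"Gr"`, `"Gfr"`, `"Sf"`, `"Sr"`,
#'   `"Sfr"`, `"Tf"`, `"Tr"`, `"Tfr"`, `"STf"`, `"STr"`, `"STfr"`.
#' @param level `"landscape"`, `"homerange"` or `"hourly"` (hourly tables use
#'   the home-range random structure).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, level = c("landscape", "homerange", "hourly")) {
  level <- match.arg(level)
  name <- match.arg(name, MODEL_NAMES)
  covs <- if (name == "0") "WC"
          else switch(sub("^(G|S|T|ST)", "", name),
                      f = c("WC", "SVD", "NDVI"),
                      r = c("WC", "ProxW", "TRI"),
                      fr = COVARIATES)
  modifier <- if (name == "0") "" else sub("(f|r|fr)$", "", name)
  base <- paste(covs, collapse = " + ")
  fixed <- if (modifier %in% c("", "G")) base
           else switch(modifier,
                       "S" = sprintf("(%s) * in_out", base),
                       "T" = sprintf("(%s) * moon", base),
                       "ST" = sprintf("(%s) * (in_out + moon)", base))
  random <- if (level == "landscape") c("area_id", "individual_id")
            else c("area_id", "individual_id", "year_f", "season_year")
  structure(list(name = name, level = level, covariates = covs,
                 modifier = modifier, fixed = fixed,
                 random_intercepts = random),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec %s (%s)> %s + %s\n", x$name, x$level, x$fixed,
              paste(sprintf("(1|%s)", x$random_intercepts), collapse = " + ")))
  invisible(x)
}

# Prepare a use-availability table for fitting: z-score the continuous
# covariates on the full (used + available) pool, moon as percent/100,
# inside as the in_out reference level, season nested in year as the
# year x season combination factor.
prepare_model_frame <- function(table, spec, scaling = NULL) {
  need <- c("response", spec$covariates)
  if (spec$modifier %in% c("S", "ST")) need <- c(need, "in_out")
  if (spec$modifier %in% c("T", "ST")) need <- c(need, "moon_pct")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) stop("missing column: ", paste(miss, collapse = ", "))
  d <- as.data.frame(table)
  if (is.null(scaling))
    scaling <- data.frame(
      covariate = COVARIATES,
      mean = vapply(COVARIATES, function(cv)
        mean(d[[cv]], na.rm = TRUE), 0),
      sd = vapply(COVARIATES, function(cv)
        stats::sd(d[[cv]], na.rm = TRUE), 0))
  for (cv in COVARIATES) {
    if (!cv %in% names(d)) next
    s <- scaling[scaling$covariate == cv, ]
    d[[cv]] <- (d[[cv]] - s$mean) / s$sd
  }
  d$in_out <- factor(as.character(d$in_out), levels = c("inside", "outside"))
  if ("moon_pct" %in% names(d)) d$moon <- d$moon_pct / 100
  if ("year" %in% names(d) && !all(is.na(d$year))) {
    d$year_f <- factor(d$year)
    d$season_year <- interaction(d$year, d$season, drop = TRUE)
  }
  d$individual_id <- factor(d$individual_id)
  d$area_id <- factor(d$area_id)
  attr(d, "scaling") <- scaling
  d
}

#' Build design matrices for a model specification
#'
#' Constructs the fixed-effects design (intercept, z-scored continuous
#' covariates, inside-reference `in_out` factor, moon as percent/100, and the
#' interaction columns the specification calls for) plus the random-intercept
#' grouping factors.
#'
#' @param table a `useavail` data.frame.
#' @param spec a [model_spec()].
#' @return list with `X` (fixed design matrix), `groups` (named list of
#'   grouping factors), `n_fixed`, `n_vc`, `df` (their sum), `scaling` and
#'   the prepared model frame `data`.
#' @export
build_model_matrix <- function(table, spec) {
  d <- prepare_model_frame(table, spec)
  X <- stats::model.matrix(stats::as.formula(paste("~", spec$fixed)), d)
  groups <- lapply(spec$random_intercepts, function(g) d[[g]])
  names(groups) <- spec$random_intercepts
  list(X = X, groups = groups, n_fixed = ncol(X),
       n_vc = length(spec$random_intercepts),
       df = ncol(X) + length(spec$random_intercepts),
       scaling = attr(d, "scaling"), data = d)
}

#' Fit a use-availability mixed model
#'
#' Binomial (logit) GLMM with the specification's fixed structure and random
#' intercepts, fitted by Laplace-approximated maximum likelihood
#' (`lme4::glmer`). Non-convergence is flagged on the result, never silent;
#' variance components estimated at the zero boundary are reported via the
#' `singular` flag.
#'
#' @param table a `useavail` data.frame.
#' @param spec a [model_spec()].
#' @param keep_model keep the underlying `glmerMod` object (needed for
#'   cross-validation scoring and conditional modes).
#' @param optimizer optimizer passed to [lme4::glmerControl()]; `"bobyqa"`
#'   (default) or `"nloptwrap"`, which is faster on large single-factor
#'   designs. Fits are deterministic for a fixed optimizer.
#' @return object of class `rsf_fit`: coefficient table (standardised and
#'   back-transformed to raw covariate units), variance components,
#'   conditional modes, log-likelihood, `df = n_fixed + n_vc`,
#'   `aic = -2 logLik + 2 df`, convergence flags.
#' @export
fit_glmm <- function(table, spec, keep_model = TRUE, optimizer = "bobyqa") {
  d <- prepare_model_frame(table, spec)
  for (g in spec$random_intercepts)
    if (is.null(d[[g]]) || length(unique(stats::na.omit(d[[g]]))) < 2L)
      stop("random factor ", g, " needs at least 2 levels")
  form <- stats::as.formula(paste(
    "response ~", spec$fixed, "+",
    paste(sprintf("(1 | %s)", spec$random_intercepts), collapse = " + ")))
  msgs <- character(0)
  model <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial(),
                control = lme4::glmerControl(optimizer = optimizer,
                                             calc.derivs = FALSE)),
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- model@optinfo$conv$opt == 0 &&
    !any(grepl("failed to converge", msgs))
  scaling <- attr(d, "scaling")
  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  z <- fe / se
  coefs <- data.frame(term = names(fe), estimate = unname(fe),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))),
                      row.names = NULL)
  # back-transform: a term containing covariate cv scales by 1 / sd(cv)
  fac <- rep(1, nrow(coefs))
  for (k in seq_len(nrow(coefs))) {
    parts <- strsplit(coefs$term[k], ":", fixed = TRUE)[[1L]]
    for (cv in COVARIATES)
      if (cv %in% parts)
        fac[k] <- fac[k] / scaling$sd[scaling$covariate == cv]
  }
  coefs$estimate_raw <- coefs$estimate * fac
  coefs$se_raw <- coefs$se * fac
  vc <- lme4::VarCorr(model)
  varcomp <- stats::setNames(
    vapply(spec$random_intercepts, function(g) as.numeric(vc[[g]]), 0),
    spec$random_intercepts)
  ll <- as.numeric(stats::logLik(model))
  n_fixed <- length(fe); n_vc <- length(spec$random_intercepts)
  structure(
    list(spec = spec, coefficients = coefs, varcomp = varcomp,
         vcov_fixed = as.matrix(stats::vcov(model)),
         logLik = ll, n_fixed = n_fixed, n_vc = n_vc, df = n_fixed + n_vc,
         aic = -2 * ll + 2 * (n_fixed + n_vc),
         n_obs = nrow(d), scaling = scaling,
         converged = converged, singular = lme4::isSingular(model),
         messages = msgs,
         conditional_modes = lapply(lme4::ranef(model), function(r)
           data.frame(level = rownames(r), mode = r[["(Intercept)"]])),
         model = if (keep_model) model else NULL),
    class = "rsf_fit")
}

#' @export
print.rsf_fit <- function(x, ...) {
  cat(sprintf("<rsf_fit %s (%s)> n = %d, logLik = %.2f, df = %d, AIC = %.1f%s\n",
              x$spec$name, x$spec$level, x$n_obs, x$logLik, x$df, x$aic,
              if (!x$converged) " [NOT CONVERGED]"
              else if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Akaike's information criterion of a fit
#'
#' `-2 logLik + 2 df` with `df = n_fixed + n_variance_components`.
#'
#' @param fit an [fit_glmm()] result.
#' @return numeric AIC.
#' @export
aic <- function(fit) {
  stopifnot(inherits(fit, "rsf_fit"))
  if (!fit$converged) stop("AIC requested for a non-converged fit")
  fit$aic
}

#' Fixed-effect linear predictor for new rows
#'
#' Scores rows of a use-availability table with the fitted fixed effects
#' only; random effects are set to their population mean (zero), so rows
#' from groups unseen in training score identically to seen ones. Continuous
#' covariates are standardised with the *training* scaling.
#'
#' @param fit an [fit_glmm()] result.
#' @param table new `useavail` rows.
#' @return numeric vector of linear-predictor scores.
#' @export
predict_rsf <- function(fit, table) {
  d <- prepare_model_frame(table, fit$spec, scaling = fit$scaling)
  X <- stats::model.matrix(stats::as.formula(paste("~", fit$spec$fixed)), d)
  beta <- stats::setNames(fit$coefficients$estimate, fit$coefficients$term)
  as.vector(X[, names(beta), drop = FALSE] %*% beta)
}

#' Serialise a fit as JSON
#'
#' @param fit an [fit_glmm()] result.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$spec$name, level = fit$spec$level,
         coefficients = fit$coefficients,
         varcomp = as.list(fit$varcomp), logLik = fit$logLik,
         df = fit$df, aic = fit$aic, n_obs = fit$n_obs,
         converged = fit$converged, singular = fit$singular),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
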