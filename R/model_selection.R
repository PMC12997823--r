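# Hypothesis-set model selection: fit the named structures at a level,
# rank by AIC, and compute the delta-AIC-ratio support statistic for the
# named model sets.

#' The hypothesis model set for a level
#'
#' Seven structures at the landscape level (the temporal and spatio-temporal
#' models need per-row timestamps, which landscape rows do not carry);
#' all thirteen at the home-range level.
#'
#' @param level `"landscape"` or `"homerange"`.
#' @return list of [model_spec()] objects.
#' @export
model_set <- function(level = c("landscape", "homerange")) {
  level <- match.arg(level)
  names <- if (level == "landscape")
    c("0", "Gf", "Gr", "Gfr", "Sf", "Sr", "Sfr") else MODEL_NAMES
  lapply(names, model_spec, level = level)
}

#' Named model-set memberships
#'
#' The sets over which the delta-AIC-ratio is reported: `G`, `S` (and at the
#' home-range level `T`, `ST`) are the three structures sharing the prefix;
#' `f`, `r`, `fr` are the structures sharing the covariate suffix. The null
#' model `"0"` belongs to no set.
#'
#' @param level `"landscape"` or `"homerange"`.
#' @return named list of character vectors of model names.
#' @export
model_sets <- function(level = c("landscape", "homerange")) {
  level <- match.arg(level)
  avail <- setdiff(vapply(model_set(level), `[[`, "", "name"), "0")
  pre <- function(p) avail[grepl(paste0("^", p, "(f|r|fr)$"), avail)]
  suf <- function(s) avail[grepl(paste0("^(G|S|T|ST)", s, "$"), avail)]
  sets <- list(G = pre("G"), S = pre("S"), T = pre("T"), ST = pre("ST"),
               f = suf("f"), r = suf("r"), fr = suf("fr"))
  sets[vapply(sets, length, 0L) > 0]
}

#' Fit every model of a level's hypothesis set
#'
#' @param table a `useavail` data.frame.
#' @param level `"landscape"` or `"homerange"`.
#' @param keep_model keep the underlying model objects.
#' @param optimizer passed to [fit_glmm()]; the default favours the
#'   optimizer that handles the moon-interaction structures fastest.
#' @return named list of [fit_glmm()] results.
#' @export
fit_model_set <- function(table, level = c("landscape", "homerange"),
                          keep_model = FALSE, optimizer = "nloptwrap") {
  level <- match.arg(level)
  specs <- model_set(level)
  fits <- lapply(specs, function(s)
    fit_glmm(table, s, keep_model = keep_model, optimizer = optimizer))
  names(fits) <- vapply(specs, `[[`, "", "name")
  fits
}

#' Compare fitted models by AIC
#'
#' Computes delta AIC (AIC minus the minimum AIC) and ranks models; ties are
#' flagged and broken toward fewer degrees of freedom. Non-converged fits
#' are excluded with a warning.
#'
#' @param fits named list of [fit_glmm()] results, or a data.frame with
#'   columns `model`, `df`, `aic` (and optionally `delta_aic`, taken as
#'   given) for comparisons built from printed tables.
#' @param level level label attached to the result.
#' @return object of class `model_comparison`: data.frame with columns
#'   `model`, `df`, `aic`, `delta_aic`, sorted by (`aic`, `df`), with
#'   attributes `best` and `tie`.
#' @export
compare <- function(fits, level = NULL) {
  if (is.data.frame(fits)) {
    d <- data.frame(model = as.character(fits$model), df = fits$df,
                    aic = fits$aic)
    if ("delta_aic" %in% names(fits)) d$delta_aic <- fits$delta_aic
  } else {
    conv <- vapply(fits, `[[`, TRUE, "converged")
    if (any(!conv))
      warning("excluding non-converged model(s): ",
              paste(names(fits)[!conv], collapse = ", "))
    fits <- fits[conv]
    if (length(fits) < 2L) stop("need at least 2 converged fits to compare")
    d <- data.frame(model = names(fits),
                    df = vapply(fits, `[[`, 0L, "df"),
                    aic = vapply(fits, `[[`, 0, "aic"))
    if (is.null(level)) level <- fits[[1L]]$spec$level
  }
  if (is.null(d$delta_aic)) d$delta_aic <- d$aic - min(d$aic)
  d <- d[order(d$aic, d$df), , drop = FALSE]
  rownames(d) <- NULL
  tie <- nrow(d) > 1L && d$aic[1L] == d$aic[2L]
  structure(d, class = c("model_comparison", "data.frame"),
            best = d$model[1L], tie = tie, level = level)
}

#' Delta-AIC-ratio support for a model set
#'
#' The ratio of the mean delta AIC across all hypothesis models (the null
#' model `"0"` excluded) to the mean delta AIC within the named set. Values
#' above 1 indicate above-average support for the set.
#'
#' @param comparison a [compare()] result.
#' @param set_members character vector of model names, or a set name from
#'   [model_sets()].
#' @return the ratio, rounded to 2 decimals; `Inf` with a warning when the
#'   set mean is zero while the overall mean is not.
#' @export
delta_aic_ratio <- function(comparison, set_members) {
  stopifnot(inherits(comparison, "model_comparison"))
  if (length(set_members) == 1L && !is.null(attr(comparison, "level")) &&
      set_members %in% names(model_sets(attr(comparison, "level"))))
    set_members <- model_sets(attr(comparison, "level"))[[set_members]]
  hyp <- comparison[comparison$model != "0", , drop = FALSE]
  if (!all(set_members %in% hyp$model))
    stop("set members absent from comparison: ",
         paste(setdiff(set_members, hyp$model), collapse = ", "))
  overall <- mean(hyp$delta_aic)
  setm <- mean(hyp$delta_aic[hyp$model %in% set_members])
  if (setm == 0 && overall > 0) {
    warning("set mean delta AIC is zero; ratio is infinite")
    return(Inf)
  }
  round(overall / setm, 2)
}

#' All delta-AIC-ratios of a comparison
#'
#' @param comparison a [compare()] result with a level attribute.
#' @return named numeric vector of ratios over [model_sets()].
#' @export
delta_aic_ratios <- function(comparison) {
  sets <- model_sets(attr(comparison, "level"))
  vapply(sets, function(s) delta_aic_ratio(comparison, s), 0)
}

#' Published Serengeti impala parsimony table
#'
#' The degrees of freedom, AIC and delta-AIC of the thirteen hypothesis
#' models as reported for the Serengeti impala telemetry study (seven models
#' at the landscape level, thirteen at the home-range level), bundled so the
#' delta-AIC-ratio arithmetic can be exercised against the published values.
#'
#' @param level `"landscape"` or `"homerange"`.
#' @return a [compare()]-style `model_comparison` built from the printed
#'   integer-rounded table.
#' @export
serengeti_parsimony <- function(level = c("landscape", "homerange")) {
  level <- match.arg(level)
  d <- utils::read.csv(system.file("extdata", "serengeti_impala_aic.csv",
                                   package = "rsfscales"),
                       colClasses = c(model = "character"))
  compare(d[d$level == level, c("model", "df", "aic", "delta_aic")],
          level = level)
}
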