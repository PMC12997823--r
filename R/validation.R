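# k-fold cross-validation of fitted selection functions: held-out rows are
# scored by the fixed-effect linear predictor, scores are cut into
# equal-available-count bins, and the Spearman correlation between bin rank
# and area-adjusted frequency measures predictive success.

#' Area-adjusted frequencies and their rank correlation
#'
#' Cuts scores into `n_bins` classes whose edges are quantiles of the
#' *available* scores (equal available count; `binning = "width"` uses
#' equal-width bins instead), computes per bin the area-adjusted frequency
#' (share of used rows in the bin divided by share of available rows), and
#' Spearman-correlates bin rank with that frequency. Bins collapsed by tied
#' score quantiles are merged with their neighbour and flagged.
#'
#' @param scores_used,scores_available linear-predictor scores of held-out
#'   used and available rows.
#' @param n_bins number of score bins (default 10).
#' @param binning `"quantile"` (default) or `"width"`.
#' @return list with `bins` (data.frame: `bin`, `n_used`, `n_available`,
#'   `adj_freq`), `rho`, `p`, `n_bins_effective`, `merged`.
#' @export
area_adjusted_frequencies <- function(scores_used, scores_available,
                                      n_bins = 10,
                                      binning = c("quantile", "width")) {
  binning <- match.arg(binning)
  if (binning == "quantile") {
    br <- stats::quantile(scores_available, probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE)
    br <- unique(br)
  } else {
    br <- seq(min(scores_available), max(scores_available),
              length.out = n_bins + 1)
  }
  br[1] <- -Inf; br[length(br)] <- Inf
  merged <- length(br) < n_bins + 1
  cu <- cut(scores_used, br, labels = FALSE, include.lowest = TRUE)
  ca <- cut(scores_available, br, labels = FALSE, include.lowest = TRUE)
  B <- length(br) - 1L
  n_used <- tabulate(cu, B); n_avail <- tabulate(ca, B)
  keep <- n_avail > 0  # width binning can leave empty available bins
  merged <- merged || any(!keep)
  bins <- data.frame(bin = seq_len(B)[keep], n_used = n_used[keep],
                     n_available = n_avail[keep])
  bins$adj_freq <- (bins$n_used / max(1, sum(bins$n_used))) /
    (bins$n_available / sum(bins$n_available))
  ct <- suppressWarnings(
    stats::cor.test(seq_len(nrow(bins)), bins$adj_freq, method = "spearman",
                    exact = FALSE))
  list(bins = bins, rho = unname(ct$estimate), p = ct$p.value,
       n_bins_effective = nrow(bins), merged = merged)
}

#' k-fold cross-validation of a selection-function structure
#'
#' Rows are randomly binned into `k` classes, stratified by the response;
#' for each held-out class the model is refitted on the remaining rows, the
#' held-out rows are scored by the fixed-effect linear predictor (random
#' effects at their population mean, so unseen groups are handled), and the
#' Spearman correlation between score-bin rank and area-adjusted frequency
#' is recorded. Fold p-values are combined with Fisher's method.
#'
#' @param table a `useavail` data.frame.
#' @param spec a [model_spec()].
#' @param k number of folds (default 10).
#' @param n_bins number of score bins (default 10).
#' @param seed integer seed for fold assignment.
#' @param binning passed to [area_adjusted_frequencies()].
#' @return object of class `cv_result`: `per_fold` data.frame, `mean_rho`,
#'   `range_rho`, `combined_p`, `k`, `n_bins`.
#' @export
kfold_crossvalidate <- function(table, spec, k = 10, n_bins = 10, seed = 1L,
                                binning = "quantile") {
  stopifnot(k >= 2)
  set.seed(seed)
  fold <- integer(nrow(table))
  for (r in c(0L, 1L)) {
    rows <- which(table$response == r)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  if (min(table(fold[table$response == 1])) < n_bins)
    stop("fewer used rows per fold than bins")
  per_fold <- vector("list", k)
  for (i in seq_len(k)) {
    train <- table[fold != i, , drop = FALSE]
    test <- table[fold == i, , drop = FALSE]
    fit <- fit_glmm(train, spec, keep_model = FALSE)
    sc <- predict_rsf(fit, test)
    aa <- area_adjusted_frequencies(sc[test$response == 1],
                                    sc[test$response == 0],
                                    n_bins = n_bins, binning = binning)
    per_fold[[i]] <- data.frame(fold = i, rho = aa$rho, p = aa$p,
                                n_bins_effective = aa$n_bins_effective,
                                merged = aa$merged)
  }
  per_fold <- do.call(rbind, per_fold)
  fisher <- -2 * sum(log(pmax(per_fold$p, 1e-300)))
  structure(
    list(per_fold = per_fold, mean_rho = mean(per_fold$rho),
         range_rho = range(per_fold$rho),
         combined_p = stats::pchisq(fisher, df = 2 * k, lower.tail = FALSE),
         k = k, n_bins = n_bins, fold = fold),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold, mean rho = %.3f [%.3f, %.3f], combined p = %.2g\n",
              x$k, x$mean_rho, x$range_rho[1], x$range_rho[2], x$combined_p))
  invisible(x)
}

#' Cross-validate the 24 hourly models
#'
#' Runs [kfold_crossvalidate()] on each hourly table and averages the
#' goodness-of-fit across hours.
#'
#' @param hourly_tables list of 24 `useavail` tables from
#'   [build_hourly_tables()].
#' @param spec a [model_spec()] (the selected home-range structure).
#' @param ... passed to [kfold_crossvalidate()].
#' @return list with `per_hour` (data.frame of hourly mean rho), `mean_rho`
#'   (across-hour mean), `range_rho`.
#' @export
hourly_crossvalidate <- function(hourly_tables, spec, ...) {
  stopifnot(length(hourly_tables) == 24L)
  res <- lapply(hourly_tables, kfold_crossvalidate, spec = spec, ...)
  per_hour <- data.frame(hour = 0:23,
                         mean_rho = vapply(res, `[[`, 0, "mean_rho"))
  list(per_hour = per_hour, mean_rho = mean(per_hour$mean_rho),
       range_rho = range(per_hour$mean_rho), folds = res)
}
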