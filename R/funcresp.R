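# Individual-level functional response: does within-home-range selection
# strength depend on landscape-level exposure? Measured as the Pearson
# correlation across individuals between the two levels' selection ratios
# (mean covariate at used points / mean at available points).

#' Per-individual selection ratios at both levels
#'
#' For each individual, covariate and level, the ratio of the mean covariate
#' value at used points to the mean at available points. At the landscape
#' level the available pool is shared by all individuals and an individual's
#' used points are its share of the MCP random points; at the home-range
#' level availability is restricted to the individual's own MCP points.
#' Proximity-to-water ratios use the raw distance, so a ratio above 1 means
#' farther from water than available. Each individual is classified inside
#' or outside the protected core by the majority of its home-range used
#' points.
#'
#' @param landscape_table,homerange_table `useavail` tables from
#'   [build_landscape_table()] and [build_homerange_table()].
#' @param min_used individuals with fewer used rows at either level are
#'   excluded with a warning (default 30).
#' @return object of class `selection_ratios`: data.frame with columns
#'   `individual_id`, `side`, `covariate`, `landscape`, `homerange`.
#' @export
selection_ratios <- function(landscape_table, homerange_table, min_used = 30) {
  lt <- as.data.frame(landscape_table); ht <- as.data.frame(homerange_table)
  ids <- sort(unique(ht$individual_id[ht$response == 1]))
  avail_l <- lt[lt$response == 0, , drop = FALSE]
  out <- list()
  excluded <- character(0)
  for (id in ids) {
    used_l <- lt[lt$response == 1 & lt$individual_id == id, , drop = FALSE]
    used_h <- ht[ht$response == 1 & ht$individual_id == id, , drop = FALSE]
    avail_h <- ht[ht$response == 0 & ht$individual_id == id, , drop = FALSE]
    if (nrow(used_l) < min_used || nrow(used_h) < min_used) {
      excluded <- c(excluded, id)
      next
    }
    side <- if (mean(used_h$in_out == "inside") >= 0.5) "inside" else "outside"
    for (cv in COVARIATES) {
      out[[length(out) + 1L]] <- data.frame(
        individual_id = id, side = side, covariate = cv,
        landscape = mean(used_l[[cv]]) / mean(avail_l[[cv]]),
        homerange = mean(used_h[[cv]]) / mean(avail_h[[cv]]))
    }
  }
  if (length(excluded) > 0)
    warning("excluded individuals with < ", min_used, " used rows: ",
            paste(excluded, collapse = ", "))
  if (length(out) == 0L)
    out <- list(data.frame(individual_id = character(0), side = character(0),
                           covariate = character(0), landscape = numeric(0),
                           homerange = numeric(0)))
  structure(do.call(rbind, out),
            class = c("selection_ratios", "data.frame"))
}

#' Functional-response correlation test
#'
#' Pearson product-moment correlation across individuals between the
#' landscape-level and home-range-level selection ratios of one covariate on
#' one side of the protected boundary, with a two-sided p-value. A negative
#' estimate indicates within-range selection weakening as landscape-level
#' exposure rises (a functional response).
#'
#' @param ratios a [selection_ratios()] table.
#' @param covariate covariate name.
#' @param side `"inside"` or `"outside"`.
#' @return list with `estimate`, `p`, `n`.
#' @export
functional_response_test <- function(ratios, covariate,
                                     side = c("inside", "outside")) {
  side <- match.arg(side)
  sub <- ratios[ratios$covariate == covariate & ratios$side == side, ,
                drop = FALSE]
  if (nrow(sub) < 5L)
    stop("need at least 5 individuals on side '", side, "' (have ",
         nrow(sub), ")")
  if (stats::sd(sub$landscape) == 0 || stats::sd(sub$homerange) == 0)
    stop("zero variance in selection ratios")
  ct <- stats::cor.test(sub$landscape, sub$homerange, method = "pearson")
  list(estimate = unname(ct$estimate), p = ct$p.value, n = nrow(sub))
}

#' All functional-response tests with enough individuals
#'
#' @param ratios a [selection_ratios()] table.
#' @return data.frame with `covariate`, `side`, `estimate`, `p`, `n` (rows
#'   only for combinations with at least 5 individuals).
#' @export
functional_response_table <- function(ratios) {
  out <- list()
  for (cv in unique(ratios$covariate)) for (sd_ in unique(ratios$side)) {
    res <- tryCatch(functional_response_test(ratios, cv, sd_),
                    error = function(e) NULL)
    if (!is.null(res))
      out[[length(out) + 1L]] <- data.frame(covariate = cv, side = sd_,
                                            estimate = res$estimate,
                                            p = res$p, n = res$n)
  }
  if (length(out) == 0L)
    return(data.frame(covariate = character(0), side = character(0),
                      estimate = numeric(0), p = numeric(0), n = integer(0)))
  do.call(rbind, out)
}
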