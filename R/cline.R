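# Isolation-by-distance admixture cline regression: observation assembly
# with the published exclusion rules, OLS with leverage diagnostics, and
# the admixture-through-time trend.

#' Assemble cline regression observations
#'
#' Joins per-individual admixture responses (an f4 value or an admixture
#' proportion) with least-cost distances and metadata, annotating the
#' exclusion rules: individuals assayed by SNP capture are excluded (batch
#' effects on f4), as are individuals whose response is based on fewer than
#' `min_sites` sites.
#'
#' @param fstat_table `data.frame` with columns `id`, `response`, `n_sites`.
#' @param distance_table `data.frame` with columns `id`, `dist_whg`,
#'   `dist_ag3` (accumulated-cost units; which min/median/total variant was
#'   used is recorded by the caller in `distance_kind`).
#' @param meta an `individual_meta` (for the assay flag).
#' @param min_sites site threshold (default 5000).
#' @param distance_kind label recording the distance variant.
#' @return A `data.frame` with an `included` flag and `exclusion_reason`.
#' @export
assemble_observations <- function(fstat_table, distance_table, meta,
                                  min_sites = 5000, distance_kind = "min") {
  if (anyDuplicated(fstat_table$id) || anyDuplicated(distance_table$id)) {
    stop("duplicate join keys")
  }
  obs <- merge(fstat_table, distance_table, by = "id")
  obs$assay <- meta$assay[match(obs$id, meta$id)]
  obs$exclusion_reason <- NA_character_
  obs$exclusion_reason[!is.na(obs$assay) & obs$assay == "capture"] <- "capture assay"
  low <- is.na(obs$exclusion_reason) & obs$n_sites < min_sites
  obs$exclusion_reason[low] <- sprintf("fewer than %d sites", min_sites)
  obs$included <- is.na(obs$exclusion_reason)
  attr(obs, "distance_kind") <- distance_kind
  obs
}

#' Fit the admixture isolation-by-distance model
#'
#' Ordinary least squares of the admixture response on the least-cost
#' distances from the two source regions (`y ~ a x + b z + c`), with
#' per-observation leverage, studentized residuals and Cook's distance.
#'
#' @param obs observations from [assemble_observations()] (only `included`
#'   rows are fitted).
#' @param formula model formula (default `response ~ dist_whg + dist_ag3`).
#' @return A list of class `cline_model`: `fit` (the `lm`), `coefficients`
#'   table, `r_squared`, `diagnostics`, `data`.
#' @export
fit_cline <- function(obs, formula = response ~ dist_whg + dist_ag3) {
  dat <- obs[if (!is.null(obs$included)) obs$included else TRUE, , drop = FALSE]
  p <- length(attr(stats::terms(formula), "term.labels")) + 1L
  if (nrow(dat) < p + 1L) {
    stop("need at least ", p + 1L, " included observations, have ", nrow(dat))
  }
  X <- stats::model.matrix(formula, dat)
  if (qr(X)$rank < ncol(X)) stop("collinear predictors")
  fit <- stats::lm(formula, data = dat)
  sm <- summary(fit)
  coefs <- as.data.frame(sm$coefficients)
  names(coefs) <- c("estimate", "se", "t_value", "p_value")
  diag_tab <- data.frame(
    id = if (!is.null(dat$id)) dat$id else seq_len(nrow(dat)),
    leverage = stats::hatvalues(fit),
    studentized = stats::rstudent(fit),
    cooks = stats::cooks.distance(fit),
    stringsAsFactors = FALSE
  )
  structure(list(fit = fit, coefficients = coefs,
                 r_squared = sm$r.squared, diagnostics = diag_tab,
                 data = dat, formula = formula),
            class = "cline_model")
}

#' @export
print.cline_model <- function(x, ...) {
  cat("cline model:", deparse(x$formula), " (n =", nrow(x$data), ")\n")
  print(round(x$coefficients, 8))
  cat("R-squared:", round(x$r_squared, 4), "\n")
  invisible(x)
}

#' Refit after removing high-influence points
#'
#' Replaces visual inspection of regression diagnostic plots with a
#' reproducible numeric rule: points with Cook's distance above
#' `threshold` (default `4/n`) are removed and the model refit; both fits
#' are returned side by side.
#'
#' @param model a `cline_model`.
#' @param threshold Cook's distance cutoff; `NULL` means `4/n`.
#' @return List with `original`, `refit`, `flagged` (ids removed).
#' @export
leverage_refit <- function(model, threshold = NULL) {
  n <- nrow(model$data)
  if (is.null(threshold)) threshold <- 4 / n
  flagged <- model$diagnostics$id[model$diagnostics$cooks > threshold]
  if (!length(flagged)) {
    return(list(original = model, refit = model, flagged = character(0)))
  }
  keep <- model$data[!(model$diagnostics$id %in% flagged), , drop = FALSE]
  p <- length(attr(stats::terms(model$formula), "term.labels")) + 1L
  if (nrow(keep) < p + 1L) {
    stop("leverage removal leaves too few points to refit")
  }
  keep$included <- TRUE
  list(original = model, refit = fit_cline(keep, model$formula),
       flagged = flagged)
}

#' Admixture-proportion trend through time
#'
#' OLS of the admixture proportion on the calibrated age midpoint. Because
#' the predictor is in years BP, a NEGATIVE coefficient means the
#' proportion increases toward the present. An optional exclusion list
#' (e.g. individuals with the most extreme estimates) is applied and
#' reported.
#'
#' @param alpha_table `data.frame` with columns `id`, `alpha`,
#'   `cal_bp_mid`.
#' @param exclude ids to drop before fitting.
#' @return A `cline_model` (single predictor) with the applied exclusions
#'   in `excluded`.
#' @export
admixture_time_trend <- function(alpha_table, exclude = character(0)) {
  dat <- alpha_table[!(alpha_table$id %in% exclude), , drop = FALSE]
  dat$included <- TRUE
  m <- fit_cline(dat, alpha ~ cal_bp_mid)
  m$excluded <- intersect(exclude, alpha_table$id)
  m
}
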