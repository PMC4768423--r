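# Orchestration of the full model-comparison experiment: fit all models to the
# truncated and full series, score extrapolations on the held-out half, compute
# clinical predictions from both fits, and report percent changes and fold
# spreads across models.

#' Percent change between truncated-fit and full-fit estimates
#'
#' 100 * (full - truncated) / truncated. If either input is the unbounded
#' sentinel (`Inf`) or missing, the comparison is not applicable and `NA` is
#' returned (never NaN).
#'
#' @param truncated_value Estimate from the truncated (early) fit.
#' @param full_value Estimate from the full-series fit.
#' @return Percent change (signed), or `NA` when not applicable.
#' @examples
#' percent_change(10, 15) # +50
#' @export
percent_change <- function(truncated_value, full_value) {
  bad <- !is.finite(truncated_value) | !is.finite(full_value) |
    truncated_value == 0
  out <- ifelse(bad, NA_real_,
                100 * (full_value - truncated_value) / truncated_value)
  as.numeric(out)
}

#' Fold spread (max/min) of per-model estimates
#'
#' The ratio of the largest to the smallest finite positive value — the
#' "N-fold disagreement" between models on a quantity such as the doubling
#' time. Non-finite entries (unbounded models) and non-positive entries
#' (non-growing fits) are excluded; the names of excluded entries are attached
#' as attribute `excluded`.
#'
#' @param values Numeric vector (optionally named by model).
#' @return max/min ratio (>= 1) with attribute `excluded`.
#' @examples
#' fold_spread(c(2, 26)) # 13
#' @export
fold_spread <- function(values) {
  keep <- is.finite(values) & values > 0
  if (sum(keep) < 2L) {
    stop("fold spread needs at least two finite positive values", call. = FALSE)
  }
  structure(max(values[keep]) / min(values[keep]),
            excluded = names(values)[!keep])
}

fit_row <- function(fit, window, ssr_prediction = NA_real_) {
  p <- if (is.null(fit$model)) c(a = NA_real_) else fit$model$params
  cl <- if (is.null(fit$model)) NULL else clinical_predictions(fit$model)
  data.frame(
    window = window,
    model = fit$name,
    a = unname(p["a"]),
    b = unname(if ("b" %in% names(p)) p["b"] else NA_real_),
    c = unname(if ("c" %in% names(p)) p["c"] else NA_real_),
    v0 = fit$v0,
    n = fit$n,
    k = fit$k,
    converged = fit$converged,
    ssr_fit = fit$ssr,
    aicc = fit$aicc,
    ssr_prediction = as.numeric(ssr_prediction),
    growth_condition_met = if (is.null(cl)) NA else cl$growth_condition_met,
    max_size = if (is.null(cl)) NA_real_ else cl$max_size,
    doubling_time = if (is.null(cl)) NA_real_ else cl$doubling_time,
    min_cure_concentration = if (is.null(cl)) NA_real_ else cl$min_cure_concentration,
    stringsAsFactors = FALSE
  )
}

#' Run the full truncated-vs-full model comparison experiment
#'
#' Executes the complete workflow on one tumor-volume series: split the series
#' into an early and a held-out late part, fit every model to the early part,
#' score each truncated fit's extrapolation on the held-out points, fit every
#' model to the full series, compute the clinical predictions (maximum size,
#' doubling time, minimum suppression concentration) from both fits, and
#' summarize percent changes and across-model fold spreads. Deterministic
#' given the data and `config$seed`.
#'
#' @param data A [tumor_series()] with at least 6 points.
#' @param design A [study_design()] (only `truncation_fraction` is used here).
#' @param config A [fit_config()].
#' @param models Character vector of model names to compare.
#' @return An object of class `comparison_report`: list with `fits` (per-model
#'   per-window data.frame), `percent_change` (per-model per-quantity),
#'   `spreads` (fold spreads per window and quantity), `selected` (best model
#'   under each criterion), and `unbounded_models` (models predicting
#'   unbounded untreated growth, per window).
#' @export
run_comparison <- function(data, design = study_design(), config = fit_config(),
                           models = growth_model_names()) {
  if (nrow(data) < 6L) {
    stop("need at least 6 observations so both halves support fitting",
         call. = FALSE)
  }
  parts <- truncate_series(data, design)

  fits_early <- fit_all_models(parts$early, models, config)
  pred_ssr <- vapply(fits_early, function(f) {
    as.numeric(extrapolate_and_score(f, parts$late))
  }, numeric(1))
  fits_full <- fit_all_models(data, models, config)

  rows <- rbind(
    do.call(rbind, lapply(models, function(m) {
      fit_row(fits_early[[m]], "truncated", pred_ssr[[m]])
    })),
    do.call(rbind, lapply(models, function(m) fit_row(fits_full[[m]], "full")))
  )
  rownames(rows) <- NULL

  tr <- rows[rows$window == "truncated", ]
  fu <- rows[rows$window == "full", ]
  quantities <- c("max_size", "doubling_time", "min_cure_concentration")
  pc <- do.call(rbind, lapply(quantities, function(q) {
    data.frame(
      model = tr$model,
      quantity = q,
      truncated = tr[[q]],
      full = fu[[q]],
      pct_change = percent_change(tr[[q]], fu[[q]]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(pc) <- NULL

  spread_tab <- do.call(rbind, lapply(c("truncated", "full"), function(w) {
    sub <- rows[rows$window == w, ]
    do.call(rbind, lapply(c("doubling_time", "min_cure_concentration"), function(q) {
      vals <- stats::setNames(sub[[q]], sub$model)
      fs <- tryCatch(as.numeric(fold_spread(vals)), error = function(e) NA_real_)
      data.frame(window = w, quantity = q, fold_spread = fs,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(spread_tab) <- NULL

  sel_early <- select_model(fits_early)
  selected <- list(
    lowest_ssr = tr$model[which.min(tr$ssr_fit)],
    lowest_aicc = sel_early$best,
    lowest_prediction_ssr = tr$model[which.min(tr$ssr_prediction)]
  )

  structure(
    list(
      fits = rows,
      percent_change = pc,
      spreads = spread_tab,
      selected = selected,
      ranking_truncated = sel_early$ranking,
      unbounded_models = list(
        truncated = tr$model[is.infinite(tr$max_size)],
        full = fu$model[is.infinite(fu$max_size)]
      ),
      label = attr(data, "label"),
      seed = config$seed
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$label, " (seed ", x$seed, ")\n\n", sep = "")
  show <- x$fits
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], signif, 4)
  print(show, row.names = FALSE)
  cat("\nSelected model by criterion (truncated fits):\n")
  cat("  lowest fit SSR:        ", x$selected$lowest_ssr, "\n")
  cat("  lowest AICc:           ", x$selected$lowest_aicc, "\n")
  cat("  lowest prediction SSR: ", x$selected$lowest_prediction_ssr, "\n")
  cat("\nAcross-model fold spreads:\n")
  print(transform(x$spreads, fold_spread = signif(fold_spread, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write a comparison report to disk
#'
#' Writes the per-model fit table as CSV and the whole report (fits, percent
#' changes, spreads, selections) as JSON. Unbounded sentinels are serialized
#' as the string "unbounded" in JSON.
#'
#' @param report A `comparison_report`.
#' @param dir Output directory (created if absent).
#' @param format Any of "csv", "json".
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  format <- match.arg(format, c("csv", "json"), several.ok = TRUE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  if ("csv" %in% format) {
    p <- file.path(dir, "model_fits.csv")
    utils::write.csv(report$fits, p, row.names = FALSE)
    paths <- c(paths, p)
    p2 <- file.path(dir, "percent_change.csv")
    utils::write.csv(report$percent_change, p2, row.names = FALSE)
    paths <- c(paths, p2)
  }
  if ("json" %in% format) {
    p <- file.path(dir, "comparison_report.json")
    fits <- report$fits
    for (col in c("max_size", "ssr_prediction", "ssr_fit")) {
      fits[[col]] <- ifelse(is.infinite(fits[[col]]), "unbounded",
                            as.character(fits[[col]]))
    }
    fits$aicc <- as.character(fits$aicc) # may be -Inf for a perfect fit
    jsonlite::write_json(
      list(fits = fits, percent_change = report$percent_change,
           spreads = report$spreads, selected = report$selected,
           unbounded_models = report$unbounded_models, seed = report$seed),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
    )
    paths <- c(paths, p)
  }
  invisible(paths)
}
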