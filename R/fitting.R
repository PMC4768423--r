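# Least-squares fitting of growth models to tumor-volume time series, AICc
# model selection, and extrapolation scoring on held-out observations.

#' Assemble a tumor-volume time series
#'
#' @param times Observation times in days, strictly increasing.
#' @param volumes Tumor volumes in mm^3, positive, same length as `times`.
#' @param label Free-text label.
#' @return A data.frame of class `tumor_series` with columns `time_days` and
#'   `volume_mm3`; `label` stored as an attribute.
#' @export
tumor_series <- function(times, volumes, label = "") {
  if (length(times) != length(volumes) || length(times) < 2L) {
    stop("times and volumes must have equal length >= 2", call. = FALSE)
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(volumes <= 0)) stop("volumes must be positive", call. = FALSE)
  structure(
    data.frame(time_days = as.numeric(times), volume_mm3 = as.numeric(volumes)),
    label = label,
    class = c("tumor_series", "data.frame")
  )
}

#' Read / write a tumor-volume series as CSV
#'
#' The on-disk dialect is comma-separated UTF-8 with a `time_days,volume_mm3`
#' header and `.` decimal marks.
#'
#' @param path File path.
#' @return `read_series` returns a [tumor_series()].
#' @export
read_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_days", "volume_mm3") %in% names(d))) {
    stop("expected columns time_days, volume_mm3 in ", path, call. = FALSE)
  }
  tumor_series(d$time_days, d$volume_mm3, label = basename(path))
}

#' @rdname read_series
#' @param series A [tumor_series()].
#' @export
write_series <- function(series, path) {
  utils::write.csv(
    data.frame(time_days = series$time_days, volume_mm3 = series$volume_mm3),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Fitting configuration
#'
#' Controls the bounded multistart least-squares fit. Optimization runs in
#' log-parameter space under box bounds with a quasi-Newton (L-BFGS-B)
#' minimizer, seeded from a data-driven initial guess plus a Latin-hypercube
#' sample of the log-bounded box.
#'
#' @param n_starts Number of multistarts (the data-driven guess plus
#'   `n_starts - 1` Latin-hypercube draws).
#' @param seed Integer seed making the fit deterministic.
#' @param fit_v0 If TRUE the initial volume is an extra free parameter
#'   (increments K); by default v0 is fixed to the first observation.
#' @param residuals "absolute" (plain volume residuals, the default) or
#'   "relative" (residuals divided by observed volume).
#' @param rtol,atol ODE solver tolerances used inside the objective.
#' @param bounds Named list of per-parameter `c(lower, upper)` bounds on the
#'   natural scale; see [default_parameter_bounds()].
#' @param maxit Maximum L-BFGS-B iterations per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 32L, seed = 1L, fit_v0 = FALSE,
                       residuals = c("absolute", "relative"),
                       rtol = 1e-8, atol = 1e-10,
                       bounds = NULL, maxit = 300L) {
  residuals <- match.arg(residuals)
  structure(
    list(n_starts = as.integer(n_starts), seed = as.integer(seed),
         fit_v0 = isTRUE(fit_v0), residuals = residuals,
         rtol = rtol, atol = atol, bounds = bounds, maxit = as.integer(maxit)),
    class = "fit_config"
  )
}

#' Read a fitting configuration from YAML or JSON
#'
#' Recognized fields match the arguments of [fit_config()]; unknown fields are
#' ignored with a warning. An optional `models` field (character vector) is
#' passed through for use by pipeline drivers.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `fit_config` with attribute `models` if the file names any.
#' @export
read_fit_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- c("n_starts", "seed", "fit_v0", "residuals", "rtol", "atol",
             "bounds", "maxit")
  extra <- setdiff(names(raw), c(known, "models"))
  if (length(extra)) {
    warning("ignoring unknown config fields: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  cfg <- do.call(fit_config, raw[intersect(names(raw), known)])
  if (!is.null(raw$models)) attr(cfg, "models") <- raw$models
  cfg
}

#' Default box bounds for model parameters
#'
#' Bounds on the natural scale, used (log-transformed) by the optimizer:
#' rate-like `a` in \[1e-6, 10\] /day (the linear and surface laws, whose `a`
#' carries volume units, get \[1e-6, 1e6\]); volume-like `b` and `c` in
#' \[1e-6, 1e6\] mm^3; the mendelsohn exponent `b` in \[0.1, 3\].
#'
#' @param name Model name.
#' @return Named list of `c(lower, upper)` per parameter.
#' @export
default_parameter_bounds <- function(name) {
  name <- match.arg(name, growth_model_names())
  vol <- c(1e-6, 1e6)
  rate <- c(1e-6, 10)
  switch(name,
    exponential = list(a = rate),
    mendelsohn  = list(a = rate, b = c(0.1, 3)),
    logistic    = list(a = rate, b = vol),
    # linear/surface 'a' has mm^3-flavored units (late-time slope); allow wide
    linear      = list(a = vol, b = vol),
    surface     = list(a = vol, b = vol),
    gompertz    = list(a = rate, b = vol, c = vol),
    bertalanffy = list(a = rate, b = rate)
  )
}

#' Sum of squared residuals of a model against observations
#'
#' SSR = sum_i (x_i - m_i)^2, where x_i are the observed volumes and m_i the
#' model-predicted volumes at the observation times, integrating from `v0` at
#' the first observation time. A diverged trajectory yields `Inf` so that an
#' optimizer rejects that parameter region.
#'
#' @param observed A [tumor_series()].
#' @param model A [growth_model()].
#' @param v0 Initial volume at the first observation time (default: the first
#'   observed volume).
#' @return SSR in mm^6.
#' @export
compute_ssr <- function(observed, model, v0 = observed$volume_mm3[1]) {
  pred <- solve_trajectory(model, v0, observed$time_days)
  if (pred$diverged || anyNA(pred$volumes)) return(Inf)
  sum((observed$volume_mm3 - pred$volumes)^2)
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = n ln(SSR/n) + 2 (K + 1) n / (n - K - 2), where n is the number of
#' observations and K the number of free model parameters. Defined only for
#' n - K - 2 > 0 (otherwise NA with a warning); a perfect fit (SSR = 0) gives
#' -Inf with a warning so that it deterministically ranks first.
#'
#' @param ssr Sum of squared residuals.
#' @param n Number of observations.
#' @param k Number of free parameters.
#' @return AICc value (dimensionless), NA if undefined, -Inf for SSR = 0.
#' @examples
#' compute_aicc(ssr = 7, n = 7, k = 1) # = 7
#' @export
compute_aicc <- function(ssr, n, k) {
  if (ssr < 0) stop("ssr must be non-negative", call. = FALSE)
  if (n - k - 2 <= 0) {
    warning("AICc undefined: need n - k - 2 > 0 (n = ", n, ", k = ", k, ")",
            call. = FALSE)
    return(NA_real_)
  }
  if (ssr == 0) {
    warning("perfect fit (SSR = 0): AICc is -Inf", call. = FALSE)
    return(-Inf)
  }
  n * log(ssr / n) + 2 * (k + 1) * n / (n - k - 2)
}

# Deterministic RNG scope that restores the caller's RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Data-driven starting values on the natural scale, clipped to bounds.
initial_guess <- function(name, observed) {
  tt <- observed$time_days
  vv <- observed$volume_mm3
  n <- length(tt)
  # early log-slope as a crude initial growth rate
  i2 <- min(3L, n)
  lam <- (log(vv[i2]) - log(vv[1])) / max(tt[i2] - tt[1], 1e-6)
  lam <- min(max(lam, 1e-4), 5)
  vmax <- max(vv)
  late_slope <- (vv[n] - vv[1]) / max(tt[n] - tt[1], 1e-6)
  late_slope <- max(late_slope, 1e-4)
  switch(name,
    exponential = c(a = lam),
    mendelsohn  = c(a = lam, b = 1),
    logistic    = c(a = lam, b = 2 * vmax),
    linear      = c(a = late_slope, b = late_slope / lam),
    surface     = c(a = lam * vmax^(1 / 3), b = vmax),
    gompertz    = c(a = lam / max(log(2 * vmax / vv[1]), 0.5), b = 2 * vmax, c = 1),
    bertalanffy = {
      r <- (2 * vmax)^(1 / 3)
      b <- lam / max(r - 1, 0.1)
      c(a = r * b, b = b)
    }
  )
}

fit_objective <- function(logp, name, observed, v0, config) {
  params <- exp(logp)
  model <- tryCatch(
    suppressWarnings(growth_model(name, a = params[1],
                                  b = if (length(params) >= 2) params[2],
                                  c = if (length(params) >= 3) params[3])),
    error = function(e) NULL
  )
  if (is.null(model)) return(1e100)
  pred <- predict_volumes(model, v0, observed$time_days,
                          rtol = config$rtol, atol = config$atol)
  if (anyNA(pred)) return(1e100)
  res <- observed$volume_mm3 - pred
  if (config$residuals == "relative") res <- res / observed$volume_mm3
  ssr <- sum(res^2)
  if (!is.finite(ssr)) return(1e100)
  ssr
}

#' Fit one growth model to a tumor-volume series
#'
#' Minimizes the sum of squared residuals over log-transformed, box-bounded
#' parameters with a bounded quasi-Newton method (L-BFGS-B), multistarted from
#' a data-driven guess plus a seeded Latin-hypercube sample. The initial
#' volume v0 is fixed to the first observation unless `config$fit_v0` is set.
#' Deterministic given the data, `config$seed` and `config$n_starts`.
#'
#' @param observed A [tumor_series()].
#' @param name Model name, one of [growth_model_names()].
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: list with elements `model` (fitted
#'   [growth_model()]), `v0`, `ssr`, `aicc`, `n`, `k`, `converged`, `n_starts`,
#'   `seed`, and the fitted series' time range.
#' @export
fit_model <- function(observed, name, config = fit_config()) {
  name <- match.arg(name, growth_model_names())
  n <- nrow(observed)
  k <- model_param_count(name) + as.integer(config$fit_v0)
  if (n < k + 3L) {
    warning("n = ", n, " observations cannot support AICc for k = ", k,
            " parameters (need n >= k + 3)", call. = FALSE)
  }
  bounds <- config$bounds
  if (is.null(bounds)) bounds <- default_parameter_bounds(name)
  pnames <- names(bounds)
  lower <- log(vapply(bounds, `[`, numeric(1), 1L))
  upper <- log(vapply(bounds, `[`, numeric(1), 2L))
  v0 <- observed$volume_mm3[1]

  guess <- initial_guess(name, observed)
  guess <- pmin(pmax(guess, exp(lower)), exp(upper))
  npar <- length(pnames)

  starts <- with_local_seed(config$seed, {
    u <- lhs::randomLHS(max(config$n_starts - 1L, 1L), npar)
    sweep(sweep(u, 2, upper - lower, `*`), 2, lower, `+`)
  })
  starts <- rbind(log(guess), starts)
  starts <- starts[seq_len(max(config$n_starts, 1L)), , drop = FALSE]

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(
        par = starts[i, ], fn = fit_objective,
        name = name, observed = observed, v0 = v0, config = config,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = config$maxit)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (fit$convergence == 0) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }

  if (!is.null(best) && best$value < 1e99) {
    # polish the winning start with tighter finite-difference steps and
    # convergence tolerance than the exploration passes
    polished <- tryCatch(
      stats::optim(
        par = best$par, fn = fit_objective,
        name = name, observed = observed, v0 = v0, config = config,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = config$maxit, factr = 1e3,
                       ndeps = rep(1e-6, npar))
      ),
      error = function(e) NULL
    )
    if (!is.null(polished) && polished$value <= best$value) best <- polished
  }

  if (is.null(best) || best$value >= 1e99) {
    return(structure(
      list(model = NULL, name = name, v0 = v0, ssr = Inf, aicc = NA_real_,
           n = n, k = k, converged = FALSE, n_starts = config$n_starts,
           seed = config$seed, t_range = range(observed$time_days)),
      class = "fit_result"
    ))
  }

  params <- exp(best$par)
  model <- suppressWarnings(growth_model(
    name, a = params[1],
    b = if (npar >= 2) params[2], c = if (npar >= 3) params[3]
  ))
  ssr <- best$value
  aicc <- if (n - k - 2 > 0) suppressWarnings(compute_aicc(ssr, n, k)) else NA_real_
  structure(
    list(model = model, name = name, v0 = v0, ssr = ssr, aicc = aicc,
         n = n, k = k, converged = any_converged, n_starts = config$n_starts,
         seed = config$seed, t_range = range(observed$time_days)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", x$name, if (!x$converged) " [NOT converged]", "\n", sep = "")
  if (!is.null(x$model)) {
    cat("  params: ", paste(names(x$model$params), signif(x$model$params, 6),
                            sep = " = ", collapse = ", "), "\n", sep = "")
  }
  cat("  v0 = ", format(signif(x$v0, 6)), " mm^3 (fixed), n = ", x$n,
      ", k = ", x$k, "\n  SSR = ", format(signif(x$ssr, 6)),
      ", AICc = ", format(signif(x$aicc, 6)), "\n", sep = "")
  invisible(x)
}

#' Fit several growth models to the same series
#'
#' @param observed A [tumor_series()].
#' @param models Character vector of model names (default: all seven).
#' @param config A [fit_config()].
#' @return Named list of [fit_model()] results.
#' @export
fit_all_models <- function(observed, models = growth_model_names(),
                           config = fit_config()) {
  fits <- lapply(models, function(m) fit_model(observed, m, config))
  names(fits) <- models
  fits
}

#' Rank fitted models by AICc
#'
#' The model with the lowest AICc is selected; ties (difference below 1e-9)
#' are broken toward the model with fewer parameters. All fits must share the
#' same observation count n.
#'
#' @param fits List of `fit_result` objects on the same data.
#' @return List with `best` (model name) and `ranking` (data.frame with model,
#'   k, ssr, aicc, delta_aicc ordered by rank).
#' @export
select_model <- function(fits) {
  if (length(fits) < 2L) stop("need at least two fits to select", call. = FALSE)
  ns <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(ns)) != 1L) {
    stop("fits compare different observation counts n; AICc ranking is only ",
         "valid on the same data", call. = FALSE)
  }
  tab <- data.frame(
    model = vapply(fits, `[[`, character(1), "name"),
    k = vapply(fits, `[[`, numeric(1), "k"),
    ssr = vapply(fits, `[[`, numeric(1), "ssr"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    stringsAsFactors = FALSE
  )
  aicc_key <- ifelse(is.na(tab$aicc), Inf, tab$aicc)
  # round ties (delta < 1e-9) to a common key, then prefer fewer parameters
  ord <- order(aicc_key, tab$k)
  for (i in seq_len(nrow(tab) - 1L)) {
    a <- aicc_key[ord[i]]; b <- aicc_key[ord[i + 1L]]
    if (is.finite(a) && is.finite(b) && abs(a - b) < 1e-9 &&
        tab$k[ord[i + 1L]] < tab$k[ord[i]]) {
      ord[c(i, i + 1L)] <- ord[c(i + 1L, i)]
    }
  }
  tab <- tab[ord, , drop = FALSE]
  finite <- is.finite(tab$aicc)
  tab$delta_aicc <- tab$aicc - if (any(finite)) min(tab$aicc[finite]) else NA_real_
  rownames(tab) <- NULL
  list(best = tab$model[1L], ranking = tab)
}

#' Score a fitted model's extrapolation on held-out observations
#'
#' Integrates the fitted model from its fitted initial volume (anchored at the
#' first fitted time point) across the full horizon and returns the SSR on the
#' held-out points only — the prediction error of the truncated fit.
#'
#' @param fit A `fit_result`.
#' @param heldout A [tumor_series()] whose times all exceed the fitted range.
#' @return Prediction SSR in mm^6; `Inf` with attribute `diverged = TRUE` if
#'   the trajectory diverges before the last held-out time.
#' @export
extrapolate_and_score <- function(fit, heldout) {
  if (!inherits(fit, "fit_result")) stop("expected a fit_result", call. = FALSE)
  if (is.null(fit$model)) return(structure(Inf, diverged = TRUE))
  if (min(heldout$time_days) <= fit$t_range[2]) {
    stop("held-out times must all be later than the fitted series", call. = FALSE)
  }
  times <- c(fit$t_range[1], heldout$time_days)
  traj <- solve_trajectory(fit$model, fit$v0, times)
  pred <- traj$volumes[-1L]
  if (traj$diverged || anyNA(pred)) return(structure(Inf, diverged = TRUE))
  sum((heldout$volume_mm3 - pred)^2)
}
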