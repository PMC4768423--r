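# Synthetic xenograft-like tumor-volume series with known ground truth, so the
# whole fit/extrapolate/compare workflow is testable without external data.

#' Study design for a synthetic growth experiment
#'
#' Defaults emulate a long subcutaneous-xenograft growth study: 14 measurement
#' days spanning 114 days, lightly jittered spacing, and a 50/50 early/late
#' split so the early half covers roughly the first 65 days.
#'
#' @param n_points Number of measurements (>= 4).
#' @param horizon Last measurement day.
#' @param spacing "jittered" (uniform grid perturbed by ±10% of the spacing,
#'   the default) or "uniform".
#' @param truncation_fraction Fraction of points in the "early" subset used
#'   for truncated fits, strictly between 0 and 1.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_points = 14L, horizon = 114, spacing = c("jittered", "uniform"),
                         truncation_fraction = 0.5) {
  spacing <- match.arg(spacing)
  if (n_points < 4L) stop("n_points must be at least 4", call. = FALSE)
  if (truncation_fraction <= 0 || truncation_fraction >= 1) {
    stop("truncation_fraction must be strictly between 0 and 1", call. = FALSE)
  }
  structure(
    list(n_points = as.integer(n_points), horizon = horizon,
         spacing = spacing, truncation_fraction = truncation_fraction),
    class = "study_design"
  )
}

#' Measurement-noise configuration
#'
#' Multiplicative lognormal noise with unit mean: observed volume =
#' true volume × exp(sigma Z - sigma^2/2) with sigma chosen so the
#' coefficient of variation equals `cv`. Volumes are floored at `floor`
#' (a minimum reportable volume). `cv = 0` returns exact model curves.
#'
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param seed Integer seed.
#' @param floor Minimum reportable volume in mm^3.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(cv = 0.1, seed = 1L, floor = 0.01) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  structure(list(cv = cv, seed = as.integer(seed), floor = floor),
            class = "noise_config")
}

#' Default ground-truth parameter sets for synthetic experiments
#'
#' Plausible per-model parameters producing xenograft-like curves from
#' v0 = 50 mm^3: a slow start, growth into the thousands of mm^3 over ~114
#' days. These are illustrative values chosen for the synthetic study design,
#' not estimates from any experimental data set.
#'
#' @param name Model name.
#' @return A [growth_model()].
#' @export
default_truth <- function(name) {
  name <- match.arg(name, growth_model_names())
  switch(name,
    exponential = growth_model("exponential", a = 0.04),
    mendelsohn  = growth_model("mendelsohn", a = 0.5, b = 0.6),
    logistic    = growth_model("logistic", a = 0.08, b = 6000),
    linear      = growth_model("linear", a = 40, b = 400),
    surface     = growth_model("surface", a = 0.4, b = 1000),
    gompertz    = growth_model("gompertz", a = 0.08, b = 8000, c = 1),
    bertalanffy = growth_model("bertalanffy", a = 1, b = 0.05)
  )
}

#' Generate a synthetic tumor-volume series with known ground truth
#'
#' Integrates the true model from `v0`, samples it on the design's time grid,
#' and applies multiplicative mean-one lognormal noise. The returned object
#' carries the ground truth (true model, v0, and the true clinical
#' predictions) so recovery can be scored.
#'
#' @param truth A [growth_model()] satisfying the growth condition.
#' @param v0 Initial volume in mm^3 (default 50).
#' @param design A [study_design()].
#' @param noise A [noise_config()].
#' @return A list of class `synthetic_series` with elements `series`
#'   (a [tumor_series()]), `truth` (list: model, v0, clinical).
#' @examples
#' gen <- generate_series(default_truth("gompertz"))
#' head(gen$series)
#' @export
generate_series <- function(truth, v0 = 50, design = study_design(),
                            noise = noise_config()) {
  stop_if_not_model(truth)
  if (!growth_condition(truth)) {
    stop("ground-truth model does not satisfy its growth condition", call. = FALSE)
  }
  if (v0 <= 0) stop("v0 must be positive", call. = FALSE)

  out <- with_local_seed(noise$seed, {
    base <- seq(0, design$horizon, length.out = design$n_points)
    times <- base
    if (design$spacing == "jittered") {
      dt <- base[2] - base[1]
      jit <- stats::runif(design$n_points, -0.1 * dt, 0.1 * dt)
      jit[c(1, design$n_points)] <- 0 # keep endpoints on the stated horizon
      times <- sort(base + jit)
      times <- pmax(times, 0)
    }
    traj <- solve_trajectory(truth, v0, times)
    if (traj$diverged) {
      stop("ground-truth model diverges before the design horizon; ",
           "shorten the horizon or change parameters", call. = FALSE)
    }
    vols <- traj$volumes
    if (noise$cv > 0) {
      sigma <- sqrt(log(1 + noise$cv^2))
      vols <- vols * stats::rlnorm(length(vols), meanlog = -sigma^2 / 2, sdlog = sigma)
    }
    vols <- pmax(vols, noise$floor)
    list(times = times, vols = vols)
  })

  structure(
    list(
      series = tumor_series(out$times, out$vols,
                            label = paste0("synthetic-", truth$name)),
      truth = list(model = truth, v0 = v0,
                   clinical = clinical_predictions(truth),
                   design = design, noise = noise)
    ),
    class = "synthetic_series"
  )
}

#' Write the ground truth of a synthetic series as a JSON sidecar
#'
#' @param gen A `synthetic_series` from [generate_series()].
#' @param path Output JSON path.
#' @export
write_truth_json <- function(gen, path) {
  cl <- gen$truth$clinical
  rec <- list(
    model = gen$truth$model$name,
    params = as.list(gen$truth$model$params),
    v0 = gen$truth$v0,
    synthetic = TRUE,
    note = "illustrative synthetic ground truth, not experimental estimates",
    clinical = list(
      max_size = if (is.infinite(cl$max_size)) "unbounded" else cl$max_size,
      doubling_time = cl$doubling_time,
      min_cure_concentration = cl$min_cure_concentration
    ),
    design = unclass(gen$truth$design),
    noise = unclass(gen$truth$noise)
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Split a series into early (fitted) and late (held-out) subsets
#'
#' The first `ceiling(fraction * n)` points form the early subset; the rest
#' are held out. The two parts are disjoint, order-preserving, and their union
#' is the original series.
#'
#' @param series A [tumor_series()].
#' @param design A [study_design()] (its `truncation_fraction` is used), or a
#'   bare numeric fraction.
#' @return List with `early` and `late` [tumor_series()] objects.
#' @export
truncate_series <- function(series, design = study_design()) {
  frac <- if (inherits(design, "study_design")) design$truncation_fraction else design
  if (frac <= 0 || frac >= 1) {
    stop("truncation fraction must be strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(series)
  if (n < 4L) stop("series must have at least 4 points to split", call. = FALSE)
  n_early <- as.integer(ceiling(frac * n))
  if (n_early < 2L || n_early > n - 2L) {
    stop("truncation fraction leaves too few points on one side ",
         "(need >= 2 early and >= 2 late)", call. = FALSE)
  }
  lab <- attr(series, "label")
  list(
    early = tumor_series(series$time_days[seq_len(n_early)],
                         series$volume_mm3[seq_len(n_early)],
                         label = paste0(lab, " [early]")),
    late = tumor_series(series$time_days[-seq_len(n_early)],
                        series$volume_mm3[-seq_len(n_early)],
                        label = paste0(lab, " [late]"))
  )
}
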