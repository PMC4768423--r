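# Model definitions and trajectory solving for the seven classical ODE models of
# tumor volume growth. Volumes are mm^3, times are days throughout; no unit layer.

#' The seven tumor growth model names
#'
#' Canonical lowercase names of the growth models handled by this package, in
#' the conventional order: exponential, mendelsohn, logistic, linear, surface,
#' gompertz, bertalanffy.
#'
#' @return Character vector of the seven model names.
#' @export
growth_model_names <- function() {
  c("exponential", "mendelsohn", "logistic", "linear",
    "surface", "gompertz", "bertalanffy")
}

#' Number of free ODE parameters of a growth model
#'
#' @param name Model name (one of [growth_model_names()]).
#' @return Integer: 1 for exponential, 3 for gompertz, 2 otherwise.
#' @export
model_param_count <- function(name) {
  name <- match.arg(name, growth_model_names())
  switch(name, exponential = 1L, gompertz = 3L, 2L)
}

#' Construct a growth model specification
#'
#' Builds a validated model object holding one of the seven growth laws and its
#' parameter vector. The right-hand sides are, with volume V in mm^3:
#' \describe{
#'   \item{exponential}{dV/dt = a V}
#'   \item{mendelsohn}{dV/dt = a V^b}
#'   \item{logistic}{dV/dt = a V (1 - V/b)}
#'   \item{linear}{dV/dt = a V / (V + b)}
#'   \item{surface}{dV/dt = a V / (V + b)^(1/3)}
#'   \item{gompertz}{dV/dt = a V ln(b / (V + c))}
#'   \item{bertalanffy}{dV/dt = a V^(2/3) - b V}
#' }
#'
#' @param name Model name, one of [growth_model_names()].
#' @param a Rate-like parameter (per-day flavor), strictly positive.
#' @param b Second parameter: carrying-capacity-like volume (logistic, gompertz),
#'   volume offset (linear, surface), dimensionless exponent (mendelsohn), or
#'   loss rate (bertalanffy). Required for all models except exponential.
#' @param c Volume offset in mm^3, gompertz only.
#' @return An object of class `growth_model`: a list with elements `name` and
#'   `params` (named numeric vector).
#' @examples
#' growth_model("logistic", a = 0.08, b = 6000)
#' growth_model("gompertz", a = 0.08, b = 8000, c = 1)
#' @export
growth_model <- function(name, a, b = NULL, c = NULL) {
  name <- match.arg(name, growth_model_names())
  k <- model_param_count(name)
  params <- c(a = as.numeric(a))
  if (k >= 2L) {
    if (is.null(b)) stop("model '", name, "' requires parameter b", call. = FALSE)
    params["b"] <- as.numeric(b)
  } else if (!is.null(b)) {
    stop("exponential model takes a single parameter a", call. = FALSE)
  }
  if (k == 3L) {
    if (is.null(c)) stop("gompertz requires parameter c", call. = FALSE)
    params["c"] <- as.numeric(c)
  } else if (!is.null(c)) {
    stop("parameter c is only used by the gompertz model", call. = FALSE)
  }
  if (any(!is.finite(params)) || any(params <= 0)) {
    stop("all model parameters must be strictly positive and finite", call. = FALSE)
  }
  if (name == "gompertz" && params["b"] <= params["c"]) {
    warning("gompertz with b <= c has a non-positive initial growth rate ",
            "(growth condition a*ln(b/c) > 0 not met)", call. = FALSE)
  }
  if (name == "mendelsohn" && params["b"] == 1) {
    warning("mendelsohn with b = 1 degenerates to the exponential model; ",
            "clinical formulas involving 1/(b-1) are singular", call. = FALSE)
  }
  structure(list(name = name, params = params), class = "growth_model")
}

#' @export
print.growth_model <- function(x, ...) {
  cat("<growth_model> ", x$name, ": ",
      paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

is_growth_model <- function(x) inherits(x, "growth_model")

stop_if_not_model <- function(model) {
  if (!is_growth_model(model)) {
    stop("expected a 'growth_model' object; see growth_model()", call. = FALSE)
  }
  invisible(model)
}

#' Evaluate the growth rate dV/dt of a model
#'
#' Evaluates the model right-hand side at volume `v`, optionally under constant
#' chemotherapy, which subtracts a kill term `c0 * v` from every model.
#'
#' @param model A [growth_model()].
#' @param v Volume in mm^3, non-negative (vectorized).
#' @param c0 Constant chemotherapy kill rate in /day, non-negative.
#' @return dV/dt in mm^3/day, same length as `v`.
#' @examples
#' m <- growth_model("logistic", a = 1, b = 100)
#' rhs_eval(m, 100) # zero growth at carrying capacity
#' @export
rhs_eval <- function(model, v, c0 = 0) {
  stop_if_not_model(model)
  if (any(v < 0)) stop("volume must be non-negative", call. = FALSE)
  if (length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("c0 must be a single non-negative kill rate", call. = FALSE)
  }
  p <- model$params
  growth <- switch(model$name,
    exponential = p[["a"]] * v,
    mendelsohn  = p[["a"]] * v^p[["b"]],
    logistic    = p[["a"]] * v * (1 - v / p[["b"]]),
    linear      = p[["a"]] * v / (v + p[["b"]]),
    surface     = p[["a"]] * v / (v + p[["b"]])^(1 / 3),
    gompertz    = p[["a"]] * v * log(p[["b"]] / (v + p[["c"]])),
    bertalanffy = p[["a"]] * v^(2 / 3) - p[["b"]] * v
  )
  growth - c0 * v
}

#' Attach a constant-chemotherapy term to a model
#'
#' Returns the right-hand side of the model with a constant drug kill term
#' subtracted: dV/dt = f(V) - c0 V.
#'
#' @inheritParams rhs_eval
#' @return A function of a single volume argument returning dV/dt.
#' @export
with_chemotherapy <- function(model, c0) {
  stop_if_not_model(model)
  if (length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("c0 must be a single non-negative kill rate", call. = FALSE)
  }
  force(model)
  force(c0)
  function(v) rhs_eval(model, v, c0 = c0)
}

#' Does a model have an implemented analytic solution?
#'
#' @param model A [growth_model()] or model name.
#' @return Logical. TRUE for exponential, mendelsohn, logistic and bertalanffy.
#' @export
has_closed_form <- function(model) {
  name <- if (is_growth_model(model)) model$name else match.arg(model, growth_model_names())
  name %in% c("exponential", "mendelsohn", "logistic", "bertalanffy")
}

#' Analytic volume trajectory where a standard integral exists
#'
#' Closed-form solutions of the untreated growth ODEs:
#' exponential `V = v0 exp(a t)`; logistic
#' `V = b / (1 + (b/v0 - 1) exp(-a t))`; mendelsohn (b != 1)
#' `V = (v0^(1-b) + a (1-b) t)^(1/(1-b))`, which blows up in finite time for
#' b > 1; bertalanffy, via the substitution u = V^(1/3),
#' `V = (a/b + (v0^(1/3) - a/b) exp(-b t / 3))^3`.
#' The linear, surface, and (offset) gompertz laws have no elementary solution
#' and raise an error — use [solve_trajectory()].
#'
#' @param model A [growth_model()] for which [has_closed_form()] is TRUE.
#' @param v0 Initial volume in mm^3, positive.
#' @param t Times in days (vectorized), measured from the time of `v0`.
#' @return Volumes in mm^3; `Inf` past a finite-time blow-up (mendelsohn b > 1).
#' @export
closed_form_volume <- function(model, v0, t) {
  stop_if_not_model(model)
  if (v0 <= 0) stop("v0 must be positive", call. = FALSE)
  p <- model$params
  switch(model$name,
    exponential = v0 * exp(p[["a"]] * t),
    logistic = {
      b <- p[["b"]]
      b / (1 + (b / v0 - 1) * exp(-p[["a"]] * t))
    },
    mendelsohn = {
      b <- p[["b"]]
      if (b == 1) return(v0 * exp(p[["a"]] * t))
      base <- v0^(1 - b) + p[["a"]] * (1 - b) * t
      out <- ifelse(base > 0, base^(1 / (1 - b)), if (b > 1) Inf else 0)
      as.numeric(out)
    },
    bertalanffy = {
      u_inf <- p[["a"]] / p[["b"]]
      u <- u_inf + (v0^(1 / 3) - u_inf) * exp(-p[["b"]] * t / 3)
      u^3
    },
    stop("no closed-form solution implemented for model '", model$name,
         "'; use solve_trajectory()", call. = FALSE)
  )
}

#' Numerically integrate a growth model trajectory
#'
#' Adaptive-step integration (deSolve's `lsodar`) of the model ODE, with an
#' optional constant-chemotherapy kill term. Unbounded models are stopped
#' cleanly when the volume crosses `v_max` (default 1e12 mm^3) and the result
#' is flagged as diverged rather than returning Inf or NaN. Tiny negative
#' excursions are clipped to zero before fractional powers are evaluated.
#'
#' @inheritParams rhs_eval
#' @param v0 Initial volume in mm^3 at `times[1]`, positive.
#' @param times Strictly increasing observation times in days, `times[1] >= 0`.
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param v_max Divergence threshold in mm^3.
#' @return An object of class `trajectory`: list with `times`, `volumes`
#'   (NA past divergence), `diverged` flag and `last_valid_time`.
#' @examples
#' m <- growth_model("gompertz", a = 0.08, b = 8000, c = 1)
#' solve_trajectory(m, v0 = 50, times = seq(0, 114, by = 6))
#' @export
solve_trajectory <- function(model, v0, times, c0 = 0,
                             rtol = 1e-8, atol = 1e-10, v_max = 1e12) {
  stop_if_not_model(model)
  if (v0 <= 0) stop("v0 must be positive", call. = FALSE)
  if (length(times) < 1L || any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] < 0) stop("times must start at or after day 0", call. = FALSE)
  if (length(times) == 1L) {
    return(structure(
      list(times = times, volumes = v0, diverged = FALSE, last_valid_time = times[1]),
      class = "trajectory"
    ))
  }

  out <- tryCatch(
    suppressWarnings(deSolve::lsodar(
      y = c(V = v0), times = times,
      func = "growth_deriv", parms = model_solver_parms(model, c0, v_max),
      dllname = "tumorgrowth", initfunc = "growth_init",
      rootfunc = "growth_root", nroot = 1L,
      rtol = rtol, atol = atol
    )),
    error = function(e) NULL
  )

  volumes <- rep(NA_real_, length(times))
  diverged <- FALSE
  if (is.null(out)) {
    diverged <- TRUE
    volumes[1] <- v0
  } else {
    got <- match(round(times, 10), round(out[, "time"], 10))
    volumes <- out[got, "V"]
    volumes[!is.na(volumes) & volumes < 0] <- 0
    if (anyNA(volumes) || any(volumes[!is.na(volumes)] >= v_max)) {
      diverged <- TRUE
      volumes[!is.na(volumes) & volumes >= v_max] <- NA_real_
    }
  }
  last_valid <- if (all(is.na(volumes))) NA_real_ else max(times[!is.na(volumes)])
  structure(
    list(times = times, volumes = as.numeric(volumes),
         diverged = diverged, last_valid_time = last_valid),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", length(x$times), " time points, ",
      format(min(x$times)), "-", format(max(x$times)), " days",
      if (x$diverged) paste0(" [diverged after t = ", format(x$last_valid_time), "]"),
      "\n", sep = "")
  invisible(x)
}

# Parameter vector handed to the compiled right-hand side (src/growth_models.c):
# model id (position in growth_model_names()), a, b, c, kill rate, divergence cap.
model_solver_parms <- function(model, c0, v_max) {
  p <- model$params
  c(match(model$name, growth_model_names()),
    p[["a"]],
    if ("b" %in% names(p)) p[["b"]] else 0,
    if ("c" %in% names(p)) p[["c"]] else 0,
    c0, v_max)
}

# Volumes at given times, preferring the analytic solution (untreated only).
# Used by the fitting objective where speed matters; agreement between the two
# routes is asserted by the test suite.
predict_volumes <- function(model, v0, times, rtol = 1e-8, atol = 1e-10) {
  if (has_closed_form(model)) {
    v <- closed_form_volume(model, v0, times - times[1])
    v[!is.finite(v)] <- NA_real_
    return(v)
  }
  solve_trajectory(model, v0, times, rtol = rtol, atol = atol)$volumes
}
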