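# Closed-form clinical quantities: fixed points, maximum tumor size, doubling
# time, growth condition and the minimum chemotherapy concentration for
# suppression, for each of the seven growth laws.

#' Initial growth rate (lambda) of a growth model
#'
#' The linearized growth rate of a nascent tumor, obtained from the behavior of
#' the growth law near V = 0: exponential/mendelsohn/logistic `a`; linear
#' `a/b`; surface `a/b^(1/3)`; gompertz `a ln(b/c)`; bertalanffy `a - b`.
#' For the fractional-power mendelsohn and bertalanffy laws a strict Taylor
#' expansion about V = 0 is singular; their rates follow the unit-volume
#' convention (relative growth rate at V = 1 mm^3), which is the convention the
#' clinical doubling-time and cure-threshold formulas adopt.
#'
#' @param model A [growth_model()].
#' @return Growth rate in /day (may be non-positive if the growth condition
#'   fails, e.g. bertalanffy with a < b).
#' @export
initial_growth_rate <- function(model) {
  stop_if_not_model(model)
  p <- model$params
  switch(model$name,
    exponential = p[["a"]],
    mendelsohn  = p[["a"]],
    logistic    = p[["a"]],
    linear      = p[["a"]] / p[["b"]],
    surface     = p[["a"]] / p[["b"]]^(1 / 3),
    gompertz    = p[["a"]] * log(p[["b"]] / p[["c"]]),
    bertalanffy = p[["a"]] - p[["b"]]
  )
}

#' Growth condition of a model
#'
#' TRUE when the tumor-free state is unstable, i.e. a nascent tumor grows:
#' the initial growth rate lambda is positive.
#'
#' @param model A [growth_model()].
#' @return Logical.
#' @export
growth_condition <- function(model) {
  initial_growth_rate(model) > 0
}

#' Tumor volume doubling time
#'
#' DT = ln(2) / lambda, where lambda is the initial growth rate of the tumor
#' (see [initial_growth_rate()]). Model by model this gives ln2/a for
#' exponential, mendelsohn and logistic; b ln2 / a for linear;
#' b^(1/3) ln2 / a for surface; ln2 / (a ln(b/c)) for gompertz; and
#' ln2 / (a - b) for bertalanffy.
#'
#' @param model A [growth_model()].
#' @return Doubling time in days.
#' @export
doubling_time <- function(model) {
  lam <- initial_growth_rate(model)
  if (lam <= 0) {
    stop("doubling time undefined: growth condition not met (initial growth ",
         "rate ", signif(lam, 4), " <= 0 for model '", model$name, "')",
         call. = FALSE)
  }
  log(2) / lam
}

#' Minimum chemotherapy concentration needed for tumor suppression
#'
#' The smallest constant kill rate C0 whose subtraction (dV/dt -> dV/dt - C0 V)
#' makes the tumor-free state attracting: a kill rate equal to the initial
#' growth rate. Model by model: a (exponential, mendelsohn, logistic); a/b
#' (linear); a/b^(1/3) (surface); a ln(b/c) (gompertz); a - b (bertalanffy).
#' If the growth condition is not met no drug is needed and 0 is returned.
#'
#' For mendelsohn (b != 1) and bertalanffy the fractional power dominates the
#' linear kill term near V = 0, so V = 0 is never strictly attracting under
#' this drug model; the returned threshold is where the treated equilibrium
#' crosses unit volume (1 mm^3), consistent with the unit-volume growth-rate
#' convention. See the package vignette.
#'
#' @param model A [growth_model()].
#' @return Kill rate in /day.
#' @export
min_cure_concentration <- function(model) {
  lam <- initial_growth_rate(model)
  max(lam, 0)
}

#' Maximum tumor size, untreated or under constant chemotherapy
#'
#' The nonzero fixed point of the (possibly chemotherapy-modified) growth law.
#' Untreated (`c0 = 0`): `Inf` for exponential, mendelsohn, linear and surface
#' (unbounded growth); `b` for logistic; `b - c` for gompertz; `(a/b)^3` for
#' bertalanffy. Under a constant kill rate `c0 > 0`: exponential stays
#' unbounded while it grows (c0 < a); mendelsohn `(c0/a)^(1/(b-1))`; logistic
#' `b (a - c0) / a`; linear `a/c0 - b`; surface `(a/c0)^3 - b`; gompertz
#' `b exp(-c0/a) - c`; bertalanffy `(a/(b + c0))^3`. Non-positive values mean
#' the drug eradicates the tumor and are reported as 0 with attribute
#' `eradicated = TRUE`.
#'
#' @inheritParams rhs_eval
#' @return Volume in mm^3, possibly `Inf` (unbounded) or 0 (eradicated, with
#'   attribute `eradicated`).
#' @examples
#' max_tumor_size(growth_model("gompertz", a = 1, b = 10, c = 1)) # 9
#' max_tumor_size(growth_model("linear", a = 10, b = 2), c0 = 1)  # 8
#' @export
max_tumor_size <- function(model, c0 = 0) {
  stop_if_not_model(model)
  if (length(c0) != 1L || !is.finite(c0) || c0 < 0) {
    stop("c0 must be a single non-negative kill rate", call. = FALSE)
  }
  p <- model$params
  if (c0 == 0) {
    v <- switch(model$name,
      exponential = Inf,
      mendelsohn  = Inf,
      linear      = Inf,
      surface     = Inf,
      logistic    = p[["b"]],
      gompertz    = p[["b"]] - p[["c"]],
      bertalanffy = (p[["a"]] / p[["b"]])^3
    )
  } else {
    v <- switch(model$name,
      exponential = if (c0 < p[["a"]]) Inf else 0,
      mendelsohn  = {
        if (p[["b"]] == 1) {
          if (c0 < p[["a"]]) Inf else 0
        } else {
          (c0 / p[["a"]])^(1 / (p[["b"]] - 1))
        }
      },
      logistic    = p[["b"]] * (p[["a"]] - c0) / p[["a"]],
      linear      = p[["a"]] / c0 - p[["b"]],
      surface     = (p[["a"]] / c0)^3 - p[["b"]],
      gompertz    = p[["b"]] * exp(-c0 / p[["a"]]) - p[["c"]],
      bertalanffy = (p[["a"]] / (p[["b"]] + c0))^3
    )
  }
  v <- unname(v)
  if (is.finite(v) && v <= 0) {
    return(structure(0, eradicated = TRUE))
  }
  v
}

#' Fixed points of a growth model with stability labels
#'
#' Every model has two fixed points, one of which is V = 0; the other is the
#' maximum tumor size (finite, or the unbounded sentinel `Inf` when no positive
#' finite root exists). Stability is classified numerically by the sign of the
#' right-hand side just below and above each fixed point (offset 1e-4
#' relative); the `Inf` entry is labeled stable when the flow still points
#' outward at large volume.
#'
#' @inheritParams rhs_eval
#' @return A data.frame with columns `volume` and `stability`
#'   ("stable"/"unstable").
#' @examples
#' fixed_points(growth_model("logistic", a = 1, b = 100))
#' @export
fixed_points <- function(model, c0 = 0) {
  stop_if_not_model(model)
  vstar <- as.numeric(max_tumor_size(model, c0 = c0))

  eps_v <- 1e-8
  zero_stab <- if (rhs_eval(model, eps_v, c0 = c0) > 0) "unstable" else "stable"

  if (is.infinite(vstar)) {
    big <- 1e9
    star_stab <- if (rhs_eval(model, big, c0 = c0) > 0) "stable" else "unstable"
  } else if (vstar == 0) {
    # eradicated: the two fixed points coincide at most; report the treated
    # nonzero root collapsed to 0 (stable side)
    star_stab <- "stable"
  } else {
    below <- rhs_eval(model, vstar * (1 - 1e-4), c0 = c0)
    above <- rhs_eval(model, vstar * (1 + 1e-4), c0 = c0)
    star_stab <- if (below > 0 && above < 0) "stable" else "unstable"
  }
  data.frame(
    volume = c(0, vstar),
    stability = c(zero_stab, star_stab),
    stringsAsFactors = FALSE
  )
}

#' Clinical predictions for one fitted or specified model
#'
#' Bundles the clinically relevant quantities for one model: maximum tumor
#' size (untreated and, if `c0 > 0`, under chemotherapy), doubling time, the
#' growth condition, and the minimum chemotherapy concentration needed for
#' suppression.
#'
#' @inheritParams rhs_eval
#' @return An object of class `clinical_predictions` (a list).
#' @export
clinical_predictions <- function(model, c0 = 0) {
  stop_if_not_model(model)
  growing <- growth_condition(model)
  res <- list(
    model = model$name,
    params = model$params,
    growth_condition_met = growing,
    max_size = as.numeric(max_tumor_size(model)),
    doubling_time = if (growing) doubling_time(model) else NA_real_,
    min_cure_concentration = min_cure_concentration(model),
    c0 = c0
  )
  if (c0 > 0) {
    ms <- max_tumor_size(model, c0 = c0)
    res$max_size_treated <- as.numeric(ms)
    res$eradicated <- isTRUE(attr(ms, "eradicated"))
  }
  structure(res, class = "clinical_predictions")
}

#' @export
print.clinical_predictions <- function(x, ...) {
  fmt_v <- function(v) if (is.infinite(v)) "unbounded" else format(signif(v, 5))
  cat("<clinical_predictions> ", x$model, "\n",
      "  growth condition met:   ", x$growth_condition_met, "\n",
      "  maximum size:           ", fmt_v(x$max_size), " mm^3\n",
      "  doubling time:          ", format(signif(x$doubling_time, 5)), " days\n",
      "  min cure concentration: ", format(signif(x$min_cure_concentration, 5)),
      " /day\n", sep = "")
  if (!is.null(x$max_size_treated)) {
    cat("  max size at c0 = ", format(x$c0), ": ", fmt_v(x$max_size_treated),
        " mm^3", if (isTRUE(x$eradicated)) " (eradicated)", "\n", sep = "")
  }
  invisible(x)
}

#' Serialize clinical predictions to a flat record
#'
#' Flattens a [clinical_predictions()] object to a one-row data.frame; the
#' unbounded sentinel is serialized as the string "unbounded".
#'
#' @param x A `clinical_predictions` object.
#' @return One-row data.frame with character-safe columns.
#' @export
as.data.frame.clinical_predictions <- function(x, ...) {
  fmt <- function(v) {
    if (is.null(v) || length(v) == 0) return(NA_character_)
    if (is.infinite(v)) "unbounded" else as.character(v)
  }
  data.frame(
    model = x$model,
    growth_condition_met = x$growth_condition_met,
    max_size = fmt(x$max_size),
    doubling_time = if (is.na(x$doubling_time)) NA_character_ else as.character(x$doubling_time),
    min_cure_concentration = as.character(x$min_cure_concentration),
    c0 = x$c0,
    max_size_treated = fmt(x$max_size_treated),
    stringsAsFactors = FALSE
  )
}
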