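# Shared helpers: independent oracles and seeded random parameter draws.

# Independent re-implementation of the small-sample-corrected AIC, kept as a
# separate code path from compute_aicc() on purpose.
aicc_reference <- function(ssr, n, k) {
  n * log(ssr / n) + (2 * (k + 1) * n) / (n - k - 2)
}

# One random but plausible parameter set per model. Ranges keep the growth
# condition satisfied and the dynamics well-scaled (volumes in mm^3, days).
random_model <- function(name) {
  a <- switch(name,
    exponential = runif(1, 0.02, 0.5),
    mendelsohn  = runif(1, 0.1, 1),
    logistic    = runif(1, 0.05, 0.5),
    linear      = runif(1, 5, 100),
    surface     = runif(1, 0.2, 5),
    gompertz    = runif(1, 0.05, 0.5),
    bertalanffy = runif(1, 0.5, 3)
  )
  switch(name,
    exponential = growth_model("exponential", a = a),
    mendelsohn  = growth_model("mendelsohn", a = a, b = runif(1, 0.3, 0.9)),
    logistic    = growth_model("logistic", a = a, b = runif(1, 500, 10000)),
    linear      = growth_model("linear", a = a, b = runif(1, 50, 2000)),
    surface     = growth_model("surface", a = a, b = runif(1, 50, 2000)),
    gompertz    = {
      cc <- runif(1, 0.5, 20)
      growth_model("gompertz", a = a, b = cc * runif(1, 50, 5000), c = cc)
    },
    bertalanffy = growth_model("bertalanffy", a = a, b = a * runif(1, 0.05, 0.6))
  )
}

# Brute-force oracle: locate the nonzero root of the (treated) RHS by sign
# scanning on a log grid followed by uniroot refinement. Returns NA when no
# positive finite root exists.
root_oracle <- function(model, c0 = 0) {
  f <- function(v) rhs_eval(model, v, c0 = c0)
  grid <- 10^seq(-8, 11, length.out = 4000)
  fv <- vapply(grid, f, numeric(1))
  sgn <- sign(fv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flip) == 0) return(NA_real_)
  i <- flip[1]
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-13)$root
}
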