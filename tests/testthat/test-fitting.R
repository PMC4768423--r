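# SSR, AICc, bounded multistart fitting, model selection, extrapolation.

test_that("SSR is the sum of squared volume residuals", {
  m <- growth_model("logistic", a = 0.15, b = 5000)
  times <- seq(0, 100, length.out = 7)
  truth <- solve_trajectory(m, 10, times)$volumes
  obs <- tumor_series(times, truth)
  expect_lt(compute_ssr(obs, m, v0 = 10), 1e-10)

  shift <- c(1, -2, 3, -1, 2, -3, 1)
  obs2 <- tumor_series(times, truth + shift)
  expect_equal(compute_ssr(obs2, m, v0 = 10), sum(shift^2), tolerance = 1e-6)

  # a diverging parameter region scores +Inf so optimizers reject it
  obs3 <- tumor_series(c(0, 100, 200), c(1e6, 2e6, 3e6))
  expect_identical(compute_ssr(obs3, growth_model("exponential", a = 0.5)), Inf)
})

test_that("AICc matches an independent implementation and hand arithmetic", {
  expect_equal(compute_aicc(ssr = 7, n = 7, k = 1), 7)
  # ln term vanishes whenever ssr = n
  for (n in c(7, 10, 14)) {
    expect_equal(compute_aicc(n, n, 2), 2 * 3 * n / (n - 4))
  }
  set.seed(31)
  for (i in 1:100) {
    ssr <- 10^runif(1, -3, 8)
    n <- sample(6:30, 1)
    k <- sample(1:3, 1)
    expect_equal(compute_aicc(ssr, n, k), aicc_reference(ssr, n, k),
                 tolerance = 1e-12)
  }
  # penalty is monotone in k at equal SSR
  expect_lt(compute_aicc(5, 7, 1), compute_aicc(5, 7, 2))
  expect_warning(out <- compute_aicc(0, 10, 2), "-Inf")
  expect_identical(out, -Inf)
  expect_warning(out <- compute_aicc(3, 5, 3), "undefined")
  expect_true(is.na(out))
})

test_that("fitting is deterministic given the seed", {
  gen <- generate_series(default_truth("logistic"),
                         noise = noise_config(cv = 0.1, seed = 5))
  cfg <- fit_config(n_starts = 8, seed = 99)
  f1 <- fit_model(gen$series, "logistic", cfg)
  f2 <- fit_model(gen$series, "logistic", cfg)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-10)
  expect_identical(f1$ssr, f2$ssr)
})

test_that("noiseless self-fits recover the generating parameters", {
  des <- study_design(spacing = "uniform")
  for (nm in c("exponential", "logistic", "bertalanffy")) {
    truth <- default_truth(nm)
    gen <- generate_series(truth, v0 = 50, design = des,
                           noise = noise_config(cv = 0, seed = 1))
    f <- fit_model(gen$series, nm)
    expect_true(f$converged)
    expect_equal(unname(f$model$params), unname(truth$params),
                 tolerance = 1e-3)
    expect_lt(f$ssr, 1e-6 * sum(gen$series$volume_mm3^2))
  }
})

test_that("series too short for the AICc correction are signalled", {
  s <- tumor_series(c(0, 10, 20), c(10, 30, 90))
  expect_warning(f <- fit_model(s, "gompertz", fit_config(n_starts = 4)),
                 "cannot support AICc")
  expect_true(is.na(f$aicc))
})

test_that("model selection ranks by AICc with ties broken to fewer parameters", {
  mk_fit <- function(name, k, ssr, n = 14) {
    structure(list(model = NULL, name = name, v0 = 50, ssr = ssr,
                   aicc = compute_aicc(ssr, n, k), n = n, k = k,
                   converged = TRUE, n_starts = 1, seed = 1,
                   t_range = c(0, 100)),
              class = "fit_result")
  }
  # equal SSR: the 1-parameter model must win
  sel <- select_model(list(mk_fit("exponential", 1, 100),
                           mk_fit("logistic", 2, 100)))
  expect_identical(sel$best, "exponential")

  # halved SSR at n = 14: decided strictly by the AICc values
  f1 <- mk_fit("exponential", 1, 200)
  f2 <- mk_fit("logistic", 2, 100)
  sel <- select_model(list(f1, f2))
  expect_identical(sel$best,
                   if (f2$aicc < f1$aicc) "logistic" else "exponential")
  expect_lt(f2$aicc, f1$aicc) # 14*ln(1/2) ~ -9.7 beats the +2.9 penalty gap

  # mixed observation counts are not comparable
  expect_error(select_model(list(mk_fit("exponential", 1, 10, n = 7),
                                 mk_fit("logistic", 2, 10, n = 14))),
               "same data")
})

test_that("extrapolation scores held-out points from the fitted trajectory", {
  truth <- default_truth("gompertz")
  gen <- generate_series(truth, v0 = 50, design = study_design(spacing = "uniform"),
                         noise = noise_config(cv = 0, seed = 2))
  parts <- truncate_series(gen$series)
  f <- fit_model(parts$early, "gompertz")
  ssr_pred <- extrapolate_and_score(f, parts$late)
  # noiseless data from the fitted family: near-perfect extrapolation
  expect_lt(as.numeric(ssr_pred), 1e-4 * sum(parts$late$volume_mm3^2))

  # exponential fit to early sigmoidal growth overshoots the held-out points
  fe <- fit_model(parts$early, "exponential")
  ssr_pred_e <- as.numeric(extrapolate_and_score(fe, parts$late))
  expect_gt(ssr_pred_e, 100 * fe$ssr)

  expect_error(extrapolate_and_score(f, parts$early), "later than")
})

test_that("fit configuration round-trips through YAML and JSON", {
  cfg <- list(n_starts = 8, seed = 7, residuals = "relative",
              models = c("logistic", "gompertz"))
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  got <- read_fit_config(yml)
  expect_identical(got$n_starts, 8L)
  expect_identical(got$seed, 7L)
  expect_identical(got$residuals, "relative")
  expect_identical(attr(got, "models"), c("logistic", "gompertz"))

  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(c(cfg[1:2], list(unknown_field = 1)), jsn, auto_unbox = TRUE)
  expect_warning(got2 <- read_fit_config(jsn), "unknown config fields")
  expect_identical(got2$n_starts, 8L)
})
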