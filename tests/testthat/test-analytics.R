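# Fixed points, clinical formulas, and their numeric verification oracles.

test_that("every model has two fixed points, zero among them", {
  set.seed(21)
  for (nm in growth_model_names()) {
    for (i in 1:5) {
      fp <- fixed_points(random_model(nm))
      expect_identical(nrow(fp), 2L)
      expect_identical(fp$volume[1], 0)
      expect_identical(fp$stability[1], "unstable") # growth condition holds
    }
  }
})

test_that("documented fixed-point examples", {
  fp <- fixed_points(growth_model("logistic", a = 1, b = 100))
  expect_equal(fp$volume, c(0, 100))
  expect_equal(fp$stability, c("unstable", "stable"))

  fp <- fixed_points(growth_model("bertalanffy", a = 2, b = 1))
  expect_equal(fp$volume, c(0, 8))
  expect_equal(fp$stability[2], "stable")

  # surface under chemotherapy: aV/(V+b)^(1/3) = c0 V at V = (a/c0)^3 - b
  fp <- fixed_points(growth_model("surface", a = 1, b = 8), c0 = 0.25)
  expect_equal(fp$volume, c(0, 56))
})

test_that("untreated maximum size: unbounded for exactly four models", {
  set.seed(22)
  ms <- vapply(growth_model_names(),
               function(nm) as.numeric(max_tumor_size(random_model(nm))),
               numeric(1))
  expect_identical(names(which(is.infinite(ms))),
                   c("exponential", "mendelsohn", "linear", "surface"))
  expect_equal(as.numeric(max_tumor_size(growth_model("gompertz", 1, 10, 1))), 9)
  expect_equal(as.numeric(max_tumor_size(growth_model("logistic", 1, 100))), 100)
  expect_equal(as.numeric(max_tumor_size(growth_model("bertalanffy", 2, 1))), 8)
})

test_that("treated maximum size follows the chemotherapy fixed points", {
  expect_equal(as.numeric(max_tumor_size(growth_model("linear", a = 10, b = 2),
                                         c0 = 1)), 8)
  # logistic at the cure boundary c0 = a is eradicated
  ms <- max_tumor_size(growth_model("logistic", a = 1, b = 100), c0 = 1)
  expect_equal(as.numeric(ms), 0)
  expect_true(attr(ms, "eradicated"))
  # under any positive dose only the exponential model stays unbounded
  set.seed(23)
  for (i in 1:5) {
    ms <- vapply(growth_model_names(), function(nm) {
      m <- random_model(nm)
      as.numeric(max_tumor_size(m, c0 = 0.5 * initial_growth_rate(m)))
    }, numeric(1))
    expect_identical(names(which(is.infinite(ms))), "exponential")
  }
})

test_that("finite treated fixed points agree with numeric root-finding", {
  set.seed(24)
  for (nm in growth_model_names()) {
    for (i in 1:20) {
      m <- random_model(nm)
      c0 <- runif(1, 0.1, 0.9) * initial_growth_rate(m)
      v_formula <- as.numeric(max_tumor_size(m, c0 = c0))
      if (!is.finite(v_formula) || v_formula == 0) next
      v_root <- root_oracle(m, c0 = c0)
      expect_equal(v_formula, v_root, tolerance = 1e-9)
    }
    # untreated finite roots too
    m <- random_model(nm)
    v_formula <- as.numeric(max_tumor_size(m))
    if (is.finite(v_formula)) {
      expect_equal(v_formula, root_oracle(m), tolerance = 1e-9)
    }
  }
})

test_that("treated formulas reduce to the untreated column as c0 vanishes", {
  set.seed(25)
  for (nm in c("logistic", "gompertz", "bertalanffy", "mendelsohn")) {
    m <- random_model(nm)
    v0 <- as.numeric(max_tumor_size(m))
    v_eps <- as.numeric(max_tumor_size(m, c0 = 1e-9))
    if (is.finite(v0)) {
      expect_equal(v_eps, v0, tolerance = 1e-4)
    } else {
      # mendelsohn: the treated root runs away as c0 -> 0
      expect_gt(v_eps, 1e6)
    }
  }
})

test_that("doubling time, growth condition and cure threshold share lambda", {
  expect_equal(doubling_time(growth_model("exponential", a = log(2))), 1)
  expect_equal(doubling_time(growth_model("gompertz", a = 1, b = exp(1), c = 1)),
               log(2))
  expect_equal(doubling_time(growth_model("linear", a = 2, b = 4)), 2 * log(2))
  expect_equal(doubling_time(growth_model("surface", a = 1, b = 8)),
               2 * log(2))
  expect_equal(min_cure_concentration(growth_model("logistic", a = 0.5, b = 77)),
               0.5)
  expect_equal(min_cure_concentration(growth_model("surface", a = 1, b = 8)), 0.5)

  # bertalanffy with a < b: no growth, no doubling time, no drug needed
  m <- growth_model("bertalanffy", a = 1, b = 2)
  expect_false(growth_condition(m))
  expect_error(doubling_time(m), "growth condition")
  expect_equal(min_cure_concentration(m), 0)

  # lambda recovered from DT equals the cure threshold for every model
  set.seed(26)
  for (nm in growth_model_names()) {
    m <- random_model(nm)
    expect_true(growth_condition(m))
    expect_equal(log(2) / doubling_time(m), min_cure_concentration(m))
  }
})

test_that("cure threshold brackets decay versus growth", {
  # For models whose growth law is linearizable at V = 0, a dose 1% above the
  # threshold drives a small tumor to below half its size and a dose 1% below
  # lets it more than double.
  regular <- c("exponential", "logistic", "linear", "surface", "gompertz")
  set.seed(27)
  for (nm in regular) {
    for (i in 1:3) {
      m <- random_model(nm)
      lam <- initial_growth_rate(m)
      v0 <- 1e-3
      horizon <- 600 / lam
      times <- seq(0, horizon, length.out = 50)
      hi <- solve_trajectory(m, v0, times, c0 = 1.01 * lam)
      expect_lt(hi$volumes[50], v0 / 2)
      lo <- solve_trajectory(m, v0, times, c0 = 0.99 * lam)
      expect_gt(lo$volumes[50], 2 * v0)
    }
  }
  # Fractional-power laws (mendelsohn b < 1, bertalanffy): V = 0 is never
  # strictly attracting, and the threshold marks where the treated equilibrium
  # crosses unit volume instead.
  for (nm in c("mendelsohn", "bertalanffy")) {
    m <- default_truth(nm)
    lam <- initial_growth_rate(m)
    times <- seq(0, 600 / lam, length.out = 50)
    hi <- solve_trajectory(m, 5, times, c0 = 1.01 * lam)
    expect_lt(hi$volumes[50], 1)
    lo <- solve_trajectory(m, 5, times, c0 = 0.99 * lam)
    expect_gt(lo$volumes[50], 1)
  }
})

test_that("clinical predictions serialize with an explicit unbounded sentinel", {
  cp <- clinical_predictions(growth_model("linear", a = 10, b = 100), c0 = 0.05)
  df <- as.data.frame(cp)
  expect_identical(df$max_size, "unbounded")
  expect_equal(as.numeric(df$max_size_treated), 10 / 0.05 - 100)
  cp2 <- clinical_predictions(default_truth("gompertz"))
  expect_equal(as.numeric(as.data.frame(cp2)$max_size), 7999)
})
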