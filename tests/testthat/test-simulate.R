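test_that("no dynamics leaves the initial profile unchanged", {
  dom <- pop_domain(0, 10, 5, 50, 20)
  zero <- function(s, N) rep(0, length(s))
  model <- vital_rates(g = zero, f = function(s, n, N) 0 * n, beta = zero)
  ic <- function(s) exp(-(s - 4)^2)
  fld <- simulate_population(model, dom, ic)
  for (i in seq_len(dom$n_snapshots)) {
    expect_equal(fld$values[i, ], fld$values[1, ], tolerance = 1e-14)
  }
  expect_equal(fld$values[1, ], ic(cell_midpoints(dom)), tolerance = 1e-12)
})

test_that("constant-birth constant-death balance gives exponential growth", {
  # g=1, f=-0.3n, beta=0.4 with support away from the outflow boundary:
  # dN/dt = (0.4 - 0.3) N, so N(t) = N(0) exp(0.1 t)
  ef <- example_field("L.1")
  N <- total_population(ef$field)
  tt <- ef$field$times
  expect_lt(max(abs(N / (N[1] * exp(0.1 * tt)) - 1)), 1e-4)
  expect_equal(N[1], 1, tolerance = 1e-12)  # ic normalised to unit mass
})

test_that("total population of trivial fields", {
  dom <- pop_domain(0, 15, 1, 30, 5)
  zero_fld <- population_field(matrix(0, 5, 30), dom)
  expect_equal(total_population(zero_fld), rep(0, 5))
  const_fld <- population_field(matrix(2, 5, 30), dom)
  expect_equal(total_population(const_fld), rep(30, 5), tolerance = 1e-12)
})

test_that("pure transport with speed vanishing at both boundaries conserves mass", {
  model <- vital_rates(
    g = function(s, N) s * (3 - s) / 3,
    f = function(s, n, N) 0 * n,
    beta = function(s, N) rep(0, length(s))
  )
  dom <- pop_domain(0, 3, 4, 150, 30)
  fld <- simulate_population(model, dom, gaussian_bump_ic(1, 0.3, mass = 1))
  N <- total_population(fld)
  expect_lt(max(abs(N - N[1])), 1e-12)
})

test_that("solver output stays nonnegative on all preset examples", {
  for (ex in c("L.1", "L.2", "L.3", "L.4")) {
    ef <- example_field(ex)
    expect_gte(min(ef$field$values), 0)
  }
})

test_that("discrete mass budget closes to time-integration accuracy", {
  # d/dt N = B(t) + int f ds - outflow; support well inside, so outflow = 0
  ef <- example_field("L.2")
  fld <- ef$field
  m <- ef$m
  ds <- cell_width(fld$domain)
  ss <- cell_midpoints(fld$domain)
  N <- total_population(fld)
  rhs <- vapply(seq_along(fld$times), function(i) {
    n <- fld$values[i, ]
    B <- ds * sum(m$model$beta(ss, N[i]) * n)
    B + ds * sum(m$model$f(ss, n, N[i]))
  }, numeric(1))
  dt <- diff(fld$times)[1]
  i <- 2:(length(N) - 1)
  dNdt <- (N[i + 1] - N[i - 1]) / (2 * dt)
  expect_lt(max(abs(dNdt - rhs[i])) / max(abs(rhs)), 5e-4)
})

test_that("self-convergence order is at least 1.5 on smooth solutions", {
  model <- vital_rates(
    g = function(s, N) rep(1, length(s)),
    f = function(s, n, N) -0.3 * n,
    beta = function(s, N) rep(0, length(s))
  )
  ic <- gaussian_bump_ic(3, 0.8, mass = 1)
  ref <- simulate_population(model, pop_domain(0, 15, 10, 1600, 21), ic)
  errs <- vapply(c(200, 400), function(nc) {
    f <- simulate_population(model, pop_domain(0, 15, 10, nc, 21), ic)
    refc <- coarsen_bins(ref, nc)
    sqrt(mean((f$values - refc$values)^2)) / sqrt(mean(refc$values^2))
  }, numeric(1))
  expect_gte(log2(errs[1] / errs[2]), 1.5)
})

test_that("preset example models evaluate to their defining formulas", {
  nl1 <- example_model("NL.1", n_cells = 10, n_snapshots = 5)
  expect_equal(nl1$model$f(1, 2, 3), -0.6 * 3 * 2)
  l3 <- example_model("L.3", n_cells = 10, n_snapshots = 5)
  s <- c(0, 1.5, 3)
  expect_equal(l3$model$g(s, 1), 0.2 * (3 - s))
  expect_equal(l3$model$beta(s, 1), 1 / (1 + exp(-2 * (s - 1))))
  l2 <- example_model("L.2", n_cells = 10, n_snapshots = 5)
  expect_equal(l2$model$beta(10, 1), 1)      # Gaussian peak at s = 10
  expect_equal(l2$model$f(2, 3, 1), -0.1 * exp(0.16) * 3)
  l4 <- example_model("L.4", n_cells = 10, n_snapshots = 5)
  expect_equal(l4$domain$s_min, 1)
  expect_equal(l4$domain$s_max, 4)
  expect_error(example_model("L.9"), "unknown")
})

test_that("true weight vectors sit on the correct library columns", {
  for (ex in c("L.1", "L.2", "L.3", "L.4", "NL.1", "NL.2")) {
    m <- example_model(ex, n_cells = 10, n_snapshots = 5)
    lib <- preset_library(ex)
    expect_identical(names(m$w_true), lib$names)
    expect_gt(sum(m$w_true != 0), 2)
  }
  m <- example_model("L.3", n_cells = 10, n_snapshots = 5)
  expect_equal(unname(m$w_true[c("g:s^0", "g:s^1")]), c(0.6, -0.2))
  expect_equal(unname(m$w_true["f:s^1"]), -0.3)
})
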