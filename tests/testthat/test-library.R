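test_that("term evaluation honours family shapes and the n/N factors", {
  s <- seq(0, 15, by = 0.5)
  ones <- library_term("g:1", "transport", function(x) x^0)
  expect_equal(evaluate_term(ones, s, N_values = c(1, 2)),
               matrix(1, 2, length(s)))
  gauss <- library_term("b:g", "boundary", function(x) exp(-(x - 10)^2 / 50))
  n <- matrix(1, 3, length(s))
  out <- evaluate_term(gauss, s, n, N_values = c(1, 1, 1))
  expect_equal(out[, s == 10], rep(1, 3))       # peak value regardless of t
  sig <- library_term("b:s", "boundary", function(x) 1 / (1 + exp(-2 * (x - 1))))
  expect_equal(evaluate_term(sig, 1, matrix(1, 1, 1), 1)[1, 1], 0.5)
  # source terms multiply the density
  f1 <- library_term("f:n", "source", function(x) x^0)
  nm <- matrix(seq_len(6), 2, 3)
  expect_equal(evaluate_term(f1, 1:3, nm, c(1, 1)), nm)
  # N factor scales rows (time) not columns
  fn <- library_term("f:nN", "source", function(x) x^0, function(N) N)
  expect_equal(evaluate_term(fn, 1:3, nm, c(1, 2)), nm * c(1, 2))
})

test_that("preset libraries match their published construction", {
  l1 <- preset_library("L.1")
  expect_length(l1$names, 3 + 4 + 4)
  l2 <- preset_library("L.2")
  rates <- vapply(l2$source, function(tm) log(tm$s_factor(1)), numeric(1))
  expect_equal(rates, 0.08 * (4 * (0:4) + 1))
  # boundary Gaussians peak at 5, 10, 15
  peaks <- vapply(l2$boundary, function(tm) {
    s <- seq(0, 15, by = 0.01)
    s[which.max(tm$s_factor(s))]
  }, numeric(1))
  expect_equal(peaks, c(5, 10, 15))
  l3 <- preset_library("L.3")
  # sigmoid centres 1..4 (value 1/2 at the centre)
  for (k in 1:4) expect_equal(l3$boundary[[k]]$s_factor(k), 0.5)
  l4 <- preset_library("L.4")
  expect_equal(vapply(l4$source, function(tm) log(tm$s_factor(1)), numeric(1)),
               0.2 + 0.5 * (0:3))
  expect_error(preset_library("X"), "unknown")
})

test_that("nonlinear presets tensor structural terms with population factors", {
  nl1 <- preset_library("NL.1")
  expect_length(nl1$transport, 3 * 4)
  expect_true("f:s^0*N" %in% nl1$names)
  expect_true("b:s^0*exp(-0.25N)" %in% nl1$names)
  tm <- nl1$source[[which(nl1$names == "f:s^0*N") - length(nl1$transport)]]
  expect_equal(tm$N_factor(c(1, 3)), c(1, 3))
})

test_that("distinguishability libraries bracket the true ingredient", {
  lib <- distinguishability_library("source", delta = 0.04, k = 1)
  rates <- vapply(lib$source, function(tm) log(tm$s_factor(1)), numeric(1))
  expect_equal(rates, c(0.04, 0.08, 0.12))
  expect_length(lib$boundary, 1)
  libb <- distinguishability_library("boundary", delta = 1, k = 2)
  expect_length(libb$boundary, 2 * 2 + 1)
  mus <- vapply(libb$boundary, function(tm) {
    s <- seq(0, 15, by = 0.01)
    s[which.max(tm$s_factor(s))]
  }, numeric(1))
  expect_equal(mus, 8:12)
  # true term at i = 0 equals the true ingredient
  mid <- libb$boundary[[3]]
  s <- seq(0, 15, by = 0.5)
  expect_equal(mid$s_factor(s), exp(-(s - 10)^2 / 50))
})

test_that("condition number agrees with an eigenvalue oracle and flags rank loss", {
  expect_equal(library_condition_number(diag(4))$kappa, 1)
  expect_equal(library_condition_number(cbind(1:3, 1:3))$kappa, Inf)
  withr::with_seed(8, {
    for (rep in 1:5) {
      G <- matrix(rnorm(2000), 200, 10)
      kap <- library_condition_number(G)$kappa_raw
      ev <- eigen(crossprod(G), symmetric = TRUE, only.values = TRUE)$values
      expect_equal(kap, sqrt(max(ev) / min(ev)), tolerance = 1e-6)
    }
  })
})

test_that("library order and names survive serialisation", {
  lib <- preset_library("L.2")
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(lib, path)
  lib2 <- readRDS(path)
  expect_identical(lib2$names, lib$names)
  s <- seq(0, 15, by = 1)
  expect_equal(lib2$source[[3]]$s_factor(s), lib$source[[3]]$s_factor(s))
})
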