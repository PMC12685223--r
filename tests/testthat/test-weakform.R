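test_that("bump test functions are normalised with compact support", {
  phi <- test_function_1d(0, 1, p = 14, q = 14)
  expect_equal(phi$value(0.5), 1)
  expect_equal(phi$value(c(0, 1, -0.2, 1.3)), rep(0, 4))
  # asymmetric exponents peak at (p*b + q*a) / (p + q)
  psi <- test_function_1d(2, 6, p = 3, q = 5)
  x_star <- (3 * 6 + 5 * 2) / 8
  xs <- seq(2, 6, by = 1e-4)
  expect_equal(xs[which.max(psi$value(xs))], x_star, tolerance = 1e-3)
  expect_equal(max(psi$value(xs)), 1, tolerance = 1e-8)
})

test_that("bump derivative integrates to zero and matches finite differences", {
  phi <- test_function_1d(1, 4, p = 14, q = 14)
  xs <- seq(1, 4, length.out = 4001)
  w <- c(0.5, rep(1, 3999), 0.5) * diff(xs)[1]
  expect_lt(abs(sum(w * phi$deriv(xs))), 1e-12)
  h <- 1e-6
  mid <- seq(1.2, 3.8, by = 0.2)
  fd <- (phi$value(mid + h) - phi$value(mid - h)) / (2 * h)
  expect_equal(phi$deriv(mid), fd, tolerance = 1e-7)
})

test_that("trapezoid integral of the bump matches the Beta closed form", {
  a <- 0; b <- 1; p <- 14; q <- 14
  phi <- test_function_1d(a, b, p = p, q = q)
  x_star <- (p * b + q * a) / (p + q)
  C <- 1 / ((x_star - a)^p * (b - x_star)^q)
  exact <- C * (b - a)^(p + q + 1) * beta(p + 1, q + 1)
  xs <- seq(a, b, length.out = 2000)
  w <- c(0.5, rep(1, 1998), 0.5) * diff(xs)[1]
  expect_equal(sum(w * phi$value(xs)), exact, tolerance = 1e-12)
})

test_that("basis supports cover the requested fractions inside the open domain", {
  dom <- pop_domain(0, 15, 10, 100, 50)
  basis <- build_test_basis(dom, r_t = 0.5, r_s = 0.4,
                            n_centers_t = 5, n_centers_s = 7, ode_centers = 4)
  for (f in basis$time_functions) {
    expect_equal(f$b - f$a, 5)
    expect_gt(f$a, 0); expect_lt(f$b, 10)
  }
  for (f in basis$space_functions) {
    expect_equal(f$b - f$a, 6)
    expect_gt(f$a, 0); expect_lt(f$b, 15)
  }
  expect_equal(nrow(basis$pde_pairs), 35)
  expect_length(basis$ode_functions, 4)
  expect_error(build_test_basis(dom, r_t = 1.2), "r_t")
})

test_that("weak PDE entries vanish on constant data as required by calculus", {
  dom <- pop_domain(0, 15, 10, 200, 80)
  fld <- population_field(matrix(3, 80, 200), dom)
  basis <- build_test_basis(dom, n_centers_t = 4, n_centers_s = 4,
                            ode_centers = 4)
  pde <- assemble_pde_system(fld, NULL, plain_library(), basis)
  scale <- max(abs(pde$G_f))
  expect_lt(max(abs(pde$b_pde)), 1e-12 * scale)   # dt(phi) vs time-constant
  expect_lt(max(abs(pde$G_g)), 1e-12 * scale)     # ds(psi) vs space-constant
  ode <- assemble_ode_system(fld, NULL, plain_library(), basis)
  expect_lt(max(abs(ode$b_ode)), 1e-12 * max(abs(ode$Xi_f)))  # N constant
})

test_that("assembled entries match an independent high-order quadrature oracle", {
  fld <- manufactured_field()
  dom <- fld$domain
  basis <- build_test_basis(dom, n_centers_t = 3, n_centers_s = 4,
                            ode_centers = 3)
  lib <- plain_library()
  pde <- assemble_pde_system(fld, NULL, lib, basis)
  ode <- assemble_ode_system(fld, NULL, lib, basis)
  worst <- 0
  for (k in seq_len(nrow(basis$pde_pairs))) {
    phi <- basis$time_functions[[basis$pde_pairs$ti[k]]]
    psi <- basis$space_functions[[basis$pde_pairs$si[k]]]
    o_b <- -gl_quad2d(function(t, s) phi$deriv(t) * psi$value(s) *
                        manufactured_fun(t, s),
                      phi$a, phi$b, psi$a, psi$b)
    o_gg <- gl_quad2d(function(t, s) phi$value(t) * psi$deriv(s) *
                        manufactured_fun(t, s),
                      phi$a, phi$b, psi$a, psi$b)
    o_gf <- gl_quad2d(function(t, s) phi$value(t) * psi$value(s) *
                        manufactured_fun(t, s),
                      phi$a, phi$b, psi$a, psi$b)
    worst <- max(worst,
                 abs(pde$b_pde[k] - o_b) / abs(o_b),
                 abs(pde$G_g[k, 1] - o_gg) / abs(o_gg),
                 abs(pde$G_f[k, 1] - o_gf) / abs(o_gf))
  }
  # N(t) for the manufactured profile, via 1-D quadrature in s
  Nfun <- function(t) {
    vapply(t, function(ti) {
      gl_quad1d(function(s) manufactured_fun(ti, s), 0, 15)
    }, numeric(1))
  }
  for (k in seq_along(basis$ode_functions)) {
    phk <- basis$ode_functions[[k]]
    o_bode <- -gl_quad1d(function(t) phk$deriv(t) * Nfun(t), phk$a, phk$b)
    o_xif <- gl_quad1d(function(t) phk$value(t) * Nfun(t), phk$a, phk$b)
    worst <- max(worst,
                 abs(ode$b_ode[k] - o_bode) / abs(o_bode),
                 abs(ode$Xi_f[k, 1] - o_xif) / abs(o_xif),
                 abs(ode$Xi_b[k, 1] - o_xif) / abs(o_xif))
  }
  expect_lt(worst, 1e-8)
})

test_that("assembly is linear in the data", {
  fld <- manufactured_field(200, 80)
  dom <- fld$domain
  basis <- build_test_basis(dom, n_centers_t = 3, n_centers_s = 3,
                            ode_centers = 3)
  lib <- plain_library()
  fld2 <- population_field(2.5 * fld$values + 1, dom)
  fld_sum <- population_field(fld$values + fld2$values, dom)
  b1 <- assemble_pde_system(fld, NULL, lib, basis)$b_pde
  b2 <- assemble_pde_system(fld2, NULL, lib, basis)$b_pde
  bs <- assemble_pde_system(fld_sum, NULL, lib, basis)$b_pde
  expect_equal(bs, b1 + b2, tolerance = 1e-12)
})

test_that("stacked system has the block zero pattern and shared source column", {
  fld <- manufactured_field(200, 80)
  basis <- build_test_basis(fld$domain, n_centers_t = 2, n_centers_s = 1,
                            ode_centers = 1)
  sys <- assemble_weak_system(fld, NULL, plain_library(), basis)
  K <- sys$n_pde
  expect_equal(dim(sys$G), c(K + 1, 3))
  expect_equal(sys$G[seq_len(K), 3], rep(0, K))       # boundary absent in PDE
  expect_equal(sys$G[K + 1, 1], 0)                    # transport absent in ODE
  expect_identical(sys$column_labels, c("g:1", "f:n", "b:1"))
  # for the unit source and boundary terms both ODE columns integrate phi * N
  expect_equal(sys$G[K + 1, 2], sys$G[K + 1, 3], tolerance = 1e-12)
})

test_that("known transport moves its column onto the left-hand side exactly", {
  fld <- manufactured_field(200, 80)
  basis <- build_test_basis(fld$domain, n_centers_t = 3, n_centers_s = 3,
                            ode_centers = 3)
  lib <- plain_library()
  free <- assemble_pde_system(fld, NULL, lib, basis)
  known <- assemble_pde_system(fld, NULL, lib, basis,
                               known_transport = function(s) rep(1, length(s)))
  expect_equal(ncol(known$G_g), 0)
  expect_equal(known$b_pde, free$b_pde - free$G_g[, 1], tolerance = 1e-12)
})

test_that("true weights give a small stacked residual on clean benchmark data", {
  ef <- example_field("L.1")
  basis <- build_test_basis(ef$field$domain)
  sys <- assemble_weak_system(ef$field, NULL, preset_library("L.1"), basis)
  expect_lt(relative_residual(sys, unname(ef$m$w_true)), 1e-3)
})

test_that("permuting library columns permutes the fit consistently", {
  ef <- example_field("L.1")
  lib <- preset_library("L.1")
  lib_perm <- term_library(
    transport = lib$transport[c(2, 1, 3)],
    source = lib$source[c(4, 3, 2, 1)],
    boundary = lib$boundary
  )
  basis <- build_test_basis(ef$field$domain, n_centers_t = 6, n_centers_s = 6,
                            ode_centers = 6)
  sys <- assemble_weak_system(ef$field, NULL, lib, basis)
  sys_p <- assemble_weak_system(ef$field, NULL, lib_perm, basis)
  w <- unname(ef$m$w_true)
  w_p <- w[c(2, 1, 3, 7, 6, 5, 4, 8:11)]
  expect_equal(relative_residual(sys, w), relative_residual(sys_p, w_p),
               tolerance = 1e-12)
})
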