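# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# moderate-resolution clean simulations of the preset examples
example_field <- function(name, n_cells = 400, n_snapshots = 120) {
  cached(sprintf("%s-%d-%d", name, n_cells, n_snapshots), {
    m <- example_model(name, n_cells = n_cells, n_snapshots = n_snapshots)
    list(m = m, field = simulate_population(m$model, m$domain, m$ic))
  })
}

# tensor Gauss-Legendre quadrature: the independent oracle for weak-form
# integrals (nodes and weights unrelated to the data grid)
gl_quad2d <- function(f2, a1, b1, a2, b2, n = 120) {
  gt <- pracma::gaussLegendre(n, a1, b1)
  gs <- pracma::gaussLegendre(n, a2, b2)
  sum(outer(gt$w, gs$w) * outer(gt$x, gs$x, f2))
}

gl_quad1d <- function(f1, a, b, n = 160) {
  g <- pracma::gaussLegendre(n, a, b)
  sum(g$w * f1(g$x))
}

# smooth manufactured density (asymmetric so no weak-form entry degenerates)
manufactured_fun <- function(t, s) {
  exp(-t) * sin(pi * s / 15)^2 * (1 + s / 30)
}

manufactured_field <- function(n_cells = 600, n_snapshots = 300) {
  cached(sprintf("manufactured-%d-%d", n_cells, n_snapshots), {
    dom <- pop_domain(0, 15, 10, n_cells, n_snapshots)
    population_field(
      outer(snapshot_times(dom), cell_midpoints(dom), manufactured_fun), dom
    )
  })
}

# minimal one-term-per-role library on [0, 15]
plain_library <- function() {
  term_library(
    transport = list(library_term("g:1", "transport",
                                  function(s) rep(1, length(s)))),
    source = list(library_term("f:n", "source",
                               function(s) rep(1, length(s)))),
    boundary = list(library_term("b:1", "boundary",
                                 function(s) rep(1, length(s))))
  )
}

# noisy L.2 fit exhibiting stacked/ODE boundary-support disagreement that the
# bagging step resolves to the true (ODE-consistent) boundary term
bagging_case <- function() {
  cached("bagging-case", {
    ef <- example_field("L.2", 400, 100)
    noisy <- apply_lognormal_noise(
      ef$field, noise_spec(sigma_nr = 0.25, seed = 4)
    )
    list(
      fit = wsindy_fit_field(noisy, preset_library("L.2"), t_test = 5),
      w_true = ef$m$w_true
    )
  })
}

# random sparse regression problem with known support
random_sparse_system <- function(n = 100, m = 8, k = 2, snr = 100) {
  G <- matrix(stats::rnorm(n * m), n, m)
  supp <- sample.int(m, k)
  w <- numeric(m)
  w[supp] <- sample(c(-1, 1), k, TRUE) * stats::runif(k, 0.5, 2)
  signal <- as.vector(G %*% w)
  noise <- stats::rnorm(n)
  noise <- noise * sqrt(sum(signal^2)) / (snr * sqrt(sum(noise^2)))
  list(G = G, b = signal + noise, w = w, supp = sort(supp))
}

# exhaustive oracle for the sparsity-penalised regression: for every lambda
# on the grid the best-subset minimiser of ||b - Gw||_2 + lambda * |supp| is
# found by enumeration, and lambda is then selected with the same normalised
# selection loss as the sequential-thresholding path; returns that support
exhaustive_l0_support <- function(G, b, lambdas = default_lambda_grid()) {
  m <- ncol(G)
  w_ls <- qr.coef(qr(G), b)
  Gw_ls <- as.vector(G %*% w_ls)
  nGw <- sqrt(sum(Gw_ls^2))
  subsets <- vector("list", 2^m)
  subsets[[1]] <- list(supp = integer(0), resid = sqrt(sum(b^2)),
                       dist = 1, size = 0L)
  for (code in seq_len(2^m - 1)) {
    supp <- which(bitwAnd(code, bitwShiftL(1, seq_len(m) - 1)) != 0)
    A <- G[, supp, drop = FALSE]
    w <- qr.coef(qr(A), b)
    w[is.na(w)] <- 0
    Gw <- as.vector(A %*% w)
    subsets[[code + 1]] <- list(
      supp = supp,
      resid = sqrt(sum((b - Gw)^2)),
      dist = sqrt(sum((Gw - Gw_ls)^2)) / nGw,
      size = length(supp)
    )
  }
  resids <- vapply(subsets, `[[`, 0, "resid")
  sizes <- vapply(subsets, `[[`, 0L, "size")
  dists <- vapply(subsets, `[[`, 0, "dist")
  best_loss <- Inf
  best_supp <- integer(0)
  for (lam in lambdas) {
    i <- which.min(resids + lam * sizes)
    loss <- dists[i] + sizes[i] / m
    if (loss < best_loss - 1e-12) {
      best_loss <- loss
      best_supp <- subsets[[i]]$supp
    }
  }
  best_supp
}
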