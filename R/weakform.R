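#' Piecewise-polynomial compactly supported test function
#'
#' The bump \eqn{\phi(t) = C (t - a)^p (b - t)^q} on \eqn{(a, b)}, zero
#' outside, with \eqn{C} chosen so the maximum value is 1 (attained at
#' \eqn{(p b + q a)/(p + q)}). With \eqn{p, q \ge 2} the first derivative
#' also vanishes at the endpoints, so integration by parts in the weak form
#' produces no boundary terms.
#'
#' @param a,b Support endpoints (`a < b`).
#' @param p,q Left/right exponents (>= 2).
#' @return An object of class `test_function_1d` with evaluator elements
#'   `value(x)` and `deriv(x)`.
#' @export
test_function_1d <- function(a, b, p = 14, q = 14) {
  stopifnot(a < b, p >= 2, q >= 2)
  x_star <- (p * b + q * a) / (p + q)
  logC <- -(p * log(x_star - a) + q * log(b - x_star))
  value <- function(x) {
    inside <- x > a & x < b
    out <- numeric(length(x))
    xi <- x[inside]
    out[inside] <- exp(logC + p * log(xi - a) + q * log(b - xi))
    out
  }
  deriv <- function(x) {
    inside <- x > a & x < b
    out <- numeric(length(x))
    xi <- x[inside]
    out[inside] <- exp(logC + (p - 1) * log(xi - a) + (q - 1) * log(b - xi)) *
      (p * (b - xi) - q * (xi - a))
    out
  }
  structure(
    list(a = a, b = b, p = p, q = q, value = value, deriv = deriv),
    class = "test_function_1d"
  )
}

#' Separable test-function basis for the weak systems
#'
#' Builds the tensor-product basis \eqn{\phi_k(t, s) = \varphi_i(t)
#' \psi_j(s)} used for the PDE block and the time-only family used for the
#' total-population ODE block. Supports cover the fractions `r_t` (of the
#' time horizon) and `r_s` (of the structural domain), with centres uniformly
#' spaced so every support lies inside the open domain.
#'
#' @param domain A [pop_domain()].
#' @param p,q Bump exponents.
#' @param r_t,r_s Support fractions in (0, 1).
#' @param n_centers_t,n_centers_s Numbers of time/space centres; the PDE
#'   block has `n_centers_t * n_centers_s` rows.
#' @param ode_centers Number of time-only test functions for the ODE block.
#' @return An object of class `test_basis`.
#' @export
build_test_basis <- function(domain, p = 14, q = 14, r_t = 0.5, r_s = 0.5,
                             n_centers_t = 20, n_centers_s = 20,
                             ode_centers = 40) {
  stopifnot(inherits(domain, "pop_domain"),
            r_t > 0, r_t < 1, r_s > 0, r_s < 1,
            n_centers_t >= 1, n_centers_s >= 1, ode_centers >= 1)
  len_t <- r_t * domain$T
  len_s <- r_s * (domain$s_max - domain$s_min)
  make_family <- function(lo, hi, len, n) {
    margin <- 1e-9 * (hi - lo)
    c_lo <- lo + len / 2 + margin
    c_hi <- hi - len / 2 - margin
    centers <- if (n == 1) (c_lo + c_hi) / 2 else seq(c_lo, c_hi, length.out = n)
    lapply(centers, function(cc) {
      test_function_1d(cc - len / 2, cc + len / 2, p = p, q = q)
    })
  }
  time_functions <- make_family(0, domain$T, len_t, n_centers_t)
  space_functions <- make_family(domain$s_min, domain$s_max, len_s, n_centers_s)
  ode_functions <- make_family(0, domain$T, len_t, ode_centers)
  pde_pairs <- expand.grid(
    ti = seq_len(n_centers_t), si = seq_len(n_centers_s)
  )
  structure(
    list(
      time_functions = time_functions, space_functions = space_functions,
      ode_functions = ode_functions,
      pde_pairs = pde_pairs,
      p = p, q = q, r_t = r_t, r_s = r_s
    ),
    class = "test_basis"
  )
}

#' @export
print.test_basis <- function(x, ...) {
  cat(sprintf(
    "<test_basis> p=%g q=%g r_t=%g r_s=%g: %d PDE rows (%d x %d), %d ODE rows\n",
    x$p, x$q, x$r_t, x$r_s, nrow(x$pde_pairs),
    length(x$time_functions), length(x$space_functions),
    length(x$ode_functions)
  ))
  invisible(x)
}

# evaluate a family of test functions (and derivatives) at nodes, already
# multiplied by quadrature weights: columns are test functions
family_matrix <- function(fns, nodes, weights, deriv = FALSE) {
  sapply(fns, function(f) (if (deriv) f$deriv else f$value)(nodes)) * weights
}

# trapezoid weights on a (uniform) node vector
trapezoid_weights <- function(nodes) {
  n <- length(nodes)
  h <- diff(nodes)
  w <- numeric(n)
  w[1] <- h[1] / 2
  w[n] <- h[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (h[-1] + h[-(n - 1)]) / 2
  w
}

#' Assemble the weak-form PDE linear system
#'
#' Computes the PDE block of the stacked regression system: for each product
#' test function \eqn{\phi_k} and library column,
#' \deqn{b^{pde}_k = -\langle \partial_t \phi_k, n \rangle, \quad
#'       G^g_{k,m} = \langle \partial_s \phi_k, g_m(\cdot, N)\, n \rangle,
#'       \quad G^f_{k,m} = \langle \phi_k, f_m(\cdot, n, N) \rangle.}
#' Integrals use the midpoint rule over structural cells (exactly consistent
#' with bin-averaged data) and the trapezoid rule over snapshots; both
#' converge rapidly because the integrands are smooth and compactly
#' supported. With a known transport speed `known_transport` (the a priori
#' age-time relationship), the transport contribution moves to the left-hand
#' side: `b_pde = -<dt phi, n> - <ds phi, alpha n>` and `G_g` is empty.
#'
#' @param field A [population_field()].
#' @param N Total-population vector used inside N-dependent terms (defaults
#'   to the bin-sum of `field`; pass a debiased estimate for noisy data).
#' @param library A [term_library()].
#' @param basis A [build_test_basis()] result on the same domain.
#' @param known_transport Optional function `s -> alpha(s)`.
#' @return A list with `b_pde`, `G_g` (zero-column when `known_transport`
#'   given), `G_f`.
#' @export
assemble_pde_system <- function(field, N = NULL, library, basis,
                                known_transport = NULL) {
  stopifnot(inherits(field, "population_field"),
            inherits(library, "term_library"), inherits(basis, "test_basis"))
  if (is.null(N)) N <- total_population(field)
  stopifnot(length(N) == length(field$times))
  tt <- field$times - field$times[1]
  ss <- cell_midpoints(field$domain)
  wt <- trapezoid_weights(tt)
  ws <- rep(cell_width(field$domain), length(ss))
  n <- field$values
  Phi <- family_matrix(basis$time_functions, tt, wt)          # nt x Kt
  dPhi <- family_matrix(basis$time_functions, tt, wt, TRUE)
  Psi <- family_matrix(basis$space_functions, ss, ws)         # ns x Ks
  dPsi <- family_matrix(basis$space_functions, ss, ws, TRUE)
  ti <- basis$pde_pairs$ti
  si <- basis$pde_pairs$si
  # <A(t) x B(s), F> for all (time, space) pairs via two matrix products
  pair_integrals <- function(Tmat, Smat, F) {
    M <- crossprod(Tmat, F %*% Smat)    # Kt x Ks
    M[cbind(ti, si)]
  }
  b_pde <- -pair_integrals(dPhi, Psi, n)
  K <- length(b_pde)
  if (is.null(known_transport)) {
    G_g <- matrix(0, K, length(library$transport))
    for (m in seq_along(library$transport)) {
      tv <- evaluate_term(library$transport[[m]], ss, n, N)
      G_g[, m] <- pair_integrals(Phi, dPsi, tv * n)
    }
  } else {
    alpha <- known_transport(ss)
    b_pde <- b_pde - pair_integrals(Phi, dPsi, sweep(n, 2, alpha, "*"))
    G_g <- matrix(0, K, 0)
  }
  G_f <- matrix(0, K, length(library$source))
  for (m in seq_along(library$source)) {
    fv <- evaluate_term(library$source[[m]], ss, n, N)
    G_f[, m] <- pair_integrals(Phi, Psi, fv)
  }
  list(b_pde = b_pde, G_g = G_g, G_f = G_f)
}

#' Assemble the total-population ODE weak system
#'
#' The ODE block ties the boundary (birth) process to the data: for time-only
#' test functions \eqn{\varphi_k},
#' \deqn{b^{ode}_k = -\int_0^T \varphi_k'(t) N(t)\, dt, \quad
#'       \Xi^f_{k,m} = \langle \varphi_k, f_m \rangle, \quad
#'       \Xi^\beta_{k,m} = \langle \varphi_k, \beta_m(\cdot, N)\, n \rangle,}
#' with the structural variable integrated out by the bin sum. The `Xi_f`
#' columns match the `G_f` columns one-to-one so the source weights are
#' shared across blocks.
#'
#' @inheritParams assemble_pde_system
#' @return A list with `b_ode`, `Xi_f`, `Xi_b`.
#' @export
assemble_ode_system <- function(field, N = NULL, library, basis) {
  stopifnot(inherits(field, "population_field"),
            inherits(library, "term_library"), inherits(basis, "test_basis"))
  if (is.null(N)) N <- total_population(field)
  tt <- field$times - field$times[1]
  ss <- cell_midpoints(field$domain)
  wt <- trapezoid_weights(tt)
  ds <- cell_width(field$domain)
  n <- field$values
  Phi <- family_matrix(basis$ode_functions, tt, wt)
  dPhi <- family_matrix(basis$ode_functions, tt, wt, TRUE)
  b_ode <- -as.vector(crossprod(dPhi, N))
  int_s <- function(term) {
    # integrate the structural variable out with the bin sum -> vector in t
    tv <- evaluate_term(term, ss, n, N)
    rowSums(tv) * ds
  }
  Xi_f <- sapply(library$source, function(tm) as.vector(crossprod(Phi, int_s(tm))))
  Xi_b <- sapply(library$boundary, function(tm) as.vector(crossprod(Phi, int_s(tm))))
  Xi_f <- matrix(Xi_f, nrow = length(b_ode))
  Xi_b <- matrix(Xi_b, nrow = length(b_ode))
  list(b_ode = b_ode, Xi_f = Xi_f, Xi_b = Xi_b)
}

#' Stack the PDE and ODE blocks into one linear system
#'
#' Concatenates the two blocks into
#' \deqn{\begin{pmatrix} b^{pde} \\ b^{ode} \end{pmatrix} =
#'  \begin{pmatrix} G^g & G^f & 0 \\ 0 & \Xi^f & \Xi^\beta \end{pmatrix}
#'  \begin{pmatrix} w_g \\ w_f \\ w_\beta \end{pmatrix}.}
#'
#' @param pde Output of [assemble_pde_system()].
#' @param ode Output of [assemble_ode_system()].
#' @param library The [term_library()] used for both (fixes column labels).
#' @return An object of class `weak_system` with elements `b`, `G`,
#'   `column_labels`, `roles`, `n_pde` (PDE row count), and the blocks.
#' @export
stack_systems <- function(pde, ode, library) {
  stopifnot(ncol(pde$G_f) == ncol(ode$Xi_f))
  Mg <- ncol(pde$G_g); Mf <- ncol(pde$G_f); Mb <- ncol(ode$Xi_b)
  K <- length(pde$b_pde); Kp <- length(ode$b_ode)
  G <- rbind(
    cbind(pde$G_g, pde$G_f, matrix(0, K, Mb)),
    cbind(matrix(0, Kp, Mg), ode$Xi_f, ode$Xi_b)
  )
  labels <- library$names
  if (Mg == 0) {
    labels <- labels[-seq_along(library$transport)]
  }
  stopifnot(length(labels) == ncol(G))
  structure(
    list(
      b = c(pde$b_pde, ode$b_ode), G = G,
      column_labels = labels,
      roles = rep(c("transport", "source", "boundary"), c(Mg, Mf, Mb)),
      n_pde = K, pde = pde, ode = ode
    ),
    class = "weak_system"
  )
}

#' @export
print.weak_system <- function(x, ...) {
  cat(sprintf(
    "<weak_system> %d rows (%d PDE + %d ODE) x %d columns\n",
    length(x$b), x$n_pde, length(x$b) - x$n_pde, ncol(x$G)
  ))
  invisible(x)
}

#' Assemble the full stacked weak system for a data set
#'
#' Convenience wrapper: builds [assemble_pde_system()] and
#' [assemble_ode_system()] on the same basis and stacks them.
#'
#' @inheritParams assemble_pde_system
#' @return A `weak_system`.
#' @export
assemble_weak_system <- function(field, N = NULL, library, basis,
                                 known_transport = NULL) {
  pde <- assemble_pde_system(field, N, library, basis, known_transport)
  ode <- assemble_ode_system(field, N, library, basis)
  stack_systems(pde, ode, library)
}
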