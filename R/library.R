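#' Candidate library terms for vital rates
#'
#' A library term is a named candidate function for one of the three model
#' roles: `transport` (candidate for the growth speed g), `source` (candidate
#' for the mortality/division density, entering as \eqn{h(s, N)\, n}), or
#' `boundary` (candidate per-capita birth rate, entering the renewal integral
#' as \eqn{\beta(s, N)\, n}). Each term factorises as
#' `s_factor(s) * N_factor(N)`, times the density `n` for source and boundary
#' roles.
#'
#' @param name Unique column label.
#' @param role One of `"transport"`, `"source"`, `"boundary"`.
#' @param s_factor Function of the structural variable.
#' @param N_factor Function of the total population (default: constant 1).
#'
#' @return An object of class `library_term`.
#' @export
library_term <- function(name, role, s_factor, N_factor = NULL) {
  role <- match.arg(role, c("transport", "source", "boundary"))
  if (is.null(N_factor)) N_factor <- function(N) rep(1, length(N))
  stopifnot(is.function(s_factor), is.function(N_factor))
  structure(
    list(
      name = name, role = role, s_factor = s_factor, N_factor = N_factor,
      multiplies_n = role != "transport"
    ),
    class = "library_term"
  )
}

# family constructors used by presets; kept as plain closures so parameters
# are frozen at construction time
term_poly <- function(role, p, prefix) {
  force(p)
  library_term(sprintf("%s:s^%d", prefix, p), role, function(s) s^p)
}
term_exp <- function(role, k, prefix) {
  force(k)
  library_term(sprintf("%s:exp(%gs)", prefix, k), role, function(s) exp(k * s))
}
term_gauss <- function(role, mu, sigma, prefix) {
  force(mu); force(sigma)
  library_term(sprintf("%s:gauss(%g,%g)", prefix, mu, sigma), role,
               function(s) exp(-(s - mu)^2 / (2 * sigma^2)))
}
term_sigmoid <- function(role, sc, k, prefix) {
  force(sc); force(k)
  library_term(sprintf("%s:sig(%g,%g)", prefix, sc, k), role,
               function(s) 1 / (1 + exp(-k * (s - sc))))
}
term_shifted_exp <- function(role, gamma, s0, prefix) {
  force(gamma); force(s0)
  library_term(sprintf("%s:exp(%g(s-%g))", prefix, gamma, s0), role,
               function(s) exp(gamma * (s - s0)))
}

#' Ordered library of candidate terms
#'
#' Holds the ordered candidate sets \eqn{\{g_m\}}, \eqn{\{f_m\}},
#' \eqn{\{\beta_m\}} whose sparse linear combination is sought. Ordering is
#' fixed at construction and shared by assembly, regression and metrics.
#'
#' @param transport,source,boundary Lists of [library_term()]s (roles must
#'   match the slot).
#' @return An object of class `term_library` with element `names`, the flat
#'   ordered column labels (transport, then source, then boundary).
#' @export
term_library <- function(transport = list(), source = list(), boundary = list()) {
  chk <- function(terms, role) {
    for (tm in terms) stopifnot(inherits(tm, "library_term"), tm$role == role)
    terms
  }
  transport <- chk(transport, "transport")
  source <- chk(source, "source")
  boundary <- chk(boundary, "boundary")
  names <- c(
    vapply(transport, `[[`, "", "name"),
    vapply(source, `[[`, "", "name"),
    vapply(boundary, `[[`, "", "name")
  )
  if (anyDuplicated(names)) stop("duplicate term names in library")
  structure(
    list(transport = transport, source = source, boundary = boundary,
         names = names),
    class = "term_library"
  )
}

#' @export
print.term_library <- function(x, ...) {
  cat(sprintf(
    "<term_library> %d transport + %d source + %d boundary terms\n",
    length(x$transport), length(x$source), length(x$boundary)
  ))
  cat(" ", paste(x$names, collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy term_library
#' @export
tidy.term_library <- function(x, ...) {
  tibble::tibble(
    term = x$names,
    role = rep(c("transport", "source", "boundary"),
               c(length(x$transport), length(x$source), length(x$boundary)))
  )
}

#' Evaluate a library term on the data grid
#'
#' Returns the full space-time grid of term values:
#' `s_factor(s) * N_factor(N(t))`, times `n(t, s)` when the term multiplies
#' the density (source and boundary roles).
#'
#' @param term A [library_term()].
#' @param s_grid Structural evaluation points.
#' @param n_values Matrix of density values (times x cells), used when the
#'   term multiplies `n`.
#' @param N_values Total-population vector, one entry per time.
#' @return A `length(N_values)` x `length(s_grid)` matrix.
#' @export
evaluate_term <- function(term, s_grid, n_values = NULL, N_values = 1) {
  sf <- term$s_factor(s_grid)
  Nf <- term$N_factor(N_values)
  if (length(Nf) == 1L) Nf <- rep(Nf, length(N_values))
  out <- outer(Nf, sf)
  if (term$multiplies_n) {
    stopifnot(!is.null(n_values), all(dim(n_values) == dim(out)))
    out <- out * n_values
  }
  if (!all(is.finite(out))) stop("non-finite term values for ", term$name)
  out
}

# tensor a list of s-only terms with N-factors; used for nonlinear presets
tensor_with_N <- function(terms, role, prefix) {
  nf <- list(
    list(suffix = "", fn = function(N) rep(1, length(N))),
    list(suffix = "*N", fn = function(N) N),
    list(suffix = "*N^2", fn = function(N) N^2),
    list(suffix = "*exp(-0.25N)", fn = function(N) exp(-0.25 * N))
  )
  out <- list()
  for (tm in terms) {
    for (f2 in nf) {
      out[[length(out) + 1L]] <- library_term(
        paste0(tm$name, f2$suffix), role, tm$s_factor, f2$fn
      )
    }
  }
  out
}

#' Preset libraries for the example problems
#'
#' The candidate libraries paired with each [example_model()]. For the linear
#' examples these are small role-specific families (polynomials,
#' exponentials, sigmoids, Gaussians) containing the true ingredient among
#' close alternatives. For the nonlinear examples each structural term is
#' tensored with the population factors \eqn{\{1, N, N^2, e^{-0.25N}\}}.
#'
#' @param name Example name (`"L.1"` ... `"NL.2"`).
#' @return A [term_library()].
#' @export
preset_library <- function(name) {
  polys <- function(role, ps, prefix) lapply(ps, term_poly, role = role, prefix = prefix)
  switch(name,
    "L.1" = term_library(
      transport = polys("transport", 0:2, "g"),
      source = polys("source", 0:3, "f"),
      boundary = polys("boundary", 0:3, "b")
    ),
    "L.2" = term_library(
      transport = polys("transport", 0:2, "g"),
      source = lapply(0.08 * (4 * (0:4) + 1), term_exp,
                      role = "source", prefix = "f"),
      boundary = lapply(5 * (1:3), term_gauss, sigma = 5,
                        role = "boundary", prefix = "b")
    ),
    "L.3" = term_library(
      transport = polys("transport", 0:2, "g"),
      source = polys("source", 0:4, "f"),
      boundary = lapply(1:4, term_sigmoid, k = 2,
                        role = "boundary", prefix = "b")
    ),
    "L.4" = term_library(
      transport = polys("transport", 0:2, "g"),
      source = lapply(0.2 + 0.5 * (0:3), term_exp,
                      role = "source", prefix = "f"),
      boundary = polys("boundary", 1:4, "b")
    ),
    "NL.1" = term_library(
      transport = tensor_with_N(polys("transport", 0:2, "g"), "transport", "g"),
      source = tensor_with_N(polys("source", 0:2, "f"), "source", "f"),
      boundary = tensor_with_N(polys("boundary", 0:2, "b"), "boundary", "b")
    ),
    "NL.2" = term_library(
      transport = tensor_with_N(polys("transport", 0:1, "g"), "transport", "g"),
      source = tensor_with_N(polys("source", 0:2, "f"), "source", "f"),
      boundary = tensor_with_N(
        lapply(1:2, term_sigmoid, k = 2, role = "boundary", prefix = "b"),
        "boundary", "b"
      )
    ),
    stop("unknown preset library: ", name)
  )
}

#' Perturbed libraries for the term-distinguishability study
#'
#' Builds the one-role family of `2k + 1` closely spaced candidates around the
#' true ingredient of example L.2: perturbed exponentials
#' \eqn{\{e^{(0.08 + \delta i)s} n\}_{i=-k}^{k}} for the source case, or
#' Gaussians \eqn{\{\mathrm{Gauss}(s; 10 + \delta i, 5)\}_{i=-k}^{k}} for the
#' boundary case. The other two roles contain only the true L.2 ingredient,
#' so ambiguity is confined to the varied role.
#'
#' @param case `"source"` or `"boundary"`.
#' @param delta Spacing between candidate parameters (> 0).
#' @param k Half-width: the library has `2k + 1` terms, with `i = 0` the truth.
#' @return A [term_library()].
#' @export
distinguishability_library <- function(case = c("source", "boundary"),
                                       delta, k) {
  case <- match.arg(case)
  stopifnot(delta > 0, k >= 1)
  idx <- -k:k
  transport <- list(term_poly("transport", 0L, "g"))
  if (case == "source") {
    source <- lapply(0.08 + delta * idx, term_exp, role = "source", prefix = "f")
    boundary <- list(term_gauss("boundary", 10, 5, "b"))
  } else {
    source <- list(term_exp("source", 0.08, "f"))
    boundary <- lapply(10 + delta * idx, term_gauss, sigma = 5,
                       role = "boundary", prefix = "b")
  }
  term_library(transport = transport, source = source, boundary = boundary)
}

#' Condition number of an assembled weak matrix
#'
#' 2-norm condition number (ratio of extreme singular values). The headline
#' value is computed after normalising each column to unit 2-norm, which
#' isolates angular (in)dependence of the candidate terms from their scales;
#' the raw value is also returned.
#'
#' @param G Numeric matrix with at least one column.
#' @return A list with `kappa` (normalised columns) and `kappa_raw`; exactly
#'   rank-deficient matrices report `Inf`.
#' @export
library_condition_number <- function(G) {
  G <- as.matrix(G)
  stopifnot(ncol(G) >= 1, nrow(G) >= 1)
  kap <- function(M) {
    d <- svd(M, nu = 0, nv = 0)$d
    if (min(d) <= max(d) * .Machine$double.eps * max(dim(M))) Inf
    else max(d) / min(d)
  }
  nrm <- sqrt(colSums(G^2))
  Gn <- sweep(G, 2, pmax(nrm, .Machine$double.xmin), "/")
  list(kappa = kap(Gn), kappa_raw = kap(G))
}
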