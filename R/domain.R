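#' Space-time domain for a structured population
#'
#' Describes the 1-D structural domain \eqn{\Omega = [s_{min}, s_{max}]}, the
#' time horizon \eqn{[0, T]}, and the discretisation used for simulation and
#' storage: `n_cells` equal-width structural cells (bins) and `n_snapshots`
#' uniformly spaced saved time points (including `t = 0` and `t = T`).
#'
#' @param s_min,s_max Endpoints of the structural domain (e.g. age or size range).
#' @param T Final time (> 0).
#' @param n_cells Number of structural cells (>= 2).
#' @param n_snapshots Number of saved time points (>= 2).
#'
#' @return An object of class `pop_domain`.
#' @examples
#' pop_domain(0, 15, T = 10, n_cells = 300, n_snapshots = 100)
#' @export
pop_domain <- function(s_min, s_max, T, n_cells, n_snapshots) {
  stopifnot(
    is.numeric(s_min), is.numeric(s_max), s_min < s_max,
    is.numeric(T), T > 0,
    n_cells >= 2, n_snapshots >= 2
  )
  structure(
    list(
      s_min = as.numeric(s_min), s_max = as.numeric(s_max), T = as.numeric(T),
      n_cells = as.integer(n_cells), n_snapshots = as.integer(n_snapshots)
    ),
    class = "pop_domain"
  )
}

#' @export
print.pop_domain <- function(x, ...) {
  cat(sprintf(
    "<pop_domain> Omega = [%g, %g], t in [0, %g], %d cells x %d snapshots\n",
    x$s_min, x$s_max, x$T, x$n_cells, x$n_snapshots
  ))
  invisible(x)
}

#' @rdname pop_domain
#' @param domain A `pop_domain`.
#' @export
cell_width <- function(domain) (domain$s_max - domain$s_min) / domain$n_cells

#' @rdname pop_domain
#' @export
cell_midpoints <- function(domain) {
  ds <- cell_width(domain)
  domain$s_min + (seq_len(domain$n_cells) - 0.5) * ds
}

#' @rdname pop_domain
#' @export
cell_edges <- function(domain) {
  seq(domain$s_min, domain$s_max, length.out = domain$n_cells + 1L)
}

#' @rdname pop_domain
#' @export
snapshot_times <- function(domain) {
  seq(0, domain$T, length.out = domain$n_snapshots)
}

#' Bin-averaged population density on a space-time grid
#'
#' The universal data object: bin averages \eqn{n_{ij} \approx
#' \frac{1}{|\Lambda_j|}\int_{\Lambda_j} n(t_i, s)\,ds} over a disjoint
#' partition of the structural domain, stored time-major (rows are snapshots,
#' columns are structural cells).
#'
#' @param values Numeric matrix, `n_snapshots` x `n_cells`.
#' @param domain A [pop_domain()].
#' @param times Optional snapshot times; defaults to the uniform grid of `domain`.
#'
#' @return An object of class `population_field`.
#' @export
population_field <- function(values, domain, times = NULL) {
  values <- as.matrix(values)
  if (is.null(times)) times <- snapshot_times(domain)
  stopifnot(
    inherits(domain, "pop_domain"),
    nrow(values) == length(times),
    ncol(values) == domain$n_cells,
    all(is.finite(values))
  )
  structure(
    list(values = values, domain = domain, times = as.numeric(times)),
    class = "population_field"
  )
}

#' @export
print.population_field <- function(x, ...) {
  cat(sprintf(
    "<population_field> %d snapshots x %d cells on [%g, %g], t in [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$domain$s_min, x$domain$s_max,
    min(x$times), max(x$times)
  ))
  N <- total_population(x)
  cat(sprintf("  N(t): %.4g .. %.4g\n", N[1], N[length(N)]))
  invisible(x)
}

#' Total population time series
#'
#' Integrates the number density over the structural domain at each snapshot:
#' \eqn{N(t_i) = \Delta s \sum_j n_{ij}}.
#'
#' @param field A [population_field()].
#' @return Numeric vector of \eqn{N(t_i)}, one entry per snapshot.
#' @export
total_population <- function(field) {
  stopifnot(inherits(field, "population_field"))
  unname(rowSums(field$values) * cell_width(field$domain))
}

#' Tidy a population field into long format
#'
#' @param x A [population_field()].
#' @param ... Unused.
#' @return A tibble with columns `time`, `s` (cell midpoint), `density`.
#' @method tidy population_field
#' @export
tidy.population_field <- function(x, ...) {
  s <- cell_midpoints(x$domain)
  tibble::tibble(
    time = rep(x$times, times = length(s)),
    s = rep(s, each = length(x$times)),
    density = as.vector(x$values)
  )
}

#' Restrict a field to a time window
#'
#' Keeps snapshots with `t_lo <= t <= t_hi` and rebuilds the stored domain so
#' downstream consumers (test bases, fits) see the restricted horizon.
#'
#' @param field A [population_field()].
#' @param t_lo,t_hi Window endpoints.
#' @return A `population_field` on the restricted window, with times shifted
#'   so the window starts at 0.
#' @export
window_field <- function(field, t_lo = 0, t_hi = Inf) {
  keep <- field$times >= t_lo - 1e-12 & field$times <= t_hi + 1e-12
  stopifnot(sum(keep) >= 2)
  times <- field$times[keep] - field$times[keep][1]
  dom <- field$domain
  dom2 <- pop_domain(dom$s_min, dom$s_max, max(times), dom$n_cells, sum(keep))
  population_field(field$values[keep, , drop = FALSE], dom2, times = times)
}

#' Read and write histogram CSV files
#'
#' The on-disk format is: a header row `time,edge_0,edge_1,...,edge_J` giving
#' the J+1 bin edges of the structural partition, followed by one row per
#' snapshot holding the time and the J bin averages. Bins are half-open
#' `[edge_{j-1}, edge_j)` with the last bin closed. Values are written with
#' full double precision so exact decimal inputs round-trip bit-exactly.
#'
#' @param path File path.
#' @param field A [population_field()] (for writing).
#' @param T Optional final time override when reading (defaults to the last
#'   snapshot time).
#' @return `read_histogram_csv()` returns a `population_field`;
#'   `write_histogram_csv()` returns `path` invisibly.
#' @export
read_histogram_csv <- function(path, T = NULL) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 3)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  stopifnot(header[1] == "time", length(header) >= 3)
  edges <- as.numeric(sub("^edge_", "", header[-1]))
  J <- length(edges) - 1L
  body <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, ",", fixed = TRUE)[[1]])
  }))
  stopifnot(ncol(body) == J + 1L)
  times <- body[, 1]
  if (is.null(T)) T <- times[length(times)]
  widths <- diff(edges)
  if (diff(range(widths)) > 1e-10 * mean(widths)) {
    warning("non-uniform bin edges; using mean width for the stored domain")
  }
  dom <- pop_domain(edges[1], edges[J + 1L], T, J, length(times))
  population_field(body[, -1, drop = FALSE], dom, times = times)
}

#' @rdname read_histogram_csv
#' @export
write_histogram_csv <- function(field, path) {
  stopifnot(inherits(field, "population_field"))
  edges <- cell_edges(field$domain)
  fmt <- function(x) sprintf("%.17g", x)
  # the J+1 header fields after "time" are the numeric bin edges
  header <- paste(c("time", fmt(edges)), collapse = ",")
  rows <- vapply(seq_along(field$times), function(i) {
    paste(c(fmt(field$times[i]), fmt(field$values[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
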