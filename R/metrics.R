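#' Coefficient recovery errors
#'
#' \eqn{E_\infty = \max_{j: w^\star_j \ne 0} |w_j - w^\star_j| /
#' |w^\star_j|} (worst relative error over true-support coefficients; a
#' missed true term contributes 1) and \eqn{E_2 = \|w - w^\star\|_2 /
#' \|w^\star\|_2} (overall magnitude of coefficient error, including false
#' positives in the numerator).
#'
#' @param w,w_true Stacked weight vectors in identical column order.
#' @return A list with `e_inf` and `e_2`.
#' @export
coefficient_errors <- function(w, w_true) {
  stopifnot(length(w) == length(w_true), any(w_true != 0))
  supp <- w_true != 0
  list(
    e_inf = max(abs(w[supp] - w_true[supp]) / abs(w_true[supp])),
    e_2 = sqrt(sum((w - w_true)^2)) / sqrt(sum(w_true^2))
  )
}

#' True positivity ratio of a recovered support
#'
#' \eqn{TPR = TP / (TP + FP + FN)} over the stacked weight vector: the
#' Jaccard index of the recovered and true supports.
#'
#' @inheritParams coefficient_errors
#' @return A number in `[0, 1]`.
#' @export
true_positive_ratio <- function(w, w_true) {
  stopifnot(length(w) == length(w_true))
  sw <- which(w != 0)
  st <- which(w_true != 0)
  tp <- length(intersect(sw, st))
  fp <- length(setdiff(sw, st))
  fn <- length(setdiff(st, sw))
  if (tp + fp + fn == 0) return(1)
  tp / (tp + fp + fn)
}

#' Relative residual of the stacked system at given weights
#'
#' \eqn{R = \|b - Gw\|_2 / \|b\|_2}.
#'
#' @param system A `weak_system`.
#' @param w Stacked weight vector.
#' @return A nonnegative number.
#' @export
relative_residual <- function(system, w) {
  stopifnot(inherits(system, "weak_system"), length(w) == ncol(system$G))
  nb <- sqrt(sum(system$b^2))
  if (nb == 0) stop("zero right-hand side")
  sqrt(sum((system$b - as.vector(system$G %*% w))^2)) / nb
}

# build a vital_rates object from library + stacked weights
learned_vital_rates <- function(library, w) {
  Mg <- length(library$transport)
  Mf <- length(library$source)
  Mb <- length(library$boundary)
  stopifnot(length(w) == Mg + Mf + Mb)
  w_g <- w[seq_len(Mg)]
  w_f <- w[Mg + seq_len(Mf)]
  w_b <- w[Mg + Mf + seq_len(Mb)]
  combo <- function(terms, wts) {
    act <- which(wts != 0)
    function(s, N) {
      out <- numeric(length(s))
      for (m in act) {
        tm <- terms[[m]]
        out <- out + wts[m] * tm$s_factor(s) * tm$N_factor(N)[1]
      }
      out
    }
  }
  g_fn <- combo(library$transport, w_g)
  h_fn <- combo(library$source, w_f)
  b_fn <- combo(library$boundary, w_b)
  depends <- any(vapply(
    c(library$transport, library$source, library$boundary)[which(w != 0)],
    function(tm) abs(tm$N_factor(2) - 1) > 1e-14, logical(1)
  ))
  vital_rates(
    g = g_fn,
    f = function(s, n, N) h_fn(s, N) * n,
    beta = b_fn,
    depends_on_N = depends
  )
}

#' Held-out prediction error of a learned model
#'
#' Re-simulates the learned model from the true state at `t_test` and
#' compares it to the true field on the held-out window:
#' \eqn{E_p = \|\tilde n - n^\star\|_{L^2((T_{test}, T) \times \Omega)} /
#' \|n^\star\|}, with discrete trapezoid-in-time, midpoint-in-space norms.
#' A learned model that blows up before `T` returns `Inf` (a recorded
#' failure, not an error).
#'
#' @param w Stacked weight vector (e.g. `fit$w`).
#' @param truth The noise-free [population_field()] on the full horizon.
#' @param library The [term_library()] the weights refer to.
#' @param t_test Training/testing split time (`< T`).
#' @param cfl CFL fraction for the re-simulation.
#' @return The scalar \eqn{E_p}.
#' @export
prediction_error <- function(w, truth, library, t_test, cfl = 0.4) {
  stopifnot(inherits(truth, "population_field"),
            t_test < max(truth$times), t_test >= min(truth$times))
  keep <- truth$times >= t_test - 1e-12
  times_out <- truth$times[keep]
  i0 <- which(keep)[1]
  dom <- truth$domain
  # snapshot spacing of the truth is reused on the held-out window
  dom_test <- pop_domain(dom$s_min, dom$s_max,
                         times_out[length(times_out)] - times_out[1],
                         dom$n_cells, length(times_out))
  model <- learned_vital_rates(library, w)
  pred <- tryCatch(
    simulate_population(model, dom_test, truth$values[i0, ],
                        cfl = cfl, t0 = times_out[1]),
    error = function(e) NULL
  )
  if (is.null(pred) || !all(is.finite(pred$values))) return(Inf)
  wt <- trapezoid_weights(times_out)
  diff2 <- rowSums((pred$values - truth$values[keep, , drop = FALSE])^2)
  ref2 <- rowSums(truth$values[keep, , drop = FALSE]^2)
  sqrt(sum(wt * diff2) / sum(wt * ref2))
}

#' All recovery metrics for a fit against a known truth
#'
#' @param fit A `wsindy_fit`.
#' @param w_true True stacked weight vector (same column order).
#' @param system The `weak_system` the fit was computed on.
#' @param truth Optional noise-free field for the prediction error.
#' @param library,t_test Passed to [prediction_error()] when `truth` given.
#' @return A one-row tibble with `e_inf`, `e_2`, `tpr`, `residual`, `e_p`.
#' @export
metrics_report <- function(fit, w_true, system, truth = NULL, library = NULL,
                           t_test = NULL) {
  ce <- coefficient_errors(fit$w, w_true)
  e_p <- NA_real_
  if (!is.null(truth)) {
    stopifnot(!is.null(library), !is.null(t_test))
    e_p <- prediction_error(fit$w, truth, library, t_test)
  }
  tibble::tibble(
    e_inf = ce$e_inf,
    e_2 = ce$e_2,
    tpr = true_positive_ratio(fit$w, w_true),
    residual = relative_residual(system, fit$w),
    e_p = e_p
  )
}
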