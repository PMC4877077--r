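#' q-values from permutation p-values
#'
#' Step-up false-discovery-rate adjustment:
#' `q_i = pi0 * min_{j : p_(j) >= p_(i)} m * p_(j) / rank_j`, clipped to
#' `[0, 1]`. With `pi0_method = "fixed_one"` (pi0 = 1) this is exactly the
#' Benjamini-Hochberg adjusted p-value. With `"storey_smoother"`, the
#' proportion of true nulls pi0 is estimated by evaluating
#' `#\{p > lambda\} / (m (1 - lambda))` on a lambda grid and extrapolating a
#' cubic smoothing spline to the largest lambda.
#'
#' @param p numeric vector of p-values, all in `(0, 1]`.
#' @param pi0_method `"fixed_one"` (default) or `"storey_smoother"`.
#' @param lambda grid for the Storey smoother (default `seq(0.05, 0.95,
#'   0.05)`).
#' @return numeric vector of q-values in the order of `p`.
#' @export
qvalues <- function(p, pi0_method = c("fixed_one", "storey_smoother"),
                    lambda = seq(0.05, 0.95, 0.05)) {
  pi0_method <- match.arg(pi0_method)
  if (length(p) == 0) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  pi0 <- if (pi0_method == "fixed_one") 1 else estimate_pi0_smoother(p, lambda)

  m <- length(p)
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

estimate_pi0_smoother <- function(p, lambda) {
  m <- length(p)
  pi0_lambda <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                       numeric(1))
  pi0 <- if (length(lambda) >= 4) {
    fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
    stats::predict(fit, x = max(lambda))$y
  } else {
    pi0_lambda[which.max(lambda)]
  }
  min(max(pi0, 1 / m), 1)
}
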