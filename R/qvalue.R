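#' Storey q-values with bootstrap pi0 estimation
#'
#' Computes q-values from a vector of p-values by the Storey procedure:
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` over a lambda grid, with
#' the tuning value chosen by the bootstrap method (the lambda minimizing the
#' estimated mean squared error of `pi0` relative to the plug-in minimum),
#' then `q_i = min over p_j >= p_i of pi0 * m * p_j / rank(p_j)`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambdas Grid of tuning values.
#' @param n_boot Bootstrap resamples for the pi0 selection.
#' @param seed Optional seed for the bootstrap.
#' @return List with `qvalues` (same order as `p`) and `pi0`.
#' @export
qvalues <- function(p, lambdas = seq(0.05, 0.95, by = 0.05), n_boot = 100,
                    seed = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (all(p == 0)) return(list(qvalues = rep(0, m), pi0 = 0))
  if (!is.null(seed)) set.seed(seed)
  pi0_at <- function(pp, l) mean(pp > l) / (1 - l)
  pi0s <- vapply(lambdas, function(l) pi0_at(p, l), numeric(1))
  min_pi0 <- min(pi0s)
  if (m > 1) {
    mse <- numeric(length(lambdas))
    for (b in seq_len(n_boot)) {
      pb <- p[sample.int(m, m, replace = TRUE)]
      pi0b <- vapply(lambdas, function(l) pi0_at(pb, l), numeric(1))
      mse <- mse + (pi0b - min_pi0)^2
    }
    pi0 <- pi0s[which.min(mse)]
  } else {
    pi0 <- pi0s[1]
  }
  pi0 <- min(max(pi0, 0), 1)
  ord <- order(p, decreasing = TRUE)
  rk <- rank(p, ties.method = "max")
  q <- pi0 * m * p / rk
  q[ord] <- cummin(q[ord])
  q <- pmin(q, 1)
  list(qvalues = q, pi0 = pi0)
}
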