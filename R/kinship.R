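#' Genetic relatedness from founder genotype probabilities
#'
#' Computes kinship as the average cross-product of founder dosage vectors,
#' `K = (1/M) * sum_m P_m P_m'` over the included markers.  In `"loco"` mode
#' (leave one chromosome out) a matrix is produced per chromosome using all
#' markers *not* on that chromosome, avoiding proximal contamination in the
#' genome scan; `"full"` uses all markers (for heritability estimation).
#'
#' @param probs Genotype probabilities, samples x 8 x markers.
#' @param map Genome map matching the marker dimension.
#' @param mode `"loco"` or `"full"`.
#' @return An object of class `kinship_set`: list with `full` (samples x
#'   samples matrix) and, in loco mode, `loco` (named list per chromosome).
#' @export
calc_kinship <- function(probs, map, mode = c("loco", "full")) {
  mode <- match.arg(mode)
  .check_map(map)
  stopifnot(dim(probs)[3] == nrow(map))
  chrs <- unique(map$chr)
  if (mode == "loco" && length(chrs) < 2)
    stop("loco kinship requires at least 2 chromosomes")
  n <- dim(probs)[1]
  # per-chromosome raw cross-products
  xp <- lapply(chrs, function(ch) {
    jj <- which(map$chr == ch)
    tcrossprod(.flatten_probs(probs[, , jj, drop = FALSE]))
  })
  names(xp) <- chrs
  mcount <- vapply(chrs, function(ch) sum(map$chr == ch), numeric(1))
  tot <- Reduce("+", xp)
  M <- sum(mcount)
  full <- tot / M
  full <- (full + t(full)) / 2
  dimnames(full) <- list(dimnames(probs)[[1]], dimnames(probs)[[1]])
  out <- list(full = full, mode = mode, n_markers = M)
  if (mode == "loco") {
    out$loco <- lapply(chrs, function(ch) {
      K <- (tot - xp[[ch]]) / (M - mcount[[ch]])
      K <- (K + t(K)) / 2
      dimnames(K) <- dimnames(full)
      K
    })
    names(out$loco) <- chrs
  }
  structure(out, class = "kinship_set")
}

#' @export
print.kinship_set <- function(x, ...) {
  cat(sprintf("Kinship set (%s): %d samples, %d markers", x$mode,
              nrow(x$full), x$n_markers))
  if (!is.null(x$loco)) cat(sprintf(", %d LOCO matrices", length(x$loco)))
  cat("\n")
  invisible(x)
}

# eigendecomposition of a kinship matrix with PSD check; tiny negative
# eigenvalues from roundoff are clamped to zero
.kinship_eigen <- function(K) {
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values), 1))
    stop("kinship matrix is not positive semidefinite")
  eg$values <- pmax(eg$values, 0)
  eg
}

# profile (restricted) log-likelihood over h2 on the kinship eigenbasis.
# yr, Xr are the rotated phenotype and covariates; lam the eigenvalues.
# Returns the function value; used by both est_herit and the scan null fits.
.profile_ll <- function(h2, yr, Xr, lam, reml = FALSE) {
  n <- length(yr)
  p <- ncol(Xr)
  d <- h2 * lam + (1 - h2)
  w <- 1 / sqrt(d)
  qx <- qr(Xr * w)
  r <- qr.resid(qx, yr * w)
  rss <- sum(r^2)
  if (reml) {
    XtX <- crossprod(Xr * w)
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(d)) +
              determinant(XtX, logarithm = TRUE)$modulus[1])
  } else {
    -0.5 * (n * log(rss / n) + sum(log(d)))
  }
}

# maximize the profile likelihood over h2 in [0, 1); returns h2, the
# variance scale, and a flatness flag (likelihood uninformative about h2)
.fit_vc <- function(yr, Xr, lam, reml = FALSE) {
  f <- function(h2) .profile_ll(h2, yr, Xr, lam, reml)
  probe <- vapply(c(0, 0.25, 0.5, 0.75, 0.99), f, numeric(1))
  flat <- diff(range(probe)) < 1e-8
  if (flat) {
    h2 <- 0
  } else {
    opt <- optimize(f, c(0, 1 - 1e-6), maximum = TRUE, tol = 1e-6)
    h2 <- opt$maximum
    if (f(0) >= opt$objective) h2 <- 0
  }
  d <- h2 * lam + (1 - h2)
  w <- 1 / sqrt(d)
  qx <- qr(Xr * w)
  rss <- sum(qr.resid(qx, yr * w)^2)
  n <- length(yr)
  sigma2 <- if (reml) rss / (n - ncol(Xr)) else rss / n
  list(h2 = h2, sigma2 = sigma2, Vg = h2 * sigma2, Ve = (1 - h2) * sigma2,
       weights = w, flat = flat, loglik = f(h2))
}

#' Estimate narrow-sense heritability of a phenotype
#'
#' Fits the polygenic mixed model `y = X b + g + e` with
#' `cov(g) = Vg * K`, `cov(e) = Ve * I`, maximizing the restricted likelihood
#' by a one-dimensional profile over `h2 = Vg / (Vg + Ve)` on the eigenbasis
#' of the kinship matrix.
#'
#' @param y Phenotype vector (finite values, n >= 20).
#' @param K Full kinship matrix (symmetric PSD).
#' @param covar Covariate matrix or data frame (an intercept is added), or
#'   `NULL`.
#' @param reml Use REML (default) or ML.
#' @return Object of class `herit_fit`: list with `h2`, `Vg`, `Ve`,
#'   `flat` (TRUE when the likelihood carries no information about h2, e.g.
#'   `K = I`), `loglik`.
#' @export
est_herit <- function(y, K, covar = NULL, reml = TRUE) {
  stopifnot(all(is.finite(y)), length(y) >= 20, nrow(K) == length(y))
  X <- .design_matrix(covar, length(y))
  eg <- .kinship_eigen(K)
  yr <- drop(crossprod(eg$vectors, y))
  Xr <- crossprod(eg$vectors, X)
  fit <- .fit_vc(yr, Xr, eg$values, reml = reml)
  structure(list(h2 = if (fit$flat) 0 else fit$h2, Vg = fit$Vg, Ve = fit$Ve,
                 flat = fit$flat, loglik = fit$loglik, reml = reml),
            class = "herit_fit")
}

#' @export
print.herit_fit <- function(x, ...) {
  cat(sprintf("Heritability (%s): h2 = %.3f  (Vg = %.3g, Ve = %.3g)%s\n",
              if (x$reml) "REML" else "ML", x$h2, x$Vg, x$Ve,
              if (x$flat) "  [likelihood flat in h2]" else ""))
  invisible(x)
}

# build a full-rank design matrix: intercept plus covariates
.design_matrix <- function(covar, n) {
  if (is.null(covar)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  if (is.data.frame(covar)) {
    covar <- stats::model.matrix(~ ., data = covar)[, -1, drop = FALSE]
  }
  covar <- as.matrix(covar)
  stopifnot(nrow(covar) == n)
  X <- cbind(intercept = 1, covar)
  if (qr(X)$rank < ncol(X)) stop("covariates are rank deficient")
  X
}
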