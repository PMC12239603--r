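#' Permutation-based genome-wide LOD thresholds
#'
#' Permutes the sample index of the genotype array while keeping the
#' phenotype-covariate pairing intact, rescans, and retains the genome-wide
#' maximum LOD of each permutation.  Null maxima are pooled across the
#' supplied phenotypes to form one genome-wide null distribution; the
#' threshold for significance level `alpha` is its `(1 - alpha)` quantile.
#'
#' Permuting the genotypes (and their kinship) is implemented as applying the
#' inverse permutation to the phenotype and covariates, which is equivalent
#' and lets the genotype-side computations be reused.  Null variance
#' components are taken from the unpermuted null fits and reused across
#' permutations.
#'
#' @param Y Phenotype vector or samples x phenotypes matrix.
#' @param probs,map,kinship,covar As in [scan1_lmm()].
#' @param n_perm Number of permutations (>= 10; >= 100 recommended).
#' @param alphas Named significance levels; defaults give the significant
#'   (alpha = 0.05) and suggestive (alpha = 0.25) thresholds.
#' @param seed Integer seed (required).
#' @return Object of class `scan_thresholds`: list with `thresholds`
#'   (named vector of LODs), `null_maxima` (n_perm x phenotypes matrix),
#'   `alphas`, `n_perm`.
#' @export
perm_threshold <- function(Y, probs, map, kinship = NULL, covar = NULL,
                           n_perm = 1000,
                           alphas = c(significant = 0.05, suggestive = 0.25),
                           seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  if (n_perm < 10) stop("n_perm must be at least 10")
  .check_map(map)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "pheno"))
  n <- nrow(Y)
  X0 <- .design_matrix(covar, n)
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  inv <- apply(perms, 2, order)  # inverse permutations

  const_design <- all(apply(X0, 2, function(x) diff(range(x)) == 0))
  maxima <- if (const_design) {
    .perm_maxima_batched(Y, probs, map, kinship, X0, inv)
  } else {
    .perm_maxima_loop(Y, probs, map, kinship, X0, inv)
  }
  dimnames(maxima) <- list(NULL, colnames(Y))
  pooled <- as.vector(maxima)
  thr <- vapply(alphas, function(a) quantile(pooled, 1 - a, type = 1,
                                             names = FALSE), numeric(1))
  structure(list(thresholds = thr, null_maxima = maxima, alphas = alphas,
                 n_perm = n_perm), class = "scan_thresholds")
}

#' @export
print.scan_thresholds <- function(x, ...) {
  cat(sprintf("Permutation thresholds (%d permutations x %d phenotypes):\n",
              x$n_perm, ncol(x$null_maxima)))
  for (i in seq_along(x$thresholds))
    cat(sprintf("  %s (alpha = %.3g): LOD > %.2f\n",
                names(x$thresholds)[i], x$alphas[i], x$thresholds[i]))
  invisible(x)
}

#' Permutation p-values for observed LOD scores
#'
#' Fraction of pooled null genome-wide maxima at least as large as each
#' observed LOD.
#'
#' @param thresholds A [perm_threshold()] result.
#' @param lod Vector of observed genome-wide maximum LODs.
#' @return Vector of permutation p-values.
#' @export
perm_pvalues <- function(thresholds, lod) {
  stopifnot(inherits(thresholds, "scan_thresholds"))
  pooled <- as.vector(thresholds$null_maxima)
  vapply(lod, function(l) mean(pooled >= l), numeric(1))
}

# fast path: permutation-invariant design (intercept-only covariates).
# Per (phenotype, chromosome) the whitened, residualized founder columns are
# fixed across permutations, so orthonormal bases per marker are precomputed
# and all permutations handled by one matrix product.
.perm_maxima_batched <- function(Y, probs, map, kinship, X0, inv) {
  n <- nrow(Y)
  n_perm <- ncol(inv)
  chrs <- unique(map$chr)
  maxima <- matrix(0, n_perm, ncol(Y))
  for (ch in chrs) {
    jj <- which(map$chr == ch)
    Mc <- length(jj)
    G <- .flatten_probs(probs[, , jj, drop = FALSE])
    K <- .pick_kinship(kinship, ch)
    eg <- if (is.null(K)) NULL else .kinship_eigen(K)
    Gr0 <- if (is.null(eg)) G else crossprod(eg$vectors, G)
    X0r <- if (is.null(eg)) X0 else crossprod(eg$vectors, X0)
    Yr <- if (is.null(eg)) Y else crossprod(eg$vectors, Y)
    for (j in seq_len(ncol(Y))) {
      if (is.null(eg)) {
        w <- rep(1, n)
      } else {
        fit <- .fit_vc(Yr[, j], X0r, eg$values, reml = FALSE)
        w <- fit$weights
      }
      X0w <- X0r * w
      q0 <- qr(X0w)
      Gw <- qr.resid(q0, Gr0 * w)
      # orthonormal basis per marker
      Bs <- vector("list", Mc)
      grp <- integer(0)
      for (m in seq_len(Mc)) {
        qg <- qr(Gw[, (m * 8L - 7L):(m * 8L)])
        r <- qg$rank
        Bs[[m]] <- qr.Q(qg)[, seq_len(r), drop = FALSE]
        grp <- c(grp, rep.int(m, r))
      }
      B <- do.call(cbind, Bs)
      # permuted phenotype copies, rotated and whitened
      Yp <- matrix(Y[as.vector(inv), j], n, n_perm)
      Ypw <- if (is.null(eg)) Yp else crossprod(eg$vectors, Yp)
      Ypw <- Ypw * w
      Ypr <- qr.resid(q0, Ypw)
      rss0 <- colSums(Ypr^2)
      T2 <- crossprod(B, Ypr)^2
      expl <- rowsum(T2, grp)           # Mc x n_perm
      rss1 <- pmax(sweep(-expl, 2, rss0, "+"), 1e-12)
      lodc <- (n / 2) * log10(sweep(1 / rss1, 2, rss0, "*"))
      maxima[, j] <- pmax(maxima[, j], apply(lodc, 2, max))
    }
  }
  maxima
}

# general path: covariates permute along with the phenotype
.perm_maxima_loop <- function(Y, probs, map, kinship, X0, inv) {
  n <- nrow(Y)
  n_perm <- ncol(inv)
  chrs <- unique(map$chr)
  maxima <- matrix(0, n_perm, ncol(Y))
  # precompute per-chromosome rotations and per-phenotype weights
  pre <- lapply(chrs, function(ch) {
    jj <- which(map$chr == ch)
    G <- .flatten_probs(probs[, , jj, drop = FALSE])
    K <- .pick_kinship(kinship, ch)
    eg <- if (is.null(K)) NULL else .kinship_eigen(K)
    Gr <- if (is.null(eg)) G else crossprod(eg$vectors, G)
    ws <- lapply(seq_len(ncol(Y)), function(j) {
      if (is.null(eg)) return(rep(1, n))
      Yr <- drop(crossprod(eg$vectors, Y[, j]))
      X0r <- crossprod(eg$vectors, X0)
      .fit_vc(Yr, X0r, eg$values, reml = FALSE)$weights
    })
    list(eg = eg, Gr = Gr, ws = ws, jj = jj)
  })
  names(pre) <- chrs
  for (k in seq_len(n_perm)) {
    iv <- inv[, k]
    Yp <- Y[iv, , drop = FALSE]
    X0p <- X0[iv, , drop = FALSE]
    for (ch in chrs) {
      pc <- pre[[ch]]
      Ypr <- if (is.null(pc$eg)) Yp else crossprod(pc$eg$vectors, Yp)
      X0r <- if (is.null(pc$eg)) X0p else crossprod(pc$eg$vectors, X0p)
      for (j in seq_len(ncol(Y))) {
        w <- pc$ws[[j]]
        lodc <- .scan_chr(Ypr[, j] * w, X0r * w, pc$Gr * w, n)
        maxima[k, j] <- max(maxima[k, j], max(lodc))
      }
    }
  }
  maxima
}
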