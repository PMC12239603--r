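#' Find and classify eQTL peaks
#'
#' For each phenotype (gene) and chromosome, reports the maximum-LOD marker
#' when it exceeds the threshold.  A peak is classified `local` when it lies
#' on the gene's chromosome within +/-10 Mbp (inclusive) of the gene
#' midpoint, `distant` otherwise; the midpoint is `(start + end) / 2`.
#'
#' @param scan A [scan1_lmm()] result (phenotype columns named by gene id).
#' @param annot Gene annotation data frame with columns `gene`, `chr`,
#'   `start`, `end` (Mbp); must cover every peaked gene.
#' @param threshold LOD threshold for reporting a peak.
#' @param local_window_mbp Half-width of the local window (default 10 Mbp).
#' @return Data frame of class `qtl_peaks`: gene, chr, marker, cM, Mbp,
#'   lod, class.
#' @export
find_peaks_eqtl <- function(scan, annot, threshold,
                            local_window_mbp = 10) {
  stopifnot(inherits(scan, "scan_result"))
  map <- attr(scan, "map")
  chrs <- unique(map$chr)
  rows <- list()
  for (j in seq_len(ncol(scan))) {
    gene <- colnames(scan)[j]
    for (ch in chrs) {
      jj <- which(map$chr == ch)
      i <- jj[which.max(scan[jj, j])]
      if (scan[i, j] > threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, chr = ch, marker = map$marker[i],
          cM = map$cM[i], Mbp = map$Mbp[i], lod = scan[i, j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    peaks <- data.frame(gene = character(0), chr = character(0),
                        marker = character(0), cM = numeric(0),
                        Mbp = numeric(0), lod = numeric(0),
                        class = character(0), stringsAsFactors = FALSE)
    class(peaks) <- c("qtl_peaks", "data.frame")
    return(peaks)
  }
  peaks <- do.call(rbind, rows)
  missing <- setdiff(unique(peaks$gene), annot$gene)
  if (length(missing) > 0)
    stop("no annotation for peaked gene(s): ", paste(missing, collapse = ", "))
  ai <- match(peaks$gene, annot$gene)
  mid <- (annot$start[ai] + annot$end[ai]) / 2
  peaks$class <- ifelse(peaks$chr == annot$chr[ai] &
                          abs(peaks$Mbp - mid) <= local_window_mbp,
                        "local", "distant")
  rownames(peaks) <- NULL
  class(peaks) <- c("qtl_peaks", "data.frame")
  peaks
}

#' @export
print.qtl_peaks <- function(x, ...) {
  cat(sprintf("QTL peaks: %d (%d local, %d distant)\n", nrow(x),
              sum(x$class == "local"), sum(x$class == "distant")))
  NextMethod()
}

#' BLUP founder allele effects at a marker
#'
#' Estimates the eight founder effects at a QTL peak as best linear unbiased
#' predictors: the effects are treated as random with a common variance,
#' the effect and residual variances are estimated by maximum likelihood on
#' the kinship-whitened model, and the returned predictors are shrunken
#' toward zero relative to the fixed-effect estimates.  Effects are centered
#' to sum to zero.
#'
#' @param y Phenotype vector.
#' @param P Samples x 8 founder dosage matrix at the peak marker.
#' @param K Kinship matrix for the peak's chromosome (LOCO), or `NULL`.
#' @param covar Covariates as in [scan1_lmm()].
#' @return Named numeric vector of 8 founder effects summing to zero.
#' @export
blup_effects <- function(y, P, K = NULL, covar = NULL) {
  n <- length(y)
  stopifnot(nrow(P) == n, ncol(P) == 8)
  X0 <- .design_matrix(covar, n)
  if (!is.null(K)) {
    eg <- .kinship_eigen(K)
    yr <- drop(crossprod(eg$vectors, y))
    X0r <- crossprod(eg$vectors, X0)
    fit <- .fit_vc(yr, X0r, eg$values, reml = FALSE)
    w <- fit$weights
    yw <- yr * w
    X0w <- X0r * w
    Pw <- crossprod(eg$vectors, P) * w
  } else {
    yw <- y; X0w <- X0; Pw <- P
  }
  sv <- svd(Pw)
  # profile ML over the effect-to-residual variance ratio r:
  # V = I + r * Pw Pw'; log|V| and V^{-1} via the SVD of Pw (Woodbury)
  ll <- function(logr) {
    r <- exp(logr)
    d2 <- sv$d^2
    # GLS estimate of covariate effects under V
    Vinv_times <- function(M) {
      U <- sv$u
      M - U %*% ((r * d2 / (1 + r * d2)) * crossprod(U, M))
    }
    ViX <- Vinv_times(X0w)
    Viy <- Vinv_times(yw)
    beta <- solve(crossprod(X0w, ViX), crossprod(X0w, Viy))
    e <- yw - X0w %*% beta
    quad <- sum(e * Vinv_times(e))
    -0.5 * (n * log(quad / n) + sum(log(1 + r * d2)))
  }
  opt <- optimize(ll, c(-12, 8), maximum = TRUE)
  r <- exp(opt$maximum)
  if (ll(-20) >= opt$objective) r <- exp(-20)
  d2 <- sv$d^2
  Vinv_times <- function(M) {
    U <- sv$u
    M - U %*% ((r * d2 / (1 + r * d2)) * crossprod(U, M))
  }
  beta <- solve(crossprod(X0w, Vinv_times(X0w)), crossprod(X0w, Vinv_times(yw)))
  resid <- yw - X0w %*% beta
  u <- r * crossprod(Pw, Vinv_times(resid))
  u <- drop(u) - mean(u)
  setNames(u, do_founders)
}

#' Attach BLUP founder effects to a peak table
#'
#' Convenience wrapper computing [blup_effects()] at every peak of a
#' [find_peaks_eqtl()] table.
#'
#' @param peaks A `qtl_peaks` data frame.
#' @param Y Samples x phenotypes matrix containing the peaked genes.
#' @param probs Genotype probabilities.
#' @param kinship A [calc_kinship()] result or `NULL`.
#' @param covar Covariates.
#' @return The peak table with columns `eff_A` .. `eff_H` appended.
#' @export
add_blup_effects <- function(peaks, Y, probs, kinship = NULL, covar = NULL) {
  eff <- matrix(NA_real_, nrow(peaks), 8,
                dimnames = list(NULL, paste0("eff_", do_founders)))
  for (i in seq_len(nrow(peaks))) {
    K <- .pick_kinship(kinship, peaks$chr[i])
    eff[i, ] <- blup_effects(Y[, peaks$gene[i]],
                             probs[, , peaks$marker[i]], K, covar)
  }
  out <- cbind(as.data.frame(peaks), as.data.frame(eff))
  class(out) <- c("qtl_peaks", "data.frame")
  out
}
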