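#' Mediation scan: LOD drop for candidate mediator genes
#'
#' For each candidate mediator, restricts to the samples complete in the
#' target, covariates, genotype *and* mediator; computes the base LOD
#' (association of the target with the 8 founder dosages at the QTL peak,
#' plus covariates) on that subset, and the mediated LOD with the mediator's
#' expression added as an additional additive covariate to both the null and
#' the QTL model.  The LOD drop is `base - mediated` on the identical
#' subset, which neutralizes sample-set differences caused by missing values
#' (the double-LOD-difference device); with no missing data it reduces
#' exactly to the plain difference on the full sample set.
#'
#' Models are ordinary least squares at the single peak marker; a
#' kinship-whitened variant is available via `K`.
#'
#' @param target Named phenotype vector (e.g. a hotspot eigengene).
#' @param P Samples x 8 founder dosage matrix at the QTL peak.
#' @param covar Covariates (rows matching `target`), or `NULL`.
#' @param mediators Gene x sample expression matrix of candidate mediators;
#'   samples are matched to `target` by name (cross-cell-type mediation
#'   restricts to the donor intersection automatically).
#' @param min_n Minimum complete-case count; mediators below it are skipped
#'   with a warning.
#' @param K Optional kinship matrix for whitening (default none).
#' @return Data frame of class `mediation_result`, ranked by LOD drop
#'   descending: mediator, n, lod_base, lod_med, drop.
#' @export
mediation_scan <- function(target, P, covar = NULL, mediators, min_n = 30,
                           K = NULL) {
  common <- intersect(names(target), colnames(mediators))
  if (length(common) == 0)
    stop("mediators share no samples with the target")
  y <- target[common]
  P <- P[common, , drop = FALSE]
  X0 <- .design_matrix(if (is.null(covar)) NULL else
    covar[common, , drop = FALSE], length(common))
  Med <- mediators[, common, drop = FALSE]
  if (!is.null(K)) {
    eg <- .kinship_eigen(K[common, common])
    fit <- .fit_vc(drop(crossprod(eg$vectors, y)),
                   crossprod(eg$vectors, X0), eg$values)
    W <- t(eg$vectors) * fit$weights
    y <- drop(W %*% y); X0 <- W %*% X0; P <- W %*% P
    Med <- Med %*% t(W)  # caution: whitening mixes samples; only valid
    # when the mediator has no missing values
  }
  base_ok <- complete.cases(cbind(y, X0, P))
  out <- lapply(rownames(Med), function(g) {
    m <- Med[g, ]
    S <- base_ok & !is.na(m)
    n <- sum(S)
    if (n < min_n) {
      warning("mediator ", g, " skipped: only ", n, " complete samples")
      return(NULL)
    }
    ys <- y[S]; X0s <- X0[S, , drop = FALSE]; Ps <- P[S, , drop = FALSE]
    ms <- m[S]
    lod_base <- .lod_from_rss(.rss(ys, X0s), .rss(ys, cbind(X0s, Ps)), n)
    X0m <- cbind(X0s, mediator = ms)
    lod_med <- .lod_from_rss(.rss(ys, X0m), .rss(ys, cbind(X0m, Ps)), n)
    data.frame(mediator = g, n = n, lod_base = lod_base, lod_med = lod_med,
               drop = lod_base - lod_med, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$drop), ]
  rownames(out) <- NULL
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation scan: %d candidates; top drop = %.2f (%s)\n",
              nrow(x), x$drop[1], x$mediator[1]))
  print(head(as.data.frame(x), 10))
  invisible(x)
}

#' Genome-wide significance of mediation results
#'
#' Standardizes each candidate's mediated LOD against the genome-wide null
#' distribution formed by all candidates:
#' `z = (lod_med - mean(lod_med)) / sd(lod_med)`.  A candidate is
#' significant when `z < z_cut` (default -4 SD).  The positional filter
#' (gene midpoint within `window_mbp` of the QTL peak) is applied afterward
#' to flag eligible candidates.  A rank-based inverse-normal variant of the
#' score is available via `method = "ranknorm"`.
#'
#' @param res A [mediation_scan()] result computed genome-wide
#'   (>= 100 candidates).
#' @param annot Gene annotation (gene, chr, start, end in Mbp).
#' @param peak_chr,peak_mbp QTL peak position.
#' @param method `"moment"` (mean/SD standardization) or `"ranknorm"`.
#' @param z_cut Significance cutoff on z (default -4).
#' @param window_mbp Positional eligibility window (default 10 Mbp).
#' @return The result table with `z`, `significant`, `eligible` columns,
#'   still ordered by drop.
#' @export
mediation_significance <- function(res, annot, peak_chr, peak_mbp,
                                   method = c("moment", "ranknorm"),
                                   z_cut = -4, window_mbp = 10) {
  stopifnot(inherits(res, "mediation_result"))
  method <- match.arg(method)
  if (nrow(res) < 100)
    stop("genome-wide null requires at least 100 candidates")
  if (method == "moment") {
    s <- sd(res$lod_med)
    if (s == 0) stop("zero SD of mediated LODs")
    res$z <- (res$lod_med - mean(res$lod_med)) / s
  } else {
    res$z <- qnorm((rank(res$lod_med, ties.method = "average") - 0.5) /
                     nrow(res))
  }
  res$significant <- res$z < z_cut
  ai <- match(res$mediator, annot$gene)
  mid <- (annot$start[ai] + annot$end[ai]) / 2
  res$eligible <- !is.na(ai) & annot$chr[ai] == peak_chr &
    abs(mid - peak_mbp) <= window_mbp
  res
}

#' Classify samples by ancestry at a QTL peak
#'
#' Under a 4:4 founder allele split, sums each sample's dosage over the
#' "Alt"-side founders and labels the sample `Ref` (alt dosage < 0.25),
#' `Het` (0.25-0.75) or `Alt` (> 0.75).
#'
#' @param P Samples x 8 founder dosage matrix at the peak.
#' @param alt_founders Four founder letters forming the Alt side.
#' @return Data frame of class `genotype_class`: sample, alt_dosage, class.
#' @export
classify_genotype <- function(P, alt_founders) {
  stopifnot(ncol(P) == 8)
  if (!all(alt_founders %in% do_founders) || anyDuplicated(alt_founders) > 0 ||
      length(alt_founders) < 1 || length(alt_founders) > 7)
    stop("alt_founders must form one side of a 2-part partition of the 8 founders")
  g <- rowSums(P[, alt_founders, drop = FALSE])
  cls <- ifelse(g < 0.25, "Ref", ifelse(g > 0.75, "Alt", "Het"))
  out <- data.frame(sample = rownames(P) %||% seq_len(nrow(P)),
                    alt_dosage = g, class = cls, stringsAsFactors = FALSE)
  class(out) <- c("genotype_class", "data.frame")
  out
}

#' Partial correlation between mediator expression and an eigengene,
#' controlling for genotype
#'
#' Residualizes both the candidate mediator's expression and the eigengene
#' on the genotype class at the QTL peak (numeric 0/1/2 coding of
#' Ref/Het/Alt), then computes the Pearson correlation of the residuals with
#' the standard t-based p-value at `n - 3` degrees of freedom.  A true
#' causal mediator should still co-vary with the target eigengene after the
#' shared QTL effect is removed; a decoy gene that merely shares the locus
#' should not.  P-values are BH-adjusted across candidates.
#'
#' @param mediators Gene x sample expression matrix of candidates (e.g. the
#'   genes within 10 Mbp of the peak).
#' @param scores Named eigengene score vector.
#' @param geno_class A [classify_genotype()] result (or a named vector of
#'   Ref/Het/Alt labels).
#' @return Data frame: mediator, n, r_partial, p, p_adj.
#' @export
partial_cor <- function(mediators, scores, geno_class) {
  if (inherits(geno_class, "genotype_class")) {
    cls <- setNames(geno_class$class, geno_class$sample)
  } else cls <- geno_class
  common <- Reduce(intersect, list(colnames(mediators), names(scores),
                                   names(cls)))
  if (length(common) < 10)
    stop("fewer than 10 samples shared between mediators, scores and genotypes")
  gnum <- c(Ref = 0, Het = 1, Alt = 2)[cls[common]]
  X <- cbind(1, gnum)
  qx <- qr(X)
  ry <- qr.resid(qx, scores[common])
  out <- do.call(rbind, lapply(rownames(mediators), function(g) {
    m <- mediators[g, common]
    ok <- !is.na(m)
    n <- sum(ok)
    rm_ <- if (all(ok)) qr.resid(qx, m) else
      qr.resid(qr(X[ok, , drop = FALSE]), m[ok])
    ryo <- if (all(ok)) ry else qr.resid(qr(X[ok, , drop = FALSE]),
                                         scores[common][ok])
    if (sd(rm_) < 1e-12 || sd(ryo) < 1e-12)
      return(data.frame(mediator = g, n = n, r_partial = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    r <- cor(rm_, ryo)
    tt <- r * sqrt((n - 3) / max(1 - r^2, 1e-12))
    p <- 2 * pt(-abs(tt), df = n - 3)
    data.frame(mediator = g, n = n, r_partial = r, p = p,
               stringsAsFactors = FALSE)
  }))
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- p.adjust(out$p[ok], method = "BH")
  rownames(out) <- NULL
  out
}
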