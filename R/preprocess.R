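#' Scale counts to a length-free abundance proxy
#'
#' Divides each sample's counts by its total and multiplies by one million,
#' giving a TPM-like per-million abundance without gene-length correction
#' (appropriate for the synthetic data, which has no transcript lengths).
#'
#' @param counts Gene x sample count matrix.
#' @return Matrix of per-million abundances.
#' @export
counts_per_million <- function(counts) {
  tot <- colSums(counts)
  tot[tot == 0] <- 1
  sweep(counts, 2, tot, "/") * 1e6
}

#' Filter lowly expressed genes
#'
#' A gene is kept when its median abundance across samples is at least 0.5
#' and it is expressed (nonzero) in at least half of the samples.
#'
#' @param expr Gene x sample matrix of TPM-like abundances (values >= 0).
#' @return Character vector of kept gene ids (row names), original order.
#' @export
filter_genes <- function(expr) {
  if (is.null(dim(expr)) || nrow(expr) == 0 || ncol(expr) == 0)
    stop("expression matrix is empty")
  stopifnot(all(expr >= 0))
  med <- apply(expr, 1, median)
  nzero <- rowSums(expr == 0)
  keep <- med >= 0.5 & nzero <= ncol(expr) / 2
  rownames(expr)[keep]
}

#' Upper-quartile normalization
#'
#' Divides each sample by the 75th percentile of its nonzero counts and
#' rescales by the geometric mean of those percentiles across samples, so the
#' output stays on a count-like scale.  Invariant to per-sample rescaling of
#' the input.
#'
#' @param counts Gene x sample count matrix.
#' @return Normalized matrix of the same shape.
#' @export
uq_normalize <- function(counts) {
  q <- vapply(seq_len(ncol(counts)), function(j) {
    x <- counts[, j]
    x <- x[x > 0]
    if (length(x) == 0)
      stop("sample ", colnames(counts)[j] %||% j, " has all-zero counts")
    quantile(x, 0.75, names = FALSE)
  }, numeric(1))
  scale <- exp(mean(log(q)))
  sweep(counts, 2, q, "/") * scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove additive covariate effects by location-scale adjustment
#'
#' For each gene and each factor (applied sequentially), within-level means
#' are equalized to the grand mean and within-level SDs to the pooled SD.
#' This is a location-scale batch correction: on balanced designs it has the
#' same contract as empirical-Bayes batch adjustment but without shrinkage
#' across genes.
#'
#' @param expr Gene x sample matrix.
#' @param factors Data frame (samples x factors) or a single factor/vector;
#'   every level needs at least 2 samples.
#' @return Corrected matrix.
#' @export
remove_covariate_effects <- function(expr, factors) {
  if (!is.data.frame(factors)) factors <- data.frame(f = factors)
  stopifnot(nrow(factors) == ncol(expr))
  out <- expr
  for (fc in names(factors)) {
    f <- factor(factors[[fc]])
    if (any(table(f) < 2))
      stop("factor '", fc, "' has a level with fewer than 2 samples")
    grand <- rowMeans(out)
    lev <- levels(f)
    m <- vapply(lev, function(l) rowMeans(out[, f == l, drop = FALSE]),
                numeric(nrow(out)))
    v <- vapply(lev, function(l)
      apply(out[, f == l, drop = FALSE], 1, var), numeric(nrow(out)))
    # pooled within-level SD
    nl <- as.numeric(table(f))
    pooled <- sqrt(as.vector(v %*% (nl - 1)) / (sum(nl) - length(lev)))
    for (l in seq_along(lev)) {
      jj <- which(f == lev[l])
      s <- sqrt(v[, l])
      ratio <- ifelse(s > 1e-12 & pooled > 1e-12, pooled / s, 1)
      out[, jj] <- (out[, jj, drop = FALSE] - m[, l]) * ratio + grand
    }
  }
  out
}

#' Rank-based inverse normal transform (rankZ)
#'
#' Per gene, values map to normal scores `qnorm((rank - 0.5) / n)` with
#' average ranks for ties.  Output rows have mean ~0 and SD ~1 and the
#' transform is invariant to monotone transformations of the input.
#'
#' @param expr Gene x sample matrix (or a single numeric vector).
#' @return Transformed matrix (or vector).
#' @export
rankz <- function(expr) {
  tr <- function(x) qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
  if (is.null(dim(expr))) return(tr(expr))
  out <- t(apply(expr, 1, tr))
  dimnames(out) <- dimnames(expr)
  out
}

#' Match samples between two genotype datasets
#'
#' Correlates each sample's genotype vector in dataset A with every sample in
#' dataset B over the shared markers, reporting the best-correlated partner
#' and flagging labelled pairs that are not each other's best match
#' (sample mix-ups).  Same-sample correlations are typically far higher than
#' different-sample correlations, which makes the assignment unambiguous.
#'
#' @param genoA,genoB Sample x marker numeric matrices (e.g. flattened founder
#'   dosages); column names identify markers, row names identify samples.
#' @return List with `assignment` (data frame: sample, best_match, cor,
#'   labelled_cor, mixup) and `cor_matrix`.
#' @export
match_samples <- function(genoA, genoB) {
  shared <- intersect(colnames(genoA), colnames(genoB))
  if (length(shared) < 10)
    stop("fewer than 10 shared markers between genotype datasets")
  C <- cor(t(genoA[, shared, drop = FALSE]), t(genoB[, shared, drop = FALSE]))
  best <- apply(C, 1, which.max)
  lab <- match(rownames(genoA), rownames(genoB))
  assignment <- data.frame(
    sample = rownames(genoA),
    best_match = colnames(C)[best] %||% rownames(genoB)[best],
    cor = C[cbind(seq_len(nrow(C)), best)],
    labelled_cor = ifelse(is.na(lab), NA_real_,
                          C[cbind(seq_len(nrow(C)), lab)]),
    mixup = is.na(lab) | best != lab,
    stringsAsFactors = FALSE)
  rownames(C) <- rownames(genoA)
  colnames(C) <- rownames(genoB)
  list(assignment = assignment, cor_matrix = C)
}

#' Inter-transcriptome Spearman correlations
#'
#' Computes Spearman correlations between every pair of samples across the
#' two cell types over shared genes, then splits the matrix into the
#' matched-donor (same sample id) and mismatched-donor sets.
#'
#' @param exprA,exprB Gene x sample matrices; row names identify genes,
#'   column names identify donors.
#' @return List with `cor_matrix`, `matched`, `mismatched`,
#'   `median_matched`, `median_mismatched`.
#' @export
correlate_transcriptomes <- function(exprA, exprB) {
  shared <- intersect(rownames(exprA), rownames(exprB))
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  C <- cor(exprA[shared, , drop = FALSE], exprB[shared, , drop = FALSE],
           method = "spearman")
  common <- intersect(colnames(exprA), colnames(exprB))
  matched <- C[cbind(match(common, rownames(C)), match(common, colnames(C)))]
  names(matched) <- common
  mis <- C
  mis[cbind(match(common, rownames(C)), match(common, colnames(C)))] <- NA
  mismatched <- mis[!is.na(mis)]
  list(cor_matrix = C, matched = matched, mismatched = mismatched,
       median_matched = median(matched),
       median_mismatched = median(mismatched))
}

#' Differential expression between cell types
#'
#' Per gene: a two-sided Wilcoxon rank-sum test comparing the two groups of
#' samples, Benjamini-Hochberg adjustment across genes, and
#' `log2FC = log2(mean(B)/mean(A))`.  Genes are labelled up/down in B only
#' when adjusted p < 0.05 and |log2FC| > 2; genes with a non-positive group
#' mean get an undefined fold change and are excluded from labelling.
#'
#' @param exprA,exprB Gene x sample matrices on a positive expression scale;
#'   rows are matched by gene id.
#' @param p_cut,lfc_cut Label thresholds.
#' @return Data frame of class `de_result`: gene, p, p_adj, log2fc, label.
#' @export
differential_expression <- function(exprA, exprB, p_cut = 0.05, lfc_cut = 2) {
  shared <- intersect(rownames(exprA), rownames(exprB))
  stopifnot(length(shared) >= 1, ncol(exprA) >= 2, ncol(exprB) >= 2)
  exact <- ncol(exprA) <= 25 && ncol(exprB) <= 25
  p <- vapply(shared, function(g) {
    suppressWarnings(
      wilcox.test(exprB[g, ], exprA[g, ], exact = exact)$p.value)
  }, numeric(1))
  p[is.na(p)] <- 1  # degenerate (all-tied) genes carry no evidence
  mA <- rowMeans(exprA[shared, , drop = FALSE])
  mB <- rowMeans(exprB[shared, , drop = FALSE])
  ok <- mA > 0 & mB > 0
  lfc <- ifelse(ok, log2(mB / mA), NA_real_)
  padj <- p.adjust(p, method = "BH")
  label <- rep("ns", length(shared))
  label[ok & padj < p_cut & lfc > lfc_cut] <- "up"
  label[ok & padj < p_cut & lfc < -lfc_cut] <- "down"
  label[!ok] <- "undefined_fc"
  res <- data.frame(gene = shared, p = p, p_adj = padj, log2fc = lfc,
                    label = label, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

#' Principal component summary of an expression matrix
#'
#' Centers each gene and decomposes the sample covariance, returning sample
#' scores, gene loadings, variance fractions and the driver-gene sets (genes
#' whose absolute loading exceeds a quantile cutoff) for the leading
#' components.
#'
#' @param expr Gene x sample matrix (one cell type, or both combined).
#' @param n_pc Number of components to return.
#' @param driver_quantile Quantile of |loading| defining driver genes.
#' @return List with `scores` (samples x PCs), `loadings` (genes x PCs),
#'   `var_frac`, `drivers` (list of gene id vectors).
#' @export
pca_scores <- function(expr, n_pc = 2, driver_quantile = 0.95) {
  Xc <- expr - rowMeans(expr)
  sv <- svd(Xc)
  pos <- sum(sv$d > max(sv$d) * 1e-10)
  if (n_pc > pos)
    stop("requested ", n_pc, " components but matrix rank is ", pos)
  scores <- sv$v[, seq_len(n_pc), drop = FALSE] %*%
    diag(sv$d[seq_len(n_pc)], n_pc)
  rownames(scores) <- colnames(expr)
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  loadings <- sv$u[, seq_len(n_pc), drop = FALSE]
  rownames(loadings) <- rownames(expr)
  colnames(loadings) <- colnames(scores)
  var_frac <- sv$d^2 / sum(sv$d^2)
  drivers <- lapply(seq_len(n_pc), function(k) {
    a <- abs(loadings[, k])
    rownames(expr)[a >= quantile(a, driver_quantile)]
  })
  names(drivers) <- colnames(scores)
  list(scores = scores, loadings = loadings,
       var_frac = var_frac[seq_len(n_pc)], drivers = drivers)
}
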