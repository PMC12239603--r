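#' Founder-haplotype LMM genome scan
#'
#' Maps each phenotype against the 8 founder dosages at every marker with a
#' linear mixed model.  Per chromosome, the null variance components are
#' estimated once against that chromosome's LOCO kinship, the data are
#' rotated to the kinship eigenbasis and whitened, and each marker is fit by
#' weighted least squares on the founder dosage columns plus covariates using
#' a pseudoinverse (the eight dosage columns sum to one and absorb the
#' intercept).  `LOD = (n/2) log10(RSS_null / RSS_marker)`.
#'
#' With `kinship = NULL` the scan reduces exactly to fixed-effects least
#' squares regression.
#'
#' @param Y Phenotype vector or samples x phenotypes matrix.
#' @param probs Genotype probabilities (samples x 8 x markers).
#' @param map Genome map matching the marker dimension.
#' @param kinship A [calc_kinship()] result (LOCO matrices used when
#'   present), a single matrix, or `NULL` for no polygenic term.
#' @param covar Covariates (data frame or matrix); an intercept is added to
#'   the null model.
#' @param reml Use REML for the null variance components (default ML).
#' @return Object of class `scan_result`: LOD matrix (markers x phenotypes)
#'   with the map and per-phenotype, per-chromosome variance components as
#'   attributes.
#' @examples
#' st <- sim_study(n_samples = 40, n_shared = 30,
#'                 map = sim_map(n_chr = 2, markers_per_chr = 30),
#'                 n_genes = 40, n_local = 4, n_targets = 3,
#'                 n_targets_weak = 0, n_decoys = 1, seed = 2)
#' y <- rankz(st$latent$A[st$truth$local$gene[1], ])
#' sc <- scan1_lmm(y, st$probs, st$map)
#' max(sc)
#' @export
scan1_lmm <- function(Y, probs, map, kinship = NULL, covar = NULL,
                      reml = FALSE) {
  .check_map(map)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "pheno"))
  n <- nrow(Y)
  stopifnot(dim(probs)[1] == n, dim(probs)[3] == nrow(map))
  X0 <- .design_matrix(covar, n)
  chrs <- unique(map$chr)
  lod <- matrix(NA_real_, nrow(map), ncol(Y),
                dimnames = list(map$marker, colnames(Y)))
  vc <- list()
  for (ch in chrs) {
    jj <- which(map$chr == ch)
    G <- .flatten_probs(probs[, , jj, drop = FALSE])
    K <- .pick_kinship(kinship, ch)
    if (is.null(K)) {
      for (j in seq_len(ncol(Y)))
        lod[jj, j] <- .scan_chr(Y[, j], X0, G, n)
    } else {
      eg <- .kinship_eigen(K)
      Gr <- crossprod(eg$vectors, G)
      X0r <- crossprod(eg$vectors, X0)
      Yr <- crossprod(eg$vectors, Y)
      vc[[ch]] <- vector("list", ncol(Y))
      for (j in seq_len(ncol(Y))) {
        fit <- .fit_vc(Yr[, j], X0r, eg$values, reml = reml)
        vc[[ch]][[j]] <- fit[c("h2", "Vg", "Ve")]
        w <- fit$weights
        lod[jj, j] <- .scan_chr(Yr[, j] * w, X0r * w, Gr * w, n)
      }
    }
  }
  structure(lod, class = c("scan_result", "matrix"), map = map, vc = vc)
}

# choose the kinship matrix for a chromosome
.pick_kinship <- function(kinship, ch) {
  if (is.null(kinship)) return(NULL)
  if (inherits(kinship, "kinship_set")) {
    if (!is.null(kinship$loco)) return(kinship$loco[[ch]])
    return(kinship$full)
  }
  kinship
}

# LOD scores for one chromosome on (already whitened) data.
# Founder columns are residualized on the null design; the per-marker fit
# uses the eigendecomposition of the 8x8 cross-product, i.e. a pseudoinverse.
.scan_chr <- function(yw, X0w, Gw, n) {
  q0 <- qr(X0w)
  yr <- qr.resid(q0, yw)
  rss0 <- sum(yr^2)
  Gr <- qr.resid(q0, Gw)
  cty <- drop(crossprod(Gr, yr))
  Mc <- ncol(Gw) / 8L
  lod <- numeric(Mc)
  if (rss0 <= .Machine$double.eps * n) return(lod)
  for (m in seq_len(Mc)) {
    j <- (m * 8L - 7L):(m * 8L)
    A <- crossprod(Gr[, j])
    e <- eigen(A, symmetric = TRUE)
    pos <- e$values > max(e$values[1], 1e-300) * 1e-9
    if (!any(pos)) next
    z <- crossprod(e$vectors[, pos, drop = FALSE], cty[j])
    expl <- sum(z^2 / e$values[pos])
    lod[m] <- .lod_from_rss(rss0, rss0 - expl, n)
  }
  lod
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Genome scan: %d markers x %d phenotype(s); max LOD = %.2f\n",
              nrow(x), ncol(x), max(x)))
  invisible(x)
}

#' @method summary scan_result
#' @export
summary.scan_result <- function(object, ...) {
  map <- attr(object, "map")
  i <- apply(object, 2, which.max)
  data.frame(pheno = colnames(object),
             chr = map$chr[i], marker = map$marker[i],
             cM = map$cM[i], Mbp = map$Mbp[i],
             lod = object[cbind(i, seq_len(ncol(object)))],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @method plot scan_result
#' @export
plot.scan_result <- function(x, pheno = 1, ...) {
  map <- attr(x, "map")
  chrs <- unique(map$chr)
  off <- c(0, cumsum(tapply(map$cM, factor(map$chr, levels = chrs), max)))
  pos <- map$cM + off[match(map$chr, chrs)]
  graphics::plot(pos, x[, pheno], type = "l", xlab = "position (cM, cumulative)",
                 ylab = "LOD", ...)
  graphics::abline(v = off[-1], col = "grey80", lty = 2)
  invisible(x)
}
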