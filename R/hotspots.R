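#' Detect distant-eQTL hotspots by sliding window
#'
#' Counts distant eQTL in 1 cM windows shifted by 0.25 cM across the genome,
#' selects the bins whose counts reach the `(1 - top_fraction)` quantile of
#' all bin counts (ties included), merges selected bins that overlap or abut
#' into candidate intervals, and keeps intervals with more than `min_members`
#' significant distant eQTL.  Bins are half-open `[start, start + window)`.
#'
#' @param peaks A `qtl_peaks` table at the significant threshold (only rows
#'   with `class == "distant"` are counted).
#' @param map Genome map (supplies chromosome lengths and the cM-Mbp
#'   relation).
#' @param top_fraction Fraction of top bins selected (default 0.005, i.e.
#'   the top 0.5%).
#' @param min_members Minimum number of significant distant eQTL members for
#'   a reported hotspot (default 20, i.e. hotspots contain > 20).
#' @param window_cM,step_cM Window width and shift.
#' @param suggestive_peaks Optional `qtl_peaks` table at the suggestive
#'   threshold; member target genes are collected per hotspot.
#' @return Object of class `hotspot_set`: list with `hotspots` (data frame:
#'   chr, start_cM, end_cM, start_Mbp, end_Mbp, n_significant,
#'   n_suggestive), `members` (list of significant member peak tables),
#'   `targets` (list of suggestive target gene vectors), `bins`,
#'   `count_threshold`.
#' @export
call_hotspots <- function(peaks, map, top_fraction = 0.005, min_members = 20,
                          window_cM = 1, step_cM = 0.25,
                          suggestive_peaks = NULL) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  .check_map(map)
  dist <- peaks[peaks$class == "distant", , drop = FALSE]
  empty <- list(hotspots = data.frame(chr = character(0), start_cM = numeric(0),
                                      end_cM = numeric(0), start_Mbp = numeric(0),
                                      end_Mbp = numeric(0),
                                      n_significant = integer(0),
                                      n_suggestive = integer(0),
                                      stringsAsFactors = FALSE),
                members = list(), targets = list(), bins = NULL,
                count_threshold = NA_real_)
  if (nrow(dist) == 0) return(structure(empty, class = "hotspot_set"))

  chr_len <- attr(map, "chr_len")
  if (is.null(chr_len))
    chr_len <- tapply(map$cM, map$chr, max)
  bins <- do.call(rbind, lapply(unique(map$chr), function(ch) {
    starts <- seq(0, max(chr_len[[ch]] - window_cM, 0), by = step_cM)
    data.frame(chr = ch, start = starts, end = starts + window_cM,
               stringsAsFactors = FALSE)
  }))
  cnt <- integer(nrow(bins))
  for (ch in unique(bins$chr)) {
    bi <- which(bins$chr == ch)
    pp <- dist$cM[dist$chr == ch]
    if (length(pp) == 0) next
    cnt[bi] <- vapply(bi, function(i)
      sum(pp >= bins$start[i] & pp < bins$end[i]), integer(1))
  }
  bins$count <- cnt
  thr <- quantile(cnt, 1 - top_fraction, type = 1, names = FALSE)
  thr <- max(thr, 1)
  sel <- bins[bins$count >= thr, , drop = FALSE]
  if (nrow(sel) == 0) {
    empty$bins <- bins; empty$count_threshold <- thr
    return(structure(empty, class = "hotspot_set"))
  }

  # merge overlapping/abutting selected bins per chromosome (integer
  # quarter-cM coordinates so IRanges can reduce them)
  hs <- list(); members <- list(); targets <- list()
  for (ch in unique(sel$chr)) {
    sc <- sel[sel$chr == ch, ]
    ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(round(sc$start * 100)),
                                           end = as.integer(round(sc$end * 100)) - 1L))
    for (k in seq_along(ir)) {
      s_cM <- IRanges::start(ir)[k] / 100
      e_cM <- (IRanges::end(ir)[k] + 1L) / 100
      mem <- dist[dist$chr == ch & dist$cM >= s_cM & dist$cM < e_cM, ,
                  drop = FALSE]
      if (nrow(mem) < min_members) next
      tg <- character(0)
      n_sug <- NA_integer_
      if (!is.null(suggestive_peaks)) {
        tg <- .targets_in_interval(suggestive_peaks, ch, s_cM, e_cM)
        n_sug <- length(tg)
      }
      hs[[length(hs) + 1L]] <- data.frame(
        chr = ch, start_cM = s_cM, end_cM = e_cM,
        start_Mbp = cm_to_mbp(map, ch, s_cM),
        end_Mbp = cm_to_mbp(map, ch, e_cM),
        n_significant = nrow(mem), n_suggestive = n_sug,
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- mem
      targets[[length(targets) + 1L]] <- tg
    }
  }
  if (length(hs) == 0) {
    empty$bins <- bins; empty$count_threshold <- thr
    return(structure(empty, class = "hotspot_set"))
  }
  structure(list(hotspots = do.call(rbind, hs), members = members,
                 targets = targets, bins = bins, count_threshold = thr),
            class = "hotspot_set")
}

.targets_in_interval <- function(peaks, chr, start_cM, end_cM) {
  sel <- peaks$class == "distant" & peaks$chr == chr &
    peaks$cM >= start_cM & peaks$cM < end_cM
  unique(peaks$gene[sel])
}

#' Target genes of a hotspot at the suggestive threshold
#'
#' Genes whose suggestive distant peak falls inside the hotspot interval.
#'
#' @param hotspots A [call_hotspots()] result.
#' @param suggestive_peaks `qtl_peaks` table at the suggestive threshold.
#' @param which Index of the hotspot.
#' @return Character vector of unique gene ids.
#' @export
hotspot_targets <- function(hotspots, suggestive_peaks, which = 1) {
  stopifnot(inherits(hotspots, "hotspot_set"),
            which <= nrow(hotspots$hotspots))
  h <- hotspots$hotspots[which, ]
  .targets_in_interval(suggestive_peaks, h$chr, h$start_cM, h$end_cM)
}

#' @export
print.hotspot_set <- function(x, ...) {
  cat(sprintf("Hotspots: %d called (bin count threshold %s)\n",
              nrow(x$hotspots),
              format(x$count_threshold)))
  if (nrow(x$hotspots) > 0) print(x$hotspots)
  invisible(x)
}

#' Eigengene of a target gene set
#'
#' First principal component of the targets x samples expression matrix
#' (genes centered), used as a composite phenotype for hotspot-level QTL
#' mapping.  The sign is oriented so the scores correlate positively with
#' the mean target expression.
#'
#' @param expr Gene x sample expression matrix (rankZ stage recommended).
#' @param target_genes Character vector of at least 3 target gene ids
#'   present in `expr`.
#' @return List with `scores` (named per sample), `var_frac` (variance
#'   fraction of PC1), `n_genes`.
#' @export
eigengene <- function(expr, target_genes) {
  target_genes <- intersect(target_genes, rownames(expr))
  if (length(target_genes) < 3)
    stop("eigengene requires at least 3 target genes present in the matrix")
  X <- expr[target_genes, , drop = FALSE]
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  scores <- sv$v[, 1] * sv$d[1]
  if (cor(scores, colMeans(X)) < 0) scores <- -scores
  names(scores) <- colnames(expr)
  list(scores = scores, var_frac = sv$d[1]^2 / sum(sv$d^2),
       n_genes = length(target_genes))
}
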