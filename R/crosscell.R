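#' Classify eQTL as shared or unique between two cell types
#'
#' For each peak of cell type A (at the main threshold): if the gene is not
#' in cell type B's expressed gene list the verdict is
#' `not_expressed_in_B`; otherwise B's peaks for the same gene on the same
#' chromosome within `max_dist_mbp` are candidates (the closest wins, ties
#' broken by higher LOD), the Pearson correlation of the two 8-founder
#' effect vectors is tested (two-sided, n = 8), p-values are BH-adjusted
#' across all tested pairs, and the peak is called `shared` when the
#' distance gate passes and the adjusted p is below `p_cut`.  Negative
#' effect correlations with small adjusted p also count as shared; the sign
#' is reported.
#'
#' @param peaksA Cell-type-A peak table with BLUP effect columns
#'   `eff_A`..`eff_H` (see [add_blup_effects()]), at the significant
#'   threshold.
#' @param peaksB Cell-type-B peak table with effect columns, typically at a
#'   relaxed threshold (LOD > 5 by convention).
#' @param genesB Character vector of genes expressed in cell type B.
#' @param max_dist_mbp Peak distance gate (default 5 Mbp).
#' @param p_cut Adjusted-p cutoff for effect-correlation significance
#'   (default 0.1).
#' @return List with `calls` (data frame: gene, class, verdict, dist_Mbp,
#'   r, p, p_adj) and `summary` (shared fraction among local and distant
#'   A peaks).
#' @export
match_shared_eqtl <- function(peaksA, peaksB, genesB, max_dist_mbp = 5,
                              p_cut = 0.1) {
  effc <- paste0("eff_", do_founders)
  if (!all(effc %in% names(peaksA)) || !all(effc %in% names(peaksB)))
    stop("both peak tables must carry 8 founder effect columns eff_A..eff_H")
  calls <- data.frame(gene = peaksA$gene, class = peaksA$class,
                      verdict = NA_character_, dist_Mbp = NA_real_,
                      r = NA_real_, p = NA_real_, p_adj = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaksA))) {
    g <- peaksA$gene[i]
    if (!(g %in% genesB)) {
      calls$verdict[i] <- "not_expressed_in_B"
      next
    }
    cand <- which(peaksB$gene == g & peaksB$chr == peaksA$chr[i] &
                    abs(peaksB$Mbp - peaksA$Mbp[i]) <= max_dist_mbp)
    if (length(cand) == 0) {
      calls$verdict[i] <- "not_mapped_in_B"
      next
    }
    d <- abs(peaksB$Mbp[cand] - peaksA$Mbp[i])
    cand <- cand[order(d, -peaksB$lod[cand])]
    b <- cand[1]
    ea <- as.numeric(peaksA[i, effc])
    eb <- as.numeric(peaksB[b, effc])
    ct <- suppressWarnings(cor.test(ea, eb))
    calls$dist_Mbp[i] <- abs(peaksB$Mbp[b] - peaksA$Mbp[i])
    calls$r[i] <- unname(ct$estimate)
    calls$p[i] <- ct$p.value
  }
  tested <- !is.na(calls$p)
  calls$p_adj[tested] <- p.adjust(calls$p[tested], method = "BH")
  calls$verdict[tested] <- ifelse(calls$p_adj[tested] < p_cut,
                                  "shared", "not_mapped_in_B")
  shared_frac <- function(cl) {
    sel <- calls$class == cl
    if (!any(sel)) return(NA_real_)
    mean(calls$verdict[sel] == "shared")
  }
  list(calls = calls,
       summary = c(shared_local = shared_frac("local"),
                   shared_distant = shared_frac("distant")))
}
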