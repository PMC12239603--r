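#' Standard expression processing chain
#'
#' Counts to per-million abundances, low-expression filtering, upper-quartile
#' normalization, optional location-scale batch correction, and rankZ.
#'
#' @param counts Gene x sample count matrix.
#' @param batch Optional batch labels (vector or data frame of factors).
#' @return Gene x sample rankZ matrix of the kept genes.
#' @export
preprocess_counts <- function(counts, batch = NULL) {
  keep <- filter_genes(counts_per_million(counts))
  x <- uq_normalize(counts[keep, , drop = FALSE])
  if (!is.null(batch)) x <- remove_covariate_effects(x, batch)
  rankz(x)
}

#' Run the full eQTL pipeline on synthetic data
#'
#' End-to-end driver: simulate a two-cell-type study, process expression,
#' compute LOCO kinship, scan every gene, estimate permutation thresholds,
#' call and classify peaks with BLUP effects, detect hotspots, map the first
#' hotspot's eigengene, run the mediation scan and partial-correlation
#' analysis, and (optionally) write the result tables as TSV.  Fully
#' deterministic given `seed`: two runs with the same configuration produce
#' byte-identical output files.
#'
#' @param outdir Output directory for TSV tables, or `NULL` to skip writing.
#' @param seed Master seed.
#' @param n_perm Permutations for the threshold estimate.
#' @param perm_phenos Number of phenotypes pooled in the permutation run.
#' @param sim_args List of arguments passed to [sim_study()].
#' @return Invisibly, a list with the intermediate objects (`study`,
#'   `expr`, `kinship`, `scans`, `thresholds`, `peaks`,
#'   `peaks_suggestive`, `hotspots`, `eigen`, `mediation`, `partial`).
#' @export
run_pipeline <- function(outdir = NULL, seed = 1, n_perm = 100,
                         perm_phenos = 5, sim_args = list()) {
  st <- do.call(sim_study, c(list(seed = seed), sim_args))
  exprB <- preprocess_counts(st$counts$B, st$covariates$B$batch)
  exprA <- preprocess_counts(st$counts$A, st$covariates$A$batch)

  samples_b <- colnames(exprB)
  probsB <- st$probs[samples_b, , , drop = FALSE]
  kinB <- calc_kinship(probsB, st$map, "loco")
  covB <- st$covariates$B[samples_b, "sex", drop = FALSE]

  Y <- t(exprB)
  scans <- scan1_lmm(Y, probsB, st$map, kinB, covB)
  thr <- perm_threshold(Y[, seq_len(min(perm_phenos, ncol(Y))), drop = FALSE],
                        probsB, st$map, kinB, covB,
                        n_perm = n_perm, seed = .subseed(seed, 101))
  peaks <- find_peaks_eqtl(scans, st$arch$genes,
                           thr$thresholds[["significant"]])
  peaks_sug <- find_peaks_eqtl(scans, st$arch$genes,
                               thr$thresholds[["suggestive"]])
  peaks <- add_blup_effects(peaks, Y, probsB, kinB, covB)

  hs <- call_hotspots(peaks, st$map, suggestive_peaks = peaks_sug)

  eig <- NULL; med <- NULL; pcors <- NULL
  if (nrow(hs$hotspots) > 0) {
    targets <- hotspot_targets(hs, peaks_sug, 1)
    eig <- eigengene(exprB, targets)
    esc <- scan1_lmm(eig$scores, probsB, st$map, kinB, covB)
    pk <- summary(esc)
    Ppeak <- probsB[, , pk$marker[1]]
    med <- mediation_scan(eig$scores, Ppeak, covB, exprB)
    med <- mediation_significance(med, st$arch$genes, pk$chr[1], pk$Mbp[1])
    gc <- classify_genotype(Ppeak, st$arch$mediator$alt_founders)
    elig <- med$mediator[med$eligible]
    if (length(elig) > 0)
      pcors <- partial_cor(exprB[elig, , drop = FALSE], eig$scores, gc)
  }

  out <- list(study = st, expr = list(A = exprA, B = exprB), kinship = kinB,
              scans = scans, thresholds = thr, peaks = peaks,
              peaks_suggestive = peaks_sug, hotspots = hs, eigen = eig,
              mediation = med, partial = pcors)
  if (!is.null(outdir)) write_pipeline_tables(out, outdir)
  invisible(out)
}

#' Write pipeline result tables as TSV
#'
#' @param res A [run_pipeline()] result.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
write_pipeline_tables <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    f <- file.path(outdir, name)
    write.table(format(as.data.frame(df), digits = 10, trim = TRUE), f,
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, f)
  }
  w(res$peaks, "peaks.tsv")
  w(res$peaks_suggestive, "peaks_suggestive.tsv")
  w(res$hotspots$hotspots, "hotspots.tsv")
  if (!is.null(res$mediation)) w(res$mediation, "mediation.tsv")
  if (!is.null(res$partial)) w(res$partial, "partial_correlation.tsv")
  jsonlite::write_json(as.list(res$thresholds$thresholds),
                       file.path(outdir, "thresholds.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(outdir, "thresholds.json")))
}
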