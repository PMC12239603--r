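#' Simulate a complete two-cell-type eQTL study
#'
#' One-stop generator used throughout the package's tests and examples:
#' simulates a DO-style genome, founder genotype probabilities, covariates,
#' latent expression for two donor-matched cell types under a planted
#' architecture, and negative-binomial counts.  Defaults mirror the scale of
#' a typical DO cell-line panel: 186 donors profiled in the derived cell
#' type B (the one carrying the distant-eQTL hotspot), of which 127 common
#' donors also carry progenitor cell-type-A expression.
#'
#' @param n_samples Number of donors (cell type B samples).
#' @param n_shared Number of common donors also profiled in cell type A.
#' @param map Genome map; default [sim_map()] (5 chromosomes x 100 cM x 200
#'   markers).
#' @param recomb_rate Crossovers per cM for the haplotype mosaics.
#' @param blur_sd Genotype-probability blur.
#' @param seed Master seed; all stages derive their seeds from it.
#' @param ... Passed to [sim_architecture()].
#'
#' @return A list of class `sim_study` with elements `map`, `probs`,
#'   `arch`, `covariates` (list A/B), `latent` (list A/B), `counts`
#'   (list A/B), `truth`, `samples_a`, `seed`.
#' @examples
#' st <- sim_study(n_samples = 40, n_shared = 30,
#'                 map = sim_map(n_chr = 2, markers_per_chr = 30),
#'                 n_genes = 60, n_local = 5, n_targets = 5,
#'                 n_targets_weak = 0, n_decoys = 2, seed = 1)
#' dim(st$counts$A)
#' @export
sim_study <- function(n_samples = 186, n_shared = 127, map = sim_map(),
                      recomb_rate = 0.1, blur_sd = 0.02, seed = 1, ...) {
  stopifnot(n_shared <= n_samples)
  mos <- sim_mosaics(map, n_samples, recomb_rate, seed = .subseed(seed, 1))
  set.seed(.subseed(seed, 2))
  probs <- mosaics_to_probs(mos, map, blur_sd = blur_sd)
  samples <- dimnames(probs)[[1]]
  samples_a <- samples[seq_len(n_shared)]

  arch <- sim_architecture(map, seed = .subseed(seed, 3), ...)

  set.seed(.subseed(seed, 4))
  sex <- sample(rep(c("F", "M"), length.out = n_samples))
  covB <- data.frame(sex = sex,
                     batch = sample(paste0("b", seq_len(arch$params$n_batches)),
                                    n_samples, replace = TRUE),
                     row.names = samples, stringsAsFactors = FALSE)
  covA <- data.frame(sex = sex[seq_len(n_shared)],
                     batch = sample(paste0("b", seq_len(arch$params$n_batches)),
                                    n_shared, replace = TRUE),
                     row.names = samples_a, stringsAsFactors = FALSE)
  covariates <- list(A = covA, B = covB)

  ex <- sim_expression(probs, map, arch, covariates, samples_a = samples_a,
                       seed = .subseed(seed, 5))

  set.seed(.subseed(seed, 6))
  lsr <- arch$params$lib_size_range
  libA <- runif(n_shared, lsr[1], lsr[2])
  libB <- runif(n_samples, lsr[1], lsr[2])
  counts <- list(
    A = sim_counts(ex$latent$A, dispersion = arch$params$dispersion,
                   lib_sizes = libA, seed = .subseed(seed, 7)),
    B = sim_counts(ex$latent$B, dispersion = arch$params$dispersion,
                   lib_sizes = libB, seed = .subseed(seed, 8)))

  structure(list(map = map, probs = probs, arch = arch,
                 covariates = covariates, latent = ex$latent,
                 counts = counts, truth = ex$truth,
                 samples_a = samples_a, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic two-cell-type eQTL study\n")
  cat(sprintf("  %d samples (%d shared donors), %d markers on %d chromosomes\n",
              dim(x$probs)[1], length(x$samples_a), dim(x$probs)[3],
              length(unique(x$map$chr))))
  cat(sprintf("  %d genes/cell type; %d local eQTL; hotspot on chr %s at %.1f cM (%d strong targets)\n",
              nrow(x$arch$genes), nrow(x$truth$local), x$truth$mediator$chr,
              x$truth$mediator$cM, sum(x$truth$targets$strong)))
  invisible(x)
}

#' Write study objects as plain-text files
#'
#' Writers for the package's on-disk formats: marker map, genotype
#' probabilities (one TSV per chromosome, rows = sample x founder, columns =
#' markers), expression matrices (genes x samples), truth tables, and a JSON
#' run-metadata file carrying the seed.
#'
#' @param study A [sim_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  w <- function(df, name, rn = FALSE) {
    f <- file.path(dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = rn)
    files <<- c(files, f)
  }
  w(study$map, "map.tsv")
  for (ch in unique(study$map$chr)) {
    jj <- which(study$map$chr == ch)
    sl <- study$probs[, , jj, drop = FALSE]
    d <- dim(sl)
    flat <- matrix(aperm(sl, c(2, 1, 3)), d[1] * d[2], d[3])
    rownames(flat) <- paste(rep(dimnames(sl)[[1]], each = 8),
                            rep(do_founders, d[1]), sep = ":")
    colnames(flat) <- dimnames(sl)[[3]]
    w(round(flat, 6), sprintf("probs_chr%s.tsv", ch), rn = TRUE)
  }
  w(study$counts$A, "counts_A.tsv", rn = TRUE)
  w(study$counts$B, "counts_B.tsv", rn = TRUE)
  w(study$covariates$A, "covar_A.tsv", rn = TRUE)
  w(study$covariates$B, "covar_B.tsv", rn = TRUE)
  w(study$arch$genes, "annotation.tsv")
  w(study$truth$local, "truth_local.tsv")
  w(study$truth$targets, "truth_targets.tsv")
  meta <- list(seed = study$seed,
               n_samples = dim(study$probs)[1],
               n_shared = length(study$samples_a),
               mediator = study$truth$mediator$gene,
               hotspot_marker = study$truth$mediator$marker)
  jsonlite::write_json(meta, file.path(dir, "run_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, file.path(dir, "run_meta.json")))
}
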