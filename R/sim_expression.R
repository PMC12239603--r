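#' Define a planted genetic architecture
#'
#' Specifies the ground truth for a two-cell-type synthetic expression study:
#' a set of local eQTL with chosen heritabilities, one distant-eQTL hotspot
#' whose effect flows entirely through a mediator gene with a 4:4 founder
#' allele split, decoy local eQTL near the hotspot, and covariate effects.
#' Cell type A plays the progenitor (ESC-like) role, cell type B the derived
#' (NPC-like) role carrying the hotspot targets.
#'
#' @param map Genome map from [sim_map()].
#' @param n_genes Total number of genes per cell type (non-eQTL genes are
#'   pure noise).
#' @param n_local Number of planted local eQTL genes (effects shared between
#'   cell types).
#' @param local_h2 QTL heritability of each local eQTL, in `[0, 1)`.
#' @param hotspot_chr,hotspot_cM Location of the planted hotspot.
#' @param mediator_h2 QTL heritability of the mediator's local eQTL at the
#'   hotspot marker.
#' @param mediator_cell Cell type(s) whose expression matrix contains the
#'   mediator transcript: `"B"` (same cell as the targets), `"A"`
#'   (progenitor only; the cross-cell-type design) or `"both"`.
#' @param alt_founders Founder letters forming the "Alt" side of the 4:4
#'   allele split at the hotspot.
#' @param n_targets,target_slope,target_noise_sd Strong hotspot targets:
#'   each target in cell B equals `target_slope` times the mediator's latent
#'   value plus Gaussian noise; there is no direct genotype term.
#' @param n_targets_weak,weak_slope Additional weak targets (suggestive-level
#'   effects).
#' @param n_decoys Local eQTL genes placed within 10 Mbp of the hotspot
#'   peak; they share the locus but do not mediate.
#' @param sex_effect_sd,batch_effect_sd,n_batches Nuisance covariate effects.
#' @param noise_sd Residual latent SD for genes without any planted effect.
#' @param dispersion Negative-binomial size parameter for the count layer.
#' @param lib_size_range Range of per-sample library sizes.
#' @param seed Integer seed used for gene placement and effect draws.
#'
#' @return A list of class `architecture_spec` with components `genes`
#'   (annotation: gene, chr, start, end, midpoint Mbp), `local`, `mediator`,
#'   `targets`, `params`.
#' @export
sim_architecture <- function(map,
                             n_genes = 1200,
                             n_local = 50,
                             local_h2 = 0.5,
                             hotspot_chr = "1",
                             hotspot_cM = 50,
                             mediator_h2 = 0.6,
                             mediator_cell = c("B", "A", "both"),
                             alt_founders = c("A", "E", "G", "H"),
                             n_targets = 30,
                             target_slope = 1,
                             target_noise_sd = 0.7,
                             n_targets_weak = 10,
                             weak_slope = 0.5,
                             n_decoys = 5,
                             sex_effect_sd = 0.3,
                             batch_effect_sd = 0.3,
                             n_batches = 3,
                             noise_sd = 1,
                             dispersion = 10,
                             lib_size_range = c(8e5, 1.2e6),
                             seed = NULL) {
  .check_map(map)
  mediator_cell <- match.arg(mediator_cell)
  stopifnot(local_h2 >= 0, local_h2 < 1, mediator_h2 >= 0, mediator_h2 < 1,
            length(alt_founders) == 4, all(alt_founders %in% do_founders))
  if (!is.null(seed)) set.seed(seed)

  chr_len <- attr(map, "chr_len")
  chrs <- names(chr_len)
  hot_marker_idx <- {
    jj <- which(map$chr == hotspot_chr)
    jj[which.min(abs(map$cM[jj] - hotspot_cM))]
  }
  hot_cM <- map$cM[hot_marker_idx]
  hot_mbp <- map$Mbp[hot_marker_idx]

  # place genes uniformly; midpoints in Mbp
  gchr <- sample(chrs, n_genes, replace = TRUE,
                 prob = chr_len / sum(chr_len))
  gmid <- vapply(gchr, function(ch) {
    runif(1, 0.5, max(map$Mbp[map$chr == ch]) - 0.5)
  }, numeric(1))
  genes <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
                      chr = gchr,
                      start = gmid - 0.01, end = gmid + 0.01,
                      midpoint = gmid, stringsAsFactors = FALSE)
  rownames(genes) <- genes$gene

  # mediator: a gene near the hotspot peak (within the +/-10 Mbp window)
  med_i <- 1L
  genes$chr[med_i] <- hotspot_chr
  genes$midpoint[med_i] <- hot_mbp + runif(1, -4, 4)
  genes$start[med_i] <- genes$midpoint[med_i] - 0.01
  genes$end[med_i] <- genes$midpoint[med_i] + 0.01

  # decoys: local eQTL genes near the hotspot
  decoy_i <- if (n_decoys > 0) 1L + seq_len(n_decoys) else integer(0)
  for (i in decoy_i) {
    genes$chr[i] <- hotspot_chr
    genes$midpoint[i] <- hot_mbp + runif(1, -8, 8)
    genes$start[i] <- genes$midpoint[i] - 0.01
    genes$end[i] <- genes$midpoint[i] + 0.01
  }

  # targets: genes on other chromosomes (distant from the hotspot)
  off_chr <- which(genes$chr != hotspot_chr)
  n_t <- n_targets + n_targets_weak
  target_i <- off_chr[seq_len(n_t)]
  used <- c(med_i, decoy_i, target_i)

  # local eQTL genes (beyond the decoys, which are also local eQTL)
  pool <- setdiff(seq_len(n_genes), used)
  n_extra <- max(0L, n_local - n_decoys)
  local_i <- c(decoy_i, sample(pool, min(n_extra, length(pool))))

  nearest_marker <- function(chr, mbp) {
    jj <- which(map$chr == chr)
    jj[which.min(abs(map$Mbp[jj] - mbp))]
  }
  local <- data.frame(
    gene = genes$gene[local_i],
    marker = map$marker[vapply(local_i, function(i)
      nearest_marker(genes$chr[i], genes$midpoint[i]), integer(1))],
    h2 = local_h2,
    decoy = local_i %in% decoy_i,
    stringsAsFactors = FALSE)
  local_beta <- matrix(rnorm(8 * nrow(local)), nrow(local), 8,
                       dimnames = list(local$gene, do_founders))
  local_beta <- local_beta - rowMeans(local_beta)

  ref_founders <- setdiff(do_founders, alt_founders)
  med_beta <- setNames(ifelse(do_founders %in% alt_founders, 0.5, -0.5),
                       do_founders)

  targets <- data.frame(
    gene = genes$gene[target_i],
    slope = rep(c(target_slope, weak_slope), c(n_targets, n_targets_weak)),
    strong = rep(c(TRUE, FALSE), c(n_targets, n_targets_weak)),
    stringsAsFactors = FALSE)

  structure(list(
    genes = genes,
    local = local,
    local_beta = local_beta,
    mediator = list(gene = genes$gene[med_i], marker = map$marker[hot_marker_idx],
                    marker_idx = hot_marker_idx, chr = hotspot_chr,
                    cM = hot_cM, Mbp = hot_mbp, h2 = mediator_h2,
                    beta = med_beta, cell = mediator_cell,
                    alt_founders = alt_founders, ref_founders = ref_founders),
    targets = targets,
    params = list(target_noise_sd = target_noise_sd, noise_sd = noise_sd,
                  sex_effect_sd = sex_effect_sd,
                  batch_effect_sd = batch_effect_sd, n_batches = n_batches,
                  dispersion = dispersion, lib_size_range = lib_size_range)
  ), class = "architecture_spec")
}

# scale a genetic component to a target variance fraction and add noise
.h2_scale <- function(g, h2) {
  s <- sd(g)
  if (s < 1e-12) return(rep(0, length(g)))
  (g - mean(g)) / s * sqrt(h2)
}

#' Simulate latent expression for two cell types
#'
#' Builds donor-level latent expression under the planted architecture.  For
#' each local eQTL the genetic component is the founder-dosage inner product
#' with the effect vector, rescaled so its variance fraction equals the
#' specified QTL heritability.  The mediator gene carries a local eQTL at the
#' hotspot marker with effects split 4:4 across the founder partition; each
#' hotspot target in cell B equals its slope times the mediator's latent
#' value plus noise, with no direct genotype term.  Sex and batch effects are
#' added on top.
#'
#' @param probs Genotype probabilities (samples x 8 x markers).
#' @param map Genome map.
#' @param arch Architecture from [sim_architecture()].
#' @param covariates List with data frames `A` and `B` holding `sex` and
#'   `batch` per sample of each cell type (see [sim_study()]).
#' @param samples_a,samples_b Sample ids carrying expression of each cell
#'   type; default all samples.  In the default study design the derived
#'   cell type B is profiled in every donor while the progenitor cell type A
#'   covers the shared-donor subset.
#' @param seed Integer seed.
#'
#' @return List with `latent` (list of gene x sample matrices `A`, `B`),
#'   and `truth` (planted local eQTL, mediator, targets).
#' @export
sim_expression <- function(probs, map, arch, covariates, samples_a = NULL,
                           samples_b = NULL, seed = NULL) {
  stopifnot(inherits(arch, "architecture_spec"))
  if (!is.null(seed)) set.seed(seed)
  samples <- dimnames(probs)[[1]]
  if (is.null(samples_a)) samples_a <- samples
  if (is.null(samples_b)) samples_b <- samples
  stopifnot(all(samples_a %in% samples), all(samples_b %in% samples))
  genes <- arch$genes
  med <- arch$mediator
  if (med$gene %in% arch$targets$gene)
    stop("mediator gene must not be among the hotspot targets")

  n <- length(samples)
  ng <- nrow(genes)
  p <- arch$params

  # genetic components at donor level
  gen <- matrix(0, ng, n, dimnames = list(genes$gene, samples))
  h2 <- setNames(rep(0, ng), genes$gene)
  for (k in seq_len(nrow(arch$local))) {
    if (arch$local$h2[k] >= 1) stop("QTL heritability must be < 1")
    g <- arch$local$gene[k]
    P <- probs[, , arch$local$marker[k]]
    gen[g, ] <- .h2_scale(P %*% arch$local_beta[g, ], arch$local$h2[k])
    h2[g] <- arch$local$h2[k]
  }
  Pm <- probs[, , med$marker]
  gen[med$gene, ] <- .h2_scale(Pm %*% med$beta, med$h2)
  h2[med$gene] <- med$h2

  # mediator causal latent (donor level): genetic + intrinsic noise, var ~ 1
  med_latent <- gen[med$gene, ] + rnorm(n, sd = sqrt(1 - med$h2))

  make_cell <- function(cell, cell_samples) {
    keep <- genes$gene
    if (med$cell != "both" && med$cell != cell) keep <- setdiff(keep, med$gene)
    lat <- matrix(0, length(keep), length(cell_samples),
                  dimnames = list(keep, cell_samples))
    for (g in keep) {
      if (g == med$gene) {
        # the mediator's expression is the latent value the targets follow
        lat[g, ] <- med_latent[cell_samples]
      } else if (cell == "B" && g %in% arch$targets$gene) {
        sl <- arch$targets$slope[match(g, arch$targets$gene)]
        lat[g, ] <- sl * med_latent[cell_samples] +
          rnorm(length(cell_samples), sd = p$target_noise_sd)
      } else if (h2[g] > 0) {
        lat[g, ] <- gen[g, cell_samples] +
          rnorm(length(cell_samples), sd = sqrt(1 - h2[g]))
      } else {
        lat[g, ] <- rnorm(length(cell_samples), sd = p$noise_sd)
      }
    }
    # covariate effects
    cv <- covariates[[cell]][cell_samples, , drop = FALSE]
    sex_coef <- rnorm(length(keep), sd = p$sex_effect_sd)
    sx <- as.numeric(cv$sex == "F")
    lat <- lat + outer(sex_coef, sx)
    bl <- levels(factor(cv$batch))
    for (b in bl) {
      off <- rnorm(length(keep), sd = p$batch_effect_sd)
      lat[, cv$batch == b] <- lat[, cv$batch == b] + off
    }
    lat
  }

  latent <- list(A = make_cell("A", samples_a),
                 B = make_cell("B", samples_b))

  truth <- list(
    local = data.frame(
      gene = arch$local$gene, marker = arch$local$marker,
      chr = map[arch$local$marker, "chr"],
      cM = map[arch$local$marker, "cM"],
      Mbp = map[arch$local$marker, "Mbp"],
      h2 = arch$local$h2, decoy = arch$local$decoy,
      stringsAsFactors = FALSE),
    mediator = med,
    targets = arch$targets)

  list(latent = latent, truth = truth)
}

#' Draw negative-binomial counts from latent expression
#'
#' Counts are drawn with mean `lib_size * exp(base + latent) / mean(lib_size)`
#' (log link with a per-gene baseline log-mean) and negative-binomial size
#' `dispersion`.  A zero library size yields an all-zero column.
#'
#' @param latent Gene x sample latent matrix.
#' @param dispersion NB size parameter (> 0); the Poisson limit is approached
#'   as it grows.
#' @param lib_sizes Per-sample library sizes (recycled from
#'   `lib_size_range` draws by [sim_study()]); named or positional.
#' @param base_log_mean Per-gene baseline log mean; default draws around
#'   `log(100)`.
#' @param seed Integer seed.
#'
#' @return Integer-valued count matrix of the same shape as `latent`.
#' @export
sim_counts <- function(latent, dispersion = 10, lib_sizes = NULL,
                       base_log_mean = NULL, seed = NULL) {
  stopifnot(dispersion > 0)
  if (!is.null(seed)) set.seed(seed)
  ng <- nrow(latent); n <- ncol(latent)
  if (is.null(lib_sizes)) lib_sizes <- rep(1e6, n)
  stopifnot(length(lib_sizes) == n, all(lib_sizes >= 0))
  if (is.null(base_log_mean)) base_log_mean <- rnorm(ng, log(100), 0.7)
  # reference library of 1e6 reads: the baseline log-mean is per million
  rel <- lib_sizes / 1e6
  mu <- exp(base_log_mean + latent) * rep(rel, each = ng)
  counts <- matrix(rnbinom(ng * n, mu = mu, size = dispersion), ng, n,
                   dimnames = dimnames(latent))
  counts
}
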