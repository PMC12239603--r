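#' Build a synthetic genome map
#'
#' Constructs a marker map for a desk-scale synthetic genome: `n_chr`
#' chromosomes of `chr_len_cM` centimorgans each, with evenly spaced markers.
#' Physical positions follow a fixed, configurable conversion of
#' `mbp_per_cM` megabases per centimorgan (both coordinate systems are
#' needed downstream: hotspot windows are defined in cM, the local/distant
#' rule in Mbp).
#'
#' @param n_chr Number of chromosomes.
#' @param chr_len_cM Chromosome length in centimorgans (recycled).
#' @param markers_per_chr Number of markers per chromosome (recycled).
#' @param mbp_per_cM Megabases per centimorgan for the cM-to-Mbp conversion.
#'
#' @return A data frame with columns `marker`, `chr`, `cM`, `Mbp` and
#'   attribute `chr_len` (named vector of chromosome lengths in cM).
#' @examples
#' map <- sim_map(n_chr = 2, chr_len_cM = 50, markers_per_chr = 20)
#' head(map)
#' @export
sim_map <- function(n_chr = 5, chr_len_cM = 100, markers_per_chr = 200,
                    mbp_per_cM = 2) {
  stopifnot(n_chr >= 1, all(chr_len_cM > 0), all(markers_per_chr >= 2))
  len <- rep_len(chr_len_cM, n_chr)
  nm <- rep_len(markers_per_chr, n_chr)
  chrs <- as.character(seq_len(n_chr))
  pieces <- lapply(seq_len(n_chr), function(i) {
    pos <- seq(len[i] / (2 * nm[i]), len[i] - len[i] / (2 * nm[i]),
               length.out = nm[i])
    data.frame(marker = sprintf("c%s_m%03d", chrs[i], seq_len(nm[i])),
               chr = chrs[i], cM = pos, Mbp = pos * mbp_per_cM,
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- map$marker
  attr(map, "chr_len") <- setNames(len, chrs)
  attr(map, "mbp_per_cM") <- mbp_per_cM
  .check_map(map)
  map
}

#' Simulate DO-style haplotype mosaics
#'
#' Each haploid chromosome is generated as a Markov mosaic of the eight
#' founder haplotypes: the founder at the chromosome start is drawn uniformly,
#' crossover breakpoints arrive as a Poisson process with rate `recomb_rate`
#' crossovers per cM, and at each breakpoint a new founder is drawn uniformly
#' from the other seven.  This reproduces the dosage structure and LD decay of
#' an outbred multiparent population without simulating the breeding design.
#'
#' @param map Genome map from [sim_map()] (or any map with a `chr_len`
#'   attribute or markers covering each chromosome).
#' @param n_samples Number of diploid samples (>= 2).
#' @param recomb_rate Expected crossovers per cM (> 0).  The default 0.1
#'   gives founder segments of ~10 cM on average, comparable to a DO
#'   population after roughly 20 outbreeding generations; much lower values
#'   produce chromosome-length segments and near-total within-chromosome
#'   linkage.
#' @param seed Integer seed; the result is deterministic given the seed.
#'
#' @return An object of class `haplotype_mosaics`: a list with one element per
#'   sample; each sample is a list over chromosomes holding two haplotypes,
#'   each a data frame of `(founder, end_cM)` segments tiling the chromosome.
#' @export
sim_mosaics <- function(map, n_samples, recomb_rate = 0.1, seed = NULL) {
  .check_map(map)
  stopifnot(n_samples >= 2, recomb_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  chr_len <- attr(map, "chr_len")
  if (is.null(chr_len)) {
    chr_len <- tapply(map$cM, map$chr, max)
    chr_len <- setNames(as.numeric(chr_len) * 1.001, names(chr_len))
  }
  chrs <- unique(map$chr)
  one_hap <- function(len) {
    # exponential inter-arrival breakpoints; cap segments defensively
    ends <- numeric(0)
    pos <- 0
    repeat {
      pos <- pos + rexp(1, rate = recomb_rate)
      if (pos >= len) break
      ends <- c(ends, pos)
      if (length(ends) > 10000) break
    }
    k <- length(ends) + 1L
    founders <- integer(k)
    founders[1] <- sample.int(8L, 1L)
    if (k > 1) for (j in 2:k) {
      founders[j] <- sample(setdiff(1:8, founders[j - 1L]), 1L)
    }
    data.frame(founder = founders, end_cM = c(ends, len))
  }
  samples <- lapply(seq_len(n_samples), function(i) {
    per_chr <- lapply(chrs, function(ch) {
      len <- chr_len[[ch]]
      list(h1 = one_hap(len), h2 = one_hap(len))
    })
    names(per_chr) <- chrs
    per_chr
  })
  names(samples) <- sprintf("S%03d", seq_len(n_samples))
  structure(samples, class = "haplotype_mosaics", chr_len = chr_len)
}

# founder index of a haplotype at given cM positions
.hap_at <- function(hap, pos) {
  idx <- findInterval(pos, hap$end_cM, left.open = TRUE) + 1L
  idx[idx > nrow(hap)] <- nrow(hap)
  hap$founder[idx]
}

#' Convert haplotype mosaics to founder genotype probabilities
#'
#' At each marker the 8-vector of founder dosages is the count of that
#' founder among the two haplotypes divided by two.  Optional symmetric
#' Gaussian blur emulates genotype-inference uncertainty; blurred values are
#' clipped at zero and renormalized so each (sample, marker) row sums to one.
#'
#' @param mosaics Result of [sim_mosaics()].
#' @param map Genome map.
#' @param blur_sd Standard deviation of the dosage noise (>= 0; 0 = exact).
#'
#' @return A numeric array of dimension samples x 8 founders x markers with
#'   dimnames, class `genotype_probs`.  Every row over founders sums to 1.
#' @export
mosaics_to_probs <- function(mosaics, map, blur_sd = 0) {
  stopifnot(inherits(mosaics, "haplotype_mosaics"), blur_sd >= 0)
  .check_map(map)
  n <- length(mosaics)
  M <- nrow(map)
  probs <- array(0, dim = c(n, 8, M),
                 dimnames = list(names(mosaics), do_founders, map$marker))
  for (ch in unique(map$chr)) {
    jj <- which(map$chr == ch)
    pos <- map$cM[jj]
    for (i in seq_len(n)) {
      f1 <- .hap_at(mosaics[[i]][[ch]]$h1, pos)
      f2 <- .hap_at(mosaics[[i]][[ch]]$h2, pos)
      # marker indices are distinct, so each triple is hit once per haplotype
      ix1 <- cbind(i, f1, jj)
      ix2 <- cbind(i, f2, jj)
      probs[ix1] <- probs[ix1] + 0.5
      probs[ix2] <- probs[ix2] + 0.5
    }
  }
  if (blur_sd > 0) {
    noise <- array(rnorm(length(probs), sd = blur_sd), dim = dim(probs))
    probs <- pmax(probs + noise, 0)
    tot <- apply(probs, c(1, 3), sum)
    tot[tot == 0] <- 1
    for (f in 1:8) probs[, f, ] <- probs[, f, ] / tot
  }
  class(probs) <- c("genotype_probs", class(probs))
  probs
}
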