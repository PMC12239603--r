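# Shared fixtures, built in code at test time.

tiny_map <- function(n_chr = 2, len = 50, m = 25)
  sim_map(n_chr = n_chr, chr_len_cM = len, markers_per_chr = m)

# a small cached study used by several test files
small_study <- local({
  st <- NULL
  function() {
    if (is.null(st))
      st <<- sim_study(n_samples = 60, n_shared = 45,
                       map = tiny_map(3, 80, 40),
                       n_genes = 90, n_local = 8, n_targets = 6,
                       n_targets_weak = 2, n_decoys = 2, seed = 42)
    st
  }
})

# independent oracle: naive fixed-effects LOD scan via lm() at each marker
naive_lod_scan <- function(y, probs) {
  n <- length(y)
  vapply(seq_len(dim(probs)[3]), function(m) {
    P <- probs[, , m]
    rss0 <- sum(resid(lm(y ~ 1))^2)
    rss1 <- sum(resid(lm(y ~ P))^2)
    (n / 2) * log10(rss0 / rss1)
  }, numeric(1))
}

# draw a phenotype with a given polygenic heritability on kinship K
draw_polygenic <- function(K, h2) {
  eg <- eigen(K, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  g <- eg$vectors %*% (sqrt(lam) * rnorm(nrow(K)))
  drop(sqrt(h2) * g + sqrt(1 - h2) * rnorm(nrow(K)))
}
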