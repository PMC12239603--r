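test_that("gene filtering applies the median and zero-count rules", {
  n <- 20
  expr <- rbind(
    mostly_zero = c(rep(0, 12), rep(5, 8)),     # 60% zeros -> dropped
    constant    = rep(10, n),                    # kept
    low_median  = rep(0.4, n),                   # median 0.4, no zeros -> dropped
    borderline  = c(rep(0, 10), rep(2, 10)),     # exactly half zeros, median >= 0.5? median = 1 -> kept
    ok          = runif(n, 1, 5))
  keep <- filter_genes(expr)
  expect_false("mostly_zero" %in% keep)
  expect_true("constant" %in% keep)
  expect_false("low_median" %in% keep)
  expect_true("ok" %in% keep)
  expect_error(filter_genes(matrix(0, 0, 0)), "empty")
})

test_that("upper-quartile normalization is scale invariant per sample", {
  set.seed(1)
  a <- rpois(100, 50)
  a[a == 0] <- 1
  counts <- cbind(s1 = a, s2 = 2 * a, s3 = rpois(100, 30) + 1)
  uq <- uq_normalize(counts)
  expect_equal(uq[, "s1"], uq[, "s2"], ignore_attr = TRUE)

  # identical samples stay identical; single sample returns a global rescale
  two <- cbind(x = a, y = a)
  uq2 <- uq_normalize(two)
  expect_equal(uq2[, 1], uq2[, 2], ignore_attr = TRUE)
  one <- uq_normalize(cbind(z = a))
  expect_equal(cor(one[, 1], a), 1)

  bad <- cbind(s1 = a, empty = rep(0, 100))
  expect_error(uq_normalize(bad), "empty")
})

test_that("location-scale correction equalizes batch moments and preserves null data", {
  set.seed(2)
  expr <- matrix(rnorm(50 * 30), 50, 30,
                 dimnames = list(paste0("g", 1:50), paste0("s", 1:30)))
  batch <- rep(c("b1", "b2"), each = 15)
  shifted <- expr
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 2
  fixed <- remove_covariate_effects(shifted, batch)
  m1 <- rowMeans(fixed[, batch == "b1"])
  m2 <- rowMeans(fixed[, batch == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-10)

  # no planted batch effect: correction is close to identity
  nullfix <- remove_covariate_effects(expr, batch)
  expect_lt(max(abs(nullfix - expr)), 1.5)
  expect_gt(cor(as.numeric(nullfix), as.numeric(expr)), 0.95)

  # agreement with an established mean-adjustment on the location part
  lf <- limma::removeBatchEffect(shifted, batch = batch)
  expect_lt(max(abs(rowMeans(fixed[, batch == "b2"]) -
                      rowMeans(lf[, batch == "b2"]))), 1e-6)

  # constant gene stays constant
  cexpr <- rbind(const = rep(3, 30), expr)
  cf <- remove_covariate_effects(cexpr, batch)
  expect_equal(unname(cf["const", ]), rep(3, 30))

  expect_error(remove_covariate_effects(expr, c("a", rep("b", 29))), "fewer than 2")
})

test_that("rankZ matches its closed form, absorbs ties, and is rank invariant", {
  x <- c(5, 1, 3)
  expect_equal(rankz(x)[order(x)], qnorm(c(1, 3, 5) / 6))
  expect_equal(rankz(rep(2, 7)), rep(0, 7))

  set.seed(3)
  y <- rnorm(40)
  expect_equal(rankz(y), rankz(exp(y)))          # monotone invariance
  expect_equal(rankz(y), rankz(rankz(y)))        # idempotence
  m <- matrix(rnorm(60), 3, 20)
  rz <- rankz(m)
  expect_lt(max(abs(rowMeans(rz))), 1e-10)
  expect_true(all(abs(apply(rz, 1, sd) - 1) < 0.1))
})

test_that("sample matching recovers permutations and flags swaps", {
  set.seed(4)
  G <- matrix(rbinom(40 * 200, 2, 0.3), 40, 200,
              dimnames = list(sprintf("S%02d", 1:40), paste0("m", 1:200)))
  # permuted labels: best match recovers the permutation
  perm <- sample(40)
  Gp <- G[perm, ]
  rownames(Gp) <- rownames(G)
  res <- match_samples(Gp, G)
  expect_equal(res$assignment$best_match, rownames(G)[perm])

  # a planted swap of two samples flags exactly those two as mix-ups,
  # even with 10% genotype call errors
  Ge <- G
  flip <- matrix(runif(length(G)) < 0.10, nrow(G))
  Ge[flip] <- rbinom(sum(flip), 2, 0.3)
  Gs <- Ge
  Gs[c(1, 2), ] <- Ge[c(2, 1), ]
  res2 <- match_samples(Gs, G)
  expect_true(all(res2$assignment$mixup[1:2]))
  expect_false(any(res2$assignment$mixup[-(1:2)]))

  expect_error(match_samples(G[, 1:5], G[, 1:5]), "shared markers")
})

test_that("matched-donor transcriptome correlations exceed mismatched under shared signal", {
  set.seed(5)
  ng <- 150; n <- 30
  donor <- matrix(rnorm(ng * n), ng, n)
  exprA <- 0.85 * donor + sqrt(1 - 0.85^2) * matrix(rnorm(ng * n), ng, n)
  exprB <- 0.85 * donor + sqrt(1 - 0.85^2) * matrix(rnorm(ng * n), ng, n)
  dimnames(exprA) <- dimnames(exprB) <- list(paste0("g", 1:ng), paste0("d", 1:n))
  cc <- correlate_transcriptomes(exprA, exprB)
  expect_gt(cc$median_matched, cc$median_mismatched)
  expect_gt(cc$median_matched, 0.5)

  # a monotone transform of the same matrix correlates perfectly on the diagonal
  cc2 <- correlate_transcriptomes(exprA, exp(exprA))
  expect_equal(unname(cc2$matched), rep(1, n))

  # independent matrices: matched correlations center near zero
  cc3 <- correlate_transcriptomes(matrix(rnorm(ng * n), ng, n,
                                         dimnames = dimnames(exprA)),
                                  matrix(rnorm(ng * n), ng, n,
                                         dimnames = dimnames(exprB)))
  expect_lt(abs(cc3$median_matched), 0.15)
})

test_that("differential expression labels follow the Wilcoxon/BH/fold-change rules", {
  set.seed(6)
  n <- 30
  # identical groups: no evidence, no labels
  base <- matrix(rpois(100 * n, 50) + 1, 100, n,
                 dimnames = list(paste0("g", 1:100), paste0("a", 1:n)))
  same <- base
  colnames(same) <- paste0("b", 1:n)
  de0 <- differential_expression(base, same)
  expect_true(all(de0$label == "ns"))
  expect_true(all(de0$p > 0.9))

  # exact fold change arithmetic
  a <- matrix(4, 2, 4, dimnames = list(c("g1", "g2"), paste0("a", 1:4)))
  b <- matrix(c(16, 16, 16, 16, 1, 1, 1, 1), 2, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("b", 1:4)))
  de1 <- differential_expression(a, b)
  expect_equal(de1$log2fc[de1$gene == "g1"], 2)
  expect_equal(de1$log2fc[de1$gene == "g2"], -2)

  # 1000 null + 50 strongly shifted genes: shifted recovered, few false calls
  ng <- 1050
  A <- matrix(rnorm(ng * n, 100, 5), ng, n,
              dimnames = list(paste0("g", 1:ng), paste0("a", 1:n)))
  B <- matrix(rnorm(ng * n, 100, 5), ng, n,
              dimnames = list(paste0("g", 1:ng), paste0("b", 1:n)))
  B[1:50, ] <- B[1:50, ] * 8
  de2 <- differential_expression(A, B)
  expect_gte(sum(de2$label[1:50] == "up"), 45)
  expect_lte(sum(de2$label[-(1:50)] != "ns"), 5)
  expect_true(all(de2$p_adj >= de2$p - 1e-12))
})

test_that("null differential expression keeps BH discoveries at the nominal level", {
  set.seed(7)
  ng <- 2000; n <- 25
  A <- matrix(rnorm(ng * n, 50, 5), ng, n,
              dimnames = list(paste0("g", 1:ng), paste0("a", 1:n)))
  B <- matrix(rnorm(ng * n, 50, 5), ng, n,
              dimnames = list(paste0("g", 1:ng), paste0("b", 1:n)))
  de <- differential_expression(A, B)
  expect_lte(mean(de$p_adj < 0.05), 0.05)
})

test_that("PCA summaries behave on rank-1, clustered, and rotated data", {
  # rank-1 matrix: PC1 carries all variance
  u <- rnorm(20); v <- rnorm(12)
  X <- outer(u, v)
  dimnames(X) <- list(paste0("g", 1:20), paste0("s", 1:12))
  ps <- pca_scores(X, n_pc = 1)
  expect_equal(ps$var_frac[1], 1)

  # two clusters offset by a constant vector: PC1 sign splits the groups
  set.seed(8)
  Y <- matrix(rnorm(50 * 20, sd = 0.5), 50, 20,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:20)))
  Y[, 11:20] <- Y[, 11:20] + 3
  ps2 <- pca_scores(Y, n_pc = 2)
  s1 <- sign(ps2$scores[1:10, 1])
  s2 <- sign(ps2$scores[11:20, 1])
  expect_true(all(s1 == s1[1]) && all(s2 == s2[1]) && s1[1] != s2[1])

  # an orthogonal rotation of sample space that preserves the mean direction
  # leaves the variance fractions unchanged
  n_s <- ncol(Y)
  C <- qr.Q(qr(cbind(rep(1, n_s) / sqrt(n_s), contr.helmert(n_s))))
  R <- qr.Q(qr(matrix(rnorm((n_s - 1)^2), n_s - 1)))
  Q <- C %*% rbind(c(1, rep(0, n_s - 1)), cbind(0, R)) %*% t(C)
  Yr <- Y %*% Q
  dimnames(Yr) <- dimnames(Y)
  expect_equal(pca_scores(Yr, n_pc = 2)$var_frac, ps2$var_frac)

  expect_error(pca_scores(X, n_pc = 5), "rank")
})
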