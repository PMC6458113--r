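test_that("hypergeometric enrichment matches hand-computed examples", {
  bg <- paste0("p", 1:20)
  e <- hypergeom_enrichment(paste0("p", 1:4), paste0("p", c(1:3, 10, 11)), bg)
  expect_equal(e$overlap, 3L)
  expect_equal(e$fold, (3 / 4) / (5 / 20))
  expect_equal(e$p_enrich, 155 / 4845, tolerance = 1e-12)
  # cluster = background saturates
  sat <- hypergeom_enrichment(bg, paste0("p", 1:5), bg)
  expect_equal(sat$fold, 1)
  expect_equal(sat$p_enrich, 1)
  # empty overlap
  none <- hypergeom_enrichment(paste0("p", 1:4), paste0("p", 15:18), bg)
  expect_equal(none$fold, 0)
  expect_equal(none$p_enrich, 1, tolerance = 1e-12)
  expect_error(hypergeom_enrichment(character(), bg, bg), "empty")
})

test_that("hypergeometric tails match brute-force enumeration for small N", {
  set.seed(111)
  for (rep in 1:12) {
    N <- sample(6:15, 1)
    K <- sample(2:(N - 1), 1)
    n <- sample(2:(N - 1), 1)
    bg <- paste0("g", seq_len(N))
    ann <- paste0("g", seq_len(K))
    cl <- paste0("g", sample(N, n))
    ours <- hypergeom_enrichment(cl, ann, bg)
    oracle <- brute_hypergeom(N, K, n, ours$overlap)
    expect_equal(ours$p_enrich, oracle$p_enrich, tolerance = 1e-12)
    expect_equal(ours$p_deplete, oracle$p_deplete, tolerance = 1e-12)
  }
})

test_that("cluster enrichment table reports folds with BH adjustment", {
  labels <- setNames(rep(c("up", "down"), each = 50), paste0("p", 1:100))
  sets <- list(immunity = paste0("p", 1:30), plasma = paste0("p", 60:80))
  tab <- cluster_enrichment(labels, sets)
  expect_true(all(c("fold", "p_enrich", "p_enrich_bh") %in% names(tab)))
  up_imm <- tab[tab$group == "up" & tab$set == "immunity", ]
  expect_equal(up_imm$fold, (30 / 50) / (30 / 100))
  expect_true(all(tab$p_enrich_bh >= tab$p_enrich - 1e-12))
})

test_that("PCA variance fractions follow the covariance eigenstructure", {
  # build a matrix whose sample covariance is exactly [[2, 1], [1, 2]]
  set.seed(112)
  raw <- matrix(stats::rnorm(400), 200, 2)
  cen <- scale(raw, center = TRUE, scale = FALSE)
  whitened <- cen %*% solve(chol(stats::cov(cen)))
  X <- whitened %*% chol(matrix(c(2, 1, 1, 2), 2))
  dimnames(X) <- list(paste0("p", 1:200), c("s1", "s2"))
  pc <- pca_decompose(X, n_perm = 0)
  expect_equal(unname(pc$variance_fraction), c(0.75, 0.25), tolerance = 1e-9)
  # rank-one input loads everything on PC1
  one <- matrix(stats::rnorm(50), 50, 1) %*% t(c(1, 2, 3))
  dimnames(one) <- list(paste0("p", 1:50), c("a", "b", "c"))
  pc1 <- pca_decompose(one, n_perm = 0)
  expect_equal(unname(pc1$variance_fraction), c(1, 0, 0), tolerance = 1e-9)
  # scores of distinct components are orthogonal
  set.seed(113)
  Y <- matrix(stats::rnorm(600), 100, 6,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:6)))
  pcy <- pca_decompose(Y, n_perm = 0)
  cp <- crossprod(pcy$scores)
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-9)
  expect_equal(sum(pcy$variance_fraction), 1, tolerance = 1e-12)
})

test_that("permutation test flags real structure and not noise", {
  set.seed(114)
  base <- stats::rnorm(150, sd = 2)
  X <- outer(base, rep(1, 4)) + matrix(stats::rnorm(600, sd = 0.3), 150, 4)
  dimnames(X) <- list(paste0("p", 1:150), paste0("s", 1:4))
  pc <- pca_decompose(X, n_perm = 199, seed = 2)
  expect_true(pc$significant[1])
  noise <- matrix(stats::rnorm(600), 150, 4,
                  dimnames = list(paste0("p", 1:150), paste0("s", 1:4)))
  pcn <- pca_decompose(noise, n_perm = 199, seed = 2)
  expect_lt(pcn$n_significant, 2)
})

test_that("component-abundance correlations recover built-in structure", {
  set.seed(115)
  X <- matrix(stats::rnorm(400), 100, 4,
              dimnames = list(paste0("p", 1:100), paste0("s", 1:4)))
  pc <- pca_decompose(X, n_perm = 0)
  # a pseudo-sample equal to the centered first component correlates exactly
  aug <- cbind(X, pc1_copy = pc$scores[, 1])
  cc <- loading_abundance_corr(pc, aug, components = 1)
  expect_equal(cc$r[cc$sample == "pc1_copy"], 1, tolerance = 1e-9)
  # orthogonal component has no correlation with that pseudo-sample
  cc2 <- loading_abundance_corr(pc, aug, components = 2)
  expect_lt(abs(cc2$r[cc2$sample == "pc1_copy"]), 1e-9)
})
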