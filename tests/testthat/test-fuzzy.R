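test_that("the fuzzifier estimator matches its closed form and limits", {
  expect_equal(estimate_fuzzifier(805, 4), 2.64, tolerance = 0.005)
  expect_lt(estimate_fuzzifier(1e6, 1000), 1.01)
  m_by_d <- vapply(2:10, function(D) estimate_fuzzifier(500, D), numeric(1))
  expect_true(all(diff(m_by_d) < 0))
  expect_error(estimate_fuzzifier(5, 4))
})

test_that("single-cluster model is the column-mean centroid", {
  set.seed(101)
  X <- matrix(stats::rnorm(80), 20, 4)
  fit <- fuzzy_cmeans(X, 1, m = 1.5)
  expect_equal(as.numeric(fit$centroids), colMeans(X))
  expect_true(all(fit$memberships == 1))
  expect_error(fuzzy_cmeans(X, 20, m = 1.5), "c <")
})

test_that("memberships are a proper soft partition with a monotone objective", {
  set.seed(102)
  X <- matrix(stats::rnorm(200), 50, 4)
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  fit <- fuzzy_cmeans(X, 3, m = 2, seed = 9)
  expect_equal(unname(rowSums(fit$memberships)), rep(1, 50), tolerance = 1e-9)
  expect_true(all(fit$memberships > 0 & fit$memberships <= 1))
  expect_true(all(diff(fit$objectives) <= 1e-8))
})

test_that("row permutation permutes memberships identically", {
  set.seed(103)
  X <- matrix(stats::rnorm(160), 40, 4,
              dimnames = list(paste0("p", 1:40), NULL))
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  perm <- sample(40)
  a <- fuzzy_cmeans(X, 3, m = 1.8, seed = 4)
  b <- fuzzy_cmeans(X[perm, ], 3, m = 1.8, seed = 4)
  # centroids may come out in a different label order; match rows
  match_cl <- apply(b$centroids, 1, function(v)
    which.min(colSums((t(a$centroids) - v)^2)))
  expect_equal(sort(unname(match_cl)), 1:3)
  # both runs reach the same optimum; memberships agree to the convergence
  # tolerance of the alternating updates
  expect_equal(unname(b$memberships[, order(match_cl)][rownames(X), ]),
               unname(a$memberships), tolerance = 0.01)
})

test_that("well-separated profile groups earn decisive memberships", {
  set.seed(104)
  up <- matrix(rep(c(-1, -1, 1, 1), each = 30), 30, 4) +
    stats::rnorm(120, 0, 0.05)
  dn <- matrix(rep(c(1, 1, -1, -1), each = 30), 30, 4) +
    stats::rnorm(120, 0, 0.05)
  X <- rbind(up, dn)
  rownames(X) <- paste0("p", 1:60)
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  fit <- fuzzy_cmeans(X, 2, m = 1.25, seed = 5)
  own <- apply(fit$memberships, 1, max)
  expect_true(all(own > 0.95))
})

test_that("near-hard fuzzy assignments agree with independent k-means", {
  set.seed(105)
  centers <- rbind(c(2, 0, -2, 0), c(-2, 0, 2, 0), c(0, 2, 0, -2))
  X <- centers[rep(1:3, each = 25), ] + stats::rnorm(300, 0, 0.15)
  rownames(X) <- paste0("p", 1:75)
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  fit <- fuzzy_cmeans(X, 3, m = 1.05, seed = 6)
  hard <- max.col(fit$memberships)
  km <- stats::kmeans(X, centers = 3, nstart = 20)
  expect_equal(adjusted_rand(hard, km$cluster), 1)
})

test_that("fuzzy objective matches the e1071 reference implementation", {
  set.seed(106)
  X <- rbind(matrix(stats::rnorm(120, 1), 30, 4),
             matrix(stats::rnorm(120, -1), 30, 4))
  rownames(X) <- paste0("p", 1:60)
  X <- (X - rowMeans(X)) / apply(X, 1, sd)
  m <- 1.6
  ours <- fuzzy_cmeans(X, 2, m = m, seed = 7)
  ref <- e1071::cmeans(X, centers = 2, m = m, iter.max = 300)
  obj_ref <- sum(ref$membership^m * as.matrix(stats::dist(
    rbind(ref$centers, X)))[-(1:2), 1:2]^2)
  expect_equal(ours$objective, obj_ref, tolerance = 1e-3)
})

test_that("cluster-number selection finds planted group counts", {
  Xs4 <- prep_standardized(high_signal_sim(2))
  m <- estimate_fuzzifier(nrow(Xs4), ncol(Xs4))
  sel4 <- select_cluster_number(Xs4, 2:6, m = m, seed = 4, n_starts = 5)
  expect_equal(sel4$c, 4L)
  Xs2 <- prep_standardized(high_signal_sim(3, fractions = c(0.5, 0.5, 0, 0)))
  sel2 <- select_cluster_number(Xs2, 2:6, m = m, seed = 4, n_starts = 5)
  expect_equal(sel2$c, 2L)
  # structureless data takes the warning path
  flat <- simulate_proteome(proteome_sim_config(
    n_proteins = 300, cluster_fractions = c(0, 0, 0, 0),
    profile_amplitude = 0, count_depth = 50, dispersion = 0.2,
    annotation_plan = list(), seed = 5))
  Xf <- prep_standardized(flat)
  expect_warning(self <- select_cluster_number(Xf, 2:6, m = m, seed = 4,
                                               n_starts = 5), "no abrupt")
  expect_equal(self$c, 2L)
  expect_true(self$collapsed)
})

test_that("centroid shapes classify into the four temporal profiles", {
  mk <- function(profiles) {
    cent <- do.call(rbind, profiles)
    colnames(cent) <- paste0("combined_", c("M1", "M2", "M3", "F2"))
    u <- matrix(1 / nrow(cent), 4 * nrow(cent), nrow(cent),
                dimnames = list(paste0("p", seq_len(4 * nrow(cent))),
                                paste0("C", seq_len(nrow(cent)))))
    u[, 1] <- 2; u <- u / rowSums(u)
    structure(list(centroids = cent, memberships = u, m = 2, c = nrow(cent)),
              class = "ejacdyn_fuzzy")
  }
  model <- mk(list(c(1.2, 0.4, -0.4, -1.2),
                   c(-0.5, -0.5, -0.5, 1.5),
                   c(-1.2, -0.4, 0.4, 1.2),
                   c(0.3, 0.3, 0.3, -1.0)))
  cls <- attr(classify_profiles(model), "cluster_classes")
  expect_equal(unname(cls), c("depleted", "novelty_up", "enriched",
                              "novelty_down"))
  frac <- attr(classify_profiles(model), "class_fractions")
  expect_equal(sum(frac), 1)
})

test_that("planted profile fractions are recovered at high signal", {
  sim <- high_signal_sim(2)
  Xs <- prep_standardized(sim)
  m <- estimate_fuzzifier(nrow(Xs), ncol(Xs))
  fit <- fuzzy_cmeans(Xs, 4, m = m, seed = 5, n_starts = 5)
  asg <- classify_profiles(fit)
  expect_gte(adjusted_rand(asg$cluster, sim$true_clusters[asg$protein_id]),
             0.8)
  frac <- attr(asg, "class_fractions")
  expect_lt(abs(frac[["depleted"]] - 0.43), 0.05)
  expect_lt(abs(frac[["enriched"]] - 0.19), 0.05)
  expect_lt(abs(frac[["novelty_up"]] - 0.21), 0.05)
  expect_lt(abs(frac[["novelty_down"]] - 0.17), 0.05)
})

test_that("membership comparisons use exact rank-sum inference", {
  asg <- data.frame(
    protein_id = paste0("p", 1:6),
    cluster = rep(c("A", "B"), each = 3),
    membership = c(0.9, 0.95, 0.92, 0.5, 0.55, 0.6),
    profile_class = "other", stringsAsFactors = FALSE)
  class(asg) <- c("ejacdyn_assignment", "data.frame")
  res <- membership_compare(asg)
  expect_equal(res$p_a_greater, 1 / choose(6, 3))
  # singleton clusters are skipped with a flag
  asg2 <- asg; asg2$cluster <- c("A", "A", "A", "B", "B", "C")
  res2 <- membership_compare(asg2)
  expect_true(any(res2$skipped))
})
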