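# Soft (fuzzy c-means) clustering of temporal protein-abundance profiles:
# fuzzifier estimation, cluster-number selection by minimum centroid
# distance, hard assignment by maximal membership, profile-shape
# classification and membership comparisons.

#' Variance-based estimate of the fuzzy c-means fuzzifier
#'
#' `m = 1 + (1418/N + 22.05) * D^-2 +
#'      (12.33/N + 0.243) * D^(-0.0406 * log(N) - 0.1134)`,
#' where `N` is the number of profiles (proteins) and `D` the number of
#' time points (samples). Large, long datasets push `m` toward 1 (hard
#' clustering); short profiles need a softer `m`.
#'
#' @param N Number of profiles; must be >= 10.
#' @param D Number of time points; must be >= 2.
#' @return The fuzzifier `m > 1`.
#' @examples
#' estimate_fuzzifier(805, 4)
#' @export
estimate_fuzzifier <- function(N, D) {
  stopifnot(N >= 10, D >= 2)
  1 + (1418 / N + 22.05) * D^-2 +
    (12.33 / N + 0.243) * D^(-0.0406 * log(N) - 0.1134)
}

fcm_memberships <- function(X, centroids, m) {
  # u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1)); exact coincidences get full
  # membership on (the first of) their coincident centroids
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") -
    2 * X %*% t(centroids)
  d2 <- pmax(d2, 0)
  u <- d2^(-1 / (m - 1))
  coincident <- !is.finite(u) | d2 < 1e-300
  hitrow <- rowSums(coincident) > 0
  if (any(hitrow)) {
    u[hitrow, ] <- 0
    first <- apply(coincident[hitrow, , drop = FALSE], 1, which.max)
    u[cbind(which(hitrow), first)] <- 1
  }
  u / rowSums(u)
}

fcm_objective <- function(X, centroids, u, m) {
  d2 <- outer(rowSums(X^2), rowSums(centroids^2), "+") -
    2 * X %*% t(centroids)
  sum(u^m * pmax(d2, 0))
}

fcm_single <- function(X, c, m, tol, max_iter, init_idx) {
  centroids <- X[init_idx, , drop = FALSE]
  obj <- Inf
  objectives <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u <- fcm_memberships(X, centroids, m)
    um <- u^m
    centroids <- (t(um) %*% X) / colSums(um)
    new_obj <- fcm_objective(X, centroids, u, m)
    objectives <- c(objectives, new_obj)
    if (is.finite(obj) && obj - new_obj < tol) {
      converged <- TRUE
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  u <- fcm_memberships(X, centroids, m)
  list(centroids = centroids, memberships = u, objective = obj,
       objectives = objectives, iterations = length(objectives),
       converged = converged)
}

#' Fuzzy c-means clustering of standardized temporal profiles
#'
#' Alternating optimisation of the fuzzy c-means objective
#' `sum_ik u_ik^m ||x_i - v_k||^2` with membership update
#' `u_ik = 1 / sum_j (||x_i - v_k|| / ||x_i - v_j||)^(2/(m-1))` and centroid
#' update `v_k = sum_i u_ik^m x_i / sum_i u_ik^m`, run from `n_starts`
#' seeded random initialisations (centroids drawn from the data rows) and
#' keeping the best final objective. Rows coinciding exactly with a centroid
#' receive full membership in (the nearest of) the coincident centroids.
#'
#' @param X Numeric matrix, proteins x samples, rows standardized to mean 0
#'   and SD 1 (see [log_standardize()]).
#' @param c Number of clusters, `2 <= c < nrow(X)` (`c = 1` is allowed and
#'   returns the trivial single-cluster model).
#' @param m Fuzzifier (> 1); default estimated by [estimate_fuzzifier()].
#' @param seed Master seed; per-start seeds are derived from it.
#' @param tol Convergence tolerance on the objective decrease. Default 1e-6.
#' @param max_iter Maximum iterations per start. Default 500.
#' @param n_starts Number of random restarts. Default 10.
#' @return An object of class `ejacdyn_fuzzy`: list with `centroids`
#'   (c x D), `memberships` (N x c, rows summing to 1), `m`, `objective`,
#'   `objectives` (per-iteration trace of the best start), `iterations`,
#'   `converged`, `seed`.
#' @export
fuzzy_cmeans <- function(X, c, m = NULL, seed = 1L, tol = 1e-6,
                         max_iter = 500L, n_starts = 10L) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (c >= N) stop("fuzzy_cmeans: need c < number of proteins", call. = FALSE)
  if (is.null(m)) m <- estimate_fuzzifier(N, ncol(X))
  stopifnot(m > 1)
  if (c == 1L) {
    centroids <- matrix(colMeans(X), 1, ncol(X),
                        dimnames = list(NULL, colnames(X)))
    u <- matrix(1, N, 1, dimnames = list(rownames(X), NULL))
    out <- list(centroids = centroids, memberships = u, m = m,
                objective = fcm_objective(X, centroids, u, m),
                objectives = numeric(0), iterations = 0L,
                converged = TRUE, c = 1L, seed = seed)
    class(out) <- "ejacdyn_fuzzy"
    return(out)
  }
  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init_idx <- sample.int(N, c)
    res <- fcm_single(X, c, m, tol, max_iter, init_idx)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  dimnames(best$centroids) <- list(paste0("C", seq_len(c)), colnames(X))
  dimnames(best$memberships) <- list(rownames(X), paste0("C", seq_len(c)))
  out <- c(best, list(m = m, c = c, seed = seed))
  class(out) <- "ejacdyn_fuzzy"
  out
}

#' @export
print.ejacdyn_fuzzy <- function(x, ...) {
  cat(sprintf(
    "Fuzzy c-means: c = %d, m = %.3f, objective = %.4g (%d iterations%s)\n",
    x$c, x$m, x$objective, x$iterations,
    if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Cluster-number selection by minimum centroid distance
#'
#' Runs [fuzzy_cmeans()] for each candidate `c` and records the minimum
#' pairwise distance between centroids, `D_min(c)`. When the requested
#' cluster number exceeds the number of genuinely distinct profile groups,
#' surplus centroids crowd into one group and `D_min` drops abruptly. The
#' selection rule takes the `c` preceding the most abrupt relative drop:
#' `c* = argmin_c D_min(c + 1) / D_min(c)`, provided that minimum ratio
#' falls below `drop_frac` (otherwise no drop is abrupt, the centroid
#' distances have collapsed smoothly -- no structure -- and 2 is returned
#' with a warning). The partition coefficient `sum(u^2) / N` is reported
#' alongside.
#'
#' @param X Row-standardized matrix as in [fuzzy_cmeans()].
#' @param c_range Candidate cluster numbers. Default `2:8`.
#' @param m Fuzzifier; default [estimate_fuzzifier()].
#' @param drop_frac Ratio below which a drop counts as abrupt. Default 0.5.
#' @param seed,n_starts Passed to [fuzzy_cmeans()].
#' @return List with `c` (selected), `curve` (data.frame: c, d_min,
#'   partition_coefficient), `collapsed` (TRUE when even small `c` fails the
#'   rule and 2 is returned with a warning).
#' @export
select_cluster_number <- function(X, c_range = 2:8, m = NULL,
                                  drop_frac = 0.5, seed = 1L, n_starts = 10L) {
  X <- as.matrix(X)
  if (is.null(m)) m <- estimate_fuzzifier(nrow(X), ncol(X))
  c_range <- sort(unique(as.integer(c_range)))
  stopifnot(all(c_range >= 2), all(c_range < nrow(X)))
  # include c_max + 1 so a drop after the largest candidate is visible
  c_eval <- c(c_range, max(c_range) + 1L)
  d_min <- pc <- numeric(length(c_eval))
  for (i in seq_along(c_eval)) {
    fit <- fuzzy_cmeans(X, c_eval[i], m = m, seed = seed + i,
                        n_starts = n_starts)
    d_min[i] <- min(dist(fit$centroids))
    pc[i] <- sum(fit$memberships^2) / nrow(X)
  }
  ratio <- d_min[-1] / d_min[-length(d_min)]
  collapsed <- FALSE
  if (all(!is.finite(ratio)) || min(ratio, na.rm = TRUE) >= drop_frac) {
    warning("select_cluster_number: no abrupt centroid-distance drop; returning 2")
    sel <- 2L
    collapsed <- TRUE
  } else {
    sel <- c_eval[which.min(ratio)]
  }
  list(c = sel,
       curve = data.frame(c = c_eval, d_min = d_min,
                          partition_coefficient = pc),
       collapsed = collapsed)
}

#' Hard assignment and temporal profile classification
#'
#' Assigns each protein to its maximal-membership cluster and classifies
#' every cluster centroid by its shape over the mating sequence M1, M2, M3,
#' F2: a jump at the novel-female sample F2 that dominates the spread over
#' M1..M3 gives `novelty_up`/`novelty_down`; otherwise monotone
#' nonincreasing centroids are `depleted`, monotone nondecreasing ones
#' `enriched`, anything else `other`. With status-split samples
#' (`<status>_<mating>` columns) centroids are first averaged per mating.
#'
#' @param model An `ejacdyn_fuzzy` object.
#' @param mating_order Mating labels in temporal order. Default
#'   `c("M1", "M2", "M3", "F2")`.
#' @return An object of class `ejacdyn_assignment`: data.frame with
#'   `protein_id`, `cluster`, `membership` (maximal membership value),
#'   `profile_class`; attributes `cluster_classes` (per-cluster class) and
#'   `class_fractions` (per-class protein fractions, summing to 1).
#' @export
classify_profiles <- function(model, mating_order = c("M1", "M2", "M3", "F2")) {
  stopifnot(inherits(model, "ejacdyn_fuzzy"))
  cent <- model$centroids
  cols <- colnames(cent)
  mating <- sub("^.*_", "", cols)
  if (!all(mating_order %in% mating)) {
    stop("classify_profiles: centroid columns do not cover the mating order",
         call. = FALSE)
  }
  prof <- t(vapply(mating_order, function(mm) {
    rowMeans(cent[, mating == mm, drop = FALSE])
  }, numeric(nrow(cent))))  # matings x clusters
  classes <- apply(prof, 2, classify_one_profile)
  cl <- max.col(model$memberships)
  memb <- model$memberships[cbind(seq_len(nrow(model$memberships)), cl)]
  out <- data.frame(
    protein_id = rownames(model$memberships),
    cluster = colnames(model$memberships)[cl],
    membership = memb,
    profile_class = classes[cl],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  frac <- table(factor(out$profile_class,
                       levels = c("depleted", "enriched", "novelty_up",
                                  "novelty_down", "other"))) / nrow(out)
  attr(out, "cluster_classes") <- classes
  attr(out, "class_fractions") <- c(frac)
  class(out) <- c("ejacdyn_assignment", "data.frame")
  out
}

# A profile is novelty-specific when its F2 value breaks away from the
# linear trend of the familiar-female matings by more than their own spread
# (an F2 point continuing a monotone decline is depletion, not novelty).
# Tolerances are relative to the profile's range so centred/standardized
# centroids of any scale classify identically.
classify_one_profile <- function(p, rel_tol = 0.05) {
  rng <- diff(range(p))
  if (rng < 1e-12) return("other")
  tol <- rel_tol * rng
  early <- p[-length(p)]
  x <- seq_along(early)
  slope <- stats::cov(x, early) / stats::var(x)
  extrap <- mean(early) + slope * (length(p) - mean(x))
  residual <- p[length(p)] - extrap
  spread <- diff(range(early))
  if (abs(residual) > spread + tol) {
    return(if (residual > 0) "novelty_up" else "novelty_down")
  }
  d <- diff(p)
  if (all(d <= tol) && any(d < -tol)) return("depleted")
  if (all(d >= -tol) && any(d > tol)) return("enriched")
  "other"
}

#' @export
print.ejacdyn_assignment <- function(x, ...) {
  cat("Profile classification of", nrow(x), "proteins\n")
  print(round(attr(x, "class_fractions"), 3))
  invisible(x)
}

#' Pairwise comparison of maximal membership values between clusters
#'
#' Tests, for every pair of clusters, whether one cluster's proteins follow
#' their centroid more tightly than the other's, by a two-sample rank-sum
#' test on the maximal membership values ([rank_sum_test()]). Pairs
#' involving a singleton cluster are skipped and flagged.
#'
#' @param assignment An `ejacdyn_assignment` object.
#' @return Data.frame with one row per cluster pair: `cluster_a`,
#'   `cluster_b`, `n_a`, `n_b`, `median_a`, `median_b`, `W`, `p_two_sided`,
#'   `p_a_greater`, `skipped`.
#' @export
membership_compare <- function(assignment) {
  stopifnot(inherits(assignment, "ejacdyn_assignment"))
  cl <- split(assignment$membership, assignment$cluster)
  if (length(cl) < 2L) {
    stop("membership_compare: need at least 2 clusters", call. = FALSE)
  }
  prs <- combn(names(cl), 2)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    if (length(cl[[a]]) < 2L || length(cl[[b]]) < 2L) {
      return(data.frame(cluster_a = a, cluster_b = b,
                        n_a = length(cl[[a]]), n_b = length(cl[[b]]),
                        median_a = stats::median(cl[[a]]),
                        median_b = stats::median(cl[[b]]),
                        W = NA_real_, p_two_sided = NA_real_,
                        p_a_greater = NA_real_, skipped = TRUE))
    }
    tst <- rank_sum_test(cl[[a]], cl[[b]])
    data.frame(cluster_a = a, cluster_b = b,
               n_a = tst$n1, n_b = tst$n2,
               median_a = stats::median(cl[[a]]),
               median_b = stats::median(cl[[b]]),
               W = tst$W, p_two_sided = tst$p_two_sided,
               p_a_greater = tst$p_greater, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
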