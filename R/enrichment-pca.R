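# Hypergeometric fold-enrichment of cluster membership against annotation
# sets, and PCA of the protein x sample abundance matrix with
# loading-abundance correlation testing.

#' Hypergeometric enrichment of an annotation set in a protein cluster
#'
#' With background universe of size `N`, `K` annotated proteins, a cluster of
#' size `n` containing `k` annotated members, computes the fold enrichment
#' `(k/n) / (K/N)` and exact hypergeometric tail probabilities for
#' enrichment (`P(X >= k)`) and depletion (`P(X <= k)`).
#'
#' @param cluster Character vector of protein ids (the cluster).
#' @param annotation Character vector of protein ids (the annotation set).
#' @param background Character vector: the background universe; both sets
#'   are intersected with it.
#' @return List of class `ejacdyn_enrichment`: `set_size` (K), `cluster_size`
#'   (n), `background_size` (N), `overlap` (k), `fold`, `p_enrich`,
#'   `p_deplete`.
#' @examples
#' hypergeom_enrichment(paste0("p", 1:4), paste0("p", c(1:3, 10, 11)),
#'                      paste0("p", 1:20))
#' @export
hypergeom_enrichment <- function(cluster, annotation, background) {
  background <- unique(background)
  cluster <- intersect(unique(cluster), background)
  annotation <- intersect(unique(annotation), background)
  N <- length(background); n <- length(cluster); K <- length(annotation)
  if (n == 0L || K == 0L) {
    stop("hypergeom_enrichment: empty cluster or annotation set", call. = FALSE)
  }
  k <- length(intersect(cluster, annotation))
  out <- list(
    set_size = K, cluster_size = n, background_size = N, overlap = k,
    fold = (k / n) / (K / N),
    p_enrich = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
    p_deplete = phyper(k, K, N - K, n)
  )
  class(out) <- "ejacdyn_enrichment"
  out
}

#' @export
print.ejacdyn_enrichment <- function(x, ...) {
  cat(sprintf(
    "Enrichment: k = %d of n = %d (set K = %d, background N = %d)\n",
    x$overlap, x$cluster_size, x$set_size, x$background_size))
  cat(sprintf("  fold = %.3g, p(enrich) = %.4g, p(deplete) = %.4g\n",
              x$fold, x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Enrichment of annotation sets across profile clusters
#'
#' Applies [hypergeom_enrichment()] to every (cluster, annotation set) pair
#' and adjusts enrichment p-values across sets within each cluster by
#' Benjamini-Hochberg.
#'
#' @param assignment An `ejacdyn_assignment` object (or a named character
#'   vector of cluster labels per protein id).
#' @param annotations Named list of protein-id vectors (e.g. from
#'   [read_gmt()] or [simulate_proteome()]).
#' @param background Background universe; defaults to the analyzed proteins
#'   (the names of `assignment`). Supply a genome-wide id list to test
#'   against a wider background.
#' @param by `"profile_class"` (default) or `"cluster"`: the grouping of
#'   proteins tested for enrichment.
#' @return Data.frame: `group`, `set`, `overlap`, `cluster_size`,
#'   `set_size`, `background_size`, `fold`, `p_enrich`, `p_deplete`,
#'   `p_enrich_bh`.
#' @export
cluster_enrichment <- function(assignment, annotations, background = NULL,
                               by = c("profile_class", "cluster")) {
  by <- match.arg(by)
  if (inherits(assignment, "ejacdyn_assignment")) {
    labels <- setNames(assignment[[by]], assignment$protein_id)
  } else {
    labels <- assignment
  }
  if (is.null(background)) background <- names(labels)
  groups <- split(names(labels), labels)
  rows <- list()
  for (g in names(groups)) {
    for (s in names(annotations)) {
      e <- tryCatch(
        hypergeom_enrichment(groups[[g]], annotations[[s]], background),
        error = function(err) NULL
      )
      if (is.null(e)) next
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, set = s, overlap = e$overlap,
        cluster_size = e$cluster_size, set_size = e$set_size,
        background_size = e$background_size, fold = e$fold,
        p_enrich = e$p_enrich, p_deplete = e$p_deplete,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_enrich_bh <- stats::ave(out$p_enrich, out$group,
                                FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}

#' PCA of a protein x sample abundance matrix
#'
#' Eigen-decomposition of the sample covariance with proteins as
#' observations and samples as variables (columns centred, unscaled by
#' default). Component significance is assessed against a permutation null
#' in which every sample column is permuted independently (samples carry the
#' same marginal abundance distributions but no between-sample
#' correlation): a component is significant when its variance fraction
#' exceeds the 95th percentile of its permuted variance fractions.
#'
#' @param mat Numeric matrix, proteins x samples (log abundances).
#' @param scale Unit-scale the sample columns. Default `FALSE` (abundances
#'   share a compositional scale).
#' @param n_perm Number of row-wise permutations for significance (0 skips
#'   the test). Default 999.
#' @param seed Seed for the permutations.
#' @return Object of class `ejacdyn_pca`: list with `variance_fraction`
#'   (length = number of samples; trailing zero-variance components are 0),
#'   `scores` (protein scores per component), `rotation`, `significant`
#'   (logical per component), `perm_quantile95`, `n_significant`.
#' @export
pca_decompose <- function(mat, scale = FALSE, n_perm = 999L, seed = 1L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L || nrow(mat) < 3L) {
    stop("pca_decompose: need >= 2 samples and >= 3 proteins", call. = FALSE)
  }
  pc <- prcomp(mat, center = TRUE, scale. = scale)
  ev <- pc$sdev^2
  vf <- numeric(ncol(mat))
  vf[seq_along(ev)] <- ev / sum(ev)
  scores <- matrix(0, nrow(mat), ncol(mat),
                   dimnames = list(rownames(mat),
                                   paste0("PC", seq_len(ncol(mat)))))
  scores[, seq_len(ncol(pc$x))] <- pc$x
  sig <- rep(NA, ncol(mat))
  q95 <- rep(NA_real_, ncol(mat))
  if (n_perm > 0L) {
    set.seed(seed)
    perm_vf <- matrix(0, n_perm, ncol(mat))
    for (p in seq_len(n_perm)) {
      pm <- apply(mat, 2, sample)
      pev <- prcomp(pm, center = TRUE, scale. = scale)$sdev^2
      perm_vf[p, seq_along(pev)] <- pev / sum(pev)
    }
    q95 <- apply(perm_vf, 2, stats::quantile, probs = 0.95)
    sig <- vf > q95
  }
  out <- list(
    variance_fraction = setNames(vf, paste0("PC", seq_len(ncol(mat)))),
    scores = scores,
    rotation = pc$rotation,
    center = pc$center,
    significant = sig,
    perm_quantile95 = q95,
    n_significant = if (all(is.na(sig))) NA_integer_ else sum(sig),
    n_perm = n_perm
  )
  class(out) <- "ejacdyn_pca"
  out
}

#' @export
print.ejacdyn_pca <- function(x, digits = 3, ...) {
  cat("PCA of protein x sample abundances\n")
  df <- data.frame(
    component = names(x$variance_fraction),
    variance_fraction = round(x$variance_fraction, digits),
    significant = x$significant
  )
  print(df, row.names = FALSE)
  if (!is.na(x$n_significant)) {
    cat(sprintf("%d significant components (%d permutations)\n",
                x$n_significant, x$n_perm))
  }
  invisible(x)
}

#' Correlation between component scores and per-sample abundances
#'
#' For each principal component and sample, the Pearson correlation between
#' the protein scores on that component and the sample's protein abundances,
#' with the two-sided t-test p-value. Identifies which samples load on which
#' axis of interproteomic variation.
#'
#' @param pca An `ejacdyn_pca` object.
#' @param mat The matrix passed to [pca_decompose()].
#' @param components Component indices to report. Default all.
#' @return Data.frame: `component`, `sample`, `r`, `r_squared`, `p`.
#' @export
loading_abundance_corr <- function(pca, mat, components = NULL) {
  stopifnot(inherits(pca, "ejacdyn_pca"))
  mat <- as.matrix(mat)
  if (is.null(components)) components <- seq_len(ncol(mat))
  rows <- list()
  for (comp in components) {
    sc <- pca$scores[, comp]
    for (s in colnames(mat)) {
      y <- mat[, s]
      if (sd(sc) == 0 || sd(y) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          component = paste0("PC", comp), sample = s,
          r = NA_real_, r_squared = NA_real_, p = NA_real_)
        next
      }
      ct <- cor.test(sc, y)
      rows[[length(rows) + 1L]] <- data.frame(
        component = paste0("PC", comp), sample = s,
        r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
        p = ct$p.value, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
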