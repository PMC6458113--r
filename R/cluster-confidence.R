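# Hierarchical clustering of seminal fluid samples with multiscale-bootstrap
# edge confidence: BP (raw bootstrap probability) and AU (approximately
# unbiased p-value from the signed-distance/curvature fit across resampling
# scales).

#' Complete-linkage euclidean dendrogram of samples
#'
#' Clusters the samples (columns) of a log-abundance matrix with euclidean
#' distance and complete linkage. Columns are ordered lexicographically by
#' sample id first, so ties in minimal distance are broken reproducibly.
#'
#' @param mat Numeric matrix, proteins (features) x samples.
#' @return An object of class `hclust`.
#' @export
hcluster <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("hcluster: need at least 2 samples", call. = FALSE)
  mat <- mat[, order(colnames(mat)), drop = FALSE]
  hclust(dist(t(mat), method = "euclidean"), method = "complete")
}

# weighted-least-squares fit of the multiscale signed-distance model
# z(r) = v*sqrt(r) + c/sqrt(r) to per-scale bootstrap probabilities;
# weights follow from the binomial variance of bp through the
# normal-quantile delta method. AU = 1 - Phi(v - c), BP = 1 - Phi(v + c).
au_fit <- function(bp, rho, B) {
  # saturated support: the edge is found in (essentially) every replicate at
  # every scale, so the signed-distance model has no information to separate
  # v from c; report certainty directly
  if (all(bp >= 1 - 1 / (2 * B))) {
    return(list(v = -Inf, c = 0, au = 1, bp = 1, degenerate = FALSE))
  }
  if (all(bp <= 1 / (2 * B))) {
    return(list(v = Inf, c = 0, au = 0, bp = 0, degenerate = FALSE))
  }
  bp <- pmin(pmax(bp, 1 / (2 * B)), 1 - 1 / (2 * B))
  z <- qnorm(1 - bp)
  wt <- B * dnorm(z)^2 / (bp * (1 - bp))
  X <- cbind(sqrt(rho), 1 / sqrt(rho))
  usable <- is.finite(z) & is.finite(wt) & wt > 0
  if (sum(usable) < 2L || length(unique(rho[usable])) < 2L) {
    return(list(v = NA_real_, c = NA_real_, au = NA_real_, bp = NA_real_,
                degenerate = TRUE))
  }
  fit <- stats::lm.wfit(X[usable, , drop = FALSE], z[usable], wt[usable])
  v <- unname(fit$coefficients[1])
  cc <- unname(fit$coefficients[2])
  list(v = v, c = cc, au = 1 - pnorm(v - cc), bp = 1 - pnorm(v + cc),
       degenerate = FALSE)
}

# clade leaf sets of an hclust tree, canonicalized to the bipartition side
# not containing the lexicographically smallest leaf (so topologically
# equivalent trees match regardless of rotation/rooting)
clade_keys <- function(hc) {
  labs <- hc$labels
  anchor <- min(labs)
  n <- length(labs)
  members <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[i, ]
    got <- unlist(lapply(kids, function(k) {
      if (k < 0) labs[-k] else members[[k]]
    }))
    members[[i]] <- got
  }
  keys <- vapply(members, function(m) {
    side <- if (anchor %in% m) setdiff(labs, m) else m
    paste(sort(side), collapse = "|")
  }, character(1))
  list(keys = keys, members = members)
}

#' Multiscale bootstrap confidence for dendrogram edges
#'
#' Assesses the support of every edge (sample bipartition) of a
#' complete-linkage euclidean dendrogram by multiscale bootstrap resampling
#' of the proteins (features). For each scale `r`, `B` resamples of
#' `ceiling(r * N)` proteins are drawn with replacement, the dendrogram is
#' rebuilt, and `bp_r` is the fraction of replicates whose tree contains the
#' edge's bipartition. The probabilities (clamped away from 0 and 1 by
#' `1/(2B)`) are mapped to normal quantiles `z_r = qnorm(1 - bp_r)` and
#' fitted by weighted least squares to `z(r) = v * sqrt(r) + c / sqrt(r)`
#' (weights from the binomial variance of `bp_r` through the delta method).
#' The approximately unbiased p-value is `AU = 1 - pnorm(v - c)` and the
#' bias-corrected bootstrap probability `BP = 1 - pnorm(v + c)`. The edge
#' containing all samples has `AU = BP = 1` by convention.
#'
#' @param mat Numeric matrix, proteins x samples (log abundances).
#' @param scales Resampling scale multipliers; default `seq(0.5, 1.4, 0.1)`.
#' @param B Bootstrap replicates per scale; default 1000.
#' @param seed Integer seed.
#' @return An object of class `ejacdyn_edge_support`: a data.frame with one
#'   row per internal edge (`edge` key, `members`, `au`, `bp` (fitted),
#'   `bp_raw` (observed at the scale nearest 1), `v`, `c`, `degenerate_fit`),
#'   with attributes `bp_per_scale` (edges x scales matrix), `scales`
#'   (realized `n'/N`), `B`, and `tree` (the `hclust` object).
#' @examples
#' x <- rbind(matrix(rnorm(40), 10, 4),
#'            matrix(rnorm(40, 3), 10, 4))
#' colnames(x) <- paste0("s", 1:4)
#' multiscale_bootstrap(x, B = 100, seed = 1)
#' @export
multiscale_bootstrap <- function(mat, scales = seq(0.5, 1.4, by = 0.1),
                                 B = 1000L, seed = 1L) {
  mat <- as.matrix(mat)
  if (!any(abs(scales - 1) < 1e-9)) {
    stop("multiscale_bootstrap: scales must include 1.0", call. = FALSE)
  }
  if (B < 100L) stop("multiscale_bootstrap: B must be >= 100", call. = FALSE)
  N <- nrow(mat)
  hc <- hcluster(mat)
  obs <- clade_keys(hc)
  E <- length(obs$keys)
  set.seed(seed)

  sizes <- pmax(2L, as.integer(ceiling(scales * N)))
  rho <- sizes / N
  hits <- matrix(0L, E, length(scales),
                 dimnames = list(obs$keys, sprintf("r=%.2f", rho)))
  for (s in seq_along(scales)) {
    for (b in seq_len(B)) {
      idx <- sample.int(N, sizes[s], replace = TRUE)
      bk <- clade_keys(hcluster(mat[idx, , drop = FALSE]))$keys
      hit <- obs$keys %in% bk
      hits[hit, s] <- hits[hit, s] + 1L
    }
  }
  bp_per_scale <- hits / B

  is_root <- vapply(obs$members, length, integer(1)) == ncol(mat)
  au <- bp_fit <- v <- cc <- numeric(E)
  degen <- logical(E)
  near1 <- which.min(abs(rho - 1))
  for (e in seq_len(E)) {
    if (is_root[e]) {
      au[e] <- bp_fit[e] <- 1
      v[e] <- cc[e] <- 0
      next
    }
    fit <- au_fit(bp_per_scale[e, ], rho, B)
    v[e] <- fit$v
    cc[e] <- fit$c
    au[e] <- fit$au
    bp_fit[e] <- fit$bp
    degen[e] <- fit$degenerate
    if (fit$degenerate) au[e] <- bp_fit[e] <- bp_per_scale[e, near1]
  }
  out <- data.frame(
    edge = obs$keys,
    members = vapply(obs$members, function(m) paste(sort(m), collapse = "|"),
                     character(1)),
    au = au, bp = bp_fit, bp_raw = bp_per_scale[, near1],
    v = v, c = cc, degenerate_fit = degen,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "bp_per_scale") <- bp_per_scale
  attr(out, "scales") <- rho
  attr(out, "B") <- B
  attr(out, "tree") <- hc
  class(out) <- c("ejacdyn_edge_support", "data.frame")
  out
}

#' @export
print.ejacdyn_edge_support <- function(x, digits = 3, ...) {
  cat(sprintf("Multiscale bootstrap edge support (B = %d per scale, %d scales)\n",
              attr(x, "B"), length(attr(x, "scales"))))
  keep <- intersect(c("members", "au", "bp", "bp_raw", "v", "c"), names(x))
  y <- as.data.frame(x)[, keep]
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}
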