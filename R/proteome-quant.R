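# Compositional spectral-count quantitation (detectability-weighted, APEX
# style), consistency filtering, log/standardize transforms and
# between-sample similarity.

#' Detectability-weighted compositional protein abundances
#'
#' Converts spectral counts to compositional abundances: per sample,
#' `p_i = C * (n_i / O_i) / sum_j (n_j / O_j)`, where `O_i` is the per-protein
#' detectability probability (how likely the protein is to generate observed
#' spectra, here supplied externally; uniform by default) and `C` the fixed
#' per-sample total. With uniform `O` this reduces exactly to spectral-count
#' proportions, and it is invariant to per-sample count rescaling.
#'
#' @param counts Nonnegative integer matrix, proteins x samples, with
#'   rownames (protein ids) and colnames (sample ids).
#' @param detectability Positive numeric vector `O`; either unnamed of length
#'   `nrow(counts)` or named covering all proteins. Default uniform (1).
#' @param total Per-sample abundance total `C`. Default 1 (proportions).
#' @return Numeric matrix of abundances with the same dimnames; each column
#'   sums to `total`.
#' @examples
#' m <- matrix(c(10, 30), 2, 1, dimnames = list(c("a", "b"), "s"))
#' apex_compositional(m, detectability = c(a = 1, b = 2))
#' @export
apex_compositional <- function(counts, detectability = NULL, total = 1) {
  counts <- as.matrix(counts)
  if (total <= 0) stop("apex_compositional: total must be positive", call. = FALSE)
  if (any(counts < 0)) stop("apex_compositional: negative counts", call. = FALSE)
  n <- nrow(counts)
  if (is.null(detectability)) {
    O <- rep(1, n)
  } else if (!is.null(names(detectability))) {
    miss <- setdiff(rownames(counts), names(detectability))
    if (length(miss)) {
      stop("apex_compositional: detectability missing for ",
           length(miss), " proteins (e.g. ", miss[1], ")", call. = FALSE)
    }
    O <- as.numeric(detectability[rownames(counts)])
  } else {
    if (length(detectability) != n) {
      stop("apex_compositional: detectability length mismatch", call. = FALSE)
    }
    O <- as.numeric(detectability)
  }
  if (any(!is.finite(O)) || any(O <= 0)) {
    stop("apex_compositional: detectability must be positive", call. = FALSE)
  }
  wtd <- counts / O
  tot <- colSums(wtd)
  if (any(tot == 0)) {
    stop("apex_compositional: sample(s) with all-zero counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "), call. = FALSE)
  }
  sweep(wtd, 2, tot, "/") * total
}

#' Proteins identified consistently across all sample groups
#'
#' Returns the ids of proteins with nonzero evidence in every group of
#' samples (typically the four successive matings M1, M2, M3, F2, each group
#' possibly containing several status-specific samples).
#'
#' @param mat Counts or abundance matrix, proteins x samples, with dimnames.
#' @param sample_groups Named list partitioning the sample ids into groups,
#'   or `NULL` to group by the mating suffix of `<status>_<mating>` column
#'   names.
#' @return Character vector of retained protein ids.
#' @export
filter_consistent <- function(mat, sample_groups = NULL) {
  mat <- as.matrix(mat)
  if (is.null(sample_groups)) {
    mating <- sub("^.*_", "", colnames(mat))
    sample_groups <- split(colnames(mat), mating)
  }
  if (any(lengths(sample_groups) == 0L)) {
    stop("filter_consistent: empty sample group", call. = FALSE)
  }
  keep <- rep(TRUE, nrow(mat))
  for (g in sample_groups) {
    keep <- keep & rowSums(mat[, g, drop = FALSE] > 0) > 0
  }
  rownames(mat)[keep]
}

#' Log transform and (optionally) per-protein standardization
#'
#' Natural-log transform of an abundance matrix after flooring zeros at a
#' pseudo-abundance (default half the smallest positive entry). With
#' `standardize = TRUE` every protein row is additionally centred to mean 0
#' and scaled to SD 1 across samples -- the representation used for fuzzy
#' temporal clustering; constant rows cannot be standardized and are dropped
#' (recorded in the `dropped` attribute).
#'
#' @param mat Abundance matrix, proteins x samples.
#' @param standardize Standardize rows after the log. Default `FALSE`.
#' @param floor Pseudo-abundance replacing zeros; default half the smallest
#'   positive value of `mat`.
#' @return Transformed matrix; if `standardize = TRUE` the attribute
#'   `dropped` lists removed constant proteins.
#' @export
log_standardize <- function(mat, standardize = FALSE, floor = NULL) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("log_standardize: negative abundances", call. = FALSE)
  if (is.null(floor)) {
    pos <- mat[mat > 0]
    if (length(pos) == 0L) stop("log_standardize: all-zero matrix", call. = FALSE)
    floor <- min(pos) / 2
  }
  mat[mat == 0] <- floor
  lg <- log(mat)
  if (!standardize) return(lg)
  rs <- apply(lg, 1, sd)
  dropped <- rownames(lg)[rs == 0 | !is.finite(rs)]
  keep <- setdiff(rownames(lg), dropped)
  lg <- lg[keep, , drop = FALSE]
  lg <- (lg - rowMeans(lg)) / apply(lg, 1, sd)
  attr(lg, "dropped") <- dropped
  lg
}

#' Pairwise squared Pearson correlation between samples
#'
#' For each pair of samples, computes the squared Pearson correlation over
#' proteins present (nonzero) in both samples, on log abundances by default.
#' Pairs sharing fewer than `min_shared` proteins get `NA` (flagged).
#'
#' @param mat Abundance matrix, proteins x samples.
#' @param log If `TRUE` (default), correlate log abundances (zeros floored as
#'   in [log_standardize()]); if `FALSE`, raw abundances.
#' @param min_shared Minimum shared proteins per pair. Default 3.
#' @return Symmetric samples x samples matrix of R-squared values with unit
#'   diagonal.
#' @export
pairwise_r2 <- function(mat, log = TRUE, min_shared = 3L) {
  mat <- as.matrix(mat)
  S <- ncol(mat)
  lg <- if (log) log_standardize(mat) else mat
  out <- matrix(NA_real_, S, S, dimnames = list(colnames(mat), colnames(mat)))
  diag(out) <- 1
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (j <= i) next
      shared <- mat[, i] > 0 & mat[, j] > 0
      if (sum(shared) < min_shared) next
      r <- cor(lg[shared, i], lg[shared, j])
      out[i, j] <- out[j, i] <- r^2
    }
  }
  out
}
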