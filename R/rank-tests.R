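# Exact small-sample rank tests with midrank tie handling.
#
# Both tests work on "doubled" midranks (2 * rank), which are integers even
# under ties, so exact null distributions can be built by dynamic programming
# over integer sums instead of explicit enumeration.

# distribution of the signed-rank statistic V (doubled scale) over all 2^n
# sign assignments: generating-function convolution
signed_rank_null <- function(doubled_ranks) {
  total <- sum(doubled_ranks)
  p <- numeric(total + 1)
  p[1] <- 1
  for (r in doubled_ranks) {
    shifted <- c(rep(0, r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p # p[s + 1] = P(2V = s)
}

#' Paired Wilcoxon signed-rank test with exact small-sample inference
#'
#' Computes `V`, the sum of the ranks (midranks under ties) of the positive
#' differences `observed - predicted`, and its null distribution. Zero
#' differences are dropped by default (their count is reported); the exact
#' distribution over all `2^n` sign assignments is obtained by dynamic
#' programming for `n_used <= exact_limit`, otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param observed,predicted Paired numeric vectors, or `observed` may be a
#'   vector of differences with `predicted = 0`.
#' @param exact_limit Largest `n_used` for which the exact distribution is
#'   computed. Default 25.
#' @param zero_method `"drop"` (classic: discard zero differences) or
#'   `"pratt"` (rank zeros, then discard their signs).
#' @return An object of class `ejacdyn_signed_rank`: list with `V`,
#'   `p_two_sided`, `p_greater`, `p_less`, `n_used`, `n_zero`, `exact`,
#'   and `pairs` (a data.frame of the paired values).
#' @examples
#' signed_rank_test(c(3, 1, 4), c(1, 2, 1)) # differences +2, -1, +3
#' @export
signed_rank_test <- function(observed, predicted = 0, exact_limit = 25L,
                             zero_method = c("drop", "pratt")) {
  zero_method <- match.arg(zero_method)
  d <- observed - predicted
  d <- d[!is.na(d)]
  n_zero <- sum(d == 0)
  if (all(d == 0)) {
    stop("signed_rank_test: all differences are zero (degenerate test)",
         call. = FALSE)
  }
  if (zero_method == "drop") {
    dd <- d[d != 0]
    r <- rank(abs(dd))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    dd <- d[keep]
    r <- r_all[keep]
  }
  n_used <- length(dd)
  V <- sum(r[dd > 0])
  R2 <- as.integer(round(2 * r))
  v2 <- as.integer(round(2 * V))
  if (n_used <= exact_limit) {
    null <- signed_rank_null(R2)
    p_greater <- sum(null[(v2 + 1):length(null)])
    p_less <- sum(null[1:(v2 + 1)])
    exact <- TRUE
  } else {
    mu <- sum(r) / 2
    sigma2 <- sum(r^2) / 4
    z_g <- (V - 0.5 - mu) / sqrt(sigma2)
    z_l <- (V + 0.5 - mu) / sqrt(sigma2)
    p_greater <- pnorm(z_g, lower.tail = FALSE)
    p_less <- pnorm(z_l)
    exact <- FALSE
  }
  out <- list(
    V = V,
    p_two_sided = min(1, 2 * min(p_greater, p_less)),
    p_greater = p_greater,
    p_less = p_less,
    n_used = n_used,
    n_zero = n_zero,
    exact = exact,
    pairs = data.frame(observed = observed,
                       predicted = rep_len(predicted, length(observed)))
  )
  class(out) <- "ejacdyn_signed_rank"
  out
}

#' @export
print.ejacdyn_signed_rank <- function(x, ...) {
  cat(sprintf(
    "Paired signed-rank test: V = %.4g (n = %d, %d zero diffs dropped)\n",
    x$V, x$n_used, x$n_zero))
  cat(sprintf("  p (two-sided) = %.4g, p (greater) = %.4g [%s]\n",
              x$p_two_sided, x$p_greater,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}

# distribution of the rank sum of the first group (doubled scale) over all
# C(N, n1) equally likely subsets; dp counts stored as doubles (sums of
# positive terms, so relative error stays at machine precision)
rank_sum_null <- function(doubled_ranks, n1) {
  total <- sum(doubled_ranks)
  dp <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  dp[1, 1] <- 1
  for (r in doubled_ranks) {
    for (k in seq(min(n1, 1e9), 1)) {
      src <- dp[k, seq_len(total + 1 - r)]
      if (any(src != 0)) {
        idx <- (r + 1):(total + 1)
        dp[k + 1, idx] <- dp[k + 1, idx] + src
      }
    }
  }
  counts <- dp[n1 + 1, ]
  counts / sum(counts) # P(2W = s), s = 0..total
}

#' Two-sample Wilcoxon rank-sum test with exact small-sample inference
#'
#' Rank-sum statistic `W` of group `x` (midranks under ties). Exact null
#' distribution over all subsets of pooled ranks by dynamic programming when
#' `min(n1, n2) <= exact_limit`; otherwise normal approximation with tie and
#' continuity corrections.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest smaller-group size for exact inference.
#'   Default 10.
#' @return An object of class `ejacdyn_rank_sum`: list with `W` (rank sum of
#'   `x`), `U` (Mann-Whitney statistic), `p_two_sided`, `p_greater`,
#'   `p_less`, `n1`, `n2`, `exact`.
#' @examples
#' rank_sum_test(c(2.0, 1.8), c(0.5, 0.6))
#' @export
rank_sum_test <- function(x, y, exact_limit = 10L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop("rank_sum_test: a group is empty", call. = FALSE)
  }
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  N <- n1 + n2
  if (min(n1, n2) <= exact_limit) {
    # DP over the smaller group; convert tail for the larger if swapped
    swap <- n2 < n1
    ns <- if (swap) n2 else n1
    Ws <- if (swap) sum(r[n1 + seq_len(n2)]) else W
    null <- rank_sum_null(as.integer(round(2 * r)), ns)
    w2 <- as.integer(round(2 * Ws))
    p_g_s <- sum(null[(w2 + 1):length(null)])
    p_l_s <- sum(null[1:(w2 + 1)])
    if (swap) {
      p_greater <- p_l_s
      p_less <- p_g_s
    } else {
      p_greater <- p_g_s
      p_less <- p_l_s
    }
    exact <- TRUE
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    p_greater <- pnorm((W - 0.5 - mu) / sqrt(sigma2), lower.tail = FALSE)
    p_less <- pnorm((W + 0.5 - mu) / sqrt(sigma2))
    exact <- FALSE
  }
  out <- list(
    W = W,
    U = W - n1 * (n1 + 1) / 2,
    p_two_sided = min(1, 2 * min(p_greater, p_less)),
    p_greater = p_greater,
    p_less = p_less,
    n1 = n1, n2 = n2,
    exact = exact
  )
  class(out) <- "ejacdyn_rank_sum"
  out
}

#' @export
print.ejacdyn_rank_sum <- function(x, ...) {
  cat(sprintf("Rank-sum test: W = %.4g (n1 = %d, n2 = %d)\n", x$W, x$n1, x$n2))
  cat(sprintf("  p (two-sided) = %.4g, p (greater) = %.4g [%s]\n",
              x$p_two_sided, x$p_greater,
              if (x$exact) "exact" else "normal approximation"))
  invisible(x)
}
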