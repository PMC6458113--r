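# Per-male depletion-prediction ("Coolidge") test: does the ejaculate
# delivered to the second, sexually novel female exceed what the male's own
# depletion line over matings with the first female predicts?

response_column <- function(response) {
  switch(response,
    sperm = "sperm_number",
    volume = "sf_volume_ul",
    protein = "sf_protein_ug_per_ul",
    stop("unknown response '", response, "'", call. = FALSE)
  )
}

#' Per-male depletion line and novel-female prediction
#'
#' Fits an ordinary least-squares line of `log(1 + y)` on cumulative exposure
#' over a male's opportunities with the first female -- including
#' opportunities without an ejaculate, which enter as zeros -- and predicts
#' the response at the exposure of his single mating with the second, novel
#' female. The prediction is back-transformed as `exp(yhat) - 1` and clamped
#' at zero.
#'
#' @param records Data.frame of one male's mating records (columns as in
#'   [simulate_behavior()]).
#' @param response One of `"sperm"`, `"volume"`, `"protein"`.
#' @param include_female2 If `TRUE`, the female-2 row itself is included in
#'   the fitted line (sensitivity mode); default `FALSE` fits on female-1
#'   rows only and predicts the female-2 exposure.
#' @return List with `fit` (list: `male_id`, `slope`, `intercept`,
#'   `n_points`, `response`), `predicted` (clamped, response units) and
#'   `observed` (the female-2 value).
#' @examples
#' rec <- data.frame(male_id = "m", female_order = c(1, 1, 1, 2),
#'                   cumulative_exposure = 1:4, ejaculated = 1,
#'                   sperm_number = c(exp(1.5), exp(1), exp(0.5), 9) - 1)
#' fit_depletion_predict(rec, "sperm")
#' @export
fit_depletion_predict <- function(records, response = "sperm",
                                  include_female2 = FALSE) {
  col <- response_column(response)
  f2 <- records[records$female_order == 2L, , drop = FALSE]
  if (nrow(f2) != 1L) {
    stop("fit_depletion_predict: need exactly one female-2 record, got ",
         nrow(f2), call. = FALSE)
  }
  train <- if (include_female2) records else
    records[records$female_order == 1L, , drop = FALSE]
  if (sum(records$female_order == 1L) < 2L) {
    stop("fit_depletion_predict: fewer than 2 female-1 opportunities",
         call. = FALSE)
  }
  x <- train$cumulative_exposure
  y <- log1p(train[[col]])
  b <- stats::cov(x, y) / stats::var(x)
  a <- mean(y) - b * mean(x)
  yhat <- a + b * f2$cumulative_exposure
  predicted <- max(expm1(yhat), 0)
  list(
    fit = list(male_id = as.character(records$male_id[1]), slope = b,
               intercept = a, n_points = length(x), response = response),
    predicted = predicted,
    observed = f2[[col]]
  )
}

#' Observed-vs-predicted test of preferential investment in female novelty
#'
#' For every usable male, fits the per-male depletion line
#' ([fit_depletion_predict()]), assembles the pair (observed female-2 value,
#' back-transformed zero-truncated prediction) and tests whether observed
#' values systematically exceed predictions with the paired Wilcoxon
#' signed-rank test ([signed_rank_test()]). Males with fewer than two
#' female-1 opportunities or no female-2 record are skipped and listed.
#'
#' @param data Behavioral dataset.
#' @param response One of `"sperm"`, `"volume"`, `"protein"`.
#' @param include_female2 Passed to [fit_depletion_predict()].
#' @param zero_method Passed to [signed_rank_test()].
#' @return An object of class `ejacdyn_coolidge`: list with `pairs`
#'   (data.frame: male_id, observed, predicted, difference), `test`
#'   (the `ejacdyn_signed_rank` result), `V`, `p_two_sided`, `p_greater`,
#'   `n_used`, `skipped` (character vector of male ids), `response`.
#' @examples
#' dat <- simulate_behavior(behavior_sim_config(seed = 11))
#' coolidge_analysis(dat, "sperm")
#' @export
coolidge_analysis <- function(data, response = "sperm",
                              include_female2 = FALSE,
                              zero_method = "drop") {
  d <- as.data.frame(data)
  males <- unique(d$male_id)
  obs <- pred <- numeric(0)
  ids <- skipped <- character(0)
  for (m in males) {
    rec <- d[d$male_id == m, , drop = FALSE]
    res <- tryCatch(
      fit_depletion_predict(rec, response, include_female2 = include_female2),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- c(skipped, m)
    } else {
      ids <- c(ids, m)
      obs <- c(obs, res$observed)
      pred <- c(pred, res$predicted)
    }
  }
  if (length(ids) < 1L) {
    stop("coolidge_analysis: no usable male", call. = FALSE)
  }
  test <- signed_rank_test(obs, pred, zero_method = zero_method)
  out <- list(
    pairs = data.frame(male_id = ids, observed = obs, predicted = pred,
                       difference = obs - pred, stringsAsFactors = FALSE),
    test = test,
    V = test$V,
    p_two_sided = test$p_two_sided,
    p_greater = test$p_greater,
    n_used = test$n_used,
    skipped = skipped,
    response = response
  )
  class(out) <- "ejacdyn_coolidge"
  out
}

#' @export
print.ejacdyn_coolidge <- function(x, ...) {
  cat(sprintf(
    "Coolidge depletion-prediction test (%s): %d males (%d skipped)\n",
    x$response, nrow(x$pairs), length(x$skipped)))
  cat(sprintf("  V = %.4g, p (two-sided) = %.4g, p (greater) = %.4g\n",
              x$V, x$p_two_sided, x$p_greater))
  invisible(x)
}

#' Status contrast of proportional investment in the novel female
#'
#' For each male with an ejaculate at both his last female-1 mating and the
#' female-2 mating, forms the ratio female-2 value / last female-1 value and
#' compares dominant vs subdominant males with the two-sample rank-sum test
#' ([rank_sum_test()]). Males without both values (or a zero denominator)
#' are skipped and listed.
#'
#' @param data Behavioral dataset.
#' @param response One of `"sperm"`, `"volume"`, `"protein"`.
#' @return An object of class `ejacdyn_status_ratio`: list with `ratios`
#'   (data.frame: male_id, status, ratio), `test` (`ejacdyn_rank_sum`),
#'   `skipped`, `response`.
#' @export
status_ratio_compare <- function(data, response = "sperm") {
  col <- response_column(response)
  d <- as.data.frame(data)
  males <- unique(d$male_id)
  ids <- stat <- character(0)
  ratio <- numeric(0)
  skipped <- character(0)
  for (m in males) {
    rec <- d[d$male_id == m, , drop = FALSE]
    f2 <- rec[rec$female_order == 2L & rec$ejaculated == 1L, , drop = FALSE]
    f1 <- rec[rec$female_order == 1L & rec$ejaculated == 1L, , drop = FALSE]
    if (nrow(f2) != 1L || nrow(f1) == 0L) {
      skipped <- c(skipped, m)
      next
    }
    last1 <- f1[[col]][which.max(f1$cumulative_exposure)]
    if (!is.finite(last1) || last1 <= 0) {
      skipped <- c(skipped, m)
      next
    }
    ids <- c(ids, m)
    stat <- c(stat, as.character(rec$status[1]))
    ratio <- c(ratio, f2[[col]] / last1)
  }
  dom <- ratio[stat == "dominant"]
  sub <- ratio[stat == "subdominant"]
  if (length(dom) == 0L || length(sub) == 0L) {
    stop("status_ratio_compare: a status group is empty", call. = FALSE)
  }
  out <- list(
    ratios = data.frame(male_id = ids, status = stat, ratio = ratio,
                        stringsAsFactors = FALSE),
    test = rank_sum_test(dom, sub),
    skipped = skipped,
    response = response
  )
  class(out) <- "ejacdyn_status_ratio"
  out
}

#' @export
print.ejacdyn_status_ratio <- function(x, ...) {
  cat(sprintf(
    "Status contrast of novel/last-familiar %s ratios (%d dominant, %d subdominant)\n",
    x$response, x$test$n1, x$test$n2))
  print(x$test)
  invisible(x)
}
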