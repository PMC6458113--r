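#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 * loglik + 2k + 2k(k + 1) / (n - k - 1)`. The correction is the
#' appropriate criterion when the observations-per-parameter ratio is small
#' (n/k < 40), as in short mating-sequence trials.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (fixed effects including the
#'   intercept, plus one per variance component).
#' @param n Number of observations.
#' @return The AICc value.
#' @examples
#' aicc(-82.33, 5, 55) # 175.88
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc correction undefined: need n > k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights of a candidate model set
#'
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)` with
#' `delta_i = AICc_i - min(AICc)`: the normalized relative likelihood of each
#' model given the set.
#'
#' @param aicc_values Numeric vector of AICc values.
#' @return Weights summing to 1, in the input order.
#' @examples
#' round(akaike_weights(c(112.34, 113.77, 115.11, 122.46, 123.95)), 2)
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0L) {
    stop("akaike_weights: empty AICc list", call. = FALSE)
  }
  delta <- aicc_values - min(aicc_values)
  w <- exp(-delta / 2)
  w / sum(w)
}

# the fixed candidate set: Null, F, CE, CE + F, CE + F + CE:F
candidate_terms <- function() {
  list(
    "Null" = character(),
    "F" = "F",
    "CE" = "CE",
    "CE + F" = c("CE", "F"),
    "CE + F + CE x F" = c("CE", "F", "CE:F")
  )
}

response_spec <- function(response) {
  switch(response,
    ejaculation = list(var = "ejaculated", family = "binomial",
                       transform = identity, subset_ejaculated = FALSE),
    sperm = list(var = "sperm_number", family = "gaussian",
                 transform = log, subset_ejaculated = TRUE),
    volume = list(var = "sf_volume_ul", family = "gaussian",
                  transform = log, subset_ejaculated = TRUE),
    protein = list(var = "sf_protein_ug_per_ul", family = "gaussian",
                   transform = identity, subset_ejaculated = TRUE),
    stop("unknown response '", response, "'", call. = FALSE)
  )
}

# model frame with response y, predictors CE (exposure) and F (novelty 0/1),
# optionally standardized to mean 0 / SD 0.5 for effect-size comparability
build_model_frame <- function(data, response, standardize = FALSE) {
  rs <- response_spec(response)
  d <- as.data.frame(data)
  if (rs$subset_ejaculated) d <- d[d$ejaculated == 1L, , drop = FALSE]
  y <- rs$transform(d[[rs$var]])
  mf <- data.frame(
    y = y,
    CE = as.numeric(d$cumulative_exposure),
    F = as.numeric(d$female_order == 2L),
    male_id = factor(d$male_id)
  )
  std <- NULL
  if (standardize) {
    std <- list(
      CE = c(center = mean(mf$CE), scale = 2 * sd(mf$CE)),
      F = c(center = mean(mf$F), scale = 2 * sd(mf$F))
    )
    mf$CE <- (mf$CE - std$CE["center"]) / std$CE["scale"]
    mf$F <- (mf$F - std$F["center"]) / std$F["scale"]
  }
  attr(mf, "standardization") <- std
  attr(mf, "family") <- rs$family
  mf
}

fit_one_model <- function(mf, terms, family, nAGQ = 25L) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", rhs, "+ (1 | male_id)"))
  n <- nrow(mf)
  # boundary/singular messages are recorded in the result instead of printed
  fit <- tryCatch(suppressMessages({
    if (family == "binomial") {
      lme4::glmer(form, data = mf, family = stats::binomial(), nAGQ = nAGQ)
    } else {
      lme4::lmer(form, data = mf, REML = FALSE)
    }
  }), error = function(e) e)
  if (inherits(fit, "error")) {
    return(list(ok = FALSE, message = conditionMessage(fit)))
  }
  ll <- as.numeric(logLik(fit))
  beta <- lme4::fixef(fit)
  vc <- lme4::VarCorr(fit)
  re_var <- as.numeric(vc$male_id[1, 1])
  resid_var <- if (family == "gaussian") attr(vc, "sc")^2 else NA_real_
  # k: fixed effects (incl. intercept) + RE variance + residual variance (gaussian)
  k <- length(beta) + 1L + as.integer(family == "gaussian")
  se <- sqrt(diag(as.matrix(vcov(fit))))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  # a singular fit (RE variance at the 0 boundary) is allowed and reported;
  # only genuine optimizer failures disqualify a model from the top set
  failed <- any(grepl("failed to converge", msgs, fixed = TRUE)) ||
    fit@optinfo$conv$opt != 0
  list(ok = TRUE, fit = fit, loglik = ll, k = k, n = n,
       coefficients = beta, se = se, re_variance = re_var,
       residual_variance = resid_var,
       singular = lme4::isSingular(fit),
       converged = !failed)
}

#' Fit and rank the candidate mixed-model set for an expenditure response
#'
#' Fits the five-model candidate set {Null, F, CE, CE + F, CE + F + CE x F}
#' by maximum (marginal) likelihood with a random intercept per male, where
#' CE is cumulative exposure (continuous) and F female novelty (two-level:
#' first vs second female), then ranks models by AICc and computes Akaike
#' weights. The binomial family (probability of ejaculation) uses adaptive
#' Gauss-Hermite quadrature over the male random intercept; gaussian
#' responses (log sperm number, log SF volume, SF protein concentration) use
#' ML linear mixed fits and are restricted to opportunities with an
#' ejaculate. The top model set contains models within `delta_top` AICc of
#' the best; the best minimal model is the top-set member with fewest
#' parameters (ties broken by lower AICc).
#'
#' @param data A behavioral dataset (`ejacdyn_behavior` or a data.frame with
#'   the same columns).
#' @param response One of `"ejaculation"`, `"sperm"`, `"volume"`,
#'   `"protein"`.
#' @param standardize Standardize CE and F to mean 0, SD 0.5 before fitting
#'   (the effect-size convention used for model averaging). Default `FALSE`:
#'   the ranking is invariant to affine predictor coding, so selection tables
#'   are reported on the natural scale.
#' @param delta_top AICc window defining the top model set. Default 2.
#' @param nAGQ Quadrature nodes for the binomial marginal likelihood.
#'   Default 25 (the likelihood is stable well below 0.01 under doubling).
#' @return An object of class `ejacdyn_selection`: a list with `table` (one
#'   row per model: model, k, loglik, aicc, delta, weight, in_top_set,
#'   best_minimal, converged), `fits` (per-model fit details), `response`,
#'   `family`, `n_obs`, `n_males`, `standardization`.
#' @examples
#' dat <- simulate_behavior(behavior_sim_config(seed = 3))
#' sel <- fit_candidate_set(dat, "sperm")
#' print(sel)
#' @export
fit_candidate_set <- function(data, response,
                              standardize = FALSE,
                              delta_top = 2,
                              nAGQ = 25L) {
  mf <- build_model_frame(data, response, standardize = standardize)
  if (length(unique(mf$male_id)) < 2L) {
    stop("fit_candidate_set: need records from at least 2 males", call. = FALSE)
  }
  family <- attr(mf, "family")
  cand <- candidate_terms()
  fits <- lapply(cand, fit_one_model, mf = mf, family = family, nAGQ = nAGQ)
  ok <- vapply(fits, `[[`, logical(1), "ok")
  if (!any(ok)) stop("fit_candidate_set: no model converged", call. = FALSE)

  tab <- data.frame(
    model = names(cand)[ok],
    k = vapply(fits[ok], `[[`, integer(1), "k"),
    loglik = vapply(fits[ok], `[[`, numeric(1), "loglik"),
    stringsAsFactors = FALSE
  )
  n <- nrow(mf)
  tab$aicc <- aicc(tab$loglik, tab$k, n)
  ord <- order(tab$aicc)
  tab <- tab[ord, , drop = FALSE]
  tab$delta <- tab$aicc - tab$aicc[1]
  tab$weight <- akaike_weights(tab$aicc)
  conv <- vapply(fits[ok], `[[`, logical(1), "converged")[ord]
  tab$converged <- conv
  tab$in_top_set <- tab$delta <= delta_top & tab$converged
  minimal <- rep(FALSE, nrow(tab))
  if (any(tab$in_top_set)) {
    cand_idx <- which(tab$in_top_set)
    best <- cand_idx[order(tab$k[cand_idx], tab$aicc[cand_idx])][1]
    minimal[best] <- TRUE
  }
  tab$best_minimal <- minimal
  rownames(tab) <- NULL

  out <- list(
    table = tab,
    fits = fits[ok][ord],
    terms = cand[ok][ord],
    response = response,
    family = family,
    n_obs = n,
    n_males = length(unique(mf$male_id)),
    delta_top = delta_top,
    standardization = attr(mf, "standardization"),
    data = data
  )
  class(out) <- "ejacdyn_selection"
  out
}

#' @export
print.ejacdyn_selection <- function(x, digits = 2, ...) {
  cat("Candidate-set AICc selection --", x$response,
      sprintf("(%s family, %d obs, %d males)\n", x$family, x$n_obs, x$n_males))
  tab <- x$table
  tab$loglik <- round(tab$loglik, digits)
  tab$aicc <- round(tab$aicc, digits)
  tab$delta <- round(tab$delta, digits)
  tab$weight <- round(tab$weight, digits)
  print(tab[, c("model", "k", "loglik", "aicc", "delta", "weight",
                "in_top_set", "best_minimal")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.ejacdyn_selection <- function(object, ...) {
  print(object, ...)
  cat("\nBest minimal model:",
      object$table$model[object$table$best_minimal], "\n")
  invisible(object)
}

#' Model-averaged standardized effect sizes over the top model set
#'
#' Refits the top model set (models within the AICc window of
#' [fit_candidate_set()]) with predictors standardized to mean 0 and SD 0.5,
#' renormalizes Akaike weights over that set, and averages coefficients two
#' ways: the full average substitutes 0 for a term absent from a model
#' (shrinking weakly supported effects), the conditional average averages
#' only over models containing the term. Unconditional standard errors
#' follow the usual model-averaging formula
#' `sum_m w_m * sqrt(se_m^2 + (b_m - b_bar)^2)`.
#'
#' @param selection An `ejacdyn_selection` object.
#' @param data The behavioral dataset used for the selection (defaults to the
#'   dataset stored in `selection`).
#' @return An object of class `ejacdyn_averaged`: a data.frame with columns
#'   `term`, `estimate` (full average), `estimate_conditional`,
#'   `unconditional_se`, plus attributes `weights` (renormalized) and
#'   `standardization` (per-predictor centers and scales).
#' @export
model_average <- function(selection, data = selection$data) {
  stopifnot(inherits(selection, "ejacdyn_selection"))
  tab <- selection$table
  top <- which(tab$in_top_set)
  if (length(top) == 0L) {
    stop("model_average: empty top model set", call. = FALSE)
  }
  mf <- build_model_frame(data, selection$response, standardize = TRUE)
  family <- attr(mf, "family")
  w <- tab$weight[top] / sum(tab$weight[top])
  refits <- lapply(selection$terms[top], fit_one_model, mf = mf,
                   family = family)
  all_terms <- unique(unlist(lapply(refits, function(f) names(f$coefficients))))
  full <- cond <- use <- setNames(numeric(length(all_terms)), all_terms)
  sem <- matrix(0, length(refits), length(all_terms),
                dimnames = list(NULL, all_terms))
  bm <- matrix(0, length(refits), length(all_terms),
               dimnames = list(NULL, all_terms))
  present <- matrix(FALSE, length(refits), length(all_terms),
                    dimnames = list(NULL, all_terms))
  for (i in seq_along(refits)) {
    b <- refits[[i]]$coefficients
    bm[i, names(b)] <- b
    sem[i, names(b)] <- refits[[i]]$se
    present[i, names(b)] <- TRUE
  }
  full <- colSums(w * bm)
  cond <- vapply(all_terms, function(tm) {
    idx <- present[, tm]
    sum(w[idx] * bm[idx, tm]) / sum(w[idx])
  }, numeric(1))
  unc_se <- vapply(all_terms, function(tm) {
    sum(w * sqrt(sem[, tm]^2 + (bm[, tm] - full[tm])^2))
  }, numeric(1))
  out <- data.frame(
    term = all_terms,
    estimate = as.numeric(full),
    estimate_conditional = as.numeric(cond),
    unconditional_se = as.numeric(unc_se),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "weights") <- w
  attr(out, "standardization") <- attr(mf, "standardization")
  class(out) <- c("ejacdyn_averaged", "data.frame")
  out
}

#' @export
print.ejacdyn_averaged <- function(x, digits = 3, ...) {
  cat("Model-averaged standardized coefficients (predictors: mean 0, SD 0.5)\n")
  y <- as.data.frame(x)
  y$estimate <- round(y$estimate, digits)
  y$estimate_conditional <- round(y$estimate_conditional, digits)
  y$unconditional_se <- round(y$unconditional_se, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ejacdyn_selection <- function(object, model = which(object$table$best_minimal), ...) {
  object$fits[[model]]$coefficients
}
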