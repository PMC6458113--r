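#' Configuration for the behavioral mating-sequence simulator
#'
#' Bundles and validates the parameters of [simulate_behavior()]. The defaults
#' emulate a sequential-mating trial design in fowl: each male is first
#' habituated (a geometric number of female exposures until he first
#' copulates), then allowed up to `max_matings_female1` consecutive mating
#' opportunities with a first female, and finally exactly one opportunity with
#' a second, sexually novel female. Sperm numbers, seminal fluid (SF) volume
#' and SF protein concentration decline log-linearly with cumulative exposure
#' (depletion) and may receive an additive boost at the novel-female mating
#' (the Coolidge pattern).
#'
#' The latent depletion trajectory at cumulative exposure `c` is
#' `t(c) = intercept_log1p + depletion_slope * c + novelty_boost * I(female 2)`
#' on the `log(1 + y)` scale; sperm numbers are `expm1` of a normal draw around
#' `t(c)`, while SF volume and protein concentration use the same trajectory
#' scaled by `sf_volume_scale` and `sf_protein_scale` respectively. Whether a
#' mating opportunity yields an ejaculate is Bernoulli with
#' `plogis(ejaculation_logit_intercept + ejaculation_logit_slope * c +
#' ejaculation_logit_novelty * I(female 2))`; a male's female-1 phase ends at
#' his first failure to ejaculate (or after `max_matings_female1`
#' opportunities), after which the single female-2 opportunity always occurs.
#'
#' @param n_males Number of males (trials). Default 19.
#' @param p_dominant Probability a male is socially dominant. Default `11/19`.
#' @param max_matings_female1 Maximum opportunities with the first female.
#'   Default 5.
#' @param intercept_log1p Trajectory anchor at cumulative exposure 0, log1p
#'   scale. Default 18.5 (sperm numbers of order 1e7--1e8 at early exposures).
#' @param depletion_slope Per-exposure change of the trajectory (log1p scale);
#'   negative under depletion. Default -0.35.
#' @param novelty_boost Additive log1p-scale shift applied only at the
#'   female-2 mating. Default 0.7.
#' @param ejaculation_logit_intercept,ejaculation_logit_slope Logistic
#'   ejaculation propensity in cumulative exposure. Defaults 2.8 and -0.5
#'   give roughly 90 opportunity rows over 19 males, the scale of the
#'   emulated trials.
#' @param ejaculation_logit_novelty Optional additive logit shift at the
#'   female-2 opportunity. Default 0.
#' @param noise_sd Normal noise SD on the log1p scale. Default 0.5.
#' @param sf_volume_scale,sf_protein_scale Positive factors coupling SF volume
#'   (microlitres) and SF protein concentration (ug/uL) to the sperm
#'   trajectory. Defaults 0.2 and 0.1.
#' @param habituation_mean_exposures Mean number of female exposures needed
#'   before the first copulation (geometric law, support 1, 2, ...).
#'   Default 2.05.
#' @param seed Integer seed; every random draw in [simulate_behavior()] flows
#'   from it.
#'
#' @return An object of class `ejacdyn_behavior_config` (a validated list).
#' @seealso [simulate_behavior()]
#' @export
behavior_sim_config <- function(n_males = 19L,
                                p_dominant = 11 / 19,
                                max_matings_female1 = 5L,
                                intercept_log1p = 18.5,
                                depletion_slope = -0.35,
                                novelty_boost = 0.7,
                                ejaculation_logit_intercept = 2.8,
                                ejaculation_logit_slope = -0.5,
                                ejaculation_logit_novelty = 0,
                                noise_sd = 0.5,
                                sf_volume_scale = 0.2,
                                sf_protein_scale = 0.1,
                                habituation_mean_exposures = 2.05,
                                seed = 1L) {
  cfg <- list(
    n_males = as.integer(n_males),
    p_dominant = p_dominant,
    max_matings_female1 = as.integer(max_matings_female1),
    intercept_log1p = intercept_log1p,
    depletion_slope = depletion_slope,
    novelty_boost = novelty_boost,
    ejaculation_logit_intercept = ejaculation_logit_intercept,
    ejaculation_logit_slope = ejaculation_logit_slope,
    ejaculation_logit_novelty = ejaculation_logit_novelty,
    noise_sd = noise_sd,
    sf_volume_scale = sf_volume_scale,
    sf_protein_scale = sf_protein_scale,
    habituation_mean_exposures = habituation_mean_exposures,
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_males) || cfg$n_males < 0L) {
    stop("invalid config: n_males must be a nonnegative integer", call. = FALSE)
  }
  if (cfg$p_dominant < 0 || cfg$p_dominant > 1) {
    stop("invalid config: p_dominant must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$max_matings_female1 < 1L) {
    stop("invalid config: max_matings_female1 must be >= 1", call. = FALSE)
  }
  if (cfg$noise_sd < 0) {
    stop("invalid config: noise_sd must be >= 0", call. = FALSE)
  }
  if (cfg$sf_volume_scale <= 0 || cfg$sf_protein_scale <= 0) {
    stop("invalid config: SF scale parameters must be positive", call. = FALSE)
  }
  if (cfg$habituation_mean_exposures < 1) {
    stop("invalid config: habituation_mean_exposures must be >= 1", call. = FALSE)
  }
  class(cfg) <- "ejacdyn_behavior_config"
  cfg
}

#' Simulate behavioral mating-sequence records with known ground truth
#'
#' Generates one record per mating opportunity per male under the trial design
#' described in [behavior_sim_config()]. The output satisfies the invariants
#' assumed by the expenditure analyses: cumulative exposure runs 1..(k+1)
#' within each male, exactly the last opportunity is with the novel second
#' female, and opportunities without an ejaculate carry zero sperm/SF values
#' but are retained (the depletion-prediction procedure needs them).
#'
#' @param config An [behavior_sim_config()] object.
#' @return A `data.frame` of class `ejacdyn_behavior` with columns `trial_id`,
#'   `male_id`, `status`, `female_order`, `cumulative_exposure`, `ejaculated`,
#'   `sperm_number`, `sf_volume_ul`, `sf_protein_ug_per_ul`, plus attributes
#'   `truth` (the generating parameters and per-male habituation exposures)
#'   and `config`.
#' @examples
#' dat <- simulate_behavior(behavior_sim_config(n_males = 5, seed = 42))
#' table(dat$female_order)
#' @export
simulate_behavior <- function(config = behavior_sim_config()) {
  stopifnot(inherits(config, "ejacdyn_behavior_config"))
  set.seed(config$seed)
  n <- config$n_males
  if (n == 0L) {
    empty <- data.frame(
      trial_id = character(), male_id = character(), status = character(),
      female_order = integer(), cumulative_exposure = integer(),
      ejaculated = integer(), sperm_number = numeric(),
      sf_volume_ul = numeric(), sf_protein_ug_per_ul = numeric(),
      stringsAsFactors = FALSE
    )
    attr(empty, "truth") <- list(params = unclass(config),
                                 habituation_exposures = integer())
    attr(empty, "config") <- config
    class(empty) <- c("ejacdyn_behavior", "data.frame")
    return(empty)
  }

  male_id <- sprintf("M%02d", seq_len(n))
  status <- ifelse(runif(n) < config$p_dominant, "dominant", "subdominant")
  # geometric number of habituation exposures, support 1, 2, ...
  p_hab <- 1 / config$habituation_mean_exposures
  habituation <- rgeom(n, p_hab) + 1L

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ce <- 0L
    ej <- integer()
    # female-1 phase: stop at first failure to ejaculate or at the cap
    repeat {
      ce <- ce + 1L
      eta <- config$ejaculation_logit_intercept +
        config$ejaculation_logit_slope * ce
      e <- rbinom(1L, 1L, plogis(eta))
      ej <- c(ej, e)
      if (e == 0L || ce >= config$max_matings_female1) break
    }
    k1 <- ce
    # single female-2 opportunity at exposure k1 + 1
    ce2 <- k1 + 1L
    eta2 <- config$ejaculation_logit_intercept +
      config$ejaculation_logit_slope * ce2 + config$ejaculation_logit_novelty
    ej <- c(ej, rbinom(1L, 1L, plogis(eta2)))
    exposure <- seq_len(ce2)
    fem <- c(rep(1L, k1), 2L)
    traj <- config$intercept_log1p + config$depletion_slope * exposure +
      config$novelty_boost * (fem == 2L)
    m <- length(exposure)
    sperm <- expm1(traj + rnorm(m, 0, config$noise_sd))
    vol <- expm1(config$sf_volume_scale * traj + rnorm(m, 0, config$noise_sd))
    prot <- expm1(config$sf_protein_scale * traj + rnorm(m, 0, config$noise_sd))
    sperm <- pmax(sperm, 0) * ej
    vol <- pmax(vol, 0) * ej
    prot <- pmax(prot, 0) * ej
    rows[[i]] <- data.frame(
      trial_id = sprintf("T%02d", i), male_id = male_id[i],
      status = status[i], female_order = fem, cumulative_exposure = exposure,
      ejaculated = ej, sperm_number = sperm, sf_volume_ul = vol,
      sf_protein_ug_per_ul = prot, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    params = unclass(config),
    status = setNames(status, male_id),
    habituation_exposures = setNames(habituation, male_id)
  )
  attr(out, "config") <- config
  class(out) <- c("ejacdyn_behavior", "data.frame")
  out
}
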