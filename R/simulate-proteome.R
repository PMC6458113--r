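#' Configuration for the cluster-structured proteome simulator
#'
#' Parameters of [simulate_proteome()], which plants four temporal abundance
#' profiles over the mating sequence M1, M2, M3, F2 (three successive matings
#' with a first female, then the single mating with a second, novel female):
#' monotone decrease (depletion), monotone increase (enrichment), and
#' novelty-specific increase/decrease confined to the F2 sample. Remaining
#' proteins are flat. Spectral counts are drawn negative-binomially around
#' compositional expectations, so every downstream stage (compositional
#' quantitation, clustering, enrichment) has a known ground truth.
#'
#' @param n_proteins Number of proteins. Default 805, the scale of a
#'   consistently identified seminal-fluid protein set.
#' @param cluster_fractions Length-4 nonnegative fractions summing to at most
#'   1, in the order decrease, increase, novelty-up, novelty-down; the
#'   remainder is flat. Default `c(0.43, 0.19, 0.21, 0.17)`, the observed
#'   decomposition of temporal profiles the simulator emulates.
#' @param profile_amplitude Peak-to-trough amplitude of the planted profiles
#'   on the natural-log scale. Default 1.
#' @param count_depth Expected spectral counts per protein per sample (so a
#'   sample's expected column total is `count_depth * n_proteins`). Default 10.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.3.
#' @param annotation_plan List of plan entries, each a list with elements
#'   `label`, `target_cluster` (one of `"decrease"`, `"increase"`,
#'   `"novelty_up"`, `"novelty_down"`, `"flat"`), `fold` (planted
#'   fold-enrichment of the label inside the target cluster relative to the
#'   background rate) and optional `prevalence` (overall label rate, default
#'   0.1). Default: an "immunity" set planted at fold 2.8 in the increasing
#'   cluster, emulating the enrichment the pipeline is meant to recover.
#' @param statuses If `TRUE`, generate 8 samples (dominant/subdominant x
#'   M1..F2, sharing temporal profiles); if `FALSE` (default) 4 pooled
#'   samples.
#' @param between_protein_sd SD of per-protein baseline log abundance
#'   (realistic abundance heterogeneity). Default 1.
#' @param seed Integer seed.
#'
#' @return An object of class `ejacdyn_proteome_config`.
#' @export
proteome_sim_config <- function(n_proteins = 805L,
                                cluster_fractions = c(0.43, 0.19, 0.21, 0.17),
                                profile_amplitude = 1,
                                count_depth = 10,
                                dispersion = 0.3,
                                annotation_plan = list(
                                  list(label = "immunity",
                                       target_cluster = "increase",
                                       fold = 2.8, prevalence = 0.1)
                                ),
                                statuses = FALSE,
                                between_protein_sd = 1,
                                seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins),
    cluster_fractions = cluster_fractions,
    profile_amplitude = profile_amplitude,
    count_depth = count_depth,
    dispersion = dispersion,
    annotation_plan = annotation_plan,
    statuses = isTRUE(statuses),
    between_protein_sd = between_protein_sd,
    seed = as.integer(seed)
  )
  if (is.na(cfg$n_proteins) || cfg$n_proteins < 1L) {
    stop("invalid config: n_proteins must be a positive integer", call. = FALSE)
  }
  if (length(cfg$cluster_fractions) != 4L || any(cfg$cluster_fractions < 0)) {
    stop("invalid config: cluster_fractions must be 4 nonnegative fractions",
         call. = FALSE)
  }
  if (sum(cfg$cluster_fractions) > 1 + 1e-12) {
    stop("invalid config: cluster_fractions sum to more than 1", call. = FALSE)
  }
  if (cfg$count_depth <= 0) {
    stop("invalid config: count_depth must be positive", call. = FALSE)
  }
  if (cfg$dispersion < 0) {
    stop("invalid config: dispersion must be >= 0", call. = FALSE)
  }
  class(cfg) <- "ejacdyn_proteome_config"
  cfg
}

# planted log-scale profile offsets over the ordered matings M1, M2, M3, F2
profile_shapes <- function(amplitude) {
  half <- amplitude / 2
  list(
    decrease    = half * c(1, 1 / 3, -1 / 3, -1),
    increase    = half * c(-1, -1 / 3, 1 / 3, 1),
    novelty_up  = c(0, 0, 0, amplitude),
    novelty_down = c(0, 0, 0, -amplitude),
    flat        = c(0, 0, 0, 0)
  )
}

#' Simulate a cluster-structured spectral-count matrix with annotations
#'
#' Draws a proteins x samples integer spectral-count matrix whose expected
#' compositional profiles over the mating sequence M1, M2, M3, F2 follow the
#' four planted temporal shapes of [proteome_sim_config()], plants annotation
#' labels at configured fold-enrichments in chosen clusters, and returns the
#' true cluster labels for recovery tests.
#'
#' @param config A [proteome_sim_config()] object.
#' @return A list of class `ejacdyn_proteome_sim` with elements `counts`
#'   (integer matrix, rownames protein ids, colnames `<status>_<mating>`),
#'   `annotations` (named list of protein-id vectors, an annotation
#'   collection), `true_clusters` (named character vector of planted classes)
#'   and `config`.
#' @examples
#' sim <- simulate_proteome(proteome_sim_config(n_proteins = 100, seed = 7))
#' table(sim$true_clusters)
#' @export
simulate_proteome <- function(config = proteome_sim_config()) {
  stopifnot(inherits(config, "ejacdyn_proteome_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  fr <- config$cluster_fractions
  n_per <- floor(fr * n)
  # distribute rounding remainder to the largest fractional parts
  rem <- fr * n - n_per
  short <- round(sum(fr) * n) - sum(n_per)
  if (short > 0) {
    idx <- order(rem, decreasing = TRUE)[seq_len(short)]
    n_per[idx] <- n_per[idx] + 1L
  }
  classes <- c("decrease", "increase", "novelty_up", "novelty_down")
  labels <- c(rep(classes, times = n_per),
              rep("flat", n - sum(n_per)))
  protein_ids <- sprintf("P%04d", seq_len(n))
  names(labels) <- protein_ids

  matings <- c("M1", "M2", "M3", "F2")
  statuses <- if (config$statuses) c("dominant", "subdominant") else "combined"
  sample_ids <- as.vector(outer(statuses, matings, function(s, m) paste(s, m, sep = "_")))
  mating_of <- rep(matings, each = length(statuses))

  shapes <- profile_shapes(config$profile_amplitude)
  base <- rnorm(n, 0, config$between_protein_sd)
  # log relative intensity per protein x sample
  offs <- t(vapply(labels, function(cl) shapes[[cl]], numeric(4)))
  colnames(offs) <- matings
  logw <- base + offs[, mating_of, drop = FALSE]
  colnames(logw) <- sample_ids
  w <- exp(logw)
  # compositional expectation: column totals fixed at count_depth * n
  mu <- sweep(w, 2, colSums(w), "/") * (config$count_depth * n)
  counts <- matrix(0L, n, length(sample_ids),
                   dimnames = list(protein_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    counts[, j] <- if (config$dispersion == 0) {
      rpois(n, mu[, j])
    } else {
      rnbinom(n, size = 1 / config$dispersion, mu = mu[, j])
    }
  }

  annotations <- list()
  for (plan in config$annotation_plan) {
    prev <- if (is.null(plan$prevalence)) 0.1 else plan$prevalence
    in_cl <- labels == plan$target_cluster
    pi_cl <- mean(in_cl)
    p_in <- plan$fold * prev
    p_out <- prev * (1 - plan$fold * pi_cl) / (1 - pi_cl)
    if (p_in > 1 || p_out < 0) {
      stop("invalid annotation plan: planted fold ", plan$fold,
           " is infeasible at prevalence ", prev, call. = FALSE)
    }
    hit <- runif(n) < ifelse(in_cl, p_in, p_out)
    annotations[[plan$label]] <- protein_ids[hit]
  }

  out <- list(counts = counts, annotations = annotations,
              true_clusters = labels, config = config)
  class(out) <- "ejacdyn_proteome_sim"
  out
}
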