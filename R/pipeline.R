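# End-to-end orchestration: run every analysis stage on supplied (or
# simulated) inputs and aggregate the results into one machine-readable
# report.

#' Pipeline configuration
#'
#' Assembles the configuration for [run_pipeline()]. With no file paths the
#' pipeline runs in demo mode on seeded synthetic data, so a full run needs
#' zero inputs. A YAML file with the same field names may be supplied
#' instead via `yaml_path` (requires the yaml package).
#'
#' @param behavior_csv Optional path to a behavioral CSV
#'   (see [validate_behavior()]).
#' @param counts_tsv Optional path to a spectral-count TSV.
#' @param detectability_tsv Optional detectability TSV.
#' @param gmt Optional GMT annotation file.
#' @param out_dir Optional output directory for stage TSVs; `NULL` writes
#'   nothing.
#' @param stages Character vector of stages to run, a subset of the default.
#' @param seed Master seed.
#' @param total Compositional total `C` for [apex_compositional()].
#' @param bootstrap_B Replicates per scale for [multiscale_bootstrap()].
#' @param fuzzy_c Number of fuzzy clusters, or `NULL` to select by minimum
#'   centroid distance.
#' @param n_perm Permutations for PCA significance.
#' @param yaml_path Optional YAML file overriding the above fields.
#' @return List of class `ejacdyn_pipeline_config`.
#' @export
pipeline_config <- function(behavior_csv = NULL, counts_tsv = NULL,
                            detectability_tsv = NULL, gmt = NULL,
                            out_dir = NULL,
                            stages = c("behavior", "coolidge", "proteome",
                                       "cluster", "fuzzy", "enrichment",
                                       "pca"),
                            seed = 1L, total = 1, bootstrap_B = 1000L,
                            fuzzy_c = NULL, n_perm = 999L,
                            yaml_path = NULL) {
  cfg <- list(behavior_csv = behavior_csv, counts_tsv = counts_tsv,
              detectability_tsv = detectability_tsv, gmt = gmt,
              out_dir = out_dir, stages = stages, seed = as.integer(seed),
              total = total, bootstrap_B = as.integer(bootstrap_B),
              fuzzy_c = fuzzy_c, n_perm = as.integer(n_perm))
  if (!is.null(yaml_path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("pipeline_config: the yaml package is required for yaml_path",
           call. = FALSE)
    }
    cfg <- modifyList(cfg, yaml::read_yaml(yaml_path))
  }
  for (p in c("behavior_csv", "counts_tsv", "detectability_tsv", "gmt")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("pipeline_config: file not found: ", cfg[[p]], call. = FALSE)
    }
  }
  class(cfg) <- "ejacdyn_pipeline_config"
  cfg
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(expr, error = function(e) {
    warning("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    structure(list(message = conditionMessage(e)), class = "ejacdyn_stage_error")
  })
  report[[name]] <- res
  report
}

#' Run the full analysis pipeline
#'
#' Executes, in order: candidate-set selection and model averaging for the
#' four expenditure responses; the Coolidge depletion-prediction test for
#' three responses; status-ratio contrasts; compositional quantitation and
#' consistency filtering; sample clustering with multiscale-bootstrap
#' support; fuzzy temporal clustering with profile classification and
#' membership comparisons; annotation enrichment; and PCA with
#' loading-abundance correlations. Stages read from the configured files or,
#' when absent, from the seeded synthetic generators. A failing stage is
#' recorded and skips only its dependents.
#'
#' @param config A [pipeline_config()] object.
#' @return List of class `ejacdyn_report` holding every stage result plus a
#'   `run_info` record (package version, seed, parameters).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "ejacdyn_pipeline_config"))
  report <- list(run_info = list(
    package_version = as.character(utils::packageVersion("ejacdyn")),
    seed = config$seed,
    stages = config$stages,
    parameters = list(total = config$total, bootstrap_B = config$bootstrap_B,
                      fuzzy_c = config$fuzzy_c, n_perm = config$n_perm)
  ))

  behavior <- NULL
  if (any(c("behavior", "coolidge") %in% config$stages)) {
    behavior <- if (is.null(config$behavior_csv)) {
      simulate_behavior(behavior_sim_config(seed = config$seed))
    } else {
      validate_behavior(config$behavior_csv)
    }
    report$behavior_summary <- list(
      n_males = length(unique(behavior$male_id)),
      n_records = nrow(behavior),
      simulated = is.null(config$behavior_csv)
    )
  }

  if ("behavior" %in% config$stages) {
    for (resp in c("ejaculation", "sperm", "volume", "protein")) {
      report <- run_stage(report, paste0("selection_", resp), {
        sel <- fit_candidate_set(behavior, resp)
        list(table = sel$table, averaged = as.data.frame(model_average(sel)))
      })
    }
  }
  if ("coolidge" %in% config$stages) {
    for (resp in c("sperm", "volume", "protein")) {
      report <- run_stage(report, paste0("coolidge_", resp), {
        co <- coolidge_analysis(behavior, resp)
        list(pairs = co$pairs, V = co$V, p_two_sided = co$p_two_sided,
             p_greater = co$p_greater, n_used = co$n_used,
             skipped = co$skipped)
      })
      report <- run_stage(report, paste0("status_ratio_", resp), {
        sr <- status_ratio_compare(behavior, resp)
        list(ratios = sr$ratios, W = sr$test$W,
             p_two_sided = sr$test$p_two_sided)
      })
    }
  }

  proteome_needed <- any(c("proteome", "cluster", "fuzzy", "enrichment",
                           "pca") %in% config$stages)
  abundance <- NULL
  annotations <- NULL
  if (proteome_needed) {
    if (is.null(config$counts_tsv)) {
      sim <- simulate_proteome(proteome_sim_config(seed = config$seed))
      counts <- sim$counts
      annotations <- sim$annotations
      report$proteome_summary <- list(simulated = TRUE,
                                      n_proteins = nrow(counts))
    } else {
      counts <- read_matrix_tsv(config$counts_tsv)
      if (!is.null(config$gmt)) annotations <- read_gmt(config$gmt)
      report$proteome_summary <- list(simulated = FALSE,
                                      n_proteins = nrow(counts))
    }
    O <- if (is.null(config$detectability_tsv)) NULL else
      read_detectability(config$detectability_tsv)
    report <- run_stage(report, "quantitation", {
      ab <- apex_compositional(counts, O, total = config$total)
      consistent <- filter_consistent(counts)
      list(abundance = ab, consistent = consistent,
           n_consistent = length(consistent),
           r2 = pairwise_r2(ab[consistent, , drop = FALSE]))
    })
    if (!inherits(report$quantitation, "ejacdyn_stage_error")) {
      abundance <- report$quantitation$abundance[
        report$quantitation$consistent, , drop = FALSE]
    }
  }

  if (!is.null(abundance)) {
    lg <- log_standardize(abundance)
    if ("cluster" %in% config$stages) {
      report <- run_stage(report, "cluster_support", {
        multiscale_bootstrap(lg, B = config$bootstrap_B,
                             seed = config$seed)
      })
    }
    assignment <- NULL
    if (any(c("fuzzy", "enrichment") %in% config$stages)) {
      report <- run_stage(report, "fuzzy", {
        Xs <- log_standardize(abundance, standardize = TRUE)
        m <- estimate_fuzzifier(nrow(Xs), ncol(Xs))
        cc <- if (is.null(config$fuzzy_c)) {
          select_cluster_number(Xs, m = m, seed = config$seed)$c
        } else {
          config$fuzzy_c
        }
        model <- fuzzy_cmeans(Xs, cc, m = m, seed = config$seed)
        asg <- classify_profiles(model)
        list(model = model, assignment = asg,
             class_fractions = attr(asg, "class_fractions"),
             membership_tests = membership_compare(asg))
      })
      if (!inherits(report$fuzzy, "ejacdyn_stage_error")) {
        assignment <- report$fuzzy$assignment
      }
    }
    if ("enrichment" %in% config$stages && !is.null(assignment) &&
        length(annotations)) {
      report <- run_stage(report, "enrichment", {
        cluster_enrichment(assignment, annotations)
      })
    }
    if ("pca" %in% config$stages) {
      report <- run_stage(report, "pca", {
        pc <- pca_decompose(lg, n_perm = config$n_perm, seed = config$seed)
        list(variance_fraction = pc$variance_fraction,
             significant = pc$significant,
             n_significant = pc$n_significant,
             correlations = loading_abundance_corr(pc, lg))
      })
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(
      jsonlite::toJSON(report_to_json(report), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null"),
      file.path(config$out_dir, "report.json"))
  }
  class(report) <- "ejacdyn_report"
  report
}

# strip heavy/opaque objects so the report serializes cleanly
report_to_json <- function(report) {
  lapply(report, function(x) {
    if (inherits(x, "ejacdyn_stage_error")) {
      return(list(error = x$message))
    }
    if (inherits(x, "ejacdyn_edge_support")) {
      return(as.data.frame(x)[, c("members", "au", "bp", "bp_raw", "v", "c")])
    }
    if (is.list(x)) {
      x <- x[!vapply(x, function(el)
        inherits(el, c("ejacdyn_fuzzy", "hclust")) || is.matrix(el) &&
          length(el) > 1e5, logical(1))]
      return(lapply(x, function(el) {
        if (is.matrix(el)) as.data.frame(el) else el
      }))
    }
    x
  })
}

#' @export
print.ejacdyn_report <- function(x, ...) {
  cat("ejacdyn pipeline report (seed", x$run_info$seed, ")\n")
  cat("stages:", paste(setdiff(names(x), "run_info"), collapse = ", "), "\n")
  invisible(x)
}
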