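# File I/O and validation for the pipeline's plain-text formats: behavioral
# CSV, spectral-count / abundance TSV, detectability TSV, GMT annotation
# sets.

behavior_columns <- c("trial_id", "male_id", "status", "female_order",
                      "cumulative_exposure", "ejaculated", "sperm_number",
                      "sf_volume_ul", "sf_protein_ug_per_ul")

#' Write / read a behavioral dataset as CSV
#'
#' @param data Behavioral dataset.
#' @param path File path.
#' @return `write_behavior` returns `path` invisibly; [read_behavior()] a
#'   data.frame (unvalidated; see [validate_behavior()]).
#' @export
write_behavior <- function(data, path) {
  utils::write.csv(as.data.frame(data)[, behavior_columns], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read and validate a behavioral mating-record CSV
#'
#' Checks the header and per-male invariants: cumulative exposures are
#' distinct consecutive integers from 1; exactly (at most) one female-2
#' record per male, at the maximal exposure; no sperm recorded without an
#' ejaculate. All violations are collected and reported together with the
#' offending males/rows.
#'
#' @param path CSV path, or a data.frame to validate in place.
#' @return The validated dataset (class `ejacdyn_behavior`).
#' @export
validate_behavior <- function(path) {
  d <- if (is.character(path)) read_behavior(path) else as.data.frame(path)
  problems <- character(0)
  missing_cols <- setdiff(behavior_columns, names(d))
  if (length(missing_cols)) {
    stop("validate_behavior: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(d$cumulative_exposure) ||
      any(d$cumulative_exposure != round(d$cumulative_exposure))) {
    problems <- c(problems, "cumulative_exposure must be integer")
  }
  if (!all(d$female_order %in% c(1L, 2L))) {
    problems <- c(problems, "female_order must be 1 or 2")
  }
  bad_sperm <- which(d$ejaculated == 0L & d$sperm_number > 0)
  if (length(bad_sperm)) {
    problems <- c(problems, paste0(
      "rows with sperm_number > 0 but ejaculated = 0: ",
      paste(bad_sperm, collapse = ", ")))
  }
  for (m in unique(d$male_id)) {
    rec <- d[d$male_id == m, , drop = FALSE]
    ce <- sort(rec$cumulative_exposure)
    if (!identical(as.integer(ce), seq_len(nrow(rec)))) {
      problems <- c(problems, paste0(
        "male ", m, ": cumulative exposures are not 1..",
        nrow(rec)))
    }
    f2 <- rec[rec$female_order == 2L, , drop = FALSE]
    if (nrow(f2) > 1L) {
      problems <- c(problems, paste0("male ", m, ": more than one female-2 row"))
    } else if (nrow(f2) == 1L &&
               f2$cumulative_exposure != max(rec$cumulative_exposure)) {
      problems <- c(problems, paste0(
        "male ", m, ": female-2 row is not at the maximal exposure"))
    }
  }
  if (length(problems)) {
    stop("validate_behavior: ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  class(d) <- c("ejacdyn_behavior", "data.frame")
  d
}

#' Write / read a proteins x samples matrix as TSV
#'
#' First column `protein_id`, remaining columns samples named
#' `<status>_<mating>`.
#'
#' @param mat Matrix with dimnames.
#' @param path File path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(protein_id = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write annotation collections in GMT format
#'
#' One set per line: set name, description, then tab-separated protein ids.
#'
#' @param path GMT file path.
#' @param sets Named list of protein-id vectors.
#' @param descriptions Optional per-set description strings.
#' @return `read_gmt` returns a named list of protein-id vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) next
    out[[parts[1]]] <- parts[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  lines <- vapply(names(sets), function(nm) {
    desc <- if (is.null(descriptions)) "" else descriptions[[nm]]
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column detectability TSV (protein_id, O)
#'
#' @param path TSV path.
#' @return Named numeric vector of detectability probabilities.
#' @export
read_detectability <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), df[[1]])
}
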