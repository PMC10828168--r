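# Delimited reader built on base R's correctly-rounding double parser, so
# that write -> read round-trips doubles bit-exactly (readr emits
# shortest-round-trip representations; vroom's fast parser can be 1 ulp off).
read_table_exact <- function(path, delim = NULL) {
  delim <- guess_delim(path, delim)
  tibble::as_tibble(utils::read.delim(path, sep = delim, check.names = FALSE,
                                      na.strings = c("", "NA"),
                                      stringsAsFactors = FALSE))
}

#' Read a beta-value matrix
#'
#' Reads a delimited text file of methylation beta values (fractions in
#' \[0, 1\]): first column CpG identifiers, header row sample identifiers.
#' The delimiter is guessed from the extension (`.csv` comma, `.tsv`/`.txt`
#' tab) unless given. Missing values may be encoded as `NA` or empty fields.
#'
#' @param path Path to the file.
#' @param delim Optional explicit delimiter overriding the extension guess.
#' @return A numeric matrix, rows = CpGs (rownames), columns = samples
#'   (colnames), validated by [validate_beta_matrix()].
#' @export
read_beta_matrix <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  df <- read_table_exact(path, delim)
  if (ncol(df) < 2L) stop_format("beta matrix needs a CpG id column plus >= 1 sample column")
  cpg_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop_format("non-numeric beta values found (malformed header or cells?)")
  rownames(vals) <- cpg_ids
  validate_beta_matrix(vals)
}

#' Validate a beta matrix
#'
#' Checks the container invariants: unique row (CpG) and column (sample)
#' names, and every non-missing value in \[0, 1\]. Violations raise a
#' validation error naming the offending CpG/sample.
#'
#' @param beta Numeric matrix with rownames (CpG ids) and colnames (sample ids).
#' @return `beta`, invisibly validated.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop_validation("beta must be a numeric matrix")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop_validation("beta must carry CpG rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stop_validation("duplicate CpG ids in beta matrix")
  if (anyDuplicated(colnames(beta))) stop_validation("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, ]
    stop_validation(sprintf(
      "beta value out of [0,1] at CpG '%s', sample '%s' (%.4g)%s",
      rownames(beta)[i[1L]], colnames(beta)[i[2L]], beta[i[1L], i[2L]],
      if (nrow(bad) > 1L) sprintf(" and %d more", nrow(bad) - 1L) else ""
    ))
  }
  beta
}

#' Write a beta matrix to delimited text
#'
#' @param beta Validated beta matrix.
#' @param path Output path; delimiter guessed from extension unless `delim` given.
#' @param delim Optional delimiter.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path, delim = NULL) {
  beta <- validate_beta_matrix(beta)
  delim <- guess_delim(path, delim)
  df <- tibble::as_tibble(beta, rownames = "cpg_id")
  readr::write_delim(df, path, delim = delim, na = "NA")
  invisible(path)
}

#' Read a sample sheet
#'
#' Delimited file with header and required columns `sample_id`, `species`,
#' `tissue`, `age_years`; optional `sex` (defaulting to `"unknown"`) and
#' `cohort` (defaulting to `"human"` for human samples, `"frog"` otherwise).
#'
#' @param path Path to the file.
#' @param delim Optional delimiter.
#' @return A tibble of sample records, validated by [validate_sample_sheet()].
#' @export
read_sample_sheet <- function(path, delim = NULL) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  validate_sample_sheet(read_table_exact(path, delim))
}

#' Validate a sample sheet
#'
#' @param samples Data frame of sample records.
#' @return A tibble with columns `sample_id`, `species`, `tissue`,
#'   `age_years`, `sex`, `cohort`; missing `sex` filled as `"unknown"`,
#'   missing `cohort` inferred from species.
#' @export
validate_sample_sheet <- function(samples) {
  samples <- tibble::as_tibble(samples)
  need <- c("sample_id", "species", "tissue", "age_years")
  miss <- setdiff(need, names(samples))
  if (length(miss)) {
    stop_validation(paste0("sample sheet is missing columns: ", toString(miss)))
  }
  if (!"sex" %in% names(samples)) samples$sex <- "unknown"
  samples$sex <- dplyr::coalesce(as.character(samples$sex), "unknown")
  bad_sex <- setdiff(unique(samples$sex), c("female", "male", "unknown"))
  if (length(bad_sex)) {
    stop_validation(paste0("invalid sex values: ", toString(bad_sex)))
  }
  if (!"cohort" %in% names(samples)) {
    samples$cohort <- ifelse(samples$species == "human", "human", "frog")
  }
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    dup <- unique(samples$sample_id[duplicated(samples$sample_id)])
    stop_validation(paste0("duplicate sample_id: ", toString(head(dup, 5L))))
  }
  if (any(!is.finite(samples$age_years) | samples$age_years < 0)) {
    bad <- samples$sample_id[!is.finite(samples$age_years) | samples$age_years < 0]
    stop_validation(paste0("negative or missing age_years for: ", toString(head(bad, 5L))))
  }
  dplyr::select(samples, "sample_id", "species", "tissue", "age_years",
                "sex", "cohort", dplyr::everything())
}

#' Write a sample sheet
#'
#' @param samples Validated sample sheet tibble.
#' @inheritParams write_beta_matrix
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path, delim = NULL) {
  samples <- validate_sample_sheet(samples)
  readr::write_delim(samples, path, delim = guess_delim(path, delim), na = "NA")
  invisible(path)
}

#' Assemble a methylation cohort
#'
#' Joins a beta matrix with its per-sample metadata. The sheet may be a
#' superset of the beta columns; beta columns are reordered (and subset) to
#' the sheet order, so the cohort invariant — beta column order equals sample
#' record order — holds by construction. A beta column with no sheet record
#' is an error.
#'
#' @param beta Beta matrix (see [read_beta_matrix()]).
#' @param samples Sample sheet (see [read_sample_sheet()]).
#' @return A `methyl_cohort`: list with elements `beta` (matrix) and
#'   `samples` (tibble), columns aligned.
#' @export
assemble_cohort <- function(beta, samples) {
  beta <- validate_beta_matrix(beta)
  samples <- validate_sample_sheet(samples)
  orphans <- setdiff(colnames(beta), samples$sample_id)
  if (length(orphans)) {
    stop_validation(paste0(
      "beta columns with no sample-sheet record: ", toString(head(orphans, 10L))
    ))
  }
  keep <- samples$sample_id[samples$sample_id %in% colnames(beta)]
  new_methyl_cohort(beta[, keep, drop = FALSE],
                    samples[match(keep, samples$sample_id), ])
}

new_methyl_cohort <- function(beta, samples) {
  stopifnot(identical(colnames(beta), samples$sample_id))
  structure(list(beta = beta, samples = samples), class = "methyl_cohort")
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat(sprintf("<methyl_cohort> %d CpGs x %d samples\n",
              nrow(x$beta), ncol(x$beta)))
  print(dplyr::count(x$samples, .data$species, .data$cohort))
  invisible(x)
}

#' Subset a cohort by sample metadata
#'
#' Filters the sample sheet with dplyr-style predicates and subsets the beta
#' columns to match.
#'
#' @param cohort A `methyl_cohort`.
#' @param ... Logical predicates on the sample sheet columns, as in
#'   [dplyr::filter()].
#' @return A `methyl_cohort` restricted to the matching samples.
#' @examples
#' # frogs only: filter_samples(cohort, cohort == "frog")
#' @export
filter_samples <- function(cohort, ...) {
  samples <- dplyr::filter(cohort$samples, ...)
  new_methyl_cohort(cohort$beta[, samples$sample_id, drop = FALSE], samples)
}

#' Handle missing beta values
#'
#' Downstream model fitting needs a complete matrix. Default policy drops any
#' CpG with a missing value; the alternative imputes each CpG's missing
#' entries with its across-sample mean.
#'
#' @param cohort A `methyl_cohort`.
#' @param method `"drop"` (default) or `"impute_mean"`.
#' @return A complete-case `methyl_cohort`.
#' @export
handle_missing <- function(cohort, method = c("drop", "impute_mean")) {
  method <- match.arg(method)
  beta <- cohort$beta
  if (!anyNA(beta)) return(cohort)
  if (method == "drop") {
    keep <- rowSums(is.na(beta)) == 0L
    new_methyl_cohort(beta[keep, , drop = FALSE], cohort$samples)
  } else {
    means <- rowMeans(beta, na.rm = TRUE)
    idx <- which(is.na(beta), arr.ind = TRUE)
    beta[idx] <- means[idx[, 1L]]
    new_methyl_cohort(beta, cohort$samples)
  }
}

#' Annotation sets on a restricted CpG background
#'
#' Enrichment is computed against an explicit background universe (e.g. the
#' CpGs that map to the frog genome), with named subsets such as PRC2 target
#' CpGs or chromatin states.
#'
#' @param background Character vector of CpG ids (the universe).
#' @param sets Named list of character vectors, each a subset of `background`.
#' @return An `annotation_sets` object.
#' @export
annotation_sets <- function(background, sets) {
  background <- unique(as.character(background))
  if (length(sets) && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    stop_validation("every annotation set must be named")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], background)
    if (length(extra)) {
      stop_validation(sprintf(
        "annotation set '%s' contains CpGs outside the background: %s",
        nm, toString(head(extra, 5L))
      ))
    }
  }
  structure(list(background = background, sets = sets),
            class = "annotation_sets")
}

#' @export
print.annotation_sets <- function(x, ...) {
  cat(sprintf("<annotation_sets> background: %d CpGs; %d sets\n",
              length(x$background), length(x$sets)))
  for (nm in names(x$sets)) cat(sprintf("  %s: %d\n", nm, length(x$sets[[nm]])))
  invisible(x)
}

#' Read annotation sets from delimited files
#'
#' @param sets_path Two-column delimited file (`set_name`, `cpg_id`).
#' @param background_path One-column file of background CpG ids (header
#'   optional column name `cpg_id`).
#' @param delim Optional delimiter for both files.
#' @return An [annotation_sets()] object.
#' @export
read_annotation_sets <- function(sets_path, background_path, delim = NULL) {
  bg <- read_table_exact(background_path, delim)
  sets_df <- read_table_exact(sets_path, delim)
  if (ncol(sets_df) < 2L) stop_format("annotation sets file needs columns set_name, cpg_id")
  sets <- split(as.character(sets_df[[2L]]), as.character(sets_df[[1L]]))
  annotation_sets(as.character(bg[[1L]]), sets)
}

#' Write annotation sets
#'
#' @param annotations An [annotation_sets()] object.
#' @param sets_path,background_path Output paths.
#' @param delim Optional delimiter.
#' @return Invisibly, a list of the two paths.
#' @export
write_annotation_sets <- function(annotations, sets_path, background_path,
                                  delim = NULL) {
  sets_df <- purrr::imap_dfr(annotations$sets, function(ids, nm) {
    tibble::tibble(set_name = nm, cpg_id = ids)
  })
  readr::write_delim(sets_df, sets_path, delim = guess_delim(sets_path, delim))
  readr::write_delim(tibble::tibble(cpg_id = annotations$background),
                     background_path,
                     delim = guess_delim(background_path, delim))
  invisible(list(sets = sets_path, background = background_path))
}
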