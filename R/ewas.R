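#' Epigenome-wide correlation screen of age
#'
#' Correlates every CpG's methylation with chronological age across the
#' cohort's samples. Per CpG with correlation `r` over `n` samples, the test
#' statistic is `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with a two-sided
#' p-value from the Student t distribution on `n - 2` degrees of freedom, and
#' a signed standard-normal equivalent `z = sign(r) * qnorm(1 - p/2)`.
#' P-values are floored at 1e-300 (so `z` stays finite when `|r|` reaches 1
#' numerically). Zero-variance CpGs are emitted with `r = NA` and are
#' excluded from downstream ranking and meta-analysis.
#'
#' Tissue is ignored within the screen by default (appropriate at small n);
#' `split_by_tissue = TRUE` instead screens each tissue separately and
#' returns one table per tissue, which callers may combine with
#' [stouffer_combine()].
#'
#' @param cohort A `methyl_cohort` (typically one species).
#' @param universe Optional CpG id vector restricting the screen (e.g. the
#'   genome-mapped subset); defaults to all cohort CpGs.
#' @param split_by_tissue Screen per tissue and return a named list of tables.
#' @return A tibble (`cpg_id`, `n`, `r`, `z`, `p`, `direction`), or a named
#'   list of such tibbles when `split_by_tissue = TRUE`.
#' @export
correlation_screen <- function(cohort, universe = NULL,
                               split_by_tissue = FALSE) {
  if (split_by_tissue) {
    tissues <- unique(cohort$samples$tissue)
    out <- lapply(tissues, function(ti) {
      correlation_screen(filter_samples(cohort, .data$tissue == ti), universe)
    })
    names(out) <- tissues
    return(out)
  }
  beta <- cohort$beta
  if (!is.null(universe)) {
    keep <- intersect(rownames(beta), universe)
    if (!length(keep)) stop_validation("universe shares no CpGs with the cohort")
    beta <- beta[keep, , drop = FALSE]
  }
  age <- cohort$samples$age_years
  if (length(age) < 4L) stop_validation("correlation screen needs >= 4 samples")
  # plain-summation Pearson (pairwise-complete): bit-reproducible run to run,
  # unlike threaded-BLAS matrix products
  ok <- !is.na(beta)
  y <- matrix(age, nrow(beta), ncol(beta), byrow = TRUE)
  n <- rowSums(ok)
  sx <- rowSums(beta, na.rm = TRUE)
  sxx <- rowSums(beta^2, na.rm = TRUE)
  sy <- rowSums(y * ok)
  syy <- rowSums(y^2 * ok)
  sxy <- rowSums(beta * y, na.rm = TRUE)
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  den <- sqrt(vx * vy)
  r <- unname(ifelse(vx <= 0 | vy <= 0, NA_real_,
                     pmin(pmax((sxy - sx * sy / n) / den, -1), 1)))
  n <- unname(n)
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- pmax(2 * pt(-abs(tstat), df = n - 2), 1e-300)
  z <- sign(r) * qnorm(p / 2, lower.tail = FALSE)
  tibble::tibble(
    cpg_id = rownames(beta),
    n = as.integer(n),
    r = r, z = z, p = ifelse(is.na(r), NA_real_, p),
    direction = dplyr::case_when(is.na(r) ~ NA_character_,
                                 r >= 0 ~ "+", TRUE ~ "-")
  )
}

#' Stouffer meta-analysis of EWAS tables
#'
#' Combines two or more per-CpG z statistics with equal weights:
#' `z_meta = sum(z_i) / sqrt(k)`, which is standard normal under the null of
#' no age correlation in any study, with `p_meta = 2 * pnorm(-|z_meta|)`.
#' Tables are combined over their CpG intersection; CpGs with an undefined
#' correlation in any table are excluded.
#'
#' @param tables A list of >= 2 EWAS tables from [correlation_screen()].
#' @return A tibble `cpg_id`, `z_meta`, `p_meta`, `k`.
#' @export
stouffer_combine <- function(tables) {
  if (!is.list(tables) || length(tables) < 2L) {
    stop_validation("stouffer_combine needs a list of >= 2 EWAS tables")
  }
  zs <- lapply(tables, function(t) {
    t <- t[!is.na(t$r), c("cpg_id", "z")]
    stats::setNames(t$z, t$cpg_id)
  })
  common <- Reduce(intersect, lapply(zs, names))
  if (!length(common)) stop_validation("EWAS tables share no CpGs")
  k <- length(zs)
  zmat <- vapply(zs, function(z) z[common], numeric(length(common)))
  z_meta <- unname(rowSums(zmat)) / sqrt(k)
  tibble::tibble(
    cpg_id = common,
    z_meta = z_meta,
    p_meta = pmax(2 * pnorm(-abs(z_meta)), 1e-300),
    k = k
  )
}

#' Significance threshold report
#'
#' Counts and lists the CpGs passing the genome-wide and suggestive p-value
#' cutoffs (defaults 1e-7 and 1e-5), split by direction of the age
#' correlation. Works on per-species tables (`z`/`p` columns) and
#' meta-analysis tables (`z_meta`/`p_meta`).
#'
#' @param rows An EWAS or meta-analysis tibble.
#' @param genomewide,suggestive P-value cutoffs, `genomewide <= suggestive`.
#' @return A tibble `level`, `cutoff`, `direction`, `n_cpgs`, `cpg_ids`
#'   (list-column).
#' @export
threshold_report <- function(rows, genomewide = 1e-7, suggestive = 1e-5) {
  if (!(genomewide > 0 && suggestive < 1 && genomewide <= suggestive)) {
    stop_config("cutoffs must satisfy 0 < genomewide <= suggestive < 1")
  }
  p <- rows[["p"]] %||% rows[["p_meta"]]
  z <- rows[["z"]] %||% rows[["z_meta"]]
  if (is.null(p) || is.null(z)) stop_validation("rows must carry p/z or p_meta/z_meta")
  ok <- !is.na(p)
  dirs <- ifelse(z >= 0, "+", "-")
  purrr::map_dfr(
    list(genomewide = genomewide, suggestive = suggestive),
    function(cut) {
      purrr::map_dfr(c("+", "-"), function(d) {
        hit <- ok & p < cut & dirs == d
        tibble::tibble(direction = d, n_cpgs = sum(hit),
                       cpg_ids = list(rows$cpg_id[hit]))
      })
    },
    .id = "level"
  ) |>
    dplyr::mutate(cutoff = ifelse(.data$level == "genomewide",
                                  genomewide, suggestive),
                  .after = "level")
}

#' Correlate two EWAS z-statistic profiles
#'
#' Pearson correlation (with its two-sided p-value) between two per-CpG z
#' vectors over their CpG intersection — e.g. a frog meta-analysis against an
#' external eutherian EWAS of age.
#'
#' @param a,b EWAS/meta tibbles (columns `cpg_id` and `z` or `z_meta`) or
#'   named numeric vectors of z statistics.
#' @return A one-row tibble `pearson_r`, `p`, `n`.
#' @export
compare_z <- function(a, b) {
  za <- as_z_vector(a)
  zb <- as_z_vector(b)
  common <- intersect(names(za), names(zb))
  if (length(common) < 3L) stop_validation("z vectors share fewer than 3 CpGs")
  x <- za[common]
  y <- zb[common]
  if (sd(x) == 0 || sd(y) == 0) {
    stop_domain("constant z vector; correlation undefined")
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(pearson_r = unname(ct$estimate), p = ct$p.value,
                 n = length(common))
}

as_z_vector <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) return(x[!is.na(x)])
  z <- x[["z"]] %||% x[["z_meta"]]
  if (is.null(z) || is.null(x$cpg_id)) {
    stop_validation("expected a named numeric vector or a table with cpg_id and z/z_meta")
  }
  keep <- !is.na(z)
  stats::setNames(z[keep], x$cpg_id[keep])
}
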