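#' Select the top-k age-related CpGs
#'
#' Ranks an EWAS (or meta-analysis) table by its z statistic — descending for
#' positively age-related CpGs, ascending for negative ones — keeping only
#' CpGs whose z has the requested sign, and returns the first `k` ids. Ties
#' break deterministically by lexicographic CpG id. CpGs with undefined
#' correlations are ineligible.
#'
#' @param rows EWAS or meta tibble (columns `cpg_id` and `z` or `z_meta`).
#' @param k Number of CpGs to select (fewer are returned if fewer are
#'   eligible).
#' @param direction `"+"` (increasing with age) or `"-"`.
#' @return Character vector of CpG ids.
#' @export
select_top_k <- function(rows, k = 500, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (k < 1) stop_config("k must be >= 1")
  z <- rows[["z"]] %||% rows[["z_meta"]]
  if (is.null(z)) stop_validation("rows must carry z or z_meta")
  eligible <- !is.na(z) & if (direction == "+") z > 0 else z < 0
  if (!any(eligible)) {
    stop_validation(sprintf("no eligible CpGs with direction '%s'", direction))
  }
  ids <- rows$cpg_id[eligible]
  zz <- z[eligible]
  ord <- order(if (direction == "+") -zz else zz, ids)
  head(ids[ord], k)
}

#' Hypergeometric overlap of a CpG list with annotation sets
#'
#' For each named set, tests over-representation of the selected CpGs in the
#' set against the restricted background: with `N` background CpGs, `K` in
#' the set, `n` selected and `k` overlapping, the one-sided upper-tail
#' p-value is `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. The
#' complementary lower-tail (depletion) p-value `P(X <= k)` is also emitted.
#' The effect size is the sample odds ratio of the 2x2 overlap table, with a
#' Haldane–Anscombe 0.5 correction applied to all cells when any cell is
#' zero.
#'
#' @param selected Character vector of CpG ids, a subset of the background.
#' @param sets An [annotation_sets()] object.
#' @param direction Optional direction label (`"+"`/`"-"`) attached to rows.
#' @return A tibble: `set_name`, `direction`, `k_overlap`, `K_set`,
#'   `n_selected`, `N_background`, `odds_ratio`, `p` (enrichment),
#'   `p_depletion`.
#' @export
hypergeom_enrich <- function(selected, sets, direction = NA_character_) {
  selected <- unique(as.character(selected))
  outside <- setdiff(selected, sets$background)
  if (length(outside)) {
    stop_validation(paste0("selected CpGs outside the background: ",
                           toString(head(outside, 10L))))
  }
  N <- length(sets$background)
  n <- length(selected)
  purrr::imap_dfr(sets$sets, function(ids, nm) {
    K <- length(ids)
    k <- length(intersect(selected, ids))
    # 2x2 cells: in-set/selected, out-of-set/selected, in-set/rest, out/rest
    a <- k; b <- n - k; c <- K - k; d <- N - K - n + k
    if (min(a, b, c, d) == 0) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    tibble::tibble(
      set_name = nm, direction = direction,
      k_overlap = k, K_set = K, n_selected = n, N_background = N,
      odds_ratio = (a * d) / (b * c),
      p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      p_depletion = phyper(k, K, N - K, n)
    )
  })
}

#' Enrichment report across EWAS sources and directions
#'
#' Runs [select_top_k()] and [hypergeom_enrich()] for every combination of
#' EWAS source (e.g. meta-analysis, each single-species screen), direction
#' (`+`/`-`), and annotation set, returning one tidy table with a signed
#' display column `signed_log10_p = -log10(p) * sign(OR > 1)` suitable for
#' heatmaps.
#'
#' @param sources Named list of EWAS/meta tibbles.
#' @param sets An [annotation_sets()] object.
#' @param k Number of top CpGs per direction (default 500).
#' @return A tibble with one row per source x direction x set.
#' @export
enrichment_report <- function(sources, sets, k = 500) {
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    stop_validation("`sources` must be a named list of EWAS tables")
  }
  if (!length(sets$sets)) {
    return(tibble::tibble(
      source = character(), set_name = character(), direction = character(),
      k_overlap = integer(), K_set = integer(), n_selected = integer(),
      N_background = integer(), odds_ratio = numeric(), p = numeric(),
      p_depletion = numeric(), signed_log10_p = numeric()
    ))
  }
  out <- purrr::imap_dfr(sources, function(rows, src) {
    purrr::map_dfr(c("+", "-"), function(d) {
      top <- select_top_k(rows, k, d)
      dplyr::mutate(hypergeom_enrich(top, sets, d), source = src,
                    .before = 1L)
    })
  })
  dplyr::mutate(out,
                signed_log10_p = -log10(.data$p) *
                  ifelse(.data$odds_ratio > 1, 1, -1))
}
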