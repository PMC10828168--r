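#' Correlation dissimilarity between samples
#'
#' Sample-to-sample dissimilarity `d(i, j) = 1 - cor(beta_i, beta_j)` across
#' CpGs (Pearson, pairwise-complete over missing betas), the distance
#' underlying the cohort QC dendrogram. Ranges over \[0, 2\]; a duplicated
#' sample has distance 0, a perfectly anti-correlated one distance 2.
#'
#' @param cohort A `methyl_cohort` with >= 2 samples and >= 3 variable CpGs.
#' @return A `dist` object over samples.
#' @export
correlation_dissimilarity <- function(cohort) {
  beta <- cohort$beta
  if (ncol(beta) < 2L) stop_validation("need >= 2 samples")
  sds <- apply(beta, 2L, sd, na.rm = TRUE)
  if (any(sds == 0 | is.na(sds))) {
    stop_validation(paste0(
      "constant beta column for sample(s): ",
      toString(head(colnames(beta)[sds == 0 | is.na(sds)], 5L))))
  }
  if (sum(apply(beta, 1L, sd, na.rm = TRUE) > 0, na.rm = TRUE) < 3L) {
    stop_validation("need >= 3 CpGs with variance")
  }
  d <- 1 - cor(beta, use = "pairwise.complete.obs")
  as.dist(d)
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Agglomerative clustering where the distance between clusters is the mean
#' pairwise dissimilarity of their members; merge heights are nondecreasing.
#'
#' @param dist A `dist` object or a symmetric dissimilarity matrix with zero
#'   diagonal.
#' @return An [stats::hclust] tree (`n - 1` merges for `n` leaves).
#' @export
average_linkage <- function(dist) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist), tol = 1e-12)) {
      stop_validation("dissimilarity matrix must be symmetric")
    }
    dist <- as.dist(dist)
  }
  if (!inherits(dist, "dist")) stop_validation("`dist` must be a dist or matrix")
  hclust(dist, method = "average")
}

#' Cut a dendrogram at a height
#'
#' Branch labels are the connected components of merges below `h`, numbered
#' 1..B in leaf (plotting) order — the convention used for dendrogram color
#' bands.
#'
#' @param tree An `hclust` tree.
#' @param h Cut height, >= 0.
#' @return A tibble `sample_id`, `branch`.
#' @export
cut_height <- function(tree, h) {
  if (h < 0) stop_config("cut height must be >= 0")
  raw <- cutree(tree, h = h)
  # relabel in leaf order
  leaf_labels <- raw[tree$order]
  map <- stats::setNames(seq_along(unique(leaf_labels)), unique(leaf_labels))
  tibble::tibble(
    sample_id = names(raw),
    branch = as.integer(map[as.character(raw)])
  )
}

#' Export a dendrogram as Newick text
#'
#' @param tree An `hclust` tree.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly if written to a file).
#' @export
dendrogram_newick <- function(tree, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop_validation("Newick export needs the 'ape' package")
  }
  txt <- ape::write.tree(ape::as.phylo(tree))
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
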