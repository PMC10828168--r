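qc_cohort <- function(beta) {
  sheet <- tibble::tibble(sample_id = colnames(beta), species = "laevis",
                          tissue = "liver",
                          age_years = seq_len(ncol(beta)))
  assemble_cohort(beta, sheet)
}

test_that("correlation dissimilarity matches hand-computed Pearson distances", {
  beta <- matrix(c(0.1, 0.4, 0.7,
                   0.2, 0.5, 0.6,
                   0.9, 0.6, 0.1), 3, 3,
                 dimnames = list(paste0("cg", 1:3), paste0("s", 1:3)))
  d <- as.matrix(correlation_dissimilarity(qc_cohort(beta)))
  # closed-form Pearson, written out independently of stats::cor
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  for (i in 1:3) for (j in 1:3) {
    expect_equal(d[i, j], 1 - pearson(beta[, i], beta[, j]), tolerance = 1e-12)
  }
  # duplicated sample -> distance 0; anti-correlated -> 2
  beta2 <- cbind(beta, s4 = beta[, "s1"], s5 = 1 - beta[, "s1"])
  d2 <- as.matrix(correlation_dissimilarity(qc_cohort(beta2)))
  expect_equal(d2["s1", "s4"], 0, tolerance = 1e-12)
  expect_equal(d2["s1", "s5"], 2, tolerance = 1e-12)

  const <- beta; const[, 2] <- 0.5
  expect_error(correlation_dissimilarity(qc_cohort(const)), "s2",
               class = "frogclock_validation_error")
})

test_that("average linkage reproduces a hand-executed UPGMA trace", {
  # two points merge at their distance
  d2 <- as.dist(matrix(c(0, 0.4, 0.4, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  t2 <- average_linkage(d2)
  expect_equal(t2$height, 0.4)

  # three mutually equidistant points: both merges at the common distance
  m3 <- matrix(1, 3, 3) - diag(3)
  dimnames(m3) <- list(letters[1:3], letters[1:3])
  t3 <- average_linkage(m3)
  expect_equal(t3$height, c(1, 1))

  # four points, hand-traced UPGMA:
  # d12=0.2 d34=0.3; then d({1,2},{3,4}) = mean(0.5,0.9,0.6,1.0) = 0.75
  m4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m4["a", "b"] <- m4["b", "a"] <- 0.2
  m4["a", "c"] <- m4["c", "a"] <- 0.5
  m4["a", "d"] <- m4["d", "a"] <- 0.9
  m4["b", "c"] <- m4["c", "b"] <- 0.6
  m4["b", "d"] <- m4["d", "b"] <- 1.0
  m4["c", "d"] <- m4["d", "c"] <- 0.3
  t4 <- average_linkage(m4)
  expect_equal(t4$height, c(0.2, 0.3, 0.75))

  asym <- m4; asym["a", "b"] <- 0.9
  expect_error(average_linkage(asym), class = "frogclock_validation_error")
})

test_that("UPGMA merge heights are nondecreasing on random dissimilarities", {
  for (s in 1:10) {
    x <- withr::with_seed(s, matrix(runif(12 * 5), 12))
    tree <- average_linkage(dist(x))
    expect_true(all(diff(tree$height) >= -1e-12))
  }
})

test_that("cutting behaves at the extremes and labels branches in leaf order", {
  x <- withr::with_seed(3, matrix(runif(8 * 4), 8))
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:8)
  tree <- average_linkage(d)
  all_own <- cut_height(tree, 0)
  expect_identical(max(all_own$branch), 8L)
  one <- cut_height(tree, max(tree$height) + 1)
  expect_identical(unique(one$branch), 1L)
  # labels run 1..B along the dendrogram leaf order
  mid <- cut_height(tree, median(tree$height))
  leaf_first <- mid$branch[match(tree$labels[tree$order], mid$sample_id)]
  expect_identical(unique(leaf_first), sort(unique(leaf_first)))
  expect_error(cut_height(tree, -1), class = "frogclock_config_error")
})

test_that("clustering is invariant to sample order up to branch relabeling", {
  gen <- small_gen()
  frogs <- gen$cohort
  tree <- average_linkage(correlation_dissimilarity(frogs))
  h <- mean(sort(tree$height, decreasing = TRUE)[1:2])
  br <- cut_height(tree, h)
  perm <- withr::with_seed(5, sample(ncol(frogs$beta)))
  shuffled <- assemble_cohort(frogs$beta[, perm], frogs$samples[perm, ])
  br2 <- cut_height(average_linkage(correlation_dissimilarity(shuffled)), h)
  joined <- dplyr::inner_join(br, br2, by = "sample_id")
  # identical partitions: branch labels map 1:1
  expect_identical(nrow(dplyr::distinct(joined, branch.x, branch.y)),
                   dplyr::n_distinct(joined$branch.x))
})

test_that("the two-species cohort splits by species at a two-branch cut", {
  frogs <- default_frogs()
  tree <- average_linkage(correlation_dissimilarity(frogs))
  h <- mean(sort(tree$height, decreasing = TRUE)[1:2])
  br <- cut_height(tree, h)
  expect_identical(max(br$branch), 2L)
  ari <- mclust::adjustedRandIndex(
    br$branch, frogs$samples$species[match(br$sample_id,
                                           frogs$samples$sample_id)])
  expect_gt(ari, 0.9)
})

test_that("dendrograms export to parseable Newick", {
  x <- withr::with_seed(4, matrix(runif(6 * 3), 6))
  d <- dist(x)
  attr(d, "Labels") <- paste0("s", 1:6)
  tree <- average_linkage(d)
  nwk <- dendrogram_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, paste0("s", 1:6))
})
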