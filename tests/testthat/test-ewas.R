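screen_cohort <- function(beta_rows, ages, species = "laevis") {
  beta <- do.call(rbind, beta_rows)
  rownames(beta) <- sprintf("cg%02d", seq_along(beta_rows))
  colnames(beta) <- sprintf("s%02d", seq_along(ages))
  sheet <- tibble::tibble(sample_id = colnames(beta), species = species,
                          tissue = "liver", age_years = ages)
  assemble_cohort(beta, sheet)
}

test_that("the correlation screen matches closed-form and cor.test oracles", {
  cohort <- screen_cohort(
    list(c(0.1, 0.2, 0.3, 0.4),   # collinear with age
         c(0.2, 0.1, 0.4, 0.3),   # r = 0.6
         c(0.5, 0.5, 0.5, 0.5)),  # zero variance
    ages = 1:4)
  tab <- correlation_screen(cohort)
  expect_equal(tab$r[1], 1)
  expect_identical(tab$direction[1], "+")
  expect_true(is.finite(tab$z[1])) # p floored so z stays finite
  expect_equal(tab$r[2], 0.6)
  ct <- cor.test(c(0.2, 0.1, 0.4, 0.3), 1:4) # independent oracle
  expect_equal(tab$p[2], ct$p.value, tolerance = 1e-12)
  expect_equal(tab$p[2], 0.4, tolerance = 0.01)
  expect_true(is.na(tab$r[3]) && is.na(tab$p[3]))
})

test_that("z and p are consistent and z increases with r at fixed n", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  tab <- correlation_screen(lae)
  ok <- !is.na(tab$r) & tab$p > 1e-290
  expect_true(all(abs(tab$p[ok] - 2 * pnorm(-abs(tab$z[ok]))) < 1e-10))
  expect_true(all(sign(tab$z[ok]) == sign(tab$r[ok]) | tab$r[ok] == 0))
  ord <- order(tab$r[ok])
  expect_true(all(diff(tab$z[ok][ord]) >= 0))
})

test_that("per-species screens match a per-CpG cor.test route", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  tab <- correlation_screen(lae)
  idx <- c(1, 50, 200)
  for (i in idx) {
    ct <- cor.test(lae$beta[tab$cpg_id[i], ], lae$samples$age_years)
    expect_equal(tab$r[i], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(tab$p[i], ct$p.value, tolerance = 1e-9)
  }
})

test_that("Stouffer combination has the stated algebra and symmetry", {
  mk <- function(z) tibble::tibble(cpg_id = c("a", "b", "c"), n = 10L,
                                   r = z / 10, z = z,
                                   p = 2 * pnorm(-abs(z)),
                                   direction = ifelse(z >= 0, "+", "-"))
  t1 <- mk(c(0, 1, 2))
  t2 <- mk(c(0, -1, 2))
  meta <- stouffer_combine(list(t1, t2))
  expect_equal(meta$z_meta[meta$cpg_id == "a"], 0)
  expect_equal(meta$z_meta[meta$cpg_id == "b"], 0) # (z, -z) cancels
  expect_equal(meta$z_meta[meta$cpg_id == "c"], 4 / sqrt(2))
  expect_equal(meta$z_meta[meta$cpg_id == "c"], 2.828427, tolerance = 1e-6)
  # symmetric under table exchange
  swapped <- stouffer_combine(list(t2, t1))
  expect_equal(swapped, meta)
  # undefined rows drop out of the intersection
  t3 <- mk(c(1, 1, 1)); t3$r[1] <- NA
  expect_setequal(stouffer_combine(list(t1, t3))$cpg_id, c("b", "c"))
  t4 <- mk(1:3); t4$cpg_id <- c("x", "y", "z")
  expect_error(stouffer_combine(list(t1, t4)),
               class = "frogclock_validation_error")
})

test_that("threshold report nests genome-wide hits inside suggestive ones", {
  rows <- tibble::tibble(cpg_id = paste0("cg", 1:4),
                         n = 30L, r = c(0.9, -0.8, 0.1, 0.2),
                         z = c(6, -5.5, 0.5, 0.7),
                         p = c(1e-9, 3e-6, 0.5, 0.5),
                         direction = c("+", "-", "+", "+"))
  rep_ <- threshold_report(rows, 1e-7, 1e-5)
  gw <- rep_[rep_$level == "genomewide", ]
  sug <- rep_[rep_$level == "suggestive", ]
  expect_equal(gw$n_cpgs[gw$direction == "+"], 1L)
  expect_equal(gw$n_cpgs[gw$direction == "-"], 0L)
  expect_equal(sug$n_cpgs[sug$direction == "+"], 1L)
  expect_equal(sug$n_cpgs[sug$direction == "-"], 1L)
  expect_identical(gw$cpg_ids[gw$direction == "+"][[1]], "cg1")

  none <- threshold_report(dplyr::mutate(rows, p = 0.5), 1e-7, 1e-5)
  expect_true(all(none$n_cpgs == 0L))
  expect_error(threshold_report(rows, 1e-4, 1e-6),
               class = "frogclock_config_error")
})

test_that("cross-study z comparison behaves like a Pearson correlation", {
  z <- withr::with_seed(7, rnorm(1000))
  names(z) <- paste0("cg", seq_along(z))
  expect_equal(compare_z(z, z)$pearson_r, 1)
  expect_equal(compare_z(z, -z)$pearson_r, -1)
  z2 <- withr::with_seed(8, rnorm(1000))
  names(z2) <- names(z)
  expect_lt(abs(compare_z(z, z2)$pearson_r), 0.1)
  const <- rep(1, 1000); names(const) <- names(z)
  expect_error(compare_z(z, const), class = "frogclock_domain_error")
  expect_error(compare_z(z[1:2], z[1:2]), class = "frogclock_validation_error")
})

test_that("per-tissue screening mode feeds Stouffer across tissues", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  by_tissue <- correlation_screen(lae, split_by_tissue = TRUE)
  expect_setequal(names(by_tissue), unique(lae$samples$tissue))
  big <- by_tissue[vapply(by_tissue, function(t) all(t$n >= 4), TRUE)]
  meta <- stouffer_combine(big)
  expect_identical(unique(meta$k), length(big))
})
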