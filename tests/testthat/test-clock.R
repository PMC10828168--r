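test_that("detectability filtering keeps CpGs by training mean beta", {
  beta <- matrix(c(0.02, 0.5, 0.97), 3, 4,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  sheet <- tibble::tibble(sample_id = paste0("s", 1:4), species = "laevis",
                          tissue = "liver", age_years = 1:4)
  cohort <- assemble_cohort(beta, sheet)
  kept <- filter_detectable(cohort, 0.05, 0.95)
  expect_identical(rownames(kept$beta), "b")
  expect_identical(filter_detectable(cohort, 0, 1)$beta, cohort$beta)
  expect_error(filter_detectable(cohort, 0.4, 0.45),
               class = "frogclock_validation_error")
  expect_error(filter_detectable(cohort, 0.9, 0.1),
               class = "frogclock_config_error")
})

test_that("a noise-free perfect CpG is recovered almost exactly in-sample", {
  cohort <- toy_cohort()
  spec <- clock_spec("toy", "laevis", "loglinear", "loo")
  model <- fit_clock(cohort, spec, seed = 1)
  expect_lt(max(abs(model$fitted$predicted - cohort$samples$age_years)), 0.01)
  # prediction on the training cohort reproduces fit-time fitted values
  again <- predict_age(model, cohort)
  expect_equal(again$predicted, model$fitted$predicted)
})

test_that("fitting is deterministic and invariant to sample order", {
  gen <- small_gen()
  frogs <- gen$cohort
  spec <- clock_spec("pan", c("laevis", "tropicalis"), "loglinear", "loo")
  m1 <- fit_clock(frogs, spec, seed = 4)
  m2 <- fit_clock(frogs, spec, seed = 4)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$intercept, m2$intercept)

  perm <- withr::with_seed(8, sample(ncol(frogs$beta)))
  shuffled <- assemble_cohort(frogs$beta[, perm], frogs$samples[perm, ])
  m3 <- fit_clock(shuffled, spec, seed = 4)
  expect_equal(m3$coefficients, m1$coefficients)
  p1 <- predict_age(m1, frogs)
  p3 <- predict_age(m3, shuffled)
  expect_equal(p3$predicted[match(p1$sample_id, p3$sample_id)], p1$predicted)
})

test_that("prediction back-transforms the linear score per species", {
  reg <- default_species_registry()
  tr <- age_transform("loglinear", reg)
  # zero-coefficient clock with intercept F(5): every laevis prediction is 5 y
  model <- structure(list(
    name = "const", transform = tr,
    intercept = transform_age(tr, 5, "laevis"),
    coefficients = tibble::tibble(cpg_id = character(), coefficient = numeric())
  ), class = "clock_model")
  cohort <- toy_cohort(n = 5)
  expect_equal(predict_age(model, cohort)$predicted, rep(5, 5),
               tolerance = 1e-12)

  # relative clocks return the score itself, species-free
  rel <- structure(list(
    name = "rel", transform = age_transform("relative", reg),
    intercept = 0.5,
    coefficients = tibble::tibble(cpg_id = character(), coefficient = numeric())
  ), class = "clock_model")
  expect_equal(unique(predict_age(rel, cohort)$predicted), 0.5)

  # missing model CpGs are reported by id
  bad <- model
  bad$coefficients <- tibble::tibble(cpg_id = "cg_missing", coefficient = 1)
  expect_error(predict_age(bad, cohort), "cg_missing",
               class = "frogclock_validation_error")
})

test_that("cross-validation yields one out-of-fold prediction per sample", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  spec <- clock_spec("laevis", "laevis", "identity", "loo")
  cv <- cross_validate(lae, spec, seed = 2)
  expect_identical(nrow(cv$predictions), ncol(lae$beta))
  expect_identical(sort(cv$predictions$sample_id), sort(lae$samples$sample_id))
  expect_identical(anyDuplicated(cv$predictions$sample_id), 0L)
  expect_true(cv$metrics$pearson_r >= -1 && cv$metrics$pearson_r <= 1)
  expect_gte(cv$metrics$median_abs_error, 0)

  # stratified k-fold covers every sample once and mixes cohorts per fold
  spec_k <- clock_spec("dual", c("laevis", "tropicalis"), "loglinear", "kfold",
                       k = 5)
  cv_k <- cross_validate(gen$cohort, spec_k, seed = 2)
  expect_identical(nrow(cv_k$predictions), ncol(gen$cohort$beta))
  expect_identical(anyDuplicated(cv_k$predictions$sample_id), 0L)
  expect_identical(sort(unique(cv_k$predictions$fold)), 1:5)
})

test_that("LOO predictions are independent of the held-out sample's label", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  spec <- clock_spec("laevis", "laevis", "identity", "loo")
  cv1 <- cross_validate(lae, spec, seed = 2)
  altered <- lae
  i <- 7L
  altered$samples$age_years[i] <- altered$samples$age_years[i] + 5
  cv2 <- cross_validate(altered, spec, seed = 2)
  id <- lae$samples$sample_id[i]
  expect_equal(cv2$predictions$predicted[cv2$predictions$sample_id == id],
               cv1$predictions$predicted[cv1$predictions$sample_id == id])
})

test_that("real signal beats a permutation null in LOO accuracy", {
  gen <- small_gen()
  lae <- filter_samples(gen$cohort, species == "laevis")
  spec <- clock_spec("laevis", "laevis", "identity", "loo")
  cv <- cross_validate(lae, spec, seed = 1)
  shuffled <- lae
  shuffled$samples$age_years <- withr::with_seed(
    13, sample(shuffled$samples$age_years))
  cv_null <- cross_validate(shuffled, spec, seed = 1)
  expect_gt(cv$metrics$pearson_r, 0.8)
  expect_lt(abs(cv_null$metrics$pearson_r), 0.5)
  expect_gt(cv$metrics$pearson_r, cv_null$metrics$pearson_r + 0.3)
})

test_that("accuracy metrics follow the Pearson R / median-error definitions", {
  obs <- c(1, 2, 3, 5, 8)
  expect_equal(evaluate_clock(obs, obs),
               tibble::tibble(pearson_r = 1, median_abs_error = 0, n = 5L))
  shifted <- evaluate_clock(obs + 2, obs)
  expect_equal(shifted$pearson_r, 1)
  expect_equal(shifted$median_abs_error, 2)
  rev3 <- evaluate_clock(c(1, 2, 3), c(3, 2, 1))
  expect_equal(rev3$pearson_r, -1)
  expect_equal(rev3$median_abs_error, 2)
  expect_error(evaluate_clock(1:3, c(2, 2, 2)), class = "frogclock_domain_error")
  expect_error(evaluate_clock(1:3, 1:4), class = "frogclock_validation_error")
})

test_that("a serialized clock round-trips through its text format", {
  model <- fit_clock(toy_cohort(), clock_spec("toy", "laevis", "loglinear"),
                     seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clock(model, path)
  back <- read_clock(path)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$intercept, model$intercept)
  expect_equal(back$transform$kind, model$transform$kind)
  expect_equal(back$transform$params, model$transform$params)
  # the deserialized clock predicts identically
  expect_equal(predict_age(back, toy_cohort())$predicted,
               predict_age(model, toy_cohort())$predicted)
})

test_that("tidy and glance expose coefficients and metadata", {
  model <- fit_clock(toy_cohort(), clock_spec("toy", "laevis", "loglinear"),
                     seed = 3)
  td <- tidy(model)
  expect_identical(td$term[1], "(Intercept)")
  expect_identical(nrow(td), nrow(model$coefficients) + 1L)
  gl <- glance(model)
  expect_identical(gl$n_train, 16L)
  expect_identical(gl$name, "toy")
})
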