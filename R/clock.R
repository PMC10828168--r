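#' Clock specification
#'
#' A clock is defined by which samples it is trained on (species, cohorts,
#' an optional upper age bound), the response transform, the outer
#' cross-validation scheme, and the elastic-net settings. [clock_specs()]
#' returns the seven canonical clocks:
#'
#' | name            | samples                  | transform   | outer CV |
#' |-----------------|--------------------------|-------------|----------|
#' | `pan`           | both frog species        | log-linear  | LOO      |
#' | `relative_pan`  | both frog species        | relative    | LOO      |
#' | `young`         | frogs, age < 2 y         | log-linear  | LOO      |
#' | `laevis`        | *X. laevis* only         | identity    | LOO      |
#' | `tropicalis`    | *X. tropicalis* only     | identity    | LOO      |
#' | `dual_chrono`   | frogs + human            | log-linear  | 10-fold  |
#' | `dual_relative` | frogs + human            | relative    | 10-fold  |
#'
#' All use elastic net with mixing `alpha = 0.5` and the penalty chosen by an
#' inner 10-fold cross-validation minimizing mean squared error on the
#' transformed scale. CpGs are pre-filtered to those detectable in the
#' training set (mean beta within `detect_lo`..`detect_hi`).
#'
#' @param name Clock name (free-form for custom clocks).
#' @param species Character vector of species the clock is trained on.
#' @param transform_kind `"identity"`, `"loglinear"`, or `"relative"`.
#' @param cv `"loo"` or `"kfold"`.
#' @param max_age Upper age bound in years (exclusive); `Inf` for none.
#' @param k Number of outer folds when `cv = "kfold"`.
#' @param alpha Elastic-net mixing parameter.
#' @param inner_folds Folds of the penalty-selection cross-validation.
#' @param detect_lo,detect_hi Detectability bounds on training mean beta.
#' @return A `clock_spec` object.
#' @export
clock_spec <- function(name, species,
                       transform_kind = c("loglinear", "identity", "relative"),
                       cv = c("loo", "kfold"),
                       max_age = Inf, k = 10L, alpha = 0.5,
                       inner_folds = 10L,
                       detect_lo = 0.05, detect_hi = 0.95) {
  transform_kind <- match.arg(transform_kind)
  cv <- match.arg(cv)
  if (!(detect_lo >= 0 && detect_lo < detect_hi && detect_hi <= 1)) {
    stop_config("detectability bounds need 0 <= lo < hi <= 1")
  }
  structure(
    list(name = name, species = species, transform_kind = transform_kind,
         cv = cv, max_age = max_age, k = as.integer(k), alpha = alpha,
         inner_folds = as.integer(inner_folds),
         detect_lo = detect_lo, detect_hi = detect_hi),
    class = "clock_spec"
  )
}

#' @rdname clock_spec
#' @param frog_species Species labels of the two frog cohorts.
#' @param human_species Species label of the human cohort.
#' @return For `clock_specs()`: a named list of the seven `clock_spec`s.
#' @export
clock_specs <- function(frog_species = c("laevis", "tropicalis"),
                        human_species = "human") {
  all_sp <- c(frog_species, human_species)
  list(
    pan = clock_spec("pan", frog_species, "loglinear", "loo"),
    relative_pan = clock_spec("relative_pan", frog_species, "relative", "loo"),
    young = clock_spec("young", frog_species, "loglinear", "loo", max_age = 2),
    laevis = clock_spec("laevis", frog_species[1], "identity", "loo"),
    tropicalis = clock_spec("tropicalis", frog_species[2], "identity", "loo"),
    dual_chrono = clock_spec("dual_chrono", all_sp, "loglinear", "kfold"),
    dual_relative = clock_spec("dual_relative", all_sp, "relative", "kfold")
  )
}

#' Filter CpGs to the detectable range
#'
#' Retains CpGs whose mean beta across the cohort's samples lies within
#' `[lo, hi]`; CpGs stuck near 0 or 1 carry little usable signal for
#' penalized regression. Row order is preserved.
#'
#' @param cohort A `methyl_cohort`.
#' @param lo,hi Bounds on the mean beta, `0 <= lo < hi <= 1`.
#' @return The filtered `methyl_cohort`.
#' @export
filter_detectable <- function(cohort, lo = 0.05, hi = 0.95) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    stop_config("detectability bounds need 0 <= lo < hi <= 1")
  }
  m <- rowMeans(cohort$beta, na.rm = TRUE)
  keep <- m >= lo & m <= hi
  if (!any(keep)) {
    stop_validation(sprintf(
      "no CpG has mean beta in [%.3g, %.3g]; widen the detectability bounds",
      lo, hi))
  }
  new_methyl_cohort(cohort$beta[keep, , drop = FALSE], cohort$samples)
}

# samples a clock spec is eligible to train on
eligible_samples <- function(cohort, spec) {
  filter_samples(cohort,
                 .data$species %in% spec$species,
                 .data$age_years < spec$max_age)
}

# deterministic inner-CV fold ids, keyed to sorted sample ids so the
# assignment is invariant to sample order in the cohort
inner_foldid <- function(ids, folds, seed) {
  perm <- withr::with_seed(seed, sample(rep_len(seq_len(folds), length(ids))))
  perm[match(ids, sort(ids))]
}

#' Fit an elastic-net methylation clock
#'
#' Fits a sparse linear model of the (transformed) age on CpG beta values by
#' elastic-net regression (`glmnet`, mixing `alpha`), with the penalty chosen
#' automatically by an inner k-fold cross-validation minimizing mean squared
#' error on the transformed scale. The cohort is restricted to the spec's
#' eligible samples, CpGs with missing values are dropped, and CpGs are
#' filtered to the detectable mean-beta range before fitting. Coefficients
#' are reported on the raw beta scale, so the fitted clock is a single linear
#' formula on betas followed by the inverse age transform.
#'
#' @param cohort A `methyl_cohort`.
#' @param spec A [clock_spec()].
#' @param registry Species registry for the age transform.
#' @param seed Integer seed controlling the inner fold assignment (the fit is
#'   deterministic given the seed).
#' @return A `clock_model`: coefficients (`tidy()` them), intercept, the
#'   serialized [age_transform()], and training metadata (`glance()`).
#' @export
fit_clock <- function(cohort, spec, registry = default_species_registry(),
                      seed = 1L) {
  train <- prepare_training(cohort, spec, registry)
  if (nrow(train$samples) < max(10L, spec$inner_folds)) {
    stop_validation(sprintf(
      "clock '%s': %d eligible samples; need at least %d",
      spec$name, nrow(train$samples), max(10L, spec$inner_folds)))
  }
  x <- t(train$beta)
  y <- transform_age(train$transform, train$samples$age_years,
                     train$samples$species)
  foldid <- inner_foldid(train$samples$sample_id, spec$inner_folds, seed)
  # glmnet switches to ungrouped CV error estimates below 3 obs/fold anyway;
  # request it explicitly to keep small-cohort fits quiet and deterministic
  grouped <- nrow(x) >= 3L * spec$inner_folds
  fit <- glmnet::cv.glmnet(x, y, alpha = spec$alpha, foldid = foldid,
                           standardize = TRUE, grouped = grouped)
  # if the CV optimum sits at the end of the automatically generated path
  # (near-noiseless responses), extend the path toward weaker penalties so
  # the selected penalty is an interior optimum, not a path-truncation artifact
  tries <- 0L
  while (fit$lambda.min <= min(fit$lambda) && tries < 3L) {
    lam <- exp(seq(log(max(fit$lambda)), log(min(fit$lambda) * 1e-3),
                   length.out = 100))
    fit <- glmnet::cv.glmnet(x, y, alpha = spec$alpha, foldid = foldid,
                             standardize = TRUE, grouped = grouped,
                             lambda = lam)
    tries <- tries + 1L
  }
  b <- as.matrix(coef(fit, s = "lambda.min"))
  nz <- which(b[-1L, 1L] != 0)
  model <- structure(
    list(
      name = spec$name,
      transform = train$transform,
      intercept = unname(b[1L, 1L]),
      coefficients = tibble::tibble(
        cpg_id = rownames(b)[-1L][nz],
        coefficient = unname(b[-1L, 1L][nz])
      ),
      lambda = fit$lambda.min,
      alpha = spec$alpha,
      n_train = nrow(x),
      n_cpgs_in = ncol(x),
      species = sort(unique(train$samples$species)),
      seed = as.integer(seed)
    ),
    class = "clock_model"
  )
  model$fitted <- predict_age(model, new_methyl_cohort(train$beta, train$samples))
  model
}

# shared filtering/transform setup for fit and CV
prepare_training <- function(cohort, spec, registry) {
  sub <- eligible_samples(cohort, spec)
  missing_sp <- setdiff(unique(sub$samples$species), registry$species)
  if (length(missing_sp)) {
    stop_validation(paste0("species not in registry: ", toString(missing_sp)))
  }
  sub <- handle_missing(sub, "drop")
  sub <- filter_detectable(sub, spec$detect_lo, spec$detect_hi)
  # canonical sample order: the fit is exactly invariant to how the cohort
  # columns were arranged (summation order and penalty selection included)
  ord <- order(sub$samples$sample_id)
  list(beta = sub$beta[, ord, drop = FALSE], samples = sub$samples[ord, ],
       transform = age_transform(spec$transform_kind, registry))
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model '%s'> %d/%d CpGs selected, n_train = %d, transform = %s\n",
              x$name, nrow(x$coefficients), x$n_cpgs_in, x$n_train,
              x$transform$kind))
  invisible(x)
}

#' @rdname fit_clock
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return `tidy()`: tibble of `term` (intercept + CpG ids) and `estimate`.
#' @export
tidy.clock_model <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "(Intercept)", estimate = x$intercept),
    tibble::tibble(term = x$coefficients$cpg_id,
                   estimate = x$coefficients$coefficient)
  )
}

#' @rdname fit_clock
#' @return `glance()`: one-row tibble of fit metadata.
#' @export
glance.clock_model <- function(x, ...) {
  tibble::tibble(
    name = x$name, transform = x$transform$kind,
    n_train = x$n_train, n_cpgs_in = x$n_cpgs_in,
    n_selected = nrow(x$coefficients),
    lambda = x$lambda, alpha = x$alpha, seed = x$seed
  )
}

#' Predict ages with a fitted clock
#'
#' Computes the linear score `intercept + sum(coef * beta)` for every sample
#' and back-transforms it with the clock's age transform using each sample's
#' species parameters. Relative clocks return lifespan fractions, which are
#' species-free; chronological clocks return years. Predictions are reported
#' raw (not clipped to the species age range).
#'
#' @param model A `clock_model`.
#' @param cohort A `methyl_cohort` containing every model CpG.
#' @return A tibble `sample_id`, `species`, `age_years`, `predicted`.
#' @export
predict_age <- function(model, cohort) {
  missing <- setdiff(model$coefficients$cpg_id, rownames(cohort$beta))
  if (length(missing)) {
    stop_validation(paste0("cohort lacks model CpGs: ",
                           toString(head(missing, 10L))))
  }
  score <- as.numeric(
    model$intercept +
      crossprod(cohort$beta[model$coefficients$cpg_id, , drop = FALSE],
                model$coefficients$coefficient)
  )
  tibble::tibble(
    sample_id = cohort$samples$sample_id,
    species = cohort$samples$species,
    age_years = cohort$samples$age_years,
    predicted = untransform_age(model$transform, score,
                                cohort$samples$species)
  )
}

#' Cross-validate a methylation clock
#'
#' Out-of-fold evaluation of a [clock_spec()]: leave-one-out (each sample
#' predicted by a clock trained on all others) or seeded 10-fold with folds
#' stratified by cohort so every fold mixes human and frog samples. Each fold
#' repeats the full training pipeline — detectability filtering and inner
#' penalty selection — on its training samples only, so predictions are
#' leak-free. Accuracy is summarized as the Pearson correlation and the
#' *median* absolute error between out-of-fold predictions and truth, in
#' years for chronological clocks and lifespan fractions for relative clocks.
#'
#' @inheritParams fit_clock
#' @return A `clock_cv` object; `tidy()` gives per-sample out-of-fold
#'   predictions, `glance()` the metrics.
#' @export
cross_validate <- function(cohort, spec, registry = default_species_registry(),
                           seed = 1L) {
  eligible <- eligible_samples(cohort, spec)
  n <- nrow(eligible$samples)
  if (n < max(10L, spec$inner_folds) + 1L) {
    stop_validation(sprintf("clock '%s': too few samples (%d) to cross-validate",
                            spec$name, n))
  }
  fold <- if (spec$cv == "loo") {
    seq_len(n)
  } else {
    stratified_folds(eligible$samples$cohort, eligible$samples$sample_id,
                     spec$k, seed)
  }
  preds <- purrr::map_dfr(sort(unique(fold)), function(f) {
    tr_idx <- which(fold != f)
    te_idx <- which(fold == f)
    train <- new_methyl_cohort(eligible$beta[, tr_idx, drop = FALSE],
                               eligible$samples[tr_idx, ])
    test <- new_methyl_cohort(eligible$beta[, te_idx, drop = FALSE],
                              eligible$samples[te_idx, ])
    model <- fit_clock(train, spec, registry, seed)
    dplyr::mutate(predict_age(model, test), fold = f)
  })
  preds <- preds[match(eligible$samples$sample_id, preds$sample_id), ]
  preds <- dplyr::left_join(
    preds,
    dplyr::select(eligible$samples, "sample_id", "tissue", "cohort"),
    by = "sample_id"
  )
  tr <- age_transform(spec$transform_kind, registry)
  preds$observed <- observed_on_report_scale(tr, preds$age_years, preds$species)
  metrics <- evaluate_clock(preds$predicted, preds$observed)
  structure(
    list(name = spec$name, transform_kind = spec$transform_kind,
         cv = spec$cv, seed = as.integer(seed),
         predictions = preds, metrics = metrics),
    class = "clock_cv"
  )
}

# seeded fold assignment stratified by a grouping label, keyed to sorted
# sample ids within each stratum for sample-order invariance
stratified_folds <- function(group, ids, k, seed) {
  fold <- integer(length(group))
  withr::with_seed(seed, {
    for (g in sort(unique(group))) {
      idx <- which(group == g)
      perm <- sample(rep_len(seq_len(k), length(idx)))
      fold[idx] <- perm[match(ids[idx], sort(ids[idx]))]
    }
  })
  fold
}

#' @export
print.clock_cv <- function(x, ...) {
  cat(sprintf("<clock_cv '%s'> %s, %d out-of-fold predictions\n",
              x$name, x$cv, nrow(x$predictions)))
  print(x$metrics)
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `clock_cv`.
#' @param ... Unused.
#' @export
tidy.clock_cv <- function(x, ...) x$predictions

#' @rdname cross_validate
#' @export
glance.clock_cv <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(name = x$name, cv = x$cv), x$metrics)
}

#' Clock accuracy metrics
#'
#' Pearson correlation between predicted and observed age, and the median of
#' the absolute prediction errors (the robust "MAE" used for epigenetic
#' clocks, in the units of the response: years, or lifespan fractions for
#' relative clocks).
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3).
#' @return A one-row tibble: `pearson_r`, `median_abs_error`, `n`.
#' @export
evaluate_clock <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 3L) {
    stop_validation("predicted and observed must have equal length >= 3")
  }
  if (sd(observed) == 0) {
    stop_domain("observed ages are constant; correlation undefined")
  }
  tibble::tibble(
    pearson_r = cor(predicted, observed),
    median_abs_error = median(abs(predicted - observed)),
    n = length(observed)
  )
}

#' Serialize / deserialize a fitted clock
#'
#' A clock is written as a self-describing two-part delimited text file: a
#' `#`-prefixed header block (name, transform kind and per-species
#' parameters, intercept, training metadata) followed by the CpG coefficient
#' table, so a saved clock can be applied to new data without the training
#' cohort.
#'
#' @param model A `clock_model`.
#' @param path Output path (tab-delimited).
#' @return `write_clock()`: `path`, invisibly. `read_clock()`: the
#'   `clock_model`.
#' @export
write_clock <- function(model, path) {
  p <- model$transform$params
  header <- c(
    sprintf("# name\t%s", model$name),
    sprintf("# transform\t%s", model$transform$kind),
    sprintf("# intercept\t%.17g", model$intercept),
    sprintf("# lambda\t%.17g", model$lambda),
    sprintf("# alpha\t%.17g", model$alpha),
    sprintf("# n_train\t%d", model$n_train),
    sprintf("# n_cpgs_in\t%d", model$n_cpgs_in),
    sprintf("# seed\t%d", model$seed),
    sprintf("# species\t%s\t%.17g\t%.17g\t%.17g",
            p$species, p$maturity_years, p$offset_years, p$max_lifespan_years)
  )
  writeLines(c(header, "cpg_id\tcoefficient",
               sprintf("%s\t%.17g", model$coefficients$cpg_id,
                       model$coefficients$coefficient)),
             path)
  invisible(path)
}

#' @rdname write_clock
#' @export
read_clock <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  body <- lines[!startsWith(lines, "# ")]
  fields <- strsplit(sub("^# ", "", hdr), "\t", fixed = TRUE)
  keyed <- split(fields, vapply(fields, `[[`, "", 1L))
  get1 <- function(key) keyed[[key]][[1L]][2L]
  sp_rows <- keyed[["species"]] %||% list()
  params <- purrr::map_dfr(sp_rows, function(f) {
    tibble::tibble(species = f[2L],
                   maturity_years = as.numeric(f[3L]),
                   offset_years = as.numeric(f[4L]),
                   max_lifespan_years = as.numeric(f[5L]))
  })
  tab <- readr::read_tsv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE)
  structure(
    list(
      name = get1("name"),
      transform = structure(list(kind = get1("transform"), params = params),
                            class = "age_transform"),
      intercept = as.numeric(get1("intercept")),
      coefficients = tibble::tibble(cpg_id = as.character(tab$cpg_id),
                                    coefficient = tab$coefficient),
      lambda = as.numeric(get1("lambda")),
      alpha = as.numeric(get1("alpha")),
      n_train = as.integer(get1("n_train")),
      n_cpgs_in = as.integer(get1("n_cpgs_in")),
      species = params$species,
      seed = as.integer(get1("seed"))
    ),
    class = "clock_model"
  )
}
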