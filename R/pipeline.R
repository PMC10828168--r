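#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> QC clustering -> clock fitting and
#' cross-validation -> EWAS of age with Stouffer meta-analysis -> annotation
#' enrichment, writing each stage's tables plus a JSON manifest (seeds,
#' configuration echo, per-stage row counts) to the output directory.
#' Identical configuration and seed give byte-identical outputs.
#'
#' The configuration is a named list (or path to a YAML file) with fields:
#' * `simulate`: arguments for [default_study_plan()] (`n_human`, `n_cpgs`,
#'   ...), or `NULL` to load data from `beta`, `sheet`, and optionally
#'   `annotation_sets` + `annotation_background` paths;
#' * `stages`: subset of `c("simulate", "qc", "clocks", "ewas", "enrich")`
#'   (default all that are applicable);
#' * `clocks`: clock names among the seven canonical specs (default all);
#' * `seed` (default 1), `thresholds` (`genomewide` 1e-7, `suggestive` 1e-5),
#'   `top_k` (500), `detectability` (`lo` 0.05, `hi` 0.95), `cut_height`
#'   (0.29).
#'
#' @param config Named list or path to a YAML config file.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_config(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_config("`config` must be a list or a YAML path")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  seed <- as.integer(config$seed %||% 1L)
  thr <- config$thresholds %||% list()
  genomewide <- thr$genomewide %||% 1e-7
  suggestive <- thr$suggestive %||% 1e-5
  top_k <- config$top_k %||% 500
  cut_h <- config$cut_height %||% 0.29
  registry <- default_species_registry()
  state <- new.env(parent = emptyenv())
  state$counts <- list()
  manifest <- list(package = "frogclock",
                   version = as.character(utils::packageVersion("frogclock")),
                   seed = seed, config = config, stages = list())

  simulate_cfg <- config$simulate
  stages <- config$stages %||%
    c(if (!is.null(simulate_cfg)) "simulate", "qc", "clocks", "ewas", "enrich")

  # --- inputs: simulate or load ---
  annotations <- NULL
  if (!is.null(simulate_cfg)) {
    sim <- do.call(default_study_plan, simulate_cfg[setdiff(names(simulate_cfg), "")])
    gen <- generate_cohort(sim, seed)
    cohort <- gen$cohort
    annotations <- gen$annotations
    if ("simulate" %in% stages) {
      write_beta_matrix(cohort$beta, file.path(out_dir, "beta_matrix.csv"))
      write_sample_sheet(cohort$samples, file.path(out_dir, "sample_sheet.csv"))
      write_annotation_sets(annotations,
                            file.path(out_dir, "annotation_sets.csv"),
                            file.path(out_dir, "annotation_background.csv"))
      readr::write_csv(gen$truth$cpgs, file.path(out_dir, "truth_cpgs.csv"))
      state$counts$simulate <- list(n_cpgs = nrow(cohort$beta),
                              n_samples = ncol(cohort$beta),
                              clip_rate = gen$truth$clip_rate)
    }
  } else {
    if (is.null(config$beta) || is.null(config$sheet)) {
      stop_config("config needs either `simulate` or `beta` + `sheet` paths")
    }
    for (p in c(config$beta, config$sheet, config$annotation_sets,
                config$annotation_background)) {
      if (!is.null(p) && !file.exists(p)) {
        stop_config(paste0("input path does not exist: ", p))
      }
    }
    cohort <- assemble_cohort(read_beta_matrix(config$beta),
                              read_sample_sheet(config$sheet))
    if (!is.null(config$annotation_sets)) {
      annotations <- read_annotation_sets(config$annotation_sets,
                                          config$annotation_background)
    }
  }

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", stage,
                    conditionMessage(e)),
            class = "frogclock_stage_error", parent = e)
    })
  }

  # --- QC clustering ---
  if ("qc" %in% stages) {
    run_stage("qc", {
      tree <- average_linkage(correlation_dissimilarity(cohort))
      merges <- tibble::tibble(step = seq_along(tree$height),
                               left = tree$merge[, 1L],
                               right = tree$merge[, 2L],
                               height = tree$height)
      branches <- cut_height(tree, cut_h)
      readr::write_csv(merges, file.path(out_dir, "qc_merges.csv"))
      readr::write_csv(branches, file.path(out_dir, "qc_branches.csv"))
      state$counts$qc <- list(n_merges = nrow(merges),
                         n_branches = max(branches$branch))
    })
  }

  # --- clocks ---
  if ("clocks" %in% stages) {
    run_stage("clocks", {
      specs <- clock_specs()
      wanted <- config$clocks %||% names(specs)
      unknown <- setdiff(wanted, names(specs))
      if (length(unknown)) stop_config(paste0("unknown clocks: ", toString(unknown)))
      cv_list <- lapply(specs[wanted], function(sp) {
        cv <- cross_validate(cohort, sp, registry, seed)
        model <- fit_clock(cohort, sp, registry, seed)
        write_clock(model, file.path(out_dir, paste0("clock_", sp$name, ".tsv")))
        cv
      })
      preds <- purrr::map_dfr(cv_list, function(cv) {
        dplyr::mutate(tidy(cv), clock = cv$name, .before = 1L)
      })
      metrics <- purrr::map_dfr(cv_list, glance)
      readr::write_csv(preds, file.path(out_dir, "cv_predictions.csv"))
      readr::write_csv(metrics, file.path(out_dir, "cv_metrics.csv"))
      state$counts$clocks <- list(n_clocks = length(cv_list),
                             n_predictions = nrow(preds))
    })
  }

  # --- EWAS ---
  if ("ewas" %in% stages || "enrich" %in% stages) {
    run_stage("ewas", {
      frog_species <- unique(cohort$samples$species[cohort$samples$cohort == "frog"])
      screens <- lapply(frog_species, function(sp) {
        correlation_screen(filter_samples(cohort, .data$species == sp))
      })
      names(screens) <- frog_species
      meta <- stouffer_combine(screens)
      state$ewas_sources <- c(list(meta = meta), screens)
      if ("ewas" %in% stages) {
        for (sp in frog_species) {
          readr::write_csv(screens[[sp]],
                           file.path(out_dir, paste0("ewas_", sp, ".csv")))
        }
        readr::write_csv(meta, file.path(out_dir, "ewas_meta.csv"))
        thresholds <- purrr::imap_dfr(state$ewas_sources, function(tab, nm) {
          dplyr::mutate(
            dplyr::select(threshold_report(tab, genomewide, suggestive),
                          -"cpg_ids"),
            source = nm, .before = 1L)
        })
        readr::write_csv(thresholds, file.path(out_dir, "ewas_thresholds.csv"))
        state$counts$ewas <- list(n_sources = length(state$ewas_sources),
                             n_cpgs = nrow(meta))
      }
    })
  }

  # --- enrichment ---
  if ("enrich" %in% stages) {
    run_stage("enrich", {
      if (is.null(annotations)) {
        stop_config("enrichment stage requires annotation sets")
      }
      enr <- enrichment_report(state$ewas_sources, annotations, top_k)
      readr::write_csv(enr, file.path(out_dir, "enrichment.csv"))
      state$counts$enrich <- list(n_rows = nrow(enr))
    })
  }

  manifest$stages <- state$counts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
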