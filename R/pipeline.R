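#' Configuration for a full verification run
#'
#' @param seed Master integer seed; every stage derives its streams from
#'   it.
#' @param sizes Cohort sizes for the regression dataset.
#' @param replicates Cohorts per size.
#' @param methods Surrogate methods to tune and compare.
#' @param test_fraction Held-out fraction for evaluation.
#' @param folds CV folds for grid search.
#' @param grids Optional named list of tuning-grid overrides.
#' @param out_dir Directory for the stage artifacts.
#' @param demographics_path Optional path to a demographics YAML;
#'   defaults to the bundled tables.
#' @return An object of class `deid_config`.
#' @export
pipeline_config <- function(seed = 42L,
                            sizes = c(100L, 500L, 1000L, 5000L),
                            replicates = 1L,
                            methods = surrogate_methods(),
                            test_fraction = 0.2, folds = 5L,
                            grids = list(),
                            out_dir = tempfile("deidverify-run-"),
                            demographics_path = NULL) {
  if (length(seed) != 1L || is.na(suppressWarnings(as.integer(seed)))) {
    stop("seed must be a single integer", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), sizes = as.integer(sizes),
                 replicates = as.integer(replicates), methods = methods,
                 test_fraction = test_fraction, folds = as.integer(folds),
                 grids = grids, out_dir = out_dir,
                 demographics_path = demographics_path),
            class = "deid_config")
}

stage_wrap <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full verification pipeline
#'
#' Executes all stages in order — load demographics, generate an example
#' cohort, mask and score it, build the regression dataset, tune and
#' compare the surrogate models, and explain the best boosted surrogate
#' with TreeSHAP — writing one CSV artifact per stage plus a JSON run
#' manifest (seed, sizes, artifact MD5 hashes) to `config$out_dir`.
#'
#' SHAP attributions are computed on the held-out test rows for the
#' best-by-RMSE boosted model (the lowest-RMSE xgboost-backend method).
#'
#' @param config A `deid_config` from [pipeline_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "deid_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(config$out_dir, f)

  spec <- stage_wrap("demographics", {
    if (is.null(config$demographics_path)) default_demographics()
    else load_demographics(config$demographics_path)
  })

  cohort <- stage_wrap("generate", {
    ch <- generate_cohort(max(config$sizes), spec,
                          seed = derive_seed(config$seed, 0L))
    write_cohort(ch, path("cohort.csv"))
    ch
  })

  example_policy <- masking_policy(name_level = 1L, age_level = 1L,
                                   phone_level = "partial",
                                   illness_mask = TRUE)
  stage_wrap("mask", {
    utils::write.csv(apply_policy(cohort, example_policy),
                     path("masked_example.csv"), row.names = FALSE)
  })

  stage_wrap("score", {
    sc <- score_policy(cohort, example_policy)
    utils::write.csv(
      data.frame(usability = sc$usability,
                 confidentiality_pct = sc$confidentiality_pct,
                 confidentiality_value = sc$confidentiality_value,
                 final_score = sc$final_score),
      path("scores.csv"), row.names = FALSE)
  })

  dataset <- stage_wrap("build", {
    ds <- build_dataset(config$sizes, config$replicates, config$seed, spec)
    write_dataset(ds, path("dataset.csv"))
    ds
  })

  comparison <- stage_wrap("train", {
    cmp <- compare_models(dataset, config$methods,
                          test_fraction = config$test_fraction,
                          folds = config$folds, seed = config$seed,
                          grids = config$grids)
    write_comparison(cmp, path("model_comparison.csv"))
    cmp
  })

  shap <- stage_wrap("explain", {
    boosted <- comparison$table$method[
      vapply(comparison$table$method,
             function(m) comparison$models[[m]]$model$backend == "xgboost",
             logical(1))]
    if (length(boosted) == 0L) {
      stop("no boosted surrogate available to explain", call. = FALSE)
    }
    tbl <- comparison$table
    target <- boosted[which.min(tbl$rmse[match(boosted, tbl$method)])]
    rep <- compute_shap(comparison$models[[target]],
                        comparison$split$test)
    write_shap(rep, path("shap_attributions.csv"), path("shap_ranking.csv"))
    list(model = target, report = rep)
  })

  artifacts <- c("cohort.csv", "masked_example.csv", "scores.csv",
                 "dataset.csv", "model_comparison.csv",
                 "shap_attributions.csv")
  manifest <- list(
    package = "deidverify",
    version = as.character(utils::packageVersion("deidverify")),
    seed = config$seed,
    sizes = config$sizes,
    replicates = config$replicates,
    methods = config$methods,
    best_model = comparison$best,
    explained_model = shap$model,
    artifacts = lapply(stats::setNames(artifacts, artifacts), function(f)
      list(file = f, md5 = unname(tools::md5sum(path(f)))))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Small bundled fixtures for examples and tests
#'
#' Builds, deterministically from `seed`, the tiny objects used
#' throughout the documentation and test-suite: cohorts of sizes 5, 6
#' and 200; a set of named policies (`clear` = no masking, `full` =
#' everything masked, `worked_example` = one name token, one age digit
#' and seven phone digits masked with the illness hidden); and one
#' hand-written record matching the worked scoring example (labels
#' 12/11/17/1/1/0/1, usability 13).
#'
#' @param seed Integer seed.
#' @return A list with elements `cohorts` (list of data.frames keyed
#'   `n5`, `n6`, `n200`), `policies` (named list of `deid_policy`), and
#'   `worked_record` (a 1-row cohort data.frame).
#' @export
make_fixtures <- function(seed = 1L) {
  spec <- default_demographics()
  cohorts <- list(
    n5 = generate_cohort(5L, spec, seed = derive_seed(seed, 1L)),
    n6 = generate_cohort(6L, spec, seed = derive_seed(seed, 2L)),
    n200 = generate_cohort(200L, spec, seed = derive_seed(seed, 3L))
  )
  policies <- list(
    clear = masking_policy(),
    full = masking_policy(name_level = 3L, age_level = 2L,
                          phone_level = "full", blood_mask = TRUE,
                          region_mask = TRUE, illness_mask = TRUE,
                          smoking_mask = TRUE),
    worked_example = masking_policy(name_level = 1L, age_level = 1L,
                                    phone_level = "partial",
                                    illness_mask = TRUE)
  )
  worked_record <- data.frame(
    name = "Lee Jun Hak", age = 25L, phone = "010-7123-4567",
    region = "Seoul", illness = "bruise", blood = "A", smoking = FALSE,
    stringsAsFactors = FALSE)
  list(cohorts = cohorts, policies = policies,
       worked_record = worked_record)
}
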