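#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage configurations. A single global seed deterministically
#' derives per-stage seeds by stage name (see [derive_seed()]), so adding a
#' stage never perturbs the random streams of earlier stages.
#'
#' @param out_dir Run directory for all artifacts.
#' @param cohort A [cohort_config()] for the simulate stage, or `NULL` when
#'   `cohort_dir` supplies measured data.
#' @param cohort_dir Optional directory with `cohort_donors.csv` /
#'   `cohort_signals.csv` to consume instead of simulating.
#' @param dose Challenge dose in Gy for the kinetic fit.
#' @param boruta List of shadow-selection settings (`n_iter`, `alpha`,
#'   `num_trees`).
#' @param forest List of forest settings (`n_trees`, `mode`).
#' @param bootstrap List of CI settings (`n_boot`, `level`).
#' @param seed Global integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            cohort_dir = NULL,
                            dose = 3,
                            boruta = list(n_iter = 100, alpha = 0.05,
                                          num_trees = 200),
                            forest = list(n_trees = 500, mode = "oob"),
                            bootstrap = list(n_boot = 10000, level = 0.95),
                            seed = 1L) {
  structure(list(out_dir = out_dir, cohort = cohort, cohort_dir = cohort_dir,
                 dose = dose, boruta = boruta, forest = forest,
                 bootstrap = bootstrap, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or ingest) the cohort; fit repair kinetics per donor
#' and subtype; assemble the feature table; shadow-feature selection over
#' the 14 kinetic candidates; random-forest classification of three models
#' (confirmed kinetic features; age at blood draw alone; both combined)
#' with AUC/accuracy, bootstrap CIs, DeLong and Fisher comparisons; and a
#' manifest with config echo, derived seeds and artifact checksums. Reruns
#' with the same config reproduce identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the stage results (cohort, fit, features,
#'   selection, reports) with `out_dir` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  # -- simulate / ingest ----------------------------------------------------
  if (!is.null(config$cohort_dir)) {
    if (!dir.exists(config$cohort_dir)) {
      stop_parse(sprintf("cohort_dir '%s' does not exist", config$cohort_dir))
    }
    cohort <- read_cohort(config$cohort_dir)
  } else {
    cc <- config$cohort
    cc$seed <- derive_seed(config$seed, "simulate")
    cohort <- generate_cohort(cc)
  }
  write_cohort(cohort$donors, cohort$signals, out)

  # -- fit ------------------------------------------------------------------
  fit <- fit_cohort(cohort$donors, cohort$signals, dose = config$dose)
  readr::write_csv(fit$params, file.path(out, "repair_params.csv"))
  if (nrow(fit$skipped) > 0) {
    readr::write_csv(fit$skipped, file.path(out, "fit_skipped.csv"))
  }

  # -- features -------------------------------------------------------------
  ft <- build_feature_table(fit$params, cohort$donors, include_age = TRUE)
  readr::write_csv(ft$table, file.path(out, "feature_table.csv"))
  kinetic <- setdiff(names(ft$table), c("donor_id", "age_at_draw", "status"))
  labels <- ft$table$status

  # -- select ---------------------------------------------------------------
  sel <- boruta_select(ft$table[kinetic], labels,
                       n_iter = config$boruta$n_iter,
                       alpha = config$boruta$alpha,
                       num_trees = config$boruta$num_trees,
                       seed = derive_seed(config$seed, "select"))
  write_json_report(
    list(decisions = sel$decisions, confirmed = sel$confirmed,
         n_iter = sel$n_iter, alpha = sel$alpha, seed = sel$seed),
    file.path(out, "selection_report.json"))

  # -- classify -------------------------------------------------------------
  # the paper-style model triple: selected kinetics, age alone, combined
  selected <- if (length(sel$confirmed) > 0) sel$confirmed else "fres_CD19"
  fc <- forest_config(n_trees = config$forest$n_trees,
                      mode = config$forest$mode,
                      seed = derive_seed(config$seed, "classify"))
  cmp <- compare_models(ft$table[c(selected, "age_at_draw")],
                        ft$table["age_at_draw"], labels, fc,
                        label_a = "selected_plus_age", label_b = "age_only")
  scores_sel <- rf_fit_predict(ft$table[selected], labels, fc)
  bseed <- derive_seed(config$seed, "bootstrap")
  nb <- config$bootstrap$n_boot; lv <- config$bootstrap$level
  mk_report <- function(scores, name) {
    ra <- roc_auc(scores, labels)
    list(model = name,
         auc = ra$auc,
         auc_ci = as.list(bootstrap_ci(scores, labels, "auc", nb, lv,
                                       derive_seed(bseed, paste0(name, "_auc")))),
         accuracy = accuracy(scores, labels),
         accuracy_ci = as.list(bootstrap_ci(scores, labels, "accuracy", nb, lv,
                                            derive_seed(bseed, paste0(name, "_acc")))),
         n_bootstrap = nb)
  }
  reports <- list(
    selected = mk_report(scores_sel, "selected_kinetics"),
    age = mk_report(cmp$scores_b, "age_only"),
    combined = mk_report(cmp$scores_a, "selected_plus_age"))
  top <- selected[1]
  assoc <- list(
    feature = top,
    spearman_r = spearman_cor(ft$table[[top]], labels),
    u_test = mann_whitney_u(ft$table[[top]][labels == 1],
                            ft$table[[top]][labels == 0]))
  classifier_report <- list(
    models = reports, association = assoc,
    selected_features = selected, seed = config$seed,
    probabilities = stats::setNames(as.list(scores_sel), ft$table$donor_id))
  write_json_report(classifier_report, file.path(out, "classifier_report.json"))
  write_json_report(
    cmp[c("model_a", "model_b", "auc_a", "auc_b", "delong_p",
          "acc_a", "acc_b", "fisher_p")],
    file.path(out, "comparison_report.json"))
  readr::write_csv(roc_auc(cmp$scores_a, labels)$roc,
                   file.path(out, "roc_points.csv"))

  # -- manifest -------------------------------------------------------------
  artifacts <- list.files(out, pattern = "\\.(csv|json)$")
  artifacts <- setdiff(artifacts, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out, artifacts)))
  names(checksums) <- artifacts
  manifest <- list(
    package_version = as.character(utils::packageVersion("drcphenotype")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       select = derive_seed(config$seed, "select"),
                       classify = derive_seed(config$seed, "classify"),
                       bootstrap = derive_seed(config$seed, "bootstrap")),
    config = list(dose = config$dose, boruta = config$boruta,
                  forest = config$forest, bootstrap = config$bootstrap,
                  n_pairs = if (is.null(config$cohort)) NA else config$cohort$n_pairs,
                  cohort_dir = config$cohort_dir),
    checksums = checksums)
  write_json_report(manifest, file.path(out, "manifest.json"))

  invisible(list(out_dir = out, cohort = cohort, fit = fit,
                 features = ft, selection = sel,
                 classifier_report = classifier_report,
                 comparison = cmp, manifest = manifest))
}
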