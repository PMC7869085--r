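#' Pipeline configuration
#'
#' Bundles every stage's settings with one global seed; each stochastic
#' stage derives its own seed deterministically from the global seed and
#' the stage name. The defaults are smoke-scale (small cohort, 3-model
#' subspace) so an end-to-end run completes in minutes; study-scale runs
#' use the full 21-model space and the 40/33 cohort.
#'
#' @param out_dir Run directory for artifacts.
#' @param cohort A [cohort_spec()].
#' @param paradigm A [paradigm_spec()].
#' @param models Model ids to invert per subject.
#' @param inversion [inversion_settings()].
#' @param n_perm_bms,n_perm_svm Permutation counts.
#' @param seed Global seed.
#' @param stages Stages to run, in dependency order.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("mdcm_run_"),
                            cohort = cohort_spec(n_controls = 6, n_patients = 6),
                            paradigm = paradigm_spec(),
                            models = c(6, 9, 14),
                            inversion = inversion_settings(max_iter = 16, dt = 2),
                            n_perm_bms = 200, n_perm_svm = 500,
                            seed = 1,
                            stages = c("simulate", "invert", "bms",
                                       "features", "classify")) {
  structure(list(out_dir = out_dir, cohort = cohort, paradigm = paradigm,
                 models = models, inversion = inversion,
                 n_perm_bms = n_perm_bms, n_perm_svm = n_perm_svm,
                 seed = seed, stages = stages),
            class = "pipeline_config")
}

# deterministic stage seed from the global seed and stage name
stage_seed <- function(seed, stage) {
  (seed * 131 + sum(utf8ToInt(stage))) %% .Machine$integer.max
}

.stage_done <- function(dir, stage) file.exists(file.path(dir, paste0(".done_", stage)))
.mark_done <- function(dir, stage) {
  writeLines(format(Sys.time()), file.path(dir, paste0(".done_", stage)))
}

#' Run the simulate-invert-select-classify pipeline
#'
#' Executes the requested stages in dependency order, caching each stage's
#' artifacts in the run directory; rerunning with the same configuration
#' skips completed stages. Stages: `simulate` (paradigm, ground-truth
#' cohort, noisy datasets), `invert` (per-subject model fits over the
#' configured model ids; evidence matrix), `bms` (greedy family search and
#' leave-one-out permutation BMS), `features` (mismatch peaks and the group
#' x condition ANOVA), `classify` (leave-one-out SVM on V, J and ERF
#' features).
#'
#' @param config A [pipeline_config()].
#' @return The run directory path, invisibly. Artifacts: `config.json`,
#'   `paradigm.csv`, `cohort_truth.csv`, `datasets.csv`, `evidence.csv`,
#'   `bms.json`, `loo_bms.csv`, `features.csv`, `anova.json`,
#'   `classification.csv`, `report.txt`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  if (file.exists(cfg_path) &&
      !identical(as.character(cfg_json), paste(readLines(cfg_path), collapse = ""))) {
    stop("run directory contains a different configuration; use a fresh out_dir")
  }
  writeLines(as.character(cfg_json), cfg_path)
  dir <- config$out_dir
  log <- file.path(dir, "log.jsonl")
  note <- function(stage, msg) {
    cat(jsonlite::toJSON(list(time = format(Sys.time()), stage = stage,
                              message = msg, seed = stage_seed(config$seed, stage)),
                         auto_unbox = TRUE), "\n", file = log, append = TRUE)
  }

  space <- build_model_space()

  if ("simulate" %in% config$stages && !.stage_done(dir, "simulate")) {
    note("simulate", "generating paradigm, cohort and datasets")
    par <- make_paradigm(config$paradigm, seed = stage_seed(config$seed, "paradigm"))
    write.csv(par, file.path(dir, "paradigm.csv"), row.names = FALSE)
    spec <- config$cohort
    spec$seed <- stage_seed(config$seed, "cohort")
    cohort <- make_cohort(spec)
    truth <- data.frame(cohort$subjects, cohort$theta, check.names = FALSE)
    write.csv(truth, file.path(dir, "cohort_truth.csv"), row.names = FALSE)
    datasets <- simulate_cohort(cohort, dt = config$inversion$dt)
    write_evoked_csv(datasets, file.path(dir, "datasets.csv"))
    .mark_done(dir, "simulate")
  }

  if ("invert" %in% config$stages && !.stage_done(dir, "invert")) {
    if (!file.exists(file.path(dir, "datasets.csv")))
      stop("missing upstream artifact datasets.csv: rerun stage 'simulate'")
    note("invert", sprintf("fitting %d models per subject", length(config$models)))
    datasets <- read_evoked_csv(file.path(dir, "datasets.csv"))
    Fm <- matrix(NA_real_, length(datasets), length(config$models),
                 dimnames = list(names(datasets), as.character(config$models)))
    fits <- list()
    for (s in names(datasets)) {
      for (m in config$models) {
        arch <- space$models[[m]]
        res <- invert(datasets[[s]], arch, cmc_priors(arch),
                      settings = config$inversion)
        Fm[s, as.character(m)] <- res$F
        if (m == max(config$models) || length(config$models) == 1)
          fits[[s]] <- res
      }
    }
    write_evidence_csv(evidence_matrix(Fm), file.path(dir, "evidence.csv"))
    saveRDS(fits, file.path(dir, "fits_lead.rds"))
    .mark_done(dir, "invert")
  }

  if ("bms" %in% config$stages && !.stage_done(dir, "bms")) {
    if (!file.exists(file.path(dir, "evidence.csv")))
      stop("missing upstream artifact evidence.csv: rerun stage 'invert'")
    note("bms", "greedy family search and leave-one-out BMS")
    ev <- read_evidence_csv(file.path(dir, "evidence.csv"))
    gs <- greedy_family_search(ev, space, seed = stage_seed(config$seed, "bms"))
    write_bms_json(gs, file.path(dir, "bms.json"))
    loo <- loo_bms_permutations(ev, n_perm = config$n_perm_bms,
                                seed = stage_seed(config$seed, "loo_bms"))
    write.csv(loo, file.path(dir, "loo_bms.csv"), row.names = FALSE)
    .mark_done(dir, "bms")
  }

  if ("features" %in% config$stages && !.stage_done(dir, "features")) {
    if (!file.exists(file.path(dir, "datasets.csv")))
      stop("missing upstream artifact datasets.csv: rerun stage 'simulate'")
    note("features", "mismatch features and group x condition ANOVA")
    datasets <- read_evoked_csv(file.path(dir, "datasets.csv"))
    feats <- cohort_condition_features(datasets)
    write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
    an <- group_condition_anova(feats)
    jsonlite::write_json(an, file.path(dir, "anova.json"), digits = NA,
                         auto_unbox = TRUE, force = TRUE)
    .mark_done(dir, "features")
  }

  if ("classify" %in% config$stages && !.stage_done(dir, "classify")) {
    for (f in c("fits_lead.rds", "datasets.csv"))
      if (!file.exists(file.path(dir, f)))
        stop("missing upstream artifact ", f, ": rerun earlier stages")
    note("classify", "leave-one-out SVM over V, J and ERF features")
    fits <- readRDS(file.path(dir, "fits_lead.rds"))
    datasets <- read_evoked_csv(file.path(dir, "datasets.csv"))
    subjects <- names(fits)
    groups <- vapply(datasets[subjects], function(d) as.character(d$group),
                     character(1))
    reports <- list()
    for (kind in c("V", "J")) {
      tab <- assemble_features(fits, kind, subjects = subjects, groups = groups)
      reports[[kind]] <- loo_svm_permutation(
        tab, n_perm = config$n_perm_svm,
        seed = stage_seed(config$seed, paste0("svm_", kind)))
    }
    tab <- assemble_features(datasets[subjects], "ERF")
    reports$ERF <- loo_svm_permutation(
      tab, n_perm = config$n_perm_svm,
      seed = stage_seed(config$seed, "svm_ERF"))
    write.csv(classification_report(reports),
              file.path(dir, "classification.csv"), row.names = FALSE)
    .mark_done(dir, "classify")
  }

  write_report(dir)
  invisible(dir)
}

#' Write a human-readable run report
#'
#' Summarises the completed stages of a pipeline run: the family-search
#' step table, the parameter-recovery/feature tables and the
#' classification table, each with the seeds used.
#'
#' @param run_dir A [run_pipeline()] output directory.
#' @return Path of `report.txt`, invisibly.
#' @export
write_report <- function(run_dir) {
  out <- file.path(run_dir, "report.txt")
  lines <- c("microdcm pipeline report", strrep("=", 24), "")
  done <- list.files(run_dir, pattern = "^\\.done_", all.files = TRUE)
  if (length(done) == 0) {
    lines <- c(lines, "no stages completed")
    writeLines(lines, out)
    return(invisible(out))
  }
  lines <- c(lines, paste("completed stages:",
                          paste(sub("^\\.done_", "", done), collapse = ", ")), "")
  bms_path <- file.path(run_dir, "bms.json")
  if (file.exists(bms_path)) {
    gs <- jsonlite::read_json(bms_path, simplifyVector = TRUE)
    lines <- c(lines, "Family search:")
    for (nm in setdiff(names(gs$steps), "final_model_level")) {
      st <- gs$steps[[nm]]
      if (isTRUE(st$degenerate)) {
        lines <- c(lines, sprintf("  %-18s winner=%s (degenerate: one side empty)",
                                  nm, st$winner))
      } else {
        lines <- c(lines, sprintf(
          "  %-18s winner=%s  RFX family EP: %s | FFX family prob: %s",
          nm, st$winner,
          paste(sprintf("%s=%.3f", names(st$rfx$family_ep),
                        as.numeric(st$rfx$family_ep)), collapse = " "),
          paste(sprintf("%s=%.3f", names(st$ffx$family_prob),
                        as.numeric(st$ffx$family_prob)), collapse = " ")))
      }
    }
    lines <- c(lines, sprintf("  surviving model: %s", gs$survivor), "")
  }
  loo_path <- file.path(run_dir, "loo_bms.csv")
  if (file.exists(loo_path)) {
    loo <- read.csv(loo_path)
    lines <- c(lines, "Leave-one-out BMS winner frequencies:",
               sprintf("  model %-4s %5.1f%%", loo$model, 100 * loo$freq), "")
  }
  cls_path <- file.path(run_dir, "classification.csv")
  if (file.exists(cls_path)) {
    cl <- read.csv(cls_path)
    lines <- c(lines, "Classification (leave-one-out SVM, % of permutations):",
               sprintf("  %-4s correct=%5.1f%% TP=%5.1f TN=%5.1f FP=%5.1f FN=%5.1f (n_perm=%d, seed=%d)",
                       cl$features, cl$correct_pct, cl$TP, cl$TN, cl$FP, cl$FN,
                       cl$n_perm, cl$seed), "")
  }
  writeLines(lines, out)
  invisible(out)
}
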