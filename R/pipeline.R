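#' Run the full normal-database validation analysis
#'
#' Reproduces the study's analysis structure on supplied cohorts, per
#' imaging phase:
#' 1. builds the two population databases and the subject-pooled combined
#'    database from the disease-free cohorts;
#' 2. scores the validation cohort against each database (automated) and
#'    by the visual percent-count rule, and quantifies agreement
#'    (Pearson r, Bland-Altman) of the combined-database scores with each
#'    population database and with the visual scores;
#' 3. contrasts HMR and the combined-database summed score across the
#'    CAD / DCM / no-disease groups (Kruskal-Wallis);
#' 4. evaluates disease discrimination by ROC for the visual score, the
#'    automated score, the HMR, and the logistic combination of HMR with
#'    the automated score, including the paired DeLong comparison of
#'    automated versus visual scores.
#'
#' @param jp_normals,it_normals Disease-free cohort data frames (both
#'   phases present) used to build the databases.
#' @param validation Cohort data frame with a `label` column
#'   (`"none"`, `"CAD"`, `"DCM"`) and an `hmr` column.
#' @param thresholds,sd_floor Automated-scoring parameters (see
#'   [auto_score_segment()]).
#' @param alpha Significance level used throughout.
#' @return An object of class `evaluation_report`: a nested list with one
#'   element per phase (`ndb` summaries, `agreement`, `group_contrast`,
#'   `roc`, `combined`) plus `config`.
#' @export
run_validation_pipeline <- function(jp_normals, it_normals, validation,
                                    thresholds = c(2, 3, 4, 5),
                                    sd_floor = 0.5, alpha = 0.05) {
  for (col in c("label", "hmr"))
    if (!col %in% names(validation))
      stop("pipeline dependency error: validation cohort lacks '", col,
           "' column", call. = FALSE)
  phases <- intersect(c("early", "late"), unique(validation$phase))
  if (!length(phases))
    stop("pipeline dependency error: validation cohort has no early/late ",
         "rows", call. = FALSE)
  report <- list()
  for (ph in phases) {
    ndb_jp <- build_ndb(jp_normals, phase = ph, label = "Jp")
    ndb_it <- build_ndb(it_normals, phase = ph, label = "It")
    ndb_jpit <- combine_ndbs(jp_normals, it_normals, phase = ph,
                             label = "JpIt")
    val <- validation[validation$phase == ph, , drop = FALSE]
    is_case <- val$label != "none"
    sc_jp <- score_cohort(val, "ndb_auto", ndb_jp,
                          thresholds = thresholds, sd_floor = sd_floor)
    sc_it <- score_cohort(val, "ndb_auto", ndb_it,
                          thresholds = thresholds, sd_floor = sd_floor)
    sc_jpit <- score_cohort(val, "ndb_auto", ndb_jpit,
                            thresholds = thresholds, sd_floor = sd_floor)
    sc_vis <- score_cohort(val, "visual_rule")
    auto <- sc_jpit$summed
    visual <- sc_vis$summed
    roc_auto <- roc(auto, is_case, direction = ">")
    roc_visual <- roc(visual, is_case, direction = ">")
    roc_hmr <- roc(val$hmr, is_case, direction = "<")
    cmb <- fit_combined(val$hmr, auto, is_case)
    roc_combined <- roc(cmb$fitted, is_case, direction = ">")
    report[[ph]] <- list(
      ndb = list(Jp = ndb_summary(ndb_jp), It = ndb_summary(ndb_it),
                 JpIt = ndb_summary(ndb_jpit),
                 segment_anova = compare_ndbs(list(ndb_jp, ndb_it),
                                              alpha = alpha)),
      scores = list(auto_jpit = auto, auto_jp = sc_jp$summed,
                    auto_it = sc_it$summed, visual = visual,
                    subject_id = val$subject_id, label = val$label),
      agreement = list(
        jpit_vs_jp = agreement(sc_jpit$summed, sc_jp$summed),
        jpit_vs_it = agreement(sc_jpit$summed, sc_it$summed),
        auto_vs_visual = agreement(visual, auto)),
      group_contrast = list(
        hmr = kruskal_wallis(val$hmr, val$label, alpha = alpha),
        auto_score = kruskal_wallis(auto, val$label, alpha = alpha)),
      roc = list(visual = roc_visual, auto = roc_auto, hmr = roc_hmr,
                 combined = roc_combined,
                 auto_vs_visual = compare_rocs(auto, visual, is_case)),
      combined = cmb)
  }
  report$config <- list(thresholds = thresholds, sd_floor = sd_floor,
                        alpha = alpha,
                        normalization = "max_segment",
                        n_jp = length(unique(jp_normals$subject_id)),
                        n_it = length(unique(it_normals$subject_id)),
                        n_validation = length(unique(
                          validation$subject_id)))
  class(report) <- "evaluation_report"
  report
}

ndb_summary <- function(ndb) {
  list(population = ndb$population, sex = ndb$sex, phase = ndb$phase,
       n = ndb$n, mean = ndb$mean, sd = ndb$sd)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report\n")
  for (ph in intersect(c("early", "late"), names(x))) {
    r <- x[[ph]]
    cat(sprintf("\n== %s phase ==\n", ph))
    cat(sprintf(
      "agreement (summed scores): JpIt~Jp r=%.3f, JpIt~It r=%.3f, visual~auto r=%.3f\n",
      r$agreement$jpit_vs_jp$r, r$agreement$jpit_vs_it$r,
      r$agreement$auto_vs_visual$r))
    cat(sprintf(
      "Kruskal-Wallis p: HMR %.4g, automated score %.4g\n",
      r$group_contrast$hmr$p, r$group_contrast$auto_score$p))
    cat(sprintf(
      "AUC: visual %.3f, automated %.3f (DeLong p=%.3f), HMR %.3f, combined %.3f\n",
      r$roc$visual$auc, r$roc$auto$auc, r$roc$auto_vs_visual$p,
      r$roc$hmr$auc, r$roc$combined$auc))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Round-trippable JSON of the full report (databases, agreement, group
#' contrasts, ROC results, combined model).
#'
#' @param report An `evaluation_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass_deep(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}
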