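# End-to-end orchestration: simulate -> differential expression -> membrane
# features -> per-sample aggregation -> Fenton-set scoring -> enzyme
# selection -> classification -> reaction accounting.

#' Pipeline configuration
#'
#' Collects the analysis thresholds, the cross-validation settings and the
#' synthetic-cohort configuration for one deterministic run.
#'
#' @param cohort A [cohort_config()] describing the synthetic inputs.
#' @param fc_threshold,p_threshold DEG calling thresholds (|log2FC| >= 1
#'   inclusive, p < 0.05 strict).
#' @param pcc_threshold,pcc_p Co-expression thresholds (PCC > 0.6,
#'   p < 1e-4).
#' @param enrich_p Pathway-enrichment p-value cutoff (p < 1e-4).
#' @param min_segment Minimum extracellular segment length in residues.
#' @param k_enzymes Number of enzymes kept by SVM-RFE (default 20).
#' @param folds Cross-validation folds (default 5; at least 2).
#' @param rfe_inside_cv Recompute the enzyme ranking inside each training
#'   fold (default) or once globally before cross-validation.
#' @param seed Integer seed for every random stage.
#' @param out_dir Optional directory for plain-text stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(seed = seed),
                            fc_threshold = 1, p_threshold = 0.05,
                            pcc_threshold = 0.6, pcc_p = 1e-4,
                            enrich_p = 1e-4, min_segment = 10L,
                            k_enzymes = 20L, folds = 5L,
                            rfe_inside_cv = TRUE,
                            seed = 1L, out_dir = NULL) {
  stopifnot(fc_threshold > 0, p_threshold > 0, pcc_threshold > 0,
            pcc_p > 0, enrich_p > 0, min_segment >= 1L, k_enzymes >= 1L)
  if (folds < 2L) stop("folds must be at least 2")
  structure(list(cohort = cohort, fc_threshold = fc_threshold,
                 p_threshold = p_threshold, pcc_threshold = pcc_threshold,
                 pcc_p = pcc_p, enrich_p = enrich_p,
                 min_segment = as.integer(min_segment),
                 k_enzymes = as.integer(k_enzymes), folds = as.integer(folds),
                 rfe_inside_cv = rfe_inside_cv,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full two-factor brain-metastasis analysis
#'
#' Generates the synthetic cohort and protein records, calls differentially
#' expressed genes, computes extracellular feature vectors for the
#' differentially expressed transmembrane proteins, aggregates them per
#' sample weighted by TPM, scores the planted Fenton-reaction gene set,
#' ranks enzymes by SVM-RFE, cross-validates the three classifiers
#' (physical features, selected enzyme expressions, combined), and labels
#' the bundled enzymatic reactions by net proton production. Deterministic
#' under a fixed configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with per-stage results and a
#'   `summary` element (seed, thresholds, DEG counts, group medians, the
#'   three AUCs, the selected enzymes, reaction label counts).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  records <- stage("simulate", generate_protein_records(
    n = config$cohort$n_tm_de, seed = config$seed + 1L,
    gene_ids = cohort$truth$de_gene_ids))

  labels <- factor(cohort$labels$class, levels = c("NBMP", "BMP"))
  de <- stage("de", differential_expression(
    cohort$counts, labels, positive_class = "BMP",
    fc_threshold = config$fc_threshold, p_threshold = config$p_threshold))

  deg_tm <- intersect(de$gene_id[de$is_deg], cohort$truth$de_gene_ids)
  use <- vapply(records, function(r) r$gene_id %in% deg_tm, logical(1))
  if (!any(use)) stop("pipeline stage 'features' failed: no DEG transmembrane proteins")
  vectors <- stage("features", compute_feature_vectors(
    records[use], table = aa_property_table(), min_len = config$min_segment))
  direction <- stats::setNames(
    de$direction[match(vectors$gene_id, de$gene_id)], vectors$protein_id)
  feature_summary <- stage("features",
                           summarize_feature_table(vectors, direction))

  sample_features <- stage("aggregate",
                           aggregate_sample_features(cohort$tpm, vectors))
  class_group <- stats::setNames(cohort$labels$class, cohort$labels$sample_id)
  fine_group <- stats::setNames(
    ifelse(cohort$labels$class == "BMP", "BMP",
           paste0("NBMP-", cohort$labels$subgroup)),
    cohort$labels$sample_id)
  fine_medians <- group_medians(sample_features, fine_group)
  medians <- stage("aggregate", rbind(
    group_medians(sample_features, class_group),
    fine_medians[fine_medians$group != "BMP", , drop = FALSE]))

  fr_score <- stage("fenton",
                    gene_set_score(cohort$tpm, cohort$gene_sets$fenton_reaction))
  fr_test <- stage("fenton", stats::t.test(
    fr_score[labels == "BMP"], fr_score[labels == "NBMP"]))

  spec <- classifier_spec(seed = config$seed)
  enz_expr <- t(cohort$tpm[cohort$truth$enzyme_ids, , drop = FALSE])
  ranking <- stage("select", svm_rfe_rank(enz_expr, labels, spec))
  selected <- stage("select", select_top_k(ranking, config$k_enzymes))

  phys <- as.matrix(sample_features[, c("S_EP", "S_EN", "S_EW", "S_EH")])
  rownames(phys) <- sample_features$sample_id
  cv_physical <- stage("classify", run_classifier(
    phys, labels, spec, k_folds = config$folds, positive_class = "BMP"))
  cv_enzyme <- stage("classify", run_classifier(
    enz_expr, labels, spec, k_folds = config$folds, positive_class = "BMP",
    select_k = config$k_enzymes, rfe_inside_cv = config$rfe_inside_cv))
  cv_combined <- stage("classify", run_classifier(
    cbind(phys, enz_expr), labels, spec, k_folds = config$folds,
    positive_class = "BMP", select_k = config$k_enzymes,
    select_from = colnames(enz_expr), rfe_inside_cv = config$rfe_inside_cv))

  reactions <- stage("reactions",
                     classify_h_producing(bmp_enzyme_reactions()$reaction))

  summary <- list(
    seed = config$seed,
    thresholds = config[c("fc_threshold", "p_threshold", "pcc_threshold",
                          "pcc_p", "enrich_p", "min_segment", "k_enzymes",
                          "folds")],
    n_deg = sum(de$is_deg), n_deg_tm = length(deg_tm),
    fr_mean_bmp = unname(fr_test$estimate[1]),
    fr_mean_nbmp = unname(fr_test$estimate[2]),
    fr_p_value = fr_test$p.value,
    auc = c(physical = cv_physical$auc, enzyme = cv_enzyme$auc,
            combined = cv_combined$auc),
    selected_enzymes = selected,
    reaction_counts = as.list(reactions$counts))

  report <- structure(
    list(cohort = cohort, records = records, de = de, vectors = vectors,
         feature_summary = feature_summary, sample_features = sample_features,
         group_medians = medians, fr_score = fr_score,
         enzyme_ranking = ranking,
         cv = list(physical = cv_physical, enzyme = cv_enzyme,
                   combined = cv_combined),
         reactions = reactions, summary = summary),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) .write_pipeline_artifacts(report, config)
  report
}

# Plain-text stage artifacts so a run can be audited and resumed.
.write_pipeline_artifacts <- function(report, config) {
  dir <- config$out_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(report$cohort, dir)
  write_protein_records(report$records, file.path(dir, "topology.tsv"),
                        file.path(dir, "proteins.fasta"))
  utils::write.table(report$de, file.path(dir, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$vectors, file.path(dir, "feature_vectors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$sample_features,
                     file.path(dir, "sample_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$group_medians, file.path(dir, "group_medians.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$enzyme_ranking,
                     file.path(dir, "enzyme_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$reactions$table,
                     file.path(dir, "reaction_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$cv)) {
    utils::write.table(report$cv[[nm]]$roc,
                       file.path(dir, paste0("roc_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary_json <- report$summary
  summary_json$auc <- as.list(summary_json$auc)
  jsonlite::write_json(summary_json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(config[setdiff(names(unclass(config)), "cohort")],
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
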