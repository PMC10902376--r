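#' End-to-end radiogenomic subtyping pipeline
#'
#' Runs simulate (or load) -> preprocess + L2,1 selection -> anchor-based
#' partial multi-modal clustering -> survival characterization -> mutation
#' co-occurrence -> CCA, writing every intermediate table plus a JSON
#' manifest of parameters and seeds to `out_dir`. A single global seed
#' deterministically derives a per-stage seed from the stage name, so the
#' same config always yields byte-identical outputs and stages can be rerun
#' in isolation.
#'
#' @param config list; either `simulate` (a [synthetic_config()]) or
#'   `input_dir` (directory holding imaging.csv, genomic.csv, clinical.csv
#'   written by a previous run), never both. Optional blocks: `n_features`
#'   (selected imaging features, default 12), `apmc` (an [apmc_config()];
#'   its seed is overridden by the derived stage seed), `cca_n_perm`
#'   (default 999).
#' @param out_dir output directory (created if absent).
#' @param seed global seed.
#' @return invisibly, a list with all stage results (`cohort`, `selection`,
#'   `assignment`, `labels` (risk-ordered), `km`, `cox`, `pairwise_hr`,
#'   `cooccurrence`, `cca`, `knn`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  has_sim <- !is.null(config$simulate)
  has_dir <- !is.null(config$input_dir)
  if (has_sim == has_dir)
    stop("config must contain exactly one of `simulate` or `input_dir`")

  # --- stage: cohort -------------------------------------------------------
  if (has_sim) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- stage_seed(seed, "simulate")
    cohort <- generate_cohort(sim_cfg)
    write_cohort_csvs(cohort, out_dir)
  } else {
    cohort <- tryCatch(read_cohort_csvs(config$input_dir),
                       error = function(e)
                         stop("stage load_cohort failed: ", conditionMessage(e)))
  }
  dataset <- cohort$dataset
  clinical <- cohort$clinical
  if (is.null(clinical))
    stop("stage subtype_survival requires a clinical table; none found")

  # --- stage: preprocess + selection --------------------------------------
  both <- dataset$has_imaging & dataset$has_genomic
  n_features <- config$n_features %||% 12L
  rd <- reduce_dataset(dataset, n_features = n_features)
  sel <- rd$selection
  sel_cols <- rd$selected_columns
  utils::write.csv(data.frame(
    feature = colnames(dataset$imaging)[sel_cols],
    original_index = sel_cols,
    row_norm = sel$row_norms[sel$selected_feature_ids],
    rank = seq_along(sel_cols)),
    file.path(out_dir, "selected_features.csv"), row.names = FALSE)
  reduced <- rd$dataset

  # --- stage: clustering ---------------------------------------------------
  apmc_cfg <- config$apmc %||% apmc_config()
  apmc_cfg$seed <- stage_seed(seed, "cluster")
  assignment <- run_apmc(reduced, apmc_cfg)
  labels <- order_subtypes_by_risk(clinical, assignment$labels)
  utils::write.csv(data.frame(subject_id = dataset$subject_ids,
                              subtype = labels,
                              cohort = dataset$cohort_split),
                   file.path(out_dir, "subtypes.csv"), row.names = FALSE)
  utils::write.csv(round(assignment$similarity$S, 10),
                   file.path(out_dir, "similarity.csv"), row.names = FALSE)

  # --- stage: survival -----------------------------------------------------
  km <- km_logrank(clinical, labels)
  cox <- cox_fit(clinical, labels)
  phr <- pairwise_subtype_hr(clinical, labels)
  utils::write.csv(km$curves, file.path(out_dir, "km_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(rbind(cox$univariate,
                         cox$multivariate %||% cox$univariate[0, ]),
                   file.path(out_dir, "cox_report.csv"), row.names = FALSE)
  utils::write.csv(phr, file.path(out_dir, "pairwise_hr.csv"),
                   row.names = FALSE)

  # --- stage: mutation patterns -------------------------------------------
  gen_present <- dataset$has_genomic
  cooc <- pairwise_mutation_or(dataset$genomic[gen_present, , drop = FALSE],
                               labels[gen_present])
  for (st in setdiff(names(cooc), "pairs")) {
    sub <- cooc$pairs[cooc$pairs$subtype == st, , drop = FALSE]
    utils::write.csv(sub,
                     file.path(out_dir, paste0("cooccurrence_", st, ".csv")),
                     row.names = FALSE)
  }
  props <- mutation_proportions(dataset$genomic[gen_present, , drop = FALSE],
                                labels[gen_present])
  utils::write.csv(props, file.path(out_dir, "mutation_proportions.csv"),
                   row.names = FALSE)

  # --- stage: CCA ----------------------------------------------------------
  Xb <- reduced$imaging[both, , drop = FALSE]
  Yb <- reduced$genomic[both, , drop = FALSE]
  cca <- fit_cca(Xb, Yb)
  cca_p <- cca_pvalue(cca, "permutation",
                      n_perm = config$cca_n_perm %||% 999L,
                      seed = stage_seed(seed, "cca"))
  scores <- data.frame(subject_id = dataset$subject_ids[both],
                       u = cca$u, v = cca$v,
                       subtype = labels[both],
                       cohort = dataset$cohort_split[both])
  utils::write.csv(scores, file.path(out_dir, "cca_scores.csv"),
                   row.names = FALSE)
  disc <- scores$cohort == "discovery"
  knn <- NULL
  if (any(disc) && any(!disc)) {
    knn <- knn_latent_predict(cbind(scores$u, scores$v)[disc, , drop = FALSE],
                              scores$subtype[disc],
                              cbind(scores$u, scores$v)[!disc, , drop = FALSE],
                              k = min(13L, sum(disc)),
                              test_labels = scores$subtype[!disc])
  }
  jsonlite::write_json(list(r = cca$r, p_value = cca_p,
                            n_subjects = cca$n_subjects,
                            knn_accuracy = if (is.null(knn)) NULL
                                           else knn$accuracy),
                       file.path(out_dir, "cca_report.json"),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("radjoint")),
    global_seed = seed,
    stage_seeds = list(simulate = stage_seed(seed, "simulate"),
                       cluster = stage_seed(seed, "cluster"),
                       cca = stage_seed(seed, "cca")),
    n_features = n_features,
    k = assignment$k,
    n_subjects = length(dataset$subject_ids))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, selection = sel, assignment = assignment,
                 labels = labels, km = km, cox = cox, pairwise_hr = phr,
                 cooccurrence = cooc, cca = cca, cca_p = cca_p, knn = knn))
}

#' Preprocess, select features and reduce a dataset for clustering
#'
#' Applies the fixed imaging preprocessing pipeline (z-score, SD filter,
#' correlation filter) over the imaging-present subjects, derives pathway
#' alteration labels for the both-modality subjects, runs pathway-supervised
#' L2,1 selection on them, and returns a dataset whose imaging view holds
#' the selected (preprocessed) features and whose genomic view is restricted
#' to the pathway gene panel.
#'
#' @param dataset a [partial_mm_dataset()].
#' @param n_features number of imaging features to keep.
#' @param pathway_map named list, pathway -> member genes.
#' @param ... passed to [l21_select()].
#' @return list: `dataset` (reduced), `selection` (the `selection_result`),
#'   `selected_columns` (original imaging column indices, selection order),
#'   `preprocess` (the [preprocess_imaging()] result).
#' @export
reduce_dataset <- function(dataset, n_features = 12L,
                           pathway_map = gbm_pathways(), ...) {
  both <- dataset$has_imaging & dataset$has_genomic
  if (!any(both))
    stop("feature selection needs subjects with both modalities")
  prep <- preprocess_imaging(dataset$imaging[dataset$has_imaging, ,
                                             drop = FALSE])
  Z <- prep$matrix
  pw <- derive_pathway_labels(dataset$genomic[both, , drop = FALSE],
                              pathway_map)
  X <- t(Z[rownames(Z) %in% dataset$subject_ids[both], , drop = FALSE])
  sel <- l21_select(X, t(pw), n_features = n_features, ...)
  sel_cols <- prep$kept[sel$selected_feature_ids]
  reduced <- dataset
  reduced$imaging <- matrix(NA_real_, length(dataset$subject_ids),
                            length(sel_cols),
                            dimnames = list(dataset$subject_ids,
                                            colnames(dataset$imaging)[sel_cols]))
  reduced$imaging[dataset$has_imaging, ] <-
    Z[, sel$selected_feature_ids, drop = FALSE]
  pw_genes <- intersect(unlist(pathway_map), colnames(dataset$genomic))
  reduced$genomic <- dataset$genomic[, pw_genes, drop = FALSE]
  list(dataset = reduced, selection = sel, selected_columns = sel_cols,
       preprocess = prep)
}

# cohort CSV round-trip -----------------------------------------------------

write_cohort_csvs <- function(cohort, out_dir) {
  ds <- cohort$dataset
  img <- data.frame(subject_id = ds$subject_ids[ds$has_imaging],
                    ds$imaging[ds$has_imaging, , drop = FALSE],
                    check.names = FALSE)
  gen <- data.frame(subject_id = ds$subject_ids[ds$has_genomic],
                    ds$genomic[ds$has_genomic, , drop = FALSE],
                    check.names = FALSE)
  utils::write.csv(img, file.path(out_dir, "imaging.csv"), row.names = FALSE)
  utils::write.csv(gen, file.path(out_dir, "genomic.csv"), row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(
      list(subtype_labels = as.list(cohort$truth$subtype_labels),
           informative_feature_ids = cohort$truth$informative_feature_ids,
           true_hazard_multipliers = cohort$truth$true_hazard_multipliers),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

read_cohort_csvs <- function(dir) {
  need <- file.path(dir, c("imaging.csv", "genomic.csv", "clinical.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing input file(s): ", paste(basename(missing), collapse = ", "))
  img <- utils::read.csv(need[1], check.names = FALSE)
  gen <- utils::read.csv(need[2], check.names = FALSE)
  clinical <- utils::read.csv(need[3], check.names = FALSE,
                              stringsAsFactors = FALSE)
  ids <- clinical$subject_id
  imaging <- matrix(NA_real_, length(ids), ncol(img) - 1,
                    dimnames = list(ids, colnames(img)[-1]))
  imaging[match(img$subject_id, ids), ] <- as.matrix(img[, -1])
  genomic <- matrix(NA_integer_, length(ids), ncol(gen) - 1,
                    dimnames = list(ids, colnames(gen)[-1]))
  genomic[match(gen$subject_id, ids), ] <- as.matrix(gen[, -1])
  ds <- partial_mm_dataset(ids, imaging, genomic,
                           ids %in% img$subject_id, ids %in% gen$subject_id,
                           clinical$cohort)
  list(dataset = ds, clinical = clinical, truth = NULL)
}
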