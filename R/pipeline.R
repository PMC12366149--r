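# End-to-end runs: filter -> merge -> features -> model -> ranked VCF,
# plus training and benchmarking entry points. These are the functions a
# thin command-line wrapper (inst/cli/svmeld.R) calls; each writes a
# machine-readable provenance record alongside its outputs.

parse_inputs <- function(vcf_paths, dialects, fconf) {
  out <- list()
  for (cl in names(vcf_paths)) {
    dialect <- dialects[[cl]]
    if (is.null(dialect)) stopf("unknown caller '%s' (no dialect)", cl)
    out[[cl]] <- filter_sv_calls(parse_caller_vcf(vcf_paths[[cl]], dialect),
                                 fconf)
  }
  out
}

subset_type <- function(calls_by_caller, svt) {
  out <- lapply(calls_by_caller, function(x) x[svtype == svt])
  out[vapply(out, nrow, integer(1)) > 0]
}

provenance <- function(...) {
  cfg <- list(..., package_version = as.character(utils::packageVersion("svmeld")))
  cfg$config_hash <- dialect_registry_hash(cfg)
  cfg
}

#' Train basic and full models from caller VCFs and a truth VCF
#'
#' Parses and filters the caller VCFs, merges per SV type, labels the
#' consensus by matching against the truth set, builds the basic
#' (length + presence) and full (harmonized quality metrics) feature
#' matrices, optionally applies correlation pre-selection, grid-searches
#' hyperparameters, prunes zero-importance features, and saves both model
#' artifacts plus a training report.
#'
#' @param vcf_paths Named list/vector: caller -> VCF path.
#' @param truth_path Truth-set VCF path.
#' @param stats A [sequencing_stats()] (required with VCF input; coverage
#'   and read length cannot be inferred from VCFs).
#' @param svtype `"DEL"` or `"INS"`.
#' @param out_dir Output directory for artifacts (NULL: return only).
#' @param dialects,fconf,mparams,match_p,tconfig,registry Configuration
#'   objects; defaults follow the package defaults for the SV type.
#' @param select_features Apply [correlation_select()] before training.
#' @param prune Iterate zero-importance pruning after training.
#' @return List: `fm_model`, `bm_model`, `report` (list), `consensus`,
#'   `features`.
#' @export
run_train <- function(vcf_paths, truth_path, stats, svtype,
                      out_dir = NULL,
                      dialects = default_dialects(),
                      fconf = filter_config(),
                      mparams = merge_params(),
                      match_p = match_params(),
                      tconfig = training_config(),
                      registry = default_feature_registry(svtype, dialects),
                      select_features = TRUE, prune = TRUE) {
  svtype <- match.arg(svtype, c("DEL", "INS"))
  svt_arg <- svtype
  stopifnot(inherits(stats, "sequencing_stats"))
  calls <- subset_type(parse_inputs(vcf_paths, dialects, fconf), svtype)
  truth_conf <- fconf
  truth_conf$require_nonref_genotype <- TRUE
  truth <- filter_sv_calls(parse_caller_vcf(truth_path, dialects$truth),
                           truth_conf)[svtype == svt_arg]
  consensus <- merge_calls(calls, mparams)
  labels <- label_consensus(consensus, truth, match_p)

  fm <- set_labels(build_feature_matrix(consensus, calls, registry, stats),
                   labels)
  bm <- set_labels(basic_feature_matrix(consensus, calls), labels)

  feats <- if (select_features) correlation_select(fm) else colnames(fm$x)
  fm_model <- grid_search_train(fm, tconfig, features = feats)
  if (prune) fm_model <- prune_zero_importance(fm_model, fm, tconfig)
  bm_model <- grid_search_train(bm, tconfig)

  report <- list(
    svtype = svtype, n_consensus = nrow(consensus),
    n_tp = sum(labels), n_fp = sum(!labels),
    truth_count = nrow(truth),
    initial_features = ncol(fm$x),
    selected_features = length(feats),
    final_features = length(fm_model$feature_names),
    pruned = setdiff(feats, fm_model$feature_names),
    fm_hyperparameters = fm_model$hyperparameters,
    fm_cv_auc = fm_model$cv_auc, bm_cv_auc = bm_model$cv_auc,
    importances = as.list(sort(fm_model$importances, decreasing = TRUE)),
    provenance = provenance(seed = tconfig$seed, svtype = svtype,
                            registry_hash = dialect_registry_hash(registry)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_meta_model(fm_model, file.path(out_dir, paste0("fm_", svtype)))
    save_meta_model(bm_model, file.path(out_dir, paste0("bm_", svtype)))
    jsonlite::write_json(report, file.path(out_dir,
                                           paste0("train_report_", svtype, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(fm_model = fm_model, bm_model = bm_model, report = report,
       consensus = consensus, features = fm)
}

#' Score caller VCFs into a probability-ranked consensus VCF
#'
#' Runs filter -> merge -> features -> prediction per SV type with the
#' matching type-specific model, concatenates, sorts by (chrom, pos) and
#' writes the consensus VCF with QUAL = TP probability. A model whose
#' registry hash disagrees with the feature configuration is refused.
#'
#' @param vcf_paths Named list/vector: caller -> VCF path.
#' @param stats A [sequencing_stats()].
#' @param models Named list of `meta_model` objects (or artifact dirs),
#'   e.g. `list(DEL = ..., INS = ...)`; types without a model are skipped.
#' @param out_vcf Output consensus VCF path.
#' @param dialects,fconf,mparams Configuration objects.
#' @param registries Named list of [feature_registry()] per svtype.
#' @return data.table of scored consensus calls (all types), invisibly
#'   written to `out_vcf`.
#' @export
run_predict <- function(vcf_paths, stats, models, out_vcf,
                        dialects = default_dialects(),
                        fconf = filter_config(),
                        mparams = merge_params(),
                        registries = NULL) {
  stopifnot(inherits(stats, "sequencing_stats"))
  all_calls <- parse_inputs(vcf_paths, dialects, fconf)
  scored <- list()
  for (svt in intersect(c("DEL", "INS"), names(models))) {
    model <- models[[svt]]
    if (is.character(model)) model <- load_meta_model(model)
    if (!is.null(model$svtype) && !is.na(model$svtype) && model$svtype != svt)
      stopf("model for %s was trained for %s", svt, model$svtype)
    registry <- registries[[svt]] %||% default_feature_registry(svt, dialects)
    if (!is.null(model$registry_hash) && !is.na(model$registry_hash) &&
        model$registry_hash != dialect_registry_hash(registry))
      stopf("registry hash mismatch for %s model: features were built under a different metric configuration", svt)
    calls <- subset_type(all_calls, svt)
    consensus <- merge_calls(calls, mparams)
    if (nrow(consensus) == 0L) next
    need_presence <- any(grepl("^presence_", model$feature_names))
    fm <- if (need_presence && !any(grepl("\\.", model$feature_names)))
      basic_feature_matrix(consensus, calls)
    else build_feature_matrix(consensus, calls, registry, stats)
    consensus[, probability := predict_probabilities(model, fm)]
    scored[[svt]] <- consensus
  }
  out <- data.table::rbindlist(scored)
  if (is.null(out) || nrow(out) == 0L)
    out <- merge_calls(list(), mparams)[, probability := numeric(0)]
  data.table::setorder(out, chrom, pos)
  write_consensus_vcf(out, out_vcf,
                      registry_hash = dialect_registry_hash(default_dialects()),
                      merge_params = mparams)
  invisible(out)
}

#' Benchmark a call VCF against a truth VCF
#'
#' Matches under the configured protocol and reports TP/FP/FN, precision,
#' recall and F1; when the call VCF carries probabilities in QUAL (the
#' consensus format), ROC AUC and a per-decile table are added.
#'
#' @param call_path Call-set VCF (consensus or any SV VCF).
#' @param truth_path Truth-set VCF.
#' @param svtype `"DEL"` or `"INS"`.
#' @param params A [match_params()].
#' @param fconf A [filter_config()] applied to both sets.
#' @param out_prefix Optional path prefix: writes `<prefix>_metrics.json`
#'   and, when deciles are available, `<prefix>_deciles.tsv`.
#' @param dialects Dialect registry.
#' @return List with `metrics` (a `benchmark_metrics`), `match`
#'   (`match_result`), and optional `auc`, `deciles`.
#' @export
run_bench <- function(call_path, truth_path, svtype,
                      params = match_params(), fconf = filter_config(),
                      out_prefix = NULL, dialects = default_dialects()) {
  svtype <- match.arg(svtype, c("DEL", "INS"))
  svt_arg <- svtype
  calls <- tryCatch(read_consensus_vcf(call_path), error = function(e) NULL)
  has_probs <- !is.null(calls) && "probability" %in% names(calls) &&
    nrow(calls) > 0 && !anyNA(calls$probability)
  if (!has_probs) calls <- parse_caller_vcf(call_path, dialects$truth)
  calls <- filter_sv_calls(calls, fconf)[svtype == svt_arg]
  truth_conf <- fconf
  truth_conf$require_nonref_genotype <- TRUE
  truth <- filter_sv_calls(parse_caller_vcf(truth_path, dialects$truth),
                           truth_conf)[svtype == svt_arg]
  mr <- match_to_truth(calls, truth, params)
  metrics <- compute_metrics(mr)
  res <- list(metrics = metrics, match = mr)
  if ("probability" %in% names(calls) && nrow(calls)) {
    labels <- calls$id %in% mr$pairs$call_id
    if (length(unique(labels)) == 2L)
      res$auc <- roc_auc(calls$probability, labels)
    res$deciles <- decile_report(calls$probability, labels)
  }
  if (!is.null(out_prefix)) {
    jsonlite::write_json(
      list(svtype = svtype, tp = metrics$tp, fp = metrics$fp, fn = metrics$fn,
           precision = metrics$precision, recall = metrics$recall,
           f1 = metrics$f1, auc = res$auc,
           provenance = provenance(call_path = call_path,
                                   truth_path = truth_path)),
      paste0(out_prefix, "_metrics.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
    if (!is.null(res$deciles))
      data.table::fwrite(res$deciles, paste0(out_prefix, "_deciles.tsv"),
                         sep = "\t")
  }
  res
}
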