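#' Analysis configuration with the published defaults
#'
#' Collects every tunable threshold of the training/validation pipeline in
#' one list. The defaults are the published analysis settings: MAD
#' variability filter at 0.5 (unscaled), univariate screen at p < 0.001,
#' 10-fold cross-validated LASSO Cox, 5-year time-dependent ROC horizon,
#' GSEA at 10,000 permutations with an FDR threshold of 0.002.
#'
#' @param mad_threshold MAD retention threshold.
#' @param mad_scale multiplier on the raw MAD (1.4826 for normal
#'   consistency; default 1, unscaled).
#' @param screen_p univariate screen p-value threshold.
#' @param folds cross-validation folds for the LASSO.
#' @param stratify_folds stratify CV folds by event status.
#' @param min_freq minimum within-cohort minority frequency for a pair to be
#'   kept (0 removes only strictly constant pairs).
#' @param time_unit `"days"` or `"months"`; fixes the 5-year ROC horizon at
#'   1825 days or 60 months.
#' @param horizon ROC horizon override in `time_unit`s (`NULL` = 5 years).
#' @param gsea_fdr significance threshold applied to GSEA FDR.
#' @param n_perm GSEA permutation count.
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @return a named list of class `irgp_config`.
#' @export
irgp_config <- function(mad_threshold = 0.5, mad_scale = 1.0,
                        screen_p = 0.001, folds = 10L,
                        stratify_folds = TRUE, min_freq = 0,
                        time_unit = c("days", "months"), horizon = NULL,
                        gsea_fdr = 0.002, n_perm = 10000L, seed = 1L) {
  time_unit <- match.arg(time_unit)
  if (is.null(horizon))
    horizon <- if (time_unit == "days") 5 * 365 else 60
  cfg <- list(mad_threshold = mad_threshold, mad_scale = mad_scale,
              screen_p = screen_p, folds = as.integer(folds),
              stratify_folds = stratify_folds, min_freq = min_freq,
              time_unit = time_unit, horizon = horizon,
              gsea_fdr = gsea_fdr, n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  stopifnot(cfg$mad_threshold >= 0, cfg$screen_p > 0, cfg$folds >= 2L,
            cfg$horizon > 0, cfg$n_perm > 0L)
  structure(cfg, class = c("irgp_config", "list"))
}

.stage_seed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

.provenance <- function(config) {
  list(package = "irgpair",
       version = as.character(utils::packageVersion("irgpair")),
       seed = config$seed,
       config = unclass(config),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Train a gene-pair signature end to end
#'
#' Runs the full training funnel on one or more cohorts: immune-gene
#' intersection, MAD variability filter (per cohort, intersecting the
#' survivors), exhaustive pair indicators, constant-pair removal across all
#' cohorts, univariate log-rank screen on the training cohort, and
#' LASSO-Cox selection. The first cohort is the training cohort; any others
#' participate only in the gene intersection and constancy filter, mirroring
#' the meta-training / meta-testing design.
#'
#' @param expr expression matrix, or named list of matrices
#'   (first = training cohort).
#' @param clinical clinical table for the training cohort (`sample_id`,
#'   `os_time`, `os_event`).
#' @param immune_genes character vector of immune-related gene symbols.
#' @param config an [irgp_config()].
#' @param out_dir optional directory; when given, writes `signature.tsv`,
#'   `screen.tsv` and `train_report.json` (with a provenance block).
#' @return list with `signature` (an `irgp_signature`), `screen` (screen
#'   survivors), and `report` (stage-count funnel: `genes_in`,
#'   `genes_after_mad`, `pairs_built`, `pairs_after_constant`,
#'   `screen_survivors`, `selected_pairs`).
#' @export
run_train <- function(expr, clinical, immune_genes, config = irgp_config(),
                      out_dir = NULL) {
  cohorts <- if (is.matrix(expr)) list(training = expr) else expr
  stopifnot(length(cohorts) >= 1L)
  train_expr <- cohorts[[1L]]
  genes_in <- intersect_gene_lists(cohorts, immune_genes)
  mad_ok <- Reduce(intersect, lapply(cohorts, function(m)
    mad_filter(m, genes_in, threshold = config$mad_threshold,
               scale_constant = config$mad_scale)))
  if (length(mad_ok) < 2L)
    stop("stage mad_filter: fewer than 2 genes pass the variability filter")
  ind_all <- lapply(cohorts, build_pair_indicators, genes = mad_ok)
  kept_pairs <- remove_constant_pairs(ind_all, min_freq = config$min_freq)
  if (nrow(kept_pairs) == 0L)
    stop("stage remove_constant_pairs: no non-constant pair")
  ind_train <- subset_pairs(ind_all[[1L]], kept_pairs)
  al <- align_cohort(train_expr, clinical)
  ind_train$scores <- ind_train$scores[, al$clinical$sample_id, drop = FALSE]
  screen <- univariate_screen(ind_train, al$clinical,
                              p_threshold = config$screen_p)
  if (nrow(screen) < 2L)
    stop("stage univariate_screen: fewer than 2 pairs pass p < ",
         config$screen_p)
  ind_screened <- subset_pairs(ind_train, screen[, c("gene1", "gene2")])
  sig <- lasso_cox_select(ind_screened, al$clinical, folds = config$folds,
                          seed = .stage_seed(config, 101L),
                          stratify_folds = config$stratify_folds)
  report <- list(genes_in = length(genes_in),
                 genes_after_mad = length(mad_ok),
                 pairs_built = nrow(ind_all[[1L]]$pairs),
                 pairs_after_constant = nrow(kept_pairs),
                 screen_survivors = nrow(screen),
                 selected_pairs = nrow(sig))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_signature(sig, file.path(out_dir, "signature.tsv"))
    write.table(screen, file.path(out_dir, "screen.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_json(c(report, list(provenance = .provenance(config))),
                file.path(out_dir, "train_report.json"))
  }
  list(signature = sig, screen = screen, report = report)
}

#' Validate a signature on a cohort and write a report
#'
#' Scores the cohort with the signature, derives (or applies) the risk
#' cutoff, and reports the Kaplan-Meier split, log-rank test, univariate
#' and multivariate Cox fits and the time-dependent ROC AUC at the
#' configured horizon.
#'
#' @param expr expression matrix, genes x samples.
#' @param clinical clinical table (`sample_id`, `os_time`, `os_event`,
#'   optional covariates).
#' @param sig an `irgp_signature` (default: the packaged 41-pair signature).
#' @param config an [irgp_config()]; supplies the ROC horizon.
#' @param cutoff optional fixed cutoff (skips the tdROC derivation).
#' @param covariates clinical columns for the multivariate Cox model.
#' @param out_dir optional directory; when given, writes `risk.tsv`,
#'   `cox_univariate.tsv`, `cox_multivariate.tsv` (when fitted),
#'   `km_curves.tsv` and `validate_report.json`.
#' @param allow_missing passed to [compute_irgpi()].
#' @return the [validate_signature()] result list, extended with `auc`
#'   (tdROC AUC at the horizon) and `report`.
#' @export
run_validate <- function(expr, clinical, sig = default_signature(),
                         config = irgp_config(), cutoff = NULL,
                         covariates = character(0), out_dir = NULL,
                         allow_missing = FALSE) {
  val <- validate_signature(expr, clinical, sig, cutoff = cutoff,
                            horizon = config$horizon,
                            covariates = covariates,
                            allow_missing = allow_missing)
  if (is.null(val$roc)) {
    al <- align_cohort(expr, clinical)
    val$roc <- td_roc(val$risk$irgpi, al$clinical$os_time,
                      al$clinical$os_event, config$horizon)
  }
  val$auc <- val$roc$auc
  val$report <- list(n_samples = nrow(val$risk),
                     n_low = sum(val$risk$group == "low"),
                     n_high = sum(val$risk$group == "high"),
                     cutoff = val$cutoff,
                     logrank_chi2 = val$logrank$chi2,
                     logrank_p = val$logrank$p,
                     tdroc_auc = val$auc,
                     horizon = config$horizon)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(val$risk, file.path(out_dir, "risk.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(val$cox_uni$table, file.path(out_dir, "cox_univariate.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(val$cox_multi))
      write.table(val$cox_multi$table,
                  file.path(out_dir, "cox_multivariate.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    km_tab <- do.call(rbind, lapply(names(val$km), function(g)
      cbind(group = g, val$km[[g]])))
    write.table(km_tab, file.path(out_dir, "km_curves.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .write_json(c(val$report, list(provenance = .provenance(config))),
                file.path(out_dir, "validate_report.json"))
  }
  val
}
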