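#' Compute the gene-pair index (IRGPI) risk score
#'
#' The score of a sample is the sum, over the signature's rows, of the
#' coefficient times the indicator that `gene1` expression strictly exceeds
#' `gene2` expression in that sample. The pair direction printed in the
#' signature is used as-is. Because only within-sample orderings enter, the
#' score is invariant to any strictly increasing transform of the expression
#' values, and it is additive over any partition of the signature's rows.
#'
#' @param expr numeric matrix, genes x samples (a single named numeric
#'   vector is accepted as a one-sample profile).
#' @param sig an `irgp_signature` (default: the packaged 41-pair signature).
#' @param allow_missing if TRUE, signature pairs touching a gene absent from
#'   `expr` are dropped with a warning naming each pair (this changes the
#'   score scale — no renormalisation is applied); if FALSE (default),
#'   missing genes are an error.
#' @return named numeric vector of scores, one per sample.
#' @export
compute_irgpi <- function(expr, sig = default_signature(),
                          allow_missing = FALSE) {
  if (is.null(dim(expr))) {
    expr <- matrix(expr, ncol = 1L,
                   dimnames = list(names(expr), "sample_1"))
  }
  if (nrow(sig) == 0L) stop("empty signature")
  need <- unique(c(sig$gene1, sig$gene2))
  missing <- setdiff(need, rownames(expr))
  if (length(missing)) {
    if (!allow_missing)
      stop("signature gene(s) absent from expression matrix: ",
           paste(missing, collapse = ", "))
    drop <- sig$gene1 %in% missing | sig$gene2 %in% missing
    warning("dropping ", sum(drop), " signature pair(s) with missing genes: ",
            paste(paste(sig$gene1[drop], sig$gene2[drop], sep = "|"),
                  collapse = ", "))
    sig <- sig[!drop, , drop = FALSE]
    if (nrow(sig) == 0L) stop("no signature pair is scoreable")
  }
  ind <- (expr[sig$gene1, , drop = FALSE] >
            expr[sig$gene2, , drop = FALSE]) + 0
  scores <- as.numeric(crossprod(ind, sig$coefficient))
  names(scores) <- colnames(expr)
  scores
}

#' Assign low/high risk groups at a cutoff
#'
#' Samples scoring strictly above the cutoff are labelled `high`, the rest
#' `low` (so a sample scoring exactly at the cutoff is low-risk).
#'
#' @param scores named numeric vector of IRGPI scores.
#' @param cutoff the threshold.
#' @return data frame of class `risk_profile` with columns `sample_id`,
#'   `irgpi`, `group` (factor low/high) and `cutoff_used`.
#' @export
assign_groups <- function(scores, cutoff) {
  stopifnot(all(is.finite(scores)), is.finite(cutoff))
  grp <- factor(ifelse(scores > cutoff, "high", "low"),
                levels = c("low", "high"))
  structure(data.frame(sample_id = names(scores) %||%
                         paste0("sample_", seq_along(scores)),
                       irgpi = as.numeric(scores), group = grp,
                       cutoff_used = cutoff, stringsAsFactors = FALSE),
            class = c("risk_profile", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a cohort and validate the signature against survival
#'
#' Computes the IRGPI for every sample, derives the risk cutoff from the
#' time-dependent ROC at `horizon` when none is given (Youden-optimal
#' threshold), splits the cohort into low/high risk groups, and reports
#' Kaplan-Meier curves per group, the log-rank test, a univariate Cox fit of
#' the continuous score and, when covariates are named, a multivariate Cox
#' fit of score plus covariates.
#'
#' @param expr numeric matrix, genes x samples.
#' @param clinical data frame with `sample_id`, `os_time`, `os_event` and
#'   optional covariate columns; aligned to `expr` via [align_cohort()].
#' @param sig an `irgp_signature`.
#' @param cutoff optional fixed cutoff; derived from the tdROC when `NULL`.
#' @param horizon ROC evaluation time (same unit as `os_time`), used only
#'   when `cutoff` is `NULL`.
#' @param covariates character vector of clinical column names to include in
#'   the multivariate model.
#' @param allow_missing passed to [compute_irgpi()].
#' @return list with `risk` (a `risk_profile`), `cutoff`, `km` (list of two
#'   curves), `logrank` (chi2, p), `cox_uni`, `cox_multi` (NULL when no
#'   covariates), and `roc` (NULL when the cutoff was supplied).
#' @export
validate_signature <- function(expr, clinical, sig = default_signature(),
                               cutoff = NULL, horizon = NULL,
                               covariates = character(0),
                               allow_missing = FALSE) {
  al <- align_cohort(expr, clinical)
  expr <- al$expr; clinical <- al$clinical
  scores <- compute_irgpi(expr, sig, allow_missing = allow_missing)
  roc <- NULL
  if (is.null(cutoff)) {
    if (is.null(horizon))
      stop("either a cutoff or a tdROC horizon must be given")
    roc <- td_roc(scores, clinical$os_time, clinical$os_event, horizon)
    cutoff <- optimal_cutoff(roc)
  }
  risk <- assign_groups(scores, cutoff)
  if (nlevels(droplevels(risk$group)) < 2L)
    warning("all samples fall on one side of the cutoff")
  km <- km_estimate(clinical$os_time, clinical$os_event, risk$group)
  lr <- if (nlevels(droplevels(risk$group)) == 2L)
    logrank_test(clinical$os_time, clinical$os_event, risk$group)
  else list(chi2 = NA_real_, p = NA_real_, direction = NA_real_)
  uni <- cox_fit(data.frame(irgpi = scores),
                 clinical$os_time, clinical$os_event)
  multi <- NULL
  if (length(covariates)) {
    missing <- setdiff(covariates, names(clinical))
    if (length(missing))
      stop("covariate(s) absent from clinical table: ",
           paste(missing, collapse = ", "))
    covs <- cbind(data.frame(irgpi = scores),
                  clinical[, covariates, drop = FALSE])
    multi <- cox_fit(covs, clinical$os_time, clinical$os_event)
  }
  list(risk = risk, cutoff = cutoff, km = km, logrank = lr,
       cox_uni = uni, cox_multi = multi, roc = roc)
}

#' Build an expression profile realising a chosen set of pair indicators
#'
#' Constructs a single-sample expression profile over the signature's genes
#' in which exactly the pairs named in `active` have `gene1` strictly above
#' `gene2` and every other pair has `gene1` strictly below `gene2`. The
#' orderings are treated as edges of a directed graph over the genes and the
#' values are assigned by longest-path depth; an error is raised when the
#' requested orderings are cyclic and hence unrealisable. Useful for worked
#' examples and for exercising the scoring path with known indicator
#' patterns.
#'
#' @param sig an `irgp_signature`.
#' @param active character vector of `"gene1|gene2"` pair labels whose
#'   indicator should be 1; `"all"` activates every pair, `"none"`
#'   (equivalently `character(0)`) none.
#' @return named numeric vector, one value per signature gene.
#' @export
signature_profile <- function(sig, active = "none") {
  labels <- paste(sig$gene1, sig$gene2, sep = "|")
  if (identical(active, "all")) active <- labels
  if (identical(active, "none")) active <- character(0)
  unknown <- setdiff(active, labels)
  if (length(unknown))
    stop("unknown pair label(s): ", paste(unknown, collapse = ", "))
  genes <- unique(c(sig$gene1, sig$gene2))
  on <- labels %in% active
  # edge from lower to higher gene: active pair => gene2 -> gene1
  from <- ifelse(on, sig$gene2, sig$gene1)
  to <- ifelse(on, sig$gene1, sig$gene2)
  val <- setNames(rep(0, length(genes)), genes)
  for (iter in seq_len(length(genes) + 1L)) {
    changed <- FALSE
    for (e in seq_along(from)) {
      if (val[to[e]] <= val[from[e]]) {
        val[to[e]] <- val[from[e]] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (changed)
    stop("requested pair orderings are cyclic and cannot be realised")
  val
}
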