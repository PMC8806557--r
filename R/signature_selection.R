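#' Construct a gene-pair signature table
#'
#' A signature is a data frame of directed gene pairs and nonzero Cox
#' coefficients. The pair direction is meaningful — the indicator is
#' 1 when `gene1` exceeds `gene2` — so no canonical reordering is applied.
#'
#' @param gene1,gene2 character vectors of gene symbols.
#' @param coefficient numeric, finite and nonzero.
#' @return data frame of class `irgp_signature` with columns `gene1`,
#'   `gene2`, `coefficient`.
#' @export
irgp_signature <- function(gene1, gene2, coefficient) {
  stopifnot(length(gene1) == length(gene2),
            length(gene1) == length(coefficient))
  if (any(gene1 == gene2)) stop("a pair cannot repeat one gene")
  if (any(!is.finite(coefficient)) || any(coefficient == 0))
    stop("coefficients must be finite and nonzero")
  key <- paste(gene1, gene2, sep = "|")
  if (anyDuplicated(key)) stop("duplicate pairs in signature")
  structure(data.frame(gene1 = as.character(gene1),
                       gene2 = as.character(gene2),
                       coefficient = as.numeric(coefficient),
                       stringsAsFactors = FALSE),
            class = c("irgp_signature", "data.frame"))
}

#' The packaged 41-pair melanoma signature
#'
#' The published 41 immune-related gene pairs with their penalised Cox
#' coefficients, shipped with the package as a scoring asset. The coefficient
#' of each pair multiplies the indicator that `gene1` expression strictly
#' exceeds `gene2` expression within a sample.
#'
#' @return an `irgp_signature` with 41 rows.
#' @export
default_signature <- function() {
  path <- system.file("extdata", "table1_signature.tsv", package = "irgpair",
                      mustWork = TRUE)
  read_signature(path)
}

#' Read a signature from tab-delimited text
#'
#' @param path TSV with columns `gene1`, `gene2`, `coefficient`.
#' @return an `irgp_signature`.
#' @export
read_signature <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene1", "gene2", "coefficient")
  if (!all(need %in% names(df)))
    stop("signature file needs columns: ", paste(need, collapse = ", "))
  irgp_signature(df$gene1, df$gene2, df$coefficient)
}

#' Write a signature as tab-delimited text
#'
#' Coefficients are written to 6 significant digits; the write/read round
#' trip reproduces the table.
#'
#' @param sig an `irgp_signature`.
#' @param path output path.
#' @export
export_signature <- function(sig, path) {
  stopifnot(nrow(sig) > 0L)
  out <- data.frame(gene1 = sig$gene1, gene2 = sig$gene2,
                    coefficient = signif(sig$coefficient, 6L))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Univariate survival screen of candidate gene pairs
#'
#' Each pair indicator is tested as a binary covariate against overall
#' survival with the log-rank (Cox score) test; pairs with p below
#' `p_threshold` survive. Pairs whose indicator is constant in the aligned
#' cohort are untestable and skipped with a message giving the count.
#'
#' @param indicators a `pair_indicators` object, columns aligned with
#'   `clinical` rows.
#' @param clinical data frame with `os_time` and `os_event`.
#' @param p_threshold retention threshold on the score-test p-value,
#'   default 0.001.
#' @return data frame with columns `gene1`, `gene2`, `p`, `coef_sign`
#'   (+1 when the pair's 1-group has the higher hazard), sorted by p.
#'   Zero rows (with a warning) when nothing survives.
#' @export
univariate_screen <- function(indicators, clinical, p_threshold = 0.001) {
  z <- indicators$scores
  stopifnot(ncol(z) == nrow(clinical))
  freq <- rowMeans(z)
  testable <- freq > 0 & freq < 1
  if (any(!testable))
    message(sum(!testable), " constant pair(s) skipped in screen")
  if (!any(testable)) {
    warning("no testable pairs")
    return(cbind(indicators$pairs[0, ], p = numeric(0),
                 coef_sign = numeric(0)))
  }
  res <- .logrank_many(z[testable, , drop = FALSE],
                       clinical$os_time, clinical$os_event)
  keep <- which(res$p < p_threshold)
  if (length(keep) == 0L) {
    warning("no pair passed the p < ", p_threshold, " screen")
    return(cbind(indicators$pairs[0, ], p = numeric(0),
                 coef_sign = numeric(0)))
  }
  out <- cbind(indicators$pairs[testable, , drop = FALSE][keep, ],
               p = res$p[keep],
               coef_sign = sign(res$observed - res$expected)[keep])
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' LASSO-penalised Cox selection of a sparse pair signature
#'
#' Fits an L1-penalised Cox model over the screened pair indicators with
#' [glmnet::cv.glmnet()] (partial-likelihood deviance, 10-fold
#' cross-validation by default, folds stratified by event status) and keeps
#' the pairs with nonzero coefficients at the deviance-minimising lambda.
#' The lambda path is glmnet's standard geometric grid of `nlambda` points
#' spanning `lambda_ratio` decades below the smallest lambda that zeroes
#' every coefficient. With the seed fixed the selection is reproducible.
#'
#' @param indicators a `pair_indicators` restricted to screened pairs.
#' @param clinical data frame with `os_time`, `os_event`, rows aligned with
#'   the indicator columns.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @param stratify_folds stratify fold assignment by event status
#'   (default TRUE); set FALSE for plain random folds.
#' @param nlambda,lambda_ratio lambda grid size and min/max ratio.
#' @param refit if TRUE, refit an unpenalised Cox model on the selected
#'   pairs and report its coefficients instead of the penalised ones.
#' @return an `irgp_signature` of the selected pairs.
#' @export
lasso_cox_select <- function(indicators, clinical, folds = 10L, seed = 1L,
                             stratify_folds = TRUE, nlambda = 100L,
                             lambda_ratio = 1e-4, refit = FALSE) {
  z <- indicators$scores
  stopifnot(ncol(z) == nrow(clinical))
  if (nrow(z) < 2L) stop("need at least 2 screened pairs for selection")
  n_events <- sum(clinical$os_event == 1)
  if (folds > n_events) stop("more folds than events")
  x <- t(z)
  y <- survival::Surv(clinical$os_time, clinical$os_event)
  foldid <- .make_folds(clinical$os_event, folds, seed, stratify_folds)
  cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid,
                          nlambda = nlambda, lambda.min.ratio = lambda_ratio,
                          type.measure = "deviance", standardize = FALSE)
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  nz <- which(beta != 0)
  if (length(nz) == 0L)
    stop("LASSO selected no pair at any lambda; ",
         "consider relaxing the screen threshold")
  sel <- indicators$pairs[nz, , drop = FALSE]
  coefs <- beta[nz]
  if (refit) {
    rf <- cox_fit(as.data.frame(x[, nz, drop = FALSE]),
                  clinical$os_time, clinical$os_event)
    coefs <- rf$table$coef
  }
  sig <- irgp_signature(sel$gene1, sel$gene2, coefs)
  attr(sig, "lambda_min") <- cv$lambda.min
  attr(sig, "cv_deviance") <- min(cv$cvm)
  sig
}

# Seeded fold assignment, optionally stratified by event status so each fold
# holds a similar number of events (stabilises CV deviance under censoring).
.make_folds <- function(events, folds, seed, stratify = TRUE) {
  n <- length(events)
  foldid <- integer(n)
  assign_in <- function(idx) {
    k <- length(idx)
    rep_len(seq_len(folds), k)[sample.int(k)]
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  if (stratify) {
    for (lev in unique(events)) {
      idx <- which(events == lev)
      foldid[idx] <- assign_in(idx)
    }
  } else {
    foldid <- assign_in(seq_len(n))
  }
  foldid
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
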