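#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator via [survival::survfit()]. With no censoring the
#' curve equals the empirical survival function.
#'
#' @param times positive survival times.
#' @param events event indicators (1 = event observed, 0 = censored).
#' @param group optional group labels; one curve is returned per level.
#' @return named list of data frames with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (one element named `"all"` when `group`
#'   is `NULL`).
#' @export
km_estimate <- function(times, events, group = NULL) {
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(times))
  if (length(group) != length(times)) stop("group length mismatch")
  if (any(table(group) == 0L)) stop("empty group")
  out <- lapply(split(seq_along(times), group), function(idx) {
    fit <- survival::survfit(
      survival::Surv(times[idx], events[idx]) ~ 1, conf.type = "none")
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv)
  })
  out
}

# Vectorised one-degree-of-freedom log-rank over many binary covariates.
# z: binary matrix (features x samples). Returns per-feature observed and
# expected events in the z=1 group, the hypergeometric variance, chi-square
# and p. This is the score test of a Cox model with Breslow tie handling,
# computed for thousands of candidate pair indicators in one pass.
.logrank_many <- function(z, times, events) {
  stopifnot(is.matrix(z), ncol(z) == length(times),
            length(times) == length(events))
  et <- sort(unique(times[events == 1]))
  if (length(et) == 0L) stop("no events observed; log-rank undefined")
  risk <- outer(times, et, `>=`) + 0           # samples x K at-risk
  evt <- outer(times, et, `==`) * (events == 1) # samples x K events
  n_k <- colSums(risk)
  d_k <- colSums(evt)
  n1 <- z %*% risk                              # features x K
  o1 <- z %*% evt
  frac <- sweep(n1, 2L, n_k, `/`)
  e1 <- sweep(frac, 2L, d_k, `*`)
  vk <- sweep(frac * (1 - frac), 2L,
              d_k * ifelse(n_k > 1, (n_k - d_k) / (n_k - 1), 0), `*`)
  O <- rowSums(o1); E <- rowSums(e1); V <- rowSums(vk)
  chi2 <- ifelse(V > 0, (O - E)^2 / V, NA_real_)
  p <- pchisq(chi2, df = 1L, lower.tail = FALSE)
  data.frame(observed = O, expected = E, variance = V, chi2 = chi2, p = p,
             row.names = rownames(z))
}

#' Two-group log-rank test
#'
#' One-degree-of-freedom log-rank statistic from hypergeometric moments at
#' each distinct event time; identical to the statistic reported by
#' [survival::survdiff()] and to the score test of a binary-covariate Cox
#' model with Breslow tie handling.
#'
#' @param times positive survival times.
#' @param events event indicators in \{0, 1\}.
#' @param group binary labels (two non-empty groups).
#' @return list with `chi2`, `p` and `direction` (+1 when the second level
#'   has more events than expected, i.e. higher hazard).
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("log-rank test needs exactly two groups")
  if (any(table(g) == 0L)) stop("empty group")
  z <- matrix(as.numeric(g == levels(g)[2L]), nrow = 1L)
  res <- .logrank_many(z, times, events)
  list(chi2 = res$chi2, p = res$p,
       direction = sign(res$observed - res$expected))
}

#' Cox proportional-hazards fit with Wald summaries
#'
#' Fits a Cox model by partial-likelihood maximisation
#' (via [survival::coxph()]) and returns a tidy coefficient table with hazard
#' ratios, 95% Wald confidence intervals and p-values. Non-convergence or
#' separation is reported through the `converged` flag rather than an error.
#'
#' @param covariates vector, matrix or data frame of covariates
#'   (samples in rows).
#' @param times positive survival times.
#' @param events event indicators in \{0, 1\}.
#' @param ties `"efron"` (default) or `"breslow"` tie handling.
#' @return object of class `cox_fit`: list with `table` (term, coef, hr,
#'   ci_low, ci_high, p), `loglik`, `score_chi2`, `score_p`, `n`, `n_event`,
#'   `converged`.
#' @export
cox_fit <- function(covariates, times, events, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (is.null(dim(covariates)))
    covariates <- data.frame(covariate = covariates)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(times))
  const <- vapply(covariates, function(x) length(unique(x)) < 2L, logical(1L))
  if (any(const))
    stop("constant covariate(s): ", paste(names(covariates)[const],
                                          collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("converge|infinite|singular|loglik", conditionMessage(w)))
        converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  tab <- data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_low = s$conf.int[, "lower .95"],
    ci_high = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  tab$term <- gsub("`", "", tab$term)
  structure(list(table = tab, loglik = fit$loglik[2L],
                 score_chi2 = unname(s$sctest["test"]),
                 score_p = unname(s$sctest["pvalue"]),
                 n = s$n, n_event = s$nevent, converged = converged),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (n =", x$n, ", events =", x$n_event, ")\n")
  print(x$table, digits = 3)
  if (!x$converged) cat("WARNING: fit did not converge cleanly\n")
  invisible(x)
}

# KM estimate of the censoring distribution G(t); returns a function
# G(t, left) giving the survival probability of the censoring time at t
# (left = TRUE gives the left limit G(t-)).
.censor_km <- function(times, events) {
  fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1,
                           conf.type = "none")
  tt <- fit$time[fit$n.event > 0]
  ss <- fit$surv[fit$n.event > 0]
  function(t, left = FALSE) {
    if (length(tt) == 0L) return(rep(1, length(t)))
    idx <- if (left) findInterval(t, tt, left.open = TRUE)
           else findInterval(t, tt)
    c(1, ss)[idx + 1L]
  }
}

#' Time-dependent ROC curve (cumulative/dynamic, IPCW)
#'
#' Cases are subjects with an observed event by the `horizon`; controls are
#' subjects still under observation beyond it. Subjects censored before the
#' horizon contribute through inverse-probability-of-censoring weights
#' derived from the Kaplan-Meier estimate of the censoring distribution, so
#' the estimator is consistent under independent censoring. Sensitivity and
#' specificity are computed at every unique score threshold and the AUC by
#' the trapezoidal rule; with no censoring this reduces exactly to the
#' empirical ROC of the binary outcome "event by horizon".
#'
#' @param scores numeric marker (higher = predicted higher risk).
#' @param times positive survival times.
#' @param events event indicators in \{0, 1\}.
#' @param horizon evaluation time, within the observed time range.
#' @return object of class `td_roc`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `horizon`.
#' @export
td_roc <- function(scores, times, events, horizon) {
  stopifnot(length(scores) == length(times), length(times) == length(events))
  if (horizon <= min(times) || horizon >= max(times))
    stop("horizon must lie strictly within the observed time range")
  case <- times <= horizon & events == 1
  ctrl <- times > horizon
  if (!any(case)) stop("no cases (events before horizon)")
  if (!any(ctrl)) stop("no controls (subjects beyond horizon)")
  G <- .censor_km(times, events)
  w <- numeric(length(scores))
  w[case] <- 1 / G(times[case], left = TRUE)
  w[ctrl] <- 1 / G(horizon)
  if (any(!is.finite(w[case | ctrl])))
    stop("censoring-distribution weight is infinite at the horizon; ",
         "choose an earlier horizon")
  thr <- sort(unique(scores))
  wc <- w * case
  wk <- w * ctrl
  sens <- vapply(thr, function(c) sum(wc[scores > c]) / sum(wc), numeric(1L))
  spec <- vapply(thr, function(c) sum(wk[scores <= c]) / sum(wk), numeric(1L))
  # trapezoid over (FPR, TPR), closed at (0,0) and (1,1)
  fpr <- c(0, rev(1 - spec), 1)
  tpr <- c(0, rev(sens), 1)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, horizon = horizon),
            class = "td_roc")
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("time-dependent ROC at t = %g: AUC = %.4f (%d thresholds)\n",
              x$horizon, x$auc, length(x$thresholds)))
  invisible(x)
}

#' Youden-optimal threshold of a time-dependent ROC curve
#'
#' Returns the threshold maximising Youden's J = sensitivity + specificity
#' \eqn{- 1}; ties are broken toward the smallest threshold, making the choice
#' deterministic.
#'
#' @param roc a `td_roc` object.
#' @return the optimal cutoff (a single number).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "td_roc"), length(roc$thresholds) > 0L)
  j <- roc$sensitivity + roc$specificity - 1
  roc$thresholds[which.max(j)]
}
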