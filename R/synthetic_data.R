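#' The 22 immune cell types of the standard deconvolution panel
#'
#' Cell-type labels used by the usual 22-type bulk deconvolution signature
#' matrix; the default column set of [generate_fractions()].
#'
#' @return character vector of length 22.
#' @export
cibersort_cell_types <- function() {
  c("B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
    "T cells CD4 naive", "T cells CD4 memory resting",
    "T cells CD4 memory activated", "T cells follicular helper",
    "T cells regulatory (Tregs)", "T cells gamma delta",
    "NK cells resting", "NK cells activated", "Monocytes",
    "Macrophages M0", "Macrophages M1", "Macrophages M2",
    "Dendritic cells resting", "Dendritic cells activated",
    "Mast cells resting", "Mast cells activated",
    "Eosinophils", "Neutrophils")
}

#' Generate a synthetic log-scale expression matrix
#'
#' Gene g in sample s is `mu_g + sigma_g * z` with standard-normal noise,
#' `mu_g ~ Uniform(2, 12)` (log2-intensity-like baselines) and
#' `sigma_g` log-normal with median `mad_spread`, so per-gene variability is
#' heavy-tailed and the cohort contains genes on both sides of the usual
#' MAD > 0.5 variability filter. Deterministic given the seed.
#'
#' @param n_genes,n_samples dimensions (each at least 2).
#' @param seed integer seed.
#' @param mad_spread median of the per-gene noise scale (default 0.5).
#' @return numeric matrix, genes x samples, with gene/sample names and the
#'   generating `mu`/`sigma` attached as attributes.
#' @export
generate_expression <- function(n_genes, n_samples, seed = 1L,
                                mad_spread = 0.5) {
  stopifnot(n_genes >= 2L, n_samples >= 2L)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  mu <- runif(n_genes, 2, 12)
  sigma <- exp(rnorm(n_genes, mean = log(mad_spread), sd = 1))
  m <- mu + sigma * matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
  dimnames(m) <- list(sprintf("g%04d", seq_len(n_genes)),
                      sprintf("s%04d", seq_len(n_samples)))
  attr(m, "mu") <- setNames(mu, rownames(m))
  attr(m, "sigma") <- setNames(sigma, rownames(m))
  m
}

#' Plant a gene-pair signature in a synthetic expression matrix
#'
#' Picks `n_pairs` disjoint gene pairs whose indicators flip between samples
#' — genes that pass the MAD filter and whose baseline means are close on
#' the scale of their combined noise — and assigns them alternating-sign
#' coefficients. These pairs drive survival in [generate_survival()] and are
#' the recovery target in end-to-end selection tests.
#'
#' @param expr matrix from [generate_expression()] (needs the `mu`/`sigma`
#'   attributes).
#' @param n_pairs number of pairs to plant.
#' @param coef_size absolute coefficient value (default 1).
#' @param mad_threshold variability filter the planted genes must pass.
#' @return an `irgp_signature` of planted pairs.
#' @export
plant_signature <- function(expr, n_pairs = 5L, coef_size = 1,
                            mad_threshold = 0.5) {
  eligible <- mad_filter(expr, threshold = mad_threshold)
  if (length(eligible) < 2L * n_pairs)
    stop("not enough variable genes to plant ", n_pairs, " pairs")
  mu <- attr(expr, "mu")[eligible]
  sigma <- attr(expr, "sigma")[eligible]
  ord <- names(sort(mu))
  # consecutive-in-mu disjoint pairs, most 'flippable' first
  cand <- data.frame(a = ord[seq(1L, length(ord) - 1L, by = 2L)],
                     b = ord[seq(2L, length(ord), by = 2L)],
                     stringsAsFactors = FALSE)
  sep <- abs(mu[cand$a] - mu[cand$b]) /
    sqrt(sigma[cand$a]^2 + sigma[cand$b]^2)
  cand <- cand[order(sep), , drop = FALSE][seq_len(n_pairs), , drop = FALSE]
  coefs <- coef_size * rep_len(c(1, -1), n_pairs)
  irgp_signature(cand$a, cand$b, coefs)
}

#' Generate right-censored survival from planted pair indicators
#'
#' Event times follow a Cox model with constant baseline hazard: sample s
#' has hazard `baseline_hazard * exp(eta_s)` where `eta_s` is the planted
#' signature's IRGPI (sum of coefficient x pair indicator). Censoring times
#' are Uniform(0, T_c), independent of the covariates, with `T_c` tuned by
#' bisection so the realised censoring fraction hits `censor_rate` within
#' 0.02. `censor_rate = 0` disables censoring.
#'
#' @param expr expression matrix containing the planted genes.
#' @param planted an `irgp_signature` of planted pairs, or `NULL` for a
#'   null cohort in which survival is independent of expression.
#' @param baseline_hazard constant baseline hazard (> 0), events per time
#'   unit.
#' @param censor_rate target censoring fraction in [0, 1).
#' @param seed integer seed.
#' @return data frame with `sample_id`, `os_time`, `os_event`; the linear
#'   predictor is attached as attribute `eta`.
#' @export
generate_survival <- function(expr, planted = NULL, baseline_hazard = 0.05,
                              censor_rate = 0.3, seed = 1L) {
  stopifnot(baseline_hazard > 0, censor_rate >= 0, censor_rate < 1)
  n <- ncol(expr)
  eta <- if (is.null(planted) || nrow(planted) == 0L) rep(0, n)
         else compute_irgpi(expr, planted)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  t_event <- rexp(n, rate = baseline_hazard * exp(eta))
  if (censor_rate == 0) {
    out <- data.frame(sample_id = colnames(expr), os_time = t_event,
                      os_event = 1, stringsAsFactors = FALSE)
    attr(out, "eta") <- eta
    return(out)
  }
  u <- runif(n)
  frac <- function(tc) mean(t_event > tc * u)
  lo <- min(t_event) / 2; hi <- max(t_event) * 2
  while (frac(hi) > censor_rate) hi <- hi * 2
  tc <- NA_real_
  for (i in seq_len(50L)) {
    mid <- (lo + hi) / 2
    f <- frac(mid)
    if (abs(f - censor_rate) <= 0.02) { tc <- mid; break }
    if (f > censor_rate) lo <- mid else hi <- mid
  }
  if (is.na(tc))
    stop("could not reach censoring rate ", censor_rate,
         " within 50 bisection steps")
  cens <- tc * u
  out <- data.frame(sample_id = colnames(expr),
                    os_time = pmin(t_event, cens),
                    os_event = as.integer(t_event <= cens),
                    stringsAsFactors = FALSE)
  attr(out, "eta") <- eta
  out
}

#' Generate Dirichlet immune-cell fractions with group shifts
#'
#' Each sample's 22 cell fractions are drawn from a Dirichlet distribution;
#' for cell types named in `shifted_types` the concentration parameter is
#' multiplied by `exp(effect)` in the `shift_group` risk group, shifting
#' that type's mean fraction up (positive effect) or down in that group.
#' Rows sum to 1 exactly.
#'
#' @param risk a `risk_profile` (needs `sample_id` and `group`).
#' @param shifted_types named numeric vector of log-concentration effects,
#'   e.g. `c("Macrophages M1" = 1)`.
#' @param seed integer seed.
#' @param base_alpha baseline Dirichlet concentration per type (scalar or
#'   named vector over `cell_types`).
#' @param cell_types cell-type labels (default the 22-type panel).
#' @param shift_group which group receives the shift (default `"high"`).
#' @return numeric matrix, samples x cell types, rows summing to 1.
#' @export
generate_fractions <- function(risk, shifted_types = numeric(0), seed = 1L,
                               base_alpha = 2, cell_types =
                                 cibersort_cell_types(),
                               shift_group = c("high", "low")) {
  shift_group <- match.arg(shift_group)
  stopifnot(all(is.finite(shifted_types)))
  unknown <- setdiff(names(shifted_types), cell_types)
  if (length(unknown))
    stop("unknown cell type(s): ", paste(unknown, collapse = ", "))
  alpha0 <- if (length(base_alpha) == 1L)
    setNames(rep(base_alpha, length(cell_types)), cell_types)
  else base_alpha[cell_types]
  if (any(alpha0 <= 0)) stop("Dirichlet concentrations must be positive")
  alpha1 <- alpha0
  alpha1[names(shifted_types)] <-
    alpha1[names(shifted_types)] * exp(shifted_types)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  n <- nrow(risk)
  m <- matrix(0, n, length(cell_types),
              dimnames = list(risk$sample_id, cell_types))
  for (i in seq_len(n)) {
    a <- if (risk$group[i] == shift_group) alpha1 else alpha0
    g <- rgamma(length(a), shape = a, rate = 1)
    m[i, ] <- g / sum(g)
  }
  m
}

#' Simulate a complete cohort: expression, planted signature, survival
#'
#' Convenience wrapper chaining [generate_expression()],
#' [plant_signature()] and [generate_survival()]; per-stage seeds are
#' derived from the single `seed` by fixed offsets so each stage is
#' independently reproducible.
#'
#' @param n_genes,n_samples cohort dimensions.
#' @param n_planted number of survival-driving pairs (0 for a null cohort).
#' @param seed master seed.
#' @param coef_size planted |coefficient|.
#' @param baseline_hazard,censor_rate passed to [generate_survival()].
#' @param mad_spread passed to [generate_expression()].
#' @return list with `expr`, `clinical`, `truth` (list: `planted`,
#'   `baseline_hazard`, `censor_rate`, `seed`).
#' @export
simulate_cohort <- function(n_genes = 60L, n_samples = 500L, n_planted = 5L,
                            seed = 1L, coef_size = 1,
                            baseline_hazard = 0.05, censor_rate = 0.3,
                            mad_spread = 0.5) {
  expr <- generate_expression(n_genes, n_samples, seed = seed,
                              mad_spread = mad_spread)
  planted <- if (n_planted > 0L)
    plant_signature(expr, n_pairs = n_planted, coef_size = coef_size)
  else NULL
  clinical <- generate_survival(expr, planted,
                                baseline_hazard = baseline_hazard,
                                censor_rate = censor_rate,
                                seed = seed + 1000L)
  list(expr = expr, clinical = clinical,
       truth = list(planted = planted, baseline_hazard = baseline_hazard,
                    censor_rate = censor_rate, seed = seed))
}
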