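test_that("signature constructor enforces its invariants", {
  expect_error(irgp_signature("A", "A", 1), "repeat")
  expect_error(irgp_signature("A", "B", 0), "nonzero")
  expect_error(irgp_signature(c("A", "A"), c("B", "B"), c(1, 2)), "duplicate")
  sig <- irgp_signature(c("A", "B"), c("B", "A"), c(0.5, -0.5))
  expect_s3_class(sig, "irgp_signature")  # flipped pair is a distinct feature
})

test_that("packaged asset has 41 rows and survives a write/read round trip", {
  sig <- default_signature()
  expect_equal(nrow(sig), 41L)
  path <- tempfile(fileext = ".tsv")
  export_signature(sig, path)
  expect_equal(read_signature(path), sig)

  ref <- parse_asset_independently()
  expect_equal(sum(sig$coefficient), sum(ref$coefficient))
})

test_that("univariate screen keeps planted pairs, skips constant ones", {
  sim <- simulate_cohort(n_genes = 40, n_samples = 300, n_planted = 2,
                         seed = 91, coef_size = log(4), censor_rate = 0.3)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  scr <- univariate_screen(ind, sim$clinical)
  expect_true(nrow(scr) >= 1)
  expect_true(all(scr$p < 0.001))
  planted_keys <- paste(pmin(sim$truth$planted$gene1, sim$truth$planted$gene2),
                        pmax(sim$truth$planted$gene1, sim$truth$planted$gene2),
                        sep = "|")
  scr_keys <- paste(scr$gene1, scr$gene2, sep = "|")
  expect_true(all(planted_keys %in% scr_keys))
  # survivors are a subset of the candidates
  expect_true(all(scr_keys %in% rownames(ind$scores)))

  # a constant pair is skipped, not tested
  const <- ind
  const$scores[1, ] <- 1L
  expect_message(univariate_screen(const, sim$clinical), "constant pair")
})

test_that("screen is calibrated under the null", {
  # null cohorts, ~100 candidate pairs: survivors at p < 0.001 stay <= 3
  for (s in c(101, 202, 303)) {
    sim <- simulate_cohort(n_genes = 30, n_samples = 200, n_planted = 0,
                           seed = s, censor_rate = 0.2)
    genes <- mad_filter(sim$expr, threshold = 0.2)
    ind <- build_pair_indicators(sim$expr, genes)
    kept <- remove_constant_pairs(ind)
    kept <- kept[seq_len(min(100L, nrow(kept))), ]
    ind <- subset_pairs(ind, kept)
    ind$scores <- ind$scores[, sim$clinical$sample_id]
    scr <- suppressWarnings(univariate_screen(ind, sim$clinical))
    expect_lte(nrow(scr), 3L)
  }
})

test_that("LASSO selection recovers a single strong pair among noise", {
  sim <- simulate_cohort(n_genes = 50, n_samples = 400, n_planted = 1,
                         seed = 11, coef_size = 1.5, censor_rate = 0.2)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  kept <- remove_constant_pairs(ind)
  ind <- subset_pairs(ind, kept)
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  scr <- univariate_screen(ind, sim$clinical, p_threshold = 0.05)
  sel <- lasso_cox_select(subset_pairs(ind, scr[, c("gene1", "gene2")]),
                          sim$clinical, seed = 11)
  sel_keys <- paste(sel$gene1, sel$gene2, sep = "|")
  planted_key <- paste(pmin(sim$truth$planted$gene1, sim$truth$planted$gene2),
                       pmax(sim$truth$planted$gene1, sim$truth$planted$gene2),
                       sep = "|")
  expect_true(planted_key %in% sel_keys)
  expect_true(all(sel$coefficient != 0))
})

test_that("LASSO selection is reproducible for a fixed seed", {
  sim <- simulate_cohort(n_genes = 30, n_samples = 250, n_planted = 2,
                         seed = 5, censor_rate = 0.3)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  ind <- subset_pairs(ind, remove_constant_pairs(ind))
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  scr <- univariate_screen(ind, sim$clinical, p_threshold = 0.05)
  ind2 <- subset_pairs(ind, scr[, c("gene1", "gene2")])
  a <- lasso_cox_select(ind2, sim$clinical, seed = 99)
  b <- lasso_cox_select(ind2, sim$clinical, seed = 99)
  expect_identical(a, b)
})

test_that("the penalised path shrinks to the empty model at its head", {
  sim <- simulate_cohort(n_genes = 30, n_samples = 250, n_planted = 2,
                         seed = 6, censor_rate = 0.3)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  ind <- subset_pairs(ind, remove_constant_pairs(ind))
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  fit <- glmnet::glmnet(t(ind$scores),
                        survival::Surv(sim$clinical$os_time,
                                       sim$clinical$os_event),
                        family = "cox", nlambda = 50)
  expect_equal(sum(abs(fit$beta[, 1])), 0)
  # and the number of active pairs grows as lambda falls
  expect_true(max(fit$df) > 0)
})

test_that("duplicated predictors leave the achievable deviance unchanged", {
  sim <- simulate_cohort(n_genes = 20, n_samples = 200, n_planted = 1,
                         seed = 13, censor_rate = 0.2)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  ind <- subset_pairs(ind, remove_constant_pairs(ind))
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  x <- t(ind$scores)
  y <- survival::Surv(sim$clinical$os_time, sim$clinical$os_event)
  f1 <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE)
  f2 <- glmnet::glmnet(cbind(x, x), y, family = "cox", standardize = FALSE,
                       lambda = f1$lambda)
  expect_equal(f2$dev.ratio, f1$dev.ratio, tolerance = 1e-4)
})

test_that("selection refuses impossible fold counts", {
  sim <- simulate_cohort(n_genes = 20, n_samples = 40, n_planted = 1,
                         seed = 14, censor_rate = 0.9)
  genes <- mad_filter(sim$expr, threshold = 0.5)
  ind <- build_pair_indicators(sim$expr, genes)
  ind <- subset_pairs(ind, remove_constant_pairs(ind))
  ind$scores <- ind$scores[, sim$clinical$sample_id]
  expect_error(lasso_cox_select(ind, sim$clinical, folds = 1000L),
               "folds")
})
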