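test_that("Wilcoxon comparison reproduces the exact worked case", {
  frac <- matrix(c(1, 2, 3, 4, 5, 6) / 21, ncol = 1,
                 dimnames = list(paste0("s", 1:6), "T cells CD8"))
  frac <- cbind(frac, 1 - frac)
  colnames(frac)[2] <- "Other"
  risk <- assign_groups(setNames(c(-1, -1, -1, 1, 1, 1), paste0("s", 1:6)), 0)
  res <- compare_fractions(frac, risk)
  row <- res[res$cell_type == "T cells CD8", ]
  expect_equal(row$p, 2 / choose(6, 3))  # = 0.1, fully separated groups
  expect_equal(row$direction, "higher_in_high")
})

test_that("Wilcoxon comparison is symmetric and label-swap invariant", {
  set.seed(81)
  frac <- matrix(runif(40), 20, 2,
                 dimnames = list(paste0("s", 1:20), c("A", "B")))
  frac <- normalize_fractions(frac)
  risk1 <- assign_groups(setNames(rep(c(-1, 1), 10), paste0("s", 1:20)), 0)
  risk2 <- assign_groups(setNames(rep(c(1, -1), 10), paste0("s", 1:20)), 0)
  r1 <- compare_fractions(frac, risk1)
  r2 <- compare_fractions(frac, risk2)
  expect_equal(r1$p[order(r1$cell_type)], r2$p[order(r2$cell_type)])

  # mirrored samples: identical distributions give p = 1 under the exact test
  mirror <- rbind(frac[1:5, ], frac[1:5, ])
  rownames(mirror) <- paste0("m", 1:10)
  riskm <- assign_groups(setNames(rep(c(-1, 1), each = 5), paste0("m", 1:10)), 0)
  rm <- compare_fractions(mirror, riskm)
  expect_true(all(rm$p == 1))
})

test_that("a planted fraction shift is detected with the right direction", {
  hits <- 0
  for (s in 1:20) {
    risk <- assign_groups(
      setNames(rep(c(-1, 1), each = 100), sprintf("p%03d", 1:200)), 0)
    frac <- generate_fractions(risk, c("Macrophages M1" = 1), seed = s,
                               shift_group = "low")
    res <- compare_fractions(frac, risk)
    m1 <- res[res$cell_type == "Macrophages M1", ]
    if (m1$p < 0.05 && m1$direction == "higher_in_low") hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of seeded runs
})

test_that("hypergeometric enrichment matches the closed-form tail", {
  universe <- paste0("g", 1:10)
  sets <- list(S = paste0("g", 1:5), Tiny = c("g9", "g10"))
  query <- paste0("g", 1:4)
  res <- hypergeom_enrich(query, universe, sets)
  expect_equal(res$p[res$set_name == "S"], 5 / 210)
  expect_equal(res$p[res$set_name == "Tiny"], 1)  # overlap 0 boundary
  expect_true(all(res$fdr >= res$p - 1e-12))
  expect_error(hypergeom_enrich(query, character(0), sets), "universe")
  expect_error(hypergeom_enrich("zz", universe, sets), "universe")
})

test_that("hypergeometric p falls monotonically with overlap", {
  N <- 50; setsize <- 10; q <- 12
  p <- vapply(0:10, function(k)
    phyper(k - 1, setsize, N - setsize, q, lower.tail = FALSE), numeric(1))
  universe <- paste0("u", 1:N)
  s <- universe[1:setsize]
  for (k in c(2, 5, 8)) {
    query <- c(s[1:k], universe[(setsize + 1):(setsize + q - k)])
    res <- hypergeom_enrich(query, universe, list(S = s))
    expect_equal(res$p, p[k + 1])
  }
  expect_true(all(diff(p) < 0))
})

test_that("GSEA enrichment score agrees with a brute-force running sum", {
  stats <- setNames(c(5, 4, 3, 2, 1), paste0("g", 1:5))
  sets <- list(head2 = c("g1", "g2"), spread = c("g2", "g5"))
  res <- preranked_gsea(stats, sets, n_perm = 200, seed = 1)
  expect_equal(res$es[res$set_name == "head2"], 1.0)
  for (nm in names(sets)) {
    expect_equal(res$es[res$set_name == nm], brute_es(stats, sets[[nm]]))
  }
  set.seed(82)
  for (i in 1:5) {
    st <- setNames(rnorm(12), paste0("r", 1:12))
    set_g <- sample(names(st), 4)
    r <- suppressWarnings(preranked_gsea(st, list(x = set_g),
                                         n_perm = 50, seed = i))
    expect_equal(r$es, brute_es(st, set_g))
    expect_true(abs(r$es) <= 1)
  }
})

test_that("GSEA agrees with the fgsea reference statistic", {
  skip_if_not_installed("fgsea")
  set.seed(83)
  st <- setNames(sort(rnorm(40), decreasing = TRUE), paste0("g", 1:40))
  set_g <- sample(names(st), 8)
  ours <- suppressWarnings(
    preranked_gsea(st, list(s = set_g), n_perm = 10, seed = 1))$es
  ref <- fgsea::calcGseaStat(st, selectedStats = which(names(st) %in% set_g),
                             gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("GSEA permutation p is calibrated under the null and reproducible", {
  set.seed(84)
  st <- setNames(rnorm(50), paste0("n", 1:50))
  sets <- list(rand = sample(names(st), 10))
  r1 <- preranked_gsea(st, sets, n_perm = 500, seed = 7)
  r2 <- preranked_gsea(st, sets, n_perm = 500, seed = 7)
  expect_identical(r1, r2)
  expect_gt(r1$p, 0.01)  # a random set should not look enriched

  expect_warning(preranked_gsea(st, list(small = "n1", ok = sets$rand),
                                n_perm = 10, seed = 1),
                 "skipping")
})

test_that("log2 fold-change ranking matches direct computation", {
  m <- rbind(up = c(1, 1, 2, 2), flat = c(3, 3, 3, 3))
  colnames(m) <- paste0("s", 1:4)
  risk <- assign_groups(setNames(c(-1, -1, 1, 1), paste0("s", 1:4)), 0)
  fc <- rank_genes_by_logfc(m, risk)
  expect_equal(unname(fc["up"]), 1.0, tolerance = 1e-6)
  expect_equal(unname(fc["flat"]), 0, tolerance = 1e-6)

  # log-scale mode returns the mean difference
  fc_log <- rank_genes_by_logfc(m, risk, log_scale = TRUE)
  expect_equal(unname(fc_log["up"]), 1.0)

  set.seed(85)
  r <- matrix(abs(rnorm(60)) + 0.5, 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  riskr <- assign_groups(setNames(rnorm(10), paste0("s", 1:10)), 0)
  fcr <- rank_genes_by_logfc(r, riskr)
  grp <- riskr$group[match(colnames(r), riskr$sample_id)]
  for (g in rownames(r)) {
    expect_equal(unname(fcr[g]),
                 log2((mean(r[g, grp == "high"]) + 1e-9) /
                        (mean(r[g, grp == "low"]) + 1e-9)))
  }
})

test_that("GMT parsing and fraction-table reading behave to contract", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tg1\tg2\tg2\tg3",
               "SET_B\tna\tg4\tg5"), gmt)
  sets <- read_gmt(gmt)
  expect_equal(sets$SET_A, c("g1", "g2", "g3"))  # deduplicated
  expect_equal(length(sets), 2L)

  ft <- tempfile(fileext = ".tsv")
  df <- data.frame(Mixture = c("s1", "s2"),
                   `B cells naive` = c(0.4, 0.2),
                   Monocytes = c(0.6, 0.6),
                   `P-value` = c(0.01, 0.5),
                   RMSE = c(0.3, 0.4), check.names = FALSE)
  write.table(df, ft, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_fractions(ft)
  expect_equal(colnames(m), c("B cells naive", "Monocytes"))
  expect_equal(unname(rowSums(m)), c(1, 1))
  m2 <- read_fractions(ft, max_deconv_p = 0.05)
  expect_equal(rownames(m2), "s1")
})
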