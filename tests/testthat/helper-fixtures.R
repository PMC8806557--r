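# Small in-code fixtures shared across test files.

tiny_expr <- function() {
  m <- matrix(c(5, 1, 2,
                3, 4, 6,
                1, 2, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  m
}

write_tsv_fixture <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  write.table(df, path, sep = if (ext == ".csv") "," else "\t",
              quote = FALSE, row.names = FALSE)
  path
}

# independent parse of the packaged signature asset, bypassing the package's
# reader: plain read.delim on the installed file
parse_asset_independently <- function() {
  path <- system.file("extdata", "table1_signature.tsv", package = "irgpair")
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

# rank-sum AUC of scores for binary labels (1 = case), ties counted 1/2
rank_auc <- function(scores, is_case) {
  r <- rank(scores)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# brute-force weighted running-sum enrichment score
brute_es <- function(stats, set_genes, weight = 1) {
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  hit <- names(s) %in% set_genes
  w <- abs(s)^weight
  run <- 0; best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) w[i] / sum(w[hit]) else -1 / sum(!hit)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}
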