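#' Read an immune-cell fraction table (CIBERSORT export dialect)
#'
#' Samples in rows, cell types in columns. The bookkeeping columns CIBERSORT
#' appends (`P-value`, `Correlation`, `RMSE`, and variants) are recognised
#' and set aside; `max_deconv_p` optionally drops samples whose
#' deconvolution p-value exceeds it. Fractions are renormalised to sum to 1
#' per sample.
#'
#' @param path delimited text file, first column sample IDs.
#' @param max_deconv_p optional filter on the deconvolution p-value column.
#' @param delimiter field separator, inferred from the extension by default.
#' @return numeric matrix, samples x cell types, rows summing to 1.
#' @export
read_fractions <- function(path, max_deconv_p = NULL, delimiter = NULL) {
  sep <- .delim_for(path, delimiter)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  meta <- grepl("^(p[. -]?value|correlation|rmse|absolute score)",
                names(df), ignore.case = TRUE)
  pcol <- grep("^p[. -]?value", names(df), ignore.case = TRUE)
  if (!is.null(max_deconv_p)) {
    if (length(pcol) == 0L)
      stop("no deconvolution p-value column to filter on")
    keep <- df[[pcol[1L]]] <= max_deconv_p
    df <- df[keep, , drop = FALSE]; ids <- ids[keep]
  }
  m <- as.matrix(df[, !meta, drop = FALSE])
  rownames(m) <- ids
  normalize_fractions(m)
}

#' Renormalise a fraction matrix so each sample sums to 1
#'
#' @param fractions non-negative matrix, samples x cell types.
#' @return matrix with rows summing to 1 (within 1e-6).
#' @export
normalize_fractions <- function(fractions) {
  if (any(fractions < 0)) stop("cell fractions must be non-negative")
  rs <- rowSums(fractions)
  if (any(rs == 0)) stop("sample with all-zero fractions")
  sweep(fractions, 1L, rs, `/`)
}

#' Compare immune-cell fractions between risk groups
#'
#' Two-sided Wilcoxon rank-sum test per cell type between the low- and
#' high-risk groups ([stats::wilcox.test()]: exact when both groups are
#' small and tie-free, normal approximation with tie correction otherwise),
#' with Benjamini-Hochberg adjustment across cell types.
#'
#' @param fractions numeric matrix, samples x cell types.
#' @param risk a `risk_profile` (or data frame with `sample_id`, `group`).
#' @return data frame with `cell_type`, `median_low`, `median_high`,
#'   `direction` (`"higher_in_high"`/`"higher_in_low"`/`"equal"`, by median),
#'   `p`, `fdr`, ordered by p.
#' @export
compare_fractions <- function(fractions, risk) {
  shared <- intersect(rownames(fractions), risk$sample_id)
  if (length(shared) < 4L) stop("too few samples shared with the risk table")
  grp <- risk$group[match(shared, risk$sample_id)]
  m <- fractions[shared, , drop = FALSE]
  if (min(table(grp)) < 2L) stop("need at least 2 samples per risk group")
  res <- lapply(colnames(m), function(ct) {
    lo <- m[grp == "low", ct]; hi <- m[grp == "high", ct]
    p <- suppressWarnings(wilcox.test(lo, hi, exact = NULL)$p.value)
    ml <- median(lo); mh <- median(hi)
    data.frame(cell_type = ct, median_low = ml, median_high = mh,
               direction = if (mh > ml) "higher_in_high"
                           else if (mh < ml) "higher_in_low" else "equal",
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Members are deduplicated; duplicate set names are an error.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", which(bad)[1L])
  nm <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) stop("duplicate gene-set names in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  sets
}

#' Hypergeometric over-representation test
#'
#' One-sided hypergeometric tail probability P(X >= overlap) of each gene
#' set's overlap with the query, all sets first intersected with the
#' universe; Benjamini-Hochberg adjustment across sets.
#'
#' @param query character vector of genes of interest (must lie in the
#'   universe).
#' @param universe character vector: all genes that could have been selected.
#' @param sets named list of gene sets.
#' @return data frame with `set_name`, `set_size` (in-universe), `overlap`,
#'   `p`, `fdr`, ordered by p.
#' @export
hypergeom_enrich <- function(query, universe, sets) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must lie in the universe")
  N <- length(universe); q <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- phyper(k - 1L, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score of one set
# against a ranked list. stats must be sorted decreasing; hit increments are
# proportional to |stat|^weight, miss decrements uniform. Returns the
# maximum-deviation ES (signed).
.gsea_es <- function(stat_sorted, in_set, weight = 1) {
  n <- length(stat_sorted)
  nh <- sum(in_set)
  w <- abs(stat_sorted)^weight
  hit_sum <- sum(w[in_set])
  if (hit_sum == 0) hit_sum <- 1   # all-zero stats: fall back to uniform
  inc <- ifelse(in_set, w / hit_sum, -1 / (n - nh))
  run <- cumsum(inc)
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment (GSEA) with gene-label permutations
#'
#' Computes, per gene set, the classic weighted Kolmogorov-Smirnov
#' enrichment score: a running sum over the ranked list that rises by
#' \eqn{|s|^{weight}} (normalised) at set members and falls uniformly
#' elsewhere, with ES the maximum deviation from zero. Significance is
#' assessed by gene-label permutation preserving the set size: the p-value
#' is the fraction of permuted scores of the same sign at least as extreme,
#' and NES divides the ES by the mean magnitude of same-sign permuted
#' scores. FDR is Benjamini-Hochberg across sets. Sets with fewer than 2
#' members in the list are skipped with a warning.
#'
#' @param stats named numeric vector (e.g. log2 fold changes), unique names.
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (default 10000).
#' @param weight exponent on |stat| for hit increments (default 1).
#' @param seed integer seed for the permutations.
#' @return data frame with `set_name`, `size`, `es`, `nes`, `p`, `fdr`,
#'   ordered by p.
#' @export
preranked_gsea <- function(stats, sets, n_perm = 10000L, weight = 1,
                           seed = 1L) {
  if (anyDuplicated(names(stats))) stop("ranked list has duplicate genes")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  genes <- names(s)
  n <- length(s)
  sizes <- vapply(sets, function(g) sum(genes %in% g), integer(1L))
  skip <- sizes < 2L
  if (any(skip))
    warning("skipping ", sum(skip), " set(s) with < 2 genes in the list: ",
            paste(names(sets)[skip], collapse = ", "))
  sets <- sets[!skip]; sizes <- sizes[!skip]
  if (length(sets) == 0L) stop("no analysable gene set")
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  perm_cache <- new.env()
  res <- lapply(names(sets), function(nm) {
    in_set <- genes %in% sets[[nm]]
    es <- .gsea_es(s, in_set, weight)
    k <- as.character(sum(in_set))
    if (is.null(perm_cache[[k]])) {
      perm_cache[[k]] <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n, sum(in_set))
        flag <- logical(n); flag[idx] <- TRUE
        .gsea_es(s, flag, weight)
      }, numeric(1L))
    }
    null_es <- perm_cache[[k]]
    same <- null_es[sign(null_es) == sign(es)]
    p <- (sum(abs(same) >= abs(es)) + 1) / (length(same) + 1)
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    data.frame(set_name = nm, size = sum(in_set), es = es, nes = nes, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank genes by log2 fold change between risk groups
#'
#' On linear-scale data, per gene: log2((mean_high + c) / (mean_low + c))
#' with pseudo-count `c`; when `log_scale = TRUE` the data are taken as
#' already log2 and the plain mean difference (high minus low) is returned.
#'
#' @param expr numeric matrix, genes x samples.
#' @param risk a `risk_profile` covering the samples.
#' @param log_scale is the matrix already on a log2 scale?
#' @param pseudo_count stabiliser for linear-scale ratios.
#' @return named numeric vector of per-gene statistics (unsorted).
#' @export
rank_genes_by_logfc <- function(expr, risk, log_scale = FALSE,
                                pseudo_count = 1e-9) {
  shared <- intersect(colnames(expr), risk$sample_id)
  grp <- risk$group[match(shared, risk$sample_id)]
  if (!all(c("low", "high") %in% grp)) stop("both risk groups must be present")
  m <- expr[, shared, drop = FALSE]
  mh <- rowMeans(m[, grp == "high", drop = FALSE])
  ml <- rowMeans(m[, grp == "low", drop = FALSE])
  if (log_scale) mh - ml
  else log2((mh + pseudo_count) / (ml + pseudo_count))
}
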