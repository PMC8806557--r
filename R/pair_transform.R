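#' Genes shared by every cohort and an immune-gene list
#'
#' Returns, sorted lexicographically, the genes that appear in the supplied
#' immune-related gene list and in the rows of every expression matrix.
#' Restricting pair construction to this intersection guarantees that any
#' signature built on one cohort can be scored on the others.
#'
#' @param expr_list list of expression matrices (genes x samples).
#' @param immune_genes character vector of immune-related gene symbols.
#' @return sorted character vector of shared genes.
#' @export
intersect_gene_lists <- function(expr_list, immune_genes) {
  if (is.matrix(expr_list)) expr_list <- list(expr_list)
  stopifnot(length(expr_list) >= 1L, length(immune_genes) >= 1L)
  shared <- Reduce(intersect, lapply(expr_list, rownames), unique(immune_genes))
  if (length(shared) == 0L)
    stop("no immune gene is present in every cohort; ",
         "check gene identifier conventions (symbols vs probes/Ensembl)")
  sort(shared)
}

#' Filter genes by median absolute deviation
#'
#' Keeps genes whose MAD across samples strictly exceeds `threshold`. The MAD
#' is unscaled by default (`scale_constant = 1`); pass 1.4826 for the usual
#' normal-consistency scaling.
#'
#' @param expr numeric matrix, genes x samples.
#' @param genes genes to consider; defaults to all rows.
#' @param threshold retention threshold, default 0.5.
#' @param scale_constant multiplier applied to the raw MAD.
#' @return character vector of retained genes, in input order.
#' @export
mad_filter <- function(expr, genes = rownames(expr), threshold = 0.5,
                       scale_constant = 1.0) {
  stopifnot(threshold >= 0, all(genes %in% rownames(expr)))
  if (ncol(expr) < 2L) stop("MAD filter needs at least 2 samples")
  sub <- expr[genes, , drop = FALSE]
  med <- apply(sub, 1L, median)
  mads <- apply(abs(sub - med), 1L, median) * scale_constant
  genes[mads > threshold]
}

.canonical_pairs <- function(genes) {
  genes <- sort(unique(genes))
  cmb <- combn(genes, 2L)
  data.frame(gene1 = cmb[1L, ], gene2 = cmb[2L, ], stringsAsFactors = FALSE)
}

.pair_names <- function(pairs) paste(pairs$gene1, pairs$gene2, sep = "|")

#' Build binary gene-pair indicator features
#'
#' For every unordered pair of `genes` (canonical lexicographic direction,
#' gene1 < gene2) and every sample, the indicator is 1 when the first gene's
#' expression strictly exceeds the second's and 0 otherwise — ties score 0.
#' The indicator depends only on the within-sample ordering of the two genes,
#' so it is invariant to any strictly increasing transform of the expression
#' scale (log, quantile, scaling), which is what makes pair features portable
#' across platforms.
#'
#' @param expr numeric matrix, genes x samples.
#' @param genes character vector, at least 2, all present in `expr`.
#' @return object of class `pair_indicators`: a list with `pairs` (data frame
#'   of `gene1`, `gene2`) and `scores` (binary matrix, pairs x samples, row
#'   names `"gene1|gene2"`).
#' @export
build_pair_indicators <- function(expr, genes) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing))
    stop("gene(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (length(unique(genes)) < 2L) stop("need at least 2 distinct genes")
  pairs <- .canonical_pairs(genes)
  a <- expr[pairs$gene1, , drop = FALSE]
  b <- expr[pairs$gene2, , drop = FALSE]
  scores <- (a > b) + 0L
  dimnames(scores) <- list(.pair_names(pairs), colnames(expr))
  structure(list(pairs = pairs, scores = scores), class = "pair_indicators")
}

#' @export
print.pair_indicators <- function(x, ...) {
  cat("pair_indicators:", nrow(x$scores), "pairs x",
      ncol(x$scores), "samples\n")
  invisible(x)
}

#' Drop gene pairs with (near-)constant indicators
#'
#' A pair is kept only if, in every cohort, its frequency of 1s lies strictly
#' inside `[min_freq, 1 - min_freq]`. With the default `min_freq = 0` this
#' removes exactly the pairs that are constant (all 0 or all 1) in at least
#' one cohort; a positive `min_freq` additionally drops rarely-flipping pairs,
#' which stabilises downstream model selection on small cohorts.
#'
#' @param indicator_list one `pair_indicators` object per cohort (a single
#'   object is accepted); all must share an identical pair list.
#' @param min_freq minimum within-cohort frequency of the minority value.
#' @return data frame of retained pairs (`gene1`, `gene2`).
#' @export
remove_constant_pairs <- function(indicator_list, min_freq = 0) {
  if (inherits(indicator_list, "pair_indicators"))
    indicator_list <- list(indicator_list)
  stopifnot(length(indicator_list) >= 1L, min_freq >= 0, min_freq < 0.5)
  ref <- rownames(indicator_list[[1L]]$scores)
  for (ind in indicator_list[-1L]) {
    if (!identical(rownames(ind$scores), ref))
      stop("cohorts carry different pair lists; build them from one gene set")
  }
  keep <- rep(TRUE, length(ref))
  for (ind in indicator_list) {
    freq <- rowMeans(ind$scores)
    keep <- keep & freq > min_freq & freq < 1 - min_freq
  }
  indicator_list[[1L]]$pairs[keep, , drop = FALSE]
}

#' Subset a pair-indicator matrix to a pair list
#'
#' @param indicators a `pair_indicators` object.
#' @param pairs data frame with `gene1`, `gene2` (subset of the object's pairs).
#' @return a `pair_indicators` object restricted to `pairs`, in their order.
#' @export
subset_pairs <- function(indicators, pairs) {
  want <- .pair_names(pairs)
  missing <- setdiff(want, rownames(indicators$scores))
  if (length(missing))
    stop("pair(s) not present in indicator matrix: ",
         paste(missing, collapse = ", "))
  structure(list(pairs = pairs,
                 scores = indicators$scores[want, , drop = FALSE]),
            class = "pair_indicators")
}

#' Write pair indicators as tab-delimited text
#'
#' Columns are `gene1`, `gene2`, then one 0/1 column per sample.
#'
#' @param indicators a `pair_indicators` object.
#' @param path output path.
#' @export
write_pair_indicators <- function(indicators, path) {
  df <- cbind(indicators$pairs,
              as.data.frame(indicators$scores, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
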