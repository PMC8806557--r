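#' @importFrom stats median setNames complete.cases rexp rgamma rnorm runif
#'   pchisq phyper p.adjust wilcox.test quantile coef sd
#' @importFrom utils read.delim write.table head combn
NULL

.delim_for <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene-expression matrix from delimited text
#'
#' Expects genes in rows and samples in columns, with the first row holding
#' sample identifiers and the first column gene (or probe) identifiers.
#' The delimiter is inferred from the file extension (`.csv` gives comma,
#' anything else tab) unless given explicitly.
#'
#' Rows containing any missing value are dropped with a warning that reports
#' the count; duplicated gene identifiers are collapsed by averaging their
#' rows, the same rule used for probe-to-gene collapsing.
#'
#' @param path path to a delimited text file.
#' @param delimiter field separator; `NULL` (default) infers it from the
#'   extension.
#' @return a numeric matrix, genes x samples, with unique non-empty dimnames.
#' @seealso [collapse_probes()] for probe-level matrices.
#' @export
read_expression <- function(path, delimiter = NULL) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("expression file not found: ", path)
  sep <- .delim_for(path, delimiter)
  df <- read.delim(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("malformed header in ", path,
                          ": need an ID column plus at least one sample")
  ids <- as.character(df[[1L]])
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(conv <- as.numeric(vals[[j]]))
      bad <- which(is.na(conv) & !is.na(vals[[j]]) &
                     !vals[[j]] %in% c("", "NA"))
      if (length(bad)) {
        stop("non-numeric expression value at row ", bad[1L] + 1L,
             ", column '", colnames(vals)[j], "' of ", path)
      }
      vals[[j]] <- conv
    }
  }
  m <- as.matrix(vals)
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m))) stop("duplicate sample IDs in ", path)
  keep <- complete.cases(m)
  if (any(!keep)) {
    warning(sum(!keep), " gene row(s) with missing values dropped")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("no usable expression rows in ", path)
  .average_duplicate_rows(m)
}

.average_duplicate_rows <- function(m) {
  if (!anyDuplicated(rownames(m))) return(m)
  ids <- rownames(m)
  out <- rowsum(m, group = ids, reorder = FALSE) /
    as.vector(table(factor(ids, levels = unique(ids))))
  out
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [read_expression()]; the round trip is exact for finite values
#' because numbers are written with full precision.
#'
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse a probe-level matrix to gene symbols
#'
#' Each gene's expression is the arithmetic mean, per sample, of all probes
#' annotated to it. Probes absent from the map are dropped with a warning
#' giving the count. Applying the function a second time (with probe IDs
#' equal to gene symbols) is a no-op.
#'
#' @param probe_matrix numeric matrix, probes x samples.
#' @param probe_map data frame with columns `probe_id` and `gene_symbol`;
#'   many probes may map to one symbol, but each probe maps to one symbol.
#' @return numeric matrix, genes x samples.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  stopifnot(is.matrix(probe_matrix),
            all(c("probe_id", "gene_symbol") %in% names(probe_map)))
  map <- probe_map[!is.na(probe_map$gene_symbol) &
                     nzchar(probe_map$gene_symbol), , drop = FALSE]
  if (anyDuplicated(map$probe_id))
    stop("probe map assigns some probe to more than one symbol")
  idx <- match(rownames(probe_matrix), map$probe_id)
  unmapped <- is.na(idx)
  if (all(unmapped)) stop("no probe in the matrix is present in the map")
  if (any(unmapped))
    warning(sum(unmapped), " unmapped probe(s) dropped")
  m <- probe_matrix[!unmapped, , drop = FALSE]
  rownames(m) <- map$gene_symbol[idx[!unmapped]]
  .average_duplicate_rows(m)
}

#' Read a clinical table with overall-survival columns
#'
#' Loads a delimited table, renames the configured identifier, time and event
#' columns to `sample_id`, `os_time`, `os_event`, recodes event aliases
#' (e.g. `dead`/`alive`) to 1/0, and drops rows with missing or non-positive
#' survival time or missing event, reporting the count.
#'
#' @param path delimited text file.
#' @param id_col,time_col,event_col column names in the file.
#' @param event_alias named vector mapping text event codes to 0/1; the
#'   default understands `dead`/`deceased` = 1 and `alive`/`living` = 0.
#' @param delimiter field separator, inferred from the extension by default.
#' @return data frame with `sample_id`, `os_time`, `os_event` and any further
#'   covariate columns untouched.
#' @export
read_clinical <- function(path, id_col = "sample_id", time_col = "os_time",
                          event_col = "os_event",
                          event_alias = c(dead = 1, deceased = 1,
                                          alive = 0, living = 0),
                          delimiter = NULL) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  sep <- .delim_for(path, delimiter)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (col in c(id_col, time_col, event_col)) {
    if (!col %in% names(df)) stop("clinical table lacks column '", col, "'")
  }
  names(df)[match(c(id_col, time_col, event_col), names(df))] <-
    c("sample_id", "os_time", "os_event")
  ev <- df$os_event
  if (!is.numeric(ev)) {
    key <- tolower(trimws(as.character(ev)))
    ev <- unname(event_alias[key])
    direct <- suppressWarnings(as.numeric(key))
    ev[is.na(ev) & !is.na(direct)] <- direct[is.na(ev) & !is.na(direct)]
    df$os_event <- ev
  }
  suppressWarnings(df$os_time <- as.numeric(df$os_time))
  n0 <- nrow(df)
  ok <- !is.na(df$os_time) & !is.na(df$os_event) &
    df$os_time > 0 & df$os_event %in% c(0, 1)
  if (any(!ok)) warning(n0 - sum(ok),
                        " clinical row(s) dropped (missing/invalid time or event)")
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) stop("no usable clinical rows in ", path)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample IDs in ", path)
  rownames(df) <- NULL
  df
}

#' Restrict an expression matrix and clinical table to shared samples
#'
#' Both outputs are subset to the intersection of sample identifiers and put
#' in the same order (the expression matrix's column order restricted to the
#' intersection).
#'
#' @param expr numeric matrix, genes x samples.
#' @param clinical data frame with a `sample_id` column.
#' @return list with elements `expr` and `clinical`.
#' @export
align_cohort <- function(expr, clinical) {
  shared <- intersect(colnames(expr), clinical$sample_id)
  if (length(shared) == 0L)
    stop("expression and clinical tables share no sample IDs")
  expr2 <- expr[, shared, drop = FALSE]
  clin2 <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin2) <- NULL
  list(expr = expr2, clinical = clin2)
}
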