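#' Construct an expression matrix container
#'
#' Holds log2 intensities for probes x samples, with optional per-cell
#' detection P-values (same shape) and optional per-probe gene symbols.
#' This is the common currency of the pipeline: probes are rows, samples
#' are columns, and all downstream statistics index by the row/column names.
#'
#' @param values numeric matrix of log2 intensities with unique rownames
#'   (probe ids) and colnames (sample ids).
#' @param detection_p optional numeric matrix of detection P-values in
#'   \[0,1\], same dimensions and dimnames as `values`.
#' @param gene_symbols optional character vector of per-probe annotation,
#'   either named by probe id or in row order.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, detection_p = NULL, gene_symbols = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (anyNA(values))
    stop("`values` contains missing cells; missing values are rejected at construction")
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("P%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe id: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!is.null(detection_p)) {
    if (!is.matrix(detection_p) || !all(dim(detection_p) == dim(values)))
      stop("`detection_p` must be a matrix with the same dimensions as `values`")
    if (anyNA(detection_p) || any(detection_p < 0) || any(detection_p > 1))
      stop("`detection_p` must lie in [0, 1] with no missing cells")
    dimnames(detection_p) <- dimnames(values)
  }
  if (!is.null(gene_symbols)) {
    if (is.null(names(gene_symbols))) {
      if (length(gene_symbols) != nrow(values))
        stop("`gene_symbols` must have one entry per probe")
      names(gene_symbols) <- rownames(values)
    }
    gene_symbols <- gene_symbols[rownames(values)]
  }
  structure(
    list(values = values, detection_p = detection_p, gene_symbols = gene_symbols),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples (log2 scale)%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$detection_p)) ", detection P present" else "",
              if (!is.null(x$gene_symbols)) ", annotated" else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

probe_ids <- function(expr) rownames(expr$values)
sample_ids <- function(expr) colnames(expr$values)

# Subset probes/samples keeping detection P and annotation in register.
subset_expr <- function(expr, probes = NULL, samples = NULL) {
  pr <- if (is.null(probes)) seq_len(nrow(expr$values)) else probes
  sa <- if (is.null(samples)) seq_len(ncol(expr$values)) else samples
  expression_matrix(
    expr$values[pr, sa, drop = FALSE],
    detection_p = if (!is.null(expr$detection_p)) expr$detection_p[pr, sa, drop = FALSE],
    gene_symbols = if (!is.null(expr$gene_symbols)) {
      gs <- expr$gene_symbols[pr]
      names(gs) <- rownames(expr$values[pr, sa, drop = FALSE])
      gs
    }
  )
}

#' Validate a sample metadata table against an expression matrix
#'
#' Metadata carries one row per sample with its cohort (`control`/`case`),
#' batch label, stimulation state and, optionally, a minor-allele dosage.
#'
#' @param meta data.frame with at least `sample_id`, `cohort`, `batch`.
#' @param expr optional `expr_matrix`; when given, every expression sample
#'   must have exactly one metadata row.
#' @return the validated metadata (invisibly usable), rows in expression
#'   column order when `expr` is supplied.
#' @export
validate_metadata <- function(meta, expr = NULL) {
  req <- c("sample_id", "cohort", "batch")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  bad <- setdiff(unique(as.character(meta$cohort)), c("control", "case"))
  if (length(bad))
    stop("cohort labels must be 'control' or 'case'; found: ",
         paste(bad, collapse = ", "))
  if (!is.null(expr)) {
    ids <- sample_ids(expr)
    if (!all(ids %in% meta$sample_id))
      stop("expression samples without metadata: ",
           paste(setdiff(ids, meta$sample_id), collapse = ", "))
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  }
  meta
}

#' Express a count as a percentage of a total
#'
#' Small reporting helper used for outlier-burden and carrier summaries,
#' e.g. 385 flagged of 10468 expressed probes is 3.7%.
#'
#' @param k count.
#' @param n total (> 0).
#' @param digits decimal places to keep (default 1).
#' @return numeric percentage.
#' @export
as_percent <- function(k, n, digits = 1) {
  if (n <= 0) stop("total must be positive")
  round(100 * k / n, digits)
}
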