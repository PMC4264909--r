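# Tab-delimited readers/writers for the pipeline's tables. Expression
# matrices use a plain dialect (probe id, optional gene-symbol column,
# then one column per sample) and also accept the GCT 2-line-header
# dialect. Sample identifiers are the join key everywhere; column order
# never carries meaning beyond the matrix itself.

read_tsv_matrix <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (identical(trimws(first), "#1.2")) 2L else 0L
  df <- utils::read.delim(path, header = TRUE, sep = "\t", skip = skip,
                          check.names = FALSE, colClasses = "character")
  if (!ncol(df) || !nrow(df)) stop("empty expression file: ", path)
  ids <- df[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate probe id in ", basename(path), ": ",
         paste(utils::head(dup, 5), collapse = ", "))
  ann_names <- c("description", "gene", "gene_symbol", "symbol")
  has_gene <- ncol(df) >= 2 && tolower(names(df)[2]) %in% ann_names
  genes <- if (has_gene) df[[2]] else NULL
  datacols <- seq((if (has_gene) 3 else 2), ncol(df))
  vals <- matrix(NA_real_, nrow(df), length(datacols),
                 dimnames = list(ids, names(df)[datacols]))
  for (j in seq_along(datacols)) {
    raw <- df[[datacols[j]]]
    v <- suppressWarnings(as.numeric(raw))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop("non-numeric or missing cell in ", basename(path),
           " at data row ", i, " (probe ", ids[i], "), column '",
           names(df)[datacols[j]], "': '", raw[i], "'")
    }
    vals[, j] <- v
  }
  list(values = vals, genes = genes)
}

#' Read an expression matrix (plain or GCT-style tab-delimited)
#'
#' The plain dialect has a header row, probe ids in column 1, an optional
#' gene-symbol column named `gene`/`gene_symbol`/`symbol`/`Description`,
#' and one numeric column per sample. A `#1.2` first line switches to the
#' GCT dialect (2 header lines before the column header). The optional
#' detection file must have identical probe and sample ids in identical
#' order.
#'
#' @param path expression file.
#' @param detection_path optional detection P-value file, same shape.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, detection_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ex <- read_tsv_matrix(path)
  detp <- NULL
  if (!is.null(detection_path)) {
    if (!file.exists(detection_path)) stop("file not found: ", detection_path)
    de <- read_tsv_matrix(detection_path)
    if (!identical(dimnames(de$values), dimnames(ex$values)))
      stop("detection matrix does not match the expression matrix: probe and ",
           "sample ids must agree in the same order")
    detp <- de$values
  }
  gs <- if (!is.null(ex$genes)) stats::setNames(ex$genes, rownames(ex$values))
  expression_matrix(ex$values, detection_p = detp, gene_symbols = gs)
}

#' Write an expression matrix (and optionally its detection P-values)
#'
#' @param expr an `expr_matrix`.
#' @param path output expression file.
#' @param detection_path optional output file for detection P-values.
#' @export
write_expression <- function(expr, path, detection_path = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  write_mat <- function(m, p, genes = NULL) {
    df <- data.frame(probe_id = rownames(m), stringsAsFactors = FALSE)
    if (!is.null(genes)) df$gene_symbol <- unname(genes)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(expr$values, path, expr$gene_symbols)
  if (!is.null(detection_path)) {
    if (is.null(expr$detection_p))
      stop("no detection P-values to write")
    write_mat(expr$detection_p, detection_path)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-delimited with required columns `sample_id`, `cohort`, `batch`;
#' `stimulation` and `genotype_dosage` are carried through when present.
#'
#' @param path metadata file.
#' @return validated data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validate_metadata(utils::read.delim(path, sep = "\t",
                                      stringsAsFactors = FALSE))
}

#' Read a cytokine secretion table
#'
#' Tab-delimited with columns `sample_id`, `cohort`, `cytokine`,
#' `concentration_pg_ml` and optionally `viability_a570`.
#'
#' @param path cytokine file.
#' @return data.frame.
#' @export
read_cytokines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("sample_id", "cohort", "cytokine", "concentration_pg_ml")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cytokine table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(df$concentration_pg_ml < 0))
    stop("concentrations must be non-negative")
  df
}

#' Read a genotype dosage table
#'
#' Tab-delimited with columns `sample_id` and `dosage` (0/1/2).
#'
#' @param path genotype file.
#' @return data.frame.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "dosage") %in% names(df)))
    stop("genotype table needs `sample_id` and `dosage` columns")
  if (!all(df$dosage %in% 0:2)) stop("dosage values must be 0, 1 or 2")
  df
}

#' Write a simulated cohort to the pipeline's standard file formats
#'
#' Writes `expression.tsv`, `detection.tsv`, `metadata.tsv`,
#' `cytokines.tsv`, `genotypes.tsv` (when the scenario has an eQTL) and
#' the ground-truth sidecar `truth.json` into a directory.
#'
#' @param cohort a `sim_cohort` from [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             detection = file.path(dir, "detection.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             cytokines = file.path(dir, "cytokines.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths["expression"], paths["detection"])
  utils::write.table(cohort$metadata, paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$cytokines, paths["cytokines"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$metadata$genotype_dosage)) {
    paths["genotypes"] <- file.path(dir, "genotypes.tsv")
    utils::write.table(
      data.frame(sample_id = cohort$metadata$sample_id,
                 dosage = cohort$metadata$genotype_dosage),
      paths["genotypes"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(paths)
}
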