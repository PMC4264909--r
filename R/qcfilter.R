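# Probe quality filtering and simplified covariate-protected batch
# adjustment. The batch model is a per-probe two-way additive fit
# (cohort + batch) with per-batch residual rescaling to the pooled
# spread -- a deliberately transparent location/scale adjustment that
# protects the cohort contrast; it is not an empirical-Bayes method.

#' Drop blacklisted probes
#'
#' Removes probes named in a blacklist (e.g. platform-annotation "poor
#' quality" probes), preserving the order of the rest.
#'
#' @param expr an `expr_matrix`.
#' @param blacklist character vector of probe ids (may be empty).
#' @return filtered `expr_matrix`.
#' @export
filter_low_quality_probes <- function(expr, blacklist = character()) {
  stopifnot(inherits(expr, "expr_matrix"))
  keep <- !(probe_ids(expr) %in% blacklist)
  if (!any(keep))
    warning("blacklist removes every probe; returning an empty matrix")
  subset_expr(expr, probes = which(keep))
}

#' Filter probes by detection call rate
#'
#' Retains a probe iff it is detected (detection P strictly below
#' `p_threshold`) in at least `min_fraction` of the samples. Defaults are
#' the conventional P < 0.01 in at least 50% of samples; a probe detected
#' in exactly half the samples is retained.
#'
#' @param expr an `expr_matrix` with `detection_p` present.
#' @param p_threshold detection P cutoff in (0,1); strict inequality.
#' @param min_fraction minimum detected fraction in (0,1].
#' @return filtered `expr_matrix`.
#' @export
filter_by_detection <- function(expr, p_threshold = 0.01, min_fraction = 0.5) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (is.null(expr$detection_p))
    stop("detection P-values are absent from this expression matrix; ",
         "filter_by_detection requires the `detection_p` component")
  if (p_threshold <= 0 || p_threshold >= 1)
    stop("p_threshold must lie in (0, 1)")
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  frac <- rowMeans(expr$detection_p < p_threshold)
  subset_expr(expr, probes = which(frac >= min_fraction))
}

#' Remove batch structure while protecting the cohort contrast
#'
#' Per probe, fits an additive model with cohort and batch effects,
#' subtracts the estimated batch effects (centred over samples, so the
#' overall location is untouched), and rescales each batch's residual
#' spread to the pooled residual spread. The cohort effect is part of the
#' fit and is never removed, so a balanced case-control contrast passes
#' through unchanged. A single-batch design is returned as-is.
#'
#' @param expr an `expr_matrix`.
#' @param meta metadata with `sample_id`, `cohort`, `batch`.
#' @return adjusted `expr_matrix`.
#' @export
adjust_batches <- function(expr, meta) {
  stopifnot(inherits(expr, "expr_matrix"))
  meta <- validate_metadata(meta, expr)
  batch <- factor(meta$batch)
  cohort <- factor(meta$cohort)
  if (nlevels(batch) < 2) return(expr)
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("every batch needs at least 2 samples; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  D <- stats::model.matrix(~ cohort + batch)
  if (qr(D)$rank < ncol(D))
    stop("batch is aliased with cohort (confounded design); ",
         "batch effects cannot be separated from the cohort contrast")
  Y <- expr$values
  B <- Y %*% D %*% solve(crossprod(D))        # probes x coefficients
  bcols <- grep("^batch", colnames(D))
  gamma <- B[, bcols, drop = FALSE] %*% t(D[, bcols, drop = FALSE])
  gamma <- gamma - rowMeans(gamma)            # location-preserving centring
  fitted <- B %*% t(D)
  R <- Y - fitted
  pooled <- sqrt(rowSums(R^2) / (ncol(Y) - 1))
  Radj <- R
  for (b in levels(batch)) {
    j <- batch == b
    sb <- sqrt(rowSums(R[, j, drop = FALSE]^2) / (sum(j) - 1))
    f <- ifelse(sb > 0 & pooled > 0, pooled / sb, 1)
    Radj[, j] <- R[, j, drop = FALSE] * f
  }
  out <- fitted - gamma + Radj
  dimnames(out) <- dimnames(Y)
  expression_matrix(out, detection_p = expr$detection_p,
                    gene_symbols = expr$gene_symbols)
}

#' Fraction of expression variance explained by batch, before vs after
#'
#' Per probe, computes the one-way R-squared of the batch factor in both
#' matrices and summarizes it; a successful adjustment drives the mean
#' after-R-squared towards 0.
#'
#' @param expr_before,expr_after `expr_matrix` objects over the same
#'   probes and samples.
#' @param meta metadata with `batch`.
#' @return list with `mean_before`, `mean_after`, `max_before`,
#'   `max_after`, and the per-probe data.frame `per_probe`.
#' @export
batch_variance_check <- function(expr_before, expr_after, meta) {
  stopifnot(inherits(expr_before, "expr_matrix"),
            inherits(expr_after, "expr_matrix"))
  if (!all(dim(expr_before$values) == dim(expr_after$values)) ||
      !identical(dimnames(expr_before$values), dimnames(expr_after$values)))
    stop("the two matrices must share probes and samples")
  meta <- validate_metadata(meta, expr_before)
  batch <- factor(meta$batch)
  r2 <- function(Y) {
    tot <- rowSums((Y - rowMeans(Y))^2)
    between <- 0
    for (b in levels(batch)) {
      j <- batch == b
      between <- between +
        sum(j) * (rowMeans(Y[, j, drop = FALSE]) - rowMeans(Y))^2
    }
    ifelse(tot > 0, between / tot, 0)
  }
  before <- r2(expr_before$values)
  after <- r2(expr_after$values)
  list(mean_before = mean(before), mean_after = mean(after),
       max_before = max(before), max_after = max(after),
       per_probe = data.frame(probe_id = probe_ids(expr_before),
                              r2_before = before, r2_after = after))
}
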