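# Cohort-level statistics: per-probe Student's t differential expression
# with Benjamini-Hochberg correction, paired induction testing, and
# delta-delta-Ct relative quantification for qPCR validation.
#
# The DE route deliberately uses the plain pooled-variance t per probe
# rather than a moderated statistic; at cohort sizes of ~40-60 per group
# the two are close, and the plain t keeps every number reproducible in
# closed form. Fold change is case minus control on the log2 scale.

#' Pooled-variance two-sample Student's t-test
#'
#' @param group_a,group_b numeric vectors, each of length >= 2; pooled
#'   variance must be positive.
#' @return list: `t`, `p` (two-sided, df = n_a + n_b - 2), `df`.
#' @export
two_sample_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  na <- length(group_a); nb <- length(group_b)
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0) stop("pooled variance is zero; t is undefined")
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Paired t-test (one-sample t on differences)
#'
#' @param before,after numeric vectors of equal length >= 2; the
#'   differences must have positive variance.
#' @return list: `t`, `p` (two-sided, df = n - 1), `df`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop("paired vectors must have equal length")
  if (length(before) < 2) stop("need at least 2 pairs")
  d <- after - before
  if (stats::var(d) == 0)
    stop("differences have zero variance; paired t is undefined")
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Benjamini-Hochberg step-up adjusted P-values
#'
#' Step-up FDR adjustment, returned in input order and capped at 1.
#'
#' @param p_values numeric vector in \[0,1\].
#' @return adjusted P-values.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1))
    stop("p_values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-probe differential expression between cohorts
#'
#' For each probe: group means, log2 fold change (case - control),
#' pooled-variance Student's t, two-sided P, and BH-adjusted P across all
#' retained probes; rows ranked by raw P.
#'
#' @param expr an `expr_matrix`.
#' @param meta metadata with `cohort`; each cohort needs >= 2 samples.
#' @return data.frame: `probe_id`, `gene`, `mean_control`, `mean_case`,
#'   `fold_change`, `t`, `p`, `adjp`.
#' @export
differential_expression <- function(expr, meta) {
  stopifnot(inherits(expr, "expr_matrix"))
  meta <- validate_metadata(meta, expr)
  is_ctrl <- meta$cohort == "control"
  is_case <- meta$cohort == "case"
  na <- sum(is_ctrl); nb <- sum(is_case)
  if (na < 2 || nb < 2) stop("each cohort needs at least 2 samples")
  A <- expr$values[, is_ctrl, drop = FALSE]
  B <- expr$values[, is_case, drop = FALSE]
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (mb - ma) / se
  df <- na + nb - 2
  p <- 2 * stats::pt(-abs(tstat), df)
  res <- data.frame(
    probe_id = probe_ids(expr),
    gene = if (!is.null(expr$gene_symbols)) unname(expr$gene_symbols) else NA_character_,
    mean_control = ma, mean_case = mb,
    fold_change = mb - ma,
    t = tstat, p = p, adjp = bh_adjust(p),
    stringsAsFactors = FALSE
  )
  res <- res[order(res$p, res$probe_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Assemble a qPCR record
#'
#' Ct values supplied as triplicate (or any replicate) vectors are
#' averaged before delta-Ct computation.
#'
#' @param sample_id sample label.
#' @param target_ct,reference_ct cycle-threshold values (target gene and
#'   endogenous-control gene); vectors are averaged.
#' @param group `"test"` or `"calibrator"`.
#' @return list of class `qpcr_record`.
#' @export
qpcr_record <- function(sample_id, target_ct, reference_ct,
                        group = c("test", "calibrator")) {
  group <- match.arg(group)
  tc <- mean(target_ct); rc <- mean(reference_ct)
  if (!is.finite(tc) || !is.finite(rc) || tc <= 0 || rc <= 0)
    stop("Ct values must be positive and finite")
  structure(list(sample_id = sample_id, target_ct = tc, reference_ct = rc,
                 group = group), class = "qpcr_record")
}

#' Relative expression by the delta-delta-Ct method
#'
#' delta-Ct = target Ct - reference Ct per record; delta-delta-Ct =
#' delta-Ct(test) - delta-Ct(calibrator); relative quantity =
#' 2^(-delta-delta-Ct), i.e. amplification efficiency exactly 2.
#'
#' @param test,calibrator `qpcr_record` objects (see [qpcr_record()]).
#' @return relative expression of the test sample vs the calibrator
#'   (dimensionless; 1 means equal).
#' @export
ddct_relative_expression <- function(test, calibrator) {
  stopifnot(inherits(test, "qpcr_record"), inherits(calibrator, "qpcr_record"))
  dct_test <- test$target_ct - test$reference_ct
  dct_cal <- calibrator$target_ct - calibrator$reference_ct
  2^(-(dct_test - dct_cal))
}
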