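# Single-SNP eQTL analysis: ordinary least squares of one gene's log2
# expression on minor-allele dosage (0/1/2), reported per cohort.

#' Additive eQTL regression of expression on allele dosage
#'
#' Ordinary least squares of log2 expression on minor-allele dosage.
#' The slope is the log2 expression change per minor allele; r-squared
#' is the squared Pearson correlation between dosage and expression; the
#' P-value comes from the t-statistic on the slope with n - 2 df.
#'
#' @param expression numeric vector of log2 intensities.
#' @param dosage integer vector of minor-allele dosages in \{0, 1, 2\},
#'   same length, with at least two distinct values.
#' @param probe_id,snp_id,cohort optional labels carried into the result.
#' @return list of class `eqtl_fit`: `probe_id`, `snp_id`, `cohort`,
#'   `beta`, `intercept`, `se` (standard error of the slope),
#'   `r_squared`, `p`, `n`, `n_by_genotype`.
#' @export
additive_regression <- function(expression, dosage, probe_id = NA_character_,
                                snp_id = NA_character_,
                                cohort = NA_character_) {
  if (length(expression) != length(dosage))
    stop("expression and dosage must have equal length")
  n <- length(expression)
  if (n < 3) stop("need at least 3 samples")
  if (!all(dosage %in% 0:2)) stop("dosage values must be 0, 1 or 2")
  if (length(unique(dosage)) < 2)
    stop("dosage is monomorphic (every sample has dosage ", dosage[1],
         "); the additive model is degenerate")
  fit <- stats::lm(expression ~ dosage)
  cf <- stats::coef(fit)
  if (stats::var(expression) == 0) {
    r2 <- 0; p <- 1; se <- NA_real_       # flat response: no association
  } else {
    r2 <- stats::cor(expression, dosage)^2
    # an exact line fit makes summary.lm warn about a perfect fit; the
    # resulting se = 0, p = 0 are the intended limits
    sm <- suppressWarnings(summary(fit))$coefficients
    p <- sm["dosage", "Pr(>|t|)"]
    se <- sm["dosage", "Std. Error"]
  }
  structure(
    list(probe_id = probe_id, snp_id = snp_id, cohort = cohort,
         beta = unname(cf["dosage"]), intercept = unname(cf["(Intercept)"]),
         se = se, r_squared = r2, p = p, n = n,
         n_by_genotype = c(`0` = sum(dosage == 0), `1` = sum(dosage == 1),
                           `2` = sum(dosage == 2))),
    class = "eqtl_fit"
  )
}

#' @export
print.eqtl_fit <- function(x, ...) {
  cat(sprintf(
    "eqtl_fit%s%s%s: beta = %.3f, r^2 = %.3f, P = %.3g (n = %d; 0/1/2 = %d/%d/%d)\n",
    if (is.na(x$probe_id)) "" else paste0(" ", x$probe_id),
    if (is.na(x$snp_id)) "" else paste0(" x ", x$snp_id),
    if (is.na(x$cohort)) "" else paste0(" [", x$cohort, "]"),
    x$beta, x$r_squared, x$p, x$n,
    x$n_by_genotype[1], x$n_by_genotype[2], x$n_by_genotype[3]))
  invisible(x)
}

#' Minor-allele dosage from biallelic genotype calls
#'
#' Converts calls like `"G/G"`, `"T/G"`, `"T/T"` into the count of the
#' minor allele per sample (G/G -> 2, T/G -> 1, T/T -> 0 when G is
#' minor). Calls must use exactly the two declared alleles.
#'
#' @param allele_pairs character vector of `"X/Y"` calls.
#' @param minor_allele the minor-allele symbol.
#' @param major_allele optional; inferred as the unique non-minor symbol
#'   when absent.
#' @return integer dosage vector.
#' @export
genotype_from_calls <- function(allele_pairs, minor_allele,
                                major_allele = NULL) {
  parts <- strsplit(allele_pairs, "/", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("genotype calls must be biallelic 'X/Y' pairs")
  alleles <- unlist(parts)
  if (is.null(major_allele)) {
    others <- setdiff(unique(alleles), minor_allele)
    if (length(others) > 1)
      stop("unknown allele symbol(s): ",
           paste(setdiff(others, others[1]), collapse = ", "),
           " (more than one non-minor allele observed)")
    major_allele <- if (length(others)) others else minor_allele
  }
  bad <- setdiff(unique(alleles), c(minor_allele, major_allele))
  if (length(bad))
    stop("unknown allele symbol(s): ", paste(bad, collapse = ", "))
  vapply(parts, function(p) sum(p == minor_allele), integer(1))
}
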