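# Cytokine secretion analysis: viability normalization, per-cytokine
# cohort comparison, and pairwise co-secretion correlation networks
# built separately per cohort on log2-transformed concentrations, with a
# Fisher-transform edge-wise comparison between cohorts. The network
# comparison is an extension beyond qualitative side-by-side reading of
# the two networks and is labelled as such in its output.

#' Normalize cytokine concentrations by cell viability
#'
#' Rescales each sample's concentrations by reference / absorbance, so a
#' well with half the viable cells (half the MTT absorbance) has its
#' concentrations doubled. Units (pg/ml) are preserved.
#'
#' @param table cytokine data.frame with `concentration_pg_ml` and
#'   `viability_a570` (> 0).
#' @param reference reference absorbance; defaults to the mean absorbance
#'   over the table's unique samples.
#' @return the table with rescaled `concentration_pg_ml`.
#' @export
normalize_by_viability <- function(table, reference = NULL) {
  if (!all(c("concentration_pg_ml", "viability_a570") %in% names(table)))
    stop("table needs `concentration_pg_ml` and `viability_a570` columns")
  if (anyNA(table$viability_a570) || any(table$viability_a570 <= 0))
    stop("viability absorbance must be positive")
  if (is.null(reference)) {
    per_sample <- !duplicated(table$sample_id)
    reference <- mean(table$viability_a570[per_sample])
  }
  table$concentration_pg_ml <-
    table$concentration_pg_ml * (reference / table$viability_a570)
  table
}

#' Pearson correlation with a t-based P-value
#'
#' Sample Pearson r with a two-sided P from the t transform
#' t = r sqrt((n-2)/(1-r^2)) on n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list: `r`, `p`, `n`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance; correlation is undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(r = r, p = p, n = n)
}

# Wide samples x cytokines matrix of log2(concentration + 1), complete
# profiles only.
cyto_wide_log2 <- function(table) {
  cytos <- sort(unique(table$cytokine))
  samples <- unique(table$sample_id)
  m <- matrix(NA_real_, length(samples), length(cytos),
              dimnames = list(samples, cytos))
  m[cbind(match(table$sample_id, samples), match(table$cytokine, cytos))] <-
    table$concentration_pg_ml
  m <- m[stats::complete.cases(m), , drop = FALSE]
  log2(m + 1)
}

#' Build a cytokine co-secretion correlation network for one cohort
#'
#' Log2-transforms concentrations (with +1 pg/ml to admit zeros) and
#' computes [pearson()] for every unordered cytokine pair; edges are
#' significant at two-sided P below `alpha`.
#'
#' @param table cytokine data.frame (`sample_id`, `cohort`, `cytokine`,
#'   `concentration_pg_ml`).
#' @param cohort `"control"` or `"case"`.
#' @param alpha edge significance threshold (default 0.05).
#' @return data.frame of class `cytokine_network`, one row per pair:
#'   `cytokine_a`, `cytokine_b`, `r`, `p`, `n`, `significant`, `sign`;
#'   attribute `cohort`.
#' @export
build_network <- function(table, cohort, alpha = 0.05) {
  sub <- table[table$cohort == cohort, , drop = FALSE]
  if (!nrow(sub)) stop("no samples for cohort '", cohort, "'")
  m <- cyto_wide_log2(sub)
  if (nrow(m) < 3)
    stop("need at least 3 samples with complete cytokine profiles; have ",
         nrow(m))
  cytos <- colnames(m)
  pairs <- utils::combn(cytos, 2)
  edges <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pr <- pearson(m[, pairs[1, k]], m[, pairs[2, k]])
    data.frame(cytokine_a = pairs[1, k], cytokine_b = pairs[2, k],
               r = pr$r, p = pr$p, n = pr$n,
               significant = pr$p < alpha,
               sign = ifelse(pr$r >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  structure(edges, cohort = cohort, class = c("cytokine_network", "data.frame"))
}

#' @export
print.cytokine_network <- function(x, ...) {
  cat(sprintf("cytokine_network (%s cohort): %d edges, %d significant\n",
              attr(x, "cohort"), nrow(x), sum(x$significant)))
  print.data.frame(x, digits = 3, ...)
  invisible(x)
}

#' Edge-wise comparison of two correlation networks
#'
#' For each cytokine pair, transforms both r values with Fisher's
#' z = atanh(r) and tests the difference with standard error
#' sqrt(1/(n_a-3) + 1/(n_b-3)); also lists edges significant in one
#' network only. This quantitative comparison is an extension of the
#' side-by-side network reading.
#'
#' @param net_a,net_b `cytokine_network` objects over the same cytokines.
#' @return list: `edges` (per-pair `r_a`, `r_b`, `z_diff`, `p_diff`),
#'   `lost` (significant in a only), `gained` (significant in b only),
#'   `note`.
#' @export
compare_networks <- function(net_a, net_b) {
  key <- function(nw) paste(nw$cytokine_a, nw$cytokine_b, sep = "~")
  if (!setequal(key(net_a), key(net_b)))
    stop("networks must cover the same cytokine pairs")
  b <- net_b[match(key(net_a), key(net_b)), , drop = FALSE]
  if (any(abs(net_a$r) >= 1) || any(abs(b$r) >= 1))
    stop("|r| = 1 edge: the Fisher transform diverges")
  if (any(net_a$n <= 3) || any(b$n <= 3))
    stop("need n > 3 in both networks for the Fisher comparison")
  se <- sqrt(1 / (net_a$n - 3) + 1 / (b$n - 3))
  zd <- (atanh(net_a$r) - atanh(b$r)) / se
  edges <- data.frame(
    cytokine_a = net_a$cytokine_a, cytokine_b = net_a$cytokine_b,
    r_a = net_a$r, r_b = b$r,
    z_diff = zd, p_diff = 2 * stats::pnorm(-abs(zd)),
    stringsAsFactors = FALSE
  )
  pair <- key(net_a)
  list(edges = edges,
       lost = pair[net_a$significant & !b$significant],
       gained = pair[!net_a$significant & b$significant],
       note = "Fisher-transform network comparison (extension)")
}

#' Per-cytokine cohort comparison of secretion
#'
#' Two-sample Student's t per cytokine, on log2(concentration + 1) by
#' default (consistent with the correlation analysis) or on the raw
#' pg/ml scale.
#'
#' @param table cytokine data.frame with both cohorts present.
#' @param log_scale compare log2-transformed values (default `TRUE`).
#' @return data.frame: `cytokine`, `mean_control`, `mean_case`, `t`, `p`
#'   (means on the analysis scale).
#' @export
compare_secretion <- function(table, log_scale = TRUE) {
  if (!all(c("control", "case") %in% table$cohort))
    stop("both cohorts must be present")
  vals <- if (log_scale) log2(table$concentration_pg_ml + 1) else
    table$concentration_pg_ml
  out <- do.call(rbind, lapply(sort(unique(table$cytokine)), function(cy) {
    i <- table$cytokine == cy
    a <- vals[i & table$cohort == "control"]
    b <- vals[i & table$cohort == "case"]
    tt <- two_sample_t(a, b)
    data.frame(cytokine = cy, mean_control = mean(a), mean_case = mean(b),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
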