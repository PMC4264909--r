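# Per-individual z-score outlier detection: each case sample's log2
# expression is compared against the control cohort's per-probe mean and
# SD; a call passes when both the standardized deviation is significant
# (two-sided normal P strictly below p_threshold) and the absolute log2
# difference from the control mean strictly exceeds fc_threshold.
# Recurrent calls on the same probe and direction define case subgroups.

#' Standardized-deviation outlier statistic for a single value
#'
#' Computes z = (test - mean(control)) / sd(control) with the unbiased
#' (n-1) sample SD, the two-sided standard-normal tail probability, and
#' the dual-threshold pass decision: p < `p_threshold` AND
#' |delta| > `fc_threshold`, both strict.
#'
#' @param test_value log2 intensity of the test sample.
#' @param control_values numeric vector of >= 3 control log2 intensities
#'   with nonzero spread.
#' @param p_threshold significance cutoff (default 0.005).
#' @param fc_threshold log2 fold-change cutoff (default 1).
#' @return list of class `outlier_call`: `z`, `p`, `delta`, `direction`
#'   (`"under"` iff delta < 0), `passes`.
#' @export
zscore_outlier <- function(test_value, control_values,
                           p_threshold = 0.005, fc_threshold = 1.0) {
  if (length(control_values) < 3)
    stop("need at least 3 control values")
  s <- stats::sd(control_values)
  if (s == 0)
    stop("control SD is zero; the standardized deviation is undefined")
  delta <- test_value - mean(control_values)
  z <- delta / s
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(z = z, p = p, delta = delta,
         direction = if (delta < 0) "under" else "over",
         passes = (p < p_threshold) && (abs(delta) > fc_threshold)),
    class = "outlier_call"
  )
}

#' Call outliers for every (probe, case sample) pair
#'
#' Control statistics (mean, unbiased SD) are computed once per probe
#' from the control samples only; case samples never enter the reference.
#' Intended for filtered, batch-adjusted, unstimulated-sample matrices; a
#' warning is emitted if stimulated samples are included.
#'
#' @param expr an `expr_matrix`.
#' @param meta metadata with `cohort` (needs >= 3 controls and >= 1 case)
#'   and optionally `stimulation`.
#' @param p_threshold,fc_threshold dual thresholds as in
#'   [zscore_outlier()].
#' @param passing_only if `TRUE`, return only passing calls (the attributes
#'   below still describe the full test set).
#' @return data.frame with one row per tested (probe, case) pair (or per
#'   passing pair): `probe_id`, `sample_id`, `z`, `p`, `delta`,
#'   `direction`, `passes`; attributes `n_tests`, `n_probes`, `n_cases`.
#' @export
call_outliers <- function(expr, meta, p_threshold = 0.005, fc_threshold = 1.0,
                          passing_only = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  meta <- validate_metadata(meta, expr)
  if ("stimulation" %in% names(meta) &&
      any(meta$stimulation != "unstimulated"))
    warning("stimulated samples are included; outlier calling is designed ",
            "for unstimulated-sample matrices")
  is_ctrl <- meta$cohort == "control"
  is_case <- meta$cohort == "case"
  if (sum(is_ctrl) < 3) stop("need at least 3 control samples")
  if (!any(is_case)) stop("no case samples to test")
  ctrl <- expr$values[, is_ctrl, drop = FALSE]
  cases <- expr$values[, is_case, drop = FALSE]
  m <- rowMeans(ctrl)
  s <- sqrt(rowSums((ctrl - m)^2) / (ncol(ctrl) - 1))
  if (any(s == 0))
    stop("control SD is zero for probe(s): ",
         paste(utils::head(probe_ids(expr)[s == 0], 5), collapse = ", "))
  delta <- cases - m
  z <- delta / s
  p <- 2 * stats::pnorm(-abs(z))
  passes <- (p < p_threshold) & (abs(delta) > fc_threshold)
  n_tests <- length(passes)
  keep <- if (passing_only) which(passes) else seq_len(n_tests)
  pid <- rep(rownames(cases), ncol(cases))
  sid <- rep(colnames(cases), each = nrow(cases))
  calls <- data.frame(
    probe_id = pid[keep], sample_id = sid[keep],
    z = z[keep], p = p[keep], delta = delta[keep],
    direction = ifelse(delta[keep] < 0, "under", "over"),
    passes = passes[keep],
    stringsAsFactors = FALSE
  )
  attr(calls, "n_tests") <- n_tests
  attr(calls, "n_probes") <- nrow(cases)
  attr(calls, "n_cases") <- ncol(cases)
  calls
}

#' Aggregate outlier calls into per-probe recurrence counts
#'
#' Counts passing carriers per probe by direction; a probe with carriers
#' on both sides is flagged `both_directions` and counted in both
#' columns. Restricting to `min_carriers` keeps probes whose larger
#' directional count reaches the threshold (the subgroup definition).
#'
#' @param calls data.frame from [call_outliers()].
#' @param min_carriers minimum carrier count in the dominant direction
#'   (default 1 = keep every probe with any passing call).
#' @return data.frame: `probe_id`, `count_under`, `count_over`,
#'   `carriers_under`, `carriers_over` (semicolon-joined sample ids),
#'   `both_directions`; ordered by total carriers, descending.
#' @export
aggregate_recurrence <- function(calls, min_carriers = 1L) {
  pass <- calls[calls$passes, , drop = FALSE]
  if (!nrow(pass)) {
    return(data.frame(probe_id = character(), count_under = integer(),
                      count_over = integer(), carriers_under = character(),
                      carriers_over = character(), both_directions = logical(),
                      stringsAsFactors = FALSE))
  }
  probes <- unique(pass$probe_id)
  under <- pass[pass$direction == "under", ]
  over <- pass[pass$direction == "over", ]
  cu <- table(factor(under$probe_id, levels = probes))
  co <- table(factor(over$probe_id, levels = probes))
  join <- function(df) {
    v <- vapply(probes, function(p)
      paste(sort(df$sample_id[df$probe_id == p]), collapse = ";"), character(1))
    unname(v)
  }
  out <- data.frame(
    probe_id = probes,
    count_under = as.integer(cu), count_over = as.integer(co),
    carriers_under = join(under), carriers_over = join(over),
    both_directions = as.integer(cu) >= 1 & as.integer(co) >= 1,
    stringsAsFactors = FALSE
  )
  out <- out[pmax(out$count_under, out$count_over) >= min_carriers, , drop = FALSE]
  out <- out[order(-(out$count_under + out$count_over), out$probe_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize the cohort-wide outlier burden
#'
#' Reports how many of the expressed probes carry any passing call, split
#' by direction, with the percentage to one decimal. The four counts are
#' reported independently (a probe flagged in both directions appears in
#' both directional counts and once in the any-direction count).
#'
#' @param calls data.frame from [call_outliers()].
#' @param expr the `expr_matrix` the calls were computed on.
#' @return list: `n_probes_expressed`, `n_probes_flagged_any`, `n_under`,
#'   `n_over`, `n_both`, `percent_flagged`.
#' @export
summarize_outlier_burden <- function(calls, expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  pass <- calls[calls$passes, , drop = FALSE]
  under <- unique(pass$probe_id[pass$direction == "under"])
  over <- unique(pass$probe_id[pass$direction == "over"])
  any_ <- union(under, over)
  n_expr <- nrow(expr$values)
  list(
    n_probes_expressed = n_expr,
    n_probes_flagged_any = length(any_),
    n_under = length(under),
    n_over = length(over),
    n_both = length(intersect(under, over)),
    percent_flagged = as_percent(length(any_), n_expr, 1)
  )
}
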