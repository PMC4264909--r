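# End-to-end driver: detection filter -> batch adjustment -> differential
# expression -> outlier calling -> recurrence, with optional secretion
# and eQTL stages, writing every table plus a run manifest with input
# and output digests and the analysis deviations stated explicitly.

#' Assemble and validate a pipeline configuration
#'
#' Collects the input paths and every analysis threshold in one place.
#' Thresholds are validated here, before any computation; referenced
#' files are checked at run time by [run_pipeline()].
#'
#' @param expression,metadata required input paths.
#' @param detection,cytokines,genotypes optional input paths.
#' @param eqtl_probe probe id to regress on dosage (needs `genotypes`).
#' @param blacklist character vector of probe ids to drop first.
#' @param detection_p,detection_min_fraction detection-filter settings.
#' @param outlier_p,fc_threshold dual outlier-calling thresholds.
#' @param min_carriers recurrence-table subgroup threshold.
#' @param alpha significance level for network edges.
#' @param normalize_viability rescale cytokine concentrations by MTT
#'   absorbance before analysis.
#' @param seed integer seed recorded in the manifest (the pipeline stages
#'   themselves are deterministic given their inputs).
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, metadata, detection = NULL,
                            cytokines = NULL, genotypes = NULL,
                            eqtl_probe = NULL, blacklist = character(),
                            detection_p = 0.01, detection_min_fraction = 0.5,
                            outlier_p = 0.005, fc_threshold = 1.0,
                            min_carriers = 3L, alpha = 0.05,
                            normalize_viability = TRUE,
                            seed = 1L, out_dir = "cytodet_out") {
  chk <- function(x, lo, hi, nm, lo_open = TRUE, hi_open = TRUE) {
    ok <- (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi)
    if (!ok) stop("`", nm, "` = ", x, " is outside its valid range")
  }
  chk(detection_p, 0, 1, "detection_p")
  chk(detection_min_fraction, 0, 1, "detection_min_fraction", hi_open = FALSE)
  chk(outlier_p, 0, 1, "outlier_p")
  if (fc_threshold < 0) stop("`fc_threshold` must be non-negative")
  chk(alpha, 0, 1, "alpha")
  if (min_carriers < 1) stop("`min_carriers` must be at least 1")
  structure(
    list(expression = expression, metadata = metadata, detection = detection,
         cytokines = cytokines, genotypes = genotypes,
         eqtl_probe = eqtl_probe, blacklist = blacklist,
         detection_p = detection_p,
         detection_min_fraction = detection_min_fraction,
         outlier_p = outlier_p, fc_threshold = fc_threshold,
         min_carriers = as.integer(min_carriers), alpha = alpha,
         normalize_viability = normalize_viability,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read / write a pipeline configuration file
#'
#' Plain-text YAML holding the same fields as [pipeline_config()].
#'
#' @param path configuration file.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage <- function(name, fun) {
  tryCatch(fun(), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes detection filtering, batch adjustment, differential
#' expression, outlier calling and recurrence aggregation, plus the
#' secretion and eQTL stages when their inputs are configured; writes
#' every result table under `config$out_dir` and returns the run
#' manifest (also written as `manifest.json`). With fixed inputs and
#' seed the output digests are identical across runs.
#'
#' @param config a [pipeline_config()].
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  inputs <- c(expression = config$expression, metadata = config$metadata,
              detection = config$detection, cytokines = config$cytokines,
              genotypes = config$genotypes)
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("input file(s) not found: ", paste(missing_in, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[name]] <<- p
    p
  }

  expr <- stage("read", function()
    read_expression(config$expression, config$detection))
  meta <- stage("read", function() {
    m <- read_metadata(config$metadata)
    validate_metadata(m, expr)
  })
  counts$probes_input <- nrow(expr$values)

  expr <- stage("blacklist", function()
    filter_low_quality_probes(expr, config$blacklist))
  if (!is.null(expr$detection_p)) {
    expr <- stage("detection-filter", function()
      filter_by_detection(expr, config$detection_p,
                          config$detection_min_fraction))
  }
  counts$probes_retained <- nrow(expr$values)
  message("cytodet: ", counts$probes_retained, " of ", counts$probes_input,
          " probes retained")

  if (length(unique(meta$batch)) > 1) {
    expr <- stage("batch-adjust", function() adjust_batches(expr, meta))
  }

  de <- stage("differential-expression", function()
    differential_expression(expr, meta))
  emit(de, "differential_expression.tsv")

  calls <- stage("outliers", function()
    call_outliers(expr, meta, config$outlier_p, config$fc_threshold,
                  passing_only = TRUE))
  counts$outlier_tests <- attr(calls, "n_tests")
  counts$passing_calls <- nrow(calls)
  emit(calls, "outlier_calls.tsv")
  message("cytodet: ", counts$passing_calls, " passing outlier calls")

  recurrence <- stage("recurrence", function()
    aggregate_recurrence(calls, config$min_carriers))
  counts$recurrent_probes <- nrow(recurrence)
  emit(recurrence, "recurrence.tsv")

  burden <- stage("burden", function() summarize_outlier_burden(calls, expr))
  bpath <- file.path(config$out_dir, "outlier_burden.json")
  jsonlite::write_json(burden, bpath, auto_unbox = TRUE, digits = NA)
  outputs[["outlier_burden.json"]] <- bpath

  if (!is.null(config$cytokines)) {
    cyto <- stage("secretion", function() {
      tb <- read_cytokines(config$cytokines)
      if (config$normalize_viability && "viability_a570" %in% names(tb))
        tb <- normalize_by_viability(tb)
      tb
    })
    cmp <- stage("secretion", function() compare_secretion(cyto))
    emit(cmp, "secretion_comparison.tsv")
    net_hc <- stage("secretion", function()
      build_network(cyto, "control", config$alpha))
    net_cd <- stage("secretion", function()
      build_network(cyto, "case", config$alpha))
    emit(as.data.frame(net_hc), "network_control.tsv")
    emit(as.data.frame(net_cd), "network_case.tsv")
    nc <- stage("secretion", function() compare_networks(net_hc, net_cd))
    npath <- file.path(config$out_dir, "network_comparison.json")
    jsonlite::write_json(nc, npath, auto_unbox = TRUE, digits = NA)
    outputs[["network_comparison.json"]] <- npath
    counts$cytokine_rows <- nrow(cyto)
  }

  if (!is.null(config$genotypes) && !is.null(config$eqtl_probe)) {
    fits <- stage("eqtl", function() {
      g <- read_genotypes(config$genotypes)
      if (!config$eqtl_probe %in% probe_ids(expr))
        stop("eQTL probe ", config$eqtl_probe,
             " is not in the retained expression matrix")
      y <- expr$values[config$eqtl_probe, ]
      d <- g$dosage[match(names(y), g$sample_id)]
      if (anyNA(d)) stop("genotypes missing for expression sample(s)")
      lapply(c("control", "case"), function(co) {
        i <- meta$cohort == co
        unclass(additive_regression(y[i], d[i], probe_id = config$eqtl_probe,
                                    cohort = co))
      })
    })
    epath <- file.path(config$out_dir, "eqtl.json")
    jsonlite::write_json(fits, epath, auto_unbox = TRUE, digits = NA)
    outputs[["eqtl.json"]] <- epath
  }

  manifest <- list(
    tool = "cytodet",
    version = as.character(utils::packageVersion("cytodet")),
    config = unclass(config),
    input_digests = as.list(tools::md5sum(inputs)),
    stage_counts = counts,
    outputs = as.list(tools::md5sum(unlist(outputs))),
    deviations = c(
      "batch adjustment is an additive location/scale fit with cohort protection, not empirical-Bayes ComBat",
      "differential expression uses the per-probe pooled-variance Student t, not a moderated t"
    )
  )
  mpath <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
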