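test_that("z-score outlier statistic matches its numerical oracle", {
  # centred test value: the null midpoint
  call <- zscore_outlier(3, c(1, 2, 3, 4, 5))
  expect_equal(call$z, 0)
  expect_equal(call$p, 1)
  expect_false(call$passes)
  # controls 1..5, test 6: z = 3 / sd(1:5); P by integrating the normal density
  call <- zscore_outlier(6, c(1, 2, 3, 4, 5))
  expect_equal(call$delta, 3)
  expect_equal(call$z, 3 / sd(1:5), tolerance = 1e-12)
  expect_equal(call$p, tail2_oracle(call$z, dnorm), tolerance = 1e-10)
  expect_equal(round(call$z, 3), 1.897)
  expect_equal(round(call$p, 4), 0.0578)
  expect_false(call$passes)  # p above 0.005
  # constructed control mean 8, sd 0.2: strong under-expression call
  ctrl <- 8 + 0.2 * scale(seq(-2, 2, length.out = 9))[, 1]
  expect_equal(mean(ctrl), 8, tolerance = 1e-12)
  expect_equal(sd(ctrl), 0.2, tolerance = 1e-12)
  call <- zscore_outlier(6.5, ctrl)
  expect_equal(call$delta, -1.5, tolerance = 1e-12)
  expect_equal(call$z, -7.5, tolerance = 1e-12)
  expect_lt(call$p, 1e-13)
  expect_true(call$passes)
  expect_equal(call$direction, "under")
})

test_that("both thresholds must bind: a huge z with small delta fails", {
  ctrl <- 8 + 0.05 * scale(seq(-2, 2, length.out = 9))[, 1]  # sd 0.05
  call <- zscore_outlier(8.9, ctrl)                          # delta 0.9, z 18
  expect_gt(abs(call$z), 10)
  expect_false(call$passes)
  # delta just above 1 passes
  expect_true(zscore_outlier(9.01, ctrl)$passes)
})

test_that("degenerate control sets are rejected", {
  expect_error(zscore_outlier(5, c(1, 2)), "at least 3")
  expect_error(zscore_outlier(5, c(2, 2, 2)), "SD is zero")
})

test_that("z and p are affine-invariant; delta scales", {
  set.seed(3)
  ctrl <- rnorm(20, 8, 0.5)
  test <- 9.7
  base <- zscore_outlier(test, ctrl)
  shift <- zscore_outlier(test + 2.5, ctrl + 2.5)
  expect_equal(shift$z, base$z, tolerance = 1e-12)
  expect_equal(shift$p, base$p, tolerance = 1e-12)
  expect_equal(shift$passes, base$passes)
  scaled <- zscore_outlier(3 * test, 3 * ctrl)
  expect_equal(scaled$z, base$z, tolerance = 1e-12)
  expect_equal(scaled$delta, 3 * base$delta, tolerance = 1e-12)
})

test_that("matrix calling agrees with the scalar statistic and uses controls only", {
  co <- simulate_expression(quick_scenario(seed = 17, n_probes = 40))
  expr <- co$expression
  meta <- co$metadata
  calls <- call_outliers(expr, meta)
  expect_equal(nrow(calls), 40 * 58)
  expect_equal(attr(calls, "n_tests"), 40 * 58)
  ctrl_ids <- meta$sample_id[meta$cohort == "control"]
  for (i in sample(nrow(calls), 25)) {
    sc <- zscore_outlier(expr$values[calls$probe_id[i], calls$sample_id[i]],
                         expr$values[calls$probe_id[i], ctrl_ids])
    expect_equal(calls$z[i], sc$z, tolerance = 1e-12)
    expect_equal(calls$p[i], sc$p, tolerance = 1e-12)
    expect_equal(calls$passes[i], sc$passes)
  }
  # perturbing one case sample leaves every other sample's calls intact
  expr2 <- expr
  expr2$values[, "CD001"] <- expr2$values[, "CD001"] + 5
  calls2 <- call_outliers(expr2, meta)
  other <- calls$sample_id != "CD001"
  expect_equal(calls2$z[other], calls$z[other], tolerance = 1e-12)
})

test_that("planted carriers are recovered with high pooled sensitivity", {
  hits <- 0L; total <- 0L
  for (k in 1:20) {
    co <- simulate_expression(quick_scenario(seed = 100 + k, n_probes = 50))
    expr <- filter_by_detection(co$expression)
    calls <- call_outliers(expr, co$metadata, passing_only = TRUE)
    tr <- co$truth$planted[[1]]
    flagged <- calls$sample_id[calls$probe_id == tr$probe_id &
                                 calls$direction == "under"]
    hits <- hits + sum(tr$carriers %in% flagged)
    total <- total + length(tr$carriers)
  }
  expect_gte(hits / total, 0.95)
})

test_that("a case equal to the control mean on every probe is never called", {
  co <- simulate_expression(quick_scenario(seed = 19, n_probes = 30,
                                           planted_outliers = NULL,
                                           eqtl = NULL))
  expr <- co$expression
  ctrl_ids <- co$metadata$sample_id[co$metadata$cohort == "control"]
  expr$values[, "CD002"] <- rowMeans(expr$values[, ctrl_ids])
  calls <- call_outliers(expr, co$metadata)
  expect_false(any(calls$passes[calls$sample_id == "CD002"]))
})

test_that("recurrence aggregation counts carriers by direction", {
  empty <- aggregate_recurrence(data.frame(probe_id = character(),
                                           sample_id = character(),
                                           direction = character(),
                                           passes = logical()))
  expect_equal(nrow(empty), 0)
  calls <- data.frame(
    probe_id = c("A", "A", "A", "B", "B", "B", "C"),
    sample_id = paste0("s", 1:7),
    direction = c("under", "under", "under", "under", "under", "over", "over"),
    passes = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  at3 <- aggregate_recurrence(calls, min_carriers = 3)
  expect_equal(at3$probe_id, "A")
  expect_equal(at3$count_under, 3)
  expect_equal(at3$count_over, 0)
  expect_false(at3$both_directions)
  at1 <- aggregate_recurrence(calls, min_carriers = 1)
  expect_setequal(at1$probe_id, c("A", "B"))
  b <- at1[at1$probe_id == "B", ]
  expect_equal(b$count_under, 2)
  expect_equal(b$count_over, 1)
  expect_true(b$both_directions)
  expect_equal(b$carriers_under, "s4;s5")
})

test_that("recurrence conserves passing calls across probes", {
  co <- simulate_expression(quick_scenario(seed = 23, n_probes = 400))
  calls <- call_outliers(co$expression, co$metadata)
  rec <- aggregate_recurrence(calls, min_carriers = 1)
  expect_equal(sum(rec$count_under) + sum(rec$count_over), sum(calls$passes))
})

test_that("burden summary reports directional counts and the flagged percent", {
  ex <- expression_matrix(matrix(0, 10468, 3))
  pid <- sprintf("Q%05d", 1:10468)
  # 166 under-only, 204 over-only minus overlap handled via shared ids:
  # construct 381 distinct probes carrying calls, 15 of them both ways
  under <- pid[1:166]
  over <- pid[c(1:15, 167:355)]          # 15 shared with under, 189 new
  calls <- data.frame(
    probe_id = c(under, over),
    sample_id = "cd", direction = rep(c("under", "over"),
                                      c(length(under), length(over))),
    passes = TRUE
  )
  s <- summarize_outlier_burden(calls, ex)
  expect_equal(s$n_under, 166)
  expect_equal(s$n_over, 204)
  expect_equal(s$n_both, 15)
  expect_equal(s$n_probes_flagged_any, 355)
  expect_equal(s$percent_flagged, as_percent(355, 10468))
  none <- summarize_outlier_burden(calls[0, ], ex)
  expect_equal(none$percent_flagged, 0)
  all_called <- summarize_outlier_burden(
    data.frame(probe_id = rownames(ex$values), sample_id = "cd",
               direction = "over", passes = TRUE), ex)
  expect_equal(all_called$percent_flagged, 100)
})

test_that("stimulated samples trigger a warning and no-case input errors", {
  co <- simulate_expression(quick_scenario(seed = 29, n_probes = 20))
  meta <- co$metadata
  meta$stimulation[1] <- "stimulated"
  expect_warning(call_outliers(co$expression, meta), "stimulated")
  meta2 <- co$metadata
  meta2$cohort <- "control"
  expect_error(suppressWarnings(call_outliers(co$expression, meta2)),
               "no case samples")
})
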