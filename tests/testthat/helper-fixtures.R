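# Shared fixtures and independent oracles, built in code.

# Small, fast scenario for pipeline-level tests.
quick_scenario <- function(seed = 1L, n_probes = 300L, ...) {
  sim_scenario(n_probes = n_probes, seed = seed, ...)
}

# Pure-null scenario: no planted carriers, no eQTL, fixed probe SD.
null_scenario <- function(seed, n_probes, n_control = 42L, n_case = 58L,
                          sd = 0.5) {
  sim_scenario(n_control = n_control, n_case = n_case, n_probes = n_probes,
               probe_sd_range = c(sd, sd), planted_outliers = NULL,
               eqtl = NULL, detection_dropout_rate = 0, seed = seed)
}

# Brute-force Monte-Carlo oracle for the z-score outlier pass rate under
# the null: normal data, plug-in sample mean/SD from n_ctrl controls,
# two-sided normal-quantile test plus the fold-change criterion.
# Independent of the package's calling path by construction.
mc_zodet_oracle <- function(n_sim, n_ctrl = 42L, sd = 0.5,
                            p_thr = 0.005, fc_thr = 1.0, chunk = 1e5L) {
  passes <- 0L
  done <- 0L
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    ctrl <- matrix(rnorm(n_ctrl * m, 0, sd), n_ctrl, m)
    mu <- colMeans(ctrl)
    s <- sqrt(colSums(sweep(ctrl, 2, mu)^2) / (n_ctrl - 1))
    test <- rnorm(m, 0, sd)
    delta <- test - mu
    p <- 2 * pnorm(-abs(delta / s))
    passes <- passes + sum(p < p_thr & abs(delta) > fc_thr)
    done <- done + m
  }
  passes / n_sim
}

# Deterministic balanced two-batch, two-cohort additive matrix:
# value = probe mean + cohort effect + batch shift (+ optional noise).
balanced_batch_data <- function(n_probes = 50, per_cell = 5,
                                cohort_effect = 0.4, batch_shift = 0.8,
                                noise_sd = 0) {
  n <- 4 * per_cell
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    cohort = rep(rep(c("control", "case"), each = per_cell), 2),
    batch = rep(c("b1", "b2"), each = 2 * per_cell),
    stringsAsFactors = FALSE
  )
  mu <- seq(6, 10, length.out = n_probes)
  vals <- outer(mu, rep(1, n)) +
    outer(rep(1, n_probes), ifelse(meta$cohort == "case", cohort_effect, 0)) +
    outer(rep(1, n_probes), ifelse(meta$batch == "b2", batch_shift, 0))
  if (noise_sd > 0)
    vals <- vals + matrix(rnorm(n_probes * n, 0, noise_sd), n_probes, n)
  dimnames(vals) <- list(sprintf("P%03d", seq_len(n_probes)), meta$sample_id)
  list(expr = expression_matrix(vals), meta = meta)
}

# Two-sided tail probability by numerical integration of a density --
# used as the oracle for normal and t based P-values.
tail2_oracle <- function(stat, dens) {
  2 * integrate(dens, abs(stat), Inf, rel.tol = 1e-12)$value
}

# Independent step-up FDR oracle (direct implementation of the rule).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m / i * p[o[i]])
    adj[o[i]] <- running
  }
  adj
}
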