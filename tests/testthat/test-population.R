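test_that("LHS draws are contained and stratified per marginal", {
  p1 <- sampling_plan(1, "lhs", seed = 3)
  d1 <- lhs_sample(p1)
  expect_true(d1$scale >= 0.2 && d1$scale <= 5)
  expect_true(d1$Cm_pF >= 8 && d1$Cm_pF <= 22)
  expect_true(d1$Rs_MOhm >= 4 && d1$Rs_MOhm <= 15)

  n <- 10000
  d <- lhs_sample(sampling_plan(n, "lhs", seed = 4))
  # exactly one draw per equal-probability bin of each marginal
  u_scale <- (log(d$scale) - log(0.2)) / (log(5) - log(0.2))
  u_cm <- (d$Cm_pF - 8) / 14
  u_rs <- (d$Rs_MOhm - 4) / 11
  for (u in list(u_scale, u_cm, u_rs)) {
    counts <- tabulate(findInterval(u, seq(0, 1, length.out = n + 1),
                                    rightmost.closed = TRUE), nbins = n)
    expect_true(all(counts == 1L))
  }

  # cardiomyocyte-range plan stays in range
  d2 <- lhs_sample(sampling_plan(200, "lhs", Cm_range_pF = c(50, 150),
                                 Rs_range_MOhm = c(0.5, 2), seed = 5))
  expect_true(all(d2$Cm_pF >= 50 & d2$Cm_pF <= 150))
  expect_true(all(d2$Rs_MOhm >= 0.5 & d2$Rs_MOhm <= 2))
})

test_that("lognormal conditions match their natural-scale moments", {
  plan <- sampling_plan(1e5, "distributional", qc_Rs_max_MOhm = Inf,
                        estimate_error_sd = 0, seed = 6)
  d <- sample_conditions(plan)
  expect_lt(abs(mean(d$Rs_MOhm) - 2.5) / 2.5, 0.02)
  expect_lt(abs(stats::sd(d$Rs_MOhm) - 1.5) / 1.5, 0.03)
  expect_lt(abs(mean(d$Cm_pF) - 40) / 40, 0.02)
  expect_lt(abs(stats::sd(d$Cm_pF) - 10) / 10, 0.03)
  expect_lt(abs(mean(d$Voff_mV)), 0.05)
  # no estimation error: machine estimates equal the truth
  expect_equal(d$Rs_est_MOhm, d$Rs_MOhm)
  expect_equal(d$Cm_est_pF, d$Cm_pF)
})

test_that("QC rejection keeps only sub-threshold series resistances", {
  plan <- sampling_plan(500, "distributional", qc_Rs_max_MOhm = 4, seed = 7)
  d <- sample_conditions(plan)
  expect_equal(nrow(d), 500)
  expect_true(all(d$Rs_MOhm < 4))
  # near-impossible QC raises the nonconvergence error
  hard <- sampling_plan(10, "distributional", qc_Rs_max_MOhm = 1e-4,
                        seed = 8)
  expect_error(sample_conditions(hard), "acceptance probability")
})

test_that("averaging returns pointwise mean and SEM", {
  c1 <- iv_curve(c(-40, -30, -20), c(-100, -400, -300))
  expect_equal(average_iv(list(c1, c1))$mean$I_peak, c1$I_peak)
  expect_equal(average_iv(list(c1, c1))$sem$I_peak, c(0, 0, 0))
  c2 <- iv_curve(c(-40, -30, -20), c(0, 0, 0))
  c3 <- iv_curve(c(-40, -30, -20), c(2, 2, 2))
  av <- average_iv(list(c2, c3))
  expect_equal(av$mean$I_peak, c(1, 1, 1))
  expect_equal(av$sem$I_peak, c(1, 1, 1))  # SD sqrt(2) / sqrt(2)
  bad <- iv_curve(c(-45, -30, -20), c(0, 0, 0))
  expect_error(average_iv(list(c1, bad)), "voltage grid")
})

test_that("SEM shrinks as sqrt(n) at matched variance", {
  set.seed(9)
  mk <- function(n) {
    curves <- lapply(seq_len(n), function(i)
      iv_curve(c(-40, -30, -20), c(-100, -400, -300) + stats::rnorm(3, 0, 50)))
    mean(average_iv(curves)$sem$I_peak)
  }
  sems5 <- replicate(40, mk(5))
  sems75 <- replicate(40, mk(75))
  ratio <- mean(sems5) / mean(sems75)
  expect_gt(ratio, sqrt(75 / 5) * 0.8)
  expect_lt(ratio, sqrt(75 / 5) * 1.2)
})

test_that("normalization scales the peak to unit magnitude, invariantly", {
  cv <- iv_curve(c(-40, -30, -20), c(-100, -400, -300))
  nv <- normalize_iv(cv)
  expect_equal(min(nv$I_peak), -1)
  cv3 <- iv_curve(c(-40, -30, -20), 3 * c(-100, -400, -300))
  expect_equal(normalize_iv(cv3)$I_peak, nv$I_peak)
  expect_error(normalize_iv(iv_curve(c(-40, -30, -20), c(0, 0, 0))),
               "all-zero")
})

test_that("bias report reduces to zero at equality and does arithmetic", {
  ideal <- iv_curve(seq(-60, 0, by = 10),
                    c(-5, -50, -300, -1000, -800, -400, -100))
  b0 <- bias_report(ideal, ideal)
  expect_equal(b0$peak_shift_mV, 0)
  expect_equal(b0$peak_reduction_pct, 0)
  expect_equal(b0$gradient_underestimation_pct, 0)
  avg <- ideal
  avg$I_peak <- c(-5, -50, -300, -700, -560, -280, -70)
  b <- bias_report(avg, ideal)
  expect_equal(b$peak_reduction_pct, 30)
})

test_that("sampling and population runs are reproducible under a seed", {
  plan <- sampling_plan(8, "distributional", seed = 11)
  expect_identical(sample_conditions(plan), sample_conditions(plan))
  lplan <- sampling_plan(6, "lhs", seed = 12)
  expect_identical(lhs_sample(lplan), lhs_sample(lplan))
  protos <- iv_protocol(-100, -40, 0, 20, hold_dur_ms = 20, step_dur_ms = 10,
                        sample_interval_ms = 0.05)
  tv <- attr(protos, "test_voltages")
  p2 <- sampling_plan(2, "lhs", seed = 13)
  a <- iv_population(p2, ohara_ina_file(), protocols = protos,
                     test_voltages = tv)
  b <- iv_population(p2, ohara_ina_file(), protocols = protos,
                     test_voltages = tv)
  expect_identical(a$curves[[1]]$I_peak, b$curves[[1]]$I_peak)
  expect_identical(a$conditions, b$conditions)
})

test_that("conductance-only scaling leaves the ideal peak voltage fixed", {
  protos <- iv_protocol(-100, -60, 20, 10, hold_dur_ms = 50, step_dur_ms = 20,
                        sample_interval_ms = 0.02)
  tv <- attr(protos, "test_voltages")
  full <- ideal_iv_curve(ohara_ina(), protos, tv, scale = 1)
  third <- ideal_iv_curve(ohara_ina(), protos, tv, scale = 1 / 3)
  m_full <- iv_metrics(full, interpolate = TRUE)
  m_third <- iv_metrics(third, interpolate = TRUE)
  expect_equal(m_third$peak_voltage, m_full$peak_voltage, tolerance = 1e-6)
  expect_equal(m_third$peak_current, m_full$peak_current / 3,
               tolerance = 1e-6)
})
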