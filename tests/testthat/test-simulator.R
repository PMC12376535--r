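test_that("passive charging recovers the Rs*Cm time constant", {
  # with compensation off and amplifier delays much faster than Rs*Cm,
  # Vm relaxes toward the step as a single exponential with tau = Rs*Cm
  cell <- cell_parameters(Rs_MOhm = 10, Cm_pF = 50, Cp_pF = 0, g_leak_nS = 0)
  amp <- matched_amplifier(cell, tau_clamp_ms = 1e-4, tau_sum_ms = 1e-4,
                           tau_z_ms = 1e-4)
  tau_true <- cell$Rs * cell$Cm          # 0.5 ms
  proto <- step_protocol(-80, 0, 5, 10, 5, sample_interval_ms = 0.01)
  tr <- run_artifact(proto, cell, amp, passive_membrane(0))
  sel <- tr$t_ms >= 5.05 & tr$t_ms <= 7
  y <- log(-(tr$V_m_mV[sel]) / 80)       # (Vm - 0)/(V0 - 0)
  fitc <- stats::coef(stats::lm(y ~ tr$t_ms[sel]))
  tau_fit <- -1 / fitc[[2]]
  expect_lt(abs(tau_fit - tau_true) / tau_true, 0.05)
})

test_that("linear model cell trace agrees with the exact oracle", {
  cell <- cell_parameters(Rs_MOhm = 4, Cm_pF = 20, Cp_pF = 5)
  amp <- matched_amplifier(cell, 0.7, 0.7)
  proto <- fast_step(-100, 50, 8)
  o <- linear_oracle(proto, cell, amp, model_cell_params(), oracle_opts())
  s <- run_model_cell(proto, cell, amp, model_cell_params(), oracle_opts())
  expect_lt(max(abs(o$I_out_pA - s$I_out_pA)) / max(abs(o$I_out_pA)), 1e-8)
})

test_that("increasing supercharging moves the INa peak earlier", {
  # high-Rs (perforated-patch-like) cell, where membrane charging is slow
  # enough for prediction to dominate the timing of the observed peak
  cell <- cell_parameters(Rs_MOhm = 19.5, Cm_pF = 27.4, Cp_pF = 4)
  ina <- set_scale(bind_density(ohara_ina(), cell$Cm), 1)
  proto <- step_protocol(-80, 0, 10, 20, 5, sample_interval_ms = 0.01)
  t_peaks <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(aP) {
    amp <- matched_amplifier(cell, 0, aP)
    tr <- run_artifact(proto, cell, amp, ina)
    step <- tr$t_ms >= 10.05 & tr$t_ms < 30
    tr$t_ms[step][which.min(tr$I_out_pA[step])]
  })
  expect_true(all(diff(t_peaks) < 0))
})

test_that("time to 90% of a commanded step decreases with supercharging", {
  cell <- cell_parameters(Rs_MOhm = 10, Cm_pF = 50, Cp_pF = 0)
  proto <- step_protocol(-80, 0, 2, 5, 2, sample_interval_ms = 0.005)
  t90 <- sapply(c(0, 0.2, 0.4, 0.6, 0.8), function(aP) {
    amp <- matched_amplifier(cell, 0, aP)
    tr <- run_artifact(proto, cell, amp, passive_membrane(0))
    step <- tr$t_ms >= 2
    tr$t_ms[step][min(which(tr$V_m_mV[step] >= -80 + 0.9 * 80))] - 2
  })
  expect_true(all(diff(t90) < 0))
})

test_that("steady |Vm - Vcmd| decreases monotonically with alpha_R", {
  # static post-step current from a passive conductance, perfect estimates
  cell <- cell_parameters(Rs_MOhm = 10, Cm_pF = 30, Cp_pF = 0)
  proto <- step_protocol(-80, 0, 5, 20, 5, sample_interval_ms = 0.05)
  errs <- sapply(c(0, 0.2, 0.4, 0.6, 0.8, 0.95), function(aR) {
    amp <- matched_amplifier(cell, aR, 0)
    tr <- run_artifact(proto, cell, amp, passive_membrane(20, -80))
    i <- max(which(tr$t_ms < 25))
    abs(tr$V_m_mV[i] - 0)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("the artifact model converges to the ideal clamp in the limit", {
  ina <- set_scale(bind_density(ohara_ina(), 15), 1)
  proto <- step_protocol(-100, -20, 10, 10, 5, sample_interval_ms = 0.01)
  ideal <- run_ideal(proto, ina)
  cell <- cell_parameters(Rs_MOhm = 0.01, Cm_pF = 15, Cp_pF = 0,
                          g_leak_nS = 0, V_off_err_mV = 0)
  amp <- matched_amplifier(cell, 0, 0, tau_clamp_ms = 1e-4,
                           tau_sum_ms = 1e-4, tau_z_ms = 1e-4)
  art <- run_artifact(proto, cell, amp, ina)
  pk_i <- min(ideal$I_post_pA)
  pk_a <- min(art$I_post_pA)
  expect_lt(abs(pk_a - pk_i) / abs(pk_i), 0.01)
})

test_that("ideal clamp gives algebraic currents and bitwise repeatability", {
  proto <- fast_step(-80, 20, 5)
  tr <- run_ideal(proto, passive_membrane(2, -10))
  expect_equal(tr$V_m_mV, tr$V_cmd_mV)
  within_seg <- tr$t_ms > 5 & tr$t_ms < 10
  expect_equal(unique(tr$I_ion_pA[within_seg]), 2 * (20 - -10))
  ina <- set_scale(bind_density(ohara_ina(), 15), 1)
  a <- run_ideal(proto, ina)
  b <- run_ideal(proto, ina)
  expect_identical(a$I_post_pA, b$I_post_pA)
  cell <- small_cell()
  amp <- matched_amplifier(cell, 0.8, 0.8)
  c1 <- run_artifact(proto, cell, amp, ina)
  c2 <- run_artifact(proto, cell, amp, ina)
  expect_identical(c1$I_out_pA, c2$I_out_pA)
})

test_that("summarize_iv picks the signed minimum in the window", {
  # constructed triangular pulse: -500 pA at 2 ms inside the test step
  proto <- step_protocol(-80, -20, 5, 10, 5, sample_interval_ms = 0.05)
  t <- seq(0, 20, by = 0.05)
  I <- numeric(length(t))
  in_step <- t >= 5 & t <= 15
  I[in_step] <- -500 * pmax(0, 1 - abs(t[in_step] - 7) / 1)
  fake <- structure(data.frame(t_ms = t, V_cmd_mV = v_cmd(proto, t),
                               I_post_pA = I),
                    metadata = list(protocol = proto),
                    class = c("clamp_trace", "data.frame"))
  curve <- summarize_iv(list(fake), -20)
  expect_equal(curve$I_peak, -500)
  expect_equal(curve$t_peak_ms, 2)
  I0 <- fake; I0$I_post_pA <- 0
  curve0 <- summarize_iv(list(I0), -20)
  expect_equal(curve0$I_peak, 0)
  expect_error(summarize_iv(list(fake), -20, window = c(20, 25)), "window")
})

test_that("iv_metrics computes peak, location and activation-limb gradient", {
  cv <- iv_curve(c(-40, -30, -20), c(-100, -400, -300))
  m <- iv_metrics(cv)
  expect_equal(m$peak_current, -400)
  expect_equal(m$peak_voltage, -30)
  expect_equal(m$max_gradient, 30)
  mono <- iv_curve(c(-40, -30, -20), c(-100, -200, -300))
  m2 <- iv_metrics(mono)
  expect_equal(m2$peak_voltage, -20)
  expect_equal(m2$max_gradient, 10)
  expect_error(iv_metrics(iv_curve(c(-40, -30), c(-1, -2))), "3 points")
  # parabolic refinement lands between grid points and below the grid peak
  sym <- iv_curve(c(-40, -30, -20), c(-300, -400, -350))
  mi <- iv_metrics(sym, interpolate = TRUE)
  expect_gt(mi$peak_voltage, -40)
  expect_lt(mi$peak_voltage, -20)
  expect_lte(mi$peak_current, -400)
})

test_that("halving solver tolerances changes the peak by < 0.1%", {
  cell <- small_cell()
  amp <- matched_amplifier(cell, 0.8, 0.8)
  ina <- set_scale(bind_density(ohara_ina(), cell$Cm), 1)
  proto <- step_protocol(-100, -20, 10, 10, 5, sample_interval_ms = 0.01)
  p1 <- min(run_artifact(proto, cell, amp, ina)$I_post_pA)
  p2 <- min(run_artifact(proto, cell, amp, ina,
                         solver_opts(rtol = 5e-9, atol = 5e-11))$I_post_pA)
  expect_lt(abs(p1 - p2) / abs(p1), 1e-3)
})

test_that("compensation raises the apparent peak and right-shifts it", {
  cell <- small_cell()
  ina <- set_scale(bind_density(ohara_ina(), cell$Cm), 1)
  protos <- iv_protocol(-100, -80, 40, 10, hold_dur_ms = 50, step_dur_ms = 20,
                        sample_interval_ms = 0.02)
  tv <- attr(protos, "test_voltages")
  res <- lapply(c(0, 0.2, 0.4, 0.6, 0.8), function(a) {
    amp <- matched_amplifier(cell, a, a)
    trs <- lapply(protos, run_artifact, cell = cell, amp = amp, ionic = ina)
    iv_metrics(summarize_iv(trs, tv, blank_ms = 0.3))
  })
  peaks <- sapply(res, function(m) abs(m$peak_current))
  volts <- sapply(res, function(m) m$peak_voltage)
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(volts) >= 0))
  expect_gt(volts[5], volts[1])
})

test_that("near-threshold activation is delayed by loss of clamp", {
  # steep-activation INa at moderate compensation: the positive feedback
  # between escape depolarization and activation delays the peak near
  # threshold far more than at a strongly suprathreshold step
  cell <- cell_parameters(Rs_MOhm = 4.3, Cm_pF = 10.7, Cp_pF = 4)
  amp <- matched_amplifier(cell, 0.4, 0.4)
  ina <- hh_sodium(g_max_nS = 600)
  tp <- sapply(c(-40, 0), function(v) {
    tr <- run_artifact(step_protocol(-100, v, 20, 20, 5), cell, amp, ina)
    summarize_iv(list(tr), v, blank_ms = 0.3)$t_peak_ms
  })
  expect_gt(tp[1] / tp[2], 2)
})

test_that("traces round-trip through CSV with sidecar metadata", {
  cell <- small_cell()
  amp <- matched_amplifier(cell, 0.5, 0.5)
  tr <- run_artifact(fast_step(dt = 0.1), cell, amp, passive_membrane(1))
  path <- file.path(tempdir(), "trace.csv")
  write_trace_csv(tr, path)
  back <- read_trace_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(tr), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "metadata")$amp$alpha_R, 0.5)
})
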