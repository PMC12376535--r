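test_that("HH sodium current obeys reversal, closed gates and arithmetic", {
  expect_equal(hh_sodium_current(65, 0.5, 0.5, 100, 65), 0)
  expect_equal(hh_sodium_current(-20, 0, 0.9, 100, 65), 0)
  expect_equal(hh_sodium_current(-20, 0.9, 0, 100, 65), 0)
  expect_equal(hh_sodium_current(-25, 0.5, 0.8, 100, 65),
               100 * 0.125 * 0.8 * (-90))
})

test_that("Boltzmann steady states hit midpoint, slope point and limits", {
  g <- gating_steady_state(-34)
  expect_equal(g$m_inf, 0.5)
  g2 <- gating_steady_state(-34 + 5.5)
  expect_equal(g2$m_inf, 1 / (1 + exp(-1)), tolerance = 1e-12)
  g3 <- gating_steady_state(200)
  expect_gt(g3$m_inf, 1 - 1e-9)
  expect_lt(g3$h_inf, 1e-9)
  m <- hh_sodium()
  vs <- seq(-100, 40, by = 5)
  it <- m$inf_tau(vs)
  expect_true(all(diff(it$inf[, "m"]) > 0))
  expect_true(all(diff(it$inf[, "h"]) < 0))
  expect_true(all(it$tau > 0))
})

test_that("passive membrane current is ohmic", {
  expect_equal(passive_membrane_current(-30, 5, -30), 0)
  expect_equal(passive_membrane_current(100, 0), 0)
  expect_equal(passive_membrane_current(30, 10, -20), 500)
})

test_that("current scales linearly in the conductance multiplier", {
  proto <- fast_step(-100, -20, 5)
  m1 <- set_scale(bind_density(ohara_ina(), 20), 1)
  m2 <- set_scale(bind_density(ohara_ina(), 20), 2)
  t1 <- run_ideal(proto, m1)
  t2 <- run_ideal(proto, m2)
  expect_equal(t2$I_ion_pA, 2 * t1$I_ion_pA, tolerance = 1e-12)
})

test_that("gating stays in [0, 1] under random step protocols", {
  set.seed(7)
  cell <- small_cell()
  amp <- matched_amplifier(cell, 0.5, 0.5)
  for (i in 1:50) {
    vs <- runif(3, -120, 60)
    proto <- clamp_protocol(vs, runif(3, 1, 5), sample_interval_ms = 0.05)
    ionic <- if (i %% 2 == 0) hh_sodium(g_max_nS = runif(1, 50, 800))
             else set_scale(bind_density(ohara_ina(), cell$Cm),
                            runif(1, 0.2, 5))
    tr <- run_artifact(proto, cell, amp, ionic)
    gates <- attr(tr, "metadata")  # gating not in the trace; re-extract
    # integrate once more keeping states: check via ideal run + artifact Vm
    # bounds are enforced implicitly; here assert the currents stay finite
    expect_true(all(is.finite(tr$I_out_pA)))
  }
  # direct gating-bound check through the ideal-clamp exact solution
  for (i in 1:50) {
    vs <- runif(3, -120, 60)
    proto <- clamp_protocol(vs, runif(3, 1, 5), sample_interval_ms = 0.05)
    m <- hh_sodium(g_max_nS = 100)
    st <- initial_states(m, vs[1])
    for (v in vs) {
      it <- m$inf_tau(v)
      st <- as.numeric(it$inf) + (st - as.numeric(it$inf)) *
        exp(-runif(1, 1, 5) / as.numeric(it$tau))
      expect_true(all(st >= -1e-9 & st <= 1 + 1e-9))
    }
  }
})

test_that("INa under ideal clamp is biphasic with one interior peak", {
  proto <- fast_step(-100, -20, 10, dt = 0.01)
  tr <- run_ideal(proto, set_scale(bind_density(ohara_ina(), 15), 1))
  step <- tr[tr$t_ms >= 10 & tr$t_ms < 20, ]
  i_peak <- which.min(step$I_ion_pA)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, nrow(step))
  before <- step$I_ion_pA[seq_len(i_peak)]
  after <- step$I_ion_pA[i_peak:nrow(step)]
  expect_true(all(diff(before) <= 1e-9))   # activation: monotone down
  expect_true(all(diff(after) >= -1e-9))   # inactivation: monotone up
})

test_that("definition-file adapter reproduces the passive membrane", {
  path <- file.path(tempdir(), "passive_def.txt")
  writeLines(c("name: passive_test", "type: passive",
               "g_nS: 2.5", "E_mV: -10"), path)
  m <- load_ionic_model(path)
  vs <- seq(-100, 50, by = 10)
  expect_equal(ionic_current(m, vs), passive_membrane_current(vs, 2.5, -10))
})

test_that("per-capacitance conductance binds through the cell Cm", {
  gf <- gray_franz_ina()
  expect_true(is.na(gf$g_max))
  expect_equal(bind_density(gf, 100)$g_max, 2000)
  expect_equal(bind_density(ohara_ina(), 10)$g_max, 750)
})

test_that("steady-state initialization is a gating fixed point", {
  for (m in list(hh_sodium(g_max_nS = 100),
                 set_scale(bind_density(ohara_ina(), 15), 1),
                 bind_density(gray_franz_ina(), 15))) {
    st <- initial_states(m, -100)
    d <- ionic_derivatives(m, -100, st)
    expect_lt(max(abs(d)), 1e-12)
  }
})

test_that("incomplete definition files report the missing rate functions", {
  path <- file.path(tempdir(), "broken_def.txt")
  writeLines(c("type: custom", "states: m h",
               "m_inf: 1/(1+exp(-(v+40)/5))", "m_tau: 0.2",
               "current: g * m^3 * h * (v - E)"), path)
  expect_error(load_ionic_model(path), "h_inf")
  path2 <- file.path(tempdir(), "broken_hh.txt")
  writeLines(c("type: hh_sodium", "E_rev_mV: 65", "m_V_half_mV: -40"), path2)
  expect_error(load_ionic_model(path2), "m_k_mV")
})

test_that("custom expression models match the built-in rates", {
  # transcribe the bundled minimal INa as free-form expressions and check
  # the adapter reproduces the parametric family
  path <- file.path(tempdir(), "gf_custom.txt")
  writeLines(c(
    "name: gf_custom", "type: custom", "states: m h",
    "g_max_nS: 214", "E_rev_mV: 65",
    "m_inf: 1/(1+exp(-(v+41)/4))",
    "m_tau: 0.12 + 0*v",
    "h_inf: 1/(1+exp((v+74.9)/4.4))",
    "h_tau: 13.61356*exp(0.799163*(v+74.9)/4.4)/(1+exp((v+74.9)/4.4))",
    "current: g * m^3 * h * (v - E)"), path)
  custom <- load_ionic_model(path)
  ref <- set_scale(bind_density(gray_franz_ina(), 10.7), 1)
  vs <- seq(-100, 40, by = 10)
  it_c <- custom$inf_tau(vs)
  it_r <- ref$inf_tau(vs)
  expect_equal(unname(it_c$inf), unname(it_r$inf), tolerance = 1e-10)
  expect_equal(unname(it_c$tau), unname(it_r$tau), tolerance = 1e-10)
  st <- cbind(runif(length(vs)), runif(length(vs)))
  expect_equal(ionic_current(custom, vs, st), ionic_current(ref, vs, st),
               tolerance = 1e-10)
})
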