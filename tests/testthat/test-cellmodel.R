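test_that("nernst potential has the textbook symmetry, scale and valence behaviour", {
  expect_equal(nernst(1, 5.4, 5.4), 0)
  ek <- nernst(1, 145, 5.4, 310)
  expect_lt(ek, 0)
  expect_equal(nernst(2, 145, 5.4, 310), ek / 2)
  expect_error(nernst(1, 0, 5.4), "positive")
  expect_error(nernst(1, 145, -1), "positive")
})

test_that("identity scaling leaves the right-hand side unchanged and conductance scaling is linear", {
  st <- ord_initial_state()
  base <- ord_rhs(st, scaling_factors())
  again <- ord_rhs(st, rep(1, 13))
  expect_identical(base$deriv, again$deriv)

  # depolarized plateau-like state so IKr is appreciable
  st2 <- st
  st2[["v"]] <- 0
  a <- ord_rhs(st2, scaling_factors())
  b <- ord_rhs(st2, scaling_factors(gKr = 0.01))
  expect_equal(b$currents[["IKr"]], a$currents[["IKr"]] * 0.01)
  untouched <- setdiff(names(a$currents), c("IKr"))
  expect_equal(a$currents[untouched], b$currents[untouched])

  st_bad <- st
  st_bad[["cai"]] <- NaN
  expect_error(ord_rhs(st_bad), "cai")
})

test_that("an unstimulated, pre-equilibrated cell stays quiescent", {
  eq <- integrate_cell(ord_initial_state(), duration = 20000)
  res <- integrate_cell(eq$final_state, duration = 1000)
  expect_true(res$ok)
  expect_lt(diff(range(res$trace$v)), 0.1)
})

test_that("a paced beat reproduces the published endocardial AP biomarkers", {
  res <- pace_to_steady_state(pcl = 1000, settle_s = 10)
  expect_true(res$ok)
  bm <- ap_biomarkers(res$trace, 90)
  # reference values for the endocardial cell at 1 Hz
  expect_gt(bm$apd, 255); expect_lt(bm$apd, 290)
  expect_gt(bm$rmp, -90); expect_lt(bm$rmp, -85)
  expect_gt(bm$amplitude, 110)
})

test_that("halving the step cap changes steady-paced APD90 by less than 1 ms", {
  r1 <- pace_to_steady_state(pcl = 1000, settle_s = 10, dt_max = 1)
  r2 <- pace_to_steady_state(pcl = 1000, settle_s = 10, dt_max = 0.5)
  a1 <- ap_biomarkers(r1$trace, 90)$apd
  a2 <- ap_biomarkers(r2$trace, 90)$apd
  expect_lt(abs(a1 - a2), 1)
})

test_that("gates stay in [0,1] and concentrations positive during pacing", {
  st <- ord_initial_state()
  for (i in 1:10) {
    res <- integrate_cell(st, duration = 500, stim_times = 0, pcl = 500)
    expect_true(res$ok)
    st <- res$final_state
    gates <- st[10:38]   # gating-type variables
    expect_true(all(gates >= 0 & gates <= 1))
    expect_true(all(st[2:9] > 0))
  }
})

test_that("single-beat settle equals one plain pacing interval", {
  direct <- integrate_cell(ord_initial_state(), duration = 800,
                           stim_times = 0, pcl = 800)
  via_pace <- pace_to_steady_state(pcl = 800, settle_s = 0.8)
  expect_equal(via_pace$trace$v, direct$trace$v)
  expect_equal(via_pace$final_state, direct$final_state)
  expect_true(is.na(via_pace$apd_diff))
})

test_that("beat-to-beat APD difference shrinks with settle time", {
  st <- fig2_state(1)
  d <- vapply(c(10, 100, 400), function(s)
    pace_to_steady_state(state = st, pcl = 1000, settle_s = s)$apd_diff,
    numeric(1))
  expect_true(all(diff(d) <= 0))
})

test_that("toy AP is deterministic, monotone in its duration parameter, and restitutes", {
  p <- toy_reference()
  expect_identical(toy_ap(p, 500)$v, toy_ap(p, 500)$v)
  apds <- vapply(c(0.8, 1.0, 1.3), function(m) {
    q <- p; q[["apd"]] <- p[["apd"]] * m
    ap_biomarkers(toy_ap(q, 1000), 90)$apd
  }, numeric(1))
  expect_true(all(diff(apds) > 0))
  # APD90 increases with PCL (restitution) and tracks the closed form
  r <- vapply(c(300, 500, 1000, 2000), function(pcl)
    ap_biomarkers(toy_ap(p, pcl), 90)$apd, numeric(1))
  expect_true(all(diff(r) > 0))
  # APD90 of the sigmoid-product shape tracks the nominal duration loosely
  closed <- p[["apd"]] * exp(-p[["rst"]] * exp(-(1000 - 300) / 250))
  expect_lt(abs(r[3] - closed) / closed, 0.15)
  expect_error(toy_ap(c(rest = -1, amp = 1, apd = 1, rst = 1), 500), "positive")
})

test_that("integration failure is flagged, not thrown", {
  st <- ord_initial_state()
  res <- integrate_cell(st, duration = 100, stim_times = 0,
                        stim_amplitude = -5000, stim_duration = 20)
  expect_false(res$ok)
})
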