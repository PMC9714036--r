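test_that("slope fitting matches exact lines and single-point ratios", {
  tc <- enrichment_tc(c(0, 10, 20, 30), c(0, 0.1, 0.2, 0.3))
  fit <- fit_label_slope(tc, window = c(0, 30))
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)

  one <- enrichment_tc(60, 0.12)
  fit1 <- fit_label_slope(one, window = c(50, 70))
  expect_equal(fit1$slope, 0.002)

  expect_error(fit_label_slope(tc, window = c(40, 50)),
               class = "tcaflux_data_error")
  expect_error(fit_label_slope(enrichment_tc(0, 0), window = c(0, 0)),
               class = "tcaflux_fit_error")
})

test_that("fitted slope agrees with a numerical derivative midwindow", {
  tc <- default_glucose_sim()
  et <- enrichment_table(tc)
  et <- et[et$metabolite == "citrate", ]
  fd <- (et$enrichment[et$time_min == 20] -
           et$enrichment[et$time_min == 10]) / 10
  slope <- fit_label_slope(tc, window = c(0, 30))$slope
  expect_lt(abs(slope / fd - 1), 0.05)
})

test_that("relative flux normalization behaves and guards its domain", {
  expect_equal(relative_vcs(0.01, 0.01), 1)
  expect_equal(relative_vcs(0.02, 0.01), 2)
  expect_error(relative_vcs(0.01, 0), class = "tcaflux_domain_error")
})

test_that("relative V_CS is invariant to a global enrichment rescale", {
  times <- c(0, 10, 20, 30)
  for (c_scale in c(0.5, 2)) {
    tc_a <- enrichment_tc(times, 0.004 * times, condition = "A")
    tc_b <- enrichment_tc(times, 0.007 * times, condition = "B")
    tc_as <- enrichment_tc(times, c_scale * 0.004 * times, condition = "A")
    tc_bs <- enrichment_tc(times, c_scale * 0.007 * times, condition = "B")
    plain <- vcs_fit(label_timecourse(
      rbind(as.data.frame(tc_a), as.data.frame(tc_b))), reference = "A")
    scaled <- vcs_fit(label_timecourse(
      rbind(as.data.frame(tc_as), as.data.frame(tc_bs))), reference = "A")
    expect_equal(coef(scaled), coef(plain), tolerance = 1e-9)
  }
})

test_that("vcs_fit methods are mutually consistent", {
  times <- c(0, 10, 20, 30)
  tc <- label_timecourse(rbind(
    as.data.frame(enrichment_tc(times, 0.004 * times, condition = "A")),
    as.data.frame(enrichment_tc(times, 0.008 * times, condition = "B"))))
  fit <- vcs_fit(tc, reference = "A")
  expect_equal(unname(coef(fit)["A"]), 1)
  expect_equal(unname(coef(fit)["B"]), 2, tolerance = 1e-9)
  expect_equal(predict(fit, data.frame(condition = "B", time_min = 10)),
               0.08, tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  expect_output(print(fit), "Reference condition: A")
  expect_s3_class(summary(fit), "summary.vcs_fit")
  expect_error(vcs_fit(tc, reference = "missing"),
               class = "tcaflux_lookup_error")
})

test_that("steady-state decision follows the t test", {
  reps <- function(t, vals) enrichment_tc(rep(t, length(vals)), vals,
                                          replicate = seq_along(vals))
  same <- label_timecourse(rbind(
    as.data.frame(reps(60, c(0.10, 0.11, 0.12))),
    as.data.frame(reps(150, c(0.10, 0.11, 0.12)))))
  res <- steady_state_check(same)
  expect_true(res$steady)
  expect_equal(res$p, 1)

  set.seed(14)
  far <- label_timecourse(rbind(
    as.data.frame(reps(60, rnorm(5, 0.10, 0.01))),
    as.data.frame(reps(150, rnorm(5, 0.30, 0.01)))))
  res2 <- steady_state_check(far)
  expect_false(res2$steady)
  # oracle: p for means 0.1 vs 0.3 at sd 0.01, n = 5 is astronomically small
  expect_lt(res2$p, 1e-6)

  expect_true(steady_state_check(far, alpha = 0)$steady)
  expect_error(steady_state_check(reps(60, c(0.1, 0.1))),
               class = "tcaflux_data_error")
})

test_that("glycolysis readout and lactate rate are guarded ratios", {
  expect_equal(glycolysis_index(0, 0.5), 0)
  expect_equal(glycolysis_index(0.25, 0.5), 0.5)
  expect_error(glycolysis_index(0.25, 0), class = "tcaflux_domain_error")

  expect_equal(lactate_production_rate(0, 6, 6, 1), 1)
  expect_equal(lactate_production_rate(2, 2, 6, 3), 0)
  expect_error(lactate_production_rate(0, 6, 6, 0),
               class = "tcaflux_domain_error")
})

test_that("dilution profile quantifies downstream label loss", {
  mk <- function(vals) {
    dfs <- mapply(function(m, v) as.data.frame(enrichment_tc(60, v,
                                                             metabolite = m)),
                  names(vals), vals, SIMPLIFY = FALSE)
    label_timecourse(do.call(rbind, dfs))
  }
  equal <- mk(c(citrate = 0.2, glutamate = 0.2, succinate = 0.2,
                malate = 0.2))
  dp <- dilution_profile(equal)
  expect_true(all(dp$dilution_index == 0))

  lost <- mk(c(citrate = 0.2, malate = 0))
  dp2 <- dilution_profile(lost)
  expect_equal(dp2$dilution_index[dp2$metabolite == "malate"], 1)

  # antitone in downstream enrichment at fixed reference
  idx <- vapply(c(0.05, 0.10, 0.15), function(e)
    with(dilution_profile(mk(c(citrate = 0.2, malate = e))),
         dilution_index[metabolite == "malate"]), 0)
  expect_true(all(diff(idx) < 0))

  none <- mk(c(citrate = 0, malate = 0))
  expect_error(dilution_profile(none),
               class = "tcaflux_degenerate_reference_error")
})
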