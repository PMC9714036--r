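test_that("every simulated MID is a probability distribution", {
  tc <- default_glucose_sim()
  key <- interaction(tc$metabolite, tc$time_min)
  sums <- tapply(tc$fraction, key, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_true(all(tc$fraction >= -1e-9))
})

test_that("no citrate synthase flux means no citrate labeling", {
  net <- build_tca_network(network_config(vcs = 0, glycolysis = 1))
  tc <- simulate_timecourse(net, tracer_spec("glucose_U13C6"),
                            times = c(0, 15, 30), metabolites = "citrate")
  et <- enrichment_table(tc)
  expect_true(all(et$enrichment == 0))
})

test_that("first-turn labeling reproduces the tracer schemes", {
  net <- build_tca_network(network_config())
  for (tr_name in c("glucose_U13C6", "palmitate_U13C16")) {
    tc <- simulate_timecourse(net, tracer_spec(tr_name), times = c(10, 30),
                              metabolites = "citrate",
                              first_turn_only = TRUE)
    m <- tc_mid(tc, "citrate", 30)
    off <- m$fractions[-c(1L, 3L)]      # everything except M0 and M+2
    expect_lt(max(off), 1e-6)
    expect_gt(m$fractions[3L], 0)       # M+2 actually labeled
  }
  tc <- simulate_timecourse(net, tracer_spec("glutamine_U13C5"),
                            times = c(10, 30), metabolites = "citrate",
                            first_turn_only = TRUE)
  m <- tc_mid(tc, "citrate", 30)
  off <- m$fractions[-c(1L, 5L)]        # everything except M0 and M+4
  expect_lt(max(off), 1e-6)
  expect_gt(m$fractions[5L], 0)
})

test_that("integrator matches the closed-form two-pool cascade", {
  # constant input (prime saturates the step), pyruvate tau = 1 min,
  # acetyl-CoA tau = 0.5 min, no acetyl dilution: both pools have
  # analytic solutions
  E <- 0.4
  cfg <- network_config(
    pools = c(pyruvate = 2, acetyl_coa = 0.5),
    glycolysis = 2, acetyl_from_pdh = 1, dil_acetyl = 0)
  net <- build_tca_network(cfg)
  tr <- tracer_spec("glucose_U13C6", prime_multiplier = 3,
                    rate_constant = 0.5, plateau_enrichment = E)
  tc <- simulate_timecourse(net, tr, times = c(1, 5, 10),
                            metabolites = c("pyruvate", "acetyl_coa"))
  a_rate <- 2 / 2    # glycolysis / pyruvate pool
  b_rate <- 1 / 0.5  # vcs / acetyl pool
  for (t in c(1, 5, 10)) {
    p_m3 <- isotopologue_fraction(tc_mid(tc, "pyruvate", t), 3)
    expect_equal(p_m3, E * (1 - exp(-a_rate * t)), tolerance = 1e-6)
    a_m2 <- isotopologue_fraction(tc_mid(tc, "acetyl_coa", t), 2)
    closed <- E * (1 - (b_rate * exp(-a_rate * t) -
                          a_rate * exp(-b_rate * t)) / (b_rate - a_rate))
    expect_equal(a_m2, closed, tolerance = 1e-6)
  }
})

test_that("label accumulation is linear over the first 30 minutes", {
  et <- enrichment_table(default_glucose_sim())
  et <- et[et$metabolite == "citrate" & et$time_min <= 30, ]
  fit <- lm(enrichment ~ time_min, data = et)
  rel_rms <- sqrt(mean(resid(fit)^2)) / diff(range(fitted(fit)))
  expect_lt(rel_rms, 0.05)
})

test_that("primed infusion reaches steady state by 60 minutes", {
  et <- enrichment_table(default_glucose_sim())
  e60 <- et$enrichment[et$metabolite == "citrate" & et$time_min == 60]
  e150 <- et$enrichment[et$metabolite == "citrate" & et$time_min == 150]
  expect_lt(abs(e60 / e150 - 1), 0.05)
})

test_that("anaplerosis monotonically dilutes malate relative to citrate", {
  ratio <- vapply(c(0, 0.2, 0.4), function(ana) {
    net <- build_tca_network(network_config(ana = ana))
    tc <- simulate_timecourse(net, tracer_spec("glucose_U13C6"),
                              times = 60,
                              metabolites = c("citrate", "malate"))
    et <- enrichment_table(tc)
    et$enrichment[et$metabolite == "malate"] /
      et$enrichment[et$metabolite == "citrate"]
  }, 0)
  expect_true(all(diff(ratio) < 0))
})

test_that("simulation inputs are validated", {
  net <- build_tca_network(network_config())
  tr <- tracer_spec("glucose_U13C6")
  expect_error(simulate_timecourse(net, tr, times = c(10, 5)),
               class = "tcaflux_data_error")
  expect_error(simulate_timecourse(net, tr, times = c(-1, 5)),
               class = "tcaflux_data_error")
  expect_error(simulate_timecourse(net, tr, times = 10, step = 0.5),
               class = "tcaflux_config_error")
  expect_error(simulate_timecourse(net, tr, times = 10,
                                   metabolites = "fumarate"),
               class = "tcaflux_config_error")
})
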