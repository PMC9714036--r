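test_that("measurement noise layer is reproducible and unbiased", {
  tc <- default_glucose_sim()

  # sd 0 and p13 0 leave the time course untouched
  clean <- add_measurement_noise(tc, noise_model(p13 = 0, sd_mid = 0,
                                                 seed = 5))
  expect_equal(clean$fraction, tc$fraction, tolerance = 1e-12)

  # determinism contract
  n1 <- add_measurement_noise(tc, noise_model(sd_mid = 0.01, seed = 99))
  n2 <- add_measurement_noise(tc, noise_model(sd_mid = 0.01, seed = 99))
  expect_identical(n1$fraction, n2$fraction)
  n3 <- add_measurement_noise(tc, noise_model(sd_mid = 0.01, seed = 100))
  expect_false(identical(n1$fraction, n3$fraction))

  # law of large numbers: 1000 noised replicates of one fixed MID
  # (kept away from 0 so clamping cannot bias the mean)
  truth <- c(0.3, 0.5, 0.2)
  base <- do.call(rbind, lapply(1:1000, function(r)
    data.frame(sample_id = paste0("s", r), condition = "c", tracer = "t",
               metabolite = "pyruvate", time_min = 10, replicate = r,
               mass_shift = 0:2, fraction = truth)))
  noisy <- add_measurement_noise(label_timecourse(base),
                                 noise_model(sd_mid = 0.01, seed = 2),
                                 convolve = FALSE)
  means <- tapply(noisy$fraction, noisy$mass_shift, mean)
  expect_true(all(abs(means - truth) < 0.005))
})

test_that("synthetic cohort plants recoverable correlation structure", {
  co <- planted_cohort()
  expect_true(all(co$expr > 0))
  expect_true(all(co$covariate$leukocyte_fraction >= 0 &
                    co$covariate$leukocyte_fraction <= 1))
  cv <- setNames(co$covariate$leukocyte_fraction, co$covariate$sample_id)

  r_pos <- pearson_r(co$expr["SLC7A7", ], cv)$r
  expect_gt(r_pos, 0.6)
  expect_lt(r_pos, 0.95)
  r_neg <- pearson_r(co$expr["SLC7A5", ], cv)$r
  expect_lt(r_neg, -0.6)

  # CYT correlates positively with the infiltration covariate
  expect_gt(pearson_r(cyt_score(co$expr), cv)$r, 0.3)

  # reproducibility
  co2 <- generate_expression_cohort(
    cohort_spec(n_genes = 200L, n_samples = 200L, target_r = 0.8,
                seed = 42L))
  expect_identical(co$expr, co2$expr)
})

test_that("null cohort shows no systematic correlation", {
  co <- generate_expression_cohort(
    cohort_spec(n_genes = 150L, n_samples = 200L,
                planted_positive = character(),
                planted_negative = character(), seed = 8L))
  cv <- setNames(co$covariate$leukocyte_fraction, co$covariate$sample_id)
  null_genes <- grep("^GENE", rownames(co$expr), value = TRUE)
  rs <- vapply(null_genes, function(g) pearson_r(co$expr[g, ], cv)$r, 0)
  expect_lt(median(abs(rs)), 0.2)
})

test_that("cohort specification is validated", {
  expect_error(cohort_spec(target_r = 1), class = "tcaflux_config_error")
  expect_error(cohort_spec(n_samples = 2), class = "tcaflux_config_error")
  expect_error(cohort_spec(planted_positive = "GLUL",
                           planted_negative = "GLUL"),
               class = "tcaflux_config_error")
})

test_that("growth curves honor their construction", {
  conds <- data.frame(condition = c("full", "noQ"),
                      media = c("full", "glutamine-free"),
                      rate = c(0.06, 0.02), plateau = c(5e5, 5e5))
  g <- generate_growth_dataset(conds, seed = 4)
  m72 <- tapply(g$cell_count[g$time_h == 72], g$condition[g$time_h == 72],
                mean)
  expect_lt(m72[["noQ"]], m72[["full"]])
  expect_identical(g, generate_growth_dataset(conds, seed = 4))

  flat <- generate_growth_dataset(
    data.frame(condition = "c", media = "m", rate = 0, plateau = 1e5),
    seed = 1, cv = 0)
  expect_equal(length(unique(flat$cell_count)), 1L)
  expect_equal(nrow(flat), 3 * 3 * 3)  # 3 times x 3 replicates x 3 counts

  expect_error(generate_growth_dataset(
    data.frame(condition = "c", media = "m", rate = 0.1, plateau = -1)),
    class = "tcaflux_config_error")
})

test_that("relative flux is recovered end-to-end from noisy data", {
  bench <- vcs_recovery_benchmark(true_ratio = 2, seed = 20260920L)
  expect_lt(abs(bench$estimate / 2 - 1), 0.10)
})
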